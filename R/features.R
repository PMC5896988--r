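#' Global Otsu threshold of the red (KI-67) channel
#'
#' The KI-67 coverage measure needs a single intensity cutoff separating
#' red signal from background; it is computed once over the whole red
#' raster with the same Otsu contract as [otsu_threshold()], not per
#' nucleus.
#'
#' @param red Red-channel intensity matrix (0-255).
#' @return Integer threshold in 0-255.
#' @export
red_global_threshold <- function(red) {
  otsu_threshold(red)
}

#' Major-axis length of a pixel region
#'
#' Length of the major axis of the ellipse having the same normalized
#' second central moments as the region: `4 * sqrt(lambda_max)` of the
#' population covariance matrix of the pixel center coordinates. This is
#' the standard morphometric definition; a single pixel has zero
#' covariance and hence length 0.
#'
#' @param region Logical matrix marking the region, or a two-column matrix
#'   of (row, col) pixel coordinates.
#' @return Major-axis length in pixels.
#' @export
#' @examples
#' major_axis_length(cbind(1, 1:9))  # 4 * sqrt(20/3)
major_axis_length <- function(region) {
  if (is.logical(region) || (is.matrix(region) && ncol(region) != 2)) {
    idx <- which(region != 0)
    if (!length(idx)) stop("region is empty")
    coords <- cbind((idx - 1L) %% nrow(region) + 1L,
                    (idx - 1L) %/% nrow(region) + 1L)
  } else {
    coords <- region
    if (!nrow(coords)) stop("region is empty")
  }
  n <- nrow(coords)
  vr <- sum((coords[, 1] - mean(coords[, 1]))^2) / n
  vc <- sum((coords[, 2] - mean(coords[, 2]))^2) / n
  cv <- sum((coords[, 1] - mean(coords[, 1])) *
              (coords[, 2] - mean(coords[, 2]))) / n
  lmax <- (vr + vc + sqrt((vr - vc)^2 + 4 * cv^2)) / 2
  4 * sqrt(lmax)
}

#' Extract per-nucleus KI-67 measures from the red channel
#'
#' For each labeled nucleus, measures are computed over exactly the labeled
#' pixels of the red channel (the germ-nucleus mask restricts everything,
#' so somatic KI-67 signal outside the mask cannot influence any value):
#' area, maximum red intensity, sum of red intensities, mean red intensity,
#' major-axis length, and the coverage fraction -- the proportion of
#' nuclear pixels whose red intensity exceeds the global red threshold.
#'
#' @param labels A `label_map` (from [segment_nuclei()]) or an integer
#'   label matrix.
#' @param red Red-channel intensity matrix, same shape as the labels.
#' @param red_threshold Global red intensity threshold, typically from
#'   [red_global_threshold()].
#' @return Data frame with one row per nucleus: `nucleus_id`, `area`,
#'   `max_red`, `sum_red`, `mean_red`, `major_axis`, `coverage_frac`,
#'   centroid coordinates (`centroid_row`, `centroid_col`, 1-based), and a
#'   `label` column initialized to `NA` for later manual annotation.
#' @export
extract_features <- function(labels, red, red_threshold) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  if (!identical(dim(lab), dim(red)))
    stop("labels and red raster must have the same shape")
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(nucleus_id = integer(0), area = integer(0),
                      max_red = numeric(0), sum_red = numeric(0),
                      mean_red = numeric(0), major_axis = numeric(0),
                      coverage_frac = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  g <- lab[idx]
  ids <- sort(unique(g))
  v <- as.numeric(red[idx])
  prow <- as.numeric((idx - 1L) %% nrow(lab) + 1L)
  pcol <- as.numeric((idx - 1L) %/% nrow(lab) + 1L)
  n <- as.vector(rowsum(rep(1, length(g)), g))
  s <- as.vector(rowsum(v, g))
  mx <- as.vector(tapply(v, g, max))
  above <- as.vector(rowsum(as.numeric(v > red_threshold), g))
  sr <- as.vector(rowsum(prow, g)); sc <- as.vector(rowsum(pcol, g))
  sr2 <- as.vector(rowsum(prow^2, g)); sc2 <- as.vector(rowsum(pcol^2, g))
  src <- as.vector(rowsum(prow * pcol, g))
  vr <- sr2 / n - (sr / n)^2
  vc <- sc2 / n - (sc / n)^2
  cv <- src / n - (sr / n) * (sc / n)
  lmax <- (vr + vc + sqrt(pmax(0, (vr - vc)^2 + 4 * cv^2))) / 2
  data.frame(nucleus_id = as.integer(ids),
             area = as.integer(n),
             max_red = mx,
             sum_red = s,
             mean_red = s / n,
             major_axis = 4 * sqrt(pmax(0, lmax)),
             coverage_frac = above / n,
             centroid_row = sr / n,
             centroid_col = sc / n,
             label = NA_character_,
             stringsAsFactors = FALSE)
}

#' Label segmented nuclei from simulation ground truth
#'
#' Matches each segmented nucleus to the nearest ground-truth germ nucleus
#' by centroid distance and copies the true KI-67 status into the `label`
#' column (`"positive"`/`"negative"`). Nuclei with no truth germ nucleus
#' within `max_dist` stay unlabeled. Intended for building labeled training
#' and validation sets from [generate_field()] output.
#'
#' @param features Feature table from [extract_features()].
#' @param truth Truth table from [generate_field()].
#' @param max_dist Maximum centroid distance in pixels for a match.
#' @return The feature table with `label` filled in where matched, plus a
#'   `truth_id` column giving the matched truth nucleus (or `NA`).
#' @export
label_from_truth <- function(features, truth, max_dist = 5) {
  germ <- truth[truth$is_germ & !truth$touches_border, , drop = FALSE]
  features$truth_id <- NA_integer_
  if (!nrow(features) || !nrow(germ)) return(features)
  for (i in seq_len(nrow(features))) {
    d2 <- (germ$row - features$centroid_row[i])^2 +
      (germ$col - features$centroid_col[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) {
      features$truth_id[i] <- germ$nucleus_id[j]
      features$label[i] <- if (isTRUE(germ$is_ki67_pos[j])) "positive" else "negative"
    }
  }
  features
}

#' Write a per-field feature table as CSV
#'
#' @param features Feature table from [extract_features()].
#' @param path Output CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
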