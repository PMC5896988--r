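#' Otsu threshold of an intensity raster
#'
#' Computes the global threshold `t` maximizing the between-class variance
#' of the two pixel classes `{intensity <= t}` and `{intensity > t}` over a
#' 256-bin histogram. Foreground is defined downstream as strictly greater
#' than `t`, so a constant raster yields its own value as threshold and an
#' empty foreground. When several thresholds tie, the smallest maximizer is
#' returned (deterministic).
#'
#' @param raster Numeric/integer matrix with values in 0-255.
#' @return Integer threshold in 0-255.
#' @export
#' @examples
#' otsu_threshold(matrix(c(rep(10, 100), rep(200, 100)), 10))
otsu_threshold <- function(raster) {
  if (length(raster) == 0) stop("raster is empty")
  v <- as.vector(raster)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 255))
    stop("raster values must be finite and within [0,255]")
  vi <- as.integer(round(v))
  if (all(vi == vi[1])) return(vi[1])  # constant raster: empty foreground
  counts <- tabulate(vi + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)                       # P(intensity <= t)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance w0*w1*(mu0-mu1)^2, guarded for empty classes
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, 0)
  as.integer(lev[which.max(sigma_b)])   # which.max takes the first maximum
}

#' Binarize a raster at a threshold
#'
#' Foreground is strictly greater than the threshold.
#'
#' @param raster Numeric matrix.
#' @param threshold Scalar threshold.
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(raster, threshold) {
  raster > threshold
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; label
# with it first, then merge 4-components that touch diagonally via
# union-find over the component graph.
label_components8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbor pairs: (r,c)-(r+1,c+1) and (r+1,c)-(r,c+1)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- pairs[i, 1]; rb <- pairs[i, 2]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- seq_len(nl)
  for (k in seq_len(nl)) {
    r <- k
    while (parent[r] != r) r <- parent[r]
    root[k] <- r
  }
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Remove foreground components touching the image border
#'
#' Every 8-connected foreground component containing at least one pixel on
#' the first/last row or column is removed; all other components are left
#' untouched. This discards nuclei that are truncated by the field of view
#' and would otherwise bias size and intensity measures.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with border-touching components cleared.
#' @export
remove_edge_objects <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components8(mask)
  h <- nrow(lab); w <- ncol(lab)
  border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labels <- border_labels[border_labels > 0L]
  out <- mask
  if (length(border_labels)) out[lab %in% border_labels] <- FALSE
  out
}

# Constructor for a label map: relabels to consecutive 1..n_labels.
label_map <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    labels[labels > 0L] <- match(labels[labels > 0L], ids)
  }
  structure(list(labels = labels, n_labels = length(ids)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d labeled nuclei\n",
              nrow(x$labels), ncol(x$labels), x$n_labels))
  invisible(x)
}

#' Separate touching nuclei by watershed on the distance transform
#'
#' Applies marker-based watershed to the negated Euclidean distance
#' transform of the binary mask: markers are local maxima of the distance
#' transform, with `min_marker_sep` controlling the minimum separation
#' (radius of the local-maximum neighborhood) so a single elongated nucleus
#' is not split. When no objects touch, the result is identical to
#' connected-component labeling. The output labels partition the foreground
#' exactly.
#'
#' @param mask Logical matrix.
#' @param min_marker_sep Minimum marker separation in pixels.
#' @return A `label_map`: list with `labels` (integer matrix, 0 =
#'   background) and `n_labels`.
#' @export
separate_touching <- function(mask, min_marker_sep = 7.5) {
  if (!any(mask)) {
    return(label_map(matrix(0L, nrow(mask), ncol(mask))))
  }
  m <- matrix(as.numeric(mask), nrow(mask))
  d <- EBImage::distmap(m)
  ws <- EBImage::watershed(d, tolerance = 1,
                           ext = max(1L, as.integer(round(min_marker_sep))))
  label_map(matrix(as.integer(ws), nrow(mask)))
}

#' Segment germ-cell nuclei from the green (TRA98) channel
#'
#' Full nucleus segmentation pipeline: Otsu threshold, binarization,
#' removal of border-touching objects, watershed separation of touching
#' nuclei, and a minimum-area filter that discards speckle regions created
#' by noise.
#'
#' @param green Green-channel intensity matrix (0-255).
#' @param min_area Minimum region area in pixels (default 15; set to 0 to
#'   keep every region).
#' @param min_marker_sep Passed to [separate_touching()].
#' @return A `label_map` of segmented nuclei.
#' @export
#' @examples
#' f <- generate_field(field_spec(n_nuclei = 15, noise_sd = 0,
#'                                touching_pair_prob = 0), seed = 2)
#' segment_nuclei(f$field$green)$n_labels
segment_nuclei <- function(green, min_area = 15, min_marker_sep = 7.5) {
  t <- otsu_threshold(green)
  mask <- binarize(green, t)
  mask <- remove_edge_objects(mask)
  lm <- separate_touching(mask, min_marker_sep = min_marker_sep)
  if (min_area > 0 && lm$n_labels > 0) {
    areas <- tabulate(lm$labels[lm$labels > 0L], nbins = lm$n_labels)
    drop <- which(areas < min_area)
    if (length(drop)) {
      lab <- lm$labels
      lab[lab %in% drop] <- 0L
      lm <- label_map(lab)
    }
  }
  lm
}

#' Write a label map and its region table
#'
#' Stores the labels as a 16-bit grayscale TIFF and a CSV of per-region
#' id, area, and centroid (1-based row/col pixel coordinates).
#'
#' @param lm A `label_map`.
#' @param tiff_path Output TIFF path (optional, `NULL` to skip).
#' @param csv_path Output CSV path (optional, `NULL` to skip).
#' @return Invisibly, the region table.
#' @export
write_label_map <- function(lm, tiff_path = NULL, csv_path = NULL) {
  lab <- lm$labels
  regions <- data.frame(nucleus_id = integer(0), area = integer(0),
                        centroid_row = numeric(0), centroid_col = numeric(0))
  if (lm$n_labels > 0) {
    idx <- which(lab > 0L)
    g <- lab[idx]
    prow <- (idx - 1L) %% nrow(lab) + 1L
    pcol <- (idx - 1L) %/% nrow(lab) + 1L
    regions <- data.frame(
      nucleus_id = seq_len(lm$n_labels),
      area = as.integer(tabulate(g, nbins = lm$n_labels)),
      centroid_row = as.vector(tapply(prow, g, mean)),
      centroid_col = as.vector(tapply(pcol, g, mean)))
  }
  if (!is.null(tiff_path))
    tiff::writeTIFF(lab / 65535, tiff_path, bits.per.sample = 16L)
  if (!is.null(csv_path))
    utils::write.csv(regions, csv_path, row.names = FALSE)
  invisible(regions)
}
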