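# Pixel indices (linear, column-major) of the raster ellipse centered at
# (r0, c0) with semi-axes a >= b and major axis at angle theta from the
# column axis. A pixel belongs to the ellipse when its center lies inside.
ellipse_pixels <- function(r0, c0, a, b, theta, h, w) {
  rr <- max(1L, floor(r0 - a)):min(h, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(w, ceiling(c0 + a))
  dr <- matrix(rr - r0, length(rr), length(cc))
  dc <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  row_idx <- matrix(rr, length(rr), length(cc))[inside]
  col_idx <- matrix(cc, length(rr), length(cc), byrow = TRUE)[inside]
  (col_idx - 1L) * h + row_idx
}

# Radial extent of the ellipse from its center in direction phi
# (angle from the column axis).
ellipse_extent <- function(a, b, theta, phi) {
  psi <- phi - theta
  1 / sqrt((cos(psi) / a)^2 + (sin(psi) / b)^2)
}

# Deterministic per-field seed stream derived from one master seed, so the
# same replicate seed always produces the same sequence of fields.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + i * 1000003) %%
    2147483646L + 1L
}

#' Generate one synthetic two-channel fluorescence field with ground truth
#'
#' Renders the nuclei described by a [field_spec()] into an 8-bit green
#' (germ-cell marker) and red (KI-67) channel pair and returns the exact
#' per-nucleus truth of what was rendered. Nuclei are placed by rejection
#' sampling so that, apart from deliberately generated touching pairs, no
#' two nuclei overlap. Red signal is painted as a contiguous sub-region of
#' each nucleus whose pixel count matches the drawn coverage fraction.
#' Identical `(spec, seed)` input yields bit-identical output.
#'
#' @param spec A [field_spec()].
#' @param seed Integer seed; fully determines the field.
#' @return A list with elements:
#' \describe{
#'   \item{field}{`field_pair`: list of `green` and `red` integer matrices
#'     (`height` x `width`, values 0-255).}
#'   \item{truth}{data frame with one row per nucleus: `nucleus_id`, center
#'     `row`/`col` (1-based pixel coordinates), `semi_major`, `semi_minor`,
#'     `orientation` (radians from the column axis), `is_germ`,
#'     `is_ki67_pos` (`NA` for somatic nuclei), `coverage`,
#'     `touches_border` (from the rendered pixels).}
#' }
#' @export
#' @examples
#' f <- generate_field(field_spec(n_nuclei = 20, noise_sd = 0), seed = 1)
#' nrow(f$truth)
generate_field <- function(spec, seed) {
  if (!inherits(spec, "field_spec")) stop("spec must be a field_spec")
  validate_field_spec(spec)
  set.seed(as.integer(seed))
  h <- spec$height; w <- spec$width
  n <- spec$n_nuclei
  axr <- spec$nucleus_axis_range
  max_try <- 500L

  ctr <- matrix(NA_real_, n, 2)  # row, col
  ax <- matrix(NA_real_, n, 2)   # semi-major, semi-minor
  ang <- numeric(n)

  draw_shape <- function() {
    s <- sort(stats::runif(2, axr[1], axr[2]), decreasing = TRUE)
    list(a = s[1], b = s[2], th = stats::runif(1, 0, pi))
  }
  clear_of_placed <- function(r0, c0, a, upto, skip = 0L) {
    if (upto < 1L) return(TRUE)
    keep <- seq_len(upto)
    if (skip > 0L) keep <- keep[keep != skip]
    if (!length(keep)) return(TRUE)
    d2 <- (ctr[keep, 1] - r0)^2 + (ctr[keep, 2] - c0)^2
    all(d2 > (a + ax[keep, 1] + 1.5)^2)
  }

  i <- 1L
  while (i <= n) {
    want_pair <- (i < n) && (stats::runif(1) < spec$touching_pair_prob)
    want_edge <- stats::runif(1) < spec$edge_nucleus_prob
    sh <- draw_shape()
    placed <- FALSE
    for (t in seq_len(max_try)) {
      if (want_edge) {
        side <- sample.int(4L, 1L)
        vext <- ellipse_extent(sh$a, sh$b, sh$th, pi / 2)
        hext <- ellipse_extent(sh$a, sh$b, sh$th, 0)
        off_v <- stats::runif(1, 0, max(0, vext - 1))
        off_h <- stats::runif(1, 0, max(0, hext - 1))
        if (side == 1L) {        # top
          r0 <- 1 + off_v; c0 <- stats::runif(1, 1 + sh$a, w - sh$a)
        } else if (side == 2L) { # bottom
          r0 <- h - off_v; c0 <- stats::runif(1, 1 + sh$a, w - sh$a)
        } else if (side == 3L) { # left
          c0 <- 1 + off_h; r0 <- stats::runif(1, 1 + sh$a, h - sh$a)
        } else {                 # right
          c0 <- w - off_h; r0 <- stats::runif(1, 1 + sh$a, h - sh$a)
        }
      } else {
        r0 <- stats::runif(1, 1 + sh$a, h - sh$a)
        c0 <- stats::runif(1, 1 + sh$a, w - sh$a)
      }
      if (clear_of_placed(r0, c0, sh$a, i - 1L)) { placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place nucleus ", i, " without overlap; ",
           "field too small or too crowded for the requested density")
    ctr[i, ] <- c(r0, c0); ax[i, ] <- c(sh$a, sh$b); ang[i] <- sh$th

    if (want_pair) {
      sh2 <- draw_shape()
      for (t in seq_len(max_try)) {
        phi <- stats::runif(1, 0, 2 * pi)
        d <- ellipse_extent(sh$a, sh$b, sh$th, phi) +
          ellipse_extent(sh2$a, sh2$b, sh2$th, phi + pi) - 1.2
        r2 <- r0 + d * sin(phi); c2 <- c0 + d * cos(phi)
        if (r2 > 1 + sh2$a && r2 < h - sh2$a &&
            c2 > 1 + sh2$a && c2 < w - sh2$a &&
            clear_of_placed(r2, c2, sh2$a, i, skip = i)) {
          ctr[i + 1L, ] <- c(r2, c2)
          ax[i + 1L, ] <- c(sh2$a, sh2$b)
          ang[i + 1L] <- sh2$th
          i <- i + 1L
          break
        }
      }
    }
    i <- i + 1L
  }

  # Identity draws (one stream, fixed order => deterministic)
  is_germ <- stats::runif(n) < spec$germ_fraction
  red_status_pos <- stats::runif(n) < spec$ki67_pos_fraction
  coverage <- ifelse(red_status_pos,
                     stats::runif(n, spec$ki67_coverage_pos[1], spec$ki67_coverage_pos[2]),
                     stats::runif(n, spec$ki67_coverage_neg[1], spec$ki67_coverage_neg[2]))
  green_level <- ifelse(is_germ,
                        round(stats::runif(n, spec$green_intensity[1], spec$green_intensity[2])),
                        spec$somatic_green_intensity)
  red_level <- ifelse(red_status_pos,
                      round(stats::runif(n, spec$red_intensity_pos[1], spec$red_intensity_pos[2])),
                      round(stats::runif(n, spec$red_intensity_neg[1], spec$red_intensity_neg[2])))

  green <- matrix(spec$background, h, w)
  red <- matrix(spec$background, h, w)
  touches_border <- logical(n)
  for (k in seq_len(n)) {
    idx <- ellipse_pixels(ctr[k, 1], ctr[k, 2], ax[k, 1], ax[k, 2], ang[k], h, w)
    if (!length(idx)) next
    prow <- (idx - 1L) %% h + 1L
    pcol <- (idx - 1L) %/% h + 1L
    touches_border[k] <- any(prow == 1L | prow == h | pcol == 1L | pcol == w)
    green[idx] <- pmax(green[idx], green_level[k])
    n_paint <- round(coverage[k] * length(idx))
    if (n_paint > 0) {
      seed_px <- sample.int(length(idx), 1L)
      d2 <- (prow - prow[seed_px])^2 + (pcol - pcol[seed_px])^2
      paint <- idx[order(d2)[seq_len(n_paint)]]
      red[paint] <- pmax(red[paint], red_level[k])
    }
  }

  clip8 <- function(m, sd) {
    if (sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
    m <- round(m)
    m[m < 0] <- 0; m[m > 255] <- 255
    storage.mode(m) <- "integer"
    m
  }
  field <- structure(list(green = clip8(green, spec$noise_sd),
                          red = clip8(red, spec$noise_sd)),
                     class = "field_pair")
  truth <- data.frame(nucleus_id = seq_len(n),
                      row = ctr[, 1], col = ctr[, 2],
                      semi_major = ax[, 1], semi_minor = ax[, 2],
                      orientation = ang,
                      is_germ = is_germ,
                      is_ki67_pos = ifelse(is_germ, red_status_pos, NA),
                      coverage = coverage,
                      touches_border = touches_border)
  list(field = field, truth = truth)
}

#' Generate a biological replicate of several fields
#'
#' Produces `n_fields` independent fields from deterministically split
#' seeds, mirroring image acquisition of at least three non-overlapping
#' fields per tissue section.
#'
#' @param spec A [field_spec()].
#' @param n_fields Number of fields (default 3).
#' @param seed Master integer seed.
#' @return List of length `n_fields`, each element as from
#'   [generate_field()].
#' @export
generate_replicate <- function(spec, n_fields = 3, seed) {
  if (n_fields < 1) stop("n_fields must be >= 1")
  lapply(seq_len(n_fields), function(i)
    generate_field(spec, derive_seed(seed, i)))
}

#' Generate a synthetic per-tubule positive-cell count table
#'
#' Emulates manual counting of immunostained cells across seminiferous
#' tubule cross-sections: per-tubule positive-cell counts follow a Poisson
#' law, and a configurable fraction of sections are oblique cuts whose
#' measured length is expressed in circular-tubule diameter units.
#'
#' @param n_tubules Number of tubule cross-sections (>= 1).
#' @param oblique_fraction Probability that a section is oblique.
#' @param positive_rate Expected positive cells per tubule (Poisson mean).
#' @param seed Integer seed.
#' @param oblique_length_range Range of oblique section lengths in
#'   circular-diameter units.
#' @return A `tubule_count_table` data frame with columns `tubule_id`,
#'   `shape` (`"circular"`/`"oblique"`), `positives`, and `oblique_length`
#'   (`NA` for circular sections).
#' @export
generate_tubule_table <- function(n_tubules, oblique_fraction = 0,
                                  positive_rate, seed,
                                  oblique_length_range = c(0.5, 3)) {
  if (n_tubules < 1) stop("n_tubules must be >= 1")
  if (oblique_fraction < 0 || oblique_fraction > 1)
    stop("oblique_fraction must be in [0,1]")
  if (positive_rate < 0) stop("positive_rate must be >= 0")
  set.seed(as.integer(seed))
  oblique <- stats::runif(n_tubules) < oblique_fraction
  tab <- data.frame(tubule_id = seq_len(n_tubules),
                    shape = ifelse(oblique, "oblique", "circular"),
                    positives = stats::rpois(n_tubules, positive_rate),
                    oblique_length = ifelse(oblique,
                                            stats::runif(n_tubules,
                                                         oblique_length_range[1],
                                                         oblique_length_range[2]),
                                            NA_real_))
  class(tab) <- c("tubule_count_table", "data.frame")
  tab
}

#' Write / read a field pair as single-channel 8-bit images
#'
#' Fields are stored as two grayscale files `<prefix>_green.<ext>` and
#' `<prefix>_red.<ext>` (PNG or TIFF).
#'
#' @param x A `field_pair` (as in the `field` element of
#'   [generate_field()] output).
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default `"field"`.
#' @param format `"png"` or `"tiff"`.
#' @return `write_field` invisibly returns the two file paths;
#'   `read_field` returns a `field_pair`.
#' @export
write_field <- function(x, dir, prefix = "field",
                        format = c("png", "tiff")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  paths <- file.path(dir, paste0(prefix, "_", c("green", "red"), ".", ext))
  for (i in 1:2) {
    m <- x[[c("green", "red")[i]]] / 255
    if (format == "png") png::writePNG(m, paths[i])
    else tiff::writeTIFF(m, paths[i], bits.per.sample = 8L)
  }
  invisible(paths)
}

#' @rdname write_field
#' @param green_path,red_path Paths of the two channel images.
#' @export
read_field <- function(green_path, red_path) {
  read1 <- function(p) {
    m <- if (grepl("\\.png$", p, ignore.case = TRUE)) png::readPNG(p)
    else tiff::readTIFF(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- round(m * 255)
    storage.mode(m) <- "integer"
    m
  }
  structure(list(green = read1(green_path), red = read1(red_path)),
            class = "field_pair")
}

#' Write / read a ground-truth table as CSV
#'
#' One row per nucleus with the columns documented in [generate_field()].
#'
#' @param truth Truth data frame.
#' @param path CSV file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
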