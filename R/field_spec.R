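#' Specification of a synthetic two-channel fluorescence field
#'
#' A `field_spec` describes one simulated microscope field of view of a
#' testis section stained for a nuclear germ-cell marker (TRA98, green
#' channel) and the proliferation marker KI-67 (red channel). The generator
#' renders elliptical nuclei into both 8-bit channels and keeps an exact
#' per-nucleus ground-truth record, so segmentation, feature extraction and
#' classification can be validated without real micrographs.
#'
#' Germ nuclei carry full green signal; somatic (germ-negative) nuclei are
#' rendered at a separate, typically much lower, green intensity but still
#' receive red signal, because KI-67 labels cycling somatic cells too --
#' this makes the germ-mask restriction of downstream feature extraction
#' testable. KI-67 status drives how much of the nuclear area is painted
#' with red ("coverage") and how bright that paint is.
#'
#' @param width,height Field size in pixels.
#' @param n_nuclei Number of nuclei to place (germ plus somatic).
#' @param germ_fraction Probability that a nucleus is a germ cell.
#' @param ki67_pos_fraction Probability that a nucleus is KI-67 positive
#'   (applied to germ nuclei; somatic nuclei draw red signal with the same
#'   rate but their status is not part of the germ-cell truth).
#' @param nucleus_axis_range Length-2 numeric, min and max nuclear
#'   semi-axis in pixels.
#' @param ki67_coverage_pos,ki67_coverage_neg Length-2 ranges in [0,1]:
#'   fraction of the nuclear area painted with red signal for KI-67
#'   positive / negative nuclei.
#' @param red_intensity_pos,red_intensity_neg,green_intensity Length-2
#'   8-bit intensity ranges for the painted signal.
#' @param somatic_green_intensity Single 8-bit green intensity given to
#'   somatic nuclei (0 = invisible in the green channel).
#' @param touching_pair_prob Probability that a placed nucleus spawns a
#'   companion rendered in contact with it (a touching pair).
#' @param edge_nucleus_prob Probability that a nucleus is placed crossing
#'   the image border (such nuclei must be discarded by segmentation).
#' @param noise_sd Standard deviation of additive Gaussian read-out noise,
#'   in intensity units; applied to both channels and clipped to [0,255].
#' @param background Constant 8-bit background level of both channels.
#'
#' @return An object of class `field_spec` (a validated named list).
#' @seealso [generate_field()], [generate_replicate()]
#' @export
#' @examples
#' spec <- field_spec(n_nuclei = 30, noise_sd = 0)
#' spec$germ_fraction
field_spec <- function(width = 512, height = 512,
                       n_nuclei = 140,
                       germ_fraction = 0.8,
                       ki67_pos_fraction = 0.5,
                       nucleus_axis_range = c(5, 10),
                       ki67_coverage_pos = c(0.4, 0.9),
                       ki67_coverage_neg = c(0, 0.08),
                       red_intensity_pos = c(170, 230),
                       red_intensity_neg = c(120, 160),
                       green_intensity = c(120, 220),
                       somatic_green_intensity = 0,
                       touching_pair_prob = 0.05,
                       edge_nucleus_prob = 0.1,
                       noise_sd = 4,
                       background = 8) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_nuclei = as.integer(n_nuclei),
               germ_fraction = germ_fraction,
               ki67_pos_fraction = ki67_pos_fraction,
               nucleus_axis_range = as.numeric(nucleus_axis_range),
               ki67_coverage_pos = as.numeric(ki67_coverage_pos),
               ki67_coverage_neg = as.numeric(ki67_coverage_neg),
               red_intensity_pos = as.numeric(red_intensity_pos),
               red_intensity_neg = as.numeric(red_intensity_neg),
               green_intensity = as.numeric(green_intensity),
               somatic_green_intensity = somatic_green_intensity,
               touching_pair_prob = touching_pair_prob,
               edge_nucleus_prob = edge_nucleus_prob,
               noise_sd = noise_sd,
               background = background)
  class(spec) <- "field_spec"
  validate_field_spec(spec)
  spec
}

validate_field_spec <- function(spec) {
  in01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  rng <- function(x) length(x) == 2 && x[1] <= x[2]
  if (spec$n_nuclei < 0) stop("n_nuclei must be >= 0")
  for (p in c("germ_fraction", "ki67_pos_fraction", "touching_pair_prob",
              "edge_nucleus_prob")) {
    if (!in01(spec[[p]])) stop(p, " must be a proportion in [0,1]")
  }
  for (p in c("ki67_coverage_pos", "ki67_coverage_neg")) {
    if (!rng(spec[[p]]) || !in01(spec[[p]]))
      stop(p, " must be an increasing range within [0,1]")
  }
  for (p in c("red_intensity_pos", "red_intensity_neg", "green_intensity")) {
    if (!rng(spec[[p]]) || any(spec[[p]] < 0) || any(spec[[p]] > 255))
      stop(p, " must be an increasing range within [0,255]")
  }
  if (spec$somatic_green_intensity < 0 || spec$somatic_green_intensity > 255)
    stop("somatic_green_intensity must be in [0,255]")
  if (spec$background < 0 || spec$background > 255)
    stop("background must be in [0,255]")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!rng(spec$nucleus_axis_range) || spec$nucleus_axis_range[1] < 1)
    stop("nucleus_axis_range must be an increasing range with min >= 1 pixel")
  if (spec$width < 4 * spec$nucleus_axis_range[2] ||
      spec$height < 4 * spec$nucleus_axis_range[2])
    stop("field must be at least 4x the maximum semi-axis in each dimension")
  invisible(spec)
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %d x %d px, %d nuclei (germ %.0f%%, KI-67+ %.0f%%)\n",
              x$width, x$height, x$n_nuclei,
              100 * x$germ_fraction, 100 * x$ki67_pos_fraction))
  cat(sprintf("  semi-axes %.1f-%.1f px, touching %.0f%%, edge %.0f%%, noise sd %.1f, background %g\n",
              x$nucleus_axis_range[1], x$nucleus_axis_range[2],
              100 * x$touching_pair_prob, 100 * x$edge_nucleus_prob,
              x$noise_sd, x$background))
  invisible(x)
}
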