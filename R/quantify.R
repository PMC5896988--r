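#' Quantify one field: percent KI-67-positive germ cells
#'
#' Runs the full per-field pipeline: segment germ-cell nuclei from the
#' green channel, compute the global red threshold, extract the six
#' KI-67 measures per nucleus, classify each nucleus, and count.
#'
#' @param green,red Registered channel intensity matrices (0-255), or a
#'   `field_pair` passed as `green` with `red` missing.
#' @param model A `ki67_classifier`.
#' @param field_id Identifier for the field (default `"field"`).
#' @param min_area,min_marker_sep Passed to [segment_nuclei()].
#' @return One-row data frame (`field_summary`): `field_id`, `n_germ`,
#'   `n_pos`, `n_neg`, `percent_pos` (100 * n_pos / n_germ; `NA` when the
#'   field holds no germ nuclei -- undefined, not zero).
#' @export
quantify_field <- function(green, red, model, field_id = "field",
                           min_area = 15, min_marker_sep = 7.5) {
  if (missing(red) && inherits(green, "field_pair")) {
    red <- green$red
    green <- green$green
  }
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must have the same shape")
  lm <- segment_nuclei(green, min_area = min_area,
                       min_marker_sep = min_marker_sep)
  n_pos <- 0L
  if (lm$n_labels > 0) {
    thr <- red_global_threshold(red)
    feats <- extract_features(lm, red, thr)
    n_pos <- sum(predict(model, feats) == "positive")
  }
  n_germ <- lm$n_labels
  data.frame(field_id = field_id,
             n_germ = n_germ,
             n_pos = as.integer(n_pos),
             n_neg = as.integer(n_germ - n_pos),
             percent_pos = if (n_germ > 0) 100 * n_pos / n_germ else NA_real_,
             stringsAsFactors = FALSE)
}

#' Aggregate field summaries into a replicate summary
#'
#' Counts are summed over fields and the percent positive is recomputed
#' from the pooled counts (not averaged over field percentages), mirroring
#' pooling of all nuclei counted for one animal.
#'
#' @param field_summaries Data frame of rows from [quantify_field()] (or
#'   `rbind` thereof).
#' @param replicate_id Identifier for the animal/replicate.
#' @param genotype Genotype label, e.g. `"WT"` or `"KO"`.
#' @param min_fields Minimum expected number of fields; fewer triggers a
#'   warning (quantification conventionally uses at least three
#'   non-overlapping fields per section).
#' @return One-row data frame: `replicate_id`, `genotype`, `n_fields`,
#'   `n_germ`, `n_pos`, `n_neg`, `percent_pos`.
#' @export
aggregate_replicate <- function(field_summaries, replicate_id = "rep",
                                genotype = NA_character_, min_fields = 3) {
  if (!nrow(field_summaries)) stop("no field summaries to aggregate")
  if (nrow(field_summaries) < min_fields)
    warning("replicate has ", nrow(field_summaries),
            " field(s); at least ", min_fields, " are recommended")
  n_germ <- sum(field_summaries$n_germ)
  n_pos <- sum(field_summaries$n_pos)
  data.frame(replicate_id = replicate_id,
             genotype = genotype,
             n_fields = nrow(field_summaries),
             n_germ = n_germ,
             n_pos = n_pos,
             n_neg = n_germ - n_pos,
             percent_pos = if (n_germ > 0) 100 * n_pos / n_germ else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compare percent KI-67-positive germ cells between genotypes
#'
#' Pools positive/negative nucleus counts over the replicates of each
#' genotype and tests the two pooled proportions with an (uncorrected)
#' Pearson chi-square on the 2x2 table.
#'
#' @param wt_summaries,ko_summaries Replicate summaries (rows from
#'   [aggregate_replicate()]) for the two genotypes.
#' @return A `comparison_result` (see [chi_square_2x2()]).
#' @export
compare_genotypes <- function(wt_summaries, ko_summaries) {
  if (!nrow(wt_summaries) || !nrow(ko_summaries))
    stop("both genotype groups must be nonempty")
  pos1 <- sum(wt_summaries$n_pos); neg1 <- sum(wt_summaries$n_neg)
  pos2 <- sum(ko_summaries$n_pos); neg2 <- sum(ko_summaries$n_neg)
  if (pos1 + neg1 == 0 || pos2 + neg2 == 0)
    stop("a genotype group has zero total nuclei")
  chi_square_2x2(pos1, neg1, pos2, neg2)
}
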