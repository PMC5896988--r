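# comparison_result constructor shared by the statistical tests
comparison_result <- function(statistic, df, p, n_per_group, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), n_per_group = n_per_group, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, df = %g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Tubule-count equivalents of an oblique cross-section
#'
#' Oblique (lengthwise) tubule sections are counted in units of circular
#' tubule diameters: one circular diameter of measured length counts as
#' one tubule. Partial diameters are dropped (floor), but an observed
#' oblique section always counts at least once.
#'
#' @param circular_diameter Diameter of a circular tubule cross-section
#'   (> 0), in the same length units as `oblique_length`.
#' @param oblique_length Measured length of the oblique section (> 0).
#' @return Integer count of tubule equivalents (vectorized).
#' @export
#' @examples
#' oblique_equivalents(50, 175)  # 3
oblique_equivalents <- function(circular_diameter, oblique_length) {
  if (any(circular_diameter <= 0) || any(oblique_length <= 0))
    stop("circular_diameter and oblique_length must be > 0")
  pmax(1L, as.integer(floor(oblique_length / circular_diameter)))
}

#' Mean positive cells per tubule cross-section
#'
#' Averages per-tubule positive-cell counts over circular cross-sections;
#' a warning is emitted below 40 circular sections (the conventional
#' minimum for a stable per-tubule mean). Optionally oblique sections
#' contribute, weighted by their diameter equivalents.
#'
#' @param table A `tubule_count_table` (see [generate_tubule_table()]);
#'   `oblique_length` is in circular-diameter units.
#' @param include_oblique If `TRUE`, oblique rows enter the mean with
#'   weight [oblique_equivalents()]`(1, oblique_length)`.
#' @return Mean positives per (equivalent) tubule.
#' @export
mean_positive_per_tubule <- function(table, include_oblique = FALSE) {
  if (!nrow(table)) stop("empty tubule table")
  circ <- table[table$shape == "circular", , drop = FALSE]
  if (!nrow(circ)) stop("table contains no circular tubule cross-sections")
  if (nrow(circ) < 40)
    warning("only ", nrow(circ),
            " circular cross-sections; >= 40 are recommended")
  if (!include_oblique) return(mean(circ$positives))
  obl <- table[table$shape == "oblique", , drop = FALSE]
  wts <- c(rep(1, nrow(circ)),
           if (nrow(obl)) oblique_equivalents(1, obl$oblique_length) else numeric(0))
  sum(c(circ$positives, obl$positives)) / sum(wts)
}

#' Unpaired two-sample Student's t-test
#'
#' Classical equal-variance (pooled) two-tailed t-test on per-animal
#' means, with `df = nA + nB - 2`. When the pooled variance is zero the
#' test degenerates: equal means give `t = 0, p = 1`; unequal means with
#' zero variance are an error.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return A `comparison_result` with `statistic` (t), `df`, `p`.
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
unpaired_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  n <- c(length(group_a), length(group_b))
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(comparison_result(0, sum(n) - 2, 1, n, "unpaired Student's t-test"))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  comparison_result(ht$statistic, ht$parameter, ht$p.value, n,
                    "unpaired Student's t-test")
}

#' Pool per-replicate positive-tubule frequencies
#'
#' Sums numerators (tubules with at least one positive cell) and
#' denominators (tubules counted) over biological replicates and reports
#' the pooled percentage. Records are expected to come from one genotype
#' and one timepoint; pooling across mixed groups requires an explicit
#' override.
#'
#' @param records Data frame with columns `positives` and `total`, and
#'   optionally `genotype` and `dpp` (days post-partum) used for the
#'   consistency check.
#' @param allow_mixed Set `TRUE` to pool across genotypes/timepoints.
#' @return List with `positives`, `total`, `percentage` (full precision)
#'   and `display` (2-decimal, half-away-from-zero).
#' @export
#' @examples
#' pool_frequencies(data.frame(positives = c(11, 0, 1),
#'                             total = c(121, 93, 104)))
pool_frequencies <- function(records, allow_mixed = FALSE) {
  if (!nrow(records)) stop("no frequency records")
  if (any(records$positives < 0) || any(records$positives > records$total))
    stop("each record needs 0 <= positives <= total")
  if (!allow_mixed) {
    for (key in c("genotype", "dpp")) {
      if (key %in% names(records) && length(unique(records[[key]])) > 1)
        stop("records mix more than one ", key,
             "; pass allow_mixed = TRUE to pool anyway")
    }
  }
  pos <- sum(records$positives)
  tot <- sum(records$total)
  pct <- 100 * pos / tot
  list(positives = pos, total = tot,
       percentage = pct, display = round_half_up(pct, 2))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' expected counts from the marginal products, `df = 1`. Used to compare
#' pooled positive/negative counts between two groups.
#'
#' @param pos1,neg1 Counts for group 1.
#' @param pos2,neg2 Counts for group 2.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A `comparison_result`.
#' @export
chi_square_2x2 <- function(pos1, neg1, pos2, neg2, correct = FALSE) {
  counts <- c(pos1, neg1, pos2, neg2)
  if (any(counts < 0)) stop("counts must be >= 0")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every margin of the 2x2 table must be > 0")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  comparison_result(ht$statistic, ht$parameter, ht$p.value,
                    rowSums(tab), "Pearson chi-square (2x2)")
}

#' Chi-square goodness of fit against expected class counts
#'
#' Direct `sum((O - E)^2 / E)` with `df = length(observed) - 1`, taking
#' the expected counts as given (they are not rescaled to the observed
#' total). Used e.g. for Mendelian segregation ratios.
#'
#' @param observed Observed class counts.
#' @param expected Expected class counts (> 0), same length.
#' @return A `comparison_result`.
#' @export
#' @examples
#' chi_square_gof(c(20, 0, 42, 0), rep(15.5, 4))
chi_square_gof <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have the same length")
  if (length(observed) < 2) stop("need at least 2 classes")
  if (any(expected <= 0)) stop("expected counts must be > 0")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  comparison_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                    sum(observed), "chi-square goodness of fit")
}

#' Read / write tubule and frequency tables
#'
#' CSV interchange for per-tubule count tables
#' (`tubule_id,shape,positives,oblique_length`) and per-replicate
#' frequency tables (`replicate_id,genotype,dpp,positives,total`).
#'
#' @param path CSV file path.
#' @return A data frame (`tubule_count_table` class for tubule tables).
#' @export
read_tubule_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("tubule_count_table", "data.frame")
  tab
}

#' @rdname read_tubule_table
#' @param table Data frame to write.
#' @export
write_tubule_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tubule_table
#' @export
read_frequency_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
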