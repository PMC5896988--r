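#' Reference per-replicate cleaved caspase-3 tubule frequencies
#'
#' Per-replicate counts of seminiferous tubules containing at least one
#' cleaved caspase-3-positive (apoptotic) cell, over the total tubules
#' counted, in wild-type (`WT`, Uxt floxed) and germline conditional
#' knockout (`KO`, Uxt floxed; Vasa-Cre) mouse testes at 5, 6 and 7 days
#' post-partum. Each row is one biological replicate (animal). Bundled as
#' the worked input for [pool_frequencies()] and [chi_square_2x2()]: the
#' pooled percentages are 3.77/5.00 (5dpp), 8.25/11.85 (6dpp) and
#' 11.65/18.22 (7dpp) for WT/KO, and only the 7dpp contrast is
#' significant (p < 0.0001).
#'
#' @return Data frame with columns `replicate_id`, `genotype`, `dpp`,
#'   `positives`, `total`.
#' @export
#' @examples
#' freqs <- caspase3_frequencies()
#' with(subset(freqs, genotype == "WT" & dpp == 5),
#'      pool_frequencies(data.frame(positives, total)))
caspase3_frequencies <- function() {
  data.frame(
    replicate_id = c(paste0("WT5_", 1:3), paste0("KO5_", 1:3),
                     paste0("WT6_", 1:4), paste0("KO6_", 1:4),
                     paste0("WT7_", 1:5), paste0("KO7_", 1:5)),
    genotype = c(rep("WT", 3), rep("KO", 3),
                 rep("WT", 4), rep("KO", 4),
                 rep("WT", 5), rep("KO", 5)),
    dpp = c(rep(5L, 6), rep(6L, 8), rep(7L, 10)),
    positives = c(11, 0, 1,          # WT 5dpp
                  15, 0, 1,          # KO 5dpp
                  21, 3, 0, 10,      # WT 6dpp
                  20, 1, 7, 15,      # KO 6dpp
                  10, 12, 15, 16, 12,  # WT 7dpp
                  25, 14, 37, 12, 35), # KO 7dpp
    total = c(121, 93, 104,
              117, 113, 90,
              96, 99, 100, 117,
              92, 53, 95, 123,
              102, 135, 95, 113, 113,
              99, 137, 110, 97, 232),
    stringsAsFactors = FALSE)
}

#' Reference Mendelian segregation counts for the knockout allele
#'
#' Observed progeny counts from heterozygous knockout mothers crossed to
#' wild-type males, by sex and genotype, against the 1:1:1:1 Mendelian
#' expectation (15.5 per class for 62 pups). The complete absence of
#' hemizygous knockout males and heterozygous-expressing knockout females
#' indicates embryonic lethality of the null allele; the goodness-of-fit
#' statistic on these counts is 1203/15.5 (about 77.61) on 3 degrees of
#' freedom.
#'
#' @return Data frame with columns `class`, `observed`, `expected`.
#' @export
#' @examples
#' cross <- mendelian_cross_counts()
#' chi_square_gof(cross$observed, cross$expected)
mendelian_cross_counts <- function() {
  data.frame(class = c("male_WT", "male_KO", "female_WT", "female_KO"),
             observed = c(20, 0, 42, 0),
             expected = rep(15.5, 4),
             stringsAsFactors = FALSE)
}
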