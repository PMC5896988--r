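# Shared fixtures, all generated in code.

# Clean imaging conditions: no noise, no background, no touching pairs.
clean_spec <- function(n_nuclei = 60, width = 320, height = 320, ...) {
  field_spec(width = width, height = height, n_nuclei = n_nuclei,
             noise_sd = 0, background = 0, touching_pair_prob = 0, ...)
}

# Ellipse membership computed independently of the generator internals:
# brute-force test of every pixel center against the ellipse equation.
truth_ellipse_mask <- function(truth_row, h, w) {
  r0 <- truth_row$row; c0 <- truth_row$col
  a <- truth_row$semi_major; b <- truth_row$semi_minor
  th <- truth_row$orientation
  dr <- matrix(seq_len(h) - r0, h, w)
  dc <- matrix(seq_len(w) - c0, h, w, byrow = TRUE)
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Directly constructed, linearly separable feature records (no imaging).
separable_features <- function(n_pos = 10, n_neg = 10, seed = 1) {
  set.seed(seed)
  pos <- data.frame(area = round(runif(n_pos, 150, 300)),
                    max_red = runif(n_pos, 180, 230),
                    sum_red = runif(n_pos, 2e4, 5e4),
                    mean_red = runif(n_pos, 120, 200),
                    major_axis = runif(n_pos, 12, 22),
                    coverage_frac = runif(n_pos, 0.8, 0.95),
                    label = "positive", stringsAsFactors = FALSE)
  neg <- data.frame(area = round(runif(n_neg, 150, 300)),
                    max_red = runif(n_neg, 120, 170),
                    sum_red = runif(n_neg, 1e3, 8e3),
                    mean_red = runif(n_neg, 5, 40),
                    major_axis = runif(n_neg, 12, 22),
                    coverage_frac = runif(n_neg, 0.05, 0.15),
                    label = "negative", stringsAsFactors = FALSE)
  rbind(pos, neg)
}

# Labeled nucleus records obtained by running the imaging pipeline on
# generated fields and copying the true KI-67 status. Cached because
# several tests share the pool.
.pool_cache <- new.env(parent = emptyenv())
labeled_pool <- function(n_fields = 6, seed = 11, ki67_pos_fraction = 0.6) {
  key <- paste(n_fields, seed, ki67_pos_fraction, sep = "_")
  if (!is.null(.pool_cache[[key]])) return(.pool_cache[[key]])
  spec <- clean_spec(ki67_pos_fraction = ki67_pos_fraction,
                     edge_nucleus_prob = 0.05)
  pool <- do.call(rbind, lapply(seq_len(n_fields), function(i) {
    f <- generate_field(spec, seed = seed + i)
    lm <- segment_nuclei(f$field$green)
    fe <- extract_features(lm, f$field$red,
                           red_global_threshold(f$field$red))
    label_from_truth(fe, f$truth)
  }))
  pool <- pool[!is.na(pool$label), , drop = FALSE]
  .pool_cache[[key]] <- pool
  pool
}

# Exhaustive-search Otsu oracle: naive sweep of all 256 candidate
# thresholds with the between-class variance formula, independent of the
# histogram/cumsum implementation under test.
otsu_oracle <- function(raster) {
  v <- as.vector(raster)
  best_t <- 0L; best_s <- -1
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    s <- if (!length(lo) || !length(hi)) 0 else
      (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}
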