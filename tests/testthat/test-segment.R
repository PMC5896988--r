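test_that("otsu returns the smallest maximizing threshold", {
  bimodal <- matrix(c(rep(10, 100), rep(200, 100)), 20)
  expect_identical(otsu_threshold(bimodal), 10L)

  flat <- matrix(7, 5, 5)
  expect_identical(otsu_threshold(flat), 7L)
  expect_false(any(binarize(flat, otsu_threshold(flat))))

  expect_error(otsu_threshold(matrix(numeric(0), 0, 0)), "empty")
  expect_error(otsu_threshold(matrix(300, 2, 2)), "\\[0,255\\]")
})

test_that("otsu equals the exhaustive between-class-variance sweep", {
  set.seed(71)
  for (i in 1:30) {
    # mix of unimodal, bimodal, and skewed rasters
    v <- switch(1 + i %% 3,
                sample(0:255, 400, replace = TRUE),
                c(round(rnorm(200, 60, 10)), round(rnorm(200, 180, 25))),
                round(rexp(400, 1 / 40)))
    v <- pmax(0, pmin(255, v))
    r <- matrix(v, 20)
    expect_identical(otsu_threshold(r), as.integer(otsu_oracle(r)))
  }
})

test_that("binarize uses strict inequality and is monotone in the threshold", {
  expect_false(any(binarize(matrix(0, 4, 4), 0)))
  set.seed(72)
  r <- matrix(sample(0:255, 900, replace = TRUE), 30)
  f1 <- binarize(r, 100)
  f2 <- binarize(r, 140)
  expect_true(all(f1[f2]))          # raising threshold never adds pixels
  expect_identical(f1, r > 100)
})

test_that("otsu binarization of a noiseless field recovers the germ mask", {
  spec <- clean_spec(n_nuclei = 30, germ_fraction = 1, edge_nucleus_prob = 0.2)
  f <- generate_field(spec, seed = 73)
  mask <- binarize(f$field$green, otsu_threshold(f$field$green))
  truth_mask <- matrix(FALSE, spec$height, spec$width)
  for (k in seq_len(nrow(f$truth))) {
    truth_mask <- truth_mask | truth_ellipse_mask(f$truth[k, ],
                                                  spec$height, spec$width)
  }
  expect_identical(mask, truth_mask)
})

test_that("border-touching components are removed exactly", {
  m <- matrix(FALSE, 10, 10)
  m[4:6, 4:6] <- TRUE                      # interior blob
  expect_identical(remove_edge_objects(m), m)

  m2 <- m
  m2[1, 5] <- TRUE; m2[2:3, 5] <- TRUE      # bridge to row 1
  expect_false(any(remove_edge_objects(m2)))

  # separate interior blob survives while the edge blob goes
  m3 <- m
  m3[9:10, 9:10] <- TRUE
  out <- remove_edge_objects(m3)
  expect_identical(out, m)

  # synthetic field: removed component count equals truth border count
  spec <- clean_spec(n_nuclei = 30, germ_fraction = 1, edge_nucleus_prob = 0.3)
  f <- generate_field(spec, seed = 74)
  mask <- binarize(f$field$green, otsu_threshold(f$field$green))
  lm_before <- separate_touching(mask)
  lm_after <- separate_touching(remove_edge_objects(mask))
  expect_equal(lm_before$n_labels - lm_after$n_labels,
               sum(f$truth$touches_border))
})

test_that("watershed separates touching nuclei and partitions the mask", {
  # disjoint blobs: watershed reduces to component labeling
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE
  m[20:26, 18:25] <- TRUE
  lm <- separate_touching(m)
  expect_equal(lm$n_labels, 2)
  expect_equal(sum(lm$labels > 0), sum(m))

  # two overlapping discs, radius 10, centers 14 px apart
  h <- 40; w <- 60
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  discs <- (rr - 20)^2 + (cc - 20)^2 <= 100 | (rr - 20)^2 + (cc - 34)^2 <= 100
  lm2 <- separate_touching(discs)
  expect_equal(lm2$n_labels, 2)
  expect_equal(sum(lm2$labels > 0), sum(discs))  # no pixel lost or duplicated
  # split boundary within 1 px of the perpendicular bisector (col 27)
  left <- unique(lm2$labels[discs & cc <= 26])
  right <- unique(lm2$labels[discs & cc >= 28])
  expect_length(left[left > 0], 1)
  expect_length(right[right > 0], 1)
  expect_false(left[left > 0] == right[right > 0])

  # empty mask
  lm3 <- separate_touching(matrix(FALSE, 5, 5))
  expect_equal(lm3$n_labels, 0)
  expect_true(all(lm3$labels == 0L))
})

test_that("labels are consecutive and 8-connectivity is honored", {
  # diagonal-only contact is one 8-connected object
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(remove_edge_objects(m), m)  # interior, untouched
  m[1, 1] <- TRUE                              # now diagonally chained to border
  expect_false(any(remove_edge_objects(m)))

  spec <- clean_spec(n_nuclei = 25)
  f <- generate_field(spec, seed = 75)
  lm <- segment_nuclei(f$field$green)
  ids <- sort(unique(as.vector(lm$labels[lm$labels > 0])))
  expect_identical(ids, seq_len(lm$n_labels))
})

test_that("end-to-end segmentation recovers exactly the interior germ nuclei", {
  for (seed in 76:79) {
    spec <- clean_spec(n_nuclei = 40, edge_nucleus_prob = 0.15)
    f <- generate_field(spec, seed = seed)
    lm <- segment_nuclei(f$field$green)
    interior_germ <- f$truth[f$truth$is_germ & !f$truth$touches_border, ]
    expect_equal(lm$n_labels, nrow(interior_germ))
  }
  # empty field
  lm0 <- segment_nuclei(matrix(0L, 64, 64))
  expect_equal(lm0$n_labels, 0)
  # min-area filter drops small regions
  f <- generate_field(clean_spec(n_nuclei = 20), seed = 80)
  full <- segment_nuclei(f$field$green, min_area = 0)
  big <- segment_nuclei(f$field$green, min_area = 5000)
  expect_gt(full$n_labels, 0)
  expect_equal(big$n_labels, 0)
})

test_that("label maps round-trip through TIFF and region CSV", {
  f <- generate_field(clean_spec(n_nuclei = 12), seed = 81)
  lm <- segment_nuclei(f$field$green)
  dir <- withr::local_tempdir()
  regions <- write_label_map(lm, tiff_path = file.path(dir, "lab.tif"),
                             csv_path = file.path(dir, "lab.csv"))
  expect_equal(nrow(regions), lm$n_labels)
  expect_equal(sum(regions$area), sum(lm$labels > 0))
  back <- utils::read.csv(file.path(dir, "lab.csv"))
  expect_equal(back$area, regions$area)
  tif <- round(tiff::readTIFF(file.path(dir, "lab.tif")) * 65535)
  expect_equal(max(tif), lm$n_labels)
})
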