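test_that("identical tables give one common peak per input peak", {
  a <- peak_table("S1", c(5, 10), c(1, 2))
  b <- peak_table("S2", c(5, 10), c(1, 2))
  m <- match_common_peaks(list(a, b))
  expect_equal(length(m$peak_ids), 2L)
  expect_equal(unname(m$occupancy), c(1, 1))
  expect_equal(unname(m$areas), rbind(c(1, 2), c(1, 2)))
})

test_that("peaks outside the window form excluded singleton clusters", {
  a <- peak_table("S1", c(5.00, 10.00), c(1, 1))
  b <- peak_table("S2", c(5.04, 10.30), c(1, 1))
  m <- match_common_peaks(list(a, b), time_window = 0.1)
  expect_equal(length(m$peak_ids), 1L)           # only the 5-min cluster
  expect_equal(unname(m$median_rt), 5.02)
  expect_equal(unname(m$occupancy), 1)
  # relaxing occupancy reveals the two 10-min singletons
  m_all <- match_common_peaks(list(a, b), time_window = 0.1,
                              min_occupancy = 0.5)
  expect_equal(length(m_all$peak_ids), 3L)
  # agrees with the brute-force pairwise enumeration
  bf <- brute_pair_clusters(c(5.00, 10.00), c(5.04, 10.30), 0.1)
  expect_equal(sum(lengths(bf) == 2L), 1L)
})

test_that("matching is invariant to batch order and within-batch peak order", {
  set.seed(11)
  tabs <- lapply(1:5, function(b)
    peak_table(paste0("S", b), rt_min = 1:8 + rnorm(8, sd = 0.02),
               area = runif(8, 1, 5)))
  m1 <- match_common_peaks(tabs)
  shuffled <- lapply(rev(tabs), function(tb) tb[sample(nrow(tb)), ])
  m2 <- match_common_peaks(shuffled)
  expect_equal(m1$median_rt, m2$median_rt)
  expect_equal(m1$areas, m2$areas[rownames(m1$areas), , drop = FALSE])
})

test_that("a batch contributing two equally-near peaks keeps the earlier rt", {
  a <- peak_table("S1", c(4.98, 5.02), c(7, 9))
  b <- peak_table("S2", 5.00, 3)
  expect_warning(m <- match_common_peaks(list(a, b)), "contributed")
  expect_equal(unname(m$areas["S1", 1L]), 7)
})

test_that("the packaged relative-rt table re-matches into 15 common peaks", {
  t2 <- load_fixture("table2")
  rts <- fixture_matrix(t2) * 15               # nominal 15-min reference rt
  tabs <- lapply(rownames(rts), function(b)
    peak_table(b, rt_min = rts[b, ], area = rep(1, ncol(rts))))
  m <- match_common_peaks(tabs, time_window = 0.1)
  expect_equal(length(m$peak_ids), 15L)
  expect_true(all(m$occupancy == 1))
  # precondition the clustering relies on, checked by brute-force scan
  expect_true(all(apply(rts, 2L, function(r) max(abs(r - median(r)))) < 0.1))
})

test_that("relative quantities have an exact unit reference column", {
  X <- table3_matrix()
  tabs <- lapply(rownames(X), function(b)
    peak_table(b, rt_min = seq(2, 30, by = 2), area = X[b, ]))
  m <- match_common_peaks(tabs)
  rel <- relative_to_reference(m, 9)
  expect_equal(unname(rel$relative_areas[, 9L]), rep(1, 10))
  expect_equal(unname(rel$relative_rts[, 9L]), rep(1, 10))
  expect_identical(rsd(rel$relative_areas[, 9L]), 0)
  # single-batch-style ratio check on one row
  expect_equal(unname(rel$relative_areas["S1", ]),
               unname(X["S1", ] / X["S1", 9L]))
  # permuting batches permutes rows identically
  m2 <- match_common_peaks(rev(tabs))
  rel2 <- relative_to_reference(m2, 9)
  expect_equal(rel2$relative_areas[rownames(rel$relative_areas), ],
               rel$relative_areas)
})

test_that("relative_to_reference refuses a non-positive reference", {
  a <- peak_table("S1", c(1, 2), c(0, 5))
  b <- peak_table("S2", c(1, 2), c(1, 5))
  m <- match_common_peaks(list(a, b))
  expect_error(relative_to_reference(m, 1), "S1")
})

test_that("rsd follows the sample-SD convention", {
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_equal(rsd(rep(3.7, 6)), 0)
  expect_error(rsd(1), "at least two")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("reference fingerprint uses the stated median conventions", {
  m <- rbind(a = c(1, 1), b = c(2, 2), c = c(10, 10))
  expect_equal(reference_fingerprint(m), c(2, 2))
  m4 <- rbind(m, d = c(3, 3))
  expect_equal(reference_fingerprint(m4), c(2.5, 2.5))
  expect_equal(reference_fingerprint(m4, method = "mean"), c(4, 4))
  ident <- rbind(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(reference_fingerprint(ident), c(1, 2, 3))
})

test_that("cosine similarity matches the direct formula", {
  v <- c(0.3, 1.2, 5)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "all-zero")
})

test_that("similarity matrix is symmetric, unit-diagonal and scale-invariant", {
  X <- table3_matrix()
  S <- similarity_matrix(X)
  expect_equal(dim(S), c(11L, 11L))             # 10 batches + reference
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 11))
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  # scaling one batch's vector leaves all pairwise similarities unchanged
  # (the consensus reference itself shifts, so compare without it)
  X2 <- X; X2["S3", ] <- 17 * X2["S3", ]
  expect_equal(similarity_matrix(X2, include_reference = FALSE),
               similarity_matrix(X, include_reference = FALSE))
  # duplicated batches are perfectly similar
  D <- similarity_matrix(rbind(a = X["S1", ], b = X["S1", ]),
                         include_reference = FALSE)
  expect_equal(D["a", "b"], 1)
  # two-batch toy against the raw formula
  expect_equal(similarity_matrix(X[1:2, ], include_reference = FALSE)[1L, 2L],
               sum(X[1L, ] * X[2L, ]) / sqrt(sum(X[1L, ]^2) * sum(X[2L, ]^2)))
})

test_that("multipoint rt correction interpolates and extrapolates linearly", {
  tab <- peak_table("S1", c(0.5, 1.5, 3), c(1, 2, 3))
  ident <- multipoint_rt_correction(tab, cbind(c(1, 10), c(1, 10)))
  expect_equal(ident$rt_min, tab$rt_min)
  out <- multipoint_rt_correction(tab, cbind(c(1, 2), c(2, 4)))
  expect_equal(out$rt_min, c(1, 3, 6))          # doubling map, extrapolated
  expect_equal(out$area, tab$area)
  expect_error(multipoint_rt_correction(tab, cbind(c(2, 1), c(1, 2))),
               "increasing")
})

test_that("correction with jittered anchors restores the uncorrected clustering", {
  gen <- generate(synthetic_spec(n_batches = 6, n_peaks = 8, seed = 21))
  truth <- match_common_peaks(gen$tables)
  # distort every batch with a smooth rt warp, then undo it via anchors
  warped <- lapply(gen$tables, function(tb) {
    tb$rt_min <- tb$rt_min * 1.05 + 0.3
    tb
  })
  anchors <- cbind(c(1, 20) * 1.05 + 0.3, c(1, 20))
  restored <- lapply(warped, multipoint_rt_correction, anchors = anchors)
  m <- match_common_peaks(restored)
  expect_equal(length(m$peak_ids), length(truth$peak_ids))
  expect_equal(m$areas, truth$areas)
})

test_that("chromatogram resampling feeds the similarity path", {
  ch1 <- chromatogram("a", seq(0, 10, 0.1), dnorm(seq(0, 10, 0.1), 5, 0.3))
  ch2 <- chromatogram("b", seq(0, 10, 0.05), dnorm(seq(0, 10, 0.05), 5, 0.3))
  S <- similarity_matrix(list(ch1, ch2), include_reference = FALSE)
  expect_gt(S["a", "b"], 0.999)
  expect_error(resample_chromatograms(list()), "length")
})
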