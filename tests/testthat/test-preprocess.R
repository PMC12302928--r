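test_that("peak QC boundaries are inclusive and reasons are reported", {
  peaks <- data.frame(feature_id = c("a", "b", "c", "d"),
                      signal_to_noise = c(50, 49.9, 500, 10),
                      similarity = c(700, 999, 650, 500))
  out <- filterPeaks(peaks)
  expect_identical(out$retained, "a")        # both thresholds met exactly
  expect_equal(out$rejections$reason[out$rejections$feature_id == "b"],
               "S/N")
  expect_equal(out$rejections$reason[out$rejections$feature_id == "c"],
               "similarity")
  expect_equal(out$rejections$reason[out$rejections$feature_id == "d"],
               "S/N+similarity")
})

test_that("peak QC matches the brute-force predicate on random records", {
  set.seed(31)
  peaks <- data.frame(feature_id = paste0("p", 1:10),
                      signal_to_noise = runif(10, 0, 100),
                      similarity = round(runif(10, 400, 999)))
  out <- filterPeaks(peaks, qcThresholds(min_sn = 50, min_similarity = 700))
  manual <- peaks$feature_id[peaks$signal_to_noise >= 50 &
                               peaks$similarity >= 700]
  expect_identical(out$retained, manual)
  expect_identical(sort(c(out$retained, out$rejections$feature_id)),
                   sort(peaks$feature_id))
})

test_that("internal-standard normalization is element-wise division", {
  set.seed(32)
  m <- matrix(rlnorm(40), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:8)))
  tab <- featureTable(m, rep(c("A", "B"), c(2, 3)), internalStandard = "f8")
  norm <- normalizeInternalStandard(tab)
  expect_false("f8" %in% featureIds(norm))
  expect_equal(intensityMatrix(norm), m[, 1:7] / m[, 8])
  # scale invariance: multiplying one sample's whole row leaves it unchanged
  m2 <- m
  m2[3, ] <- m2[3, ] * 7
  norm2 <- normalizeInternalStandard(
    featureTable(m2, rep(c("A", "B"), c(2, 3)), internalStandard = "f8"))
  expect_equal(intensityMatrix(norm2), intensityMatrix(norm))
  # a sample whose intensities all equal its IS value normalizes to 1
  m3 <- m
  m3[1, ] <- 5
  norm3 <- normalizeInternalStandard(
    featureTable(m3, rep(c("A", "B"), c(2, 3)), internalStandard = "f8"))
  expect_true(all(intensityMatrix(norm3)[1, ] == 1))
})

test_that("missing or zero internal standard is a hard error naming the sample", {
  m <- matrix(rlnorm(8), 2, 4,
              dimnames = list(c("s1", "s2"), paste0("f", 1:4)))
  m[2, 4] <- NA
  tab <- featureTable(m, c("A", "B"), internalStandard = "f4")
  expect_error(normalizeInternalStandard(tab), "s2")
  expect_error(normalizeInternalStandard(featureTable(m[, 1:3], c("A", "B"))),
               "internal-standard")
})

test_that("missingness filter removes strictly above the threshold", {
  m <- matrix(rlnorm(9 * 3), 9, 3,
              dimnames = list(paste0("s", 1:9), c("f_over", "f_half", "f_ok")))
  m[1:5, 1] <- NA                       # 5/9 = 55.6% -> removed
  m[1:4, 2] <- NA                       # 44% -> kept
  tab <- featureTable(m, rep(c("A", "B", "C"), each = 3))
  out <- filterMissingness(tab, 0.5)
  expect_identical(out$removed, "f_over")
  # exactly half missing is kept under the strict "more than" rule
  m2 <- matrix(rlnorm(8 * 2), 8, 2,
               dimnames = list(paste0("s", 1:8), c("f_half", "f_ok")))
  m2[1:4, 1] <- NA
  out2 <- filterMissingness(featureTable(m2, rep(c("A", "B"), each = 4)), 0.5)
  expect_length(out2$removed, 0L)
})

test_that("missingness filter agrees with a counting oracle on random masks", {
  set.seed(33)
  m <- matrix(rlnorm(12 * 20), 12, 20,
              dimnames = list(paste0("s", 1:12), paste0("f", 1:20)))
  m[matrix(runif(length(m)) < 0.4, nrow(m))] <- NA
  m[, 1] <- rlnorm(12)   # keep one feature fully observed
  tab <- featureTable(m, rep(c("A", "B"), each = 6))
  out <- filterMissingness(tab, 0.35)
  manual <- colnames(m)[colSums(is.na(m)) / nrow(m) > 0.35]
  expect_identical(out$removed, manual)
})

test_that("half-minimum imputation fills every gap with half the feature minimum", {
  m <- matrix(c(4, 8, NA, 1, 2, 3), 3, 2,
              dimnames = list(paste0("s", 1:3), c("f1", "f2")))
  tab <- featureTable(m, c("A", "A", "B"))
  out <- imputeHalfMin(tab)
  expect_equal(intensityMatrix(out)[3, "f1"], 2)   # min(4, 8) / 2
  expect_equal(intensityMatrix(out)[, "f2"], c(s1 = 1, s2 = 2, s3 = 3))
  # fully observed tables pass through unchanged
  expect_identical(intensityMatrix(imputeHalfMin(out)),
                   intensityMatrix(out))
  # per-column oracle on a random table
  set.seed(34)
  m2 <- matrix(rlnorm(10 * 20), 10, 20,
               dimnames = list(paste0("s", 1:10), paste0("f", 1:20)))
  m2[matrix(runif(length(m2)) < 0.2, nrow(m2))] <- NA
  m2[1, ] <- rlnorm(20)
  imp <- intensityMatrix(imputeHalfMin(featureTable(m2, rep("A", 10))))
  for (j in seq_len(ncol(m2))) {
    expected <- m2[, j]
    expected[is.na(expected)] <- min(m2[, j], na.rm = TRUE) / 2
    expect_equal(imp[, j], expected)
  }
  # an all-missing feature is an error, not a silent fill
  m3 <- m
  m3[, 2] <- NA
  expect_error(imputeHalfMin(featureTable(m3, c("A", "A", "B"))), "f2")
})

test_that("retention indices follow the van den Dool-Kratz closed form", {
  ladder <- data.frame(carbon_number = c(10, 11),
                       retention_time = c(10, 12))
  expect_equal(computeRI(11, ladder), 1050)
  expect_equal(computeRI(10, ladder), 1000)
  expect_equal(computeRI(12, ladder), 1100)
  expect_error(computeRI(9.5, ladder), "outside")
  expect_error(computeRI(12.5, ladder), "outside")
})

test_that("interpolated RI matches an independent oracle and is monotone", {
  set.seed(35)
  ladder <- generateStudy(synthConfig(seed = 35, n_metabolites = 5,
                                      n_vocs = 5))$ladder
  times <- sort(runif(50, min(ladder$retention_time),
                      max(ladder$retention_time)))
  mine <- vapply(times, computeRI, numeric(1), ladder = ladder)
  oracle <- approx(ladder$retention_time, 100 * ladder$carbon_number,
                   xout = times)$y
  expect_equal(max(abs(mine - oracle)), 0)
  expect_false(is.unsorted(mine))
  # alkane anchors are exact
  anchors <- vapply(ladder$retention_time, computeRI, numeric(1),
                    ladder = ladder)
  expect_identical(anchors, 100 * ladder$carbon_number)
})

test_that("identity confirmation uses a strict tolerance", {
  expect_true(confirmIdentity(1050, 1065))          # |d| = 15
  expect_false(confirmIdentity(1050, 1070))         # |d| = 20, strict
  set.seed(36)
  a <- runif(100, 900, 1100)
  b <- a + runif(100, -40, 40)
  expect_identical(confirmIdentity(a, b, 20), abs(a - b) < 20)
})

test_that("the preprocessing chain is a no-op on its own output", {
  s <- smallStudy(seed = 37, missing_rate = 0.1, lod_quantile = 0.05)
  prep <- preprocessTable(s$vocs, peaks = s$peaks,
                          annotations = s$annotations, ladder = s$ladder)
  again <- preprocessTable(prep$table)
  expect_identical(intensityMatrix(again$table),
                   intensityMatrix(prep$table))
  # the log records the fixed stage order
  expect_identical(prep$log$stage,
                   c("input", "peak_qc", "ri_confirmation",
                     "is_normalization", "missingness_filter", "imputation"))
})
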