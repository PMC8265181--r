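mkTable <- function(rows, samples, groups = rep("g", length(samples))) {
  PeakTable(rows, mz = seq(100, by = 10, length.out = nrow(rows)),
            groups = groups, sampleIds = samples)
}

test_that("replicate merging follows the missing-proportion and CV rules", {
  # one subject per row scenario, built as a 1-feature table each time
  merge1 <- function(values, subject_n) {
    X <- matrix(NA_real_, 1, subject_n)
    X[1, seq_along(values)] <- values
    pt <- mkTable(X, paste0("r", seq_len(subject_n)))
    reps <- setNames(rep("subj", subject_n), paste0("r", seq_len(subject_n)))
    intensities(mergeTechnicalReplicates(pt, reps))[1, 1]
  }
  # no missing: plain mean
  expect_equal(merge1(c(100, 110, 90), 3), 100)
  # f = 1/4 <= 1/3: mean of non-missing (oracle: direct arithmetic)
  expect_equal(merge1(c(1, 10, 100), 4), mean(c(1, 10, 100)))
  # f = 2/5 > 1/3 and CV = sd/mean = 54.7449.../37 > 1: sentinel 0
  cv <- sd(c(1, 10, 100)) / mean(c(1, 10, 100))
  expect_gt(cv, 1)
  expect_equal(round(cv, 4), 1.4796)
  expect_equal(merge1(c(1, 10, 100), 5), 0)
  # f = 2/3 > 1/3 but a single surviving value has CV 0: retained
  expect_equal(merge1(300, 3), 300)
  # all replicates missing stays missing
  expect_true(is.na(merge1(numeric(0), 3)))
})

test_that("replicate merging keeps multi-subject structure and group labels", {
  X <- matrix(c(1, 2, 3, 4,
                10, NA, 30, 40), nrow = 2, byrow = TRUE)
  pt <- mkTable(X, c("a1", "a2", "b1", "b2"), groups = c("g1", "g1", "g2", "g2"))
  reps <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  m <- mergeTechnicalReplicates(pt, reps)
  expect_equal(colnames(m), c("A", "B"))
  expect_equal(unname(groupLabels(m)), c("g1", "g2"))
  expect_equal(unname(intensities(m)[1, ]), c(1.5, 3.5))
  # f = 1/2 > 1/3 for feature 2 subject A; CV of single value 10 is 0
  expect_equal(unname(intensities(m)[2, ]), c(10, 35))
  expect_error(mergeTechnicalReplicates(pt, c(reps, zz = "C")), "zz")
})

test_that("replicate merging is idempotent for singleton subjects and bounded", {
  set.seed(11)
  X <- matrix(rlnorm(40), 8, 5)
  X[sample(length(X), 6)] <- NA
  pt <- mkTable(X, paste0("s", 1:5))
  ident <- mergeTechnicalReplicates(pt, setNames(paste0("s", 1:5),
                                                 paste0("s", 1:5)))
  expect_equal(intensities(ident), intensities(pt))
  # merged values stay inside [min, max] of contributing replicates
  # except the CV sentinel 0
  reps <- setNames(c("A", "A", "A", "B", "B"), paste0("s", 1:5))
  m <- intensities(mergeTechnicalReplicates(pt, reps))
  for (i in seq_len(nrow(X))) {
    for (s in c("A", "B")) {
      v <- X[i, reps == s]
      got <- m[i, s]
      if (is.na(got)) { expect_true(all(is.na(v))); next }
      if (got == 0 && !any(v[!is.na(v)] == 0)) next   # sentinel
      expect_gte(got, min(v, na.rm = TRUE))
      expect_lte(got, max(v, na.rm = TRUE))
    }
  }
})

test_that("background filtering excludes long consecutive runs", {
  mkCent <- function(scans, mz = 200) data.frame(scan_index = scans, mz = mz)
  # run of 60 >= ceil(0.5 * 100): excluded
  res <- filterBackgroundFeatures(mkCent(0:59), n_scans = 100)
  expect_length(res$excluded, 1L)
  expect_length(res$kept, 0L)
  # 10 scattered scans, longest run < 50: kept
  res <- filterBackgroundFeatures(mkCent(seq(0, 90, by = 10)), n_scans = 100)
  expect_length(res$kept, 1L)
  # runs 49 and 49 separated by one absent scan: kept
  res <- filterBackgroundFeatures(mkCent(c(0:48, 50:98)), n_scans = 100)
  expect_length(res$kept, 1L)
  expect_equal(res$bins$longest_run, 49L)
  # empty stream
  res <- filterBackgroundFeatures(data.frame(scan_index = integer(),
                                             mz = numeric()), n_scans = 100)
  expect_length(res$kept, 0L)
  expect_length(res$excluded, 0L)
})

test_that("background filtering partitions bins and is monotone in run_fraction", {
  set.seed(5)
  cent <- data.frame(
    scan_index = sample(0:99, 400, replace = TRUE),
    mz = sample(c(100.0, 100.5, 200.0, 350.1), 400, replace = TRUE) *
      (1 + rnorm(400, 0, 2e-6)))
  res5 <- filterBackgroundFeatures(cent, 100, run_fraction = 0.5)
  expect_equal(sort(c(res5$kept, res5$excluded)), sort(res5$bins$mz_center))
  expect_length(intersect(res5$kept, res5$excluded), 0L)
  res2 <- filterBackgroundFeatures(cent, 100, run_fraction = 0.2)
  # smaller fraction excludes a superset of bins
  expect_true(all(res5$excluded %in% res2$excluded))
})

test_that("feature ranking performs Welch tests on log intensities", {
  groups <- rep(c("g1", "g2"), each = 4)
  # identical values in both groups: no effect
  X <- rbind(rep(5, 8),
             c(10, 10, 10, 10, 20, 20, 20, 20) + seq(0, 7e-7, by = 1e-7))
  pt <- mkTable(X, paste0("s", 1:8), groups = groups)
  rp <- rankFeatures(pt)
  df <- peakData(rp)
  flat <- df[df$mz == 100, ]
  expect_equal(flat$p_value, 1)
  expect_equal(flat$statistic, 0)
  sep <- df[df$mz == 110, ]
  expect_lt(sep$p_value, 1e-6)
  expect_lt(sep$statistic, 0)        # group1 - group2 orientation
  # agreement with stats::t.test on a non-degenerate feature
  set.seed(21)
  Y <- matrix(rlnorm(8 * 10), 10, 8)
  pty <- mkTable(Y, paste0("s", 1:8), groups = groups)
  got <- peakData(rankFeatures(pty))
  i <- which.min(got$mz)  # feature 1 is mz 100
  ref <- t.test(log(Y[1, 1:4] + 1), log(Y[1, 5:8] + 1))
  expect_equal(got$p_value[got$mz == 100], unname(ref$p.value))
  expect_equal(got$statistic[got$mz == 100], unname(ref$statistic))
})

test_that("feature ranking drops underpowered features and checks groups", {
  X <- matrix(rlnorm(12), 3, 4)
  X[2, 1:3] <- NA  # only one value left in group 1
  pt <- mkTable(X, paste0("s", 1:4), groups = c("a", "a", "b", "b"))
  rp <- rankFeatures(pt)
  expect_equal(nrow(peakData(rp)), 2L)
  expect_equal(attr(rp, "dropped"), 1L)
  pt3 <- mkTable(X, paste0("s", 1:4), groups = c("a", "b", "c", "c"))
  expect_error(rankFeatures(pt3), "contrast")
})

test_that("ranking p-values are invariant to sample permutation within groups", {
  set.seed(31)
  X <- matrix(rlnorm(60), 5, 12)
  groups <- rep(c("g1", "g2"), each = 6)
  pt <- mkTable(X, paste0("s", 1:12), groups = groups)
  perm <- c(sample(1:6), sample(7:12))
  ptp <- mkTable(X[, perm], paste0("s", 1:12), groups = groups)
  expect_equal(peakData(rankFeatures(pt))$p_value,
               peakData(rankFeatures(ptp))$p_value)
})

test_that("null tables give a uniform p-value fraction near the cutoff", {
  set.seed(41)
  X <- matrix(rlnorm(200 * 12), 200, 12)
  pt <- mkTable(X, paste0("s", 1:12), groups = rep(c("g1", "g2"), each = 6))
  p <- peakData(rankFeatures(pt))$p_value
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
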