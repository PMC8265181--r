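test_that("adduct m/z prediction matches hand arithmetic", {
  expect_equal(predictedMz(180.06339, 1, PROTON, 1), 181.070666,
               tolerance = 1e-9)
  expect_equal(predictedMz(180.06339, 1, 2 * PROTON, 2), 91.038971,
               tolerance = 1e-8)
  expect_identical(predictedMz(123.456, 1, 0, 1), 123.456)
})

test_that("peak annotation respects the ppm tolerance and currency flag", {
  db <- tinyDb()
  rules <- defaultAdductRules("positive")
  hit <- annotatePeaks(mkRanked(181.070666), db, rules, ppm_tol = 5)
  m <- annotationMatches(hit)
  expect_equal(m$compound_id, "glc")
  expect_equal(m$adduct, "M+H")
  expect_lt(abs(m$ppm_error), 1e-6)
  # ~51 ppm off: no match
  miss <- annotatePeaks(mkRanked(181.080000), db, rules, ppm_tol = 5)
  expect_equal(nrow(annotationMatches(miss)), 0L)
  # currency-only database
  cur <- CompoundDb("h2o", 18.010565, currency = "h2o")
  water <- mkRanked(predictedMz(18.010565, 1, PROTON, 1))
  expect_length(annotatedCompounds(annotatePeaks(water, cur, rules)), 0L)
  kept <- annotatePeaks(water, cur, rules, drop_currency = FALSE)
  expect_equal(annotatedCompounds(kept), "h2o")
  expect_error(annotatePeaks(mkRanked(100, mode = "negative"), db,
                             rules[rules$mode == "positive", ]), "negative")
})

test_that("annotation equals brute-force enumeration on random databases", {
  rules <- defaultAdductRules("positive")
  for (s in 1:25) {
    set.seed(s)
    nC <- sample(5:50, 1)
    db <- CompoundDb(sprintf("C%03d", seq_len(nC)), runif(nC, 80, 800),
                     currency = sprintf("C%03d", sample(nC, 2)))
    nP <- sample(20:200, 1)
    realIdx <- sample(nC, ceiling(nP / 2), replace = TRUE)
    ri <- sample(nrow(rules), ceiling(nP / 2), replace = TRUE)
    mzReal <- predictedMz(unname(compoundMasses(db))[realIdx], rules$nmer[ri],
                          rules$mass_shift[ri], rules$charge[ri]) *
      (1 + rnorm(length(realIdx), 0, 3e-6))
    mz <- c(mzReal, runif(nP - length(mzReal), 80, 800))
    peaks <- mkRanked(unique(mz))
    got <- annotationMatches(annotatePeaks(peaks, db, rules, ppm_tol = 5))
    want <- bruteAnnotate(peaks, db, rules, ppm_tol = 5)
    expect_identical(matchKey(got), matchKey(want))
  }
})

test_that("annotation match count is monotone in ppm tolerance", {
  set.seed(77)
  db <- CompoundDb(sprintf("C%02d", 1:30), runif(30, 80, 800))
  peaks <- mkRanked(runif(150, 80, 820))
  rules <- defaultAdductRules("positive")
  counts <- vapply(c(1, 5, 20, 100, 500),
                   function(tol) nrow(annotationMatches(
                     annotatePeaks(peaks, db, rules, ppm_tol = tol))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("empirical compounds merge co-eluting adducts and split RT clusters", {
  db <- CompoundDb("glc", 180.06339)
  rules <- defaultAdductRules("positive")
  mzMH <- predictedMz(180.06339, 1, PROTON, 1)
  mzNa <- predictedMz(180.06339, 1, 22.989218, 1)
  # co-eluting M+H / M+Na at 35.1 and 35.3 s: one EC with 2 member peaks
  peaks <- mkRanked(c(mzMH, mzNa), rt = c(35.1, 35.3))
  ecs <- buildEmpiricalCompounds(annotatePeaks(peaks, db, rules), peaks,
                                 rt_tol = 5)
  expect_equal(nrow(empiricalCompounds(ecs)), 1L)
  expect_equal(empiricalCompounds(ecs)$n_peaks, 2L)
  # same compound at rt 35 and 300: two ECs
  far <- mkRanked(c(mzMH, mzNa), rt = c(35, 300))
  ecs2 <- buildEmpiricalCompounds(annotatePeaks(far, db, rules), far,
                                  rt_tol = 5)
  expect_equal(nrow(empiricalCompounds(ecs2)), 2L)
  # single-linkage chains through intermediate peaks
  chain <- mkRanked(c(mzMH, mzNa, predictedMz(180.06339, 1, 38.963158, 1)),
                    rt = c(10, 14, 18))
  ecs3 <- buildEmpiricalCompounds(annotatePeaks(chain, db, rules), chain,
                                  rt_tol = 5)
  expect_equal(nrow(empiricalCompounds(ecs3)), 1L)
  # missing rt is an error pointing at the v1 path
  noRt <- mkRanked(mzMH)
  expect_error(buildEmpiricalCompounds(annotatePeaks(noRt, db, rules), noRt,
                                       rt_tol = 5), "v1")
})

test_that("empirical compounds partition the matches", {
  fix <- plantedFixture(3)
  rp <- rankFeatures(fix$gen$table)
  ann <- annotatePeaks(rp, fix$db)
  ecs <- buildEmpiricalCompounds(ann, rp)
  m <- annotationMatches(ecs)
  expect_equal(nrow(m), nrow(annotationMatches(ann)))
  expect_true(all(nzchar(m$ec_id)))
  # each match carries exactly one ec_id and sizes add up
  expect_equal(sum(table(m$ec_id) > 0), nrow(empiricalCompounds(ecs)))
})

test_that("compound name normalization canonicalizes lipid shorthand", {
  expect_equal(normalizeCompoundName("PC (16:0/18:1)"), "pc(16:0/18:1)")
  expect_equal(normalizeCompoundName("PC(16:0/18:1)"), "pc(16:0/18:1)")
  expect_equal(normalizeCompoundName("pc 16:0/18:1"), "pc(16:0/18:1)")
  expect_equal(normalizeCompoundName("PC 16:0_18:1"), "pc(16:0_18:1)")
  expect_equal(normalizeCompoundName("PC [16:0/18:1]"), "pc(16:0/18:1)")
  expect_equal(normalizeCompoundName("Glucose"), "glucose")
  expect_equal(normalizeCompoundName("  alpha   D  Glucose "),
               "alpha d glucose")
  # idempotent on a battery of inputs
  raw <- c("PC (16:0/18:1)", "pc 18:2_20:4", "TG{54:2}", "Glucose",
           "weird  name (x) ", "PE 36:2")
  once <- normalizeCompoundName(raw)
  expect_identical(normalizeCompoundName(once), once)
})

test_that("name matching honours the exact > synonym > normalized priority", {
  db <- CompoundDb(ids = c("glc", "pc1"),
                   masses = c(180.06339, 759.57797),
                   names = c("Glucose", "PC(16:0/18:1)"),
                   synonyms = list(c("Dextrose"), character()))
  res <- matchNames(c("Glucose", "Dextrose", "PC (16:0/18:1)", "unobtainium"),
                    db)
  expect_equal(res$compound_id, c("glc", "glc", "pc1", NA))
  expect_equal(res$match_type, c("exact", "synonym", "normalized", "none"))
})
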