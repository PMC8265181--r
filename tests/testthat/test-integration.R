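test_that("Fisher combination matches the chi-square closed form", {
  got <- combineFisher(c(0.05, 0.05))
  x <- -4 * log(0.05)
  expect_equal(got$statistic, x, tolerance = 1e-10)
  # df = 4 survival closed form exp(-x/2) (1 + x/2)
  expect_equal(got$p_combined, exp(-x / 2) * (1 + x / 2), tolerance = 1e-10)
  expect_equal(round(got$p_combined, 6), 0.017479)
  expect_equal(combineFisher(c(1, 1)),
               list(statistic = 0, p_combined = 1))
  # df-2 identity: a single p passes through
  expect_equal(combineFisher(0.3)$p_combined, 0.3, tolerance = 1e-12)
  expect_warning(z <- combineFisher(c(0, 0.5)), "clamped")
  expect_lte(z$p_combined, 1e-100)
})

test_that("Stouffer combination matches the normal closed form", {
  got <- combineStouffer(c(0.05, 0.05))
  expect_equal(got$statistic, sqrt(2) * qnorm(0.95), tolerance = 1e-10)
  expect_equal(got$p_combined, pnorm(sqrt(2) * qnorm(0.95), lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(got$p_combined, 4), 0.0100)
  # one-hot weights return the selected p
  expect_equal(combineStouffer(c(0.37, 0.9), c(1, 0))$p_combined, 0.37,
               tolerance = 1e-12)
  # weighted example: (0.8 z(0.01) + 0.2 z(0.5)) / sqrt(0.68)
  got <- combineStouffer(c(0.01, 0.5), c(0.8, 0.2))
  zc <- 0.8 * qnorm(0.99) / sqrt(0.8^2 + 0.2^2)
  expect_equal(got$statistic, zc, tolerance = 1e-10)
  expect_equal(got$p_combined, pnorm(zc, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(got$p_combined, 4), 0.0120)
  expect_warning(combineStouffer(c(0, 1)), "clamped")
})

test_that("both combiners are permutation-invariant and monotone", {
  set.seed(8)
  for (i in 1:20) {
    ps <- runif(sample(2:6, 1))
    w <- runif(length(ps))
    perm <- sample(length(ps))
    expect_equal(combineFisher(ps)$p_combined,
                 combineFisher(ps[perm])$p_combined)
    expect_equal(combineStouffer(ps, w)$p_combined,
                 combineStouffer(ps[perm], w[perm])$p_combined)
    # decreasing one input cannot increase the combination
    j <- sample(length(ps), 1)
    ps2 <- ps; ps2[j] <- ps[j] / 2
    expect_lte(combineFisher(ps2)$p_combined, combineFisher(ps)$p_combined)
    expect_lte(combineStouffer(ps2, w)$p_combined,
               combineStouffer(ps, w)$p_combined)
    # evidence accumulates across k copies of a small p (for mediocre p
    # near 1 Fisher correctly *increases* the combined p)
    p <- runif(1, 0.001, 0.1)
    expect_lte(combineFisher(rep(p, 3))$p_combined, p)
  }
})

mkJointLib <- function() {
  PathwayLibrary(
    ids = c("P1", "P2", "P3"),
    compounds = list(c("m1", "m2"), c("m3", "m4", "m5"), character()),
    genes = list(sprintf("g%d", 1:8), sprintf("g%d", 9:12), sprintf("g%d", 13:16)))
}

test_that("joint pathway analysis weights omics as specified", {
  lib <- mkJointLib()
  q <- omicsQuery(gene_hits = c("g1", "g2", "g3"), metabolite_hits = "m1",
                  G = 16, C = 5)
  res <- jointPathwayAnalysis(q, lib, method = "stouffer_pathway")
  p1 <- res[res$pathway_id == "P1", ]
  # P1 has 8 genes and 2 compounds: weights 0.8 / 0.2
  expect_equal(c(p1$w_gene, p1$w_met), c(0.8, 0.2))
  expect_equal(p1$p_combined,
               combineStouffer(c(p1$p_gene, p1$p_met), c(0.8, 0.2))$p_combined)
  # a pathway with no compounds takes the gene p directly
  p3 <- res[res$pathway_id == "P3", ]
  expect_equal(p3$p_combined, p3$p_gene)
  # single-omics modes skip combination
  g <- jointPathwayAnalysis(q, lib, library_mode = "gene_only")
  expect_equal(g$p_combined, g$p_gene)
  m <- jointPathwayAnalysis(q, lib, library_mode = "metabolite_only")
  expect_equal(m$p_combined, m$p_met)
  expect_error(jointPathwayAnalysis(omicsQuery(), lib), "empty")
})

test_that("pathway-level weights reduce to overall weights at the global ratio", {
  # every pathway with gene:metabolite ratio 3:1 equal to the global ratio
  lib <- PathwayLibrary(
    ids = c("A", "B"),
    compounds = list(c("m1"), c("m2")),
    genes = list(sprintf("g%d", 1:3), sprintf("g%d", 4:6)))
  q <- omicsQuery(gene_hits = c("g1", "g4"), metabolite_hits = "m1",
                  G = 6, C = 2)
  a <- jointPathwayAnalysis(q, lib, method = "stouffer_pathway")
  b <- jointPathwayAnalysis(q, lib, method = "stouffer_overall")
  expect_equal(a$p_combined, b$p_combined)
})

test_that("fisher and equal-weight stouffer rank identically on equal omics p", {
  set.seed(17)
  # mirrored pathways: gene and metabolite structures identical so
  # p_gene == p_met per pathway, G == C
  n <- 20
  cpds <- lapply(1:n, function(i) sprintf("m%d_%d", i, 1:4))
  genes <- lapply(1:n, function(i) sprintf("g%d_%d", i, 1:4))
  lib <- PathwayLibrary(sprintf("P%02d", 1:n), compounds = cpds, genes = genes)
  hitIdx <- lapply(1:n, function(i) sample(0:4, 1))
  mh <- unlist(lapply(1:n, function(i)
    if (hitIdx[[i]] > 0) cpds[[i]][seq_len(hitIdx[[i]])] else character()))
  gh <- sub("^m", "g", mh)
  q <- omicsQuery(gh, mh, G = 4 * n, C = 4 * n)
  f <- jointPathwayAnalysis(q, lib, method = "fisher")
  s <- jointPathwayAnalysis(q, lib, method = "stouffer_overall")
  expect_equal(f[, c("p_gene", "p_met")], s[, c("p_gene", "p_met")])
  expect_equal(f$pathway_id, s$pathway_id)
})

test_that("pathway-level meta-analysis integrates and flags datasets", {
  r1 <- mkEnrichResult(c("P1", "P2"), c(0.05, 0.5))
  r2 <- mkEnrichResult(c("P1", "P3"), c(0.05, 0.01))
  res <- metaPathwayLevel(list(a = r1, b = r2), method = "fisher")
  p1 <- res[res$pathway_id == "P1", ]
  x <- -4 * log(0.05)
  expect_equal(p1$p_integrated, exp(-x / 2) * (1 + x / 2), tolerance = 1e-9)
  expect_true(p1$sig_a && p1$sig_b)
  # P2 significant nowhere, present only in dataset a
  p2 <- res[res$pathway_id == "P2", ]
  expect_false(p2$sig_a || p2$sig_b)
  expect_true(p2$present_a && !p2$present_b)
  # absent pathway contributes p = 1: integrated never beats the single p
  p3 <- res[res$pathway_id == "P3", ]
  expect_gte(p3$p_integrated, 0.01)
  expect_error(metaPathwayLevel(list(r1)), "2 datasets")
  st <- metaPathwayLevel(list(a = r1, b = r2), method = "stouffer")
  expect_true(all(st$p_integrated >= 0 & st$p_integrated <= 1))
})

test_that("peak pooling unions complementary annotations", {
  db <- CompoundDb(c("A", "B"), c(180.06339, 255.53))
  lib <- PathwayLibrary("P1", compounds = list(c("A", "B")))
  bgPos <- seq(500.123, 500.723, by = 0.0667)  # un-annotatable filler
  posMz <- c(predictedMz(180.06339, 1, PROTON, 1), bgPos)
  negMz <- c(predictedMz(255.53, 1, -PROTON, 1), bgPos)
  pos <- RankedPeakList(posMz, p_value = c(0.01, rep(0.6, length(bgPos))),
                        statistic = rep(1, length(posMz)), mode = "positive")
  neg <- RankedPeakList(negMz, p_value = c(0.01, rep(0.6, length(bgPos))),
                        statistic = rep(1, length(negMz)), mode = "negative")
  cfg <- enrichmentConfig(seed = 1)
  pooled <- suppressWarnings(metaPeakPooling(list(pos, neg), db, lib,
                                             cfg = cfg))
  expect_equal(resultTable(pooled)$hits_sig, 2L)
  single <- suppressWarnings(mummichogEnrich(pos, db, lib, cfg = cfg))
  expect_equal(resultTable(single)$hits_sig, 1L)
  # pooling a list with itself under a distinct mode tag is idempotent:
  # the re-tagged copy annotates nothing new and the union is unchanged
  neg2 <- RankedPeakList(posMz, p_value = c(0.01, rep(0.6, length(bgPos))),
                         statistic = rep(1, length(posMz)), mode = "negative")
  twice <- suppressWarnings(metaPeakPooling(list(pos, neg2), db, lib,
                                            cfg = cfg))
  expect_equal(resultTable(twice)$hits_sig, resultTable(single)$hits_sig)
  expect_equal(resultTable(twice)$hits_total, resultTable(single)$hits_total)
  # conflicting duplicates (same mz, rt and mode in two lists) are rejected
  expect_error(metaPeakPooling(list(pos, pos), db, lib, cfg = cfg),
               "duplicate")
})

test_that("pooling complementary modes sharpens the planted pathway", {
  wins <- vapply(1:5, function(s) {
    spec <- fixtureSpec(seed = s)
    db <- generateCompoundDb(spec)
    lib <- generatePathwayLibrary(db, spec)
    comp <- generateComplementaryPeakTables(db, lib, spec)
    cfg <- enrichmentConfig(seed = s)
    gp <- function(res) {
      tb <- resultTable(res)
      tb$gamma_p[match(comp$active_pathways, tb$pathway_id)]
    }
    rpos <- rankFeatures(comp$positive$table)
    rneg <- rankFeatures(comp$negative$table)
    pooled <- gp(metaPeakPooling(list(rpos, rneg), db, lib, cfg = cfg))
    pooled < min(gp(mummichogEnrich(rpos, db, lib, cfg = cfg)),
                 gp(mummichogEnrich(rneg, db, lib, cfg = cfg)), na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})
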