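# Shared in-code fixtures and independent oracles.

PROTON <- 1.007276

tinyDb <- function() {
  CompoundDb(
    ids = c("glc", "ala", "h2o"),
    masses = c(180.06339, 89.04768, 18.010565),
    names = c("Glucose", "Alanine", "Water"),
    synonyms = list(c("Dextrose", "alpha-D-Glucose"), character(), character()),
    currency = "h2o")
}

writeTmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

mkRanked <- function(mz, p = rep(0.5, length(mz)), t = rep(1, length(mz)),
                     rt = NULL, mode = "positive") {
  RankedPeakList(mz = mz, p_value = p, statistic = t, rt = rt, mode = mode)
}

# brute-force annotation oracle: enumerate every (peak, compound, rule)
# triple directly from the adduct formula
bruteAnnotate <- function(peaks, db, rules, ppm_tol, drop_currency = TRUE) {
  pk <- peakData(peaks)
  ids <- compoundIds(db)
  mass <- unname(compoundMasses(db))
  if (drop_currency) {
    keep <- !(ids %in% currencyIds(db))
    ids <- ids[keep]; mass <- mass[keep]
  }
  grid <- expand.grid(pi = seq_len(nrow(pk)), ci = seq_along(ids),
                      ri = seq_len(nrow(rules)))
  pred <- (rules$nmer[grid$ri] * mass[grid$ci] +
             rules$mass_shift[grid$ri]) / abs(rules$charge[grid$ri])
  err <- (pk$mz[grid$pi] - pred) / pred * 1e6
  hit <- abs(err) <= ppm_tol
  data.frame(feature_index = grid$pi[hit], compound_id = ids[grid$ci[hit]],
             adduct = rules$name[grid$ri[hit]])
}

matchKey <- function(df) sort(paste(df$feature_index, df$compound_id, df$adduct))

# exact combinatorial EASE oracle: P(X >= k - 1), k = 0 -> 1
easeOracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  lo <- max(k - 1, 0, n - (N - K))
  hi <- min(n, K)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

# minimal enrichment result for meta-analysis tests
mkEnrichResult <- function(ids, gamma_p, ease_p = gamma_p) {
  new("EnrichmentResult",
      table = data.frame(pathway_id = ids, pathway_name = ids,
                         pathway_size = 10L, hits_total = 10L, hits_sig = 1L,
                         ease_p = ease_p, gamma_p = gamma_p),
      config = list(), gammaFit = list())
}

# small deterministic fixture chain for pipeline tests
plantedFixture <- function(seed, effect_size = 2) {
  spec <- fixtureSpec(seed = seed, effect_size = effect_size)
  db <- generateCompoundDb(spec)
  lib <- generatePathwayLibrary(db, spec)
  gen <- generatePeakTable(db, lib, spec)
  list(spec = spec, db = db, lib = lib, gen = gen)
}
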