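## Pathway activity prediction from annotated peaks: the mummichog v1/v2
## core with a permutation-calibrated Gamma null, plus enrichment of
## arbitrary user-selected peak groups.

#' Enrichment configuration
#'
#' @param sig_cutoff p-value threshold defining significant peaks, in (0,1).
#' @param n_permutations number of peak-list permutations (>= 20).
#' @param seed RNG seed for the permutations.
#' @param version `"v1"` (compound-level counting, m/z only) or `"v2"`
#'   (empirical-compound counting, requires retention times).
#' @param min_pathway_hits pathways with fewer annotatable members are
#'   dropped from the result.
#' @param ppm_tol annotation tolerance in ppm.
#' @param rt_tol empirical-compound retention-time tolerance (seconds);
#'   `NULL` = 1 percent of the observed RT range.
#' @return list of validated settings.
#' @export
enrichmentConfig <- function(sig_cutoff = 0.05, n_permutations = 100,
                             seed = 42, version = c("v1", "v2"),
                             min_pathway_hits = 1, ppm_tol = 5,
                             rt_tol = NULL) {
  version <- match.arg(version)
  stopifnot(sig_cutoff > 0, sig_cutoff < 1, n_permutations >= 20,
            min_pathway_hits >= 0)
  list(sig_cutoff = sig_cutoff, n_permutations = as.integer(n_permutations),
       seed = as.integer(seed), version = version,
       min_pathway_hits = as.integer(min_pathway_hits), ppm_tol = ppm_tol,
       rt_tol = rt_tol)
}

#' EASE-adjusted hypergeometric overlap p-value
#'
#' Right-tail hypergeometric probability `P(X >= k - 1)` for an overlap of
#' `k` out of `n_sig` significant units against a pathway of annotatable
#' size `K` in a universe of size `N` — the conservative EASE variant that
#' discounts one overlapping member. `k = 0` returns 1.
#'
#' @param k observed overlap; vectorized.
#' @param n_sig number of significant (drawn) units.
#' @param K pathway annotatable size.
#' @param N universe annotatable size.
#' @return p-value(s) in \[0,1\].
#' @examples
#' easePvalue(5, 5, 5, 10)  # 26/252
#' @export
easePvalue <- function(k, n_sig, K, N) {
  if (any(K > N) || any(n_sig > N) || any(k > pmin(n_sig, K)) || any(k < 0))
    stop("inconsistent counts: need 0 <= k <= min(n_sig, K) and K <= N",
         call. = FALSE)
  p <- phyper(k - 2, K, N - K, n_sig, lower.tail = FALSE)
  p[k == 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' Fit a Gamma null to permutation p-values
#'
#' Transforms the pooled permutation p-values as `s = -ln(p)` and fits a
#' Gamma(shape, scale) with location fixed at 0 by maximum likelihood.
#' Permutation EASE p-values contain a point mass at exactly 1 (pathways
#' with zero overlap in a permutation), i.e. `s = 0`, where a Gamma
#' likelihood is unbounded; the fit therefore uses the positive part and
#' records its proportion, and the tail probability is the mixture
#' `P(S >= s) = prop_positive * P(Gamma >= s)` for `s > 0` (and 1 at
#' `s = 0`). With no mass at 1 this is exactly the plain Gamma fit. A
#' degenerate null (all values identical, or too few positive values) falls
#' back to the empirical tail with a warning.
#'
#' @param null_p pooled permutation p-values in (0, 1\]; at least 100.
#' @return list with `method` (`"gamma"` or `"empirical"`), `shape`,
#'   `scale`, `location` (0), `prop_positive`, and for the empirical
#'   fallback the retained null scores.
#' @export
fitGammaNull <- function(null_p) {
  if (length(null_p) < 100)
    stop("need at least 100 pooled null values", call. = FALSE)
  if (any(null_p <= 0 | null_p > 1))
    stop("null p-values must lie in (0, 1]", call. = FALSE)
  s <- -log(null_p)
  degenerate <- length(unique(s)) == 1L
  sPos <- s[s > 0]
  propPos <- length(sPos) / length(s)
  fit <- NULL
  if (!degenerate && length(sPos) >= 20 && sd(sPos) > 0) {
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(sPos, "gamma")),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    warning("degenerate permutation null; falling back to the empirical tail")
    return(list(method = "empirical", null_s = s, shape = NA_real_,
                scale = NA_real_, location = 0, prop_positive = propPos))
  }
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  list(method = "gamma", shape = shape, scale = 1 / rate, location = 0,
       prop_positive = propPos)
}

#' Upper-tail probability of an observed p-value under a fitted null
#'
#' @param fit result of [fitGammaNull()].
#' @param p_obs observed EASE p-value(s).
#' @return `P(S >= -ln(p_obs))` under the fitted null.
#' @export
gammaTailP <- function(fit, p_obs) {
  s <- -log(pmin(pmax(p_obs, .Machine$double.xmin), 1))
  if (fit$method == "empirical") {
    n <- length(fit$null_s)
    out <- vapply(s, function(si) (sum(fit$null_s >= si) + 1) / (n + 1), 0)
  } else {
    out <- fit$prop_positive *
      pgamma(s, shape = fit$shape, scale = fit$scale, lower.tail = FALSE)
  }
  out[s <= 0] <- 1
  pmin(pmax(out, 0), 1)
}

## Shared permutation engine.
## memberMat: 0/1 matrix, peaks x universe units (a unit is a compound for
## v1, an empirical compound for v2). unitSets: list of integer unit-index
## vectors per pathway. sigIdx: indices of significant peaks.
.runEnrichment <- function(memberMat, unitSets, sigIdx, n_permutations, seed) {
  nPeaks <- nrow(memberMat)
  N <- ncol(memberMat)
  K <- lengths(unitSets)
  U <- matrix(0, N, length(unitSets))
  for (j in seq_along(unitSets)) U[unitSets[[j]], j] <- 1
  score <- function(idx) {
    sigUnits <- as.numeric(colSums(memberMat[idx, , drop = FALSE]) > 0)
    nSig <- sum(sigUnits)
    k <- as.vector(crossprod(sigUnits, U))
    list(k = k, nSig = nSig,
         p = easePvalue(k, nSig, K, N))
  }
  obs <- score(sigIdx)
  nullP <- matrix(NA_real_, n_permutations, length(unitSets))
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(nPeaks, length(sigIdx))
    nullP[b, ] <- score(idx)$p
  }
  fit <- fitGammaNull(as.vector(nullP))
  list(K = K, k = obs$k, nSig = obs$nSig, ease_p = obs$p,
       gamma_p = gammaTailP(fit, obs$p), fit = fit)
}

## Build the peaks x units membership matrix and per-pathway unit sets.
## Returns NULL unit info when there are no matches.
.annotationUnits <- function(ann, peaks, lib, version, rt_tol) {
  m <- annotationMatches(ann)
  if (nrow(m) == 0L) return(NULL)
  if (version == "v2") {
    ecs <- buildEmpiricalCompounds(ann, peaks, rt_tol = rt_tol)
    mm <- annotationMatches(ecs)
    unitIds <- empiricalCompounds(ecs)$ec_id
    unitCompound <- empiricalCompounds(ecs)$compound_id
    unitOf <- match(mm$ec_id, unitIds)
    featureOf <- mm$feature_index
  } else {
    unitIds <- sort(unique(m$compound_id))
    unitCompound <- unitIds
    unitOf <- match(m$compound_id, unitIds)
    featureOf <- m$feature_index
  }
  memberMat <- matrix(0, max(featureOf), length(unitIds))
  memberMat[cbind(featureOf, unitOf)] <- 1
  unitSets <- lapply(seq_along(lib@ids), function(j)
    which(unitCompound %in% lib@compounds[[j]]))
  list(memberMat = memberMat, unitIds = unitIds, unitCompound = unitCompound,
       unitSets = unitSets)
}

#' Predict pathway activity from a ranked peak list (mummichog)
#'
#' Runs the full mummichog-style pipeline: putative annotation of all peaks
#' ([annotatePeaks()]), counting at the compound level (v1) or the
#' empirical-compound level after retention-time grouping (v2), an
#' EASE-adjusted hypergeometric overlap test of the significant peaks'
#' annotations per pathway, and calibration of the observed p-value against
#' a permutation null: for each permutation, `|Lsig|` peaks are drawn
#' uniformly without replacement from the full peak list, their annotations
#' are scored identically, and a Gamma distribution fitted to the pooled
#' null yields `gamma_p` ([fitGammaNull()]). The universe is the set of
#' units annotatable from the input peak list (what the instrument could
#' see), not the whole database.
#'
#' @param peaks a [RankedPeakList-class].
#' @param db a [CompoundDb-class].
#' @param lib a [PathwayLibrary-class].
#' @param rules adduct rules (default: rules for the peak list's mode).
#' @param cfg an [enrichmentConfig()] list.
#' @param explicit_sig optional integer indices (rows of `peakData(peaks)`)
#'   defining the peak group of interest, overriding the p-value cutoff —
#'   this supports enrichment of any selected peak group, e.g. a heatmap
#'   cluster.
#' @return An [EnrichmentResult-class] sorted by `gamma_p` (ties: `ease_p`,
#'   then pathway id).
#' @export
mummichogEnrich <- function(peaks, db, lib,
                            rules = defaultAdductRules(ionMode(peaks)),
                            cfg = enrichmentConfig(),
                            explicit_sig = NULL) {
  stopifnot(is(peaks, "RankedPeakList"), is(db, "CompoundDb"),
            is(lib, "PathwayLibrary"))
  if (cfg$version == "v2" && !hasRt(peaks))
    stop("mummichog v2 requires retention times; use version = 'v1'",
         call. = FALSE)
  pk <- peakData(peaks)
  sigIdx <- if (is.null(explicit_sig)) which(pk$p_value <= cfg$sig_cutoff)
            else sort(unique(as.integer(explicit_sig)))
  if (length(sigIdx) == 0L)
    stop("no significant peaks at the chosen cutoff", call. = FALSE)
  ann <- annotatePeaks(peaks, db, rules, ppm_tol = cfg$ppm_tol)
  units <- .annotationUnits(ann, peaks, lib, cfg$version, cfg$rt_tol)
  if (is.null(units))
    stop("no annotation possible: no peak matched any database compound",
         call. = FALSE)
  ## pad membership matrix to the full peak count so permutations draw from
  ## the entire peak list (unannotated peaks contribute nothing)
  memberMat <- matrix(0, nrow(pk), length(units$unitIds))
  memberMat[seq_len(nrow(units$memberMat)), ] <- units$memberMat
  res <- .runEnrichment(memberMat, units$unitSets, sigIdx,
                        cfg$n_permutations, cfg$seed)
  tb <- data.frame(pathway_id = lib@ids, pathway_name = lib@pathwayNames,
                   pathway_size = res$K, hits_total = res$K,
                   hits_sig = as.integer(res$k), ease_p = res$ease_p,
                   gamma_p = res$gamma_p)
  tb <- tb[tb$hits_total >= max(cfg$min_pathway_hits, 1L), , drop = FALSE]
  tb <- tb[order(tb$gamma_p, tb$ease_p, tb$pathway_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("EnrichmentResult", table = tb,
      config = c(cfg, list(n_sig_peaks = length(sigIdx),
                           n_sig_units = res$nSig,
                           universe_size = length(units$unitIds))),
      gammaFit = res$fit)
}
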