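## Joint gene+metabolite pathway analysis via weighted p-value combination,
## and functional meta-analysis across multiple peak tables.

.clampP <- function(ps, what = "p-value") {
  eps <- .Machine$double.xmin
  if (any(ps <= 0)) {
    warning(sprintf("%s of 0 clamped to smallest positive representable", what))
    ps[ps <= 0] <- eps
  }
  ps
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(ln p_i)` referred to a chi-square distribution with `2k`
#' degrees of freedom. One-sided throughout: small p-values accumulate
#' evidence.
#'
#' @param ps p-values in (0, 1\]; zeros are clamped with a warning.
#' @return list with `statistic` (X2) and `p_combined`.
#' @examples
#' combineFisher(c(0.05, 0.05))$p_combined  # ~0.01748
#' @export
combineFisher <- function(ps) {
  stopifnot(length(ps) >= 1, all(ps <= 1))
  ps <- .clampP(ps)
  x2 <- -2 * sum(log(ps))
  list(statistic = x2,
       p_combined = pchisq(x2, df = 2 * length(ps), lower.tail = FALSE))
}

#' Combine p-values with the weighted Stouffer Z-score method
#'
#' `Z_i = qnorm(1 - p_i)`; `Z_c = sum(w_i Z_i) / sqrt(sum(w_i^2))`;
#' `p = 1 - pnorm(Z_c)`. With a one-hot weight vector the corresponding
#' input p-value is returned unchanged.
#'
#' @param ps p-values; values of exactly 0 or 1 are clamped into the open
#'   interval with a warning.
#' @param weights non-negative weights, not all zero, same length as `ps`;
#'   default equal.
#' @return list with `statistic` (Z_c) and `p_combined`.
#' @examples
#' combineStouffer(c(0.05, 0.05))$p_combined  # ~0.0100
#' @export
combineStouffer <- function(ps, weights = rep(1, length(ps))) {
  stopifnot(length(ps) >= 1, length(weights) == length(ps),
            all(weights >= 0), sum(weights) > 0)
  eps <- 1e-300
  if (any(ps <= 0 | ps >= 1)) {
    warning("p-values at 0 or 1 clamped into the open interval")
    ps <- pmin(pmax(ps, eps), 1 - 1e-16)
  }
  z <- qnorm(ps, lower.tail = FALSE)
  zc <- sum(weights * z) / sqrt(sum(weights^2))
  list(statistic = zc, p_combined = pnorm(zc, lower.tail = FALSE))
}

## plain hypergeometric over-representation p (no EASE adjustment):
## P(X >= k) for k hits out of n drawn, against K of N.
.oraP <- function(k, n, K, N) {
  if (K == 0 || n == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a joint gene + metabolite query
#'
#' @param gene_hits,metabolite_hits character vectors of identified hits.
#' @param G,C background universe sizes (genes, metabolites); default: the
#'   pathway-library universes at analysis time.
#' @return list describing the query.
#' @export
omicsQuery <- function(gene_hits = character(), metabolite_hits = character(),
                       G = NULL, C = NULL) {
  list(gene_hits = unique(as.character(gene_hits)),
       metabolite_hits = unique(as.character(metabolite_hits)),
       G = G, C = C)
}

#' Joint pathway analysis of genes and metabolites
#'
#' Per pathway, a plain hypergeometric over-representation p-value is
#' computed separately for the gene hits (universe `G`) and metabolite hits
#' (universe `C`), and the two are combined: unweighted by Fisher's method,
#' or by Stouffer's Z with weights equal to the proportions of genes and
#' metabolites in the combined universe (`stouffer_overall`:
#' `w_g = G/(G+C)`) or within each individual pathway (`stouffer_pathway`:
#' `w_g = g_p/(g_p+c_p)`). The weighting counters the tendency of
#' transcriptomics to dominate the combined result. A pathway in which one
#' omics has no members takes the other omics' p-value directly. The
#' single-omics library modes skip combination.
#'
#' @param query an [omicsQuery()].
#' @param lib a [PathwayLibrary-class] whose pathways carry compound and/or
#'   gene members.
#' @param method `"fisher"`, `"stouffer_overall"` or `"stouffer_pathway"`.
#' @param library_mode `"metabolic"`/`"all"` use both omics;
#'   `"metabolite_only"` and `"gene_only"` restrict to one.
#' @return data.frame with per-pathway columns `pathway_id`, `pathway_name`,
#'   `n_genes`, `n_compounds`, `hits_gene`, `hits_met`, `p_gene`, `p_met`,
#'   `w_gene`, `w_met`, `p_combined`, `method`, sorted by `p_combined`.
#' @export
jointPathwayAnalysis <- function(query, lib,
                                 method = c("fisher", "stouffer_overall",
                                            "stouffer_pathway"),
                                 library_mode = c("metabolic", "all",
                                                  "metabolite_only",
                                                  "gene_only")) {
  method <- match.arg(method)
  library_mode <- match.arg(library_mode)
  stopifnot(is(lib, "PathwayLibrary"))
  useGenes <- library_mode != "metabolite_only"
  useMets <- library_mode != "gene_only"
  gh <- if (useGenes) query$gene_hits else character()
  mh <- if (useMets) query$metabolite_hits else character()
  if (length(gh) + length(mh) == 0L)
    stop("empty query: no gene or metabolite hits", call. = FALSE)
  G <- query$G %||% length(universeGenes(lib))
  C <- query$C %||% length(universeCompounds(lib))
  n <- length(lib@ids)
  pg <- pm <- rep(1, n); wg <- wm <- rep(NA_real_, n)
  kg <- km <- integer(n); sg <- sm <- integer(n); pc <- rep(1, n)
  for (i in seq_len(n)) {
    genes <- if (useGenes) lib@genes[[i]] else character()
    cpds <- if (useMets) lib@compounds[[i]] else character()
    sg[i] <- length(genes); sm[i] <- length(cpds)
    kg[i] <- length(intersect(gh, genes))
    km[i] <- length(intersect(mh, cpds))
    pg[i] <- .oraP(kg[i], length(gh), sg[i], G)
    pm[i] <- .oraP(km[i], length(mh), sm[i], C)
    if (!useGenes || sg[i] == 0) { pc[i] <- pm[i]; next }
    if (!useMets || sm[i] == 0) { pc[i] <- pg[i]; next }
    if (method == "fisher") {
      pc[i] <- combineFisher(c(pg[i], pm[i]))$p_combined
    } else {
      w <- if (method == "stouffer_overall") c(G, C) / (G + C)
           else c(sg[i], sm[i]) / (sg[i] + sm[i])
      wg[i] <- w[1L]; wm[i] <- w[2L]
      pc[i] <- combineStouffer(c(pg[i], pm[i]), w)$p_combined
    }
  }
  out <- data.frame(pathway_id = lib@ids, pathway_name = lib@pathwayNames,
                    n_genes = sg, n_compounds = sm, hits_gene = kg,
                    hits_met = km, p_gene = pg, p_met = pm,
                    w_gene = wg, w_met = wm, p_combined = pc,
                    method = if (library_mode %in% c("metabolite_only",
                                                     "gene_only"))
                      library_mode else method)
  out <- out[order(out$p_combined, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway-level functional meta-analysis
#'
#' Reconciles per-dataset enrichment results by pathway id and combines the
#' per-dataset `gamma_p` values with Fisher's or (equal-weight by default)
#' Stouffer's method. A pathway absent from a dataset contributes p = 1 —
#' absence of evidence penalizes — and is flagged. Per-dataset significance
#' flags at `alpha` give the Venn structure of the result.
#'
#' @param results named list (>= 2) of [EnrichmentResult-class] objects.
#' @param method `"fisher"` or `"stouffer"`.
#' @param alpha per-dataset significance level for the Venn flags.
#' @param weights optional Stouffer weights per dataset (default equal).
#' @return data.frame with `pathway_id`, `pathway_name`, one `p_*` and one
#'   `sig_*`/`present_*` column per dataset, and `p_integrated`, sorted by
#'   `p_integrated`.
#' @export
metaPathwayLevel <- function(results, method = c("fisher", "stouffer"),
                             alpha = 0.05, weights = NULL) {
  method <- match.arg(method)
  if (length(results) < 2L)
    stop("pathway-level meta-analysis needs at least 2 datasets",
         call. = FALSE)
  stopifnot(all(vapply(results, is, TRUE, "EnrichmentResult")))
  dsNames <- names(results) %||% paste0("dataset", seq_along(results))
  if (is.null(names(results))) names(results) <- dsNames
  tabs <- lapply(results, resultTable)
  allIds <- sort(unique(unlist(lapply(tabs, `[[`, "pathway_id"))))
  nm <- rep(NA_character_, length(allIds))
  P <- matrix(1, length(allIds), length(results),
              dimnames = list(allIds, dsNames))
  present <- matrix(FALSE, length(allIds), length(results),
                    dimnames = list(allIds, dsNames))
  for (d in seq_along(tabs)) {
    i <- match(tabs[[d]]$pathway_id, allIds)
    P[i, d] <- tabs[[d]]$gamma_p
    present[i, d] <- TRUE
    nm[i] <- tabs[[d]]$pathway_name
  }
  if (is.null(weights)) weights <- rep(1, length(results))
  pInt <- apply(P, 1L, function(p)
    if (method == "fisher") combineFisher(p)$p_combined
    else suppressWarnings(combineStouffer(p, weights)$p_combined))
  out <- data.frame(pathway_id = allIds, pathway_name = nm,
                    check.names = FALSE)
  for (d in dsNames) out[[paste0("p_", d)]] <- P[, d]
  for (d in dsNames) out[[paste0("present_", d)]] <- present[, d]
  for (d in dsNames) out[[paste0("sig_", d)]] <- present[, d] & P[, d] <= alpha
  out$p_integrated <- pInt
  out <- out[order(out$p_integrated, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional meta-analysis by peak pooling
#'
#' Combines complementary ranked peak lists from the same samples (for
#' example positive and negative ionization mode) to improve metabolome
#' coverage: each list is annotated under its own adduct rules, the
#' annotatable compounds and the significant peaks' annotations are pooled
#' by set union, and a single enrichment runs on the pooled annotation with
#' permutations drawing from the pooled peak space. Counting is at the
#' compound level.
#'
#' @param peaklists list (>= 1) of [RankedPeakList-class] objects, each
#'   tagged with its own ionization mode. The same `(mz, rt, mode)` triple
#'   may not occur in two lists.
#' @param db a [CompoundDb-class].
#' @param lib a [PathwayLibrary-class].
#' @param rules_per_list optional list of adduct rule tables, one per peak
#'   list (default: the mode-default rules of each list).
#' @param cfg an [enrichmentConfig()] list.
#' @return An [EnrichmentResult-class] over the pooled annotation.
#' @export
metaPeakPooling <- function(peaklists, db, lib, rules_per_list = NULL,
                            cfg = enrichmentConfig()) {
  stopifnot(length(peaklists) >= 1,
            all(vapply(peaklists, is, TRUE, "RankedPeakList")))
  if (is.null(rules_per_list))
    rules_per_list <- lapply(peaklists, function(p)
      defaultAdductRules(ionMode(p)))
  stopifnot(length(rules_per_list) == length(peaklists))
  triples <- lapply(peaklists, function(p)
    paste(peakData(p)$mz, peakData(p)$rt, ionMode(p)))
  if (length(peaklists) > 1L) {
    for (a in seq_along(triples)) for (b in seq_along(triples)) {
      if (a < b && length(intersect(triples[[a]], triples[[b]])))
        stop("conflicting duplicate (mz, rt, mode) triples across lists",
             call. = FALSE)
    }
  }
  anns <- mapply(function(p, r) annotatePeaks(p, db, r, ppm_tol = cfg$ppm_tol),
                 peaklists, rules_per_list, SIMPLIFY = FALSE)
  allCpds <- sort(unique(unlist(lapply(anns, annotatedCompounds))))
  if (length(allCpds) == 0L)
    stop("no annotation possible: no peak matched any database compound",
         call. = FALSE)
  nPer <- vapply(peaklists, function(p) nrow(peakData(p)), 0L)
  offsets <- cumsum(c(0L, nPer[-length(nPer)]))
  memberMat <- matrix(0, sum(nPer), length(allCpds))
  sigIdx <- integer()
  for (d in seq_along(peaklists)) {
    m <- annotationMatches(anns[[d]])
    if (nrow(m))
      memberMat[cbind(offsets[d] + m$feature_index,
                      match(m$compound_id, allCpds))] <- 1
    p <- peakData(peaklists[[d]])$p_value
    sigIdx <- c(sigIdx, offsets[d] + which(p <= cfg$sig_cutoff))
  }
  if (length(sigIdx) == 0L)
    stop("no significant peaks at the chosen cutoff", call. = FALSE)
  unitSets <- lapply(seq_along(lib@ids), function(j)
    which(allCpds %in% lib@compounds[[j]]))
  res <- .runEnrichment(memberMat, unitSets, sigIdx, cfg$n_permutations,
                        cfg$seed)
  tb <- data.frame(pathway_id = lib@ids, pathway_name = lib@pathwayNames,
                   pathway_size = res$K, hits_total = res$K,
                   hits_sig = as.integer(res$k), ease_p = res$ease_p,
                   gamma_p = res$gamma_p)
  tb <- tb[tb$hits_total >= max(cfg$min_pathway_hits, 1L), , drop = FALSE]
  tb <- tb[order(tb$gamma_p, tb$ease_p, tb$pathway_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("EnrichmentResult", table = tb,
      config = c(cfg, list(pooled = TRUE, n_lists = length(peaklists),
                           n_sig_peaks = length(sigIdx),
                           n_sig_units = res$nSig,
                           universe_size = length(allCpds))),
      gammaFit = res$fit)
}
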