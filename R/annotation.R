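## Putative annotation of m/z features against a compound database under an
## adduct model, empirical-compound formation using retention time, and
## compound-name normalization.

#' Default adduct rules
#'
#' The shipped rule table (editable TSV at
#' `system.file("extdata", "adduct_rules.tsv", package = "peaks2func")`).
#' Mass shifts are in Da and include the proton mass (1.007276 Da); the
#' electron mass is ignored (below 0.5 ppm for typical metabolites).
#'
#' @param mode restrict to one ionization mode; `"mixed"` returns all rules.
#' @param file alternative rule table (columns `name`, `nmer`, `mass_shift`,
#'   `charge`, `mode`).
#' @return data.frame of adduct rules.
#' @export
defaultAdductRules <- function(mode = "mixed", file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "adduct_rules.tsv", package = "peaks2func")
  rules <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "nmer", "mass_shift", "charge", "mode") %in%
                colnames(rules)))
  if (mode != "mixed") rules <- rules[rules$mode == mode, , drop = FALSE]
  rules
}

#' Predicted m/z of an adduct
#'
#' `(nmer * M + mass_shift) / |charge|` for a neutral monoisotopic mass `M`.
#'
#' @param mass neutral monoisotopic mass in Da (> 0); vectorized.
#' @param nmer molecular multiplier (2 for dimers).
#' @param mass_shift signed mass shift in Da.
#' @param charge nonzero integer charge.
#' @return predicted m/z in Da.
#' @examples
#' predictedMz(180.06339, 1, 1.007276, 1)   # glucose M+H
#' @export
predictedMz <- function(mass, nmer = 1, mass_shift = 0, charge = 1) {
  stopifnot(all(mass > 0), charge != 0)
  (nmer * mass + mass_shift) / abs(charge)
}

.rulesForMode <- function(rules, mode) {
  if (mode != "mixed") rules <- rules[rules$mode == mode, , drop = FALSE]
  rules
}

#' Putatively annotate MS peaks against a compound database
#'
#' Matches every peak against every (compound, adduct rule) pair whose
#' predicted m/z lies within `ppm_tol` parts-per-million of the observed
#' m/z. Matching is many-to-many: one peak can hit several compounds and
#' vice versa. Currency metabolites (ubiquitous compounds such as water or
#' CO2) are excluded by default.
#'
#' @param peaks a [RankedPeakList-class].
#' @param db a [CompoundDb-class].
#' @param rules adduct rule data.frame (see [defaultAdductRules()]); must
#'   contain rules for the peak list's ionization mode.
#' @param ppm_tol instrument tolerance in ppm.
#' @param drop_currency exclude currency metabolites from matches.
#' @return A [PeakAnnotation-class].
#' @export
annotatePeaks <- function(peaks, db, rules = defaultAdductRules(ionMode(peaks)),
                          ppm_tol = 5.0, drop_currency = TRUE) {
  stopifnot(is(peaks, "RankedPeakList"), is(db, "CompoundDb"), ppm_tol > 0)
  rules <- .rulesForMode(rules, ionMode(peaks))
  if (nrow(rules) == 0L)
    stop(sprintf("no adduct rules available for mode '%s'", ionMode(peaks)),
         call. = FALSE)
  ids <- compoundIds(db)
  mass <- unname(compoundMasses(db))
  if (drop_currency) {
    keep <- !(ids %in% currencyIds(db))
    ids <- ids[keep]; mass <- mass[keep]
  }
  pk <- peakData(peaks)
  out <- vector("list", nrow(rules))
  if (length(ids)) {
    for (r in seq_len(nrow(rules))) {
      pred <- predictedMz(mass, rules$nmer[r], rules$mass_shift[r],
                          rules$charge[r])
      ## ppm error of each (peak, compound) pair; tolerance on predicted m/z
      err <- outer(pk$mz, pred, function(o, p) (o - p) / p * 1e6)
      hit <- which(abs(err) <= ppm_tol, arr.ind = TRUE)
      if (nrow(hit))
        out[[r]] <- data.frame(feature_index = hit[, 1L],
                               mz = pk$mz[hit[, 1L]],
                               rt = pk$rt[hit[, 1L]],
                               compound_id = ids[hit[, 2L]],
                               adduct = rules$name[r],
                               ppm_error = err[hit])
    }
  }
  matches <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(matches))
    matches <- data.frame(feature_index = integer(), mz = numeric(),
                          rt = numeric(), compound_id = character(),
                          adduct = character(), ppm_error = numeric())
  matches <- matches[order(matches$feature_index, matches$compound_id,
                           matches$adduct), , drop = FALSE]
  rownames(matches) <- NULL
  new("PeakAnnotation", matches = matches, nPeaks = nrow(pk),
      ppmTol = ppm_tol)
}

## single-linkage clustering of 1-d retention times: split sorted values at
## gaps above the tolerance (equivalent to connected components of the
## rt-proximity graph)
.rtClusters <- function(rt, tol) {
  ord <- order(rt)
  gaps <- c(0, diff(rt[ord]))
  cl <- cumsum(gaps > tol)
  cl[order(ord)] + 1L
}

#' Group annotation matches into empirical compounds
#'
#' An empirical compound is a set of co-eluting peaks whose m/z values are
#' consistent with adducts of one candidate compound (the mummichog v2
#' unit). Within each candidate compound the member peaks are clustered on
#' retention time by single linkage at `rt_tol`; each cluster becomes one
#' empirical compound, so the same compound observed at well-separated
#' retention times yields distinct empirical compounds. Every match belongs
#' to exactly one empirical compound.
#'
#' @param ann a [PeakAnnotation-class].
#' @param peaks the annotated [RankedPeakList-class] (must carry retention
#'   times).
#' @param rt_tol retention-time tolerance in seconds; default 1 percent of
#'   the observed RT range.
#' @return An [EmpiricalCompoundSet-class].
#' @export
buildEmpiricalCompounds <- function(ann, peaks, rt_tol = NULL) {
  stopifnot(is(ann, "PeakAnnotation"), is(peaks, "RankedPeakList"))
  if (!hasRt(peaks))
    stop("peaks carry no retention times; use the mummichog v1 path",
         call. = FALSE)
  rts <- peakData(peaks)$rt
  if (is.null(rt_tol)) {
    rt_tol <- diff(range(rts)) * 0.01
    if (!is.finite(rt_tol) || rt_tol <= 0) rt_tol <- 1
  }
  stopifnot(rt_tol > 0)
  m <- annotationMatches(ann)
  if (nrow(m) == 0L)
    return(new("EmpiricalCompoundSet",
               matches = cbind(m, ec_id = character(0)),
               ecs = data.frame(ec_id = character(), compound_id = character(),
                                rt_center = numeric(), n_peaks = integer())))
  m$rt <- rts[m$feature_index]
  ecOf <- character(nrow(m))
  ecRows <- list()
  counter <- 0L
  for (cpd in unique(m$compound_id)) {
    rows <- which(m$compound_id == cpd)
    cl <- .rtClusters(m$rt[rows], rt_tol)
    for (k in sort(unique(cl))) {
      counter <- counter + 1L
      id <- sprintf("EC%05d", counter)
      sel <- rows[cl == k]
      ecOf[sel] <- id
      ecRows[[counter]] <- data.frame(
        ec_id = id, compound_id = cpd,
        rt_center = mean(unique(m$rt[sel])),
        n_peaks = length(unique(m$feature_index[sel])))
    }
  }
  matches <- cbind(m, ec_id = ecOf)
  new("EmpiricalCompoundSet", matches = matches,
      ecs = do.call(rbind, ecRows))
}

#' Normalize a compound name to a canonical form
#'
#' Lowercases, collapses whitespace, normalizes brackets around lipid chain
#' descriptors to `(...)` and removes spaces between the lipid class token
#' and the descriptor, so vendor variants such as `"PC (16:0/18:1)"`,
#' `"PC(16:0/18:1)"` and `"pc 16:0/18:1"` all map to `"pc(16:0/18:1)"`.
#' Chain separators `/` (known sn-positions) and `_` (unknown) are
#' preserved as given. Idempotent.
#'
#' @param name character vector of compound names.
#' @return canonical names.
#' @export
normalizeCompoundName <- function(name) {
  x <- tolower(trimws(name))
  x <- gsub("\\s+", " ", x)
  x <- chartr("[]{}", "()()", x)
  x <- gsub(" ?\\( ?", "(", x)
  x <- gsub(" ?\\)", ")", x)
  ## bare lipid shorthand "pc 16:0/18:1" -> "pc(16:0/18:1)"
  bare <- !grepl("(", x, fixed = TRUE) &
    grepl("^[a-z0-9-]+ [0-9]+:[0-9]", x)
  x[bare] <- sub("^([a-z0-9-]+) ([0-9]+:[0-9][^ ]*)$", "\\1(\\2)", x[bare])
  x
}

#' Match compound names against a database
#'
#' Match priority: exact primary name, then exact synonym, then match of the
#' normalized form (see [normalizeCompoundName()]) against normalized
#' primary names and synonyms. The first hit in database order wins.
#'
#' @param names character vector of query names.
#' @param db a [CompoundDb-class].
#' @return data.frame with columns `input`, `compound_id` (`NA` when
#'   unmatched) and `match_type` (`exact`, `synonym`, `normalized`, `none`).
#' @export
matchNames <- function(names, db) {
  stopifnot(is(db, "CompoundDb"))
  ids <- compoundIds(db)
  primary <- unname(compoundNames(db))
  syn <- compoundSynonyms(db)
  synFlat <- data.frame(
    name = unlist(syn, use.names = FALSE) %||% character(),
    id = rep(ids, lengths(syn)))
  normPrimary <- normalizeCompoundName(primary)
  normSyn <- if (nrow(synFlat)) normalizeCompoundName(synFlat$name) else character()
  lookup <- function(q) {
    i <- match(q, primary)
    if (!is.na(i)) return(c(ids[i], "exact"))
    j <- match(q, synFlat$name)
    if (!is.na(j)) return(c(synFlat$id[j], "synonym"))
    nq <- normalizeCompoundName(q)
    i <- match(nq, normPrimary)
    if (!is.na(i)) return(c(ids[i], "normalized"))
    j <- match(nq, normSyn)
    if (!is.na(j)) return(c(synFlat$id[j], "normalized"))
    c(NA_character_, "none")
  }
  hits <- vapply(names, lookup, character(2))
  data.frame(input = names, compound_id = hits[1L, ],
             match_type = hits[2L, ], row.names = NULL)
}
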