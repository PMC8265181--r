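#' @import methods
#' @useDynLib peaks2func, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats pchisq pgamma phyper pnorm qnorm rnorm runif rlnorm sd
#'   var p.adjust setNames median quantile
#' @importFrom utils head
NULL

.VALID_MODES <- c("positive", "negative", "mixed")

#' PeakTable: feature x sample intensity matrix with m/z and retention time
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding an
#' untargeted LC-MS peak intensity table. Rows are features keyed by m/z (Da)
#' and optionally retention time (seconds); columns are samples carrying one
#' categorical group label each. Missing measurements are `NA` in the
#' `"intensity"` assay and are distinct from measured zeros.
#'
#' @slot ionMode ionization mode, one of `"positive"`, `"negative"`, `"mixed"`.
#' @export
setClass("PeakTable",
  contains = "SummarizedExperiment",
  representation(ionMode = "character"),
  prototype(ionMode = "positive")
)

setValidity("PeakTable", function(object) {
  msg <- character()
  if (!(length(object@ionMode) == 1L && object@ionMode %in% .VALID_MODES))
    msg <- c(msg, "ionMode must be one of positive/negative/mixed")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"mz" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain an 'mz' column")
  } else if (any(!is.finite(rd$mz) | rd$mz <= 0)) {
    msg <- c(msg, "mz must be strictly positive and finite")
  }
  if ("rt" %in% colnames(rd)) {
    rt <- rd$rt
    if (any(rt[!is.na(rt)] < 0)) msg <- c(msg, "rt must be non-negative")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(a[!is.na(a)] < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakTable
#'
#' @param intensities numeric matrix, features x samples; `NA` marks a missing
#'   (unmeasured) entry, which is distinct from a measured zero.
#' @param mz numeric vector of feature m/z values (Da), strictly positive.
#' @param rt optional numeric vector of retention times (seconds).
#' @param groups character vector of group labels, one per sample.
#' @param mode ionization mode (`"positive"`, `"negative"` or `"mixed"`).
#' @param featureIds,sampleIds optional identifiers; defaults are derived from
#'   the m/z-RT key and the matrix column names.
#' @return A [PeakTable-class] object.
#' @examples
#' pt <- PeakTable(matrix(1:6, 2), mz = c(181.07, 212.00),
#'                 groups = c("a", "a", "b"))
#' peakMz(pt)
#' @export
PeakTable <- function(intensities, mz, rt = NULL, groups,
                      mode = "positive", featureIds = NULL, sampleIds = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(featureIds)) {
    featureIds <- if (is.null(rt)) formatC(mz, format = "fg") else
      paste(formatC(mz, format = "fg"), formatC(rt, format = "fg"), sep = "__")
  }
  if (is.null(sampleIds)) {
    sampleIds <- colnames(intensities)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(intensities)))
  }
  rownames(intensities) <- featureIds
  colnames(intensities) <- sampleIds
  rd <- S4Vectors::DataFrame(mz = as.numeric(mz), row.names = featureIds)
  if (!is.null(rt)) rd$rt <- as.numeric(rt)
  cd <- S4Vectors::DataFrame(group = as.character(groups),
                             row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities), rowData = rd, colData = cd)
  new("PeakTable", se, ionMode = mode)
}

#' RankedPeakList: per-feature statistics driving functional analysis
#'
#' Rows of (m/z, optional retention time, p-value, signed test statistic),
#' sorted ascending by p-value with deterministic tie-breaking (descending
#' absolute statistic, then ascending m/z). This is the input unit of the
#' mummichog-style enrichment.
#'
#' @slot peaks data.frame with columns `mz`, `rt`, `p_value`, `statistic`.
#' @slot ionMode ionization mode.
#' @export
setClass("RankedPeakList",
  representation(peaks = "data.frame", ionMode = "character"))

setValidity("RankedPeakList", function(object) {
  msg <- character()
  need <- c("mz", "rt", "p_value", "statistic")
  if (!all(need %in% colnames(object@peaks)))
    msg <- c(msg, paste("peaks must have columns", paste(need, collapse = ", ")))
  else {
    p <- object@peaks$p_value
    if (any(!is.finite(p) | p < 0 | p > 1))
      msg <- c(msg, "p_value must lie in [0,1]")
    if (any(object@peaks$mz <= 0)) msg <- c(msg, "mz must be positive")
    key <- paste(object@peaks$mz, object@peaks$rt)
    if (anyDuplicated(key)) msg <- c(msg, "rows must be unique on (mz, rt)")
  }
  if (!(length(object@ionMode) == 1L && object@ionMode %in% .VALID_MODES))
    msg <- c(msg, "ionMode must be one of positive/negative/mixed")
  if (length(msg)) msg else TRUE
})

.sortRanked <- function(df) {
  df[order(df$p_value, -abs(df$statistic), df$mz), , drop = FALSE]
}

#' Construct a RankedPeakList
#'
#' @param mz,p_value,statistic numeric vectors of equal length.
#' @param rt optional retention times (seconds); `NA` when unavailable.
#' @param mode ionization mode.
#' @return A [RankedPeakList-class], sorted by p-value with deterministic ties.
#' @export
RankedPeakList <- function(mz, p_value, statistic, rt = NULL,
                           mode = "positive") {
  if (is.null(rt)) rt <- rep(NA_real_, length(mz))
  df <- data.frame(mz = as.numeric(mz), rt = as.numeric(rt),
                   p_value = as.numeric(p_value),
                   statistic = as.numeric(statistic))
  df <- .sortRanked(df)
  rownames(df) <- NULL
  new("RankedPeakList", peaks = df, ionMode = mode)
}

#' PathwayLibrary: compound / gene set definitions
#'
#' @slot ids,pathwayNames character vectors, one entry per pathway.
#' @slot compounds,genes lists of member-ID character vectors per pathway.
#' @slot universeCompounds,universeGenes union of members across pathways.
#' @export
setClass("PathwayLibrary",
  representation(ids = "character", pathwayNames = "character",
                 compounds = "list", genes = "list",
                 universeCompounds = "character", universeGenes = "character"))

setValidity("PathwayLibrary", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@pathwayNames) != n || length(object@compounds) != n ||
      length(object@genes) != n)
    msg <- c(msg, "per-pathway slots must have equal length")
  if (anyDuplicated(object@ids)) msg <- c(msg, "pathway ids must be unique")
  if (n) {
    empty <- vapply(seq_len(n), function(i)
      length(object@compounds[[i]]) + length(object@genes[[i]]) == 0L,
      logical(1))
    if (any(empty)) msg <- c(msg, "each pathway needs at least one member")
    if (!all(unlist(object@compounds) %in% object@universeCompounds))
      msg <- c(msg, "compound members must appear in universeCompounds")
    if (!all(unlist(object@genes) %in% object@universeGenes))
      msg <- c(msg, "gene members must appear in universeGenes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayLibrary
#'
#' @param ids,names pathway identifiers and display names.
#' @param compounds,genes lists of member ID vectors (sets; deduplicated).
#' @return A [PathwayLibrary-class].
#' @export
PathwayLibrary <- function(ids, names = ids, compounds,
                           genes = rep(list(character()), length(ids))) {
  compounds <- lapply(compounds, function(x) unique(as.character(x)))
  genes <- lapply(genes, function(x) unique(as.character(x)))
  new("PathwayLibrary", ids = as.character(ids),
      pathwayNames = as.character(names),
      compounds = compounds, genes = genes,
      universeCompounds = unique(unlist(compounds, use.names = FALSE)) %||% character(),
      universeGenes = unique(unlist(genes, use.names = FALSE)) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CompoundDb: reference compounds with monoisotopic masses and synonyms
#'
#' @slot ids compound identifiers (unique).
#' @slot masses monoisotopic masses in Da (> 0).
#' @slot primaryNames display names.
#' @slot synonyms list of synonym character vectors per compound.
#' @slot currencyIds ids of ubiquitous ("currency") metabolites such as water
#'   or CO2, excluded from annotation by default to avoid spurious hits.
#' @export
setClass("CompoundDb",
  representation(ids = "character", masses = "numeric",
                 primaryNames = "character", synonyms = "list",
                 currencyIds = "character"))

setValidity("CompoundDb", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "compound ids must be unique")
  if (length(object@masses) != n || length(object@primaryNames) != n ||
      length(object@synonyms) != n)
    msg <- c(msg, "per-compound slots must have equal length")
  if (any(!is.finite(object@masses) | object@masses <= 0))
    msg <- c(msg, "monoisotopic masses must be strictly positive")
  if (!all(object@currencyIds %in% object@ids))
    msg <- c(msg, "currencyIds must be known compound ids")
  if (length(msg)) msg else TRUE
})

#' Construct a CompoundDb
#'
#' @param ids,masses,names parallel vectors of compound id, monoisotopic mass
#'   (Da) and primary name.
#' @param synonyms list of synonym vectors (default none).
#' @param currency ids flagged as currency metabolites.
#' @return A [CompoundDb-class].
#' @export
CompoundDb <- function(ids, masses, names = ids,
                       synonyms = rep(list(character()), length(ids)),
                       currency = character()) {
  new("CompoundDb", ids = as.character(ids), masses = as.numeric(masses),
      primaryNames = as.character(names),
      synonyms = lapply(synonyms, as.character),
      currencyIds = as.character(currency))
}

#' PeakAnnotation: putative peak-to-compound matches under an adduct model
#'
#' Many-to-many matches between peaks of a [RankedPeakList-class] and
#' compounds of a [CompoundDb-class]; each match records the adduct rule and
#' the signed ppm mass error.
#'
#' @slot matches data.frame with columns `feature_index`, `mz`, `rt`,
#'   `compound_id`, `adduct`, `ppm_error`.
#' @slot nPeaks number of peaks in the annotated list.
#' @slot ppmTol instrument tolerance used (ppm).
#' @export
setClass("PeakAnnotation",
  representation(matches = "data.frame", nPeaks = "integer", ppmTol = "numeric"))

setValidity("PeakAnnotation", function(object) {
  msg <- character()
  need <- c("feature_index", "mz", "rt", "compound_id", "adduct", "ppm_error")
  if (!all(need %in% colnames(object@matches)))
    msg <- c(msg, paste("matches must have columns", paste(need, collapse = ", ")))
  else if (nrow(object@matches) &&
           any(abs(object@matches$ppm_error) > object@ppmTol + 1e-9))
    msg <- c(msg, "ppm_error exceeds the stated tolerance")
  if (length(msg)) msg else TRUE
})

#' EmpiricalCompoundSet: retention-time resolved compound hypotheses
#'
#' Groups annotation matches into empirical compounds: co-eluting peaks whose
#' m/z values are consistent with adducts of one underlying compound. Each
#' match belongs to exactly one empirical compound.
#'
#' @slot matches the annotation matches with an added `ec_id` column.
#' @slot ecs per-EC summary: `ec_id`, `compound_id`, `rt_center`, `n_peaks`.
#' @export
setClass("EmpiricalCompoundSet",
  representation(matches = "data.frame", ecs = "data.frame"))

#' EnrichmentResult: per-pathway activity prediction
#'
#' @slot table data.frame with columns `pathway_id`, `pathway_name`,
#'   `pathway_size`, `hits_total`, `hits_sig`, `ease_p`, `gamma_p`, sorted by
#'   `gamma_p` (ties: `ease_p`, then id).
#' @slot config the enrichment configuration used.
#' @slot gammaFit fitted permutation-null parameters.
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", config = "list", gammaFit = "list"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("pathway_id", "pathway_name", "pathway_size", "hits_total",
            "hits_sig", "ease_p", "gamma_p")
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  else if (nrow(tb)) {
    if (any(tb$hits_sig > tb$hits_total) || any(tb$hits_total > tb$pathway_size))
      msg <- c(msg, "hits_sig <= hits_total <= pathway_size violated")
    if (any(tb$ease_p < 0 | tb$ease_p > 1) || any(tb$gamma_p < 0 | tb$gamma_p > 1))
      msg <- c(msg, "p-values must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' DSPCNetwork: debiased sparse partial correlation network
#'
#' @slot nodes feature identifiers (network nodes).
#' @slot edges significant edges at the FDR threshold: `node1`, `node2`,
#'   `pcor`, `p_value`, `q_value` with `node1 < node2`.
#' @slot pairs the full pair table (same columns) over all feature pairs.
#' @slot lambda graphical-LASSO regularization used.
#' @slot nSamples number of samples the network was estimated from.
#' @slot fdrAlpha FDR level defining `edges`.
#' @export
setClass("DSPCNetwork",
  representation(nodes = "character", edges = "data.frame",
                 pairs = "data.frame", lambda = "numeric",
                 nSamples = "integer", fdrAlpha = "numeric"))

setValidity("DSPCNetwork", function(object) {
  msg <- character()
  ed <- object@pairs
  need <- c("node1", "node2", "pcor", "p_value", "q_value")
  if (!all(need %in% colnames(ed)))
    msg <- c(msg, paste("pairs must have columns", paste(need, collapse = ", ")))
  else if (nrow(ed)) {
    if (any(abs(ed$pcor) > 1 + 1e-12)) msg <- c(msg, "|pcor| must be <= 1")
    i <- match(ed$node1, object@nodes); j <- match(ed$node2, object@nodes)
    if (any(is.na(i)) || any(is.na(j)) || any(i >= j))
      msg <- c(msg, "edges must satisfy node1 < node2 over known nodes")
  }
  if (length(msg)) msg else TRUE
})
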