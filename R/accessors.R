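#' Accessors for peaks2func classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peakMz", function(x) standardGeneric("peakMz"))
#' @rdname accessors
#' @export
setGeneric("peakRt", function(x) standardGeneric("peakRt"))
#' @rdname accessors
#' @export
setGeneric("ionMode", function(x) standardGeneric("ionMode"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("peakData", function(x) standardGeneric("peakData"))
#' @rdname accessors
#' @export
setGeneric("annotationMatches", function(x) standardGeneric("annotationMatches"))
#' @rdname accessors
#' @export
setGeneric("annotatedFeatures", function(x) standardGeneric("annotatedFeatures"))
#' @rdname accessors
#' @export
setGeneric("annotatedCompounds", function(x) standardGeneric("annotatedCompounds"))
#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))
#' @rdname accessors
#' @export
setGeneric("pathwayMembers", function(x) standardGeneric("pathwayMembers"))
#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname accessors
#' @export
setGeneric("compoundMasses", function(x) standardGeneric("compoundMasses"))
#' @rdname accessors
#' @export
setGeneric("currencyIds", function(x) standardGeneric("currencyIds"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkPairs", function(x) standardGeneric("networkPairs"))

#' @rdname accessors
#' @export
setMethod("peakMz", "PeakTable", function(x)
  SummarizedExperiment::rowData(x)$mz)
#' @rdname accessors
#' @export
setMethod("peakRt", "PeakTable", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("rt" %in% colnames(rd)) rd$rt else NULL
})
#' @rdname accessors
#' @export
setMethod("ionMode", "PeakTable", function(x) x@ionMode)
#' @rdname accessors
#' @export
setMethod("intensities", "PeakTable", function(x)
  SummarizedExperiment::assay(x, "intensity"))
#' @rdname accessors
#' @export
setMethod("groupLabels", "PeakTable", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x)))

#' @rdname accessors
#' @export
setMethod("peakData", "RankedPeakList", function(x) x@peaks)
#' @rdname accessors
#' @export
setMethod("ionMode", "RankedPeakList", function(x) x@ionMode)
#' @rdname accessors
#' @export
setMethod("peakMz", "RankedPeakList", function(x) x@peaks$mz)
#' @rdname accessors
#' @export
setMethod("peakRt", "RankedPeakList", function(x)
  if (all(is.na(x@peaks$rt))) NULL else x@peaks$rt)

#' Does a ranked peak list carry retention times?
#' @param x a [RankedPeakList-class]
#' @return logical scalar
#' @export
hasRt <- function(x) {
  stopifnot(is(x, "RankedPeakList"))
  !all(is.na(peakData(x)$rt))
}

#' @rdname accessors
#' @export
setMethod("pathwayIds", "PathwayLibrary", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("pathwayMembers", "PathwayLibrary", function(x)
  setNames(mapply(function(cpd, g) list(compounds = cpd, genes = g),
                  x@compounds, x@genes, SIMPLIFY = FALSE), x@ids))

#' Pathway display names
#' @param x a [PathwayLibrary-class]
#' @export
pathwayNames <- function(x) setNames(x@pathwayNames, x@ids)

#' Compound / gene universes of a pathway library
#' @param x a [PathwayLibrary-class]
#' @export
universeCompounds <- function(x) x@universeCompounds

#' @rdname universeCompounds
#' @export
universeGenes <- function(x) x@universeGenes

#' @rdname accessors
#' @export
setMethod("compoundIds", "CompoundDb", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("compoundMasses", "CompoundDb", function(x) setNames(x@masses, x@ids))
#' @rdname accessors
#' @export
setMethod("currencyIds", "CompoundDb", function(x) x@currencyIds)

#' Primary names and synonyms of database compounds
#' @param x a [CompoundDb-class]
#' @export
compoundNames <- function(x) setNames(x@primaryNames, x@ids)

#' @rdname compoundNames
#' @export
compoundSynonyms <- function(x) setNames(x@synonyms, x@ids)

#' @rdname accessors
#' @export
setMethod("annotationMatches", "PeakAnnotation", function(x) x@matches)
#' @rdname accessors
#' @export
setMethod("annotatedFeatures", "PeakAnnotation", function(x)
  sort(unique(x@matches$feature_index)))
#' @rdname accessors
#' @export
setMethod("annotatedCompounds", "PeakAnnotation", function(x)
  sort(unique(x@matches$compound_id)))

#' @rdname accessors
#' @export
setMethod("annotationMatches", "EmpiricalCompoundSet", function(x) x@matches)

#' Per-empirical-compound summary table
#' @param x an [EmpiricalCompoundSet-class]
#' @export
empiricalCompounds <- function(x) x@ecs

#' @rdname accessors
#' @export
setMethod("resultTable", "EnrichmentResult", function(x) x@table)

#' Configuration and fitted permutation null of an enrichment run
#' @param x an [EnrichmentResult-class]
#' @export
resultConfig <- function(x) x@config

#' @rdname resultConfig
#' @export
gammaNull <- function(x) x@gammaFit

#' @rdname accessors
#' @export
setMethod("networkEdges", "DSPCNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkPairs", "DSPCNetwork", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("resultTable", "DSPCNetwork", function(x) x@pairs)

setMethod("show", "PeakTable", function(object) {
  cat("PeakTable:", nrow(object), "features x", ncol(object), "samples;",
      "mode:", ionMode(object), "\n")
  cat("  groups:", paste(unique(groupLabels(object)), collapse = ", "), "\n")
  cat("  rt:", if (is.null(peakRt(object))) "absent" else "present", ";",
      sum(is.na(intensities(object))), "missing entries\n")
})

setMethod("show", "RankedPeakList", function(object) {
  df <- peakData(object)
  cat("RankedPeakList:", nrow(df), "peaks; mode:", ionMode(object),
      "; rt:", if (hasRt(object)) "present" else "absent", "\n")
  if (nrow(df)) print(head(df, 3))
})

setMethod("show", "PathwayLibrary", function(object) {
  cat("PathwayLibrary:", length(object@ids), "pathways;",
      length(object@universeCompounds), "compounds,",
      length(object@universeGenes), "genes in universe\n")
})

setMethod("show", "CompoundDb", function(object) {
  cat("CompoundDb:", length(object@ids), "compounds;",
      length(object@currencyIds), "currency-flagged\n")
})

setMethod("show", "PeakAnnotation", function(object) {
  cat("PeakAnnotation:", nrow(object@matches), "matches;",
      length(annotatedFeatures(object)), "of", object@nPeaks,
      "peaks annotated;", length(annotatedCompounds(object)),
      "compounds; ppm tol", object@ppmTol, "\n")
})

setMethod("show", "EmpiricalCompoundSet", function(object) {
  cat("EmpiricalCompoundSet:", nrow(object@ecs), "empirical compounds over",
      nrow(object@matches), "matches\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", nrow(object@table), "pathways;",
      "version", object@config$version %||% "?", "\n")
  if (nrow(object@table)) print(head(object@table, 5))
})

setMethod("show", "DSPCNetwork", function(object) {
  cat("DSPCNetwork:", length(object@nodes), "nodes;",
      nrow(object@edges), "edges at FDR", object@fdrAlpha,
      "; lambda =", signif(object@lambda, 4), "\n")
})
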