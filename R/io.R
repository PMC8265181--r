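## Readers/writers for every external representation the package touches.
## All text I/O is UTF-8 and line-ending agnostic (\n and \r\n both accepted).

.readLinesClean <- function(file) {
  x <- readLines(file, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", x)
}

.splitFields <- function(lines, sep) strsplit(lines, sep, fixed = TRUE)

.MISSING_SENTINELS <- c("", "na", "nan")

## strict numeric parser: sentinels -> NA, anything else non-numeric -> error
.parseIntensity <- function(x, row, col) {
  out <- rep(NA_real_, length(x))
  xs <- trimws(x)
  miss <- tolower(xs) %in% .MISSING_SENTINELS
  val <- suppressWarnings(as.numeric(xs[!miss]))
  if (anyNA(val)) {
    bad <- which(!miss)[which(is.na(val))[1]]
    stop(sprintf("non-numeric intensity '%s' at row %d, column %d",
                 xs[bad], row, col[bad]), call. = FALSE)
  }
  out[!miss] <- val
  out
}

.parseFeatureKey <- function(keys) {
  parts <- strsplit(keys, "__", fixed = TRUE)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  rt <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, "")))
  if (anyNA(mz))
    stop(sprintf("feature key '%s' does not start with a numeric m/z",
                 keys[which(is.na(mz))[1]]), call. = FALSE)
  list(mz = mz, rt = if (all(is.na(rt))) NULL else rt)
}

#' Read a peak intensity table
#'
#' Expects a header row of sample IDs, a second header row of group labels,
#' and one row per feature whose first column is the feature key encoded
#' `"mz__rt"` (double underscore) or plain `"mz"`. Empty cells, `NA` and
#' `NaN` (case-insensitive) become missing values, distinct from measured 0.
#'
#' @param file path or connection.
#' @param dialect `"tsv"` or `"csv"`.
#' @param mode ionization mode recorded on the returned table.
#' @return A [PeakTable-class].
#' @export
readPeakTable <- function(file, dialect = c("tsv", "csv"), mode = "positive") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- .readLinesClean(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L)
    stop("peak table needs two header rows and at least one feature row",
         call. = FALSE)
  rows <- .splitFields(lines, sep)
  sampleIds <- rows[[1L]][-1L]
  groups <- rows[[2L]][-1L]
  if (length(groups) != length(sampleIds))
    stop("group-label row length does not match sample-ID row", call. = FALSE)
  body <- rows[-(1:2)]
  keys <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(keys))
    stop(sprintf("duplicate feature key: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(sampleIds))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    if (length(cells) < length(sampleIds))
      cells <- c(cells, rep("", length(sampleIds) - length(cells)))
    mat[i, ] <- .parseIntensity(cells, row = i + 2L, col = seq_along(cells) + 1L)
  }
  key <- .parseFeatureKey(keys)
  PeakTable(mat, mz = key$mz, rt = key$rt, groups = groups, mode = mode,
            featureIds = keys, sampleIds = sampleIds)
}

#' Write a peak table in the canonical two-header-row TSV layout
#'
#' Missing values are written as `NA`; intensities at 6 significant digits.
#' `readPeakTable()` of the output reproduces values to that precision and
#' the missingness pattern exactly.
#'
#' @param x a [PeakTable-class].
#' @param file path or connection.
#' @export
writePeakTable <- function(x, file) {
  mat <- intensities(x)
  vals <- apply(mat, 1:2, .fmtNum)
  vals[is.na(mat)] <- "NA"
  lines <- c(
    paste(c("Feature", colnames(x)), collapse = "\t"),
    paste(c("Label", unname(groupLabels(x))), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i)
      paste(c(rownames(mat)[i], vals[i, ]), collapse = "\t"), ""))
  writeLines(lines, file, useBytes = TRUE)
  invisible(NULL)
}

.fmtNum <- function(v) {
  if (is.na(v)) return("NA")
  if (is.numeric(v) && !is.integer(v)) sprintf("%.6g", v) else as.character(v)
}

#' Read a ranked peak list
#'
#' Columns `m.z`, optional `r.t`, `p.value`, `t.score` in any order, matched
#' case-insensitively (`mz`, `rt`, `p`, `t`/`statistic` accepted as aliases).
#' Rows are sorted ascending by p-value, ties broken by descending absolute
#' statistic, then ascending m/z.
#'
#' @param file path or connection.
#' @param has_rt require and read a retention-time column.
#' @param mode ionization mode of the list.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A [RankedPeakList-class].
#' @export
readRankedPeaks <- function(file, has_rt = FALSE, mode = "positive",
                            dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- .readLinesClean(file)
  lines <- lines[nzchar(lines)]
  rows <- .splitFields(lines, sep)
  hdr <- tolower(gsub("[^a-z0-9]", "", tolower(rows[[1L]])))
  aliases <- list(mz = c("mz"), rt = c("rt"),
                  p_value = c("pvalue", "p"),
                  statistic = c("tscore", "t", "statistic", "tstat"))
  idx <- vapply(aliases, function(a) {
    hit <- which(hdr %in% a)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  mandatory <- c("mz", "p_value", "statistic", if (has_rt) "rt")
  missing <- mandatory[is.na(idx[mandatory])]
  if (length(missing))
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  body <- rows[-1L]
  pull <- function(k) {
    if (is.na(idx[[k]])) return(rep(NA_real_, length(body)))
    v <- suppressWarnings(as.numeric(vapply(body, `[`, "", idx[[k]])))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s'", k), call. = FALSE)
    v
  }
  p <- pull("p_value")
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  RankedPeakList(mz = pull("mz"), p_value = p, statistic = pull("statistic"),
                 rt = if (has_rt) pull("rt") else NULL, mode = mode)
}

#' Read a pathway library in GMT dialect
#'
#' Each line: `pathway_id TAB pathway_name TAB member TAB member ...`.
#' Members prefixed `cpd:` or `gene:`; unprefixed members default to
#' compounds. Member lists are sets (duplicates counted once).
#'
#' @param file path or connection.
#' @return A [PathwayLibrary-class]; universes are the unions of members.
#' @export
readPathwayLibrary <- function(file) {
  lines <- .readLinesClean(file)
  keep <- nzchar(lines)
  rows <- .splitFields(lines[keep], "\t")
  lineno <- which(keep)
  short <- lengths(rows) < 3L
  if (any(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", lineno[which(short)[1]]),
         call. = FALSE)
  ids <- vapply(rows, `[`, "", 1L)
  nms <- vapply(rows, `[`, "", 2L)
  members <- lapply(rows, function(r) r[-(1:2)])
  cpds <- lapply(members, function(m)
    unique(sub("^cpd:", "", m[!startsWith(m, "gene:")])))
  genes <- lapply(members, function(m)
    unique(sub("^gene:", "", m[startsWith(m, "gene:")])))
  PathwayLibrary(ids = ids, names = nms, compounds = cpds, genes = genes)
}

#' Read a compound database table
#'
#' TSV with columns `id`, `monoisotopic_mass`, `name`, `synonyms`
#' (semicolon-separated) and `is_currency` (0/1).
#'
#' @param file path or connection.
#' @return A [CompoundDb-class]; `currencyIds` are the rows flagged 1.
#' @export
readCompoundDb <- function(file) {
  lines <- .readLinesClean(file)
  lines <- lines[nzchar(lines)]
  rows <- .splitFields(lines, "\t")
  hdr <- tolower(rows[[1L]])
  need <- c("id", "monoisotopic_mass", "name", "synonyms", "is_currency")
  idx <- match(need, hdr)
  if (anyNA(idx))
    stop(sprintf("compound table missing column(s): %s",
                 paste(need[is.na(idx)], collapse = ", ")), call. = FALSE)
  body <- rows[-1L]
  get <- function(k) vapply(body, function(r) {
    i <- idx[match(k, need)]
    if (length(r) >= i) r[i] else ""
  }, "")
  ids <- get("id")
  mass <- suppressWarnings(as.numeric(get("monoisotopic_mass")))
  bad <- is.na(mass) | mass <= 0
  if (any(bad))
    stop(sprintf("non-positive or unparsable mass for compound %s",
                 ids[which(bad)[1]]), call. = FALSE)
  syn <- lapply(strsplit(get("synonyms"), ";", fixed = TRUE),
                function(s) s[nzchar(trimws(s))])
  currency <- ids[get("is_currency") == "1"]
  CompoundDb(ids = ids, masses = mass, names = get("name"),
             synonyms = syn, currency = currency)
}

#' Read the small-molecule summary of an mzTab-M 2.0 document
#'
#' Parses the MTD and SML sections only. Each SML row becomes one feature;
#' `abundance_assay[n]` columns become intensities (`null` entries become
#' missing values, not zeros); the assay-to-study-variable mapping in MTD
#' provides the group labels. Per row, `exp_mass_to_charge` is preferred as
#' the m/z; rows falling back to `theoretical_neutral_mass` are flagged in
#' `metadata(x)$neutral_mass` so annotation can skip adduct mass shifts.
#'
#' @param file path or connection.
#' @return A [PeakTable-class].
#' @export
readMzTabM <- function(file) {
  lines <- .readLinesClean(file)
  lines <- lines[nzchar(lines)]
  rows <- .splitFields(lines, "\t")
  tag <- vapply(rows, `[`, "", 1L)
  mtd <- rows[tag == "MTD"]
  smh <- rows[tag == "SMH"]
  sml <- rows[tag == "SML"]
  if (!length(smh) || !length(sml))
    stop("no SML section found in mzTab-M document", call. = FALSE)
  mtdKey <- vapply(mtd, `[`, "", 2L)
  mtdVal <- vapply(mtd, function(r) if (length(r) >= 3L) r[3L] else "", "")
  ver <- mtdVal[mtdKey == "mzTab-version"]
  if (!length(ver) || ver[1L] != "2.0.0-M")
    warning("mzTab-version is not '2.0.0-M'; attempting to parse anyway")
  hdr <- smh[[1L]]
  col <- function(name) match(name, hdr)
  cell <- function(r, i) {
    if (is.na(i) || length(r) < i) return(NA_character_)
    v <- trimws(r[i])
    if (tolower(v) %in% c("null", "")) NA_character_ else v
  }
  assayCols <- grep("^abundance_assay\\[[0-9]+\\]$", hdr)
  if (!length(assayCols))
    stop("SML section has no abundance_assay columns", call. = FALSE)
  assayIds <- sub("^abundance_", "", hdr[assayCols])
  ## study-variable -> assay mapping from MTD
  svNames <- mtdVal[grepl("^study_variable\\[[0-9]+\\]$", mtdKey)]
  names(svNames) <- mtdKey[grepl("^study_variable\\[[0-9]+\\]$", mtdKey)]
  groups <- rep("unassigned", length(assayIds))
  refKeys <- grep("^study_variable\\[[0-9]+\\]-assay_refs$", mtdKey)
  for (i in refKeys) {
    sv <- sub("-assay_refs$", "", mtdKey[i])
    refs <- trimws(strsplit(mtdVal[i], "|", fixed = TRUE)[[1L]])
    label <- if (sv %in% names(svNames)) svNames[[sv]] else sv
    groups[assayIds %in% refs] <- label
  }
  iExp <- col("exp_mass_to_charge")
  iTheo <- col("theoretical_neutral_mass")
  iId <- col("SML_ID")
  mz <- numeric(length(sml)); neutral <- logical(length(sml))
  ids <- character(length(sml))
  mat <- matrix(NA_real_, length(sml), length(assayCols))
  for (r in seq_along(sml)) {
    row <- sml[[r]]
    idv <- cell(row, iId)
    ids[r] <- if (is.na(idv)) paste0("SML", r) else idv
    e <- cell(row, iExp)
    if (!is.na(e)) {
      mz[r] <- as.numeric(e)
    } else {
      t <- cell(row, iTheo)
      if (is.na(t))
        stop(sprintf("SML row %d has neither exp_mass_to_charge nor theoretical_neutral_mass", r),
             call. = FALSE)
      mz[r] <- as.numeric(t); neutral[r] <- TRUE
    }
    for (k in seq_along(assayCols)) {
      v <- cell(row, assayCols[k])
      if (!is.na(v)) {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num))
          stop(sprintf("non-numeric abundance '%s' in SML row %d", v, r),
               call. = FALSE)
        mat[r, k] <- num
      }
    }
  }
  pt <- PeakTable(mat, mz = mz, groups = groups, mode = "mixed",
                  featureIds = ids, sampleIds = assayIds)
  S4Vectors::metadata(pt)$neutral_mass <- neutral
  pt
}

#' Write a result table as deterministic TSV
#'
#' Column order is the documented order of the result type; floating point
#' values are written at 6 significant digits; the same object always yields
#' byte-identical output. An empty result produces a header-only file.
#'
#' @param x a tabular result (`data.frame`, [EnrichmentResult-class],
#'   [DSPCNetwork-class], [EmpiricalCompoundSet-class]) or a
#'   [PeakTable-class] (written in the two-header-row layout).
#' @param file path or connection.
#' @export
setGeneric("writeResultsTable", function(x, file)
  standardGeneric("writeResultsTable"))

#' @rdname writeResultsTable
#' @export
setMethod("writeResultsTable", "data.frame", function(x, file) {
  fmtCol <- function(v) {
    if (is.double(v)) vapply(v, .fmtNum, "")
    else { out <- as.character(v); out[is.na(out)] <- "NA"; out }
  }
  cols <- lapply(x, fmtCol)
  lines <- paste(colnames(x), collapse = "\t")
  if (nrow(x))
    lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, file, useBytes = TRUE)
  invisible(NULL)
})

#' @rdname writeResultsTable
#' @export
setMethod("writeResultsTable", "EnrichmentResult", function(x, file)
  writeResultsTable(resultTable(x), file))

#' @rdname writeResultsTable
#' @export
setMethod("writeResultsTable", "DSPCNetwork", function(x, file)
  writeResultsTable(networkPairs(x), file))

#' @rdname writeResultsTable
#' @export
setMethod("writeResultsTable", "EmpiricalCompoundSet", function(x, file)
  writeResultsTable(annotationMatches(x), file))

#' @rdname writeResultsTable
#' @export
setMethod("writeResultsTable", "PeakTable", function(x, file)
  writePeakTable(x, file))

#' @rdname writeResultsTable
#' @export
setMethod("writeResultsTable", "RankedPeakList", function(x, file)
  writeResultsTable(peakData(x), file))
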