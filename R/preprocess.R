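## Pre-analysis utilities: technical-replicate merging, background-feature
## exclusion, and per-feature ranking that produces the enrichment input.

#' Merge technical replicates into one column per biological subject
#'
#' For each feature within each subject with `r` replicates, let
#' `f = (number missing) / r`. If `f` is at or below `missing_threshold`
#' the merged value is the mean of the non-missing replicates. If `f`
#' exceeds the threshold, the coefficient of variation (sample SD / mean over
#' the non-missing replicates) is evaluated: a CV above `cv_threshold` marks
#' the feature "highly variant" and the merged value is 0; otherwise the
#' mean is kept. Both comparisons are strict ("over 1/3", "over 1.0"). A
#' subject whose replicates are all missing for a feature stays missing; a
#' single surviving replicate has CV 0 by convention and is retained.
#'
#' @param table a [PeakTable-class].
#' @param reps named character vector or 2-column data.frame mapping
#'   `sample_id -> subject_id`; every sample of `table` must appear once.
#' @param missing_threshold missing-proportion trigger, in (0, 1].
#' @param cv_threshold CV trigger for the "highly variant" call, > 0.
#' @return A [PeakTable-class] with one column per subject. Subjects with a
#'   single replicate pass through unchanged.
#' @export
mergeTechnicalReplicates <- function(table, reps, missing_threshold = 1 / 3,
                                     cv_threshold = 1.0) {
  stopifnot(is(table, "PeakTable"),
            missing_threshold > 0, missing_threshold <= 1, cv_threshold > 0)
  if (is.data.frame(reps)) {
    m <- setNames(as.character(reps[[2L]]), as.character(reps[[1L]]))
  } else m <- reps
  samples <- colnames(table)
  unknown <- setdiff(names(m), samples)
  if (length(unknown))
    stop(sprintf("unknown sample_id in replicate map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!setequal(names(m), samples) || anyDuplicated(names(m)))
    stop("replicate map must list every sample exactly once", call. = FALSE)
  subjects <- unique(unname(m[samples]))
  X <- intensities(table)
  grp <- groupLabels(table)
  out <- matrix(NA_real_, nrow(X), length(subjects),
                dimnames = list(rownames(X), subjects))
  outGroups <- character(length(subjects))
  for (s in seq_along(subjects)) {
    cols <- samples[m[samples] == subjects[s]]
    outGroups[s] <- grp[[cols[1L]]]
    sub <- X[, cols, drop = FALSE]
    r <- length(cols)
    nMiss <- rowSums(is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[nMiss == r] <- NA_real_
    if (r == 1L) { out[, s] <- sub[, 1L]; next }
    merged <- mu
    f <- nMiss / r
    check <- which(f > missing_threshold & nMiss < r)
    if (length(check)) {
      nObs <- r - nMiss[check]
      sdv <- apply(sub[check, , drop = FALSE], 1L, sd, na.rm = TRUE)
      sdv[nObs == 1L] <- 0
      cv <- ifelse(mu[check] == 0, Inf, sdv / mu[check])
      cv[nObs == 1L] <- 0
      merged[check][cv > cv_threshold] <- 0
    }
    out[, s] <- merged
  }
  PeakTable(out, mz = peakMz(table), rt = peakRt(table), groups = outGroups,
            mode = ionMode(table), featureIds = rownames(table),
            sampleIds = subjects)
}

#' Exclude background m/z features from a centroid stream
#'
#' Bins spectrum-wide m/z centroids within a ppm tolerance (single-linkage on
#' the sorted m/z values) and excludes every bin whose centroids appear in a
#' run of consecutive scans covering at least `run_fraction` of the whole
#' chromatogram (`ceiling(run_fraction * n_scans)` scans) — the signature of
#' background noise and contaminants that elute throughout the run.
#'
#' @param centroids data.frame with columns `scan_index` (0-based, `<
#'   n_scans`) and `mz`.
#' @param n_scans total number of scans in the chromatogram (>= 2).
#' @param mz_bin_ppm binning tolerance in ppm.
#' @param run_fraction fraction of the chromatogram a consecutive run must
#'   cover to be called background.
#' @return list with elements `kept` and `excluded` (numeric vectors of bin
#'   center m/z) and `bins` (data.frame: `mz_center`, `n_scans_present`,
#'   `longest_run`, `excluded`).
#' @export
filterBackgroundFeatures <- function(centroids, n_scans, mz_bin_ppm = 10,
                                     run_fraction = 0.5) {
  stopifnot(n_scans >= 2L, mz_bin_ppm > 0, run_fraction > 0, run_fraction <= 1)
  empty <- list(kept = numeric(), excluded = numeric(),
                bins = data.frame(mz_center = numeric(),
                                  n_scans_present = integer(),
                                  longest_run = integer(),
                                  excluded = logical()))
  if (is.null(centroids) || nrow(centroids) == 0L) return(empty)
  stopifnot(all(c("scan_index", "mz") %in% colnames(centroids)))
  if (any(centroids$scan_index < 0L | centroids$scan_index >= n_scans))
    stop("scan_index must lie in [0, n_scans)", call. = FALSE)
  ord <- order(centroids$mz)
  mz <- centroids$mz[ord]
  scan <- centroids$scan_index[ord]
  ## single-linkage ppm binning on sorted m/z: a gap above tolerance starts
  ## a new bin
  gapPpm <- c(Inf, diff(mz) / mz[-length(mz)] * 1e6)
  bin <- cumsum(gapPpm > mz_bin_ppm)
  need <- ceiling(run_fraction * n_scans)
  longestRun <- function(scans) {
    s <- sort(unique(scans))
    if (length(s) == 1L) return(1L)
    brk <- c(0L, which(diff(s) > 1L), length(s))
    max(diff(brk))
  }
  binIds <- unique(bin)
  center <- vapply(binIds, function(b) median(mz[bin == b]), 0)
  runs <- vapply(binIds, function(b) as.integer(longestRun(scan[bin == b])), 0L)
  npres <- vapply(binIds, function(b) length(unique(scan[bin == b])), 0L)
  excl <- runs >= need
  list(kept = center[!excl], excluded = center[excl],
       bins = data.frame(mz_center = center, n_scans_present = npres,
                         longest_run = runs, excluded = excl))
}

## Vectorised Welch two-sample t-test on a matrix (rows = features).
## Degenerate rows (zero pooled variance) get t = 0, p = 1 when the group
## means coincide, and |t| = Inf, p = 0 when they differ.
.welchRows <- function(X, g1, g2) {
  n1 <- rowSums(!is.na(X[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(X[, g2, drop = FALSE]))
  m1 <- rowMeans(X[, g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(X[, g2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(X[, g1, drop = FALSE], 1L, var, na.rm = TRUE)
  v2 <- apply(X[, g2, drop = FALSE], 1L, var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zero <- !is.na(se2) & se2 == 0
  if (any(zero)) {
    same <- zero & (m1 == m2)
    t[same] <- 0; p[same] <- 1
    diffm <- zero & (m1 != m2)
    t[diffm] <- sign(m1 - m2)[diffm] * Inf; p[diffm] <- 0
  }
  list(t = t, p = p, n1 = n1, n2 = n2)
}

#' Rank peak-table features by a two-group Welch t-test
#'
#' Performs a Welch two-sample t-test per feature on log-transformed
#' intensities (`log(x + 1)` by default; intensity data are right-skewed)
#' and returns the ranked peak list that drives functional analysis. The
#' statistic is oriented as group1 minus group2 in the order the group
#' labels first appear. Features with fewer than two non-missing values in
#' either group are dropped (the count is recorded in the result's
#' `dropped` attribute).
#'
#' @param table a [PeakTable-class] with exactly two group labels.
#' @param log_transform apply `log(x + 1)` before testing (default `TRUE`).
#' @return A [RankedPeakList-class].
#' @export
rankFeatures <- function(table, log_transform = TRUE) {
  stopifnot(is(table, "PeakTable"))
  grp <- groupLabels(table)
  lv <- unique(grp)
  if (length(lv) != 2L)
    stop(sprintf("found %d groups; select a two-group contrast first",
                 length(lv)), call. = FALSE)
  X <- intensities(table)
  if (log_transform) X <- log(X + 1)
  w <- .welchRows(X, which(grp == lv[1L]), which(grp == lv[2L]))
  keep <- w$n1 >= 2L & w$n2 >= 2L
  rt <- peakRt(table)
  res <- RankedPeakList(mz = peakMz(table)[keep], p_value = w$p[keep],
                        statistic = w$t[keep],
                        rt = if (is.null(rt)) NULL else rt[keep],
                        mode = ionMode(table))
  attr(res, "dropped") <- sum(!keep)
  res
}
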