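## Debiased sparse partial correlation (DSPC) network inference: graphical
## LASSO precision estimation, de-sparsified (de-biased) entries with
## asymptotic p-values, and BH control across all feature pairs.

## Graphical LASSO precision estimate (compiled block coordinate descent in
## src/glasso.cpp). For lambda = 0 the exact dense inverse is used.
.glasso <- function(S, lambda, maxit = 100L, tol = 1e-5) {
  if (lambda == 0) return(solve(S))
  .glassoCpp(S, lambda, as.integer(maxit), tol)
}

## extended BIC (gamma = 0.5) for glasso model selection on a grid
.ebic <- function(Theta, S, n, gamma = 0.5) {
  p <- ncol(S)
  E <- sum(abs(Theta[upper.tri(Theta)]) > 1e-8)
  ll <- n / 2 * (determinant(Theta, logarithm = TRUE)$modulus[1] -
                   sum(S * Theta))
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}

#' Debiased sparse partial correlation network
#'
#' Estimates a sparse precision matrix by graphical LASSO on the empirical
#' correlation matrix, de-biases it with the de-sparsified estimator
#' `T = Theta + Theta' - Theta' S Theta`, converts entries to partial
#' correlations `rho_ij = -T_ij / sqrt(T_ii T_jj)`, and assigns each pair a
#' two-sided p-value from the asymptotic normal with variance
#' `(T_ii T_jj + T_ij^2) / n`. Benjamini-Hochberg q-values are computed
#' across all pairs; edges with `q <= fdr_alpha` form the network (the full
#' pair table is also retained).
#'
#' @param X numeric sample-by-feature matrix (>= 10 samples), or a
#'   [PeakTable-class] (samples taken from its columns). Features are
#'   column-standardized internally; by default intensities are
#'   `log(x + 1)`-transformed first. Features with more than
#'   `missing_max` missing values are dropped with a warning; remaining
#'   missing entries are imputed with half the feature minimum.
#' @param lambda graphical-LASSO penalty; `"auto"` (default) picks the value
#'   minimizing the extended BIC over a small grid in \[0.01, 0.5\].
#'   `lambda = 0` requires fewer features than samples and reproduces the
#'   dense-inverse partial correlations.
#' @param fdr_alpha FDR level defining the edge set.
#' @param log_transform apply `log(x + 1)` before standardization.
#' @param missing_max maximum tolerated missing fraction per feature.
#' @return A [DSPCNetwork-class].
#' @export
setGeneric("dspc", function(X, lambda = "auto", fdr_alpha = 0.05,
                            log_transform = TRUE, missing_max = 0.2)
  standardGeneric("dspc"))

#' @rdname dspc
#' @export
setMethod("dspc", "matrix", function(X, lambda = "auto", fdr_alpha = 0.05,
                                     log_transform = TRUE,
                                     missing_max = 0.2) {
  n <- nrow(X)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  missFrac <- colMeans(is.na(X))
  if (any(missFrac > missing_max)) {
    drop <- colnames(X)[missFrac > missing_max]
    warning(sprintf("dropping %d feature(s) with > %.0f%% missing values: %s",
                    length(drop), 100 * missing_max,
                    paste(head(drop, 5), collapse = ", ")))
    X <- X[, missFrac <= missing_max, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- min(X[!na, j]) / 2
  }
  if (log_transform) {
    if (any(X < 0))
      stop("negative values: disable log_transform for already-transformed data",
           call. = FALSE)
    X <- log(X + 1)
  }
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("constant feature(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")),
         call. = FALSE)
  Xs <- scale(X)
  p <- ncol(Xs)
  S <- crossprod(Xs) / (n - 1)
  if (identical(lambda, "auto")) {
    grid <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5)
    fits <- lapply(grid, function(l) .glasso(S, l))
    scores <- vapply(seq_along(grid), function(i) .ebic(fits[[i]], S, n), 0)
    best <- which.min(scores)
    lambda <- grid[best]
    Theta <- fits[[best]]
  } else {
    lambda <- as.numeric(lambda)
    stopifnot(lambda >= 0)
    if (lambda == 0 && p >= n)
      stop("lambda = 0 with p >= n: regularization required", call. = FALSE)
    Theta <- .glasso(S, lambda)
  }
  Tm <- Theta + t(Theta) - t(Theta) %*% S %*% Theta
  dT <- diag(Tm)
  ij <- which(upper.tri(Tm), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  tij <- Tm[ij]
  pcor <- pmin(pmax(-tij / sqrt(dT[ij[, 1L]] * dT[ij[, 2L]]), -1), 1)
  se <- sqrt((dT[ij[, 1L]] * dT[ij[, 2L]] + tij^2) / n)
  z <- tij / se
  pval <- 2 * pnorm(-abs(z))
  qval <- p.adjust(pval, method = "BH")
  pairs <- data.frame(node1 = colnames(Xs)[ij[, 1L]],
                      node2 = colnames(Xs)[ij[, 2L]],
                      pcor = pcor, p_value = pval, q_value = qval)
  new("DSPCNetwork", nodes = colnames(Xs),
      edges = pairs[pairs$q_value <= fdr_alpha, , drop = FALSE],
      pairs = pairs, lambda = lambda, nSamples = as.integer(n),
      fdrAlpha = fdr_alpha)
})

#' @rdname dspc
#' @export
setMethod("dspc", "PeakTable", function(X, lambda = "auto", fdr_alpha = 0.05,
                                        log_transform = TRUE,
                                        missing_max = 0.2) {
  dspc(t(intensities(X)), lambda = lambda, fdr_alpha = fdr_alpha,
       log_transform = log_transform, missing_max = missing_max)
})

#' Node degrees of a DSPC network
#'
#' Counts, per node, the edges with `q <= q_threshold`. Deterministic
#' ordering: degree descending, then node id.
#'
#' @param net a [DSPCNetwork-class].
#' @param q_threshold q-value cutoff (default: the network's FDR level).
#' @return data.frame with columns `node` and `degree`.
#' @export
degreeTable <- function(net, q_threshold = NULL) {
  stopifnot(is(net, "DSPCNetwork"))
  if (is.null(q_threshold)) q_threshold <- net@fdrAlpha
  ed <- networkPairs(net)
  ed <- ed[ed$q_value <= q_threshold, , drop = FALSE]
  deg <- setNames(rep(0L, length(net@nodes)), net@nodes)
  if (nrow(ed)) {
    t1 <- table(ed$node1); t2 <- table(ed$node2)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  out <- data.frame(node = names(deg), degree = as.integer(deg))
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
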