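## Deterministic generators for every input the other modules need, with
## known ground truth. Every generator is a pure function of its seed.

#' Fixture specification for the synthetic generators
#'
#' Defaults describe a small but realistic untargeted LC-MS study: 100
#' database compounds between 80 and 800 Da, 20 pathways of 8-15 compounds,
#' two groups of 6 samples, log-normal intensities with 0.5 log-units of
#' noise, a planted log-fold-change of 2 on the members of one active
#' pathway, 2 ppm mass error, adducts of one compound co-eluting within 2
#' seconds, and 25 percent decoy peaks placed at least 10 ppm away from
#' every predicted adduct m/z.
#'
#' @param seed integer seed; every generator derives its RNG stream from it.
#' @param n_compounds,n_currency database size and number of
#'   currency-flagged compounds.
#' @param n_pathways,pathway_size_range pathway library shape.
#' @param n_samples samples per group.
#' @param n_active_pathways number of pathways receiving the planted effect.
#' @param effect_size log-fold-change applied to group 2 of planted
#'   features (>= 0).
#' @param noise_sd log-scale intensity noise SD.
#' @param decoy_peak_fraction decoy peaks as a fraction of compound peaks.
#' @param rt_range chromatogram span in seconds.
#' @param mass_error_ppm SD of the peak m/z error (ppm).
#' @param coelute_window adducts of one compound fall within this many
#'   seconds of each other.
#' @param adducts_per_compound range of adducts emitted per compound.
#' @param mode ionization mode of generated tables.
#' @return validated list of settings.
#' @export
fixtureSpec <- function(seed = 1, n_compounds = 100, n_currency = 3,
                        n_pathways = 20, pathway_size_range = c(8, 15),
                        n_samples = 6, n_active_pathways = 1,
                        effect_size = 2, noise_sd = 0.5,
                        decoy_peak_fraction = 0.25, rt_range = c(30, 1200),
                        mass_error_ppm = 2, coelute_window = 2,
                        adducts_per_compound = c(1, 3), mode = "positive") {
  stopifnot(n_compounds > 0, n_pathways > 0, n_samples > 0,
            n_active_pathways >= 0, effect_size >= 0, noise_sd > 0,
            decoy_peak_fraction >= 0, length(rt_range) == 2,
            rt_range[1] < rt_range[2],
            pathway_size_range[1] <= pathway_size_range[2])
  list(seed = as.integer(seed), n_compounds = n_compounds,
       n_currency = n_currency, n_pathways = n_pathways,
       pathway_size_range = pathway_size_range, n_samples = n_samples,
       n_active_pathways = n_active_pathways, effect_size = effect_size,
       noise_sd = noise_sd, decoy_peak_fraction = decoy_peak_fraction,
       rt_range = rt_range, mass_error_ppm = mass_error_ppm,
       coelute_window = coelute_window,
       adducts_per_compound = adducts_per_compound, mode = mode)
}

#' Generate a synthetic compound database
#'
#' Monoisotopic masses uniform in 80-800 Da with pairwise spacing above 50
#' ppm (so annotation is unambiguous at typical tolerances); a configurable
#' number of compounds is flagged as currency.
#'
#' @param spec a [fixtureSpec()].
#' @return A [CompoundDb-class].
#' @export
generateCompoundDb <- function(spec = fixtureSpec()) {
  set.seed(spec$seed)
  n <- spec$n_compounds
  masses <- numeric(0)
  for (round in 1:50) {
    cand <- sort(c(masses, runif(4 * n, 80, 800)))
    ## greedy pass: drop any candidate within 50 ppm of the previous kept one
    kept <- numeric(0)
    for (m in cand) {
      if (!length(kept) || (m - kept[length(kept)]) / kept[length(kept)] * 1e6 > 50)
        kept <- c(kept, m)
    }
    masses <- kept
    if (length(masses) >= n) break
  }
  if (length(masses) < n)
    stop("cannot place the requested number of compounds at > 50 ppm spacing",
         call. = FALSE)
  masses <- sort(sample(masses, n))
  ids <- sprintf("C%04d", seq_len(n))
  currency <- sample(ids, min(spec$n_currency, n))
  CompoundDb(ids = ids, masses = masses,
             names = sprintf("compound_%04d", seq_len(n)),
             currency = currency)
}

#' Generate a synthetic pathway library
#'
#' Pathways are sampled without replacement within each pathway from the
#' non-currency compounds; overlap between pathways is allowed unless
#' `zero_overlap`. Optional per-pathway gene members support joint-analysis
#' fixtures.
#'
#' @param db a [CompoundDb-class].
#' @param spec a [fixtureSpec()].
#' @param zero_overlap partition compounds so pairwise pathway
#'   intersections are empty.
#' @param genes_per_pathway number of (distinct) gene members per pathway.
#' @return A [PathwayLibrary-class].
#' @export
generatePathwayLibrary <- function(db, spec = fixtureSpec(),
                                   zero_overlap = FALSE,
                                   genes_per_pathway = 0) {
  set.seed(spec$seed + 1000L)
  pool <- setdiff(compoundIds(db), currencyIds(db))
  sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
                  spec$n_pathways, replace = TRUE)
  if (any(sizes > length(pool)))
    stop("pathway size exceeds available (non-currency) compounds",
         call. = FALSE)
  if (zero_overlap && sum(sizes) > length(pool))
    stop("zero-overlap library needs more compounds than available",
         call. = FALSE)
  cpds <- vector("list", spec$n_pathways)
  if (zero_overlap) {
    perm <- sample(pool)
    at <- 1L
    for (i in seq_along(sizes)) {
      cpds[[i]] <- perm[at:(at + sizes[i] - 1L)]
      at <- at + sizes[i]
    }
  } else {
    for (i in seq_along(sizes)) cpds[[i]] <- sample(pool, sizes[i])
  }
  genes <- if (genes_per_pathway > 0) {
    lapply(seq_along(sizes), function(i)
      sprintf("G%04d", (i - 1L) * genes_per_pathway + seq_len(genes_per_pathway)))
  } else rep(list(character()), spec$n_pathways)
  PathwayLibrary(ids = sprintf("P%03d", seq_len(spec$n_pathways)),
                 names = sprintf("pathway_%03d", seq_len(spec$n_pathways)),
                 compounds = cpds, genes = genes)
}

#' Generate a synthetic peak table with known ground truth
#'
#' Each observed (non-currency) compound emits one peak per sampled adduct
#' at the predicted m/z plus a Normal(0, `mass_error_ppm`) relative error,
#' at a retention time uniform in `rt_range` with the compound's adducts
#' co-eluting within `coelute_window` seconds. Intensities are log-normal;
#' features of compounds in the active pathways have their group-2
#' intensities multiplied by `exp(effect_size)`. Decoy peaks matching no
#' compound within 10 ppm under any adduct rule are added at
#' `decoy_peak_fraction`.
#'
#' @param db a [CompoundDb-class].
#' @param lib a [PathwayLibrary-class].
#' @param spec a [fixtureSpec()].
#' @param mode ionization mode (default from `spec`).
#' @param compounds optional subset of compound ids to observe (default all
#'   non-currency compounds).
#' @param seed RNG seed (default derived from `spec$seed`).
#' @param active_pathways optionally fix the active pathway ids.
#' @return list with `table` (a [PeakTable-class]), `active_pathways`,
#'   `planted_features` (feature ids carrying the effect), and
#'   `peak_compound` (the generating compound per feature, `NA` for
#'   decoys).
#' @export
generatePeakTable <- function(db, lib, spec = fixtureSpec(),
                              mode = spec$mode, compounds = NULL,
                              seed = spec$seed + 2000L,
                              active_pathways = NULL) {
  set.seed(seed)
  if (spec$n_active_pathways > length(pathwayIds(lib)))
    stop("n_active_pathways exceeds the library size", call. = FALSE)
  rules <- defaultAdductRules(mode)
  if (is.null(compounds)) compounds <- setdiff(compoundIds(db), currencyIds(db))
  masses <- compoundMasses(db)[compounds]
  if (is.null(active_pathways)) {
    active_pathways <- if (spec$n_active_pathways > 0)
      sort(sample(pathwayIds(lib), spec$n_active_pathways)) else character()
  }
  activeCpds <- unique(unlist(lib@compounds[match(active_pathways, lib@ids)]))
  mz <- rt <- numeric(0); cpd <- character(0)
  for (i in seq_along(compounds)) {
    nAdd <- sample(seq(spec$adducts_per_compound[1],
                       spec$adducts_per_compound[2]), 1L)
    nAdd <- min(nAdd, nrow(rules))
    rr <- rules[sample.int(nrow(rules), nAdd), , drop = FALSE]
    base <- runif(1, spec$rt_range[1], spec$rt_range[2])
    for (a in seq_len(nrow(rr))) {
      pm <- predictedMz(masses[i], rr$nmer[a], rr$mass_shift[a], rr$charge[a])
      mz <- c(mz, pm * (1 + rnorm(1, 0, spec$mass_error_ppm * 1e-6)))
      rt <- c(rt, base + runif(1, -spec$coelute_window / 2,
                               spec$coelute_window / 2))
      cpd <- c(cpd, compounds[i])
    }
  }
  ## decoys: uniformly placed, provably un-annotatable (>= 10 ppm from every
  ## predicted adduct m/z of every database compound)
  nDecoy <- round(spec$decoy_peak_fraction * length(mz))
  if (nDecoy > 0) {
    allPred <- sort(unlist(lapply(seq_len(nrow(rules)), function(a)
      predictedMz(unname(compoundMasses(db)), rules$nmer[a],
                  rules$mass_shift[a], rules$charge[a]))))
    placed <- 0L
    while (placed < nDecoy) {
      cand <- runif(1, min(allPred), max(allPred))
      near <- allPred[findInterval(cand, allPred, all.inside = FALSE) +
                        c(0L, 1L)]
      near <- near[!is.na(near) & near > 0]
      if (all(abs(cand - near) / near * 1e6 >= 10)) {
        mz <- c(mz, cand)
        rt <- c(rt, runif(1, spec$rt_range[1], spec$rt_range[2]))
        cpd <- c(cpd, NA_character_)
        placed <- placed + 1L
      }
    }
  }
  nFeat <- length(mz)
  nSamp <- 2L * spec$n_samples
  groups <- rep(c("group1", "group2"), each = spec$n_samples)
  baseLog <- rnorm(nFeat, mean = log(1e5), sd = 1)
  X <- matrix(rnorm(nFeat * nSamp, 0, spec$noise_sd), nFeat, nSamp) + baseLog
  planted <- !is.na(cpd) & cpd %in% activeCpds
  X[planted, groups == "group2"] <- X[planted, groups == "group2"] +
    spec$effect_size
  X <- exp(X)
  ## unique (mz, rt) keys are required downstream; nudge rare collisions
  key <- paste(mz, rt)
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    rt[d] <- rt[d] + 0.001
    key <- paste(mz, rt)
  }
  ids <- sprintf("%.6f__%.2f", mz, rt)
  pt <- PeakTable(X, mz = mz, rt = rt, groups = groups, mode = mode,
                  featureIds = ids,
                  sampleIds = paste0(rep(c("A", "B"), each = spec$n_samples),
                                     seq_len(spec$n_samples)))
  list(table = pt, active_pathways = active_pathways,
       planted_features = ids[planted], peak_compound = setNames(cpd, ids))
}

#' Generate complementary-mode peak tables for peak-pooling fixtures
#'
#' Assigns each non-currency compound to exactly one ionization mode, then
#' generates one positive-mode and one negative-mode table so that any
#' pathway is only fully observable by pooling the two.
#'
#' @param db,lib,spec as in [generatePeakTable()].
#' @param seed RNG seed (default derived from `spec$seed`).
#' @return list with `positive` and `negative` (each a [generatePeakTable()]
#'   result), and `active_pathways`.
#' @export
generateComplementaryPeakTables <- function(db, lib, spec = fixtureSpec(),
                                            seed = spec$seed + 3000L) {
  set.seed(seed)
  pool <- setdiff(compoundIds(db), currencyIds(db))
  toPos <- sample(c(TRUE, FALSE), length(pool), replace = TRUE)
  active <- if (spec$n_active_pathways > 0)
    sort(sample(pathwayIds(lib), spec$n_active_pathways)) else character()
  pos <- generatePeakTable(db, lib, spec, mode = "positive",
                           compounds = pool[toPos], seed = seed + 1L,
                           active_pathways = active)
  neg <- generatePeakTable(db, lib, spec, mode = "negative",
                           compounds = pool[!toPos], seed = seed + 2L,
                           active_pathways = active)
  list(positive = pos, negative = neg, active_pathways = active)
}

#' Build a chain (tridiagonal) precision matrix
#'
#' Diagonal 2, first off-diagonal 1: every adjacent pair has true partial
#' correlation -0.5; all other pairs 0.
#'
#' @param p dimension.
#' @return p x p precision matrix.
#' @export
chainPrecision <- function(p) {
  Theta <- diag(2, p)
  for (i in seq_len(p - 1L)) Theta[i, i + 1L] <- Theta[i + 1L, i] <- 1
  Theta
}

#' Generate multivariate-normal data from a known precision matrix
#'
#' @param precision symmetric positive-definite precision matrix.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return list with `X` (n x p matrix) and `pcor_true`
#'   (`-Theta_ij / sqrt(Theta_ii Theta_jj)`).
#' @export
generateNetworkData <- function(precision, n, seed = 1) {
  precision <- as.matrix(precision)
  if (!isSymmetric(precision, tol = 1e-10))
    stop("precision matrix must be symmetric", call. = FALSE)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision matrix must be positive definite", call. = FALSE)
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu = rep(0, ncol(precision)),
                     Sigma = solve(precision))
  colnames(X) <- paste0("F", seq_len(ncol(precision)))
  d <- sqrt(diag(precision))
  pcor <- -precision / outer(d, d)
  diag(pcor) <- 1
  list(X = X, pcor_true = pcor)
}
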