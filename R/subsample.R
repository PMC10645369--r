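# Sub-alignment construction with controlled quantity (B) and relevance (D):
# hard distance cutoffs around the wild type and exponentially biased random
# subsampling without replacement.

#' Hard distance-cutoff filter ("focusing")
#'
#' Keeps the sequences within `d_cut` raw Hamming distance of the wild type
#' and recomputes weights on the sub-alignment (when the parent alignment was
#' reweighted).
#'
#' @param aln an `msa_alignment`.
#' @param d_cut cutoff in raw site counts, `0 <= d_cut <= N`.
#' @return an `msa_alignment`.
#' @export
cutoff_filter <- function(aln, d_cut) {
  N <- ncol(aln$seqs)
  if (d_cut < 0 || d_cut > N)
    abort("d_cut must lie in [0, N]", class = "pf_parameter_error")
  idx <- which(wt_distances(aln) <= d_cut)
  if (length(idx) == 0)
    abort(sprintf("no sequences within d_cut = %g of the wild type", d_cut),
          class = "pf_empty_alignment")
  msa_subset(aln, idx)
}

# Analytic expectation of the distance under exponential selection weights
# (with-replacement approximation used to initialize the bias parameter).
expected_d <- function(alpha, d) {
  e <- -alpha * d
  w <- exp(e - max(e))
  sum(w * d) / sum(w)
}

# Selection weights proportional to exp(-alpha d), stabilized in log space.
selection_weights <- function(alpha, d) {
  e <- -alpha * d
  pmax(exp(e - max(e)), 1e-300)
}

# Bracketed bisection for alpha such that expected_d(alpha) = target.
solve_alpha <- function(target, d, tol = 1e-10, max_expand = 60) {
  lo <- -1; hi <- 1
  f <- function(a) expected_d(a, d) - target
  # expected_d is decreasing in alpha; expand the bracket until signs differ
  for (k in seq_len(max_expand)) {
    if (f(lo) > 0 && f(hi) < 0) break
    if (f(lo) <= 0) lo <- lo * 2
    if (f(hi) >= 0) hi <- hi * 2
  }
  if (!(f(lo) > 0 && f(hi) < 0)) return(if (f(0) > 0) hi else lo)
  for (k in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * (1 + abs(lo))) break
  }
  (lo + hi) / 2
}

# Weighted sampling without replacement (exponential-keys / top-B0 method);
# keys kept in log space so extreme weights cannot underflow.
sample_without_replacement <- function(w, b0) {
  keys <- log(runif(length(w))) / w
  order(keys, decreasing = TRUE)[seq_len(b0)]
}

#' Exponentially biased subsampling to a target mean distance
#'
#' Draws `B0` distinct sequences with selection probability proportional to
#' `exp(-alpha d(s, wt))`, tuning `alpha` (bisection on the analytic
#' expectation, then a stochastic refinement loop) until the realized
#' normalized mean distance `D/N` of the sub-alignment is within `precision`
#' of the target.
#'
#' @param aln an `msa_alignment`.
#' @param target_D target mean Hamming distance, in raw site counts.
#' @param B0 number of sequences to draw (before reweighting).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @param precision tolerance on the achieved normalized distance.
#' @param max_iter maximum refinement resamples.
#' @return an `msa_alignment` with attributes `alpha`, `achieved_D`,
#'   `target_D`.
#' @export
biased_subsample <- function(aln, target_D, B0, seed = NULL,
                             precision = 0.01, max_iter = 50) {
  M <- nrow(aln$seqs)
  N <- ncol(aln$seqs)
  if (B0 > M) abort("B0 exceeds the number of sequences",
                    class = "pf_parameter_error")
  d <- wt_distances(aln)
  ds <- sort(d)
  lo_att <- mean(ds[seq_len(B0)])
  hi_att <- mean(ds[seq(M - B0 + 1, M)])
  if (target_D < lo_att - precision * N || target_D > hi_att + precision * N)
    abort(sprintf(
      "target D = %.2f unattainable for B0 = %d (achievable range [%.2f, %.2f])",
      target_D, B0, lo_att, hi_att), class = "pf_convergence_error")

  run <- function() {
    best <- NULL
    draw <- function(alpha) {
      idx <- sample_without_replacement(selection_weights(alpha, d), B0)
      sub <- msa_subset(aln, idx)
      achieved <- msa_descriptors(sub)$D
      err <- abs(achieved - target_D) / N
      if (is.null(best) || err < best$err)
        best <<- list(sub = sub, alpha = alpha, achieved = achieved, err = err)
      achieved
    }
    # initial guess from the analytic (with-replacement) expectation, then
    # bisection on alpha against the realized without-replacement D, which
    # decreases (stochastically) in alpha
    alpha <- solve_alpha(target_D, d)
    achieved <- draw(alpha)
    iters <- 1
    a_lo <- a_hi <- alpha # a_lo: achieved above target, a_hi: below
    step <- 0.5
    while (iters < max_iter && best$err > precision) {
      if (achieved > target_D) {
        a_lo <- alpha
        if (a_hi <= a_lo) { alpha <- alpha + step; step <- step * 2 }
        else alpha <- (a_lo + a_hi) / 2
      } else {
        a_hi <- alpha
        if (a_lo >= a_hi) { alpha <- alpha - step; step <- step * 2 }
        else alpha <- (a_lo + a_hi) / 2
      }
      achieved <- draw(alpha)
      iters <- iters + 1
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (best$err > precision)
    abort(sprintf(
      "biased_subsample did not reach D = %.2f within %.3f (closest %.2f)",
      target_D, precision, best$achieved), class = "pf_convergence_error")
  out <- best$sub
  attr(out, "alpha") <- best$alpha
  attr(out, "achieved_D") <- best$achieved
  attr(out, "target_D") <- target_D
  out
}

#' Grid of sub-alignments over target distance and size
#'
#' Draws one sub-alignment per (target `D`, `B0`) cell with
#' [biased_subsample()]; per-cell seeds are derived deterministically from
#' `seed`. Unattainable cells are skipped with a warning and flagged in the
#' manifest.
#'
#' @param aln an `msa_alignment`.
#' @param D_targets target mean distances (raw sites). Default: 16 evenly
#'   spaced values in `[0.4 N, 0.8 N]`.
#' @param B0_values sub-alignment sizes before reweighting.
#' @param seed master seed.
#' @param precision tolerance passed to [biased_subsample()].
#' @return a list with `alignments` (named list) and `manifest` (tibble with
#'   cell id, targets, achieved `B` and `D`, `alpha`, seed, `ok`).
#' @export
subsample_grid <- function(aln, D_targets = NULL, B0_values, seed = 1L,
                           precision = 0.01) {
  N <- ncol(aln$seqs)
  if (is.null(D_targets)) D_targets <- seq(0.4 * N, 0.8 * N, length.out = 16)
  cells <- tidyr::expand_grid(target_D = D_targets, B0 = B0_values)
  alns <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell_seed <- derive_seed(seed, k)
    res <- tryCatch(
      biased_subsample(aln, cells$target_D[k], cells$B0[k],
                       seed = cell_seed, precision = precision),
      pf_convergence_error = function(e) e, pf_parameter_error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("grid cell %d (D = %.2f, B0 = %d) skipped: %s",
                   k, cells$target_D[k], cells$B0[k], conditionMessage(res)))
      rows[[k]] <- tibble(cell = k, target_D = cells$target_D[k],
                          B0 = cells$B0[k], B = NA_real_, D = NA_real_,
                          alpha = NA_real_, seed = cell_seed, ok = FALSE)
    } else {
      dsc <- msa_descriptors(res)
      alns[[k]] <- res
      rows[[k]] <- tibble(cell = k, target_D = cells$target_D[k],
                          B0 = cells$B0[k], B = dsc$B, D = dsc$D,
                          alpha = attr(res, "alpha"), seed = cell_seed,
                          ok = TRUE)
    }
  }
  manifest <- bind_rows(rows)
  names(alns) <- paste0("cell", manifest$cell)
  list(alignments = alns[manifest$ok], manifest = manifest)
}
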