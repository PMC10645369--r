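# The trade-off theory as executable estimators: analytic predictor variance,
# the linear bias model mu^2 = J0 * D with its best-scaling fit, focusing
# curves, cutoff predictors and the shuffle null.

#' Analytic global variance of the fitness predictor
#'
#' Sampling-noise estimate of the variance of the K-link predictor,
#' `sigma^2 = (1/B) (1/(N Q)) sum_{i, a != wt_i} { |k_i - 1| / p~_i(a) +
#' |k_i - 1| / p~_i(wt_i) + sum_{j in N_i} [ 1 / p~_ij(a, wt_j) +
#' 1 / p~_ij(wt_i, wt_j) ] }` with Q = 20. The `|k_i - 1|` factor is applied
#' literally, so a site with exactly one link contributes no single-site
#' term; the conventional 1/(NQ) prefactor is kept even though the inner sum has
#' Q - 1 terms per site (constant factors are absorbed by the fitted bias
#' factor).
#'
#' @param ft a `freq_tables` with `lambda > 0`.
#' @param model a `potts_model` (supplies the neighborhoods).
#' @param B effective sequence count; defaults to the table's `B`.
#' @return sigma^2 (squared log-probability units).
#' @export
variance_estimate <- function(ft, model, B = ft$B) {
  if (B <= 0) abort("B must be positive", class = "pf_parameter_error")
  if (any(ft$p <= 0)) abort("frequencies must be strictly positive")
  N <- ft$N; Q <- ft$Q
  wt <- ft$wt
  total <- 0
  inv_p <- 1 / ft$p
  for (i in seq_len(N)) {
    wti <- wt[i]
    others <- setdiff(seq_len(Q), wti)
    ki <- model$degrees[i]
    total <- total + abs(ki - 1) * (sum(inv_p[i, others]) +
                                      (Q - 1) * inv_p[i, wti])
    nb <- model$neighborhoods[[i]]
    for (r in seq_len(NROW(nb))) {
      j <- nb[r, 1]
      pij <- pair_frequencies(ft, i, j) # orientation (i, j)
      wtj <- wt[j]
      total <- total + sum(1 / pij[others, wtj]) +
        (Q - 1) / pij[wti, wtj]
    }
  }
  total / (B * N * Q)
}

#' Signal-to-noise ratio of a prediction table
#'
#' Population variance of the defined predicted effects divided by the
#' analytic variance `sigma2`.
#'
#' @param pred a `prediction_table`.
#' @param sigma2 analytic variance (positive).
#' @return a double.
#' @export
snr <- function(pred, sigma2) {
  if (sigma2 <= 0) abort("sigma2 must be positive")
  e <- defined_effects(pred)
  if (length(e) < 2) abort("need at least 2 defined predictions")
  (mean(e^2) - mean(e)^2) / sigma2
}

#' Best-scaling fit of the bias factor J0
#'
#' Finds `J0 >= 0` maximizing the absolute Spearman correlation between the
#' performance `rho` and the error proxy `J0 * D + sigma^2` across trade-off
#' records. The search uses a 200-point log-spaced grid scaled by
#' `median(sigma2) / median(D)` (so it is scale-aware), refined by a local
#' golden-section pass; among grid ties the smallest maximizing `J0` is
#' returned.
#'
#' @param records a tibble with columns `rho`, `D`, `sigma2` (e.g. from
#'   [run_tradeoff_workflow()]), at least 10 rows with non-constant `rho`.
#' @param n_grid grid resolution.
#' @param min_records minimum number of records required.
#' @return a `j0_fit` object; see [tidy.j0_fit()].
#' @export
fit_bias_factor <- function(records, n_grid = 200, min_records = 10) {
  stopifnot(all(c("rho", "D", "sigma2") %in% names(records)))
  records <- records[complete.cases(records[, c("rho", "D", "sigma2")]), ]
  if (nrow(records) < min_records)
    abort(sprintf("need at least %d records", min_records),
          class = "pf_parameter_error")
  if (sd(records$rho) == 0)
    abort("constant rho: bias factor unidentifiable",
          class = "pf_degenerate_fit")
  scale <- median(records$sigma2) / median(records$D)
  grid <- exp(seq(log(1e-6), log(1e3), length.out = n_grid)) * scale
  rs <- function(j0)
    abs(cor(records$rho, j0 * records$D + records$sigma2, method = "spearman"))
  vals <- vapply(grid, rs, 0)
  best <- which.max(vals) # first maximum = smallest maximizing grid point
  j0 <- grid[best]
  r_best <- vals[best]
  # local refinement (the objective is piecewise constant; keep the grid
  # point unless the refined value is strictly better)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(n_grid, best + 1)]
  opt <- stats::optimize(function(l) -rs(exp(l)), c(log(lo), log(hi)))
  if (-opt$objective > r_best + 1e-12) {
    j0 <- exp(opt$minimum)
    r_best <- -opt$objective
  }
  structure(list(J0 = j0, r_S = r_best, n = nrow(records),
                 K = if ("K" %in% names(records)) unique(records$K) else NA,
                 grid_range = range(grid)),
            class = "j0_fit")
}

#' @export
print.j0_fit <- function(x, ...) {
  cat(sprintf("<j0_fit> J0 = %.4g, r_S = %.3f (n = %d records)\n",
              x$J0, x$r_S, x$n))
  invisible(x)
}

#' Tidy a bias-factor fit
#'
#' @param x a `j0_fit`.
#' @param ... unused.
#' @return a one-row tibble with `J0`, `r_S`, `K`, `n`.
#' @export
tidy.j0_fit <- function(x, ...) {
  tibble(J0 = x$J0, r_S = x$r_S,
         K = if (length(x$K) == 1) x$K else NA_integer_, n = x$n)
}

#' @rdname tidy.j0_fit
#' @export
glance.j0_fit <- function(x, ...) tidy(x, ...)

#' Shuffle null for the scaling correlation
#'
#' Permutes `rho` across records `n_shuffles` times, refits the bias factor
#' each time, and summarizes the null distribution of the attained `r_S`.
#'
#' @param records as in [fit_bias_factor()].
#' @param n_shuffles number of permutations (default 100).
#' @param seed RNG seed.
#' @param min_records passed to [fit_bias_factor()].
#' @return a list with `r_s_null` (vector), `mean`, `sd`, `observed`, and
#'   the empirical `p_value` of the observed `r_S`.
#' @export
chance_null_rs <- function(records, n_shuffles = 100, seed = 1L,
                           min_records = 10) {
  observed <- fit_bias_factor(records, min_records = min_records)$r_S
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      shuffled <- records
      shuffled$rho <- sample(shuffled$rho)
      fit_bias_factor(shuffled, min_records = min_records)$r_S
    }, 0)
  })
  list(r_s_null = nulls, mean = mean(nulls), sd = sd(nulls),
       observed = observed,
       p_value = (1 + sum(nulls >= observed)) / (1 + n_shuffles))
}

#' Focusing curve: sweep the distance cutoff
#'
#' For each cutoff: filter the alignment with [cutoff_filter()], recompute
#' weights, train the requested K-link model, and record `B`, `D`, the
#' analytic `sigma2`, the `SNR`, and (when a scan is given) the performance
#' `rho`. Cells whose sub-alignment has fewer than `min_rows` sequences are
#' skipped.
#'
#' @param aln an `msa_alignment`.
#' @param scan optional `mutational_scan`.
#' @param d_cut_values cutoffs (raw sites); default: every distinct distance
#'   value up to N.
#' @param K number of links in the model trained at each cutoff.
#' @param lambda,reg_h,reg_J model hyper-parameters.
#' @param min_rows minimum sub-alignment size for a cell to be evaluated.
#' @return a `focus_curve` tibble with columns `d_cut`, `n_seq`, `B`, `D`,
#'   `D_norm`, `sigma2`, `snr`, `rho`.
#' @export
focus_curve <- function(aln, scan = NULL, d_cut_values = NULL, K = 0,
                        lambda = 0.01, reg_h = 0.01, reg_J = 0.01,
                        min_rows = 3) {
  N <- ncol(aln$seqs)
  if (is.null(d_cut_values)) {
    d <- sort(unique(wt_distances(aln)))
    d_cut_values <- unique(c(d, N))
  }
  if (any(d_cut_values < 0 | d_cut_values > N))
    abort("d_cut values must lie in [0, N]", class = "pf_parameter_error")
  rows <- purrr::map(sort(d_cut_values), function(dc) {
    sub <- tryCatch(cutoff_filter(aln, dc),
                    pf_empty_alignment = function(e) NULL)
    if (is.null(sub) || nrow(sub$seqs) < min_rows) return(NULL)
    ft <- frequencies(sub, lambda)
    model <- tryCatch(
      infer_potts(sub, K, lambda, reg_h, reg_J, ft = ft),
      error = function(e) NULL)
    if (is.null(model)) return(NULL)
    pred <- predict_mutations(model, sub$wt)
    s2 <- variance_estimate(ft, model)
    dsc <- msa_descriptors(sub)
    tibble(d_cut = dc, n_seq = dsc$n_seq, B = dsc$B, D = dsc$D,
           D_norm = dsc$D_norm, sigma2 = s2, snr = snr(pred, s2),
           rho = if (is.null(scan)) NA_real_ else
             as.numeric(performance(pred, scan)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("all cutoff cells were skipped",
                            class = "pf_data_error")
  class(out) <- c("focus_curve", class(out))
  attr(out, "K") <- K
  attr(out, "N") <- N
  out
}

#' Bias-variance optimal cutoff
#'
#' `d_bv = argmin_{d_cut} J0 * D(d_cut) + sigma^2(d_cut)`; ties resolve to
#' the larger cutoff (more data at equal predicted error).
#'
#' @param curve a `focus_curve`.
#' @param J0 bias factor (>= 0), e.g. from [fit_bias_factor()].
#' @return the selected cutoff.
#' @export
predict_cutoff_bv <- function(curve, J0) {
  if (J0 < 0) abort("J0 must be non-negative", class = "pf_parameter_error")
  if (nrow(curve) == 0) abort("empty focus curve")
  obj <- J0 * curve$D + curve$sigma2
  cand <- which(obj <= min(obj) + 1e-12)
  max(curve$d_cut[cand])
}

#' Signal-to-noise cutoff heuristic
#'
#' The smallest cutoff whose SNR still reaches `threshold` (focus as tightly
#' as the signal allows). Falls back to the largest swept cutoff with a
#' warning when no cell reaches the threshold.
#'
#' @param curve a `focus_curve`.
#' @param threshold SNR threshold; the default 3 is a rule of thumb, with
#'   consistent behaviour for thresholds in roughly 2..4.
#' @return the selected cutoff.
#' @export
predict_cutoff_snr <- function(curve, threshold = 3) {
  ok <- which(curve$snr >= threshold)
  if (length(ok) == 0) {
    warn("no cutoff reaches the SNR threshold; returning the full sweep range")
    return(max(curve$d_cut))
  }
  min(curve$d_cut[ok])
}

#' Empirically optimal cutoff
#'
#' The cutoff maximizing the measured performance; ties (plateaus) resolve
#' to the larger cutoff.
#'
#' @param curve a `focus_curve` with a `rho` column.
#' @return the selected cutoff.
#' @export
optimal_cutoff <- function(curve) {
  if (all(is.na(curve$rho))) abort("curve has no performance values")
  cand <- which(curve$rho >= max(curve$rho, na.rm = TRUE) - 1e-12)
  max(curve$d_cut[cand])
}

#' Plot a focusing curve
#'
#' Performance (when present) and the bias/variance decomposition along the
#' cutoff sweep.
#'
#' @param object a `focus_curve`.
#' @param J0 optional bias factor used to draw `J0 D + sigma^2`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.focus_curve <- function(object, J0 = NULL, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(
    mutate(df,
           `sigma^2` = .data$sigma2,
           `J0 D + sigma^2` = if (is.null(J0)) NA_real_ else
             J0 * .data$D + .data$sigma2,
           rho = .data$rho),
    cols = c("rho", "sigma^2", "J0 D + sigma^2"),
    names_to = "quantity", values_to = "value")
  long <- filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$d_cut, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cutoff distance d_cut (sites)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot trade-off records against the fitted error proxy
#'
#' @param records trade-off records (columns `rho`, `D`, `sigma2`,
#'   optionally `K`).
#' @param fit a `j0_fit` (or a bare J0 value).
#' @return a ggplot object.
#' @export
plot_tradeoff <- function(records, fit) {
  j0 <- if (inherits(fit, "j0_fit")) fit$J0 else as.numeric(fit)
  df <- mutate(records, proxy = j0 * .data$D + .data$sigma2)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$proxy, .data$rho)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(J[0] * D + sigma^2), y = expression(rho)) +
    ggplot2::theme_minimal()
  if ("K" %in% names(records) && length(unique(records$K)) > 1)
    p <- p + ggplot2::facet_wrap(~K, labeller = ggplot2::label_both)
  p
}
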