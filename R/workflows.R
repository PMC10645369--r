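# End-to-end, reproducible workflows tying the modules together: the
# lattice-protein bench world, the trade-off (subsample grid -> per-cell
# training -> bias-factor fits -> shuffle null) workflow, and the focusing
# workflow.

#' Build a self-contained lattice-protein bench world
#'
#' Assembles everything the validation workflows need: a (reduced) fold
#' repertoire, a native fold, a designed wild type with `P_nat` around
#' 0.995, the exact single-mutant effects, and a pooled alignment sampled
#' with the four distance-bias strengths `gamma = 0, 0.025, 0.050, 0.075`
#' (duplicates removed, unit weights — no reweighting for lattice data).
#'
#' The full repertoire has ~1e5 folds; desk-scale runs use a seeded random
#' sub-repertoire (default 2000 folds) so that the whole bench fits in
#' minutes. The landscape remains exactly computable, just over a smaller
#' competition set.
#'
#' @param seed master seed; all stages derive their own seeds from it.
#' @param n_folds size of the competition repertoire (including the native).
#' @param n_per_gamma recorded samples per chain.
#' @param gammas distance-bias strengths.
#' @param beta,thin Metropolis settings (defaults 1000 and 1000).
#' @param theta observability threshold for the ground truth.
#' @param mj contact-energy matrix.
#' @return a `lattice_world`: list with `repertoire`, `native`, `wt`,
#'   `truth`, `scan` (ground truth as a mutational scan), `msa` (pooled
#'   alignment), `mj`, `seed`.
#' @export
lattice_world <- function(seed = 1L, family_seed = 1L, n_folds = 2000,
                          n_per_gamma = 600,
                          gammas = c(0, 0.025, 0.05, 0.075), beta = 1000,
                          thin = 1000, theta = 5, mj = contact_energies()) {
  full <- enumerate_folds()
  native_full <- withr::with_seed(derive_seed(family_seed, 1),
                                  sample.int(full$n_folds, 1))
  red <- subsample_repertoire(full, n_folds, native_full,
                              seed = derive_seed(family_seed, 2))
  rep <- red$repertoire
  native <- red$native
  wt <- select_wildtype(rep, native, mj, seed = derive_seed(family_seed, 3))
  truth <- ground_truth_effects(wt, rep, native, mj, theta = theta)
  chains <- purrr::imap(gammas, function(g, k) {
    metropolis_sample(wt, rep, native, n_samples = n_per_gamma, gamma = g,
                      beta = beta, thin = thin, mj = mj,
                      seed = derive_seed(seed, 10 + k))$seqs
  })
  seqs <- do.call(rbind, chains)
  keep <- !duplicated(apply(seqs, 1, paste, collapse = ","))
  msa <- new_alignment(seqs[keep, , drop = FALSE],
                       ids = paste0("lp", which(keep)), wt = wt,
                       reweighted = FALSE)
  structure(list(repertoire = rep, native = native, wt = wt, truth = truth,
                 scan = truth_scan(truth), msa = msa, mj = mj, seed = seed),
            class = "lattice_world")
}

#' @export
print.lattice_world <- function(x, ...) {
  cat(sprintf(
    "<lattice_world> %d folds, wt P_nat = %.4f, pooled MSA %d x %d\n",
    x$repertoire$n_folds, attr(x$wt, "pnat"), nrow(x$msa$seqs),
    ncol(x$msa$seqs)))
  invisible(x)
}

#' Trade-off workflow: subsample grid, per-cell models, bias-factor fits
#'
#' Draws `n_rep` sub-alignments per (target D, B0) cell, trains one K-link
#' model per requested K on each (one pseudo-likelihood fit per
#' sub-alignment, shared across K), and records per cell and K the mean
#' performance `rho`, analytic variance `sigma2`, achieved `B` and `D`.
#' When a `lattice_truth` is supplied, the numerical squared bias and
#' variance across the repetitions are recorded too. The bias factor is
#' then fitted per K, with the shuffle null.
#'
#' @param aln alignment to subsample.
#' @param scan mutational scan used to measure performance.
#' @param K_values link counts to evaluate.
#' @param D_targets,B0_values,precision subsampling grid (see
#'   [subsample_grid()]); defaults: 16 D values in `[0.4 N, 0.8 N]`.
#' @param n_rep repetitions (independent sub-alignments) per cell.
#' @param lambda,reg_h,reg_J model hyper-parameters.
#' @param truth optional `lattice_truth` for ground-truth bias/variance.
#' @param n_shuffles shuffle-null size (0 to skip).
#' @param min_records minimum grid cells required for a bias-factor fit.
#' @param seed master seed.
#' @return a list with `records` (tibble: cell, K, target_D, B0, rep-mean
#'   `B`, `D`, `sigma2`, `rho`, and `mu_bar2`, `sigma_bar2` when truth is
#'   given), `j0_fits` (tibble per K), `nulls` (list per K), `skipped`
#'   (tibble of unattainable cells).
#' @export
run_tradeoff_workflow <- function(aln, scan, K_values = c(0, 8, 24),
                                  D_targets = NULL, B0_values,
                                  n_rep = 3, lambda = 0.01, reg_h = 0.01,
                                  reg_J = 0.01, precision = 0.01,
                                  truth = NULL, n_shuffles = 100,
                                  min_records = 10, seed = 1L) {
  N <- ncol(aln$seqs)
  if (is.null(D_targets)) D_targets <- seq(0.4 * N, 0.8 * N, length.out = 16)
  cells <- tidyr::expand_grid(target_D = D_targets, B0 = B0_values)
  max_K <- max(K_values)
  records <- list()
  skipped <- list()
  for (cidx in seq_len(nrow(cells))) {
    tD <- cells$target_D[cidx]
    B0 <- cells$B0[cidx]
    reps <- vector("list", n_rep)
    failed <- FALSE
    for (r in seq_len(n_rep)) {
      sub <- tryCatch(
        biased_subsample(aln, tD, B0, precision = precision,
                         seed = derive_seed(seed, cidx * 100 + r)),
        pf_convergence_error = function(e) e,
        pf_parameter_error = function(e) e)
      if (inherits(sub, "error")) {
        skipped[[length(skipped) + 1]] <-
          tibble(cell = cidx, target_D = tD, B0 = B0,
                 reason = conditionMessage(sub))
        failed <- TRUE
        break
      }
      ft <- frequencies(sub, lambda)
      scores <- if (max_K > 0)
        frobenius_scores(infer_plm(sub, reg_h, reg_J, maxit = 80)) else NULL
      dsc <- msa_descriptors(sub)
      per_K <- purrr::map(K_values, function(K) {
        model <- if (K == 0) infer_independent(ft) else
          infer_two_site(ft, select_links(scores, K))
        pred <- predict_mutations(model, sub$wt)
        list(K = K, pred = pred,
             sigma2 = variance_estimate(ft, model),
             rho = as.numeric(performance(pred, scan)))
      })
      reps[[r]] <- list(B = dsc$B, D = dsc$D, per_K = per_K)
    }
    if (failed) next
    for (kidx in seq_along(K_values)) {
      K <- K_values[kidx]
      sig <- mean(vapply(reps, function(x) x$per_K[[kidx]]$sigma2, 0))
      rho <- mean(vapply(reps, function(x) x$per_K[[kidx]]$rho, 0))
      row <- tibble(cell = cidx, K = K, target_D = tD, B0 = B0,
                    B = mean(vapply(reps, function(x) x$B, 0)),
                    D = mean(vapply(reps, function(x) x$D, 0)),
                    sigma2 = sig, rho = rho)
      if (!is.null(truth) && n_rep >= 2) {
        nbv <- numeric_bias_variance(
          purrr::map(reps, function(x) x$per_K[[kidx]]$pred), truth)
        row$mu_bar2 <- nbv$mu2
        row$sigma_bar2 <- nbv$sigma2
      }
      records[[length(records) + 1]] <- row
    }
  }
  records <- bind_rows(records)
  if (nrow(records) == 0) abort("no grid cell could be evaluated",
                                class = "pf_data_error")
  j0_fits <- records |>
    dplyr::group_split(.data$K) |>
    purrr::map(function(df)
      tidy(fit_bias_factor(df, min_records = min_records))) |>
    bind_rows()
  nulls <- if (n_shuffles > 0) {
    ks <- sort(unique(records$K))
    setNames(purrr::imap(ks, function(K, kk)
      chance_null_rs(filter(records, .data$K == K), n_shuffles,
                     seed = derive_seed(seed, 90000 + kk),
                     min_records = min_records)), ks)
  } else list()
  list(records = records, j0_fits = j0_fits, nulls = nulls,
       skipped = bind_rows(skipped))
}

#' Focusing workflow: cutoff sweep with annotated optimal cutoffs
#'
#' Sweeps the distance cutoff with [focus_curve()] and annotates the
#' empirically optimal cutoff `d_opt`, the bias-variance prediction `d_bv`
#' (when a bias factor is available), the SNR heuristic `d_snr`, and the
#' performance gains relative to the full alignment.
#'
#' @inheritParams focus_curve
#' @param J0 bias factor for `d_bv` (omitted with a warning when `NULL`).
#' @param snr_threshold SNR threshold for `d_snr`.
#' @return a list with `curve` and `summary` (one-row tibble: d_opt, d_bv,
#'   d_snr, rho at each, rho_full, delta_rho at each cutoff).
#' @export
run_focus_workflow <- function(aln, scan, d_cut_values = NULL, K = 0,
                               lambda = 0.01, reg_h = 0.01, reg_J = 0.01,
                               J0 = NULL, snr_threshold = 3) {
  curve <- focus_curve(aln, scan, d_cut_values, K, lambda, reg_h, reg_J)
  rho_at <- function(dc) curve$rho[match(dc, curve$d_cut)]
  d_opt <- optimal_cutoff(curve)
  d_snr <- predict_cutoff_snr(curve, snr_threshold)
  if (is.null(J0)) {
    warn("no bias factor supplied: d_bv omitted")
    d_bv <- NA_real_
  } else {
    d_bv <- predict_cutoff_bv(curve, J0)
  }
  rho_full <- curve$rho[which.max(curve$d_cut)]
  summary <- tibble(
    d_opt = d_opt, d_bv = d_bv, d_snr = d_snr,
    rho_full = rho_full, rho_opt = rho_at(d_opt),
    rho_bv = if (is.na(d_bv)) NA_real_ else rho_at(d_bv),
    rho_snr = rho_at(d_snr),
    delta_rho_opt = rho_at(d_opt) - rho_full,
    delta_rho_bv = if (is.na(d_bv)) NA_real_ else rho_at(d_bv) - rho_full,
    delta_rho_snr = rho_at(d_snr) - rho_full)
  list(curve = curve, summary = summary)
}

#' Write workflow outputs to disk
#'
#' Records and manifests as CSV, fits and summaries as JSON; everything is
#' reproducible from the seeds stored alongside.
#'
#' @param result output of [run_tradeoff_workflow()] or
#'   [run_focus_workflow()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_workflow <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (is.data.frame(obj)) {
      readr::write_csv(obj, file.path(dir, paste0(nm, ".csv")))
    } else if (nm == "nulls") {
      jsonlite::write_json(
        purrr::map(obj, function(x) x[c("mean", "sd", "observed", "p_value")]),
        file.path(dir, "nulls.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}
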