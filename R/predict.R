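# Mutation scoring with a Potts model and benchmarking against a scan.

#' Predicted fitness difference of a single mutation
#'
#' For the K-link model the predictor is
#' `h_i(a) - h_i(wt_i) + sum_{j in N_i} (J_ij(a, wt_j) - J_ij(wt_i, wt_j))`,
#' which equals the exact log-probability difference
#' `log P(wt_{i->a}) - log P(wt)` (the normalization cancels).
#'
#' @param model a `potts_model`.
#' @param wt wild-type integer codes (length N, no gaps).
#' @param i site index (1-based).
#' @param a target residue code (1..Q).
#' @return a real number; 0 when `a` equals the wild-type residue.
#' @export
delta_fitness <- function(model, wt, i, a) {
  if (i < 1 || i > model$N) abort("site out of range")
  if (a < 1 || a > model$Q)
    abort("target residue must be an amino-acid code (gap not allowed)",
          class = "pf_domain_error")
  wti <- wt[i]
  e <- model$h[i, a] - model$h[i, wti]
  nb <- model$neighborhoods[[i]]
  for (r in seq_len(NROW(nb))) {
    Jk <- model$J[[nb[r, 2]]]
    b <- wt[nb[r, 1]]
    e <- e + if (nb[r, 3] == 0L) Jk[a, b] - Jk[wti, b] else Jk[b, a] - Jk[b, wti]
  }
  e
}

#' Score every single mutation of the wild type
#'
#' @param model a `potts_model`.
#' @param wt wild-type integer codes.
#' @return a `prediction_table`: N x Q matrix `E` of predicted fitness
#'   differences (0 on the wild-type residue), with the wild type attached.
#'   `tidy()` turns it into a tibble of defined (a != wt_i) entries.
#' @export
predict_mutations <- function(model, wt) {
  N <- model$N; Q <- model$Q
  E <- model$h - model$h[cbind(seq_len(N), wt)]
  nb_all <- model$neighborhoods
  for (i in seq_len(N)) {
    nb <- nb_all[[i]]
    for (r in seq_len(NROW(nb))) {
      Jk <- model$J[[nb[r, 2]]]
      b <- wt[nb[r, 1]]
      col <- if (nb[r, 3] == 0L) Jk[, b] else Jk[b, ]
      E[i, ] <- E[i, ] + col - col[wt[i]]
    }
  }
  structure(list(E = E, wt = as.integer(wt), N = N, Q = Q),
            class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat(sprintf("<prediction_table> %d x %d (%d defined single mutations)\n",
              x$N, x$Q, x$N * (x$Q - 1)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname predict_mutations
#' @param x a `prediction_table`.
#' @param ... unused.
#' @export
tidy.prediction_table <- function(x, ...) {
  grid <- tidyr::expand_grid(site = seq_len(x$N), mut_code = seq_len(x$Q))
  out <- mutate(grid,
                wt_code = x$wt[.data$site],
                effect = x$E[cbind(.data$site, .data$mut_code)])
  filter(out, .data$mut_code != .data$wt_code)
}

# Defined prediction entries as a flat vector (a != wt_i).
defined_effects <- function(pred) {
  mask <- col(pred$E) != pred$wt[row(pred$E)]
  pred$E[mask]
}

#' Predictive performance against a mutational scan
#'
#' Spearman rank correlation between measured and predicted effects over the
#' intersection of the scan with the defined predictions (ties get average
#' ranks).
#'
#' @param pred a `prediction_table`.
#' @param scan a `mutational_scan` tibble (columns `site`, `mut_code`,
#'   `score`).
#' @param sign_convention `+1` when higher score means fitter (default),
#'   `-1` for scans where lower is fitter.
#' @return a double with attribute `n_overlap`.
#' @export
performance <- function(pred, scan, sign_convention = 1) {
  ok <- scan$site >= 1 & scan$site <= pred$N &
    scan$mut_code >= 1 & scan$mut_code <= pred$Q &
    scan$mut_code != pred$wt[scan$site]
  sc <- scan[ok, ]
  if (nrow(sc) < 3)
    abort("fewer than 3 overlapping mutations: performance undefined",
          class = "pf_undefined_performance")
  x <- pred$E[cbind(sc$site, sc$mut_code)]
  rho <- cor(x, sign_convention * sc$score, method = "spearman")
  attr(rho, "n_overlap") <- nrow(sc)
  rho
}
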