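# Lattice-protein ground truth: compact 27-mer folds on the 3x3x3 cube,
# contact-energy landscapes, native-fold probability, wild-type design,
# distance-biased Metropolis sampling, exact mutational effects, and
# numerical bias/variance of a predictor against them.

#' Pairwise residue contact energies (synthetic stand-in)
#'
#' A 20 x 20 symmetric contact-energy matrix for the lattice landscape. The
#' published Miyazawa-Jernigan table is not redistributed here; this is a
#' SYNTHETIC stand-in built as the rank-one product of the Miyazawa (1985)
#' per-residue contact propensities (the dominant mode of the empirical
#' contact matrix) plus a small fixed symmetric perturbation that provides
#' pair specificity. Deterministic; any symmetric finite matrix can be
#' supplied in its place throughout the lattice API.
#'
#' @param product_scale scale of the hydrophobic product term.
#' @param specificity_sd spread of the fixed perturbation term.
#' @return a 20 x 20 symmetric numeric matrix (dimnames = amino acids),
#'   in energy units of k_B T.
#' @export
contact_energies <- function(product_scale = 0.1, specificity_sd = 0.3) {
  # Miyazawa (1985) contact propensity scale, alphabetical one-letter order
  q <- c(A = 5.33, C = 7.93, D = 3.59, E = 3.65, F = 9.03, G = 4.48,
         H = 5.10, I = 8.83, K = 2.95, L = 8.47, M = 8.95, N = 3.71,
         P = 3.87, Q = 3.87, R = 4.18, S = 4.09, T = 4.49, V = 7.63,
         W = 7.66, Y = 5.89)
  e <- -product_scale * outer(q, q)
  pert <- withr::with_seed(19961L, {
    m <- matrix(stats::rnorm(400, sd = specificity_sd), 20, 20)
    (m + t(m)) / 2
  })
  e <- e + pert
  dimnames(e) <- list(AA_LETTERS, AA_LETTERS)
  e
}

#' Enumerate all compact folds of a 27-mer on the 3x3x3 cube
#'
#' Exhaustive depth-first enumeration of Hamiltonian self-avoiding walks,
#' canonicalized under the 48 cube rotations/reflections — the classic
#' repertoire of 103,346 symmetry-distinct compact conformations. Also
#' identifying a chain with its reverse gives 51,704 folds
#' (`identify_reversal = TRUE`). Each fold carries its 28-contact list. The
#' result is cached for the session.
#'
#' @param identify_reversal treat a chain and its reverse as the same fold
#'   (default `FALSE`, matching the 103,346 count).
#' @return a `fold_repertoire`: list with `paths` (F x 27 matrix of 0-based
#'   cell ids), `contacts` (F x 56 matrix: 28 (i, j) residue pairs per row,
#'   1-based), `n_folds`, `identify_reversal`.
#' @export
enumerate_folds <- function(identify_reversal = FALSE) {
  key <- paste0("repertoire_", identify_reversal)
  rep <- .pf_cache[[key]]
  if (is.null(rep)) {
    paths <- enumerate_folds_cpp(identify_reversal)
    contacts <- fold_contacts_cpp(paths)
    rep <- structure(list(paths = paths, contacts = contacts,
                          n_folds = nrow(paths),
                          identify_reversal = identify_reversal),
                     class = "fold_repertoire")
    .pf_cache[[key]] <- rep
  }
  rep
}

#' @export
print.fold_repertoire <- function(x, ...) {
  cat(sprintf("<fold_repertoire> %d compact folds (reversal identified: %s)\n",
              x$n_folds, x$identify_reversal))
  invisible(x)
}

#' Count folds with an independently coded enumerator
#'
#' Cross-check for [enumerate_folds()]: an iterative (non-recursive)
#' enumeration with reversed neighbour ordering and a different
#' canonicalization rule. Returns the count only.
#'
#' @inheritParams enumerate_folds
#' @return the number of symmetry-distinct folds.
#' @export
count_folds_independent <- function(identify_reversal = FALSE) {
  count_folds_check_cpp(identify_reversal)
}

#' Random sub-repertoire for desk-scale benches
#'
#' Keeps `n_folds` folds drawn without replacement (always retaining
#' `native`) and returns the reduced repertoire together with the new index
#' of the native fold.
#'
#' @param rep a `fold_repertoire`.
#' @param n_folds target size.
#' @param native index of the native fold in `rep`.
#' @param seed RNG seed.
#' @return a list with `repertoire` and `native`.
#' @export
subsample_repertoire <- function(rep, n_folds, native, seed = 1L) {
  keep <- withr::with_seed(seed, {
    pool <- setdiff(seq_len(rep$n_folds), native)
    c(native, sample(pool, n_folds - 1))
  })
  out <- rep
  out$paths <- rep$paths[keep, , drop = FALSE]
  out$contacts <- rep$contacts[keep, , drop = FALSE]
  out$n_folds <- length(keep)
  list(repertoire = out, native = 1L)
}

#' Folding energy of a sequence on one fold
#'
#' Sum of the contact energies over the fold's 28 contacts.
#'
#' @param rep a `fold_repertoire`.
#' @param fold fold index.
#' @param seq sequence (length-27 integer codes 1..20 or a string; gaps are
#'   not allowed).
#' @param mj 20 x 20 contact-energy matrix.
#' @return the energy (scalar).
#' @export
fold_energy <- function(rep, fold, seq, mj = contact_energies()) {
  seq <- as_lattice_seq(seq)
  contacts <- rep$contacts[fold, ]
  i <- contacts[c(TRUE, FALSE)]
  j <- contacts[c(FALSE, TRUE)]
  sum(mj[cbind(seq[i], seq[j])])
}

as_lattice_seq <- function(seq) {
  if (is.character(seq)) seq <- encode_residues(strsplit(seq, "")[[1]])
  seq <- as.integer(seq)
  if (length(seq) != 27) abort("lattice sequences have 27 sites")
  if (any(seq > 20L)) abort("gaps are not allowed in lattice sequences")
  seq
}

#' Native-fold probability and lattice fitness
#'
#' `p_nat` is the Boltzmann probability of the native fold among all folds
#' of the repertoire (softmax of minus the folding energies, numerically
#' stabilized); the fitness cost is `H = -log P_nat >= 0`.
#'
#' @param seqs a single sequence or an integer matrix (rows = sequences).
#' @param rep a `fold_repertoire`.
#' @param native native fold index.
#' @param mj contact-energy matrix.
#' @return `p_nat()` returns probabilities; `lattice_fitness()` returns `H`.
#' @export
p_nat <- function(seqs, rep, native, mj = contact_energies()) {
  pnat_h(seqs, rep, native, mj)$pnat
}

#' @rdname p_nat
#' @export
lattice_fitness <- function(seqs, rep, native, mj = contact_energies()) {
  pnat_h(seqs, rep, native, mj)$H
}

pnat_h <- function(seqs, rep, native, mj) {
  if (rep$n_folds == 0) abort("empty repertoire")
  if (!is.matrix(seqs)) seqs <- matrix(as_lattice_seq(seqs), 1)
  storage.mode(seqs) <- "integer"
  pnat_h_cpp(rep$contacts, as.integer(native), seqs, mj)
}

#' Design a wild-type sequence with target native stability
#'
#' Greedy Monte-Carlo search maximizing `P_nat`, stopped as soon as the
#' native-fold probability lies in `target` (default around 0.995: stable
#' but leaving room for beneficial mutations). When a greedy step overshoots
#' the band, the in-band single mutant closest to the band's centre is
#' taken. The returned wild type is guaranteed to admit at least one fitness
#' -improving single mutation.
#'
#' @param rep a `fold_repertoire`.
#' @param native native fold index.
#' @param mj contact-energy matrix.
#' @param target inclusive `P_nat` band, default `c(0.990, 0.997)`.
#' @param seed RNG seed.
#' @param max_restarts random restarts before giving up.
#' @return integer codes of the wild type, with attribute `pnat`.
#' @export
select_wildtype <- function(rep, native, mj = contact_energies(),
                            target = c(0.990, 0.997), seed = 1L,
                            max_restarts = 20) {
  centre <- mean(target)
  search <- function() {
    best_found <- NULL
    for (restart in seq_len(max_restarts)) {
      s <- sample.int(20L, 27, replace = TRUE)
      p <- p_nat(s, rep, native, mj)
      for (step in seq_len(500)) {
        if (p >= target[1] && p <= target[2]) {
          if (has_positive_mutation(s, rep, native, mj)) {
            attr(s, "pnat") <- p
            return(s)
          }
          break # stable but no beneficial mutant: restart
        }
        muts <- all_single_mutants(s)
        pm <- p_nat(muts, rep, native, mj)
        in_band <- which(pm >= target[1] & pm <= target[2])
        nxt <- if (length(in_band)) in_band[which.min(abs(pm[in_band] - centre))]
               else which.max(pm)
        if (pm[nxt] <= p && length(in_band) == 0) break # local maximum
        s <- muts[nxt, ]
        p <- pm[nxt]
      }
      if (is.null(best_found) || abs(p - centre) < abs(attr(best_found, "pnat") - centre)) {
        attr(s, "pnat") <- p
        best_found <- s
      }
    }
    abort(sprintf(
      "wild-type search failed: best P_nat = %.4f outside [%.3f, %.3f]",
      attr(best_found, "pnat"), target[1], target[2]),
      class = "pf_convergence_error")
  }
  withr::with_seed(seed, search())
}

all_single_mutants <- function(s) {
  out <- matrix(rep(s, each = 27 * 19), 27 * 19, 27)
  k <- 0
  for (i in seq_len(27)) {
    for (a in setdiff(1:20, s[i])) {
      k <- k + 1
      out[k, ] <- s
      out[k, i] <- a
    }
  }
  storage.mode(out) <- "integer"
  out
}

has_positive_mutation <- function(s, rep, native, mj) {
  H0 <- lattice_fitness(s, rep, native, mj)
  any(lattice_fitness(all_single_mutants(s), rep, native, mj) < H0)
}

#' Sample a lattice MSA with a distance-biased Metropolis chain
#'
#' Samples sequences from the distance-biased Hamiltonian
#' `H_gamma(s) = -log P_nat(s) + gamma d(wt, s)` (raw-count distance) with
#' the Metropolis rule at inverse temperature `beta`, recording one sequence
#' every `thin` proposals. `gamma > 0` attracts the chain toward the wild
#' type, so the mean distance D of the samples decreases as `gamma` grows;
#' sweeping `gamma` therefore tunes the relevance of the sampled family. No
#' sequence reweighting is applied to lattice data (weights stay 1).
#'
#' @param wt wild-type codes (chain start).
#' @param rep a `fold_repertoire`.
#' @param native native fold index.
#' @param n_samples number of recorded sequences.
#' @param gamma distance-bias strength; the sampling settings used for the
#'   bench are 0, 0.025, 0.050, 0.075.
#' @param beta inverse-temperature factor (default 1000).
#' @param thin proposals between recorded sequences (default 1000).
#' @param mj contact-energy matrix.
#' @param seed RNG seed.
#' @return an `msa_alignment` with unit weights and `wt` as reference.
#' @export
metropolis_sample <- function(wt, rep, native, n_samples, gamma = 0,
                              beta = 1000, thin = 1000,
                              mj = contact_energies(), seed = NULL) {
  wt <- as_lattice_seq(wt)
  if (gamma < 0 || beta <= 0 || thin < 1)
    abort("invalid sampler configuration", class = "pf_parameter_error")
  run <- function() metropolis_sample_cpp(rep$contacts, as.integer(native),
                                          wt, mj, gamma, beta,
                                          as.integer(thin),
                                          as.integer(n_samples))
  seqs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new_alignment(seqs, ids = sprintf("mc_g%s_%d", gamma, seq_len(n_samples)),
                wt = wt, reweighted = FALSE)
}

#' Exact single-mutant fitness effects (ground truth)
#'
#' `E_ia = H(wt_{i->a}) - H(wt)` for all 27 x 19 single mutants, computed
#' exactly from the repertoire, plus the observability mask `|E_ia| < theta`
#' excluding mutations too deleterious to ever be observed in sampled data.
#'
#' @param wt wild-type codes.
#' @param rep a `fold_repertoire`.
#' @param native native fold index.
#' @param mj contact-energy matrix.
#' @param theta observability threshold (default 5.0).
#' @return a `lattice_truth`: list with `E` (27 x 20, 0 at the wild-type
#'   residue), `mask` (logical 27 x 20, `FALSE` at wt entries and outliers),
#'   `wt`, `theta`, `H_wt`.
#' @export
ground_truth_effects <- function(wt, rep, native, mj = contact_energies(),
                                 theta = 5) {
  wt <- as_lattice_seq(wt)
  H0 <- lattice_fitness(wt, rep, native, mj)
  muts <- all_single_mutants(wt)
  Hm <- lattice_fitness(muts, rep, native, mj)
  E <- matrix(0, 27, 20)
  k <- 0
  for (i in seq_len(27)) {
    for (a in setdiff(1:20, wt[i])) {
      k <- k + 1
      E[i, a] <- Hm[k] - H0
    }
  }
  mask <- abs(E) < theta & col(E) != wt[row(E)]
  structure(list(E = E, mask = mask, wt = wt, theta = theta, H_wt = H0),
            class = "lattice_truth")
}

#' @export
print.lattice_truth <- function(x, ...) {
  cat(sprintf(
    "<lattice_truth> 27 x 19 exact effects, H(wt) = %.4f, %d observable (theta = %g)\n",
    x$H_wt, sum(x$mask), x$theta))
  invisible(x)
}

#' Ground truth as a mutational scan
#'
#' Converts exact lattice effects into a `mutational_scan` tibble (masked
#' entries only). Measured fitness *costs* H increase for deleterious
#' mutations, so scores are negated: higher score = fitter, matching the
#' predictor's sign convention.
#'
#' @param truth a `lattice_truth`.
#' @return a `mutational_scan` tibble.
#' @export
truth_scan <- function(truth) {
  idx <- which(truth$mask, arr.ind = TRUE)
  out <- tibble(site = as.integer(idx[, 1]),
                wt_aa = AA_LETTERS[truth$wt[idx[, 1]]],
                mut_aa = AA_LETTERS[idx[, 2]],
                mut_code = as.integer(idx[, 2]),
                score = -truth$E[idx])
  class(out) <- c("mutational_scan", class(out))
  out
}

#' Numerical bias and variance of a predictor against the ground truth
#'
#' Given `n` prediction tables obtained from as many independently sampled
#' alignments at fixed (B, D), computes per mutation the signed bias
#' `mean(E^hat) - E` and the across-repetition variance, then the global
#' aggregates: `mu_bar^2` = population variance of the signed bias over the
#' observability mask (the global shift is removed because rank correlations
#' ignore constants), and `sigma_bar^2` = mean per-mutation variance over
#' the mask.
#'
#' Predictions and ground truth are compared on the predictor's scale:
#' `E_ia` is a fitness *cost* (`H` increases for deleterious mutations)
#' while the Potts predictor is a log-probability *fitness* difference, so
#' the target of the predictor is `-E_ia`.
#'
#' @param preds list of `prediction_table`s (>= 2) from repeated inference.
#' @param truth a `lattice_truth`.
#' @return a list with `mu2`, `sigma2`, and a tibble `per_mutation`
#'   (site, mut_code, bias, variance).
#' @export
numeric_bias_variance <- function(preds, truth) {
  if (length(preds) < 2) abort("need at least 2 repetitions")
  if (sum(truth$mask) == 0) abort("empty observability mask")
  stack <- vapply(preds, function(p) p$E, truth$E) # 27 x 20 x n
  m1 <- apply(stack, c(1, 2), mean)
  m2 <- apply(stack^2, c(1, 2), mean)
  bias <- m1 - (-truth$E)
  v <- m2 - m1^2
  idx <- which(truth$mask, arr.ind = TRUE)
  b <- bias[truth$mask]
  mu2 <- mean(b^2) - mean(b)^2
  sigma2 <- mean(v[truth$mask])
  list(mu2 = mu2, sigma2 = sigma2,
       per_mutation = tibble(site = as.integer(idx[, 1]),
                             mut_code = as.integer(idx[, 2]),
                             bias = b, variance = v[truth$mask]))
}

#' Structural vs non-structural coupling variance and the effective bias curve
#'
#' Infers a fully-connected Potts model from a large unbiased lattice
#' alignment (pairwise approximation of the true landscape), pools the
#' zero-sum-gauge coupling entries over native-contact pairs versus all
#' other pairs, and builds the effective bias-factor curve under the
#' assumption that a K-link model captures structural couplings first:
#' `J0_eff(K) = (Nc - min(K, Nc)) V_struct + (Kmax - Nc) V_nonstruct`,
#' reported normalized by `J0_eff(0)`. The curve is exactly constant once
#' all `Nc = 28` structural couplings are modelled.
#'
#' @param aln a large lattice `msa_alignment` (gamma = 0 sampling).
#' @param rep a `fold_repertoire`.
#' @param native native fold index.
#' @param K_range link counts for the curve (default 0..40).
#' @param reg_h,reg_J,maxit passed to [infer_plm()].
#' @return a list with `V_struct`, `V_nonstruct`, and `curve` (tibble with
#'   `K`, `j0_eff`, `j0_eff_norm`).
#' @export
structural_coupling_analysis <- function(aln, rep, native, K_range = 0:40,
                                         reg_h = 0.01, reg_J = 0.01,
                                         maxit = 100) {
  N <- ncol(aln$seqs)
  Kmax <- max_links(N)
  if (any(K_range < 0 | K_range > Kmax))
    abort("K_range outside [0, Kmax]", class = "pf_parameter_error")
  fit <- infer_plm(aln, reg_h, reg_J, reweight = FALSE, maxit = maxit)
  contacts <- matrix(rep$contacts[native, ], ncol = 2, byrow = TRUE)
  key <- paste(pmin(contacts[, 1], contacts[, 2]),
               pmax(contacts[, 1], contacts[, 2]))
  pair_key <- paste(fit$pairs[, 1], fit$pairs[, 2])
  is_struct <- pair_key %in% key
  ent <- function(sel) as.vector(fit$blocks[, , sel])
  V_struct <- var(ent(is_struct))
  V_nonstruct <- var(ent(!is_struct))
  Nc <- nrow(contacts)
  j0 <- (Nc - pmin(K_range, Nc)) * V_struct + (Kmax - Nc) * V_nonstruct
  j0_at_0 <- Nc * V_struct + (Kmax - Nc) * V_nonstruct
  list(V_struct = V_struct, V_nonstruct = V_nonstruct, Nc = Nc,
       curve = tibble(K = K_range, j0_eff = j0, j0_eff_norm = j0 / j0_at_0))
}
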