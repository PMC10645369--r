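# Sparse (K-link) Potts models: independent-site fields, pseudo-likelihood
# estimation of a fully-connected coupling tensor, Frobenius ranking of
# links, two-site re-inference of the selected couplings, and Gibbs sampling.

#' Construct a Potts model
#'
#' @param h N x Q field matrix (log scale).
#' @param links integer matrix with two columns (i < j per row), or `NULL`
#'   for the independent-site model.
#' @param J list of Q x Q coupling matrices, one per link row
#'   (`J[[k]][a, b]` couples residue `a` at site `links[k, 1]` with `b` at
#'   `links[k, 2]`).
#' @param provenance optional named list recorded on the model.
#' @return a `potts_model`.
#' @export
potts_model <- function(h, links = NULL, J = list(), provenance = list()) {
  N <- nrow(h); Q <- ncol(h)
  if (is.null(links) || NROW(links) == 0) {
    links <- matrix(integer(0), 0, 2)
    J <- list()
  } else {
    links <- matrix(as.integer(links), ncol = 2)
    if (any(links[, 1] >= links[, 2]) || any(links < 1) || any(links > N))
      abort("links must satisfy 1 <= i < j <= N", class = "pf_parameter_error")
    if (anyDuplicated(links)) abort("duplicate links")
    if (length(J) != nrow(links)) abort("one coupling matrix per link required")
  }
  if (!all(vapply(J, function(m) all(dim(m) == c(Q, Q)) && all(is.finite(m)),
                  TRUE)))
    abort("coupling matrices must be finite Q x Q")
  if (!all(is.finite(h))) abort("fields must be finite")
  neigh <- vector("list", N)
  for (k in seq_len(nrow(links))) {
    i <- links[k, 1]; j <- links[k, 2]
    neigh[[i]] <- rbind(neigh[[i]], c(j, k, 0L)) # partner, link id, transposed?
    neigh[[j]] <- rbind(neigh[[j]], c(i, k, 1L))
  }
  structure(list(N = N, Q = Q, h = h, links = links, J = J,
                 neighborhoods = neigh,
                 degrees = vapply(neigh, NROW, 0L),
                 K = nrow(links), provenance = provenance),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("<potts_model> N = %d sites, Q = %d states, K = %d links\n",
              x$N, x$Q, x$K))
  invisible(x)
}

#' Independent-site model from frequency tables
#'
#' The K = 0 model: `h_i(a) = log p~_i(a)`, no couplings.
#'
#' @param ft a `freq_tables` object with `lambda > 0` (or strictly positive
#'   raw frequencies), so all logs are finite.
#' @return a `potts_model` with `K = 0`.
#' @export
infer_independent <- function(ft) {
  if (any(ft$p <= 0))
    abort("zero frequencies: use a pseudocount lambda > 0",
          class = "pf_parameter_error")
  potts_model(log(ft$p),
              provenance = list(method = "independent", lambda = ft$lambda,
                                B = ft$B))
}

# One-hot encoding of an integer alignment over n_states codes.
one_hot <- function(seqs, n_states) {
  M <- nrow(seqs); N <- ncol(seqs)
  X <- matrix(0, M, N * n_states)
  idx <- rep(seq_len(M), N)
  col <- (rep(seq_len(N) - 1L, each = M)) * n_states + as.vector(seqs)
  X[cbind(idx, col)] <- 1
  X
}

#' Pseudo-likelihood estimation of a fully-connected Potts model
#'
#' Per-site L2-regularized multinomial logistic regressions (gap excluded as
#' a prediction target but allowed as context), sequence weights applied,
#' asymmetric coupling estimates symmetrized by averaging, and every 20 x 20
#' amino-acid block shifted to the zero-sum gauge.
#'
#' @param aln an `msa_alignment` with at least 2 rows and 2 sites.
#' @param reg_h,reg_J L2 penalties on fields and couplings (per parameter,
#'   relative to the weight-normalized log-pseudo-likelihood; defaults 0.01).
#' @param reweight use the alignment's sequence weights (default: whatever
#'   the alignment carries)?
#' @param maxit L-BFGS iteration cap per site.
#' @return a `plm_fit`: list with `blocks` (20 x 20 x P array in zero-sum
#'   gauge), `pairs` (P x 2 matrix of site pairs, i < j), `convergence`.
#' @export
infer_plm <- function(aln, reg_h = 0.01, reg_J = 0.01,
                      reweight = aln$reweighted, maxit = 100) {
  M <- nrow(aln$seqs); N <- ncol(aln$seqs)
  if (M < 2 || N < 2) abort("need at least 2 sequences and 2 sites")
  Q <- 20L; S <- 21L
  w_all <- if (reweight) aln$weights else rep(1, M)
  X_all <- one_hot(aln$seqs, S)
  Jhat <- vector("list", N) # Jhat[[r]]: Q x (S*(N-1)) couplings from site r
  conv <- integer(N)
  for (r in seq_len(N)) {
    y <- aln$seqs[, r]
    use <- y <= Q
    keep_cols <- rep(seq_len(N) != r, each = S)
    X <- X_all[use, keep_cols, drop = FALSE]
    yy <- y[use]
    w <- w_all[use]
    Bw <- sum(w)
    # centring the one-hot features fixes the inference gauge: constant
    # context columns carry no coupling mass (it goes to the fields)
    X <- sweep(X, 2, colSums(X * w) / Bw)
    if (Bw <= 0) abort("no usable rows for site ", r)
    P <- ncol(X)
    Y <- matrix(0, length(yy), Q)
    Y[cbind(seq_along(yy), yy)] <- 1
    cache <- new.env(parent = emptyenv())
    compute <- function(par) {
      if (identical(par, cache$par)) return(invisible(NULL))
      b <- par[seq_len(Q)]
      W <- matrix(par[-seq_len(Q)], Q, P)
      logits <- tcrossprod(X, W)
      logits <- sweep(logits, 2, b, "+")
      mx <- apply(logits, 1, max)
      ex <- exp(logits - mx)
      Z <- rowSums(ex)
      Pm <- ex / Z
      nll <- -sum(w * (rowSums(Y * logits) - (log(Z) + mx)))
      cache$par <- par
      cache$value <- nll / Bw + reg_h * sum(b^2) + reg_J * sum(W^2)
      R <- (Pm - Y) * w
      cache$grad <- c(colSums(R) / Bw + 2 * reg_h * b,
                      as.vector(crossprod(R, X) / Bw + 2 * reg_J * W))
      invisible(NULL)
    }
    fn <- function(par) { compute(par); cache$value }
    gr <- function(par) { compute(par); cache$grad }
    fit <- optim(numeric(Q + Q * P), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e10))
    conv[r] <- fit$convergence
    Jhat[[r]] <- matrix(fit$par[-seq_len(Q)], Q, P)
  }
  if (any(!conv %in% c(0L, 1L)))
    abort(sprintf("pseudo-likelihood optimizer failed at site(s) %s",
                  paste(which(!conv %in% c(0L, 1L)), collapse = ", ")),
          class = "pf_convergence_error")
  pairs <- t(combn(N, 2))
  blocks <- array(0, dim = c(Q, Q, nrow(pairs)))
  # column offset of site j inside site r's design (sites != r, S codes each)
  col_block <- function(r, j) {
    pos <- j - (j > r)
    (pos - 1L) * S
  }
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Ji <- Jhat[[i]][, col_block(i, j) + seq_len(Q), drop = FALSE] # a x b
    Jj <- Jhat[[j]][, col_block(j, i) + seq_len(Q), drop = FALSE] # b x a
    blocks[, , p] <- zero_sum_gauge((Ji + t(Jj)) / 2)
  }
  structure(list(blocks = blocks, pairs = pairs, N = N, Q = Q,
                 reg_h = reg_h, reg_J = reg_J, convergence = conv),
            class = "plm_fit")
}

#' Zero-sum gauge projection of a coupling block
#'
#' Subtracts row and column means and restores the grand mean, so every row
#' and column of the returned matrix sums to zero.
#'
#' @param J a numeric matrix.
#' @return the gauge-fixed matrix.
#' @export
zero_sum_gauge <- function(J) {
  J - outer(rowMeans(J), rep(1, ncol(J))) -
    outer(rep(1, nrow(J)), colMeans(J)) + mean(J)
}

#' Frobenius link scores
#'
#' Score of pair (i, j) = Frobenius norm of the zero-sum-gauge 20 x 20
#' amino-acid coupling block. No APC correction is applied.
#'
#' @param fit a `plm_fit` from [infer_plm()], or an array of blocks with a
#'   matching `pairs` attribute.
#' @return a tibble with columns `i`, `j`, `score`, sorted by (i, j).
#' @export
frobenius_scores <- function(fit) {
  blocks <- fit$blocks
  pairs <- fit$pairs
  score <- vapply(seq_len(nrow(pairs)), function(p) {
    b <- zero_sum_gauge(blocks[, , p])
    sqrt(sum(b^2))
  }, 0)
  tibble(i = pairs[, 1], j = pairs[, 2], score = score)
}

#' Select the top-K links
#'
#' Ties are broken lexicographically on (i, j), so selection is
#' deterministic; link sets are nested in K for fixed scores.
#'
#' @param scores tibble from [frobenius_scores()].
#' @param K number of links, `0 <= K <= N(N-1)/2`.
#' @return an integer matrix with K rows (i < j).
#' @export
select_links <- function(scores, K) {
  if (K < 0 || K > nrow(scores))
    abort("K out of range", class = "pf_parameter_error")
  if (K == 0) return(matrix(integer(0), 0, 2))
  top <- head(arrange(scores, desc(.data$score), .data$i, .data$j), K)
  cbind(top$i, top$j)
}

#' Two-site re-inference of selected couplings
#'
#' Builds the K-link model: fields `h_i(a) = log p~_i(a)` everywhere and,
#' for each selected link, the pointwise-mutual-information coupling
#' `J_ij(a, b) = log p~_ij(a, b) - log p~_i(a) - log p~_j(b)`. With this
#' choice the predictor of a site with a single link depends only on pair
#' frequencies, consistent with the `|k_i - 1|` factor in the analytic
#' variance.
#'
#' @param ft a `freq_tables` with `lambda > 0`.
#' @param links integer matrix (rows i < j), e.g. from [select_links()].
#' @return a `potts_model`.
#' @export
infer_two_site <- function(ft, links) {
  if (any(ft$p <= 0))
    abort("zero frequencies: use a pseudocount lambda > 0",
          class = "pf_parameter_error")
  links <- if (NROW(links)) matrix(as.integer(links), ncol = 2) else matrix(integer(0), 0, 2)
  if (NROW(links) && (any(links < 1) || any(links > ft$N)))
    abort("link site out of range", class = "pf_parameter_error")
  h <- log(ft$p)
  J <- lapply(seq_len(NROW(links)), function(k) {
    i <- links[k, 1]; j <- links[k, 2]
    pij <- pair_frequencies(ft, i, j)
    log(pij) - outer(h[i, ], h[j, ], "+")
  })
  potts_model(h, links, J,
              provenance = list(method = "two_site", lambda = ft$lambda,
                                B = ft$B))
}

#' Fit a K-link sparse Potts model from an alignment
#'
#' Convenience wrapper chaining [frequencies()], [infer_plm()] (skipped for
#' K = 0 or when `scores` are supplied), [select_links()] and
#' [infer_two_site()].
#'
#' @param aln an `msa_alignment`.
#' @param K number of links.
#' @param lambda pseudocount for the frequency tables.
#' @param reg_h,reg_J pseudo-likelihood penalties.
#' @param scores optional precomputed link scores (reused across K values).
#' @param ft optional precomputed `freq_tables`.
#' @return a `potts_model`.
#' @export
infer_potts <- function(aln, K, lambda = 0.01, reg_h = 0.01, reg_J = 0.01,
                        scores = NULL, ft = NULL) {
  ft <- ft %||% frequencies(aln, lambda)
  if (K == 0) return(infer_independent(ft))
  if (is.null(scores)) scores <- frobenius_scores(infer_plm(aln, reg_h, reg_J))
  infer_two_site(ft, select_links(scores, K))
}

# Energy terms of residue a at site i given the rest of sequence s.
site_conditional_logits <- function(model, s, i) {
  e <- model$h[i, ]
  nb <- model$neighborhoods[[i]]
  for (r in seq_len(NROW(nb))) {
    Jk <- model$J[[nb[r, 2]]]
    b <- s[nb[r, 1]]
    e <- e + if (nb[r, 3] == 0L) Jk[, b] else Jk[b, ]
  }
  e
}

#' Gibbs-sample sequences from a Potts model
#'
#' @param model a `potts_model`.
#' @param n number of sequences to record.
#' @param burn_in full sweeps discarded before recording.
#' @param thin full sweeps between recorded sequences.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return an `msa_alignment` (unit weights) whose wild type is the first
#'   recorded sequence.
#' @export
sample_potts <- function(model, n, burn_in = 100, thin = 5, seed = NULL) {
  run <- function() {
    N <- model$N; Q <- model$Q
    s <- vapply(seq_len(N), function(i)
      sample.int(Q, 1, prob = softmax(model$h[i, ])), 0L)
    out <- matrix(0L, n, N)
    sweep1 <- function(s) {
      for (i in seq_len(N)) {
        p <- softmax(site_conditional_logits(model, s, i))
        s[i] <- sample.int(Q, 1, prob = p)
      }
      s
    }
    for (b in seq_len(burn_in)) s <- sweep1(s)
    for (k in seq_len(n)) {
      for (t in seq_len(thin)) s <- sweep1(s)
      out[k, ] <- s
    }
    out
  }
  seqs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new_alignment(seqs, ids = paste0("potts_", seq_len(n)), wt = seqs[1, ],
                reweighted = FALSE)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Combinatorics helpers
#'
#' `n_single_mutants()` is the number of possible single mutants of a
#' wild type ((Q - 1) per site); `max_links()` the number of site pairs
#' N(N-1)/2; `link_parameters()` the parameter count per coupling block Q^2.
#'
#' @param n_sites,n_states problem dimensions.
#' @return integer count.
#' @export
n_single_mutants <- function(n_sites, n_states = 20) n_sites * (n_states - 1)

#' @rdname n_single_mutants
#' @export
max_links <- function(n_sites) n_sites * (n_sites - 1) / 2

#' @rdname n_single_mutants
#' @export
link_parameters <- function(n_states = 20) n_states^2
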