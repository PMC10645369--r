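# Shared fixtures. Everything is generated in code; the expensive lattice
# objects are memoised for the test session.

.tcache <- new.env(parent = emptyenv())

aa_str <- function(codes) paste(pottsfocus:::decode_residues(codes), collapse = "")

# Build an msa_alignment directly from residue strings.
toy_alignment <- function(strings, wt = strings[[1]], reweight = FALSE,
                          ids = paste0("s", seq_along(strings))) {
  seqs <- pottsfocus:::encode_residues(
    do.call(rbind, strsplit(toupper(strings), "")))
  wt_codes <- pottsfocus:::encode_residues(strsplit(toupper(wt), "")[[1]])
  aln <- pottsfocus:::new_alignment(seqs, ids, wt_codes, reweighted = FALSE)
  if (reweight) aln <- compute_weights(aln)
  aln
}

write_toy_fasta <- function(strings, ids = paste0("s", seq_along(strings))) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), strings)), path)
  path
}

# Alignment whose rows sit at a controlled spread of distances from wt
# (random alignments concentrate near d = N * 19/20, useless for
# distance-targeted subsampling tests).
spread_alignment <- function(n_seq, n_site, seed = 1) {
  withr::with_seed(seed, {
    wt <- sample.int(20, n_site)
    seqs <- t(vapply(seq_len(n_seq), function(k) {
      s <- wt
      nmut <- sample.int(n_site, 1)
      sites <- sample.int(n_site, nmut)
      s[sites] <- sample.int(20, nmut, replace = TRUE)
      s
    }, integer(n_site)))
    storage.mode(seqs) <- "integer"
    pottsfocus:::new_alignment(seqs, paste0("m", seq_len(n_seq)), wt,
                               reweighted = FALSE)
  })
}

random_alignment <- function(n_seq, n_site, seed = 1, q = 20) {
  withr::with_seed(seed, {
    seqs <- matrix(sample.int(q, n_seq * n_site, replace = TRUE),
                   n_seq, n_site)
    storage.mode(seqs) <- "integer"
    pottsfocus:::new_alignment(seqs, paste0("r", seq_len(n_seq)), seqs[1, ],
                               reweighted = FALSE)
  })
}

# Small random Potts model over arbitrary N, Q (for exhaustive oracles).
random_potts <- function(N, Q, K = 1, seed = 1, scale = 0.8) {
  withr::with_seed(seed, {
    h <- matrix(rnorm(N * Q, sd = scale), N, Q)
    pairs <- t(combn(N, 2))
    pick <- sample(nrow(pairs), K)
    links <- pairs[pick, , drop = FALSE]
    links <- links[order(links[, 1], links[, 2]), , drop = FALSE]
    J <- lapply(seq_len(K), function(k) matrix(rnorm(Q * Q, sd = scale), Q, Q))
    potts_model(h, links, J)
  })
}

# Exact log-probability of every sequence of a small Potts model, by full
# enumeration of Q^N sequences (independent oracle for the predictor).
enumerate_logp <- function(model) {
  N <- model$N; Q <- model$Q
  grid <- as.matrix(expand.grid(rep(list(seq_len(Q)), N)))
  loge <- apply(grid, 1, function(s) {
    e <- sum(model$h[cbind(seq_len(N), s)])
    for (k in seq_len(model$K)) {
      i <- model$links[k, 1]; j <- model$links[k, 2]
      e <- e + model$J[[k]][s[i], s[j]]
    }
    e
  })
  logz <- log(sum(exp(loge - max(loge)))) + max(loge)
  list(grid = grid, logp = loge - logz)
}

# The lattice fixtures used across test files (shared, seeded).
test_repertoire <- function() {
  if (is.null(.tcache$rep)) .tcache$rep <- enumerate_folds()
  .tcache$rep
}

# Pooled two-gamma alignment over the small world, giving a wide spread of
# distances for subsampling-based workflow tests.
mini_msa <- function() {
  if (is.null(.tcache$mini_msa)) {
    w <- small_world()
    s1 <- metropolis_sample(w$wt, w$rep, w$native, n_samples = 350,
                            gamma = 0.025, thin = 150, seed = 71)$seqs
    s2 <- metropolis_sample(w$wt, w$rep, w$native, n_samples = 350,
                            gamma = 0.075, thin = 150, seed = 72)$seqs
    seqs <- rbind(s1, s2)
    keep <- !duplicated(apply(seqs, 1, paste, collapse = ","))
    .tcache$mini_msa <- pottsfocus:::new_alignment(
      seqs[keep, , drop = FALSE], paste0("p", which(keep)), w$wt,
      reweighted = FALSE)
  }
  .tcache$mini_msa
}

# A small world for fast lattice tests: few hundred competing folds.
small_world <- function() {
  if (is.null(.tcache$world)) {
    full <- test_repertoire()
    red <- subsample_repertoire(full, 400, native = 4242L, seed = 99)
    rep <- red$repertoire
    wt <- select_wildtype(rep, red$native, seed = 5)
    .tcache$world <- list(rep = rep, native = red$native, wt = wt,
                          truth = ground_truth_effects(wt, rep, red$native))
  }
  .tcache$world
}
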