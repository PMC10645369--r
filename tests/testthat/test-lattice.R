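# Lattice-protein geometry, energies, native-fold probability, wild-type
# design, Metropolis sampling, ground truth and numerical bias/variance.

test_that("every compact fold has exactly 28 contacts and a valid path", {
  rep <- test_repertoire()
  # the contact builder errors unless every fold has exactly 28 contacts,
  # so constructing the repertoire already asserts the count; spot-check
  # structure on a random subset as well
  expect_equal(ncol(rep$contacts), 56L)
  withr::with_seed(1, {
    for (f in sample.int(rep$n_folds, 25)) {
      path <- rep$paths[f, ]
      expect_setequal(path, 0:26) # visits every cube cell once
      xyz <- cbind(path %% 3, (path %/% 3) %% 3, path %/% 9)
      steps <- abs(diff(xyz))
      expect_true(all(rowSums(steps) == 1)) # chain of lattice neighbours
      cm <- matrix(rep$contacts[f, ], ncol = 2, byrow = TRUE)
      expect_true(all(abs(cm[, 1] - cm[, 2]) > 1)) # non-consecutive pairs
      # contacts are lattice-adjacent residue pairs
      d <- abs(xyz[cm[, 1], ] - xyz[cm[, 2], ])
      expect_true(all(rowSums(d) == 1))
    }
  })
})

test_that("fold energies: homopolymer, zero matrix, brute-force loop", {
  rep <- test_repertoire()
  mj <- contact_energies()
  homo <- rep(3L, 27)
  expect_equal(fold_energy(rep, 1, homo, mj), 28 * mj[3, 3])
  expect_equal(fold_energy(rep, 5, homo, matrix(0, 20, 20)), 0)
  withr::with_seed(2, {
    s <- sample.int(20, 27, replace = TRUE)
    f <- sample.int(rep$n_folds, 1)
    cm <- matrix(rep$contacts[f, ], ncol = 2, byrow = TRUE)
    brute <- sum(vapply(seq_len(28), function(k) mj[s[cm[k, 1]], s[cm[k, 2]]], 0))
    expect_equal(fold_energy(rep, f, s, mj), brute)
  })
})

test_that("contact energy matrix is symmetric, finite and attractive on average", {
  mj <- contact_energies()
  expect_equal(mj, t(mj))
  expect_true(all(is.finite(mj)))
  expect_lt(mean(mj), 0)
  # deterministic across calls
  expect_identical(mj, contact_energies())
})

test_that("P_nat: closed forms, invariance under fold relabelling", {
  w <- small_world()
  mj <- contact_energies()
  # single-fold repertoire: P_nat = 1, H = 0
  one <- w$rep
  one$paths <- one$paths[1, , drop = FALSE]
  one$contacts <- one$contacts[1, , drop = FALSE]
  one$n_folds <- 1L
  s <- rep(4L, 27)
  expect_equal(p_nat(s, one, 1, mj), 1)
  expect_equal(lattice_fitness(s, one, 1, mj), 0)

  # two folds with equal energy (homopolymer): P_nat = 1/2
  two <- w$rep
  two$paths <- two$paths[1:2, , drop = FALSE]
  two$contacts <- two$contacts[1:2, , drop = FALSE]
  two$n_folds <- 2L
  expect_equal(p_nat(s, two, 1, mj), 0.5)

  # closed-form softmax on a 3-fold toy with controlled energy offsets:
  # P_nat = 1 / (1 + e^{-1} + e^{-2}) for energies (0, 1, 2) relative
  # to the native; verify on equal-energy folds with a shifted matrix trick
  eps <- vapply(1:3, function(f) fold_energy(w$rep, f, s, mj), 0)
  three <- w$rep
  three$paths <- three$paths[1:3, , drop = FALSE]
  three$contacts <- three$contacts[1:3, , drop = FALSE]
  three$n_folds <- 3L
  expect_equal(p_nat(s, three, 2, mj),
               exp(-eps[2]) / sum(exp(-eps + max(eps))) * exp(max(eps)),
               tolerance = 1e-9)

  # permuting the repertoire (and tracking the native index) is neutral
  w2 <- w$rep
  perm <- withr::with_seed(3, sample.int(w$rep$n_folds))
  w2$paths <- w$rep$paths[perm, , drop = FALSE]
  w2$contacts <- w$rep$contacts[perm, , drop = FALSE]
  expect_equal(p_nat(w$wt, w2, which(perm == w$native), mj),
               p_nat(w$wt, w$rep, w$native, mj), tolerance = 1e-12)
})

test_that("cube symmetries leave energies and P_nat unchanged", {
  w <- small_world()
  mj <- contact_energies()
  # a cube symmetry permutes cells; paths transform, contacts (as residue
  # pairs) are invariant, hence so are all energies. Apply a reflection:
  reflect <- function(cell) {
    x <- cell %% 3; y <- (cell %/% 3) %% 3; z <- cell %/% 9
    (2 - x) + 3 * y + 9 * z
  }
  w2 <- w$rep
  w2$paths <- matrix(reflect(w$rep$paths), nrow = w$rep$n_folds)
  w2$contacts <- pottsfocus:::fold_contacts_cpp(w2$paths)
  s <- withr::with_seed(4, sample.int(20, 27, replace = TRUE))
  # contact lists may be reordered, but energies are sums over them
  for (f in c(1, 7, 100)) {
    expect_equal(fold_energy(w2, f, s, mj), fold_energy(w$rep, f, s, mj),
                 tolerance = 1e-12)
  }
  expect_equal(p_nat(s, w2, w$native, mj), p_nat(s, w$rep, w$native, mj),
               tolerance = 1e-12)
})

test_that("select_wildtype hits the stability band and admits improvements", {
  w <- small_world()
  p <- attr(w$wt, "pnat")
  expect_gte(p, 0.990)
  expect_lte(p, 0.997)
  # at least one beneficial single mutation exists
  H0 <- lattice_fitness(w$wt, w$rep, w$native)
  muts <- pottsfocus:::all_single_mutants(w$wt)
  expect_true(any(lattice_fitness(muts, w$rep, w$native) < H0))
  # determinism
  wt2 <- select_wildtype(w$rep, w$native, seed = 5)
  expect_identical(as.integer(w$wt), as.integer(wt2))
})

test_that("ground truth effects: zeros at wt, 513 entries, masking", {
  w <- small_world()
  truth <- w$truth
  expect_equal(truth$E[cbind(1:27, truth$wt)], rep(0, 27))
  expect_equal(sum(col(truth$E) != truth$wt[row(truth$E)]), 27 * 19)
  expect_true(all(abs(truth$E[truth$mask]) < truth$theta))
  expect_false(any(truth$mask[cbind(1:27, truth$wt)]))
  # a tighter theta masks more mutations
  t2 <- ground_truth_effects(w$wt, w$rep, w$native, theta = 1)
  expect_lt(sum(t2$mask), sum(truth$mask))
  # scan view: scores are negated costs over the mask
  scan <- truth_scan(truth)
  expect_equal(nrow(scan), sum(truth$mask))
  expect_equal(scan$score, -truth$E[truth$mask])
})

test_that("metropolis sampling: determinism, wt start, gamma monotonicity", {
  w <- small_world()
  a1 <- metropolis_sample(w$wt, w$rep, w$native, n_samples = 40,
                          gamma = 0.05, thin = 200, seed = 21)
  a2 <- metropolis_sample(w$wt, w$rep, w$native, n_samples = 40,
                          gamma = 0.05, thin = 200, seed = 21)
  expect_identical(a1$seqs, a2$seqs)
  expect_equal(ncol(a1$seqs), 27L)
  expect_true(all(a1$weights == 1)) # no reweighting for lattice data

  # mean distance decreases with gamma (averaged over seeds)
  mean_d <- function(g) {
    mean(vapply(1:3, function(s) {
      a <- metropolis_sample(w$wt, w$rep, w$native, n_samples = 60,
                             gamma = g, thin = 150, seed = 100 + s)
      msa_descriptors(a)$D
    }, 0))
  }
  ds <- vapply(c(0, 0.05, 0.1), mean_d, 0)
  expect_true(all(diff(ds) < 0))
  expect_error(metropolis_sample(w$wt, w$rep, w$native, 5, gamma = -1),
               class = "pf_parameter_error")
})

test_that("fast sampler matches the naive reference implementation", {
  # the production sampler maintains Boltzmann weights incrementally; the
  # naive reference recomputes the full stabilized log-sum-exp on every
  # proposal. Same seed, same chain.
  w <- small_world()
  mj <- contact_energies()
  for (g in c(0, 0.05)) {
    set.seed(123)
    fast <- pottsfocus:::metropolis_sample_cpp(w$rep$contacts, w$native,
                                               w$wt, mj, g, 1000, 80L, 120L)
    set.seed(123)
    naive <- pottsfocus:::metropolis_sample_naive_cpp(w$rep$contacts,
                                                      w$native, w$wt, mj, g,
                                                      1000, 80L, 120L)
    expect_identical(fast, naive)
  }
})

test_that("numerical bias and variance: perfect predictor gives zeros", {
  w <- small_world()
  perfect <- structure(list(E = -w$truth$E, wt = w$truth$wt, N = 27, Q = 20),
                       class = "prediction_table")
  nbv <- numeric_bias_variance(list(perfect, perfect, perfect), w$truth)
  expect_equal(nbv$mu2, 0, tolerance = 1e-12)
  expect_equal(nbv$sigma2, 0, tolerance = 1e-12)
  expect_error(numeric_bias_variance(list(perfect), w$truth))
})

test_that("independent-model bias shrinks as B grows on profile data", {
  # teacher = independent Potts model; student = the same class, so the
  # residual bias is purely statistical and must decrease with B
  N <- 8; Q <- 20
  teacher <- random_potts(N, Q, K = 1, seed = 51, scale = 0.5)
  teacher$J[[1]][, ] <- 0 # no epistasis
  wt <- withr::with_seed(52, sample.int(Q, N))
  truth_E <- predict_mutations(teacher, wt)$E
  truth <- structure(list(E = -truth_E, mask = col(truth_E) != wt[row(truth_E)],
                          wt = wt, theta = Inf, H_wt = 0),
                     class = "lattice_truth")
  mu2_at <- function(B) {
    preds <- lapply(1:4, function(r) {
      aln <- sample_potts(teacher, B, burn_in = 10, thin = 1,
                          seed = 7000 + 13 * r + B)
      aln$wt <- wt
      predict_mutations(infer_independent(frequencies(aln, 0.01)), wt)
    })
    numeric_bias_variance(preds, truth)$mu2
  }
  mus <- vapply(c(100, 1000, 10000), mu2_at, 0)
  expect_true(all(diff(mus) < 0))
})

test_that("effective bias curve: structural variance dominance degenerates", {
  # V_struct = V_nonstruct makes the curve linear down to K = Nc, then flat
  Nc <- 28; Kmax <- 351
  V <- 0.5
  K <- c(0, 7, 14, 28, 40)
  j0 <- (Nc - pmin(K, Nc)) * V + (Kmax - Nc) * V
  expect_equal(diff(j0[1:4]) / diff(K[1:4]), rep(-V, 3))
  expect_equal(j0[4], j0[5])
})
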