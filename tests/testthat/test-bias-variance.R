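# Analytic variance, bias-factor fitting, focusing curves, cutoff
# predictors, SNR, shuffle null.

test_that("variance estimate: hand arithmetic and exact 1/B scaling", {
  # single site, two states p = (0.8, 0.2), B = 10, independent model
  aln <- toy_alignment(c("A", "A", "A", "A", "C"))
  ft <- frequencies(aln, lambda = 0)
  ft$p <- ft$p # p[1,] = (0.8, 0.2, 0, ...)
  # avoid zero entries: restrict to the hand formula on a 2-state toy by
  # pseudocount-free manual computation
  m <- potts_model(matrix(0, 1, 20))
  # hand: sum over a != wt (19 terms); only a = C has finite 1/p via lambda
  ftl <- frequencies(aln, lambda = 0.01)
  s2 <- variance_estimate(ftl, m, B = 10)
  pC <- 0.99 * 0.2 + 0.0005
  pA <- 0.99 * 0.8 + 0.0005
  pUnseen <- 0.0005
  hand <- (1 / pC + 18 / pUnseen + 19 / pA) / (10 * 1 * 20)
  expect_equal(s2, hand, tolerance = 1e-12)

  # doubling B exactly halves sigma^2; slope of log sigma2 on log B is -1
  expect_equal(variance_estimate(ftl, m, B = 20), s2 / 2, tolerance = 1e-12)
  Bs <- c(5, 10, 40, 160)
  ls <- vapply(Bs, function(b) log(variance_estimate(ftl, m, B = b)), 0)
  expect_equal(unname(coef(lm(ls ~ log(Bs)))[2]), -1, tolerance = 1e-12)
})

test_that("the |k_i - 1| factor zeroes single-site terms at degree one", {
  aln <- random_alignment(60, 3, seed = 17)
  ft <- frequencies(aln, 0.01)
  # model with one link (1,2): sites 1 and 2 have k = 1, site 3 has k = 0
  m1 <- infer_two_site(ft, cbind(1L, 2L))
  m0 <- infer_independent(ft)
  s_ind <- variance_estimate(ft, m0)
  s_link <- variance_estimate(ft, m1)
  # site 3 contributes its single-site terms in both; sites 1-2 swap their
  # single-site terms for pair terms. Recompute by hand for site 3 only:
  wt <- ft$wt
  site3 <- sum(1 / ft$p[3, -wt[3]]) + 19 / ft$p[3, wt[3]]
  pair12 <- {
    p <- pair_frequencies(ft, 1, 2)
    sum(1 / p[-wt[1], wt[2]]) + 19 / p[wt[1], wt[2]] +
      sum(1 / t(p)[-wt[2], wt[1]]) + 19 / t(p)[wt[2], wt[1]]
  }
  expect_equal(s_link, (site3 + pair12) / (ft$B * 3 * 20), tolerance = 1e-10)
  expect_gt(s_link, s_ind) # pair terms dominate at this B
})

test_that("analytic variance matches a bootstrap of repeated inference", {
  # independent-model world: alignments drawn iid from a fixed profile;
  # the profile keeps every state at B * p >= ~6 so the sampling-theory
  # (delta-method) regime of the analytic formula applies
  N <- 6; Q <- 20; B <- 250
  p0 <- withr::with_seed(19, {
    m <- matrix(rexp(N * Q) + 2, N, Q)
    m / rowSums(m)
  })
  wt <- apply(p0, 1, which.max)
  lambda <- 0.01
  draw_pred <- function(seed) {
    seqs <- withr::with_seed(seed, {
      vapply(seq_len(N), function(i)
        sample.int(Q, B, replace = TRUE, prob = p0[i, ]), integer(B))
    })
    aln <- pottsfocus:::new_alignment(seqs, paste0("b", 1:B), wt,
                                      reweighted = FALSE)
    predict_mutations(infer_independent(frequencies(aln, lambda)), wt)$E
  }
  preds <- lapply(1:200, draw_pred)
  stack <- simplify2array(preds)
  v <- apply(stack, c(1, 2), function(x) mean(x^2) - mean(x)^2)
  mask <- col(v) != wt[row(v)]
  boot <- mean(v[mask]) * (Q - 1) / Q # Eq-18-style mean over defined entries
  # analytic sigma^2 evaluated at the true profile
  ft0 <- list(p = (1 - lambda) * p0 + lambda / Q, N = N, Q = Q, wt = wt,
              B = B, lambda = lambda, pair_cache = new.env())
  class(ft0) <- "freq_tables"
  s2 <- variance_estimate(ft0, potts_model(matrix(0, N, Q)), B = B)
  expect_lt(abs(s2 - boot) / boot, 0.25)
})

test_that("fit_bias_factor recovers a planted bias factor", {
  withr::with_seed(23, {
    n <- 40
    D <- runif(n, 8, 22)
    sigma2 <- runif(n, 0.5, 3)
    J0_true <- 0.8
    records <- tibble::tibble(
      D = D, sigma2 = sigma2,
      rho = -(J0_true * D + sigma2) + rnorm(n, sd = 0.3))
    fit <- fit_bias_factor(records)
    expect_gt(fit$r_S, 0.95)
    expect_lt(abs(log(fit$J0 / J0_true)), log(2)) # within a factor of 2
    # invariance under monotone transforms of rho (Spearman-based)
    records2 <- dplyr::mutate(records, rho = tanh(rho / 10) * 3 + 1)
    fit2 <- fit_bias_factor(records2)
    expect_equal(fit2$J0, fit$J0, tolerance = 1e-6)
    # tidy/glance methods
    expect_equal(tidy(fit)$J0, fit$J0)
    expect_named(glance(fit), c("J0", "r_S", "K", "n"))
  })
})

test_that("fit_bias_factor degenerate and tie-break behaviour", {
  rec <- tibble::tibble(D = 1:12, sigma2 = rep(1, 12), rho = rep(0.5, 12))
  expect_error(fit_bias_factor(rec), class = "pf_degenerate_fit")
  # rho strictly decreasing in D with constant sigma2: r_S = 1 on a plateau
  # of large J0 values; the smallest maximizing grid point is returned
  rec2 <- tibble::tibble(D = 1:12, sigma2 = rep(1, 12),
                         rho = seq(1, 0, length.out = 12))
  fit <- fit_bias_factor(rec2)
  expect_equal(fit$r_S, 1)
  grid <- exp(seq(log(1e-6), log(1e3), length.out = 200)) *
    median(rec2$sigma2) / median(rec2$D)
  plateau <- grid[vapply(grid, function(j)
    abs(cor(rec2$rho, j * rec2$D + rec2$sigma2, method = "spearman")), 0) == 1]
  expect_equal(fit$J0, plateau[1])
})

test_that("shuffle null is reproducible and centred below the signal", {
  withr::with_seed(31, {
    records <- tibble::tibble(D = runif(30, 5, 20), sigma2 = runif(30, 0.5, 2),
                              rho = NA)
    records$rho <- -(records$D * 0.5 + records$sigma2) + rnorm(30, sd = 0.5)
    null <- chance_null_rs(records, n_shuffles = 30, seed = 7)
    null2 <- chance_null_rs(records, n_shuffles = 30, seed = 7)
    expect_identical(null$r_s_null, null2$r_s_null)
    expect_lt(null$mean + 2 * null$sd, null$observed)
    expect_lt(null$p_value, 0.05)
    # when rho is independent of (D, sigma2), the observed r_S sits inside
    # the null band
    records$rho <- rnorm(30)
    null3 <- chance_null_rs(records, n_shuffles = 50, seed = 8)
    expect_lt(abs(null3$observed - null3$mean), 2.5 * null3$sd)
  })
})

test_that("snr: hand arithmetic and degenerate input", {
  m <- potts_model(matrix(0, 1, 20))
  pred <- predict_mutations(m, 1L)
  pred$E[1, 2:5] <- c(0, 1, 2, 3)
  # defined entries: {0,1,2,3} plus 15 zeros -> set the rest to make the
  # textbook case exact
  pred$E[1, 6:20] <- rep(c(0, 1, 2, 3), length.out = 15)
  e <- pottsfocus:::defined_effects(pred)
  expect_equal(snr(pred, sigma2 = 0.25),
               (mean(e^2) - mean(e)^2) / 0.25)
  pred2 <- predict_mutations(m, 1L)
  pred2$E[1, ] <- 2; pred2$E[1, 1] <- 0
  expect_equal(snr(pred2, 1), 0) # all predictions equal
  # balanced populations {0,1,2,3}: population variance 1.25, so with
  # sigma2 = 0.25 the ratio is 5
  m4 <- potts_model(matrix(0, 4, 20))
  pred4 <- predict_mutations(m4, c(1L, 1L, 1L, 1L))
  for (i in 1:4) pred4$E[i, 2:20] <- i - 1
  expect_equal(snr(pred4, 0.25), 1.25 / 0.25)
})

test_that("focus curve sweeps cutoffs; d_bv and d_snr behave at limits", {
  # alignment with a controlled spread of distances to wt
  aln <- spread_alignment(150, 12, seed = 40)
  curve <- focus_curve(aln, d_cut_values = c(4, 6, 8, 10, 12), K = 0)
  expect_equal(nrow(curve), 5L)
  expect_s3_class(curve, "focus_curve")
  expect_true(all(diff(curve$B) >= 0)) # B non-decreasing with d_cut
  # single d_cut = N equals whole-alignment training
  c1 <- focus_curve(aln, d_cut_values = 12, K = 0)
  ft <- frequencies(aln, 0.01)
  expect_equal(c1$sigma2,
               variance_estimate(ft, infer_independent(ft)))
  expect_equal(c1$B, msa_descriptors(aln)$B)

  # J0 = 0: pick the sigma2 minimizer (largest alignment in practice)
  expect_equal(predict_cutoff_bv(curve, 0), curve$d_cut[which.min(curve$sigma2)])
  # J0 huge: the smallest-D cell wins
  expect_equal(predict_cutoff_bv(curve, 1e9), curve$d_cut[which.min(curve$D)])
  expect_error(predict_cutoff_bv(curve, -1), class = "pf_parameter_error")
  # brute-force argmin agreement on a random J0
  for (j0 in c(0.01, 0.3, 2)) {
    obj <- j0 * curve$D + curve$sigma2
    expect_equal(predict_cutoff_bv(curve, j0), curve$d_cut[which.min(obj)])
  }
  # d_bv is weakly decreasing in J0
  j0s <- c(0, 0.01, 0.1, 1, 10, 1e4)
  dbvs <- vapply(j0s, function(j) predict_cutoff_bv(curve, j), 0)
  expect_true(all(diff(dbvs) <= 0))

  # d_snr: smallest cutoff reaching the threshold; fallback warns
  curve$snr <- c(1, 2.5, 3.2, 4, 5)
  expect_equal(predict_cutoff_snr(curve, 3), 8)
  expect_warning(dd <- predict_cutoff_snr(curve, 99), "threshold")
  expect_equal(dd, 12)
})
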