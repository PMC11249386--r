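test_that("unconditional_moments matches a triple-loop oracle and the tie-free identities", {
  r <- random_rank_matrix(4, 9, seed = 41)
  mom <- unconditional_moments(r)
  xc <- r - rowMeans(r)
  n <- ncol(r)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(mom$Q[i, j], mean(xc[i, ] * xc[j, ]))
    for (k in 1:4) {
      expect_equal(mom$T[i, j, k], mean(xc[i, ] * xc[j, ] * xc[k, ]))
    }
  }
  # permutation symmetry of the tensor
  expect_equal(mom$T[1, 2, 3], mom$T[3, 1, 2])
  expect_equal(mom$T[2, 4, 1], mom$T[4, 2, 1])
  # tie-free identities: m2 = (N^2-1)/12 exactly, m3 = 0 exactly
  big <- random_rank_matrix(6, 200, seed = 42)
  bm <- unconditional_moments(big)
  expect_equal(unname(bm$m2), rep((200^2 - 1) / 12, 6))
  expect_true(all(abs(bm$m3) < 1e-8 * 200^3))
})

test_that("rank_one_covariance_fit recovers the planted signal regardless of diagonal", {
  rho <- 0.3
  delta <- c(10, 20, 30)
  Q <- rho * (1 - rho) * outer(delta, delta)
  diag(Q) <- c(500, 700, 900)   # arbitrary diagonal; only off-diagonal is signal
  fit <- rank_one_covariance_fit(Q, tol = 1e-12, max_iter = 5000)
  expect_true(fit$converged)
  expect_equal(fit$ell, 0.21 * sum(delta^2), tolerance = 1e-8)
  expect_equal(fit$q, sqrt(0.21) * delta, tolerance = 1e-6)
  # exactly rank-one input (diagonal included) converges immediately
  Q1 <- 0.21 * outer(delta, delta)
  f1 <- rank_one_covariance_fit(Q1)
  expect_equal(f1$n_iter, 1L)
  expect_equal(f1$q, sqrt(0.21) * delta, tolerance = 1e-9)
  expect_error(rank_one_covariance_fit(Q[1:2, 1:2]), "M >= 3")
})

test_that("rank_one_tensor_fit recovers the planted factor with the data-identified sign", {
  rho <- 0.3
  delta <- c(10, 20, 30, 15)
  cc <- rho * (1 - rho) * (2 * rho - 1)   # negative for rho < 1/2
  T <- array(cc * outer(outer(delta, delta), delta), dim = rep(4, 3))
  fit <- rank_one_tensor_fit(T, tol = 1e-12)
  expect_true(fit$converged && fit$identifiable)
  t_expect <- sign(cc) * abs(cc)^(1 / 3) * delta
  expect_equal(fit$t, t_expect, tolerance = 1e-6)
  # products on distinct entries reproduce the tensor
  expect_equal(fit$t[1] * fit$t[2] * fit$t[3], cc * delta[1] * delta[2] * delta[3],
               tolerance = 1e-6)
  # rho = 1/2 kills the off-diagonal tensor: unidentifiable
  T0 <- array(0, dim = rep(4, 3))
  f0 <- rank_one_tensor_fit(T0)
  expect_false(f0$identifiable)
})

test_that("infer_prevalence_delta inverts exact population moments", {
  for (rho in c(0.2, 0.3, 0.45, 0.7)) {
    delta <- c(10, 20, 30)
    pm <- population_moments(rho, delta, s0 = c(4, 5, 6), s1 = c(2, 3, 4))
    cf <- rank_one_covariance_fit(pm$Q, tol = 1e-13, max_iter = 10000)
    tf <- rank_one_tensor_fit(pm$T, tol = 1e-13, init = cf$u)
    inf <- infer_prevalence_delta(cf$q, cf$ell, tf$t)
    expect_equal(inf$rho_hat, rho, tolerance = 1e-8)
    expect_equal(inf$delta_hat, delta, tolerance = 1e-8)
    expect_equal(sign(inf$gamma), sign(1 - 2 * rho))
  }
  # gamma ~ 0 degenerates gracefully to rho = 1/2
  delta <- c(10, 20, 30)
  q <- sqrt(0.25) * delta
  expect_warning(inf <- infer_prevalence_delta(q, 0.25 * sum(delta^2), rep(0, 3)),
                 "0.5")
  expect_equal(inf$rho_hat, 0.5)
  expect_equal(inf$delta_hat, delta, tolerance = 1e-10)
})

test_that("variance_sums solves the mixture moment system and its closed forms", {
  # uninformative classifier: sum is (N^2-1)/6
  n <- 100
  m2 <- (n^2 - 1) / 12
  expect_equal(as.numeric(variance_sums(m2, 0, 0.4, 0)), (n^2 - 1) / 6)
  expect_true(attr(variance_sums(m2, 0, 0.4, 0), "flagged"))
  # hand-evaluated closed form at N=100, rho=0.4, delta=30
  expect_equal(as.numeric(variance_sums(m2, 0, 0.4, 30)),
               2 * (9999 / 12) - 900 * (0.48 + 0.04 / 3))
  expect_equal(as.numeric(variance_sums(m2, 0, 0.4, 30)), 1222.5)
  # full system round trip from exact population moments
  rho <- 0.35
  delta <- c(8, -3, 20)
  s0 <- c(9, 4, 7); s1 <- c(5, 6, 2)
  pm <- population_moments(rho, delta, s0, s1)
  vs <- variance_sums(pm$m2, pm$m3, rho, delta)
  expect_equal(as.numeric(vs), s0 + s1, tolerance = 1e-10)
  # non-positive solutions are floored and flagged
  vf <- variance_sums(c(1), c(0), 0.4, c(10))
  expect_gt(as.numeric(vf), 0)
  expect_true(attr(vf, "flagged"))
})

test_that("fit_umoca recovers weights, prevalence and variance sums on independent simulations", {
  cors <- vapply(1:5, function(s) {
    sim <- sim_ensemble(s, n = 2500)
    uf <- fit_umoca(sim$ranks)
    wref <- reference_independent_weights(sim$ranks, sim$labels)
    c(cor = cor(as.numeric(uf$weights), wref),
      rho = uf$estimates$rho_hat,
      vs_cor = {
        mom <- conditioned_moments(sim$ranks, sim$labels)
        cor(uf$estimates$var_sums, diag(mom$C))
      },
      d_cor = cor(uf$estimates$delta_hat,
                  conditioned_moments(sim$ranks, sim$labels)$delta))
  }, numeric(4))
  expect_gt(median(cors["cor", ]), 0.99)
  expect_true(all(abs(cors["rho", ] - 0.4) < 0.05))
  expect_gt(median(cors["vs_cor", ]), 0.9)
  expect_gt(median(cors["d_cor", ]), 0.95)
})

test_that("conditional dependence degrades unsupervised weight recovery", {
  seeds <- 1:6
  indep <- vapply(seeds, function(s) {
    sim <- sim_ensemble(s, n = 1500, m = 8,
                        aucs = seq(0.55, 0.9, length.out = 8))
    cor(as.numeric(fit_umoca(sim$ranks)$weights),
        reference_independent_weights(sim$ranks, sim$labels))
  }, numeric(1))
  dep <- vapply(seeds, function(s) {
    corr <- sample_dependence_matrix(8, 0.6, seed = 100 + s)
    sim <- sim_ensemble(s, n = 1500, m = 8,
                        aucs = seq(0.55, 0.9, length.out = 8), corr = corr)
    cor(as.numeric(fit_umoca(sim$ranks)$weights),
        reference_independent_weights(sim$ranks, sim$labels))
  }, numeric(1))
  expect_lt(median(dep), median(indep))
})

test_that("identical classifier copies do not crash the unsupervised fit", {
  sim <- sim_ensemble(44, n = 400, m = 1, aucs = 0.75)
  r <- rbind(sim$ranks[1, ], sim$ranks[1, ], sim$ranks[1, ], sim$ranks[1, ])
  rownames(r) <- paste0("clf", 1:4)
  expect_warning(uf <- fit_umoca(r), "1/2|0.5")
  # maximally dependent: Q is exactly rank one with inflated leading eigenvalue
  mom <- unconditional_moments(r)
  ev <- eigen(mom$Q, symmetric = TRUE)$values
  expect_gt(ev[1], 0)
  expect_lt(ev[2] / ev[1], 1e-10)
  expect_true(all(is.finite(uf$weights)))
})

test_that("the unsupervised interface is label-free and needs at least 3 classifiers", {
  expect_false("labels" %in% names(c(formals(fit_umoca),
                                     formals(unconditional_moments),
                                     formals(rank_one_covariance_fit),
                                     formals(rank_one_tensor_fit),
                                     formals(infer_prevalence_delta))))
  r <- random_rank_matrix(2, 20, seed = 45)
  expect_error(fit_umoca(r), "M >= 3")
})
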