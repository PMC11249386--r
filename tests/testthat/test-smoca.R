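test_that("conditioned_moments matches hand values and a loop-based oracle", {
  mom <- conditioned_moments(rbind(c(1, 2, 3, 4)), c(1, 1, 0, 0))
  expect_equal(unname(mom$delta), 2)
  expect_equal(unname(drop(mom$C)), 0.5)
  expect_equal(mom$rho, 0.5)
  # duplicated classifiers make C singular
  r <- random_rank_matrix(1, 30, seed = 31)
  r2 <- rbind(r, r)
  y <- rep_len(c(1L, 0L), 30)
  mom2 <- conditioned_moments(r2, y)
  expect_equal(mom2$C[1, 1], mom2$C[1, 2])
  expect_lt(abs(det(mom2$C)), 1e-8)
  # loop-based oracle for per-class means and population covariances
  set.seed(32)
  rr <- random_rank_matrix(4, 25, seed = 33)
  yy <- integer(25); yy[sample(25, 10)] <- 1L
  mm <- conditioned_moments(rr, yy)
  for (cls in 0:1) {
    idx <- which(yy == cls)
    mu <- sapply(1:4, function(i) mean(rr[i, idx]))
    C <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      C[i, j] <- mean((rr[i, idx] - mu[i]) * (rr[j, idx] - mu[j]))
    }
    expect_equal(unname(if (cls == 0) mm$mu0 else mm$mu1), mu)
    expect_equal(unname(if (cls == 0) mm$C0 else mm$C1), C)
  }
  expect_equal(mm$C, mm$C0 + mm$C1)
  # prevalence-weighted mean identity for tie-free ranks
  expect_equal(unname(mm$rho * mm$mu1 + (1 - mm$rho) * mm$mu0), rep(13, 4))
  expect_error(conditioned_moments(rr, c(1L, rep(0L, 24))), "at least 2")
})

test_that("moca_weights solves C w = delta up to unit normalization", {
  w <- moca_weights(list(delta = c(1, 1), C = diag(c(1, 4))))
  expect_equal(as.numeric(w), c(1, 0.25) / sqrt(1.0625), tolerance = 1e-12)
  expect_equal(round(as.numeric(w), 4), c(0.9701, 0.2425))
  # scale of delta drops out
  set.seed(34)
  A <- matrix(rnorm(9), 3); C <- crossprod(A) + diag(3)
  d <- rnorm(3)
  expect_equal(moca_weights(list(delta = 7 * d, C = C)),
               moca_weights(list(delta = d, C = C)))
  expect_equal(sum(moca_weights(list(delta = d, C = C))^2), 1)
  # singular C errors unless ridged
  Cs <- matrix(1, 2, 2)
  expect_error(moca_weights(list(delta = c(1, 2), C = Cs)), "ridge")
  expect_silent(moca_weights(list(delta = c(1, 2), C = Cs), ridge = 1e-6))
})

test_that("moca_weights matches a numerical maximizer of the ensemble SNR", {
  set.seed(35)
  for (i in 1:10) {
    m <- 5
    A <- matrix(rnorm(m * m), m)
    C <- crossprod(A) + 0.1 * diag(m)
    delta <- rnorm(m)
    w <- moca_weights(list(delta = delta, C = C))
    negf <- function(v) {
      v <- v / sqrt(sum(v^2))
      -ensemble_snr(v, delta, C)
    }
    best <- NULL
    for (r in 1:3) {
      o <- optim(rnorm(m), negf, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
      o <- optim(o$par / sqrt(sum(o$par^2)), negf, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    v <- best$par / sqrt(sum(best$par^2))
    expect_gt(abs(sum(v * w)), 1 - 1e-8)
  }
})

test_that("ensemble_score is the weighted rank combination with ID alignment", {
  r <- random_rank_matrix(3, 12, seed = 36)
  y <- rep_len(c(1L, 0L), 12)
  expect_equal(unname(ensemble_score(r, c(1, 0, 0))), unname(r[1, ]))
  expect_equal(unname(ensemble_score(r, woc_weights(3))), unname(colSums(r)))
  # double-loop oracle
  w <- rnorm(3)
  s <- sapply(1:12, function(k) sum(w * r[, k]))
  expect_equal(unname(ensemble_score(r, w)), s)
  # alignment by classifier name
  wn <- w; names(wn) <- rownames(r)
  perm <- c("clf3", "clf1", "clf2")
  expect_equal(ensemble_score(r, wn[perm]), ensemble_score(r, wn))
  expect_error(ensemble_score(r, c(1, 2)), "does not match")
})

test_that("greedy selection starts from the best classifier and never loses to it", {
  sim <- sim_ensemble(37, n = 300, m = 5, aucs = c(0.6, 0.85, 0.7, 0.55, 0.75))
  w <- greedy_select(sim$ranks, sim$labels)
  sel <- attr(w, "selected")
  mom <- conditioned_moments(sim$ranks[sel, , drop = FALSE], sim$labels)
  sel_snr <- optimal_ensemble_snr(mom$delta, mom$C)
  best_single <- max(apply(sim$ranks, 1, classifier_snr, labels = sim$labels))
  expect_gte(sel_snr, best_single - 1e-10)
  # exhaustive-subset oracle: greedy cannot beat the best subset
  subsets <- unlist(lapply(1:5, function(k) combn(5, k, simplify = FALSE)),
                    recursive = FALSE)
  all_snr <- vapply(subsets, function(idx) {
    mm <- conditioned_moments(sim$ranks[idx, , drop = FALSE], sim$labels)
    tryCatch(optimal_ensemble_snr(mm$delta, mm$C), error = function(e) NA_real_)
  }, numeric(1))
  expect_lte(sel_snr, max(all_snr, na.rm = TRUE) + 1e-10)
  # zero weights exactly outside the selection
  expect_true(all(w[setdiff(1:5, sel)] == 0))
})

test_that("greedy selection keeps at most one copy of a duplicated classifier", {
  sim <- sim_ensemble(38, n = 200, m = 3, aucs = c(0.7, 0.8, 0.75))
  r <- rbind(sim$ranks, dup = sim$ranks[1, ])
  w <- greedy_select(r, sim$labels)
  sel <- attr(w, "selected")
  expect_false(all(c(1, 4) %in% sel))
  # single informative classifier selects itself with unit weight
  one <- greedy_select(sim$ranks[1, , drop = FALSE], sim$labels)
  expect_equal(abs(as.numeric(one)), 1)
})

test_that("fit_smoca converges in direction to the independence form on independent simulations", {
  sim <- sim_ensemble(39, n = 4000, m = 6, aucs = seq(0.6, 0.85, length.out = 6))
  w <- fit_smoca(sim$ranks, sim$labels)
  wref <- reference_independent_weights(sim$ranks, sim$labels)
  expect_gt(sum(as.numeric(w) * wref), 0.99)
})

test_that("classifier permutation permutes supervised weights identically", {
  sim <- sim_ensemble(40, n = 300, m = 5)
  w <- fit_smoca(sim$ranks, sim$labels)
  perm <- c(4, 2, 5, 1, 3)
  wp <- fit_smoca(sim$ranks[perm, ], sim$labels)
  expect_equal(as.numeric(wp), as.numeric(w)[perm])
})
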