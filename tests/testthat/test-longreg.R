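test_that("the objective evaluates its three terms correctly", {
  inst <- random_instance(41, n = 5, d = 4, c_ = 3, T_ = 2)
  W <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  # explicit independent recomputation
  rss <- sum((inst$X[, , 1] %*% W[, , 1] - inst$Y)^2) +
    sum((inst$X[, , 2] %*% W[, , 2] - inst$Y)^2)
  Wbar <- (W[, , 1] + W[, , 2]) / 2
  grp <- sum(sqrt(rowSums((W[, , 1] - Wbar)^2) +
                  rowSums((W[, , 2] - Wbar)^2)))
  nuc <- sum(svd(cbind(W[, , 1], W[, , 2]))$d)
  expect_equal(objective(inst$X, inst$Y, W, 2, 3), rss + 2 * grp + 3 * nuc)
  # zero coefficients: only the data term survives
  W0 <- array(0, c(4, 3, 2))
  expect_equal(objective(inst$X, inst$Y, W0, 2, 3), 2 * sum(inst$Y^2))
  # no penalties: residual sum of squares only
  expect_equal(objective(inst$X, inst$Y, W, 0, 0), rss)
  expect_error(objective(inst$X, inst$Y, W[1:3, , ], 1, 1), "W must be")
})

test_that("reweighting matrices obey their closed forms", {
  eps <- 1e-8
  # time-constant W: zero group deviation, D = 1/(2 sqrt(eps))
  Wc <- array(rep(matrix(rnorm(12), 4), 3), c(4, 3, 3))
  st <- update_reweighting(Wc, eps)
  expect_equal(st$D, rep(1 / (2 * sqrt(eps)), 4))
  expect_equal(st$Wbar, Wc[, , 1], ignore_attr = TRUE)
  # zero W: Dbb = (1/2) eps^{-1/2} I
  st0 <- update_reweighting(array(0, c(4, 3, 2)), eps)
  expect_equal(st0$Dbb, diag(0.5 / sqrt(eps), 4))
  # matrix-function oracle: (2 Dbb)^2 = (W1 W1' + eps I)^{-1}
  W <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  st <- update_reweighting(W, eps)
  W1 <- unfold_coefficients(W)
  expect_equal((2 * st$Dbb) %*% (2 * st$Dbb),
               solve(tcrossprod(W1) + eps * diag(5)), tolerance = 1e-8)
  # g via the deviation identity equals the norm identity
  g2 <- rowSums(W[, , 1]^2) + rowSums(W[, , 2]^2) -
    rowSums((W[, , 1] + W[, , 2])^2) / 2
  expect_equal(st$g, g2, tolerance = 1e-10)
})

test_that("the unpenalized single-time fit equals ordinary least squares", {
  set.seed(43)
  X <- array(rnorm(50 * 5), c(50, 5, 1))
  Y <- matrix(rnorm(50 * 3), 50, 3)
  fit <- fit_longreg(X, Y, 0, 0, max_iter = 5, tol = 0, ridge_init = 0)
  Wols <- solve(crossprod(X[, , 1]), crossprod(X[, , 1], Y))
  expect_lt(max(abs(fit$W[, , 1] - Wols)), 1e-6)
  # rank-deficient unpenalized system is refused with advice
  Xs <- array(rnorm(4 * 10), c(4, 10, 1))
  Ys <- matrix(rnorm(4 * 2), 4, 2)
  expect_error(fit_longreg(Xs, Ys, 0, 0, max_iter = 3, tol = 0,
                           ridge_init = 0), "ridge_init")
})

test_that("the objective trace never increases, across the whole theta grid", {
  for (s in 1:20) {
    inst <- random_instance(100 + s)
    th <- grid_spec()$theta_values[1 + (s %% 9)]
    fit <- fit_longreg(inst$X, inst$Y, th, th, max_iter = 60, tol = 0)
    o <- fit$objective
    expect_true(all(diff(o) <= 1e-6 * pmax(1, abs(o[-length(o)]))),
                label = sprintf("monotone trace, seed %d theta %g", s, th))
  }
})

test_that("huge temporal-smoothness weight forces time-constant coefficients", {
  inst <- random_instance(55, n = 25, d = 6, c_ = 4, T_ = 3)
  fit <- fit_longreg(inst$X, inst$Y, 1e6, 0, max_iter = 500, tol = 0)
  expect_lt(temporal_deviation(fit$W), 1e-3)
})

test_that("temporal variance shrinks with theta1; rank shrinks with theta2", {
  inst <- random_instance(42, n = 30, d = 10, c_ = 6, T_ = 3)
  devs <- vapply(c(0.1, 1, 10, 1000), function(th1) {
    f <- fit_longreg(inst$X, inst$Y, th1, 0.1, max_iter = 200, tol = 0)
    Wbar <- apply(f$W, c(1, 2), mean)
    sum(vapply(1:3, function(t) sum((f$W[, , t] - Wbar)^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  ranks <- vapply(c(0.1, 1, 10, 100), function(th2) {
    f <- fit_longreg(inst$X, inst$Y, 0.1, th2, max_iter = 200, tol = 0)
    numerical_rank(f$W)
  }, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("permuting gene columns permutes the coefficient gene axis identically", {
  inst <- random_instance(77, n = 15, d = 6, c_ = 5, T_ = 2)
  perm <- c(3, 1, 5, 2, 4)
  f1 <- fit_longreg(inst$X, inst$Y, 2, 2, max_iter = 50, tol = 0)
  f2 <- fit_longreg(inst$X, inst$Y[, perm], 2, 2, max_iter = 50, tol = 0)
  expect_equal(f2$W, f1$W[, perm, ], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("overall weights sum absolute coefficients and rank genes by time average", {
  # single nonzero entry: W'(2, 3) = 2, average 0.5 over four time points
  W <- array(0, c(6, 4, 4))
  W[5, 3, 2] <- -2
  wm <- overall_weights(W)
  expect_equal(wm$W_prime[2, 3], 2)
  expect_equal(unname(wm$avg_weight[3]), 0.5)
  expect_equal(sum(wm$W_prime), 2)
  # brute-force double loop on a random tensor
  W <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  wm <- overall_weights(W)
  for (t in 1:2) for (j in 1:3) {
    acc <- 0
    for (i in 1:5) acc <- acc + abs(W[i, j, t])
    expect_equal(wm$W_prime[t, j], acc)
  }
  # zero tensor: all weights zero
  expect_true(all(overall_weights(array(0, c(2, 2, 2)))$W_prime == 0))
  # ranking and k guards
  wm2 <- overall_weights(array(rep(c(3, 1, 2), each = 2), c(2, 3, 1)))
  expect_equal(top_genes(wm2, 2), c("1", "3"))
  expect_equal(top_genes(wm2, 3), c("1", "3", "2"))
  expect_error(top_genes(wm2, 4), "exceeds")
})

test_that("fit converges under the relative-change tolerance and records it", {
  inst <- random_instance(88)
  fit <- fit_longreg(inst$X, inst$Y, 1, 1, max_iter = 500, tol = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$iterations, 500)
  o <- fit$objective
  expect_lt(abs(o[length(o)] - o[length(o) - 1]) / abs(o[length(o) - 1]),
            1e-8)
  # trace endpoint equals the smoothed objective of the returned W
  expect_equal(objective(inst$X, inst$Y, fit$W, 1, 1, epsilon = fit$epsilon),
               o[length(o)], tolerance = 1e-10)
})

test_that("planted genes are recovered by weight ranking on the small profile", {
  rec <- vapply(1:20, function(s) {
    coh <- generate_dataset(small_profile(seed = s, effect_size = 0))
    f <- fit_longreg(coh$X, coh$Y, 10, 10, max_iter = 300, tol = 0)
    top <- top_genes(overall_weights(f), 5)
    planted <- colnames(coh$Y)[coh$active_genes]
    length(intersect(top, planted)) / length(planted)
  }, numeric(1))
  expect_gte(mean(rec), 0.8)
})
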