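test_that("modified Cholesky factors round-trip the covariance", {
  for (s in 1:20) {
    S <- random_pd(5, s)
    f <- modified_cholesky(S)
    expect_true(all(abs(diag(f$T) - 1) < 1e-12))
    expect_true(all(f$T[upper.tri(f$T)] == 0))
    expect_true(all(f$D > 0))
    # reconstruct through the inverse parameterization
    Sinv <- t(f$T) %*% diag(1 / f$D) %*% f$T
    expect_equal(Sinv %*% S, diag(5), tolerance = 1e-10)
  }
})

test_that("Cholesky-factor density matches the dense oracle", {
  # identity covariance at the mean: the standard-normal constant in d = 5
  mu <- rnorm(5)
  expect_equal(gaussian_density_cholesky(mu, mu, diag(5), rep(1, 5)),
               (2 * pi)^(-5 / 2))

  # general covariance at the mean: (2*pi)^(-d/2) |Sigma|^(-1/2)
  S <- random_pd(5, 3)
  f <- modified_cholesky(S)
  expect_equal(gaussian_density_cholesky(mu, mu, f$T, f$D),
               (2 * pi)^(-5 / 2) * prod(f$D)^(-1 / 2), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    S <- random_pd(5, 100 + i)
    f <- modified_cholesky(S)
    mu <- rnorm(5)
    X <- matrix(rnorm(50), 10)
    got <- gaussian_density_cholesky(X, mu, f$T, f$D)
    oracle <- apply(X, 1, dense_mvn, mu = mu, sigma = S)
    expect_equal(got, oracle, tolerance = 1e-10)
  }

  expect_error(gaussian_density_cholesky(mu, mu, diag(5), rep(-1, 5)),
               "positive")
  badT <- diag(5); badT[1, 2] <- 0.5
  expect_error(gaussian_density_cholesky(mu, mu, badT, rep(1, 5)),
               "lower-triangular")
})

test_that("single-component fit equals the closed-form Gaussian MLE", {
  set.seed(12)
  x <- matrix(rnorm(500, sd = 2), 100)
  fit <- longmix(x, G = 1)
  expect_equal(fit$means[1, ], colMeans(x), tolerance = 1e-10)
  S_mle <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
  expect_equal(fit$Sigma[[1]], S_mle, tolerance = 1e-8)
  f <- modified_cholesky(S_mle)
  ll_closed <- sum(gaussian_density_cholesky(x, colMeans(x), f$T, f$D,
                                             log = TRUE))
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
  expect_equal(fit$bic, 2 * ll_closed - 20 * log(100), tolerance = 1e-8)
})

test_that("EM log-likelihood is nondecreasing and responsibilities sum to 1", {
  set.seed(13)
  for (i in 1:10) {
    x <- matrix(rnorm(200 * 5), 200)
    fit <- suppressMessages(longmix(x, G = 3, n_restarts = 2,
                                    seed = 1300 + i))
    expect_true(all(diff(fit$trace) >= -1e-9))
    expect_equal(rowSums(fit$z), rep(1, 200), tolerance = 1e-12)
    expect_true(all(fit$weights > 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  }
})

test_that("well-separated planted clusters are recovered exactly", {
  shapes <- rbind(c(0, 0, 0, 0, 0), c(3, 3, 3, 3, 3))  # 6.7 sigma apart
  prof <- make_labelled_profiles(500, shapes, sigma = 1, seed = 14)
  fit <- longmix(prof$x, G = 2, n_restarts = 3, seed = 14)
  expect_equal(adjusted_rand(fit$cluster, prof$labels), 1)

  # label-permutation invariance: an independent run agrees up to labels
  fit2 <- longmix(prof$x, G = 2, n_restarts = 3, seed = 99)
  expect_equal(adjusted_rand(fit$cluster, fit2$cluster), 1)
})

test_that("BIC selection balances fit and complexity", {
  # single flat cluster: G = 1 wins
  prof <- make_labelled_profiles(300, matrix(0, 1, 5), sigma = 0.3,
                                 seed = 15)
  best <- suppressMessages(longmix_select(prof$x, G = 1:3, n_restarts = 3,
                                          seed = 15))
  expect_equal(best$G, 1L)
  expect_equal(nrow(best$selection), 3L)
  expect_true(all(diff(best$selection$loglik) >= -1e-6))

  # parameter count: G = 4 unconstrained in d = 5 has 3 + 20 + 60 params
  prof4 <- make_labelled_profiles(200, make_cluster_shapes(4, 4),
                                  sigma = 0.3, seed = 16)
  fit4 <- longmix(prof4$x, G = 4, n_restarts = 3, seed = 16)
  expect_equal(fit4$n_params, 83)
  expect_equal(fit4$bic, 2 * fit4$loglik - 83 * log(200))
})

test_that("constrained covariance families have the stated complexity", {
  prof <- make_labelled_profiles(200, make_cluster_shapes(2, 4),
                                 sigma = 0.3, seed = 17)
  shared <- longmix(prof$x, G = 2, model = "shared", n_restarts = 2,
                    seed = 17)
  expect_equal(shared$n_params, 1 + 10 + 15)
  expect_equal(shared$Sigma[[1]], shared$Sigma[[2]], tolerance = 1e-12)
  diagonal <- longmix(prof$x, G = 2, model = "diagonal", n_restarts = 2,
                      seed = 17)
  expect_equal(diagonal$n_params, 1 + 10 + 10)
  expect_equal(diagonal$T[[1]], diag(5), tolerance = 1e-12)
  expect_true(all(diff(diagonal$trace) >= -1e-9))
})

test_that("component means are recovered on planted data", {
  shapes <- make_cluster_shapes(4, 3)
  errs <- vapply(1:5, function(s) {
    prof <- make_labelled_profiles(1000, shapes, sigma = 0.25,
                                   seed = 2000 + s)
    fit <- longmix(prof$x, G = 4, n_restarts = 4, seed = 2000 + s)
    # match fitted components to truth by nearest mean
    idx <- apply(fit$means, 1, function(m)
      which.min(colSums((t(shapes) - m)^2)))
    expect_equal(sort(idx), 1:4)  # bijection
    max(abs(fit$means - shapes[idx, , drop = FALSE]))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("degenerate requests error clearly", {
  x <- matrix(rnorm(20), 4)
  expect_error(longmix(x, G = 5), "exceeds")
  expect_error(longmix(x, G = 0), "G must be")
})

test_that("profile prescreen applies the stress-vs-optimal rule", {
  prof <- rbind(hit = c(0, 1.7, 0, 0, 0),
                flat = c(0, 0, 0, 0, 0),
                late = c(0, 0.2, 1.8, 0.3, 0))
  expect_setequal(prescreen_profiles(prof, 3), c("hit", "late"))
  expect_equal(prescreen_profiles(prof, 1.01), c("hit", "late"))
  expect_setequal(prescreen_profiles(prof, 1), rownames(prof))
})

test_that("up/down splitting follows the sign of the split pair", {
  prof <- rbind(a = c(0, 1, 0, 0, 0), b = c(1, 0, 0, 0, 0),
                c = c(0.5, 0.5, 0, 0, 0))
  expect_message(s <- split_up_down(c(1, 1, 1), prof, c(2, 1)), "tie")
  expect_equal(as.character(s), c("up", "down", "down"))
  s2 <- split_up_down(c(1, 1, 1), prof, c(1, 2))
  expect_equal(as.character(s2)[1:2], c("down", "up"))
  expect_error(split_up_down(1, prof[1, , drop = FALSE], c(0, 9)),
               "split_pair")

  # mirrored profiles fall in the same cluster but opposite subgroups
  shapes <- rbind(c(0, 2, 4, 1, 0))
  up <- make_labelled_profiles(60, shapes, 0.2, seed = 18)$x
  down <- -up
  x <- rbind(up, down)
  fit <- longmix(x, G = 2, n_restarts = 3, seed = 18)
  sub <- split_up_down(fit$cluster, x, c(2, 1))
  expect_equal(as.character(sub[1:60]), rep("up", 60))
  expect_equal(as.character(sub[61:120]), rep("down", 60))
})

test_that("fitted-model methods are coherent", {
  shapes <- make_cluster_shapes(2, 4)
  prof <- make_labelled_profiles(150, shapes, 0.3, seed = 19)
  fit <- longmix(prof$x, G = 2, n_restarts = 2, seed = 19)

  expect_output(print(fit), "G = 2 components")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.longmix")
  expect_equal(sum(sm$sizes), 150L)
  expect_output(print(sm), "mean trajectories")

  co <- coef(fit)
  expect_equal(co$means, fit$means)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), fit$n_params)

  expect_equal(predict(fit), fit$cluster)
  resp <- predict(fit, type = "responsibility")
  expect_equal(max.col(resp), fit$cluster)
  # new observations at the component means classify to that component
  expect_equal(predict(fit, fit$means), 1:2)

  expect_equal(dim(residuals(fit)), dim(prof$x))
  expect_equal(fitted(fit) + residuals(fit), unname(prof$x),
               ignore_attr = TRUE)

  draws <- simulate(fit, nsim = 200, seed = 20)
  expect_equal(dim(draws), c(200L, 5L))
  # drawn profiles classify back to their source component
  expect_gte(mean(predict(fit, draws) == attr(draws, "component")), 0.95)
})
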