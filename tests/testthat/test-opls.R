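make_xy <- function(n = 20, p = 5, beta = c(2, -1, 0.5, 1, -0.3),
                    noise = 0, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("autoscaling centers, scales, round-trips, and drops constants", {
  d <- make_xy()
  sc <- autoscale(d$X, d$y)
  expect_equal(unname(colMeans(sc$X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(sc$X, 2, sd)), rep(1, 5), tolerance = 1e-12)
  back <- sweep(sweep(sc$X, 2, sc$params$sds[sc$params$kept], "*"),
                2, sc$params$means[sc$params$kept], "+")
  expect_equal(unname(back), unname(d$X), tolerance = 1e-12)
  Xc <- cbind(d$X, constant = 1)
  expect_warning(sc2 <- autoscale(Xc), "constant")
  expect_equal(sc2$params$dropped, c(constant = 6L))
  expect_equal(ncol(sc2$X), 5L)
  expect_error(autoscale(matrix(1, 5, 2)), "constant")
})

test_that("zero orthogonal components reduce to the one-component PLS1 oracle", {
  d <- make_xy(noise = 0.3, seed = 5)
  m <- fit_opls1(d$X, d$y, n_orthogonal = 0)
  oracle <- nipals_pls1_coef(scale(d$X), drop(scale(d$y)))
  expect_equal(unname(m$coefficients_scaled), unname(oracle),
               tolerance = 1e-10)
})

test_that("noiseless linear responses are reproduced exactly", {
  d <- make_xy(noise = 0)
  m <- fit_opls1(d$X, d$y, n_orthogonal = 4)
  expect_equal(m$r2y, 1, tolerance = 1e-8)
  expect_equal(m$fitted, d$y, tolerance = 1e-6)
})

test_that("orthogonal scores are orthogonal to the response and recover planted structure", {
  set.seed(7)
  n <- 40
  t_p <- rnorm(n)
  t_o <- residuals(lm(rnorm(n) ~ t_p))
  t_o <- t_o / sd(t_o)
  X <- t_p %*% matrix(rnorm(10), 1) + t_o %*% matrix(rnorm(10), 1) +
    matrix(rnorm(n * 10, sd = 0.01), n)
  y <- t_p + rnorm(n, sd = 0.05)
  m <- fit_opls1(X, y, n_orthogonal = 1)
  expect_lt(abs(cor(m$T_orth[, 1L], scale(y))), 1e-6)
  expect_gt(abs(cor(m$T_orth[, 1L], t_o)), 0.99)
  expect_equal(sqrt(sum(m$w^2)), 1)
})

test_that("VIP is normalized, closed-form, and zero for dropped columns", {
  d <- make_xy(noise = 0.5, seed = 8)
  m <- fit_opls1(d$X, d$y)
  expect_equal(sum(vip(m)^2), 5, tolerance = 1e-6)
  # two-variable closed form: orthogonal design, y = first column exactly,
  # so w = (1, 0) and VIP = (sqrt(2), 0)
  X2 <- cbind(a = rep(c(1, -1), 8), b = rep(c(1, 1, -1, -1), 4))
  m2 <- fit_opls1(X2, X2[, "a"], n_orthogonal = 0)
  expect_equal(unname(vip(m2)), c(sqrt(2), 0), tolerance = 1e-10)
  # single retained variable normalizes to VIP = 1
  set.seed(9)
  x1 <- rnorm(30)
  m1 <- fit_opls1(cbind(only = x1), 2 * x1 + rnorm(30, sd = 0.1),
                  n_orthogonal = 0)
  expect_equal(unname(vip(m1)), 1)
  # constant column reports VIP 0 and keeps full length
  Xc <- cbind(d$X, constant = 7)
  mc <- suppressWarnings(fit_opls1(Xc, d$y))
  expect_equal(length(vip(mc)), 6L)
  expect_equal(unname(vip(mc)[6L]), 0)
  expect_equal(unname(mc$coefficients_scaled[6L]), 0)
  expect_equal(sum(vip(mc)^2), 5, tolerance = 1e-6)
  expect_error(vip(structure(list(), class = "opls")), "fitted")
})

test_that("coefficients and VIP are invariant to sample permutation and duplication", {
  d <- make_xy(noise = 0.4, seed = 10)
  m <- fit_opls1(d$X, d$y)
  perm <- sample(nrow(d$X))
  mp <- fit_opls1(d$X[perm, ], d$y[perm])
  expect_equal(mp$coefficients_scaled, m$coefficients_scaled, tolerance = 1e-10)
  expect_equal(mp$vip, m$vip, tolerance = 1e-10)
  md <- fit_opls1(rbind(d$X, d$X), c(d$y, d$y))
  expect_equal(md$coefficients_scaled, m$coefficients_scaled, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  d <- make_xy()
  expect_error(fit_opls1(d$X, rep(1, 20)), "zero variance")
  expect_error(fit_opls1(d$X, d$y, n_orthogonal = 5), "rank")
  expect_error(fit_opls1(d$X[1:2, ], d$y[1:2]), "3 samples")
})

test_that("cross-validation separates signal from noise", {
  d <- make_xy(n = 30, noise = 0, seed = 11)
  expect_gte(cross_validate(d$X, d$y, n_orthogonal = 4), 0.99)
  # Q2 <= R2Y on training data
  d2 <- make_xy(n = 30, noise = 1, seed = 12)
  m <- fit_opls1(d2$X, d2$y, n_orthogonal = 1)
  expect_lte(cross_validate(d2$X, d2$y, n_orthogonal = 1), m$r2y)
  # pure-noise responses rarely look predictive
  low <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(30 * 5), 30, 5)
    yn <- rnorm(30)
    if (cross_validate(Xn, yn, n_orthogonal = 0, folds = 10) <= 0.2)
      low <- low + 1
  }
  expect_gte(low, 90)
  expect_error(cross_validate(d$X, d$y, folds = 31), "folds")
})
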