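test_that("bias rule takes its quadratic values and vanishes at the root", {
  expect_equal(bias_rate(0, 0.2, 1), 1)
  expect_equal(bias_rate(1, 0.2, 1), 1 - 7 + 5)
  # smaller positive root of 1 - 7y + 5y^2, from an independent root oracle
  y0 <- bias_rule_root(0.2)
  expect_lt(abs(bias_rate(y0, 0.2, 1)), 1e-12)
  expect_error(bias_rate(0.5, -0.1, 1), "positive")
})

test_that("bias rule sign structure matches the root oracle across targets", {
  for (mu in c(0.1, 0.2, 0.4)) {
    y0 <- bias_rule_root(mu)
    ys <- seq(0.001, 0.999, length.out = 200)
    r <- bias_rate(ys, mu, 1)
    expect_true(all(r[ys < y0 - 1e-6] > 0))
    # beyond the smaller root the rate is negative throughout (0, 1):
    # the larger root lies above 1 for these targets
    expect_true(all(r[ys > y0 + 1e-6] < 0))
  }
})

test_that("gain rule combines the 1/a drift with input-weighted bias change", {
  expect_equal(gain_rate(0, bias_rate(0.5, 0.2, 1) * 0, 1, 1), 1)
  # at the bias-rule root the gain still drifts up at eta / a
  y0 <- bias_rule_root(0.2)
  expect_equal(gain_rate(3.7, bias_rate(y0, 0.2, 1), 2, 1), 0.5,
               tolerance = 1e-12)
  expect_equal(gain_rate(1, bias_rate(1, 0.2, 1), 1, 1), 0)
  expect_error(gain_rate(1, 0, -1, 1), "positive")
})

test_that("euclidean gradient is the negated rate pair and matches finite differences of the loss integrand", {
  expect_equal(euclidean_gradient(0, 0, 1, 0.2), c(-1, -1))
  # algebraic identity against the rate formulas over random draws
  set.seed(11)
  for (i in 1:1000) {
    y <- runif(1); z <- runif(1, -10, 10); a <- runif(1, 0.1, 4)
    g <- euclidean_gradient(y, z, a, 0.2)
    db <- bias_rate(y, 0.2, 1)
    expect_equal(-g, c(gain_rate(z, db, a, 1), db))
  }
  # per-sample KL integrand: l(a, b; x) = -log a - log g - log(1-g) + g / mu
  # (x-only terms drop); central finite differences in a and b
  loss <- function(a, b, x, mu) {
    g <- plogis(a * x + b)
    -log(a) - log(g) - log(1 - g) + g / mu
  }
  h <- 1e-6
  set.seed(12)
  for (i in 1:50) {
    # keep a*x + b within +/- 9 so log(1 - g) in the oracle stays accurate
    a <- runif(1, 0.3, 2); b <- runif(1, -5, 1)
    x <- runif(1, -2, 4); mu <- runif(1, 0.05, 0.5)
    fd <- c((loss(a + h, b, x, mu) - loss(a - h, b, x, mu)) / (2 * h),
            (loss(a, b + h, x, mu) - loss(a, b - h, x, mu)) / (2 * h))
    y <- plogis(a * x + b)
    expect_equal(euclidean_gradient(y, x, a, mu), fd, tolerance = 1e-5)
  }
})

test_that("Fisher update is the moving average of gradient outer products", {
  fs <- fisher_state()
  up <- update_fisher(fs, c(1, 2), 1)
  expect_equal(up$f, matrix(c(1, 2, 2, 4), 2, 2))
  expect_equal(update_fisher(up, c(5, -3), 0)$f, up$f)
  # unrolled-recursion oracle over 500 random updates
  set.seed(5)
  lam <- 0.03
  grads <- matrix(rnorm(1000), ncol = 2)
  fs <- fisher_state()
  for (k in 1:500) fs <- update_fisher(fs, grads[k, ], lam)
  ref <- matrix(0, 2, 2)
  for (k in 1:500)
    ref <- ref + lam * (1 - lam)^(500 - k) * tcrossprod(grads[k, ])
  expect_equal(fs$f, ref, tolerance = 1e-12)
  # symmetry exact, PSD within tolerance
  expect_identical(fs$f[1, 2], fs$f[2, 1])
  expect_gte(min(eigen(fs$f, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("natural update reduces to the plain step under identity or pure-regularizer metrics", {
  tp <- transfer_params(1.5, -4)
  grad <- c(0.3, -0.8)
  # identity metric, vanishing regularization
  up <- natural_update(tp, grad, fisher_state(diag(2)), 0.01, 1e-12)
  expect_equal(c(up$a, up$b), c(1.5, -4) - 0.01 * grad, tolerance = 1e-9)
  # zero Fisher, unit regularizer
  up2 <- natural_update(tp, grad, fisher_state(), 0.01, 1)
  expect_equal(c(up2$a, up2$b), c(1.5, -4) - 0.01 * grad, tolerance = 1e-12)
})

test_that("natural update matches an independent linear solve for random PSD metrics", {
  set.seed(21)
  for (i in 1:200) {
    m <- matrix(rnorm(4), 2, 2)
    f <- crossprod(m)               # random PSD
    grad <- rnorm(2)
    eps <- 10^runif(1, -4, -1)
    tp <- transfer_params(2, -3)
    up <- natural_update(tp, grad, fisher_state(f), 0.005, eps)
    step <- solve(f + eps * diag(2), grad)   # no explicit inverse
    ref <- c(2, -3) - 0.005 * step
    ref[1] <- max(ref[1], 1e-6)              # the documented gain clamp
    expect_equal(c(up$a, up$b), ref, tolerance = 1e-6)
  }
})

test_that("a zero gradient leaves both update variants at their fixed point", {
  tp <- transfer_params(1.2, -3.3)
  fs <- fisher_state(matrix(c(2, 0.5, 0.5, 1), 2, 2))
  up <- natural_update(tp, c(0, 0), fs, 0.01, 1e-4)
  expect_equal(c(up$a, up$b), c(1.2, -3.3))
})

test_that("plasticity steps move the bias down for high output and up for low output", {
  cfg_plain <- ip_config(use_natural_gradient = FALSE)
  tp <- transfer_params(1, -5)
  fs <- fisher_state()
  hi <- ip_step(tp, fs, y = 0.9, z = 3, cfg_plain, dt = 1)
  expect_lt(hi$tp$b, tp$b)
  lo <- ip_step(tp, fs, y = 0.05, z = 3, cfg_plain, dt = 1)
  expect_gt(lo$tp$b, tp$b)
  # when the bias rule is silent the gain still drifts upward (eta / a)
  y0 <- bias_rule_root(0.2)
  still <- ip_step(tp, fs, y = y0, z = 5, cfg_plain, dt = 1)
  expect_gt(still$tp$a, tp$a)
  expect_equal(still$tp$b, tp$b, tolerance = 1e-12)
})

test_that("plain plasticity over many steps equals the scalar accumulation of the rate formulas", {
  cfg <- ip_config(eta = 0.002, mu = 0.2, use_natural_gradient = FALSE)
  set.seed(9)
  ys <- runif(100); zs <- runif(100, -2, 8)
  tp <- transfer_params(1, -5)
  fs <- fisher_state()
  for (k in 1:100) {
    st <- ip_step(tp, fs, ys[k], zs[k], cfg, dt = 0.05)
    tp <- st$tp; fs <- st$fisher
  }
  a_ref <- 1; b_ref <- -5
  for (k in 1:100) {
    db <- 0.002 * (1 - (2 + 1 / 0.2) * ys[k] + ys[k]^2 / 0.2)
    da <- 0.002 / a_ref + zs[k] * db
    a_ref <- max(a_ref + 0.05 * da, 1e-6)
    b_ref <- b_ref + 0.05 * db
  }
  expect_equal(c(tp$a, tp$b), c(a_ref, b_ref), tolerance = 1e-12)
})

test_that("gain is clamped below and never flips the transfer orientation", {
  cfg <- ip_config(use_natural_gradient = FALSE)
  tp <- transfer_params(1e-6 * 1.5, -1)
  # a large negative gain rate would push a through zero
  st <- ip_step(tp, fisher_state(), y = 1, z = 1e4, cfg, dt = 1)
  expect_gte(st$tp$a, 1e-6)
})

test_that("empirical divergence is near zero for the target itself and positive otherwise", {
  mu <- 0.2
  set.seed(31)
  # inverse-CDF sample of the exponential truncated to (0, 1)
  u <- runif(1e5)
  y <- -mu * log(1 - u * (1 - exp(-1 / mu)))
  expect_lt(empirical_kld(y, mu), 0.02)
  expect_gt(empirical_kld(runif(1e5), mu), 0.5)
  expect_error(empirical_kld(numeric(0), mu), "no samples")
})

test_that("empirical divergence matches a hand-summed four-bin case", {
  mu <- 0.25
  # masses 1/2, 1/4, 1/8, 1/8 over four equal bins on (0, 1)
  y <- c(rep(0.1, 4), rep(0.35, 2), 0.6, 0.85)
  p <- c(4, 2, 1, 1) / 8
  edges <- c(0, 0.25, 0.5, 0.75, 1)
  q <- (exp(-edges[1:4] / mu) - exp(-edges[2:5] / mu)) / (1 - exp(-1 / mu))
  ref <- p[1] * log(p[1] / q[1]) + p[2] * log(p[2] / q[2]) +
    p[3] * log(p[3] / q[3]) + p[4] * log(p[4] / q[4])
  expect_equal(empirical_kld(y, mu, n_bins = 4), ref, tolerance = 1e-12)
})
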