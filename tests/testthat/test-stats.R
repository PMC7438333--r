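test_that("reflection subtracts from max + 1 and reverses order", {
  r <- reflect(c(3, 4, 5))
  expect_equal(r$x, c(3, 2, 1))
  expect_equal(r$constant, 6)
  expect_equal(reflect(c(2, 2, 2))$x, c(1, 1, 1))
  # reflecting twice is not the identity because the constant is data-driven
  twice <- reflect(reflect(c(2, 5, 9))$x)$x
  expect_false(isTRUE(all.equal(twice, c(2, 5, 9))))
  expect_true(all(r$x >= 1))
})

test_that("power transform is monotone and picks sensible exponents", {
  set.seed(41)
  # rank preservation for an arbitrary positive sample
  x <- rlnorm(100)
  tt <- tukey_transform(x)
  expect_equal(rank(tt$x), rank(x))
  # near-normal samples keep lambda near 1, lognormal pulls it toward 0
  hits_normal <- 0
  hits_lognormal <- 0
  for (s in 1:10) {
    xn <- abs(rnorm(500, 10, 3))
    ln <- tukey_transform(xn)$lambda
    if (ln >= 0.7 && ln <= 1.3) hits_normal <- hits_normal + 1
    xl <- rlnorm(500, 0, 0.8)
    ll <- tukey_transform(xl)$lambda
    if (ll >= -0.3 && ll <= 0.3) hits_lognormal <- hits_lognormal + 1
  }
  expect_gte(hits_normal, 9)
  expect_gte(hits_lognormal, 9)
  expect_error(tukey_transform(c(-1, 2)), "positive")
})

test_that("least squares matches the normal-equations solution exactly", {
  set.seed(42)
  n <- 8
  design <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 + 0.5 * design$x1 - 1.2 * design$x2 + rnorm(n, 0, 0.3)
  fit <- ols_fit(y, design)
  X <- cbind(1, design$x1, design$x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-10)
  # exact linear response: R^2 = 1, residuals 0
  y2 <- 1 + 3 * design$x1
  fit2 <- suppressWarnings(ols_fit(y2, design["x1"]))
  expect_equal(fit2$r_squared, 1)
  expect_equal(unname(fit2$residuals), rep(0, n), tolerance = 1e-10)
  # collinearity is an error, not a silent drop
  design$x3 <- design$x1 * 2
  expect_error(ols_fit(rnorm(8), design), "collinear")
})

test_that("standardized coefficients equal coef * sd(x) / sd(y)", {
  set.seed(43)
  n <- 200
  d <- data.frame(x = rnorm(n, 0, 7), z = rnorm(n))
  y <- 0.3 * d$x + d$z + rnorm(n)
  fit <- ols_fit(y, d)
  expect_equal(unname(fit$standardized["x"]),
               unname(fit$coefficients["x"]) * sd(d$x) / sd(y))
})

test_that("type-I error of the x coefficient is near nominal 5%", {
  set.seed(44)
  hits <- 0
  n_sim <- 1000
  for (k in seq_len(n_sim)) {
    x <- rnorm(40)
    y <- rnorm(40)
    fit <- ols_fit(y, data.frame(x = x))
    if (fit$p_values["x"] < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.03)
  expect_lt(hits / n_sim, 0.07)
})

test_that("delta R^2 isolates the predictor's unique contribution", {
  set.seed(45)
  n <- 400
  cov <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  y <- cov$c1 + rnorm(n)
  # orthogonal predictor adds essentially nothing
  expect_lt(delta_r2(y, cov, rnorm(n)), 0.02)
  # the response itself adds all remaining variance
  base <- ols_fit(y, cov)$r_squared
  expect_equal(suppressWarnings(delta_r2(y, cov, y)), 1 - base,
               tolerance = 1e-10)
  expect_gte(delta_r2(y, cov, rnorm(n)), 0)
})

test_that("planted unique variance is recovered by delta R^2", {
  set.seed(46)
  n <- 5000
  cov <- data.frame(c1 = rnorm(n))
  u <- rnorm(n)
  # y = c1 + sqrt(f) * u + e with var partitioned so u uniquely explains 5%
  y <- cov$c1 + sqrt(0.1) * u + rnorm(n, 0, sqrt(0.9))
  dr <- delta_r2(y, cov, u)
  expect_lt(abs(dr - 0.05), 0.01)
})

test_that("BH adjustment matches stats and flags the documented cases", {
  f <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(f$reject))
  single <- fdr_bh(0.031)
  expect_equal(single$p_adjusted, 0.031)
  none <- fdr_bh(rep(1, 6))
  expect_false(any(none$reject))
  # adjusted p nondecreasing in raw rank
  set.seed(47)
  p <- runif(30)
  adj <- fdr_bh(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("BH equals a brute-force step-up on random p-vectors", {
  set.seed(48)
  for (rep in 1:200) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)
    f <- fdr_bh(p, 0.05)
    b <- brute_bh(p, 0.05)
    expect_equal(f$p_adjusted, b$p_adjusted, tolerance = 1e-12)
    expect_identical(f$reject, b$reject)
  }
})

test_that("mediation decomposition c = c' + a*b holds exactly", {
  set.seed(49)
  for (rep in 1:10) {
    n <- 60
    d <- data.frame(x = rnorm(n), cv = rnorm(n))
    d$m <- 0.5 * d$x + rnorm(n)
    d$y <- 0.4 * d$m - 0.2 * d$x + 0.3 * d$cv + rnorm(n)
    fit <- mediate(d, "x", "m", "y", covariates = "cv", n_boot = 50, seed = rep)
    expect_equal(fit$c, fit$c_prime + fit$indirect, tolerance = 1e-10)
  }
})

test_that("mediation recovers planted structural paths at large n", {
  set.seed(50)
  n <- 2000
  d <- data.frame(x = rnorm(n), cv = rnorm(n))
  d$m <- -0.5 * d$x + rnorm(n)
  d$y <- -0.4 * d$m + 0.3 * d$x + 0.2 * d$cv + rnorm(n)
  fit <- mediate(d, "x", "m", "y", covariates = "cv", n_boot = 500, seed = 1)
  expect_lt(abs(fit$a - (-0.5)), 0.06)
  expect_lt(abs(fit$b - (-0.4)), 0.06)
  expect_lt(abs(fit$c_prime - 0.3), 0.06)
  expect_lt(abs(fit$indirect - 0.2), 0.05)
  expect_true(fit$significant)
  expect_true(fit$ci_low <= fit$indirect && fit$indirect <= fit$ci_high)
})

test_that("mediation object methods expose the fit coherently", {
  set.seed(51)
  n <- 80
  d <- data.frame(x = rnorm(n))
  d$m <- 0.6 * d$x + rnorm(n)
  d$y <- 0.5 * d$m + rnorm(n)
  fit <- mediate(d, "x", "m", "y", n_boot = 200, seed = 3)
  cf <- coef(fit)
  expect_named(cf, c("a", "b", "c", "c_prime", "indirect"))
  expect_equal(unname(cf["indirect"]), fit$a * fit$b)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci_low, fit$ci_high))
  expect_output(print(fit), "indirect")
  s <- summary(fit)
  expect_s3_class(s, "summary.mediation")
  expect_equal(s$paths$estimate[s$paths$path == "a"], fit$a)
  expect_output(print(s), "bootstrap CI")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # deterministic under a fixed seed
  fit2 <- mediate(d, "x", "m", "y", n_boot = 200, seed = 3)
  expect_identical(fit$ci_low, fit2$ci_low)
})

test_that("mediation input validation catches degenerate data", {
  d <- data.frame(x = rnorm(30), m = rnorm(30), y = rnorm(30))
  d$flat <- 1
  expect_error(mediate(d, "x", "flat", "y", n_boot = 10), "zero variance")
  expect_error(mediate(d, "x", "m", "missing_y", n_boot = 10), "missing column")
  expect_error(mediate(d[1:5, ], "x", "m", "y", n_boot = 10), "too few")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  set.seed(52)
  make <- function(n) {
    d <- data.frame(x = rnorm(n))
    d$m <- 0.5 * d$x + rnorm(n)
    d$y <- 0.5 * d$m + rnorm(n)
    d
  }
  big <- make(3200)
  fit_small <- mediate(big[1:200, ], "x", "m", "y", n_boot = 400, seed = 1)
  fit_big <- mediate(big, "x", "m", "y", n_boot = 400, seed = 1)
  w_small <- fit_small$ci_high - fit_small$ci_low
  w_big <- fit_big$ci_high - fit_big$ci_low
  ratio <- w_small / w_big   # expect about sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
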