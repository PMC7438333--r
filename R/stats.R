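#' Reflect a negatively skewed score
#'
#' Subtracts each value from the sample maximum plus one, so the smallest
#' reflected value is 1 and the order is reversed. Used before a power
#' transformation when a score is negatively skewed; note the reflection
#' constant depends on the data, so reflecting twice is not the identity.
#'
#' @param x numeric vector.
#' @return list with \code{x} (reflected values) and \code{constant}
#'   (max(x) + 1).
#' @export
reflect <- function(x) {
  if (length(x) == 0 || !is.numeric(x)) stop("x must be a nonempty numeric vector")
  k <- max(x) + 1
  list(x = k - x, constant = k)
}

#' Tukey ladder-of-powers transformation toward normality
#'
#' Searches a grid of exponents lambda in [-3, 3] (step 0.05) and picks the
#' one maximizing the Shapiro-Wilk statistic of the transformed sample.
#' lambda = 0 uses the log; negative lambdas use -x^lambda so the transform
#' stays monotone increasing for every lambda. Input must be strictly
#' positive (reflect or shift first).
#'
#' @param x positive numeric vector.
#' @param lambdas grid of candidate exponents.
#' @return list with \code{x} (transformed), \code{lambda}, \code{w_before}
#'   and \code{w_after} (Shapiro-Wilk statistics).
#' @export
tukey_transform <- function(x, lambdas = seq(-3, 3, by = 0.05)) {
  if (any(x <= 0)) {
    stop("Tukey power transform needs strictly positive values; reflect or shift first")
  }
  if (stats::sd(x) == 0) {
    return(list(x = x, lambda = 1, w_before = NA_real_, w_after = NA_real_))
  }
  sw <- function(v) {
    # Shapiro-Wilk is defined for 3..5000 observations; thin deterministically
    if (length(v) > 5000) v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
    if (stats::sd(v) == 0) return(-Inf)
    stats::shapiro.test(v)$statistic
  }
  apply_lambda <- function(l) {
    if (abs(l) < 1e-12) log(x) else if (l > 0) x^l else -(x^l)
  }
  ws <- vapply(lambdas, function(l) as.numeric(sw(apply_lambda(l))), numeric(1))
  best <- lambdas[which.max(ws)]
  list(x = apply_lambda(best), lambda = best,
       w_before = as.numeric(sw(x)), w_after = max(ws))
}

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Ordinary least squares fit with standardized coefficients
#'
#' Thin wrapper around \code{stats::lm} that errors (rather than silently
#' dropping) on rank deficiency and reports, alongside the raw coefficients,
#' the standardized coefficients coef * sd(x)/sd(y).
#'
#' @param y response vector.
#' @param design data frame of predictors (an intercept is added).
#' @return list with \code{coefficients}, \code{se}, \code{standardized},
#'   \code{p_values}, \code{r_squared}, \code{f_statistic} (value, df1, df2),
#'   \code{residuals}, \code{fitted}, and the underlying \code{lm} fit.
#' @export
ols_fit <- function(y, design) {
  design <- as.data.frame(design)
  if (nrow(design) != length(y)) stop("design rows must match length(y)")
  if (nrow(design) <= ncol(design) + 1) stop("need n > p + 1 observations")
  dat <- cbind(.y = y, design)
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  mm <- stats::model.matrix(fit)
  sds <- apply(mm, 2, stats::sd)
  std <- cf * sds / stats::sd(y)
  std["(Intercept)"] <- NA_real_
  fstat <- sm$fstatistic
  list(
    coefficients = cf,
    se = sm$coefficients[, "Std. Error"],
    standardized = std,
    p_values = sm$coefficients[, "Pr(>|t|)"],
    r_squared = sm$r.squared,
    f_statistic = if (is.null(fstat)) c(value = NA, numdf = NA, dendf = NA) else fstat,
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    fit = fit
  )
}

#' Increment in explained variance from adding one predictor
#'
#' @param y response vector.
#' @param covariates data frame of adjustment variables.
#' @param predictor numeric vector, the predictor of interest.
#' @return R-squared of the full model minus R-squared of the covariate-only
#'   model (floored at 0 against floating-point noise).
#' @export
delta_r2 <- function(y, covariates, predictor) {
  base <- ols_fit(y, covariates)
  full <- ols_fit(y, cbind(covariates, .predictor = predictor))
  max(0, full$r_squared - base$r_squared)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment of a vector of p values with rejection flags at level
#' \code{q}.
#'
#' @param p numeric vector of p values in [0, 1].
#' @param q target false discovery rate (default 0.05).
#' @return list with \code{p_adjusted} and logical \code{reject}.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Three-step mediation with percentile bootstrap confidence intervals
#'
#' Fits the classical mediation triangle by ordinary least squares on
#' complete cases: path a from \code{mediator ~ exposure + covariates},
#' paths b and c' from \code{outcome ~ exposure + mediator + covariates},
#' and the total effect c from \code{outcome ~ exposure + covariates}.
#' The indirect effect is a*b, with a percentile confidence interval from
#' case-resampled bootstrap re-estimates; it is declared significant when the
#' interval excludes zero. Because all three regressions share the covariate
#' set, the decomposition c = c' + a*b holds exactly.
#'
#' @param data data frame holding all variables.
#' @param exposure,mediator,outcome column names of x, m and y.
#' @param covariates character vector of adjustment column names.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param ci_level confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return an object of class \code{"mediation"}; see [summary.mediation()].
#' @export
mediate <- function(data, exposure, mediator, outcome,
                    covariates = character(), n_boot = 10000,
                    ci_level = 0.95, seed = NULL) {
  vars <- c(exposure, mediator, outcome, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < 10 + length(covariates)) stop("too few complete cases for mediation")
  x <- d[[exposure]]; m <- d[[mediator]]; y <- d[[outcome]]
  for (nm in c(exposure, mediator, outcome)) {
    if (stats::sd(d[[nm]]) == 0) stop("zero variance in '", nm, "'")
  }
  cov_df <- d[covariates]
  fa <- ols_fit(m, cbind(x = x, cov_df))
  fb <- ols_fit(y, cbind(x = x, m = m, cov_df))
  fc <- ols_fit(y, cbind(x = x, cov_df))
  a <- unname(fa$coefficients["x"]); a_se <- unname(fa$se["x"])
  b <- unname(fb$coefficients["m"]); b_se <- unname(fb$se["m"])
  c_prime <- unname(fb$coefficients["x"]); c_prime_se <- unname(fb$se["x"])
  c_total <- unname(fc$coefficients["x"]); c_se <- unname(fc$se["x"])
  indirect <- a * b

  # fast bootstrap on pre-built model matrices
  Xa <- cbind(1, x, as.matrix(cov_df))
  Xb <- cbind(1, x, m, as.matrix(cov_df))
  if (!is.null(seed)) set.seed(seed)
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      ca <- stats::.lm.fit(Xa[idx, , drop = FALSE], m[idx])
      cb <- stats::.lm.fit(Xb[idx, , drop = FALSE], y[idx])
      if (ca$rank < ncol(Xa) || cb$rank < ncol(Xb)) next
      # .lm.fit permutes coefficients by pivot
      a_r <- ca$coefficients[match(2L, ca$pivot)]
      b_r <- cb$coefficients[match(3L, cb$pivot)]
      boot[r] <- a_r * b_r
    }
  }
  boot_ok <- boot[!is.na(boot)]
  alpha2 <- (1 - ci_level) / 2
  ci <- if (length(boot_ok) > 0) {
    unname(stats::quantile(boot_ok, c(alpha2, 1 - alpha2), type = 7))
  } else {
    c(NA_real_, NA_real_)
  }
  sdx <- stats::sd(x); sdm <- stats::sd(m); sdy <- stats::sd(y)
  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    covariates = covariates, n = n,
    a = a, a_se = a_se, b = b, b_se = b_se,
    c = c_total, c_se = c_se, c_prime = c_prime, c_prime_se = c_prime_se,
    indirect = indirect,
    ci_low = ci[1], ci_high = ci[2],
    significant = !any(is.na(ci)) && (ci[1] > 0 || ci[2] < 0),
    standardized = c(a = a * sdx / sdm, b = b * sdm / sdy,
                     c = c_total * sdx / sdy, c_prime = c_prime * sdx / sdy,
                     indirect = indirect * sdx / sdy),
    n_boot = n_boot, n_boot_used = length(boot_ok),
    ci_level = ci_level, seed = seed,
    p_values = c(a = unname(fa$p_values["x"]), b = unname(fb$p_values["m"]),
                 c = unname(fc$p_values["x"]),
                 c_prime = unname(fb$p_values["x"])),
    boot = boot_ok,
    call = match.call()
  ), class = "mediation")
}

#' @export
print.mediation <- function(x, digits = 4, ...) {
  cat("Mediation: ", x$exposure, " -> ", x$mediator, " -> ", x$outcome,
      "  (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  a (exposure -> mediator) : %.*g (SE %.*g)\n",
              digits, x$a, digits, x$a_se))
  cat(sprintf("  b (mediator -> outcome)  : %.*g (SE %.*g)\n",
              digits, x$b, digits, x$b_se))
  cat(sprintf("  c  (total effect)        : %.*g (SE %.*g)\n",
              digits, x$c, digits, x$c_se))
  cat(sprintf("  c' (direct effect)       : %.*g (SE %.*g)\n",
              digits, x$c_prime, digits, x$c_prime_se))
  cat(sprintf("  indirect (a*b)           : %.*g, %g%% bootstrap CI [%.*g, %.*g]%s\n",
              digits, x$indirect, 100 * x$ci_level,
              digits, x$ci_low, digits, x$ci_high,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Summarize a fitted mediation model
#'
#' @param object a \code{"mediation"} object from [mediate()].
#' @param ... unused.
#' @return list with a path-estimate table (raw and standardized), the
#'   bootstrap interval and bookkeeping fields; printed as a compact report.
#' @export
summary.mediation <- function(object, ...) {
  paths <- data.frame(
    path = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(object$a, object$b, object$c, object$c_prime, object$indirect),
    se = c(object$a_se, object$b_se, object$c_se, object$c_prime_se, NA),
    standardized = unname(object$standardized[c("a", "b", "c", "c_prime", "indirect")]),
    p_value = c(object$p_values[c("a", "b", "c", "c_prime")], NA)
  )
  out <- list(paths = paths, ci = c(object$ci_low, object$ci_high),
              ci_level = object$ci_level, n_boot_used = object$n_boot_used,
              significant = object$significant, n = object$n,
              exposure = object$exposure, mediator = object$mediator,
              outcome = object$outcome, covariates = object$covariates)
  class(out) <- "summary.mediation"
  out
}

#' @export
print.summary.mediation <- function(x, ...) {
  cat("Mediation of", x$exposure, "on", x$outcome, "through", x$mediator, "\n")
  if (length(x$covariates)) {
    cat("Adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  cat("n =", x$n, "; bootstrap resamples used:", x$n_boot_used, "\n\n")
  print(x$paths, row.names = FALSE, digits = 4)
  cat(sprintf("\n%g%% percentile bootstrap CI for a*b: [%.4g, %.4g] (%s)\n",
              100 * x$ci_level, x$ci[1], x$ci[2],
              if (isTRUE(x$significant)) "excludes 0" else "contains 0"))
  invisible(x)
}

#' @export
coef.mediation <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, c_prime = object$c_prime,
    indirect = object$indirect)
}

#' @export
confint.mediation <- function(object, parm = "indirect", level = NULL, ...) {
  if (!is.null(level) && level != object$ci_level && length(object$boot) > 0) {
    alpha2 <- (1 - level) / 2
    ci <- unname(stats::quantile(object$boot, c(alpha2, 1 - alpha2)))
  } else {
    ci <- c(object$ci_low, object$ci_high)
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("indirect", c("lower", "upper")))
  out
}

#' Path diagram of a fitted mediation model
#'
#' Draws the exposure/mediator/outcome triangle with the estimated path
#' coefficients, the indirect effect and its bootstrap interval.
#'
#' @param x a \code{"mediation"} object.
#' @param ... passed to \code{plot.default} (unused).
#' @export
plot.mediation <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10), ylim = c(0, 10))
  boxes <- list(x = c(1.6, 5), m = c(5, 8.6), y = c(8.4, 5))
  lab <- c(x = x$exposure, m = x$mediator, y = x$outcome)
  for (nm in names(boxes)) {
    p <- boxes[[nm]]
    graphics::rect(p[1] - 1.5, p[2] - 0.7, p[1] + 1.5, p[2] + 0.7)
    graphics::text(p[1], p[2], lab[nm], cex = 0.8)
  }
  arrow <- function(from, to) {
    graphics::arrows(from[1], from[2], to[1], to[2], length = 0.1)
  }
  arrow(c(2.4, 5.8), c(4.0, 7.9))   # x -> m
  arrow(c(6.0, 7.9), c(7.6, 5.8))   # m -> y
  arrow(c(3.1, 5.0), c(6.9, 5.0))   # x -> y
  fmt <- function(v) formatC(v, digits = 3, format = "g")
  graphics::text(2.6, 7.2, paste0("a = ", fmt(x$a)), cex = 0.8)
  graphics::text(7.4, 7.2, paste0("b = ", fmt(x$b)), cex = 0.8)
  graphics::text(5, 4.4,
                 paste0("c' = ", fmt(x$c_prime), "   (c = ", fmt(x$c), ")"),
                 cex = 0.8)
  graphics::title(main = sprintf("indirect a*b = %s, %g%% CI [%s, %s]",
                                 fmt(x$indirect), 100 * x$ci_level,
                                 fmt(x$ci_low), fmt(x$ci_high)),
                  cex.main = 0.9)
  invisible(x)
}
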