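#' Run the full three-step association and mediation analysis
#'
#' Reproduces the analysis chain on a phenotype table: (i) total-effect
#' regressions of each competence score on each exposure; (ii) step-1
#' regressions of each network-efficiency mediator on each exposure;
#' (iii) step-2 regressions of each score on mediators that passed step 1,
#' adjusting for the exposure; (iv) step-3 bootstrap mediation for every
#' exposure-mediator-outcome triple that passed both screening steps.
#' Each exposure is analyzed under Model 1 (base covariates) and Model 2
#' (base covariates plus the other exposure). FDR correction is applied
#' within each step's family of tests, and step-3 models are fitted only for
#' FDR-significant step-1 and step-2 associations.
#'
#' Skewed variables can be normalized first: with \code{transform = "auto"}
#' a variable with sample skewness below -0.5 is reflected (max + 1 - x) and
#' power-transformed, one with skewness above 0.5 is power-transformed
#' directly (shifted to positive support if needed), and approximately
#' symmetric variables are left alone. Reflection reverses the direction of
#' every coefficient involving that variable; the transform table flags it.
#'
#' @param phenotypes data frame with one row per subject.
#' @param exposures character vector of exposure column names (default
#'   sedentary and MVPA minutes per day).
#' @param mediators character vector of mediator column names (the
#'   network-efficiency columns).
#' @param outcomes character vector of outcome column names (the competence
#'   scores).
#' @param covariates base adjustment set (Model 1).
#' @param alpha significance level applied to FDR-adjusted p values
#'   (default 0.05).
#' @param n_boot bootstrap resamples for each step-3 mediation (default
#'   10000).
#' @param seed integer seed controlling all bootstrap draws.
#' @param transform \code{"auto"} or \code{"none"}.
#' @return list with data frames \code{total_effects}, \code{step1},
#'   \code{step2}, \code{mediation_table}, a list \code{mediations} of fitted
#'   \code{"mediation"} objects, \code{transforms}, and the \code{config}
#'   used.
#' @export
run_analysis <- function(phenotypes,
                         exposures = c("sedentary_min_day", "mvpa_min_day"),
                         mediators,
                         outcomes,
                         covariates = c("age", "sex", "education", "bmi",
                                        "iq", "ffvo2peak", "wear_min_day"),
                         alpha = 0.05, n_boot = 10000, seed = NULL,
                         transform = c("auto", "none")) {
  transform <- match.arg(transform)
  needed <- c("subject_id", exposures, mediators, outcomes, covariates)
  missing_cols <- setdiff(needed, names(phenotypes))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- phenotypes
  transforms <- data.frame(variable = character(), reflected = logical(),
                           reflection_constant = numeric(), lambda = numeric(),
                           w_before = numeric(), w_after = numeric(),
                           stringsAsFactors = FALSE)
  if (transform == "auto") {
    for (v in c(mediators, outcomes)) {
      x <- dat[[v]]
      ok <- !is.na(x)
      sk <- sample_skewness(x[ok])
      if (abs(sk) <= 0.5) next
      refl <- sk < 0
      k <- NA_real_
      xx <- x[ok]
      if (refl) {
        r <- reflect(xx)
        xx <- r$x
        k <- r$constant
      }
      if (any(xx <= 0)) xx <- xx + (1 - min(xx))
      tt <- tukey_transform(xx)
      dat[[v]][ok] <- tt$x
      transforms <- rbind(transforms, data.frame(
        variable = v, reflected = refl, reflection_constant = k,
        lambda = tt$lambda, w_before = tt$w_before, w_after = tt$w_after,
        stringsAsFactors = FALSE))
    }
  }

  other_exposure <- function(e) setdiff(exposures, e)
  model_covs <- function(e, model) {
    if (model == 1) covariates else c(covariates, other_exposure(e))
  }
  assoc_row <- function(y_name, x_name, adjust, model) {
    use <- c(y_name, x_name, adjust)
    d <- dat[stats::complete.cases(dat[use]), use, drop = FALSE]
    y <- d[[y_name]]
    x <- d[[x_name]]
    adj <- d[adjust]
    fit <- ols_fit(y, cbind(stats::setNames(data.frame(x), x_name), adj))
    dr2 <- delta_r2(y, adj, x)
    data.frame(
      outcome = y_name, predictor = x_name, model = model,
      n = nrow(d),
      coef = unname(fit$coefficients[x_name]),
      se = unname(fit$se[x_name]),
      standardized = unname(fit$standardized[x_name]),
      delta_r2 = dr2,
      model_f = unname(fit$f_statistic[1]),
      model_df1 = unname(fit$f_statistic[2]),
      model_df2 = unname(fit$f_statistic[3]),
      p_raw = unname(fit$p_values[x_name]),
      stringsAsFactors = FALSE
    )
  }
  fdr_family <- function(df) {
    if (nrow(df) == 0) return(df)
    f <- fdr_bh(df$p_raw, alpha)
    df$p_fdr <- f$p_adjusted
    df$significant <- f$reject
    df
  }

  # total effects: score ~ exposure
  total_rows <- list()
  for (e in exposures) for (model in 1:2) for (oc in outcomes) {
    total_rows[[length(total_rows) + 1L]] <-
      assoc_row(oc, e, model_covs(e, model), model)
  }
  total_effects <- fdr_family(do.call(rbind, total_rows))

  # step 1: mediator ~ exposure
  s1_rows <- list()
  for (e in exposures) for (model in 1:2) for (md in mediators) {
    s1_rows[[length(s1_rows) + 1L]] <-
      assoc_row(md, e, model_covs(e, model), model)
  }
  step1 <- fdr_family(do.call(rbind, s1_rows))

  # step 2: score ~ mediator, adjusting for the exposure it qualified with
  s1_sig <- step1[step1$significant, , drop = FALSE]
  s2_rows <- list()
  for (r in seq_len(nrow(s1_sig))) {
    md <- s1_sig$outcome[r]      # mediator was the response in step 1
    e <- s1_sig$predictor[r]
    model <- s1_sig$model[r]
    for (oc in outcomes) {
      s2_rows[[length(s2_rows) + 1L]] <-
        cbind(assoc_row(oc, md, c(e, model_covs(e, model)), model),
              exposure = e, stringsAsFactors = FALSE)
    }
  }
  step2 <- fdr_family(if (length(s2_rows)) do.call(rbind, s2_rows) else
    data.frame())

  # step 3: mediation for triples passing both screens
  mediations <- list()
  med_rows <- list()
  if (nrow(step2) > 0) {
    s2_sig <- step2[step2$significant, , drop = FALSE]
    for (r in seq_len(nrow(s2_sig))) {
      md <- s2_sig$predictor[r]
      oc <- s2_sig$outcome[r]
      e <- s2_sig$exposure[r]
      model <- s2_sig$model[r]
      med_seed <- if (is.null(seed)) NULL else
        (seed + 104729L * length(mediations)) %% .Machine$integer.max
      fit <- mediate(dat, e, md, oc, model_covs(e, model),
                     n_boot = n_boot, ci_level = 0.95, seed = med_seed)
      key <- paste(e, md, oc, paste0("model", model), sep = "|")
      mediations[[key]] <- fit
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        exposure = e, mediator = md, outcome = oc, model = model,
        n = fit$n, a = fit$a, b = fit$b, c = fit$c, c_prime = fit$c_prime,
        indirect = fit$indirect, ci_low = fit$ci_low, ci_high = fit$ci_high,
        significant = fit$significant, n_boot = fit$n_boot,
        stringsAsFactors = FALSE
      )
    }
  }
  mediation_table <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame()

  list(
    total_effects = total_effects,
    step1 = step1,
    step2 = step2,
    mediation_table = mediation_table,
    mediations = mediations,
    transforms = transforms,
    config = list(exposures = exposures, mediators = mediators,
                  outcomes = outcomes, covariates = covariates,
                  alpha = alpha, n_boot = n_boot, seed = seed,
                  transform = transform)
  )
}

#' Write an analysis report to delimited text and JSON
#'
#' @param result output of [run_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_analysis_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("total_effects", "step1", "step2", "mediation_table",
               "transforms")) {
    df <- result[[nm]]
    if (is.null(df) || nrow(df) == 0) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summary_json <- list(
    config = result$config,
    mediations = lapply(result$mediations, function(f) {
      list(exposure = f$exposure, mediator = f$mediator, outcome = f$outcome,
           a = f$a, b = f$b, c = f$c, c_prime = f$c_prime,
           indirect = f$indirect, ci = c(f$ci_low, f$ci_high),
           ci_level = f$ci_level, n_boot = f$n_boot, n = f$n,
           significant = f$significant)
    })
  )
  jp <- file.path(dir, "analysis.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}
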