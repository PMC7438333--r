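#' Run the end-to-end pipeline on a synthetic or stored cohort
#'
#' Orchestrates the stages simulate -> accelerometry -> connectivity ->
#' efficiency -> competence scoring -> association/mediation analysis with a
#' single seed, writing every stage's outputs and a manifest into a run
#' directory. Stages adapt to the cohort contents: when no epoch series is
#' present the phenotype exposure columns are used directly, and when no ROI
#' series is present the graph stages are skipped (tabular cohorts carry
#' their latent mediator column instead).
#'
#' @param out_dir run directory (created; stage outputs in subfolders).
#' @param config [sim_config()] used to simulate the cohort; ignored when
#'   \code{input_dir} is given.
#' @param input_dir optional directory from [write_cohort()] to load instead
#'   of simulating.
#' @param networks network labels analyzed by the graph stage.
#' @param variant efficiency variant, see [local_efficiency_node()].
#' @param alpha FDR-adjusted significance level for the screening steps.
#' @param n_boot bootstrap resamples per mediation.
#' @param transform variable-normalization policy for the analysis stage
#'   (\code{"auto"} or \code{"none"}).
#' @return list with \code{dir}, \code{manifest}, \code{phenotypes} (the
#'   analysis-ready table) and \code{analysis} (the [run_analysis()] result).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         input_dir = NULL,
                         networks = c("frontoparietal", "dorsal_attention",
                                      "ventral_attention", "default_mode"),
                         variant = "product", alpha = 0.05, n_boot = 1000,
                         transform = "auto") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sednet")),
    seed = config$seed, stages = list(), files = list()
  )
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  record <- function(name, info) manifest$stages[[name]] <<- info

  cohort <- stage("simulate", function() {
    if (!is.null(input_dir)) {
      co <- read_cohort(input_dir)
      co$config <- config
      co
    } else {
      co <- simulate_cohort(config)
      write_cohort(co, file.path(out_dir, "cohort"))
      co
    }
  })
  record("simulate", list(n_subjects = nrow(cohort$phenotypes),
                          mode = config$mode))
  phen <- cohort$phenotypes

  if (!is.null(cohort$epoch_series)) {
    accel <- stage("accelerometry", function() {
      res <- process_accelerometry(cohort$epoch_series)
      d <- file.path(out_dir, "accelerometry")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(res$daily, file.path(d, "daily.csv"),
                       row.names = FALSE)
      utils::write.csv(res$participants, file.path(d, "participants.csv"),
                       row.names = FALSE)
      res
    })
    part <- accel$participants[accel$participants$included, , drop = FALSE]
    phen <- phen[phen$subject_id %in% part$subject_id, , drop = FALSE]
    idx <- match(phen$subject_id, part$subject_id)
    phen$sedentary_min_day <- part$sedentary_min_day[idx]
    phen$mvpa_min_day <- part$mvpa_min_day[idx]
    phen$wear_min_day <- part$wear_min_day[idx]
    record("accelerometry",
           list(n_days = nrow(accel$daily),
                n_included = sum(accel$participants$included)))
  }

  mediator_cols <- character()
  if (!is.null(cohort$roi_series)) {
    eff <- stage("connectivity_efficiency", function() {
      nets <- lapply(phen$subject_id, function(sid) {
        fc_weights(cohort$roi_series[[sid]], cohort$assignment,
                   networks = networks)$networks
      })
      names(nets) <- phen$subject_id
      tab <- efficiency_batch(nets, variant = variant)
      d <- file.path(out_dir, "efficiency")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(tab, file.path(d, "efficiency.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(variant = variant, alpha = 0.05,
             networks = networks, weight_map = "inverse"),
        file.path(d, "provenance.json"), auto_unbox = TRUE)
      tab
    })
    for (lb in networks) {
      gcol <- paste0("eglob_", lb)
      lcol <- paste0("eloc_", lb)
      sub <- eff[eff$network_label == lb, , drop = FALSE]
      idx <- match(phen$subject_id, sub$subject_id)
      phen[[gcol]] <- sub$e_glob[idx]
      phen[[lcol]] <- sub$e_loc[idx]
      mediator_cols <- c(mediator_cols, gcol, lcol)
    }
    record("connectivity_efficiency", list(n_records = nrow(eff)))
  } else if ("mediator" %in% names(phen)) {
    mediator_cols <- "mediator"
  }

  scores <- stage("admc_scoring", function() {
    sc <- admc_index(score_admc(cohort$admc_items))
    d <- file.path(out_dir, "admc")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(sc, file.path(d, "scores.csv"), row.names = FALSE)
    sc
  })
  idx <- match(phen$subject_id, scores$subject_id)
  outcome_cols <- c("framing", "sunk_cost", "risk_consistency",
                    "social_norms", "decision_rules", "confidence", "index")
  for (oc in outcome_cols) phen[[oc]] <- scores[[oc]][idx]
  record("admc_scoring", list(n_scored = nrow(scores)))

  exposures <- if (config$mode == "tabular") {
    "exposure_std"
  } else {
    c("sedentary_min_day", "mvpa_min_day")
  }
  analysis <- stage("analysis", function() {
    res <- run_analysis(
      phen, exposures = exposures, mediators = mediator_cols,
      outcomes = outcome_cols,
      covariates = c("age", "sex", "education", "bmi", "iq", "ffvo2peak",
                     "wear_min_day"),
      alpha = alpha, n_boot = n_boot, seed = config$seed,
      transform = transform)
    write_analysis_report(res, file.path(out_dir, "analysis"))
    res
  })
  record("analysis",
         list(n_step1 = nrow(analysis$step1),
              n_mediations = length(analysis$mediations)))

  write_phenotypes(phen, file.path(out_dir, "phenotypes_analyzed.csv"))
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  sums <- tools::md5sum(files)
  manifest$files <- lapply(seq_along(files), function(i) {
    list(path = sub(paste0("^", out_dir, "/?"), "", files[i]),
         md5 = unname(sums[i]))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(dir = out_dir, manifest = manifest, phenotypes = phen,
       analysis = analysis)
}
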