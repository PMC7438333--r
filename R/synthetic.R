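#' Configuration for a synthetic cohort
#'
#' Collects every knob of the synthetic-data generator with defaults chosen
#' to emulate a young-adult cohort: roughly 10 h/day sedentary, about 40 min
#' of daily moderate-to-vigorous activity, 300-volume resting-state series,
#' and seven intrinsic connectivity networks. The planted causal structure is
#' exposure (daily sedentary minutes) -> within-network coupling -> network
#' efficiency -> decision competence, with a direct exposure -> outcome path
#' alongside.
#'
#' In \code{"tabular"} mode the time-series and graph stages are bypassed:
#' the mediator is the planted latent variable itself and the structural
#' paths act on the standardized exposure, giving exact ground truth for the
#' statistics module. In \code{"full"} mode the mediator entering the outcome
#' model is the network efficiency computed by the package's own
#' connectivity and graph stages, so the whole chain is exercised.
#'
#' @param n_subjects number of participants.
#' @param n_days days of accelerometer wear (default 7).
#' @param n_nodes number of brain nodes, split evenly over the networks
#'   (default 70).
#' @param n_volumes resting-state volumes (default 300).
#' @param network_labels the seven network names.
#' @param rho_within_base baseline within-network correlation at coupling 1
#'   (default 0.40).
#' @param rho_between between-network correlation (default 0.05).
#' @param sensory_coupling fixed coupling of the visual, somatosensory and
#'   limbic networks (default 1.25); keeping these high stabilizes the
#'   per-subject rescale maximum of the weight matrix.
#' @param path_a exposure -> coupling slope. Tabular mode: per standardized
#'   exposure unit (default -0.5). Full mode: per sedentary minute on the
#'   coupling multiplier (default -0.001).
#' @param path_b mediator -> outcome slope (tabular default -0.4; full
#'   default 10 per efficiency unit, i.e. a moderate standardized effect
#'   given an efficiency spread of a few hundredths).
#' @param path_c_prime direct exposure -> outcome slope (tabular default 0.3
#'   per standardized unit; full default 0.003 per minute).
#' @param noise_sd_m,noise_sd_y structural noise standard deviations.
#' @param covariate_effects named numeric vector of outcome effects for the
#'   covariates (default all zero: no confounding).
#' @param exposure_mean,exposure_sd population mean and SD of daily sedentary
#'   minutes used for planting and standardization (defaults 603.6, 119.2).
#' @param mvpa_mean,mvpa_sd population mean and SD of daily MVPA minutes
#'   (defaults 41.3, 24.8).
#' @param mediator_network,mediator_metric which network x metric the planted
#'   outcome model uses in full mode (default dorsal attention, global).
#' @param mode \code{"tabular"} or \code{"full"}.
#' @param seed integer seed.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 100, n_days = 7, n_nodes = 70,
                       n_volumes = 300,
                       network_labels = c("visual", "somatosensory", "limbic",
                                          "default_mode", "dorsal_attention",
                                          "ventral_attention", "frontoparietal"),
                       rho_within_base = 0.40, rho_between = 0.05,
                       sensory_coupling = 1.25,
                       path_a = NULL, path_b = NULL, path_c_prime = NULL,
                       noise_sd_m = NULL, noise_sd_y = NULL,
                       covariate_effects = NULL,
                       exposure_mean = 603.6, exposure_sd = 119.2,
                       mvpa_mean = 41.3, mvpa_sd = 24.8,
                       mediator_network = "dorsal_attention",
                       mediator_metric = "global",
                       mode = c("tabular", "full"), seed = 1L) {
  mode <- match.arg(mode)
  if (n_volumes < 10) stop("n_volumes must be at least 10")
  if (length(network_labels) != 7) stop("exactly 7 network labels expected")
  defaults <- if (mode == "tabular") {
    list(path_a = -0.5, path_b = -0.4, path_c_prime = 0.3,
         noise_sd_m = 1, noise_sd_y = 1)
  } else {
    list(path_a = -0.0006, path_b = 10, path_c_prime = 0.003,
         noise_sd_m = 0.08, noise_sd_y = 0.8)
  }
  if (is.null(path_a)) path_a <- defaults$path_a
  if (is.null(path_b)) path_b <- defaults$path_b
  if (is.null(path_c_prime)) path_c_prime <- defaults$path_c_prime
  if (is.null(noise_sd_m)) noise_sd_m <- defaults$noise_sd_m
  if (is.null(noise_sd_y)) noise_sd_y <- defaults$noise_sd_y
  if (noise_sd_m <= 0 || noise_sd_y <= 0) stop("noise SDs must be positive")
  if (is.null(covariate_effects)) {
    covariate_effects <- c(age = 0, sex = 0, education = 0, bmi = 0,
                           iq = 0, ffvo2peak = 0)
  }
  structure(list(
    n_subjects = n_subjects, n_days = n_days, n_nodes = n_nodes,
    n_volumes = n_volumes, network_labels = network_labels,
    rho_within_base = rho_within_base, rho_between = rho_between,
    sensory_coupling = sensory_coupling,
    path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
    noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
    covariate_effects = covariate_effects,
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    mvpa_mean = mvpa_mean, mvpa_sd = mvpa_sd,
    mediator_network = mediator_network, mediator_metric = mediator_metric,
    mode = mode, seed = as.integer(seed)
  ), class = "sim_config")
}

# per-band lognormal count distributions; band membership is guaranteed by
# clamping, and wear-time sedentary counts are floored at 1 so that zero runs
# occur only where non-wear is planted
default_count_profile <- function() {
  list(sedentary = c(meanlog = log(30), sdlog = 0.9),
       light = c(meanlog = log(400), sdlog = 0.7),
       mvpa = c(meanlog = log(3200), sdlog = 0.45))
}

draw_band_counts <- function(n, band, profile) {
  if (n == 0) return(numeric(0))
  p <- profile[[band]]
  x <- round(stats::rlnorm(n, p["meanlog"], p["sdlog"]))
  switch(band,
    sedentary = pmin(pmax(x, 1), 99),
    light = pmin(pmax(x, 100), 2019),
    mvpa = pmin(pmax(x, 2020), 15000)
  )
}

#' Simulate one participant's minute-epoch accelerometer counts
#'
#' Generates a full 1440-epoch day for each of \code{n_days} days. Epochs
#' outside the daily wear window and inside planted non-wear blocks are zero;
#' wear epochs are assigned to the sedentary, light and MVPA count bands to
#' hit the scheduled daily minutes exactly, with counts drawn from per-band
#' lognormal distributions clamped to the band.
#'
#' @param subject_id identifier for the series.
#' @param wear_schedule list with \code{wear_start_min}, \code{wear_end_min}
#'   (minutes from midnight, defaults 390 and 1350), \code{sedentary_min} and
#'   \code{mvpa_min} (scalar or per-day vectors of planted wear minutes), and
#'   optionally \code{nonwear_blocks}, a data frame with columns \code{day},
#'   \code{start_min}, \code{length_min} (blocks of at least 60 min inside
#'   the wear window).
#' @param n_days number of days (default 7).
#' @param profile per-band count distributions, see source for the default.
#' @param seed optional seed.
#' @param origin POSIXct midnight of day 1.
#' @return list with \code{series} (an [epoch_series()] data frame) and
#'   \code{truth} (planted per-day band minutes and non-wear blocks).
#' @export
simulate_accelerometer_counts <- function(subject_id, wear_schedule,
                                          n_days = 7,
                                          profile = default_count_profile(),
                                          seed = NULL,
                                          origin = as.POSIXct("2020-01-06 00:00:00",
                                                              tz = "UTC")) {
  if (!is.null(seed)) set.seed(seed)
  ws <- wear_schedule
  start <- rep_len(if (is.null(ws$wear_start_min)) 390L else
    as.integer(ws$wear_start_min), n_days)
  end <- rep_len(if (is.null(ws$wear_end_min)) 1350L else
    as.integer(ws$wear_end_min), n_days)
  if (any(end - start < 60)) stop("wear window shorter than 60 min")
  sed <- rep_len(as.integer(round(ws$sedentary_min)), n_days)
  mvpa <- rep_len(as.integer(round(ws$mvpa_min)), n_days)
  blocks <- ws$nonwear_blocks
  if (is.null(blocks)) {
    blocks <- data.frame(day = integer(), start_min = integer(),
                         length_min = integer())
  }
  if (nrow(blocks) > 0) {
    if (any(blocks$length_min < 60)) {
      stop("planted non-wear blocks must be at least 60 min")
    }
    if (any(blocks$start_min < start[blocks$day] |
            blocks$start_min + blocks$length_min > end[blocks$day])) {
      stop("schedule conflict: non-wear block outside the wear window")
    }
    for (d in unique(blocks$day)) {
      b <- blocks[blocks$day == d, , drop = FALSE]
      b <- b[order(b$start_min), , drop = FALSE]
      if (nrow(b) > 1 &&
          any(b$start_min[-1] < (b$start_min + b$length_min)[-nrow(b)])) {
        stop("schedule conflict: overlapping non-wear blocks on day ", d)
      }
    }
  }
  counts <- integer(n_days * 1440L)
  truth_daily <- data.frame(day = seq_len(n_days), wear_min = 0L,
                            sedentary_min = 0L, light_min = 0L, mvpa_min = 0L)
  for (d in seq_len(n_days)) {
    day_off <- (d - 1L) * 1440L
    wear_idx <- (start[d] + 1L):end[d]   # minute m occupies epoch m+1
    b <- blocks[blocks$day == d, , drop = FALSE]
    for (r in seq_len(nrow(b))) {
      drop_idx <- (b$start_min[r] + 1L):(b$start_min[r] + b$length_min[r])
      wear_idx <- setdiff(wear_idx, drop_idx)
    }
    nw <- length(wear_idx)
    if (sed[d] + mvpa[d] > nw) {
      stop("day ", d, ": planted sedentary + MVPA minutes exceed wear time")
    }
    light <- nw - sed[d] - mvpa[d]
    lab <- sample(rep(c("sedentary", "mvpa", "light"),
                      c(sed[d], mvpa[d], light)))
    day_counts <- integer(nw)
    for (band in c("sedentary", "light", "mvpa")) {
      sel <- lab == band
      day_counts[sel] <- draw_band_counts(sum(sel), band, profile)
    }
    counts[day_off + wear_idx] <- day_counts
    truth_daily[d, c("wear_min", "sedentary_min", "light_min", "mvpa_min")] <-
      c(nw, sed[d], light, mvpa[d])
  }
  ts <- origin + 60 * (seq_len(n_days * 1440L) - 1L)
  series <- epoch_series(subject_id, ts, counts,
                         day_index = rep(seq_len(n_days), each = 1440L))
  list(series = series,
       truth = list(daily = truth_daily, nonwear_blocks = blocks,
                    wear_window = data.frame(day = seq_len(n_days),
                                             start = start, end = end)))
}

# block covariance over the node-network assignment; within-network
# correlation is rho_within_base * coupling clipped to [0, 0.95]
build_block_covariance <- function(assignment, rho_within_base, rho_between,
                                   coupling) {
  labels <- unique(assignment$network_label)
  p <- nrow(assignment)
  sigma <- matrix(rho_between, p, p)
  rho_used <- numeric(length(labels))
  names(rho_used) <- labels
  for (lb in labels) {
    idx <- which(assignment$network_label == lb)
    cp <- if (lb %in% names(coupling)) coupling[[lb]] else 1
    rho <- min(max(rho_within_base * cp, 0), 0.95)
    rho_used[lb] <- rho
    sigma[idx, idx] <- rho
  }
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    worst <- names(which.min(rho_used))
    stop("block covariance is not positive definite even after clipping; ",
         "check rho_between (", rho_between, ") against the within-network ",
         "correlations (weakest block: ", worst, " at ", rho_used[worst], ")")
  }
  list(sigma = sigma, chol = ch, rho_used = rho_used)
}

#' Simulate a block-correlated regional BOLD time-series matrix
#'
#' Draws \code{n_volumes} zero-mean multivariate-normal samples whose
#' covariance has within-network correlation
#' \code{rho_within_base * coupling} (clipped to [0, 0.95]) and
#' \code{rho_between} elsewhere. Mean within-network sample correlation is
#' therefore increasing in the coupling, which is how the planted
#' exposure effect reaches the graph stage.
#'
#' @param assignment data frame with \code{node_id} and
#'   \code{network_label}.
#' @param n_volumes number of time points (default 300).
#' @param subject_coupling named list/vector of per-network coupling scales
#'   (networks absent from the list default to 1).
#' @param rho_within_base,rho_between block correlation parameters.
#' @param seed optional seed.
#' @return nodes x volumes matrix with node IDs as row names.
#' @export
simulate_roi_timeseries <- function(assignment, n_volumes = 300,
                                    subject_coupling = list(),
                                    rho_within_base = 0.40,
                                    rho_between = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_volumes < 10) stop("n_volumes must be at least 10")
  bc <- build_block_covariance(assignment, rho_within_base, rho_between,
                               subject_coupling)
  p <- nrow(assignment)
  z <- matrix(stats::rnorm(n_volumes * p), n_volumes, p)
  x <- t(z %*% bc$chol)
  rownames(x) <- as.character(assignment$node_id)
  x
}

#' Generate the outcome variable from the structural model
#'
#' Y = beta0 + b * M + c' * X + sum(gamma * covariates) + eps with
#' eps ~ N(0, noise_sd_y^2).
#'
#' @param phenotypes data frame holding the exposure column and any covariate
#'   columns named in \code{covariate_effects}.
#' @param mediator numeric mediator values aligned with \code{phenotypes};
#'   any missing value is an error listing the affected subjects.
#' @param exposure name of the exposure column.
#' @param path_b,path_c_prime structural slopes.
#' @param covariate_effects named vector of covariate slopes.
#' @param noise_sd_y residual SD.
#' @param beta0 intercept (default 0).
#' @param seed optional seed.
#' @return numeric outcome vector.
#' @export
simulate_behavior <- function(phenotypes, mediator, exposure,
                              path_b, path_c_prime,
                              covariate_effects = numeric(),
                              noise_sd_y = 1, beta0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(mediator))) {
    stop("missing mediator for subject(s): ",
         paste(phenotypes$subject_id[is.na(mediator)], collapse = ", "))
  }
  y <- beta0 + path_b * mediator + path_c_prime * phenotypes[[exposure]]
  for (nm in names(covariate_effects)) {
    if (covariate_effects[[nm]] != 0) {
      y <- y + covariate_effects[[nm]] * phenotypes[[nm]]
    }
  }
  y + stats::rnorm(nrow(phenotypes), 0, noise_sd_y)
}

#' Default item-battery design for the competence tests
#'
#' @return list of item counts, base rates and discrimination parameters used
#'   by [simulate_admc_responses()].
#' @export
admc_test_design <- function() {
  list(
    framing_items = 7,
    sunk_items = 10,
    risk_items = 12,
    norm_behaviors = 8,
    norm_base_prob = c(0.10, 0.18, 0.26, 0.34, 0.42, 0.55, 0.63, 0.72),
    rules_items = 10,
    rules_choices = 4,
    knowledge_items = 20
  )
}

#' Simulate item-level battery responses for one subject
#'
#' Response models are chosen so that each of the six computed test scores is
#' increasing in the latent ability in expectation, with typical-score levels
#' near the cohort descriptives the generator emulates.
#'
#' @param latent_ability scalar latent ability on a standard-normal scale.
#' @param test_design list from [admc_test_design()].
#' @param seed optional seed.
#' @return list with components \code{framing}, \code{sunk_cost},
#'   \code{risk}, \code{norms}, \code{rules}, \code{knowledge} in the format
#'   accepted by [score_admc()].
#' @export
simulate_admc_responses <- function(latent_ability,
                                    test_design = admc_test_design(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- latent_ability
  td <- test_design
  # framing: discrepancy between frames shrinks with ability
  p_gap <- stats::plogis(-(1.65 + 0.9 * th))
  gap <- stats::rbinom(td$framing_items, 5, p_gap)
  gain <- vapply(gap, function(d) sample.int(6 - d, 1), integer(1))
  framing <- data.frame(gain = gain, loss = gain + gap)
  # sunk cost: keyed rating drifts up with ability
  sunk <- pmin(pmax(round(3.86 + 0.55 * th +
                            stats::rnorm(td$sunk_items, 0, 0.9)), 1), 6)
  # risk consistency: each pair coherent with ability-dependent probability
  preds <- rep(c("subset", "complement", "union"),
               length.out = td$risk_items)
  coherent <- stats::runif(td$risk_items) < stats::plogis(1.2 + 0.9 * th)
  risk <- do.call(rbind, lapply(seq_len(td$risk_items), function(i) {
    pr <- preds[i]
    if (pr == "complement") {
      p1 <- stats::runif(1, 0.05, 0.95)
      p2 <- if (coherent[i]) 1 - p1 else {
        min(max(1 - p1 + sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.3), 0), 1)
      }
    } else {
      u <- sort(stats::runif(2))
      if (coherent[i]) { p1 <- u[1]; p2 <- u[2] } else { p1 <- u[2]; p2 <- u[1] }
      if (p1 == p2) p2 <- min(1, p2 + 0.01)
    }
    data.frame(p1 = p1, p2 = p2, predicate = pr, stringsAsFactors = FALSE)
  }))
  # social norms: own endorsements follow base rates; estimates track the
  # base rates with noise shrinking in ability
  own <- stats::runif(td$norm_behaviors) < td$norm_base_prob
  est_sd <- min(max(35 * exp(-0.6 * th), 5), 80)
  est <- pmin(pmax(100 * td$norm_base_prob +
                     stats::rnorm(td$norm_behaviors, 0, est_sd), 0), 100)
  norms <- data.frame(behavior_id = seq_len(td$norm_behaviors),
                      own_ok = own, est_percent = est)
  # decision rules
  key <- sample.int(td$rules_choices, td$rules_items, replace = TRUE)
  ok <- stats::runif(td$rules_items) < stats::plogis(1.7 + 0.9 * th)
  resp <- ifelse(ok, key,
                 1 + (key + sample.int(td$rules_choices - 1, td$rules_items,
                                       replace = TRUE) - 1) %% td$rules_choices)
  rules <- data.frame(response = resp, key = key)
  # knowledge with confidence: overconfidence gap shrinks with ability
  p_corr <- stats::plogis(1.4 + 0.8 * th)
  correct <- stats::runif(td$knowledge_items) < p_corr
  over <- 0.15 * (1 - stats::plogis(1.2 * th))
  conf <- pmin(pmax(p_corr + over +
                      stats::rnorm(td$knowledge_items, 0, 0.05), 0.5), 1)
  knowledge <- data.frame(correct = correct, confidence = conf)
  list(framing = framing, sunk_cost = sunk, risk = risk, norms = norms,
       rules = rules, knowledge = knowledge)
}

simulate_covariates <- function(n) {
  data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 24.2, 5.3), 1), 18), 44),
    sex = as.integer(stats::runif(n) < 0.52),
    education = as.integer(stats::runif(n) < 0.49),
    bmi = pmin(pmax(round(stats::rnorm(n, 24.2, 3.9), 1), 17), 35),
    iq = round(stats::rnorm(n, 112.2, 8.8), 1),
    ffvo2peak = round(stats::rnorm(n, 57.1, 7.3), 1)
  )
}

#' Simulate a full synthetic cohort with planted mediation structure
#'
#' See [sim_config()] for the generative model and the difference between
#' tabular and full mode. The returned truth record carries every planted
#' parameter and per-subject latent value needed to check recovery.
#'
#' @param config a [sim_config()] object.
#' @return object of class \code{"sednet_cohort"}: list with
#'   \code{phenotypes}, \code{epoch_series} (full mode), \code{roi_series}
#'   (full mode), \code{assignment}, \code{admc_items}, \code{truth} and
#'   \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  cov <- simulate_covariates(n)
  sed <- round(pmin(pmax(stats::rnorm(n, config$exposure_mean,
                                      config$exposure_sd), 200), 780))
  mvpa <- round(pmin(pmax(stats::rnorm(n, config$mvpa_mean, config$mvpa_sd),
                          2), 150))
  phen <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), cov)
  phen$sedentary_min_day <- sed
  phen$mvpa_min_day <- mvpa
  zx <- (sed - config$exposure_mean) / config$exposure_sd
  truth <- list(
    seed = config$seed, mode = config$mode,
    path_a = config$path_a, path_b = config$path_b,
    path_c_prime = config$path_c_prime,
    covariate_effects = as.list(config$covariate_effects),
    subjects = stats::setNames(vector("list", n), ids)
  )

  epochs <- NULL
  roi <- NULL
  assignment <- data.frame(
    node_id = sprintf("N%03d", seq_len(config$n_nodes)),
    network_label = rep_len(rep(config$network_labels,
                                length.out = config$n_nodes), config$n_nodes),
    stringsAsFactors = FALSE
  )

  if (config$mode == "tabular") {
    mediator <- config$path_a * zx + stats::rnorm(n, 0, config$noise_sd_m)
    phen$exposure_std <- zx
    phen$mediator <- mediator
    phen$wear_min_day <- round(stats::rnorm(n, 865.9, 119.4))
    phen_x <- phen
    phen_x$exposure_std <- zx
    outcome <- simulate_behavior(
      phen_x, mediator, "exposure_std",
      config$path_b, config$path_c_prime,
      config$covariate_effects, config$noise_sd_y)
    phen$outcome <- outcome
    ability <- as.numeric(scale(outcome))
    for (i in seq_len(n)) {
      truth$subjects[[ids[i]]] <- list(
        sedentary_min_day = sed[i], mvpa_min_day = mvpa[i],
        exposure_std = zx[i], mediator = mediator[i], outcome = outcome[i])
    }
  } else {
    # accelerometer series with planted daily minutes and one 90-min
    # planted non-wear block per day (wear window 06:30-22:30)
    epoch_list <- vector("list", n)
    for (i in seq_len(n)) {
      # clamp so boundary zero runs are always >= 60 min and classified
      # non-wear, keeping planted daily minutes exactly recoverable
      w_start <- pmin(pmax(round(390 + stats::rnorm(config$n_days, 0, 25)),
                           300), 480)
      w_end <- pmin(pmax(round(1350 + stats::rnorm(config$n_days, 0, 25)),
                         1260), 1380)
      day_wear <- w_end - w_start - 90L
      day_mvpa <- pmin(pmax(round(mvpa[i] + stats::rnorm(config$n_days, 0, 6)),
                            0), 160)
      # keep at least 30 light minutes inside the day's wear window
      day_sed <- pmin(pmax(round(sed[i] + stats::rnorm(config$n_days, 0, 15)),
                           120), day_wear - day_mvpa - 30)
      blocks <- data.frame(day = seq_len(config$n_days),
                           start_min = 780L, length_min = 90L)
      sim <- simulate_accelerometer_counts(
        ids[i],
        list(wear_start_min = w_start, wear_end_min = w_end,
             sedentary_min = day_sed, mvpa_min = day_mvpa,
             nonwear_blocks = blocks),
        n_days = config$n_days)
      epoch_list[[i]] <- sim$series
      truth$subjects[[ids[i]]] <- list(
        sedentary_min_day = mean(sim$truth$daily$sedentary_min),
        mvpa_min_day = mean(sim$truth$daily$mvpa_min),
        wear_min_day = mean(sim$truth$daily$wear_min),
        daily = sim$truth$daily,
        nonwear_blocks = sim$truth$nonwear_blocks)
      # the phenotype exposure is the planted per-day mean
      phen$sedentary_min_day[i] <- mean(sim$truth$daily$sedentary_min)
      phen$mvpa_min_day[i] <- mean(sim$truth$daily$mvpa_min)
      phen$wear_min_day[i] <- mean(sim$truth$daily$wear_min)
    }
    epochs <- do.call(rbind, epoch_list)

    # exposure -> coupling -> BOLD block covariance
    cognitive <- c("default_mode", "dorsal_attention", "ventral_attention",
                   "frontoparietal")
    lambda <- 1 + config$path_a * (phen$sedentary_min_day -
                                     config$exposure_mean) +
      stats::rnorm(n, 0, config$noise_sd_m)
    lambda <- pmin(pmax(lambda, 0), 2)
    roi <- vector("list", n)
    names(roi) <- ids
    for (i in seq_len(n)) {
      coupling <- as.list(stats::setNames(
        rep(config$sensory_coupling, 3),
        c("visual", "somatosensory", "limbic")))
      for (lb in cognitive) coupling[[lb]] <- lambda[i]
      roi[[i]] <- simulate_roi_timeseries(
        assignment, config$n_volumes, coupling,
        config$rho_within_base, config$rho_between)
      truth$subjects[[ids[i]]]$lambda <- lambda[i]
    }

    # pipeline-computed mediator feeds the outcome model
    mediator <- vapply(ids, function(sid) {
      fw <- fc_weights(roi[[sid]], assignment,
                       networks = config$mediator_network)
      w <- fw$networks[[config$mediator_network]]
      if (config$mediator_metric == "global") global_efficiency(w)
      else local_efficiency(w)
    }, numeric(1))
    for (i in seq_len(n)) truth$subjects[[ids[i]]]$mediator <- mediator[[i]]
    ability <- simulate_behavior(phen, unname(mediator), "sedentary_min_day",
                                 config$path_b, config$path_c_prime,
                                 config$covariate_effects, config$noise_sd_y)
    ability <- ability - mean(ability)
    for (i in seq_len(n)) truth$subjects[[ids[i]]]$ability <- ability[i]
  }

  items <- lapply(seq_len(n), function(i) simulate_admc_responses(ability[i]))
  names(items) <- ids

  structure(list(
    phenotypes = phen, epoch_series = epochs, roi_series = roi,
    assignment = assignment, admc_items = items, truth = truth,
    config = config
  ), class = "sednet_cohort")
}

#' @export
print.sednet_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$phenotypes), "subjects,",
      x$config$mode, "mode, seed", x$config$seed, "\n")
  cat("  planted paths: a =", x$config$path_a, " b =", x$config$path_b,
      " c' =", x$config$path_c_prime, "\n")
  if (!is.null(x$epoch_series)) {
    cat("  epoch series:", nrow(x$epoch_series), "epochs\n")
  }
  if (!is.null(x$roi_series)) {
    cat("  ROI series:", length(x$roi_series), "subjects x",
        x$config$n_nodes, "nodes x", x$config$n_volumes, "volumes\n")
  }
  invisible(x)
}
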