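test_that("planted accelerometer schedules are honored epoch by epoch", {
  sched <- list(wear_start_min = 420, wear_end_min = 1320,
                sedentary_min = 600, mvpa_min = 40,
                nonwear_blocks = data.frame(day = 2, start_min = 800,
                                            length_min = 90))
  sim <- simulate_accelerometer_counts("S1", sched, n_days = 3, seed = 61)
  # planted 90-min block on day 2 is all zeros
  day2 <- sim$series$counts[sim$series$day_index == 2]
  expect_true(all(day2[801:890] == 0))
  # truth bookkeeping: 40 MVPA min/day on every day
  expect_equal(sim$truth$daily$mvpa_min, rep(40, 3))
  expect_equal(sim$truth$daily$sedentary_min, rep(600, 3))
  expect_equal(sim$truth$daily$wear_min, c(900, 810, 900))
  # wear-band counts actually fall inside the cut-point bands
  lab <- classify_epochs(sim$series, detect_nonwear(sim$series))
  d <- summarize_days(sim$series, lab)
  expect_equal(d$sedentary_min, sim$truth$daily$sedentary_min)
  expect_equal(d$mvpa_min, sim$truth$daily$mvpa_min)
  expect_equal(d$wear_min, sim$truth$daily$wear_min)
  # seeded determinism
  sim2 <- simulate_accelerometer_counts("S1", sched, n_days = 3, seed = 61)
  expect_identical(sim$series, sim2$series)
})

test_that("conflicting or invalid wear schedules are rejected", {
  base <- list(sedentary_min = 500, mvpa_min = 30)
  bad_overlap <- c(base, list(nonwear_blocks = data.frame(
    day = c(1, 1), start_min = c(600, 650), length_min = c(90, 90))))
  expect_error(simulate_accelerometer_counts("S1", bad_overlap, 2),
               "schedule conflict")
  bad_outside <- c(base, list(nonwear_blocks = data.frame(
    day = 1, start_min = 100, length_min = 90)))
  expect_error(simulate_accelerometer_counts("S1", bad_outside, 2),
               "schedule conflict")
  short_block <- c(base, list(nonwear_blocks = data.frame(
    day = 1, start_min = 600, length_min = 30)))
  expect_error(simulate_accelerometer_counts("S1", short_block, 2),
               "at least 60")
  too_full <- list(sedentary_min = 900, mvpa_min = 100)
  expect_error(simulate_accelerometer_counts("S1", too_full, 1),
               "exceed wear time")
})

test_that("ROI simulation has the requested shape and block structure", {
  assign7 <- data.frame(
    node_id = sprintf("N%02d", 1:28),
    network_label = rep(c("visual", "somatosensory", "limbic", "default_mode",
                          "dorsal_attention", "ventral_attention",
                          "frontoparietal"), each = 4))
  x <- simulate_roi_timeseries(assign7, n_volumes = 300, seed = 62)
  expect_equal(dim(x), c(28, 300))
  # independent signals: mean off-diagonal correlation near zero
  x0 <- simulate_roi_timeseries(assign7, n_volumes = 300,
                                subject_coupling = as.list(
                                  setNames(rep(0, 7),
                                           unique(assign7$network_label))),
                                rho_within_base = 0.4, rho_between = 0,
                                seed = 63)
  r0 <- pearson_matrix(x0)
  expect_lt(abs(mean(r0[upper.tri(r0)])), 3 / sqrt(300))
  expect_error(simulate_roi_timeseries(assign7, n_volumes = 5), "at least 10")
  # impossible covariance names the weakest block
  expect_error(
    simulate_roi_timeseries(assign7, 50, rho_within_base = 0.0,
                            rho_between = 0.9),
    "not positive definite")
})

test_that("within-network correlation rises monotonically with coupling", {
  assign7 <- data.frame(
    node_id = sprintf("N%02d", 1:21),
    network_label = rep(c("visual", "somatosensory", "limbic", "default_mode",
                          "dorsal_attention", "ventral_attention",
                          "frontoparietal"), each = 3))
  dan <- assign7$network_label == "dorsal_attention"
  couplings <- c(0.2, 0.9, 1.5)
  set.seed(64)
  mean_r <- sapply(couplings, function(cp) {
    mean(replicate(20, {
      x <- simulate_roi_timeseries(
        assign7, 120, subject_coupling = list(dorsal_attention = cp),
        rho_within_base = 0.5, rho_between = 0.05)
      r <- pearson_matrix(x[dan, ])
      mean(r[upper.tri(r)])
    }))
  })
  expect_true(all(diff(mean_r) > 0))
})

test_that("outcome model reproduces its degenerate and recoverable limits", {
  set.seed(65)
  phen <- data.frame(subject_id = sprintf("S%d", 1:2000),
                     x = rnorm(2000), age = rnorm(2000))
  m <- rnorm(2000)
  # degenerate: all paths zero, vanishing noise
  y0 <- simulate_behavior(phen, m, "x", 0, 0, c(age = 0), 1e-12, beta0 = 2.5)
  expect_equal(y0, rep(2.5, 2000), tolerance = 1e-9)
  # OLS recovers the planted slopes at large n
  y <- simulate_behavior(phen, m, "x", path_b = -0.4, path_c_prime = 0.3,
                         c(age = 0.1), noise_sd_y = 1, seed = 66)
  fit <- ols_fit(y, data.frame(m = m, x = phen$x, age = phen$age))
  expect_lt(abs(unname(fit$coefficients["m"]) - (-0.4)), 0.05)
  expect_lt(abs(unname(fit$coefficients["x"]) - 0.3), 0.05)
  # missing mediator names the subjects
  m_bad <- m; m_bad[c(3, 17)] <- NA
  expect_error(simulate_behavior(phen, m_bad, "x", 1, 1, numeric(), 1),
               "S3, S17")
  # seeded determinism
  y2 <- simulate_behavior(phen, m, "x", -0.4, 0.3, c(age = 0.1), 1, seed = 66)
  expect_identical(y, y2)
})

test_that("battery responses score higher with higher latent ability", {
  set.seed(67)
  n <- 500
  ability <- rnorm(n)
  items <- lapply(ability, simulate_admc_responses)
  names(items) <- sprintf("S%03d", seq_len(n))
  sc <- score_admc(items)
  for (tn in c("framing", "sunk_cost", "risk_consistency", "social_norms",
               "decision_rules", "confidence")) {
    rho <- cor(ability, sc[[tn]], method = "spearman", use = "complete.obs")
    expect_gt(rho, 0.3)
  }
  # extreme ability gives identical frame ratings, hence the maximum score
  top <- simulate_admc_responses(50, seed = 68)
  expect_equal(score_framing(top$framing), 5)
  # fixed seed reproducibility
  a <- simulate_admc_responses(0.3, seed = 69)
  b <- simulate_admc_responses(0.3, seed = 69)
  expect_identical(a, b)
})

test_that("cohort generation is deterministic and truth-complete", {
  cfg <- sim_config(n_subjects = 12, mode = "tabular", seed = 70)
  co <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$phenotypes, co2$phenotypes)
  expect_identical(co$admc_items, co2$admc_items)
  expect_identical(co$truth, co2$truth)
  # truth carries the planted paths and per-subject latents
  expect_equal(co$truth$path_a, -0.5)
  expect_equal(co$truth$path_b, -0.4)
  expect_equal(co$truth$path_c_prime, 0.3)
  expect_equal(length(co$truth$subjects), 12)
  expect_true(all(vapply(co$truth$subjects, function(s) {
    all(c("sedentary_min_day", "mvpa_min_day", "mediator", "outcome") %in%
          names(s))
  }, logical(1))))
  # full mode additionally records per-day minutes, blocks and latents
  cfg_f <- sim_config(n_subjects = 4, n_nodes = 28, mode = "full", seed = 71)
  cof <- simulate_cohort(cfg_f)
  s1 <- cof$truth$subjects[[1]]
  expect_true(all(c("daily", "nonwear_blocks", "lambda", "mediator",
                    "ability") %in% names(s1)))
  expect_equal(nrow(s1$daily), 7)
  cof2 <- simulate_cohort(cfg_f)
  expect_identical(cof$epoch_series, cof2$epoch_series)
  expect_identical(cof$roi_series, cof2$roi_series)
})

test_that("full-mode accelerometry recovers the planted exposures exactly", {
  co <- simulate_cohort(sim_config(n_subjects = 6, n_nodes = 28,
                                   mode = "full", seed = 72))
  res <- process_accelerometry(co$epoch_series)
  truth_sed <- unlist(lapply(co$truth$subjects, function(s) s$daily$sedentary_min))
  rec <- res$daily[order(res$daily$subject_id, res$daily$day_index), ]
  expect_equal(rec$sedentary_min, unname(truth_sed))
  part <- res$participants
  expect_equal(part$sedentary_min_day[match(names(co$truth$subjects),
                                            part$subject_id)],
               unname(vapply(co$truth$subjects,
                             function(s) s$sedentary_min_day, numeric(1))))
  expect_true(all(part$included))
})
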