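test_that("framing score is 5 minus the mean absolute frame gap", {
  expect_equal(score_framing(data.frame(gain = c(3, 5), loss = c(3, 5))), 5)
  expect_equal(score_framing(data.frame(gain = 6, loss = 1)), 0)
  expect_equal(score_framing(data.frame(gain = c(4, 5), loss = c(2, 5))), 4)
  expect_error(score_framing(data.frame(gain = 7, loss = 1)), "1-6")
  expect_error(score_framing(data.frame(gain = numeric(), loss = numeric())),
               "at least one")
})

test_that("sunk-cost score is the mean keyed rating on 1-6", {
  expect_equal(score_sunk_cost(rep(6, 5)), 6)
  expect_equal(score_sunk_cost(rep(1, 5)), 1)
  expect_equal(score_sunk_cost(c(2, 4, 6)), 4)
  expect_error(score_sunk_cost(c(0, 3)), "1-6")
})

test_that("risk consistency is the fraction of coherent probability judgments", {
  all_ok <- data.frame(p1 = c(0.2, 0.7, 0.3), p2 = c(0.5, 0.3, 0.6),
                       predicate = c("subset", "complement", "union"))
  expect_equal(score_risk_consistency(all_ok), 1)
  # complement pair summing to 1.2 fails
  bad <- data.frame(p1 = 0.7, p2 = 0.5, predicate = "complement")
  expect_equal(score_risk_consistency(bad), 0)
  mixed <- data.frame(p1 = c(0.2, 0.7, 0.3, 0.9), p2 = c(0.5, 0.3, 0.6, 0.1),
                      predicate = c("subset", "complement", "union", "subset"))
  expect_equal(score_risk_consistency(mixed), 0.75)
  expect_error(score_risk_consistency(data.frame(p1 = 1.2, p2 = 0.1,
                                                 predicate = "subset")),
               "\\[0, 1\\]")
})

test_that("social-norms score is the Spearman correlation with cohort rates", {
  expect_equal(score_social_norms(c(10, 20, 30), c(0.1, 0.2, 0.3)), 1)
  expect_equal(score_social_norms(c(30, 20, 10), c(0.1, 0.2, 0.3)), -1)
  # ranks (1,2,3) vs (3,1,2)
  expect_equal(score_social_norms(c(10, 20, 30), c(0.3, 0.1, 0.2)), -0.5)
  expect_true(is.na(score_social_norms(c(10, 10, 10), c(0.1, 0.2, 0.3))))
})

test_that("decision-rules and calibration scores follow their definitions", {
  expect_equal(score_decision_rules(data.frame(response = 1:4, key = 1:4)), 1)
  expect_equal(score_decision_rules(data.frame(response = 1:4, key = 4:1)), 0)
  expect_equal(score_decision_rules(
    data.frame(response = c(rep(1, 7), rep(2, 3)), key = rep(1, 10))), 0.7)
  perf <- data.frame(correct = c(TRUE, TRUE, TRUE, FALSE),
                     confidence = rep(0.75, 4))
  expect_equal(score_confidence(perf), 1)
  over <- data.frame(correct = rep(c(TRUE, FALSE), 5), confidence = rep(1, 10))
  expect_equal(score_confidence(over), 0.5)
  expect_equal(score_confidence(data.frame(correct = c(TRUE, TRUE, FALSE,
                                                       FALSE, TRUE),
                                           confidence = rep(0.6, 5))), 1)
  expect_error(score_confidence(data.frame(correct = TRUE, confidence = 0.4)),
               "\\[0.5, 1\\]")
})

test_that("composite index is the unweighted mean of cohort z-scores", {
  scores <- data.frame(
    subject_id = c("A", "B", "C"),
    framing = c(3, 4, 5),
    sunk_cost = c(2, 4, 6),
    risk_consistency = c(0.5, 0.75, 1),
    social_norms = c(0, 0.4, 0.8),
    decision_rules = c(0.2, 0.5, 0.8),
    confidence = c(0.7, 0.8, 0.9)
  )
  out <- admc_index(scores)
  # every test is a linear ramp, so each z column is (-1, 0, 1) and the
  # hand-computed index is the same ramp
  expect_equal(out$index, c(-1, 0, 1))
  expect_equal(mean(out$index), 0)
  # subject at the cohort mean on all six tests scores 0
  expect_equal(out$index[2], 0)
  # index is invariant to an affine rescaling of a single test
  resc <- scores
  resc$sunk_cost <- 10 * resc$sunk_cost - 3
  expect_equal(admc_index(resc)$index, out$index)
  # zero-variance test is dropped with a warning
  flat <- scores
  flat$framing <- 4
  expect_warning(out_flat <- admc_index(flat), "zero variance")
  expect_equal(out_flat$index,
               rowMeans(scale(as.matrix(scores[, c(3:7)]))), ignore_attr = TRUE)
})

test_that("hand-computed 3-subject index matches explicit standardization", {
  scores <- data.frame(
    subject_id = c("A", "B", "C"),
    framing = c(4.0, 4.6, 3.2),
    sunk_cost = c(4.5, 3.0, 5.0),
    risk_consistency = c(0.8, 0.6, 0.9),
    social_norms = c(0.5, 0.2, 0.7),
    decision_rules = c(0.9, 0.6, 0.7),
    confidence = c(0.95, 0.85, 0.9)
  )
  out <- admc_index(scores)
  manual <- rowMeans(sapply(scores[, -1], function(x) (x - mean(x)) / sd(x)))
  expect_equal(out$index, manual, tolerance = 1e-12)
})

test_that("all six scores stay inside their documented ranges under fuzzing", {
  set.seed(31)
  for (rep in 1:50) {
    n_items <- sample(3:12, 1)
    framing <- data.frame(gain = sample(1:6, n_items, TRUE),
                          loss = sample(1:6, n_items, TRUE))
    f <- score_framing(framing)
    expect_true(f >= 0 && f <= 5)
    s <- score_sunk_cost(sample(1:6, n_items, TRUE))
    expect_true(s >= 1 && s <= 6)
    risk <- data.frame(p1 = runif(n_items), p2 = runif(n_items),
                       predicate = sample(c("subset", "complement", "union"),
                                          n_items, TRUE))
    rc <- score_risk_consistency(risk, tol = 0.05)
    expect_true(rc >= 0 && rc <= 1)
    sn <- score_social_norms(runif(n_items, 0, 100), runif(n_items))
    expect_true(is.na(sn) || (sn >= -1 && sn <= 1))
    dr <- score_decision_rules(data.frame(response = sample(1:4, n_items, TRUE),
                                          key = sample(1:4, n_items, TRUE)))
    expect_true(dr >= 0 && dr <= 1)
    cf <- score_confidence(data.frame(correct = runif(n_items) < 0.5,
                                      confidence = runif(n_items, 0.5, 1)))
    expect_true(cf >= 0 && cf <= 1)
  }
})

test_that("framing score never increases when any frame gap widens", {
  set.seed(32)
  for (rep in 1:20) {
    n_items <- sample(2:8, 1)
    gain <- sample(2:6, n_items, TRUE)
    loss <- pmax(gain - sample(0:1, n_items, TRUE), 1)
    base <- score_framing(data.frame(gain = gain, loss = loss))
    wider <- data.frame(gain = gain, loss = pmax(loss - 1, 1))
    expect_true(score_framing(wider) <= base + 1e-12)
  }
})

test_that("cohort scoring wires the norms base rates through correctly", {
  set.seed(33)
  items <- lapply(1:6, function(i) simulate_admc_responses(rnorm(1)))
  names(items) <- sprintf("S%d", 1:6)
  sc <- score_admc(items)
  expect_equal(nrow(sc), 6)
  expect_identical(sc$subject_id, sprintf("S%d", 1:6))
  # recompute one subject by hand from the cohort endorsement rates
  all_norms <- do.call(rbind, lapply(items, function(s) s$norms))
  props <- tapply(all_norms$own_ok, all_norms$behavior_id, mean)
  manual <- cor(items$S3$norms$est_percent, as.numeric(props),
                method = "spearman")
  expect_equal(sc$social_norms[3], manual)
})
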