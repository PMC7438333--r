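#' Score resistance to framing
#'
#' Each item presents the same problem in a gain frame and a loss frame, both
#' rated on a 1-6 scale. The score is 5 minus the mean absolute rating
#' difference between the paired frames, so identical ratings across frames
#' score the maximum of 5 and maximal discrepancy scores 0.
#'
#' @param pairs data frame with numeric columns \code{gain} and \code{loss},
#'   one row per framing pair, ratings on 1-6.
#' @return scalar in [0, 5].
#' @export
score_framing <- function(pairs) {
  if (nrow(pairs) < 1) stop("need at least one framing pair")
  r <- c(pairs$gain, pairs$loss)
  if (any(r < 1 | r > 6)) stop("framing ratings must lie on the 1-6 scale")
  5 - mean(abs(pairs$gain - pairs$loss))
}

#' Score resistance to sunk cost
#'
#' Ratings are keyed so that 6 means previous investments were fully
#' discounted (the normative response). The score is the mean keyed rating.
#'
#' @param ratings numeric vector of keyed ratings on 1-6.
#' @return scalar in [1, 6].
#' @export
score_sunk_cost <- function(ratings) {
  if (length(ratings) < 1) stop("need at least one sunk-cost rating")
  if (any(ratings < 1 | ratings > 6)) stop("sunk-cost ratings must lie on the 1-6 scale")
  mean(ratings)
}

#' Score consistency in risk perception
#'
#' Each item supplies two judged probabilities and a coherence predicate from
#' probability theory. The score is the fraction of items whose predicate
#' holds: \code{subset} (P(subset) <= P(superset)), \code{complement}
#' (P(A) + P(not A) = 1 within \code{tol}), \code{union}
#' (P(A) <= P(A or B)).
#'
#' @param risk_pairs data frame with columns \code{p1}, \code{p2} in [0, 1]
#'   and \code{predicate} in \code{c("subset", "complement", "union")}.
#' @param tol tolerance for the complement-sum check (default 1e-8, i.e.
#'   exact up to floating-point representation of probabilities that have
#'   passed through delimited text).
#' @return scalar in [0, 1].
#' @export
score_risk_consistency <- function(risk_pairs, tol = 1e-8) {
  p <- c(risk_pairs$p1, risk_pairs$p2)
  if (any(p < 0 | p > 1)) stop("judged probabilities must lie in [0, 1]")
  ok <- mapply(function(p1, p2, pred) {
    switch(pred,
      subset = p1 <= p2,
      complement = abs(p1 + p2 - 1) <= tol,
      union = p1 <= p2,
      stop("unknown predicate '", pred, "'")
    )
  }, risk_pairs$p1, risk_pairs$p2, as.character(risk_pairs$predicate))
  mean(ok)
}

#' Score recognition of social norms
#'
#' Spearman rank correlation between a subject's estimated percentage of
#' peers endorsing each undesirable behavior and the endorsement proportion
#' actually observed in the analyzed cohort.
#'
#' @param estimates subject's estimated peer percentages, one per behavior.
#' @param cohort_props cohort endorsement proportions for the same behaviors,
#'   in the same order.
#' @return Spearman correlation in [-1, 1], or \code{NA} (flagged missing)
#'   when either vector is constant so that no rank correlation exists.
#' @export
score_social_norms <- function(estimates, cohort_props) {
  if (length(estimates) != length(cohort_props)) stop("length mismatch")
  if (length(estimates) < 2) stop("need at least 2 behaviors")
  if (stats::sd(estimates) == 0 || stats::sd(cohort_props) == 0) {
    return(NA_real_)
  }
  stats::cor(estimates, cohort_props, method = "spearman")
}

#' Score application of decision rules
#'
#' @param rules data frame with columns \code{response} and \code{key}.
#' @return fraction of responses matching the keyed answer, in [0, 1].
#' @export
score_decision_rules <- function(rules) {
  if (nrow(rules) < 1) stop("need at least one rule problem")
  mean(rules$response == rules$key)
}

#' Score over/underconfidence (calibration)
#'
#' One minus the absolute difference between mean confidence and the
#' proportion of correct answers on general-knowledge items, so perfect
#' calibration scores 1 and higher is better.
#'
#' @param knowledge data frame with logical column \code{correct} and numeric
#'   column \code{confidence} in [0.5, 1].
#' @return scalar in [0, 1].
#' @export
score_confidence <- function(knowledge) {
  if (nrow(knowledge) < 1) stop("need at least one knowledge item")
  conf <- knowledge$confidence
  if (any(conf < 0.5 | conf > 1)) stop("confidence must lie in [0.5, 1]")
  1 - abs(mean(conf) - mean(knowledge$correct))
}

#' Score the full battery for a cohort of item-level responses
#'
#' The social-norms score needs cohort-level endorsement proportions, so the
#' battery is scored across subjects: proportions of "sometimes OK"
#' endorsements are computed per behavior from every subject's own responses,
#' then each subject's estimates are rank-correlated against them.
#'
#' @param items named list keyed by subject ID. Each element is a list with
#'   components \code{framing} (data frame: gain, loss), \code{sunk_cost}
#'   (numeric), \code{risk} (data frame: p1, p2, predicate), \code{norms}
#'   (data frame: behavior_id, own_ok, est_percent), \code{rules}
#'   (data frame: response, key), \code{knowledge} (data frame: correct,
#'   confidence).
#' @return data frame of the six test scores per subject (no composite; see
#'   [admc_index()]).
#' @export
score_admc <- function(items) {
  if (length(items) == 0) stop("no subjects supplied")
  if (is.null(names(items))) stop("items list must be named by subject ID")
  # cohort endorsement proportions per behavior
  norm_tabs <- lapply(items, function(s) s$norms)
  all_norms <- do.call(rbind, norm_tabs)
  props <- tapply(all_norms$own_ok, all_norms$behavior_id, mean)
  rows <- lapply(names(items), function(sid) {
    s <- items[[sid]]
    est <- s$norms$est_percent[order(s$norms$behavior_id)]
    pr <- props[as.character(sort(s$norms$behavior_id))]
    data.frame(
      subject_id = sid,
      framing = score_framing(s$framing),
      sunk_cost = score_sunk_cost(s$sunk_cost),
      risk_consistency = score_risk_consistency(s$risk),
      social_norms = score_social_norms(est, as.numeric(pr)),
      decision_rules = score_decision_rules(s$rules),
      confidence = score_confidence(s$knowledge),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composite decision-making competence index
#'
#' Standardizes each of the six test scores across the cohort (z-scores) and
#' averages them, unweighted, per subject. A test with zero variance across
#' the cohort cannot be standardized and is dropped from the index with a
#' warning.
#'
#' @param scores data frame from [score_admc()].
#' @return \code{scores} with an added \code{index} column.
#' @export
admc_index <- function(scores) {
  tests <- c("framing", "sunk_cost", "risk_consistency", "social_norms",
             "decision_rules", "confidence")
  if (nrow(scores) < 2) stop("index needs at least 2 subjects")
  zmat <- sapply(tests, function(tn) {
    x <- scores[[tn]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("test '", tn, "' has zero variance across the cohort; dropped from index")
      return(rep(NA_real_, length(x)))
    }
    (x - mean(x, na.rm = TRUE)) / s
  })
  scores$index <- rowMeans(zmat, na.rm = TRUE)
  scores
}
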