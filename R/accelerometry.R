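#' Construct a minute-epoch activity count series
#'
#' Bundles one or more participants' 60-second-epoch accelerometer counts into
#' the canonical long format used by the processing chain: one row per epoch
#' with a subject identifier, a timestamp, a nonnegative integer count and a
#' day index.
#'
#' @param subject_id character or factor, recycled to the number of epochs.
#' @param timestamp POSIXct timestamps at minute resolution. Within each
#'   subject they must be strictly increasing with exactly 60 s spacing.
#' @param counts nonnegative numeric vector of vertical-axis counts per epoch.
#' @param day_index optional integer day number per epoch; derived from the
#'   calendar date of \code{timestamp} (per subject, first date = day 1) when
#'   missing.
#' @return A \code{data.frame} with columns \code{subject_id}, \code{timestamp},
#'   \code{counts}, \code{day_index}, ordered by subject and time.
#' @export
epoch_series <- function(subject_id, timestamp, counts, day_index = NULL) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct")
  }
  n <- length(timestamp)
  subject_id <- rep_len(as.character(subject_id), n)
  if (length(counts) != n) stop("`counts` and `timestamp` lengths differ")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  df <- data.frame(
    subject_id = subject_id,
    timestamp = timestamp,
    counts = as.numeric(counts),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$subject_id, df$timestamp), , drop = FALSE]
  if (is.null(day_index)) {
    day_index <- unlist(lapply(split(df$timestamp, df$subject_id), function(ts) {
      d <- as.Date(ts, tz = "UTC")
      as.integer(d - min(d)) + 1L
    }), use.names = FALSE)
  } else {
    day_index <- as.integer(day_index)
  }
  df$day_index <- day_index
  validate_epoch_spacing(df)
  rownames(df) <- NULL
  df
}

# 60-s spacing is a hard precondition for everything downstream; resampling of
# irregular series is deliberately out of scope.
validate_epoch_spacing <- function(series) {
  for (sid in unique(series$subject_id)) {
    ts <- series$timestamp[series$subject_id == sid]
    if (length(ts) > 1) {
      dt <- diff(as.numeric(ts))
      if (any(dt != 60)) {
        stop(sprintf("subject %s: epochs are not on a strict 60-s grid", sid))
      }
    }
  }
  invisible(series)
}

#' Detect non-wear periods in a count series
#'
#' Flags every epoch that lies inside a maximal run of zero counts lasting at
#' least \code{min_zero_run} minutes as non-wear. Detection operates on the
#' continuous per-subject series, so runs spanning midnight are handled as a
#' single run; daily accounting splits them later by day index.
#'
#' @param series epoch data as returned by [epoch_series()].
#' @param min_zero_run minimum length, in minutes, of a zero run that counts
#'   as non-wear (default 60).
#' @param spike_tolerance maximum number of consecutive nonzero epochs allowed
#'   to interrupt a zero run without breaking it (default 0 = strict rule).
#'   When positive, two zero runs separated by at most this many nonzero
#'   epochs coalesce and the whole stretch is assessed against
#'   \code{min_zero_run}.
#' @return logical vector, \code{TRUE} for wear epochs, aligned with
#'   \code{series} rows.
#' @export
detect_nonwear <- function(series, min_zero_run = 60, spike_tolerance = 0) {
  validate_epoch_spacing(series)
  wear <- rep(TRUE, nrow(series))
  for (sid in unique(series$subject_id)) {
    idx <- which(series$subject_id == sid)
    wear[idx] <- wear_mask_one(series$counts[idx], min_zero_run, spike_tolerance)
  }
  wear
}

wear_mask_one <- function(counts, min_zero_run, spike_tolerance) {
  is_zero <- counts == 0
  n <- length(counts)
  wear <- rep(TRUE, n)
  r <- rle(is_zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (spike_tolerance > 0) {
    # coalesce zero runs separated by short nonzero interruptions
    zi <- which(r$values)
    if (length(zi) > 0) {
      group <- integer(length(zi))
      g <- 1L
      group[1] <- g
      if (length(zi) > 1) {
        for (k in 2:length(zi)) {
          gap <- starts[zi[k]] - ends[zi[k - 1L]] - 1L
          if (gap > spike_tolerance) g <- g + 1L
          group[k] <- g
        }
      }
      for (gg in unique(group)) {
        members <- zi[group == gg]
        span_start <- starts[members[1]]
        span_end <- ends[members[length(members)]]
        if (span_end - span_start + 1L >= min_zero_run) {
          wear[span_start:span_end] <- FALSE
        }
      }
    }
  } else {
    long <- which(r$values & r$lengths >= min_zero_run)
    for (k in long) wear[starts[k]:ends[k]] <- FALSE
  }
  wear
}

#' Classify wear epochs by count cut-points
#'
#' Applies the count-per-minute cut-points used throughout: sedentary below
#' 100 CPM, moderate-to-vigorous physical activity (MVPA) at or above
#' 2020 CPM, light in between. Non-wear epochs keep the \code{"nonwear"} label.
#'
#' @param series epoch data frame.
#' @param wear logical wear mask from [detect_nonwear()].
#' @param sedentary_cut counts-per-minute threshold below which a wear epoch is
#'   sedentary (default 100).
#' @param mvpa_cut counts-per-minute threshold at or above which a wear epoch
#'   is MVPA (default 2020).
#' @return factor with levels \code{nonwear, sedentary, light, mvpa}.
#' @export
classify_epochs <- function(series, wear, sedentary_cut = 100, mvpa_cut = 2020) {
  if (length(wear) != nrow(series)) stop("wear mask does not match series")
  lab <- rep("nonwear", nrow(series))
  cts <- series$counts
  lab[wear & cts < sedentary_cut] <- "sedentary"
  lab[wear & cts >= sedentary_cut & cts < mvpa_cut] <- "light"
  lab[wear & cts >= mvpa_cut] <- "mvpa"
  factor(lab, levels = c("nonwear", "sedentary", "light", "mvpa"))
}

#' Summarize labeled epochs into daily wear and intensity minutes
#'
#' @param series epoch data frame.
#' @param labels factor from [classify_epochs()].
#' @param min_wear_min minutes of wear a day needs to count as valid
#'   (default 600, i.e. 10 h).
#' @return data frame with one row per subject-day: \code{wear_min},
#'   \code{sedentary_min}, \code{light_min}, \code{mvpa_min},
#'   \code{valid_day}.
#' @export
summarize_days <- function(series, labels, min_wear_min = 600) {
  if (length(labels) != nrow(series)) stop("labels do not match series")
  key <- paste(series$subject_id, series$day_index, sep = "\r")
  tab <- table(factor(key, levels = unique(key)), labels)
  ids <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(
    subject_id = ids[, 1],
    day_index = as.integer(ids[, 2]),
    sedentary_min = as.integer(tab[, "sedentary"]),
    light_min = as.integer(tab[, "light"]),
    mvpa_min = as.integer(tab[, "mvpa"]),
    stringsAsFactors = FALSE
  )
  out$wear_min <- out$sedentary_min + out$light_min + out$mvpa_min
  out$valid_day <- out$wear_min >= min_wear_min
  out <- out[order(out$subject_id, out$day_index),
             c("subject_id", "day_index", "wear_min", "sedentary_min",
               "light_min", "mvpa_min", "valid_day")]
  rownames(out) <- NULL
  out
}

#' Aggregate daily summaries into participant-level activity means
#'
#' Means are computed over valid days only (at least 10 h wear). Participants
#' with fewer than \code{min_valid_days} valid days are flagged excluded; when
#' no valid day exists the means are \code{NA}, never zero. The
#' physical-activity guidelines flag treats all MVPA minutes as
#' moderate-equivalent against the 150 min/week criterion.
#'
#' @param daily per-day summary from [summarize_days()].
#' @param min_valid_days valid days required for inclusion (default 4).
#' @param guideline_min_week weekly moderate-equivalent MVPA minutes that
#'   satisfy the aerobic guideline (default 150).
#' @return one row per subject: \code{n_valid_days}, per-day means,
#'   \code{included}, \code{meets_guidelines}.
#' @export
aggregate_participants <- function(daily, min_valid_days = 4,
                                   guideline_min_week = 150) {
  if (nrow(daily) == 0) stop("no daily summaries supplied")
  split_daily <- split(daily, daily$subject_id)
  rows <- lapply(split_daily, function(d) {
    v <- d[d$valid_day, , drop = FALSE]
    nv <- nrow(v)
    mean_or_na <- function(x) if (nv > 0) mean(x) else NA_real_
    data.frame(
      subject_id = d$subject_id[1],
      n_valid_days = nv,
      wear_min_day = mean_or_na(v$wear_min),
      sedentary_min_day = mean_or_na(v$sedentary_min),
      light_min_day = mean_or_na(v$light_min),
      mvpa_min_day = mean_or_na(v$mvpa_min),
      included = nv >= min_valid_days,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$meets_guidelines <- !is.na(out$mvpa_min_day) &
    out$mvpa_min_day * 7 >= guideline_min_week
  rownames(out) <- NULL
  out
}

#' Run the full accelerometer processing chain
#'
#' Non-wear detection, cut-point classification, daily summaries and
#' participant aggregation in one call.
#'
#' @param series epoch data frame for one or more subjects.
#' @param min_zero_run,spike_tolerance see [detect_nonwear()].
#' @param sedentary_cut,mvpa_cut see [classify_epochs()].
#' @param min_wear_min see [summarize_days()].
#' @param min_valid_days see [aggregate_participants()].
#' @return list with elements \code{daily} and \code{participants}.
#' @export
process_accelerometry <- function(series, min_zero_run = 60,
                                  spike_tolerance = 0,
                                  sedentary_cut = 100, mvpa_cut = 2020,
                                  min_wear_min = 600, min_valid_days = 4) {
  wear <- detect_nonwear(series, min_zero_run, spike_tolerance)
  labels <- classify_epochs(series, wear, sedentary_cut, mvpa_cut)
  daily <- summarize_days(series, labels, min_wear_min)
  participants <- aggregate_participants(daily, min_valid_days)
  list(daily = daily, participants = participants)
}
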