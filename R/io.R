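#' Readers and writers for the pipeline's delimited-text formats
#'
#' All on-disk formats are plain delimited text so that runs are portable and
#' diffable: phenotypes and daily summaries as CSV, epoch series as CSV with
#' ISO-8601 UTC timestamps, matrices as CSV with a node-ID header row and
#' column, the truth record as JSON.
#'
#' @param x object to write.
#' @param path file path.
#' @name sednet-io
NULL

#' @rdname sednet-io
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sednet-io
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname sednet-io
#' @export
write_epochs <- function(x, path) {
  out <- data.frame(
    subject_id = x$subject_id,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    counts = x$counts,
    day_index = x$day_index
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sednet-io
#' @export
read_epochs <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  epoch_series(raw$subject_id,
               as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                          tz = "UTC"),
               raw$counts, raw$day_index)
}

#' Write a nodes-x-columns matrix with node IDs in the first column
#'
#' Used for both ROI time-series matrices (columns are volumes) and weight
#' matrices (columns are nodes, giving a node-ID header row and column).
#'
#' @rdname sednet-io
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(node_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sednet-io
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$node_id
  # generic volume columns (V1..Vn) carry no information
  if (all(grepl("^V[0-9]+$", colnames(m)))) colnames(m) <- NULL
  m
}

#' @rdname sednet-io
#' @export
write_assignment <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sednet-io
#' @export
read_assignment <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(node_id = "character"))
}

#' Write item-level battery responses, one delimited file per test
#'
#' @param items named list of per-subject response lists (see
#'   [score_admc()]).
#' @param dir output directory.
#' @rdname sednet-io
#' @export
write_admc_items <- function(items, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bind <- function(get) {
    do.call(rbind, lapply(names(items), function(sid) {
      cbind(subject_id = sid, get(items[[sid]]), stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(bind(function(s) s$framing),
                   file.path(dir, "framing.csv"), row.names = FALSE)
  utils::write.csv(bind(function(s) data.frame(rating = s$sunk_cost)),
                   file.path(dir, "sunk_cost.csv"), row.names = FALSE)
  utils::write.csv(bind(function(s) s$risk),
                   file.path(dir, "risk.csv"), row.names = FALSE)
  utils::write.csv(bind(function(s) s$norms),
                   file.path(dir, "norms.csv"), row.names = FALSE)
  utils::write.csv(bind(function(s) s$rules),
                   file.path(dir, "rules.csv"), row.names = FALSE)
  utils::write.csv(bind(function(s) s$knowledge),
                   file.path(dir, "knowledge.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname sednet-io
#' @export
read_admc_items <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  framing <- rd("framing.csv"); sunk <- rd("sunk_cost.csv")
  risk <- rd("risk.csv"); norms <- rd("norms.csv")
  rules <- rd("rules.csv"); knowledge <- rd("knowledge.csv")
  ids <- unique(framing$subject_id)
  items <- lapply(ids, function(sid) {
    pick <- function(df) {
      out <- df[df$subject_id == sid, setdiff(names(df), "subject_id"),
                drop = FALSE]
      rownames(out) <- NULL
      out
    }
    list(framing = pick(framing),
         sunk_cost = pick(sunk)$rating,
         risk = pick(risk),
         norms = pick(norms),
         rules = pick(rules),
         knowledge = pick(knowledge))
  })
  names(items) <- ids
  items
}

#' @rdname sednet-io
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname sednet-io
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a synthetic cohort to a directory of delimited files
#'
#' Layout: \code{phenotypes.csv}, \code{assignment.csv}, \code{truth.json},
#' \code{epochs.csv} (full mode), \code{roi/<subject>.csv} (full mode) and
#' \code{admc/} with one file per test.
#'
#' @param cohort a \code{"sednet_cohort"} object.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  write_assignment(cohort$assignment, file.path(dir, "assignment.csv"))
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  if (!is.null(cohort$epoch_series)) {
    write_epochs(cohort$epoch_series, file.path(dir, "epochs.csv"))
  }
  if (!is.null(cohort$roi_series)) {
    roi_dir <- file.path(dir, "roi")
    dir.create(roi_dir, showWarnings = FALSE)
    for (sid in names(cohort$roi_series)) {
      write_matrix_csv(cohort$roi_series[[sid]],
                       file.path(roi_dir, paste0(sid, ".csv")))
    }
  }
  write_admc_items(cohort$admc_items, file.path(dir, "admc"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list mirroring the \code{"sednet_cohort"} structure (without the
#'   config object).
#' @export
read_cohort <- function(dir) {
  out <- list(
    phenotypes = read_phenotypes(file.path(dir, "phenotypes.csv")),
    assignment = read_assignment(file.path(dir, "assignment.csv")),
    truth = read_truth(file.path(dir, "truth.json")),
    epoch_series = NULL, roi_series = NULL,
    admc_items = read_admc_items(file.path(dir, "admc"))
  )
  ep <- file.path(dir, "epochs.csv")
  if (file.exists(ep)) out$epoch_series <- read_epochs(ep)
  roi_dir <- file.path(dir, "roi")
  if (dir.exists(roi_dir)) {
    files <- sort(list.files(roi_dir, pattern = "\\.csv$", full.names = TRUE))
    out$roi_series <- lapply(files, read_matrix_csv)
    names(out$roi_series) <- sub("\\.csv$", "", basename(files))
  }
  out
}
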