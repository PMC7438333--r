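#' Pairwise Pearson correlation matrix of regional time series
#'
#' @param signal numeric matrix, nodes as rows and volumes (time points) as
#'   columns. Every row must have nonzero variance.
#' @return symmetric correlation matrix with unit diagonal, dimnames taken
#'   from the row names of \code{signal}.
#' @export
pearson_matrix <- function(signal) {
  signal <- as.matrix(signal)
  if (ncol(signal) < 2) stop("need at least 2 volumes")
  sds <- apply(signal, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(signal)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant (zero-variance) node(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(signal))
  # enforce exact symmetry against floating-point asymmetry
  (r + t(r)) / 2
}

#' Fisher z transformation of a correlation matrix
#'
#' Applies \code{atanh} entrywise to the off-diagonal entries. The diagonal is
#' set to 0 and carries no information downstream.
#'
#' @param r correlation matrix with all off-diagonal entries strictly inside
#'   (-1, 1).
#' @return matrix of Fisher z values.
#' @export
fisher_z <- function(r) {
  r <- as.matrix(r)
  off <- r[upper.tri(r) | lower.tri(r)]
  if (any(abs(off) >= 1)) {
    stop("|r| >= 1 off the diagonal; perfectly correlated nodes must be removed upstream")
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Standardize Fisher z values to approximate standard-normal scores
#'
#' The sampling standard deviation of a Fisher z value is approximated as
#' sigma = 1/sqrt(n - 3), with n the number of volumes. The default divides by
#' sigma, i.e. Z = z * sqrt(n - 3), so Z is approximately standard normal
#' under the null and normal-quantile (Bonferroni) thresholds apply directly.
#' \code{literal_sigma = TRUE} multiplies by sigma instead; this shrinks
#' rather than standardizes and is provided only to reproduce that reading.
#'
#' @param z Fisher z matrix.
#' @param n number of volumes used to compute the correlations; must exceed 3.
#' @param literal_sigma multiply by sigma instead of dividing (default FALSE).
#' @return matrix of standardized scores, zero diagonal.
#' @export
standardize_z <- function(z, n, literal_sigma = FALSE) {
  if (n <= 3) stop("n must exceed 3 for sigma = 1/sqrt(n - 3)")
  sigma <- 1 / sqrt(n - 3)
  out <- if (literal_sigma) z * sigma else z / sigma
  diag(out) <- 0
  out
}

#' Bonferroni threshold for a standardized connectivity matrix
#'
#' Keeps entries whose standardized score exceeds the Bonferroni-corrected
#' normal quantile over the m = p(p-1)/2 unique node pairs; everything else,
#' including every negative entry, is set to zero. Two-sided correction by
#' default (z* at alpha / (2m)).
#'
#' @param Z standardized score matrix (p x p).
#' @param alpha family-wise significance level (default 0.05).
#' @param two_sided use alpha/(2m) quantile (default TRUE); FALSE uses
#'   alpha/m.
#' @return matrix with surviving positive scores, zeros elsewhere; attribute
#'   \code{z_star} records the threshold used.
#' @export
bonferroni_threshold <- function(Z, alpha = 0.05, two_sided = TRUE) {
  p <- nrow(Z)
  if (p < 2) stop("need at least 2 nodes")
  m <- p * (p - 1) / 2
  tail_p <- if (two_sided) alpha / (2 * m) else alpha / m
  z_star <- stats::qnorm(1 - tail_p)
  out <- Z
  out[out < z_star] <- 0
  diag(out) <- 0
  attr(out, "z_star") <- z_star
  attr(out, "n_tests") <- m
  out
}

#' Rescale a thresholded score matrix to connection weights in [0, 1]
#'
#' Divides every surviving entry by the matrix maximum (per subject, whole
#' matrix), mapping the strongest surviving connection to 1 and leaving zeros
#' untouched.
#'
#' @param thresholded nonnegative matrix from [bonferroni_threshold()].
#' @return weight matrix in [0, 1] with zero diagonal. When no edge survived
#'   the all-zero matrix is returned with a warning.
#' @export
rescale_weights <- function(thresholded) {
  w <- as.matrix(thresholded)
  if (any(w < 0)) stop("thresholded matrix must be nonnegative")
  mx <- max(w)
  if (mx == 0) {
    warning("no surviving edges; returning all-zero weight matrix")
    attr(w, "z_star") <- NULL
    attr(w, "n_tests") <- NULL
    return(w)
  }
  w <- w / mx
  diag(w) <- 0
  attr(w, "z_star") <- NULL
  attr(w, "n_tests") <- NULL
  w
}

#' Extract the weighted submatrix of one intrinsic connectivity network
#'
#' @param weights whole-brain weight matrix with node IDs as dimnames.
#' @param assignment data frame with columns \code{node_id} and
#'   \code{network_label} mapping every node to one of the network labels.
#' @param network_label the label to extract.
#' @return principal submatrix over the labeled nodes (at least 2 required).
#' @export
extract_network <- function(weights, assignment, network_label) {
  labels <- unique(assignment$network_label)
  if (!network_label %in% labels) {
    stop("unknown network label '", network_label, "'; valid labels: ",
         paste(sort(labels), collapse = ", "))
  }
  nodes <- assignment$node_id[assignment$network_label == network_label]
  nodes <- intersect(rownames(weights), as.character(nodes))
  if (length(nodes) < 2) {
    stop("network '", network_label, "' has fewer than 2 nodes in the matrix")
  }
  weights[nodes, nodes, drop = FALSE]
}

#' Framewise root-mean-square signal change (DVARS)
#'
#' @param signal nodes x volumes matrix.
#' @return numeric vector of length \code{ncol(signal) - 1}: RMS across nodes
#'   of the backward temporal difference at volumes 2..T.
#' @export
dvars <- function(signal) {
  signal <- as.matrix(signal)
  d <- signal[, -1, drop = FALSE] - signal[, -ncol(signal), drop = FALSE]
  sqrt(colMeans(d^2))
}

#' Flag motion-outlier volumes by the boxplot rule
#'
#' A value is an outlier when it exceeds Q3 + 1.5 * IQR of the series, with
#' quartiles computed by linear interpolation (R quantile type 7). When a
#' nodes-x-volumes matrix is supplied the DVARS series is computed first and
#' flags refer to volumes 2..T.
#'
#' @param x framewise-change series, or a signal matrix.
#' @return logical vector of outlier flags, aligned with \code{x} when a
#'   series is given.
#' @export
dvars_outliers <- function(x) {
  if (is.matrix(x)) x <- dvars(x)
  if (length(x) < 4) stop("series must have length >= 4")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  x > q[2] + 1.5 * (q[2] - q[1])
}

#' Build whole-brain and per-network connectivity weights for one subject
#'
#' Runs the full matrix recipe: Pearson correlations between regional time
#' series, Fisher z transformation, standardization by sqrt(n - 3),
#' Bonferroni thresholding with removal of negative and non-significant
#' entries, rescaling to [0, 1] by the subject's whole-brain maximum, and
#' extraction of per-network submatrices.
#'
#' @param signal nodes x volumes matrix with node IDs as row names.
#' @param assignment node-to-network assignment table (\code{node_id},
#'   \code{network_label}).
#' @param alpha family-wise alpha for the Bonferroni threshold (default 0.05).
#' @param networks labels to extract; default all labels present in
#'   \code{assignment}.
#' @param two_sided,literal_sigma conventions passed through; see
#'   [bonferroni_threshold()] and [standardize_z()].
#' @return list with \code{whole} (whole-brain weight matrix),
#'   \code{networks} (named list of submatrices) and \code{provenance}
#'   (alpha, number of tests, z*, sigma convention, rescale denominator).
#' @export
fc_weights <- function(signal, assignment, alpha = 0.05, networks = NULL,
                       two_sided = TRUE, literal_sigma = FALSE) {
  signal <- as.matrix(signal)
  if (is.null(rownames(signal))) {
    rownames(signal) <- as.character(assignment$node_id[seq_len(nrow(signal))])
  }
  n <- ncol(signal)
  r <- pearson_matrix(signal)
  z <- fisher_z(r)
  Z <- standardize_z(z, n, literal_sigma)
  thr <- bonferroni_threshold(Z, alpha, two_sided)
  denom <- max(thr)
  w <- suppressWarnings(rescale_weights(thr))
  if (denom == 0) warning("no surviving edges in whole-brain matrix")
  if (is.null(networks)) networks <- unique(assignment$network_label)
  nets <- lapply(networks, function(lb) extract_network(w, assignment, lb))
  names(nets) <- networks
  list(
    whole = w,
    networks = nets,
    provenance = list(
      alpha = alpha,
      n_volumes = n,
      n_tests = attr(thr, "n_tests"),
      z_star = attr(thr, "z_star"),
      sigma = 1 / sqrt(n - 3),
      sigma_convention = if (literal_sigma) "multiply" else "divide",
      two_sided = two_sided,
      rescale_denominator = denom
    )
  )
}
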