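# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Floyd-Warshall instead of Dijkstra, literal
# definition sums instead of vectorized forms, O(n^2) scans instead of rle.

# all-pairs shortest paths by Floyd-Warshall on a length matrix
fw_distances <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    through <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, through)
  }
  d
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- fw_distances(len)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) total <- total + 1 / d[i, j]
    }
  }
  total / (n * (n - 1))
}

# definition-literal local efficiency: restricted neighbor subgraph,
# Floyd-Warshall distances, explicit double loop over ordered pairs
oracle_local_efficiency_node <- function(w, i, variant = "product") {
  nb <- setdiff(which(w[i, ] > 0), i)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- w[nb, nb, drop = FALSE]
  len <- ifelse(sub > 0, 1 / sub, Inf)
  diag(len) <- 0
  d <- fw_distances(len)
  acc <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b || !is.finite(d[a, b]) || d[a, b] == 0) next
      term <- w[i, nb[a]] * w[i, nb[b]] * (1 / d[a, b])
      if (variant == "rubinov_sporns") term <- term^(1 / 3)
      acc <- acc + term
    }
  }
  acc / (k * (k - 1))
}

oracle_local_efficiency <- function(w, variant = "product") {
  mean(vapply(seq_len(nrow(w)), function(i) {
    oracle_local_efficiency_node(w, i, variant)
  }, numeric(1)))
}

random_weight_graph <- function(n, p_edge = 0.4) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  sel <- up[stats::runif(length(up)) < p_edge]
  w[sel] <- stats::runif(length(sel), 0.05, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  w
}

# Benjamini-Hochberg step-up from first principles
brute_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  passing <- which(sorted <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(passing) > 0) reject[ord[seq_len(max(passing))]] <- TRUE
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    adj_sorted[k] <- min(1, min(m * sorted[k:m] / (k:m)))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  list(p_adjusted = adj, reject = reject)
}

# O(n^2) zero-run scan: epoch is non-wear if any zero run of length >= k
# contains it
brute_wear_mask <- function(counts, min_run = 60) {
  n <- length(counts)
  wear <- rep(TRUE, n)
  for (s in seq_len(n)) {
    if (counts[s] != 0) next
    e <- s
    while (e < n && counts[e + 1] == 0) e <- e + 1
    if (e - s + 1 >= min_run) wear[s:e] <- FALSE
  }
  wear
}

# two-pass covariance / sd correlation
naive_cor_matrix <- function(signal) {
  p <- nrow(signal)
  out <- diag(p)
  mu <- rowMeans(signal)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- signal[i, ] - mu[i]
      xj <- signal[j, ] - mu[j]
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# small epoch-series builder on the canonical grid
make_series <- function(counts, subject_id = "S1", n_per_day = 1440) {
  n <- length(counts)
  epoch_series(subject_id,
               as.POSIXct("2020-01-06 00:00:00", tz = "UTC") +
                 60 * (seq_len(n) - 1),
               counts,
               day_index = ((seq_len(n) - 1) %/% n_per_day) + 1L)
}
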