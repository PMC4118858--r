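# Independent oracles used to freeze expected values: naive implementations
# kept deliberately separate from the package's code paths.

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Naive O(n^3) agglomerative Ward (ward.D2 convention: Lance-Williams on
# squared dissimilarities, heights on the original scale).
naive_ward_oracle <- function(D) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b) {
        i <- active[a]; j <- active[b]
        if (D2[i, j] < bd) { bd <- D2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bd))
    merges[[length(merges) + 1L]] <- sort(c(members[[i]], members[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# Hand product-limit estimator.
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Two-group log-rank chi-squared from the observed-minus-expected sums at
# every event time.
logrank_oracle <- function(times, events, group) {
  group <- as.integer(factor(group))
  ut <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Average within-cluster consensus objective for a labeling of M's samples.
consensus_objective <- function(M, labels) {
  tot <- 0; cnt <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1L) {
      pairs <- utils::combn(idx, 2)
      tot <- tot + sum(M[t(pairs)])
      cnt <- cnt + ncol(pairs)
    }
  }
  if (cnt == 0) 0 else tot / cnt
}

# All 2-partitions of n samples (non-trivial), as label vectors.
all_two_partitions <- function(n) {
  out <- list()
  for (size in 1:floor(n / 2)) {
    for (j in seq_len(ncol(utils::combn(n, size)))) {
      idx <- utils::combn(n, size)[, j]
      if (size == n / 2 && idx[1] != 1) next  # avoid mirrored duplicates
      lab <- rep(2L, n); lab[idx] <- 1L
      out[[length(out) + 1L]] <- lab
    }
  }
  out
}

# Small fixture builders -----------------------------------------------

make_expr_fixture <- function(values, probe_ids = NULL, samples = NULL) {
  if (is.null(probe_ids)) probe_ids <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  expression_matrix(values, probe_ids = probe_ids, sample_ids = samples)
}

write_tsv_fixture <- function(path, probe_ids, sample_ids, values) {
  lines <- c(paste(c("probe_id", sample_ids), collapse = "\t"),
             vapply(seq_along(probe_ids), function(i)
               paste(c(probe_ids[i], values[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
}

write_gct_fixture <- function(path, probe_ids, sample_ids, values,
                              declared_dims = NULL) {
  if (is.null(declared_dims)) declared_dims <- dim(values)
  lines <- c("#1.2",
             paste(declared_dims, collapse = "\t"),
             paste(c("NAME", "Description", sample_ids), collapse = "\t"),
             vapply(seq_along(probe_ids), function(i)
               paste(c(probe_ids[i], probe_ids[i], values[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
}

small_sample_table <- function() {
  validate_sample_table(data.frame(
    sample_id = c("a", "b", "c", "d"),
    group = c("MSS-Y", "MSS-O", "MSI-Y", "MSI-O"),
    age_years = c(40, 70.5, 30, 80),
    survival_time = c(10, 20, 30, 40),
    event = c(1, 0, 1, 0),
    stringsAsFactors = FALSE))
}
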