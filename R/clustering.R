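# Class discovery: Ward clustering on 1-Pearson distance per variant-gene
# list, consensus over the per-list partitions at each k, selection of the
# dendrogram closest to the consensus (adjusted Rand index), and association
# of the consensus partition with clinical/molecular annotations.

#' Pearson correlation distance between samples
#'
#' D[i, j] = 1 - r(x_i, x_j) over the probes of the supplied matrix;
#' symmetric, zero diagonal, range [0, 2].
#'
#' @param x_log2 numeric matrix, probes in rows, samples in columns
#'   (log2 intensities).
#' @return a symmetric distance matrix with sample dimnames.
#' @export
pearson_distance <- function(x_log2) {
  if (nrow(x_log2) < 2L || ncol(x_log2) < 2L)
    stop("pearson_distance needs >= 2 probes and >= 2 samples")
  sds <- apply(x_log2, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x_log2)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance sample column(s): ", paste(bad, collapse = ", "))
  }
  D <- 1 - stats::cor(x_log2)
  D[abs(D) < .Machine$double.eps^0.5 & row(D) == col(D)] <- 0
  diag(D) <- 0
  D
}

#' Ward dendrogram from a distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`hclust` method `ward.D2`, which squares the supplied dissimilarities
#' internally). Merge heights are non-decreasing.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return an object of class `hclust`.
#' @export
ward_dendrogram <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

#' Cut a dendrogram into a canonical k-partition
#'
#' Labels are canonicalized: clusters numbered by decreasing size, ties by
#' the lexicographically smallest member sample id, so identical groupings
#' always yield identical label vectors.
#'
#' @param dend an `hclust` object.
#' @param k number of clusters.
#' @return named integer vector (sample id -> cluster in 1..k).
#' @export
cut_partition <- function(dend, k) {
  cl <- stats::cutree(dend, k = k)
  canonicalize_partition(cl)
}

#' Canonicalize cluster labels
#'
#' @param partition named vector of cluster labels.
#' @return named integer vector with labels 1..k assigned by decreasing
#'   cluster size, ties broken by smallest member sample id.
#' @export
canonicalize_partition <- function(partition) {
  ids <- names(partition)
  f <- as.character(partition)
  sizes <- table(f)
  first_id <- tapply(ids, f, function(s) sort(s)[1L])
  ord <- names(sizes)[order(-as.numeric(sizes), first_id[names(sizes)])]
  stats::setNames(match(f, ord), ids)
}

#' Co-classification consensus matrix
#'
#' M[i, j] = fraction of partitions in which samples i and j share a
#' cluster. Symmetric with unit diagonal; entries are multiples of 1/L for
#' L partitions.
#'
#' @param partitions list of named cluster-label vectors over identical
#'   sample sets.
#' @return samples x samples numeric matrix.
#' @export
consensus_matrix <- function(partitions) {
  if (length(partitions) < 1L) stop("need >= 1 partition")
  ids <- sort(names(partitions[[1L]]))
  for (p in partitions) {
    if (!identical(sort(names(p)), ids))
      stop("partitions are over different sample sets")
  }
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in partitions) {
    lab <- p[ids]
    M <- M + outer(lab, lab, "==")
  }
  M / length(partitions)
}

#' Consensus partition from a consensus matrix
#'
#' Ward clustering (ward.D2) of the dissimilarity 1 - M, cut at k, with
#' canonical labels.
#'
#' @param M consensus matrix from [consensus_matrix()].
#' @param k number of clusters (<= number of samples).
#' @return named integer vector of cluster labels.
#' @export
consensus_partition <- function(M, k) {
  if (k > nrow(M)) stop("k exceeds the number of samples")
  dend <- ward_dendrogram(1 - M)
  cut_partition(dend, k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 iff the partitions are identical up to
#' relabeling, 0 expected under independent random partitions.
#'
#' @param p1,p2 named cluster-label vectors over the same samples.
#' @return the ARI.
#' @export
adjusted_rand <- function(p1, p2) {
  if (!identical(sort(names(p1)), sort(names(p2))))
    stop("partitions are over different sample sets")
  p2 <- p2[names(p1)]
  tab <- table(p1, p2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Select the dendrogram closest to the consensus partition
#'
#' Each dendrogram is cut at k and compared to the consensus partition by
#' ARI; the index of the maximizer is returned (ties: lowest index, and the
#' tie is reported via a message).
#'
#' @param dendrograms list of `hclust` objects.
#' @param consensus named cluster-label vector.
#' @param k number of clusters.
#' @return list with `index` and the vector of `ari` values.
#' @export
select_closest_dendrogram <- function(dendrograms, consensus, k) {
  if (length(dendrograms) < 1L) stop("need >= 1 dendrogram")
  ari <- vapply(dendrograms, function(d) {
    adjusted_rand(cut_partition(d, k), consensus)
  }, numeric(1))
  best <- which(ari == max(ari))
  if (length(best) > 1L)
    message("closest-dendrogram tie at ARI ", format(max(ari)),
            "; keeping the first of indices ", paste(best, collapse = ", "))
  list(index = best[1L], ari = ari)
}

#' Associate a partition with clinical/molecular annotations
#'
#' One contingency test (Fisher or chi-squared, chosen by Cochran's rule via
#' [choose_test()]) per categorical variable against the cluster labels,
#' with Benjamini-Hochberg adjusted p-values. Missing values are excluded
#' pairwise; single-level variables are skipped with a warning.
#'
#' @param partition named cluster-label vector.
#' @param samples a `sample_table`.
#' @param variables character vector of column names to test.
#' @return data.frame: variable, test used, p, BH-adjusted p.
#' @export
associate_annotations <- function(partition, samples, variables) {
  stopifnot(all(variables %in% names(samples)))
  rows <- lapply(variables, function(v) {
    val <- samples[[v]][match(names(partition), samples$sample_id)]
    ok <- !is.na(val)
    if (length(unique(val[ok])) < 2L) {
      warning("variable ", v, " has a single level; skipped")
      return(NULL)
    }
    tab <- table(val[ok], partition[ok])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    ct <- contingency_test(tab)
    data.frame(variable = v, test = ct$test, p = ct$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable variable")
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Consensus clustering over variant-gene lists
#'
#' The full class-discovery procedure: for each probe list, samples are
#' clustered by Ward linkage on 1-Pearson distance of the log2 expression
#' restricted to the list, yielding one dendrogram per list. For each k in
#' `k_range`, the per-list partitions are combined into a co-classification
#' consensus matrix, a consensus partition is extracted (Ward on 1 - M), and
#' the dendrogram closest to the consensus (max ARI) is recorded.
#'
#' @param x an `expr_matrix` (linear scale; log2 applied internally).
#' @param probe_lists named list of probe-id vectors (e.g. from
#'   [build_variant_lists()]).
#' @param k_range integer vector of cluster counts (default 2:8).
#' @return object of class `consensus_fit`: list with `dendrograms`,
#'   and per-k `consensus` entries (matrix, partition, closest-list index,
#'   per-list ARIs).
#' @export
consensus_cluster <- function(x, probe_lists, k_range = 2:8) {
  validate_expression_matrix(x)
  stopifnot(length(probe_lists) >= 1L, all(k_range >= 2L),
            max(k_range) <= length(x$sample_ids))
  lx <- log2(x$values)
  usable <- lengths(probe_lists) >= 2L
  if (!all(usable)) {
    warning("dropping ", sum(!usable),
            " probe list(s) with < 2 probes (correlation undefined)")
    probe_lists <- probe_lists[usable]
  }
  if (length(probe_lists) == 0L) stop("no usable probe list")
  dendrograms <- lapply(probe_lists, function(ids) {
    ward_dendrogram(pearson_distance(lx[ids, , drop = FALSE]))
  })
  per_k <- lapply(k_range, function(k) {
    parts <- lapply(dendrograms, cut_partition, k = k)
    M <- consensus_matrix(parts)
    cons <- consensus_partition(M, k)
    sel <- select_closest_dendrogram(dendrograms, cons, k)
    list(k = k, matrix = M, partition = cons,
         closest_list = sel$index, list_ari = sel$ari)
  })
  names(per_k) <- paste0("k", k_range)
  structure(list(dendrograms = dendrograms, k_range = k_range,
                 consensus = per_k, n_lists = length(probe_lists)),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf("consensus_fit: %d gene lists, k = %s\n", x$n_lists,
              paste(range(x$k_range), collapse = "..")))
  for (ck in x$consensus) {
    cat(sprintf("  k=%d: cluster sizes %s; closest list #%d (ARI %.3f)\n",
                ck$k, paste(table(ck$partition), collapse = "/"),
                ck$closest_list, max(ck$list_ari)))
  }
  invisible(x)
}

#' @export
summary.consensus_fit <- function(object, ...) {
  df <- do.call(rbind, lapply(object$consensus, function(ck) {
    data.frame(k = ck$k, n_clusters = length(unique(ck$partition)),
               closest_list = ck$closest_list,
               mean_list_ari = mean(ck$list_ari),
               max_list_ari = max(ck$list_ari))
  }))
  rownames(df) <- NULL
  df
}

#' Plot a consensus matrix
#'
#' Heat-image of the co-classification fractions with samples ordered by the
#' consensus dendrogram.
#'
#' @param x a `consensus_fit`.
#' @param k which k to plot (default the smallest in the fit).
#' @param ... passed to [graphics::image()].
#' @export
plot.consensus_fit <- function(x, k = x$k_range[1L], ...) {
  ck <- x$consensus[[paste0("k", k)]]
  if (is.null(ck)) stop("k = ", k, " not in the fit")
  M <- ck$matrix
  ord <- stats::hclust(stats::as.dist(1 - M), method = "ward.D2")$order
  graphics::image(M[ord, rev(ord)], axes = FALSE, useRaster = TRUE,
                  main = sprintf("consensus matrix, k = %d", k),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE), ...)
  invisible(x)
}
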