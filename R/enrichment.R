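# Three-statistic permutation gene-set enrichment with mean-rank fusion.
# For a two-group contrast, each gene set is scored by (i) a SAM-GS
# statistic (sum of squared regularized d-statistics), (ii) a
# Globaltest-style score statistic, and (iii) a robust aggregate (median
# absolute moderated t over the set). All three are referred to the
# permutation distribution of the sample labels by one shared engine; the
# per-method p-values are converted to ranks and fused by the mean rank.

#' SAM fudge factor s0
#'
#' The regularizing constant added to every gene's standard deviation in the
#' SAM d-statistic. Estimated as the median of the per-gene pooled standard
#' deviations (a simplified estimator; SAM's percentile-search minimizer is
#' deliberately not used, see the methods vignette).
#'
#' @param gene_sds per-gene pooled standard deviations (>= 10 genes).
#' @return the fudge factor.
#' @export
sam_fudge_s0 <- function(gene_sds) {
  if (length(gene_sds) < 10L) stop("need >= 10 genes to estimate s0")
  if (all(gene_sds == 0)) stop("all gene SDs are zero")
  stats::median(gene_sds)
}

.two_group_index <- function(group) {
  group <- if (is.factor(group)) droplevels(group) else factor(group, levels = unique(group))
  if (nlevels(group) != 2L) stop("exactly 2 groups required")
  list(i1 = which(group == levels(group)[1L]),
       i2 = which(group == levels(group)[2L]),
       levels = levels(group))
}

#' SAM-GS gene-set statistic
#'
#' SAMGS = sum over set members of d_i^2 with
#' d_i = (mean_1 - mean_2) / (s_i + s0), where s_i is the pooled
#' within-group standard deviation of gene i.
#'
#' @param x_set_log2 set-member genes x samples matrix (log2 scale).
#' @param group two-group labels (each group >= 2 samples).
#' @param s0 fudge factor (>= 0; must not be 0 when some s_i is 0).
#' @return the SAM-GS statistic.
#' @export
samgs_statistic <- function(x_set_log2, group, s0) {
  if (is.null(dim(x_set_log2))) x_set_log2 <- matrix(x_set_log2, nrow = 1L)
  if (nrow(x_set_log2) == 0L) stop("empty gene set")
  gi <- .two_group_index(group)
  if (length(gi$i1) < 2L || length(gi$i2) < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x_set_log2[, gi$i1, drop = FALSE])
  m2 <- rowMeans(x_set_log2[, gi$i2, drop = FALSE])
  dg <- length(gi$i1) + length(gi$i2) - 2L
  s2 <- (rowSums((x_set_log2[, gi$i1, drop = FALSE] - m1)^2) +
         rowSums((x_set_log2[, gi$i2, drop = FALSE] - m2)^2)) / dg
  s <- sqrt(s2)
  if (s0 < 0) stop("s0 must be >= 0")
  if (any(s + s0 == 0)) stop("zero denominator: gene SD and s0 both zero")
  sum(((m1 - m2) / (s + s0))^2)
}

#' Globaltest-style gene-set score statistic
#'
#' With y-tilde the centered binary outcome and each gene row centered,
#' Q = sum over set genes of (x_g . y_tilde)^2, divided by
#' (set size * sum(y_tilde^2)). Large Q indicates association between the
#' set's expression and the outcome; significance is assessed by
#' permutation (not the asymptotic distribution).
#'
#' @param x_set_log2 set-member genes x samples matrix (log2 scale).
#' @param group binary outcome (two groups).
#' @return the score statistic Q.
#' @export
globaltest_statistic <- function(x_set_log2, group) {
  if (is.null(dim(x_set_log2))) x_set_log2 <- matrix(x_set_log2, nrow = 1L)
  if (nrow(x_set_log2) == 0L) stop("empty gene set")
  gi <- .two_group_index(group)
  y <- as.numeric(seq_len(ncol(x_set_log2)) %in% gi$i1)
  yt <- y - mean(y)
  if (all(yt == 0)) stop("single-class outcome")
  xc <- x_set_log2 - rowMeans(x_set_log2)
  sum((xc %*% yt)^2) / (nrow(x_set_log2) * sum(yt^2))
}

#' Robust aggregate gene-set statistic
#'
#' The median of the per-gene absolute moderated t-statistics over the set.
#' This is the package's documented stand-in for the third enrichment method
#' of the procedure it implements, chosen to be robust to a single extreme
#' member gene; it is swappable behind the same permutation interface.
#'
#' @param x_set_log2 set-member genes x samples matrix (log2 scale).
#' @param group two-group labels.
#' @param prior optional list(d0, s2_0); when NULL, estimated from the
#'   supplied genes if there are >= 10, otherwise d0 = 0 (ordinary pooled t).
#' @return median |moderated t| over the set.
#' @export
robust_aggregate_statistic <- function(x_set_log2, group, prior = NULL) {
  if (is.null(dim(x_set_log2))) x_set_log2 <- matrix(x_set_log2, nrow = 1L)
  if (nrow(x_set_log2) == 0L) stop("empty gene set")
  if (is.null(prior) && nrow(x_set_log2) < 10L) prior <- list(d0 = 0)
  fit <- moderated_t(x_set_log2, group, prior = prior)
  stats::median(abs(fit$t))
}

#' Permutation p-value for any gene-set statistic
#'
#' Permutes the two-group sample labels and compares the observed statistic
#' to the permutation distribution (upper tail). When the total number of
#' distinct group-1 assignments choose(n, n1) is at most B, exhaustive
#' enumeration replaces random sampling (with a message) and the p-value is
#' the exact fraction of assignments with statistic >= observed. Otherwise
#' p = (1 + #{permuted >= observed}) / (B + 1).
#'
#' @param statistic_fn function(x, group) -> number.
#' @param x_set_log2 genes x samples matrix passed to `statistic_fn`.
#' @param group two-group labels.
#' @param B number of random permutations (>= 100).
#' @param seed integer seed (random mode only).
#' @return list with `p`, `observed`, `n_perm`, `exhaustive`.
#' @export
permutation_p <- function(statistic_fn, x_set_log2, group, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be >= 100")
  gi <- .two_group_index(group)
  n <- length(gi$i1) + length(gi$i2)
  n1 <- length(gi$i1)
  obs <- statistic_fn(x_set_log2, group)
  lv <- gi$levels
  total <- choose(n, n1)
  if (total <= B) {
    message("only ", total, " distinct label splits; using exhaustive enumeration")
    splits <- utils::combn(n, n1)
    stats <- apply(splits, 2L, function(idx) {
      g <- rep(lv[2L], n); g[idx] <- lv[1L]
      statistic_fn(x_set_log2, factor(g, levels = lv))
    })
    return(list(p = mean(stats >= obs - 1e-12), observed = obs,
                n_perm = total, exhaustive = TRUE))
  }
  set.seed(seed)
  stats <- vapply(seq_len(B), function(b) {
    g <- sample(as.character(rep(lv, c(n1, n - n1))))
    statistic_fn(x_set_log2, factor(g, levels = lv))
  }, numeric(1))
  list(p = (1 + sum(stats >= obs - 1e-12)) / (B + 1), observed = obs,
       n_perm = B, exhaustive = FALSE)
}

#' Fuse per-method enrichment p-values by mean rank
#'
#' Each method's p-values are converted to ascending ranks (ties get the
#' average rank); the mean of the per-method ranks orders the sets. Sets
#' with any missing p-value are excluded with a warning. A set passes the
#' filter when its mean rank is below `threshold`.
#'
#' @param p_table numeric matrix, sets x methods, rownames = set names.
#' @param threshold mean-rank filter threshold (default 100).
#' @return data.frame ordered by ascending mean rank: set, per-method
#'   ranks, `mean_rank`, `pass_filter`.
#' @export
mean_rank_combine <- function(p_table, threshold = 100) {
  p_table <- as.matrix(p_table)
  if (is.null(rownames(p_table)))
    rownames(p_table) <- as.character(seq_len(nrow(p_table)))
  bad <- apply(p_table, 1L, anyNA)
  if (any(bad)) {
    warning("excluding ", sum(bad), " set(s) with a missing method p-value: ",
            paste(rownames(p_table)[bad], collapse = ", "))
    p_table <- p_table[!bad, , drop = FALSE]
  }
  if (nrow(p_table) == 0L) stop("no set with complete p-values")
  ranks <- apply(p_table, 2L, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L,
                                           dimnames = list(rownames(p_table), colnames(p_table)))
  mr <- rowMeans(ranks)
  out <- data.frame(set = rownames(p_table), ranks, mean_rank = mr,
                    pass_filter = mr < threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$mean_rank, out$set), , drop = FALSE]
}

#' Signed proportion of significantly deregulated member genes
#'
#' p_up is the fraction of the set's genes (those present in the fit) that
#' are significant (BH-adjusted p < alpha) with positive fold change;
#' p_down analogously. Returns +p_up when up-regulation predominates
#' (p_up >= p_down), otherwise -p_down.
#'
#' @param set_genes character vector of member gene symbols.
#' @param de_result a `de_fit` (or data.frame with gene, log2fc, p_adj).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return signed proportion in [-1, 1], or NA (with a warning) when no set
#'   gene is present in the fit.
#' @export
direction_proportions <- function(set_genes, de_result, alpha = 0.05) {
  hit <- de_result[de_result$gene %in% set_genes, , drop = FALSE]
  if (nrow(hit) == 0L) {
    warning("no set gene present in the differential-expression result")
    return(NA_real_)
  }
  sig <- hit$p_adj < alpha
  p_up <- mean(sig & hit$log2fc > 0)
  p_down <- mean(sig & hit$log2fc < 0)
  if (p_up >= p_down) p_up else -p_down
}

# Shared permutation machinery for the full collection: computes, for the
# observed labels and every permutation, the per-gene group means, pooled
# variances and centered cross-products in one set of matrix products, then
# assembles the three statistics per set.
.perm_gene_quantities <- function(lx, ind, n1, n2) {
  dg <- n1 + n2 - 2L
  M1 <- (lx %*% ind) / n1
  M2 <- (lx %*% (1 - ind)) / n2
  E1 <- (lx^2) %*% ind
  E2 <- (lx^2) %*% (1 - ind)
  s2 <- (E1 - n1 * M1^2 + E2 - n2 * M2^2) / dg
  s2[s2 < 0] <- 0  # numeric guard
  diff <- M1 - M2
  list(diff = diff, s2 = s2, dg = dg)
}

#' Gene-set enrichment for a two-group contrast
#'
#' Runs the full procedure on an expression matrix: probes are collapsed to
#' genes (max-variance probe), the three set statistics are computed for the
#' observed labels and for B label permutations (shared permutations across
#' sets and methods, preserving group sizes), per-method permutation
#' p-values are fused by mean rank, and the signed direction proportion of
#' each set is annotated from a genome-wide moderated-t fit.
#'
#' @param x an `expr_matrix` (linear scale).
#' @param samples a `sample_table`.
#' @param groups length-2 character vector naming the contrast, e.g.
#'   `c("MSS-Y", "MSS-O")` (fold change is first minus second).
#' @param gene_sets a `gene_sets` collection.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param alpha BH threshold for the direction proportions (default 0.05).
#' @param mean_rank_threshold mean-rank filter threshold (default 100).
#' @param min_set_genes sets with fewer members present on the array are
#'   dropped with a warning (default 2).
#' @return object of class `enrichment_fit`: data.frame ordered by mean
#'   rank with columns set, category, n_genes, p_globaltest, p_samgs,
#'   p_robust, the three ranks, mean_rank, direction, pass_filter.
#' @export
run_enrichment <- function(x, samples, groups, gene_sets, B = 1000L, seed = 1L,
                           alpha = 0.05, mean_rank_threshold = 100,
                           min_set_genes = 2L) {
  validate_expression_matrix(x)
  stopifnot(inherits(gene_sets, "gene_sets"), length(groups) == 2L)
  keep <- samples$sample_id[samples$group %in% groups]
  if (length(keep) < 4L) stop("too few samples in the requested groups")
  xg <- collapse_to_genes(subset_expression(x, samples = keep))
  lx <- log2(xg$values)
  grp <- factor(as.character(samples$group[match(keep, samples$sample_id)]),
                levels = groups)
  n1 <- sum(grp == groups[1L]); n2 <- sum(grp == groups[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  n <- n1 + n2

  members <- lapply(gene_sets$sets, function(g) which(rownames(lx) %in% g))
  sizes <- lengths(members)
  drop <- sizes < min_set_genes
  if (any(drop)) {
    warning(sum(drop), " set(s) with < ", min_set_genes,
            " genes on the array dropped: ",
            paste(names(members)[drop], collapse = ", "))
    members <- members[!drop]
  }
  if (length(members) == 0L) stop("no testable gene set")

  total <- choose(n, n1)
  exhaustive <- total <= B
  ind_obs <- as.numeric(grp == groups[1L])
  if (exhaustive) {
    message("only ", total, " distinct label splits; exhaustive enumeration used")
    splits <- utils::combn(n, n1)
    ind <- matrix(0, n, total)
    ind[cbind(as.vector(splits), rep(seq_len(total), each = n1))] <- 1
    # ensure observed labeling is column 1 for indexing convenience
    obs_col <- which(colSums(abs(ind - ind_obs)) == 0)[1L]
    ind <- cbind(ind_obs, ind[, -obs_col, drop = FALSE])
  } else {
    set.seed(seed)
    ind <- cbind(ind_obs,
                 replicate(B, as.numeric(seq_len(n) %in% sample(n, n1))))
  }
  L <- ncol(ind)  # observed + permutations

  q <- .perm_gene_quantities(lx, ind, n1, n2)
  sds <- sqrt(q$s2)
  s0 <- apply(sds, 2L, stats::median)
  d <- q$diff / sweep(sds, 2L, s0, "+")
  d2 <- d^2
  # globaltest per-gene scores
  xc <- lx - rowMeans(lx)
  yt <- sweep(ind, 2L, colMeans(ind))
  z2 <- (xc %*% yt)^2
  den_y <- colSums(yt^2)
  # moderated t per labeling
  t2col <- matrix(NA_real_, nrow(lx), L)
  for (b in seq_len(L)) {
    pr <- estimate_variance_prior(q$s2[, b], q$dg)
    s2t <- if (is.infinite(pr$d0)) rep(pr$s2_0, nrow(lx))
           else (pr$d0 * pr$s2_0 + q$dg * q$s2[, b]) / (pr$d0 + q$dg)
    t2col[, b] <- abs(q$diff[, b]) / sqrt(s2t * (1 / n1 + 1 / n2))
  }

  stat_mat <- function(per_gene, combine) {
    vapply(members, function(idx) combine(per_gene[idx, , drop = FALSE]),
           numeric(L))
  }
  S_sam <- t(stat_mat(d2, function(m) colSums(m)))
  S_gt <- t(stat_mat(z2, function(m) colSums(m)))
  S_gt <- S_gt / lengths(members) / matrix(den_y, nrow(S_gt), L, byrow = TRUE)
  # rank-standardized robust aggregate: within each labeling the genes are
  # converted to genome-wide percentiles of |moderated t|, and the set
  # statistic is the median member percentile. Working on within-labeling
  # percentiles makes the statistic invariant to the labeling-level scale
  # and shape of the t distribution (which would otherwise couple all
  # sets' permutation p-values through the shared prior estimate).
  pct_col <- apply(t2col, 2L, rank) / nrow(t2col)
  S_rob <- t(stat_mat(pct_col, function(m) apply(m, 2L, stats::median)))

  perm_p <- function(S) {
    if (exhaustive) {
      rowMeans(S >= S[, 1L] - 1e-12)
    } else {
      (1 + rowSums(S[, -1L, drop = FALSE] >= S[, 1L] - 1e-12)) / (L - 1 + 1)
    }
  }
  p_tab <- cbind(globaltest = perm_p(S_gt), samgs = perm_p(S_sam),
                 robust = perm_p(S_rob))
  rownames(p_tab) <- names(members)
  fused <- mean_rank_combine(p_tab, threshold = mean_rank_threshold)
  names(fused)[names(fused) %in% c("globaltest", "samgs", "robust")] <-
    c("rank_globaltest", "rank_samgs", "rank_robust")

  de <- moderated_t(lx, grp)
  dir_prop <- vapply(fused$set, function(nm) {
    suppressWarnings(direction_proportions(rownames(lx)[members[[nm]]], de, alpha))
  }, numeric(1))
  out <- data.frame(
    set = fused$set,
    category = if (!is.null(gene_sets$category))
      unname(gene_sets$category[fused$set]) else NA_character_,
    n_genes = unname(lengths(members)[fused$set]),
    p_globaltest = unname(p_tab[fused$set, "globaltest"]),
    p_samgs = unname(p_tab[fused$set, "samgs"]),
    p_robust = unname(p_tab[fused$set, "robust"]),
    fused[, c("rank_globaltest", "rank_samgs", "rank_robust", "mean_rank",
              "pass_filter")],
    direction = dir_prop,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("enrichment_fit", "data.frame"),
            contrast = paste(groups, collapse = " vs "),
            n_perm = L - 1L, exhaustive = exhaustive, seed = seed)
}

#' @export
print.enrichment_fit <- function(x, n = 10L, ...) {
  cat(sprintf("enrichment_fit: %s; %d sets, %d permutations%s\n",
              attr(x, "contrast"), nrow(x), attr(x, "n_perm"),
              if (isTRUE(attr(x, "exhaustive"))) " (exhaustive)" else ""))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more sets\n")
  invisible(x)
}
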