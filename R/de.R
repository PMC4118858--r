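# Two-group differential expression with empirical-Bayes variance
# moderation. Per-gene pooled variances s2_g (dg = n1 + n2 - 2 df) are
# shrunk toward a prior s2_0 with d0 prior df; the hyperparameters are
# estimated by the method of moments on log s2 using digamma/trigamma
# identities for the log chi-squared distribution.

#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma, monotone and quadratic near the root;
#' used to recover the prior degrees of freedom from the excess variance of
#' log sample variances.
#'
#' @param x positive target value.
#' @return y with trigamma(y) = x.
#' @export
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the variance prior (d0, s2_0) across genes
#'
#' Method of moments on z_g = log s2_g. Under the hierarchical model
#' s2_g | sigma2_g ~ sigma2_g * chisq(dg)/dg and 1/sigma2_g ~
#' chisq(d0)/(d0 * s2_0), z has variance trigamma(dg/2) + trigamma(d0/2)
#' and mean log s2_0 + digamma(dg/2) - log(dg/2) - digamma(d0/2) +
#' log(d0/2). d0 solves trigamma(d0/2) = var(z) - trigamma(dg/2); when the
#' empirical variance does not exceed trigamma(dg/2) there is no detectable
#' gene-to-gene variance heterogeneity and d0 = Inf with s2_0 the bias-
#' corrected mean.
#'
#' @param s2 per-gene sample variances (>= 10 genes, not all zero).
#' @param dg residual degrees of freedom of each s2 (scalar).
#' @return list with `d0` (possibly `Inf`) and `s2_0`.
#' @export
estimate_variance_prior <- function(s2, dg) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 10L) stop("need >= 10 finite variances")
  if (all(s2 == 0)) stop("all variances are zero")
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  ez <- z - digamma(dg / 2) + log(dg / 2)
  vz <- stats::var(z)
  excess <- vz - trigamma(dg / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s2_0 = exp(mean(ez))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s2_0 <- exp(mean(ez) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s2_0 = s2_0)
}

#' Moderated two-group t-test
#'
#' For each gene: log2 fold change = mean(group1) - mean(group2) of log2
#' values; pooled within-group variance s2_g on dg = n1 + n2 - 2 df;
#' moderated variance s2_tilde = (d0 * s2_0 + dg * s2_g) / (d0 + dg);
#' t = lfc / sqrt(s2_tilde * (1/n1 + 1/n2)), two-sided p from the t
#' distribution with d0 + dg df (standard normal when d0 is infinite).
#' With d0 = 0 this is exactly the ordinary pooled-variance t-test.
#'
#' @param x_log2 genes x samples matrix of log2 expression.
#' @param group factor/character of length ncol with exactly 2 levels, each
#'   with >= 2 samples. The fold change is level1 minus level2 (levels in
#'   the order of `unique(group)` unless `group` is a factor).
#' @param prior optional list(d0, s2_0) to force the hyperparameters
#'   (e.g. `list(d0 = 0)` for the unmoderated limit); estimated from the
#'   data when `NULL`.
#' @return object of class `de_fit`: a data.frame (one row per gene:
#'   `gene`, `log2fc`, `s2`, `s2_tilde`, `t`, `df`, `p`, `p_adj`) with the
#'   prior in attributes `d0`, `s2_0`.
#' @export
moderated_t <- function(x_log2, group, prior = NULL) {
  group <- if (is.factor(group)) droplevels(group) else factor(group, levels = unique(group))
  if (nlevels(group) != 2L) stop("exactly 2 groups required")
  if (length(group) != ncol(x_log2)) stop("group length must match samples")
  i1 <- which(group == levels(group)[1L])
  i2 <- which(group == levels(group)[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x_log2[, i1, drop = FALSE])
  m2 <- rowMeans(x_log2[, i2, drop = FALSE])
  ss1 <- rowSums((x_log2[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x_log2[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / dg
  if (is.null(prior)) {
    prior <- estimate_variance_prior(s2, dg)
  } else {
    if (is.null(prior$s2_0)) {
      prior$s2_0 <- if (is.infinite(prior$d0))
        estimate_variance_prior(s2, dg)$s2_0 else stats::median(s2)
    }
  }
  d0 <- prior$d0; s2_0 <- prior$s2_0
  s2_tilde <- if (is.infinite(d0)) rep(s2_0, length(s2))
              else (d0 * s2_0 + dg * s2) / (d0 + dg)
  lfc <- m1 - m2
  tval <- lfc / sqrt(s2_tilde * (1 / n1 + 1 / n2))
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tval))
       else 2 * stats::pt(-abs(tval), df = df_total)
  genes <- rownames(x_log2)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(x_log2)))
  out <- data.frame(gene = genes, log2fc = lfc, s2 = s2, s2_tilde = s2_tilde,
                    t = tval, df = df_total, p = p, p_adj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("de_fit", "data.frame"),
            d0 = d0, s2_0 = s2_0, dg = dg, n = c(n1, n2),
            contrast = paste(levels(group), collapse = " vs "))
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("de_fit: %s, %d genes; prior d0 = %s, s2_0 = %.4g\n",
              attr(x, "contrast"), nrow(x),
              format(attr(x, "d0"), digits = 4), attr(x, "s2_0")))
  cat(sprintf("  BH < 0.05: %d genes; raw p < 0.001: %d genes\n",
              sum(x$p_adj < 0.05), sum(x$p < 0.001)))
  invisible(x)
}

#' @export
summary.de_fit <- function(object, alpha = 0.05, ...) {
  sig <- object$p_adj < alpha
  list(contrast = attr(object, "contrast"),
       n_genes = nrow(object), d0 = attr(object, "d0"),
       s2_0 = attr(object, "s2_0"),
       n_significant = sum(sig),
       n_up = sum(sig & object$log2fc > 0),
       n_down = sum(sig & object$log2fc < 0))
}

#' Volcano plot of a moderated-t fit
#'
#' @param x a `de_fit`.
#' @param alpha BH threshold used to highlight significant genes.
#' @param ... passed to [graphics::plot()].
#' @export
plot.de_fit <- function(x, alpha = 0.05, ...) {
  sig <- x$p_adj < alpha
  graphics::plot(x$log2fc, -log10(x$p),
                 col = ifelse(sig, "firebrick", "grey50"),
                 pch = 20, xlab = "log2 fold change",
                 ylab = "-log10 p", main = attr(x, "contrast"), ...)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the standard BH step-up procedure
#' (monotone in the raw p-values, capped at 1, original order restored).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
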