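test_that("SAM fudge factor is the median pooled SD", {
  expect_equal(sam_fudge_s0(rep(3.3, 12)), 3.3)
  expect_equal(sam_fudge_s0(1:99), 50)
  set.seed(4); v <- runif(25)
  expect_equal(sam_fudge_s0(v), sam_fudge_s0(sample(v)))
  expect_error(sam_fudge_s0(rep(0, 20)), "zero")
  expect_error(sam_fudge_s0(1:5), ">= 10")
})

test_that("SAM-GS statistic equals the sum of squared d-statistics", {
  # hand-built toy: gene 1 has d = 2, gene 2 has d = -1 (s0 = 0)
  x <- rbind(g1 = c(3, 2, 1, 1, 0, -1),
             g2 = c(0, 1, -1, 1, 2, 0))
  grp <- rep(c("A", "B"), each = 3)
  expect_equal(samgs_statistic(x, grp, s0 = 0), 2^2 + (-1)^2)
  # equal means for every gene -> 0
  x0 <- rbind(c(1, 2, 3, 1, 2, 3), c(5, 6, 7, 7, 6, 5))
  expect_equal(samgs_statistic(x0, grp, s0 = 0.1), 0)
  # additivity: a d = 0 gene changes nothing
  expect_equal(samgs_statistic(rbind(x, x0[1, ]), grp, s0 = 0),
               samgs_statistic(x, grp, s0 = 0))
  expect_error(samgs_statistic(x[0, , drop = FALSE], grp, 0), "empty")
})

test_that("Globaltest score matches its quadratic form on a toy", {
  grp <- c("A", "A", "B", "B")
  y <- c(1, 1, 0, 0); yt <- y - mean(y)
  # single gene proportional to the centered outcome
  x <- matrix(3 * yt, 1, 4)
  q <- globaltest_statistic(x, grp)
  xc <- x - mean(x)
  expect_equal(q, sum((xc %*% yt)^2) / (1 * sum(yt^2)))
  # orthogonal gene -> 0
  xo <- matrix(c(1, -1, 1, -1), 1, 4)
  expect_equal(globaltest_statistic(xo, grp), 0)
  # invariance to adding a constant to a gene row
  x2 <- rbind(c(0.3, 1.2, -0.5, 0.1), c(2, 0, 1, 1))
  expect_equal(globaltest_statistic(x2, grp),
               globaltest_statistic(x2 + 100, grp), tolerance = 1e-9)
  expect_error(globaltest_statistic(x2, c("A", "A", "A", "A")), "2 groups")
})

test_that("robust aggregate concentrates near the null median |t| and resists outliers", {
  set.seed(12)
  n <- 60
  x <- matrix(rnorm(1001 * n), 1001, n)
  grp <- rep(c("A", "B"), each = n / 2)
  stat <- robust_aggregate_statistic(x, grp)
  expect_equal(stat, qnorm(0.75), tolerance = 0.1)  # median|Z| ~ 0.674

  # one extreme gene among 11 nulls barely moves the median
  set.seed(13)
  xs <- matrix(rnorm(11 * 20), 11, 20)
  g20 <- rep(c("A", "B"), each = 10)
  base <- robust_aggregate_statistic(xs, g20, prior = list(d0 = 0))
  xs_out <- rbind(xs, c(rep(10, 10), rep(-10, 10)))
  pert <- robust_aggregate_statistic(xs_out, g20, prior = list(d0 = 0))
  expect_lt(abs(pert - base), 1.0)

  # singleton set: |moderated t| of that gene
  one <- matrix(rnorm(20), 1, 20)
  fit <- moderated_t(one, g20, prior = list(d0 = 0))
  expect_equal(robust_aggregate_statistic(one, g20, prior = list(d0 = 0)),
               abs(fit$t[1]))
})

test_that("permutation engine matches exhaustive 3v3 enumeration", {
  set.seed(9)
  x <- matrix(rnorm(5 * 6), 5, 6)
  x[, 1:3] <- x[, 1:3] + 1
  grp <- rep(c("A", "B"), each = 3)
  stat_fn <- function(m, g) samgs_statistic(m, g, s0 = 0.5)
  res <- suppressMessages(permutation_p(stat_fn, x, grp, B = 100))
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 20)
  # independent enumeration over all 20 assignments of 3 samples to group A
  obs <- stat_fn(x, factor(grp, levels = c("A", "B")))
  stats <- apply(combn(6, 3), 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    stat_fn(x, factor(g, levels = c("A", "B")))
  })
  expect_equal(res$p, mean(stats >= obs))
  expect_equal(res$observed, obs)
})

test_that("observed statistic below all permutations gives p = 1", {
  # observed group means equal for every gene: SAM-GS observed = 0, its
  # global minimum, so every permutation is at least as large
  half <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 1, 3, 5))
  x <- cbind(half, half[, 6:1])
  grp <- rep(c("A", "B"), each = 6)
  stat_fn <- function(m, g) samgs_statistic(m, g, s0 = 0.5)
  res <- permutation_p(stat_fn, x, grp, B = 900, seed = 3)
  expect_equal(res$p, 1)
  expect_error(permutation_p(stat_fn, x, grp, B = 10), ">= 100")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(77)
  n <- 30; n_genes <- 800; B <- 199; n_sets <- 500; set_size <- 15
  co_x <- expression_matrix(2^matrix(rnorm(n_genes * n, 7, 0.7), n_genes, n),
                            probe_ids = sprintf("G%04d", 1:n_genes))
  st <- validate_sample_table(data.frame(
    sample_id = co_x$sample_ids,
    group = rep(c("MSS-Y", "MSS-O"), each = n / 2)))
  sets <- lapply(seq_len(n_sets), function(i)
    sprintf("G%04d", sample(n_genes, set_size)))
  names(sets) <- sprintf("S%03d", seq_len(n_sets))
  gs <- gene_set_collection(sets)
  fit <- run_enrichment(co_x, st, c("MSS-Y", "MSS-O"), gs, B = B, seed = 5)
  for (col in c("p_globaltest", "p_samgs", "p_robust")) {
    ks <- suppressWarnings(ks.test(fit[[col]], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("mean-rank fusion reproduces hand-ranked orderings", {
  # three methods in perfect agreement: fused order equals each method's
  p_agree <- cbind(m1 = c(0.9, 0.01, 0.5), m2 = c(0.8, 0.02, 0.4),
                   m3 = c(0.7, 0.03, 0.3))
  rownames(p_agree) <- c("s1", "s2", "s3")
  out <- mean_rank_combine(p_agree)
  expect_identical(out$set, c("s2", "s3", "s1"))
  expect_equal(out$mean_rank, c(1, 2, 3))

  # hand ranking with disagreement
  p <- rbind(set1 = c(0.01, 0.5, 0.9),
             set2 = c(0.5, 0.01, 0.01),
             set3 = c(0.9, 0.9, 0.5))
  out2 <- mean_rank_combine(p)
  # per-method ascending ranks: set1 (1,2,3); set2 (2,1,1); set3 (3,3,2)
  expect_identical(out2$set, c("set2", "set1", "set3"))
  expect_equal(out2$mean_rank[out2$set == "set1"], mean(c(1, 2, 3)))
  expect_equal(out2$mean_rank[out2$set == "set2"], mean(c(2, 1, 1)))
  expect_equal(out2$mean_rank[out2$set == "set3"], mean(c(3, 3, 2)))
  expect_true(all(out2$pass_filter))  # threshold 100, 3 sets

  # average ranks on ties
  p_tie <- rbind(a = c(0.5, 0.2, 0.1), b = c(0.5, 0.3, 0.2))
  outt <- mean_rank_combine(p_tie)
  expect_equal(sort(outt$mean_rank), sort(c(mean(c(1.5, 1, 1)),
                                            mean(c(1.5, 2, 2)))))

  # monotone-transform invariance for a single method's p-values
  p_mono <- p; p_mono[, 2] <- sqrt(p_mono[, 2])
  expect_equal(mean_rank_combine(p_mono)$mean_rank, out2$mean_rank)

  # missing p excludes the set with a warning
  p_na <- p; p_na["set3", 2] <- NA
  expect_warning(out3 <- mean_rank_combine(p_na), "missing")
  expect_identical(sort(out3$set), c("set1", "set2"))
})

test_that("direction proportions count signed significant members", {
  de <- data.frame(gene = sprintf("g%02d", 1:10),
                   log2fc = c(2, 1.5, 1, -2, rep(0.1, 6)),
                   p_adj = c(0.01, 0.01, 0.01, 0.01, rep(0.9, 6)))
  expect_equal(direction_proportions(de$gene, de), 0.3)   # 3 up, 1 down of 10
  de_up <- transform(de, log2fc = abs(log2fc), p_adj = 0.001)
  expect_equal(direction_proportions(de$gene, de_up), 1.0)
  de_null <- transform(de, p_adj = 0.9)
  expect_equal(direction_proportions(de$gene, de_null), 0)
  expect_warning(res <- direction_proportions("absent", de), "no set gene")
  expect_true(is.na(res))
  # predominance of down-regulation flips the sign
  de_dn <- transform(de, log2fc = -abs(log2fc))
  expect_equal(direction_proportions(de$gene, de_dn), -0.4)
})

test_that("planted pathways earn the best mean ranks on synthetic cohorts", {
  wins <- 0L
  for (s in 1:10) {
    co <- generate_cohort(cohort_config(seed = s))
    fit <- suppressWarnings(run_enrichment(
      co$expr, co$samples, c("MSS-Y", "MSS-O"), co$gene_sets,
      B = 199, seed = s))
    if (fit$set[1] %in% co$truth$enriched_sets) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("enrichment ranks are complete and the filter flag is consistent", {
  co <- generate_cohort(cohort_config(
    group_sizes = c("MSS-Y" = 10L, "MSS-O" = 10L, "MSI-Y" = 4L, "MSI-O" = 4L),
    n_genes = 400L, n_signature = 20L, set_size = 10L, n_null_sets = 10L,
    seed = 3L))
  fit <- suppressWarnings(run_enrichment(
    co$expr, co$samples, c("MSS-Y", "MSS-O"), co$gene_sets,
    B = 149, seed = 2, mean_rank_threshold = 5))
  n_sets <- nrow(fit)
  for (rk in c("rank_globaltest", "rank_samgs", "rank_robust")) {
    expect_equal(sort(round(sum(fit[[rk]]))), sum(seq_len(n_sets)))
  }
  expect_equal(fit$mean_rank,
               unname(rowMeans(fit[, c("rank_globaltest", "rank_samgs",
                                       "rank_robust")])))
  expect_identical(fit$pass_filter, fit$mean_rank < 5)
  expect_true(all(fit$p_samgs >= 1 / 150 & fit$p_samgs <= 1))
})
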