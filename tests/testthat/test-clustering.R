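test_that("Pearson distance has the right geometry", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  D <- pearson_distance(x)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["a", "b"], 0)        # perfectly correlated
  expect_equal(D["a", "c"], 2)        # perfectly anti-correlated
  expect_true(isSymmetric(D))

  # hand-computed correlation 0.5 between two 3-vectors
  y <- cbind(s1 = c(1, 0, -1), s2 = c(1, -1, 0), s3 = c(5, 1, 2))
  r12 <- cor(y[, 1], y[, 2])
  expect_equal(pearson_distance(y)["s1", "s2"], 1 - r12)
  expect_equal(r12, 0.5)

  z <- cbind(s1 = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(pearson_distance(z), "flat")
})

test_that("Ward dendrogram matches a naive O(n^3) Ward oracle", {
  set.seed(21)
  pts <- rbind(matrix(rnorm(6, 0, 0.2), 3), matrix(rnorm(6, 4, 0.2), 3))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  dend <- ward_dendrogram(D)
  oracle <- naive_ward_oracle(D)
  expect_equal(sort(dend$height), sort(oracle$heights), tolerance = 1e-10)
  # partitions after each agglomeration step match the oracle's merge order
  oracle_partition <- function(n_merges) {
    lab <- seq_len(6)
    for (m in oracle$merges[seq_len(n_merges)]) lab[lab %in% lab[m]] <- min(lab[m])
    match(lab, unique(lab))
  }
  for (k in c(2, 3, 4)) {
    expect_equal(adjusted_rand(setNames(cutree(dend, k), sprintf("s%d", 1:6)),
                               setNames(oracle_partition(6 - k),
                                        sprintf("s%d", 1:6))), 1)
  }
  # separable case: k=2 cut equals ground truth; k=n gives singletons
  expect_equal(unname(cutree(dend, 2)), rep(c(1, 2), each = 3))
  expect_length(unique(cut_partition(dend, 6)), 6L)
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(ward_dendrogram(Dbad), "symmetric")
})

test_that("consensus matrix equals the co-classification fraction", {
  p1 <- setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  p2 <- setNames(c(1, 2, 1, 2), c("a", "b", "c", "d"))
  p3 <- setNames(c(1, 2, 2, 1), c("a", "b", "c", "d"))
  M <- consensus_matrix(list(p1, p2, p3))
  off <- M[upper.tri(M)]
  expect_true(all(abs(off - 1 / 3) < 1e-12))  # enumeration oracle
  expect_equal(unname(diag(M)), rep(1, 4))

  M1 <- consensus_matrix(list(p1))
  expect_equal(unname(M1["a", "b"]), 1)
  expect_equal(unname(M1["a", "c"]), 0)

  M7 <- consensus_matrix(rep(list(p1), 7))
  expect_true(all(M7 %in% c(0, 1)))

  expect_error(consensus_matrix(list(p1, p2[1:3])), "different sample sets")
})

test_that("consensus partition recovers blocks and matches brute force", {
  p1 <- setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  M <- consensus_matrix(rep(list(p1), 3))
  expect_equal(adjusted_rand(consensus_partition(M, 2), p1), 1)

  # noisy 8-sample consensus: Ward extraction attains the exhaustive
  # best-2-partition objective (max average within-cluster consensus)
  set.seed(1)
  truth <- setNames(rep(1:2, each = 4), letters[1:8])
  parts <- lapply(1:7, function(i) {
    lab <- truth
    flip <- sample(8, 1)
    lab[flip] <- 3 - lab[flip]
    lab
  })
  M8 <- consensus_matrix(parts)
  ours <- consensus_partition(M8, 2)
  best <- max(vapply(all_two_partitions(8),
                     function(lab) consensus_objective(M8, lab), numeric(1)))
  expect_equal(consensus_objective(M8, ours[letters[1:8]]), best,
               tolerance = 1e-12)
  expect_error(consensus_partition(M8, 9), "exceeds")
})

test_that("adjusted Rand index matches the contingency-table formula", {
  p <- setNames(c(1, 1, 2, 2), letters[1:4])
  q <- setNames(c(1, 2, 1, 2), letters[1:4])
  expect_equal(adjusted_rand(p, p), 1)
  expect_equal(adjusted_rand(p, q), -0.5)     # hand computation
  expect_equal(adjusted_rand(p, q), adjusted_rand(q, p))
  relab <- setNames(c(2, 2, 1, 1), letters[1:4])
  expect_equal(adjusted_rand(p, relab), 1)
  expect_error(adjusted_rand(p, q[1:3]), "different sample sets")
})

test_that("closest-dendrogram selection maximizes ARI with tie rule", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(8, 0, 0.3), 4), matrix(rnorm(8, 5, 0.3), 4))
  rownames(pts) <- letters[1:8]
  good <- ward_dendrogram(as.matrix(dist(pts)))
  scrambled <- pts[c(5, 2, 7, 4, 1, 6, 3, 8), ]
  rownames(scrambled) <- letters[1:8]
  bad <- ward_dendrogram(as.matrix(dist(scrambled)))
  cons <- cut_partition(good, 2)

  sel <- select_closest_dendrogram(list(bad, good), cons, 2)
  expect_equal(sel$index, 2L)
  expect_equal(max(sel$ari), 1)
  # tie -> lowest index
  expect_message(sel2 <- select_closest_dendrogram(list(bad, good, good),
                                                   cons, 2), "tie")
  expect_equal(sel2$index, 2L)
  expect_equal(select_closest_dendrogram(list(good), cons, 2)$index, 1L)
})

test_that("annotation association flags the partition-aligned variable", {
  set.seed(10)
  co <- generate_cohort(cohort_config(
    group_sizes = c("MSS-Y" = 20L, "MSS-O" = 20L, "MSI-Y" = 10L, "MSI-O" = 10L),
    n_genes = 400L, n_signature = 20L, seed = 6L))
  part <- setNames(as.integer(co$samples$group), co$samples$sample_id)
  st <- co$samples
  st$mirror <- as.character(co$samples$group)   # equals the partition
  st$constant <- "x"
  expect_warning(
    tab <- associate_annotations(part, st, c("mirror", "BRAF", "constant")),
    "single level")
  # Monte-Carlo r x c Fisher bottoms out at 1/(B+1): the aligned variable
  # must sit at that resolution floor
  expect_lte(tab$p[tab$variable == "mirror"], 1 / (2e4 + 1) + 1e-12)
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("full consensus clustering recovers planted structure end to end", {
  co <- generate_cohort(cohort_config(delta = 2.0, seed = 19L))
  f <- filter_params()
  xe <- subset_expression(co$expr, probes = filter_expressed(co$expr, f))
  xv <- subset_expression(xe, probes = filter_high_variance(xe, f))
  lists <- build_variant_lists(xv, f)
  expect_length(lists, 7L)
  fit <- suppressMessages(consensus_cluster(co$expr, lists, k_range = c(2, 4)))
  expect_equal(adjusted_rand(fit$consensus$k4$partition, co$truth$partition), 1)
  mmr <- setNames(as.integer(factor(co$truth$mmr)), names(co$truth$mmr))
  expect_equal(adjusted_rand(fit$consensus$k2$partition, mmr), 1)
  # consensus matrix entries are multiples of 1/7
  M <- fit$consensus$k4$matrix
  expect_true(all(abs(M * 7 - round(M * 7)) < 1e-9))
})
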