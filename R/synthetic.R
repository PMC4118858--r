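# Synthetic four-group cohort generator. Emulates the statistical structure
# of an age x mismatch-repair stratified colorectal tumor cohort: group sizes
# {MSS-Y 39, MSS-O 36, MSI-Y 9, MSI-O 14}, log-normal expression with planted
# group signatures, Table-1/2-style categorical covariates and mutation /
# CIMP-marker states, and exponential survival with uniform censoring.

#' Default configuration for the synthetic cohort generator
#'
#' The expression model on the log2 scale is
#' `baseline_g + shift(g, group) + Normal(0, noise_sd)`, exponentiated to
#' linear intensities. Signature structure is hierarchical, mirroring the
#' biology the pipeline is built around: the mismatch-repair (MSI vs MSS)
#' axis carries the largest transcriptional signature, each of the four
#' groups has its own moderate signature, and age carries a smaller nested
#' signature. Covariate, mutation and CIMP-marker probabilities default to
#' the observed proportions of the motivating cohort so that the
#' clinico-molecular statistics layer has realistic group-dependent inputs.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param n_genes total number of genes (probes map 1:1 to genes here).
#' @param n_signature number of signature genes per group block.
#' @param delta signature effect size in log2 units. The MMR block uses
#'   `delta`, per-group blocks `delta`, the age block `delta / 2`.
#' @param mmr_signature_factor size of EACH of the two mismatch-repair-axis
#'   blocks (genes up in MSI, genes up in MSS) relative to `n_signature`
#'   (default 2, making the MMR axis the dominant transcriptional split).
#' @param noise_sd residual SD on the log2 scale.
#' @param baseline_mean,baseline_sd per-gene log2 baseline distribution.
#' @param covariate_probs named list; per covariate a levels x groups
#'   probability matrix.
#' @param mutation_probs named list; per gene, `p` (probability mutated per
#'   group) and `miss` (probability the state is unassessed per group).
#' @param cimp_marker_prob per-group probability that any one of the five
#'   CIMP marker promoters is methylated (markers independent given group).
#' @param cimp_missing_prob probability a marker panel is unassessed.
#' @param bcat_activation_prob,bcat_missing_prob per-group probability of
#'   beta-catenin activation (nuclear staining > 50%) and of a missing stain.
#' @param hazard per-group exponential hazard (events per month).
#' @param censor_max censoring times are Uniform(0, censor_max) months.
#' @param set_size member count of each planted / null gene set.
#' @param n_null_sets number of size-matched null gene sets.
#' @param seed integer seed making the whole cohort reproducible.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("MSS-Y" = 39L, "MSS-O" = 36L,
                                          "MSI-Y" = 9L, "MSI-O" = 14L),
                          n_genes = 2000L,
                          n_signature = 100L,
                          delta = 1.5,
                          mmr_signature_factor = 2,
                          noise_sd = 0.7,
                          baseline_mean = 7, baseline_sd = 1.5,
                          covariate_probs = default_covariate_probs(),
                          mutation_probs = default_mutation_probs(),
                          cimp_marker_prob = c("MSS-Y" = 0.02, "MSS-O" = 0.32,
                                               "MSI-Y" = 0.02, "MSI-O" = 0.63),
                          cimp_missing_prob = 0.03,
                          bcat_activation_prob = c("MSS-Y" = 17 / 39, "MSS-O" = 5 / 33,
                                                   "MSI-Y" = 0.10, "MSI-O" = 0.10),
                          bcat_missing_prob = c("MSS-Y" = 0, "MSS-O" = 3 / 36,
                                                "MSI-Y" = 1, "MSI-O" = 1),
                          hazard = c("MSS-Y" = -log(0.69) / 60, "MSS-O" = -log(0.42) / 60,
                                     "MSI-Y" = -log(0.69) / 60, "MSI-O" = -log(0.60) / 60),
                          censor_max = 120,
                          set_size = 20L,
                          n_null_sets = 50L,
                          seed = 1L) {
  stopifnot(all(group_sizes >= 2L), delta >= 0, noise_sd > 0,
            all(names(group_sizes) == GROUP_LEVELS))
  for (cv in covariate_probs) {
    if (any(cv < 0 | cv > 1)) stop("covariate probabilities must lie in [0,1]")
    if (any(abs(colSums(cv) - 1) > 1e-8))
      stop("covariate probabilities must sum to 1 per group")
  }
  cfg <- list(group_sizes = group_sizes, n_genes = as.integer(n_genes),
              n_signature = as.integer(n_signature), delta = delta,
              mmr_signature_factor = mmr_signature_factor,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, covariate_probs = covariate_probs,
              mutation_probs = mutation_probs,
              cimp_marker_prob = cimp_marker_prob,
              cimp_missing_prob = cimp_missing_prob,
              bcat_activation_prob = bcat_activation_prob,
              bcat_missing_prob = bcat_missing_prob,
              hazard = hazard, censor_max = censor_max,
              set_size = as.integer(set_size),
              n_null_sets = as.integer(n_null_sets), seed = as.integer(seed))
  n_sig_total <- n_signature * (4L + 2L * mmr_signature_factor) +
    ceiling(n_signature / 2)
  if (n_sig_total > n_genes)
    stop(sprintf("signature genes (%d) exceed n_genes (%d)", n_sig_total, n_genes))
  class(cfg) <- "cohort_config"
  cfg
}

#' Default per-group categorical covariate probabilities
#'
#' Observed proportions of the motivating cohort (tumor location, UICC stage,
#' synchronous adenoma, family history of CRC, metastatic sites).
#'
#' @return named list of levels x groups probability matrices.
#' @export
default_covariate_probs <- function() {
  g <- GROUP_LEVELS
  m <- function(v, lev) {
    out <- matrix(v, nrow = length(lev), dimnames = list(lev, g))
    sweep(out, 2L, colSums(out), "/")
  }
  list(
    tumor_location = m(c(6, 16, 16, 1,   17, 16, 3, 0,   5, 4, 0, 0,   13, 1, 0, 0),
                       c("right", "left", "rectum", "multiple")),
    stage = m(c(2, 2, 11, 8, 16,   2, 2, 10, 8, 14,   0, 3, 1, 2, 3,   0, 1, 9, 4, 0),
              c("0", "I", "II", "III", "IV")),
    synchronous_adenoma = m(c(3, 36,   12, 24,   0, 9,   3, 11), c("yes", "no")),
    family_history = m(c(4, 11, 24,   3, 0, 33,   2, 1, 6,   2, 2, 10),
                       c("first_degree", "second_degree", "none")),
    metastatic_sites = m(c(23, 7, 9,   22, 12, 2,   6, 3, 0,   14, 0, 0),
                         c("none", "unique", "multiple")))
}

#' Default per-group mutation probabilities
#'
#' Observed mutation frequencies (and unassessed fractions) of the motivating
#' cohort for KRAS, BRAF V600E, TP53 and PIK3CA. BRAF mutations are absent in
#' both young groups.
#'
#' @return named list; per gene a list with `p` and `miss` per-group vectors.
#' @export
default_mutation_probs <- function() {
  g <- GROUP_LEVELS
  v <- function(x) stats::setNames(x, g)
  list(
    KRAS = list(p = v(c(14 / 38, 16 / 36, 3 / 9, 4 / 14)),
                miss = v(c(1 / 39, 0, 0, 0))),
    BRAF = list(p = v(c(0, 5 / 36, 0, 5 / 14)), miss = v(rep(0, 4))),
    TP53 = list(p = v(c(17 / 39, 17 / 36, 0, 5 / 14)), miss = v(rep(0, 4))),
    PIK3CA = list(p = v(c(5 / 24, 2 / 34, 4 / 5, 3 / 11)),
                  miss = v(c(15 / 39, 2 / 36, 4 / 9, 3 / 14))))
}

.sig_layout <- function(cfg) {
  n_mmr <- cfg$n_signature * cfg$mmr_signature_factor
  n_age <- ceiling(cfg$n_signature / 2)
  idx <- 0L
  take <- function(n) {
    out <- seq.int(idx + 1L, idx + n)
    idx <<- idx + n
    out
  }
  list(msi_up = take(n_mmr), mss_up = take(n_mmr), age = take(n_age),
       `MSS-Y` = take(cfg$n_signature), `MSS-O` = take(cfg$n_signature),
       `MSI-Y` = take(cfg$n_signature), `MSI-O` = take(cfg$n_signature))
}

#' Generate a synthetic cohort
#'
#' Draws an expression matrix, a sample annotation table, a gene-set
#' collection (planted signature sets plus size-matched null sets) and the
#' ground truth (true partition, differential-expression indicators for the
#' MSS-Y vs MSS-O contrast, per-pathway enrichment indicators). Output is
#' bit-identical for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `expr`
#'   (`expr_matrix`), `samples` (`sample_table`), `gene_sets` (`gene_sets`)
#'   and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- factor(rep(GROUP_LEVELS, times = config$group_sizes),
                   levels = GROUP_LEVELS)
  n <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  # expression: log2 = baseline + signature shift + noise
  lay <- .sig_layout(config)
  shift <- matrix(0, config$n_genes, 4L, dimnames = list(NULL, GROUP_LEVELS))
  shift[lay$msi_up, c("MSI-Y", "MSI-O")] <- 1.5 * config$delta
  shift[lay$mss_up, c("MSS-Y", "MSS-O")] <- 1.5 * config$delta
  shift[lay$age, c("MSS-Y", "MSI-Y")] <- config$delta / 2
  for (g in GROUP_LEVELS) shift[lay[[g]], g] <- config$delta
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  log2x <- baseline + shift[, as.integer(groups)] +
    matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd), config$n_genes, n)
  expr <- expression_matrix(2^log2x, probe_ids = gene_ids,
                            gene_symbols = gene_ids, sample_ids = sample_ids)

  # clinical annotation
  age <- numeric(n)
  age_pars <- list("MSS-Y" = c(39.1, 5.8, 18, 45), "MSS-O" = c(71.2, 7.3, 61, 95),
                   "MSI-Y" = c(36.7, 4.0, 18, 45), "MSI-O" = c(74.6, 9.2, 61, 95))
  for (g in GROUP_LEVELS) {
    i <- which(groups == g)
    p <- age_pars[[g]]
    age[i] <- pmin(p[4], pmax(p[3], round(stats::rnorm(length(i), p[1], p[2]), 1)))
  }
  df <- data.frame(sample_id = sample_ids, group = as.character(groups),
                   age_years = age, stringsAsFactors = FALSE)
  for (cv in names(config$covariate_probs)) {
    df[[cv]] <- .draw_categorical(groups, config$covariate_probs[[cv]])
  }
  for (mg in names(config$mutation_probs)) {
    mp <- config$mutation_probs[[mg]]
    st <- ifelse(stats::runif(n) < mp$p[as.integer(groups)], "mutated", "wild-type")
    st[stats::runif(n) < mp$miss[as.integer(groups)]] <- NA
    df[[mg]] <- st
  }
  for (mk in CIMP_MARKERS) {
    v <- as.numeric(stats::runif(n) < config$cimp_marker_prob[as.integer(groups)])
    v[stats::runif(n) < config$cimp_missing_prob] <- NA
    df[[paste0("cimp_", mk)]] <- v
  }
  act <- stats::runif(n) < config$bcat_activation_prob[as.integer(groups)]
  pct <- ifelse(act, stats::runif(n, 55, 95), stats::runif(n, 0, 45))
  pct[stats::runif(n) < config$bcat_missing_prob[as.integer(groups)]] <- NA
  df$bcat_nuclear_pct <- round(pct)
  ev_time <- stats::rexp(n, rate = config$hazard[as.integer(groups)])
  cens <- stats::runif(n, 0, config$censor_max)
  df$survival_time <- round(pmin(ev_time, cens), 2)
  df$event <- as.integer(ev_time <= cens)
  samples <- validate_sample_table(df)

  # gene sets: planted sets drawn from signature blocks, null sets from
  # non-signature genes, all of equal size
  sig_all <- unlist(lay)
  planted_names <- c("PLANTED_MSI_AXIS", "PLANTED_MSS_AXIS", "PLANTED_AGE",
                     paste0("PLANTED_", sub("-", "_", GROUP_LEVELS)))
  planted_blocks <- c(lay["msi_up"], lay["mss_up"], lay["age"], lay[GROUP_LEVELS])
  sets <- list()
  for (i in seq_along(planted_blocks)) {
    blk <- planted_blocks[[i]]
    sets[[planted_names[i]]] <-
      gene_ids[sort(sample(blk, min(config$set_size, length(blk))))]
  }
  null_pool <- setdiff(seq_len(config$n_genes), sig_all)
  if (length(null_pool) < config$set_size)
    stop(sprintf("only %d non-signature genes available for null sets of size %d; increase n_genes or lower set_size",
                 length(null_pool), config$set_size))
  for (j in seq_len(config$n_null_sets)) {
    sets[[sprintf("NULL_SET_%02d", j)]] <-
      gene_ids[sort(sample(null_pool, config$set_size))]
  }
  gs <- gene_set_collection(sets,
    category = stats::setNames(c(rep("planted", length(planted_names)),
                                 rep("null", config$n_null_sets)), names(sets)))

  # ground truth for the MSS-Y vs MSS-O contrast
  lfc <- shift[, "MSS-Y"] - shift[, "MSS-O"]
  de_genes <- gene_ids[lfc != 0]
  enriched <- vapply(names(sets), function(nm) {
    mean(sets[[nm]] %in% de_genes) > 0.5
  }, logical(1))
  truth <- list(
    partition = stats::setNames(as.integer(groups), sample_ids),
    mmr = stats::setNames(ifelse(groups %in% c("MSI-Y", "MSI-O"), "MSI", "MSS"),
                          sample_ids),
    de_log2fc = stats::setNames(lfc, gene_ids),
    de_genes = de_genes,
    signature_blocks = lapply(lay, function(i) gene_ids[i]),
    enriched_sets = names(sets)[enriched])
  structure(list(expr = expr, samples = samples, gene_sets = gs,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

.draw_categorical <- function(groups, prob_matrix) {
  out <- character(length(groups))
  for (g in levels(groups)) {
    i <- which(groups == g)
    out[i] <- sample(rownames(prob_matrix), length(i), replace = TRUE,
                     prob = prob_matrix[, g])
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:\n")
  print(x$expr)
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", ")))
  cat(sprintf("  gene sets: %d (%d enriched for MSS-Y vs MSS-O)\n",
              length(x$gene_sets), length(x$truth$enriched_sets)))
  invisible(x)
}

#' Redraw one categorical covariate with per-group level probabilities
#'
#' Used to plant (or remove) a clinical association: the covariate is redrawn
#' independently per sample from its group's probability column.
#'
#' @param samples a `sample_table`.
#' @param covariate name of an existing categorical column.
#' @param group_probs levels x groups probability matrix (columns must sum
#'   to 1; column names must be the four group labels).
#' @param seed integer seed.
#' @return the modified `sample_table`.
#' @export
plant_clinical_association <- function(samples, covariate, group_probs, seed = 1L) {
  stopifnot(inherits(samples, "sample_table"))
  if (!covariate %in% names(samples))
    stop("unknown covariate: ", covariate)
  if (any(abs(colSums(group_probs) - 1) > 1e-8))
    stop("group_probs columns must sum to 1")
  if (!all(GROUP_LEVELS %in% colnames(group_probs)))
    stop("group_probs must have one column per group")
  set.seed(seed)
  samples[[covariate]] <- .draw_categorical(samples$group,
                                            group_probs[, GROUP_LEVELS, drop = FALSE])
  samples
}

#' Write all artifacts of a synthetic cohort to a directory
#'
#' Writes the expression matrix (TSV), sample table (TSV), gene sets (GMT)
#' and truth tables in plain-text formats.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expr, file.path(dir, "expression.tsv"), "tsv")
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_results_table(
    data.frame(gene = names(cohort$truth$de_log2fc),
               true_log2fc = cohort$truth$de_log2fc),
    file.path(dir, "truth_de.tsv"))
  write_results_table(
    data.frame(sample_id = names(cohort$truth$partition),
               true_cluster = cohort$truth$partition,
               mmr = cohort$truth$mmr),
    file.path(dir, "truth_partition.tsv"))
  invisible(dir)
}
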