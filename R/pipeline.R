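# End-to-end orchestration: simulate (or load) -> filter -> cluster -> DE
# -> enrichment -> clinico-molecular statistics, with a run manifest and a
# markdown report. Every threshold actually applied is recorded in the
# manifest; rerunning with the same config and seed is bit-identical.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with their standard defaults: intensity
#' threshold 15 in at least 10% of samples, variance filter at p < 0.01,
#' seven variant-gene lists (1%..50%), k from 2 to 8, the MSS-Y vs MSS-O
#' contrast at BH 0.05, and the mean-rank < 100 enrichment filter.
#'
#' @param cohort a [cohort_config()] for the synthetic input (ignored when
#'   `inputs` supplies files).
#' @param inputs optional named list of paths (`expression`, `samples`,
#'   `gene_sets`) to run on external data instead of a simulation;
#'   `expression_dialect` selects tsv/gct.
#' @param filter a [filter_params()].
#' @param k_range cluster counts for the consensus stage.
#' @param contrast length-2 group labels for the supervised stage.
#' @param de_alpha BH threshold for differential expression.
#' @param n_perm permutations for the enrichment stage.
#' @param mean_rank_threshold enrichment mean-rank filter.
#' @param clinical_variables annotation columns tested against the
#'   partition and summarized per group.
#' @param seed integer seed governing every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(seed = seed),
                            inputs = NULL,
                            filter = filter_params(),
                            k_range = 2:8,
                            contrast = c("MSS-Y", "MSS-O"),
                            de_alpha = 0.05,
                            n_perm = 1000L,
                            mean_rank_threshold = 100,
                            clinical_variables = c("tumor_location", "stage",
                                                   "synchronous_adenoma",
                                                   "family_history",
                                                   "metastatic_sites", "KRAS",
                                                   "BRAF", "TP53", "PIK3CA"),
                            seed = 1L) {
  stopifnot(all(k_range >= 2L), length(contrast) == 2L)
  structure(list(cohort = cohort, inputs = inputs, filter = filter,
                 k_range = k_range, contrast = contrast, de_alpha = de_alpha,
                 n_perm = as.integer(n_perm),
                 mean_rank_threshold = mean_rank_threshold,
                 clinical_variables = clinical_variables,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "inputs")]), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647  # djb2 within 32-bit range
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes simulate/load, probe filtering, consensus clustering,
#' differential expression, gene-set enrichment and the clinical statistics
#' in order. Any stage failure aborts with the stage name; outputs of
#' completed stages are kept in the returned object (and written to
#' `out_dir` when given). The manifest records the package version, config
#' hash, seed and per-stage row counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory to write stage outputs to.
#' @return object of class `eocrc_run` with elements `cohort`, `filter`,
#'   `clustering`, `de`, `enrichment`, `clinical`, `survival`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("eocrc")),
                   config_hash = .config_hash(config), seed = config$seed,
                   stages = list())
  res <- list(config = config)
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    out
  }

  # 1. input
  if (is.null(config$inputs)) {
    cohort <- stage("simulate", generate_cohort(config$cohort))
  } else {
    cohort <- stage("load", {
      dialect <- if (!is.null(config$inputs$expression_dialect))
        config$inputs$expression_dialect else "tsv"
      list(expr = read_expression_matrix(config$inputs$expression, dialect),
           samples = read_sample_table(config$inputs$samples),
           gene_sets = read_gmt(config$inputs$gene_sets), truth = NULL)
    })
  }
  res$cohort <- cohort
  manifest$stages$input <- list(n_probes = nrow(cohort$expr$values),
                                n_samples = ncol(cohort$expr$values),
                                n_sets = length(cohort$gene_sets))

  # 2. probe filtering
  res$filter <- stage("filter", {
    expressed <- filter_expressed(cohort$expr, config$filter)
    xe <- subset_expression(cohort$expr, probes = expressed)
    variant <- filter_high_variance(xe, config$filter)
    xv <- subset_expression(xe, probes = variant)
    lists <- build_variant_lists(xv, config$filter)
    list(expressed = expressed, variant = variant, lists = lists,
         params = config$filter)
  })
  manifest$stages$filter <- list(
    intensity_threshold = config$filter$intensity_threshold,
    min_expressed_fraction = config$filter$min_expressed_fraction,
    variance_alpha = config$filter$variance_alpha,
    n_expressed = length(res$filter$expressed),
    n_variant = length(res$filter$variant),
    list_sizes = lengths(res$filter$lists))

  # 3. consensus clustering + annotation association
  res$clustering <- stage("cluster", {
    fit <- consensus_cluster(cohort$expr, res$filter$lists, config$k_range)
    assoc <- lapply(fit$consensus, function(ck) {
      vars <- intersect(config$clinical_variables, names(cohort$samples))
      suppressWarnings(associate_annotations(ck$partition, cohort$samples, vars))
    })
    list(fit = fit, association = assoc)
  })
  manifest$stages$cluster <- list(k_range = config$k_range,
                                  n_lists = length(res$filter$lists))

  # 4. differential expression on the contrast
  res$de <- stage("de", {
    keep <- cohort$samples$sample_id[cohort$samples$group %in% config$contrast]
    xs <- collapse_to_genes(subset_expression(cohort$expr, samples = keep))
    grp <- factor(as.character(cohort$samples$group[
      match(keep, cohort$samples$sample_id)]), levels = config$contrast)
    moderated_t(log2(xs$values), grp)
  })
  manifest$stages$de <- list(contrast = config$contrast,
                             alpha = config$de_alpha,
                             n_genes = nrow(res$de),
                             n_significant = sum(res$de$p_adj < config$de_alpha))

  # 5. gene-set enrichment
  res$enrichment <- stage("gsa", suppressWarnings(
    run_enrichment(cohort$expr, cohort$samples, config$contrast,
                   cohort$gene_sets, B = config$n_perm, seed = config$seed,
                   alpha = config$de_alpha,
                   mean_rank_threshold = config$mean_rank_threshold)))
  manifest$stages$gsa <- list(n_perm = config$n_perm,
                              mean_rank_threshold = config$mean_rank_threshold,
                              n_sets = nrow(res$enrichment),
                              n_pass = sum(res$enrichment$pass_filter))

  # 6. clinical statistics and survival
  res$clinical <- stage("clinstats", {
    vars <- intersect(config$clinical_variables, names(cohort$samples))
    ct <- clinical_table(cohort$samples, vars)
    ct$cimp <- tryCatch(cimp_status(cohort$samples), error = function(e) NULL)
    ct
  })
  manifest$stages$clinstats <- list(n_variables = nrow(res$clinical$tests))
  res$survival <- stage("survival", {
    if (!all(c("survival_time", "event") %in% names(cohort$samples))) {
      NULL
    } else {
      s <- cohort$samples
      curves <- lapply(split(s, s$group), function(d)
        km_estimate(d$survival_time, d$event))
      lr <- logrank_test(s$survival_time, s$event, s$group)
      list(curves = curves, logrank = lr)
    }
  })
  manifest$stages$survival <- list(
    available = !is.null(res$survival),
    logrank_p = if (!is.null(res$survival)) res$survival$logrank$p else NA)

  res$manifest <- manifest
  out <- structure(res, class = "eocrc_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write an `eocrc_run`'s stage outputs to a directory
#'
#' @param run an `eocrc_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(run$clustering$fit$consensus)) {
    ck <- run$clustering$fit$consensus[[k]]
    write_results_table(
      data.frame(sample_id = names(ck$partition), cluster = ck$partition),
      file.path(dir, paste0("consensus_partition_", k, ".tsv")))
  }
  write_results_table(as.data.frame(run$de),
                      file.path(dir, "differential_expression.tsv"),
                      params = list(contrast = run$config$contrast,
                                    alpha = run$config$de_alpha))
  write_results_table(as.data.frame(run$enrichment),
                      file.path(dir, "enrichment.tsv"),
                      params = list(n_perm = run$config$n_perm,
                                    seed = run$config$seed))
  write_results_table(run$clinical$tests, file.path(dir, "clinical_tests.tsv"))
  writeLines(.manifest_lines(run$manifest), file.path(dir, "manifest.txt"))
  invisible(dir)
}

.manifest_lines <- function(m) {
  c(sprintf("package_version: %s", m$package_version),
    sprintf("config_hash: %s", m$config_hash),
    sprintf("seed: %d", m$seed),
    unlist(lapply(names(m$stages), function(s) {
      fields <- m$stages[[s]]
      sprintf("%s.%s: %s", s, names(fields),
              vapply(fields, function(f) paste(format(f), collapse = ","), ""))
    })))
}

#' @export
print.eocrc_run <- function(x, ...) {
  cat("eocrc_run (", length(x$manifest$stages), " stages, seed ",
      x$manifest$seed, ", config ", x$manifest$config_hash, ")\n", sep = "")
  cat(sprintf("  input: %d probes x %d samples, %d gene sets\n",
              x$manifest$stages$input$n_probes,
              x$manifest$stages$input$n_samples,
              x$manifest$stages$input$n_sets))
  cat(sprintf("  filter: %d expressed, %d variant\n",
              x$manifest$stages$filter$n_expressed,
              x$manifest$stages$filter$n_variant))
  cat(sprintf("  de: %d/%d genes at BH < %g\n",
              x$manifest$stages$de$n_significant,
              x$manifest$stages$de$n_genes, x$config$de_alpha))
  cat(sprintf("  gsa: %d/%d sets pass mean-rank filter\n",
              x$manifest$stages$gsa$n_pass, x$manifest$stages$gsa$n_sets))
  if (isTRUE(x$manifest$stages$survival$available))
    cat(sprintf("  survival: log-rank p = %.3g\n",
                x$manifest$stages$survival$logrank_p))
  invisible(x)
}

#' @export
summary.eocrc_run <- function(object, ...) object$manifest

#' Render a markdown report for a completed run
#'
#' Sections: consensus clustering (cluster sizes and closest list per k,
#' annotation associations), differential expression (volcano summary
#' counts), top pathways by mean rank, clinical summary tables, survival.
#' Missing stages are marked unavailable rather than failing.
#'
#' @param run an `eocrc_run`.
#' @param path optional file to write the report to.
#' @param top_n number of pathways to show (default 20).
#' @return character vector of markdown lines, invisibly when `path` given.
#' @export
render_report <- function(run, path = NULL, top_n = 20L) {
  stopifnot(inherits(run, "eocrc_run"))
  L <- c("# Cohort analysis report", "",
         sprintf("Package eocrc %s; seed %d; config %s.",
                 run$manifest$package_version, run$manifest$seed,
                 run$manifest$config_hash), "")
  L <- c(L, "## Consensus clustering", "")
  if (!is.null(run$clustering)) {
    for (ck in run$clustering$fit$consensus) {
      L <- c(L, sprintf("- k=%d: cluster sizes %s; closest gene list #%d (ARI %.3f)",
                        ck$k, paste(table(ck$partition), collapse = "/"),
                        ck$closest_list, max(ck$list_ari)))
    }
    L <- c(L, "", "### Partition-annotation association (BH-adjusted p)", "")
    for (k in names(run$clustering$association)) {
      a <- run$clustering$association[[k]]
      sig <- a$variable[a$p_adj < 0.05]
      L <- c(L, sprintf("- %s: %s", k,
                        if (length(sig)) paste(sig, collapse = ", ") else "none"))
    }
  } else L <- c(L, "_unavailable_")
  L <- c(L, "", "## Differential expression", "")
  if (!is.null(run$de)) {
    s <- summary(run$de, alpha = run$config$de_alpha)
    L <- c(L, sprintf("- contrast %s: %d genes tested, %d significant at BH < %g (%d up, %d down); prior d0 = %s",
                      s$contrast, s$n_genes, s$n_significant,
                      run$config$de_alpha, s$n_up, s$n_down,
                      format(s$d0, digits = 4)))
  } else L <- c(L, "_unavailable_")
  L <- c(L, "", sprintf("## Top %d pathways by mean rank", top_n), "")
  if (!is.null(run$enrichment)) {
    top <- utils::head(run$enrichment, top_n)
    L <- c(L, "| set | mean rank | direction | pass |",
           "|---|---|---|---|",
           sprintf("| %s | %.2f | %+.2f | %s |", top$set, top$mean_rank,
                   ifelse(is.na(top$direction), 0, top$direction),
                   top$pass_filter))
  } else L <- c(L, "_unavailable_")
  L <- c(L, "", "## Clinical summary", "")
  if (!is.null(run$clinical)) {
    t <- run$clinical$tests
    L <- c(L, "| variable | test | p |", "|---|---|---|",
           sprintf("| %s | %s | %.3g |", t$variable, t$test, t$p))
  } else L <- c(L, "_unavailable_")
  L <- c(L, "", "## Survival", "")
  if (!is.null(run$survival)) {
    L <- c(L, sprintf("- log-rank over groups: chi2 = %.3f (df %d), p = %.3g",
                      run$survival$logrank$statistic, run$survival$logrank$df,
                      run$survival$logrank$p))
  } else L <- c(L, "_skipped: no survival columns_")
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}
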