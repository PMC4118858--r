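# Clinico-molecular statistics layer: contingency tests with automatic
# Fisher / chi-squared selection (Cochran's rule), Kaplan-Meier survival
# with the log-rank test, CIMP and beta-catenin calling rules, and
# group-summary tables with assessable-denominator percentages.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the observed
#' table's probability (within relative tolerance 1e-7).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(table != round(table))) stop("counts must be integers")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Pearson chi-squared test for an r x c table
#'
#' Standard Pearson statistic with (r-1)(c-1) degrees of freedom; the Yates
#' continuity correction (|O - E| reduced by 0.5 before squaring) applies
#' only to 2x2 tables.
#'
#' @param table r x c matrix of non-negative counts, no zero margin.
#' @param yates apply the continuity correction for 2x2 tables
#'   (default TRUE).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_squared_test <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row/column margin: chi-squared test undefined")
  ct <- suppressWarnings(
    stats::chisq.test(table, correct = yates && all(dim(table) == 2L)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Choose between Fisher and chi-squared for a contingency table
#'
#' Cochran's rule: Fisher when any expected count under independence is
#' strictly below 5, otherwise the chi-squared test (Yates-corrected for
#' 2x2 tables). Expected count exactly 5 stays with chi-squared.
#'
#' @param table r x c count matrix.
#' @return `"fisher"` or `"chisq"`.
#' @export
choose_test <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) "fisher" else "chisq"
}

#' Rule-selected contingency test
#'
#' Applies [choose_test()] and runs the selected test (Fisher for r x c via
#' `fisher.test`, network algorithm / simulation fallback for large tables).
#'
#' @param table r x c count matrix.
#' @return list with `test` ("fisher"/"chisq"), `p`, and (for chisq)
#'   `statistic` and `df`.
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  which_test <- choose_test(table)
  if (which_test == "fisher") {
    p <- if (all(dim(table) == 2L)) {
      fisher_exact_2x2(table)
    } else {
      # r x c exact network algorithm is impractical beyond small tables;
      # use Monte Carlo with a fixed internal seed (deterministic, and the
      # caller's RNG stream is left untouched)
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old_seed))
          assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(104729L)
      stats::fisher.test(table, simulate.p.value = TRUE, B = 2e4)$p.value
    }
    list(test = "fisher", p = p)
  } else {
    ct <- chi_squared_test(table)
    list(test = "chisq", p = ct$p, statistic = ct$statistic, df = ct$df)
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (months, >= 0).
#' @param events event indicators (1 = death/event, 0 = censored).
#' @return object of class `km_curve`: list with `time` (event times),
#'   `n_risk`, `n_event`, `surv` (step estimates of S(t)).
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be binary")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep], surv = fit$surv[keep],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d event times\n", x$n, length(x$time)))
  if (length(x$time))
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     surv = round(x$surv, 4)), row.names = FALSE)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve`.
#' @param t times at which to evaluate the step function.
#' @return S(t) (right-continuous; 1 before the first event).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (length(i) == 0L) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' k-group log-rank test
#'
#' @param times follow-up times.
#' @param events event indicators (>= 1 event overall).
#' @param group group labels (>= 2 groups).
#' @return list with `statistic` (chi-squared, k-1 df), `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  if (any(times < 0)) stop("negative survival time")
  if (sum(events) == 0) stop("log-rank test undefined with zero events")
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' CIMP (CpG-island methylator phenotype) call from five marker states
#'
#' Positive when at least 3 of the 5 marker promoters are methylated;
#' negative when at most 1 is (and missing data cannot raise the count to
#' 2); otherwise indeterminate. Exactly 2 methylated markers is
#' indeterminate: the printed classification rules (>= 3 positive, < 2
#' negative) leave that configuration unassigned. Missing states widen the
#' possible count; a call is made only when every completion agrees.
#'
#' @param marker_states numeric vector of length 5 in {0, 1, NA}.
#' @return `"CIMP_positive"`, `"CIMP_negative"` or `"indeterminate"`.
#' @export
cimp_call <- function(marker_states) {
  if (length(marker_states) > 5L) stop("more than 5 CIMP markers supplied")
  if (length(marker_states) != 5L) stop("exactly 5 CIMP marker states required")
  if (!all(marker_states %in% c(0, 1, NA))) stop("marker states must be 0, 1 or missing")
  lo <- sum(marker_states == 1, na.rm = TRUE)
  hi <- lo + sum(is.na(marker_states))
  if (lo >= 3L) "CIMP_positive" else if (hi <= 1L) "CIMP_negative"
  else "indeterminate"
}

#' Beta-catenin pathway activation call
#'
#' Activated when strong nuclear staining is seen in strictly more than 50%
#' of tumor cells.
#'
#' @param nuclear_pct percentage of tumor cells with nuclear staining
#'   (0-100; NA allowed, returned as NA).
#' @return logical (TRUE = activated).
#' @export
beta_catenin_call <- function(nuclear_pct) {
  if (is.na(nuclear_pct)) return(NA)
  if (nuclear_pct < 0 || nuclear_pct > 100)
    stop("nuclear staining percentage must lie in [0, 100]")
  nuclear_pct > 50
}

#' Per-group counts and percentages for a categorical variable
#'
#' Counts per level within each group and the percentage of ASSESSABLE
#' (non-missing) samples, rounded to the requested precision. Using
#' assessable denominators is what reproduces published cohort tables whose
#' denominators vary by variable.
#'
#' @param samples a `sample_table` (or data.frame with `group`).
#' @param variable categorical column name.
#' @param groups group labels to tabulate (default all four).
#' @param digits decimal places for the percentage (0 or 1 typically).
#' @return data.frame: group, level, n, n_assessable, pct.
#' @export
group_summary <- function(samples, variable, groups = GROUP_LEVELS, digits = 0) {
  if (!variable %in% names(samples)) stop("unknown variable: ", variable)
  bad <- setdiff(groups, GROUP_LEVELS)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  val <- samples[[variable]]
  levs <- sort(unique(val[!is.na(val)]))
  rows <- list()
  for (g in groups) {
    vg <- val[samples$group == g]
    n_ass <- sum(!is.na(vg))
    for (lv in levs) {
      n <- sum(vg == lv, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, level = as.character(lv), n = n, n_assessable = n_ass,
        pct = if (n_ass > 0) round(100 * n / n_ass, digits) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Table-style clinico-molecular summary with rule-selected tests
#'
#' For each requested variable: per-group counts/percentages and the
#' rule-selected contingency test over the requested group columns
#' (missing values excluded pairwise).
#'
#' @param samples a `sample_table`.
#' @param variables categorical column names.
#' @param groups groups to compare (default all four).
#' @return list with `summary` (long data.frame from [group_summary()])
#'   and `tests` (variable, test, p).
#' @export
clinical_table <- function(samples, variables, groups = GROUP_LEVELS) {
  summaries <- do.call(rbind, lapply(variables, function(v) {
    cbind(variable = v, group_summary(samples, v, groups))
  }))
  tests <- do.call(rbind, lapply(variables, function(v) {
    keep <- samples$group %in% groups & !is.na(samples[[v]])
    tab <- table(samples[[v]][keep], factor(samples$group[keep], levels = groups))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (any(dim(tab) < 2L))
      return(data.frame(variable = v, test = NA_character_, p = NA_real_,
                        stringsAsFactors = FALSE))
    ct <- contingency_test(tab)
    data.frame(variable = v, test = ct$test, p = ct$p, stringsAsFactors = FALSE)
  }))
  list(summary = summaries, tests = tests)
}

#' CIMP status per sample from the marker columns
#'
#' Applies [cimp_call()] to the five `cimp_<MARKER>` columns.
#'
#' @param samples a `sample_table` containing the five marker columns.
#' @return character vector of calls, named by sample id.
#' @export
cimp_status <- function(samples) {
  cols <- paste0("cimp_", CIMP_MARKERS)
  miss <- setdiff(cols, names(samples))
  if (length(miss)) stop("missing CIMP marker column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(samples[, cols])
  stats::setNames(apply(m, 1L, cimp_call), samples$sample_id)
}
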