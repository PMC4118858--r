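# Domain containers and readers/writers for the plain-text formats the
# pipeline touches: expression matrices (TSV / GCT 1.2), sample annotation
# tables (TSV) and gene-set collections (GMT).

#' The four cohort group labels (MSS/MSI crossed with young/old)
#' @export
GROUP_LEVELS <- c("MSS-Y", "MSS-O", "MSI-Y", "MSI-O")

#' The five CIMP marker promoters
#' @export
CIMP_MARKERS <- c("CACNA1G", "IGF2", "NEUROG1", "RUNX3", "SOCS1")

#' Construct an expression matrix container
#'
#' Holds probes x samples normalized intensities on the LINEAR scale
#' (strictly positive; e.g. RMA output back-transformed from log2).
#' Downstream stages apply log2 explicitly where their statistics require it,
#' because the expressed-probe intensity filter operates on the linear scale.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids character vector of unique probe identifiers.
#' @param gene_symbols character vector of per-probe gene symbols
#'   (many probes may map to one gene).
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `expr_matrix`: a list with fields `values`
#'   (dimnames set to probe and sample ids), `probe_ids`, `gene_symbols`,
#'   `sample_ids`.
#' @export
expression_matrix <- function(values, probe_ids, gene_symbols = NULL,
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(gene_symbols)) gene_symbols <- probe_ids
  x <- structure(
    list(values = values,
         probe_ids = as.character(probe_ids),
         gene_symbols = as.character(gene_symbols),
         sample_ids = as.character(sample_ids)),
    class = "expr_matrix")
  dimnames(x$values) <- list(x$probe_ids, x$sample_ids)
  validate_expression_matrix(x)
  x
}

#' Validate an expression matrix container
#'
#' Enforces the container invariants: unique probe and sample ids, matching
#' dimensions, and finite strictly positive intensities.
#'
#' @param x an `expr_matrix` object.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (anyDuplicated(x$probe_ids))
    stop("duplicate probe ids: ", paste(unique(x$probe_ids[duplicated(x$probe_ids)]), collapse = ", "))
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ", paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (nrow(x$values) != length(x$probe_ids) || ncol(x$values) != length(x$sample_ids))
    stop("dimension mismatch between values and probe/sample ids")
  if (length(x$gene_symbols) != length(x$probe_ids))
    stop("gene_symbols must be one per probe")
  if (any(!is.finite(x$values)))
    stop("expression values must be finite")
  if (any(x$values <= 0))
    stop("expression values must be strictly positive (linear intensity scale)")
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%d genes)\n",
              nrow(x$values), ncol(x$values), length(unique(x$gene_symbols))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by probe and/or sample
#'
#' @param x an `expr_matrix`.
#' @param probes probe ids or indices to keep (default all).
#' @param samples sample ids or indices to keep (default all).
#' @return an `expr_matrix` restricted to the requested probes/samples.
#' @export
subset_expression <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  pi <- if (is.null(probes)) seq_along(x$probe_ids) else {
    if (is.character(probes)) match(probes, x$probe_ids) else probes
  }
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  if (anyNA(pi)) stop("unknown probe id in subset")
  if (anyNA(si)) stop("unknown sample id in subset")
  expression_matrix(x$values[pi, si, drop = FALSE],
                    probe_ids = x$probe_ids[pi],
                    gene_symbols = x$gene_symbols[pi],
                    sample_ids = x$sample_ids[si])
}

#' Log2-transform an expression matrix
#'
#' @param x an `expr_matrix` (linear intensities).
#' @return numeric matrix of log2 intensities with the same dimnames.
#' @export
log2_values <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  log2(x$values)
}

#' Collapse probes to genes by the maximum-variance probe
#'
#' For gene-set matching, each gene symbol is represented by its single most
#' variable probe (variance of log2 intensities across samples). This is the
#' most common collapsing convention for array data; the choice is logged in
#' the returned attribute `collapse_rule`.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` with one row per gene symbol, probe ids replaced
#'   by the selected representative probes and gene symbols used as row names.
#' @export
collapse_to_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- apply(log2(x$values), 1L, stats::var)
  ord <- order(x$gene_symbols, -v, x$probe_ids)
  keep <- ord[!duplicated(x$gene_symbols[ord])]
  keep <- sort(keep)
  out <- expression_matrix(x$values[keep, , drop = FALSE],
                           probe_ids = x$gene_symbols[keep],
                           gene_symbols = x$gene_symbols[keep],
                           sample_ids = x$sample_ids)
  attr(out, "collapse_rule") <- "max-variance probe per gene symbol (log2 scale)"
  out
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' The TSV dialect has a header row with `probe_id`, optionally `gene_symbol`,
#' then one column per sample. The GCT 1.2 dialect has the `#1.2` version
#' line, a dimensions line, and `NAME`/`Description` columns; `Description`
#' carries the gene symbol.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gct"`.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") | seq_along(lines) == 1L]
  if (dialect == "gct") {
    if (length(lines) < 3L || !identical(trimws(lines[1L]), "#1.2"))
      stop("malformed GCT header: first line must be '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT header: second line must give row and column counts")
    body <- lines[-(1:2)]
    hdr <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 3L || hdr[1L] != "NAME")
      stop("malformed GCT header: expected NAME, Description, then sample columns")
    sample_ids <- hdr[-(1:2)]
    rows <- strsplit(body[-1L], "\t", fixed = TRUE)
    if (length(rows) != dims[1L] || length(sample_ids) != dims[2L])
      stop(sprintf("GCT declared dims (%d,%d) disagree with body (%d,%d)",
                   dims[1L], dims[2L], length(rows), length(sample_ids)))
    probe_ids <- vapply(rows, `[`, "", 1L)
    gene_symbols <- vapply(rows, `[`, "", 2L)
    vals <- .parse_numeric_block(rows, skip = 2L, n_cols = length(sample_ids))
  } else {
    lines <- lines[nzchar(lines)]
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (hdr[1L] != "probe_id")
      stop("malformed TSV header: first column must be 'probe_id'")
    has_sym <- length(hdr) >= 2L && hdr[2L] == "gene_symbol"
    skip <- if (has_sym) 2L else 1L
    sample_ids <- hdr[-seq_len(skip)]
    if (length(sample_ids) == 0L) stop("malformed TSV header: no sample columns")
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    probe_ids <- vapply(rows, `[`, "", 1L)
    gene_symbols <- if (has_sym) vapply(rows, `[`, "", 2L) else probe_ids
    vals <- .parse_numeric_block(rows, skip = skip, n_cols = length(sample_ids))
  }
  expression_matrix(vals, probe_ids = probe_ids, gene_symbols = gene_symbols,
                    sample_ids = sample_ids)
}

.parse_numeric_block <- function(rows, skip, n_cols) {
  n <- length(rows)
  vals <- matrix(NA_real_, n, n_cols)
  for (i in seq_len(n)) {
    cells <- rows[[i]][-seq_len(skip)]
    if (length(cells) != n_cols)
      stop(sprintf("row %d has %d value cells, expected %d", i, length(cells), n_cols))
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at data row %d, sample column %d: '%s'",
                   i, j, cells[j]))
    }
    vals[i, ] <- v
  }
  vals
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @param dialect `"tsv"` or `"gct"`.
#' @param digits significant digits used for serialization (default 10).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "gct"),
                                    digits = 10) {
  dialect <- match.arg(dialect)
  validate_expression_matrix(x)
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  body <- apply(x$values, 1L, function(r) paste(fmt(r), collapse = "\t"))
  if (dialect == "gct") {
    lines <- c("#1.2",
               paste(nrow(x$values), ncol(x$values), sep = "\t"),
               paste(c("NAME", "Description", x$sample_ids), collapse = "\t"),
               paste(x$probe_ids, x$gene_symbols, body, sep = "\t"))
  } else {
    lines <- c(paste(c("probe_id", "gene_symbol", x$sample_ids), collapse = "\t"),
               paste(x$probe_ids, x$gene_symbols, body, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Reads a TSV with one row per sample. `sample_id` and `group` are required;
#' recognised optional columns are typed (age, categorical covariates,
#' mutation states, the five CIMP marker states `cimp_<MARKER>`, survival
#' time/event and the beta-catenin nuclear-staining percentage). Unknown
#' categorical levels are preserved verbatim and reported via a message.
#' Empty cells and the literal `NA` are treated as missing.
#'
#' @param path TSV file path.
#' @return a `data.frame` with class `c("sample_table", "data.frame")`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          check.names = FALSE)
  validate_sample_table(df)
}

#' Validate (and type) a sample annotation table
#'
#' Enforces the table invariants: unique sample ids, known group labels,
#' group labels consistent with age (young: age <= 45; old: age > 60),
#' non-negative survival time, binary event, CIMP marker states in {0, 1,
#' missing} and beta-catenin percentage within [0, 100].
#'
#' @param df a data.frame with at least `sample_id` and `group`.
#' @return the validated table, classed `sample_table`.
#' @export
validate_sample_table <- function(df) {
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  if ("age_years" %in% names(df)) {
    young <- df$group %in% c("MSS-Y", "MSI-Y") & !is.na(df$age_years)
    old <- df$group %in% c("MSS-O", "MSI-O") & !is.na(df$age_years)
    if (any(df$age_years[young] > 45))
      stop("young-group sample with age > 45")
    if (any(df$age_years[old] <= 60))
      stop("old-group sample with age <= 60")
  }
  if ("survival_time" %in% names(df) &&
      any(df$survival_time < 0, na.rm = TRUE))
    stop("survival_time must be >= 0")
  if ("event" %in% names(df) && !all(df$event %in% c(0, 1, NA)))
    stop("event must be binary (0/1)")
  cimp_cols <- grep("^cimp_", names(df), value = TRUE)
  for (cc in cimp_cols) {
    if (!all(df[[cc]] %in% c(0, 1, NA)))
      stop("CIMP marker column ", cc, " must be 0, 1 or missing")
  }
  if ("bcat_nuclear_pct" %in% names(df)) {
    v <- df$bcat_nuclear_pct
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("bcat_nuclear_pct must lie in [0, 100]")
  }
  known_levels <- list(
    tumor_location = c("right", "left", "rectum", "multiple"),
    stage = c("0", "I", "II", "III", "IV"),
    synchronous_adenoma = c("yes", "no"),
    family_history = c("none", "first_degree", "second_degree"),
    metastatic_sites = c("none", "unique", "multiple"),
    KRAS = c("mutated", "wild-type"), BRAF = c("mutated", "wild-type"),
    TP53 = c("mutated", "wild-type"), PIK3CA = c("mutated", "wild-type"))
  for (v in intersect(names(known_levels), names(df))) {
    extra <- setdiff(unique(df[[v]][!is.na(df[[v]])]), known_levels[[v]])
    if (length(extra))
      message("column ", v, ": unrecognised level(s) kept verbatim: ",
              paste(extra, collapse = ", "))
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a sample annotation table
#'
#' @param df a `sample_table` (or plain data.frame with the same columns).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member gene symbols).
#' @param description optional named character vector of set descriptions.
#' @param category optional named character vector assigning each set to a
#'   functional category (e.g. cell signaling, inflammation/apoptosis).
#' @return an object of class `gene_sets`.
#' @export
gene_set_collection <- function(sets, description = NULL, category = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s): ",
    paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = lapply(sets, as.character),
                 description = description,
                 category = category),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, member counts %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' Read a gene-set collection from GMT
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene symbols. Trailing empty fields are dropped; duplicate
#' members within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return a `gene_sets` collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[!(seq_along(f) > 2L & !nzchar(f))]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d fields; need name, description and >=1 member", i, length(f)))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': %d duplicate member(s) removed",
                      f[1L], sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
    descs[f[1L]] <- f[2L]
  }
  gene_set_collection(sets, description = descs)
}

#' Write a gene-set collection to GMT
#'
#' @param gs a `gene_sets` collection.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  stopifnot(inherits(gs, "gene_sets"))
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$description[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as annotated TSV
#'
#' Writes a data.frame with a `#`-prefixed comment header recording the
#' package version, timestamp policy (none: content is run-deterministic) and
#' the serialization precision, so every emitted file documents how it was
#' produced. Numeric columns are serialized with a fixed number of
#' significant digits.
#'
#' @param records a non-empty data.frame.
#' @param path output TSV path.
#' @param digits significant digits for numeric columns (default 10).
#' @param params optional named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, digits = 10, params = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty results table")
  hdr <- c(sprintf("# eocrc %s", as.character(utils::packageVersion("eocrc"))),
           sprintf("# numeric precision: %d significant digits", digits))
  if (!is.null(params))
    hdr <- c(hdr, sprintf("# %s: %s", names(params),
                          vapply(params, function(p) paste(format(p), collapse = ","), "")))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return a data.frame (comment header skipped).
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
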