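# Core data containers for balanced 2x2x2 factorial expression experiments:
# a signal matrix (linear-scale intensities), per-sample detection calls and a
# sample design table over three binary factors
#   N  nitrogen treatment (0 = -N, 1 = +N)
#   L  light treatment    (0 = dark, 1 = light)
#   G  genotype           (0 = wild-type sibling, 1 = mutant)

#' Canonical condition labels
#'
#' Returns the eight design-cell labels in canonical order:
#' (-N-L, +N-L, -N+L, +N+L) within genotype, wild type before mutant.
#'
#' @return Character vector of length 8.
#' @export
condition_labels <- function() {
  cells <- c("-N-L", "+N-L", "-N+L", "+N+L")
  c(paste0("WT:", cells), paste0("mut:", cells))
}

# label for one design cell; vectorized over N, L, G (0/1 each)
cell_label <- function(N, L, G) {
  paste0(ifelse(G == 1, "mut", "WT"), ":",
         ifelse(N == 1, "+N", "-N"),
         ifelse(L == 1, "+L", "-L"))
}

validate_error <- function(field, msg) {
  stop(structure(
    class = c("boolgate_validation_error", "error", "condition"),
    list(message = sprintf("[%s] %s", field, msg), call = sys.call(-1))
  ))
}

#' Construct and validate a sample design table
#'
#' @param design data.frame with columns `sample_id`, `N`, `L`, `G`,
#'   `replicate`. `N`, `L`, `G` must be coded 0/1; the design must contain
#'   every (N, L, G) cell with the same number of replicates (>= 1).
#'
#' @return The validated design (class `sample_design`), rows in input order.
#' @export
sample_design <- function(design) {
  design <- as.data.frame(design)
  need <- c("sample_id", "N", "L", "G", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    validate_error("design", paste("missing columns:", paste(miss, collapse = ", ")))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    validate_error("design$sample_id", "sample_ids must be unique")
  for (f in c("N", "L", "G")) {
    v <- design[[f]]
    if (!all(v %in% c(0, 1)))
      validate_error(paste0("design$", f), "factor levels must be 0 or 1")
    design[[f]] <- as.integer(v)
  }
  design$replicate <- as.integer(design$replicate)
  if (any(design$replicate < 1))
    validate_error("design$replicate", "replicate indices must be positive")
  cell <- cell_label(design$N, design$L, design$G)
  tab <- table(factor(cell, levels = condition_labels()))
  if (any(tab == 0))
    validate_error("design", paste0("incomplete factorial design: missing cell(s) ",
                                    paste(names(tab)[tab == 0], collapse = ", ")))
  if (length(unique(as.integer(tab))) != 1)
    validate_error("design", "unbalanced design: unequal replicates per (N,L,G) cell")
  class(design) <- c("sample_design", "data.frame")
  design
}

#' Construct and validate an expression dataset
#'
#' Bundles a genes-by-samples signal matrix (non-negative, linear scale),
#' an aligned matrix of Absent/Marginal/Present detection calls and the
#' sample design. Detection-call spelling is normalized: single letters
#' `A`/`M`/`P` and full words are accepted, case-insensitively.
#'
#' @param signals Numeric matrix, genes x samples, with unique rownames
#'   (gene identifiers) and colnames matching `design$sample_id`.
#' @param calls Character matrix of the same dimension, or `NULL` for
#'   all-Present calls (a warning is issued).
#' @param design A `sample_design` or a data.frame coercible to one.
#' @param gene_info Optional data.frame with column `gene_id` and any gene
#'   metadata (e.g. `chromosome`, `position`), one row per gene.
#'
#' @return An object of class `expression_dataset` with elements `signals`,
#'   `calls`, `design`, `gene_info`.
#' @export
expression_dataset <- function(signals, calls = NULL, design, gene_info = NULL) {
  design <- sample_design(design)
  signals <- as.matrix(signals)
  if (is.null(rownames(signals)))
    validate_error("signals", "signal matrix must have gene_id rownames")
  if (anyDuplicated(rownames(signals)))
    validate_error("signals", "duplicate gene_ids in signal matrix")
  if (!is.numeric(signals) || any(!is.finite(signals)))
    validate_error("signals", "signals must be finite numeric values")
  if (any(signals < 0))
    validate_error("signals", "signals must be non-negative")
  if (ncol(signals) != nrow(design))
    validate_error("signals", sprintf(
      "dimension mismatch: %d signal columns vs %d design rows",
      ncol(signals), nrow(design)))
  if (is.null(colnames(signals))) {
    colnames(signals) <- design$sample_id
  } else if (!identical(colnames(signals), design$sample_id)) {
    if (!setequal(colnames(signals), design$sample_id))
      validate_error("signals", "signal columns do not match design sample_ids")
    signals <- signals[, design$sample_id, drop = FALSE]
  }
  if (is.null(calls)) {
    warning("no detection calls supplied; assuming all calls Present")
    calls <- matrix("P", nrow(signals), ncol(signals),
                    dimnames = dimnames(signals))
  } else {
    calls <- as.matrix(calls)
    if (!identical(dim(calls), dim(signals)))
      validate_error("calls", "dimension mismatch: calls and signals differ in shape")
    if (!is.null(colnames(calls)) && !identical(colnames(calls), colnames(signals))) {
      if (!setequal(colnames(calls), colnames(signals)))
        validate_error("calls", "call columns do not match signal columns")
      calls <- calls[, colnames(signals), drop = FALSE]
    }
    calls <- normalize_calls(calls)
    dimnames(calls) <- dimnames(signals)
  }
  if (!is.null(gene_info)) {
    gene_info <- as.data.frame(gene_info)
    if (!"gene_id" %in% names(gene_info))
      validate_error("gene_info", "missing column gene_id")
    gene_info$gene_id <- as.character(gene_info$gene_id)
    if (!all(rownames(signals) %in% gene_info$gene_id))
      validate_error("gene_info", "gene_info does not cover all genes")
    gene_info <- gene_info[match(rownames(signals), gene_info$gene_id), , drop = FALSE]
    rownames(gene_info) <- NULL
  }
  structure(list(signals = signals, calls = calls, design = design,
                 gene_info = gene_info),
            class = "expression_dataset")
}

# normalize detection-call spelling to single letters A/M/P
normalize_calls <- function(calls) {
  x <- toupper(trimws(as.character(calls)))
  x[x %in% c("ABSENT")]   <- "A"
  x[x %in% c("MARGINAL")] <- "M"
  x[x %in% c("PRESENT")]  <- "P"
  bad <- !(x %in% c("A", "M", "P"))
  if (any(bad))
    validate_error("calls", paste0("unrecognized detection call value(s): ",
                                   paste(utils::head(unique(x[bad]), 5), collapse = ", ")))
  matrix(x, nrow(calls), ncol(calls))
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d replicates per cell)\n",
              nrow(x$signals), ncol(x$signals),
              nrow(x$design) / 8L))
  calls <- table(factor(x$calls, levels = c("A", "M", "P")))
  cat(sprintf("  calls: %d Absent, %d Marginal, %d Present\n",
              calls["A"], calls["M"], calls["P"]))
  invisible(x)
}

#' Number of genes / samples in a dataset
#' @param ds An `expression_dataset`.
#' @return Integer count.
#' @export
n_genes <- function(ds) nrow(ds$signals)

#' @rdname n_genes
#' @export
n_samples <- function(ds) ncol(ds$signals)

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    validate_error(basename(path), "first column must be named gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read an expression dataset from tab-separated files
#'
#' `signals_path` and `calls_path` point to TSV tables whose first column is
#' `gene_id` and remaining columns are samples; `design_path` is a TSV with
#' columns `sample_id`, `N`, `L`, `G`, `replicate`. A missing calls file
#' (`calls_path = NULL`) yields all-Present calls with a warning.
#'
#' @param signals_path,calls_path,design_path File paths.
#' @param gene_info_path Optional TSV of gene metadata (column `gene_id`).
#' @return An `expression_dataset`.
#' @export
read_expression_table <- function(signals_path, calls_path = NULL, design_path,
                                  gene_info_path = NULL) {
  signals <- read_tsv_matrix(signals_path)
  storage.mode(signals) <- "double"
  calls <- if (!is.null(calls_path)) read_tsv_matrix(calls_path) else NULL
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  gene_info <- if (!is.null(gene_info_path))
    utils::read.delim(gene_info_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  expression_dataset(signals, calls, design, gene_info)
}

# full-precision text serialization so that read -> write -> read round-trips
# reproduce doubles bitwise
format_full <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(m, path, fmt = identity) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 2, fmt)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  writeLines(paste(rownames(m), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Write an expression dataset as TSV files
#'
#' Emits `signals.tsv` (full double precision, so round-trips are bitwise
#' exact), `calls.tsv`, `design.tsv` and, if present, `gene_info.tsv` into
#' `dir`.
#'
#' @param ds An `expression_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_expression_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(ds$signals, file.path(dir, "signals.tsv"), format_full)
  write_matrix_tsv(ds$calls, file.path(dir, "calls.tsv"))
  utils::write.table(as.data.frame(ds$design), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$gene_info))
    utils::write.table(ds$gene_info, file.path(dir, "gene_info.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Keep genes detected on at least one array
#'
#' Retains exactly the genes with at least one Marginal or Present call
#' across all samples, preserving gene order. This removes transcripts
#' declared Absent on every array before any statistical modeling.
#'
#' @param ds An `expression_dataset`.
#' @return The filtered `expression_dataset`.
#' @export
filter_by_detection_calls <- function(ds) {
  keep <- rowSums(ds$calls != "A") > 0
  if (!any(keep))
    validate_error("calls", "no genes survive detection filter")
  subset_genes(ds, rownames(ds$signals)[keep])
}

# subset an expression_dataset to a gene vector (order as given)
subset_genes <- function(ds, genes) {
  missing <- setdiff(genes, rownames(ds$signals))
  if (length(missing) > 0)
    stop("unknown gene_id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  gi <- ds$gene_info
  if (!is.null(gi)) {
    gi <- gi[match(genes, gi$gene_id), , drop = FALSE]
    rownames(gi) <- NULL
  }
  structure(list(signals = ds$signals[genes, , drop = FALSE],
                 calls = ds$calls[genes, , drop = FALSE],
                 design = ds$design, gene_info = gi),
            class = "expression_dataset")
}

#' Scan a chromosome for genotype-linked expression changes
#'
#' Quality control for T-DNA insertion lines: genes genetically linked to
#' the insertion cannot be controlled for by a wild-type sibling, so any
#' large genotype fold change on the mutated gene's chromosome (other than
#' the target itself) flags a possible linked second insertion. For each
#' gene on `chromosome` the ratio of genotype mean signals (pooled over all
#' N x L conditions and replicates, linear scale) is computed in both
#' directions; genes whose fold change exceeds `fold_threshold` are
#' returned, the target gene's own fold change separately.
#'
#' @param ds An `expression_dataset` whose `gene_info` has a `chromosome`
#'   column.
#' @param target_gene Gene id of the mutated locus (excluded from flags).
#' @param chromosome Chromosome identifier to scan.
#' @param fold_threshold Flagging threshold (> 1, default 4).
#' @return List with `target` (one-row data.frame for `target_gene`) and
#'   `flagged` (data.frame of genes exceeding the threshold, columns
#'   `gene_id`, `wt_mean`, `mut_mean`, `fold_wt_over_mut`,
#'   `fold_mut_over_wt`, `direction`).
#' @export
linkage_scan <- function(ds, target_gene, chromosome, fold_threshold = 4) {
  if (is.null(ds$gene_info) || !"chromosome" %in% names(ds$gene_info))
    validate_error("gene_info", "linkage_scan requires gene_info$chromosome")
  if (!target_gene %in% rownames(ds$signals))
    stop("target_gene not found in dataset: ", target_gene)
  if (fold_threshold <= 1)
    stop("fold_threshold must be > 1")
  on_chr <- ds$gene_info$gene_id[ds$gene_info$chromosome == chromosome]
  on_chr <- intersect(rownames(ds$signals), on_chr)
  wt <- ds$design$G == 0
  wt_mean <- rowMeans(ds$signals[on_chr, wt, drop = FALSE])
  mut_mean <- rowMeans(ds$signals[on_chr, !wt, drop = FALSE])
  eps <- .Machine$double.eps
  down <- wt_mean / pmax(mut_mean, eps)  # repression in mutant
  up <- mut_mean / pmax(wt_mean, eps)
  tab <- data.frame(gene_id = on_chr, wt_mean = wt_mean, mut_mean = mut_mean,
                    fold_wt_over_mut = down, fold_mut_over_wt = up,
                    direction = ifelse(down >= up, "down_in_mutant", "up_in_mutant"),
                    stringsAsFactors = FALSE, row.names = NULL)
  is_target <- tab$gene_id == target_gene
  flagged <- tab[!is_target & (tab$fold_wt_over_mut > fold_threshold |
                               tab$fold_mut_over_wt > fold_threshold), , drop = FALSE]
  flagged <- flagged[order(-pmax(flagged$fold_wt_over_mut, flagged$fold_mut_over_wt)), ,
                     drop = FALSE]
  rownames(flagged) <- NULL
  list(target = tab[is_target, , drop = FALSE], flagged = flagged,
       chromosome = chromosome, fold_threshold = fold_threshold)
}

#' Read a GEO series-matrix file
#'
#' Minimal parser for the `!series_matrix_table_begin` block of a GEO
#' series-matrix TXT file (uncompressed). Sample titles and accessions are
#' extracted so a user-supplied mapping can assign design factors.
#'
#' @param path Path to the series-matrix file.
#' @return List with `signals` (matrix, probes x samples, columns named by
#'   GSM accession) and `samples` (data.frame `accession`, `title`).
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  titles <- grep("^!Sample_title\\b", lines, value = TRUE)
  acc <- grep("^!Sample_geo_accession\\b", lines, value = TRUE)
  strip <- function(x) gsub('^"|"$', "", strsplit(x, "\t")[[1]][-1])
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1)
    validate_error(basename(path), "series matrix table markers not found")
  tab <- utils::read.delim(text = lines[(begin + 1):(end - 1)], header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- gsub('^"|"$', "", as.character(tab[[1]]))
  storage.mode(m) <- "double"
  samples <- data.frame(
    accession = if (length(acc)) strip(acc[1]) else colnames(m),
    title = if (length(titles)) strip(titles[1]) else colnames(m),
    stringsAsFactors = FALSE)
  list(signals = m, samples = samples)
}

#' Assemble an expression dataset from a parsed GEO series matrix
#'
#' @param geo Result of [read_geo_series_matrix()].
#' @param design Data.frame with columns `sample_id` (GSM accession or
#'   title), `N`, `L`, `G`, `replicate`.
#' @param calls Optional calls matrix aligned to the same samples.
#' @return An `expression_dataset`.
#' @export
geo_to_dataset <- function(geo, design, calls = NULL) {
  ids <- design$sample_id
  idx <- match(ids, geo$samples$accession)
  if (anyNA(idx)) idx <- match(ids, geo$samples$title)
  if (anyNA(idx))
    validate_error("design", "sample_ids not found among GEO accessions or titles")
  signals <- geo$signals[, idx, drop = FALSE]
  colnames(signals) <- ids
  expression_dataset(signals, calls, design)
}
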