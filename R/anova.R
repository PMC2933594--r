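# Per-gene full-factorial ANOVA for balanced 2^k designs with binary factors.
#
# In a balanced complete factorial, the classical sums-of-squares
# decomposition reduces to orthogonal +/-1 contrasts on the cell means:
# for a term T with contrast c over the 2^k cells and r replicates per cell,
#   SS_T = r * (c . cellmeans)^2 / 2^k,
# Type I/II/III SS coincide, every effect has 1 df, and the residual df is
# n - 2^k. This closed form is vectorized over genes; tests cross-check it
# against stats::aov.

# term definitions, paper-style factor order
TERMS3 <- list("N" = "N", "L" = "L", "G" = "G",
               "L:N" = c("L", "N"), "L:G" = c("L", "G"), "N:G" = c("N", "G"),
               "N:L:G" = c("N", "L", "G"))
TERMS2 <- list("N" = "N", "L" = "L", "L:N" = c("L", "N"))

# Balanced-factorial engine. Y: genes x samples matrix; fac: data.frame of
# 0/1 factor columns (one row per sample); terms: named list term -> factor
# subset. Returns coef/F/p matrices (genes x terms) plus SS bookkeeping.
balanced_factorial_fit <- function(Y, fac, terms) {
  if (any(!is.finite(Y)))
    stop("non-finite values in response")
  k <- ncol(fac)
  n_cells <- 2L^k
  cell_idx <- as.integer(as.matrix(fac) %*% 2L^(seq_len(k) - 1L)) + 1L
  counts <- tabulate(cell_idx, n_cells)
  if (any(counts == 0))
    validate_error("design", "incomplete factorial design")
  if (length(unique(counts)) != 1)
    validate_error("design", "unbalanced design: unequal cell counts")
  r <- counts[1]
  n <- ncol(Y)
  # cell means: genes x cells
  G <- matrix(0, n, n_cells)
  G[cbind(seq_len(n), cell_idx)] <- 1 / r
  M <- Y %*% G
  # cell-level factor levels, cells indexed 1..2^k by binary code
  cell_lev <- sapply(seq_len(k), function(j) bitwAnd(bitwShiftR(0:(n_cells - 1L), j - 1L), 1L))
  colnames(cell_lev) <- colnames(fac)
  # +/-1 contrast per term
  C <- sapply(terms, function(fs) {
    apply(cell_lev[, fs, drop = FALSE] * 2L - 1L, 1, prod)
  })
  est <- M %*% C                       # genes x terms, c . cellmeans
  ss_term <- r * est^2 / n_cells
  colnames(ss_term) <- names(terms)
  # residual and total SS
  row_mu <- rowMeans(Y)
  ss_tot <- rowSums((Y - row_mu)^2)
  ss_between <- r * rowSums((M - row_mu)^2)
  ss_res <- pmax(ss_tot - ss_between, 0)
  df_res <- n - n_cells
  resid_var <- ss_res / df_res
  # treatment-coded (0/1) coefficients: finite differences of cell means at
  # the zero level of the other factors
  coef <- matrix(NA_real_, nrow(Y), length(terms),
                 dimnames = list(NULL, names(terms)))
  for (tn in names(terms)) {
    fs <- terms[[tn]]
    in_term <- colnames(fac) %in% fs
    use <- rep(TRUE, n_cells)
    for (j in which(!in_term)) use <- use & (cell_lev[, j] == 0L)
    signs <- (-1)^(length(fs) - rowSums(cell_lev[, fs, drop = FALSE]))
    coef[, tn] <- as.vector(M[, use, drop = FALSE] %*% signs[use])
  }
  # zero residual variance: effects undetectable by convention (p = 1)
  degenerate <- ss_res <= 1e-12 * pmax(ss_tot, .Machine$double.xmin)
  Fst <- ss_term / resid_var
  P <- stats::pf(Fst, 1, df_res, lower.tail = FALSE)
  if (any(degenerate)) {
    Fst[degenerate, ] <- NA_real_
    P[degenerate, ] <- 1
  }
  list(terms = names(terms), coef = coef, F = Fst, p = P,
       ss_term = ss_term, ss_residual = ss_res, ss_total = ss_tot,
       df_effect = 1L, df_residual = df_res, residual_var = resid_var,
       cell_means = M, cell_levels = cell_lev, n_replicates = r)
}

apply_transform <- function(x, transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  if (transform == "log2") log2(x + 1) else x
}

fit_to_table <- function(fit, gene_ids) {
  terms <- fit$terms
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (t in terms) {
    key <- gsub(":", ".", t)
    out[[paste0("coef_", key)]] <- fit$coef[, t]
    out[[paste0("F_", key)]] <- fit$F[, t]
    out[[paste0("p_", key)]] <- fit$p[, t]
  }
  out$df_residual <- fit$df_residual
  out$residual_var <- fit$residual_var
  attr(out, "terms") <- terms
  attr(out, "ss") <- list(term = fit$ss_term, residual = fit$ss_residual,
                          total = fit$ss_total)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Extract the p-value (or F, coef) matrix from an ANOVA table
#'
#' @param table An `anova_table`.
#' @param what One of `"p"`, `"F"`, `"coef"`.
#' @return Numeric matrix genes x terms with gene_id rownames.
#' @export
anova_matrix <- function(table, what = c("p", "F", "coef")) {
  what <- match.arg(what)
  terms <- attr(table, "terms")
  m <- as.matrix(table[, paste0(what, "_", gsub(":", ".", terms)), drop = FALSE])
  dimnames(m) <- list(table$gene_id, terms)
  m
}

#' Fit the 3-way factorial ANOVA for a single gene
#'
#' Models the (transformed) signal of one gene as
#' `y ~ N + L + G + L:N + L:G + N:G + N:L:G` over the balanced 2x2x2
#' design, returning treatment-coded coefficients, F statistics and
#' p-values for all seven terms. Genes with zero residual variance get
#' p = 1 for every term (no within-cell noise means no valid F test; such
#' genes are treated as undetectable rather than infinitely significant).
#'
#' @param values Numeric vector of linear-scale signals, one per sample.
#' @param design A `sample_design` (rows aligned to `values`).
#' @param transform `"log2"` (default; `log2(x + 1)`) or `"identity"`.
#' @return One-row `anova_table`.
#' @export
fit_gene_anova <- function(values, design, transform = "log2") {
  design <- sample_design(design)
  if (length(values) != nrow(design))
    stop("length(values) must equal nrow(design)")
  Y <- matrix(apply_transform(as.numeric(values), transform), nrow = 1)
  fit <- balanced_factorial_fit(Y, design[, c("N", "L", "G")], TERMS3)
  fit_to_table(fit, "gene")
}

#' Fit the 3-way factorial ANOVA for every gene
#'
#' Vectorized over the whole signal matrix; numerically identical to
#' calling [fit_gene_anova()] per gene.
#'
#' @param ds An `expression_dataset` (typically after
#'   [filter_by_detection_calls()]).
#' @param transform `"log2"` (default) or `"identity"`.
#' @return An `anova_table` with one row per gene.
#' @export
fit_all <- function(ds, transform = "log2") {
  Y <- apply_transform(ds$signals, transform)
  fit <- balanced_factorial_fit(Y, ds$design[, c("N", "L", "G")], TERMS3)
  fit_to_table(fit, rownames(ds$signals))
}

#' Fit a 2-way (N, L) ANOVA within one genotype
#'
#' Restricts the dataset to samples at `genotype_level` and fits the
#' balanced 2x2 factorial `y ~ N + L + L:N` per gene, with the same
#' conventions as the 3-way engine.
#'
#' @param ds An `expression_dataset`.
#' @param genotype_level 0 (wild type) or 1 (mutant).
#' @param transform `"log2"` or `"identity"`.
#' @return An `anova_table` with terms `N`, `L`, `L:N`.
#' @export
fit_subset_anova <- function(ds, genotype_level, transform = "log2") {
  stopifnot(genotype_level %in% c(0, 1))
  keep <- ds$design$G == genotype_level
  Y <- apply_transform(ds$signals[, keep, drop = FALSE], transform)
  fit <- balanced_factorial_fit(Y, ds$design[keep, c("N", "L")], TERMS2)
  fit_to_table(fit, rownames(ds$signals))
}

#' Plug-in false-discovery-rate estimate at a fixed cutoff
#'
#' Benjamini–Hochberg-style estimate of the FDR incurred by rejecting all
#' hypotheses with p <= alpha: `(alpha * m) / max(1, #\{p <= alpha\})`,
#' where m is the number of tests. Used as a calibration report alongside
#' the fixed p-value cutoff, never as a second filter.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha Rejection cutoff (default 0.01).
#' @return Estimated FDR (may exceed 1 on pure-null input).
#' @export
estimate_fdr <- function(pvalues, alpha = 0.01) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  (alpha * length(pvalues)) / max(1, sum(pvalues <= alpha, na.rm = TRUE))
}

#' Per-term significant gene lists at a p-value cutoff
#'
#' For each ANOVA term, collects the genes with p <= alpha, ordered by
#' ascending p with ties broken by gene_id, and attaches the per-term and
#' pooled plug-in FDR estimates.
#'
#' @param table An `anova_table` from [fit_all()].
#' @param alpha Cutoff (default 0.01).
#' @return Object of class `term_gene_lists`: list with `lists` (term ->
#'   gene_id vector), `counts`, `fdr` (per term), `fdr_pooled`, `alpha`.
#' @export
select_genes <- function(table, alpha = 0.01) {
  P <- anova_matrix(table, "p")
  lists <- lapply(colnames(P), function(t) {
    p <- P[, t]
    sel <- which(p <= alpha)
    sel <- sel[order(p[sel], rownames(P)[sel])]
    rownames(P)[sel]
  })
  names(lists) <- colnames(P)
  structure(list(lists = lists,
                 counts = vapply(lists, length, integer(1)),
                 fdr = vapply(colnames(P), function(t) estimate_fdr(P[, t], alpha),
                              numeric(1)),
                 fdr_pooled = estimate_fdr(as.vector(P), alpha),
                 alpha = alpha),
            class = "term_gene_lists")
}

#' @export
print.term_gene_lists <- function(x, ...) {
  cat(sprintf("significant genes at p <= %g (plug-in FDR pooled: %.3f)\n",
              x$alpha, x$fdr_pooled))
  for (t in names(x$lists))
    cat(sprintf("  %-6s %5d genes (term FDR %.3f)\n", t, x$counts[[t]], x$fdr[[t]]))
  invisible(x)
}

#' Union of the genotype-dependent gene lists
#'
#' Genes for which the genotype factor matters on its own or in any
#' interaction: the set union of the `G`, `N:G`, `L:G` and `N:L:G` lists,
#' ordered by gene_id for reproducibility.
#'
#' @param lists A `term_gene_lists`.
#' @return Character vector of gene ids.
#' @export
genotype_union <- function(lists) {
  need <- c("G", "N:G", "L:G", "N:L:G")
  miss <- setdiff(need, names(lists$lists))
  if (length(miss) > 0)
    stop("missing term list(s): ", paste(miss, collapse = ", "))
  sort(unique(unlist(lists$lists[need], use.names = FALSE)))
}
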