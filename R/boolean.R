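# Cluster-level ANOVA, centroid binarization, Boolean gate inference and
# de-regulation typing.
#
# Per cluster and genotype, the 4-cell centroid (replicate-averaged,
# per-gene z-scored) is binarized into a high/low truth table over (N, L);
# a two-input Boolean function consistent with both the table and the
# cluster ANOVA is selected; and the wild-type/mutant pair of functions is
# classified as attenuation, inversion, hidden or complex de-regulation.

#' Cluster-level factorial ANOVA
#'
#' Fits the factorial ANOVA on all member genes of a cluster, keeping the
#' biological replicates as separate observations: the response stacks the
#' per-gene z-scored log2 signals over genes x samples, so every member
#' gene contributes equally regardless of its expression level. With
#' `genotype = NULL` the full 3-way model is fitted; with `genotype` 0 or 1
#' the 2-way (N, L) model on that genotype's samples.
#'
#' @param ds An `expression_dataset`.
#' @param genes Member gene ids (>= 1; a single-gene, single-replicate
#'   cluster is degenerate and rejected).
#' @param genotype `NULL`, 0 or 1.
#' @param transform `"log2"` or `"identity"`.
#' @param standardize Z-score each gene across all samples first
#'   (default TRUE).
#' @return Object of class `cluster_anova`: data.frame of `term`, `F`,
#'   `p`, `direction` (sign of the term's contrast on cell means), with
#'   the genotype's cell means in `attr(, "cell_means")`.
#' @export
fit_cluster_anova <- function(ds, genes, genotype = NULL, transform = "log2",
                              standardize = TRUE) {
  if (length(genes) == 0) stop("empty cluster")
  Y <- apply_transform(ds$signals[genes, , drop = FALSE], transform)
  if (standardize) {
    mu <- rowMeans(Y)
    s <- apply(Y, 1, stats::sd)
    Y <- (Y - mu) / ifelse(s > 0, s, 1)
  }
  design <- ds$design
  if (!is.null(genotype)) {
    stopifnot(genotype %in% c(0, 1))
    keep <- design$G == genotype
    Y <- Y[, keep, drop = FALSE]
    design <- design[keep, , drop = FALSE]
    terms <- TERMS2
    fac <- design[, c("N", "L")]
  } else {
    terms <- TERMS3
    fac <- design[, c("N", "L", "G")]
  }
  if (length(genes) == 1 && max(design$replicate) == 1)
    stop("degenerate cluster: single gene with a single replicate")
  # stack genes as repeated observations of the cluster profile
  stacked <- matrix(as.vector(t(Y)), nrow = 1)
  fac_rep <- fac[rep(seq_len(nrow(fac)), times = length(genes)), , drop = FALSE]
  fit <- balanced_factorial_fit(stacked, fac_rep, terms)
  lev <- fit$cell_levels
  cmeans <- fit$cell_means[1, ]
  direction <- vapply(fit$terms, function(t) {
    c_t <- apply(lev[, terms[[t]], drop = FALSE] * 2L - 1L, 1, prod)
    sign(sum(c_t * cmeans))
  }, numeric(1))
  out <- data.frame(term = fit$terms, F = fit$F[1, ], p = fit$p[1, ],
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  # cell means in canonical order for binarization/magnitudes
  cm <- cmeans
  if (is.null(genotype)) {
    names(cm) <- cell_label(lev[, "N"], lev[, "L"], lev[, "G"])
    cm <- cm[condition_labels()]
  } else {
    names(cm) <- paste0(ifelse(lev[, "N"] == 1, "+N", "-N"),
                        ifelse(lev[, "L"] == 1, "+L", "-L"))
    cm <- cm[LOGIC_CELLS]
  }
  n_obs_cell <- fit$n_replicates
  se <- sqrt(fit$residual_var[1] / n_obs_cell)
  structure(out, cell_means = cm, cell_se = rep(se, length(cm)),
            n_genes = length(genes), genotype = genotype,
            class = c("cluster_anova", "data.frame"))
}

#' Binarize a genotype's 4-condition centroid into a truth table
#'
#' Thresholds each (N, L) cell at the midpoint of the centroid's min and
#' max: cells above the midpoint are high (1), below low (0); cells within
#' `dead_band * range` of the midpoint are ambiguous (`NA`). A flat
#' profile, with range below `noise_floor`, yields an all-ambiguous table
#' signalling "unregulated".
#'
#' @param centroid Numeric vector of 4 cell means in canonical (N, L)
#'   order `-N-L, +N-L, -N+L, +N+L`.
#' @param se Optional per-cell standard errors, used for the default noise
#'   floor.
#' @param dead_band Half-width of the ambiguity band as a fraction of the
#'   range (default 0.25).
#' @param noise_floor Minimal range for the profile to count as regulated;
#'   default `4 * median(se)` (0 when no SEs are given).
#' @return Integer vector of length 4 with `NA` for ambiguous cells;
#'   `attr(, "regulated")` is FALSE when all cells are ambiguous.
#' @export
binarize_profiles <- function(centroid, se = NULL, dead_band = 0.25,
                              noise_floor = NULL) {
  stopifnot(length(centroid) == 4)
  if (is.null(noise_floor))
    noise_floor <- if (is.null(se)) 0 else 4 * stats::median(se, na.rm = TRUE)
  rng <- max(centroid) - min(centroid)
  if (rng < noise_floor || rng == 0) {
    tt <- rep(NA_integer_, 4)
  } else {
    mid <- (max(centroid) + min(centroid)) / 2
    tt <- ifelse(centroid > mid, 1L, 0L)
    tt[abs(centroid - mid) < dead_band * rng] <- NA_integer_
  }
  names(tt) <- LOGIC_CELLS
  structure(tt, regulated = !all(is.na(tt)), range = rng)
}

# boolean contrast pattern of a truth table: which of the N, L, N:L
# contrasts are non-zero
table_contrasts <- function(tt) {
  c(N = (tt[2] + tt[4]) - (tt[1] + tt[3]),
    L = (tt[3] + tt[4]) - (tt[1] + tt[2]),
    `L:N` = tt[4] - tt[3] - tt[2] + tt[1])
}

#' Infer the Boolean gate for one genotype of a cluster
#'
#' Searches the 16 two-input Boolean functions for the regulation that
#' explains both the binarized centroid and the cluster ANOVA. A candidate
#' is eliminated when it is inconsistent with a significant ANOVA term — a
#' significant interaction demands a non-additive function, a significant
#' main effect a function actually depending on that input — or when it
#' contradicts the truth table on an unambiguous cell. Non-significant
#' terms never eliminate (absence of evidence); instead, ties among
#' surviving candidates are broken by minimal description (fewer inputs,
#' then fewer negations), so a sole significant main effect with a
#' single-input-compatible table yields the single-input function, and
#' finally by agreement with the centroid (the dominant contrast's
#' direction). With no surviving candidate an `"UNRESOLVED"` spec is
#' returned — the inference never guesses.
#'
#' @param table Binarized truth table from [binarize_profiles()].
#' @param cluster_anova The genotype's 2-way `cluster_anova`.
#' @param alpha Significance cutoff for cluster-level terms (default 0.01,
#'   inherited from the gene-level cutoff).
#' @return A `boolean_spec` (canonical form, see [spec_from_table()]).
#' @export
infer_boolean_gate <- function(table, cluster_anova, alpha = 0.01) {
  sig <- stats::setNames(cluster_anova$p <= alpha, cluster_anova$term)
  sig <- sig[c("N", "L", "L:N")]
  # an edge is only ever drawn for a significant signal: without any
  # significant term the genotype is unregulated, whatever the table hints
  if (!any(sig)) return(boolean_spec())
  cand <- all_truth_tables()
  matches_table <- vapply(cand, function(tt) {
    ok <- is.na(table) | (tt == table)
    all(ok)
  }, logical(1))
  pattern_ok <- vapply(cand, function(tt) {
    ctr <- table_contrasts(tt) != 0
    all(ctr[sig])  # every significant term must have a non-zero contrast
  }, logical(1))
  cm <- attr(cluster_anova, "cell_means")
  pick <- function(idx) {
    specs <- lapply(cand[idx], spec_from_table)
    cx <- t(vapply(specs, spec_complexity, numeric(2)))
    # minimal description first; remaining ties resolved by agreement of the
    # candidate table with the centroid (dominant-contrast direction)
    score <- if (is.null(cm)) rep(0, length(idx)) else
      -vapply(cand[idx], function(tt) sum(cm * (tt - mean(tt))), numeric(1))
    specs[[order(cx[, 1], cx[, 2], score)[1]]]
  }
  both <- which(matches_table & pattern_ok)
  if (length(both) > 0) return(pick(both))
  if (!anyNA(table)) {
    # fully determined table: trust it over a noisy significance pattern
    exact <- which(matches_table)
    if (length(exact) > 0) return(pick(exact))
  }
  boolean_spec(c("N", "L"), c(FALSE, FALSE), "UNRESOLVED")
}

#' Classify a cluster's genotype-dependent de-regulation
#'
#' Decision cascade on the wild-type and mutant regulation. A genotype
#' counts as \emph{unregulated} when all its cluster ANOVA terms are
#' non-significant or its binarized table is all-ambiguous. The cascade:
#' \enumerate{
#'   \item \strong{none} — neither genotype regulated, or identical
#'     regulation without attenuation (no genotype-dependent change).
#'   \item \strong{hidden} — wild type unregulated while the mutant is
#'     regulated: the mutation reveals a new regulation.
#'   \item \strong{inversion} — same cells regulated but with opposite
#'     sign (the mutant truth table is the complement of the wild-type
#'     one).
#'   \item \strong{attenuation} — the mutant shows the same regulation at
#'     a magnitude (centroid range) below `theta` times the wild-type
#'     magnitude. This includes the limit where the weakened mutant
#'     response can no longer support a gate of its own: significant
#'     mutant terms whose binarized table does not contradict the
#'     wild-type table on any unambiguous cell, at ratio < `theta`, are
#'     attenuated wild-type regulation.
#'   \item \strong{complex} — everything else: unresolved gates,
#'     regulation fully lost in the mutant (no significant mutant term),
#'     and partial/condition-dependent flips.
#' }
#' The cascade is total and deterministic. Note the asymmetry: regulation
#' appearing only in the mutant is "hidden", regulation lost in the mutant
#' is "complex".
#'
#' @param wt_spec,mut_spec `boolean_spec` per genotype.
#' @param wt_anova,mut_anova The genotypes' 2-way `cluster_anova` fits.
#' @param theta Attenuation threshold on the mutant/wild-type magnitude
#'   ratio (default 0.5).
#' @param alpha Significance cutoff used for the "unregulated" judgement.
#' @param wt_table,mut_table Binarized truth tables from
#'   [binarize_profiles()]; recomputed from the ANOVA cell means when
#'   omitted.
#' @param dead_band Binarization band used when tables are recomputed.
#' @return Object of class `deregulation_call`: list with `class`,
#'   `wt_spec`, `mut_spec` (modulator filled in) and `evidence`.
#' @export
classify_deregulation <- function(wt_spec, mut_spec, wt_anova, mut_anova,
                                  theta = 0.5, alpha = 0.01,
                                  wt_table = NULL, mut_table = NULL,
                                  dead_band = 0.25) {
  if (is.null(wt_table))
    wt_table <- binarize_profiles(attr(wt_anova, "cell_means"),
                                  attr(wt_anova, "cell_se"), dead_band)
  if (is.null(mut_table))
    mut_table <- binarize_profiles(attr(mut_anova, "cell_means"),
                                   attr(mut_anova, "cell_se"), dead_band)
  mag <- function(an) {
    cm <- attr(an, "cell_means")
    max(cm) - min(cm)
  }
  any_sig <- function(an) any(an$p <= alpha)
  wt_reg <- !is_unregulated(wt_spec) && any_sig(wt_anova) &&
    attr(wt_table, "regulated")
  mut_reg <- !is_unregulated(mut_spec) && any_sig(mut_anova) &&
    attr(mut_table, "regulated")
  wt_mag <- mag(wt_anova); mut_mag <- mag(mut_anova)
  ratio <- if (wt_mag > 0) mut_mag / wt_mag else NA_real_
  evidence <- list(wt_magnitude = wt_mag, mut_magnitude = mut_mag,
                   magnitude_ratio = ratio,
                   wt_min_p = min(wt_anova$p), mut_min_p = min(mut_anova$p),
                   theta = theta, alpha = alpha)
  # a weakened mutant response consistent with the wild-type table: no
  # unambiguous mutant cell contradicts an unambiguous wild-type cell
  compatible <- !any(!is.na(wt_table) & !is.na(mut_table) &
                       wt_table != mut_table)
  attenuated <- wt_reg && any_sig(mut_anova) && compatible &&
    !is.na(ratio) && ratio < theta
  cls <-
    if (!wt_reg && !mut_reg) "none"
    else if (!wt_reg && mut_reg) "hidden"
    else if (wt_reg && !mut_reg) {
      if (attenuated) "attenuation" else "complex"
    }
    else if (is_unresolved(wt_spec) || is_unresolved(mut_spec)) {
      if (attenuated) "attenuation" else "complex"
    }
    else {
      wt_tt <- unname(spec_truth_table(wt_spec))
      mut_tt <- unname(spec_truth_table(mut_spec))
      if (identical(mut_tt, 1L - wt_tt)) "inversion"
      else if (identical(mut_tt, wt_tt)) {
        if (!is.na(ratio) && ratio < theta) "attenuation" else "none"
      }
      else if (attenuated) "attenuation"
      else "complex"
    }
  if (cls == "attenuation" && !spec_equivalent(mut_spec, wt_spec))
    mut_spec <- wt_spec  # attenuated copy of the wild-type regulation
  # an arm judged unregulated by the cascade carries no supported edge
  if (cls == "hidden" && !is_unregulated(wt_spec)) wt_spec <- boolean_spec()
  if (cls == "none" && !wt_reg && !is_unregulated(wt_spec)) wt_spec <- boolean_spec()
  if (cls == "none" && !mut_reg && !is_unregulated(mut_spec)) mut_spec <- boolean_spec()
  mut_spec$modulator <- switch(cls,
    none = "absent",
    attenuation = "enables",
    hidden = if (mean(attr(mut_anova, "cell_means")) >=
                 mean(attr(wt_anova, "cell_means"))) "represses" else "enables",
    inversion = "switches",
    complex = "switches")
  structure(list(class = cls, wt_spec = wt_spec, mut_spec = mut_spec,
                 evidence = evidence),
            class = "deregulation_call")
}

#' @export
print.deregulation_call <- function(x, ...) {
  cat(sprintf("%s  [WT: %s | mut: %s]\n", x$class, format(x$wt_spec),
              format(x$mut_spec)))
  invisible(x)
}

#' Infer Boolean models and de-regulation classes for all clusters
#'
#' For each cluster: 2-way cluster ANOVAs per genotype, centroid
#' binarization, gate inference per genotype, and the de-regulation
#' cascade; the 3-way cluster ANOVA is attached as evidence.
#'
#' @param ds An `expression_dataset`.
#' @param clusters A `gene_clusters` object (or list of gene-id vectors).
#' @param alpha Cluster-level significance cutoff (default 0.01).
#' @param theta Attenuation threshold (default 0.5).
#' @param dead_band Binarization ambiguity band (default 0.25).
#' @param transform `"log2"` or `"identity"`.
#' @return Object of class `boolean_model_set`: per cluster a list with
#'   `cluster_id`, `genes`, `wt_spec`, `mut_spec`, `class`, `evidence`,
#'   `anova3` (term/F/p data.frame).
#' @export
infer_cluster_models <- function(ds, clusters, alpha = 0.01, theta = 0.5,
                                 dead_band = 0.25, transform = "log2") {
  out <- lapply(clusters, function(cl) {
    genes <- if (is.list(cl)) cl$genes else cl
    cid <- if (is.list(cl)) cl$cluster_id else NA_character_
    wt_an <- fit_cluster_anova(ds, genes, genotype = 0, transform = transform)
    mut_an <- fit_cluster_anova(ds, genes, genotype = 1, transform = transform)
    an3 <- fit_cluster_anova(ds, genes, genotype = NULL, transform = transform)
    wt_tt <- binarize_profiles(attr(wt_an, "cell_means"),
                               attr(wt_an, "cell_se"), dead_band)
    mut_tt <- binarize_profiles(attr(mut_an, "cell_means"),
                                attr(mut_an, "cell_se"), dead_band)
    wt_spec <- infer_boolean_gate(wt_tt, wt_an, alpha)
    mut_spec <- infer_boolean_gate(mut_tt, mut_an, alpha)
    call <- classify_deregulation(wt_spec, mut_spec, wt_an, mut_an,
                                  theta = theta, alpha = alpha,
                                  wt_table = wt_tt, mut_table = mut_tt,
                                  dead_band = dead_band)
    list(cluster_id = cid, genes = genes, size = length(genes),
         wt_spec = call$wt_spec, mut_spec = call$mut_spec,
         class = call$class, evidence = call$evidence,
         wt_table = wt_tt, mut_table = mut_tt,
         anova3 = as.data.frame(an3))
  })
  structure(out, class = "boolean_model_set")
}

#' @export
print.boolean_model_set <- function(x, ...) {
  for (m in x)
    cat(sprintf("%-11s n=%-3d %-12s WT: %-28s mut: %s\n", m$cluster_id,
                m$size, m$class, format(m$wt_spec), format(m$mut_spec)))
  invisible(x)
}

#' Tally of de-regulation classes in a model set
#' @param models A `boolean_model_set`.
#' @return Named integer vector.
#' @export
class_tally <- function(models) {
  cls <- vapply(models, `[[`, character(1), "class")
  table(factor(cls, levels = c("attenuation", "inversion", "hidden",
                               "complex", "none")))
}
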