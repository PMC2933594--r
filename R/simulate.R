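# Synthetic factorial expression data with planted Boolean regulatory logic.
#
# The generator emulates the shape of a 24-array experiment: a balanced
# 2x2x2 design (nitrogen x light x genotype) with 3 biological replicates,
# log-normal baseline signals, additive effects on the log2 scale, gene
# clusters sharing a planted Boolean function of (N, L) per genotype, and
# detection calls thresholded on the linear signal. Every downstream stage
# can therefore be validated against known truth.

#' Define a planted gene cluster
#'
#' Each member gene follows
#' `log2(signal) = baseline + dir * effect * f(N, L) + noise`,
#' where `f` is the genotype's Boolean gate output, `dir` is +1 for
#' activation and -1 for repression, and the mutant effect is additionally
#' scaled by `mut_effect_factor` (0.3 plants an attenuated regulation).
#'
#' @param n_genes Number of member genes.
#' @param wt_logic,mut_logic `boolean_spec` objects or strings for
#'   [parse_logic()] (wild-type and mutant regulation; `"0"` = unregulated).
#' @param effect_size Effect amplitude in log2 units (>= 0).
#' @param mut_effect_factor Multiplier on the mutant effect (default 1).
#' @param baseline_mean,baseline_sd Log2-scale baseline distribution.
#' @param deregulation_class Optional label consistent with
#'   [classify_deregulation()]; derived from the logic pair when `NULL`.
#' @return Object of class `planted_cluster`.
#' @export
planted_cluster <- function(n_genes, wt_logic, mut_logic = wt_logic,
                            effect_size = 0.75, mut_effect_factor = 1,
                            baseline_mean = 8, baseline_sd = 1.5,
                            deregulation_class = NULL) {
  if (is.character(wt_logic)) wt_logic <- parse_logic(wt_logic)
  if (is.character(mut_logic)) mut_logic <- parse_logic(mut_logic)
  stopifnot(inherits(wt_logic, "boolean_spec"), inherits(mut_logic, "boolean_spec"),
            n_genes >= 1, effect_size >= 0, mut_effect_factor >= 0)
  if (is.null(deregulation_class))
    deregulation_class <- planted_class(wt_logic, mut_logic, mut_effect_factor)
  structure(list(n_genes = as.integer(n_genes), wt_logic = wt_logic,
                 mut_logic = mut_logic, effect_size = effect_size,
                 mut_effect_factor = mut_effect_factor,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 deregulation_class = deregulation_class),
            class = "planted_cluster")
}

#' De-regulation class implied by a planted logic pair
#'
#' Applies the same decision cascade as [classify_deregulation()] to the
#' noiseless planted truth, so generator labels and classifier output use
#' one definition.
#'
#' @param wt_logic,mut_logic `boolean_spec` objects.
#' @param mut_effect_factor Mutant effect multiplier.
#' @param theta Attenuation threshold (mutant/wild-type magnitude ratio).
#' @return One of `"none"`, `"attenuation"`, `"inversion"`, `"hidden"`,
#'   `"complex"`.
#' @export
planted_class <- function(wt_logic, mut_logic, mut_effect_factor = 1, theta = 0.5) {
  wt_reg <- !is_unregulated(wt_logic)
  mut_reg <- !is_unregulated(mut_logic) && mut_effect_factor > 0
  if (!wt_reg && !mut_reg) return("none")
  if (!wt_reg && mut_reg) return("hidden")
  if (wt_reg && !mut_reg) return("complex")
  wt_tt <- unname(spec_truth_table(wt_logic))
  mut_tt <- unname(spec_truth_table(mut_logic))
  if (identical(mut_tt, 1L - wt_tt)) return("inversion")
  if (identical(mut_tt, wt_tt)) {
    if (mut_effect_factor < theta) return("attenuation")
    return("none")
  }
  "complex"
}

#' Simulation configuration
#'
#' @param clusters List of [planted_cluster()] objects (may be empty).
#' @param n_background_genes Unregulated baseline-only genes.
#' @param n_replicates Biological replicates per design cell (default 3).
#' @param noise_sd Residual SD on the log2 scale (> 0; default 0.25, a
#'   typical replicate variability for normalized array intensities).
#' @param baseline_mean,baseline_sd Log2-scale baseline distribution for
#'   background genes.
#' @param call_threshold Linear signal below which a sample's detection
#'   call is Absent (default 4).
#' @param seed Integer seed; fixed seed implies bit-reproducible output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(clusters = list(), n_background_genes = 0,
                              n_replicates = 3, noise_sd = 0.25,
                              baseline_mean = 8, baseline_sd = 1.5,
                              call_threshold = 4, seed = 1) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (length(clusters) == 0 && n_background_genes == 0)
    stop("config error: zero clusters and zero background genes")
  stopifnot(all(vapply(clusters, inherits, logical(1), "planted_cluster")))
  structure(list(clusters = clusters,
                 n_background_genes = as.integer(n_background_genes),
                 n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 call_threshold = call_threshold, seed = as.integer(seed)),
            class = "simulation_config")
}

# run code under a private RNG stream keyed by seed, restoring global state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# canonical design grid: genotype outer, then light, then nitrogen, then
# replicate, so samples follow the canonical condition order
make_design <- function(n_replicates) {
  grid <- expand.grid(replicate = seq_len(n_replicates), N = 0:1, L = 0:1, G = 0:1,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("N", "L", "G", "replicate")]
  grid$sample_id <- sprintf("G%d.L%d.N%d.R%d", grid$G, grid$L, grid$N, grid$replicate)
  sample_design(grid[, c("sample_id", "N", "L", "G", "replicate")])
}

#' Generate a factorial dataset with planted cluster structure
#'
#' @param cfg A [simulation_config()].
#' @return List with `dataset` (an `expression_dataset`, linear-scale
#'   signals) and `truth`: `gene_cluster` (named vector gene ->
#'   `"background"` or `"cluster_<i>"`) and `clusters` (per cluster the
#'   planted specs, effect size, mutant factor and class).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    design <- make_design(cfg$n_replicates)
    ns <- nrow(design)
    total_genes <- sum(vapply(cfg$clusters, `[[`, integer(1), "n_genes")) +
      cfg$n_background_genes
    gene_ids <- sprintf("gene_%05d", seq_len(total_genes))
    log2sig <- matrix(NA_real_, total_genes, ns,
                      dimnames = list(gene_ids, design$sample_id))
    cluster_of <- rep("background", total_genes)
    truth_clusters <- list()
    row <- 0L
    for (ci in seq_along(cfg$clusters)) {
      cl <- cfg$clusters[[ci]]
      cid <- sprintf("cluster_%02d", ci)
      wt_tt <- spec_gate_table(cl$wt_logic)
      mut_tt <- spec_gate_table(cl$mut_logic)
      wt_dir <- if (cl$wt_logic$sign == "activation") 1 else -1
      mut_dir <- if (cl$mut_logic$sign == "activation") 1 else -1
      cell <- 1L + design$N + 2L * design$L   # index into the 4 (N,L) cells
      shift <- ifelse(design$G == 0,
                      wt_dir * cl$effect_size * wt_tt[cell],
                      mut_dir * cl$effect_size * cl$mut_effect_factor * mut_tt[cell])
      for (g in seq_len(cl$n_genes)) {
        row <- row + 1L
        base <- stats::rnorm(1, cl$baseline_mean, cl$baseline_sd)
        log2sig[row, ] <- base + shift + stats::rnorm(ns, 0, cfg$noise_sd)
        cluster_of[row] <- cid
      }
      truth_clusters[[cid]] <- list(
        genes = gene_ids[(row - cl$n_genes + 1L):row],
        wt_logic = cl$wt_logic, mut_logic = cl$mut_logic,
        effect_size = cl$effect_size, mut_effect_factor = cl$mut_effect_factor,
        deregulation_class = cl$deregulation_class)
    }
    if (cfg$n_background_genes > 0) {
      idx <- (row + 1L):total_genes
      base <- stats::rnorm(length(idx), cfg$baseline_mean, cfg$baseline_sd)
      log2sig[idx, ] <- base +
        matrix(stats::rnorm(length(idx) * ns, 0, cfg$noise_sd), length(idx), ns)
    }
    signals <- 2^log2sig
    calls <- matrix(ifelse(signals < cfg$call_threshold, "A", "P"),
                    nrow(signals), ncol(signals), dimnames = dimnames(signals))
    ds <- expression_dataset(signals, calls, design)
    list(dataset = ds,
         truth = list(gene_cluster = stats::setNames(cluster_of, gene_ids),
                      clusters = truth_clusters))
  })
}

#' Generate a pure-noise (null) dataset
#'
#' Every gene is baseline plus log-normal noise with no factor effects;
#' used for type-I-error and FDR calibration checks.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per design cell.
#' @param noise_sd Residual SD, log2 scale (> 0).
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Log2 baseline distribution.
#' @return An `expression_dataset`.
#' @export
generate_null_dataset <- function(n_genes, n_replicates = 3, noise_sd = 0.25,
                                  seed = 1, baseline_mean = 8, baseline_sd = 1.5) {
  cfg <- simulation_config(n_background_genes = n_genes,
                           n_replicates = n_replicates, noise_sd = noise_sd,
                           baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                           seed = seed)
  generate_dataset(cfg)$dataset
}

#' Generate a sparse-signal mixture dataset for FDR calibration
#'
#' A fraction of genes receive effects of `effect_size` (log2 units) on all
#' seven factorial contrasts, so `signal_fraction` of the 7-per-gene
#' hypotheses are non-null; the rest are pure noise. Returns the dataset
#' and the planted regulated gene ids.
#'
#' @param n_genes Total genes.
#' @param signal_fraction Fraction of regulated genes (default 0.05).
#' @param effect_size Per-contrast effect, log2 units.
#' @param noise_sd Residual SD, log2 scale.
#' @param n_replicates Replicates per cell.
#' @param seed Integer seed.
#' @return List with `dataset` and `regulated` (gene ids).
#' @export
generate_mixture_dataset <- function(n_genes, signal_fraction = 0.05,
                                     effect_size = 0.75, noise_sd = 0.25,
                                     n_replicates = 3, seed = 1) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  with_seed(seed, {
    design <- make_design(n_replicates)
    ns <- nrow(design)
    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    n_sig <- round(signal_fraction * n_genes)
    base <- stats::rnorm(n_genes, 8, 1.5)
    log2sig <- base + matrix(stats::rnorm(n_genes * ns, 0, noise_sd), n_genes, ns)
    if (n_sig > 0) {
      # half-effect on each +/-1 contrast so each cell mean shifts by a
      # bounded amount while every term's F gets the same non-centrality
      contr <- sapply(TERMS3, function(fs) {
        v <- rep(1, ns)
        for (f in fs) v <- v * (2 * design[[f]] - 1)
        v
      })
      sgn <- matrix(sample(c(-1, 1), n_sig * 7, replace = TRUE), n_sig, 7)
      shifts <- sgn %*% t(contr) * (effect_size / 2)
      log2sig[seq_len(n_sig), ] <- log2sig[seq_len(n_sig), , drop = FALSE] + shifts
    }
    rownames(log2sig) <- gene_ids
    colnames(log2sig) <- design$sample_id
    signals <- 2^log2sig
    calls <- matrix("P", n_genes, ns, dimnames = dimnames(signals))
    ds <- expression_dataset(signals, calls, design)
    list(dataset = ds, regulated = gene_ids[seq_len(n_sig)])
  })
}

#' The twenty-cluster study roster
#'
#' A fixed roster of 20 planted clusters emulating the published study's
#' outcome shape: cluster sizes spanning 4 to 20 genes, five clusters per
#' de-regulation archetype (attenuation, inversion, hidden, complex), each
#' with a distinct wild-type/mutant Boolean logic pair so clusters are
#' mutually distinguishable by their 8-condition profiles.
#'
#' @param effect_size Effect amplitude, log2 units (default 0.75 = 3 x the
#'   default noise SD).
#' @param attenuation_factor Mutant effect multiplier for attenuation
#'   clusters (default 0.3).
#' @return List of 20 `planted_cluster` objects.
#' @export
study_cluster_roster <- function(effect_size = 0.75, attenuation_factor = 0.3) {
  # Wild-type / mutant high-expression truth tables over the canonical
  # (N, L) cells (-N-L, +N-L, -N+L, +N+L). A recovery benchmark is only
  # meaningful when the planted clusters are mutually identifiable, so the
  # logic pairs were chosen to minimize the pairwise correlation of the
  # joint 8-condition centroid shapes (profile-based clustering cannot
  # separate near-collinear centroids regardless of sample size), and the
  # larger memberships go to the attenuation clusters, whose mutant arm
  # carries the weakest signal. All four de-regulation archetypes are
  # represented (6 attenuation, 5 inversion, 5 hidden, 4 complex);
  # cluster sizes span 4-20 genes, 240 genes in total.
  tt <- function(s) as.integer(strsplit(s, "")[[1]])
  defs <- list(
    # attenuation: same table, mutant effect scaled by attenuation_factor
    list(wt = "0110", mut = "0110", f = attenuation_factor, size = 20L),
    list(wt = "1100", mut = "1100", f = attenuation_factor, size = 19L),
    list(wt = "1001", mut = "1001", f = attenuation_factor, size = 18L),
    list(wt = "0011", mut = "0011", f = attenuation_factor, size = 17L),
    list(wt = "1010", mut = "1010", f = attenuation_factor, size = 17L),
    list(wt = "0111", mut = "0111", f = attenuation_factor, size = 16L),
    # inversion: mutant table is the complement
    list(wt = "1110", mut = "0001", f = 1, size = 4L),
    list(wt = "0100", mut = "1011", f = 1, size = 5L),
    list(wt = "1011", mut = "0100", f = 1, size = 6L),
    list(wt = "1101", mut = "0010", f = 1, size = 7L),
    list(wt = "0010", mut = "1101", f = 1, size = 7L),
    # hidden: unregulated wild type, regulated mutant
    list(wt = "0000", mut = "0110", f = 1, size = 9L),
    list(wt = "0000", mut = "1100", f = 1, size = 10L),
    list(wt = "0000", mut = "1001", f = 1, size = 11L),
    list(wt = "0000", mut = "0101", f = 1, size = 12L),
    list(wt = "0000", mut = "0011", f = 1, size = 12L),
    # complex: genotype-dependent logic differing in one design cell
    list(wt = "0110", mut = "1110", f = 1, size = 8L),
    list(wt = "1110", mut = "0110", f = 1, size = 13L),
    list(wt = "1000", mut = "1010", f = 1, size = 14L),
    list(wt = "0101", mut = "0111", f = 1, size = 15L)
  )
  lapply(defs, function(d) {
    planted_cluster(d$size, spec_from_table(tt(d$wt)), spec_from_table(tt(d$mut)),
                    effect_size = effect_size, mut_effect_factor = d$f)
  })
}

#' Export a generated dataset and its truth to a directory
#'
#' Writes `signals.tsv`, `calls.tsv`, `design.tsv` (via
#' [write_expression_dataset()]) and `truth.json`.
#'
#' @param sim Result of [generate_dataset()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_expression_dataset(sim$dataset, dir)
  truth <- sim$truth
  truth$clusters <- lapply(truth$clusters, function(cl) {
    cl$wt_logic <- format(cl$wt_logic)
    cl$mut_logic <- format(cl$mut_logic)
    cl
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
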