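# Pipeline orchestration and gene-list reporting: binomial
# over-representation of functional terms and the end-to-end run
# (filter -> per-gene ANOVA -> genotype union -> FOM clustering ->
# per-cluster ANOVA -> Boolean gates -> de-regulation classes).

#' Read a flat gene annotation table
#'
#' Two-column TSV `gene_id`, `term`, one row per (gene, term) pair.
#'
#' @param path File path.
#' @return data.frame with columns `gene_id`, `term`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(ann)))
    validate_error(basename(path), "annotation needs columns gene_id, term")
  ann[, c("gene_id", "term")]
}

#' Binomial over-representation of functional terms in a gene list
#'
#' For each term, tests whether its frequency in `gene_list` exceeds its
#' background frequency using the upper-tail binomial test: with n = list
#' size, k = annotated list genes and p0 = background frequency,
#' p = P(X >= k), X ~ Binomial(n, p0). No multiple-testing correction is
#' applied; the raw cutoff `alpha` flags significance.
#'
#' @param gene_list Character vector of gene ids (subset of `background`).
#' @param annotation data.frame `gene_id`, `term` covering the background.
#' @param background Character vector: the gene universe.
#' @param alpha Significance cutoff (default 0.05).
#' @return data.frame sorted by p: `term`, `observed`, `list_size`,
#'   `observed_freq` and `expected_freq` (percent), `background_count`,
#'   `background_size`, `p_value`, `significant`.
#' @export
binomial_overrepresentation <- function(gene_list, annotation, background,
                                        alpha = 0.05) {
  if (length(gene_list) == 0) stop("empty gene list")
  if (length(background) == 0) stop("empty background")
  if (!all(gene_list %in% background))
    stop("gene_list must be a subset of the background universe")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  n <- length(unique(gene_list))
  m <- length(unique(background))
  bg_count <- table(unique(ann[, c("gene_id", "term")])$term)
  in_list <- ann$gene_id %in% gene_list
  obs_count <- table(factor(unique(ann[in_list, c("gene_id", "term")])$term,
                            levels = names(bg_count)))
  p0 <- as.numeric(bg_count) / m
  k <- as.numeric(obs_count)
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  out <- data.frame(term = names(bg_count),
                    observed = as.integer(k), list_size = n,
                    observed_freq = 100 * k / n,
                    expected_freq = 100 * p0,
                    background_count = as.integer(bg_count),
                    background_size = m,
                    p_value = p,
                    significant = p <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either `dataset` (an
#' `expression_dataset`) or the three input paths must be supplied.
#'
#' @param dataset Optional `expression_dataset` (takes precedence).
#' @param signals_path,calls_path,design_path Input TSV paths.
#' @param annotation_path Optional annotation TSV for enrichment.
#' @param alpha Gene- and cluster-level p cutoff (default 0.01).
#' @param transform `"log2"` or `"identity"`.
#' @param k_min,k_max FOM search range for the number of clusters.
#' @param elbow_threshold FOM elbow rule threshold (default 0.05).
#' @param theta Attenuation threshold (default 0.5).
#' @param enrichment_alpha Enrichment cutoff (default 0.05).
#' @param dead_band Binarization ambiguity band (default 0.25).
#' @param seed Integer seed recorded for provenance.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, signals_path = NULL,
                            calls_path = NULL, design_path = NULL,
                            annotation_path = NULL, alpha = 0.01,
                            transform = "log2", k_min = 2, k_max = 40,
                            elbow_threshold = 0.05, theta = 0.5,
                            enrichment_alpha = 0.05, dead_band = 0.25,
                            seed = 1, out_dir = tempfile("boolgate_run_")) {
  if (is.null(dataset) && (is.null(signals_path) || is.null(design_path)))
    stop("supply a dataset or signals_path + design_path")
  structure(list(dataset = dataset, signals_path = signals_path,
                 calls_path = calls_path, design_path = design_path,
                 annotation_path = annotation_path, alpha = alpha,
                 transform = transform, k_min = k_min, k_max = k_max,
                 elbow_threshold = elbow_threshold, theta = theta,
                 enrichment_alpha = enrichment_alpha, dead_band = dead_band,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_json <- function(cfg) {
  echo <- cfg[setdiff(names(cfg), "dataset")]
  echo$dataset <- if (is.null(cfg$dataset)) NULL else "<in-memory dataset>"
  as.character(jsonlite::toJSON(echo, auto_unbox = TRUE, null = "null"))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config: ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes detection filtering, per-gene 3-way ANOVA, per-term gene-list
#' selection with plug-in FDR, the genotype union, profile construction,
#' FOM-guided average-linkage clustering, per-cluster ANOVAs, Boolean gate
#' inference, de-regulation classification, and (when annotation is
#' supplied) binomial enrichment of the union list. All intermediates are
#' written under `cfg$out_dir`; every table carries the configuration
#' echoed in its header line.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a summary list: `n_genes_input`, `n_genes_filtered`,
#'   `term_counts`, `fdr` (per term), `fdr_pooled`, `n_union`,
#'   `selected_k`, `class_tally`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- config_json(cfg)
  stage <- "read"
  result <- tryCatch({
    ds <- if (!is.null(cfg$dataset)) cfg$dataset else
      read_expression_table(cfg$signals_path, cfg$calls_path, cfg$design_path)
    n_input <- n_genes(ds)

    stage <- "detection_filter"
    fds <- filter_by_detection_calls(ds)

    stage <- "anova"
    tab <- fit_all(fds, transform = cfg$transform)
    write_tsv_with_header(as.data.frame(tab), file.path(cfg$out_dir, "anova.tsv"), hdr)

    stage <- "gene_lists"
    lists <- select_genes(tab, alpha = cfg$alpha)
    dir.create(file.path(cfg$out_dir, "lists"), showWarnings = FALSE)
    for (t in names(lists$lists))
      writeLines(lists$lists[[t]],
                 file.path(cfg$out_dir, "lists",
                           paste0(gsub(":", "x", t), ".txt")))

    stage <- "genotype_union"
    union_genes <- genotype_union(lists)
    if (length(union_genes) < 3)
      stop("genotype union has fewer than 3 genes; nothing to cluster")
    writeLines(union_genes, file.path(cfg$out_dir, "union.txt"))

    stage <- "profiles"
    pm <- condition_profiles(fds, union_genes, transform = cfg$transform)

    stage <- "fom"
    k_max <- min(cfg$k_max, length(union_genes) - 1)
    fom <- figure_of_merit(pm, k_range = cfg$k_min:k_max,
                           elbow_threshold = cfg$elbow_threshold)
    write_tsv_with_header(data.frame(k = fom$k, fom = fom$fom,
                                     raw_fom = fom$raw_fom),
                          file.path(cfg$out_dir, "fom.tsv"), hdr)

    stage <- "clustering"
    dend <- hierarchical_cluster(correlation_distance(standardize_rows(pm)))
    clusters <- cut_clusters(dend, fom$selected_k, pm)
    member <- cluster_membership(clusters)
    write_tsv_with_header(data.frame(gene_id = names(member),
                                     cluster_id = unname(member)),
                          file.path(cfg$out_dir, "clusters.tsv"), hdr)
    centroids <- t(vapply(clusters, `[[`, numeric(8), "centroid"))
    write_tsv_with_header(data.frame(cluster_id = vapply(clusters, `[[`,
                                                         character(1), "cluster_id"),
                                     as.data.frame(centroids),
                                     check.names = FALSE),
                          file.path(cfg$out_dir, "centroids.tsv"), hdr)

    stage <- "boolean_models"
    models <- infer_cluster_models(fds, clusters, alpha = cfg$alpha,
                                   theta = cfg$theta, dead_band = cfg$dead_band,
                                   transform = cfg$transform)
    model_json <- lapply(models, function(m) {
      list(cluster_id = m$cluster_id, members = m$genes, size = m$size,
           class = m$class, wt_spec = format(m$wt_spec),
           mut_spec = format(m$mut_spec),
           wt_table = as.list(m$wt_table), mut_table = as.list(m$mut_table),
           evidence = m$evidence)
    })
    jsonlite::write_json(list(config = jsonlite::fromJSON(hdr),
                              clusters = model_json),
                         file.path(cfg$out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_tsv_with_header(
      data.frame(cluster_id = vapply(models, `[[`, character(1), "cluster_id"),
                 size = vapply(models, `[[`, integer(1), "size"),
                 class = vapply(models, `[[`, character(1), "class"),
                 wt_gate = vapply(models, function(m) format(m$wt_spec), character(1)),
                 mut_gate = vapply(models, function(m) format(m$mut_spec), character(1))),
      file.path(cfg$out_dir, "model_summary.tsv"), hdr)

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(cfg$annotation_path)) {
      ann <- read_annotation(cfg$annotation_path)
      enrichment <- binomial_overrepresentation(union_genes, ann,
                                                rownames(fds$signals),
                                                alpha = cfg$enrichment_alpha)
      write_tsv_with_header(enrichment,
                            file.path(cfg$out_dir, "enrichment.tsv"), hdr)
    }

    stage <- "summary"
    summary <- list(n_genes_input = n_input, n_genes_filtered = n_genes(fds),
                    term_counts = as.list(lists$counts),
                    fdr = as.list(lists$fdr), fdr_pooled = lists$fdr_pooled,
                    n_union = length(union_genes), selected_k = fom$selected_k,
                    class_tally = as.list(unclass(class_tally(models))),
                    alpha = cfg$alpha, seed = cfg$seed, out_dir = cfg$out_dir)
    jsonlite::write_json(list(config = jsonlite::fromJSON(hdr), summary = summary),
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(c(paste0("boolgate ", as.character(utils::packageVersion("boolgate"))),
                 paste0("R ", R.version.string),
                 paste0("config: ", hdr),
                 paste0("seed: ", cfg$seed)),
               file.path(cfg$out_dir, "log.txt"))

    # internal consistency: persisted intermediates re-derive the counts
    stopifnot(length(readLines(file.path(cfg$out_dir, "union.txt"))) ==
                summary$n_union)
    stopifnot(nrow(utils::read.delim(file.path(cfg$out_dir, "clusters.tsv"),
                                     comment.char = "#")) == summary$n_union)
    summary$enrichment <- enrichment
    summary
  }, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
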