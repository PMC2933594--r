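# Scoring of pipeline output against generator truth.

#' Score planted-truth recovery of gates and classes
#'
#' Matches each planted cluster to the inferred cluster holding the
#' plurality of its recovered genes and checks whether that cluster's
#' inferred Boolean specs (both genotypes, compared by logical
#' equivalence) and de-regulation class equal the planted ones.
#'
#' @param truth The `truth` element of [generate_dataset()].
#' @param membership Named vector gene -> inferred cluster id
#'   ([cluster_membership()]).
#' @param models A `boolean_model_set` for the inferred clusters.
#' @return data.frame per planted cluster: `cluster`, `size`,
#'   `n_recovered`, `matched`, `gate_ok`, `class_ok`, `found_class`;
#'   recovery fractions in `attr(, "summary")`.
#' @export
score_recovery <- function(truth, membership, models) {
  names(models) <- vapply(models, `[[`, character(1), "cluster_id")
  rows <- lapply(names(truth$clusters), function(cid) {
    tc <- truth$clusters[[cid]]
    rec <- intersect(tc$genes, names(membership))
    if (length(rec) == 0)
      return(data.frame(cluster = cid, size = length(tc$genes), n_recovered = 0L,
                        matched = NA_character_, gate_ok = FALSE, class_ok = FALSE,
                        found_class = NA_character_, stringsAsFactors = FALSE))
    hit <- names(which.max(table(membership[rec])))
    m <- models[[hit]]
    data.frame(cluster = cid, size = length(tc$genes),
               n_recovered = length(rec), matched = hit,
               gate_ok = spec_equivalent(m$wt_spec, tc$wt_logic) &&
                 spec_equivalent(m$mut_spec, tc$mut_logic),
               class_ok = m$class == tc$deregulation_class,
               found_class = m$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(gate_recovery = mean(out$gate_ok),
                            class_recovery = mean(out$class_ok))
  out
}
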