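test_that("dataset construction validates design, dimensions and ids", {
  design <- toy_design(3)
  m <- matrix(runif(3 * 24, 10, 100), 3, 24,
              dimnames = list(c("g1", "g2", "g3"), design$sample_id))
  calls <- matrix("P", 3, 24, dimnames = dimnames(m))
  ds <- expression_dataset(m, calls, design)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(n_genes(ds), 3)
  expect_equal(n_samples(ds), 24)

  # missing factorial cell
  bad <- design[design$N != 1 | design$L != 1 | design$G != 1, ]
  expect_error(expression_dataset(m[, bad$sample_id], calls[, bad$sample_id], bad),
               "incomplete factorial design")
  # duplicate gene ids
  m2 <- m; rownames(m2) <- c("g1", "g1", "g3")
  expect_error(expression_dataset(m2, calls, design), "duplicate gene_ids")
  # dimension mismatch
  expect_error(expression_dataset(m[, 1:20], calls[, 1:20], design), "mismatch")
  # non-binary factor level
  d3 <- design; d3$N[1] <- 2
  expect_error(expression_dataset(m, calls, d3), "0 or 1")
  # negative signals
  m4 <- m; m4[1, 1] <- -1
  expect_error(expression_dataset(m4, calls, design), "non-negative")
  # unbalanced replicates
  d5 <- as.data.frame(design)
  d5$G[1] <- 1  # moves a replicate across cells
  expect_error(expression_dataset(m, calls, d5), "unbalanced|incomplete")
})

test_that("detection call spellings are normalized and bad values rejected", {
  design <- toy_design(3)
  m <- matrix(50, 2, 24, dimnames = list(c("g1", "g2"), design$sample_id))
  calls <- matrix(rep(c("Present", "marginal", "A", "p"), 12), 2, 24)
  ds <- expression_dataset(m, calls, design)
  expect_true(all(ds$calls %in% c("A", "M", "P")))
  calls[1, 1] <- "X"
  expect_error(expression_dataset(m, calls, design), "unrecognized detection call")
  expect_warning(expression_dataset(m, NULL, design), "assuming all calls Present")
})

test_that("TSV round trip reproduces matrices bitwise", {
  sim <- generate_dataset(simulation_config(
    clusters = list(planted_cluster(5, parse_logic("N & L"))),
    n_background_genes = 10, seed = 42))
  dir1 <- withr::local_tempdir()
  write_expression_dataset(sim$dataset, dir1)
  ds2 <- read_expression_table(file.path(dir1, "signals.tsv"),
                               file.path(dir1, "calls.tsv"),
                               file.path(dir1, "design.tsv"))
  expect_identical(ds2$signals, sim$dataset$signals)
  expect_identical(ds2$calls, sim$dataset$calls)
  dir2 <- withr::local_tempdir()
  write_expression_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir1, "signals.tsv")),
                   readLines(file.path(dir2, "signals.tsv")))
})

test_that("detection filter keeps exactly genes with a non-Absent call", {
  design <- toy_design(3)
  set.seed(11)
  n <- 40
  m <- matrix(runif(n * 24, 1, 100), n, 24,
              dimnames = list(sprintf("g%02d", 1:n), design$sample_id))
  calls <- matrix(sample(c("A", "M", "P"), n * 24, TRUE, prob = c(0.9, 0.05, 0.05)),
                  n, 24, dimnames = dimnames(m))
  calls[1, ] <- "A"                      # all Absent: removed
  calls[2, ] <- c("M", rep("A", 23))     # one Marginal: retained
  ds <- expression_dataset(m, calls, design)
  fds <- filter_by_detection_calls(ds)
  expect_false("g01" %in% rownames(fds$signals))
  expect_true("g02" %in% rownames(fds$signals))
  # brute-force row scan oracle
  keep <- apply(calls, 1, function(r) any(r != "A"))
  expect_identical(rownames(fds$signals), rownames(m)[keep])
  # idempotence
  expect_identical(filter_by_detection_calls(fds)$signals, fds$signals)
  # empty result
  calls[] <- "A"
  expect_error(filter_by_detection_calls(expression_dataset(m, calls, design)),
               "no genes survive")
})

test_that("linkage_scan flags large genotype fold changes on a chromosome", {
  design <- toy_design(3)
  n <- 20
  set.seed(7)
  base <- matrix(2^rnorm(n * 24, 8, 0.05), n, 24,
                 dimnames = list(sprintf("g%02d", 1:n), design$sample_id))
  mut_cols <- design$G == 1
  base["g01", mut_cols] <- base["g01", mut_cols] / 32  # the mutated locus
  info <- data.frame(gene_id = rownames(base),
                     chromosome = rep(c("5", "2"), each = 10))
  ds <- expression_dataset(base, NULL, design, info) |> suppressWarnings()
  scan <- linkage_scan(ds, "g01", "5", fold_threshold = 4)
  expect_equal(nrow(scan$flagged), 0)
  expect_gt(scan$target$fold_wt_over_mut, 16)

  # planted 8x repression of a neighbour is flagged
  base2 <- base
  base2["g05", mut_cols] <- base2["g05", mut_cols] / 8
  ds2 <- suppressWarnings(expression_dataset(base2, NULL, design, info))
  scan2 <- linkage_scan(ds2, "g01", "5", fold_threshold = 4)
  expect_identical(scan2$flagged$gene_id, "g05")
  expect_equal(scan2$flagged$direction, "down_in_mutant")
  # genes on other chromosomes are never scanned
  base3 <- base
  base3["g15", mut_cols] <- base3["g15", mut_cols] / 50
  ds3 <- suppressWarnings(expression_dataset(base3, NULL, design, info))
  expect_equal(nrow(linkage_scan(ds3, "g01", "5", 4)$flagged), 0)
  # permutation of samples within design cells leaves folds unchanged
  perm <- order(design$G, design$L, design$N, -design$replicate)
  dsp <- suppressWarnings(expression_dataset(
    base2[, perm], NULL, as.data.frame(design)[perm, ], info))
  scanp <- linkage_scan(dsp, "g01", "5", 4)
  expect_equal(scanp$flagged$fold_wt_over_mut, scan2$flagged$fold_wt_over_mut)
  expect_error(linkage_scan(ds, "nope", "5"), "not found")
})

test_that("GEO series-matrix parser extracts signals and sample metadata", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    '!Series_title\t"demo"',
    '!Sample_title\t"wt_rep1"\t"mut_rep1"',
    '!Sample_geo_accession\t"GSM1"\t"GSM2"',
    "!series_matrix_table_begin",
    paste("ID_REF", "GSM1", "GSM2", sep = "\t"),
    paste('"At1g01010"', "120.5", "80.25", sep = "\t"),
    paste('"At5g49450"', "900", "28.125", sep = "\t"),
    "!series_matrix_table_end"), tmp)
  geo <- read_geo_series_matrix(tmp)
  expect_equal(dim(geo$signals), c(2, 2))
  expect_equal(geo$samples$title, c("wt_rep1", "mut_rep1"))
  expect_equal(geo$signals["At5g49450", "GSM2"], 28.125)
})
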