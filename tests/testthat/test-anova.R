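test_that("single-gene fits agree with stats::aov on random instances", {
  design <- toy_design(3)
  set.seed(101)
  for (i in 1:20) {
    y <- 2^(rnorm(24, 8, 0.5) + 2 * design$L * runif(1))
    tab <- fit_gene_anova(y, design, transform = "log2")
    oracle <- aov_oracle(y, design, "log2")
    expect_equal(unname(anova_matrix(tab, "F")[1, oracle$term]), oracle$F,
                 tolerance = 1e-10)
    expect_equal(unname(anova_matrix(tab, "p")[1, oracle$term]), oracle$p,
                 tolerance = 1e-10)
  }
  # identity transform path
  y <- runif(24, 10, 100)
  tab <- fit_gene_anova(y, design, transform = "identity")
  oracle <- aov_oracle(y, design, "identity")
  expect_equal(unname(anova_matrix(tab, "F")[1, oracle$term]), oracle$F,
               tolerance = 1e-10)
})

test_that("degenerate and invalid inputs are handled per convention", {
  design <- toy_design(3)
  tab <- fit_gene_anova(rep(50, 24), design)
  expect_true(all(anova_matrix(tab, "p") == 1))
  expect_error(fit_gene_anova(c(rep(1, 23), NA), design), "finite|missing")
  expect_error(fit_gene_anova(1:10, design), "length")
  unb <- as.data.frame(toy_design(3))[-1, ]
  expect_error(fit_gene_anova(runif(23), unb), "incomplete|unbalanced")
})

test_that("sums of squares are conserved and F is affine-invariant", {
  design <- toy_design(3)
  set.seed(22)
  Y <- matrix(2^rnorm(10 * 24, 8, 0.4), 10, 24,
              dimnames = list(sprintf("g%d", 1:10), design$sample_id))
  ds <- suppressWarnings(expression_dataset(Y, NULL, design))
  tab <- fit_all(ds, transform = "identity")
  ss <- attr(tab, "ss")
  expect_equal(rowSums(ss$term) + ss$residual, ss$total, tolerance = 1e-9)
  # affine rescale of the response leaves F untouched
  ds2 <- suppressWarnings(expression_dataset(Y * 3 + 7, NULL, design))
  tab2 <- fit_all(ds2, transform = "identity")
  expect_equal(anova_matrix(tab2, "F"), anova_matrix(tab, "F"), tolerance = 1e-9)
  # permuting samples within design cells leaves p untouched
  perm <- order(design$G, design$L, design$N, -design$replicate)
  dsp <- suppressWarnings(expression_dataset(Y[, perm], NULL,
                                             as.data.frame(design)[perm, ]))
  expect_equal(anova_matrix(fit_all(dsp, "identity"), "p"),
               anova_matrix(tab, "p"), tolerance = 1e-9)
})

test_that("planted effects land on the matching model term", {
  design <- toy_design(3)
  set.seed(33)
  # strong L main effect
  y <- 2^(8 + 2 * design$L + rnorm(24, 0, 0.2))
  p <- anova_matrix(fit_gene_anova(y, design), "p")[1, ]
  expect_equal(names(which.min(p)), "L")
  expect_equal(anova_matrix(fit_gene_anova(y, design), "coef")[1, "L"], 2,
               tolerance = 0.5)
  # pure G x N interaction, no main effects
  shift <- (2 * design$N - 1) * (2 * design$G - 1)
  y2 <- 2^(8 + 0.8 * shift + rnorm(24, 0, 0.2))
  p2 <- anova_matrix(fit_gene_anova(y2, design), "p")[1, ]
  expect_equal(names(which.min(p2)), "N:G")
  expect_gt(min(p2[c("N", "L", "G")]), 0.001)
})

test_that("fit_all is numerically identical to per-gene fits", {
  sim <- generate_dataset(simulation_config(
    clusters = list(planted_cluster(3, parse_logic("N"))), seed = 17))
  ds <- sim$dataset
  all_tab <- fit_all(ds)
  for (g in rownames(ds$signals)) {
    one <- fit_gene_anova(ds$signals[g, ], ds$design)
    expect_equal(anova_matrix(one, "F")[1, ],
                 anova_matrix(all_tab, "F")[g, ], tolerance = 1e-12)
  }
})

test_that("plug-in FDR estimate follows its defining arithmetic", {
  # pure null: everything rejected at alpha is a false discovery
  p_null <- (1:1000) / 1000
  expect_equal(estimate_fdr(p_null, 0.01), 1.0)
  # 900 spread nulls + 100 strong signals: (0.01 * 1000) / 109
  p_mix <- c((1:900) / 900, rep(1e-6, 100))
  expect_equal(estimate_fdr(p_mix, 0.01), 10 / 109, tolerance = 1e-12)
  expect_error(estimate_fdr(numeric(0)), "empty")
  expect_error(estimate_fdr(c(0.5, 2)), "0, 1")
})

test_that("gene lists are selected per term with deterministic ordering", {
  design <- toy_design(3)
  set.seed(44)
  n <- 50
  Y <- 2^(matrix(rnorm(n * 24, 8, 0.3), n, 24) +
            outer(rep(c(1.5, 0), c(10, n - 10)), design$L))
  rownames(Y) <- sprintf("g%02d", n:1)  # reverse-ordered ids to exercise ties
  colnames(Y) <- design$sample_id
  ds <- suppressWarnings(expression_dataset(Y, NULL, design))
  tab <- fit_all(ds)
  lists <- select_genes(tab, alpha = 0.01)
  expect_true(all(sprintf("g%02d", 41:50) %in% lists$lists$L))
  p <- anova_matrix(tab, "p")[lists$lists$L, "L"]
  expect_true(all(diff(p) >= 0))
  # constant genes produce empty lists
  Yc <- matrix(64, 4, 24, dimnames = list(paste0("c", 1:4), design$sample_id))
  dsc <- suppressWarnings(expression_dataset(Yc, NULL, design))
  expect_true(all(select_genes(fit_all(dsc))$counts == 0))
})

test_that("genotype union equals the brute-force set union", {
  set.seed(55)
  fake <- list(lists = list(
    "N" = c("a", "b"), "L" = c("c"), "G" = c("d", "e"),
    "L:N" = character(0), "L:G" = c("e", "f"), "N:G" = c("g"),
    "N:L:G" = c("d", "h")))
  class(fake) <- "term_gene_lists"
  u <- genotype_union(fake)
  expect_identical(u, sort(unique(c("d", "e", "e", "f", "g", "d", "h"))))
  fake$lists[["N:L:G"]] <- NULL
  expect_error(genotype_union(fake), "missing term")
})

test_that("within-genotype 2-way fits recover subset structure", {
  design <- toy_design(3)
  set.seed(66)
  # N effect present only in the wild type; G contrasts cancel by symmetry
  y <- 2^(8 + 1.5 * design$N * (design$G == 0) + rnorm(24, 0, 0.15))
  Y <- matrix(y, 1, dimnames = list("g1", design$sample_id))
  ds <- suppressWarnings(expression_dataset(Y, NULL, design))
  wt <- fit_subset_anova(ds, 0)
  mut <- fit_subset_anova(ds, 1)
  expect_lt(anova_matrix(wt, "p")[1, "N"], 1e-4)
  expect_gt(anova_matrix(mut, "p")[1, "N"], 0.01)
  # constant gene: all terms at p = 1
  Yc <- matrix(32, 1, 24, dimnames = list("c1", design$sample_id))
  dsc <- suppressWarnings(expression_dataset(Yc, NULL, design))
  expect_true(all(anova_matrix(fit_subset_anova(dsc, 0), "p") == 1))
  # agreement with a 2-way aov oracle on the subset
  keep <- design$G == 0
  df <- data.frame(y = log2(y + 1)[keep], N = factor(design$N[keep]),
                   L = factor(design$L[keep]))
  s <- summary(stats::aov(y ~ N * L, df))[[1]]
  expect_equal(unname(anova_matrix(wt, "F")[1, c("N", "L", "L:N")]),
               s[1:3, "F value"], tolerance = 1e-10)
})
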