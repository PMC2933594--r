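# helper: simulate one cluster (and optional flat background arm) and return
# its genotype-0 dataset pieces for gate inference
simulate_cluster_ds <- function(wt_logic, mut_logic = wt_logic, n_genes = 8,
                                effect = 0.75, noise = 0.25, seed = 1,
                                mut_factor = 1) {
  cl <- planted_cluster(n_genes, wt_logic, mut_logic, effect_size = effect,
                        mut_effect_factor = mut_factor,
                        deregulation_class = "none")
  generate_dataset(simulation_config(clusters = list(cl), noise_sd = noise,
                                     seed = seed))$dataset
}

test_that("cluster ANOVA stacks replicate observations with directions", {
  design <- toy_design(3)
  # constant cluster: no signal anywhere
  Y <- matrix(16, 4, 24, dimnames = list(paste0("g", 1:4), design$sample_id))
  ds <- suppressWarnings(expression_dataset(Y, NULL, design))
  an <- fit_cluster_anova(ds, paste0("g", 1:4))
  expect_true(all(an$p == 1))
  # planted N induction: strong positive N term
  ds2 <- simulate_cluster_ds(parse_logic("N"), n_genes = 8, seed = 2)
  an2 <- fit_cluster_anova(ds2, rownames(ds2$signals), genotype = 0)
  expect_lt(an2$p[an2$term == "N"], 1e-4)
  expect_equal(an2$direction[an2$term == "N"], 1)
  # mutant-only N induction: N:G interaction in the 3-way fit
  ds3 <- simulate_cluster_ds(parse_logic("0"), parse_logic("N"), n_genes = 8, seed = 3)
  an3 <- fit_cluster_anova(ds3, rownames(ds3$signals))
  expect_lt(an3$p[an3$term == "N:G"], 1e-4)
})

test_that("centroid binarization thresholds at the range midpoint", {
  tt <- binarize_profiles(c(1, 1, 1, 5))
  expect_equal(as.vector(tt), c(0L, 0L, 0L, 1L))
  expect_true(attr(tt, "regulated"))
  # flat profile below the noise floor is all-ambiguous
  flat <- binarize_profiles(c(1, 1.02, 0.99, 1.01), se = rep(0.5, 4))
  expect_true(all(is.na(flat)))
  expect_false(attr(flat, "regulated"))
  # cells inside the dead band are ambiguous, outside are called
  tt2 <- binarize_profiles(c(0, 0.45, 0.55, 1), dead_band = 0.25)
  expect_equal(as.vector(tt2), c(0L, NA, NA, 1L))
  # planted NOT-N-AND-NOT-L: high only at -N-L
  tt3 <- binarize_profiles(c(5, 1, 1, 1))
  expect_equal(as.vector(tt3), c(1L, 0L, 0L, 0L))
})

test_that("gate inference recovers every representable Boolean function", {
  hit <- 0; total <- 0
  for (tab_i in seq_along(all_truth_tables())) {
    tt <- all_truth_tables()[[tab_i]]
    spec <- spec_from_table(tt)
    if (is_unregulated(spec)) next
    for (seed in 1:5) {
      ds <- simulate_cluster_ds(spec, n_genes = 8, seed = 1000 * tab_i + seed)
      an <- fit_cluster_anova(ds, rownames(ds$signals), genotype = 0)
      bt <- binarize_profiles(attr(an, "cell_means"), attr(an, "cell_se"))
      got <- infer_boolean_gate(bt, an)
      total <- total + 1
      hit <- hit + spec_equivalent(got, spec)
    }
  }
  expect_gte(hit / total, 0.95)
})

test_that("gate inference uses significance to resolve ambiguity, never guesses", {
  # single-input N with clean evidence
  ds <- simulate_cluster_ds(parse_logic("N"), n_genes = 10, seed = 4)
  an <- fit_cluster_anova(ds, rownames(ds$signals), genotype = 0)
  bt <- binarize_profiles(attr(an, "cell_means"), attr(an, "cell_se"))
  got <- infer_boolean_gate(bt, an)
  expect_true(spec_equivalent(got, parse_logic("N")))
  expect_length(got$inputs, 1)
  # no significant term at all: unregulated, whatever the table hints
  flat <- simulate_cluster_ds(parse_logic("0"), parse_logic("0"), n_genes = 10, seed = 5)
  an0 <- fit_cluster_anova(flat, rownames(flat$signals), genotype = 0)
  bt0 <- binarize_profiles(attr(an0, "cell_means"), attr(an0, "cell_se"))
  expect_true(is_unregulated(infer_boolean_gate(bt0, an0)))
  # a fully determined table outweighs a conflicting significance pattern:
  # an exclusive-or table with (spuriously) significant main effects still
  # resolves to the exclusive-or gate
  xnor_table <- structure(c(1L, 0L, 0L, 1L), regulated = TRUE,
                          names = c("-N-L", "+N-L", "-N+L", "+N+L"))
  fake_an <- data.frame(term = c("N", "L", "L:N"), F = c(50, 50, 0.1),
                        p = c(1e-6, 1e-6, 0.9), direction = c(1, 1, 0))
  attr(fake_an, "cell_means") <- c(`-N-L` = 1, `+N-L` = 0, `-N+L` = 0, `+N+L` = 1)
  got <- infer_boolean_gate(xnor_table, fake_an)
  expect_true(spec_equivalent(got, spec_from_table(c(1, 0, 0, 1))))
})

test_that("the de-regulation cascade reproduces the canonical cases", {
  mk_an <- function(p, cells) {
    an <- data.frame(term = c("N", "L", "L:N"), F = 10, p = p,
                     direction = sign(c(cells[2] + cells[4] - cells[1] - cells[3],
                                        cells[3] + cells[4] - cells[1] - cells[2],
                                        cells[4] - cells[3] - cells[2] + cells[1])))
    attr(an, "cell_means") <- setNames(cells, c("-N-L", "+N-L", "-N+L", "+N+L"))
    attr(an, "cell_se") <- rep(0.02, 4)
    an
  }
  unreg <- boolean_spec()
  # hidden: wild type flat, mutant over-expressed unless N or L present
  wt_an <- mk_an(rep(0.5, 3), c(0, 0.01, -0.01, 0))
  mut_an <- mk_an(rep(1e-5, 3), c(2, 0.1, 0.1, 0.1))
  call <- classify_deregulation(unreg, parse_logic("!N & !L"), wt_an, mut_an)
  expect_equal(call$class, "hidden")
  expect_equal(call$mut_spec$modulator, "represses")
  # inversion: N activation in wild type, N repression in mutant
  wt2 <- mk_an(c(1e-6, 0.5, 0.5), c(0, 1, 0, 1))
  mut2 <- mk_an(c(1e-6, 0.5, 0.5), c(1, 0, 1, 0))
  call2 <- classify_deregulation(parse_logic("N"), parse_logic("N", "repression"),
                                 wt2, mut2)
  expect_equal(call2$class, "inversion")
  # attenuation: same L repression, mutant magnitude 0.6 vs 2.0
  wt3 <- mk_an(c(0.5, 1e-6, 0.5), c(2, 2, 0, 0))
  mut3 <- mk_an(c(0.5, 1e-4, 0.5), c(0.6, 0.6, 0, 0))
  call3 <- classify_deregulation(parse_logic("L", "repression"),
                                 parse_logic("L", "repression"), wt3, mut3)
  expect_equal(call3$class, "attenuation")
  # dark-restricted sign flip: repressed by N in the dark vs induced in the dark
  wt4 <- mk_an(c(1e-4, 0.2, 1e-4), c(1, 0, 0.5, 0.5))
  mut4 <- mk_an(c(1e-4, 0.2, 1e-4), c(0, 1, 0.5, 0.5))
  call4 <- classify_deregulation(spec_from_table(c(1, 0, 0, 0)),
                                 spec_from_table(c(0, 1, 0, 0)), wt4, mut4)
  expect_equal(call4$class, "complex")
})

test_that("regulation lost in the mutant is complex, not hidden (asymmetry)", {
  mk_an <- function(p, cells) {
    an <- data.frame(term = c("N", "L", "L:N"), F = 10, p = p, direction = 1)
    attr(an, "cell_means") <- setNames(cells, c("-N-L", "+N-L", "-N+L", "+N+L"))
    attr(an, "cell_se") <- rep(0.02, 4)
    an
  }
  reg_an <- mk_an(c(1e-6, 0.5, 0.5), c(0, 1.5, 0, 1.5))
  flat_an <- mk_an(rep(0.6, 3), c(0, 0.01, 0, 0.02))
  fwd <- classify_deregulation(boolean_spec(), parse_logic("N"), flat_an, reg_an)
  expect_equal(fwd$class, "hidden")
  swapped <- classify_deregulation(parse_logic("N"), boolean_spec(), reg_an, flat_an)
  expect_equal(swapped$class, "complex")
})

test_that("the cascade is total and deterministic over random inputs", {
  set.seed(77)
  classes <- c("attenuation", "inversion", "hidden", "complex", "none")
  for (i in 1:50) {
    cells_w <- rnorm(4); cells_m <- rnorm(4)
    mk <- function(cells) {
      an <- data.frame(term = c("N", "L", "L:N"), F = rexp(3),
                       p = runif(3), direction = sample(c(-1, 1), 3, TRUE))
      attr(an, "cell_means") <- setNames(cells, c("-N-L", "+N-L", "-N+L", "+N+L"))
      attr(an, "cell_se") <- rep(0.1, 4)
      an
    }
    wt_an <- mk(cells_w); mut_an <- mk(cells_m)
    sw <- spec_from_table(all_truth_tables()[[sample(16, 1)]])
    sm <- spec_from_table(all_truth_tables()[[sample(16, 1)]])
    c1 <- classify_deregulation(sw, sm, wt_an, mut_an)
    c2 <- classify_deregulation(sw, sm, wt_an, mut_an)
    expect_true(c1$class %in% classes)
    expect_identical(c1$class, c2$class)
  }
})

test_that("end-to-end cluster models recover a planted mutant-only induction", {
  # wild type flat, mutant strongly N-induced (a hidden-regulation cluster)
  ds <- simulate_cluster_ds(parse_logic("0"), parse_logic("N"), n_genes = 8,
                            seed = 11)
  models <- infer_cluster_models(ds, list(list(cluster_id = "c1",
                                               genes = rownames(ds$signals))))
  m <- models[[1]]
  expect_equal(m$class, "hidden")
  expect_true(is_unregulated(m$wt_spec))
  expect_true(spec_equivalent(m$mut_spec, parse_logic("N")))
  expect_lt(m$anova3$p[m$anova3$term == "N:G"], 1e-4)
})
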