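test_that("config validation catches out-of-range parameters", {
  expect_error(generative_config(n_genes = 50,
                                 programs = list(program_spec("p", 100, 2))),
               "exceed")
  expect_error(program_spec("p", 10, -1, direction = "up"), "positive")
  expect_error(generative_config(ortholog_coverage = 0))
  expect_error(generative_config(refset_precision = 1.5))
  expect_error(generative_config(n_replicates_per_group = 1))
})

test_that("the generator is fully deterministic given config and seed", {
  cfg <- study_config(42)
  s1 <- simulate_de_study(cfg)
  s2 <- simulate_de_study(cfg)
  expect_identical(s1, s2)
  p1 <- simulate_pair(cfg)
  p2 <- simulate_pair(cfg)
  expect_identical(p1, p2)
  s3 <- simulate_de_study(study_config(43))
  expect_false(identical(s1$table$log2fc, s3$table$log2fc))
})

test_that("truth bookkeeping: members have nonzero beta, non-members zero", {
  sim <- simulate_de_study(study_config(7))
  members <- !is.na(sim$truth$program)
  expect_true(all(sim$truth$beta[members] != 0))
  expect_true(all(sim$truth$beta[!members] == 0))
  expect_setequal(sim$truth$gene, sim$table$gene)
})

test_that("with no programs, p-values are uniform at the 0.05 gate", {
  cfg <- generative_config(n_genes = 10000L, programs = list(), seed = 101)
  sim <- simulate_de_study(cfg)
  frac <- mean(sim$table$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("the noiseless limit pins member fold changes at the program effect", {
  cfg <- generative_config(n_genes = 200L,
                           programs = list(program_spec("p", 20, 2)),
                           residual_sd = 1e-9, seed = 3)
  sim <- simulate_de_study(cfg)
  members <- sim$table$gene[!is.na(sim$truth$program)]
  fc <- sim$table$log2fc[sim$table$gene %in% members]
  expect_equal(fc, rep(2, 20), tolerance = 1e-6)
  expect_true(all(sim$table$pvalue[sim$table$gene %in% members] < 1e-100))
})

test_that("member power at the p<0.05 gate matches the closed-form normal oracle", {
  tau <- 1 * sqrt(2 / 4)
  closed_form <- pnorm(2 / tau - qnorm(0.975)) +
    pnorm(-2 / tau - qnorm(0.975))
  hits <- vapply(1:200, function(s) {
    sim <- simulate_de_study(study_config(s))
    members <- !is.na(sim$truth$program)
    mean(sim$table$pvalue[members] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(hits) - closed_form), 0.02)
})

test_that("null calibration: BH at FDR 0.1 keeps the realized FDP small", {
  fdp <- vapply(1:100, function(s) {
    cfg <- generative_config(n_genes = 2000L, programs = list(), seed = s)
    sim <- simulate_de_study(cfg)
    sel <- sim$table$fdr <= 0.1
    if (any(sel)) 1 else 0   # all discoveries are false under the null
  }, numeric(1))
  expect_lte(mean(fdp), 0.15)
})

test_that("paired studies share the planted signal through the ortholog map", {
  cfg <- generative_config(ortholog_coverage = 1, one_to_many_fraction = 0,
                           seed = 17)
  pair <- simulate_pair(cfg)
  # bijective map over the full universe
  expect_equal(nrow(pair$map), 2000L)
  mult <- ortholog_multiplicity(pair$map)
  expect_equal(mult$one_to_one, 2000L)
  # planted members' mean observed fold change near the effect in both tables
  tau <- fc_standard_error(cfg)
  members_a <- pair$truth$table_a$gene[!is.na(pair$truth$table_a$program)]
  members_b <- pair$truth$table_b$gene[!is.na(pair$truth$table_b$program)]
  mean_a <- mean(pair$table_a$log2fc[pair$table_a$gene %in% members_a])
  mean_b <- mean(pair$table_b$log2fc[pair$table_b$gene %in% members_b])
  expect_lt(abs(mean_a - 2), 3 * tau / sqrt(100))
  expect_lt(abs(mean_b - 2), 3 * tau / sqrt(100))
  # species-B symbols are uppercased species-A symbols
  expect_true(all(pair$map$gene_b == toupper(pair$map$gene_a)))
})

test_that("coverage and ambiguity shape the map as configured", {
  cfg <- generative_config(n_genes = 1000L, ortholog_coverage = 0.8,
                           one_to_many_fraction = 0, seed = 23)
  pair <- simulate_pair(cfg)
  expect_equal(nrow(pair$map), 800L)
  paired <- pair_fold_changes(pair$table_a, pair$table_b, pair$map)
  expect_equal(attr(paired, "n_pairs"), 800L)

  cfg2 <- generative_config(n_genes = 1000L, ortholog_coverage = 0.8,
                            one_to_many_fraction = 0.1, seed = 23)
  pair2 <- simulate_pair(cfg2)
  mult <- ortholog_multiplicity(pair2$map)
  expect_equal(mult$n_pairs, 800L + 80L)
  paired2 <- pair_fold_changes(pair2$table_a, pair2$table_b, pair2$map)
  # the 80 ambiguous A genes drop out of strict pairing
  expect_equal(attr(paired2, "n_pairs"), 720L)
})

test_that("unshared programs leave paired fold changes uncorrelated", {
  rhos <- vapply(1:20, function(s) {
    cfg <- generative_config(n_genes = 2000L, seed = s)
    pair <- simulate_pair(cfg, shared_programs = character(0))
    spearman_rho(pair_fold_changes(pair$table_a, pair$table_b, pair$map))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("reference sets hit the configured sensitivity and stay exact at 1/1", {
  sim <- simulate_de_study(study_config(31))
  exact <- simulate_reference_sets(sim$truth, 1, 1, seed = 1)
  members <- sim$truth$gene[!is.na(sim$truth$program)]
  expect_setequal(exact[["program1"]], members)

  true_counts <- vapply(1:100, function(s) {
    sets <- simulate_reference_sets(sim$truth, 0.8, 0.8, seed = s)
    length(intersect(sets[["program1"]], members))
  }, numeric(1))
  se <- sqrt(100 * 0.8 * 0.2)
  expect_lt(abs(mean(true_counts) - 80), 3 * se / sqrt(100))
  # decoys are size-matched and from non-program genes
  sets <- simulate_reference_sets(sim$truth, 0.8, 0.8, seed = 1)
  expect_length(intersect(sets[["decoy_program1"]], members), 0)
  expect_error(simulate_reference_sets(sim$truth, 0, 0.5), "\\(0, 1\\]")
})

test_that("write_study_pair emits files the io layer reads back", {
  pair <- simulate_pair(generative_config(n_genes = 200L,
                                          programs = list(
                                            program_spec("p", 20, 2)),
                                          seed = 5))
  dir <- tempfile()
  paths <- write_study_pair(pair, dir)
  tab <- read_de_table(paths[["de_a"]], "a", "synthetic")
  expect_equal(nrow(tab), 200L)
  expect_equal(tab$log2fc, pair$table_a$log2fc, tolerance = 1e-12)
  map <- read_ortholog_map(paths[["map"]], "synthetic", "synthetic")
  expect_equal(nrow(map), nrow(pair$map))
  sets <- read_gmt(paths[["sets"]])
  expect_setequal(names(sets), names(pair$reference_sets))
})
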