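test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(shared_peptide_fraction = 1.2), "proportion")
  expect_error(sim_config(screen_n_mutant = 20, screen_n_lines = 5),
               "screen_n_mutant")
  expect_error(sim_config(core_effect = 0.6), "core_effect")
  expect_error(sim_config(phospho_effect_fold = 0), "positive")
  expect_error(sim_config(dose_response_params = list(a = c(Dm = -1, m = 1))),
               "positive")
  expect_error(sim_config(dose_response_params = list()), "non-empty")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_baits = 2, n_prey_per_bait = 5,
                    n_background = 5, phospho_n_sites = 20,
                    screen_n_lines = 4, screen_n_mutant = 2,
                    screen_n_genes = 10, core_genes = c("CORE01", "CORE02"),
                    drug_n_compounds = 5)
  a <- simulate_tap(cfg); b <- simulate_tap(cfg)
  expect_identical(a, b)
  expect_identical(simulate_phospho(cfg), simulate_phospho(cfg))
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))
  expect_identical(simulate_drug_tables(cfg), simulate_drug_tables(cfg))
  # different seed changes output
  expect_false(identical(simulate_tap(sim_config(seed = 43, n_baits = 2,
    n_prey_per_bait = 5, n_background = 5))$evidence, a$evidence))
})

test_that("simulate_tap respects its construction contracts", {
  # n_background = 0: control pulldowns contain no proteins
  cfg <- sim_config(seed = 3, n_baits = 2, n_prey_per_bait = 5,
                    n_background = 0)
  sim <- simulate_tap(cfg)
  ctrl_runs <- sim$manifest$run_id[sim$manifest$is_control]
  expect_true(length(ctrl_runs) >= 1)
  expect_equal(sum(sim$evidence$run_id %in% ctrl_runs), 0)
  # every run in the evidence appears exactly once in the manifest
  expect_true(all(sim$evidence$run_id %in% sim$manifest$run_id))
  expect_false(anyDuplicated(sim$manifest$run_id) > 0)
  # planted entities appear in the emitted tables
  prots <- unique(unlist(strsplit(sim$evidence$protein_ids, ";")))
  expect_true(all(sim$truth$true_edges$prey %in% prots))
})

test_that("simulate_phospho plants perturbation and extension truth", {
  # frac 0: all sites null, truth empty
  cfg0 <- sim_config(seed = 2, phospho_n_sites = 30,
                     phospho_frac_perturbed = 0)
  s0 <- simulate_phospho(cfg0)
  expect_length(s0$truth$true_perturbed_sites, 0)
  expect_equal(nrow(s0$counts), 30)
  expect_true(all(s0$counts[, 3:6] >= 0))

  # planted extension proteins are exactly the perturbed external proteins
  # with a PPI path of length 1 to a TAP protein
  cfg <- sim_config(seed = 2, phospho_n_sites = 60, count_mean = 40)
  tapp <- sprintf("TAP%02d", 1:10)
  s <- simulate_phospho(cfg, tap_proteins = tapp)
  for (p in s$truth$true_extension_proteins)
    expect_true(length(intersect(ppi_neighbors(s$ppi, p), tapp)) >= 1)
  for (p in s$truth$true_null_external)
    expect_length(intersect(ppi_neighbors(s$ppi, p), tapp), 0)
})

test_that("simulate_screen plants the core and honors cv = 0", {
  cfg <- sim_config(seed = 9, screen_n_lines = 3, screen_n_mutant = 2,
                    screen_n_genes = 6, core_genes = c("CORE01", "CORE02"),
                    replicate_cv = 0, core_effect = 0.25)
  scr <- simulate_screen(cfg)$screen
  r <- scr$readings
  mut <- scr$meta$cell_line[scr$meta$group == "mutant"]
  core_mut <- r$readout[r$cell_line %in% mut & r$gene == "CORE01"]
  expect_true(all(core_mut == 2000 * 0.25))  # replicates equal planted mean
  wt <- setdiff(scr$meta$cell_line, mut)
  expect_true(all(r$readout[r$cell_line %in% wt & !r$is_control] == 2000))
  # core genes produce no hits in wild-type lines (no effect planted)
  hits <- suppressWarnings(call_hits(normalize_screen(scr)))
  wt_hits <- hits$gene[hits$is_hit & hits$cell_line %in% wt]
  expect_length(intersect(wt_hits, cfg$core_genes), 0)
})

test_that("simulate_drug_tables plants binders and exact dose curves", {
  cfg <- sim_config(seed = 4, drug_n_compounds = 10,
                    dose_response_params = list(d1 = c(Dm = 1, m = 1),
                                                d2 = c(Dm = 1, m = 2)))
  sim <- simulate_drug_tables(cfg)
  # median-effect closed forms: (Dm=1, m=1), D=1 -> 0.5; (Dm=1, m=2), D=2 -> 0.8
  dr <- sim$dose_response
  expect_equal(dr$fa[dr$drug_id == "d1" & dr$dose == 1], 0.5)
  expect_equal(dr$fa[dr$drug_id == "d2" & dr$dose == 2], 0.8)
  # planted allele binders are present, tagged and below 100 nM
  ab <- sim$truth$true_allele_binders
  expect_equal(nrow(ab), 2)
  rows <- sim$drug_targets[sim$drug_targets$allele == "T790M", ]
  expect_setequal(rows$compound_id, ab$compound)
  expect_true(all(rows$value_nM < 100))
  # noiseless fits recover the planted parameters
  f <- fit_median_effect(dr$dose[dr$drug_id == "d2"],
                         dr$fa[dr$drug_id == "d2"], "d2")
  expect_equal(f$Dm, 1, tolerance = 1e-9)
  expect_equal(f$m, 2, tolerance = 1e-9)
})
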