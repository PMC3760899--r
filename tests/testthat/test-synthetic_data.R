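test_that("identical seeds give bit-identical simulations", {
  s1 <- quick_sim(seed = 11)
  s2 <- quick_sim(seed = 11)
  expect_identical(s1$scans$A$spots, s2$scans$A$spots)
  expect_identical(s1$scans$B$spots, s2$scans$B$spots)
  expect_identical(s1$truth$patterns, s2$truth$patterns)
  s3 <- quick_sim(seed = 12)
  expect_false(identical(s1$scans$A$spots, s3$scans$A$spots))
})

test_that("null configuration plants no true fold changes", {
  sim <- quick_sim(seed = 3, n_de_per_line = 0, n_discordant = 0)
  expect_length(sim$truth$de_genes, 0)
  expect_true(all(sim$truth$patterns$A == 0))
  expect_true(all(sim$truth$patterns$B == 0))
})

test_that("spot tables are well formed", {
  sim <- quick_sim(seed = 4)
  for (ln in c("A", "B")) {
    sp <- sim$scans[[ln]]$spots
    expect_true(all(sp$cy3 > 0 & sp$cy5 > 0))
    expect_false(anyDuplicated(paste(sp$array_id, sp$clone_id, sp$col)) > 0)
    expect_equal(nrow(sp), 10 * 400)
  }
})

test_that("noise-free planted effects are recovered by the model fit", {
  cfg <- truth_config(
    n_genes = 60, n_de_per_line = 10, n_discordant = 0,
    archetype_profiles = matrix(rep(c(1, 0.5, -0.5, 0), each = 1), 1),
    concordant_target_r = 1, noise_sd = 1e-9, dye_bias_sd = 0,
    array_effect_sd = 0, printtip_curvature_amplitude = 0,
    pattern_jitter_sd = 0, amplitude_range = c(1, 1), seed = 5
  )
  d <- study_design()
  sim <- simulate_paired_experiment(d, cfg)
  fit <- fit_gene_model(ma_values(sim$scans$A), d)
  res <- contrast_test(fit, var = "genewise")
  patt <- extract_patterns(res, sim$truth$de_genes)
  truth <- sim$truth$patterns$A[sim$truth$de_genes, ]
  expect_lt(max(abs(patt - truth)), 1e-6)
  # constant planted pattern: averaged per-time contrast hits 1 exactly
  cfg2 <- cfg
  cfg2$archetype_profiles <- matrix(1, 1, 4)
  sim2 <- simulate_paired_experiment(d, cfg2)
  fit2 <- fit_gene_model(ma_values(sim2$scans$A), d)
  res2 <- contrast_test(fit2, var = "genewise")
  patt2 <- extract_patterns(res2, sim2$truth$de_genes)
  expect_lt(max(abs(patt2 - 1)), 1e-6)
})

test_that("planted discordant genes hit their target correlation", {
  sim <- quick_sim(seed = 6, n_de_per_line = 100, n_discordant = 15)
  tr <- sim$truth
  expect_length(tr$discordant_genes, 15)
  # direct correlation oracle on the planted vectors
  r <- vapply(tr$discordant_genes, function(g) {
    stats::cor(tr$patterns$A[g, ], tr$patterns$B[g, ])
  }, numeric(1))
  expect_true(all(r <= -0.9))
  conc <- setdiff(tr$de_genes, tr$discordant_genes)
  rc <- vapply(conc, function(g) {
    stats::cor(tr$patterns$A[g, ], tr$patterns$B[g, ])
  }, numeric(1))
  expect_true(all(abs(rc - 0.9) < 1e-8))
})

test_that("print-tip curvature bias leaves per-tip mean log-ratio unchanged", {
  sim <- quick_sim(seed = 7, n_de_per_line = 0, n_discordant = 0,
                   noise_sd = 1e-9, dye_bias_sd = 0,
                   printtip_curvature_amplitude = 0.5)
  ma <- ma_values(sim$scans$A)
  tipmeans <- tapply(ma$M, paste(ma$array_id, ma$printtip), mean)
  expect_lt(max(abs(tipmeans)), 1e-6)
})

test_that("invalid truth configurations are rejected", {
  expect_error(truth_config(noise_sd = 0), "noise_sd")
  expect_error(truth_config(n_de_per_line = 10, n_genes = 5), "n_de_per_line")
  expect_error(truth_config(n_discordant = 20, n_de_per_line = 10), "n_discordant")
  expect_error(truth_config(discordant_target_r = -0.2), "discordant_target_r")
})

test_that("spot tables round-trip through TSV", {
  sim <- quick_sim(seed = 8, n_genes = 50, n_de_per_line = 5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(sim$scans$A, tf)
  back <- read_spot_table(tf, study_design(), line = "A")
  expect_equal(back$spots$cy5, sim$scans$A$spots$cy5, tolerance = 1e-12)
  expect_equal(back$spots$clone_id, sim$scans$A$spots$clone_id)
})
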