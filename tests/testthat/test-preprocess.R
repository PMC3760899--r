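test_that("pin-wise lowess removes planted intensity curvature", {
  sim <- quick_sim(seed = 21, n_genes = 1000, n_de_per_line = 0,
                   n_discordant = 0, noise_sd = 0.05,
                   dye_bias_sd = 0, printtip_curvature_amplitude = 0.6)
  norm <- printtip_lowess_normalize(sim$scans$A)
  tipmean <- tapply(abs(norm$M), paste(norm$array_id, norm$printtip), mean)
  raw <- ma_values(sim$scans$A)
  raw_dev <- tapply(abs(raw$M), paste(raw$array_id, raw$printtip), mean)
  # curvature is mostly gone and the fit never inflates a tip group
  grpmean <- tapply(norm$M, paste(norm$array_id, norm$printtip), mean)
  expect_lt(max(abs(grpmean)), 0.02)
  expect_lt(mean(tipmean), mean(raw_dev))
})

test_that("normalization is a no-op on identically zero log-ratios", {
  sim <- quick_sim(seed = 22, n_genes = 200, n_de_per_line = 0,
                   n_discordant = 0)
  scan <- sim$scans$A
  scan$spots$cy5 <- scan$spots$cy3          # M == 0 everywhere
  norm <- printtip_lowess_normalize(scan)
  expect_true(all(abs(norm$M) < 1e-12))
})

test_that("small print-tip groups fall back to whole-array lowess", {
  sim <- quick_sim(seed = 23, n_genes = 60, n_de_per_line = 0,
                   n_discordant = 0, n_printtips = 10)  # 6 spots per tip
  w <- testthat::capture_warnings(
    norm <- printtip_lowess_normalize(sim$scans$A))
  expect_true(all(grepl("whole-array lowess", w)))
  expect_length(w, 10)   # one warning per array
  expect_setequal(attr(norm, "fallback_arrays"),
                  unique(sim$scans$A$spots$array_id))
})

test_that("normalization is approximately idempotent", {
  sim <- quick_sim(seed = 24, n_genes = 800, n_de_per_line = 100)
  once <- printtip_lowess_normalize(sim$scans$A)
  twice <- printtip_lowess_normalize(once)
  delta <- abs(twice$M - once$M)
  # a second pass only refits local noise averages, O(noise/sqrt(window));
  # spots at the intensity extremes of a tip group see larger boundary
  # effects, so the bulk of spots is what approximate idempotence bounds
  expect_lt(median(delta), 0.02)
  expect_lt(unname(quantile(delta, 0.99)), 0.1)
})

test_that("model fit matches the dense pseudo-inverse solver", {
  for (seed in 1:5) {
    d <- random_small_design(seed)
    Z <- uvbloop:::design_matrix(d)
    set.seed(seed + 100)
    m <- rnorm(nrow(Z))
    norm <- data.frame(array_id = rownames(Z), clone_id = "g1", M = m)
    fit <- fit_gene_model(norm, d)
    expect_true(fit$estimable[["g1"]])
    beta <- ginv_fit(Z, m)
    expect_lt(max(abs(fit$coefficients["g1", ] - beta)), 1e-9)
  }
})

test_that("minimum-norm coefficients carry the sum-to-zero constraint", {
  sim <- quick_sim(seed = 25, n_genes = 50)
  d <- study_design()
  fit <- fit_gene_model(ma_values(sim$scans$A), d)
  s <- fit$coefficients[, d$samples$sample_id]
  expect_lt(max(abs(rowSums(s))), 1e-8)
})

test_that("estimates are invariant to permutation of input rows", {
  sim <- quick_sim(seed = 26, n_genes = 40)
  d <- study_design()
  norm <- ma_values(sim$scans$A)
  fit1 <- fit_gene_model(norm, d)
  set.seed(1)
  fit2 <- fit_gene_model(norm[sample(nrow(norm)), ], d)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-12)
})

test_that("a gene observed on a single array is inestimable", {
  d <- study_design()
  sim <- quick_sim(seed = 27, n_genes = 30)
  norm <- ma_values(sim$scans$A)
  norm <- norm[!(norm$clone_id == "g00001" & norm$array_id != "A01"), ]
  fit <- fit_gene_model(norm, d)
  expect_false(fit$estimable[["g00001"]])
  res <- contrast_test(fit)
  expect_false("g00001" %in% res$gene)
})

test_that("a null contrast gives F = 0 and p = 1", {
  d <- study_design()
  norm <- data.frame(array_id = d$arrays$array_id, clone_id = "g1", M = 0)
  fit <- fit_gene_model(norm, d)
  res <- contrast_test(fit, var = "genewise")
  expect_equal(res$F, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
})

test_that("F statistic matches hand-computed arithmetic on a dye-swap toy", {
  samples <- data.frame(sample_id = c("C4", "UV4"), time_hours = 4,
                        treated = c(FALSE, TRUE))
  arrays <- data.frame(array_id = paste0("A", 1:4),
                       cy3_sample = c("C4", "UV4", "C4", "UV4"),
                       cy5_sample = c("UV4", "C4", "UV4", "C4"))
  d <- loop_design(arrays, samples)
  norm <- data.frame(array_id = arrays$array_id, clone_id = "g1",
                     M = c(1.0, -0.6, 0.8, -0.8))
  fit <- fit_gene_model(norm, d)
  res <- contrast_test(fit, times = 4, var = "genewise")
  # by hand: contrast (m1+m3-m2-m4)/4 = 0.8, RSS = 0.04 on 2 df,
  # contrast variance sigma^2/4, so F = 0.64 / (0.25 * 0.02) = 128
  expect_equal(res$log2fc, 0.8, tolerance = 1e-12)
  expect_equal(res$F, 128, tolerance = 1e-9)
  expect_equal(res$p, pf(128, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("raw p-values are uniform under the null", {
  sim <- quick_sim(seed = 28, n_genes = 2000, n_de_per_line = 0,
                   n_discordant = 0)
  fit <- fit_gene_model(printtip_lowess_normalize(sim$scans$A), study_design())
  res <- contrast_test(fit)
  p4 <- res$p[res$time == 4]
  ks <- suppressWarnings(stats::ks.test(p4, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p4 < 0.05) - 0.05), 0.02)
})

test_that("DE calling applies the dual criterion", {
  res <- fake_results(
    gene = c("a", "b", "c", "d"),
    time = 4,
    log2fc = c(0.5, 1.2, -1.0, 2.0),     # a: fold 1.41, below threshold
    p_adj = c(1e-8, 1e-4, 0.2, 0.01)     # c: not significant
  )
  de <- call_de_genes(res)
  expect_setequal(de$per_time$t4, c("b", "d"))
  expect_setequal(de$union, c("b", "d"))
  expect_equal(de$direction$direction[de$direction$gene == "b"], "up")
  expect_identical(call_de_genes(res[0, ])$union, character())
})

test_that("clone-to-gene collapsing unions clones at the gene level", {
  res <- fake_results(gene = c("cl1", "cl2", "cl3"), time = 4,
                      log2fc = c(1.5, -1.5, 1.5), p_adj = c(0.001, 0.001, 0.5))
  map <- data.frame(clone_id = c("cl1", "cl2", "cl3"),
                    gene_id = c("G1", "G1", "G2"))
  de <- call_de_genes(res, clone_map = map)
  expect_setequal(de$union, "G1")
})

test_that("Bonferroni keeps expected null false positives at the nominal level", {
  # 50 replicate null studies; expected false calls per time point <= alpha
  total <- 0L
  for (seed in 1:50) {
    sim <- quick_sim(seed = 300 + seed, n_genes = 300, n_de_per_line = 0,
                     n_discordant = 0)
    fit <- fit_gene_model(ma_values(sim$scans$A), study_design())
    de <- call_de_genes(contrast_test(fit))
    total <- total + sum(vapply(de$per_time, length, 1L))
  }
  # 200 families with expectation <= 0.05 each
  expect_lte(total, 30)
})

test_that("patterns come out in time order regardless of input order", {
  res <- fake_results(gene = rep("g", 4), time = c(16, 4, 24, 8),
                      log2fc = c(3, 1, 4, 2), p_adj = 1)
  m <- extract_patterns(res)
  expect_equal(colnames(m), c("t4", "t8", "t16", "t24"))
  expect_equal(unname(m["g", ]), c(1, 2, 3, 4))
  expect_equal(nrow(extract_patterns(res, genes = character())), 0)
  res2 <- rbind(res, fake_results("h", 4, 1, 1))
  expect_warning(m2 <- extract_patterns(res2), "missing time points")
  expect_false("h" %in% rownames(m2))
})

test_that("the Table-style count layout is consistent with the union", {
  sim <- quick_sim(seed = 29, n_genes = 500, n_de_per_line = 60)
  d <- study_design()
  de <- lapply(sim$scans, function(s) {
    call_de_genes(contrast_test(fit_gene_model(printtip_lowess_normalize(s), d)))
  })
  names(de) <- c("MRC-5", "MRC5CVI")
  tab <- de_count_table(de)
  expect_equal(names(tab), c(" ", "MRC-5", "MRC5CVI", "Union"))
  expect_true(all(tab$Union >= pmax(tab[["MRC-5"]], tab[["MRC5CVI"]])))
  expect_equal(tab$Union[5],
               length(unique(c(de[[1]]$union, de[[2]]$union))))
})
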