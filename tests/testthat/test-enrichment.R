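test_that("single-gene and empty overlaps can never score below 1", {
  expect_equal(ease_score(0, 10, 20, 100), 1)
  expect_equal(ease_score(1, 10, 20, 100), 1)
  expect_equal(ease_score(1, 3, 5, 50), 1)
})

test_that("the score equals the brute-force hypergeometric tail sum", {
  # independent oracle: sum the point masses P(X = j) for j = k-1 .. min(K,n)
  brute <- function(k, K, n, N) {
    if (k <= 1) return(1)
    sum(vapply((k - 1):min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }, numeric(1)))
  }
  expect_equal(ease_score(5, 10, 20, 100), brute(5, 10, 20, 100),
               tolerance = 1e-12)
  expect_equal(ease_score(5, 10, 20, 100), 0.109571850959277,
               tolerance = 1e-12)  # frozen from the oracle
  set.seed(1)
  for (i in 1:50) {
    N <- sample(20:150, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(ease_score(k, K, n, N), brute(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("the score is conservative and monotone in the overlap", {
  set.seed(2)
  for (i in 1:30) {
    N <- sample(30:200, 1); K <- sample(2:N, 1); n <- sample(2:N, 1)
    ks <- 1:min(K, n)
    ease <- ease_score(ks, K, n, N)
    fisher <- stats::phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
    expect_true(all(ease >= fisher - 1e-14))
    expect_true(all(diff(ease) <= 1e-14))   # non-increasing in k
  }
  expect_error(ease_score(5, 3, 10, 100), "inconsistent")
  expect_error(ease_score(2, 10, 1, 100), "inconsistent")
})

test_that("a fully recovered term is flagged significant", {
  universe <- sprintf("g%04d", 1:1000)
  ann <- annotation_set(list(hit = universe[1:30], other = universe[31:90]),
                        universe)
  res <- enrich_terms(universe[1:30], ann)
  expect_true(res$significant[res$term == "hit"])
  expect_equal(res$k[res$term == "hit"], 30)
})

test_that("random groups stay at or below the nominal significance rate", {
  set.seed(3)
  universe <- sprintf("g%04d", 1:1000)
  sets <- lapply(1:500, function(i) sample(universe, sample(10:40, 1)))
  names(sets) <- sprintf("T%03d", 1:500)
  ann <- annotation_set(sets, universe)
  sig <- vapply(1:100, function(i) {
    sum(enrich_terms(sample(universe, 50), ann)$significant)
  }, numeric(1))
  expect_lte(mean(sig), 0.05 * 500)
})

test_that("a planted pathway attains the minimum EASE score", {
  sim <- quick_sim(seed = 41, n_genes = 600, n_de_per_line = 120)
  ann <- simulate_annotation(sim$truth, n_random_terms = 60, seed = 2)
  tr <- sim$truth
  group <- names(tr$archetype)[tr$archetype == 1]
  res <- enrich_terms(group, ann)
  planted <- grep("^PLANTED", res$term)[1]
  expect_equal(res$ease_p[1], min(res$ease_p))
  expect_true(startsWith(res$term[1], "PLANTED"))
  expect_true(res$significant[1])
})

test_that("genes outside the universe are dropped with a warning", {
  universe <- sprintf("g%02d", 1:50)
  ann <- annotation_set(list(t1 = universe[1:10]), universe)
  expect_warning(res <- enrich_terms(c(universe[1:8], "alien"), ann),
                 "outside the universe")
  expect_equal(res$n, 8)
})

test_that("GMT files round-trip", {
  universe <- sprintf("g%03d", 1:100)
  ann <- annotation_set(list(alpha = universe[1:10], beta = universe[5:40]),
                        universe,
                        descriptions = c(alpha = "first", beta = "second"))
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, tf)
  back <- read_gmt(tf, universe = universe)
  expect_equal(back$sets, ann$sets)
  expect_equal(unname(back$descriptions["alpha"]), "first")
  bad <- withr::local_tempfile()
  writeLines(c("term_only\tdesc"), bad)
  expect_error(read_gmt(bad), "malformed GMT")
})
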