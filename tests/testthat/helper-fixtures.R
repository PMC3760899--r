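# Shared fixture builders; everything is generated in code at test time.

# The standard 8-sample / 10-array study design.
study_design <- function() make_loop_design(4)

# A quick simulated pair of scans with a small gene count.
quick_sim <- function(seed = 1L, n_genes = 400, n_de_per_line = NULL, ...) {
  n_de_per_line <- n_de_per_line %||% (n_genes %/% 5)
  args <- list(...)
  if (is.null(args$n_discordant)) {
    args$n_discordant <- min(15L, n_de_per_line)
  }
  cfg <- do.call(truth_config, c(list(n_genes = n_genes,
                                      n_de_per_line = n_de_per_line,
                                      seed = seed), args))
  simulate_paired_experiment(study_design(), cfg)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a contrast_result data.frame by hand (for DE-call unit tests).
fake_results <- function(gene, time, log2fc, p_adj) {
  structure(data.frame(gene = gene, time = time, log2fc = log2fc,
                       F = 1, p = p_adj, p_adj = p_adj,
                       stringsAsFactors = FALSE),
            class = c("contrast_result", "data.frame"))
}

# Random connected 4-sample design with 6 arrays (2 time points), used for
# least-squares oracle checks. Orientation of each edge is random.
random_small_design <- function(seed) {
  set.seed(seed)
  samples <- c("C4", "UV4", "C8", "UV8")
  # random spanning tree then extra edges
  perm <- sample(samples)
  edges <- cbind(perm[c(1, 1, 2)], perm[c(2, 3, 4)])
  extra <- t(replicate(3, sample(samples, 2)))
  edges <- rbind(edges, extra)
  flip <- sample(c(TRUE, FALSE), nrow(edges), replace = TRUE)
  edges[flip, ] <- edges[flip, 2:1]
  loop_design(
    arrays = data.frame(array_id = sprintf("A%d", seq_len(nrow(edges))),
                        cy3_sample = edges[, 1], cy5_sample = edges[, 2],
                        stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samples,
                         time_hours = c(4, 4, 8, 8),
                         treated = c(FALSE, TRUE, FALSE, TRUE),
                         stringsAsFactors = FALSE)
  )
}

# Dense minimum-norm least-squares oracle via MASS::ginv.
ginv_fit <- function(Z, m) drop(MASS::ginv(Z) %*% m)

# A tiny GEO series matrix fixture written to a temp file.
write_geo_fixture <- function(path, truncate = FALSE) {
  lines <- c(
    '!Series_title\t"tiny fixture"',
    '!Series_geo_accession\t"GSE00000"',
    '!Sample_title\t"s1"\t"s2"',
    '!Sample_geo_accession\t"GSM1"\t"GSM2"',
    '!series_matrix_table_begin',
    '"ID_REF"\t"GSM1"\t"GSM2"',
    '"g001"\t0.5\t-0.25',
    '"g002"\t1.25\t0.75',
    '"g003"\tnull\t2',
    '!series_matrix_table_end'
  )
  if (truncate) lines <- lines[1:8]
  writeLines(lines, path)
  path
}
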