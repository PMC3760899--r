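#' Pearson correlation of two expression patterns
#'
#' The standard product-moment correlation of a gene's time-course log2FC
#' vectors in the two cell lines. Patterns with (near) zero variance have no
#' defined correlation and return `NA`; callers exclude and count them.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA_real_` if either pattern has zero
#'   variance.
#' @export
pattern_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("patterns must have equal length", call. = FALSE)
  if (length(x) < 3) stop("patterns must have length >= 3", call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
  stats::cor(x, y)
}

# Row-wise correlations between two pattern matrices (same row order).
row_correlations <- function(a, b) {
  za <- row_standardize(a)
  zb <- row_standardize(b)
  rowSums(za * zb)
}

#' Random-matching null distribution of pattern correlations
#'
#' Estimates the distribution of between-line pattern correlations expected
#' when genes are paired at random: each iteration draws a uniform random
#' bijection from the line-A genes to the line-B genes, computes all matched
#' Pearson correlations, and pools them across iterations. The pooled
#' standard deviation is the discrepancy threshold used by
#' [select_discrepant()]. Genes with zero-variance patterns in either line
#' are excluded from the matching and counted.
#'
#' @param patterns_a,patterns_b numeric matrices (genes x time points) with
#'   gene ids as rownames; the two matrices must cover the same genes.
#' @param n_iterations number of random matchings.
#' @param seed RNG seed.
#' @return list of class `null_distribution`: `pooled` (all correlations),
#'   `mean`, `sd`, `per_iteration_sd`, `n_iterations`, `n_genes`,
#'   `n_dropped`, `seed`.
#' @export
random_match_null <- function(patterns_a, patterns_b, n_iterations = 100,
                              seed = 1L) {
  stopifnot(is.matrix(patterns_a), is.matrix(patterns_b))
  common <- intersect(rownames(patterns_a), rownames(patterns_b))
  if (length(common) < 2) stop("need at least 2 shared genes", call. = FALSE)
  a <- patterns_a[common, , drop = FALSE]
  b <- patterns_b[common, , drop = FALSE]
  za <- row_standardize(a)
  zb <- row_standardize(b)
  ok <- !is.na(za[, 1]) & !is.na(zb[, 1])
  n_dropped <- sum(!ok)
  za <- za[ok, , drop = FALSE]
  zb <- zb[ok, , drop = FALSE]
  n <- nrow(za)
  if (n < 2) stop("fewer than 2 genes with non-degenerate patterns", call. = FALSE)
  pooled <- with_seed(seed, {
    unlist(lapply(seq_len(n_iterations), function(i) {
      rowSums(za * zb[sample.int(n), , drop = FALSE])
    }), use.names = FALSE)
  })
  per_iter_sd <- vapply(seq_len(n_iterations), function(i) {
    stats::sd(pooled[((i - 1) * n + 1):(i * n)])
  }, numeric(1))
  structure(list(
    pooled = pooled,
    mean = mean(pooled),
    sd = stats::sd(pooled),
    per_iteration_sd = per_iter_sd,
    n_iterations = n_iterations,
    n_genes = n,
    n_dropped = n_dropped,
    seed = seed
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Random-matching null:", x$n_iterations, "iterations x", x$n_genes,
      "genes\n  pooled mean", signif(x$mean, 3), ", sd", signif(x$sd, 4),
      if (x$n_dropped) paste0(" (", x$n_dropped, " degenerate genes dropped)"),
      "\n")
  invisible(x)
}

#' Select the most discrepant genes between two cell lines
#'
#' Genes whose between-line pattern correlation is strictly smaller than
#' minus one standard deviation of the random-matching null are the most
#' discrepant genes; genes with correlation strictly above +1 sd are tallied
#' as concordant. Zero-variance patterns are excluded and counted.
#'
#' @param patterns_a,patterns_b pattern matrices as in [random_match_null()].
#' @param null a [random_match_null()] result (its `sd` sets the threshold).
#' @return list of class `discrepant_set`: `discrepant` (data.frame gene, r),
#'   `correlations` (all genes), `threshold`, `n_concordant` (r > +sd),
#'   `n_middle`, `n_dropped`.
#' @export
select_discrepant <- function(patterns_a, patterns_b, null) {
  stopifnot(inherits(null, "null_distribution"))
  common <- intersect(rownames(patterns_a), rownames(patterns_b))
  if (length(common) == 0) {
    return(structure(list(
      discrepant = data.frame(gene = character(), r = numeric()),
      correlations = data.frame(gene = character(), r = numeric()),
      threshold = null$sd, n_concordant = 0L, n_middle = 0L, n_dropped = 0L
    ), class = "discrepant_set"))
  }
  a <- patterns_a[common, , drop = FALSE]
  b <- patterns_b[common, , drop = FALSE]
  r <- row_correlations(a, b)
  cors <- data.frame(gene = common, r = r, stringsAsFactors = FALSE)
  dropped <- is.na(r)
  thr <- null$sd
  disc <- cors[!dropped & r < -thr, , drop = FALSE]
  disc <- disc[order(disc$r), , drop = FALSE]
  rownames(disc) <- NULL
  structure(list(
    discrepant = disc,
    correlations = cors,
    threshold = thr,
    n_concordant = sum(!dropped & r > thr),
    n_middle = sum(!dropped & r >= -thr & r <= thr),
    n_dropped = sum(dropped)
  ), class = "discrepant_set")
}

#' @export
print.discrepant_set <- function(x, ...) {
  cat("Most discrepant genes (r < -", signif(x$threshold, 4), "): ",
      nrow(x$discrepant), " of ", nrow(x$correlations), " candidates; ",
      x$n_concordant, " concordant (r > +sd)\n", sep = "")
  if (nrow(x$discrepant)) print(utils::head(x$discrepant, 15), row.names = FALSE)
  invisible(x)
}
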