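#' k-means clustering of expression patterns
#'
#' Groups genes by Euclidean k-means on their raw (unstandardized) log2
#' fold-change time courses, so that both shape and magnitude drive the
#' groups. The best of `restarts` random initializations by total
#' within-cluster sum of squares is kept; each restart runs to convergence.
#'
#' @param patterns numeric matrix, genes x time points (rownames = gene ids).
#' @param k number of clusters.
#' @param restarts number of random restarts.
#' @param max_iter maximal iterations per restart.
#' @param seed RNG seed; results are deterministic given the seed.
#' @return list of class `pattern_clustering`: `assignments` (named integer
#'   vector), `centroids` (k x T matrix), `withinss`, `tot_withinss`,
#'   `betweenss`, `totss`, `restart_withinss` (per-restart totals), `k`,
#'   `seed`.
#' @export
cluster_patterns <- function(patterns, k = 6, restarts = 1000,
                             max_iter = 300, seed = 1L) {
  stopifnot(is.matrix(patterns), !anyNA(patterns))
  if (nrow(patterns) < k) {
    stop("fewer patterns (", nrow(patterns), ") than clusters (", k,
         "); choose a smaller k", call. = FALSE)
  }
  n_distinct <- nrow(unique(patterns))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct patterns; using k = ", n_distinct,
            call. = FALSE)
    k <- n_distinct
  }
  with_seed(seed, {
    best <- NULL
    restart_ss <- numeric(restarts)
    for (r in seq_len(restarts)) {
      km <- suppressWarnings(
        stats::kmeans(patterns, centers = k, iter.max = max_iter, nstart = 1)
      )
      restart_ss[r] <- km$tot.withinss
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    n_eff <- length(unique(best$cluster))
    if (n_eff < k) {
      warning("only ", n_eff, " non-empty clusters after best restart",
              call. = FALSE)
    }
    structure(list(
      assignments = stats::setNames(best$cluster, rownames(patterns)),
      centroids = best$centers,
      withinss = best$withinss,
      tot_withinss = best$tot.withinss,
      betweenss = best$betweenss,
      totss = best$totss,
      restart_withinss = restart_ss,
      k = k, seed = seed
    ), class = "pattern_clustering")
  })
}

#' Summarize clusters as mean profiles with direction labels
#'
#' The per-cluster mean time course (the thick line of a cluster profile
#' plot) and an up/down label: "up" if the mean of the profile's components
#' is positive, "down" otherwise. Empty clusters are omitted with a warning.
#'
#' @param clustering a [cluster_patterns()] result.
#' @return data.frame: `cluster`, `n_genes`, `direction`, one column per
#'   time point with the mean log2FC.
#' @export
summarize_clusters <- function(clustering) {
  stopifnot(inherits(clustering, "pattern_clustering"))
  labs <- sort(unique(clustering$assignments))
  if (length(labs) < clustering$k) {
    warning(clustering$k - length(labs), " empty cluster(s) omitted",
            call. = FALSE)
  }
  prof <- clustering$centroids[labs, , drop = FALSE]
  data.frame(
    cluster = labs,
    n_genes = as.integer(table(factor(clustering$assignments, levels = labs))),
    direction = ifelse(rowMeans(prof) > 0, "up", "down"),
    prof,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

#' @export
print.pattern_clustering <- function(x, ...) {
  cat("k-means pattern clustering: k =", x$k, ",",
      length(x$assignments), "genes, best of", length(x$restart_withinss),
      "restarts (within-SS", signif(x$tot_withinss, 4), ")\n")
  invisible(x)
}
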