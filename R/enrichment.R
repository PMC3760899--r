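#' EASE score: conservative one-tailed Fisher's exact p-value
#'
#' The EASE score is the hypergeometric upper-tail probability computed after
#' removing one gene from the group-term overlap: with `k` group genes in the
#' term, `K` term genes in the background, group size `n` and background size
#' `N`, the score is `P(X >= k - 1)` for `X ~ Hypergeometric(N, K, n)`. A
#' single-gene overlap (`k <= 1`) can never be significant (score 1), which
#' penalizes terms supported by one gene. The score is always at least the
#' unmodified Fisher upper-tail p-value.
#'
#' Arguments are recycled to a common length.
#'
#' @param k number of group genes annotated to the term.
#' @param K number of background genes annotated to the term.
#' @param n group size.
#' @param N background (universe) size.
#' @return p-value(s) in (0, 1\].
#' @export
ease_score <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), len)
  K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len)
  N <- rep_len(as.numeric(N), len)
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  out <- rep(1, len)
  idx <- k > 1
  out[idx] <- stats::phyper(k[idx] - 2, K[idx], N[idx] - K[idx], n[idx],
                            lower.tail = FALSE)
  out
}

#' Gene-set container for enrichment analysis
#'
#' @param sets named list of character vectors (term id -> member gene ids).
#' @param universe character vector of background gene ids; term members
#'   outside the universe are dropped.
#' @param descriptions optional named character vector of term descriptions.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(sets, universe, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), is.character(universe))
  universe <- unique(universe)
  sets <- lapply(sets, function(g) intersect(unique(g), universe))
  keep <- vapply(sets, length, 1L) > 0
  if (!all(keep)) sets <- sets[keep]
  if (length(sets) == 0) stop("no non-empty terms within the universe", call. = FALSE)
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "annotation_set")
}

#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @param universe background gene ids; defaults to the union of all terms.
#' @return an [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3
  if (any(short)) {
    stop("malformed GMT: line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  universe <- universe %||% sort(unique(unlist(sets, use.names = FALSE)))
  annotation_set(sets, universe, desc)
}

#' Write gene sets to a GMT file
#'
#' @param annotation an [annotation_set()].
#' @param path output path.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  desc <- annotation$descriptions
  lines <- vapply(names(annotation$sets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, annotation$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' EASE-score over-representation test of a gene group
#'
#' Tests every annotation term with at least one group hit. A term is flagged
#' significant when strictly more than `min_term_genes` group genes are
#' annotated to it and its EASE score is below `alpha`; no further
#' multiple-testing correction is applied across terms.
#'
#' @param group character vector of gene ids (members outside the universe
#'   are dropped with a warning).
#' @param annotation an [annotation_set()].
#' @param min_term_genes group-hit count that a significant term must exceed.
#' @param alpha EASE-score significance threshold.
#' @return data.frame of class `enrichment_result`, one row per tested term:
#'   `term, k, K, n, N, ease_p, significant`, ordered by `ease_p`.
#' @export
enrich_terms <- function(group, annotation, min_term_genes = 5, alpha = 0.05) {
  stopifnot(inherits(annotation, "annotation_set"))
  group <- unique(group)
  outside <- setdiff(group, annotation$universe)
  if (length(outside)) {
    warning(length(outside), " group gene(s) outside the universe dropped",
            call. = FALSE)
    group <- setdiff(group, outside)
  }
  N <- length(annotation$universe)
  n <- length(group)
  k <- vapply(annotation$sets, function(s) length(intersect(s, group)), 1L)
  K <- vapply(annotation$sets, length, 1L)
  keep <- k >= 1
  res <- data.frame(
    term = names(annotation$sets)[keep],
    k = k[keep], K = K[keep], n = n, N = N,
    stringsAsFactors = FALSE
  )
  res$ease_p <- ease_score(res$k, res$K, res$n, res$N)
  res$significant <- res$k > min_term_genes & res$ease_p < alpha
  res <- res[order(res$ease_p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}
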