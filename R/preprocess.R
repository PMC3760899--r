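#' Compute M and A values from a two-channel scan
#'
#' M is the log2 ratio Cy5/Cy3 and A the mean log2 spot intensity; all
#' downstream modelling works on M, with A used only to remove
#' intensity-dependent bias.
#'
#' @param scan an `array_scan_set`.
#' @return data.frame with columns `array_id, clone_id, printtip, M, A`.
#' @export
ma_values <- function(scan) {
  spots <- scan$spots
  if (any(spots$cy3 <= 0) || any(spots$cy5 <= 0)) {
    stop("spot intensities must be strictly positive", call. = FALSE)
  }
  data.frame(
    array_id = spots$array_id,
    clone_id = spots$clone_id,
    printtip = spots$printtip,
    M = log2(spots$cy5) - log2(spots$cy3),
    A = (log2(spots$cy5) + log2(spots$cy3)) / 2,
    stringsAsFactors = FALSE
  )
}

#' Print-tip (pin-wise) lowess normalization
#'
#' Within each (array, print-tip) group the locally weighted regression of M
#' on A is fitted and subtracted, removing print-tip dependent
#' intensity-curvature bias; A is left untouched. Groups smaller than
#' `min_tip_spots` fall back to the whole-array lowess fit with a warning.
#'
#' @param scan an `array_scan_set` (or a data.frame of M/A values as returned
#'   by [ma_values()]).
#' @param span lowess span (fraction of spots in the local window).
#' @param min_tip_spots minimal group size for a tip-level fit.
#' @return data.frame like [ma_values()] with normalized M and class
#'   `normalized_arrays`; attribute `fallback_arrays` lists arrays where the
#'   whole-array fallback was used.
#' @export
printtip_lowess_normalize <- function(scan, span = 0.4, min_tip_spots = 10) {
  ma <- if (inherits(scan, "array_scan_set")) ma_values(scan) else scan
  stopifnot(all(c("array_id", "clone_id", "printtip", "M", "A") %in% names(ma)))
  fallback <- character()
  for (aid in unique(ma$array_id)) {
    ai <- which(ma$array_id == aid)
    tips <- split(ai, ma$printtip[ai])
    small <- vapply(tips, length, 1L) < min_tip_spots
    if (any(small)) {
      fallback <- c(fallback, aid)
      warning("array ", aid, ": ", sum(small),
              " print-tip group(s) below ", min_tip_spots,
              " spots; using whole-array lowess", call. = FALSE)
      fit <- limma::loessFit(ma$M[ai], ma$A[ai], span = span)$fitted
      ma$M[ai] <- ma$M[ai] - fit
    } else {
      for (idx in tips) {
        fit <- limma::loessFit(ma$M[idx], ma$A[idx], span = span)$fitted
        ma$M[idx] <- ma$M[idx] - fit
      }
    }
  }
  structure(ma, class = c("normalized_arrays", "data.frame"),
            fallback_arrays = fallback)
}

#' Fit the per-gene log-linear loop-design model
#'
#' For each gene the normalized log-ratios across arrays are modelled as the
#' Cy5 sample effect minus the Cy3 sample effect plus a gene-specific dye
#' term: `M_a = s[cy5(a)] - s[cy3(a)] + d + e`. The least-squares solution is
#' the minimum-norm one (SVD pseudo-inverse), which carries the sum-to-zero
#' constraint on the sample effects; only sample contrasts are interpreted.
#' Genes whose available arrays do not connect all samples of the design are
#' flagged inestimable and excluded from testing.
#'
#' @param norm normalized M values ([printtip_lowess_normalize()] output, or
#'   any data.frame with `array_id`, `clone_id`, `M`).
#' @param design the [loop_design()].
#' @return An object of class `gene_fit` with per-gene coefficients, residual
#'   variance and df, estimability flags, and the pooled residual variance.
#' @export
fit_gene_model <- function(norm, design) {
  stopifnot(all(c("array_id", "clone_id", "M") %in% names(norm)))
  Z <- design_matrix(design)
  arrays <- rownames(Z)
  norm <- norm[norm$array_id %in% arrays, , drop = FALSE]
  # average replicate spots of the same clone on the same array
  key <- paste(norm$clone_id, norm$array_id, sep = "\r")
  if (anyDuplicated(key)) {
    m <- tapply(norm$M, key, mean)
    parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
    norm <- data.frame(clone_id = parts[, 1], array_id = parts[, 2],
                       M = as.vector(m), stringsAsFactors = FALSE)
  }
  genes <- sort(unique(norm$clone_id))
  Mmat <- matrix(NA_real_, length(genes), length(arrays),
                 dimnames = list(genes, arrays))
  Mmat[cbind(match(norm$clone_id, genes), match(norm$array_id, arrays))] <- norm$M

  avail <- !is.na(Mmat)
  sig <- apply(avail, 1, function(x) paste(which(x), collapse = ","))
  p <- ncol(Z)
  coef <- matrix(NA_real_, length(genes), p, dimnames = list(genes, colnames(Z)))
  rss <- df <- rep(NA_real_, length(genes))
  estimable <- rep(FALSE, length(genes))
  names(rss) <- names(df) <- names(estimable) <- genes
  groups <- list()

  for (s in unique(sig)) {
    rows <- which(sig == s)
    cols <- as.integer(strsplit(s, ",")[[1]])
    Zg <- Z[cols, , drop = FALSE]
    sub_arrays <- design$arrays[match(rownames(Zg), design$arrays$array_id), ]
    ok <- length(cols) >= 2 && design_is_connected(design, sub_arrays)
    if (!ok) next
    sv <- svd(Zg)
    tol <- max(dim(Zg)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    rank <- sum(pos)
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    B <- Mmat[rows, cols, drop = FALSE] %*% t(pinv)
    res <- Mmat[rows, cols, drop = FALSE] - B %*% t(Zg)
    coef[rows, ] <- B
    rss[rows] <- rowSums(res^2)
    df[rows] <- length(cols) - rank
    estimable[rows] <- TRUE
    groups[[s]] <- list(
      genes = genes[rows], rank = rank, df = length(cols) - rank,
      xtx_pinv = pinv %*% t(pinv),       # (Z'Z)^+ for contrast variances
      rowspace = pinv %*% Zg             # projector onto row space of Zg
    )
  }
  sigma2 <- ifelse(df > 0, rss / df, NA_real_)
  use <- estimable & df > 0
  pooled_df <- sum(df[use])
  pooled_sigma2 <- if (pooled_df > 0) sum(rss[use]) / pooled_df else NA_real_
  structure(list(
    coefficients = coef, rss = rss, df = df, sigma2 = sigma2,
    estimable = estimable, groups = groups, signature = sig,
    pooled_sigma2 = pooled_sigma2, pooled_df = pooled_df,
    design = design
  ), class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("Log-linear loop-design fit:", nrow(x$coefficients), "genes (",
      sum(x$estimable), "estimable ), pooled residual sd",
      signif(sqrt(x$pooled_sigma2), 3), "on", x$pooled_df, "df\n")
  invisible(x)
}

#' Per-time-point F test of the UV-vs-control contrast
#'
#' For each gene and time point the treated-minus-control contrast of the
#' fitted sample effects is tested with `F = estimate^2 / var(estimate)` on
#' 1 numerator df. With `var = "pooled"` (default) the residual variance is
#' pooled across all estimable genes, as in a global gene-expression ANOVA;
#' `"genewise"` uses each gene's own residual variance (few df on a loop
#' design). Bonferroni correction multiplies each raw p by the number of
#' clones tested at that time point.
#'
#' @param fit a [fit_gene_model()] result.
#' @param times time points to test; default all in the design.
#' @param var `"pooled"` or `"genewise"` residual variance.
#' @return data.frame of class `contrast_result`: `gene, time, log2fc, F, p,
#'   p_adj`.
#' @export
contrast_test <- function(fit, times = NULL,
                          var = c("pooled", "genewise")) {
  var <- match.arg(var)
  design <- fit$design
  times <- times %||% sort(unique(design$samples$time_hours))
  out <- list()
  for (tm in times) {
    cv <- time_contrast(design, tm)
    res <- lapply(names(fit$groups), function(s) {
      g <- fit$groups[[s]]
      # contrast estimable iff cv lies in the row space of the sub-design
      if (max(abs(drop(cv %*% g$rowspace) - cv)) > 1e-8) return(NULL)
      est <- drop(fit$coefficients[g$genes, , drop = FALSE] %*% cv)
      vf <- drop(cv %*% g$xtx_pinv %*% cv)
      if (var == "pooled") {
        s2 <- fit$pooled_sigma2
        dfe <- rep(fit$pooled_df, length(est))
      } else {
        s2 <- fit$sigma2[g$genes]
        dfe <- fit$df[g$genes]
      }
      Fst <- ifelse(est == 0, 0, est^2 / (vf * s2))  # 0/0 -> null contrast
      pv <- ifelse(dfe > 0, stats::pf(Fst, 1, dfe, lower.tail = FALSE),
                   NA_real_)
      data.frame(gene = g$genes, time = tm, log2fc = est, F = Fst, p = pv,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (!is.null(res) && nrow(res)) {
      n_tested <- sum(!is.na(res$p))
      res$p_adj <- pmin(1, res$p * n_tested)
      out[[as.character(tm)]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res[order(res$time, res$gene), ],
            class = c("contrast_result", "data.frame"))
}

#' Call differentially expressed genes by the dual criterion
#'
#' A gene is significant at a time point iff its model-estimated fold change
#' exceeds `fc_threshold` (i.e. `|log2fc| > log2(fc_threshold)`) and its
#' Bonferroni-adjusted p-value is below `alpha`. The union set collects genes
#' significant at one or more time points.
#'
#' @param results a [contrast_test()] result.
#' @param fc_threshold fold-change threshold (ratio scale).
#' @param alpha significance level on the adjusted p-value.
#' @param clone_map optional data.frame `clone_id, gene_id` collapsing clones
#'   to genes; testing stays at the clone level, reported sets are gene-level
#'   unions. Default: clones are genes.
#' @return list of class `de_gene_set`: `per_time` (named list of gene id
#'   vectors), `union`, `direction` (data.frame gene/time/direction), and
#'   `counts` (per-time and union counts).
#' @export
call_de_genes <- function(results, fc_threshold = 1.5, alpha = 0.05,
                          clone_map = NULL) {
  stopifnot(inherits(results, "contrast_result") || is.data.frame(results))
  if (is.null(results) || nrow(results) == 0) {
    return(structure(list(per_time = list(), union = character(),
                          direction = data.frame(), counts = data.frame()),
                     class = "de_gene_set"))
  }
  id <- results$gene
  if (!is.null(clone_map)) {
    id <- clone_map$gene_id[match(results$gene, clone_map$clone_id)]
    id[is.na(id)] <- results$gene[is.na(id)]
  }
  sig <- !is.na(results$p_adj) &
    abs(results$log2fc) > log2(fc_threshold) & results$p_adj < alpha
  times <- sort(unique(results$time))
  per_time <- lapply(times, function(tm) sort(unique(id[sig & results$time == tm])))
  names(per_time) <- paste0("t", times)
  direction <- data.frame(
    gene = id[sig], time = results$time[sig],
    direction = ifelse(results$log2fc[sig] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  union <- sort(unique(unlist(per_time, use.names = FALSE)))
  counts <- data.frame(
    time = c(paste0(times, " h"), ">=1 time-points"),
    n = c(vapply(per_time, length, 1L), length(union)),
    stringsAsFactors = FALSE
  )
  structure(list(per_time = per_time, union = union, direction = direction,
                 counts = counts, fc_threshold = fc_threshold, alpha = alpha),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat("UVB-regulated gene calls (fold-change >", x$fc_threshold,
      ", Bonferroni p <", x$alpha, "):\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Tabulate per-time DE counts for several lines
#'
#' Lays out the per-time-point and union counts for each cell line next to
#' the across-line union, one row per time point plus the ">=1 time-points"
#' row.
#'
#' @param de_sets named list of [call_de_genes()] results, one per line.
#' @return data.frame with one column per line plus `Union`.
#' @export
de_count_table <- function(de_sets) {
  stopifnot(length(de_sets) >= 1, !is.null(names(de_sets)))
  times <- names(de_sets[[1]]$per_time)
  rows <- c(paste0("Significant at ", sub("^t", "", times), " h"),
            "Significant at >=1 time-points")
  out <- data.frame(row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE,
                    ` ` = rows)
  for (nm in names(de_sets)) {
    out[[nm]] <- c(vapply(de_sets[[nm]]$per_time, length, 1L),
                   length(de_sets[[nm]]$union))
  }
  uni <- c(vapply(times, function(tm) {
    length(unique(unlist(lapply(de_sets, function(d) d$per_time[[tm]]))))
  }, 1L), length(unique(unlist(lapply(de_sets, function(d) d$union)))))
  out$Union <- uni
  out
}

#' Extract ordered 4-point expression patterns
#'
#' One row per gene, columns the log2 fold-change estimates in time order.
#' Genes missing any time point are excluded with a warning.
#'
#' @param results a [contrast_test()] result.
#' @param genes genes to extract; default all genes present.
#' @return numeric matrix (genes x times) with columns `t<time>`.
#' @export
extract_patterns <- function(results, genes = NULL) {
  times <- sort(unique(results$time))
  genes <- genes %||% sort(unique(results$gene))
  m <- matrix(NA_real_, length(genes), length(times),
              dimnames = list(genes, paste0("t", times)))
  keep <- results$gene %in% genes
  m[cbind(match(results$gene[keep], genes),
          match(results$time[keep], times))] <- results$log2fc[keep]
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) missing time points; excluded", call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  m
}
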