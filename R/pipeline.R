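#' Configuration of a full paired UVB time-course study
#'
#' Collects the analysis parameters of the whole pipeline: the loop design,
#' the synthetic-truth configuration (or input spot tables), the
#' normalization span, the dual DE criterion, the clustering and
#' null-distribution settings, and the enrichment filters. Per-stage seeds
#' are derived deterministically from `seed`.
#'
#' @param design a [loop_design()]; default [make_loop_design(4)].
#' @param truth a [truth_config()] used when the study is simulated.
#' @param scans optional named list `A`, `B` of `array_scan_set` objects; if
#'   supplied they are analyzed instead of simulating (no ground truth).
#' @param lines labels of the two cell lines (used in reports).
#' @param span lowess span for [printtip_lowess_normalize()].
#' @param fc_threshold,alpha dual DE criterion (fold change, Bonferroni p).
#' @param var residual-variance mode for [contrast_test()].
#' @param k,kmeans_restarts k-means settings for [cluster_patterns()].
#' @param null_iterations random matchings for [random_match_null()].
#' @param min_term_genes,ease_alpha enrichment filters for [enrich_terms()].
#' @param annotation an [annotation_set()], `"simulate"` to derive one from
#'   planted truth, or `NULL` to skip enrichment.
#' @param uvb_dose_J_m2 descriptive metadata recorded in reports.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = make_loop_design(4),
                            truth = truth_config(),
                            scans = NULL,
                            lines = c("lineA", "lineB"),
                            span = 0.4,
                            fc_threshold = 1.5,
                            alpha = 0.05,
                            var = "pooled",
                            k = 6,
                            kmeans_restarts = 1000,
                            null_iterations = 100,
                            min_term_genes = 5,
                            ease_alpha = 0.05,
                            annotation = "simulate",
                            uvb_dose_J_m2 = 600,
                            seed = 1L) {
  stopifnot(inherits(design, "loop_design"))
  if (fc_threshold <= 0 || alpha <= 0 || ease_alpha <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  times <- sort(unique(design$samples$time_hours))
  if (any(diff(times) <= 0)) stop("time points must be strictly increasing",
                                  call. = FALSE)
  seed <- as.integer(seed)
  structure(list(
    design = design, truth = truth, scans = scans, lines = lines,
    span = span, fc_threshold = fc_threshold, alpha = alpha, var = var,
    k = k, kmeans_restarts = kmeans_restarts,
    null_iterations = null_iterations,
    min_term_genes = min_term_genes, ease_alpha = ease_alpha,
    annotation = annotation, uvb_dose_J_m2 = uvb_dose_J_m2,
    seeds = list(simulate = seed, cluster = seed + 1L, null = seed + 2L,
                 annotation = seed + 3L),
    seed = seed
  ), class = "pipeline_config")
}

#' Run the full paired-study pipeline
#'
#' Executes, for both cell lines: simulation (or ingestion) of spot
#' intensities, print-tip lowess normalization, the per-gene log-linear loop
#' fit, per-time F tests with the dual DE criterion, k-means clustering of
#' the UVB-regulated patterns, the random-matching discrepancy analysis of
#' the across-line union set, and (if an annotation is available) EASE-score
#' enrichment of each cluster. Fully deterministic given the config seeds.
#'
#' @param config a [pipeline_config()].
#' @return list of class `study_report`; see [write_study_report()] for the
#'   on-disk layout.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$scans)) {
    sim <- stage("simulate", {
      tc <- config$truth
      tc$seed <- config$seeds$simulate
      simulate_paired_experiment(design, tc)
    })
    scans <- sim$scans
    truth <- sim$truth
  } else {
    scans <- config$scans
  }
  names(scans) <- c("A", "B")

  norm <- stage("normalize", lapply(scans, printtip_lowess_normalize,
                                    span = config$span))
  fits <- stage("fit", lapply(norm, fit_gene_model, design = design))
  tests <- stage("test", lapply(fits, contrast_test, var = config$var))
  de <- stage("de", lapply(tests, call_de_genes,
                           fc_threshold = config$fc_threshold,
                           alpha = config$alpha))
  names(de) <- config$lines
  counts <- de_count_table(de)

  patterns <- stage("patterns", lapply(tests, extract_patterns))
  clusters <- stage("cluster", {
    out <- list()
    for (i in 1:2) {
      genes <- de[[i]]$union
      if (length(genes) >= config$k) {
        cl <- cluster_patterns(patterns[[i]][genes, , drop = FALSE],
                               k = config$k,
                               restarts = config$kmeans_restarts,
                               seed = config$seeds$cluster)
        out[[config$lines[i]]] <- list(clustering = cl,
                                       summary = summarize_clusters(cl))
      }
    }
    out
  })

  discrepancy <- stage("discrepancy", {
    union_genes <- sort(unique(c(de[[1]]$union, de[[2]]$union)))
    union_genes <- intersect(intersect(union_genes, rownames(patterns[[1]])),
                             rownames(patterns[[2]]))
    if (length(union_genes) >= 2) {
      pa <- patterns[[1]][union_genes, , drop = FALSE]
      pb <- patterns[[2]][union_genes, , drop = FALSE]
      null <- random_match_null(pa, pb,
                                n_iterations = config$null_iterations,
                                seed = config$seeds$null)
      sel <- select_discrepant(pa, pb, null)
      list(candidates = union_genes, null = null, selection = sel)
    }
  })

  annotation <- config$annotation
  if (identical(annotation, "simulate")) {
    annotation <- if (!is.null(truth) && length(truth$de_genes)) {
      simulate_annotation(truth, seed = config$seeds$annotation)
    }
  }
  enrichment <- stage("enrich", {
    if (!is.null(annotation)) {
      out <- list()
      for (ln in names(clusters)) {
        cl <- clusters[[ln]]$clustering
        out[[ln]] <- lapply(split(names(cl$assignments), cl$assignments),
                            enrich_terms, annotation = annotation,
                            min_term_genes = config$min_term_genes,
                            alpha = config$ease_alpha)
      }
      out
    }
  })

  cfg_md5 <- local({
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(utils::capture.output(utils::str(
      config[setdiff(names(config), "scans")], digits.d = 15)), tf)
    unname(tools::md5sum(tf))
  })

  structure(list(
    config = config,
    truth = truth,
    de = de,
    counts = counts,
    patterns = patterns,
    clusters = clusters,
    discrepancy = discrepancy,
    enrichment = enrichment,
    provenance = list(seeds = config$seeds, config_md5 = cfg_md5)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("UVB loop-design study report (", paste(x$config$lines, collapse = " vs "),
      ")\n\n", sep = "")
  print(x$counts, row.names = FALSE)
  if (!is.null(x$discrepancy)) {
    cat("\n")
    print(x$discrepancy$null)
    print(x$discrepancy$selection)
  }
  invisible(x)
}

#' Write a study report to TSV files
#'
#' Writes the Table-style DE counts, per-line cluster assignments and
#' summaries, the between-line correlations, null summary and discrepant
#' set, enrichment tables, pattern matrices and a provenance file, all as
#' plain TSV into `dir`. Output is byte-stable for a fixed config.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_tsv(report$counts, p("de_counts.tsv"))
  for (ln in names(report$de)) {
    d <- report$de[[ln]]
    write_tsv(data.frame(gene = d$union), p(paste0("de_union_", ln, ".tsv")))
  }
  for (i in seq_along(report$patterns)) {
    ln <- report$config$lines[i]
    m <- report$patterns[[i]]
    write_tsv(data.frame(gene = rownames(m), m, check.names = FALSE),
              p(paste0("patterns_", ln, ".tsv")))
  }
  for (ln in names(report$clusters)) {
    cl <- report$clusters[[ln]]
    write_tsv(data.frame(gene = names(cl$clustering$assignments),
                         cluster = unname(cl$clustering$assignments)),
              p(paste0("clusters_", ln, ".tsv")))
    write_tsv(cl$summary, p(paste0("cluster_summary_", ln, ".tsv")))
  }
  if (!is.null(report$discrepancy)) {
    dd <- report$discrepancy
    write_tsv(dd$selection$correlations, p("pattern_correlations.tsv"))
    write_tsv(dd$selection$discrepant, p("discrepant_genes.tsv"))
    write_tsv(data.frame(mean = dd$null$mean, sd = dd$null$sd,
                         n_iterations = dd$null$n_iterations,
                         n_genes = dd$null$n_genes,
                         n_dropped = dd$null$n_dropped),
              p("null_summary.tsv"))
  }
  if (!is.null(report$enrichment)) {
    for (ln in names(report$enrichment)) {
      for (cl in names(report$enrichment[[ln]])) {
        write_tsv(report$enrichment[[ln]][[cl]],
                  p(sprintf("enrichment_%s_cluster%s.tsv", ln, cl)))
      }
    }
  }
  write_tsv(data.frame(
    key = c("seed", "config_md5", "uvb_dose_J_m2"),
    value = c(report$config$seed, report$provenance$config_md5,
              report$config$uvb_dose_J_m2)
  ), p("provenance.tsv"))
  invisible(dir)
}

#' Squared-correlation agreement between two fold-change vectors
#'
#' Cross-platform concordance metric (e.g. array vs RT-PCR log2 fold
#' changes): the squared Pearson correlation of the paired values.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return R-squared in \[0, 1\], or `NA` if either vector has zero variance.
#' @export
compute_agreement_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning("zero variance: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)^2
}
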