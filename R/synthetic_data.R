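#' Default time-course archetype profiles
#'
#' Six 4-point log2 fold-change shapes (three up-regulated, three
#' down-regulated: early/transient, late/progressive, sustained) used as
#' cluster archetypes by the synthetic-data generator. Magnitudes span the
#' range typically seen for stress-responsive genes on spotted arrays
#' (roughly 1.2- to 3.5-fold).
#'
#' @return 6 x 4 numeric matrix, one archetype per row, columns in time order.
#' @export
default_archetypes <- function() {
  m <- rbind(
    up_early       = c( 1.2,  1.0,  0.6,  0.3),
    up_late        = c( 0.3,  0.6,  1.2,  1.8),
    up_sustained   = c( 0.8,  1.2,  1.4,  1.3),
    down_early     = c(-1.0, -0.8, -0.5, -0.3),
    down_late      = c(-0.3, -0.7, -1.2, -1.6),
    down_sustained = c(-0.7, -1.1, -1.3, -1.2)
  )
  colnames(m) <- c("t4", "t8", "t16", "t24")
  m
}

#' Configuration of planted effects for a simulated paired study
#'
#' Defines the ground truth of a two-line loop-design simulation: how many
#' genes, how many are differentially expressed, which archetype time-course
#' shapes they follow, how strongly the two lines agree or disagree, and the
#' magnitude of the technical effects layered on top (dye bias, array
#' effects, print-tip intensity curvature, spot noise).
#'
#' `noise_sd` is the standard deviation, in log2 units, of the spot-level
#' log-ratio (M) noise; each channel receives independent Gaussian noise with
#' sd `noise_sd / sqrt(2)`. Per-gene patterns are the assigned archetype
#' scaled by an amplitude drawn from `amplitude_range` plus per-component
#' shape jitter (`pattern_jitter_sd`); jitter is redrawn until the pattern's
#' within-vector sd reaches `min_pattern_sd`, reflecting that genes passing a
#' fold-change filter vary over the time course.
#'
#' @param n_genes number of clones/genes on the platform.
#' @param n_de_per_line number of planted differentially expressed genes
#'   (the same gene set responds in both lines).
#' @param archetype_profiles matrix of 4-point log2FC archetypes, one per row.
#' @param n_discordant number of planted DE genes whose line-B pattern is
#'   anti-correlated with line A at `discordant_target_r`.
#' @param discordant_target_r target between-line pattern correlation for
#'   discordant genes, in \[-1, -0.5\].
#' @param concordant_target_r target correlation for the remaining DE genes,
#'   in \[0.5, 1\].
#' @param noise_sd sd of the spot log-ratio noise (log2 units, > 0).
#' @param dye_bias_sd sd of the gene-specific dye effect (log2 units).
#' @param array_effect_sd sd of the per-array intensity effect (log2 units).
#' @param printtip_curvature_amplitude maximal amplitude of the print-tip
#'   dependent intensity-curvature bias added to M (log2 units).
#' @param n_printtips number of print-tip groups per array.
#' @param pattern_jitter_sd sd of per-gene shape jitter around the archetype.
#' @param min_pattern_sd minimal within-pattern sd enforced on planted
#'   patterns (only active when `pattern_jitter_sd > 0`).
#' @param amplitude_range range of the per-gene amplitude multiplier.
#' @param replicate_spots spots per clone per array.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   intensity.
#' @param seed integer seed making the simulation reproducible.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(n_genes = 2000,
                         n_de_per_line = 400,
                         archetype_profiles = default_archetypes(),
                         n_discordant = 15,
                         discordant_target_r = -0.95,
                         concordant_target_r = 0.9,
                         noise_sd = 0.15,
                         dye_bias_sd = 0.1,
                         array_effect_sd = 0.2,
                         printtip_curvature_amplitude = 0.3,
                         n_printtips = 8,
                         pattern_jitter_sd = 0.3,
                         min_pattern_sd = 0.5,
                         amplitude_range = c(0.7, 1.5),
                         replicate_spots = 1,
                         baseline_mean = 11,
                         baseline_sd = 1.2,
                         seed = 1L) {
  archetype_profiles <- as.matrix(archetype_profiles)
  stopifnot(ncol(archetype_profiles) == 4)
  counts <- c(n_genes = n_genes, n_de_per_line = n_de_per_line,
              n_discordant = n_discordant, n_printtips = n_printtips,
              replicate_spots = replicate_spots)
  if (any(counts < 0)) stop("config error: counts must be >= 0", call. = FALSE)
  if (n_de_per_line > n_genes) {
    stop("config error: n_de_per_line must be <= n_genes", call. = FALSE)
  }
  if (n_discordant > n_de_per_line) {
    stop("config error: n_discordant must be <= n_de_per_line", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("config error: noise_sd must be > 0", call. = FALSE)
  }
  if (discordant_target_r > -0.5 || discordant_target_r < -1) {
    stop("config error: discordant_target_r must lie in [-1, -0.5]", call. = FALSE)
  }
  if (concordant_target_r < 0.5 || concordant_target_r > 1) {
    stop("config error: concordant_target_r must lie in [0.5, 1]", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_de_per_line = as.integer(n_de_per_line),
    archetype_profiles = archetype_profiles,
    n_discordant = as.integer(n_discordant),
    discordant_target_r = discordant_target_r,
    concordant_target_r = concordant_target_r,
    noise_sd = noise_sd,
    dye_bias_sd = dye_bias_sd,
    array_effect_sd = array_effect_sd,
    printtip_curvature_amplitude = printtip_curvature_amplitude,
    n_printtips = as.integer(n_printtips),
    pattern_jitter_sd = pattern_jitter_sd,
    min_pattern_sd = min_pattern_sd,
    amplitude_range = amplitude_range,
    replicate_spots = as.integer(replicate_spots),
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    seed = as.integer(seed)
  ), class = "truth_config")
}

# Construct a 4-vector with exact sample Pearson correlation `r` to `x`,
# rescaled to x's location/spread (location sign-flipped for negative r so a
# discordant gene that goes up in one line goes down in the other).
correlated_pattern <- function(x, r) {
  sx <- stats::sd(x)
  if (sx < 1e-12) stop("cannot target a correlation against a constant pattern",
                       call. = FALSE)
  zx <- (x - mean(x)) / sx
  repeat {
    w <- stats::rnorm(length(x))
    w <- w - mean(w) - zx * sum(w * zx) / sum(zx^2)
    if (stats::sd(w) > 1e-8) break
  }
  zw <- (w - mean(w)) / stats::sd(w)
  y <- r * zx + sqrt(1 - r^2) * zw        # unit-scale, exact cor(x, y) == r
  mean(x) * sign(r) + sx * y
}

# Draw one planted pattern: archetype * amplitude + shape jitter, with the
# within-pattern sd floor enforced by redrawing the jitter.
draw_pattern <- function(profile, cfg) {
  amp <- stats::runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2])
  base <- profile * amp
  if (cfg$pattern_jitter_sd <= 0) return(base)
  for (i in 1:100) {
    p <- base + stats::rnorm(length(base), 0, cfg$pattern_jitter_sd)
    if (stats::sd(p) >= cfg$min_pattern_sd) return(p)
  }
  p
}

#' Simulate a paired two-line loop-design microarray study
#'
#' Generates raw two-channel spot intensities for two cell lines hybridized
#' with the same loop design, together with the planted ground truth. Each
#' channel's log2 intensity is gene baseline + sample-by-gene effect +
#' array effect + gene-specific dye effect (Cy5 only) + print-tip curvature
#' bias (a zero-mean quadratic in spot intensity, split between channels) +
#' Gaussian noise; intensities are `2^` of that. Treated-minus-control
#' sample effects at each time equal the planted 4-point log2FC pattern.
#'
#' @param design a [loop_design()] whose treated/control samples span the
#'   four time points.
#' @param truth a [truth_config()].
#' @return A list with elements `scans` (named list `A`, `B` of
#'   `array_scan_set` objects) and `truth` (a `ground_truth` list holding
#'   planted patterns per line, DE gene ids per time point, discordant gene
#'   ids, archetype assignments and the config).
#' @export
simulate_paired_experiment <- function(design, truth) {
  stopifnot(inherits(design, "loop_design"), inherits(truth, "truth_config"))
  with_seed(truth$seed, simulate_paired_experiment_impl(design, truth))
}

simulate_paired_experiment_impl <- function(design, cfg) {
  times <- sort(unique(design$samples$time_hours))
  if (length(times) != ncol(cfg$archetype_profiles)) {
    stop("config error: archetype profiles must have one column per time point",
         call. = FALSE)
  }
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  de <- if (cfg$n_de_per_line > 0) genes[seq_len(cfg$n_de_per_line)] else character()
  disc <- if (cfg$n_discordant > 0) de[seq_len(cfg$n_discordant)] else character()

  n_arch <- nrow(cfg$archetype_profiles)
  arch <- integer(0)
  patt_a <- patt_b <- matrix(0, cfg$n_genes, length(times),
                             dimnames = list(genes, paste0("t", times)))
  if (length(de)) {
    arch <- stats::setNames(sample(n_arch, length(de), replace = TRUE), de)
    for (g in de) {
      pa <- draw_pattern(cfg$archetype_profiles[arch[[g]], ], cfg)
      r <- if (g %in% disc) cfg$discordant_target_r else cfg$concordant_target_r
      pb <- if (abs(r) >= 1) pa * sign(r) else correlated_pattern(pa, r)
      patt_a[g, ] <- pa
      patt_b[g, ] <- pb
    }
  }

  tip <- stats::setNames(rep(seq_len(cfg$n_printtips), length.out = cfg$n_genes),
                         genes)
  scans <- list(
    A = simulate_scan_set(design, cfg, genes, patt_a, tip, times, line = "A"),
    B = simulate_scan_set(design, cfg, genes, patt_b, tip, times, line = "B")
  )

  fc_cut <- log2(1.5)
  de_by_time <- function(patt) {
    out <- lapply(seq_along(times), function(j) de[abs(patt[de, j]) > fc_cut])
    stats::setNames(out, paste0("t", times))
  }
  truth <- structure(list(
    gene_ids = genes,
    de_genes = de,
    discordant_genes = disc,
    archetype = arch,
    patterns = list(A = patt_a, B = patt_b),
    de_by_time = list(A = de_by_time(patt_a), B = de_by_time(patt_b)),
    time_hours = times,
    config = cfg
  ), class = "ground_truth")
  list(scans = scans, truth = truth)
}

# One line's worth of arrays. Spot-level technical structure is drawn
# independently per line (separate hybridizations), gene baselines too.
simulate_scan_set <- function(design, cfg, genes, patt, tip, times, line) {
  n <- length(genes)
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  dye <- stats::rnorm(n, 0, cfg$dye_bias_sd)
  samples <- design$samples
  # sample x gene effects: treated at time t carries the pattern, controls 0
  eff <- matrix(0, n, nrow(samples), dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    if (samples$treated[i]) {
      eff[, i] <- patt[, match(paste0("t", samples$time_hours[i]), colnames(patt))]
    }
  }
  arrays <- design$arrays
  arr_eff <- stats::rnorm(nrow(arrays), 0, cfg$array_effect_sd)
  ch_sd <- cfg$noise_sd / sqrt(2)
  nrep <- cfg$replicate_spots
  per_tip <- split(seq_len(n), tip)

  out <- vector("list", nrow(arrays))
  for (a in seq_len(nrow(arrays))) {
    i3 <- match(arrays$cy3_sample[a], samples$sample_id)
    i5 <- match(arrays$cy5_sample[a], samples$sample_id)
    for (rep_i in seq_len(nrep)) {
      l3 <- baseline + eff[, i3] + arr_eff[a] + stats::rnorm(n, 0, ch_sd)
      l5 <- baseline + eff[, i5] + arr_eff[a] + dye + stats::rnorm(n, 0, ch_sd)
      # print-tip curvature: zero-mean (per tip) quadratic in baseline
      # intensity, split evenly between the channels so it biases M only
      if (cfg$printtip_curvature_amplitude > 0) {
        v <- 2 * (baseline - min(baseline)) / max(diff(range(baseline)), 1e-9) - 1
        q <- (3 * v^2 - 1) / 2
        for (tp in seq_along(per_tip)) {
          idx <- per_tip[[tp]]
          amp <- cfg$printtip_curvature_amplitude * stats::runif(1, -1, 1)
          b <- amp * q[idx]
          b <- b - mean(b)
          l5[idx] <- l5[idx] + b / 2
          l3[idx] <- l3[idx] - b / 2
        }
      }
      ord <- order(tip, genes)
      out[[a]] <- rbind(out[[a]], data.frame(
        array_id = arrays$array_id[a],
        clone_id = genes[ord],
        printtip = tip[ord],
        row = as.integer(stats::ave(seq_along(ord), tip[ord], FUN = seq_along)),
        col = rep_i,
        cy3 = 2^l3[ord],
        cy5 = 2^l5[ord],
        stringsAsFactors = FALSE
      ))
    }
  }
  spots <- do.call(rbind, out)
  rownames(spots) <- NULL
  structure(list(spots = spots, design = design, line = line),
            class = "array_scan_set")
}

#' @export
print.array_scan_set <- function(x, ...) {
  cat("Two-channel scan set (line ", x$line, "): ",
      length(unique(x$spots$array_id)), " arrays, ",
      length(unique(x$spots$clone_id)), " clones, ",
      nrow(x$spots), " spots\n", sep = "")
  invisible(x)
}

#' Write / read a spot intensity table
#'
#' Plain TSV with header `array_id, clone_id, printtip, row, col, cy3, cy5`,
#' the on-disk interface between the generator and the preprocessing stage.
#'
#' @param scan an `array_scan_set`.
#' @param path file path.
#' @export
write_spot_table <- function(scan, path) {
  write_tsv(scan$spots, path)
}

#' @rdname write_spot_table
#' @param design the [loop_design()] the spots were hybridized under.
#' @param line line label to attach.
#' @export
read_spot_table <- function(path, design, line = NA_character_) {
  spots <- read_tsv(path)
  need <- c("array_id", "clone_id", "printtip", "row", "col", "cy3", "cy5")
  if (!all(need %in% names(spots))) {
    stop("spot table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(spots$cy3 <= 0) || any(spots$cy5 <= 0)) {
    stop("spot intensities must be strictly positive", call. = FALSE)
  }
  structure(list(spots = spots, design = design, line = line),
            class = "array_scan_set")
}

#' Simulate a gene-set annotation matched to planted truth
#'
#' Builds an annotation over the simulated gene universe: one term per
#' archetype (the genes planted with that time-course shape, mimicking a
#' co-regulated pathway) plus random terms drawn uniformly from the
#' universe. Useful for exercising enrichment with a known top term.
#'
#' @param truth a `ground_truth` from [simulate_paired_experiment()].
#' @param n_random_terms number of additional random terms.
#' @param term_size_range size range of the random terms.
#' @param seed RNG seed.
#' @return An [annotation_set()].
#' @export
simulate_annotation <- function(truth, n_random_terms = 100,
                                term_size_range = c(10, 60), seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(seed, {
    universe <- truth$gene_ids
    sets <- list()
    if (length(truth$archetype)) {
      for (a in sort(unique(truth$archetype))) {
        nm <- rownames(truth$config$archetype_profiles)[a] %||% paste0("archetype_", a)
        sets[[paste0("PLANTED_", toupper(nm))]] <-
          names(truth$archetype)[truth$archetype == a]
      }
    }
    for (i in seq_len(n_random_terms)) {
      sz <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      sets[[sprintf("RANDOM_%03d", i)]] <- sample(universe, sz)
    }
    annotation_set(sets, universe)
  })
}
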