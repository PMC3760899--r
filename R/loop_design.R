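#' Construct a two-color hybridization design
#'
#' A loop design hybridizes pairs of samples on the same array with opposite
#' dyes, chaining the samples into a connected graph so that all pairwise
#' contrasts are estimable without a common reference channel.
#'
#' @param arrays data.frame with columns `array_id`, `cy3_sample`,
#'   `cy5_sample`; one row per hybridization. Parallel (duplicated) edges are
#'   allowed and add replication.
#' @param samples data.frame with columns `sample_id`, `time_hours`,
#'   `treated` (logical; `TRUE` for UVB-irradiated samples).
#' @return An object of class `loop_design`.
#' @export
loop_design <- function(arrays, samples) {
  arrays <- as.data.frame(arrays, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_a <- c("array_id", "cy3_sample", "cy5_sample")
  need_s <- c("sample_id", "time_hours", "treated")
  if (!all(need_a %in% names(arrays))) {
    stop("`arrays` needs columns: ", paste(need_a, collapse = ", "), call. = FALSE)
  }
  if (!all(need_s %in% names(samples))) {
    stop("`samples` needs columns: ", paste(need_s, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in `samples`", call. = FALSE)
  }
  if (anyDuplicated(arrays$array_id)) {
    stop("duplicated array_id in `arrays`", call. = FALSE)
  }
  known <- samples$sample_id
  used <- c(arrays$cy3_sample, arrays$cy5_sample)
  if (!all(used %in% known)) {
    stop("design invalid: arrays reference unknown samples: ",
         paste(setdiff(used, known), collapse = ", "), call. = FALSE)
  }
  if (any(arrays$cy3_sample == arrays$cy5_sample)) {
    stop("design invalid: an array must pair two distinct samples", call. = FALSE)
  }
  if (!all(known %in% used)) {
    stop("design invalid: samples not on any array: ",
         paste(setdiff(known, used), collapse = ", "), call. = FALSE)
  }
  d <- structure(list(arrays = arrays, samples = samples), class = "loop_design")
  if (!design_is_connected(d)) {
    stop("design invalid: hybridization graph is disconnected", call. = FALSE)
  }
  d
}

#' Build the default loop design for a treated/control time course
#'
#' Samples are one UVB-treated (`UV<t>`) and one matched control (`C<t>`)
#' sample per time point. The default topology is a single cycle through the
#' `2 * n_timepoints` samples, alternating control and treated in time order
#' (arrow tail = Cy3, head = Cy5), plus the chords in `extra_edges`. With
#' four time points the default chords `C4 -> UV16` and `C8 -> UV24` give the
#' 8-sample / 10-array layout used for the UVB studies.
#'
#' @param n_timepoints number of post-irradiation time points (>= 2).
#' @param time_hours time values in hours; defaults to 4, 8, 16, 24.
#' @param extra_edges list of length-2 character vectors
#'   `c(cy3_sample, cy5_sample)` added to the cycle; `NULL` picks the default
#'   chords for `n_timepoints = 4` and none otherwise. Duplicating a cycle
#'   edge is allowed and yields a parallel array.
#' @return A [loop_design()].
#' @examples
#' d <- make_loop_design(4)
#' nrow(d$arrays)  # 10 arrays over 8 samples
#' @export
make_loop_design <- function(n_timepoints = 4,
                             time_hours = c(4, 8, 16, 24),
                             extra_edges = NULL) {
  if (n_timepoints < 2) stop("`n_timepoints` must be >= 2", call. = FALSE)
  if (length(time_hours) < n_timepoints) {
    stop("`time_hours` must supply at least `n_timepoints` values", call. = FALSE)
  }
  tt <- time_hours[seq_len(n_timepoints)]
  samples <- data.frame(
    sample_id = as.vector(rbind(paste0("C", tt), paste0("UV", tt))),
    time_hours = rep(tt, each = 2),
    treated = rep(c(FALSE, TRUE), n_timepoints),
    stringsAsFactors = FALSE
  )
  n <- nrow(samples)
  cy3 <- samples$sample_id
  cy5 <- samples$sample_id[c(seq_len(n)[-1], 1L)]
  if (is.null(extra_edges) && n_timepoints == 4) {
    extra_edges <- list(c(paste0("C", tt[1]), paste0("UV", tt[3])),
                        c(paste0("C", tt[2]), paste0("UV", tt[4])))
  }
  for (e in extra_edges) {
    if (length(e) != 2L) stop("each extra edge must be a pair", call. = FALSE)
    cy3 <- c(cy3, e[1])
    cy5 <- c(cy5, e[2])
  }
  arrays <- data.frame(
    array_id = sprintf("A%02d", seq_along(cy3)),
    cy3_sample = cy3,
    cy5_sample = cy5,
    stringsAsFactors = FALSE
  )
  loop_design(arrays, samples)
}

# Breadth-first connectivity of the sample graph (arrays as undirected edges).
design_is_connected <- function(design, arrays = design$arrays) {
  nodes <- design$samples$sample_id
  if (nrow(arrays) == 0L) return(length(nodes) <= 1L)
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(arrays))) {
    a <- arrays$cy3_sample[i]
    b <- arrays$cy5_sample[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(logical(length(nodes)), nodes)
  queue <- nodes[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(adj[queue], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  all(seen)
}

# Model matrix for the per-gene log-linear fit: one +1/-1 sample-incidence
# column pair per array (Cy5 minus Cy3) plus a dye intercept absorbing the
# gene-specific dye bias carried by every log-ratio.
design_matrix <- function(design) {
  s <- design$samples$sample_id
  a <- design$arrays
  X <- matrix(0, nrow(a), length(s), dimnames = list(a$array_id, s))
  X[cbind(seq_len(nrow(a)), match(a$cy5_sample, s))] <- 1
  X[cbind(seq_len(nrow(a)), match(a$cy3_sample, s))] <- -1
  cbind(X, .dye = 1)
}

# Contrast vector (treated - control) at one time point, padded with a zero
# for the dye column.
time_contrast <- function(design, time) {
  s <- design$samples
  trt <- s$sample_id[s$treated & s$time_hours == time]
  ctl <- s$sample_id[!s$treated & s$time_hours == time]
  if (length(trt) != 1L || length(ctl) != 1L) {
    stop("time ", time, " does not identify one treated and one control sample",
         call. = FALSE)
  }
  cv <- stats::setNames(numeric(nrow(s) + 1L), c(s$sample_id, ".dye"))
  cv[trt] <- 1
  cv[ctl] <- -1
  cv
}

#' @export
print.loop_design <- function(x, ...) {
  cat("Loop design:", nrow(x$samples), "samples,", nrow(x$arrays), "arrays\n")
  cat("Times (h):", paste(sort(unique(x$samples$time_hours)), collapse = ", "), "\n")
  invisible(x)
}
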