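#' Read a GEO Series Matrix file
#'
#' Parses the plain-text Series Matrix format: `!`-prefixed metadata lines
#' (series- and sample-level, values possibly quoted), and the value table
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`.
#' Mapping the parsed samples onto design roles (which sample, which dye,
#' which array) is left to the caller; deposited series often store processed
#' values whose provenance differs from this package's preprocessing.
#'
#' @param path path to an (uncompressed) series matrix file.
#' @return list with `metadata` (named list of character vectors; names are
#'   the `!` keys with repeated keys collected row-wise) and `table` (numeric
#'   matrix, probe ids as rownames, sample accessions as colnames).
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty series matrix file", call. = FALSE)
  unquote <- function(x) gsub('^"|"$', "", x)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L) {
    stop("parse error: missing !series_matrix_table_begin marker", call. = FALSE)
  }
  if (length(end) != 1L || end <= begin + 1L) {
    stop("parse error: truncated series matrix (no table end marker)",
         call. = FALSE)
  }

  meta_lines <- lines[seq_len(begin - 1L)]
  meta_lines <- meta_lines[startsWith(meta_lines, "!")]
  metadata <- list()
  for (ln in meta_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    key <- sub("^!", "", parts[1])
    val <- unquote(parts[-1])
    if (is.null(metadata[[key]])) {
      metadata[[key]] <- val
    } else {
      metadata[[key]] <- rbind(metadata[[key]], val)
    }
  }

  tbl <- lines[(begin + 1L):(end - 1L)]
  if (length(tbl) < 2L) stop("parse error: empty value table", call. = FALSE)
  header <- unquote(strsplit(tbl[1], "\t", fixed = TRUE)[[1]])
  if (toupper(header[1]) != "ID_REF") {
    stop("parse error: table header must start with ID_REF, got line: ",
         tbl[1], call. = FALSE)
  }
  rows <- strsplit(tbl[-1], "\t", fixed = TRUE)
  nfield <- vapply(rows, length, 1L)
  if (any(nfield != length(header))) {
    stop("parse error: table row(s) with wrong field count: line ",
         which(nfield != length(header))[1] + begin + 1L, call. = FALSE)
  }
  ids <- unquote(vapply(rows, `[[`, "", 1L))
  vals <- matrix(NA_real_, length(rows), length(header) - 1L,
                 dimnames = list(ids, header[-1]))
  for (j in seq_len(ncol(vals))) {
    v <- vapply(rows, `[[`, "", j + 1L)
    v[v %in% c("", "null", "NULL", "NA")] <- NA
    vals[, j] <- as.numeric(v)
  }
  list(metadata = metadata, table = vals)
}
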