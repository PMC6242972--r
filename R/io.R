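# Readers and writers for the on-disk artifacts the pipeline consumes:
# BED-family interval files, copy-number segment tables, expression matrices,
# survival tables and bedGraph fragment tracks. Everything is validated on
# read so downstream modules can assume well-formed tibbles.
#
# Coordinate convention: 0-based half-open ([start, end)) internally and on
# disk, the BED convention. Inputs recorded in 1-based inclusive coordinates
# must be declared with `one_based = TRUE` and are converted on read.
# Chromosome names are taken literally ("chr17" != "17"); `chrom_prefix`
# optionally adds or strips the "chr" prefix explicitly.

normalize_chrom <- function(chrom, chrom_prefix = c("asis", "add", "strip")) {
  chrom_prefix <- match.arg(chrom_prefix)
  switch(chrom_prefix,
    asis  = chrom,
    add   = if_else(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)),
    strip = sub("^chr", "", chrom)
  )
}

#' Validate a tibble of genomic intervals
#'
#' Checks the invariants every interval-carrying tibble in the package must
#' satisfy: non-empty chromosome names, `start >= 0`, `end > start`, and a
#' non-negative `score` when present. Used by all readers; exported so that
#' intervals constructed in code can be checked the same way.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `score` (0-based half-open coordinates).
#' @param context A string naming the source, used in error messages.
#' @return `x` as a tibble, sorted by `(chrom, start, end)`.
#' @export
validate_intervals <- function(x, context = "intervals") {
  x <- as_tibble(x)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s", context,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    return(arrange(x, .data$chrom, .data$start, .data$end))
  }
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom))
  if (length(bad) > 0) {
    abort(sprintf("%s: empty chromosome name at row %d", context, bad[1]))
  }
  bad <- which(!is.finite(x$start) | !is.finite(x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric coordinates at row %d", context, bad[1]))
  }
  bad <- which(x$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: negative start at row %d", context, bad[1]))
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf("%s: end <= start at row %d (%s:%g-%g)", context, bad[1],
                  x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if ("score" %in% names(x)) {
    bad <- which(!is.na(x$score) & x$score < 0)
    if (length(bad) > 0) {
      abort(sprintf("%s: negative score at row %d", context, bad[1]))
    }
  }
  arrange(x, .data$chrom, .data$start, .data$end)
}

read_tab_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
}

#' Read a BED3/BED5 interval file
#'
#' Parses a tab-separated BED file into a validated, sorted interval tibble.
#' With `has_score = TRUE` the signal value is taken from column 5 when the
#' file has a name column (BED5+) or from column 4 otherwise.
#'
#' @param path Path to the BED file.
#' @param has_score Parse a numeric signal column.
#' @param one_based Input coordinates are 1-based inclusive; converted to
#'   0-based half-open on read.
#' @param chrom_prefix `"asis"` (default), `"add"` or `"strip"` the `"chr"`
#'   chromosome-name prefix.
#' @return A tibble with columns `chrom`, `start`, `end` and, if requested,
#'   `score`, sorted by `(chrom, start)`.
#' @export
read_bed <- function(path, has_score = FALSE, one_based = FALSE,
                     chrom_prefix = "asis") {
  lines <- read_tab_lines(path)
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = double(), end = double())
    if (has_score) out$score <- double()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                  path, which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: non-numeric coordinate", path, bad[1]))
  }
  out <- tibble(chrom = normalize_chrom(chrom, chrom_prefix),
                start = start, end = end)
  if (one_based) out$start <- out$start - 1
  if (has_score) {
    score_col <- if_else(nf >= 5L, 5L, 4L)
    if (any(nf < 4)) {
      abort(sprintf("%s: line %d: score requested but no score column",
                    path, which(nf < 4)[1]))
    }
    raw <- mapply(function(f, i) f[[i]], fields, score_col)
    score <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(score))
    if (length(bad) > 0) {
      abort(sprintf("%s: line %d: non-numeric score '%s'",
                    path, bad[1], raw[bad[1]]))
    }
    out$score <- score
  }
  tryCatch(validate_intervals(out, context = path),
           error = function(e) {
             abort(sprintf("%s [line numbers refer to data lines]",
                           conditionMessage(e)))
           })
}

#' Write intervals as BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if ("score" %in% names(x)) {
    # BED5 requires a name column before the score
    x$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  write_tsv_plain(x[cols], path, col_names = FALSE)
}

#' Read a copy-number segment table
#'
#' Expects four tab-separated columns: chrom, start, end, log2 ratio (an
#' optional leading `sample_id` column is detected when the file has five
#' columns). A header line is detected and skipped when the second field is
#' non-numeric.
#'
#' @inheritParams read_bed
#' @return A tibble with columns `chrom`, `start`, `end`, `log2_ratio`
#'   (and `sample_id` for five-column input).
#' @export
read_segments <- function(path, one_based = FALSE, chrom_prefix = "asis") {
  lines <- read_tab_lines(path)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  log2_ratio = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  has_sample <- all(nf >= 5)
  coord_at <- if (has_sample) 3L else 2L
  # header detection: coordinate field not numeric on line 1
  if (suppressWarnings(is.na(as.numeric(fields[[1]][[coord_at]])))) {
    fields <- fields[-1]
    lines <- lines[-1]
    nf <- nf[-1]
  }
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  log2_ratio = double()))
  }
  if (any(nf < 4)) {
    abort(sprintf("%s: line %d has fewer than 4 fields", path, which(nf < 4)[1]))
  }
  off <- if (has_sample) 1L else 0L
  take <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(
    chrom = normalize_chrom(take(off + 1L), chrom_prefix),
    start = suppressWarnings(as.numeric(take(off + 2L))),
    end   = suppressWarnings(as.numeric(take(off + 3L))),
    log2_ratio = suppressWarnings(as.numeric(take(off + 4L)))
  )
  if (has_sample) out <- mutate(out, sample_id = take(1L), .before = 1)
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: non-numeric coordinate", path, bad[1]))
  }
  bad <- which(is.na(out$log2_ratio))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: non-numeric log2 ratio '%s'",
                  path, bad[1], take(off + 4L)[bad[1]]))
  }
  if (one_based) out$start <- out$start - 1
  validate_intervals(out, context = path)
}

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated, header row of sample ids, first column gene ids, values on
#' a log2 scale. Duplicate gene or sample ids are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per sample.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate gene id '%s'", path, dup[1]))
  }
  samp <- names(x)[-1]
  dup <- samp[duplicated(samp)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate sample id '%s'", path, dup[1]))
  }
  if (length(samp) == 0) abort(sprintf("%s: no sample columns", path))
  not_num <- samp[!vapply(x[samp], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(sprintf("%s: non-numeric expression column '%s'", path, not_num[1]))
  }
  as_tibble(x)
}

#' Read a survival table
#'
#' Tab-separated with header; requires columns `sample_id`, `time`
#' (follow-up, days, > 0) and `event` (1 = death/progression, 0 = censored).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble.
#' @export
read_survival <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "time", "event"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  validate_survival(x, context = path)
}

validate_survival <- function(x, context = "survival table") {
  x <- as_tibble(x)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate sample id '%s'", context, dup[1]))
  }
  if (any(!is.finite(x$time) | x$time <= 0)) {
    abort(sprintf("%s: follow-up times must be positive", context))
  }
  if (!all(x$event %in% c(0, 1))) {
    abort(sprintf("%s: event must be 0 or 1", context))
  }
  x
}

#' Read a bedGraph fragment-coverage track
#'
#' Four tab-separated columns: chrom, start, end, value (read count per
#' restriction fragment for 4C tracks). Fragments must be non-overlapping
#' and are returned sorted.
#'
#' @inheritParams read_bed
#' @return A tibble with columns `chrom`, `start`, `end`, `count`.
#' @export
read_bedgraph <- function(path, chrom_prefix = "asis") {
  x <- read_segments(path, chrom_prefix = chrom_prefix)
  rename(x, count = "log2_ratio")
}

# deterministic TSV writer: fixed column order as given, "\n" endings, UTF-8
write_tsv_plain <- function(x, path, col_names = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt_row <- function(v) paste(v, collapse = "\t")
  body <- apply(as.data.frame(x), 1L, function(r) fmt_row(trimws(format(r, trim = TRUE, scientific = FALSE))))
  if (nrow(x) == 0) body <- character()
  lines <- c(if (col_names) fmt_row(names(x)), body)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a tibble as a deterministic TSV
#'
#' Columns are written in their current order with a header, tab separators
#' and `"\n"` line endings, so identical inputs give byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Write an expression matrix
#'
#' @param x Expression tibble as returned by [read_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) write_table(x, path)
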