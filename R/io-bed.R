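#' Read a BED file of genomic intervals
#'
#' Reads BED3 to BED6 into an interval tibble. BED is natively 0-based
#' half-open, which is also the package-wide internal convention, so
#' coordinates are taken verbatim. Record order is preserved. A missing
#' strand column yields `"."`.
#'
#' @param path Path to a tab-separated BED file.
#' @param genome_sizes Optional named vector of chromosome lengths used to
#'   validate intervals.
#' @return Interval tibble (see [as_intervals()]).
#' @export
read_intervals <- function(path, genome_sizes = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(as_intervals(tibble(chrom = character(), start = integer(),
                               end = integer()), genome_sizes))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns", which(nf < 3)[1]))
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: invalid interval %d-%d",
                  bad[1], start[bad[1]], end[bad[1]]))
  }
  score <- suppressWarnings(as.numeric(get(5)))
  as_intervals(tibble(
    chrom = get(1), start = start, end = end,
    name = get(4), score = score, strand = get(6)
  ), genome_sizes)
}

#' Write intervals to a BED file
#'
#' Inverse of [read_intervals()]: writes BED6 (or BED3 when name, score and
#' strand are all absent). Round-tripping well-formed records is the
#' identity.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  x <- as_intervals(x)
  if (all(is.na(x$name)) && all(is.na(x$score)) && all(x$strand == ".")) {
    out <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  } else {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   ifelse(is.na(x$name), ".", x$name),
                   ifelse(is.na(x$score), "0", format(x$score, trim = TRUE, scientific = FALSE)),
                   x$strand)
  }
  writeLines(out, path)
  invisible(path)
}
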