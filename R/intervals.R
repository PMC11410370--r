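#' Genomic interval tibbles
#'
#' Throughout promocc a set of genomic intervals is an ordinary tibble with
#' columns `chrom` (character), `start`, `end` (integers, 0-based half-open),
#' and optionally `name`, `score`, `strand` (`"+"`, `"-"` or `"."`).
#' `as_intervals()` validates and normalises such a data frame; every
#' interval-consuming function calls it on input, so plain data frames work
#' everywhere.
#'
#' An optional named integer vector of chromosome lengths can be attached as
#' `attr(x, "genome_sizes")`; when present, intervals are checked against it.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param genome_sizes Optional named vector of chromosome lengths.
#' @return A tibble with columns chrom, start, end, name, score, strand.
#' @export
#' @examples
#' as_intervals(data.frame(chrom = "chr2L", start = 10, end = 20))
as_intervals <- function(x, genome_sizes = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("missing interval columns:", paste(miss, collapse = ", ")))
  out <- as_tibble(x)
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (!"name" %in% names(out)) out$name <- NA_character_
  if (!"score" %in% names(out)) out$score <- NA_real_
  if (!"strand" %in% names(out)) out$strand <- "."
  out$strand[is.na(out$strand)] <- "."
  out <- out[, c("chrom", "start", "end", "name", "score", "strand"),
             drop = FALSE]
  if (any(is.na(out$chrom)) || any(!nzchar(out$chrom))) abort("chrom must be non-empty")
  if (any(is.na(out$start)) || any(is.na(out$end))) abort("non-integer interval coordinates")
  bad <- which(out$start < 0L | out$start >= out$end)
  if (length(bad)) {
    abort(sprintf("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
                  bad[1], out$start[bad[1]], out$end[bad[1]]))
  }
  if (any(!out$strand %in% c("+", "-", "."))) abort("strand must be one of +, -, .")
  genome_sizes <- genome_sizes %||% attr(x, "genome_sizes")
  if (!is.null(genome_sizes)) {
    known <- out$chrom %in% names(genome_sizes)
    over <- known & out$end > genome_sizes[out$chrom]
    if (any(over)) {
      abort(sprintf("interval at row %d exceeds length of %s",
                    which(over)[1], out$chrom[which(over)[1]]))
    }
    attr(out, "genome_sizes") <- genome_sizes
  }
  out
}

# tibble <-> GRanges plumbing; all bp arithmetic is delegated to
# GenomicRanges/IRanges on the 1-based side and converted back at the edge.
gr_from_intervals <- function(x) {
  x <- as_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
}

intervals_from_gr <- function(gr) {
  st <- as.character(GenomicRanges::strand(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = NA_character_,
    score = NA_real_,
    strand = ifelse(st == "*", ".", st)
  )
}

#' Merge overlapping and bookended intervals
#'
#' Sorts intervals and merges any pair that overlaps or is directly adjacent
#' (bookended, e.g. `[0,10)` + `[10,20)` become `[0,20)`), ignoring strand.
#' This is the base-pair set semantics used by all bp arithmetic
#' ([jaccard()], [overlap_fisher()]).
#'
#' @param x Interval data frame (see [as_intervals()]).
#' @return Tibble of merged intervals, sorted by chrom then start.
#' @export
#' @examples
#' merge_intervals(data.frame(chrom = "c", start = c(0, 5), end = c(10, 15)))
merge_intervals <- function(x) {
  gr <- gr_from_intervals(x)
  GenomicRanges::strand(gr) <- "*"
  intervals_from_gr(GenomicRanges::reduce(gr))
}

interval_bp <- function(x) {
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

# midpoints, floor convention
interval_midpoint <- function(x) {
  x <- as_intervals(x)
  as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
}
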