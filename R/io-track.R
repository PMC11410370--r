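#' Binned coverage tracks
#'
#' A `coverage_track` holds per-bin signal values over a genome: a named
#' list of numeric vectors (one per chromosome, one value per `bin_size` bp
#' bin) plus a normalization label (`"raw"`, `"BPM"` or `"subtracted"`).
#' Tracks are the input to [reference_point_matrix()] and
#' [scale_regions_matrix()].
#'
#' @param values Named list of numeric vectors.
#' @param bin_size Bin width in bp.
#' @param normalized One of `"raw"`, `"BPM"`, `"subtracted"`.
#' @param genome_sizes Optional named chromosome lengths.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_size, normalized = "raw",
                           genome_sizes = NULL) {
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  normalized <- match.arg(normalized, c("raw", "BPM", "subtracted"))
  if (!is.null(genome_sizes)) {
    for (ch in names(values)) {
      if (ch %in% names(genome_sizes)) {
        expect_len <- ceiling(genome_sizes[[ch]] / bin_size)
        if (length(values[[ch]]) != expect_len) {
          abort(sprintf("track %s has %d bins, expected %d",
                        ch, length(values[[ch]]), expect_len))
        }
      }
    }
  }
  structure(
    list(values = lapply(values, as.numeric), bin_size = as.integer(bin_size),
         normalized = normalized, genome_sizes = genome_sizes),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track: %d chrom(s), bin %d bp, %s>\n",
              length(x$values), x$bin_size, x$normalized))
  invisible(x)
}

#' @export
as_tibble.coverage_track <- function(x, ...) {
  purrr::map_dfr(names(x$values), function(ch) {
    v <- x$values[[ch]]
    tibble(chrom = ch,
           start = (seq_along(v) - 1L) * x$bin_size,
           end = seq_along(v) * x$bin_size,
           value = v)
  })
}

#' Read a bedGraph file onto fixed-width bins
#'
#' Resamples bedGraph records (`chrom start end value`, 0-based half-open)
#' onto bins of `bin_size` bp by bp-weighted averaging; base pairs not
#' covered by any record count as zero (the missing-data-as-zero
#' convention). Overlapping records are an error.
#'
#' @param path bedGraph file.
#' @param bin_size Target bin width in bp.
#' @param genome_sizes Named chromosome lengths; chromosomes absent from the
#'   file still get an all-zero vector.
#' @return A [coverage_track()].
#' @export
read_track <- function(path, bin_size, genome_sizes = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", comment = "#", progress = FALSE)
  chroms <- if (!is.null(genome_sizes)) names(genome_sizes) else unique(df$chrom)
  values <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    d <- df[df$chrom == ch, , drop = FALSE]
    clen <- if (!is.null(genome_sizes)) genome_sizes[[ch]] else if (nrow(d)) max(d$end) else bin_size
    nbin <- as.integer(ceiling(clen / bin_size))
    v <- numeric(nbin)
    if (nrow(d)) {
      d <- d[order(d$start), , drop = FALSE]
      if (any(d$start[-1] < d$end[-nrow(d)])) {
        abort(paste("overlapping bedGraph records on", ch))
      }
      if (any(d$end > clen)) abort(paste("bedGraph record beyond contig end on", ch))
      for (i in seq_len(nrow(d))) {
        s <- d$start[i]; e <- d$end[i]; val <- d$value[i]
        b0 <- s %/% bin_size; b1 <- (e - 1L) %/% bin_size
        if (b0 == b1) {
          v[b0 + 1L] <- v[b0 + 1L] + val * (e - s) / bin_size
        } else {
          v[b0 + 1L] <- v[b0 + 1L] + val * ((b0 + 1L) * bin_size - s) / bin_size
          v[b1 + 1L] <- v[b1 + 1L] + val * (e - b1 * bin_size) / bin_size
          if (b1 - b0 > 1L) v[(b0 + 2L):b1] <- v[(b0 + 2L):b1] + val
        }
      }
    }
    values[[ch]] <- v
  }
  coverage_track(values, bin_size, "raw", genome_sizes)
}

#' Write a coverage track as bedGraph
#'
#' Emits one record per run of equal-valued bins; zero-valued runs are
#' omitted (they read back as zero).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep] * bs, ends[keep] * bs,
                         format(r$values[keep], trim = TRUE, scientific = FALSE,
                                digits = 10)), con)
    }
  }
  invisible(path)
}

# mean track value over [from, to) in genomic bp; positions outside the
# contig contribute 0 (clipping-as-zero, matching read_track's convention)
track_region_mean <- function(track, chrom, from, to) {
  stopifnot(to > from)
  v <- track$values[[chrom]]
  bs <- track$bin_size
  n <- length(v) %||% 0L
  if (is.null(v)) v <- numeric(0)
  total <- 0
  lo <- max(from, 0L); hi <- min(to, n * bs)
  if (hi > lo) {
    b0 <- lo %/% bs; b1 <- (hi - 1L) %/% bs
    if (b0 == b1) {
      total <- v[b0 + 1L] * (hi - lo)
    } else {
      total <- v[b0 + 1L] * ((b0 + 1L) * bs - lo) + v[b1 + 1L] * (hi - b1 * bs)
      if (b1 - b0 > 1L) total <- total + sum(v[(b0 + 2L):b1]) * bs
    }
  }
  total / (to - from)
}
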