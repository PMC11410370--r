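#' BPM-normalize a coverage track
#'
#' Bins-per-million scaling: every bin value is divided by the track total
#' and multiplied by 1e6, so the output sums to exactly one million.
#'
#' @param track A [coverage_track()].
#' @return A BPM-labelled `coverage_track`.
#' @export
bpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  total <- sum(vapply(track$values, sum, numeric(1)))
  if (total == 0) abort("cannot BPM-normalize an all-zero track")
  coverage_track(lapply(track$values, function(v) v / total * 1e6),
                 track$bin_size, "BPM", track$genome_sizes)
}

#' Subtract one track from another
#'
#' Per-bin `chip - input`, the standard enrichment-over-input operation.
#' Both tracks must share bin size and chromosome namespace (and should be
#' BPM-normalized first so library depth cancels). Negative values are
#' kept, not clipped.
#'
#' @param chip,input [coverage_track()] objects.
#' @return A `coverage_track` labelled `subtracted`.
#' @export
subtract_tracks <- function(chip, input) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_size != input$bin_size) abort("bin_size mismatch between tracks")
  if (!setequal(names(chip$values), names(input$values))) {
    abort("chromosome namespace mismatch between tracks")
  }
  vals <- lapply(names(chip$values), function(ch) {
    a <- chip$values[[ch]]; b <- input$values[[ch]]
    if (length(a) != length(b)) abort(paste("bin count mismatch on", ch))
    a - b
  })
  names(vals) <- names(chip$values)
  coverage_track(vals, chip$bin_size, "subtracted", chip$genome_sizes)
}

new_profile_matrix <- function(mat, mode, flank_bp = NULL, bin_bp = NULL,
                               body_bp = NULL) {
  structure(mat, class = c("profile_matrix", "matrix"),
            mode = mode, flank_bp = flank_bp, bin_bp = bin_bp,
            body_bp = body_bp)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix [%s]: %d rows x %d bins>\n",
              attr(x, "mode"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
as_tibble.profile_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "mode") <- attr(m, "flank_bp") <- attr(m, "bin_bp") <- attr(m, "body_bp") <- NULL
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- colnames(x)
  dplyr::bind_cols(tibble(row_id = rownames(x)), out)
}

#' Signal matrix around reference points
#'
#' For each point, averages the track over `2 * flank / bin` fixed-width
#' bins spanning `[pos - flank, pos + flank)`. Rows for minus-strand
#' points are reversed so columns always run 5' to 3' along the feature;
#' regions beyond the contig contribute zero. This is the reference-point
#' profile underlying TSS- and summit-centered density plots.
#'
#' @param track A [coverage_track()].
#' @param points Tibble with `chrom`, `pos`, optional `strand` and `name`.
#' @param flank Half-window in bp.
#' @param bin Column width in bp; must divide `flank`.
#' @return A `profile_matrix` (rows = points, columns = bins labelled by
#'   their start offset).
#' @export
reference_point_matrix <- function(track, points, flank = 2000, bin = 25) {
  stopifnot(inherits(track, "coverage_track"))
  if (flank %% bin != 0) abort("flank must be divisible by bin")
  nb <- 2L * flank %/% bin
  strand <- if ("strand" %in% names(points)) points$strand else rep("+", nrow(points))
  ids <- if ("name" %in% names(points)) points$name else sprintf("point_%d", seq_len(nrow(points)))
  mat <- matrix(0, nrow = nrow(points), ncol = nb,
                dimnames = list(ids, seq(-flank, flank - bin, by = bin)))
  for (i in seq_len(nrow(points))) {
    from <- points$pos[i] - flank
    row <- vapply(seq_len(nb) - 1L, function(k) {
      track_region_mean(track, points$chrom[i], from + k * bin, from + (k + 1L) * bin)
    }, numeric(1))
    if (strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  new_profile_matrix(mat, "reference_point", flank_bp = flank, bin_bp = bin)
}

# per-bp values of a track over [from, to); O(length) but only used on
# single regions
track_bp_values <- function(track, chrom, from, to) {
  v <- track$values[[chrom]]
  if (is.null(v)) v <- numeric(0)
  bs <- track$bin_size
  pos <- from:(to - 1L)
  idx <- pos %/% bs + 1L
  out <- numeric(length(pos))
  ok <- pos >= 0L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Scaled-region (metagene) signal matrix
#'
#' Rescales each region's signal onto a fixed number of columns
#' (`body / bin`). In `"metagene"` mode (the default) the region
#' coordinates are the exon-concatenated transcript, so intronic signal is
#' excluded; `"span"` mode uses the full gene span. Each column is the
#' bp-weighted mean of the corresponding fraction of the region, i.e. the
#' signal is linearly rescaled; minus-strand rows are reversed to read
#' 5' to 3'.
#'
#' @param track A [coverage_track()].
#' @param tx Transcript tibble ([read_gene_models()]).
#' @param body Scaled body length in bp.
#' @param bin Column width in bp; must divide `body`.
#' @param mode `"metagene"` or `"span"`.
#' @return A `profile_matrix` with rows named by `transcript_id`.
#' @export
scale_regions_matrix <- function(track, tx, body = 4000, bin = 25,
                                 mode = c("metagene", "span")) {
  mode <- match.arg(mode)
  if (body %% bin != 0) abort("body must be divisible by bin")
  nc <- body %/% bin
  mat <- matrix(0, nrow = nrow(tx), ncol = nc,
                dimnames = list(tx$transcript_id,
                                seq(0, body - bin, by = bin)))
  short <- character(0)
  for (i in seq_len(nrow(tx))) {
    vals <- if (mode == "span") {
      track_bp_values(track, tx$chrom[i], tx$start[i], tx$end[i])
    } else {
      es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
      if (!length(es)) { es <- tx$start[i]; ee <- tx$end[i] }
      unlist(purrr::map2(es, ee, function(s, e) track_bp_values(track, tx$chrom[i], s, e)))
    }
    L <- length(vals)
    if (L < bin) {
      short <- c(short, tx$transcript_id[i])
      row <- rep(mean(vals), nc)
    } else {
      # column j covers region fraction [(j-1)/nc, j/nc) with fractional
      # bp weighting at the edges
      edges <- seq(0, L, length.out = nc + 1L)
      row <- vapply(seq_len(nc), function(j) {
        a <- edges[j]; b <- edges[j + 1L]
        i0 <- floor(a); i1 <- ceiling(b)
        w <- pmin(b, seq(i0 + 1, i1)) - pmax(a, seq(i0, i1 - 1))
        sum(vals[(i0 + 1):i1] * w) / (b - a)
      }, numeric(1))
    }
    if (tx$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  if (length(short)) {
    warn(sprintf("%d region(s) shorter than one bin; filled with their mean value",
                 length(short)))
  }
  new_profile_matrix(mat, "scale_regions", bin_bp = bin, body_bp = body)
}

#' Order profile rows by a summary statistic
#'
#' Sorts rows in decreasing order of the chosen statistic (the heatmap
#' sort), breaking ties by ascending row id. The multiset of rows is
#' unchanged.
#'
#' @param mat A `profile_matrix`.
#' @param stat `"max"`, `"mean"` or `"sum"`.
#' @return The reordered `profile_matrix`.
#' @export
order_rows <- function(mat, stat = c("max", "mean", "sum")) {
  stat <- match.arg(stat)
  f <- switch(stat, max = function(r) max(r), mean = mean, sum = sum)
  key <- apply(unclass(mat), 1, f)
  ord <- order(-key, rownames(mat))
  out <- unclass(mat)[ord, , drop = FALSE]
  new_profile_matrix(out, attr(mat, "mode"), attr(mat, "flank_bp"),
                     attr(mat, "bin_bp"), attr(mat, "body_bp"))
}

#' Mean signal profile across rows
#'
#' The per-column arithmetic mean of a profile matrix -- the aggregate
#' metaprofile plotted under heatmaps.
#'
#' @param mat A `profile_matrix` with at least one row.
#' @return Tibble with `offset` (column label) and `mean_signal`.
#' @export
column_profile <- function(mat) {
  if (nrow(mat) == 0) abort("empty profile matrix")
  tibble(offset = as.numeric(colnames(mat)),
         mean_signal = unname(colMeans(unclass(mat))))
}
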