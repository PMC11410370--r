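#' Base-pair Jaccard index of two interval sets
#'
#' Both sets are merged ([merge_intervals()]) and the statistic is computed
#' base-pair-wise: intersection bp divided by union bp. Also reports how
#' many (un-merged) intervals of `a` overlap at least one interval of `b`,
#' which is the "peaks overlapping" count used to express replicate
#' agreement as a percentage.
#'
#' @param a,b Interval data frames on the same chromosome namespace.
#' @return Object of class `jaccard_result`: list with `intersection_bp`,
#'   `union_bp`, `jaccard`, `n_overlapping_pairs`, `n_a`, `n_b`.
#' @export
#' @examples
#' a <- data.frame(chrom = "c", start = 0, end = 100)
#' b <- data.frame(chrom = "c", start = 50, end = 150)
#' jaccard(a, b)$jaccard   # 50 / 150
jaccard <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  if (nrow(a) == 0 && nrow(b) == 0) abort("both interval sets empty: Jaccard is 0/0")
  ga <- gr_from_intervals(a); gb <- gr_from_intervals(b)
  GenomicRanges::strand(ga) <- "*"; GenomicRanges::strand(gb) <- "*"
  ma <- GenomicRanges::reduce(ga); mb <- GenomicRanges::reduce(gb)
  inter <- GenomicRanges::intersect(ma, mb)
  uni <- GenomicRanges::union(ma, mb)
  ibp <- sum(as.numeric(GenomicRanges::width(inter)))
  ubp <- sum(as.numeric(GenomicRanges::width(uni)))
  hits <- GenomicRanges::countOverlaps(ga, mb)
  structure(
    list(intersection_bp = ibp, union_bp = ubp, jaccard = ibp / ubp,
         n_overlapping_pairs = sum(hits > 0), n_a = nrow(a), n_b = nrow(b)),
    class = "jaccard_result"
  )
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf("Jaccard %.4f (intersection %d bp / union %d bp); %d/%d query intervals overlap\n",
              x$jaccard, x$intersection_bp, x$union_bp,
              x$n_overlapping_pairs, x$n_a))
  invisible(x)
}

#' @export
glance.jaccard_result <- function(x, ...) {
  tibble(jaccard = x$jaccard, intersection_bp = x$intersection_bp,
         union_bp = x$union_bp, n_overlapping_pairs = x$n_overlapping_pairs,
         n_a = x$n_a, n_b = x$n_b)
}

#' Relative distance of query intervals to reference points
#'
#' For each query midpoint lying between two consecutive reference points
#' `b_prev <= q <= b_next` on its chromosome, the relative distance is
#' `min(q - b_prev, b_next - q) / (b_next - b_prev)`, a value in
#' `[0, 0.5]`. Under spatial independence of queries and references the
#' values are uniform, so a flat histogram is the null; an excess near 0
#' means spatial association. Queries upstream of the first or downstream
#' of the last reference on their chromosome are dropped and counted.
#'
#' @param queries Interval data frame; midpoints `floor((start+end)/2)` are
#'   used.
#' @param references Data frame with `chrom` and `pos` columns (e.g. from
#'   [transcript_tss()]).
#' @param bin Histogram bin width on `[0, 0.5]` (default 0.02).
#' @return Object of class `reldist_result`: list with `values`,
#'   `histogram` (tibble of bin, frequency), `n_dropped`.
#' @export
relative_distance <- function(queries, references, bin = 0.02) {
  q <- as_intervals(queries)
  stopifnot(all(c("chrom", "pos") %in% names(references)))
  mids <- interval_midpoint(q)
  refs <- references |>
    arrange(.data$chrom, .data$pos)
  by_chrom <- split(refs$pos, refs$chrom)
  usable <- vapply(by_chrom, function(p) length(unique(p)) >= 2, logical(1))
  if (!any(usable[unique(q$chrom)] %+na% FALSE)) {
    abort("fewer than 2 reference points on every queried chromosome")
  }
  vals <- numeric(0); dropped <- 0L
  for (ch in unique(q$chrom)) {
    p <- sort(unique(by_chrom[[ch]]))
    m <- mids[q$chrom == ch]
    if (length(p) < 2) { dropped <- dropped + length(m); next }
    inside <- m >= p[1] & m <= p[length(p)]
    dropped <- dropped + sum(!inside)
    m <- m[inside]
    if (!length(m)) next
    i <- findInterval(m, p)
    i[i == length(p)] <- length(p) - 1L  # right endpoint belongs to last gap
    left <- m - p[i]; right <- p[i + 1L] - m
    vals <- c(vals, pmin(left, right) / (p[i + 1L] - p[i]))
  }
  breaks <- seq(0, 0.5, by = bin)
  idx <- pmin(findInterval(vals, breaks, rightmost.closed = TRUE), length(breaks) - 1L)
  freq <- tabulate(idx, nbins = length(breaks) - 1L)
  hist <- tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 count = freq,
                 frequency = if (length(vals)) freq / length(vals) else rep(0, length(freq)))
  structure(list(values = vals, histogram = hist, n_dropped = dropped),
            class = "reldist_result")
}

#' @export
print.reldist_result <- function(x, ...) {
  cat(sprintf("<reldist_result: %d values (mean %.3f), %d dropped>\n",
              length(x$values), mean(x$values), x$n_dropped))
  invisible(x)
}

#' Classify peaks as TSS, gene-body or intergenic
#'
#' A peak is labelled `TSS` when its interval contains the TSS coordinate
#' of any transcript, else `gene_body` when it overlaps any transcript
#' span, else `intergenic`. Every peak is additionally assigned its closest
#' TSS gene ([closest_tss()]). Label fractions are reported both as reals
#' and as integer percents (round half away from zero).
#'
#' @param peaks Interval data frame.
#' @param tx Transcript tibble from [read_gene_models()].
#' @return Object of class `peak_classification`: list with `peaks` (tibble
#'   with `label`, `gene_id`, `distance` columns added) and `summary`
#'   (tibble of label, n, fraction, percent).
#' @export
classify_peaks <- function(peaks, tx) {
  p <- as_intervals(peaks)
  tss <- transcript_tss(tx)
  gr_p <- gr_from_intervals(p)
  GenomicRanges::strand(gr_p) <- "*"
  gr_tss <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$pos + 1L, tss$pos + 1L))
  gr_tx <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end))
  at_tss <- GenomicRanges::countOverlaps(gr_p, gr_tss) > 0
  in_body <- GenomicRanges::countOverlaps(gr_p, gr_tx) > 0
  label <- ifelse(at_tss, "TSS", ifelse(in_body, "gene_body", "intergenic"))
  ct <- closest_tss(p, tx)
  out <- p |>
    mutate(label = factor(label, levels = c("TSS", "gene_body", "intergenic")),
           gene_id = ct$gene_id, distance = ct$distance)
  summary <- tibble(label = factor(c("TSS", "gene_body", "intergenic"),
                                   levels = c("TSS", "gene_body", "intergenic"))) |>
    left_join(count(out, .data$label), by = "label") |>
    mutate(n = .data$n %+na% 0L,
           fraction = .data$n / nrow(out),
           percent = round_half_away(100 * .data$fraction))
  structure(list(peaks = out, summary = summary), class = "peak_classification")
}

#' @export
print.peak_classification <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
tidy.peak_classification <- function(x, ...) x$summary

#' Closest TSS to each peak
#'
#' Signed genomic distance `tss - peak_midpoint` to the nearest transcript
#' TSS on the peak's chromosome. Ties (equidistant TSSs) are broken by the
#' lexicographically smaller `gene_id`.
#'
#' @param peaks Interval data frame.
#' @param tx Transcript tibble.
#' @return Tibble with one row per peak: `gene_id`, `distance`.
#' @export
closest_tss <- function(peaks, tx) {
  p <- as_intervals(peaks)
  tss <- transcript_tss(tx)
  mids <- interval_midpoint(p)
  out_gene <- character(nrow(p)); out_dist <- integer(nrow(p))
  by_chrom <- split(seq_len(nrow(tss)), tss$chrom)
  for (i in seq_len(nrow(p))) {
    idx <- by_chrom[[p$chrom[i]]]
    if (is.null(idx)) abort(paste("no transcript on chromosome", p$chrom[i]))
    d <- tss$pos[idx] - mids[i]
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1) best <- best[order(tss$gene_id[idx][best])][1]
    out_gene[i] <- tss$gene_id[idx][best]
    out_dist[i] <- d[best]
  }
  tibble(gene_id = out_gene, distance = out_dist)
}

#' Genome-wide peak-overlap Fisher test
#'
#' Builds a 2x2 contingency table asking whether intervals of `a` overlap
#' intervals of `b` more often than expected: `n11` = merged-`a` intervals
#' overlapping merged-`b`, `n12` = merged-`a` not overlapping, `n21` =
#' merged-`b` intervals not overlapping merged-`a`, and `n22` = the number
#' of remaining genome "slots",
#' `floor(genome_size / slot_width) - n11 - n12 - n21` (floored at 0),
#' where `slot_width` is the sum of the two sets' mean merged-interval
#' widths -- the footprint within which two independently placed intervals
#' collide, which calibrates the odds ratio to about 1 for spatially
#' independent sets. The slot heuristic for `n22` is a modelling choice --
#' there is no canonical fourth cell for interval overlap -- and the
#' resulting odds ratio should be read as a descriptive enrichment score,
#' not an exact probability statement.
#'
#' @param a,b Interval data frames.
#' @param genome_size Total genome length in bp.
#' @return A `fisher2x2` object (see [fisher_exact()]).
#' @export
overlap_fisher <- function(a, b, genome_size) {
  if (genome_size <= 0) abort("genome_size must be positive")
  ma <- merge_intervals(a); mb <- merge_intervals(b)
  ga <- gr_from_intervals(ma); gb <- gr_from_intervals(mb)
  o_a <- sum(GenomicRanges::countOverlaps(ga, gb) > 0)
  o_b <- sum(GenomicRanges::countOverlaps(gb, ga) > 0)
  n11 <- o_a
  n12 <- nrow(ma) - o_a
  n21 <- nrow(mb) - o_b
  slot_width <- mean(ma$end - ma$start) + mean(mb$end - mb$start)
  slots <- floor(genome_size / slot_width)
  n22 <- max(0, slots - n11 - n12 - n21)
  fisher_exact(n11, n12, n21, n22)
}

#' Fisher's exact test on a 2x2 table
#'
#' The reported headline `odds_ratio` is the sample odds ratio
#' `(n11 * n22) / (n12 * n21)` (matching what is obtained by dividing the
#' printed counts), with `+Inf` when the denominator product is zero and
#' the numerator is not. The two-sided exact p-value is the sum of
#' hypergeometric point probabilities not exceeding that of the observed
#' table with margins fixed (via `stats::fisher.test()`), and the
#' conditional maximum-likelihood odds ratio from the same fit is exposed
#' alongside. A table with any zero margin carries no information: p is 1
#' and the odds ratio `NaN`, with a warning.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts, or `n11` may be
#'   a 2x2 matrix.
#' @return Object of class `fisher2x2`: list with the four cells,
#'   `odds_ratio`, `conditional_mle`, `p_two_sided`.
#' @export
#' @examples
#' fisher_exact(666, 1632, 1328, 7178)  # bound x upregulated
fisher_exact <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL) {
  if (is.matrix(n11)) {
    m <- n11
    n11 <- m[1, 1]; n12 <- m[1, 2]; n21 <- m[2, 1]; n22 <- m[2, 2]
  }
  cells <- c(n11, n12, n21, n22)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  margins <- c(n11 + n12, n21 + n22, n11 + n21, n12 + n22)
  if (any(margins == 0)) {
    warn("a margin of the 2x2 table is zero: odds ratio undefined")
    or <- NaN; cmle <- NaN; p <- 1
  } else {
    num <- as.numeric(n11) * as.numeric(n22)
    den <- as.numeric(n12) * as.numeric(n21)
    or <- if (den == 0) {
      if (num > 0) Inf else NaN
    } else num / den
    ft <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
    cmle <- unname(ft$estimate)
    p <- ft$p.value
  }
  structure(
    list(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
         odds_ratio = or, conditional_mle = cmle, p_two_sided = p),
    class = "fisher2x2"
  )
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat(sprintf("2x2 [%d %d / %d %d]: OR = %.3g (cMLE %.3g), two-sided p = %.3g\n",
              x$n11, x$n12, x$n21, x$n22, x$odds_ratio, x$conditional_mle,
              x$p_two_sided))
  invisible(x)
}

#' @rdname fisher_exact
#' @param x A `fisher2x2` object.
#' @param ... Unused.
#' @export
tidy.fisher2x2 <- function(x, ...) {
  tibble(estimate = x$odds_ratio, conditional_mle = x$conditional_mle,
         p.value = x$p_two_sided,
         n11 = x$n11, n12 = x$n12, n21 = x$n21, n22 = x$n22)
}

#' @rdname fisher_exact
#' @export
glance.fisher2x2 <- function(x, ...) tidy.fisher2x2(x)
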