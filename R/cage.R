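#' Aggregate CAGE tags into a CTSS table
#'
#' Sums per-position tag counts into one row per (chrom, position, strand)
#' -- a CAGE-detected TSS (CTSS). Counts must be positive.
#'
#' @param tags Tibble with `chrom`, `pos`, `strand`, `count`.
#' @return CTSS tibble (`chrom`, `pos`, `strand`, `count`), sorted.
#' @export
ctss_from_tags <- function(tags) {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(tags)))
  if (any(tags$count < 0)) abort("negative tag count")
  tags |>
    filter(.data$count > 0) |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Tags-per-million normalization of a CTSS table
#'
#' `tpm = count / total * 1e6`, the simple TPM scheme: totals are
#' preserved, so the tpm column sums to one million.
#'
#' @param ctss CTSS tibble from [ctss_from_tags()].
#' @return The tibble with a `tpm` column added.
#' @export
tpm_normalize <- function(ctss) {
  if (nrow(ctss) == 0) abort("empty CTSS table")
  total <- sum(ctss$count)
  mutate(ctss, tpm = .data$count / total * 1e6)
}

#' Cluster CTSS positions into tag clusters
#'
#' CTSS below `tpm_threshold` are discarded first. `"distclu"` merges
#' surviving same-strand positions within `max_dist` bp transitively;
#' `"paraclu"` runs the maximal-density segmentation
#' ([paraclu_segments()]) per chromosome and strand, then keeps clusters
#' of length at most `max_length`, resolving overlaps in favour of the
#' higher `max_density`. In both modes single-position clusters are
#' removed unless their raw tag count is at least `keep_singletons_above`.
#'
#' @param ctss CTSS tibble with a `tpm` column ([tpm_normalize()]).
#' @param method `"distclu"` or `"paraclu"`.
#' @param max_dist Maximum merge gap in bp (distclu).
#' @param tpm_threshold Minimum tpm for a CTSS to enter clustering.
#' @param remove_singletons Drop single-position clusters?
#' @param keep_singletons_above Raw-count rescue threshold for singletons.
#' @param max_length Maximum cluster span in bp (paraclu post-filter).
#' @return Tibble of clusters: `cluster_id`, `chrom`, `strand`, `start`,
#'   `end` (half-open), `n_ctss`, `total_tpm`, `dominant_pos`,
#'   `dominant_tpm`, and for paraclu `min_density`, `max_density`.
#' @export
cluster_ctss <- function(ctss, method = c("distclu", "paraclu"), max_dist = 20,
                         tpm_threshold = 1, remove_singletons = TRUE,
                         keep_singletons_above = 5, max_length = 200) {
  method <- match.arg(method)
  if (!"tpm" %in% names(ctss)) abort("run tpm_normalize() first")
  x <- filter(ctss, .data$tpm >= tpm_threshold)
  if (nrow(x) == 0) return(tibble())
  groups <- split(x, paste(x$chrom, x$strand))
  clusters <- purrr::map_dfr(groups, function(g) {
    g <- arrange(g, .data$pos)
    if (method == "distclu") {
      brk <- cumsum(c(0L, diff(g$pos) > max_dist))
      purrr::map_dfr(split(seq_len(nrow(g)), brk), function(idx) {
        member_summary(g[idx, , drop = FALSE])
      })
    } else {
      segs <- paraclu_segments(tibble(pos = g$pos, weight = g$tpm))
      segs <- segs |>
        filter(.data$end - .data$start <= max_length) |>
        arrange(dplyr::desc(.data$max_density))
      keep <- rep(TRUE, nrow(segs))
      for (i in seq_len(nrow(segs))) {
        if (!keep[i]) next
        later <- which(keep & seq_len(nrow(segs)) > i)
        ov <- segs$start[later] < segs$end[i] & segs$end[later] > segs$start[i]
        keep[later[ov]] <- FALSE
      }
      segs <- segs[keep, , drop = FALSE]
      purrr::map_dfr(seq_len(nrow(segs)), function(i) {
        memb <- g[g$pos >= segs$start[i] & g$pos < segs$end[i], , drop = FALSE]
        bind_cols(member_summary(memb),
                  tibble(min_density = segs$min_density[i],
                         max_density = segs$max_density[i]))
      })
    }
  })
  if (remove_singletons) {
    clusters <- filter(clusters,
                       .data$n_ctss > 1 | .data$raw_count >= keep_singletons_above)
  }
  clusters |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    mutate(cluster_id = sprintf("tc_%d", row_number())) |>
    select("cluster_id", dplyr::everything())
}

member_summary <- function(memb) {
  dom <- dominant_tss(memb)
  tibble(
    chrom = memb$chrom[1], strand = memb$strand[1],
    start = min(memb$pos), end = max(memb$pos) + 1L,
    n_ctss = nrow(memb), raw_count = sum(memb$count),
    total_tpm = sum(memb$tpm),
    dominant_pos = dom$pos, dominant_tpm = dom$tpm
  )
}

#' Dominant TSS of a cluster
#'
#' The member position with maximal tpm; ties go to the 5'-most position
#' relative to the strand (lowest coordinate on `+`, highest on `-`).
#'
#' @param members Tibble of cluster members (`pos`, `tpm`, `strand`).
#' @return One-row tibble with `pos` and `tpm`.
#' @export
dominant_tss <- function(members) {
  stopifnot(nrow(members) >= 1)
  best <- which(members$tpm == max(members$tpm))
  if (length(best) > 1) {
    best <- if (members$strand[1] == "-") best[which.max(members$pos[best])]
            else best[which.min(members$pos[best])]
  }
  tibble(pos = members$pos[best], tpm = members$tpm[best])
}

#' Maximal-density segmentation of weighted positions (paraclu-style)
#'
#' Recursive parametric clustering of one chromosome strand: a segment's
#' `max_density` is its total weight divided by its half-open span; its
#' break point is the prefix/suffix boundary of minimal density
#' (`min_density`), where a prefix ending before a break is weighed over
#' the distance to the first position beyond the break (and symmetrically
#' for suffixes), so segments split preferentially at large gaps. The
#' recursion then descends into the two sub-segments.
#' All segments of the recursion whose `max_density / min_density` reaches
#' `stability` (default 1, i.e. all) are reported. A single position is the
#' degenerate case: span 1, `max_density = weight`, `min_density = 0`
#' (sentinel, documented rather than infinite).
#'
#' @param positions Tibble with sorted `pos` (integers) and positive
#'   `weight`.
#' @param stability Minimum `max_density / min_density` ratio to report.
#' @return Tibble of segments: `start`, `end` (half-open), `n_positions`,
#'   `total_weight`, `min_density`, `max_density`.
#' @export
paraclu_segments <- function(positions, stability = 1) {
  if (nrow(positions) == 0) abort("empty input")
  if (any(positions$weight <= 0)) abort("weights must be positive")
  p <- positions$pos; w <- positions$weight
  if (is.unsorted(p, strictly = TRUE)) {
    o <- order(p); p <- p[o]; w <- w[o]
    if (anyDuplicated(p)) abort("duplicate positions")
  }
  out <- list()
  recurse <- function(i, j) {
    n <- j - i + 1L
    span <- p[j] - p[i] + 1L
    tot <- sum(w[i:j])
    maxd <- tot / span
    if (n == 1L) {
      out[[length(out) + 1L]] <<- tibble(
        start = p[i], end = p[i] + 1L, n_positions = 1L, total_weight = tot,
        min_density = 0, max_density = maxd)
      return(invisible())
    }
    # candidate boundary densities for a break between positions k and k+1:
    # prefix weight over the distance to the first position across the gap,
    # and symmetrically for the suffix -- so breaks gravitate to large gaps
    ks <- i:(j - 1L)
    pre <- cumsum(w[i:j])[seq_len(n - 1L)] / (p[ks + 1L] - p[i])
    suf <- rev(cumsum(rev(w[i:j])))[2:n] / (p[j] - p[ks])
    cand <- pmin(pre, suf)
    k <- ks[which.min(cand)]
    mind <- min(cand)
    if (maxd / mind >= stability || !is.finite(mind)) {
      out[[length(out) + 1L]] <<- tibble(
        start = p[i], end = p[j] + 1L, n_positions = n, total_weight = tot,
        min_density = mind, max_density = maxd)
    }
    recurse(i, k)
    recurse(k + 1L, j)
  }
  recurse(1L, length(p))
  bind_rows(out) |> arrange(.data$start, .data$end)
}

#' Promoter windows around dominant TSSs
#'
#' Extracts `[pos - flank, pos + flank + 1)` around each TSS (a
#' `2 * flank + 1` bp window with the TSS base at index `flank`,
#' 0-based), clipping at contig edges. Minus-strand windows are
#' reverse-complemented so every sequence reads 5' to 3' with the TSS at
#' the same index.
#'
#' @param tss Tibble with `chrom`, `pos`, `strand` (e.g. dominant cluster
#'   positions).
#' @param genome Genome (path, `DNAStringSet` or named vector).
#' @param flank Bases on each side of the TSS (default 200).
#' @return Tibble: `promoter_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss_index` (0-based index of the TSS in `seq`), `clipped`, `seq`.
#' @export
promoter_windows <- function(tss, genome, flank = 200) {
  stopifnot(flank > 0)
  genome <- as_genome(genome)
  sizes <- genome_sizes_of(genome)
  out <- purrr::map_dfr(seq_len(nrow(tss)), function(i) {
    ch <- tss$chrom[i]; pos <- tss$pos[i]; st <- tss$strand[i]
    lo <- max(0L, pos - flank)
    hi <- min(sizes[[ch]], pos + flank + 1L)
    s <- fetch_sequence(genome, tibble(chrom = ch, start = lo, end = hi))
    idx <- pos - lo              # TSS index in the forward-strand window
    if (st == "-") {
      s <- revcomp(s)
      idx <- (hi - lo - 1L) - idx
    }
    tibble(promoter_id = sprintf("prom_%d", i), chrom = ch,
           start = lo, end = hi, strand = st, tss_index = idx,
           clipped = (hi - lo) != 2L * flank + 1L, seq = s)
  })
  out
}
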