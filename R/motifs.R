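#' Motif models
#'
#' A motif is a list with a `name`, an IUPAC `consensus` string and/or a
#' position probability matrix `pwm` (4 x L, rows A, C, G, T, columns
#' summing to 1), and a zero-order `background` base distribution (uniform
#' by default). Consensus strings drive [iupac_scan()]; a PWM is required
#' for [pwm_scan()] and its exact p-value threshold.
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @param pwm Optional 4 x L probability matrix (rows A, C, G, T).
#' @param background Base frequencies in A, C, G, T order.
#' @return Object of class `motif_model`.
#' @export
#' @examples
#' motif("ovo_core", "TAACNGT")
motif <- function(name, consensus = NULL, pwm = NULL,
                  background = rep(0.25, 4)) {
  if (is.null(consensus) && is.null(pwm)) abort("motif needs a consensus or a pwm")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
    bad <- !ch %in% names(IUPAC_MASK)
    if (any(bad)) abort(paste0("invalid IUPAC character in consensus: ", ch[bad][1]))
  }
  if (!is.null(pwm)) {
    pwm <- as.matrix(pwm)
    stopifnot(nrow(pwm) == 4)
    rownames(pwm) <- c("A", "C", "G", "T")
    if (any(abs(colSums(pwm) - 1) > 1e-9)) abort("pwm columns must sum to 1")
    if (!is.null(consensus) && nchar(consensus) != ncol(pwm)) {
      abort("consensus length must equal pwm length")
    }
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-9)
  structure(list(name = name, consensus = consensus, pwm = pwm,
                 background = as.numeric(background)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif %s: %s%s>\n", x$name, x$consensus %||% "(pwm only)",
              if (is.null(x$pwm)) "" else sprintf(", pwm %d bp", ncol(x$pwm))))
  invisible(x)
}

#' Probability-matrix form of a consensus
#'
#' Converts an IUPAC consensus to a PWM by spreading each position's mass
#' uniformly over its base class. Used for planting instances and for PWM
#' scanning of consensus-only motifs when explicitly requested.
#'
#' @param consensus IUPAC string.
#' @return 4 x L probability matrix.
#' @export
consensus_to_pwm <- function(consensus) {
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  mask <- IUPAC_MASK[ch]
  if (any(is.na(mask))) abort("invalid IUPAC character in consensus")
  m <- vapply(mask, function(k) {
    b <- c(A = 1L, C = 2L, G = 4L, T = 8L)
    hit <- bitwAnd(k, b) > 0
    hit / sum(hit)
  }, numeric(4))
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' The published OVO binding-motif catalog
#'
#' The four de novo OVO ChIP motifs plus the two in-vitro defined motifs
#' (SELEX and footprinting), all sharing the 5'-TAACNGT-3' core. Returned
#' as an ordered list of [motif()] objects; the order is the mask-and-rescan
#' priority (most frequent motif first).
#'
#' @return Named list of `motif_model` objects.
#' @export
ovo_motif_catalog <- function() {
  cons <- c(
    motif_one = "TAACGGTAAA",
    motif_two = "RWMTAACGGV",
    motif_three = "TAACTGTTTT",
    motif_four = "TTACSGTAA",
    garfinkel = "AGTAACNGT",
    oliver = "TGTAACNGT"
  )
  purrr::imap(as.list(cons), function(c, n) motif(n, c))
}

seq_to_mask <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- SEQ_MASK[ch]
  m[is.na(m)] <- 0L  # N and anything unexpected matches no class
  unname(m)
}

consensus_to_mask <- function(consensus) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- IUPAC_MASK[ch]
  if (any(is.na(m))) abort(paste("invalid IUPAC character in consensus:",
                                 ch[which(is.na(m))[1]]))
  unname(m)
}

scan_mask <- function(seq_mask, pat_mask) {
  n <- length(seq_mask); m <- length(pat_mask)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & bitwAnd(seq_mask[j:(n - m + j)], pat_mask[j]) > 0L
  }
  which(ok) - 1L
}

#' Scan a sequence for IUPAC consensus matches
#'
#' Exact degenerate-class matching: position `i` is a hit when every
#' sequence base falls in the IUPAC class of the aligned consensus base.
#' `N` in the *sequence* matches nothing. Minus-strand hits are found by
#' scanning with the reverse-complemented consensus and are reported in
#' forward coordinates.
#'
#' @param sequence Uppercase DNA string.
#' @param m A [motif()] (or bare IUPAC string).
#' @param both_strands Also scan the minus strand?
#' @return Tibble of hits: `motif`, `start` (0-based), `end`, `strand`,
#'   `matched`.
#' @export
#' @examples
#' iupac_scan("GGTAACAGTGG", motif("core", "TAACNGT"))
iupac_scan <- function(sequence, m, both_strands = TRUE) {
  if (is.character(m)) m <- motif(m, m)
  if (is.null(m$consensus)) abort("iupac_scan needs a consensus motif")
  sm <- seq_to_mask(sequence)
  w <- nchar(m$consensus)
  fwd <- scan_mask(sm, consensus_to_mask(m$consensus))
  hits <- tibble(motif = m$name, start = fwd, end = fwd + w, strand = "+")
  if (both_strands) {
    rev <- scan_mask(sm, consensus_to_mask(revcomp(m$consensus)))
    hits <- bind_rows(hits, tibble(motif = m$name, start = rev,
                                   end = rev + w, strand = "-"))
  }
  hits <- arrange(hits, .data$start, .data$strand)
  hits$matched <- if (nrow(hits)) substring(sequence, hits$start + 1L, hits$end) else character(0)
  hits$score <- NA_real_
  hits
}

#' Exact PWM score threshold for a p-value
#'
#' Computes the full null distribution of the log2 likelihood-ratio score
#' (PWM versus the zero-order background) by position-wise convolution on a
#' discretized grid (step = 1/1000 of the finite score range), and returns
#' the smallest grid score `s` with `P(score >= s) <= alpha` under the
#' background model. Zero-probability PWM cells score `-Inf`; words through
#' them can never reach a finite threshold and their probability mass is
#' excluded from the finite grid (the distribution plus that mass sums
#' to 1). When `alpha` is smaller than the probability of the single best
#' word, the best-word score is returned with a warning: no match can be
#' that significant.
#'
#' @param m A [motif()] with a `pwm` (a consensus-only motif is converted
#'   via [consensus_to_pwm()]).
#' @param alpha Target p-value in (0, 1).
#' @param granularity Grid steps across the score range (default 1000).
#' @return Object of class `pwm_threshold`: list with `threshold`,
#'   `p_at_threshold`, `attained` (FALSE when alpha unreachably small),
#'   `grid` (tibble of score, p_ge), `delta`.
#' @export
pwm_threshold_from_pvalue <- function(m, alpha, granularity = 1000) {
  stopifnot(alpha > 0, alpha < 1)
  pwm <- m$pwm %||% consensus_to_pwm(m$consensus)
  bg <- m$background
  L <- ncol(pwm)
  s <- log2(pwm / bg)                      # -Inf where pwm cell is 0
  fin_min <- apply(s, 2, function(col) min(col[is.finite(col)]))
  fin_max <- apply(s, 2, max)
  rng <- sum(fin_max) - sum(fin_min)
  delta <- if (rng > 0) rng / granularity else 1
  ks <- round(sweep(s, 2, fin_min) / delta) # integer grid per cell; -Inf stays -Inf
  kmax <- apply(ks, 2, max)
  dist <- 1
  for (j in seq_len(L)) {
    nd <- numeric(length(dist) + kmax[j])
    for (b in 1:4) {
      k <- ks[b, j]
      if (is.finite(k) && bg[b] > 0) {
        idx <- seq_along(dist) + k
        nd[idx] <- nd[idx] + dist * bg[b]
      }
    }
    dist <- nd
  }
  grid_scores <- sum(fin_min) + (seq_along(dist) - 1L) * delta
  p_ge <- rev(cumsum(rev(dist)))
  ok <- which(p_ge <= alpha)
  if (length(ok)) {
    i <- ok[1]
    attained <- TRUE
  } else {
    i <- max(which(dist > 0))
    attained <- FALSE
    warn(sprintf("alpha = %g is below the best attainable p-value %g; using best-word score",
                 alpha, p_ge[i]))
  }
  structure(
    list(threshold = grid_scores[i], p_at_threshold = p_ge[i],
         attained = attained, delta = delta,
         grid = tibble(score = grid_scores, prob = dist, p_ge = p_ge)),
    class = "pwm_threshold"
  )
}

#' @export
print.pwm_threshold <- function(x, ...) {
  cat(sprintf("<pwm_threshold: score >= %.4f (p = %.3g%s)>\n",
              x$threshold, x$p_at_threshold,
              if (x$attained) "" else ", alpha unattainable"))
  invisible(x)
}

pwm_revcomp <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

pwm_window_scores <- function(sequence, pwm, bg) {
  n <- nchar(sequence); L <- ncol(pwm)
  if (n < L) return(numeric(0))
  code <- utf8ToInt(sequence)
  row <- integer(length(code))
  row[code == utf8ToInt("A")] <- 1L
  row[code == utf8ToInt("C")] <- 2L
  row[code == utf8ToInt("G")] <- 3L
  row[code == utf8ToInt("T")] <- 4L
  s <- log2(pwm / bg)
  tot <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    r <- row[j:(n - L + j)]
    v <- ifelse(r == 0L, -Inf, s[cbind(pmax(r, 1L), j)])
    tot <- tot + v
  }
  tot
}

#' Scan a sequence with a PWM at an exact p-value threshold
#'
#' Scores every window with the log2 likelihood ratio and reports all
#' windows at or above the [pwm_threshold_from_pvalue()] threshold for
#' `alpha`. Overlapping hits are all reported. Windows containing `N`
#' score `-Inf` and never match.
#'
#' @inheritParams iupac_scan
#' @param alpha P-value threshold (`1` reports every window).
#' @param threshold Optional precomputed `pwm_threshold` (saves the DP when
#'   scanning many sequences).
#' @return Tibble of hits with log-likelihood `score`.
#' @export
pwm_scan <- function(sequence, m, alpha = 1e-4, both_strands = TRUE,
                     threshold = NULL) {
  pwm <- m$pwm %||% consensus_to_pwm(m$consensus)
  bg <- m$background
  if (alpha >= 1) {
    thr <- -Inf
  } else {
    threshold <- threshold %||% pwm_threshold_from_pvalue(m, alpha)
    thr <- threshold$threshold - 1e-9
  }
  L <- ncol(pwm)
  sc_f <- pwm_window_scores(sequence, pwm, bg)
  hit_f <- which(sc_f >= thr)
  hits <- tibble(motif = m$name, start = hit_f - 1L, end = hit_f - 1L + L,
                 strand = "+", score = sc_f[hit_f])
  if (both_strands) {
    sc_r <- pwm_window_scores(sequence, pwm_revcomp(pwm), bg)
    hit_r <- which(sc_r >= thr)
    hits <- bind_rows(hits, tibble(motif = m$name, start = hit_r - 1L,
                                   end = hit_r - 1L + L, strand = "-",
                                   score = sc_r[hit_r]))
  }
  hits <- arrange(hits, .data$start, .data$strand)
  hits$matched <- if (nrow(hits)) substring(sequence, hits$start + 1L, hits$end) else character(0)
  hits[, c("motif", "start", "end", "strand", "matched", "score")]
}

#' Annotate peaks with motif presence
#'
#' Scans every peak sequence against a motif catalog (both strands) and
#' reports a per-peak presence matrix, the fraction of peaks containing
#' each motif, and the fraction containing at least one catalog motif --
#' the "any variation" statistic.
#'
#' @param peaks Interval data frame (row order defines peak ids; unnamed
#'   peaks get `peak_<i>`).
#' @param genome Genome (FASTA path, `DNAStringSet` or named vector).
#' @param catalog List of [motif()] objects.
#' @param mode `"iupac"` (default, consensus-class matching) or `"pwm"`.
#' @param alpha P-value threshold for PWM mode.
#' @return Object of class `motif_annotation`: list with `presence` (tibble,
#'   one row per peak, one logical column per motif plus `any_motif`),
#'   `fractions` (tibble of motif, n, fraction, percent), `any_fraction`,
#'   `any_percent`.
#' @export
annotate_peak_motifs <- function(peaks, genome, catalog, mode = c("iupac", "pwm"),
                                 alpha = 2e-4) {
  mode <- match.arg(mode)
  p <- as_intervals(peaks)
  if (nrow(p) == 0) abort("empty peak set")
  if (!length(catalog)) abort("empty motif catalog")
  ids <- ifelse(is.na(p$name), sprintf("peak_%d", seq_len(nrow(p))), p$name)
  seqs <- fetch_sequence(genome, p)
  thresholds <- if (mode == "pwm") {
    lapply(catalog, function(m) pwm_threshold_from_pvalue(m, alpha))
  }
  pres <- purrr::map(seq_along(catalog), function(k) {
    m <- catalog[[k]]
    vapply(seqs, function(s) {
      h <- if (mode == "iupac") iupac_scan(s, m, both_strands = TRUE)
      else pwm_scan(s, m, alpha, both_strands = TRUE,
                    threshold = thresholds[[k]])
      nrow(h) > 0
    }, logical(1), USE.NAMES = FALSE)
  })
  names(pres) <- vapply(catalog, function(m) m$name, character(1))
  presence <- tibble(peak = ids, !!!pres)
  presence$any_motif <- Reduce(`|`, pres)
  fractions <- tibble(
    motif = names(pres),
    n = unname(vapply(pres, sum, integer(1))),
    fraction = unname(vapply(pres, mean, numeric(1)))
  ) |>
    mutate(percent = round_half_away(100 * .data$fraction))
  structure(
    list(presence = presence, fractions = fractions,
         any_fraction = mean(presence$any_motif),
         any_percent = round_half_away(100 * mean(presence$any_motif))),
    class = "motif_annotation"
  )
}

#' @export
print.motif_annotation <- function(x, ...) {
  print(x$fractions)
  cat(sprintf("any motif: %.1f%% of %d peaks\n", 100 * x$any_fraction,
              nrow(x$presence)))
  invisible(x)
}

#' @export
tidy.motif_annotation <- function(x, ...) x$fractions

#' Iterative mask-and-rescan motif accounting
#'
#' Mirrors the follow-up used after de novo discovery: report the fraction
#' of current peaks containing the first catalog motif, remove those peaks,
#' and repeat with the next motif on the remainder, so each fraction is
#' conditional on all earlier motifs being absent.
#'
#' @inheritParams annotate_peak_motifs
#' @return Tibble with one row per motif: `motif`, `n_peaks_scanned`,
#'   `n_containing`, `fraction`.
#' @export
motif_mask_rescan <- function(peaks, genome, catalog, mode = "iupac",
                              alpha = 2e-4) {
  ann <- annotate_peak_motifs(peaks, genome, catalog, mode = mode, alpha = alpha)
  pres <- ann$presence
  keep <- rep(TRUE, nrow(pres))
  rows <- purrr::map(vapply(catalog, function(m) m$name, character(1)), function(nm) {
    n_scan <- sum(keep)
    hit <- pres[[nm]] & keep
    out <- tibble(motif = nm, n_peaks_scanned = n_scan,
                  n_containing = sum(hit),
                  fraction = if (n_scan) sum(hit) / n_scan else NA_real_)
    keep <<- keep & !pres[[nm]]
    out
  })
  bind_rows(rows)
}

#' Positional density of motif hits around reference points
#'
#' Bins the offset of each hit midpoint from its nearest reference point
#' (offsets are sign-flipped for minus-strand points so negative always
#' means upstream) and reports, per bin, the percent of points with at
#' least one hit in that bin.
#'
#' @param hits Tibble of genomic hits (`chrom`, `start`, `end`, `strand`).
#' @param points Tibble of reference points (`chrom`, `pos`, `strand`).
#' @param window Half-window in bp (hits beyond it are ignored).
#' @param bin Bin width in bp; must divide `window`.
#' @return Tibble: `bin_lo`, `bin_hi` (offsets), `n_points`, `percent`.
#' @export
motif_density_around_points <- function(hits, points, window = 1500, bin = 25) {
  if (window %% bin != 0) abort("window must be divisible by bin")
  nb <- 2L * window %/% bin
  n_pts <- nrow(points)
  counts <- matrix(FALSE, nrow = n_pts, ncol = nb)
  if (nrow(hits)) {
    hmid <- floor((hits$start + hits$end) / 2)
    for (i in seq_len(n_pts)) {
      sel <- hits$chrom == points$chrom[i]
      if (!any(sel)) next
      off <- hmid[sel] - points$pos[i]
      if (points$strand[i] == "-") off <- -off
      off <- off[off >= -window & off < window]
      if (length(off)) counts[i, unique(off %/% bin + window %/% bin + 1L)] <- TRUE
    }
  }
  lo <- seq(-window, window - bin, by = bin)
  tibble(bin_lo = lo, bin_hi = lo + bin, n_points = n_pts,
         percent = 100 * colSums(counts) / max(n_pts, 1L))
}
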