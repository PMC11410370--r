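# Shared fixtures, built in code at load time.

# A deterministic toy genome: two contigs of simple repeated context with
# known planted words where tests need them.
toy_genome <- function() {
  set.seed(404)
  bases <- c("A", "C", "G", "T")
  g <- c(
    chrA = paste0(sample(bases, 5000, replace = TRUE), collapse = ""),
    chrB = paste0(sample(bases, 3000, replace = TRUE), collapse = "")
  )
  g
}

toy_transcripts <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    transcript_id = c("tA", "tB", "tC"),
    chrom = c("chrA", "chrA", "chrB"),
    start = c(100L, 2000L, 500L),
    end = c(1100L, 3200L, 1700L),
    strand = c("+", "-", "+"),
    exon_starts = list(c(100L, 600L), c(2000L, 2800L), 500L),
    exon_ends = list(c(400L, 1100L), c(2400L, 3200L), 1700L),
    cds_start = c(200L, 2100L, NA_integer_),
    cds_end = c(1000L, 3100L, NA_integer_)
  )
}

# One desk-scale scenario bundle, simulated once per test run and reused.
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scenario(scenario_config(seed = 20240917))
    }
    cache
  }
})

# Exhaustive two-sided Fisher p for a 2x2 with fixed margins: enumerate all
# tables, sum point probabilities <= the observed one (with a smidge of
# tolerance for float ties, as fisher.test does).
fisher_p_enum <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; c1 <- n11 + n21; n <- n11 + n12 + n21 + n22
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force PWM score distribution over all 4^L words on the same integer
# grid the DP uses.
pwm_tail_enum <- function(pwm, bg, delta, fin_min) {
  L <- ncol(pwm)
  s <- log2(pwm / bg)
  ks <- round(sweep(s, 2, fin_min) / delta)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  tot <- numeric(nrow(words))
  prob <- rep(1, nrow(words))
  for (j in seq_len(L)) {
    tot <- tot + ks[cbind(words[, j], j)]
    prob <- prob * bg[words[, j]]
  }
  keep <- is.finite(tot)
  list(k = tot[keep], prob = prob[keep])
}

random_pwm <- function(L, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(4 * L), nrow = 4)
  sweep(m, 2, colSums(m), "/")
}

# Independent paraclu oracle: iterative queue, densities from naive sums.
paraclu_oracle <- function(pos, weight, stability = 1) {
  out <- list()
  queue <- list(c(1L, length(pos)))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    i <- seg[1]; j <- seg[2]
    tot <- sum(weight[i:j])
    maxd <- tot / (pos[j] - pos[i] + 1)
    if (i == j) {
      out[[length(out) + 1]] <- data.frame(start = pos[i], end = pos[i] + 1L,
                                           min_density = 0, max_density = maxd)
      next
    }
    cand <- vapply(i:(j - 1L), function(k) {
      min(sum(weight[i:k]) / (pos[k + 1L] - pos[i]),
          sum(weight[(k + 1L):j]) / (pos[j] - pos[k]))
    }, numeric(1))
    k <- (i:(j - 1L))[which.min(cand)]
    mind <- min(cand)
    if (maxd / mind >= stability) {
      out[[length(out) + 1]] <- data.frame(start = pos[i], end = pos[j] + 1L,
                                           min_density = mind, max_density = maxd)
    }
    queue <- c(queue, list(c(i, k)), list(c(k + 1L, j)))
  }
  o <- do.call(rbind, out)
  o[order(o$start, o$end), , drop = FALSE]
}

# Naive reference-point matrix: per-bp track lookup, averaged per bin.
naive_reference_matrix <- function(track, points, flank, bin) {
  nb <- 2L * flank %/% bin
  t(vapply(seq_len(nrow(points)), function(i) {
    bp <- vapply((points$pos[i] - flank):(points$pos[i] + flank - 1L), function(p) {
      v <- track$values[[points$chrom[i]]]
      idx <- p %/% track$bin_size + 1L
      if (p < 0 || idx > length(v)) 0 else v[idx]
    }, numeric(1))
    row <- colMeans(matrix(bp, nrow = bin))
    if (!is.null(points$strand) && points$strand[i] == "-") row <- rev(row)
    row
  }, numeric(nb)))
}

# bare numeric matrix from a profile_matrix (drop class and meta attributes)
strip_pm <- function(m) matrix(as.vector(unclass(m)), nrow = nrow(m))
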