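test_that("IUPAC scanning finds degenerate matches on both strands", {
  core <- motif("core", "TAACNGT")
  h <- iupac_scan("GGTAACAGTGG", core)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 2L)
  expect_equal(h$strand, "+")
  expect_equal(h$matched, "TAACAGT")
  # reverse-complement instance is found as a minus-strand hit
  h2 <- iupac_scan("CCACAGTTACC", core)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  # N in the sequence matches nothing
  expect_equal(nrow(iupac_scan("NNNNNNN", core)), 0)
  expect_equal(nrow(iupac_scan("TAACNGT", core)), 0)
  expect_error(motif("bad", "TAACXGT"), "invalid IUPAC")
})

test_that("IUPAC hits are invariant under reverse-complementing the sequence", {
  set.seed(8)
  m <- motif("ovo", "TAACNGT")
  for (k in 1:10) {
    s <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    s <- paste0(s, "TAACGGT", s)  # guarantee at least one instance
    h_f <- iupac_scan(s, m)
    h_r <- iupac_scan(revcomp(s), m)
    expect_equal(nrow(h_f), nrow(h_r))
    # coordinates map via start' = L - end
    expect_equal(sort(nchar(s) - h_r$end), sort(h_f$start))
  }
})

test_that("IUPAC scanner agrees with Biostrings degenerate matching", {
  set.seed(19)
  m <- motif("m2", "RWMTAACGGV")
  s <- paste0(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  s <- paste0(s, "AATTAACGGA", s)
  ours <- iupac_scan(s, m, both_strands = FALSE)
  ref <- Biostrings::matchPattern(m$consensus, Biostrings::DNAString(s),
                                  fixed = "subject")
  expect_equal(ours$start, Biostrings::start(ref) - 1L)
})

test_that("exact-match PWM p-values reproduce the closed forms", {
  pwm4 <- consensus_to_pwm("ACGT")
  m4 <- motif("m4", "ACGT", pwm = pwm4)
  # best word probability 4^-4 ~ 0.0039 > 0.003: unattainable
  expect_warning(t4 <- pwm_threshold_from_pvalue(m4, 0.003), "best attainable")
  expect_false(t4$attained)
  expect_equal(t4$p_at_threshold, 4^-4, tolerance = 1e-12)

  pwm5 <- consensus_to_pwm("ACGTA")
  m5 <- motif("m5", "ACGTA", pwm = pwm5)
  t5 <- pwm_threshold_from_pvalue(m5, 0.003)
  expect_true(t5$attained)
  expect_equal(t5$p_at_threshold, 4^-5, tolerance = 1e-12)
  expect_lte(t5$p_at_threshold, 0.003)
})

test_that("score-distribution DP equals exhaustive word enumeration", {
  for (cfg in list(list(L = 4, seed = 1), list(L = 6, seed = 2),
                   list(L = 8, seed = 3))) {
    pwm <- random_pwm(cfg$L, cfg$seed)
    m <- motif("r", pwm = pwm)
    th <- pwm_threshold_from_pvalue(m, 0.01)
    # rebuild the tail from all 4^L words on the same grid
    bg <- m$background
    s <- log2(pwm / bg)
    fin_min <- apply(s, 2, function(col) min(col[is.finite(col)]))
    enum <- pwm_tail_enum(pwm, bg, th$delta, fin_min)
    expect_equal(sum(th$grid$prob), sum(enum$prob), tolerance = 1e-12)
    for (q in stats::quantile(th$grid$score, c(0.1, 0.5, 0.9, 0.99))) {
      k_cut <- (q - sum(fin_min)) / th$delta
      expect_equal(sum(th$grid$prob[th$grid$score >= q - 1e-9]),
                   sum(enum$prob[enum$k >= k_cut - 1e-9]), tolerance = 1e-12)
    }
  }
  # degenerate-consensus PWM: distribution mass + excluded -Inf mass is 1
  th <- pwm_threshold_from_pvalue(motif("one", "TAACGGTAAA"), 0.0002)
  expect_lte(sum(th$grid$prob), 1 + 1e-9)
})

test_that("pwm_scan matches naive window scoring and the IUPAC scanner", {
  set.seed(23)
  pwm <- random_pwm(5, 11)
  m <- motif("r5", pwm = pwm)
  s <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  hits <- pwm_scan(s, m, alpha = 0.01, both_strands = FALSE)
  thr <- pwm_threshold_from_pvalue(m, 0.01)$threshold
  naive <- vapply(1:(nchar(s) - 4), function(i) {
    w <- substring(s, i, i + 4)
    sum(log2(pwm[cbind(match(strsplit(w, "")[[1]], c("A", "C", "G", "T")), 1:5)] / 0.25))
  }, numeric(1))
  expect_equal(hits$start, which(naive >= thr - 1e-9) - 1L)
  expect_equal(hits$score, naive[naive >= thr - 1e-9], tolerance = 1e-9)

  # alpha = 1 reports every window
  expect_equal(nrow(pwm_scan(s, m, alpha = 1, both_strands = FALSE)),
               nchar(s) - 4)

  # a probability-1 PWM scans identically to its consensus
  word <- "ACGTT"
  m1 <- motif("w", word, pwm = consensus_to_pwm(word))
  s2 <- paste0("GGGG", word, "GGGG", revcomp(word), "CCCC")
  pw <- pwm_scan(s2, m1, alpha = 0.003)
  iu <- iupac_scan(s2, m1)
  expect_equal(pw[, c("start", "end", "strand")], iu[, c("start", "end", "strand")])
  expect_equal(nrow(pw), 2)
})

test_that("peak motif annotation recovers planted fractions", {
  # 4 peaks, motif planted in 3: any-motif fraction 0.75
  g <- c(chrZ = strrep("ACAC", 300))
  g2 <- promocc:::as_genome(g)
  word <- "TAACGGTAAA"
  s <- as.character(g2[[1]])
  for (pos in c(100, 400, 700)) substr(s, pos, pos + 9) <- word
  g <- c(chrZ = s)
  peaks <- tibble::tibble(chrom = "chrZ", start = c(50L, 350L, 650L, 950L),
                          end = c(250L, 550L, 850L, 1150L))
  ann <- annotate_peak_motifs(peaks, g, ovo_motif_catalog()["motif_one"])
  expect_equal(ann$any_fraction, 0.75)
  expect_equal(ann$fractions$n, 3L)
  expect_error(annotate_peak_motifs(peaks[0, ], g, ovo_motif_catalog()), "empty")
})

test_that("planted-motif recovery on the bundle is within the binomial 99% CI", {
  b <- shared_bundle()
  ann <- annotate_peak_motifs(b$peaks_consensus, b$genome,
                              b$config$motif_catalog)
  n <- nrow(b$peaks_consensus)
  p <- b$truth$motif_planted_fraction
  ci <- p + c(-1, 1) * stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_gte(ann$any_fraction, ci[1])
  # background hits can only push the recovered fraction up
  expect_gte(ann$any_fraction, p - 1e-12)
})

test_that("mask-and-rescan fractions follow set arithmetic on the presence matrix", {
  g <- c(chrZ = strrep("ACAC", 500))
  s <- as.character(promocc:::as_genome(g)[[1]])
  # first half of peaks get motif_one, second half motif_three
  for (pos in c(100, 400)) substr(s, pos, pos + 9) <- "TAACGGTAAA"
  for (pos in c(700, 1000)) substr(s, pos, pos + 9) <- "TAACTGTTTT"
  g <- c(chrZ = s)
  peaks <- tibble::tibble(chrom = "chrZ", start = seq(50L, 950L, 300L),
                          end = seq(250L, 1150L, 300L))
  cat2 <- ovo_motif_catalog()[c("motif_one", "motif_three")]
  mr <- motif_mask_rescan(peaks, g, cat2)
  expect_equal(mr$fraction, c(0.5, 1.0))
  expect_equal(mr$n_peaks_scanned, c(4L, 2L))
  # oracle: conditional fractions recomputed from the presence matrix
  ann <- annotate_peak_motifs(peaks, g, cat2)
  pres <- ann$presence
  expect_equal(mr$fraction[1], mean(pres$motif_one))
  expect_equal(mr$fraction[2], mean(pres$motif_three[!pres$motif_one]))
})

test_that("motif density bins respect point orientation", {
  pts <- tibble::tibble(chrom = "c", pos = 1000L, strand = "+")
  hits <- tibble::tibble(chrom = "c", start = 998L, end = 1002L, strand = "+")
  d <- motif_density_around_points(hits, pts, window = 100, bin = 25)
  expect_equal(d$percent[d$bin_lo == 0], 100)
  expect_equal(sum(d$percent), 100)
  # a hit at +30 of a minus-strand point lands in the -30 bin
  pts_m <- tibble::tibble(chrom = "c", pos = 1000L, strand = "-")
  hits2 <- tibble::tibble(chrom = "c", start = 1028L, end = 1032L, strand = "+")
  d2 <- motif_density_around_points(hits2, pts_m, window = 100, bin = 25)
  expect_equal(d2$percent[d2$bin_lo == -50], 100)  # offset -30 falls in [-50,-25)
  expect_equal(sum(d2$percent), 100)
  # planted offsets near zero put the histogram argmax at the center
  set.seed(12)
  n <- 300
  pts3 <- tibble::tibble(chrom = "c", pos = seq(5000L, by = 4000L, length.out = n),
                         strand = "+")
  off <- as.integer(round(rnorm(n, 0, 10)))
  hits3 <- tibble::tibble(chrom = "c", start = pts3$pos + off - 2L,
                          end = pts3$pos + off + 2L, strand = "+")
  d3 <- motif_density_around_points(hits3, pts3, window = 200, bin = 25)
  expect_true(d3$bin_lo[which.max(d3$percent)] %in% c(-25, 0))
})
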