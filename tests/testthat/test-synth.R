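test_that("generated genomes hit the GC target and are seed-deterministic", {
  g <- generate_genome(1e5, 1, gc = 0.5, seed = 3)
  s <- as.character(g[[1]])
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
  g2 <- generate_genome(1e5, 1, gc = 0.5, seed = 3)
  expect_identical(as.character(g[[1]]), as.character(g2[[1]]))
  expect_error(generate_genome(1e5, 1, gc = 0), "gc")
  expect_error(generate_genome(5e3, 1, gc = 0.5), "10 kb")
})

test_that("gene models never overlap and respect the spacing floor", {
  g <- generate_genome(1e6, 2, 0.43, seed = 4)
  tx <- generate_gene_models(g, 120, seed = 9)
  expect_equal(nrow(tx), 120)
  for (ch in unique(tx$chrom)) {
    t <- dplyr::arrange(tx[tx$chrom == ch, ], start)
    if (nrow(t) > 1) {
      gaps <- t$start[-1] - t$end[-nrow(t)]
      expect_true(all(gaps >= 500))
    }
  }
  expect_error(generate_gene_models(g, 1e4, seed = 1), "too large")
})

test_that("strand assignment is balanced", {
  g <- generate_genome(6e6, 3, 0.43, seed = 5)
  tx <- generate_gene_models(g, 1000, seed = 6)
  bt <- stats::binom.test(sum(tx$strand == "+"), nrow(tx), 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("replicate peaks land on the requested Jaccard", {
  b <- shared_bundle()
  sizes <- setNames(Biostrings::width(b$genome), names(b$genome))
  tx <- b$transcripts
  # identity target
  r1 <- generate_peak_replicates(tx, sizes, 100, target_jaccard = 1, seed = 2)
  expect_equal(r1$realized_jaccard, 1)
  expect_equal(nrow(r1$rep1), nrow(r1$rep2))
  # disjoint target
  r0 <- generate_peak_replicates(tx, sizes, 100, target_jaccard = 0, seed = 2)
  expect_equal(r0$realized_jaccard, 0)
  # the replicate-agreement scenario value
  r <- generate_peak_replicates(tx, sizes, 300, target_jaccard = 0.64, seed = 2)
  expect_gte(r$realized_jaccard, 0.59)
  expect_lte(r$realized_jaccard, 0.69)
})

test_that("motif planting is exhaustive at fraction 1 and centered at sd 0", {
  g <- generate_genome(5e4, 1, 0.43, seed = 10)
  set.seed(1)
  starts <- seq(1000L, 40000L, by = 1500L)
  peaks <- as_intervals(tibble::tibble(chrom = "chr1", start = starts,
                                       end = starts + 400L,
                                       name = sprintf("p%d", seq_along(starts))))
  m <- ovo_motif_catalog()$motif_one
  pl <- plant_motifs(g, peaks, m, plant_fraction = 1, offset_sd = 0, seed = 11)
  ann <- annotate_peak_motifs(peaks, pl$genome, list(m))
  expect_equal(ann$any_fraction, 1)
  # offset 0: every planted instance centered on its summit
  mids <- floor((peaks$start + peaks$end) / 2)
  expect_equal(sort(pl$truth$start), sort(as.integer(mids - 5)))
  expect_true(all(pl$truth$planted))
})

test_that("planted motif fractions are recovered within the binomial 99% CI", {
  g <- generate_genome(1e6, 1, 0.43, seed = 20)
  starts <- seq(1000L, 990000L, length.out = 500)
  starts <- as.integer(starts)
  peaks <- as_intervals(tibble::tibble(chrom = "chr1", start = starts,
                                       end = starts + 300L))
  m <- ovo_motif_catalog()$motif_one
  pl <- plant_motifs(g, peaks, m, plant_fraction = 0.72, offset_sd = 20, seed = 21)
  planted_frac <- sum(pl$truth$planted) / nrow(peaks)
  ann <- annotate_peak_motifs(peaks, pl$genome, list(m))
  ci <- planted_frac + c(-1, 1) * stats::qnorm(0.995) * sqrt(planted_frac * (1 - planted_frac) / 500)
  expect_gte(ann$any_fraction, ci[1])
  expect_lte(ann$any_fraction, ci[2] + 0.02)  # background hits only add
})

test_that("CAGE tag generation matches its Poisson/Gaussian model", {
  b <- shared_bundle()
  tx <- b$transcripts
  tags0 <- generate_cage_tags(tx, 20, spread_sd = 0, seed = 31)
  tss <- transcript_tss(tx)
  expect_true(all(paste(tags0$chrom, tags0$pos) %in% paste(tss$chrom, tss$pos)))
  # totals within 3 Poisson SDs of n_genes * tags_per_gene
  lambda <- nrow(tx) * 20
  expect_lt(abs(sum(tags0$count) - lambda), 3 * sqrt(lambda))
  # determinism
  tags0b <- generate_cage_tags(tx, 20, spread_sd = 0, seed = 31)
  expect_identical(tags0, tags0b)
})

test_that("coverage tracks put the enrichment apex on the summit", {
  sizes <- c(chr1 = 50000L)
  peak <- tibble::tibble(chrom = "chr1", start = 20000L, end = 20400L)
  cov <- generate_coverage_tracks(peak, sizes, enrichment = 5, noise_sd = 0,
                                  bin_size = 5, seed = 41)
  diffv <- cov$chip$values$chr1 - cov$input$values$chr1
  apex_bin <- which.max(diffv)
  summit_bin <- (20200 %/% 5) + 1
  # the summit sits on a bin boundary: apex is one of the two flanking bins
  expect_lte(abs(apex_bin - summit_bin), 1)
  # subtracted signal vanishes away from the peak
  sub <- subtract_tracks(bpm_normalize(cov$chip), bpm_normalize(cov$input))
  far <- sub$values$chr1[1:2000]   # first 10 kb, far from the peak
  expect_lt(mean(abs(far)), 3 * 0.1 * max(abs(sub$values$chr1)))
})

test_that("a planted odds ratio of 1 is recovered as a near-null mean", {
  genes <- sprintf("g%04d", 1:800)
  bound <- genes[1:300]
  ors <- vapply(1:200, function(k) {
    sim <- generate_de_and_lists(genes, bound, planted_or = 1, seed = 5000 + k)
    tr <- sim$truth
    (sum(tr$bound & tr$up) * sum(!tr$bound & !tr$up)) /
      (sum(tr$bound & !tr$up) * sum(!tr$bound & tr$up))
  }, numeric(1))
  expect_lt(abs(mean(ors) - 1), 0.1)
})

test_that("zero effect size never clears the fold-change threshold", {
  genes <- sprintf("g%04d", 1:500)
  sim <- generate_de_and_lists(genes, genes[1:100], effect_log2fc = 0, seed = 77)
  cls <- apply_de_thresholds(sim$de)
  expect_equal(sum(cls$de_class != "ns"), 0)
})

test_that("an infeasible odds ratio errors instead of silently drifting", {
  genes <- sprintf("g%03d", 1:100)
  expect_error(
    generate_de_and_lists(genes, genes[1:50], planted_or = 2, seed = 1,
                          frac_up = 1.2),
    "infeasible")
})

test_that("scenario bundles are byte-identical under one config", {
  cfg <- scenario_config(seed = 5150)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_scenario(cfg, dir = d1)
  simulate_scenario(cfg, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # truth round-trips through serialization
  tr <- yaml::read_yaml(file.path(d1, "truth.yaml"))
  expect_equal(tr$realized_jaccard,
               jaccard(read_intervals(file.path(d1, "peaks_rep1.bed")),
                       read_intervals(file.path(d1, "peaks_rep2.bed")))$jaccard,
               tolerance = 1e-9)
})
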