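iv <- function(...) {
  v <- c(...)
  if (!length(v)) return(tibble::tibble(chrom = character(), start = integer(),
                                        end = integer()))
  m <- matrix(v, ncol = 2, byrow = TRUE)
  tibble::tibble(chrom = "c", start = m[, 1], end = m[, 2])
}

test_that("merge_intervals merges overlaps and bookended neighbours", {
  expect_equal(merge_intervals(iv(0, 10, 5, 15))[, 1:3], iv(0, 15))
  expect_equal(merge_intervals(iv(0, 10, 10, 20))[, 1:3], iv(0, 20))
  expect_equal(merge_intervals(iv(0, 10, 20, 30))[, 1:3], iv(0, 10, 20, 30))
})

test_that("jaccard is bp-exact, symmetric and degenerate-safe", {
  j <- jaccard(iv(0, 100), iv(50, 150))
  expect_equal(j$intersection_bp, 50)
  expect_equal(j$union_bp, 150)
  expect_equal(j$jaccard, 1 / 3, tolerance = 1e-12)
  a <- iv(0, 100, 200, 250)
  expect_equal(jaccard(a, a)$jaccard, 1)
  d <- jaccard(iv(0, 10), iv(20, 30))
  expect_equal(d$jaccard, 0)
  expect_equal(d$n_overlapping_pairs, 0)
  # symmetry of the bp statistic
  b <- iv(5, 40, 90, 220)
  expect_equal(jaccard(a, b)$jaccard, jaccard(b, a)$jaccard)
  expect_error(jaccard(iv(), iv()), "empty")
})

test_that("adding an interval overlapping b never decreases the intersection", {
  set.seed(33)
  b <- tibble::tibble(chrom = "c", start = seq(0, 900, 100), end = seq(40, 940, 100))
  a <- tibble::tibble(chrom = "c", start = c(10, 300), end = c(30, 350))
  base <- jaccard(a, b)$intersection_bp
  for (k in 1:10) {
    s <- sample(seq(0, 900, 100), 1)
    a2 <- dplyr::bind_rows(a, tibble::tibble(chrom = "c", start = s, end = s + 20))
    expect_gte(jaccard(a2, b)$intersection_bp, base)
  }
})

test_that("relative distance follows the flanking-reference formula", {
  refs <- tibble::tibble(chrom = "c", pos = c(0, 100))
  q <- function(mid) tibble::tibble(chrom = "c", start = mid, end = mid + 1)
  expect_equal(relative_distance(q(25), refs)$values, 0.25)
  expect_equal(relative_distance(q(50), refs)$values, 0.5)
  expect_equal(relative_distance(q(0), refs)$values, 0)
  # outside-flank queries are dropped and counted
  r <- relative_distance(q(150), refs)
  expect_equal(length(r$values), 0)
  expect_equal(r$n_dropped, 1)
  expect_error(relative_distance(q(10), tibble::tibble(chrom = "c", pos = 5)),
               "fewer than 2")
})

test_that("relative distance is flat under the null and affine-invariant", {
  set.seed(91)
  rng <- replicate(3, {
    refs <- tibble::tibble(chrom = "c", pos = sort(sample(0:1e6, 1e3)))
    mids <- sort(sample(0:1e6, 1e4))
    r <- relative_distance(tibble::tibble(chrom = "c", start = mids,
                                          end = mids + 1), refs)
    max(r$histogram$frequency) - min(r$histogram$frequency)
  })
  expect_lt(stats::median(rng), 0.01)
  refs <- tibble::tibble(chrom = "c", pos = sort(sample(0:1e6, 1e3)))
  mids <- sort(sample(0:1e6, 1e4))
  queries <- tibble::tibble(chrom = "c", start = mids, end = mids + 1)
  r <- relative_distance(queries, refs)
  # affine rescale of every coordinate leaves the values unchanged
  r2 <- relative_distance(
    tibble::tibble(chrom = "c", start = mids * 3 + 7, end = mids * 3 + 8),
    tibble::tibble(chrom = "c", pos = refs$pos * 3 + 7)
  )
  expect_equal(r2$values, r$values, tolerance = 1e-12)
})

test_that("peaks are classified TSS > gene_body > intergenic with closest gene", {
  tx <- toy_transcripts()
  peaks <- tibble::tibble(
    chrom = c("chrA", "chrA", "chrA"),
    start = c(90L, 200L, 4000L), end = c(110L, 250L, 4100L),
    name = c("at_tss", "in_body", "far")
  )
  cl <- classify_peaks(peaks, tx)
  expect_equal(as.character(cl$peaks$label), c("TSS", "gene_body", "intergenic"))
  expect_equal(sum(cl$summary$n), nrow(peaks))
  expect_equal(sum(cl$summary$fraction), 1)
  # intergenic peak still assigned to its nearest TSS (gB TSS at 3199)
  expect_equal(cl$peaks$gene_id[3], "gB")
})

test_that("closest_tss reports signed distance with lexicographic ties", {
  tx <- tibble::tibble(
    gene_id = c("gx", "ga"), transcript_id = c("t1", "t2"),
    chrom = "c", start = c(100L, 210L), end = c(150L, 260L), strand = "+",
    exon_starts = list(100L, 210L), exon_ends = list(150L, 260L),
    cds_start = NA_integer_, cds_end = NA_integer_
  )
  peak <- tibble::tibble(chrom = "c", start = 145L, end = 155L)  # midpoint 150
  ct <- closest_tss(peak, tx)
  expect_equal(ct$gene_id, "gx")
  expect_equal(ct$distance, -50L)
  # equidistant: TSSs at 100 and 200, midpoint 150 -> smaller gene_id wins
  tx$start <- c(100L, 200L); tx$end <- c(150L, 260L)
  expect_equal(closest_tss(peak, tx)$gene_id, "ga")
  expect_error(closest_tss(tibble::tibble(chrom = "nope", start = 0, end = 10), tx),
               "no transcript")
})

test_that("overlap_fisher builds the slot table with the Inf convention", {
  five <- tibble::tibble(chrom = "c", start = seq(0, 400, 100), end = seq(10, 410, 100))
  ft <- overlap_fisher(five, five, genome_size = 1000)
  expect_equal(c(ft$n11, ft$n12, ft$n21), c(5, 0, 0))
  expect_identical(ft$odds_ratio, Inf)
  disj <- dplyr::mutate(five, start = start + 50, end = end + 60)
  ft0 <- overlap_fisher(five, disj, genome_size = 1e4)
  expect_equal(ft0$n11, 0)
  expect_equal(ft0$odds_ratio, 0)
  expect_error(overlap_fisher(five, five, genome_size = 0), "positive")
})

test_that("overlap_fisher is calibrated near OR 1 for independent sets", {
  set.seed(77)
  ors <- replicate(100, {
    mk <- function() {
      s <- sample(0:999800, 200)
      tibble::tibble(chrom = "c", start = s, end = s + 200)
    }
    overlap_fisher(mk(), mk(), genome_size = 1e6)$odds_ratio
  })
  expect_gte(stats::median(ors), 0.5)
  expect_lte(stats::median(ors), 2)
})

test_that("fisher_exact reports the sample odds ratio of printed tables", {
  ft <- fisher_exact(666, 1632, 1328, 7178)
  expect_equal(ft$odds_ratio, 2.21, tolerance = 0.005)
  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_two_sided, 1)
  expect_warning(z <- fisher_exact(0, 0, 3, 4), "margin")
  expect_true(is.nan(z$odds_ratio))
  expect_equal(z$p_two_sided, 1)
  expect_equal(tidy(ft)$p.value, ft$p_two_sided)
})

test_that("fisher_exact p matches exhaustive enumeration for all totals <= 30", {
  set.seed(5)
  combos <- expand.grid(n11 = 0:6, n12 = 0:6, n21 = 0:6, n22 = 0:6)
  combos <- combos[rowSums(combos) <= 30 & rowSums(combos) > 0, ]
  combos <- combos[apply(combos, 1, function(r) {
    all(c(r[1] + r[2], r[3] + r[4], r[1] + r[3], r[2] + r[4]) > 0)
  }), ]
  for (i in seq_len(nrow(combos))) {
    r <- as.integer(combos[i, ])
    got <- suppressWarnings(fisher_exact(r[1], r[2], r[3], r[4]))$p_two_sided
    expect_equal(got, fisher_p_enum(r[1], r[2], r[3], r[4]), tolerance = 1e-10,
                 info = paste(r, collapse = ","))
  }
})

test_that("estimated Jaccard on a synthetic bundle equals recorded truth exactly", {
  b <- shared_bundle()
  j <- jaccard(b$peaks_rep1, b$peaks_rep2)
  expect_equal(j$jaccard, b$truth$realized_jaccard, tolerance = 1e-9)
})
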