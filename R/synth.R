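#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulated study: genome composition, gene
#' models, replicate ChIP peaks with a target base-pair Jaccard, planted
#' motif instances, CAGE tag signal, enrichment-shaped coverage, and a DE
#' table with a planted bound-by-upregulated odds ratio. The defaults are
#' the package's standing study conditions: replicate agreement 0.64,
#' 45% of peaks at TSSs, 72% of peaks carrying a motif, and a
#' bound-by-up odds ratio of 2.21, at desk scale (1 Mb genome, 150 genes,
#' 300 peaks).
#'
#' @param genome_length Total genome length in bp (split evenly over
#'   chromosomes).
#' @param n_chroms Number of chromosomes.
#' @param gc_content GC fraction in (0, 1).
#' @param n_genes Number of gene models.
#' @param peak_width_mean Mean peak width in bp.
#' @param n_peaks Peaks per replicate.
#' @param target_jaccard Target bp Jaccard between the two replicates.
#' @param frac_peaks_at_tss Fraction of replicate-1 peaks centered on a
#'   TSS.
#' @param motif_catalog List of [motif()] objects to plant and scan.
#' @param motif_plant_fraction Fraction of consensus peaks receiving a
#'   planted motif instance.
#' @param motif_offset_sd SD (bp) of the planted instance offset from the
#'   peak summit.
#' @param cage_tags_per_gene Poisson mean tag count per gene.
#' @param cage_spread_sd SD (bp) of tag positions around the TSS.
#' @param de_effect_log2fc Mean |log2 fold change| of DE genes.
#' @param planted_bound_up_or Target sample odds ratio of bound x up.
#' @param coverage_enrichment Peak height of the ChIP enrichment bump.
#' @param coverage_noise_sd SD of the input-track noise.
#' @param coverage_bin_size Coverage bin size in bp.
#' @param seed Master seed; every stage derives a stable sub-seed from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(genome_length = 1e6, n_chroms = 2,
                            gc_content = 0.43, n_genes = 150,
                            peak_width_mean = 400, n_peaks = 300,
                            target_jaccard = 0.64, frac_peaks_at_tss = 0.45,
                            motif_catalog = ovo_motif_catalog(),
                            motif_plant_fraction = 0.72, motif_offset_sd = 30,
                            cage_tags_per_gene = 50, cage_spread_sd = 2,
                            de_effect_log2fc = 1.5, planted_bound_up_or = 2.21,
                            coverage_enrichment = 5, coverage_noise_sd = 0.1,
                            coverage_bin_size = 5, seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(gc_content = gc_content, target_jaccard = target_jaccard,
             frac_peaks_at_tss = frac_peaks_at_tss,
             motif_plant_fraction = motif_plant_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (gc_content <= 0 || gc_content >= 1) abort("gc_content must be in (0, 1)")
  if (planted_bound_up_or <= 0) abort("planted_bound_up_or must be positive")
  structure(cfg, class = "scenario_config")
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`; deterministic under `seed`.
#'
#' @param length Total length in bp.
#' @param n_chroms Number of chromosomes (each at least 10 kb).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return A named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(length, n_chroms = 1, gc = 0.43, seed = 1) {
  if (gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  per <- floor(length / n_chroms)
  if (per < 1e4) abort("need at least 10 kb per chromosome")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste0(sample(names(p), per, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_chroms))))
}

#' Generate non-overlapping gene models
#'
#' Places `n_genes` transcripts with random strand, 1-4 exons and at least
#' 500 bp intergenic spacing; gene lengths are uniform on 1-3 kb and a CDS
#' covering the central half of the span is attached.
#'
#' @param genome `DNAStringSet` (or named lengths are taken from it).
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param min_spacing Minimum intergenic gap in bp.
#' @return Transcript tibble (one transcript per gene).
#' @export
generate_gene_models <- function(genome, n_genes, seed = 1, min_spacing = 500) {
  sizes <- genome_sizes_of(genome)
  set.seed(seed)
  lens <- sample(1000:3000, n_genes, replace = TRUE)
  # feasibility: mean need per gene incl. spacing, spread over chroms
  if (sum(lens + min_spacing) > 0.9 * sum(sizes)) {
    abort("n_genes too large for this genome")
  }
  chrom_of <- sample(names(sizes), n_genes, replace = TRUE, prob = sizes / sum(sizes))
  rows <- list()
  g <- 0L
  for (ch in names(sizes)) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    need <- sum(lens[idx] + min_spacing)
    free <- sizes[[ch]] - need - min_spacing
    if (free < 0) abort("n_genes too large for this genome")
    # random gaps summing to <= free, then lay genes end to end
    gaps <- floor(free * diff(sort(c(0, runif(length(idx)), 1))))[seq_along(idx)]
    pos <- min_spacing
    for (k in seq_along(idx)) {
      i <- idx[k]
      start <- pos + gaps[k]
      end <- start + lens[i]
      pos <- end + min_spacing
      g <- g + 1L
      n_ex <- sample(1:4, 1)
      if (n_ex == 1L) {
        es <- as.integer(start); ee <- as.integer(end)
      } else {
        bounds <- sort(sample(seq(start + 50L, end - 50L), 2L * (n_ex - 1L)))
        es <- as.integer(c(start, bounds[seq(2, length(bounds), by = 2)]))
        ee <- as.integer(c(bounds[seq(1, length(bounds), by = 2)], end))
      }
      span <- end - start
      rows[[g]] <- tibble(
        gene_id = sprintf("gene_%04d", g),
        transcript_id = sprintf("tx_%04d", g),
        chrom = ch, start = as.integer(start), end = as.integer(end),
        strand = sample(c("+", "-"), 1),
        exon_starts = list(es), exon_ends = list(ee),
        cds_start = as.integer(start + floor(span / 4)),
        cds_end = as.integer(end - floor(span / 4))
      )
    }
  }
  validate_transcripts(bind_rows(rows))
}

#' Generate two replicate peak sets with a target bp Jaccard
#'
#' Replicate 1 places `frac_at_tss` of its peaks centered on randomly
#' chosen TSSs (with a small jitter) and the rest uniformly. Replicate 2
#' retains a computed fraction `k = 2J / (1 + J)` of replicate-1 peaks
#' (whole intervals) and adds independent non-overlapping peaks so the
#' realized base-pair Jaccard lands within about 0.05 of `target_jaccard`;
#' the realized value is returned and should be used as truth downstream.
#'
#' @param tx Transcript tibble supplying TSSs.
#' @param genome_sizes Named chromosome lengths.
#' @param n_peaks Peaks per replicate.
#' @param width Mean peak width (widths are jittered around it).
#' @param frac_at_tss Fraction of rep-1 peaks at TSSs.
#' @param target_jaccard Target bp Jaccard in [0, 1].
#' @param seed RNG seed.
#' @return List: `rep1`, `rep2` (interval tibbles), `realized_jaccard`,
#'   `shared_names` (rep-1 peaks retained in rep 2).
#' @export
generate_peak_replicates <- function(tx, genome_sizes, n_peaks, width = 400,
                                     frac_at_tss = 0.45, target_jaccard = 0.64,
                                     seed = 1) {
  stopifnot(target_jaccard >= 0, target_jaccard <= 1)
  set.seed(seed)
  tss <- transcript_tss(tx)
  widths <- pmax(100L, as.integer(round(rnorm(n_peaks, width, width / 6))))
  n_tss <- round(frac_at_tss * n_peaks)
  pick <- sample(seq_len(nrow(tss)), n_tss, replace = n_tss > nrow(tss))
  centers_tss <- tibble(chrom = tss$chrom[pick],
                        center = tss$pos[pick] + sample(-50:50, n_tss, replace = TRUE))
  n_rand <- n_peaks - n_tss
  ch_rand <- sample(names(genome_sizes), n_rand, replace = TRUE,
                    prob = genome_sizes / sum(genome_sizes))
  centers_rand <- tibble(chrom = ch_rand,
                         center = vapply(ch_rand, function(ch) {
                           sample(seq(width, genome_sizes[[ch]] - width), 1)
                         }, numeric(1)))
  centers <- bind_rows(centers_tss, centers_rand)
  rep1 <- tibble(
    chrom = centers$chrom,
    start = pmax(0L, as.integer(centers$center - widths %/% 2)),
    end = as.integer(centers$center + widths %/% 2),
    name = sprintf("peak_%04d", seq_len(n_peaks)),
    score = round(runif(n_peaks, 50, 1000), 1), strand = "."
  ) |>
    mutate(end = pmin(.data$end, genome_sizes[.data$chrom])) |>
    as_intervals()
  # deduplicate accidental overlaps within rep1 so whole-interval retention
  # maps cleanly onto bp
  k <- if (target_jaccard == 1) 1 else 2 * target_jaccard / (1 + target_jaccard)
  n_keep <- round(k * n_peaks)
  keep <- sort(sample(seq_len(n_peaks), n_keep))
  add_n <- n_peaks - n_keep
  rep1_gr <- gr_from_intervals(rep1)
  new_rows <- list(); tries <- 0L
  while (length(new_rows) < add_n && tries < add_n * 200L) {
    tries <- tries + 1L
    ch <- sample(names(genome_sizes), 1, prob = genome_sizes / sum(genome_sizes))
    w <- pmax(100L, as.integer(round(rnorm(1, width, width / 6))))
    c0 <- sample(seq(w, genome_sizes[[ch]] - w), 1)
    cand <- tibble(chrom = ch, start = as.integer(c0 - w %/% 2),
                   end = as.integer(c0 + w %/% 2))
    gr <- gr_from_intervals(cand)
    if (!length(GenomicRanges::findOverlaps(gr, rep1_gr))) {
      new_rows[[length(new_rows) + 1L]] <- cand
    }
  }
  if (length(new_rows) < add_n) abort("could not place independent rep-2 peaks")
  rep2 <- bind_rows(
    rep1[keep, , drop = FALSE],
    if (add_n) bind_rows(new_rows) |>
      mutate(name = sprintf("peak2_%04d", row_number()),
             score = round(runif(add_n, 50, 1000), 1), strand = ".")
  ) |>
    arrange(.data$chrom, .data$start) |>
    as_intervals()
  realized <- if (nrow(rep2)) jaccard(rep1, rep2)$jaccard else 0
  if (target_jaccard == 1 && !isTRUE(all.equal(realized, 1))) {
    abort("infeasible target Jaccard")
  }
  list(rep1 = rep1, rep2 = rep2, realized_jaccard = realized,
       shared_names = rep1$name[keep])
}

#' Plant motif instances into a genome near peak summits
#'
#' In a `plant_fraction` share of peaks, writes one concrete instance of
#' the motif consensus (degenerate positions drawn uniformly from their
#' class) at `summit + round(Normal(0, offset_sd))` on a random strand.
#' Instances that would run off the contig are skipped with a warning and
#' flagged in the returned truth.
#'
#' @param genome `DNAStringSet`.
#' @param peaks Interval tibble (summit = interval midpoint).
#' @param m A [motif()] with a consensus.
#' @param plant_fraction Fraction of peaks edited.
#' @param offset_sd SD (bp) of the summit offset.
#' @param seed RNG seed.
#' @return List: `genome` (edited), `truth` (tibble of peak, chrom, start,
#'   strand, word, planted).
#' @export
plant_motifs <- function(genome, peaks, m, plant_fraction = 0.72,
                         offset_sd = 30, seed = 1) {
  p <- as_intervals(peaks)
  set.seed(seed)
  n_plant <- round(plant_fraction * nrow(p))
  chosen <- sort(sample(seq_len(nrow(p)), n_plant))
  cons <- strsplit(m$consensus, "", fixed = TRUE)[[1]]
  L <- length(cons)
  classes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sizes <- genome_sizes_of(genome)
  seqs <- as.character(genome)
  truth <- list(); skipped <- 0L
  mids <- interval_midpoint(p)
  ids <- ifelse(is.na(p$name), sprintf("peak_%d", seq_len(nrow(p))), p$name)
  for (i in chosen) {
    word <- paste0(vapply(cons, function(c) sample(classes[[c]], 1), character(1)),
                   collapse = "")
    strand <- sample(c("+", "-"), 1)
    inst <- if (strand == "-") revcomp(word) else word
    pos <- mids[i] + as.integer(round(rnorm(1, 0, offset_sd))) - L %/% 2L
    ch <- p$chrom[i]
    if (pos < 0 || pos + L > sizes[[ch]]) {
      skipped <- skipped + 1L
      truth[[length(truth) + 1L]] <- tibble(
        peak = ids[i], chrom = ch, start = NA_integer_, strand = strand,
        word = word, planted = FALSE)
      next
    }
    substr(seqs[[ch]], pos + 1L, pos + L) <- inst
    truth[[length(truth) + 1L]] <- tibble(
      peak = ids[i], chrom = ch, start = as.integer(pos), strand = strand,
      word = word, planted = TRUE)
  }
  if (skipped) warn(sprintf("%d motif instance(s) would exceed a contig; skipped", skipped))
  list(genome = Biostrings::DNAStringSet(seqs), truth = bind_rows(truth))
}

#' Generate CAGE tags around gene TSSs
#'
#' Per gene, `Poisson(tags_per_gene)` tags at
#' `round(Normal(tss, spread_sd))` on the gene strand, aggregated per
#' (chrom, position, strand).
#'
#' @param tx Transcript tibble.
#' @param tags_per_gene Poisson mean per gene.
#' @param spread_sd SD of tag positions in bp (0 puts every tag exactly at
#'   the TSS).
#' @param seed RNG seed.
#' @return Tag tibble (`chrom`, `pos`, `strand`, `count`).
#' @export
generate_cage_tags <- function(tx, tags_per_gene = 50, spread_sd = 2, seed = 1) {
  stopifnot(spread_sd >= 0)
  set.seed(seed)
  tss <- transcript_tss(tx)
  rows <- purrr::map_dfr(seq_len(nrow(tss)), function(i) {
    n <- rpois(1, tags_per_gene)
    if (!n) return(tibble())
    pos <- as.integer(round(rnorm(n, tss$pos[i], spread_sd)))
    tibble(chrom = tss$chrom[i], pos = pos, strand = tss$strand[i])
  })
  rows |>
    count(.data$chrom, .data$pos, .data$strand, name = "count") |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Generate enrichment-shaped ChIP and input coverage tracks
#'
#' The input track is `|Normal(1, noise_sd)|` per bin; the ChIP track adds
#' a triangular enrichment bump of height `enrichment` centered on each
#' peak summit with half-width half the peak width.
#'
#' @param peaks Interval tibble.
#' @param genome_sizes Named chromosome lengths.
#' @param enrichment Bump height (> 0).
#' @param noise_sd Input noise SD.
#' @param bin_size Bin width in bp.
#' @param seed RNG seed.
#' @return List of `chip` and `input` [coverage_track()]s.
#' @export
generate_coverage_tracks <- function(peaks, genome_sizes, enrichment = 5,
                                     noise_sd = 0.1, bin_size = 5, seed = 1) {
  stopifnot(enrichment > 0)
  p <- as_intervals(peaks)
  set.seed(seed)
  input <- lapply(names(genome_sizes), function(ch) {
    abs(rnorm(ceiling(genome_sizes[[ch]] / bin_size), 1, noise_sd))
  })
  names(input) <- names(genome_sizes)
  chip <- input
  mids <- interval_midpoint(p)
  half <- pmax(1L, (p$end - p$start) %/% 2L)
  for (i in seq_len(nrow(p))) {
    ch <- p$chrom[i]
    nb <- length(chip[[ch]])
    centers <- (seq_len(nb) - 0.5) * bin_size
    d <- abs(centers - mids[i])
    bump <- pmax(0, 1 - d / half[i]) * enrichment
    chip[[ch]] <- chip[[ch]] + bump
  }
  list(chip = coverage_track(chip, bin_size, "raw", genome_sizes),
       input = coverage_track(input, bin_size, "raw", genome_sizes))
}

#' Generate a DE table and reference gene list with planted odds ratios
#'
#' Assigns up/down status so that the expected sample odds ratio of
#' (bound x up) equals `planted_or`: the up-probabilities for bound and
#' unbound genes are solved jointly (by `uniroot`) to satisfy the odds
#' ratio and the overall expected up fraction. Down status is assigned
#' among remaining genes independently of binding. `log2fc` is drawn as
#' `Normal(+-effect, 0.2)` for DE genes and `Normal(0, 0.2)` otherwise;
#' `padj` below 0.05 for DE genes and above for the rest. The reference
#' ("embryo") list is sampled to enrich among up genes with its own odds
#' ratio by the same construction.
#'
#' @param genes Character vector: the expressed-gene universe.
#' @param bound_genes Character vector: genes bound by the factor.
#' @param effect_log2fc Mean absolute log2 fold change of DE genes.
#' @param planted_or Target sample OR of bound x up (> 0).
#' @param seed RNG seed.
#' @param frac_up,frac_down Expected DE fractions of the universe.
#' @param reference_or Target OR of up x reference list.
#' @param frac_reference Expected fraction of the universe on the list.
#' @return List: `de` (DE tibble), `reference_list`, `truth` (tibble of
#'   gene_id, bound, up, down, in_reference).
#' @export
generate_de_and_lists <- function(genes, bound_genes, effect_log2fc = 1.5,
                                  planted_or = 2.21, seed = 1,
                                  frac_up = 1994 / 10804,
                                  frac_down = 2924 / 10804,
                                  reference_or = 2.8,
                                  frac_reference = 5482 / 10804) {
  stopifnot(planted_or > 0)
  set.seed(seed)
  n <- length(genes)
  bound <- genes %in% bound_genes
  up <- draw_with_or(bound, planted_or, frac_up)
  # down among the non-up remainder, independent of binding
  down <- rep(FALSE, n)
  pool <- which(!up)
  n_down <- min(length(pool), round(frac_down * n))
  down[sample(pool, n_down)] <- TRUE
  in_ref <- draw_with_or(up, reference_or, frac_reference)
  lfc <- rnorm(n, 0, 0.2)
  lfc[up] <- rnorm(sum(up), effect_log2fc, 0.2)
  lfc[down] <- rnorm(sum(down), -effect_log2fc, 0.2)
  padj <- runif(n, 0.06, 1)
  padj[up | down] <- runif(sum(up | down), 1e-8, 0.049)
  # an effect of zero must not clear the |log2fc| > 0.5 threshold
  if (effect_log2fc == 0) lfc[up | down] <- pmin(pmax(lfc[up | down], -0.5), 0.5)
  de <- tibble(gene_id = genes, base_mean = exp(rnorm(n, 5, 1)),
               log2fc = lfc, padj = padj)
  list(de = de, reference_list = genes[in_ref],
       truth = tibble(gene_id = genes, bound = bound, up = up, down = down,
                      in_reference = in_ref))
}

# Bernoulli draws of a trait over exposed/unexposed groups such that the
# expected 2x2 sample OR is `or` and the expected trait prevalence `prev`.
draw_with_or <- function(exposed, or, prev) {
  n <- length(exposed); n1 <- sum(exposed); n0 <- n - n1
  if (n1 == 0 || n0 == 0) {
    return(runif(n) < prev)
  }
  f <- function(p0) {
    odds0 <- p0 / (1 - p0)
    p1 <- or * odds0 / (1 + or * odds0)
    n1 * p1 + n0 * p0 - prev * n
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  if (f(lo) > 0 || f(hi) < 0) abort("requested odds ratio infeasible for these marginals")
  p0 <- uniroot(f, c(lo, hi))$root
  odds0 <- p0 / (1 - p0)
  p1 <- or * odds0 / (1 + or * odds0)
  runif(n) < ifelse(exposed, p1, p0)
}

#' Simulate a complete scenario bundle
#'
#' Runs every generator in a fixed order with stable sub-seeds derived
#' from the master seed, returning (and optionally writing) a bundle:
#' genome, gene models, two peak replicates plus their consensus
#' (replicate-1 peaks overlapping replicate 2), ChIP/input coverage, CAGE
#' tags, DE table, reference gene list, and a `truth` record of every
#' realized planted quantity.
#'
#' @param config A [scenario_config()].
#' @param dir Optional directory; when given, all bundle files are written
#'   there (genome.fa, genes.gtf, peaks_rep1.bed, peaks_rep2.bed,
#'   peaks_consensus.bed, chip.bedgraph, input.bedgraph, cage.tsv, de.tsv,
#'   embryo_genes.txt, truth.yaml).
#' @return A `scenario_bundle` list with all components and `truth`.
#' @export
simulate_scenario <- function(config = scenario_config(), dir = NULL) {
  genome <- generate_genome(config$genome_length, config$n_chroms,
                            config$gc_content, sub_seed(config$seed, "genome"))
  tx <- generate_gene_models(genome, config$n_genes,
                             sub_seed(config$seed, "genes"))
  sizes <- genome_sizes_of(genome)
  reps <- generate_peak_replicates(tx, sizes, config$n_peaks,
                                   config$peak_width_mean,
                                   config$frac_peaks_at_tss,
                                   config$target_jaccard,
                                   sub_seed(config$seed, "peaks"))
  gr1 <- gr_from_intervals(reps$rep1); gr2 <- gr_from_intervals(reps$rep2)
  consensus <- reps$rep1[GenomicRanges::countOverlaps(gr1, gr2) > 0, , drop = FALSE]
  planted <- plant_motifs(genome, consensus, config$motif_catalog[[1]],
                          config$motif_plant_fraction, config$motif_offset_sd,
                          sub_seed(config$seed, "motifs"))
  genome <- planted$genome
  cage <- generate_cage_tags(tx, config$cage_tags_per_gene,
                             config$cage_spread_sd,
                             sub_seed(config$seed, "cage"))
  cov <- generate_coverage_tracks(consensus, sizes, config$coverage_enrichment,
                                  config$coverage_noise_sd,
                                  config$coverage_bin_size,
                                  sub_seed(config$seed, "coverage"))
  bound <- gene_binding_status(tx, consensus)
  de <- generate_de_and_lists(tx$gene_id,
                              bound$gene_id[bound$bound_any],
                              config$de_effect_log2fc,
                              config$planted_bound_up_or,
                              sub_seed(config$seed, "de"))
  truth <- list(
    realized_jaccard = reps$realized_jaccard,
    n_peaks = config$n_peaks,
    n_consensus = nrow(consensus),
    motif_planted_fraction = sum(planted$truth$planted) / nrow(consensus),
    planted_bound_up_or = config$planted_bound_up_or,
    planted_motifs = planted$truth,
    de_truth = de$truth
  )
  bundle <- structure(
    list(config = config, genome = genome, transcripts = tx,
         peaks_rep1 = reps$rep1, peaks_rep2 = reps$rep2,
         peaks_consensus = consensus, coverage_chip = cov$chip,
         coverage_input = cov$input, cage_tags = cage, de_table = de$de,
         embryo_genes = de$reference_list, truth = truth),
    class = "scenario_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf(paste0("<scenario_bundle: %d chrom(s), %d genes, %d+%d peaks ",
                     "(consensus %d), realized Jaccard %.3f>\n"),
              length(x$genome), nrow(x$transcripts), nrow(x$peaks_rep1),
              nrow(x$peaks_rep2), nrow(x$peaks_consensus),
              x$truth$realized_jaccard))
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(bundle$genome, fa)
  write_gene_models(bundle$transcripts, file.path(dir, "genes.gtf"))
  write_intervals(bundle$peaks_rep1, file.path(dir, "peaks_rep1.bed"))
  write_intervals(bundle$peaks_rep2, file.path(dir, "peaks_rep2.bed"))
  write_intervals(bundle$peaks_consensus, file.path(dir, "peaks_consensus.bed"))
  write_track(bundle$coverage_chip, file.path(dir, "chip.bedgraph"))
  write_track(bundle$coverage_input, file.path(dir, "input.bedgraph"))
  readr::write_tsv(bundle$cage_tags, file.path(dir, "cage.tsv"), progress = FALSE)
  write_de_table(bundle$de_table, file.path(dir, "de.tsv"))
  writeLines(bundle$embryo_genes, file.path(dir, "embryo_genes.txt"))
  truth <- bundle$truth
  truth$planted_motifs <- as.list(as.data.frame(truth$planted_motifs))
  truth$de_truth <- as.list(as.data.frame(truth$de_truth))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"), precision = 15)
  invisible(dir)
}
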