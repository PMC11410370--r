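#' Read transcript models from GTF/GFF
#'
#' Parses gene annotation via `rtracklayer::import()` and converts the
#' 1-based inclusive GTF coordinates to the internal 0-based half-open
#' convention (`start - 1`, `end`). One row per transcript, with exon
#' coordinates in list-columns and an optional CDS span.
#'
#' The transcription start site of a `+` transcript is `start`; for a `-`
#' transcript it is `end - 1` (the biological 5' base). Use
#' [transcript_tss()] to extract TSS points.
#'
#' @param path GTF or GFF3 file.
#' @return Tibble with columns `gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, list-columns `exon_starts`, `exon_ends`, and
#'   `cds_start`, `cds_end` (NA when no CDS).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  tx_id <- as.character(mc$transcript_id)
  is_tx <- type %in% c("transcript", "mRNA")
  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  if (!any(is_tx) && !any(is_exon)) abort("no transcript or exon features found")

  df <- tibble(
    type = type,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(mc$gene_id),
    transcript_id = tx_id
  )

  ex <- df |>
    filter(.data$type == "exon") |>
    arrange(.data$transcript_id, .data$start)
  cds_rows <- filter(df, .data$type == "CDS")
  cds <- if (nrow(cds_rows)) {
    cds_rows |>
      group_by(.data$transcript_id) |>
      summarise(cds_start = min(.data$start), cds_end = max(.data$end))
  } else {
    tibble(transcript_id = character(), cds_start = integer(),
           cds_end = integer())
  }

  if (any(is_tx)) {
    tx <- df |> filter(.data$type %in% c("transcript", "mRNA"))
  } else {
    tx <- ex |>
      group_by(.data$transcript_id) |>
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                end = max(.data$end), strand = .data$strand[1],
                gene_id = .data$gene_id[1]) |>
      ungroup()
  }
  if (any(!tx$strand %in% c("+", "-"))) {
    abort(sprintf("transcript %s lacks a strand",
                  tx$transcript_id[which(!tx$strand %in% c("+", "-"))[1]]))
  }
  ex_l <- split(ex, ex$transcript_id)
  out <- tx |>
    mutate(
      exon_starts = purrr::map(.data$transcript_id, function(id) {
        e <- ex_l[[id]]
        if (is.null(e)) integer() else as.integer(e$start)
      }),
      exon_ends = purrr::map(.data$transcript_id, function(id) {
        e <- ex_l[[id]]
        if (is.null(e)) integer() else as.integer(e$end)
      })
    ) |>
    left_join(cds, by = "transcript_id") |>
    select("gene_id", "transcript_id", "chrom", "start", "end", "strand",
           "exon_starts", "exon_ends", "cds_start", "cds_end")
  validate_transcripts(out)
}

validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx))
  if (!"exon_starts" %in% names(tx)) tx$exon_starts <- purrr::map2(tx$start, tx$end, function(s, e) as.integer(s))
  if (!"exon_ends" %in% names(tx)) tx$exon_ends <- purrr::map(tx$end, as.integer)
  if (!"cds_start" %in% names(tx)) tx$cds_start <- NA_integer_
  if (!"cds_end" %in% names(tx)) tx$cds_end <- NA_integer_
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    if (length(es)) {
      if (is.unsorted(es)) abort(paste("exons not sorted in", tx$transcript_id[i]))
      if (any(es[-1] < ee[-length(ee)])) abort(paste("overlapping exons in", tx$transcript_id[i]))
      if (min(es) < tx$start[i] || max(ee) > tx$end[i]) {
        abort(paste("exon outside transcript span in", tx$transcript_id[i]))
      }
    }
  }
  as_tibble(tx)
}

#' Transcript reference points
#'
#' `transcript_tss()` returns one TSS point per transcript
#' (`start` on `+`, `end - 1` on `-`); `transcript_tes()` the transcription
#' end site (the opposite extremity); `transcript_orf_midpoint()` the
#' midpoint of the CDS span (transcripts without a CDS are dropped).
#'
#' @param tx Transcript tibble from [read_gene_models()].
#' @return Tibble with `chrom`, `pos`, `strand`, `gene_id`, `transcript_id`.
#' @export
transcript_tss <- function(tx) {
  tibble(
    chrom = tx$chrom,
    pos = ifelse(tx$strand == "+", tx$start, tx$end - 1L),
    strand = tx$strand,
    gene_id = tx$gene_id,
    transcript_id = tx$transcript_id
  )
}

#' @rdname transcript_tss
#' @export
transcript_tes <- function(tx) {
  tibble(
    chrom = tx$chrom,
    pos = ifelse(tx$strand == "+", tx$end - 1L, tx$start),
    strand = tx$strand,
    gene_id = tx$gene_id,
    transcript_id = tx$transcript_id
  )
}

#' @rdname transcript_tss
#' @export
transcript_orf_midpoint <- function(tx) {
  tx <- tx[!is.na(tx$cds_start) & !is.na(tx$cds_end), , drop = FALSE]
  tibble(
    chrom = tx$chrom,
    pos = as.integer(floor((as.numeric(tx$cds_start) + as.numeric(tx$cds_end)) / 2)),
    strand = tx$strand,
    gene_id = tx$gene_id,
    transcript_id = tx$transcript_id
  )
}

#' Write transcript models as GTF
#'
#' Emits transcript, exon and (when present) CDS features with 1-based
#' inclusive coordinates, inverting the conversion done by
#' [read_gene_models()].
#'
#' @param tx Transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(tx, path) {
  tx <- validate_transcripts(tx)
  lines <- character(0)
  attr_str <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  for (i in seq_len(nrow(tx))) {
    a <- attr_str(tx$gene_id[i], tx$transcript_id[i])
    lines <- c(lines, sprintf("%s\tpromocc\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom[i], tx$start[i] + 1L, tx$end[i], tx$strand[i], a))
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    if (length(es)) {
      lines <- c(lines, sprintf("%s\tpromocc\texon\t%d\t%d\t.\t%s\t.\t%s",
                                tx$chrom[i], es + 1L, ee, tx$strand[i], a))
    }
    if (!is.na(tx$cds_start[i])) {
      lines <- c(lines, sprintf("%s\tpromocc\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                tx$chrom[i], tx$cds_start[i] + 1L, tx$cds_end[i],
                                tx$strand[i], a))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
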