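#' Classify genes by differential-expression thresholds
#'
#' `up` when `log2fc > lfc_cut` and `padj < padj_cut`; `down` when
#' `log2fc < -lfc_cut` and `padj < padj_cut`; otherwise `ns`. Both
#' inequalities are strict, and a missing `padj` is always `ns`
#' (independent filtering leaves such genes untested).
#'
#' @param de DE tibble ([read_de_table()]).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.5).
#' @param padj_cut Adjusted-p cutoff (default 0.05).
#' @return The tibble with a `de_class` factor column added.
#' @export
apply_de_thresholds <- function(de, lfc_cut = 0.5, padj_cut = 0.05) {
  de |>
    mutate(de_class = factor(dplyr::case_when(
      !is.na(.data$padj) & .data$padj < padj_cut & .data$log2fc > lfc_cut ~ "up",
      !is.na(.data$padj) & .data$padj < padj_cut & .data$log2fc < -lfc_cut ~ "down",
      TRUE ~ "ns"
    ), levels = c("up", "down", "ns")))
}

#' Gene-level binding status from peaks
#'
#' A gene is `bound_at_tss` when any peak interval contains the TSS
#' coordinate of any of its transcripts, and `bound_any` when any peak
#' overlaps any transcript span (which includes the TSS case).
#'
#' @param tx Transcript tibble.
#' @param peaks Interval data frame.
#' @return Tibble: `gene_id`, `bound_any`, `bound_at_tss`.
#' @export
gene_binding_status <- function(tx, peaks) {
  p <- as_intervals(peaks)
  gr_p <- gr_from_intervals(p)
  GenomicRanges::strand(gr_p) <- "*"
  tss <- transcript_tss(tx)
  gr_tss <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$pos + 1L, tss$pos + 1L))
  gr_tx <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end))
  tss_hit <- GenomicRanges::countOverlaps(gr_tss, gr_p) > 0
  span_hit <- GenomicRanges::countOverlaps(gr_tx, gr_p) > 0
  tibble(gene_id = tx$gene_id, tss_hit = tss_hit, span_hit = span_hit) |>
    group_by(.data$gene_id) |>
    summarise(bound_at_tss = any(.data$tss_hit),
              bound_any = any(.data$span_hit) | any(.data$tss_hit)) |>
    select("gene_id", "bound_any", "bound_at_tss")
}

#' Full per-gene status table
#'
#' Joins DE classification, binding status and an optional reference gene
#' list (e.g. genes maternally deposited in early embryos) over the
#' expressed-gene universe defined by the DE table rows.
#'
#' @param de DE tibble (classified with [apply_de_thresholds()] or raw).
#' @param tx Transcript tibble.
#' @param peaks Interval data frame of consensus peaks.
#' @param reference_list Optional character vector of gene ids.
#' @param lfc_cut,padj_cut Thresholds, used when `de` lacks `de_class`.
#' @return Tibble: `gene_id`, `log2fc`, `padj`, `de_class`, `bound_any`,
#'   `bound_at_tss`, `in_reference_list`.
#' @export
gene_status <- function(de, tx, peaks, reference_list = NULL,
                        lfc_cut = 0.5, padj_cut = 0.05) {
  if (!"de_class" %in% names(de)) de <- apply_de_thresholds(de, lfc_cut, padj_cut)
  bind <- gene_binding_status(tx, peaks)
  out <- de |>
    left_join(bind, by = "gene_id") |>
    mutate(bound_any = .data$bound_any %+na% FALSE,
           bound_at_tss = .data$bound_at_tss %+na% FALSE,
           in_reference_list = if (is.null(reference_list)) FALSE
           else .data$gene_id %in% reference_list)
  out
}

#' Fisher 2x2 over the expressed-gene universe
#'
#' Cross-tabulates two logical predicates of the per-gene status table
#' (e.g. bound x upregulated) and runs [fisher_exact()].
#'
#' @param status Gene-status tibble ([gene_status()]).
#' @param row,col Predicates: either a column name, or a one-argument
#'   function of the status tibble returning a logical vector.
#' @return A `fisher2x2` object.
#' @export
#' @examples
#' \dontrun{
#' enrichment_2x2(status, ~ .x$bound_any, ~ .x$de_class == "up")
#' }
enrichment_2x2 <- function(status, row, col) {
  if (nrow(status) == 0) abort("empty gene universe")
  eval_pred <- function(p) {
    if (is.character(p)) return(as.logical(status[[p]]))
    f <- rlang::as_function(p)
    as.logical(f(status))
  }
  r <- eval_pred(row); c <- eval_pred(col)
  fisher_exact(sum(r & c), sum(r & !c), sum(!r & c), sum(!r & !c))
}

#' Cross-reference the DE classes with an external gene list
#'
#' Sets `in_reference_list` and returns both Fisher tables: up x list and
#' down x list, each over the expressed universe.
#'
#' @param status Gene-status tibble.
#' @param reference_list Character vector of gene ids.
#' @param label Name used in the output.
#' @return List with `status` (updated), `up_table`, `down_table`
#'   (`fisher2x2`), `label`.
#' @export
crossref_gene_list <- function(status, reference_list, label = "reference") {
  stopifnot(length(reference_list) > 0)
  status$in_reference_list <- status$gene_id %in% reference_list
  if (!any(status$in_reference_list)) {
    warn("reference list does not intersect the gene universe")
  }
  list(
    status = status,
    up_table = enrichment_2x2(status, ~ .x$de_class == "up",
                              ~ .x$in_reference_list),
    down_table = enrichment_2x2(status, ~ .x$de_class == "down",
                                ~ .x$in_reference_list),
    label = label
  )
}

#' Target-gene report: bound at the TSS and upregulated
#'
#' The stringent direct-target set: genes whose TSS lies inside a peak and
#' whose expression significantly increases. Sorted by log2 fold change,
#' descending.
#'
#' @param status Gene-status tibble.
#' @return Tibble of target genes with `gene_id`, `log2fc`, `padj`.
#' @export
target_gene_report <- function(status) {
  status |>
    filter(.data$bound_at_tss, .data$de_class == "up") |>
    arrange(dplyr::desc(.data$log2fc)) |>
    select("gene_id", "log2fc", "padj", dplyr::any_of(c("bound_any", "in_reference_list")))
}

#' Read a plain-text gene list
#'
#' One gene id per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
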