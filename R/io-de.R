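#' Read a differential-expression table
#'
#' Reads a DESeq2-style TSV of per-gene results. Column names are
#' configurable; missing adjusted p-values (`NA`) are preserved as missing,
#' never coerced to zero. Duplicate gene ids are an error.
#'
#' @param path TSV file with a header.
#' @param gene_col,lfc_col,padj_col,base_mean_col Column names in the file.
#' @return Tibble with columns `gene_id`, `base_mean`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path, gene_col = "gene",
                          lfc_col = "log2FoldChange", padj_col = "padj",
                          base_mean_col = "baseMean") {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        na = c("NA", ""))
  for (col in c(gene_col, lfc_col, padj_col)) {
    if (!col %in% names(df)) abort(paste("missing column:", col))
  }
  out <- tibble(
    gene_id = as.character(df[[gene_col]]),
    base_mean = if (base_mean_col %in% names(df)) as.numeric(df[[base_mean_col]]) else NA_real_,
    log2fc = as.numeric(df[[lfc_col]]),
    padj = as.numeric(df[[padj_col]])
  )
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup)) abort(paste("duplicate gene_id:", dup[1]))
  if (any(!is.na(out$padj) & (out$padj < 0 | out$padj > 1))) {
    abort("padj outside [0, 1]")
  }
  out
}

#' Write a differential-expression table
#'
#' @param de DE tibble as returned by [read_de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- tibble(gene = de$gene_id, baseMean = de$base_mean,
                log2FoldChange = de$log2fc, padj = de$padj)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
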