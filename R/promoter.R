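#' Core-promoter element catalog
#'
#' Default catalog of classical core-promoter elements as IUPAC consensus
#' strings with their strand rule and scanning p-value. The sequences are
#' transcribed from the core-promoter literature (TATA box, initiator,
#' downstream promoter element, motif ten element, Motif 1 / M1BP site)
#' and are configuration, not fixed truths: pass your own tibble, or PWMs
#' via [motif()] objects, to change them. OVO binding motifs
#' ([ovo_motif_catalog()]) are appended by default so promoter scans cover
#' both element classes; they are scanned on both strands, the positional
#' elements sense-only.
#'
#' @param include_ovo Append the OVO motif catalog?
#' @return Tibble: `element`, `consensus`, `strand_rule` (`sense_only` /
#'   `both`), `alpha`.
#' @export
element_catalog <- function(include_ovo = TRUE) {
  base <- tibble(
    element = c("TATA", "INR", "DPE", "MTE", "M1BP"),
    consensus = c("STATAWAAR", "TCAKTY", "RGWYVT", "CSARCSSAACGS", "GGTCACACTR"),
    strand_rule = "sense_only",
    alpha = 0.003
  )
  if (include_ovo) {
    ovo <- tibble(
      element = names(ovo_motif_catalog()),
      consensus = vapply(ovo_motif_catalog(), function(m) m$consensus, character(1)),
      strand_rule = "both",
      alpha = 0.0002
    )
    base <- bind_rows(base, ovo)
  }
  base
}

#' Scan promoter windows for core-promoter elements
#'
#' Scans each oriented promoter sequence (from [promoter_windows()]) for
#' every catalog element: sense-only elements on the given orientation
#' only, `both`-stranded elements on both strands. IUPAC class matching is
#' used for consensus entries; entries carrying a `pwm` in a `motifs`
#' list-column are scanned with [pwm_scan()] at the entry's `alpha`. Hit
#' offsets are reported relative to the TSS index (negative = upstream).
#'
#' @param windows Promoter tibble from [promoter_windows()] (needs
#'   `promoter_id`, `seq`, `tss_index`).
#' @param catalog Element tibble from [element_catalog()].
#' @param mode `"iupac"` or `"pwm"` (PWMs derived from consensus when
#'   absent).
#' @return Object of class `promoter_matrix`: long tibble `hits`
#'   (`promoter_id`, `element`, `offset`), `presence` (wide logical),
#'   `n_promoters`, `flank`.
#' @export
scan_promoters <- function(windows, catalog, mode = c("iupac", "pwm")) {
  mode <- match.arg(mode)
  stopifnot(all(c("promoter_id", "seq", "tss_index") %in% names(windows)))
  thresholds <- if (mode == "pwm") {
    lapply(seq_len(nrow(catalog)), function(k) {
      pwm_threshold_from_pvalue(motif(catalog$element[k],
                                      catalog$consensus[k]), catalog$alpha[k])
    })
  }
  hits <- purrr::map_dfr(seq_len(nrow(catalog)), function(k) {
    m <- motif(catalog$element[k], catalog$consensus[k])
    both <- catalog$strand_rule[k] == "both"
    purrr::map_dfr(seq_len(nrow(windows)), function(i) {
      s <- windows$seq[i]
      if (nchar(s) < nchar(m$consensus)) return(tibble())
      h <- if (mode == "iupac") iupac_scan(s, m, both_strands = both)
      else pwm_scan(s, m, catalog$alpha[k], both_strands = both,
                    threshold = thresholds[[k]])
      if (!nrow(h)) return(tibble())
      tibble(promoter_id = windows$promoter_id[i],
             element = catalog$element[k],
             offset = h$start - windows$tss_index[i],
             strand = h$strand)
    })
  })
  if (nrow(hits) == 0) {
    hits <- tibble(promoter_id = character(), element = character(),
                   offset = integer(), strand = character())
  }
  pres_tbl <- tibble(promoter_id = windows$promoter_id)
  for (el in catalog$element) {
    got <- unique(hits$promoter_id[hits$element == el])
    pres_tbl[[el]] <- pres_tbl$promoter_id %in% got
  }
  structure(list(hits = hits, presence = pres_tbl,
                 n_promoters = nrow(windows),
                 elements = catalog$element),
            class = "promoter_matrix")
}

#' @export
print.promoter_matrix <- function(x, ...) {
  cat(sprintf("<promoter_matrix: %d promoters x %d elements, %d hits>\n",
              x$n_promoters, length(x$elements), nrow(x$hits)))
  invisible(x)
}

#' @export
tidy.promoter_matrix <- function(x, ...) {
  tibble(element = x$elements,
         n_present = vapply(x$elements, function(e) sum(x$presence[[e]]), integer(1)),
         fraction = vapply(x$elements, function(e) mean(x$presence[[e]]), numeric(1)))
}

#' Positional histogram of elements around the TSS
#'
#' Per element and offset bin, the percent of promoters with at least one
#' hit starting in that bin. Positionally constrained elements (INR, DPE,
#' MTE, TATA) show sharp bins at their characteristic offsets; a factor
#' binding without fixed spacing shows a broad flat profile.
#'
#' @param matrix A `promoter_matrix` from [scan_promoters()].
#' @param bin Offset bin width in bp.
#' @param flank Half-window for the histogram range.
#' @return Tibble: `element`, `bin_lo`, `bin_hi`, `percent`.
#' @export
element_positional_histogram <- function(matrix, bin = 5, flank = 200) {
  lo <- seq(-flank, flank - bin, by = bin)
  purrr::map_dfr(matrix$elements, function(el) {
    h <- matrix$hits |> filter(.data$element == el,
                               .data$offset >= -flank, .data$offset < flank)
    counts <- vapply(lo, function(b) {
      length(unique(h$promoter_id[h$offset >= b & h$offset < b + bin]))
    }, integer(1))
    tibble(element = el, bin_lo = lo, bin_hi = lo + bin,
           percent = 100 * counts / matrix$n_promoters)
  })
}

#' Element enrichment between two promoter classes
#'
#' Per element, a Fisher 2x2 of promoter class (a vs b) against element
#' presence, e.g. OVO-bound vs unbound ovary promoters, or ovary vs testis
#' promoters. Elements missing from either matrix are skipped with a
#' warning. Optional Bonferroni correction across elements.
#'
#' @param matrix_a,matrix_b `promoter_matrix` objects sharing elements.
#' @param bonferroni Multiply p-values by the number of elements tested?
#' @return Tibble: `element`, cells `n11..n22` (a-with, a-without, b-with,
#'   b-without), `odds_ratio`, `conditional_mle`, `p`.
#' @export
element_class_enrichment <- function(matrix_a, matrix_b, bonferroni = FALSE) {
  shared <- intersect(matrix_a$elements, matrix_b$elements)
  missing <- setdiff(union(matrix_a$elements, matrix_b$elements), shared)
  if (length(missing)) {
    warn(paste("elements missing from one matrix, skipped:",
               paste(missing, collapse = ", ")))
  }
  out <- purrr::map_dfr(shared, function(el) {
    a <- matrix_a$presence[[el]]; b <- matrix_b$presence[[el]]
    ft <- fisher_exact(sum(a), sum(!a), sum(b), sum(!b))
    tibble(element = el, n11 = ft$n11, n12 = ft$n12, n21 = ft$n21,
           n22 = ft$n22, odds_ratio = ft$odds_ratio,
           conditional_mle = ft$conditional_mle, p = ft$p_two_sided)
  })
  if (bonferroni) out$p <- pmin(1, out$p * length(shared))
  out
}
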