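#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols left_join if_else n row_number distinct count pull rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rnorm rpois runif setNames uniroot
NULL

# IUPAC nucleotide classes as 4-bit masks over (A=1, C=2, G=4, T=8).
# N in a *sequence* is encoded as 0 so it matches no consensus class.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

SEQ_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 0L)

#' Reverse complement of a DNA/IUPAC string
#'
#' Complements all 15 IUPAC one-letter codes and reverses the string.
#'
#' @param x Character vector of uppercase DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("TAACNGT")
revcomp <- function(x) {
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
    K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
  )
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    bad <- !ch %in% names(comp)
    if (any(bad)) abort(paste0("invalid IUPAC character: ", ch[bad][1]))
    paste0(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Stable sub-seed for a named generator stage, derived from a master seed.
# Keeps every stage reproducible on its own without sharing an RNG stream.
sub_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% (2^31 - 2)) + 1L
}

# Integer percent with round-half-away-from-zero (base round() is banker's).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%+na%` <- function(a, b) ifelse(is.na(a), b, a)
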