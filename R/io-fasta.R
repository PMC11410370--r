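#' Load a genome from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` that uppercases the
#' sequences and strips FASTA description lines down to the first word, so
#' chromosome lookup is by exact name.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` named by chromosome.
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

genome_sizes_of <- function(genome) {
  genome <- as_genome(genome)
  setNames(Biostrings::width(genome), names(genome))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(load_genome(genome))
  }
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("genome must be a FASTA path, DNAStringSet, or named character vector")
}

#' Fetch the sequence of one or more intervals
#'
#' Extracts `end - start` uppercase bases per interval. Chromosome names are
#' matched as exact strings (no "chr" aliasing). With
#' `orient_by_strand = TRUE`, minus-strand intervals are reverse-complemented
#' so the returned string reads 5' to 3' along the feature.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param intervals Interval data frame.
#' @param orient_by_strand Reverse-complement `-` strand intervals?
#' @return Character vector of sequences, one per interval row.
#' @export
fetch_sequence <- function(genome, intervals, orient_by_strand = FALSE) {
  genome <- as_genome(genome)
  x <- as_intervals(intervals)
  missing_chrom <- setdiff(unique(x$chrom), names(genome))
  if (length(missing_chrom)) {
    abort(paste("chromosome absent from genome:", missing_chrom[1]))
  }
  len <- setNames(Biostrings::width(genome), names(genome))
  over <- x$end > len[x$chrom]
  if (any(over)) {
    abort(sprintf("interval %s:%d-%d exceeds contig length %d",
                  x$chrom[which(over)[1]], x$start[which(over)[1]],
                  x$end[which(over)[1]], len[x$chrom[which(over)[1]]]))
  }
  seqs <- as.character(Biostrings::subseq(
    genome[x$chrom], start = x$start + 1L, end = x$end
  ))
  seqs <- toupper(unname(seqs))
  if (orient_by_strand) {
    neg <- x$strand == "-"
    if (any(neg)) {
      seqs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[neg])
      ))
    }
  }
  seqs
}
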