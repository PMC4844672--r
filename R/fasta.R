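#' Read a genome from FASTA
#'
#' Sequences are upper-cased and keyed by the first whitespace-delimited
#' token of each header. Duplicate names are an error because a chromosome
#' namespace must be unambiguous.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in ", path, ": ", nm[duplicated(nm)][1L])
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Extract the sequence of an interval (0-based half-open) from a genome.
interval_sequence <- function(genome, interval) {
  chr <- interval$chrom
  if (!chr %in% names(genome)) {
    stop("chromosome ", chr, " not in genome")
  }
  if (interval$end > nchar(genome[[chr]])) {
    stop("interval end ", interval$end, " exceeds length of ", chr)
  }
  substr(genome[[chr]], interval$start + 1L, interval$end)
}
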