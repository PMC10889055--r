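#' Load a reference genome from FASTA
#'
#' Reads a (small) FASTA file into an indexed, read-only genome object that
#' supports substring extraction by 1-based inclusive coordinates. Contig
#' names must be unique and sequences may only contain A, C, G, T or N.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `caism_genome` object.
#' @export
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  # read as raw strings so alphabet violations are reported with coordinates
  seqs <- as.character(Biostrings::readBStringSet(fasta_path))
  # FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_from_seqs(seqs)
}

#' Build a genome object from in-memory sequences
#'
#' @param seqs A named character vector or a [Biostrings::DNAStringSet].
#' @return A `caism_genome` object.
#' @export
genome_from_seqs <- function(seqs) {
  if (!is.character(seqs)) seqs <- as.character(seqs)
  nm <- names(seqs)
  if (is.null(nm) || any(nm == "")) {
    stop("sequences must be named by contig")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate or missing contig names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  chars <- toupper(seqs)
  names(chars) <- nm
  for (i in seq_along(chars)) {
    bad <- regexpr("[^ACGTN]", chars[[i]])
    if (bad > 0L) {
      stop(sprintf("disallowed character '%s' in contig '%s' at position %d",
                   substr(chars[[i]], bad, bad), nm[[i]], as.integer(bad)))
    }
  }
  structure(list(seqs = chars, lengths = nchar(chars)),
            class = "caism_genome")
}

#' Contig lengths of a genome
#' @param genome A `caism_genome`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "caism_genome"))
  genome$lengths
}

#' Extract a genomic substring
#'
#' @param genome A `caism_genome`.
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return Character scalar of length `end - start + 1`.
#' @export
extract_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "caism_genome"))
  if (!chrom %in% names(genome$seqs)) {
    stop("unknown contig: ", chrom)
  }
  len <- genome$lengths[[chrom]]
  if (start < 1L || end > len || start > end) {
    stop(sprintf("coordinates [%d, %d] out of range for contig '%s' (length %d)",
                 as.integer(start), as.integer(end), chrom, len))
  }
  substr(genome$seqs[[chrom]], start, end)
}

#' @export
print.caism_genome <- function(x, ...) {
  cat("caism genome:", length(x$seqs), "contig(s)\n")
  for (nm in names(x$seqs)) cat(" ", nm, ":", x$lengths[[nm]], "bp\n")
  invisible(x)
}

#' Write a genome to FASTA
#' @param genome A `caism_genome`.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "caism_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), path)
  invisible(path)
}
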