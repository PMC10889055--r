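#' Window span for a center position
#'
#' For the default window length L = 2000 the window covers 999 bp upstream
#' and 1000 bp downstream of the center: 1-based positions
#' `[pos - 999, pos + 1000]`. For general L the upstream flank is
#' `ceiling(L/2) - 1` and the downstream flank `floor(L/2)`.
#'
#' @param pos 1-based center position.
#' @param L Window length.
#' @return List with `start`, `end` (1-based inclusive) and `center_index`
#'   (1-based index of the center inside the window).
#' @export
window_span <- function(pos, L = 2000L) {
  L <- as.integer(L)
  if (L < 1L) stop("window length must be positive")
  up <- as.integer(ceiling(L / 2) - 1)
  down <- as.integer(floor(L / 2))
  list(start = as.integer(pos) - up, end = as.integer(pos) + down,
       center_index = up + 1L)
}

#' Build an allele-substituted sequence window
#'
#' Extracts the fixed-length window around `center` from the genome and
#' substitutes the chosen allele (major by default) at the center and at
#' every neighbouring variant inside the window. The substitution is defined
#' by the declared alleles, not by the assembly base: when the genome base at
#' a variant position matches neither declared allele the chosen allele still
#' wins and the window is flagged (`ref_mismatch`). Windows containing N are
#' allowed but flagged.
#'
#' @param genome A `caism_genome`.
#' @param center One-row variant data.frame (see [variant_table()]).
#' @param neighbors Variant data.frame of neighbours inside the window (may
#'   be `NULL` or empty).
#' @param allele_choice Named character vector mapping variant id to
#'   `"major"` or `"minor"`; ids not listed default to `"major"`.
#' @param L Window length (default 2000).
#' @return A `seq_window` object: list with `seq`, `chrom`, `start`, `L`,
#'   `center_id`, `center_index` (1-based), `carried` (id -> chosen allele),
#'   `strand`, and `flags`.
#' @export
build_window <- function(genome, center, neighbors = NULL,
                         allele_choice = NULL, L = 2000L) {
  stopifnot(inherits(genome, "caism_genome"), nrow(center) == 1L)
  span <- window_span(center$pos, L)
  len <- contig_lengths(genome)
  if (!center$chrom %in% names(len)) stop("unknown contig: ", center$chrom)
  if (span$start < 1L || span$end > len[[center$chrom]]) {
    stop(sprintf(
      "window [%d, %d] for %s runs off contig '%s' (length %d)",
      span$start, span$end, center$id, center$chrom, len[[center$chrom]]))
  }
  vars <- center
  if (!is.null(neighbors) && nrow(neighbors)) {
    if (any(neighbors$chrom != center$chrom)) {
      stop("neighbors must be on the same contig as the center")
    }
    out <- neighbors$pos < span$start | neighbors$pos > span$end
    if (any(out)) {
      stop("neighbor(s) outside the window of ", center$id, ": ",
           paste(neighbors$id[out], collapse = ", "))
    }
    vars <- rbind(center, neighbors)
  }
  chars <- strsplit(extract_seq(genome, center$chrom, span$start, span$end),
                    "")[[1]]
  carried <- stats::setNames(rep("major", nrow(vars)), vars$id)
  if (!is.null(allele_choice)) {
    unknown <- setdiff(names(allele_choice), vars$id)
    if (length(unknown)) {
      stop("allele_choice names not among center/neighbors: ",
           paste(unknown, collapse = ", "))
    }
    if (!all(allele_choice %in% c("major", "minor"))) {
      stop("allele_choice values must be 'major' or 'minor'")
    }
    carried[names(allele_choice)] <- allele_choice
  }
  mismatch <- character(0)
  for (i in seq_len(nrow(vars))) {
    off <- vars$pos[i] - span$start + 1L
    gbase <- chars[off]
    if (gbase != vars$major[i] && gbase != vars$minor[i]) {
      mismatch <- c(mismatch, vars$id[i])
    }
    chars[off] <- if (carried[[vars$id[i]]] == "major") vars$major[i]
                  else vars$minor[i]
  }
  seq <- paste(chars, collapse = "")
  structure(list(seq = seq, chrom = center$chrom, start = span$start, L = as.integer(L),
                 center_id = center$id, center_index = span$center_index,
                 carried = carried, strand = "+",
                 flags = list(ref_mismatch = mismatch,
                              has_n = grepl("N", seq, fixed = TRUE))),
            class = "seq_window")
}

#' Reverse-complement a sequence window
#'
#' The sequence is reverse-complemented and the center index remapped to
#' `L + 1 - center_index`; carried alleles stay reported on the original
#' strand.
#'
#' @param w A `seq_window`.
#' @return A `seq_window` on the opposite strand.
#' @export
reverse_complement_window <- function(w) {
  stopifnot(inherits(w, "seq_window"))
  w$seq <- revcomp(w$seq)
  w$center_index <- w$L + 1L - w$center_index
  w$strand <- if (w$strand == "+") "-" else "+"
  w
}

#' Reverse complement of a nucleotide string (A/C/G/T/N)
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @export
print.seq_window <- function(x, ...) {
  cat(sprintf("seq_window: %s:%d-%d (%s strand), center %s at index %d\n",
              x$chrom, x$start, x$start + x$L - 1L, x$strand,
              x$center_id, x$center_index))
  al <- paste(names(x$carried), x$carried, sep = "=", collapse = "; ")
  cat("  alleles:", al, "\n")
  if (length(x$flags$ref_mismatch)) {
    cat("  ref-mismatch flagged:",
        paste(x$flags$ref_mismatch, collapse = ", "), "\n")
  }
  invisible(x)
}
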