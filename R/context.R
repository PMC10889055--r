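#' Enumerate genetic contexts over neighbouring variants
#'
#' A genetic context fixes the center allele and assigns major or minor to
#' every neighbouring variant inside the window. All `2^k` combinations over
#' the `k` neighbours are produced in a deterministic lexicographic order:
#' neighbours are canonically ordered by genomic position ascending, major
#' sorts before minor, and the first/last assignments are all-major /
#' all-minor. Enumeration refuses above `max_neighbors` with an explicit
#' combinatorial-explosion error.
#'
#' @param center One-row variant data.frame.
#' @param neighbors Variant data.frame (0 or more rows) of neighbours.
#' @param center_allele `"major"` or `"minor"`.
#' @param max_neighbors Cap on k (default 12, i.e. 4096 contexts).
#' @return List of `context_assignment` objects, each with `center_id`,
#'   `center_allele`, `neighbor_alleles` (named, position-ordered) and a
#'   canonical `label`.
#' @export
enumerate_contexts <- function(center, neighbors = NULL,
                               center_allele = c("minor", "major"),
                               max_neighbors = 12L) {
  center_allele <- match.arg(center_allele)
  if (is.null(neighbors)) {
    neighbors <- data.frame(id = character(0), pos = integer(0))
  }
  if (anyDuplicated(neighbors$id)) {
    stop("duplicate neighbor id(s): ",
         paste(unique(neighbors$id[duplicated(neighbors$id)]), collapse = ", "))
  }
  k <- nrow(neighbors)
  if (k > max_neighbors) {
    stop(sprintf(paste0(
      "%d neighbors would enumerate 2^%d contexts, above the cap of %d ",
      "(2^%d); restrict the neighbor set or raise max_neighbors"),
      k, k, as.integer(max_neighbors), as.integer(max_neighbors)))
  }
  ord <- order(neighbors$pos)
  ids <- as.character(neighbors$id)[ord]
  alleles <- c("major", "minor")
  n_ctx <- 2L^k
  out <- vector("list", n_ctx)
  for (i in seq_len(n_ctx)) {
    # binary counting, first neighbor most significant -> lexicographic order
    bits <- if (k > 0L) as.integer(intToBits(i - 1L))[k:1] else integer(0)
    nb <- stats::setNames(alleles[bits + 1L], ids)
    out[[i]] <- new_context_assignment(center$id, center_allele, nb)
  }
  out
}

new_context_assignment <- function(center_id, center_allele, neighbor_alleles) {
  label <- paste(c(paste0("center=", center_allele),
                   if (length(neighbor_alleles))
                     paste0(names(neighbor_alleles), "=", neighbor_alleles)),
                 collapse = ";")
  structure(list(center_id = center_id, center_allele = center_allele,
                 neighbor_alleles = neighbor_alleles, label = label),
            class = "context_assignment")
}

#' Parse a canonical context label back into an assignment
#'
#' Inverse of the label encoding used by [enumerate_contexts()]; the center
#' id is not part of the label and must be supplied.
#'
#' @param label Canonical label, e.g. `"center=minor;rsA=major;rsB=minor"`.
#' @param center_id Center variant id.
#' @return A `context_assignment`.
#' @export
parse_context_label <- function(label, center_id = NA_character_) {
  parts <- strsplit(label, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  if (keys[1] != "center" || !all(vals %in% c("major", "minor"))) {
    stop("malformed context label: ", label)
  }
  nb <- stats::setNames(vals[-1], keys[-1])
  new_context_assignment(center_id, vals[1], nb)
}

#' Build the sequence window for each context assignment
#'
#' One window per assignment, via [build_window()]; every window has length
#' `L` and carries the assignment's alleles at the center and neighbour
#' positions.
#'
#' @param genome A `caism_genome`.
#' @param center One-row variant data.frame.
#' @param neighbors Variant data.frame matching the assignments.
#' @param assignments List of `context_assignment` from [enumerate_contexts()].
#' @param L Window length.
#' @return List of `seq_window`, in assignment order.
#' @export
contexts_to_windows <- function(genome, center, neighbors, assignments,
                                L = 2000L) {
  lapply(assignments, function(a) {
    choice <- c(stats::setNames(a$center_allele, center$id),
                a$neighbor_alleles)
    build_window(genome, center, neighbors, allele_choice = choice, L = L)
  })
}

#' @export
print.context_assignment <- function(x, ...) {
  cat("context:", x$label, "(center", paste0(x$center_id, ")"), "\n")
  invisible(x)
}
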