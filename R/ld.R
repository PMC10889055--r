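#' Construct a phased haplotype matrix
#'
#' Rows are haplotypes (two per diploid sample), columns are variants;
#' entries are 0 (major) or 1 (minor). LD is only defined on fully phased,
#' complete data, so missing entries are rejected.
#'
#' @param mat 0/1 matrix with column names giving variant ids.
#' @return A `haplotype_matrix` object.
#' @export
haplotype_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) stop("haplotype matrix needs variant ids as column names")
  if (anyNA(mat)) stop("haplotype matrix must have no missing entries (phased input only)")
  if (!all(mat %in% c(0, 1))) stop("haplotype entries must be 0 (major) or 1 (minor)")
  storage.mode(mat) <- "integer"
  structure(list(haplotypes = mat, variant_ids = colnames(mat),
                 sample_count = nrow(mat) / 2),
            class = "haplotype_matrix")
}

#' Read phased haplotypes from a TSV matrix or a phased VCF
#'
#' TSV input: a header row of variant ids, then one 0/1 row per haplotype.
#' VCF input: GT fields must be phased (`a|b`); each sample contributes two
#' haplotype rows. ALT is coded 1; for consistency with a variant table in
#' which REF is not the major allele, recode externally.
#'
#' @param path File path.
#' @return A `haplotype_matrix`.
#' @export
read_haplotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    if (any(grepl("/", gt, fixed = TRUE))) {
      stop("unphased genotypes in VCF; LD requires phased input")
    }
    ids <- rownames(gt)
    hap <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt),
                  dimnames = list(NULL, ids))
    for (j in seq_len(nrow(gt))) {
      parts <- strsplit(gt[j, ], "|", fixed = TRUE)
      hap[, j] <- as.integer(unlist(parts))
    }
    return(haplotype_matrix(hap))
  }
  haplotype_matrix(as.matrix(utils::read.delim(path, check.names = FALSE)))
}

hap_col <- function(hap, id) {
  i <- match(id, hap$variant_ids)
  if (is.na(i)) stop("variant not in haplotype matrix: ", id)
  hap$haplotypes[, i]
}

#' Pairwise linkage disequilibrium r-squared
#'
#' `D^2 / (p_a (1-p_a) p_b (1-p_b))` with
#' `D = freq(minor, minor) - p_a * p_b`, frequencies taken over haplotype
#' rows. Undefined (error) when either column is monomorphic.
#'
#' @param hap A `haplotype_matrix`.
#' @param a,b Variant ids.
#' @return r-squared in \[0, 1\].
#' @export
r_squared <- function(hap, a, b) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  x <- hap_col(hap, a)
  y <- hap_col(hap, b)
  pa <- mean(x)
  pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    mono <- c(a, b)[c(pa, pb) %in% c(0, 1)]
    stop("LD undefined for monomorphic variant(s): ",
         paste(mono, collapse = ", "))
  }
  D <- mean(x * y) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Anchor-centred correlated variant group
#'
#' All variants whose r-squared to the anchor meets the threshold, anchor
#' included. Monomorphic variants are excluded from grouping with a warning
#' rather than silently assigned r-squared 0.
#'
#' @param hap A `haplotype_matrix`.
#' @param anchor Anchor variant id.
#' @param threshold r-squared threshold (default 0.8, the conventional
#'   "highly correlated" cut).
#' @return An `ld_group`: list with `anchor_id`, `member_ids`,
#'   `r2_to_anchor`.
#' @export
correlated_group <- function(hap, anchor, threshold = 0.8) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  if (!anchor %in% hap$variant_ids) stop("unknown anchor: ", anchor)
  r2 <- stats::setNames(rep(NA_real_, length(hap$variant_ids)),
                        hap$variant_ids)
  mono <- character(0)
  for (id in hap$variant_ids) {
    if (id == anchor) {
      r2[[id]] <- 1
      next
    }
    r2[[id]] <- tryCatch(r_squared(hap, anchor, id), error = function(e) {
      mono <<- c(mono, id)
      NA_real_
    })
  }
  if (length(mono)) {
    warning("excluded monomorphic variant(s) from LD grouping: ",
            paste(mono, collapse = ", "))
  }
  members <- names(r2)[!is.na(r2) & r2 >= threshold]
  structure(list(anchor_id = anchor, member_ids = members,
                 r2_to_anchor = r2[members], threshold = threshold),
            class = "ld_group")
}

#' Contrast predicted effects across an LD group
#'
#' Takes the no-context effect records of every group member and reports,
#' per feature, each member's log-odds change, a divergence summary (the
#' maximum pairwise absolute difference), and flags where the anchor passes
#' the effect threshold while a tightly linked member (r-squared >=
#' `flag_r2`) does not — the signature of highly correlated variants with
#' distinct predicted function.
#'
#' @param group An `ld_group`.
#' @param effects Effect-record data.frame (one context per member, e.g. the
#'   all-major no-context records).
#' @param effect_threshold |log-odds change| threshold (default 1).
#' @param flag_r2 r-squared above which a member is "tightly linked"
#'   (default 0.9).
#' @return List with `effects` (long member x feature table), `divergence`
#'   (per feature), and `flagged` (anchor-passes / member-fails rows).
#' @export
compare_group_effects <- function(group, effects, effect_threshold = 1,
                                  flag_r2 = 0.9) {
  stopifnot(inherits(group, "ld_group"))
  missing <- setdiff(group$member_ids, unique(effects$variant_id))
  if (length(missing)) {
    stop("no effect records for group member(s): ",
         paste(missing, collapse = ", "))
  }
  sub <- effects[effects$variant_id %in% group$member_ids, , drop = FALSE]
  dup <- stats::aggregate(list(n = sub$log_odds_change),
                          by = list(variant_id = sub$variant_id,
                                    feature = sub$feature), FUN = length)
  if (any(dup$n > 1)) {
    stop("multiple effect records per member/feature; pass one context ",
         "(e.g. the no-context all-major records)")
  }
  sub$r2_to_anchor <- group$r2_to_anchor[sub$variant_id]
  sub$r2_to_anchor[sub$variant_id == group$anchor_id] <- 1
  div <- stats::aggregate(list(divergence = sub$log_odds_change),
                          by = list(feature = sub$feature),
                          FUN = function(x) max(x) - min(x))
  anc <- sub[sub$variant_id == group$anchor_id, , drop = FALSE]
  anc_eff <- stats::setNames(anc$log_odds_change, anc$feature)
  mem <- sub[sub$variant_id != group$anchor_id, , drop = FALSE]
  fl <- mem[abs(anc_eff[mem$feature]) >= effect_threshold &
              abs(mem$log_odds_change) < effect_threshold &
              mem$r2_to_anchor >= flag_r2, , drop = FALSE]
  if (nrow(fl)) fl$anchor_log_odds_change <- unname(anc_eff[fl$feature])
  list(effects = sub[, c("variant_id", "feature", "log_odds_change",
                         "r2_to_anchor")],
       divergence = div, flagged = fl)
}
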