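#' Log-odds change between reference and alternate probabilities
#'
#' `logit(p_ref) - logit(p_alt)` (natural log). Positive values mean the
#' alternate (minor) allele lowers the predicted probability — a loss of
#' function; negative values a gain. Inputs must lie strictly inside (0, 1);
#' annotators clamp upstream.
#'
#' @param p_ref,p_alt Probabilities in (0, 1). Vectorized.
#' @return Numeric.
#' @export
log_odds_change <- function(p_ref, p_alt) {
  if (any(p_ref <= 0 | p_ref >= 1 | p_alt <= 0 | p_alt >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)")
  }
  stats::qlogis(p_ref) - stats::qlogis(p_alt)
}

#' E statistic: log-odds change times probability change
#'
#' The product of the relative change (log-odds change) and the absolute
#' change `p_ref - p_alt`. Because the logit is strictly increasing the two
#' factors always share a sign, so the statistic is non-negative and zero
#' iff `p_ref == p_alt`.
#'
#' @inheritParams log_odds_change
#' @return Non-negative numeric.
#' @export
e_statistic <- function(p_ref, p_alt) {
  log_odds_change(p_ref, p_alt) * (p_ref - p_alt)
}

# evaluate code with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample random background variants from a genome
#'
#' Positions are uniform over all contig positions whose window fits inside
#' the contig, optionally excluding intervals (e.g. the candidate windows,
#' so a desk-scale background is not contaminated by planted signal). The
#' genome base is taken as the major (reference) allele and the minor allele
#' is drawn uniformly from the three other bases; positions where the genome
#' has N are rejected.
#'
#' @param genome A `caism_genome`.
#' @param n Number of variants.
#' @param seed RNG seed (recorded by [build_background()]).
#' @param L Window length the variants must accommodate.
#' @param exclude Optional data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) intervals to avoid.
#' @return A `caism_variants` table with ids `bg000001, ...`.
#' @export
sample_background_variants <- function(genome, n, seed, L = 2000L,
                                       exclude = NULL) {
  lens <- contig_lengths(genome)
  up <- as.integer(ceiling(L / 2) - 1)
  down <- as.integer(floor(L / 2))
  lo <- up + 1L
  hi <- lens - down
  elig <- pmax(hi - lo + 1L, 0L)
  if (sum(elig) < 1L) stop("no contig can accommodate a window of length ", L)
  with_seed(seed, {
    chroms <- character(n)
    poss <- integer(n)
    majors <- character(n)
    minors <- character(n)
    got <- 0L
    tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 200L * n) {
        stop("background sampler exhausted before ", n, " valid variants")
      }
      ci <- sample.int(length(lens), 1L, prob = elig)
      pos <- sample.int(elig[ci], 1L) + lo[ci] - 1L
      chrom <- names(lens)[ci]
      if (!is.null(exclude)) {
        hit <- exclude$chrom == chrom & exclude$start <= pos &
          exclude$end >= pos
        if (any(hit)) next
      }
      base <- extract_seq(genome, chrom, pos, pos)
      if (base == "N") next
      got <- got + 1L
      chroms[got] <- chrom
      poss[got] <- pos
      majors[got] <- base
      minors[got] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    }
    variant_table(data.frame(id = sprintf("bg%06d", seq_len(n)),
                             chrom = chroms, pos = poss,
                             major = majors, minor = minors,
                             stringsAsFactors = FALSE))
  })
}

# no-context E statistics (matrix variants x features) for a variant table
variant_estats <- function(genome, variants, annotator, L,
                           feature_subset = NULL) {
  feats <- if (is.null(feature_subset)) feature_names(annotator)
           else feature_subset
  out <- matrix(NA_real_, nrow = nrow(variants), ncol = length(feats),
                dimnames = list(variants$id, feats))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    p_ref <- subset_features(annotate(annotator,
      build_window(genome, v, allele_choice = stats::setNames("major", v$id),
                   L = L)), feats)
    p_alt <- subset_features(annotate(annotator,
      build_window(genome, v, allele_choice = stats::setNames("minor", v$id),
                   L = L)), feats)
    out[i, ] <- e_statistic(p_ref, p_alt)
  }
  out
}

#' Build the empirical background null of E statistics
#'
#' For each of `n` randomly sampled variants the no-context E statistic is
#' computed for every feature; the per-feature sorted vectors form the
#' empirical null against which candidate statistics are ranked. Variants
#' whose window would run off a contig are skipped and counted (the default
#' sampler never produces them).
#'
#' @param genome A `caism_genome`.
#' @param annotator A `synthetic_annotator`.
#' @param n Number of background variants.
#' @param seed RNG seed, recorded in the metadata.
#' @param L Window length.
#' @param feature_subset Optional feature names to restrict to.
#' @param exclude Passed to [sample_background_variants()].
#' @param variants Optional pre-sampled variant table (overrides the
#'   sampler; `n` and `seed` are then ignored for sampling but still
#'   recorded).
#' @return A `background_null`: list with `estats` (feature -> sorted
#'   vector), `n`, and `meta`.
#' @export
build_background <- function(genome, annotator, n, seed, L = 2000L,
                             feature_subset = NULL, exclude = NULL,
                             variants = NULL) {
  if (n < 1L) stop("background size must be at least 1")
  if (is.null(variants)) {
    variants <- sample_background_variants(genome, n, seed, L, exclude)
  }
  skipped <- 0L
  keep <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    span <- window_span(variants$pos[i], L)
    clen <- contig_lengths(genome)[[variants$chrom[i]]]
    if (span$start < 1L || span$end > clen) {
      keep[i] <- FALSE
      skipped <- skipped + 1L
    }
  }
  variants <- variants[keep, , drop = FALSE]
  mat <- variant_estats(genome, variants, annotator, L, feature_subset)
  structure(list(
    estats = lapply(stats::setNames(colnames(mat), colnames(mat)),
                    function(f) sort(mat[, f])),
    n = nrow(mat),
    meta = list(seed = seed, n_requested = n, L = as.integer(L),
                skipped_boundary = skipped,
                features = colnames(mat),
                annotator_features = feature_names(annotator))),
    class = "background_null")
}

#' Empirical e-value of an E statistic against the background null
#'
#' Add-one empirical p-value `(r + 1) / (n + 1)` where `r` counts background
#' values `>= e_stat` (ties inclusive, conservative), so no e-value is
#' exactly zero and the smallest achievable value is `1 / (n + 1)`.
#'
#' @param e_stat Non-negative statistic(s); vectorized.
#' @param null A `background_null`.
#' @param feature Feature name whose null to rank against.
#' @return e-value(s) in (0, 1].
#' @export
empirical_e_value <- function(e_stat, null, feature) {
  stopifnot(inherits(null, "background_null"))
  bg <- null$estats[[feature]]
  if (is.null(bg)) stop("feature absent from background null: ", feature)
  vapply(e_stat, function(e) (sum(bg >= e) + 1) / (null$n + 1), 0)
}

#' Score a variant across genetic contexts
#'
#' For every context assignment the reference window carries the center
#' major allele and the alternate window the center minor allele, with the
#' neighbours fixed per the context in both windows: the context modifies
#' the sequence background while the ref/alt contrast is always the center
#' allele. One effect record is emitted per (context, feature).
#'
#' @param genome A `caism_genome`.
#' @param center One-row variant data.frame.
#' @param neighbors Variant data.frame of in-window neighbours (or NULL).
#' @param annotator A `synthetic_annotator`.
#' @param null Optional `background_null` for e-values (must have been built
#'   with the same annotator and L); without it `e_value` is NA.
#' @param contexts List of `context_assignment`s; defaults to the full
#'   enumeration over `neighbors`.
#' @param feature_subset Optional feature names to restrict to.
#' @param L Window length.
#' @param max_neighbors Cap passed to [enumerate_contexts()] when `contexts`
#'   is not supplied.
#' @return data.frame of effect records: `variant_id`, `context_label`,
#'   `feature`, `p_ref`, `p_alt`, `log_odds_change`, `e_stat`, `e_value`,
#'   `direction`.
#' @export
score_variant <- function(genome, center, neighbors = NULL, annotator,
                          null = NULL, contexts = NULL,
                          feature_subset = NULL, L = 2000L,
                          max_neighbors = 12L) {
  if (is.null(contexts)) {
    contexts <- enumerate_contexts(center, neighbors,
                                   center_allele = "minor",
                                   max_neighbors = max_neighbors)
  }
  feats <- if (is.null(feature_subset)) feature_names(annotator)
           else feature_subset
  recs <- vector("list", length(contexts))
  for (ci in seq_along(contexts)) {
    ctx <- contexts[[ci]]
    ref_choice <- c(stats::setNames("major", center$id), ctx$neighbor_alleles)
    alt_choice <- c(stats::setNames("minor", center$id), ctx$neighbor_alleles)
    p_ref <- subset_features(annotate(annotator,
      build_window(genome, center, neighbors, ref_choice, L)), feats)
    p_alt <- subset_features(annotate(annotator,
      build_window(genome, center, neighbors, alt_choice, L)), feats)
    loc <- log_odds_change(p_ref, p_alt)
    es <- loc * (p_ref - p_alt)
    ev <- if (is.null(null)) rep(NA_real_, length(feats)) else
      vapply(names(p_ref), function(f)
        empirical_e_value(es[[f]], null, f), 0)
    recs[[ci]] <- data.frame(
      variant_id = center$id, context_label = ctx$label,
      feature = names(p_ref), p_ref = unname(p_ref), p_alt = unname(p_alt),
      log_odds_change = unname(loc), e_stat = unname(es),
      e_value = unname(ev),
      direction = ifelse(loc > 0, "loss", ifelse(loc < 0, "gain", "none")),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, recs)
}

#' Reversed-sequence consistency check
#'
#' Recomputes feature probabilities on reverse-complemented windows and
#' reports the maximum absolute discrepancy per feature. With a
#' strand-symmetric annotator the discrepancy is exactly zero.
#'
#' @param genome,center,neighbors,annotator,L As in [score_variant()].
#' @param allele_choice Allele choice for the window (default all-major).
#' @return Named numeric vector of absolute probability discrepancies.
#' @export
reversed_check <- function(genome, center, neighbors = NULL, annotator,
                           allele_choice = NULL, L = 2000L) {
  w <- build_window(genome, center, neighbors, allele_choice, L)
  abs(annotate(annotator, w) -
        annotate(annotator, reverse_complement_window(w)))
}
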