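#' Define a motif-based chromatin feature for the synthetic annotator
#'
#' Each feature scores a sequence through one or more short motifs. A motif
#' is either a consensus string (scored 0 per matching base and `mismatch`
#' per mismatching base) or a 4 x m position-weight matrix with rows
#' A, C, G, T of per-position scores. A position's score is summed over the
#' motif; positions whose score, relative to the best achievable, falls
#' below `cutoff` contribute nothing, the rest contribute
#' `exp(score - best)` to that motif's occupancy `R` (an exact consensus
#' match contributes 1). With `strand_symmetric = TRUE` the occupancy also
#' sums matches on the reverse complement, so a sequence and its reverse
#' complement score identically. The feature's probability is
#' `plogis(intercept + sum(weights * R) + coop_weight * prod(R))`, so planted
#' effect sizes on the logit scale are exact linear combinations of
#' occupancy changes.
#'
#' `cutoff = -Inf` gives a smooth occupancy in which every position
#' contributes; any substitution then changes the score continuously, which
#' is the regime used for empirical-null calibration studies. The default
#' finite cutoff keeps only (near-)consensus sites, so substitutions away
#' from motif instances have exactly zero effect.
#'
#' An N base has zero affinity: it scores `mismatch` (consensus motifs) or
#' the column minimum (matrix motifs) at its position.
#'
#' @param name Feature name (e.g. a cell-type-qualified chromatin mark).
#' @param motifs Character vector of consensus strings and/or list of 4 x m
#'   numeric matrices (rows A, C, G, T).
#' @param weights Numeric, one per motif (recycled); logit-scale weight of
#'   each motif's occupancy.
#' @param coop_weight Logit-scale weight on the product of all motif
#'   occupancies; nonzero values create genuine context dependence
#'   (cooperative binding).
#' @param intercept Logit-scale baseline.
#' @param mismatch Per-base mismatch score for consensus motifs (negative).
#' @param cutoff Relative-score cutoff; `-Inf` for smooth occupancy.
#' @param strand_symmetric Score both strands (default TRUE).
#' @return A `motif_feature` object.
#' @export
motif_feature <- function(name, motifs, weights = 1, coop_weight = 0,
                          intercept = 0, mismatch = -30, cutoff = -15,
                          strand_symmetric = TRUE) {
  if (!is.list(motifs)) motifs <- as.list(motifs)
  if (!length(motifs)) stop("feature '", name, "' needs at least one motif")
  pwms <- lapply(motifs, as_pwm, mismatch = mismatch)
  weights <- rep_len(weights, length(pwms))
  structure(list(name = name, pwms = pwms, weights = weights,
                 coop_weight = coop_weight, intercept = intercept,
                 cutoff = cutoff, strand_symmetric = isTRUE(strand_symmetric)),
            class = "motif_feature")
}

BASES <- c("A", "C", "G", "T", "N")

# 5 x m score matrix (rows A,C,G,T,N); N scores as zero affinity
as_pwm <- function(motif, mismatch) {
  if (is.character(motif)) {
    chars <- strsplit(toupper(motif), "")[[1]]
    if (!all(chars %in% c("A", "C", "G", "T"))) {
      stop("consensus motif must be A/C/G/T only: ", motif)
    }
    m <- length(chars)
    pwm <- matrix(mismatch, nrow = 5L, ncol = m, dimnames = list(BASES, NULL))
    for (j in seq_len(m)) pwm[chars[j], j] <- 0
  } else if (is.matrix(motif)) {
    if (nrow(motif) != 4L) stop("matrix motif must have 4 rows (A,C,G,T)")
    pwm <- rbind(motif, apply(motif, 2, min))
    dimnames(pwm) <- list(BASES, NULL)
  } else {
    stop("motif must be a consensus string or a 4 x m matrix")
  }
  list(scores = pwm, smax = sum(apply(pwm[1:4, , drop = FALSE], 2, max)),
       width = ncol(pwm))
}

#' Create a deterministic synthetic sequence annotator
#'
#' The synthetic annotator is the ground-truth stand-in for a deep
#' chromatin-feature model: a pure function from a fixed-length nucleotide
#' sequence to one probability per declared feature, with planted motif
#' effects whose sizes are known in closed form (see [motif_feature()]).
#' Probabilities are clamped to `[clamp, 1 - clamp]` so logits are always
#' finite.
#'
#' @param features List of [motif_feature()] objects with unique names.
#' @param input_length Required sequence length (default 2000).
#' @param clamp Probability clamp (default 1e-6).
#' @param allow_n Accept sequences containing N (flagged windows); N bases
#'   have zero motif affinity.
#' @return A `synthetic_annotator` object.
#' @export
synthetic_annotator <- function(features, input_length = 2000L,
                                clamp = 1e-6, allow_n = TRUE) {
  nms <- vapply(features, function(f) f$name, "")
  if (anyDuplicated(nms)) {
    stop("duplicate feature name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  structure(list(features = features, feature_names = nms,
                 input_length = as.integer(input_length),
                 clamp = clamp, allow_n = isTRUE(allow_n)),
            class = "synthetic_annotator")
}

#' Feature names declared by an annotator
#' @param annotator A `synthetic_annotator`.
#' @return Character vector.
#' @export
feature_names <- function(annotator) annotator$feature_names

encode_seq <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], BASES)
  if (anyNA(code)) stop("sequence contains characters outside A/C/G/T/N")
  code
}

# occupancy contributions of one motif along one encoded strand
motif_contribs <- function(code, pwm, cutoff) {
  np <- length(code) - pwm$width + 1L
  if (np < 1L) return(numeric(0))
  s <- numeric(np)
  sc <- pwm$scores
  for (j in seq_len(pwm$width)) {
    s <- s + sc[code[j:(j + np - 1L)], j]
  }
  rel <- s - pwm$smax
  exp(rel[rel >= cutoff])
}

# occupancy R of one motif; sorted summation makes the strand-symmetric
# score bit-identical for a sequence and its reverse complement
motif_occupancy <- function(code_f, code_r, pwm, cutoff, symmetric) {
  contribs <- motif_contribs(code_f, pwm, cutoff)
  if (symmetric) contribs <- c(contribs, motif_contribs(code_r, pwm, cutoff))
  sum(sort(contribs))
}

#' Annotate a sequence (or window) with feature probabilities
#'
#' @param annotator A `synthetic_annotator`.
#' @param seq Nucleotide string of the annotator's input length, or a
#'   `seq_window`.
#' @return Named numeric vector of probabilities (a feature profile).
#' @export
annotate <- function(annotator, seq) {
  stopifnot(inherits(annotator, "synthetic_annotator"))
  if (inherits(seq, "seq_window")) seq <- seq$seq
  if (nchar(seq) != annotator$input_length) {
    stop(sprintf("sequence length %d differs from annotator input length %d",
                 nchar(seq), annotator$input_length))
  }
  if (!annotator$allow_n && grepl("N", seq, fixed = TRUE)) {
    stop("annotator configured to refuse sequences containing N")
  }
  code_f <- encode_seq(seq)
  code_r <- if (any(vapply(annotator$features, function(f) f$strand_symmetric,
                           TRUE))) encode_seq(revcomp(seq)) else NULL
  probs <- vapply(annotator$features, function(f) {
    R <- vapply(f$pwms, function(p)
      motif_occupancy(code_f, code_r, p, f$cutoff, f$strand_symmetric), 0)
    logit <- f$intercept + sum(f$weights * R) + f$coop_weight * prod(R)
    min(max(stats::plogis(logit), annotator$clamp), 1 - annotator$clamp)
  }, 0)
  stats::setNames(probs, annotator$feature_names)
}

#' Annotate a batch of sequences
#'
#' Elementwise equal to [annotate()], order preserved; the first failing
#' sequence is reported by index.
#'
#' @param annotator A `synthetic_annotator`.
#' @param seqs List (or character vector) of sequences or `seq_window`s.
#' @return List of named probability vectors.
#' @export
annotate_batch <- function(annotator, seqs) {
  if (is.character(seqs)) seqs <- as.list(seqs)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- tryCatch(annotate(annotator, seqs[[i]]),
                         error = function(e) {
                           stop(sprintf("sequence %d: %s", i,
                                        conditionMessage(e)), call. = FALSE)
                         })
  }
  out
}

#' Restrict a feature profile to a subset of features
#'
#' Keeps the profile's original feature order; unknown names in `keep` are
#' reported explicitly. This plays the role of restricting a full annotator
#' output to a curated tissue-relevant feature list.
#'
#' @param profile Named numeric vector from [annotate()].
#' @param keep Character vector of feature names to retain.
#' @return Named numeric vector.
#' @export
subset_features <- function(profile, keep) {
  unknown <- setdiff(keep, names(profile))
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  profile[names(profile) %in% keep]
}

#' Read a feature-subset file (one feature name per line)
#' @param path Plain-text file.
#' @return Character vector of feature names.
#' @export
read_feature_subset <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @export
print.synthetic_annotator <- function(x, ...) {
  cat(sprintf("synthetic annotator: %d feature(s), input length %d\n",
              length(x$features), x$input_length))
  for (f in x$features) {
    cat(sprintf("  %s: %d motif(s)%s%s\n", f$name, length(f$pwms),
                if (f$coop_weight != 0) ", cooperative" else "",
                if (is.finite(f$cutoff)) "" else ", smooth occupancy"))
  }
  invisible(x)
}

#' Smooth-occupancy annotator for empirical-null calibration studies
#'
#' Builds random real-valued PWM features with `cutoff = -Inf`, so every
#' position contributes to the occupancy and any substitution changes each
#' feature's probability continuously — the regime in which background
#' E statistics are continuously distributed and empirical e-values can be
#' checked for uniformity. Each feature's logit is auto-centred: the
#' occupancy is probed on windows extracted from `genome` and the weight and
#' intercept set so probabilities stay well inside (0, 1) across windows.
#'
#' @param genome A `caism_genome` used to probe the occupancy scale.
#' @param n_features Number of features.
#' @param seed Seed for the PWM draws.
#' @param L Window length the annotator will score.
#' @param motif_width Motif width (default 5).
#' @return A `synthetic_annotator`.
#' @export
calibration_annotator <- function(genome, n_features = 2, seed, L = 2000L,
                                  motif_width = 5L) {
  lens <- contig_lengths(genome)
  chrom <- names(lens)[which.max(lens)]
  probes <- vapply(seq(0.25, 0.75, length.out = 3), function(q) {
    start <- max(1L, as.integer(q * (lens[[chrom]] - L)))
    extract_seq(genome, chrom, start, start + L - 1L)
  }, "")
  with_seed(seed, {
    feats <- lapply(seq_len(n_features), function(i) {
      pwm <- matrix(stats::rnorm(4L * motif_width, sd = 0.7),
                    4L, motif_width)
      raw <- motif_feature(paste0("calib", i), list(pwm), weights = 1,
                           intercept = 0, cutoff = -Inf)
      Rhat <- mean(vapply(probes, function(s)
        motif_occupancy(encode_seq(s), encode_seq(revcomp(s)),
                        raw$pwms[[1]], -Inf, TRUE), 0))
      w <- 4 / Rhat
      motif_feature(paste0("calib", i), list(pwm), weights = w,
                    intercept = -0.5 - w * Rhat, cutoff = -Inf)
    })
    synthetic_annotator(feats, input_length = L)
  })
}
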