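flank <- function(core, len = 60, seed = 21) {
  set.seed(seed)
  bg <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
  paste0(substr(bg, 1, 20), core, substr(bg, 21 + nchar(core), len))
}

test_that("an exact motif match raises the feature probability by its weight", {
  f <- motif_feature("F", "TTAGGC", weights = 2, intercept = -1)
  ann <- synthetic_annotator(list(f), input_length = 60)
  hit <- flank("TTAGGC")
  miss <- sub("TTAGGC", "TTACGC", hit)
  p_hit <- annotate(ann, hit)
  p_miss <- annotate(ann, miss)
  expect_gt(p_hit[["F"]], p_miss[["F"]])
  # closed form: occupancy 1 at the planted site, 0 elsewhere (cutoff mode)
  expect_equal(p_hit[["F"]], plogis(-1 + 2 * 1))
  expect_equal(p_miss[["F"]], plogis(-1))
})

test_that("a motif with no affinity for the sequence scores the floor", {
  f <- motif_feature("F", "TTGGCC", weights = 3, intercept = -2)
  ann <- synthetic_annotator(list(f), input_length = 40)
  allA <- strrep("A", 40)
  expect_equal(annotate(ann, allA)[["F"]], plogis(-2))
})

test_that("strand-symmetric scoring is exactly reverse-complement invariant", {
  f1 <- motif_feature("sym", "TTAGGC", weights = 2, intercept = -1)
  ann <- synthetic_annotator(list(f1), input_length = 60)
  s <- flank("TTAGGC", seed = 31)
  expect_identical(annotate(ann, s), annotate(ann, revcomp(s)))
  # smooth-occupancy mode must also be bit-identical
  f2 <- motif_feature("sm", "TTAGGC", weights = 0.2, intercept = -1,
                      mismatch = -2, cutoff = -Inf)
  ann2 <- synthetic_annotator(list(f2), input_length = 60)
  expect_identical(annotate(ann2, s), annotate(ann2, revcomp(s)))
  # without symmetry the two strands generally differ
  f3 <- motif_feature("asym", "TTAGGC", weights = 0.2, intercept = -1,
                      mismatch = -2, cutoff = -Inf, strand_symmetric = FALSE)
  ann3 <- synthetic_annotator(list(f3), input_length = 60)
  expect_false(identical(annotate(ann3, s), annotate(ann3, revcomp(s))))
})

test_that("annotation is deterministic and respects the input contract", {
  f <- motif_feature("F", "ACGTAC")
  ann <- synthetic_annotator(list(f), input_length = 50)
  s <- flank("ACGTAC", len = 50)
  expect_identical(annotate(ann, s), annotate(ann, s))
  expect_error(annotate(ann, substr(s, 1, 49)), "length 49")
  expect_error(annotate(ann, paste0(substr(s, 1, 49), "Z")), "A/C/G/T/N")
  strict <- synthetic_annotator(list(f), input_length = 50, allow_n = FALSE)
  expect_error(annotate(strict, paste0(substr(s, 1, 49), "N")), "refuse")
})

test_that("N bases have zero affinity inside a motif instance", {
  f <- motif_feature("F", "TTAGGC", weights = 2, intercept = -1)
  ann <- synthetic_annotator(list(f), input_length = 60)
  hit <- flank("TTAGGC")
  broken <- sub("TTAGGC", "TTANGC", hit)
  expect_equal(annotate(ann, broken)[["F"]], plogis(-1))
})

test_that("probabilities are clamped into the open unit interval", {
  up <- motif_feature("hi", "ACGTAC", weights = 100, intercept = 0)
  dn <- motif_feature("lo", "ACGTAC", weights = -100, intercept = 0)
  ann <- synthetic_annotator(list(up, dn), input_length = 50)
  p <- annotate(ann, flank("ACGTAC", len = 50))
  expect_equal(unname(p[["hi"]]), 1 - 1e-6)
  expect_equal(unname(p[["lo"]]), 1e-6)
})

test_that("batch annotation equals elementwise calls and reports failures by index", {
  f <- motif_feature("F", "ACGTAC")
  ann <- synthetic_annotator(list(f), input_length = 50)
  seqs <- vapply(1:3, function(i) flank("ACGTAC", len = 50, seed = i), "")
  expect_identical(annotate_batch(ann, seqs),
                   lapply(seqs, function(s) annotate(ann, s)))
  expect_identical(annotate_batch(ann, list()), list())
  expect_error(annotate_batch(ann, c(seqs, "TOOSHORT")), "sequence 4")
})

test_that("feature-profile subsetting preserves order and rejects typos", {
  f <- lapply(c("a", "b", "c"), function(n) motif_feature(n, "ACGT"))
  ann <- synthetic_annotator(f, input_length = 20)
  p <- annotate(ann, strrep("ACGT", 5))
  expect_identical(subset_features(p, c("a", "b", "c")), p)
  expect_identical(names(subset_features(p, c("c", "a"))), c("a", "c"))
  expect_length(subset_features(p, "b"), 1)
  expect_error(subset_features(p, c("a", "zz")), "zz")
})

test_that("cooperative features need both motifs to move the logit", {
  f <- motif_feature("coop", c("TTAGGC", "GATCCA"), weights = c(0, 0),
                     coop_weight = 1.5, intercept = -1)
  ann <- synthetic_annotator(list(f), input_length = 80)
  both <- flank(paste0("TTAGGC", strrep("C", 10), "GATCCA"), len = 80)
  one <- sub("GATCCA", "GAACCA", both)
  none <- sub("TTAGGC", "TTACGC", one)
  expect_equal(annotate(ann, both)[["coop"]], plogis(-1 + 1.5))
  expect_equal(annotate(ann, one)[["coop"]], plogis(-1))
  expect_equal(annotate(ann, none)[["coop"]], plogis(-1))
})
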