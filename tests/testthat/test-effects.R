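test_that("log-odds change and E statistic match their closed forms", {
  expect_equal(log_odds_change(0.3, 0.3), 0)
  expect_equal(log_odds_change(0.9, 0.5), log(9))
  expect_equal(e_statistic(0.9, 0.5), log(9) * 0.4)
  expect_equal(e_statistic(0.5, 0.5), 0)
  expect_error(log_odds_change(0, 0.5), "strictly inside")
  expect_error(e_statistic(0.5, 1), "strictly inside")
})

test_that("sign identities hold across random probability pairs", {
  set.seed(1)
  p <- runif(1000, 1e-6, 1 - 1e-6)
  q <- runif(1000, 1e-6, 1 - 1e-6)
  expect_equal(log_odds_change(p, q), -log_odds_change(q, p))
  expect_equal(e_statistic(p, q), e_statistic(q, p))
  expect_true(all(e_statistic(p, q) >= 0))
  expect_true(all(sign(log_odds_change(p, q)) == sign(p - q)))
  expect_true(all((e_statistic(p, q) == 0) == (p == q)))
})

test_that("empirical e-values follow add-one rank arithmetic with ties counted", {
  null <- structure(list(estats = list(F = sort(seq_len(999) / 1000)),
                         n = 999L, meta = list()),
                    class = "background_null")
  expect_equal(empirical_e_value(2, null, "F"), 1 / 1000)
  expect_equal(empirical_e_value(0, null, "F"), 1)
  expect_equal(empirical_e_value(0.9995, null, "F"), 1 / 1000)
  # ties: value equal to background members counts them all
  expect_equal(empirical_e_value(0.999, null, "F"), 2 / 1000)
  # monotone non-increasing in the statistic
  es <- sort(runif(50))
  ev <- empirical_e_value(es, null, "F")
  expect_true(all(diff(ev) <= 0))
  expect_error(empirical_e_value(1, null, "nope"), "absent")
})

test_that("background construction is seeded, deterministic and exact at n = 1", {
  g <- toy_genome(len = 8000, seed = 4)
  ann <- synthetic_annotator(list(motif_feature("F", "TTAGGCAATT")),
                             input_length = 2000)
  b1 <- build_background(g, ann, n = 5, seed = 77)
  b2 <- build_background(g, ann, n = 5, seed = 77)
  expect_identical(b1$estats, b2$estats)
  expect_equal(b1$meta$seed, 77)
  b3 <- build_background(g, ann, n = 1, seed = 3)
  expect_length(b3$estats$F, 1)
  expect_error(build_background(g, ann, n = 0, seed = 1), "at least 1")
})

test_that("a null annotator yields an all-zero background", {
  g <- toy_genome(len = 8000, seed = 4)
  # 10-mer absent from the genome scores zero occupancy everywhere, and in
  # cutoff mode substitutions far from any instance cannot create one
  ann <- synthetic_annotator(list(motif_feature("F", "TTAGGCAATT")),
                             input_length = 2000)
  null <- build_background(g, ann, n = 50, seed = 9)
  expect_true(all(null$estats$F == 0))
})

test_that("background sampling respects exclusion intervals and edge margins", {
  g <- toy_genome(len = 8000, seed = 4)
  v <- sample_background_variants(g, 200, seed = 5, L = 2000,
                                  exclude = data.frame(chrom = "chr1",
                                                       start = 3000,
                                                       end = 5000))
  expect_true(all(v$pos >= 1000 & v$pos <= 7000))
  expect_false(any(v$pos >= 3000 & v$pos <= 5000))
  expect_true(all(vapply(seq_len(200), function(i)
    extract_seq(g, v$chrom[i], v$pos[i], v$pos[i]) == v$major[i], TRUE)))
})

test_that("score_variant recovers a planted loss of function and nothing else", {
  g <- toy_genome(len = 6000, seed = 14)
  # plant a motif whose 4th base is the major allele of the center variant
  motif <- "TTAGGCAATT"
  chars <- strsplit(g$seqs[["chr1"]], "")[[1]]
  chars[2997:3006] <- strsplit(motif, "")[[1]]
  g <- genome_from_seqs(c(chr1 = paste(chars, collapse = "")))
  v <- toy_variants("rsP", 3000, "G", "C")
  ann <- synthetic_annotator(list(
    motif_feature("hit", motif, weights = 2, intercept = -1),
    motif_feature("other", "CCGGAATTGG", weights = 2, intercept = -1)))
  eff <- score_variant(g, v, annotator = ann)
  expect_equal(nrow(eff), 2)
  expect_equal(eff$log_odds_change[eff$feature == "hit"], 2)
  expect_equal(eff$direction[eff$feature == "hit"], "loss")
  expect_equal(eff$log_odds_change[eff$feature == "other"], 0)
  expect_equal(eff$e_stat[eff$feature == "other"], 0)
})

test_that("with zero neighbours the context run equals the no-context analysis", {
  g <- toy_genome(len = 6000, seed = 15)
  maj <- extract_seq(g, "chr1", 3000, 3000)
  v <- toy_variants("rsZ", 3000, maj, setdiff(c("A", "C", "G", "T"), maj)[1])
  ann <- synthetic_annotator(list(motif_feature("F", "TTAGGCAATT",
                                                mismatch = -2,
                                                cutoff = -Inf)))
  a <- score_variant(g, v, neighbors = NULL, annotator = ann)
  b <- score_variant(g, v, annotator = ann,
                     contexts = enumerate_contexts(v, NULL, "minor"))
  expect_identical(a, b)
  expect_equal(a$context_label, "center=minor")
})
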