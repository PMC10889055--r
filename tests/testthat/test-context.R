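make_nbs <- function(k) {
  if (k == 0) return(NULL)
  toy_variants(paste0("n", seq_len(k)), 5000 + seq_len(k) * 10,
               rep("A", k), rep("G", k))
}

test_that("enumeration matches the brute-force cross-product for k = 0..6", {
  center <- toy_variants("c", 5000, "A", "G")
  for (k in 0:6) {
    nbs <- make_nbs(k)
    ctx <- enumerate_contexts(center, nbs, "minor")
    expect_length(ctx, 2^k)
    labels <- vapply(ctx, function(a) a$label, "")
    expect_false(anyDuplicated(labels) > 0)
    # independent cross-product oracle
    if (k > 0) {
      grid <- expand.grid(rep(list(c("major", "minor")), k),
                          stringsAsFactors = FALSE)
      oracle <- apply(grid, 1, function(row)
        paste0("center=minor;",
               paste0(paste0("n", seq_len(k)), "=", row, collapse = ";")))
      expect_setequal(labels, oracle)
    } else {
      expect_identical(labels, "center=minor")
    }
    # deterministic order: all-major first, all-minor last, stable on rerun
    expect_false(grepl("n[0-9]+=minor", labels[1]))
    expect_false(grepl("n[0-9]+=major", labels[2^k]))
    expect_identical(labels,
                     vapply(enumerate_contexts(center, nbs, "minor"),
                            function(a) a$label, ""))
  }
})

test_that("enumeration order is lexicographic over position-ordered neighbours", {
  center <- toy_variants("c", 5000, "A", "G")
  # ids deliberately unsorted relative to position
  nbs <- toy_variants(c("zz", "aa"), c(4900, 5100), c("A", "C"), c("G", "T"))
  labels <- vapply(enumerate_contexts(center, nbs, "minor"),
                   function(a) a$label, "")
  expect_identical(labels, c("center=minor;zz=major;aa=major",
                             "center=minor;zz=major;aa=minor",
                             "center=minor;zz=minor;aa=major",
                             "center=minor;zz=minor;aa=minor"))
})

test_that("enumeration refuses combinatorial explosions and duplicate ids", {
  center <- toy_variants("c", 50000, "A", "G")
  nbs <- make_nbs(21)
  expect_error(enumerate_contexts(center, nbs, max_neighbors = 12),
               "2\\^21.*restrict")
  dup <- rbind(make_nbs(2), make_nbs(2)[1, ])
  expect_error(enumerate_contexts(center, dup), "duplicate")
})

test_that("context labels are a bijective encoding", {
  center <- toy_variants("c", 5000, "A", "G")
  for (a in enumerate_contexts(center, make_nbs(3), "minor")) {
    back <- parse_context_label(a$label, center$id)
    expect_identical(back$center_allele, a$center_allele)
    expect_identical(back$neighbor_alleles, a$neighbor_alleles)
    expect_identical(back$label, a$label)
  }
  expect_error(parse_context_label("rsA=major;center=minor"), "malformed")
})

test_that("context windows are distinct and consistent with the no-context pair", {
  g <- toy_genome(len = 10000, seed = 13)
  pos <- c(5000, 4500, 5200, 5700)
  majors <- vapply(pos, function(p) extract_seq(g, "chr1", p, p), "")
  minors <- vapply(majors, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  v <- toy_variants(c("c", "n1", "n2", "n3"), pos, majors, minors)
  center <- v[1, ]
  nbs <- v[-1, ]
  ctx <- enumerate_contexts(center, nbs, "minor")
  ws <- contexts_to_windows(g, center, nbs, ctx)
  expect_length(ws, 8)
  seqs <- vapply(ws, function(w) w$seq, "")
  expect_equal(length(unique(seqs)), 8)
  expect_true(all(nchar(seqs) == 2000))
  # all-major context with center=major is the plain reference window
  ctx_maj <- enumerate_contexts(center, nbs, "major")
  w0 <- contexts_to_windows(g, center, nbs, ctx_maj[1])[[1]]
  expect_identical(w0$seq, build_window(g, center, nbs)$seq)
  # all-major context with center=minor is the no-context alternate sequence
  expect_identical(ws[[1]]$seq,
                   build_window(g, center, nbs,
                                allele_choice = c(c = "minor"))$seq)
})
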