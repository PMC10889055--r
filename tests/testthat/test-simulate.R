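test_that("the scenario is a deterministic function of its seed", {
  a <- default_scenario(7)
  b <- default_scenario(7)
  expect_identical(a$genome_seq, b$genome_seq)
  expect_identical(a$variants, b$variants)
  expect_identical(a$motifs, b$motifs)
  c <- default_scenario(8)
  expect_false(identical(a$genome_seq, c$genome_seq))
  # and so are the downstream generators
  expect_identical(make_haplotypes(a)$haplotypes,
                   make_haplotypes(b)$haplotypes)
  expect_identical(make_cohort(a)$geno, make_cohort(b)$geno)
})

test_that("planted motif instances sit in the genome as declared", {
  spec <- scn()
  g <- scn_genome()
  for (i in seq_len(nrow(spec$planted))) {
    pl <- spec$planted[i, ]
    inst <- extract_seq(g, spec$contig, pl$start, pl$end)
    motif <- spec$motifs[[pl$motif]]
    if (pl$completes == "major") {
      # the assembly (major allele) carries the full instance
      expect_identical(inst, motif)
    } else {
      # the assembly carries the non-binding major at the variant offset
      expect_equal(sum(strsplit(inst, "")[[1]] !=
                         strsplit(motif, "")[[1]]), 1)
      v <- get_variant(spec$variants, pl$variant_id)
      expect_identical(substr(motif, v$pos - pl$start + 1,
                              v$pos - pl$start + 1), v$minor)
    }
  }
})

test_that("no chance motif occurrence survives outside the planted sites", {
  spec <- scn()
  s <- spec$genome_seq
  for (nm in names(spec$motifs)) {
    motif <- spec$motifs[[nm]]
    for (pat in c(motif, revcomp(motif))) {
      hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      planted_here <- spec$planted$start[spec$planted$motif == nm &
                                           spec$planted$completes == "major"]
      expect_true(all(hits %in% planted_here))
    }
  }
})

test_that("haplotype LD targets are realized within tolerance", {
  spec <- scn()
  hap <- make_haplotypes(spec)
  pair <- spec$ld$pairs
  r2 <- r_squared(hap, pair$a, pair$b)
  expect_lt(abs(r2 - pair$target_r2), 0.05)
  # target 1 gives identical columns, exactly
  spec1 <- spec
  spec1$ld$pairs$target_r2 <- 1
  hap1 <- make_haplotypes(spec1)
  expect_identical(hap1$haplotypes[, pair$a], hap1$haplotypes[, pair$b])
  expect_equal(r_squared(hap1, pair$a, pair$b), 1)
  # target 0 gives independent draws
  spec0 <- spec
  spec0$ld$pairs$target_r2 <- 0
  hap0 <- make_haplotypes(spec0, n_hap = 10000)
  expect_lt(r_squared(hap0, pair$a, pair$b), 0.01)
})

test_that("infeasible haplotype requests are rejected", {
  spec <- scn()
  expect_error(make_haplotypes(spec, n_hap = 50), "at least 100")
  bad <- spec
  bad$ld$pairs$target_r2 <- 1.2
  expect_error(make_haplotypes(bad), "\\[0, 1\\]")
  uneq <- spec
  uneq$variants$maf[uneq$variants$id == "rs004"] <- 0.4
  expect_error(make_haplotypes(uneq), "unequal")
})

test_that("a neutral cohort reproduces the baseline case rate", {
  gt <- simulate_case_control(20000, 0.3, 0.3, baseline = 0.35, seed = 17)
  expect_lt(abs(mean(gt$phenotype) - 0.35), 0.01)
  expect_error(simulate_case_control(10, 0, 0.3, 0.35), "maf_a > 0")
})

test_that("scenario files round-trip through the plain-text readers", {
  dir <- withr::local_tempdir()
  spec <- scn()
  write_scenario(spec, dir)
  g <- load_reference(file.path(dir, "genome.fa"))
  expect_identical(g$seqs[[spec$contig]], spec$genome_seq)
  v <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(v$id, spec$variants$id)
  expect_equal(v$maf, spec$variants$maf)
  hap <- read_haplotypes(file.path(dir, "haplotypes.tsv"))
  expect_identical(hap$haplotypes, make_haplotypes(spec)$haplotypes)
  gt <- read_genotypes(file.path(dir, "genotypes.tsv"),
                       file.path(dir, "phenotype.tsv"))
  ref <- make_cohort(spec)
  expect_equal(unname(gt$geno[, spec$cohort$pair]),
               unname(ref$geno[, spec$cohort$pair]))
  expect_equal(gt$phenotype, ref$phenotype)
  key <- jsonlite::read_json(file.path(dir, "answer_key.json"))
  expect_equal(key$ld$anchor, "rs003")
  expect_equal(key$context$margin, spec$answer_key$context$margin)
})
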