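# Shared fixtures. Heavy objects (the default scenario scored with its full
# n = 999 background) are built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

scn <- function() cached("scn", default_scenario(7))
scn_genome <- function() cached("scn_genome", make_genome(scn()))
scn_annotator <- function() cached("scn_annotator", make_annotator(scn()))
scn_scored <- function() cached("scn_scored", score_scenario(scn()))

# one full run_all() with a small background, shared by the pipeline tests
scn_fast_run <- function() cached("scn_fast_run", {
  dir <- file.path(tempdir(), "caism-fast-run")
  res <- run_all(scn(), dir, run_config(background_n = 49L))
  list(res = res, dir = dir)
})

# a plain random genome with no planted structure
toy_genome <- function(len = 10000, seed = 99) {
  set.seed(seed)
  genome_from_seqs(c(chr1 = paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")))
}

toy_variants <- function(ids, pos, major, minor, chrom = "chr1", maf = NULL) {
  df <- data.frame(id = ids, chrom = chrom, pos = pos,
                   major = major, minor = minor, stringsAsFactors = FALSE)
  if (!is.null(maf)) df$maf <- maf
  variant_table(df)
}

# reverse complement written independently of the package
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# independent direct evaluation of the cutoff-mode occupancy scoring rule:
# plain loops and substring comparison, no shared code with the package
oracle_occupancy <- function(seq, motif, cutoff = -15, mismatch = -30) {
  mchars <- strsplit(motif, "")[[1]]
  m <- length(mchars)
  tot <- 0
  for (s in c(seq, rc_chr(seq))) {
    schars <- strsplit(s, "")[[1]]
    for (i in seq_len(nchar(s) - m + 1)) {
      sc <- sum(schars[i:(i + m - 1)] != mchars) * mismatch
      if (sc >= cutoff) tot <- tot + exp(sc)
    }
  }
  tot
}

# brute-force LD r^2 by counting the four haplotype classes
r2_brute <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  pa <- sum(x) / n
  pb <- sum(y) / n
  D <- n11 / n - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}
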