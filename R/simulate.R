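#' Default synthetic scenario with planted ground truth
#'
#' Builds a fully specified desk-scale study: a 60 kb random genome with
#' planted 10-bp motif instances, 10 candidate variants (each with three
#' in-window neighbours, hence 8 genetic contexts), a 10-feature synthetic
#' annotator, haplotype LD targets and a case/control cohort model. The
#' planted design mirrors the qualitative phenomena the pipeline is meant
#' to detect:
#'
#' * a dominant loss-of-function variant (`rs001`) whose motif disruption is
#'   identical in every context;
#' * a context-dependent pair (`rs002` with cooperative neighbour
#'   `rs002.n2`): the center's loss of function is amplified by exactly the
#'   cooperative logit weight when the neighbour carries its minor allele;
#' * a high-LD pair (`rs003`/`rs004`, target r-squared 0.96) in which only
#'   the anchor disrupts a motif — tightly linked variants with divergent
#'   predicted effects;
#' * a protective epistatic pair (`rs005`/`rs006`) in the cohort model
#'   (main-effect odds ratios 0.75/0.8, interaction odds ratio 0.5,
#'   minor-allele frequency 0.3 at both loci, baseline case rate 0.35).
#'
#' Everything downstream is a deterministic function of the seed. The
#' machine-readable answer key (see `$answer_key`) records which
#' variant/feature pairs carry true effects and their closed-form sizes.
#'
#' @param seed Integer seed.
#' @return A `scenario_spec` list.
#' @export
default_scenario <- function(seed = 7L) {
  seed <- as.integer(seed)
  contig <- "chr1"
  glen <- 60000L
  L <- 2000L
  feature_defs <- list(
    list(name = "DNase_glioblastoma",   role = "dominant",    weight = 2.5, intercept = -1.25),
    list(name = "CTCF_glioblastoma",    role = "cooperative", weight = 1.2, coop = 1.0, intercept = -1.1),
    list(name = "H3K18ac_NPC",          role = "ld_anchor",   weight = 2.0, intercept = -1.0),
    list(name = "DNase_NHA",            role = "epi_locus",   weight = 2.0, intercept = -1.0),
    list(name = "H3K23ac_NPC",          role = "null", weight = 1, intercept = -1.5),
    list(name = "DNase_monocyte_CD14",  role = "null", weight = 1, intercept = -1.5),
    list(name = "CTCF_NHA",             role = "null", weight = 1, intercept = -1.5),
    list(name = "H3K9ac_NPC",           role = "null", weight = 1, intercept = -1.5),
    list(name = "DNase_astrocyte",      role = "null", weight = 1, intercept = -1.5),
    list(name = "H3K27ac_glioblastoma", role = "null", weight = 1, intercept = -1.5))

  cand_pos <- c(rs001 = 5000L, rs002 = 9000L, rs003 = 13000L, rs004 = 13350L,
                rs005 = 17000L, rs006 = 21000L, rs007 = 25000L,
                rs008 = 29000L, rs009 = 33000L, rs010 = 37000L)

  with_seed(seed, {
    motif_names <- c("m_dom", "m_coop_center", "m_coop_partner", "m_ld",
                     "m_epi", paste0("m_null", 1:6))
    motifs <- list()
    for (nm in motif_names) {
      repeat {
        cand <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                      collapse = "")
        clash <- any(vapply(motifs, function(m)
          m == cand || revcomp(m) == cand, TRUE)) || revcomp(cand) == cand
        if (!clash) break
      }
      motifs[[nm]] <- cand
    }

    # candidates + three in-window neighbours each
    vars <- data.frame(id = names(cand_pos), pos = unname(cand_pos),
                       role = "candidate", stringsAsFactors = FALSE)
    nb_of <- list()
    for (id in names(cand_pos)) {
      p <- cand_pos[[id]]
      if (id == "rs003") {
        nbs <- data.frame(id = c("rs004", "rs003.n1", "rs003.n3"),
                          pos = c(13350L, 12600L, 13600L))
      } else if (id == "rs004") {
        nbs <- data.frame(id = c("rs003", "rs003.n1", "rs003.n3"),
                          pos = c(13000L, 12600L, 13600L))
      } else {
        off <- c(-400L, if (id == "rs002") 300L else 250L, 600L)
        nbs <- data.frame(id = paste0(id, ".n", 1:3), pos = p + off)
      }
      nb_of[[id]] <- nbs$id
      new <- !(nbs$id %in% vars$id)
      if (any(new)) {
        vars <- rbind(vars, data.frame(id = nbs$id[new], pos = nbs$pos[new],
                                       role = "neighbor",
                                       stringsAsFactors = FALSE))
      }
    }
    vars$chrom <- contig

    # planted motif instances: variant at motif offset 4 (1-based)
    planted <- data.frame(
      motif = c("m_dom", "m_coop_center", "m_coop_partner", "m_ld", "m_epi"),
      variant_id = c("rs001", "rs002", "rs002.n2", "rs003", "rs005"),
      completes = c("major", "major", "minor", "minor", "major"),
      stringsAsFactors = FALSE)
    planted$pos <- vars$pos[match(planted$variant_id, vars$id)]
    planted$start <- planted$pos - 3L
    planted$end <- planted$start + 9L

    # background genome, then plant instances
    chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    for (i in seq_len(nrow(planted))) {
      chars[planted$start[i]:planted$end[i]] <-
        strsplit(motifs[[planted$motif[i]]], "")[[1]]
    }
    # minor-completes sites: the assembly carries the (non-binding) major
    vars$major <- NA_character_
    vars$minor <- NA_character_
    for (i in seq_len(nrow(planted))) {
      vid <- planted$variant_id[i]
      j <- match(vid, vars$id)
      mbase <- substr(motifs[[planted$motif[i]]], 4, 4)
      other <- sample(setdiff(c("A", "C", "G", "T"), mbase), 1L)
      if (planted$completes[i] == "major") {
        vars$major[j] <- mbase
        vars$minor[j] <- other
      } else {
        vars$major[j] <- other
        vars$minor[j] <- mbase
        chars[vars$pos[j]] <- other
      }
    }
    protect <- sort(unique(c(unlist(mapply(seq, planted$start, planted$end,
                                           SIMPLIFY = FALSE)), vars$pos)))
    chars <- scrub_motifs(chars, unlist(motifs), protect)
    # remaining variants: major = assembly base, minor random other
    for (j in which(is.na(vars$major))) {
      vars$major[j] <- chars[vars$pos[j]]
      vars$minor[j] <- sample(setdiff(c("A", "C", "G", "T"), vars$major[j]), 1L)
    }
    vars$maf <- round(stats::runif(nrow(vars), 0.1, 0.5), 3)
    # frequencies that enter the LD / cohort ground truth are fixed by design
    vars$maf[vars$id %in% c("rs003", "rs004")] <- 0.25
    vars$maf[vars$id %in% c("rs005", "rs006")] <- 0.30
    vars <- vars[, c("id", "chrom", "pos", "major", "minor", "maf", "role")]

    null_i <- 0L
    features <- lapply(feature_defs, function(fd) {
      mot <- switch(fd$role,
                    dominant = "m_dom",
                    cooperative = c("m_coop_center", "m_coop_partner"),
                    ld_anchor = "m_ld",
                    epi_locus = "m_epi",
                    null = {
                      null_i <<- null_i + 1L
                      paste0("m_null", null_i)
                    })
      list(name = fd$name, motifs = unname(unlist(motifs[mot])),
           weights = if (fd$role == "cooperative") c(fd$weight, 0) else fd$weight,
           coop_weight = if (is.null(fd$coop)) 0 else fd$coop,
           intercept = fd$intercept)
    })

    spec <- structure(list(
      seed = seed, contig = contig, genome_length = glen, L = L,
      genome_seq = paste(chars, collapse = ""),
      motifs = motifs, planted = planted, features = features,
      variants = variant_table(vars[, 1:6]),
      roles = stats::setNames(vars$role, vars$id),
      candidates = names(cand_pos), neighbors = nb_of,
      ld = list(pairs = data.frame(a = "rs003", b = "rs004",
                                   target_r2 = 0.96,
                                   stringsAsFactors = FALSE),
                n_hap = 2000L),
      cohort = list(n = 2000L, baseline = 0.35,
                    pair = c("rs005", "rs006"),
                    or_main = c(rs005 = 0.75, rs006 = 0.8),
                    or_interaction = 0.5)),
      class = "scenario_spec")
    spec$answer_key <- scenario_answer_key(spec)
    spec
  })
}

scenario_answer_key <- function(spec) {
  fw <- function(i) spec$features[[i]]
  list(
    true_effects = data.frame(
      variant_id = c("rs001", "rs002", "rs003", "rs005"),
      feature = c(fw(1)$name, fw(2)$name, fw(3)$name, fw(4)$name),
      log_odds_change_no_context = c(fw(1)$weights[1], fw(2)$weights[1],
                                     -fw(3)$weights[1], fw(4)$weights[1]),
      stringsAsFactors = FALSE),
    context = list(center = "rs002", partner = "rs002.n2",
                   feature = fw(2)$name, margin = fw(2)$coop_weight),
    ld = list(anchor = "rs003", partner = "rs004", target_r2 = 0.96,
              feature = fw(3)$name),
    epistasis = list(a = "rs005", b = "rs006",
                     or_interaction = spec$cohort$or_interaction,
                     protective = TRUE),
    null_variants = setdiff(spec$candidates,
                            c("rs001", "rs002", "rs003", "rs005")))
}

# remove chance exact occurrences (either strand) of the motifs outside the
# protected planted instances, by mutating one unprotected base per hit
scrub_motifs <- function(chars, motif_strings, protect) {
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in 1:50) {
    s <- paste(chars, collapse = "")
    dirty <- FALSE
    for (m in motif_strings) {
      for (pat in unique(c(m, revcomp(m)))) {
        hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (h in hits) {
          span <- h:(h + nchar(pat) - 1L)
          free <- setdiff(span, protect)
          if (!length(free)) next  # the planted instance itself
          i <- free[ceiling(length(free) / 2)]
          chars[i] <- cycle[[chars[i]]]
          dirty <- TRUE
        }
      }
      if (dirty) break
    }
    if (!dirty) return(chars)
  }
  stop("could not scrub chance motif occurrences from the genome")
}

#' Genome of a scenario
#' @param spec A `scenario_spec`.
#' @param fasta Optional path; when given the genome is also written as FASTA.
#' @return A `caism_genome`.
#' @export
make_genome <- function(spec, fasta = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  g <- genome_from_seqs(stats::setNames(spec$genome_seq, spec$contig))
  if (!is.null(fasta)) write_genome(g, fasta)
  g
}

#' Synthetic annotator of a scenario
#' @param spec A `scenario_spec`.
#' @return A `synthetic_annotator` over the scenario's planted features.
#' @export
make_annotator <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  synthetic_annotator(lapply(spec$features, function(f)
    motif_feature(f$name, f$motifs, weights = f$weights,
                  coop_weight = f$coop_weight, intercept = f$intercept)),
    input_length = spec$L)
}

#' Phased haplotypes with target pairwise LD
#'
#' Variants are drawn independently as Bernoulli(maf) per haplotype except
#' for declared LD pairs, where the partner copies the anchor's allele with
#' probability `sqrt(target_r2)` (and draws independently otherwise), which
#' makes the expected r-squared equal to the target; both pair members must
#' share a minor-allele frequency for the target to be attainable.
#'
#' @param spec A `scenario_spec`.
#' @param n_hap Number of haplotype rows (default from the spec; must be at
#'   least 100).
#' @param seed Seed (default derived from the scenario seed).
#' @return A `haplotype_matrix` over all scenario variants.
#' @export
make_haplotypes <- function(spec, n_hap = spec$ld$n_hap,
                            seed = spec$seed + 101L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (n_hap < 100L) stop("haplotype count must be at least 100")
  pairs <- spec$ld$pairs
  if (any(pairs$target_r2 < 0 | pairs$target_r2 > 1)) {
    stop("target r2 must lie in [0, 1]")
  }
  if (anyDuplicated(c(pairs$a, pairs$b))) {
    stop("infeasible joint LD targets: a variant appears in several pairs")
  }
  v <- spec$variants
  maf <- stats::setNames(v$maf, v$id)
  bad <- pairs$target_r2 > 0 & maf[pairs$a] != maf[pairs$b]
  if (any(bad)) {
    stop("LD pair(s) with unequal minor-allele frequencies: ",
         paste(pairs$a[bad], pairs$b[bad], sep = "/", collapse = ", "))
  }
  with_seed(seed, {
    hap <- matrix(0L, nrow = n_hap, ncol = nrow(v),
                  dimnames = list(NULL, v$id))
    for (id in v$id) hap[, id] <- stats::rbinom(n_hap, 1L, maf[[id]])
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      copy <- stats::runif(n_hap) < sqrt(pairs$target_r2[i])
      hap[copy, b] <- hap[copy, a]
    }
    haplotype_matrix(hap)
  })
}

#' Simulate a case/control cohort with a planted pairwise interaction
#'
#' Genotypes at two loci are Binomial(2, maf) dosages; case status follows
#' `logit P(case) = logit(baseline) + log(or_a) g_a + log(or_b) g_b +
#' log(or_interaction) g_a g_b`. Additional independent loci can be appended
#' via `extra_loci`. When `seed` is NULL the current RNG stream is used (so
#' the generator composes with `replicate()` under one outer seed).
#'
#' @param n Samples.
#' @param maf_a,maf_b Minor-allele frequencies in (0, 1).
#' @param baseline Baseline case probability in (0, 1).
#' @param or_a,or_b Per-dosage main-effect odds ratios (> 0).
#' @param or_interaction Odds ratio per dosage product (> 0); 1 = no
#'   epistasis.
#' @param ids Ids of the two loci.
#' @param extra_loci Optional data.frame `id`, `maf` of independent loci.
#' @param seed Optional seed.
#' @return A `genotype_table`.
#' @export
simulate_case_control <- function(n, maf_a, maf_b, baseline,
                                  or_a = 1, or_b = 1, or_interaction = 1,
                                  ids = c("A", "B"), extra_loci = NULL,
                                  seed = NULL) {
  stopifnot(maf_a > 0, maf_a < 1, maf_b > 0, maf_b < 1,
            baseline > 0, baseline < 1,
            or_a > 0, or_b > 0, or_interaction > 0)
  run <- function() {
    ga <- stats::rbinom(n, 2L, maf_a)
    gb <- stats::rbinom(n, 2L, maf_b)
    lp <- stats::qlogis(baseline) + log(or_a) * ga + log(or_b) * gb +
      log(or_interaction) * ga * gb
    pheno <- stats::rbinom(n, 1L, stats::plogis(lp))
    geno <- cbind(ga, gb)
    colnames(geno) <- ids
    if (!is.null(extra_loci)) {
      ex <- vapply(extra_loci$maf, function(m) stats::rbinom(n, 2L, m),
                   integer(n))
      colnames(ex) <- extra_loci$id
      geno <- cbind(geno, ex)
    }
    genotype_table(geno, pheno)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Case/control cohort of a scenario
#'
#' Draws the scenario's cohort: the declared epistatic pair with its planted
#' main-effect and interaction odds ratios, plus the remaining candidate
#' variants as independent phenotype-neutral loci.
#'
#' @param spec A `scenario_spec`.
#' @param n Samples (default from the spec).
#' @param seed Seed (default derived from the scenario seed).
#' @return A `genotype_table` over the scenario's candidate variants.
#' @export
make_cohort <- function(spec, n = spec$cohort$n, seed = spec$seed + 202L) {
  stopifnot(inherits(spec, "scenario_spec"))
  ch <- spec$cohort
  v <- spec$variants
  others <- setdiff(spec$candidates, ch$pair)
  simulate_case_control(
    n = n,
    maf_a = v$maf[match(ch$pair[1], v$id)],
    maf_b = v$maf[match(ch$pair[2], v$id)],
    baseline = ch$baseline,
    or_a = ch$or_main[[ch$pair[1]]], or_b = ch$or_main[[ch$pair[2]]],
    or_interaction = ch$or_interaction,
    ids = ch$pair,
    extra_loci = data.frame(id = others,
                            maf = v$maf[match(others, v$id)],
                            stringsAsFactors = FALSE),
    seed = seed)
}

#' Write every scenario input as plain-text files
#'
#' Emits `genome.fa`, `variants.tsv`, `haplotypes.tsv`, `genotypes.tsv`,
#' `phenotype.tsv` and `answer_key.json` under `dir`.
#'
#' @param spec A `scenario_spec`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(spec, dir) {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  make_genome(spec, fasta = file.path(dir, "genome.fa"))
  utils::write.table(spec$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hap <- make_haplotypes(spec)
  utils::write.table(hap$haplotypes, file.path(dir, "haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- make_cohort(spec)
  geno <- data.frame(sample_id = gt$sample_ids, gt$geno,
                     check.names = FALSE)
  utils::write.table(geno, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = gt$sample_ids,
                                status = ifelse(gt$phenotype == 1,
                                                "case", "control")),
                     file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(spec$answer_key,
                       file.path(dir, "answer_key.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic scenario (seed %d): %d bp genome, ",
                     "%d variants (%d candidates), %d features\n"),
              x$seed, x$genome_length, nrow(x$variants),
              length(x$candidates), length(x$features)))
  invisible(x)
}
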