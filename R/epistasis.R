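#' Construct a case/control genotype table
#'
#' @param geno Matrix of minor-allele dosages in `{0, 1, 2, NA}`; rows are
#'   samples, columns are variants (column names = variant ids).
#' @param phenotype 0/1 (control/case) vector, one per sample; or a
#'   character vector with values `"case"`/`"control"`.
#' @param sample_ids Optional sample ids (default from rownames or
#'   `s1, s2, ...`).
#' @return A `genotype_table` object.
#' @export
genotype_table <- function(geno, phenotype, sample_ids = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) stop("genotype matrix needs variant ids as column names")
  if (!all(geno %in% c(0, 1, 2) | is.na(geno))) {
    stop("genotypes must be minor-allele dosages 0/1/2 or NA")
  }
  if (is.character(phenotype)) {
    if (!all(phenotype %in% c("case", "control"))) {
      stop("character phenotype must be 'case'/'control'")
    }
    phenotype <- as.integer(phenotype == "case")
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(geno) || anyNA(phenotype) ||
      !all(phenotype %in% 0:1)) {
    stop("phenotype must be a complete 0/1 vector, one entry per sample")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(geno)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(geno)))
  }
  structure(list(geno = geno, phenotype = phenotype,
                 sample_ids = sample_ids, variant_ids = colnames(geno)),
            class = "genotype_table")
}

#' Read genotypes (dosage TSV or VCF) plus a phenotype file
#'
#' Dosage TSV: sample ids in the first column, variant ids as remaining
#' headers. VCF: GT fields converted to ALT dosages. Phenotype file:
#' two tab-delimited columns `sample_id`, `status` (case/control or 1/0).
#'
#' @param geno_path Genotype file.
#' @param pheno_path Phenotype file.
#' @return A `genotype_table` restricted to samples present in both files.
#' @export
read_genotypes <- function(geno_path, pheno_path) {
  if (grepl("\\.vcf(\\.gz)?$", geno_path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(geno_path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      sum(as.integer(strsplit(g, "[|/]")[[1]]))
    })
    geno <- t(dos)
  } else {
    tab <- utils::read.delim(geno_path, check.names = FALSE)
    geno <- as.matrix(tab[, -1, drop = FALSE])
    rownames(geno) <- as.character(tab[[1]])
  }
  ph <- utils::read.delim(pheno_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(ph)[1:2] <- c("sample_id", "status")
  common <- intersect(rownames(geno), as.character(ph$sample_id))
  if (!length(common)) stop("no samples shared between genotype and phenotype files")
  geno <- geno[common, , drop = FALSE]
  status <- ph$status[match(common, ph$sample_id)]
  if (is.character(status)) status <- as.integer(status == "case")
  genotype_table(geno, status, common)
}

geno_pair <- function(gt, a, b) {
  ia <- match(a, gt$variant_ids)
  ib <- match(b, gt$variant_ids)
  if (is.na(ia) || is.na(ib)) {
    stop("variant(s) absent from genotype table: ",
         paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  }
  ga <- gt$geno[, ia]
  gb <- gt$geno[, ib]
  keep <- !is.na(ga) & !is.na(gb)
  list(ga = ga[keep], gb = gb[keep], pheno = gt$phenotype[keep],
       n_excluded = sum(!keep))
}

#' Case proportions by carrier group for a variant pair
#'
#' Samples are dichotomized per variant into carrier (dosage >= 1) versus
#' non-carrier (the 0/1 coding of genotype-group figures), and for each of
#' the four cells the sample count and case proportion are reported. Samples
#' missing either genotype are excluded and counted. Empty cells report
#' `NA` proportions with `n = 0` rather than erroring.
#'
#' @param gt A `genotype_table`.
#' @param a,b Variant ids.
#' @return data.frame with `carrier_a`, `carrier_b`, `n`, `cases`,
#'   `case_proportion`; attribute `n_excluded` carries the missing-genotype
#'   count.
#' @export
carrier_group_proportions <- function(gt, a, b) {
  stopifnot(inherits(gt, "genotype_table"))
  p <- geno_pair(gt, a, b)
  ca <- as.integer(p$ga >= 1)
  cb <- as.integer(p$gb >= 1)
  out <- expand.grid(carrier_a = 0:1, carrier_b = 0:1)
  out$n <- 0L
  out$cases <- 0L
  for (i in seq_len(4)) {
    sel <- ca == out$carrier_a[i] & cb == out$carrier_b[i]
    out$n[i] <- sum(sel)
    out$cases[i] <- sum(p$pheno[sel])
  }
  out$case_proportion <- ifelse(out$n > 0, out$cases / out$n, NA_real_)
  attr(out, "n_excluded") <- p$n_excluded
  out
}

# 2x2 expected allele-count table within one phenotype group, its log odds
# ratio, and a delta-method variance from the per-sample cell contributions
allele_table_lnor <- function(ga, gb) {
  x <- cbind(ga * gb, ga * (2 - gb), (2 - ga) * gb, (2 - ga) * (2 - gb)) / 2
  N <- colSums(x)
  haldane <- any(N == 0)
  if (haldane) N <- N + 0.5
  lnor <- log(N[1] * N[4] / (N[2] * N[3]))
  g <- c(1 / N[1], -1 / N[2], -1 / N[3], 1 / N[4])
  v <- drop(t(g) %*% (stats::cov(x) * nrow(x)) %*% g)
  list(lnor = lnor, var = v, counts = N, haldane = haldane)
}

#' Allele-based case/control epistasis test for a variant pair
#'
#' Within cases and within controls separately, the 2x2 allele-count table
#' for the pair is formed from dosage cross-products (expected allele
#' pairings per sample) and its log odds ratio computed; the test statistic
#' is the difference of the two log odds ratios divided by its standard
#' error, referred to the standard normal (two-sided). The standard error is
#' obtained by the delta method from the empirical covariance of each
#' sample's cell-contribution vector, which keeps the test calibrated on
#' unphased genotype data. Zero cells receive the Haldane-Anscombe 0.5
#' correction and are flagged. A logistic-regression interaction test
#' (`method = "logistic"`: Wald test on the dosage-product term) is
#' available as an alternative.
#'
#' @param gt A `genotype_table`.
#' @param a,b Variant ids (the test is symmetric in the pair).
#' @param method `"allelic"` (default) or `"logistic"`.
#' @return List with `statistic` (Z or Wald z), `p_value`, `method`,
#'   `n_used`, `n_excluded`, and for the allelic test `lnor_case`,
#'   `lnor_control`, `haldane`.
#' @export
epistasis_test <- function(gt, a, b, method = c("allelic", "logistic")) {
  stopifnot(inherits(gt, "genotype_table"))
  method <- match.arg(method)
  p <- geno_pair(gt, a, b)
  if (length(unique(p$ga)) < 2L || length(unique(p$gb)) < 2L) {
    mono <- c(a, b)[c(length(unique(p$ga)), length(unique(p$gb))) < 2L]
    stop("monomorphic variant(s) among retained samples: ",
         paste(mono, collapse = ", "))
  }
  if (method == "logistic") {
    fit <- stats::glm(p$pheno ~ p$ga * p$gb, family = stats::binomial())
    co <- summary(fit)$coefficients
    z <- co["p$ga:p$gb", "z value"]
    return(list(statistic = unname(z),
                p_value = unname(co["p$ga:p$gb", "Pr(>|z|)"]),
                method = "logistic", n_used = length(p$ga),
                n_excluded = p$n_excluded))
  }
  cs <- allele_table_lnor(p$ga[p$pheno == 1], p$gb[p$pheno == 1])
  ct <- allele_table_lnor(p$ga[p$pheno == 0], p$gb[p$pheno == 0])
  z <- (cs$lnor - ct$lnor) / sqrt(cs$var + ct$var)
  list(statistic = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
       method = "allelic", lnor_case = unname(cs$lnor),
       lnor_control = unname(ct$lnor),
       haldane = cs$haldane || ct$haldane,
       n_used = length(p$ga), n_excluded = p$n_excluded)
}
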