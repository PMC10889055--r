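#' Construct and validate a variant table
#'
#' A variant table holds biallelic SNVs with declared major and minor alleles.
#' Indels and multiallelic records are rejected: the in silico mutagenesis
#' procedure is defined only for single-nucleotide substitutions inside a
#' fixed-length window.
#'
#' @param df A data.frame with columns `id`, `chrom`, `pos`, `major`, `minor`
#'   and optional `maf`, `gwas_p`, `gwas_beta`.
#' @return The validated data.frame (class `caism_variants` prepended).
#' @export
variant_table <- function(df) {
  req <- c("id", "chrom", "pos", "major", "minor")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$major <- toupper(as.character(df$major))
  df$minor <- toupper(as.character(df$minor))
  if (anyDuplicated(df$id)) {
    stop("duplicate variant id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  nuc <- c("A", "C", "G", "T")
  bad <- !(df$major %in% nuc & df$minor %in% nuc)
  if (any(bad)) {
    stop("non-SNV alleles (single A/C/G/T required) for: ",
         paste(df$id[bad], collapse = ", "))
  }
  if (any(df$major == df$minor)) {
    stop("major and minor allele identical for: ",
         paste(df$id[df$major == df$minor], collapse = ", "))
  }
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  if (!is.null(df$maf)) {
    ok <- is.na(df$maf) | (df$maf > 0 & df$maf <= 0.5)
    if (!all(ok)) {
      stop("maf must lie in (0, 0.5] (minor allele by definition) for: ",
           paste(df$id[!ok], collapse = ", "))
    }
  } else {
    df$maf <- NA_real_
  }
  if (is.null(df$gwas_p)) df$gwas_p <- NA_real_
  if (is.null(df$gwas_beta)) df$gwas_beta <- NA_real_
  class(df) <- c("caism_variants", "data.frame")
  df
}

#' Read a variant table from disk
#'
#' Accepts either a tab-delimited file with columns
#' `id, chrom, pos, major, minor[, maf, gwas_p, gwas_beta]`, or a VCF of
#' biallelic SNVs. For VCF input the major/minor assignment uses the INFO AF
#' field when present (ALT is minor iff AF <= 0.5); without AF the REF allele
#' is taken as major, a convention rather than an estimate.
#'
#' @param path Path to a `.tsv`/`.txt` table or a `.vcf` file.
#' @return A `caism_variants` data.frame.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    return(read_variants_vcf(path))
  }
  variant_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  if (any(!snv)) {
    stop("non-SNV or multiallelic VCF record(s) rejected: ",
         paste(utils::head(fix$ID[!snv], 5), collapse = ", "))
  }
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  major <- ref
  minor <- alt
  maf <- rep(NA_real_, length(ref))
  has_af <- !is.na(af)
  swap <- has_af & af > 0.5
  major[swap] <- alt[swap]
  minor[swap] <- ref[swap]
  maf[has_af] <- pmin(af[has_af], 1 - af[has_af])
  id <- fix$ID
  if (any(is.na(id) | id == ".")) {
    fill <- is.na(id) | id == "."
    id[fill] <- paste0(fix$CHROM[fill], ":", fix$POS[fill])
  }
  variant_table(data.frame(id = id, chrom = fix$CHROM,
                           pos = as.integer(fix$POS),
                           major = major, minor = minor, maf = maf,
                           stringsAsFactors = FALSE))
}

#' Fetch one variant (as a one-row data.frame) by id
#' @param variants A `caism_variants` table.
#' @param id Variant id.
#' @return One-row data.frame.
#' @export
get_variant <- function(variants, id) {
  i <- match(id, variants$id)
  if (is.na(i)) stop("unknown variant id: ", id)
  variants[i, , drop = FALSE]
}
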