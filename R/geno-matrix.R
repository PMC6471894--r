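## Core containers: variant site table, genotype matrix, haplotype set.
##
## Conventions used throughout the package:
##   * coordinates are 1-based and inclusive, as in VCF;
##   * allelic dosage is the count of non-reference alleles (0/1/2);
##   * missing genotypes are NA_integer_, never 0 -- every metric skips NA
##     explicitly;
##   * ploidy is fixed at 2;
##   * sites are always sorted by (chrom, pos) and unique on (chrom, pos).

#' Build a variant site table
#'
#' A site table is an ordinary `data.frame` with one row per variant and
#' columns `chrom`, `pos`, `ref`, `alt1`, `alt2` (NA when biallelic),
#' `qual` (Phred-scaled calling quality) and `site_depth` (read depth summed
#' across samples). Up to two alternative alleles are allowed: mapping a
#' population to another species' reference genome can leave sites with two
#' alternative alleles and no reference allele, so triallelic records are
#' kept rather than discarded.
#'
#' @param chrom chromosome identifiers (character).
#' @param pos 1-based positions (integer, >= 1).
#' @param ref reference allele strings.
#' @param alt1,alt2 alternative allele strings; `alt2` is NA for biallelic
#'   sites.
#' @param qual per-site calling quality (>= 0, NA allowed).
#' @param site_depth summed read depth across samples (>= 0, NA allowed).
#' @return a `data.frame` sorted by (chrom, pos).
#' @export
variant_sites <- function(chrom, pos, ref = "A", alt1 = "T", alt2 = NA_character_,
                          qual = NA_real_, site_depth = NA_real_) {
  n <- length(pos)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt1 = rep_len(as.character(alt1), n),
    alt2 = rep_len(as.character(alt2), n),
    qual = rep_len(as.numeric(qual), n),
    site_depth = rep_len(as.numeric(site_depth), n),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1L)) stop("site positions must be >= 1")
  if (any(!is.na(df$qual) & df$qual < 0)) stop("qual must be >= 0")
  if (any(!is.na(df$site_depth) & df$site_depth < 0)) stop("site_depth must be >= 0")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(site_key(df))) stop("duplicated (chrom, pos) in site table")
  df
}

site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

sites_sorted <- function(sites) {
  !is.unsorted(order(sites$chrom, sites$pos)) &&
    identical(order(sites$chrom, sites$pos), seq_len(nrow(sites)))
}

n_alleles <- function(sites) 2L + !is.na(sites$alt2)

#' Construct a genotype matrix
#'
#' The common currency of all pipeline stages: an ordered set of samples,
#' an ordered site table, and a samples x sites integer dosage matrix with
#' values in \{0, 1, 2, NA\}.
#'
#' @param dosage integer matrix, samples in rows, sites in columns.
#' @param sites site table as built by [variant_sites()].
#' @param samples sample identifiers; defaults to `rownames(dosage)`.
#' @param phased logical flag: TRUE when the genotypes came from phased data.
#' @param sample_depth optional per-sample mean sequencing depth (X).
#' @param depth optional samples x sites per-cell read depth matrix.
#' @param a1,a2 optional allele-index matrices (0 = ref, 1 = alt1, 2 = alt2)
#'   carrying allele identity for triallelic sites; when absent, biallelic
#'   allele pairs are derived from dosage where needed.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, sites, samples = rownames(dosage), phased = FALSE,
                        sample_depth = NULL, depth = NULL, a1 = NULL, a2 = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  samples <- as.character(samples)
  if (nrow(dosage) != length(samples))
    stop("dosage row count does not match sample count")
  if (ncol(dosage) != nrow(sites))
    stop("dosage column count does not match site count")
  if (!sites_sorted(sites)) stop("sites must be sorted by (chrom, pos)")
  if (anyDuplicated(site_key(sites))) stop("duplicated (chrom, pos) in sites")
  rng <- suppressWarnings(range(dosage))       # fast single pass when NA-free
  if (anyNA(rng)) rng <- suppressWarnings(range(dosage, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
    stop("dosage values must be in {0, 1, 2, NA}")
  dimnames(dosage) <- list(samples, NULL)
  x <- list(samples = samples, sites = sites, dosage = dosage,
            phased = isTRUE(phased), sample_depth = sample_depth,
            depth = depth, a1 = a1, a2 = a2)
  class(x) <- "geno_matrix"
  x
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d sites (%s), %d chromosome(s)\n",
              length(x$samples), nrow(x$sites),
              if (x$phased) "phased" else "unphased",
              length(unique(x$sites$chrom))))
  nm <- sum(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nm,
              100 * nm / length(x$dosage)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param x a `geno_matrix`.
#' @param i sample index (integer, logical or character).
#' @param j site index (integer or logical).
#' @param ... unused.
#' @return a `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$sites))
  if (is.character(i)) i <- match(i, x$samples)
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  sites <- x$sites[j, , drop = FALSE]
  rownames(sites) <- NULL
  geno_matrix(x$dosage[i, j, drop = FALSE], sites, samples = x$samples[i],
              phased = x$phased,
              sample_depth = if (is.null(x$sample_depth)) NULL else x$sample_depth[i],
              depth = sub(x$depth), a1 = sub(x$a1), a2 = sub(x$a2))
}

#' Construct a haplotype set
#'
#' Two 0/1 haplotypes per sample; `hap_a + hap_b` is the allelic dosage.
#' Synthetic data is phased by construction; real phased input comes from
#' [read_vcf()] with `require_phase = TRUE`.
#'
#' @param hap_a,hap_b samples x sites 0/1 integer matrices.
#' @param sites site table.
#' @param samples sample identifiers.
#' @return an object of class `haplo_set`.
#' @export
haplo_set <- function(hap_a, hap_b, sites, samples = rownames(hap_a)) {
  hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
  storage.mode(hap_a) <- "integer"; storage.mode(hap_b) <- "integer"
  if (!identical(dim(hap_a), dim(hap_b))) stop("haplotype matrices differ in shape")
  if (ncol(hap_a) != nrow(sites)) stop("haplotype columns do not match sites")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(hap_a)))
  samples <- as.character(samples)
  if (length(samples) != nrow(hap_a)) stop("sample count mismatch")
  ok <- function(h) {
    rng <- suppressWarnings(range(h))          # fast single pass when NA-free
    if (anyNA(rng)) rng <- suppressWarnings(range(h, na.rm = TRUE))
    !is.finite(rng[1]) || (rng[1] >= 0L && rng[2] <= 1L)
  }
  if (!ok(hap_a) || !ok(hap_b)) stop("haplotype alleles must be 0/1")
  if (!sites_sorted(sites)) stop("sites must be sorted by (chrom, pos)")
  dimnames(hap_a) <- dimnames(hap_b) <- list(samples, NULL)
  x <- list(samples = samples, sites = sites, hap_a = hap_a, hap_b = hap_b)
  class(x) <- "haplo_set"
  x
}

#' @export
print.haplo_set <- function(x, ...) {
  cat(sprintf("<haplo_set> %d samples x %d sites, %d chromosome(s)\n",
              length(x$samples), nrow(x$sites), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Allelic dosages of a haplotype set
#'
#' @param hs a `haplo_set`.
#' @param phased mark the resulting matrix as phased (default TRUE).
#' @return a `geno_matrix` with dosage `hap_a + hap_b`.
#' @export
dosage_of <- function(hs, phased = TRUE) {
  stopifnot(inherits(hs, "haplo_set"))
  geno_matrix(hs$hap_a + hs$hap_b, hs$sites, samples = hs$samples,
              phased = phased, a1 = hs$hap_a, a2 = hs$hap_b)
}

#' Subset a haplotype set
#' @param x a `haplo_set`.
#' @param i sample index.
#' @param j site index.
#' @param ... unused.
#' @export
`[.haplo_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$sites))
  if (is.character(i)) i <- match(i, x$samples)
  sites <- x$sites[j, , drop = FALSE]
  rownames(sites) <- NULL
  haplo_set(x$hap_a[i, j, drop = FALSE], x$hap_b[i, j, drop = FALSE],
            sites, samples = x$samples[i])
}
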