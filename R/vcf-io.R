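## VCF input/output and panel intersection.
##
## Reading goes through vcfR; writing is plain VCF 4.2 text with GT (and DP
## when per-cell depths are present), which keeps the round trip exact for
## dosage, phase, coordinates, QUAL and DP.

#' Read a VCF file into a genotype matrix
#'
#' Dosage is the count of non-reference alleles in the GT field. Sites with
#' more than two alternative alleles are rejected (with a message giving the
#' count); triallelic sites are kept, with allele identity preserved in the
#' `a1`/`a2` slots. Only diploid GT records are accepted.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @param require_phase error unless every genotype is phased (`|` separator);
#'   a [haplo_set()] is then attached as `attr(, "haplotypes")`.
#' @return a `geno_matrix`; QUAL and per-cell DP are captured when present.
#' @export
read_vcf <- function(path, require_phase = FALSE) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  keep <- n_alt <= 2L
  if (any(!keep))
    message(sum(!keep), " site(s) with >3 alleles rejected")
  if (!any(keep)) stop("no site with <= 3 alleles in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- grepl("DP", unique(v@gt[, "FORMAT"])[1], fixed = TRUE)
  dp <- if (has_dp) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE) else NULL

  fix <- fix[keep, , drop = FALSE]
  alts <- alts[keep]
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]

  ## parse GT strings via a lookup over the distinct codes present
  codes <- unique(as.vector(gt))
  codes <- codes[!is.na(codes)]
  parts <- strsplit(codes, "[/|]")
  if (any(lengths(parts) != 2L))
    stop("non-diploid genotype(s) found (ploidy is fixed at 2): ",
         paste(codes[lengths(parts) != 2L], collapse = " "))
  a1c <- vapply(parts, `[`, "", 1L)
  a2c <- vapply(parts, `[`, "", 2L)
  phased_code <- grepl("|", codes, fixed = TRUE)
  missing_code <- a1c == "." | a2c == "."
  a1v <- suppressWarnings(as.integer(a1c)); a1v[missing_code] <- NA
  a2v <- suppressWarnings(as.integer(a2c)); a2v[missing_code] <- NA
  dosv <- ifelse(is.na(a1v) | is.na(a2v), NA_integer_,
                 (a1v > 0L) + (a2v > 0L))

  idx <- match(gt, codes)                     # NA for missing cells
  dim(idx) <- dim(gt)
  pick <- function(v) { m <- v[idx]; dim(m) <- dim(gt); m }
  dosage <- pick(dosv); a1 <- pick(a1v); a2 <- pick(a2v)
  phased_cells <- pick(phased_code)
  all_phased <- all(phased_cells | is.na(phased_cells)) &&
    any(phased_cells, na.rm = TRUE)
  if (require_phase && !all(phased_cells, na.rm = TRUE))
    stop("phase required but VCF contains unphased genotypes")

  max_seen <- suppressWarnings(max(c(a1, a2), na.rm = TRUE))
  if (is.finite(max_seen) && max_seen > 2L)
    stop("genotype refers to allele index > 2 at a retained site")

  sites <- variant_sites(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt1 = vapply(alts, function(a) if (length(a) >= 1) a[1] else NA_character_, ""),
    alt2 = vapply(alts, function(a) if (length(a) >= 2) a[2] else NA_character_, ""),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    site_depth = if (!is.null(dp)) rowSums(dp, na.rm = TRUE) else NA_real_
  )
  ord <- order(fix$CHROM, as.integer(fix$POS))
  samples <- colnames(gt)
  tr <- function(m) if (is.null(m)) NULL else t(m[ord, , drop = FALSE])
  gm <- geno_matrix(tr(dosage), sites, samples = samples,
                    phased = isTRUE(all_phased),
                    sample_depth = if (!is.null(dp)) colMeans(dp, na.rm = TRUE) else NULL,
                    depth = tr(dp), a1 = tr(a1), a2 = tr(a2))
  if (require_phase)
    attr(gm, "haplotypes") <- haplo_set(pmin(gm$a1, 1L), pmin(gm$a2, 1L),
                                        sites, samples = samples)
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm a `geno_matrix` or `haplo_set`.
#' @param path output path.
#' @return `path`, invisibly. `read_vcf(write_vcf(gm))` reproduces dosages,
#'   coordinates, QUAL, DP and the phase flag.
#' @export
write_vcf <- function(gm, path) {
  if (inherits(gm, "haplo_set")) gm <- dosage_of(gm)
  stopifnot(inherits(gm, "geno_matrix"))
  sep <- if (gm$phased) "|" else "/"
  a1 <- gm$a1; a2 <- gm$a2
  if (is.null(a1) || is.null(a2)) {
    if (any(n_alleles(gm$sites) > 2L))
      stop("triallelic sites need explicit allele matrices to be written")
    d <- gm$dosage
    a1 <- ifelse(d >= 1L, 1L, 0L); a1[is.na(d)] <- NA
    a2 <- ifelse(d == 2L, 1L, 0L); a2[is.na(d)] <- NA
    dim(a1) <- dim(a2) <- dim(d)
  }
  g1 <- ifelse(is.na(a1), ".", a1)
  g2 <- ifelse(is.na(a2), ".", a2)
  cells <- matrix(paste0(g1, sep, g2), nrow = nrow(gm$dosage))
  fmt <- "GT"
  if (!is.null(gm$depth)) {
    dpc <- ifelse(is.na(gm$depth), ".", format(gm$depth, trim = TRUE, scientific = FALSE))
    cells <- matrix(paste0(cells, ":", dpc), nrow = nrow(cells))
    fmt <- "GT:DP"
  }
  s <- gm$sites
  alt <- ifelse(is.na(s$alt2), s$alt1, paste(s$alt1, s$alt2, sep = ","))
  qual <- ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE, scientific = FALSE))
  body <- paste(s$chrom, s$pos, ".", s$ref, alt, qual, "PASS", ".", fmt, sep = "\t")
  for (j in seq_along(gm$samples)) body <- paste(body, cells[j, ], sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedimpute",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"),
    body), con)
  invisible(path)
}

#' Intersect two panels on (chrom, pos)
#'
#' Matching is positional; allele-string disagreements at shared positions
#' are reported, not dropped, since indel alleles mapped to a foreign
#' reference may legitimately differ in representation between callers.
#'
#' @param a,b `geno_matrix` objects with sorted sites.
#' @return list with `idx_a`, `idx_b` (parallel site indices of the shared
#'   positions) and `mismatches`, a data.frame of shared positions whose
#'   REF/ALT strings differ.
#' @export
intersect_panels <- function(a, b) {
  ka <- site_key(a$sites); kb <- site_key(b$sites)
  shared <- intersect(ka, kb)
  idx_a <- match(shared, ka); idx_b <- match(shared, kb)
  if (length(shared) == 0) message("empty panel intersection")
  sa <- a$sites[idx_a, , drop = FALSE]; sb <- b$sites[idx_b, , drop = FALSE]
  allele_str <- function(s) paste(s$ref, s$alt1, ifelse(is.na(s$alt2), "", s$alt2))
  mm <- which(allele_str(sa) != allele_str(sb))
  mismatches <- data.frame(chrom = sa$chrom[mm], pos = sa$pos[mm],
                           alleles_a = allele_str(sa)[mm],
                           alleles_b = allele_str(sb)[mm],
                           stringsAsFactors = FALSE)
  list(idx_a = idx_a, idx_b = idx_b, mismatches = mismatches)
}
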