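## Post-calling filter cascade and chip QC.
##
## The cascade mirrors the study's pipeline: per-caller quality filtering,
## removal of sites monomorphic within the population, positional
## intersection of the two callers, a >= 95% genotype-concordance filter,
## and a Mendelian-segregation filter over the available trios/duos. Each
## step returns its input unchanged in structure plus a report row, and
## every step is individually idempotent.

filter_step <- function(name, n_in, n_out) {
  data.frame(step = name, n_in = n_in, n_removed = n_in - n_out, n_out = n_out,
             stringsAsFactors = FALSE)
}

#' Combine filter-step rows into a report
#' @param ... data.frames from individual filter steps.
#' @return a `filter_report` data.frame.
#' @export
filter_report <- function(...) {
  rep <- do.call(rbind, list(...))
  class(rep) <- c("filter_report", "data.frame")
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter cascade\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Quality/allele filter
#'
#' Keeps sites with QUAL >= `min_qual`, mean per-sample depth >=
#' `min_mean_depth`, allele count within `[min_alleles, max_alleles]` and,
#' when `no_missing`, no missing genotype. Sites lacking QUAL or depth are
#' treated as failing the respective criterion.
#'
#' @param gm a `geno_matrix` carrying `qual` and depth information.
#' @param min_qual minimum Phred quality (default 30).
#' @param min_mean_depth minimum mean per-sample depth (default 2).
#' @param max_alleles,min_alleles allowed total allele count (defaults 3, 2).
#' @param no_missing require complete genotypes at kept sites.
#' @return list with the filtered `geno_matrix` and a one-row report `step`.
#' @export
filter_quality <- function(gm, min_qual = 30, min_mean_depth = 2,
                           max_alleles = 3, min_alleles = 2, no_missing = TRUE) {
  s <- gm$sites
  mean_depth <- if (!is.null(gm$depth)) colMeans(gm$depth, na.rm = TRUE)
                else s$site_depth / length(gm$samples)
  na_f <- function(x) ifelse(is.na(x), FALSE, x)
  keep <- na_f(s$qual >= min_qual) & na_f(mean_depth >= min_mean_depth) &
    n_alleles(s) >= min_alleles & n_alleles(s) <= max_alleles
  if (no_missing) keep <- keep & colSums(is.na(gm$dosage)) == 0L
  list(gm = gm[, keep], step = filter_step("quality", nrow(s), sum(keep)))
}

#' Drop sites monomorphic within the population
#'
#' A site is monomorphic when all non-missing dosages are identical --
#' including all-2 sites that differ only from the external reference
#' genome -- or when every genotype is missing (vacuously monomorphic,
#' counted separately in a message).
#'
#' @param gm a `geno_matrix`.
#' @return list with the filtered matrix and a report `step`.
#' @export
drop_monomorphic <- function(gm) {
  d <- gm$dosage
  mn <- suppressWarnings(apply(d, 2, min, na.rm = TRUE))
  mx <- suppressWarnings(apply(d, 2, max, na.rm = TRUE))
  all_na <- !is.finite(mn)
  mono <- all_na | (mn == mx)
  if (any(all_na)) message(sum(all_na), " all-missing site(s) removed")
  list(gm = gm[, !mono], step = filter_step("monomorphic", ncol(d), sum(!mono)))
}

## Unordered allele-pair equality between two panels at aligned cells.
same_genotype <- function(a, ia, b, ib) {
  a1 <- a$a1; a2 <- a$a2; b1 <- b$a1; b2 <- b$a2
  if (is.null(a1) || is.null(b1)) {
    ## dosage comparison (exact for biallelic panels)
    da <- a$dosage[, ia, drop = FALSE]; db <- b$dosage[, ib, drop = FALSE]
    return(!is.na(da) & !is.na(db) & da == db)
  }
  lo_a <- pmin(a1[, ia, drop = FALSE], a2[, ia, drop = FALSE])
  hi_a <- pmax(a1[, ia, drop = FALSE], a2[, ia, drop = FALSE])
  lo_b <- pmin(b1[, ib, drop = FALSE], b2[, ib, drop = FALSE])
  hi_b <- pmax(b1[, ib, drop = FALSE], b2[, ib, drop = FALSE])
  !is.na(lo_a) & !is.na(lo_b) & lo_a == lo_b & hi_a == hi_b
}

#' Dual-caller genotype-concordance filter
#'
#' At each position shared between the two callers, concordance is the
#' fraction of samples whose non-missing genotypes (unordered allele pairs)
#' are identical in both call sets; sites with concordance >= the threshold
#' are kept, with genotypes taken from caller `a`.
#'
#' @param a,b `geno_matrix` objects from the two callers, same sample set.
#' @param min_concordance threshold (default 0.95, compared with `>=`).
#' @return list with the filtered matrix (sites from the intersection,
#'   genotypes from `a`) and a report `step`.
#' @export
caller_concordance_filter <- function(a, b, min_concordance = 0.95) {
  if (!setequal(a$samples, b$samples))
    stop("caller panels have different sample sets")
  b_ord <- match(a$samples, b$samples)
  ix <- intersect_panels(a, b)
  eq <- same_genotype(a, ix$idx_a, b[b_ord, ], ix$idx_b)
  conc <- colMeans(eq)
  keep <- conc >= min_concordance
  out <- a[, ix$idx_a[keep]]
  list(gm = out,
       step = filter_step("caller_concordance", length(ix$idx_a), sum(keep)),
       concordance = stats::setNames(conc, site_key(a$sites)[ix$idx_a]))
}

## Allele pairs for Mendelian checks: explicit a1/a2 when present, else
## derived from (biallelic) dosage.
allele_pairs <- function(gm) {
  if (!is.null(gm$a1) && !is.null(gm$a2)) return(list(a1 = gm$a1, a2 = gm$a2))
  if (any(n_alleles(gm$sites) > 2L))
    stop("triallelic sites require explicit allele matrices for Mendelian checks")
  d <- gm$dosage
  a1 <- ifelse(d >= 1L, 1L, 0L); a1[is.na(d)] <- NA_integer_
  a2 <- ifelse(d == 2L, 1L, 0L); a2[is.na(d)] <- NA_integer_
  dim(a1) <- dim(a2) <- dim(d)
  list(a1 = a1, a2 = a2)
}

## Vectorised trio rule on allele identity: the child's two alleles can be
## partitioned so that one is carried by the sire and the other by the dam.
trio_consistent <- function(c1, c2, s1, s2, d1, d2) {
  in_s <- function(x) x == s1 | x == s2
  in_d <- function(x) x == d1 | x == d2
  (in_s(c1) & in_d(c2)) | (in_s(c2) & in_d(c1))
}

duo_consistent <- function(c1, c2, p1, p2) {
  c1 == p1 | c1 == p2 | c2 == p1 | c2 == p2
}

#' Mendelian-segregation filter
#'
#' A site is removed when any available trio is inconsistent under the
#' allele-identity rule (one child allele from each parent); duos use the
#' one-allele-shared rule. A trio with any missing member at a site is
#' non-informative there and cannot trigger removal.
#'
#' @param gm a `geno_matrix`.
#' @param ped a `pedigree` identifying trios/duos among `gm` samples.
#' @return list with the filtered matrix and a report `step`.
#' @export
mendelian_filter <- function(gm, ped) {
  trios <- ped_trios(ped, gm$samples)
  bad <- rep(FALSE, nrow(gm$sites))
  if (nrow(trios)) {
    ap <- allele_pairs(gm)
    ci <- match(trios$child, gm$samples)
    si <- match(trios$sire, gm$samples)
    di <- match(trios$dam, gm$samples)
    for (t in seq_len(nrow(trios))) {
      c1 <- ap$a1[ci[t], ]; c2 <- ap$a2[ci[t], ]
      if (!is.na(si[t]) && !is.na(di[t])) {
        ok <- trio_consistent(c1, c2, ap$a1[si[t], ], ap$a2[si[t], ],
                              ap$a1[di[t], ], ap$a2[di[t], ])
      } else {
        p <- if (!is.na(si[t])) si[t] else di[t]
        ok <- duo_consistent(c1, c2, ap$a1[p, ], ap$a2[p, ])
      }
      bad <- bad | (!ok & !is.na(ok))   # NA = uninformative trio at site
    }
  }
  list(gm = gm[, !bad],
       step = filter_step("mendelian", nrow(gm$sites), sum(!bad)))
}

#' Chip quality control
#'
#' Removes markers missing in more than `max_missing` of the samples
#' (strict `>`), then applies the Mendelian-segregation filter.
#'
#' @param chip a `geno_matrix` at chip density.
#' @param ped a `pedigree`.
#' @param max_missing maximum tolerated missing fraction (default 0.90).
#' @return list with the filtered chip and a two-row report `step`.
#' @export
chip_qc_filter <- function(chip, ped, max_missing = 0.90) {
  miss <- colMeans(is.na(chip$dosage))
  keep <- miss <= max_missing
  out1 <- chip[, keep]
  st1 <- filter_step("chip_missingness", ncol(chip$dosage), sum(keep))
  m <- mendelian_filter(out1, ped)
  m$step$step <- "chip_mendelian"
  list(gm = m$gm, step = rbind(st1, m$step))
}

#' Run the full post-calling filter cascade
#'
#' Order: quality filter on each caller set, monomorphic removal on each,
#' positional intersection, dual-caller concordance, Mendelian filter; the
#' chip panel gets its own QC (missingness + Mendelian).
#'
#' @param seq_a,seq_b sequence panels from the two callers.
#' @param chip chip panel.
#' @param ped a `pedigree`.
#' @param min_qual,min_mean_depth,max_alleles,min_concordance,max_missing
#'   thresholds, defaulting to the study's values.
#' @return list with `seq` and `chip` (filtered matrices) and `report`.
#' @export
run_filter_cascade <- function(seq_a, seq_b, chip, ped,
                               min_qual = 30, min_mean_depth = 2,
                               max_alleles = 3, min_concordance = 0.95,
                               max_missing = 0.90) {
  qa <- filter_quality(seq_a, min_qual, min_mean_depth, max_alleles)
  qb <- filter_quality(seq_b, min_qual, min_mean_depth, max_alleles)
  ma <- drop_monomorphic(qa$gm)
  mb <- drop_monomorphic(qb$gm)
  cc <- caller_concordance_filter(ma$gm, mb$gm, min_concordance)
  me <- mendelian_filter(cc$gm, ped)
  ch <- chip_qc_filter(chip, ped, max_missing)
  qa$step$step <- "quality_caller_a"; qb$step$step <- "quality_caller_b"
  ma$step$step <- "monomorphic_caller_a"; mb$step$step <- "monomorphic_caller_b"
  report <- filter_report(qa$step, qb$step, ma$step, mb$step, cc$step,
                          me$step, ch$step)
  list(seq = me$gm, chip = ch$gm, report = report)
}
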