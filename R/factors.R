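## Per-SNP and per-individual explanatory factors for imputation quality:
## minor allele frequency (FreqOri), the exact Hardy-Weinberg test p-value
## (hweOri), summed site depth (DEPTH), calling quality (QUAL), the
## chip/sequence marker density ratio in non-overlapping 500-kb windows
## (RatioDensity), per-individual mean depth (MEAN_DEPTH), and an optional
## externally computed per-SNP LD weight.

#' Minor allele frequency of a dosage column
#'
#' @param dosage dosages (0/1/2, NA missing) across individuals at one site,
#'   or a samples x sites matrix for the vectorised form.
#' @return `min(p, 1 - p)` with `p = sum(dosage) / (2 * n_called)`; NA when
#'   every genotype is missing.
#' @export
minor_allele_freq <- function(dosage) {
  if (is.matrix(dosage)) {
    p <- colMeans(dosage, na.rm = TRUE) / 2
  } else {
    p <- mean(dosage, na.rm = TRUE) / 2
  }
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

## Conditional probability mass of heterozygote counts given allele counts,
## by the standard recurrence from the mode (numerically stable, no
## factorials). Returns the full vector over h = parity, parity+2, ..., n_min.
hwe_het_distribution <- function(n_ab, n_a, n_genotypes) {
  rare <- n_a                      # count of the rarer allele
  n <- n_genotypes
  hs <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hs))
  ## start at the mode of the distribution
  mid <- rare * (2 * n - rare) / (2 * n)
  mid <- hs[which.min(abs(hs - mid))]
  i_mid <- match(mid, hs)
  probs[i_mid] <- 1
  ## downward recurrence: P(h-2)/P(h) = h*(h-1) / ((rare-h+2)*(2n-rare-h+2))
  if (i_mid > 1) for (i in (i_mid - 1):1) {
    h <- hs[i] + 2L
    probs[i] <- probs[i + 1] * h * (h - 1) /
      ((rare - h + 2) * (2 * n - rare - h + 2))
  }
  ## upward: P(h+2)/P(h) = (rare-h)*(2n-rare-h) / ((h+2)*(h+1))
  if (i_mid < length(hs)) for (i in (i_mid + 1):length(hs)) {
    h <- hs[i] - 2L
    probs[i] <- probs[i - 1] * (rare - h) * (2 * n - rare - h) /
      ((h + 2) * (h + 1))
  }
  list(hs = hs, probs = probs / sum(probs))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of HWE conditional on the allele counts: the
#' p-value is the total conditional probability of all heterozygote counts
#' whose probability does not exceed that of the observed count (standard
#' definition, not mid-p). Monomorphic sites return 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors are recycled to equal
#'   length and processed elementwise).
#' @return exact p-value(s) in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  n <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(as.integer(n_aa), n)
  n_ab <- rep_len(as.integer(n_ab), n)
  n_bb <- rep_len(as.integer(n_bb), n)
  if (any(n_aa < 0 | n_ab < 0 | n_bb < 0)) stop("genotype counts must be >= 0")
  if (any(n_aa + n_ab + n_bb < 1)) stop("at least one genotype is required")
  vapply(seq_len(n), function(i) {
    ng <- n_aa[i] + n_ab[i] + n_bb[i]
    n_a <- 2L * n_aa[i] + n_ab[i]
    rare <- min(n_a, 2L * ng - n_a)
    if (rare == 0L) return(1)
    dist <- hwe_het_distribution(n_ab[i], rare, ng)
    p_obs <- dist$probs[match(n_ab[i], dist$hs)]
    min(1, sum(dist$probs[dist$probs <= p_obs * (1 + 1e-12)]))
  }, 0)
}

#' Hardy-Weinberg p-values from a dosage matrix
#'
#' @param dosage samples x sites dosage matrix (biallelic).
#' @return per-site exact p-values.
#' @export
hwe_by_site <- function(dosage) {
  n0 <- colSums(dosage == 0L, na.rm = TRUE)
  n1 <- colSums(dosage == 1L, na.rm = TRUE)
  n2 <- colSums(dosage == 2L, na.rm = TRUE)
  hwe_exact_pvalue(n0, n1, n2)
}

#' Chip/sequence marker density ratio in non-overlapping windows
#'
#' Windows are half-open `[k * window_bp + 1, (k + 1) * window_bp]` per
#' chromosome, anchored at coordinate 1. Each sequence SNP inherits the
#' ratio of its window; windows without sequence SNPs carry no assignment.
#'
#' @param chip_sites,seq_sites site tables (sorted data.frames with `chrom`
#'   and `pos`).
#' @param window_bp window width in base pairs (default 500000).
#' @return list with `windows` (chrom, window index, n_chip, n_seq, ratio)
#'   and `per_snp`, the ratio assigned to each row of `seq_sites`.
#' @export
density_ratio <- function(chip_sites, seq_sites, window_bp = 500000) {
  if (window_bp <= 0) stop("window_bp must be positive")
  wkey <- function(s) paste(s$chrom, (s$pos - 1L) %/% window_bp)
  kc <- wkey(chip_sites); ks <- wkey(seq_sites)
  tab_c <- table(kc); tab_s <- table(ks)
  keys <- sort(unique(c(names(tab_c), names(tab_s))))
  n_chip <- as.integer(tab_c[keys]); n_chip[is.na(n_chip)] <- 0L
  n_seq <- as.integer(tab_s[keys]); n_seq[is.na(n_seq)] <- 0L
  ratio <- ifelse(n_seq > 0, n_chip / n_seq, NA_real_)
  parts <- strsplit(keys, " ")
  windows <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    window = as.integer(vapply(parts, `[`, "", 2L)),
    n_chip = n_chip, n_seq = n_seq, ratio = ratio,
    stringsAsFactors = FALSE)
  list(windows = windows, per_snp = ratio[match(ks, keys)])
}

#' Mean sequencing depth per individual
#'
#' @param gm a `geno_matrix` with a per-cell depth matrix.
#' @return named per-sample mean depth; NA when no depth data is present.
#' @export
mean_depth_by_individual <- function(gm) {
  if (is.null(gm$depth)) return(stats::setNames(rep(NA_real_, length(gm$samples)),
                                                gm$samples))
  stats::setNames(rowMeans(gm$depth, na.rm = TRUE), gm$samples)
}

#' Assemble the per-SNP factor table
#'
#' Inner join of the per-SNP quality table with the explanatory factors on
#' (chrom, pos); an optional externally computed per-SNP weight file
#' (tab-separated, columns chrom, pos, weight) is merged by position, with
#' NA for sites it does not cover.
#'
#' @param quality_snp per-SNP quality table (chrom, pos, Props, cProps, ...).
#' @param factors data.frame with chrom, pos and factor columns (FreqOri,
#'   hweOri, DEPTH, QUAL, RatioDensity, ...), e.g. from [snp_factors()].
#' @param weight_file optional path to the weight table.
#' @return the joined `data.frame`.
#' @export
assemble_factor_table <- function(quality_snp, factors, weight_file = NULL) {
  kq <- paste(quality_snp$chrom, quality_snp$pos)
  kf <- paste(factors$chrom, factors$pos)
  if (anyDuplicated(kq) || anyDuplicated(kf))
    stop("duplicated (chrom, pos) in factor-table inputs")
  out <- merge(quality_snp, factors, by = c("chrom", "pos"))
  if (nrow(out) == 0) warning("factor table join is empty (disjoint site sets)")
  if (!is.null(weight_file)) {
    w <- utils::read.table(weight_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    m <- match(paste(out$chrom, out$pos), paste(w$chrom, w$pos))
    if (anyNA(m))
      message(sum(is.na(m)), " site(s) without an external weight")
    out$Weight <- w$weight[m]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP explanatory factors of a reference panel
#'
#' @param truth_seq reference-panel `geno_matrix` (truth dosages with qual
#'   and depth).
#' @param chip_sites site table of the chip panel.
#' @param window_bp RatioDensity window width.
#' @return data.frame with chrom, pos, FreqOri, hweOri, DEPTH, QUAL,
#'   RatioDensity.
#' @export
snp_factors <- function(truth_seq, chip_sites, window_bp = 500000) {
  dr <- density_ratio(chip_sites, truth_seq$sites, window_bp)
  data.frame(chrom = truth_seq$sites$chrom, pos = truth_seq$sites$pos,
             FreqOri = minor_allele_freq(truth_seq$dosage),
             hweOri = hwe_by_site(truth_seq$dosage),
             DEPTH = truth_seq$sites$site_depth,
             QUAL = truth_seq$sites$qual,
             RatioDensity = dr$per_snp,
             stringsAsFactors = FALSE)
}

#' Rank factors by Spearman correlation with an imputation-quality variable
#'
#' A simple in-package stand-in for external factor-importance analyses:
#' the absolute Spearman rank correlation of each factor with the response.
#'
#' @param factor_table output of [assemble_factor_table()].
#' @param response column name (default `"Props"`).
#' @param factors factor column names to rank.
#' @return data.frame sorted by decreasing `|rho|`.
#' @export
factor_ranking <- function(factor_table, response = "Props",
                           factors = c("RatioDensity", "DEPTH", "QUAL",
                                       "FreqOri", "hweOri")) {
  factors <- intersect(factors, names(factor_table))
  rho <- vapply(factors, function(f)
    suppressWarnings(stats::cor(factor_table[[response]], factor_table[[f]],
                                method = "spearman", use = "complete.obs")), 0)
  out <- data.frame(factor = factors, rho = rho, abs_rho = abs(rho),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_rho), ]
  rownames(out) <- NULL
  out
}
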