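## Lewontin's D' on phased haplotypes and its distance / MAF-product
## summaries. |D'| is reported throughout (the sign depends only on
## arbitrary allele labelling).

#' Lewontin's D' for a pair of phased biallelic sites
#'
#' From haplotype frequencies, `D = f11 - p1 * q1`; the normaliser is
#' `min(p1 * q0, p0 * q1)` when D > 0 and `min(p1 * q1, p0 * q0)` when
#' D < 0. Returns `|D| / Dmax`, 0 when D = 0, NA when either site is
#' monomorphic in the haplotype sample.
#'
#' @param hap_x,hap_y 0/1 allele vectors over the same haplotypes
#'   (length >= 2).
#' @return D' in [0, 1], or NA.
#' @export
dprime <- function(hap_x, hap_y) {
  stopifnot(length(hap_x) == length(hap_y), length(hap_x) >= 2)
  p1 <- mean(hap_x); q1 <- mean(hap_y)
  if (p1 == 0 || p1 == 1 || q1 == 0 || q1 == 1) return(NA_real_)
  f11 <- mean(hap_x == 1L & hap_y == 1L)
  D <- f11 - p1 * q1
  if (D == 0) return(0)
  dmax <- if (D > 0) min(p1 * (1 - q1), (1 - p1) * q1)
          else min(p1 * q1, (1 - p1) * (1 - q1))
  abs(D) / dmax
}

#' All within-chromosome LD pairs up to a maximum distance
#'
#' Pairs with undefined D' (a monomorphic member) are dropped; their count
#' is attached as `attr(, "n_undefined")`.
#'
#' @param hs a `haplo_set`.
#' @param max_distance_bp maximum pair distance (bp).
#' @param site_filter optional site index (into `hs$sites`) restricting the
#'   pairs, e.g. from [select_high_quality_snps()].
#' @return data.frame of class `ld_pairs`: chrom, pos_a, pos_b, distance_bp,
#'   dprime, maf_a, maf_b, maf_product.
#' @export
pairwise_ld <- function(hs, max_distance_bp, site_filter = NULL) {
  stopifnot(inherits(hs, "haplo_set"), max_distance_bp >= 0)
  keep <- site_filter %||% seq_len(nrow(hs$sites))
  H <- rbind(hs$hap_a[, keep, drop = FALSE], hs$hap_b[, keep, drop = FALSE])
  sites <- hs$sites[keep, , drop = FALSE]
  p <- colMeans(H)
  maf <- pmin(p, 1 - p)
  out <- list(); n_undef <- 0L
  for (ch in unique(sites$chrom)) {
    j <- which(sites$chrom == ch)
    pos <- sites$pos[j]
    for (k in seq_along(j)) {
      part <- j[which(pos > pos[k] & pos - pos[k] <= max_distance_bp) ]
      if (!length(part)) next
      a <- j[k]
      if (p[a] == 0 || p[a] == 1) { n_undef <- n_undef + length(part); next }
      poly <- p[part] > 0 & p[part] < 1
      n_undef <- n_undef + sum(!poly)
      part <- part[poly]
      if (!length(part)) next
      f11 <- colMeans(H[, part, drop = FALSE] * H[, a])
      D <- f11 - p[a] * p[part]
      dmax <- ifelse(D > 0, pmin(p[a] * (1 - p[part]), (1 - p[a]) * p[part]),
                     pmin(p[a] * p[part], (1 - p[a]) * (1 - p[part])))
      dp <- ifelse(D == 0, 0, abs(D) / dmax)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos_a = sites$pos[k],
        pos_b = sites$pos[match(part, j)],
        distance_bp = sites$pos[match(part, j)] - sites$pos[k],
        dprime = dp, maf_a = maf[a], maf_b = maf[part],
        maf_product = maf[a] * maf[part], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos_a = integer(0), pos_b = integer(0),
               distance_bp = integer(0), dprime = numeric(0),
               maf_a = numeric(0), maf_b = numeric(0), maf_product = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_undefined") <- n_undef
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' Frequency-weighted mean D' in consecutive distance windows
#'
#' Pairs are binned by distance into consecutive windows of `window_bp`;
#' within each window the mean D' is weighted by the product of the two
#' minor allele frequencies (`weighting = "maf_product"`, the default) or
#' unweighted (`"uniform"`). Empty windows are reported as NA.
#'
#' @param pairs an `ld_pairs` data.frame.
#' @param window_bp distance window width (default 500000).
#' @param weighting `"maf_product"` or `"uniform"`.
#' @return data.frame with window index, distance bounds, n_pairs and
#'   `mean_dprime`.
#' @export
weighted_mean_dprime <- function(pairs, window_bp = 500000,
                                 weighting = c("maf_product", "uniform")) {
  if (window_bp <= 0) stop("window_bp must be positive")
  weighting <- match.arg(weighting)
  if (nrow(pairs) == 0) stop("no LD pairs supplied")
  win <- (pairs$distance_bp - 1L) %/% window_bp
  w <- if (weighting == "maf_product") pairs$maf_product else rep(1, nrow(pairs))
  wins <- 0:max(win)
  mean_dp <- vapply(wins, function(k) {
    i <- win == k
    if (!any(i) || sum(w[i]) == 0) return(NA_real_)
    sum(pairs$dprime[i] * w[i]) / sum(w[i])
  }, 0)
  data.frame(window = wins,
             dist_lo = wins * window_bp + 1,
             dist_hi = (wins + 1) * window_bp,
             n_pairs = as.integer(tabulate(win + 1L, nbins = length(wins))),
             mean_dprime = mean_dp)
}

#' Weighted mean D' over a distance x MAF-product grid
#'
#' @param pairs an `ld_pairs` data.frame.
#' @param distance_bins,mafprod_bins breakpoints passed to [cut()] (the
#'   defaults span the observed ranges in 10 bins each).
#' @param weighting as in [weighted_mean_dprime()].
#' @return data.frame grid with one row per populated (distance, MAF
#'   product) cell: bin labels, n_pairs and mean_dprime. Cell counts sum to
#'   the number of pairs.
#' @export
maf_product_profile <- function(pairs, distance_bins = 10, mafprod_bins = 10,
                                weighting = c("maf_product", "uniform")) {
  weighting <- match.arg(weighting)
  if (nrow(pairs) == 0)
    return(data.frame(dist_bin = character(0), mafprod_bin = character(0),
                      n_pairs = integer(0), mean_dprime = numeric(0)))
  db <- cut(pairs$distance_bp, distance_bins, include.lowest = TRUE)
  mb <- cut(pairs$maf_product, mafprod_bins, include.lowest = TRUE)
  w <- if (weighting == "maf_product") pairs$maf_product else rep(1, nrow(pairs))
  key <- interaction(db, mb, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(pairs)), key), function(i)
    data.frame(dist_bin = as.character(db[i[1]]),
               mafprod_bin = as.character(mb[i[1]]),
               n_pairs = length(i),
               mean_dprime = sum(pairs$dprime[i] * w[i]) / sum(w[i]),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
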