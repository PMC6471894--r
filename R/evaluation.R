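## Leave-one-out masking cross-validation and imputation-quality metrics.
##
## Metrics by individual (per chromosome): Propi, the proportion of
## correctly imputed genotypes; Cori, the Pearson correlation between true
## and imputed dosages. Metrics by SNP (across individuals): Props and Cors,
## plus cProps, the chance-corrected proportion, and the random-fill lower
## bounds lbPropi / lbProps.

#' Leave-one-out masking cross-validation
#'
#' Each reference individual in turn has its sequence genotypes masked and
#' retained only at chip density, and is imputed against the remaining
#' reference panel. Optional extra targets (e.g. unrelated accessions) are
#' imputed against the full reference.
#'
#' @param ref_haps phased reference panel (`haplo_set`) at sequence density.
#' @param chip `geno_matrix` of the reference individuals at chip density.
#' @param ped a `pedigree`.
#' @param imputer an imputer function or name, see [get_imputer()].
#' @param seed integer; fold f uses `seed + f`.
#' @param extra_targets optional chip-density `geno_matrix` for additional
#'   target individuals not in the reference.
#' @return list of class `loo_result`: `truth` (pre-masking dosages),
#'   `imputed`, `haps` (imputed haplotypes), and `extra` (result for the
#'   extra targets, or NULL).
#' @export
loo_cross_validate <- function(ref_haps, chip, ped, imputer = "family_ld",
                               seed = 1, extra_targets = NULL) {
  stopifnot(inherits(ref_haps, "haplo_set"))
  if (!all(ref_haps$samples %in% chip$samples))
    stop("reference individuals must be present in both panels")
  chip <- chip[ref_haps$samples, ]     # chip may cover a larger population
  impute_fun <- get_imputer(imputer)
  R <- length(ref_haps$samples); S <- nrow(ref_haps$sites)
  dos <- matrix(NA_integer_, R, S, dimnames = list(ref_haps$samples, NULL))
  hA <- hB <- matrix(NA_integer_, R, S)
  for (f in seq_len(R)) {
    task <- imputation_task(ref_haps[-f, ], chip[f, ], ped, seed = seed + f)
    res <- tryCatch(impute_fun(task),
                    error = function(e) stop("imputer failed in fold ", f, " (",
                                             ref_haps$samples[f], "): ",
                                             conditionMessage(e), call. = FALSE))
    dos[f, ] <- res$imputed$dosage[1, ]
    if (!is.null(res$haps)) { hA[f, ] <- res$haps$hap_a[1, ]; hB[f, ] <- res$haps$hap_b[1, ] }
  }
  extra <- NULL
  if (!is.null(extra_targets)) {
    if (any(extra_targets$samples %in% ref_haps$samples))
      stop("extra targets must not be reference individuals")
    task <- imputation_task(ref_haps, extra_targets, ped, seed = seed + R + 1L)
    extra <- impute_fun(task)
  }
  haps <- if (!anyNA(hA)) haplo_set(hA, hB, ref_haps$sites, ref_haps$samples) else NULL
  structure(list(truth = dosage_of(ref_haps),
                 imputed = geno_matrix(dos, ref_haps$sites,
                                       samples = ref_haps$samples, phased = !is.null(haps)),
                 haps = haps, extra = extra),
            class = "loo_result")
}

match_score <- function(truth, imputed, mode) {
  if (mode == "allele") (2 - abs(truth - imputed)) / 2 else (truth == imputed) * 1
}

#' Proportion of correctly imputed genotypes for one individual
#'
#' `Propi = (1/M) * sum(truth == imputed)` over the M sites with called
#' truth, by default per chromosome. `mode = "allele"` scores partial credit
#' per allele: `(1/2M) * sum(2 - |truth - imputed|)`.
#'
#' @param truth,imputed dosage vectors aligned on sites.
#' @param chrom chromosome of each site; NULL for a single overall value.
#' @param mode `"dosage"` (default) or `"allele"`.
#' @return named numeric (per chromosome) or scalar; NA when no site has
#'   called truth.
#' @export
prop_by_individual <- function(truth, imputed, chrom = NULL, mode = c("dosage", "allele")) {
  mode <- match.arg(mode)
  sc <- match_score(truth, imputed, mode)
  ok <- !is.na(truth) & !is.na(imputed)
  if (is.null(chrom)) {
    if (!any(ok)) return(NA_real_)
    return(mean(sc[ok]))
  }
  vapply(split(seq_along(truth), chrom), function(i) {
    i <- i[ok[i]]
    if (!length(i)) NA_real_ else mean(sc[i])
  }, 0)
}

#' Pearson correlation between true and imputed dosages for one individual
#'
#' @inheritParams prop_by_individual
#' @return named numeric per chromosome (or scalar); NA when either vector
#'   is constant over the evaluated sites.
#' @export
cor_by_individual <- function(truth, imputed, chrom = NULL) {
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  if (is.null(chrom)) return(safe_cor(truth, imputed))
  vapply(split(seq_along(truth), chrom),
         function(i) safe_cor(truth[i], imputed[i]), 0)
}

#' Per-SNP proportion of correctly imputed genotypes
#'
#' @param truth,imputed dosage vectors across individuals at one site.
#' @return list with `props` (NA when no individual has called truth) and
#'   `ni`, the number of individuals with called truth genotypes.
#' @export
prop_by_snp <- function(truth, imputed) {
  ok <- !is.na(truth) & !is.na(imputed)
  list(props = if (any(ok)) mean(truth[ok] == imputed[ok]) else NA_real_,
       ni = sum(!is.na(truth)))
}

#' Chance-corrected per-SNP proportion
#'
#' The probability of a correct call by chance is
#' `sum_g p_ref(g) * q_val(g)` over the three genotypes; the corrected
#' proportion is `(Props - chance) / (1 - chance)`. Values below 0 (worse
#' than chance) are reported as-is; when both panels are fixed
#' (`chance = 1`) the statistic is undefined.
#'
#' @param props per-SNP proportion(s) of correct imputation.
#' @param p_ref genotype frequencies (AA, AB, BB) observed in the reference;
#'   a length-3 vector or a 3 x sites matrix.
#' @param q_val predicted genotype frequencies in the testing population,
#'   same shape.
#' @return cProps, NA where chance = 1.
#' @export
chance_corrected_prop <- function(props, p_ref, q_val) {
  p_ref <- as.matrix(p_ref); q_val <- as.matrix(q_val)
  if (nrow(p_ref) != 3 || nrow(q_val) != 3)
    stop("genotype frequency triples must have 3 rows (AA, AB, BB)")
  if (any(abs(colSums(p_ref) - 1) > 1e-9, na.rm = TRUE) ||
      any(abs(colSums(q_val) - 1) > 1e-9, na.rm = TRUE))
    stop("genotype frequencies must sum to 1")
  chance <- colSums(p_ref * q_val)
  out <- (props - chance) / (1 - chance)
  out[abs(1 - chance) < 1e-12] <- NA_real_
  unname(out)
}

## Vectorised columnwise Pearson correlation with NA handling.
colwise_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- colSums(ok)
  x0 <- ifelse(ok, x, 0); y0 <- ifelse(ok, y, 0)
  sx <- colSums(x0); sy <- colSums(y0)
  sxx <- colSums(x0^2); syy <- colSums(y0^2); sxy <- colSums(x0 * y0)
  num <- sxy - sx * sy / n
  vx <- sxx - sx^2 / n; vy <- syy - sy^2 / n
  r <- num / sqrt(vx * vy)
  r[!is.finite(r) | n < 2] <- NA_real_
  r
}

#' Per-individual quality table
#'
#' @param truth,imputed aligned `geno_matrix` objects (individuals x sites).
#' @param ped a `pedigree` supplying the relatedness class.
#' @param mode match definition, see [prop_by_individual()].
#' @return data.frame with id, chrom, class, Propi, Cori.
#' @export
quality_by_individual <- function(truth, imputed, ped, mode = "dosage") {
  chroms <- unique(truth$sites$chrom)
  cls <- ped$class[match(truth$samples, ped$id)]
  out <- list()
  for (ch in chroms) {
    j <- truth$sites$chrom == ch
    mt <- truth$dosage[, j, drop = FALSE]; mi <- imputed$dosage[, j, drop = FALSE]
    ok <- !is.na(mt) & !is.na(mi)
    sc <- match_score(mt, mi, mode); sc[!ok] <- 0
    propi <- rowSums(sc) / rowSums(ok)
    cori <- colwise_cor(t(mt), t(mi))
    out[[ch]] <- data.frame(id = truth$samples, chrom = ch, class = cls,
                            Propi = propi, Cori = cori,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-SNP quality table
#'
#' Reference genotype frequencies come from the reference panel truth;
#' validation frequencies from the imputed genotypes of the evaluated folds.
#'
#' @param truth,imputed aligned `geno_matrix` objects.
#' @param mode match definition.
#' @return data.frame with chrom, pos, Ni, Props, Cors (NA where a vector is
#'   constant), cProps.
#' @export
quality_by_snp <- function(truth, imputed, mode = "dosage") {
  mt <- truth$dosage; mi <- imputed$dosage
  ok <- !is.na(mt) & !is.na(mi)
  sc <- match_score(mt, mi, mode); sc[!ok] <- 0
  ni <- colSums(!is.na(mt))
  props <- colSums(sc) / colSums(ok)
  props[colSums(ok) == 0] <- NA_real_
  cors <- colwise_cor(mt, mi)
  cprops <- chance_corrected_prop(props, genotype_freqs(mt), genotype_freqs(mi))
  data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
             Ni = ni, Props = props, Cors = cors, cProps = cprops,
             stringsAsFactors = FALSE)
}

#' Random-fill lower bound inside the LOO scheme
#'
#' Runs the frequency random-fill imputer through the identical
#' leave-one-out scheme and scores it per individual (lbPropi) and per SNP
#' (lbProps).
#'
#' @inheritParams loo_cross_validate
#' @param mode match definition.
#' @return list with `lb_individual` (id, chrom, lbPropi) and `lb_snp`
#'   (chrom, pos, lbProps), plus the raw `loo_result`.
#' @export
lower_bound_metrics <- function(ref_haps, chip, ped, seed = 1, mode = "dosage") {
  loo <- loo_cross_validate(ref_haps, chip, ped, imputer = "random_fill",
                            seed = seed)
  qi <- quality_by_individual(loo$truth, loo$imputed, ped, mode = mode)
  qs <- quality_by_snp(loo$truth, loo$imputed, mode = mode)
  list(lb_individual = data.frame(id = qi$id, chrom = qi$chrom,
                                  lbPropi = qi$Propi, stringsAsFactors = FALSE),
       lb_snp = data.frame(chrom = qs$chrom, pos = qs$pos, lbProps = qs$Props,
                           stringsAsFactors = FALSE),
       loo = loo)
}

#' Evaluate an imputer by leave-one-out cross-validation
#'
#' The central computation of the package: runs the LOO scheme with the
#' requested imputer and with the random-fill lower bound, and assembles the
#' per-individual x chromosome and per-SNP quality tables.
#'
#' @inheritParams loo_cross_validate
#' @param method imputer name or function.
#' @param mode match definition (`"dosage"` or `"allele"`).
#' @param lower_bound also compute lbPropi / lbProps (default TRUE).
#' @param keep_matrices keep truth/imputed matrices and imputed haplotypes
#'   in the result (needed for downstream LD profiling).
#' @param ... passed to the imputer (e.g. `window_sizes`, `overlap`).
#' @return object of class `imputation_eval` with elements
#'   `quality_individual`, `quality_snp`, and (optionally) `truth`,
#'   `imputed`, `haps`, `extra`.
#' @export
evaluate_imputation <- function(ref_haps, chip, ped, method = "family_ld",
                                seed = 1, mode = "dosage", lower_bound = TRUE,
                                extra_targets = NULL, keep_matrices = TRUE, ...) {
  imputer <- get_imputer(method, ...)
  loo <- loo_cross_validate(ref_haps, chip, ped, imputer, seed = seed,
                            extra_targets = extra_targets)
  qi <- quality_by_individual(loo$truth, loo$imputed, ped, mode = mode)
  qs <- quality_by_snp(loo$truth, loo$imputed, mode = mode)
  if (lower_bound) {
    lb <- lower_bound_metrics(ref_haps, chip, ped, seed = seed, mode = mode)
    qi$lbPropi <- lb$lb_individual$lbPropi[
      match(paste(qi$id, qi$chrom), paste(lb$lb_individual$id, lb$lb_individual$chrom))]
    qs$lbProps <- lb$lb_snp$lbProps[
      match(paste(qs$chrom, qs$pos), paste(lb$lb_snp$chrom, lb$lb_snp$pos))]
  }
  out <- list(quality_individual = qi, quality_snp = qs,
              method = if (is.character(method)) method else "custom",
              seed = seed, mode = mode)
  if (keep_matrices) {
    out$truth <- loo$truth; out$imputed <- loo$imputed
    out$haps <- loo$haps; out$extra <- loo$extra
  }
  class(out) <- "imputation_eval"
  out
}

#' @export
print.imputation_eval <- function(x, ...) {
  cat(sprintf("<imputation_eval> method=%s over %d individuals, %d sites\n",
              x$method, length(unique(x$quality_individual$id)),
              nrow(x$quality_snp)))
  cat(sprintf("  mean Propi = %.4f", mean(x$quality_individual$Propi, na.rm = TRUE)))
  if (!is.null(x$quality_individual$lbPropi))
    cat(sprintf("  (random-fill lower bound %.4f)",
                mean(x$quality_individual$lbPropi, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
summary.imputation_eval <- function(object, ...) {
  qi <- object$quality_individual
  by_class <- stats::aggregate(cbind(Propi, Cori) ~ class, data = qi,
                               FUN = function(v) mean(v, na.rm = TRUE))
  qs <- object$quality_snp
  structure(list(method = object$method, by_class = by_class,
                 snp = c(mean_Props = mean(qs$Props, na.rm = TRUE),
                         mean_cProps = mean(qs$cProps, na.rm = TRUE),
                         n_Cors_undefined = sum(is.na(qs$Cors)))),
            class = "summary.imputation_eval")
}

#' @export
print.summary.imputation_eval <- function(x, ...) {
  cat("Imputation evaluation (", x$method, ")\n", sep = "")
  cat("Per-class mean Propi / Cori:\n")
  print(x$by_class, row.names = FALSE)
  cat(sprintf("Per-SNP: mean Props = %.4f, mean cProps = %.4f, Cors undefined at %d sites\n",
              x$snp["mean_Props"], x$snp["mean_cProps"], x$snp["n_Cors_undefined"]))
  invisible(x)
}

#' Plot per-individual imputation quality
#'
#' Propi against Cori, one point per individual x chromosome, coloured by
#' relatedness class.
#'
#' @param x an `imputation_eval`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.imputation_eval <- function(x, ...) {
  qi <- x$quality_individual
  cls <- factor(qi$class, levels = PED_CLASSES)
  graphics::plot(qi$Cori, qi$Propi, col = as.integer(cls), pch = 19,
                 xlab = "Cori (Pearson r, truth vs imputed)",
                 ylab = "Propi (proportion correctly imputed)", ...)
  graphics::legend("bottomright", legend = levels(droplevels(cls)),
                   col = seq_along(levels(cls))[levels(cls) %in% unique(qi$class)],
                   pch = 19, cex = 0.8)
  invisible(x)
}

#' Select SNPs with good imputation quality
#'
#' Keeps sites with `Props > props_min` and `cProps > cprops_min` (both
#' strict); sites with undefined cProps are excluded and counted.
#'
#' @param quality_snp per-SNP quality table from [evaluate_imputation()].
#' @param props_min,cprops_min strict lower thresholds (defaults 0.90, 0.80).
#' @return the selected rows of `quality_snp`; the number of sites excluded
#'   for undefined cProps is attached as `attr(, "n_undefined")`.
#' @export
select_high_quality_snps <- function(quality_snp, props_min = 0.90,
                                     cprops_min = 0.80) {
  undef <- is.na(quality_snp$cProps) | is.na(quality_snp$Props)
  keep <- !undef & quality_snp$Props > props_min & quality_snp$cProps > cprops_min
  out <- quality_snp[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(undef)
  out
}
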