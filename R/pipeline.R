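## End-to-end pipeline: simulate -> filter -> fill chip -> leave-one-out
## evaluation (family/LD + random-fill lower bound) -> per-SNP factors ->
## D' profiles -> tab-separated reports.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a simulated study
#'
#' Simulates a study-shaped dataset, runs the post-calling filter cascade
#' and chip QC, fills residual chip missingness, evaluates the family/LD
#' imputer (against the random-fill lower bound) by leave-one-out
#' cross-validation, assembles the per-SNP factor table with a Spearman
#' factor ranking, computes distance-binned D' profiles for the chip panel
#' (true phase) and the imputed sequence panel (imputed phase, restricted
#' to high-quality SNPs), and writes all reports as TSV under `out_dir`.
#' Fully deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed.
#' @param out_dir report directory (created if needed); NULL to skip writing.
#' @param method imputer for the main evaluation.
#' @param ld_max_dist maximum pair distance for D' profiling (bp).
#' @param ld_thin maximum number of sites per chromosome entering the
#'   sequence-panel D' computation (evenly thinned).
#' @param window_bp window width for RatioDensity and D' distance bins.
#' @param props_min,cprops_min high-quality SNP selection thresholds.
#' @param ... passed to the imputer.
#' @return (invisibly) a list with `sim`, `filter`, `eval`, `factor_table`,
#'   `ranking`, `ld_chip`, `ld_seq`, `summary`.
#' @export
run_pipeline <- function(cfg = sim_config(), seed = 1, out_dir = NULL,
                         method = "family_ld", ld_max_dist = 2e6,
                         ld_thin = 300, window_bp = 5e5,
                         props_min = 0.90, cprops_min = 0.80, ...) {
  seed <- as.integer(seed)
  sim <- simulate_study(cfg, seed)
  fl <- run_filter_cascade(sim$seq_a, sim$seq_b, sim$chip_all, sim$ped)

  ## analysis-ready panels: truth haplotypes restricted to the filtered
  ## sequence sites; chip restricted to sites surviving both cascades
  seq_keep <- match(site_key(fl$seq$sites), site_key(sim$truth_haps$sites))
  ref_haps <- sim$truth_haps[, seq_keep]
  truth_seq <- sim$truth_seq[, seq_keep]
  chip_keep <- !is.na(match(site_key(fl$chip$sites), site_key(ref_haps$sites)))
  chip <- fl$chip[, which(chip_keep)]
  chip_filled <- fill_chip_missing(chip, sim$ped, seed = seed + 11L)
  chip_ref <- chip_filled[sim$reference, ]

  ev <- evaluate_imputation(ref_haps, chip_ref, sim$ped, method = method,
                            seed = seed + 101L, ...)
  ev$quality_individual$MEAN_DEPTH <-
    truth_seq$sample_depth[match(ev$quality_individual$id,
                                 names(truth_seq$sample_depth))]

  fac <- snp_factors(truth_seq, chip$sites, window_bp = window_bp)
  ft <- assemble_factor_table(ev$quality_snp, fac)
  rk <- factor_ranking(ft)

  hq <- select_high_quality_snps(ev$quality_snp, props_min, cprops_min)
  hq_idx <- match(paste(hq$chrom, hq$pos),
                  paste(ref_haps$sites$chrom, ref_haps$sites$pos))
  thin <- function(idx, sites) {
    unlist(lapply(split(idx, sites$chrom[idx]), function(i) {
      if (length(i) <= ld_thin) i
      else i[round(seq(1, length(i), length.out = ld_thin))]
    }), use.names = FALSE)
  }
  chip_idx_ref <- match(site_key(chip$sites), site_key(ref_haps$sites))
  ld_chip_pairs <- pairwise_ld(ref_haps, ld_max_dist, site_filter = chip_idx_ref)
  ld_chip <- if (nrow(ld_chip_pairs)) weighted_mean_dprime(ld_chip_pairs, window_bp)
             else NULL
  ld_seq <- NULL; ld_seq_pairs <- NULL
  if (length(hq_idx) >= 2 && !is.null(ev$haps)) {
    ld_seq_pairs <- pairwise_ld(ev$haps, ld_max_dist,
                                site_filter = thin(hq_idx, ref_haps$sites))
    if (nrow(ld_seq_pairs)) ld_seq <- weighted_mean_dprime(ld_seq_pairs, window_bp)
  }

  qi <- ev$quality_individual
  smry <- data.frame(
    quantity = c("n_individuals", "n_reference", "n_seq_sites_filtered",
                 "n_chip_sites_filtered", "mean_propi", "mean_lb_propi",
                 "mean_cori", "propi_cori_r", "mean_props", "mean_cprops",
                 "mean_lb_props", "n_high_quality_snps", "prop_sites_imputed"),
    value = c(nrow(sim$ped), length(sim$reference), nrow(ref_haps$sites),
              nrow(chip$sites),
              mean(qi$Propi, na.rm = TRUE),
              mean(qi$lbPropi, na.rm = TRUE),
              mean(qi$Cori, na.rm = TRUE),
              stats::cor(qi$Propi, qi$Cori, use = "complete.obs"),
              mean(ev$quality_snp$Props, na.rm = TRUE),
              mean(ev$quality_snp$cProps, na.rm = TRUE),
              mean(ev$quality_snp$lbProps, na.rm = TRUE),
              nrow(hq),
              1 - nrow(chip$sites) / nrow(ref_haps$sites)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pedigree(sim$ped, file.path(out_dir, "pedigree.tsv"))
    write_tsv(fl$report, file.path(out_dir, "filter_report.tsv"))
    write_tsv(qi, file.path(out_dir, "qual_individual.tsv"))
    write_tsv(ev$quality_snp, file.path(out_dir, "qual_snp.tsv"))
    write_tsv(ft, file.path(out_dir, "factors.tsv"))
    write_tsv(rk, file.path(out_dir, "factor_ranking.tsv"))
    if (!is.null(ld_chip)) write_tsv(ld_chip, file.path(out_dir, "ld_chip.tsv"))
    if (!is.null(ld_seq)) write_tsv(ld_seq, file.path(out_dir, "ld_seq.tsv"))
    write_tsv(smry, file.path(out_dir, "summary.tsv"))
  }
  invisible(list(sim = sim, filter = fl, eval = ev, factor_table = ft,
                 ranking = rk, ld_chip = ld_chip, ld_seq = ld_seq,
                 ld_chip_pairs = ld_chip_pairs, ld_seq_pairs = ld_seq_pairs,
                 summary = smry))
}
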