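## Synthetic-data generator: pedigreed, phased, two-density genotype panels.
##
## The generator emulates the structure of the study population: a
## two-mating-set pedigree (factorial + multiple-pair, 1039 individuals by
## default), founder haplotypes with tunable monotone LD decay, Mendelian
## gene dropping with Haldane (Poisson, no interference) crossovers, a chip
## subset enriched in high-MAF evenly spaced markers, per-individual depths
## in the 4-52X range with a 13X mean, and small genotype-error / chip
## missingness rates so the filter cascade has something to remove.

#' Simulation configuration
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param n_seq_sites sequence-density variant count per chromosome.
#' @param chip_fraction proportion of sequence sites placed on the chip
#'   (default 0.005, the chip/sequence marker ratio of the emulated study:
#'   roughly 7.5K chip vs 1.4M sequence SNPs).
#' @param founder_maf_dist beta parameters (length 2) for founder alternative
#'   allele frequencies; the default `c(0.4, 0.4)` gives the U-shaped site
#'   frequency spectrum typical of sequence data.
#' @param ld_rho first-order Markov copying probability in `[0, 1)` for
#'   founder haplotypes; adjacent-site latent correlation, hence pairwise LD
#'   decays as `ld_rho^k` over k intervening sites.
#' @param recomb_rate recombination rate, cM per Mb (Haldane model).
#' @param design family structure, a [study_design()].
#' @param depth_range per-individual mean depth range in X coverage.
#' @param depth_mean target mean of per-individual depths.
#' @param qual_shape,qual_scale gamma parameters for per-site QUAL.
#' @param error_rate per-genotype error probability in `[0, 0.5)` for the
#'   sequence call sets.
#' @param chip_error_rate error probability for the chip panel; the default
#'   0 reflects that an array passing design QC is essentially error-free,
#'   its residual imperfection being missingness.
#' @param missing_rate_chip proportion of chip genotypes masked missing.
#' @param maf_floor minimum MAF for chip eligibility.
#' @param chip_density_jitter coefficient of variation of the chip
#'   selection-bin widths; 0 gives evenly spaced bins, the default 1
#'   emulates the markedly uneven along-genome density of a gene-enriched
#'   array.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length_bp = 5e7, n_seq_sites = 20000,
                       chip_fraction = 0.005, founder_maf_dist = c(0.4, 0.4),
                       ld_rho = 0.998, recomb_rate = 2, design = study_design(),
                       depth_range = c(4, 52), depth_mean = 13,
                       qual_shape = 4, qual_scale = 15,
                       error_rate = 0.005, chip_error_rate = 0,
                       missing_rate_chip = 0.01,
                       maf_floor = 0.1, chip_density_jitter = 1) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length_bp = chrom_length_bp,
              n_seq_sites = as.integer(n_seq_sites), chip_fraction = chip_fraction,
              founder_maf_dist = founder_maf_dist, ld_rho = ld_rho,
              recomb_rate = recomb_rate, design = design,
              depth_range = depth_range, depth_mean = depth_mean,
              qual_shape = qual_shape, qual_scale = qual_scale,
              error_rate = error_rate, chip_error_rate = chip_error_rate,
              missing_rate_chip = missing_rate_chip,
              maf_floor = maf_floor, chip_density_jitter = chip_density_jitter)
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_length_bp > 0, cfg$n_seq_sites >= 2,
            cfg$chip_fraction > 0, cfg$chip_fraction < 1,
            cfg$ld_rho >= 0, cfg$ld_rho < 1, cfg$recomb_rate > 0,
            cfg$error_rate >= 0, cfg$error_rate < 0.5,
            cfg$chip_error_rate >= 0, cfg$chip_error_rate < 0.5,
            cfg$chip_density_jitter >= 0,
            cfg$missing_rate_chip >= 0, cfg$missing_rate_chip < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder haplotypes with decaying LD
#'
#' Per site, an alternative-allele frequency is drawn from the configured
#' beta distribution (clipped to (0.01, 0.99)). Each haplotype is generated
#' left to right through a latent uniform chain: with probability `ld_rho`
#' the latent value is copied from the previous site (so the allele keeps
#' its frequency rank), otherwise it is drawn fresh. Marginal frequencies
#' are preserved exactly and pairwise LD decays geometrically with the
#' number of intervening sites.
#'
#' @param cfg a [sim_config()].
#' @param n_haplotypes number of founder haplotypes to generate.
#' @return list of class `founder_pool`: per chromosome, `pos` (sorted
#'   positions), `p` (alt allele frequencies) and `hap`
#'   (n_haplotypes x sites 0/1 matrix).
#' @export
simulate_founder_haplotypes <- function(cfg, n_haplotypes) {
  stopifnot(n_haplotypes >= 2)
  a <- cfg$founder_maf_dist[1]; b <- cfg$founder_maf_dist[2]
  pool <- lapply(seq_len(cfg$n_chrom), function(ch) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_seq_sites))
    p <- pmin(pmax(stats::rbeta(cfg$n_seq_sites, a, b), 0.01), 0.99)
    S <- cfg$n_seq_sites
    fresh <- matrix(stats::runif(n_haplotypes * S), n_haplotypes, S)
    refresh <- matrix(stats::runif(n_haplotypes * S) >= cfg$ld_rho, n_haplotypes, S)
    refresh[, 1] <- TRUE
    ## index of the most recent refresh at or before each site
    last <- t(apply(refresh * col(refresh), 1, cummax))
    u <- fresh[cbind(rep(seq_len(n_haplotypes), S), as.vector(last))]
    dim(u) <- c(n_haplotypes, S)
    hap <- matrix(as.integer(u < rep(p, each = n_haplotypes)), n_haplotypes, S)
    list(chrom = sprintf("chr%d", ch), pos = pos, p = p, hap = hap)
  })
  structure(pool, class = "founder_pool", n_haplotypes = n_haplotypes)
}

## One recombinant gamete from a parent's two haplotype rows at one
## chromosome. Crossovers ~ Poisson(recomb_rate * L_Mb / 100), breakpoints
## uniform; segment parity alternates from a random starting haplotype.
make_gamete <- function(hap_a, hap_b, pos, length_bp, recomb_rate) {
  lambda <- recomb_rate * (length_bp / 1e6) / 100
  k <- stats::rpois(1L, lambda)
  start <- stats::runif(1) < 0.5
  if (k == 0L) return(if (start) hap_a else hap_b)
  bp <- sort(stats::runif(k, 1, length_bp))
  seg <- findInterval(pos, bp)          # 0..k
  use_a <- (seg %% 2L == 0L) == start
  out <- hap_b
  out[use_a] <- hap_a[use_a]
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders receive distinct pool haplotype pairs in pedigree order;
#' individuals with a single known parent receive one recombinant gamete
#' from that parent and one unused pool haplotype. Every child genotype is
#' Mendelian-consistent with its parents by construction.
#'
#' @param ped a `pedigree`.
#' @param pool a `founder_pool` from [simulate_founder_haplotypes()].
#' @param cfg a [sim_config()].
#' @return a `haplo_set` over all pedigree individuals at sequence density.
#' @export
gene_drop <- function(ped, pool, cfg) {
  n_founder_haps <- sum(is.na(ped$sire)) + sum(is.na(ped$dam))
  if (n_founder_haps > attr(pool, "n_haplotypes"))
    stop(sprintf("pedigree needs %d founder haplotypes but the pool has %d",
                 n_founder_haps, attr(pool, "n_haplotypes")))
  ord <- ped_topo_order(ped)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids); di <- match(ped$dam, ids)

  ## site-major (S x n) layout during the drop: column writes are contiguous
  per_chrom <- lapply(pool, function(pc) {
    S <- length(pc$pos)
    A <- matrix(NA_integer_, S, n)
    B <- matrix(NA_integer_, S, n)
    next_hap <- 1L
    for (i in ord) {
      if (is.na(si[i])) {
        A[, i] <- pc$hap[next_hap, ]; next_hap <- next_hap + 1L
      } else {
        A[, i] <- make_gamete(A[, si[i]], B[, si[i]], pc$pos,
                              cfg$chrom_length_bp, cfg$recomb_rate)
      }
      if (is.na(di[i])) {
        B[, i] <- pc$hap[next_hap, ]; next_hap <- next_hap + 1L
      } else {
        B[, i] <- make_gamete(A[, di[i]], B[, di[i]], pc$pos,
                              cfg$chrom_length_bp, cfg$recomb_rate)
      }
    }
    list(A = t(A), B = t(B))
  })
  sites <- variant_sites(
    chrom = rep(vapply(pool, `[[`, "", "chrom"),
                vapply(pool, function(pc) length(pc$pos), 0L)),
    pos = unlist(lapply(pool, `[[`, "pos")),
    ref = "A", alt1 = "T"
  )
  haplo_set(do.call(cbind, lapply(per_chrom, `[[`, "A")),
            do.call(cbind, lapply(per_chrom, `[[`, "B")),
            sites, samples = ids)
}

#' Select the chip marker subset
#'
#' Emulates a chip designed from a carefully selected set of highly
#' polymorphic, regularly spaced markers: each chromosome is cut into
#' equal-width bins (one per requested chip marker) and the highest-MAF site
#' with MAF >= `maf_floor` in each bin is taken.
#'
#' @param hs `haplo_set` over the population used to measure MAF.
#' @param cfg a [sim_config()]; `chip_fraction` controls the count and
#'   `maf_floor` the eligibility threshold.
#' @return list with `chip` and `seq` genotype matrices (chip sites are a
#'   subset of sequence sites) and `chip_idx`, the chip site indices into
#'   the sequence site table.
#' @export
select_chip_subset <- function(hs, cfg) {
  d <- hs$hap_a + hs$hap_b
  p <- colMeans(d) / 2
  maf <- pmin(p, 1 - p)
  jit <- cfg$chip_density_jitter %||% 0
  idx <- integer(0)
  requested <- 0L
  for (ch in unique(hs$sites$chrom)) {
    j <- which(hs$sites$chrom == ch)
    n_chip <- max(1L, round(length(j) * cfg$chip_fraction))
    requested <- requested + n_chip
    if (jit > 0) {
      ## bin widths with CV = jitter: uneven along-genome chip density
      w <- stats::rgamma(n_chip, shape = 1 / jit^2, scale = jit^2)
      bounds <- cfg$chrom_length_bp * cumsum(w) / sum(w)
      bin <- pmin(1L + findInterval(hs$sites$pos[j], bounds[-n_chip]), n_chip)
    } else {
      bin <- pmin(1L + ((hs$sites$pos[j] - 1L) %/%
                          ceiling(cfg$chrom_length_bp / n_chip)), n_chip)
    }
    elig <- maf[j] >= cfg$maf_floor
    for (b in unique(bin)) {
      cand <- j[bin == b & elig]
      if (length(cand)) idx <- c(idx, cand[which.max(maf[cand])])
    }
  }
  n_eligible <- sum(maf >= cfg$maf_floor)
  if (n_eligible < requested)
    stop(sprintf("chip selection short by %d site(s): %d site(s) with MAF >= %.2f for %d requested markers",
                 requested - n_eligible, n_eligible, cfg$maf_floor, requested))
  idx <- sort(idx)
  list(chip = dosage_of(hs[, idx]), seq = dosage_of(hs), chip_idx = idx)
}

#' Attach simulated depths and site qualities
#'
#' Per-individual mean depth is drawn from a shifted gamma bounded to the
#' configured range (default 4-52X, mean 13X); per-cell depth is Poisson
#' around the individual mean; site depth is the per-cell sum; QUAL is gamma
#' with a floor at 0.
#'
#' @param gm a `geno_matrix`.
#' @param cfg a [sim_config()].
#' @param mask_zero_depth set genotypes with zero simulated reads to missing.
#' @return `gm` with `sample_depth`, `depth`, `site_depth` and `qual` filled.
#' @export
simulate_depth_qual <- function(gm, cfg, mask_zero_depth = FALSE) {
  n <- length(gm$samples); S <- nrow(gm$sites)
  lo <- cfg$depth_range[1]; hi <- cfg$depth_range[2]
  mu <- cfg$depth_mean
  shape <- 2
  dm <- lo + stats::rgamma(n, shape = shape, scale = (mu - lo) / shape)
  while (any(dm > hi))
    dm[dm > hi] <- lo + stats::rgamma(sum(dm > hi), shape = shape,
                                      scale = (mu - lo) / shape)
  depth <- matrix(stats::rpois(n * S, rep(dm, S)), n, S)
  gm$sample_depth <- stats::setNames(dm, gm$samples)
  gm$depth <- depth
  gm$sites$site_depth <- colSums(depth)
  gm$sites$qual <- stats::rgamma(S, shape = cfg$qual_shape, scale = cfg$qual_scale)
  if (mask_zero_depth) {
    gm$dosage[depth == 0L] <- NA_integer_
    if (!is.null(gm$a1)) { gm$a1[depth == 0L] <- NA_integer_; gm$a2[depth == 0L] <- NA_integer_ }
  }
  gm
}

#' Inject genotype errors and chip missingness
#'
#' Each non-missing dosage is flipped to one of the other two values with
#' probability `error_rate`; a further `missing_rate` fraction of cells is
#' masked missing (used for the chip panel, emulating its residual ~1%
#' missing data).
#'
#' @param gm a `geno_matrix`.
#' @param error_rate per-genotype flip probability in `[0, 0.5)`.
#' @param missing_rate proportion of cells masked missing.
#' @return a `geno_matrix`.
#' @export
add_genotype_errors <- function(gm, error_rate, missing_rate = 0) {
  stopifnot(error_rate >= 0, error_rate < 0.5)
  d <- gm$dosage
  if (error_rate > 0) {
    flip <- which(!is.na(d) & stats::runif(length(d)) < error_rate)
    if (length(flip)) {
      shift <- 1L + (stats::runif(length(flip)) < 0.5)
      d[flip] <- (d[flip] + shift) %% 3L
    }
    ## allele matrices no longer reflect the (biallelic) dosage; rebuild
    gm$a1 <- ifelse(d >= 1L, 1L, 0L); gm$a1[is.na(d)] <- NA_integer_
    gm$a2 <- ifelse(d == 2L, 1L, 0L); gm$a2[is.na(d)] <- NA_integer_
    dim(gm$a1) <- dim(gm$a2) <- dim(d)
    gm$phased <- FALSE
  }
  if (missing_rate > 0) {
    mask <- stats::runif(length(d)) < missing_rate
    d[mask] <- NA_integer_
    if (!is.null(gm$a1)) { gm$a1[mask] <- NA_integer_; gm$a2[mask] <- NA_integer_ }
  }
  gm$dosage <- d
  gm
}

#' Simulate a full study-shaped dataset
#'
#' Orchestrates the generator: builds the pedigree, simulates founder
#' haplotypes, gene-drops them, selects the chip subset, attaches
#' depth/quality to the sequenced reference panel, and injects genotype
#' errors (two independent error realisations stand in for the two variant
#' callers) and chip missingness.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return list of class `sim_study` with elements `cfg`, `ped`,
#'   `reference` (sequenced ids), `truth_haps` (error-free phased reference
#'   haplotypes), `truth_seq` (error-free reference dosages with
#'   depth/qual), `seq_a`/`seq_b` (error-injected caller panels),
#'   `chip_all` (error+missingness chip panel over all individuals),
#'   `chip_ref` (its reference rows) and `chip_idx`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  withr::with_seed(as.integer(seed), {
    ped <- build_pedigree(cfg$design)
    reference <- attr(ped, "sequenced")
    n_haps <- sum(is.na(ped$sire)) + sum(is.na(ped$dam))
    pool <- simulate_founder_haplotypes(cfg, n_haps)
    haps_all <- gene_drop(ped, pool, cfg)
    sel <- select_chip_subset(haps_all, cfg)
    chip_idx <- sel$chip_idx

    truth_haps <- haps_all[reference, ]
    chip_all_clean <- sel$chip
    rm(haps_all, pool, sel)

    truth_seq <- simulate_depth_qual(dosage_of(truth_haps), cfg)
    truth_haps$sites <- truth_seq$sites      # carry qual/site_depth along
    seq_a <- add_genotype_errors(truth_seq, cfg$error_rate)
    seq_b <- add_genotype_errors(truth_seq, cfg$error_rate)
    chip_all <- add_genotype_errors(chip_all_clean, cfg$chip_error_rate,
                                    cfg$missing_rate_chip)
    chip_all$phased <- FALSE
    chip_ref <- chip_all[reference, ]
    structure(list(cfg = cfg, ped = ped, reference = reference,
                   truth_haps = truth_haps, truth_seq = truth_seq,
                   seq_a = seq_a, seq_b = seq_b, chip_all = chip_all,
                   chip_ref = chip_ref, chip_idx = chip_idx),
              class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d individuals (%d sequenced), %d seq sites, %d chip sites\n",
              nrow(x$ped), length(x$reference), nrow(x$truth_seq$sites),
              length(x$chip_idx)))
  invisible(x)
}
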