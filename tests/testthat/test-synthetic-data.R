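test_that("the default breeding design reproduces the study structure", {
  ped <- build_pedigree(study_design())
  expect_equal(nrow(ped), 1039L)
  expect_equal(length(attr(ped, "sequenced")), 43L)
  tab <- table(ped$class)
  expect_equal(unname(tab["Factorial_progenies"]) +
                 sum(ped$class == "MultiplePair_parents" & grepl("^FP", ped$id)),
               413L)   # 411 labelled progenies + 2 dual-role females
  expect_equal(unname(tab["MultiplePair_progenies"]), 598L)
  expect_equal(unname(tab["Unrelated"]), 6L)
  ## every parent has at least one sequenced offspring
  seqd <- attr(ped, "sequenced")
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  parents <- setdiff(parents, "GP1")
  covered <- vapply(parents, function(p)
    any((ped$sire %in% p | ped$dam %in% p) & ped$id %in% seqd), TRUE)
  expect_true(all(covered))
})

test_that("minimal and malformed designs behave as documented", {
  d <- study_design(factorial = list(n_female = 1, n_male = 1, n_crosses = 1,
                                     n_progeny = 2),
                    multipair = NULL, n_unrelated = 0, grandparent = FALSE)
  ped <- build_pedigree(d)
  expect_equal(nrow(ped), 4L)
  expect_equal(sum(grepl("progenies", ped$class)), 2L)

  bad <- study_design(factorial = list(n_female = 2, n_male = 2, n_progeny = 4,
                                       crosses = data.frame(female = 3, male = 1)),
                      multipair = NULL, n_unrelated = 0, grandparent = FALSE)
  expect_error(build_pedigree(bad), "outside the design")
})

test_that("founder haplotypes show tunable, decaying LD", {
  ## ld_rho = 0: adjacent sites essentially uncorrelated
  cfg0 <- sim_config(n_chrom = 1, n_seq_sites = 1000, chrom_length_bp = 1e6,
                     ld_rho = 0)
  withr::with_seed(5, pool0 <- simulate_founder_haplotypes(cfg0, 200))
  h <- pool0[[1]]$hap
  r2 <- vapply(seq_len(999), function(s) {
    suppressWarnings(stats::cor(h[, s], h[, s + 1]))^2
  }, 0)
  expect_lt(mean(r2, na.rm = TRUE), 0.02)

  ## ld_rho = 0.9: adjacent D' exceeds distant D' (ld_analysis as oracle)
  cfg9 <- sim_config(n_chrom = 1, n_seq_sites = 400, chrom_length_bp = 1e6,
                     ld_rho = 0.9)
  withr::with_seed(6, pool9 <- simulate_founder_haplotypes(cfg9, 200))
  h9 <- pool9[[1]]$hap
  dp_at_lag <- function(lag, idx) {
    mean(vapply(idx, function(s) {
      d <- dprime(h9[, s], h9[, s + lag])
      if (is.na(d)) 0 else d
    }, 0))
  }
  expect_gt(dp_at_lag(1, 1:200), dp_at_lag(150, 1:200))

  ## fixed seed -> bit-identical pool
  withr::with_seed(7, a <- simulate_founder_haplotypes(cfg9, 50))
  withr::with_seed(7, b <- simulate_founder_haplotypes(cfg9, 50))
  expect_identical(a, b)
})

test_that("founder-site heterozygosity matches 2p(1-p)", {
  cfg <- sim_config(n_chrom = 1, n_seq_sites = 5000, chrom_length_bp = 5e6)
  withr::with_seed(8, pool <- simulate_founder_haplotypes(cfg, 400))
  h <- pool[[1]]$hap
  p_hat <- colMeans(h)
  ## pair haplotypes into 200 diploids and compare het fraction to 2p(1-p)
  het <- colMeans(h[seq(1, 399, 2), ] + h[seq(2, 400, 2), ] == 1)
  expected <- 2 * p_hat * (1 - p_hat)
  keep <- expected > 0.05
  ## binomial z-scores of observed het counts; chi-square goodness of fit
  z <- (het[keep] - expected[keep]) /
    sqrt(expected[keep] * (1 - expected[keep]) / 200)
  pval <- stats::pchisq(sum(z^2), df = sum(keep), lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("gene dropping transmits parental haplotypes Mendelian-consistently", {
  cfg <- trio_cfg(recomb_rate = 1e-9)   # effectively zero recombination
  sim <- simulate_study(cfg, seed = 3)
  hs <- sim$truth_haps
  for (kid in c("FP001", "FP002")) {
    kidA <- hs$hap_a[kid, ]
    parent_haps <- rbind(hs$hap_a["FM1", ], hs$hap_b["FM1", ])
    expect_true(any(apply(parent_haps, 1, identical, y = kidA)))
    kidB <- hs$hap_b[kid, ]
    parent_haps <- rbind(hs$hap_a["FF1", ], hs$hap_b["FF1", ])
    expect_true(any(apply(parent_haps, 1, identical, y = kidB)))
  }

  ## with recombination: every site still passes the Mendelian filter
  sim2 <- simulate_study(small_cfg(), seed = 4)
  mf <- mendelian_filter(dosage_of(sim2$truth_haps), sim2$ped)
  expect_equal(mf$step$n_removed, 0L)

  ## pool exhaustion errors
  ped <- build_pedigree(small_design())
  tiny_pool <- withr::with_seed(1, simulate_founder_haplotypes(small_cfg(), 4))
  expect_error(gene_drop(ped, tiny_pool, small_cfg()), "founder haplotypes")
})

test_that("crossover counts follow the Haldane Poisson model", {
  ## one couple whose founder haplotypes are all-0 / all-1, so each child
  ## gamete exposes its crossover points as allele switches
  cfg <- sim_config(n_chrom = 1, n_seq_sites = 2000, chrom_length_bp = 5e7,
                    recomb_rate = 1, error_rate = 0,
                    design = study_design(
                      factorial = list(n_female = 1, n_male = 1, n_crosses = 1,
                                       n_progeny = 500),
                      multipair = NULL, n_unrelated = 0, grandparent = FALSE))
  ped <- build_pedigree(cfg$design)
  pool <- withr::with_seed(2, simulate_founder_haplotypes(cfg, 4))
  pool[[1]]$hap <- matrix(rep(c(0L, 1L), 2), 4, 2000)  # rows: 0,1,0,1
  hs <- withr::with_seed(3, gene_drop(ped, pool, cfg))
  kids <- grep("^FP", hs$samples)
  switches <- function(v) sum(diff(v) != 0)
  xo <- c(vapply(kids, function(k) switches(hs$hap_a[k, ]), 0),
          vapply(kids, function(k) switches(hs$hap_b[k, ]), 0))
  ## expectation: recomb_rate * L_Mb / 100 = 1 * 50 / 100 = 0.5 per gamete
  expect_equal(mean(xo), 0.5, tolerance = 0.15)
})

test_that("chip selection prefers spaced, polymorphic markers", {
  cfg <- small_cfg(chip_density_jitter = 0)
  sim <- withr::with_seed(9, {
    ped <- build_pedigree(cfg$design)
    n_haps <- sum(is.na(ped$sire)) + sum(is.na(ped$dam))
    pool <- simulate_founder_haplotypes(cfg, n_haps)
    hs <- gene_drop(ped, pool, cfg)
    list(hs = hs, sel = select_chip_subset(hs, cfg))
  })
  sel <- sim$sel
  ## chip sites are a subset of sequence sites
  expect_true(all(site_key(sel$chip$sites) %in% site_key(sel$seq$sites)))
  ## chip MAF respects the floor
  expect_true(all(minor_allele_freq(sel$chip$dosage) >= cfg$maf_floor))
  ## spacing more regular than a random subset of equal size
  cv <- function(x) stats::sd(x) / mean(x)
  chip_pos <- sel$chip$sites$pos[sel$chip$sites$chrom == "chr1"]
  n1 <- length(chip_pos)
  all_pos <- sim$hs$sites$pos[sim$hs$sites$chrom == "chr1"]
  rnd_cv <- withr::with_seed(10, mean(replicate(50, {
    cv(diff(sort(sample(all_pos, n1))))
  })))
  expect_lt(cv(diff(chip_pos)), rnd_cv)

  ## no site eligible -> error listing the shortfall
  cfg_bad <- small_cfg(maf_floor = 0.51)
  expect_error(withr::with_seed(9, {
    ped <- build_pedigree(cfg_bad$design)
    pool <- simulate_founder_haplotypes(cfg_bad,
                                        sum(is.na(ped$sire)) + sum(is.na(ped$dam)))
    select_chip_subset(gene_drop(ped, pool, cfg_bad), cfg_bad)
  }), "short by")
})

test_that("simulated depths match the configured coverage profile", {
  cfg <- small_cfg()
  sim <- simulate_study(cfg, seed = 12)
  sd_ <- sim$truth_seq$sample_depth
  expect_true(all(sd_ >= 4 & sd_ <= 52))
  ## many draws: the grand mean approaches the 13X target within 10%
  withr::with_seed(13, {
    gm <- toy_gm(matrix(0L, 200, 5))
    gm2 <- simulate_depth_qual(gm, cfg)
  })
  expect_equal(mean(gm2$sample_depth), 13, tolerance = 0.1 * 13)
  ## zero-depth masking
  cfg0 <- small_cfg(depth_range = c(0.2, 52), depth_mean = 0.5)
  withr::with_seed(14, gm3 <- simulate_depth_qual(toy_gm(matrix(0L, 10, 50)),
                                                  cfg0, mask_zero_depth = TRUE))
  expect_true(any(is.na(gm3$dosage[gm3$depth == 0])))
  expect_true(all(is.na(gm3$dosage[gm3$depth == 0])))
  ## determinism
  withr::with_seed(15, a <- simulate_depth_qual(toy_gm(matrix(0L, 5, 9)), cfg))
  withr::with_seed(15, b <- simulate_depth_qual(toy_gm(matrix(0L, 5, 9)), cfg))
  expect_identical(a, b)
})

test_that("error injection flips and masks at the configured rates", {
  gm <- toy_gm(matrix(1L, 100, 100))
  expect_identical(add_genotype_errors(gm, 0)$dosage, gm$dosage)
  withr::with_seed(16, masked <- add_genotype_errors(gm, 0, missing_rate = 0.01))
  n_na <- sum(is.na(masked$dosage))
  expect_gt(n_na, 100 - 3 * sqrt(100))    # ~Binomial(10000, 0.01)
  expect_lt(n_na, 100 + 3 * sqrt(100))
  withr::with_seed(17, flipped <- add_genotype_errors(gm, 0.25))
  expect_true(all(flipped$dosage %in% 0:2))
  expect_gt(sum(flipped$dosage != 1L), 0)
  expect_error(add_genotype_errors(gm, 0.5), "error_rate")
})

test_that("the whole simulation is deterministic under a fixed seed", {
  a <- simulate_study(small_cfg(), seed = 21)
  b <- simulate_study(small_cfg(), seed = 21)
  expect_identical(a$truth_haps, b$truth_haps)
  expect_identical(a$chip_all$dosage, b$chip_all$dosage)
  expect_identical(a$seq_a$dosage, b$seq_a$dosage)
})

test_that("progenies share longer haplotype segments with parents than with unrelated", {
  sim <- simulate_study(small_cfg(), seed = 22)
  hs <- sim$truth_haps
  seg_len <- function(child_hap, other) {
    ## longest run of identity with either haplotype of the other individual
    best <- 0
    for (h in list(hs$hap_a[other, ], hs$hap_b[other, ])) {
      r <- rle(child_hap == h)
      m <- max(c(0, r$lengths[r$values]))
      best <- max(best, m)
    }
    best
  }
  kids <- intersect(grep("^FP", hs$samples, value = TRUE), sim$reference)
  with_parent <- vapply(kids, function(k) {
    p <- sim$ped$sire[sim$ped$id == k]
    seg_len(hs$hap_a[k, ], p)
  }, 0)
  with_unrel <- vapply(kids, function(k) seg_len(hs$hap_a[k, ], "U1"), 0)
  expect_gt(mean(with_parent), mean(with_unrel))
})
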