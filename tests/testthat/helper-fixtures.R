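## Shared fixtures and independent oracles for the test suite. All fixtures
## are built in code; the oracles deliberately use the most naive possible
## route (double loops, full enumeration, direct factorial formulas) so they
## stay independent of the implementation they check.

## ---- designs & simulations ------------------------------------------------

small_design <- function() {
  study_design(
    factorial = list(n_female = 2, n_male = 2, n_crosses = 3, n_progeny = 30),
    multipair = list(n_female_new = 2, n_male = 2, n_crosses = 3,
                     n_progeny = 30, n_dual_role = 1),
    n_unrelated = 3, n_seq_progeny = 5)
}

cfg_with <- function(base, ...) {
  mod <- list(...)
  base[names(mod)] <- mod
  do.call(sim_config, base)
}

small_cfg <- function(...) {
  cfg_with(list(n_chrom = 2, n_seq_sites = 2000, chrom_length_bp = 5e6,
                chip_fraction = 0.02, design = small_design()), ...)
}

trio_cfg <- function(...) {
  ## one couple, two progenies, no errors
  cfg_with(list(n_chrom = 1, n_seq_sites = 600, chrom_length_bp = 1e6,
                chip_fraction = 0.02, error_rate = 0, missing_rate_chip = 0,
                design = study_design(
                  factorial = list(n_female = 1, n_male = 1, n_crosses = 1,
                                   n_progeny = 2),
                  multipair = NULL, n_unrelated = 0, grandparent = FALSE,
                  n_seq_progeny = 2)), ...)
}

## ---- small genotype objects -----------------------------------------------

toy_gm <- function(dosage, pos = NULL, chrom = "chr1", qual = 50,
                   phased = FALSE, samples = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 100L
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  geno_matrix(dosage, variant_sites(chrom, pos, qual = qual),
              samples = samples, phased = phased)
}

random_hapset <- function(n, S, seed = 1, p = NULL, chrom = "chr1") {
  withr::with_seed(seed, {
    if (is.null(p)) p <- runif(S, 0.05, 0.95)
    hA <- matrix(rbinom(n * S, 1, rep(p, each = n)), n, S)
    hB <- matrix(rbinom(n * S, 1, rep(p, each = n)), n, S)
    haplo_set(hA, hB, variant_sites(chrom, seq_len(S) * 1000L))
  })
}

## in-code VCF text fixture
write_vcf_text <- function(path, body_lines, samples = c("S1", "S2", "S3"),
                           format = "GT") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

## ---- independent oracles --------------------------------------------------

## naive per-individual / per-SNP metrics by explicit double loops
naive_propi <- function(truth, imputed) {
  hits <- 0; m <- 0
  for (k in seq_along(truth)) {
    if (is.na(truth[k]) || is.na(imputed[k])) next
    m <- m + 1
    if (truth[k] == imputed[k]) hits <- hits + 1
  }
  if (m == 0) NA_real_ else hits / m
}

naive_props_ni <- function(truth, imputed) {
  hits <- 0; m <- 0; ni <- 0
  for (k in seq_along(truth)) {
    if (!is.na(truth[k])) ni <- ni + 1
    if (is.na(truth[k]) || is.na(imputed[k])) next
    m <- m + 1
    if (truth[k] == imputed[k]) hits <- hits + 1
  }
  list(props = if (m == 0) NA_real_ else hits / m, ni = ni)
}

naive_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) NA_real_ else num / den
}

naive_genofreq <- function(v) {
  v <- v[!is.na(v)]
  c(mean(v == 0), mean(v == 1), mean(v == 2))
}

## exact HWE p-value by direct enumeration with the factorial formula:
## P(h | n, nA) = n! / (nAA! h! nBB!) * 2^h / ((2n)! / (nA! nB!))
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (na - h) / 2; nbb <- (nb - h) / 2
    if (na < nb) { t <- naa; naa <- nbb; nbb <- t }  # naa pairs with major
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(na + 1) - lgamma(nb + 1))
  }, 0)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

## D' by direct counting of the four haplotype classes
oracle_dprime <- function(hx, hy) {
  n <- length(hx)
  n11 <- sum(hx == 1 & hy == 1); n10 <- sum(hx == 1 & hy == 0)
  n01 <- sum(hx == 0 & hy == 1); n00 <- sum(hx == 0 & hy == 0)
  p1 <- (n11 + n10) / n; q1 <- (n11 + n01) / n
  if (p1 %in% c(0, 1) || q1 %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - p1 * q1
  if (D == 0) return(0)
  dmax <- if (D > 0) min(p1 * (1 - q1), (1 - p1) * q1)
          else min(p1 * q1, (1 - p1) * (1 - q1))
  abs(D) / dmax
}

## Mendelian trio consistency by exhaustive gamete enumeration
oracle_trio_ok <- function(child, sire, dam) {
  for (s in sire) for (d in dam) {
    if (identical(sort(c(s, d)), sort(child))) return(TRUE)
  }
  FALSE
}

## all unordered genotypes over a 3-allele site
all_genotypes3 <- function() {
  g <- list()
  for (a in 0:2) for (b in a:2) g[[length(g) + 1]] <- c(a, b)
  g
}

## ---- toy gene models / genome ---------------------------------------------

## A 600-bp single-chromosome genome with one + strand gene (two exons) and
## one - strand gene, written as FASTA + GFF3 temp files.
toy_annotation <- function(dir = tempfile("annot")) {
  dir.create(dir)
  set.seed(99)
  ## gene1 (+): span 101-300; exon1 101-180 (CDS 121-180), intron 181-220,
  ##           exon2 221-300 (CDS 221-280, UTR3 281-300); UTR5 101-120
  ## gene2 (-): span 401-520, single exon = CDS 401-520
  seqv <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  ## make gene1 CDS begin with ATG and gene2 (on - strand) code cleanly
  seqv[121:123] <- c("A", "T", "G")
  genome_str <- paste(seqv, collapse = "")
  fasta <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", genome_str), fasta)
  gff <- file.path(dir, "genes.gff3")
  rows <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t300\t.\t+\t.\tID=gene1",
    "chr1\ttoy\tmRNA\t101\t300\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttoy\texon\t101\t180\t.\t+\t.\tID=tx1e1;Parent=tx1",
    "chr1\ttoy\texon\t221\t300\t.\t+\t.\tID=tx1e2;Parent=tx1",
    "chr1\ttoy\tfive_prime_UTR\t101\t120\t.\t+\t.\tID=tx1u5;Parent=tx1",
    "chr1\ttoy\tCDS\t121\t180\t.\t+\t0\tID=tx1c1;Parent=tx1",
    "chr1\ttoy\tCDS\t221\t280\t.\t+\t0\tID=tx1c2;Parent=tx1",
    "chr1\ttoy\tthree_prime_UTR\t281\t300\t.\t+\t.\tID=tx1u3;Parent=tx1",
    "chr1\ttoy\tgene\t401\t520\t.\t-\t.\tID=gene2",
    "chr1\ttoy\tmRNA\t401\t520\t.\t-\t.\tID=tx2;Parent=gene2",
    "chr1\ttoy\texon\t401\t520\t.\t-\t.\tID=tx2e1;Parent=tx2",
    "chr1\ttoy\tCDS\t401\t520\t.\t-\t0\tID=tx2c1;Parent=tx2")
  writeLines(rows, gff)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub(" .*", "", names(genome))
  list(dir = dir, fasta = fasta, gff = gff, genome = genome,
       seq = genome_str)
}
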