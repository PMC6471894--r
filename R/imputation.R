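## Imputers: chip missing-data pre-pass, frequency random-fill (the lower
## bound), a windowed pedigree/LD imputer, and an adapter for external
## imputation software.
##
## The family/LD imputer is a documented stand-in for the strategy of
## pedigree-aware rolling-window imputation software: shrinking windows of
## chip markers are scanned along each chromosome, reference haplotypes
## matching the target's (partially phased) chip alleles exactly are
## searched relatives-first, and the matching haplotype's sequence-density
## alleles are copied; conflicts between overlapping windows are resolved
## by majority vote and uncovered cells fall back to frequency fill.

#' Define an imputation task
#'
#' @param ref_haps phased reference panel at sequence density (`haplo_set`).
#' @param target `geno_matrix` at chip density; every target site must exist
#'   in the reference (matched on chrom and pos).
#' @param ped a `pedigree`.
#' @param seed integer seed used by any stochastic fill.
#' @return a list of class `imputation_task`.
#' @export
imputation_task <- function(ref_haps, target, ped, seed = 1) {
  stopifnot(inherits(ref_haps, "haplo_set"), inherits(target, "geno_matrix"))
  cidx <- match(site_key(target$sites), site_key(ref_haps$sites))
  if (anyNA(cidx))
    stop("target sites absent from the reference panel: ",
         paste(utils::head(site_key(target$sites)[is.na(cidx)], 3), collapse = ", "))
  if (anyNA(ref_haps$hap_a) || anyNA(ref_haps$hap_b))
    stop("reference panel must be complete at imputation time")
  structure(list(ref = ref_haps, target = target, ped = ped,
                 seed = as.integer(seed), chip_idx = cidx),
            class = "imputation_task")
}

new_imputation_result <- function(imputed, provenance, method, haps = NULL) {
  structure(list(imputed = imputed, provenance = provenance,
                 method = method, haps = haps),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method=%s, %d samples x %d sites\n",
              x$method, length(x$imputed$samples), nrow(x$imputed$sites)))
  print(round(prop.table(table(x$provenance)), 4))
  invisible(x)
}

#' First-round imputation of missing chip genotypes
#'
#' Missing cells are filled, in order, by unambiguous Mendelian deduction
#' (from called parents, or from offspring genotypes that force both of the
#' individual's alleles) iterated to a fixed point, then by a within-chip
#' allele-frequency fill.
#'
#' @param chip `geno_matrix` at chip density (biallelic).
#' @param ped a `pedigree`.
#' @param seed seed for the frequency fill.
#' @return a complete `geno_matrix`; per-cell provenance (`observed`,
#'   `pedigree_deduced` or `frequency_filled`) is attached as
#'   `attr(, "provenance")`.
#' @export
fill_chip_missing <- function(chip, ped, seed = 1) {
  d <- chip$dosage
  prov <- matrix("observed", nrow(d), ncol(d))
  prov[is.na(d)] <- "frequency_filled"
  si <- match(ped$sire[match(chip$samples, ped$id)], chip$samples)
  di <- match(ped$dam[match(chip$samples, ped$id)], chip$samples)
  kids <- lapply(seq_along(chip$samples), function(j)
    which(si == j | di == j))
  other_parent <- function(j, k) if (!is.na(si[k]) && si[k] == j) di[k] else si[k]

  ## allele sets per dosage: 0 -> {ref}, 1 -> {ref, alt}, 2 -> {alt}
  repeat {
    changed <- FALSE
    miss <- which(is.na(d), arr.ind = TRUE)
    if (nrow(miss) == 0) break
    for (r in seq_len(nrow(miss))) {
      j <- miss[r, 1]; s <- miss[r, 2]
      ## deduction from parents
      if (!is.na(si[j]) && !is.na(di[j]) &&
          !is.na(d[si[j], s]) && !is.na(d[di[j], s])) {
        sset <- switch(d[si[j], s] + 1L, 0L, c(0L, 1L), 1L)
        dset <- switch(d[di[j], s] + 1L, 0L, c(0L, 1L), 1L)
        poss <- unique(as.vector(outer(sset, dset, `+`)))
        if (length(poss) == 1L) {
          d[j, s] <- poss; prov[j, s] <- "pedigree_deduced"; changed <- TRUE
          next
        }
      }
      ## deduction from offspring: an offspring with dosage 0 (2) forces a
      ## ref (alt) allele; a het offspring whose other parent is homozygous
      ## forces the complementary allele. Both alleles forced -> het.
      forced <- integer(0)
      for (k in kids[[j]]) {
        dk <- d[k, s]
        if (is.na(dk)) next
        if (dk == 0L) forced <- union(forced, 0L)
        if (dk == 2L) forced <- union(forced, 1L)
        if (dk == 1L) {
          op <- other_parent(j, k)
          if (!is.na(op) && !is.na(d[op, s])) {
            if (d[op, s] == 0L) forced <- union(forced, 1L)
            if (d[op, s] == 2L) forced <- union(forced, 0L)
          }
        }
      }
      if (length(forced) == 2L) {
        d[j, s] <- 1L; prov[j, s] <- "pedigree_deduced"; changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## frequency fill for the remainder
  still <- which(is.na(d), arr.ind = TRUE)
  if (nrow(still)) {
    p <- colMeans(d, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0
    withr::with_seed(as.integer(seed), {
      d[still] <- stats::rbinom(nrow(still), 1L, p[still[, 2]]) +
        stats::rbinom(nrow(still), 1L, p[still[, 2]])
    })
  }
  out <- chip
  out$dosage <- d
  out$a1 <- NULL; out$a2 <- NULL
  attr(out, "provenance") <- prov
  out
}

ref_alt_freq <- function(ref) colMeans(ref$hap_a + ref$hap_b) / 2

#' Frequency random-fill imputation (lower bound)
#'
#' For every non-chip site, each of the target's two alleles is drawn
#' independently as Bernoulli(p) with p the reference-panel alternative
#' allele frequency; chip sites are passed through. This is the accuracy
#' floor any informative imputer must beat. A variant drawing whole
#' genotypes from reference genotype frequencies is available via
#' `by_genotype = TRUE`.
#'
#' @param task an [imputation_task()].
#' @param by_genotype draw genotypes from genotype frequencies instead of
#'   two allele draws.
#' @return an `imputation_result`.
#' @export
frequency_fill_impute <- function(task, by_genotype = FALSE) {
  ref <- task$ref; tg <- task$target
  S <- nrow(ref$sites); Tn <- length(tg$samples)
  p <- ref_alt_freq(ref)
  withr::with_seed(task$seed, {
    if (by_genotype) {
      gf <- genotype_freqs(dosage_of(ref)$dosage)
      dos <- matrix(NA_integer_, Tn, S)
      for (j in seq_len(Tn)) {
        u <- stats::runif(S)
        dos[j, ] <- ifelse(u < gf[1, ], 0L, ifelse(u < gf[1, ] + gf[2, ], 1L, 2L))
      }
      hA <- ifelse(dos >= 1L, 1L, 0L); hB <- ifelse(dos == 2L, 1L, 0L)
    } else {
      hA <- matrix(stats::rbinom(Tn * S, 1L, rep(p, each = Tn)), Tn, S)
      hB <- matrix(stats::rbinom(Tn * S, 1L, rep(p, each = Tn)), Tn, S)
      dos <- hA + hB
    }
    prov <- matrix("frequency_filled", Tn, S)
    ## chip pass-through
    obs <- !is.na(tg$dosage)
    ci <- task$chip_idx
    dos[, ci][obs] <- tg$dosage[obs]
    swap <- stats::runif(Tn * length(ci)) < 0.5
    a <- ifelse(dos[, ci] >= 1L, 1L, 0L); b <- ifelse(dos[, ci] == 2L, 1L, 0L)
    het_swap <- swap & dos[, ci] == 1L
    hA[, ci] <- ifelse(het_swap, b, a)
    hB[, ci] <- ifelse(het_swap, a, b)
    prov[, ci][obs] <- "observed"
  })
  storage.mode(dos) <- "integer"
  imp <- geno_matrix(dos, ref$sites, samples = tg$samples, phased = TRUE)
  haps <- haplo_set(hA, hB, ref$sites, samples = tg$samples)
  new_imputation_result(imp, prov, "random_fill", haps)
}

genotype_freqs <- function(dosage) {
  ## 3 x sites matrix of genotype frequencies among non-missing calls
  n0 <- colSums(dosage == 0L, na.rm = TRUE)
  n1 <- colSums(dosage == 1L, na.rm = TRUE)
  n2 <- colSums(dosage == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  rbind(n0 / n, n1 / n, n2 / n)
}

## Haplotype row indices of an individual's relatives in the reference,
## parents first, then grandparents.
relative_hap_rows <- function(id, ped, ref_samples, n_ref) {
  pr <- match(id, ped$id)
  rows <- integer(0)
  if (!is.na(pr)) {
    parents <- c(ped$sire[pr], ped$dam[pr])
    gp <- unlist(lapply(parents[!is.na(parents)], function(p) {
      q <- match(p, ped$id)
      if (is.na(q)) return(NULL)
      c(ped$sire[q], ped$dam[q])
    }))
    for (anc in c(parents, gp)) {
      k <- match(anc, ref_samples)
      if (!is.na(k)) rows <- c(rows, k, k + n_ref)
    }
  }
  unique(rows)
}

#' Windowed family/LD imputation
#'
#' Per chromosome: (1) the target's chip-site phase is deduced where
#' possible from reference parents; (2) rolling windows of `W` chip markers
#' (largest `W` first, advancing by `W * (1 - overlap)`) are matched against
#' the reference haplotypes -- relatives first -- as pairs consistent with
#' the target's dosages and known phase, and the matched haplotypes'
#' sequence alleles are copied over the window's span (first/last windows
#' extend to the chromosome ends); (3) conflicting votes from overlapping
#' windows are resolved by majority, ties by the smallest matching window
#' size, then by relative-derived votes; (4) cells never covered by a match
#' fall back to frequency fill. Matching is exact (no mismatch tolerance).
#'
#' @param task an [imputation_task()].
#' @param window_sizes descending chip-marker window sizes (default 64, 16, 4).
#' @param overlap fractional overlap between consecutive windows (default 0.5).
#' @param max_tries candidate haplotypes examined per window before giving up.
#' @return an `imputation_result` with per-cell provenance.
#' @export
family_ld_impute <- function(task, window_sizes = c(64, 16, 4), overlap = 0.5,
                             max_tries = 12) {
  ref <- task$ref; tg <- task$target; ped <- task$ped
  window_sizes <- sort(unique(as.integer(window_sizes)), decreasing = TRUE)
  stopifnot(all(window_sizes >= 1), overlap >= 0, overlap < 1)
  R <- length(ref$samples); S <- nrow(ref$sites); Tn <- length(tg$samples)
  ref_dos <- ref$hap_a + ref$hap_b
  p_alt <- colMeans(ref_dos) / 2
  outA <- matrix(NA_integer_, Tn, S)
  outB <- matrix(NA_integer_, Tn, S)
  prov <- matrix("frequency_filled", Tn, S)

  chroms <- unique(ref$sites$chrom)
  for (ch in chroms) {
    scols <- which(ref$sites$chrom == ch)
    tcols <- which(tg$sites$chrom == ch)
    if (length(tcols) == 0) next
    lc <- match(task$chip_idx[tcols], scols)      # chip cols, chrom-local
    HH <- rbind(ref$hap_a[, scols, drop = FALSE],
                ref$hap_b[, scols, drop = FALSE]) # 2R x S_ch
    Hw_all <- HH[, lc, drop = FALSE]
    S_ch <- length(scols); C_ch <- length(lc)

    for (t in seq_len(Tn)) {
      d <- tg$dosage[t, tcols]
      kA <- kB <- rep(NA_integer_, C_ch)
      hom <- !is.na(d) & d != 1L
      kA[hom] <- kB[hom] <- as.integer(d[hom] == 2L)
      pr <- match(tg$samples[t], ped$id)
      sire_r <- if (!is.na(pr)) match(ped$sire[pr], ref$samples) else NA
      dam_r <- if (!is.na(pr)) match(ped$dam[pr], ref$samples) else NA
      het <- !is.na(d) & d == 1L
      if (!is.na(sire_r)) {
        sd <- ref_dos[sire_r, scols][lc]
        fix <- het & sd != 1L
        kA[fix] <- as.integer(sd[fix] == 2L); kB[fix] <- 1L - kA[fix]
      }
      if (!is.na(dam_r)) {
        dd <- ref_dos[dam_r, scols][lc]
        fix <- het & is.na(kB) & dd != 1L
        kB[fix] <- as.integer(dd[fix] == 2L); kA[fix] <- 1L - kB[fix]
      }
      rel <- relative_hap_rows(tg$samples[t], ped, ref$samples, R)
      prio <- rep(2L, 2L * R); prio[rel] <- 1L
      ## rows that already matched for this target are tried first within a
      ## priority tier: haplotype continuity across windows prevents small
      ## windows from out-voting a consistent long match
      matched_n <- integer(2L * R)

      v1A <- v0A <- v1B <- v0B <- numeric(S_ch)
      sz1A <- sz0A <- sz1B <- sz0B <-
        matrix(0, length(window_sizes), S_ch)
      r1A <- r0A <- r1B <- r0B <- numeric(S_ch)

      W_done <- integer(0)
      for (wi in seq_along(window_sizes)) {
        W <- min(window_sizes[wi], C_ch)
        if (W %in% W_done) next      # sizes clamped to the chip count collapse
        W_done <- c(W_done, W)
        step <- max(1L, as.integer(round(W * (1 - overlap))))
        starts <- unique(c(seq(1L, max(1L, C_ch - W + 1L), by = step),
                           C_ch - W + 1L))
        for (a in starts) {
          b <- a + W - 1L
          cols <- a:b
          ordprio <- order(prio, -matched_n)
          dw <- d[cols]; kAw <- kA[cols]; kBw <- kB[cols]
          Hw <- Hw_all[, cols, drop = FALSE]
          dmat <- matrix(dw, 2L * R, W, byrow = TRUE)
          cmp <- dmat - Hw
          okc <- is.na(dmat) | cmp == 0L | cmp == 1L
          compat <- rowSums(!okc) == 0L
          km <- which(!is.na(kAw))
          if (length(km)) {
            sub <- Hw[, km, drop = FALSE]
            mA <- rowSums(sub != matrix(kAw[km], 2L * R, length(km),
                                        byrow = TRUE)) == 0L
          } else mA <- rep(TRUE, 2L * R)
          candA <- ordprio[compat[ordprio] & mA[ordprio]]
          if (!length(candA)) next
          wb <- which(is.na(dw) & !is.na(kBw))
          done <- FALSE
          for (a_row in utils::head(candA, max_tries)) {
            tB <- dw - Hw[a_row, ]
            nn <- which(!is.na(tB))
            if (length(nn)) {
              sub <- Hw[, nn, drop = FALSE]
              mB <- rowSums(sub != matrix(tB[nn], 2L * R, length(nn),
                                          byrow = TRUE)) == 0L
            } else mB <- rep(TRUE, 2L * R)
            if (length(wb)) {
              sub <- Hw[, wb, drop = FALSE]
              mB <- mB & rowSums(sub != matrix(kBw[wb], 2L * R, length(wb),
                                               byrow = TRUE)) == 0L
            }
            candB <- ordprio[mB[ordprio]]
            if (!length(candB)) next
            b_row <- candB[1]
            lo <- if (a == 1L) 1L else lc[a]
            hi <- if (b == C_ch) S_ch else lc[b]
            seg <- lo:hi
            alA <- HH[a_row, seg]; alB <- HH[b_row, seg]
            v1A[seg] <- v1A[seg] + alA; v0A[seg] <- v0A[seg] + (1 - alA)
            v1B[seg] <- v1B[seg] + alB; v0B[seg] <- v0B[seg] + (1 - alB)
            sz1A[wi, seg] <- sz1A[wi, seg] + alA
            sz0A[wi, seg] <- sz0A[wi, seg] + (1 - alA)
            sz1B[wi, seg] <- sz1B[wi, seg] + alB
            sz0B[wi, seg] <- sz0B[wi, seg] + (1 - alB)
            if (prio[a_row] == 1L) { r1A[seg] <- r1A[seg] + alA
                                     r0A[seg] <- r0A[seg] + (1 - alA) }
            if (prio[b_row] == 1L) { r1B[seg] <- r1B[seg] + alB
                                     r0B[seg] <- r0B[seg] + (1 - alB) }
            ## matched copies anchor chip-site phase for later windows
            adopt <- is.na(kA[cols])
            kA[cols][adopt] <- Hw[a_row, adopt]
            kB[cols][adopt] <- HH[b_row, lc[cols]][adopt]
            matched_n[a_row] <- matched_n[a_row] + 1L
            matched_n[b_row] <- matched_n[b_row] + 1L
            done <- TRUE
            break
          }
          if (!done) next
        }
      }

      resolve <- function(v0, v1, sz0, sz1, r0, r1) {
        al <- rep(NA_integer_, S_ch)
        al[v1 > v0] <- 1L
        al[v0 > v1] <- 0L
        tie <- which(is.na(al) & (v0 + v1) > 0)
        if (length(tie)) {
          for (wi in rev(seq_along(window_sizes))) {   # smallest size first
            s0 <- sz0[wi, tie]; s1 <- sz1[wi, tie]
            dec <- s0 != s1
            al[tie[dec]] <- as.integer(s1[dec] > s0[dec])
            tie <- tie[!dec]
            if (!length(tie)) break
          }
          if (length(tie)) {
            dec <- r0[tie] != r1[tie]
            al[tie[dec]] <- as.integer(r1[tie[dec]] > r0[tie[dec]])
          }
        }
        al
      }
      aA <- resolve(v0A, v1A, sz0A, sz1A, r0A, r1A)
      aB <- resolve(v0B, v1B, sz0B, sz1B, r0B, r1B)
      covered <- !is.na(aA) & !is.na(aB)
      prov[t, scols[covered]] <- "haplotype_copied"
      outA[t, scols] <- aA
      outB[t, scols] <- aB
    }
  }

  ## frequency fill for uncovered cells, then chip pass-through
  withr::with_seed(task$seed + 1L, {
    naA <- is.na(outA); naB <- is.na(outB)
    pm <- matrix(p_alt, Tn, S, byrow = TRUE)
    outA[naA] <- stats::rbinom(sum(naA), 1L, pm[naA])
    outB[naB] <- stats::rbinom(sum(naB), 1L, pm[naB])
  })
  ci <- task$chip_idx
  obs <- !is.na(tg$dosage)
  chipA <- outA[, ci, drop = FALSE]; chipB <- outB[, ci, drop = FALSE]
  o <- tg$dosage
  fixlo <- obs & o == 0L; fixhi <- obs & o == 2L
  chipA[fixlo] <- 0L; chipB[fixlo] <- 0L
  chipA[fixhi] <- 1L; chipB[fixhi] <- 1L
  hetfix <- obs & o == 1L & (chipA + chipB != 1L)
  chipA[hetfix] <- 0L; chipB[hetfix] <- 1L
  outA[, ci] <- chipA; outB[, ci] <- chipB
  pv <- prov[, ci, drop = FALSE]; pv[obs] <- "observed"
  prov[, ci] <- pv

  dos <- outA + outB
  imp <- geno_matrix(dos, ref$sites, samples = tg$samples, phased = TRUE)
  haps <- haplo_set(outA, outB, ref$sites, samples = tg$samples)
  new_imputation_result(imp, prov, "family_ld", haps)
}

#' Run an external imputation executable
#'
#' Writes the reference (phased VCF), target (VCF) and pedigree (TSV) to a
#' scratch directory, substitutes them into `cmd_template` (placeholders
#' `{ref}`, `{target}`, `{ped}`, `{out}`, `{seed}`), runs the command, and
#' parses the returned VCF.
#'
#' @param task an [imputation_task()].
#' @param cmd_template shell command with placeholders.
#' @return an `imputation_result` with provenance `observed` at chip sites
#'   and `haplotype_copied` elsewhere.
#' @export
run_external_imputer <- function(task, cmd_template) {
  dir <- tempfile("extimp"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  paths <- list(ref = file.path(dir, "ref.vcf"),
                target = file.path(dir, "target.vcf"),
                ped = file.path(dir, "ped.tsv"),
                out = file.path(dir, "imputed.vcf"),
                seed = task$seed)
  write_vcf(task$ref, paths$ref)
  write_vcf(task$target, paths$target)
  write_pedigree(task$ped, paths$ped)
  cmd <- cmd_template
  for (k in names(paths))
    cmd <- gsub(paste0("{", k, "}"), paths[[k]], cmd, fixed = TRUE)
  status <- tryCatch(
    withCallingHandlers(
      system(paste(cmd, "2>&1"), intern = TRUE),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) structure(conditionMessage(e), status = 127L))
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(paths$out))
    stop("external imputer failed (exit ", code, "):\n",
         paste(utils::tail(status, 20), collapse = "\n"))
  gm <- read_vcf(paths$out)
  missing_s <- setdiff(task$target$samples, gm$samples)
  if (length(missing_s))
    stop("external imputer output is missing sample(s): ",
         paste(missing_s, collapse = ", "))
  gm <- gm[task$target$samples, ]
  if (anyNA(gm$dosage)) stop("external imputer left missing genotypes")
  prov <- matrix("haplotype_copied", length(gm$samples), nrow(gm$sites))
  ci <- match(site_key(task$target$sites), site_key(gm$sites))
  prov[, ci[!is.na(ci)]] <- "observed"
  new_imputation_result(gm, prov, "external")
}

#' Resolve an imputer by name
#' @param method `"family_ld"`, `"random_fill"`, or a function taking an
#'   `imputation_task`.
#' @param ... fixed arguments passed on to the imputer.
#' @return a function `task -> imputation_result`.
#' @export
get_imputer <- function(method = c("family_ld", "random_fill"), ...) {
  if (is.function(method)) return(method)
  method <- match.arg(method)
  dots <- list(...)
  switch(method,
         family_ld = function(task) do.call(family_ld_impute, c(list(task), dots)),
         random_fill = function(task) do.call(frequency_fill_impute, c(list(task), dots)))
}
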