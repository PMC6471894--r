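## Annotation profiling: classify SNP positions into genomic-region
## categories and coding-effect classes against user-supplied gene models
## (GFF3) and a genome sequence (FASTA), and compare the annotation profile
## of two panels (e.g. chip vs imputed sequence).

REGION_CATEGORIES <- c("exonic", "exonic;splicing", "splicing", "UTR5", "UTR3",
                       "UTR5;UTR3", "intronic", "upstream", "downstream",
                       "upstream;downstream", "intergenic")

MUTATION_TYPES <- c("synonymous SNV", "non-synonymous SNV", "stop gain",
                    "stop loss", "frameshift deletion", "frameshift insertion",
                    "non-frameshift deletion", "non-frameshift insertion",
                    "unclassified")

#' Read gene models from a GFF3 file
#'
#' Transcript features (`mRNA`/`transcript`) and their `exon`, `CDS`,
#' `five_prime_UTR` and `three_prime_UTR` children are collected; when UTR
#' features are absent they are derived as the exonic regions outside the
#' CDS span.
#'
#' @param path GFF3 file.
#' @return list of class `gene_models`, one element per transcript with
#'   `id`, `chrom`, `strand`, `span`, and interval matrices `exons`, `cds`,
#'   `utr5`, `utr3` (columns start, end; 1-based inclusive).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  tx_rows <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(tx_rows) == 0) stop("no mRNA/transcript features in ", path)
  get_parent <- function(d) {
    if ("Parent" %in% names(d)) vapply(d$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, "")
    else rep(NA_character_, nrow(d))
  }
  df$parent <- get_parent(df)
  models <- lapply(seq_len(nrow(tx_rows)), function(i) {
    tx <- tx_rows[i, ]
    id <- if ("ID" %in% names(tx)) as.character(tx$ID) else paste0("tx", i)
    kids <- df[!is.na(df$parent) & df$parent == id, , drop = FALSE]
    iv <- function(tp) {
      k <- kids[kids$type == tp, , drop = FALSE]
      if (nrow(k) == 0) return(matrix(numeric(0), 0, 2))
      m <- cbind(k$start, k$end)
      m[order(m[, 1]), , drop = FALSE]
    }
    exons <- iv("exon")
    cds <- iv("CDS")
    utr5 <- iv("five_prime_UTR"); utr3 <- iv("three_prime_UTR")
    strand <- as.character(tx$strand)
    if (nrow(exons) == 0) exons <- if (nrow(cds)) cds else cbind(tx$start, tx$end)
    if (nrow(utr5) == 0 && nrow(utr3) == 0 && nrow(cds) > 0) {
      ## derive UTRs: exon stretches outside the CDS span
      lo <- min(cds[, 1]); hi <- max(cds[, 2])
      left <- right <- matrix(numeric(0), 0, 2)
      for (r in seq_len(nrow(exons))) {
        s <- exons[r, 1]; e <- exons[r, 2]
        if (s < lo) left <- rbind(left, c(s, min(e, lo - 1)))
        if (e > hi) right <- rbind(right, c(max(s, hi + 1), e))
      }
      if (strand == "-") { utr5 <- right; utr3 <- left }
      else { utr5 <- left; utr3 <- right }
    }
    list(id = id, chrom = as.character(tx$seqnames), strand = strand,
         span = c(tx$start, tx$end), exons = exons, cds = cds,
         utr5 = utr5, utr3 = utr3)
  })
  structure(models, class = "gene_models")
}

in_iv <- function(pos, iv) nrow(iv) > 0 && any(pos >= iv[, 1] & pos <= iv[, 2])

## region of one position wrt one transcript; NA when unrelated to it
region_one_tx <- function(pos, tx, upstream_bp, splice_bp) {
  span <- tx$span
  if (pos >= span[1] && pos <= span[2]) {
    exons <- tx$exons
    ## internal exon boundaries (edges that abut an intron)
    internal_ends <- exons[-nrow(exons), 2]
    internal_starts <- exons[-1, 1]
    in_exon <- in_iv(pos, exons)
    near_boundary <- (length(internal_ends) &&
                        any(abs(pos - internal_ends) <= splice_bp |
                              abs(pos - internal_starts) <= splice_bp))
    if (in_iv(pos, tx$cds)) {
      near_exon_edge <- length(internal_ends) &&
        any((pos >= internal_ends - splice_bp + 1 & pos <= internal_ends) |
              (pos <= internal_starts + splice_bp - 1 & pos >= internal_starts))
      return(if (near_exon_edge) "exonic;splicing" else "exonic")
    }
    if (in_iv(pos, tx$utr5)) return("UTR5")
    if (in_iv(pos, tx$utr3)) return("UTR3")
    if (in_exon) return("exonic")   # non-coding exon without UTR annotation
    ## intronic side
    if (near_boundary) return("splicing")
    return("intronic")
  }
  tss <- if (tx$strand == "-") span[2] else span[1]
  tes <- if (tx$strand == "-") span[1] else span[2]
  up <- if (tx$strand == "-") pos > span[2] && pos - span[2] <= upstream_bp
        else pos < span[1] && span[1] - pos <= upstream_bp
  dn <- if (tx$strand == "-") pos < span[1] && span[1] - pos <= upstream_bp
        else pos > span[2] && pos - span[2] <= upstream_bp
  if (up) return("upstream")
  if (dn) return("downstream")
  NA_character_
}

#' Classify positions into genomic-region categories
#'
#' Precedence when a position hits several transcripts:
#' exonic > splicing > UTR > intronic > upstream/downstream > intergenic.
#' Splicing means within `splice_bp` of an exon/intron boundary on the
#' intron side; `exonic;splicing` is a coding-exon position that close to
#' the boundary. A position that is UTR5 for one transcript and UTR3 for an
#' overlapping one is `UTR5;UTR3` (likewise `upstream;downstream`).
#'
#' @param chrom,pos vectors of positions to classify.
#' @param models a `gene_models` object.
#' @param upstream_bp flank width defining up/downstream (default 1000).
#' @param splice_bp splice-boundary distance (default 2).
#' @return character vector of region categories.
#' @export
classify_region <- function(chrom, pos, models, upstream_bp = 1000, splice_bp = 2) {
  prec <- c("exonic;splicing" = 1, "exonic" = 1.5, "splicing" = 2,
            "UTR5" = 3, "UTR3" = 3, "intronic" = 4,
            "upstream" = 5, "downstream" = 5)
  chrom <- rep_len(as.character(chrom), length(pos))
  tx_chrom <- vapply(models, `[[`, "", "chrom")
  vapply(seq_along(pos), function(i) {
    hits <- character(0)
    for (tx in models[tx_chrom == chrom[i]]) {
      r <- region_one_tx(pos[i], tx, upstream_bp, splice_bp)
      if (!is.na(r)) hits <- c(hits, r)
    }
    if (!length(hits)) return("intergenic")
    best <- min(prec[hits])
    top <- unique(hits[prec[hits] == best])
    if (setequal(top, c("UTR5", "UTR3"))) return("UTR5;UTR3")
    if (setequal(top, c("upstream", "downstream"))) return("upstream;downstream")
    top[which.min(prec[top])]
  }, "")
}

## genomic positions of a transcript's CDS in transcription order
cds_positions <- function(tx) {
  if (nrow(tx$cds) == 0) return(integer(0))
  g <- unlist(lapply(seq_len(nrow(tx$cds)),
                     function(r) seq.int(tx$cds[r, 1], tx$cds[r, 2])))
  if (tx$strand == "-") rev(g) else g
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

base_at <- function(genome, chrom, pos) {
  as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
}

#' Classify the coding effect of a variant
#'
#' SNVs are translated through the standard codon table (strand-aware):
#' synonymous / non-synonymous SNV, stop gain, stop loss. Indels are
#' frameshift when the length difference is not a multiple of 3, otherwise
#' non-frameshift. Anything else is `unclassified`.
#'
#' @param chrom,pos,ref,alt the variant.
#' @param models a `gene_models` object.
#' @param genome a named `DNAStringSet` (or list coercible to it).
#' @return the mutation-type label, or NA when the variant does not overlap
#'   a CDS.
#' @export
classify_coding_effect <- function(chrom, pos, ref, alt, models, genome) {
  len_diff <- nchar(alt) - nchar(ref)
  for (tx in models) {
    if (tx$chrom != chrom || !in_iv(pos, tx$cds)) next
    if (len_diff != 0) {
      fs <- (abs(len_diff) %% 3) != 0
      return(if (len_diff < 0) {
        if (fs) "frameshift deletion" else "non-frameshift deletion"
      } else {
        if (fs) "frameshift insertion" else "non-frameshift insertion"
      })
    }
    if (nchar(ref) != 1 || nchar(alt) != 1) return("unclassified")
    gpos <- cds_positions(tx)
    loc <- match(pos, gpos)
    if (is.na(loc)) return("unclassified")
    idx <- (loc - 1) %/% 3
    cpos <- gpos[(idx * 3 + 1):(idx * 3 + 3)]
    if (anyNA(cpos)) return("unclassified")   # CDS phase irrecoverable
    bases <- vapply(cpos, function(p) base_at(genome, chrom, p), "")
    if (tx$strand == "-") bases <- unname(COMPLEMENT[bases])
    codon_ref <- paste(bases, collapse = "")
    if (!all(c(ref, alt) %in% names(COMPLEMENT))) return("unclassified")
    sub <- if (tx$strand == "-") unname(COMPLEMENT[alt]) else alt
    bases[match(loc, (idx * 3 + 1):(idx * 3 + 3))] <- sub
    codon_alt <- paste(bases, collapse = "")
    gc <- Biostrings::GENETIC_CODE
    aa_ref <- gc[[codon_ref]]; aa_alt <- gc[[codon_alt]]
    if (is.null(aa_ref) || is.null(aa_alt)) return("unclassified")
    if (aa_ref != "*" && aa_alt == "*") return("stop gain")
    if (aa_ref == "*" && aa_alt != "*") return("stop loss")
    return(if (aa_ref == aa_alt) "synonymous SNV" else "non-synonymous SNV")
  }
  NA_character_
}

#' Annotation profile of a variant panel
#'
#' Applies [classify_region()] to all sites and [classify_coding_effect()]
#' to the coding-exonic ones, and tabulates counts with percentages both of
#' all positions and of annotated (non-intergenic) positions.
#'
#' @param sites site table (chrom, pos, ref, alt1).
#' @param models a `gene_models` object.
#' @param genome named `DNAStringSet` genome sequence.
#' @param upstream_bp,splice_bp see [classify_region()].
#' @return list of class `annotation_profile` with `regions` and `effects`
#'   data.frames.
#' @export
annotation_profile <- function(sites, models, genome, upstream_bp = 1000,
                               splice_bp = 2) {
  if (nrow(sites) == 0) {
    regions <- data.frame(category = REGION_CATEGORIES, count = 0L,
                          pct_total = 0, pct_annotated = 0)
    effects <- data.frame(type = character(0), count = integer(0),
                          pct = numeric(0))
    return(structure(list(regions = regions, effects = effects, n_total = 0L),
                     class = "annotation_profile"))
  }
  reg <- classify_region(sites$chrom, sites$pos, models, upstream_bp, splice_bp)
  counts <- table(factor(reg, levels = REGION_CATEGORIES))
  n <- nrow(sites)
  n_annot <- sum(reg != "intergenic")
  regions <- data.frame(category = names(counts), count = as.integer(counts),
                        pct_total = 100 * as.integer(counts) / n,
                        pct_annotated = if (n_annot > 0)
                          100 * as.integer(counts) / n_annot else 0,
                        stringsAsFactors = FALSE)
  coding <- which(reg %in% c("exonic", "exonic;splicing"))
  eff <- character(0)
  for (i in coding) {
    e <- classify_coding_effect(sites$chrom[i], sites$pos[i], sites$ref[i],
                                sites$alt1[i], models, genome)
    if (!is.na(e)) eff <- c(eff, e)
  }
  etab <- table(factor(eff, levels = MUTATION_TYPES))
  etab <- etab[etab > 0]
  effects <- data.frame(type = names(etab), count = as.integer(etab),
                        pct = if (length(eff)) 100 * as.integer(etab) / length(eff)
                              else numeric(length(etab)),
                        stringsAsFactors = FALSE)
  structure(list(regions = regions, effects = effects, n_total = n),
            class = "annotation_profile")
}

#' @export
print.annotation_profile <- function(x, ...) {
  cat(sprintf("<annotation_profile> %d positions\n", x$n_total))
  print(x$regions[x$regions$count > 0, ], row.names = FALSE)
  if (nrow(x$effects)) {
    cat("Coding effects:\n")
    print(x$effects, row.names = FALSE)
  }
  invisible(x)
}
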