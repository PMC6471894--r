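## Pedigree container, IO, and the study-shaped breeding design builder.

PED_CLASSES <- c("Factorial_parents", "MultiplePair_parents",
                 "Factorial_progenies", "MultiplePair_progenies", "Unrelated")

#' Construct a pedigree
#'
#' @param id individual identifiers (unique).
#' @param sire,dam parent identifiers, NA for unknown. When present they must
#'   refer to individuals in the pedigree.
#' @param class relatedness class, one of `Factorial_parents`,
#'   `MultiplePair_parents`, `Factorial_progenies`, `MultiplePair_progenies`,
#'   `Unrelated`.
#' @return a `data.frame` of class `pedigree`.
#' @export
pedigree <- function(id, sire = NA, dam = NA, class = "Unrelated") {
  n <- length(id)
  ped <- data.frame(id = as.character(id),
                    sire = rep_len(as.character(sire), n),
                    dam = rep_len(as.character(dam), n),
                    class = rep_len(as.character(class), n),
                    stringsAsFactors = FALSE)
  ped$sire[!is.na(ped$sire) & ped$sire == ""] <- NA
  ped$dam[!is.na(ped$dam) & ped$dam == ""] <- NA
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  bad <- setdiff(ped$class, PED_CLASSES)
  if (length(bad)) stop("unknown pedigree class label(s): ", paste(bad, collapse = ", "))
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    miss <- !is.na(p) & !(p %in% ped$id)
    if (any(miss))
      stop(sprintf("%s id(s) not present in pedigree: %s", col,
                   paste(unique(p[miss]), collapse = ", ")))
  }
  ped_topo_order(ped)  # errors on cycles (incl. self-ancestry)
  invisible(ped)
}

#' Topological order of a pedigree (founders first)
#'
#' @param ped a pedigree.
#' @return integer row order such that every parent precedes its offspring.
#' @export
ped_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    ord <- c(ord, idx[ready])
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree contains cyclic ancestry (an individual is its own ancestor)")
  ord
}

#' Read a pedigree from a tab-separated file
#'
#' Expects a header line `id<TAB>sire<TAB>dam<TAB>class`; empty sire/dam
#' fields denote founders.
#'
#' @param path file path.
#' @return a `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("", "NA", "0"))
  need <- c("id", "sire", "dam", "class")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  pedigree(df$id, df$sire, df$dam, df$class)
}

#' Write a pedigree to a tab-separated file
#' @param ped a `pedigree`.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trios and duos available among a set of genotyped samples
#'
#' @param ped a pedigree.
#' @param samples sample ids with genotype data.
#' @return data.frame with columns child, sire, dam; sire or dam is NA when
#'   only one parent is genotyped (a duo).
#' @export
ped_trios <- function(ped, samples) {
  keep <- ped$id %in% samples
  child <- ped$id[keep]
  sire <- ped$sire[keep]
  dam <- ped$dam[keep]
  sire[!(sire %in% samples)] <- NA
  dam[!(dam %in% samples)] <- NA
  has <- !is.na(sire) | !is.na(dam)
  data.frame(child = child[has], sire = sire[has], dam = dam[has],
             stringsAsFactors = FALSE)
}

#' Describe a two-mating-set breeding design
#'
#' The default values reproduce the structure of the study population this
#' package emulates: an almost-complete 4 female x 4 male factorial (14 of
#' the 16 possible crosses, 413 F1), a multiple-pair set of 8 females x
#' 7 males in 21 crosses (598 F1) in which 2 of the females are themselves
#' factorial progenies, 6 unrelated wild accessions, and one grandparent of
#' a factorial parent. That yields 1039 distinct individuals, of which 43
#' (the grandparent, the 23 parents and 13 further progenies chosen so that
#' every parent has a sequenced offspring, plus the 6 unrelated) form the
#' sequenced reference.
#'
#' @param factorial list with `n_female`, `n_male`, `n_crosses`, `n_progeny`,
#'   and optionally `crosses` (data.frame of 1-based `female`/`male` indices).
#' @param multipair list with `n_female_new`, `n_male`, `n_crosses`,
#'   `n_progeny`, `n_dual_role` (factorial progenies reused as multipair
#'   dams); NULL to omit the second mating set.
#' @param n_unrelated number of unrelated accessions.
#' @param grandparent simulate one grandparent as sire of the first factorial
#'   male parent.
#' @param n_seq_progeny number of progenies (besides dual-role ones) in the
#'   sequenced reference subset.
#' @return a list of class `study_design`.
#' @export
study_design <- function(factorial = list(n_female = 4, n_male = 4,
                                          n_crosses = 14, n_progeny = 413),
                         multipair = list(n_female_new = 6, n_male = 7,
                                          n_crosses = 21, n_progeny = 598,
                                          n_dual_role = 2),
                         n_unrelated = 6, grandparent = TRUE,
                         n_seq_progeny = 13) {
  d <- list(factorial = factorial, multipair = multipair,
            n_unrelated = n_unrelated, grandparent = isTRUE(grandparent),
            n_seq_progeny = n_seq_progeny)
  class(d) <- "study_design"
  d
}

## Distribute n progenies over k families as evenly as possible.
split_progeny <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
}

## Default cross list: diagonal first (so every parent appears early), then
## the remaining grid cells row by row, truncated to n_crosses.
auto_crosses <- function(nf, nm, n_crosses) {
  diag <- data.frame(female = seq_len(min(nf, nm)), male = seq_len(min(nf, nm)))
  grid <- expand.grid(female = seq_len(nf), male = seq_len(nm))
  grid <- grid[!(paste(grid$female, grid$male) %in% paste(diag$female, diag$male)), ]
  all <- rbind(diag, grid)
  if (n_crosses > nrow(all)) stop("more crosses requested than grid cells")
  all[seq_len(n_crosses), , drop = FALSE]
}

#' Build the pedigree of a breeding design
#'
#' @param design a [study_design()].
#' @return a `pedigree` with one row per individual; the ids of the sequenced
#'   reference subset are attached as `attr(, "sequenced")`.
#' @export
build_pedigree <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  fa <- design$factorial
  id <- character(0); sire <- character(0); dam <- character(0); cls <- character(0)
  add <- function(i, s, d, c) {
    n <- length(i)
    id <<- c(id, i)
    sire <<- c(sire, rep_len(as.character(s), n))
    dam <<- c(dam, rep_len(as.character(d), n))
    cls <<- c(cls, rep_len(c, n))
  }
  ffem <- sprintf("FF%d", seq_len(fa$n_female))
  fmal <- sprintf("FM%d", seq_len(fa$n_male))
  gp <- if (design$grandparent) "GP1" else character(0)
  if (design$grandparent) add("GP1", NA, NA, "Factorial_parents")
  add(ffem, NA, NA, "Factorial_parents")
  ## grandparent is the sire of the first factorial male (single-parent duo)
  add(fmal, c(if (design$grandparent) "GP1" else NA,
              rep(NA, fa$n_male - 1L)), NA, "Factorial_parents")

  crosses <- fa$crosses
  if (is.null(crosses)) crosses <- auto_crosses(fa$n_female, fa$n_male, fa$n_crosses)
  if (any(crosses$female > fa$n_female) || any(crosses$male > fa$n_male))
    stop("factorial cross refers to a parent outside the design")
  fp <- sprintf("FP%03d", seq_len(fa$n_progeny))
  fam_sizes <- split_progeny(fa$n_progeny, nrow(crosses))
  fam_of <- rep(seq_len(nrow(crosses)), fam_sizes)
  add(fp, fmal[crosses$male[fam_of]], ffem[crosses$female[fam_of]],
      "Factorial_progenies")

  mp_seq <- character(0)
  mp <- design$multipair
  if (!is.null(mp)) {
    n_dual <- mp$n_dual_role %||% 0L
    if (n_dual > fa$n_progeny) stop("not enough factorial progenies for dual roles")
    dual <- fp[seq_len(n_dual)]
    cls[match(dual, id)] <- "MultiplePair_parents"
    mfem_new <- sprintf("MF%d", seq_len(mp$n_female_new))
    mmal <- sprintf("MM%d", seq_len(mp$n_male))
    add(mfem_new, NA, NA, "MultiplePair_parents")
    add(mmal, NA, NA, "MultiplePair_parents")
    mfem <- c(mfem_new, dual)
    mcross <- mp$crosses
    if (is.null(mcross)) {
      k <- seq_len(mp$n_crosses)
      mcross <- data.frame(female = ((k - 1L) %% length(mfem)) + 1L,
                           male = ((k - 1L) %% mp$n_male) + 1L)
    }
    if (any(mcross$female > length(mfem)) || any(mcross$male > mp$n_male))
      stop("multiple-pair cross refers to a parent outside the design")
    mpp <- sprintf("MP%03d", seq_len(mp$n_progeny))
    msz <- split_progeny(mp$n_progeny, nrow(mcross))
    mfam <- rep(seq_len(nrow(mcross)), msz)
    add(mpp, mmal[mcross$male[mfam]], mfem[mcross$female[mfam]],
        "MultiplePair_progenies")
    attr_mp <- list(mpp = mpp, mfam = mfam, mcross = mcross, mfem = mfem,
                    mmal = mmal)
  }

  if (design$n_unrelated > 0)
    add(sprintf("U%d", seq_len(design$n_unrelated)), NA, NA, "Unrelated")

  ped <- pedigree(id, sire, dam, cls)

  ## sequenced subset: grandparent + all parents + dual-role + progenies
  ## chosen greedily so every parent has a sequenced offspring + unrelated
  n_dual <- if (is.null(mp)) 0L else (mp$n_dual_role %||% 0L)
  dual <- fp[seq_len(n_dual)]
  covered <- unique(c(ped$sire[match(dual, ped$id)],
                      ped$dam[match(dual, ped$id)]))
  seq_prog <- character(0)
  take <- function(child) {
    seq_prog <<- c(seq_prog, child)
    covered <<- unique(c(covered, ped$sire[match(child, ped$id)],
                         ped$dam[match(child, ped$id)]))
  }
  pick_covering <- function(prog_ids, fam_idx) {
    for (f in unique(fam_idx)) {
      kids <- setdiff(prog_ids[fam_idx == f], dual)
      if (!length(kids)) next
      par <- c(ped$sire[match(kids[1], ped$id)], ped$dam[match(kids[1], ped$id)])
      if (!all(par %in% covered)) take(kids[1])
    }
  }
  pick_covering(fp, fam_of)
  if (!is.null(mp)) pick_covering(attr_mp$mpp, attr_mp$mfam)
  ## pad with additional first-of-family progenies up to the requested count
  pool_extra <- c(if (!is.null(mp)) attr_mp$mpp[match(unique(attr_mp$mfam),
                                                      attr_mp$mfam)],
                  fp[match(unique(fam_of), fam_of)],
                  fp, if (!is.null(mp)) attr_mp$mpp)
  for (x in setdiff(pool_extra, c(seq_prog, dual))) {
    if (length(seq_prog) >= design$n_seq_progeny) break
    take(x)
  }
  seq_prog <- seq_prog[seq_len(min(length(seq_prog), design$n_seq_progeny))]
  sequenced <- c(gp, ffem, fmal,
                 if (!is.null(mp)) c(sprintf("MF%d", seq_len(mp$n_female_new)),
                                     sprintf("MM%d", seq_len(mp$n_male)), dual),
                 seq_prog,
                 if (design$n_unrelated > 0) sprintf("U%d", seq_len(design$n_unrelated)))
  attr(ped, "sequenced") <- unique(sequenced)
  ped
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals (%d founders)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam))))
  print(table(x$class))
  invisible(x)
}
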