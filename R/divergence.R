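## Nei-Gojobori (1986) synonymous/nonsynonymous counting on codon
## alignments, Jukes-Cantor correction, and molecular-clock dating of
## haplotype-group divergence.
##
## The NG86 quantities are computed from lookup tables built once per
## session: per-codon synonymous site fractions, and per codon pair the
## pathway-averaged synonymous/nonsynonymous difference counts. Mutations
## passing through stop codons are excluded from both the viable-neighbour
## sets and the substitution pathways, following the classical method.

## ---- genetic code -------------------------------------------------------

#' @noRd
genetic_code <- function() {
  if (is.null(.tri_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .tri_cache$code <- stats::setNames(as.character(gc), names(gc))
  }
  .tri_cache$code
}

#' @noRd
all_codons <- function() {
  if (is.null(.tri_cache$codons)) {
    b <- .BASES
    .tri_cache$codons <- as.vector(t(outer(
      as.vector(t(outer(b, b, paste0))), b, paste0)))
  }
  .tri_cache$codons
}

#' @noRd
translate_codons <- function(codons) {
  aa <- genetic_code()[codons]
  unname(aa)
}

## Permutations of 1..k for k <= 3 (substitution pathway orderings).
#' @noRd
orderings <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

## Build all NG86 lookup tables: s/n per codon, and 64 x 64 matrices of
## pathway-averaged synonymous (sd) and nonsynonymous (nd) differences.
#' @noRd
ng_tables <- function() {
  if (!is.null(.tri_cache$ng)) return(.tri_cache$ng)
  codons <- all_codons()
  code <- genetic_code()
  aa <- unname(code[codons])
  sense <- aa != "*"

  s <- rep(NA_real_, 64L)
  for (i in which(sense)) {
    cod <- seq_to_vec(codons[i])
    si <- 0
    for (pos in 1:3) {
      nb <- cod
      syn <- 0L
      viable <- 0L
      for (b in setdiff(.BASES, cod[pos])) {
        nb[pos] <- b
        a2 <- code[[vec_to_seq(nb)]]
        if (a2 == "*") next
        viable <- viable + 1L
        if (a2 == aa[i]) syn <- syn + 1L
      }
      if (viable > 0L) si <- si + syn / viable
    }
    s[i] <- si
  }
  n <- ifelse(sense, 3 - s, NA_real_)

  sd <- nd <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  for (i in which(sense)) {
    ci <- seq_to_vec(codons[i])
    for (j in which(sense)) {
      cj <- seq_to_vec(codons[j])
      diffpos <- which(ci != cj)
      k <- length(diffpos)
      if (k == 0L) {
        sd[i, j] <- nd[i, j] <- 0
        next
      }
      tot_s <- tot_n <- 0
      nvalid <- 0L
      for (ord in orderings(k)) {
        cur <- ci
        cur_aa <- aa[i]
        ps <- pn <- 0L
        ok <- TRUE
        for (step in diffpos[ord]) {
          cur[step] <- cj[step]
          a2 <- code[[vec_to_seq(cur)]]
          if (a2 == "*") { ok <- FALSE; break }
          if (a2 == cur_aa) ps <- ps + 1L else pn <- pn + 1L
          cur_aa <- a2
        }
        if (ok) {
          nvalid <- nvalid + 1L
          tot_s <- tot_s + ps
          tot_n <- tot_n + pn
        }
      }
      if (nvalid > 0L) {
        sd[i, j] <- tot_s / nvalid
        nd[i, j] <- tot_n / nvalid
      }
      ## nvalid == 0: every pathway passes a stop; left NA and masked
      ## pairwise by ks_pairwise()
    }
  }
  .tri_cache$ng <- list(codons = codons, aa = aa, sense = sense,
                        s = s, n = n, sd = sd, nd = nd)
  .tri_cache$ng
}

#' @noRd
check_sense_codon <- function(codon) {
  ng <- ng_tables()
  i <- match(codon, ng$codons)
  if (is.na(i) || !ng$sense[i])
    stopf("'%s' is not a sense codon", codon)
  i
}

## ---- NG86 primitives ----------------------------------------------------

#' Nei-Gojobori synonymous and nonsynonymous site counts for one codon
#'
#' For each of the three codon positions, the synonymous site fraction is
#' the number of synonymous one-step neighbours divided by the number of
#' viable (non-stop) one-step neighbours. The three fractions sum with
#' their complements to 3 sites per codon.
#'
#' @param codon A single sense codon, e.g. `"TTT"`.
#' @return Named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3
#' ng86_sites("TGG")  # s = 0
#' @export
ng86_sites <- function(codon) {
  i <- check_sense_codon(codon)
  ng <- ng_tables()
  c(s = ng$s[i], n = ng$n[i])
}

#' Nei-Gojobori synonymous and nonsynonymous differences between two codons
#'
#' Zero or one differing positions are classified directly; two or three
#' differences are averaged over all orderings of single-base steps,
#' excluding pathways that pass through a stop codon. `sd + nd` equals the
#' number of differing positions whenever at least one pathway is viable;
#' if every pathway passes a stop, both counts are `NA` (the pair is
#' masked by [ks_pairwise()]).
#'
#' @param codon1,codon2 Sense codons.
#' @return Named numeric vector `c(sd = , nd = )`.
#' @examples
#' ng86_differences("TTT", "TTC")  # one synonymous difference
#' @export
ng86_differences <- function(codon1, codon2) {
  i <- check_sense_codon(codon1)
  j <- check_sense_codon(codon2)
  ng <- ng_tables()
  c(sd = ng$sd[i, j], nd = ng$nd[i, j])
}

## ---- codon alignments ---------------------------------------------------

#' Pairwise codon alignment
#'
#' Wraps two equal-length, codon-wise aligned nucleotide sequences.
#' Codon columns containing a gap, an ambiguous base, or a stop codon in
#' either sequence are masked and excluded from all NG86 counts.
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length, a
#'   multiple of 3. Gaps as `-`.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2))
    stopf("aligned sequences differ in length (%d vs %d)",
          nchar(seq1), nchar(seq2))
  if (nchar(seq1) %% 3L != 0L)
    stopf("alignment length %d is not a multiple of 3", nchar(seq1))
  split_codons <- function(s) {
    starts <- seq(1L, nchar(s), by = 3L)
    substring(s, starts, starts + 2L)
  }
  c1 <- split_codons(toupper(seq1))
  c2 <- split_codons(toupper(seq2))
  ng <- ng_tables()
  bad <- function(cod) {
    i <- match(cod, ng$codons)
    is.na(i) | !ng$sense[i]   # gap, ambiguity or stop
  }
  mask <- bad(c1) | bad(c2)
  structure(list(codons1 = c1, codons2 = c2, mask = mask),
            class = "codon_alignment")
}

#' Back-translate an aligned protein pair or set onto its coding sequences
#'
#' Expands each protein residue to its source codon and each protein gap
#' to a three-base gap, producing a codon-wise nucleotide alignment.
#' Every CDS must translate exactly to its ungapped protein row under the
#' standard genetic code (a terminal stop codon on the CDS is tolerated
#' and dropped); internal stops or translation mismatches are errors.
#'
#' @param protein_alignment Named character vector of aligned protein
#'   sequences (equal lengths, gaps as `-`).
#' @param cds_sequences Named character vector of unaligned coding
#'   sequences; names must match `protein_alignment`.
#' @return A list with a codon matrix (`rows` x alignment columns), the
#'   aligned nucleotide strings, and a logical `mask` of columns
#'   containing any gap or ambiguous base.
#' @export
backtranslate <- function(protein_alignment, cds_sequences) {
  if (is.null(names(protein_alignment)) ||
      !all(names(protein_alignment) %in% names(cds_sequences)))
    stopf("protein and CDS names must match")
  lens <- nchar(protein_alignment)
  if (length(unique(lens)) != 1L)
    stopf("protein rows are not aligned to equal length")
  ncol_aln <- lens[[1L]]
  code <- genetic_code()
  rows <- names(protein_alignment)
  codmat <- matrix("---", nrow = length(rows), ncol = ncol_aln,
                   dimnames = list(rows, NULL))
  for (r in rows) {
    prot <- seq_to_vec(toupper(protein_alignment[[r]]))
    cds <- toupper(cds_sequences[[r]])
    if (nchar(cds) %% 3L != 0L)
      stopf("CDS '%s' length %d is not a multiple of 3", r, nchar(cds))
    starts <- seq(1L, nchar(cds), by = 3L)
    codons <- substring(cds, starts, starts + 2L)
    aa <- code[codons]
    ## tolerate one terminal stop codon on the CDS
    if (length(aa) > 0 && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(is.na(aa)))
      stopf("CDS '%s' contains an untranslatable codon at codon %d",
            r, which(is.na(aa))[1L])
    if (any(aa == "*"))
      stopf("CDS '%s' contains an internal stop at codon %d",
            r, which(aa == "*")[1L])
    ungapped <- prot[prot != "-"]
    if (length(aa) != length(ungapped))
      stopf("CDS '%s' translates to %d residues but protein has %d",
            r, length(aa), length(ungapped))
    mism <- which(unname(aa) != ungapped)
    if (length(mism) > 0)
      stopf("CDS '%s' translation mismatch at residue %d ('%s' vs '%s')",
            r, mism[1L], aa[mism[1L]], ungapped[mism[1L]])
    codmat[r, prot != "-"] <- codons
  }
  has_gap <- apply(codmat, 2L, function(col) any(col == "---"))
  has_amb <- apply(codmat, 2L, function(col)
    any(!grepl("^[ACGT]{3}$", col) & col != "---"))
  structure(list(
    codons = codmat,
    sequences = apply(codmat, 1L, paste, collapse = ""),
    mask = has_gap | has_amb
  ), class = "codon_msa")
}

#' Extract a pairwise codon alignment from a back-translated set
#'
#' @param msa A `codon_msa` from [backtranslate()].
#' @param name1,name2 Row names to compare.
#' @return A [codon_alignment()] with the set-wide gap/ambiguity mask
#'   combined with the pairwise stop/gap mask.
#' @export
pair_alignment <- function(msa, name1, name2) {
  aln <- codon_alignment(msa$sequences[[name1]], msa$sequences[[name2]])
  aln$mask <- aln$mask | msa$mask
  aln
}

## ---- Ks -----------------------------------------------------------------

#' Pairwise Ks by the Nei-Gojobori method with Jukes-Cantor correction
#'
#' Sums per-codon synonymous/nonsynonymous site counts (averaged between
#' the two sequences) and pathway-averaged difference counts over all
#' unmasked codon columns, then corrects the synonymous difference
#' proportion `ps = Sd/S` for multiple hits:
#' `Ks = -(3/4) log(1 - (4/3) ps)`.
#'
#' @param alignment A [codon_alignment()].
#' @return An object of class `ks_result`: a list with `S`, `N`, `Sd`,
#'   `Nd`, `ps`, `pn`, `Ks` and the number of compared codons.
#' @export
ks_pairwise <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  ng <- ng_tables()
  keep <- !alignment$mask
  if (!any(keep)) stopf("no unmasked codons to compare")
  i <- match(alignment$codons1[keep], ng$codons)
  j <- match(alignment$codons2[keep], ng$codons)
  sd_vec <- ng$sd[cbind(i, j)]
  invalid <- is.na(sd_vec)
  if (any(invalid)) {
    msgf("masking %d codon pair(s) whose substitution pathways all pass through stops",
         sum(invalid))
    i <- i[!invalid]; j <- j[!invalid]
    sd_vec <- sd_vec[!invalid]
  }
  if (length(i) == 0L) stopf("no comparable codons left after masking")
  S <- (sum(ng$s[i]) + sum(ng$s[j])) / 2
  N <- (sum(ng$n[i]) + sum(ng$n[j])) / 2
  Sd <- sum(sd_vec)
  Nd <- sum(ng$nd[cbind(i, j)])
  if (S <= 0) stopf("zero synonymous sites")
  ps <- Sd / S
  pn <- Nd / N
  if (ps >= 0.75)
    stopf("synonymous difference proportion %.3f >= 3/4: saturated, Ks undefined", ps)
  Ks <- -0.75 * log(1 - ps * 4 / 3)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, n_codons = length(i)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("NG86 pairwise comparison over %d codons\n", x$n_codons))
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  ps = %.5f  Ks = %.5f\n", x$ps, x$Ks))
  invisible(x)
}

#' Convert a mean Ks to a divergence time under a strict molecular clock
#'
#' `T = Ks / (2 mu)`, with the factor 2 accounting for the two diverging
#' branches, expressed in millions of years and rounded half-up.
#'
#' @param mean_ks Mean synonymous substitutions per synonymous site
#'   (vectorized).
#' @param mu Substitution rate per site per year (default `6.5e-9`).
#' @param digits Decimals kept on the Mya scale (default 2).
#' @return Divergence time(s) in Mya.
#' @examples
#' divergence_time(0.0109)  # 0.84 Mya
#' @export
divergence_time <- function(mean_ks, mu = 6.5e-9, digits = 2) {
  if (any(mean_ks < 0)) stopf("mean_ks must be non-negative")
  if (mu <= 0) stopf("mu must be positive")
  round_half_up(mean_ks / (2 * mu) / 1e6, digits)
}

#' Mean Ks per group-pair label, pooled and per region
#'
#' @param ks Numeric vector of pairwise Ks values (or a list of
#'   `ks_result` objects).
#' @param labels Group-pair label per value (e.g. `"A-B"`).
#' @param region Optional region label per value (e.g. gene region name);
#'   when given, per-region means are reported alongside the pooled mean
#'   over all gene pairs.
#' @return A data frame with columns `label`, `region` (`"pooled"` plus
#'   any regions), `n` and `mean_ks`.
#' @export
group_mean_ks <- function(ks, labels, region = NULL) {
  if (is.list(ks)) ks <- vapply(ks, function(x) x$Ks, numeric(1))
  if (length(ks) != length(labels)) stopf("ks and labels lengths differ")
  if (length(ks) == 0L) stopf("no Ks values supplied")
  if (any(is.na(ks))) stopf("NA Ks values not allowed")
  agg <- function(k, l, reg) {
    sp <- split(k, l)
    data.frame(label = names(sp), region = reg,
               n = vapply(sp, length, integer(1)),
               mean_ks = vapply(sp, mean, numeric(1)),
               row.names = NULL)
  }
  out <- agg(ks, labels, "pooled")
  if (!is.null(region)) {
    for (r in unique(region)) {
      sel <- region == r
      out <- rbind(out, agg(ks[sel], labels[sel], r))
    }
  }
  out
}
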