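## Alignment-free phylogeny of haplotype segments: 30-mer profiles with
## homopolymer filtering, pairwise symmetric-difference distances, and a
## neighbour-joining tree written as Newick.

#' Build the k-mer profile of a sequence
#'
#' The profile is the set of distinct k-length substrings; windows
#' containing `N` are skipped, and homopolymeric k-mers (a single
#' repeated base) are discarded when `drop_homopolymers` is on.
#'
#' @param seq Nucleotide string over `A/C/G/T/N`.
#' @param k k-mer length (default 30).
#' @param drop_homopolymers Drop single-base-repeat k-mers (default TRUE).
#' @param canonical Fold each k-mer with its reverse complement
#'   (lexicographic minimum) for unoriented input (default FALSE:
#'   haplotype segments are co-oriented).
#' @param id Optional source label.
#' @return An object of class `kmer_profile`.
#' @export
kmer_profile <- function(seq, k = 30L, drop_homopolymers = TRUE,
                         canonical = FALSE, id = NULL) {
  if (k < 1L) stopf("k must be >= 1")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (k > L) {
    msgf("k = %d exceeds sequence length %d; empty profile", k, L)
    kmers <- character(0)
  } else {
    kmers <- substring(seq, 1:(L - k + 1L), k:L)
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    kmers <- unique(kmers)
    if (drop_homopolymers && length(kmers) > 0) {
      homo <- kmers == strrep(substr(kmers, 1L, 1L), k)
      kmers <- kmers[!homo]
    }
    if (canonical && length(kmers) > 0)
      kmers <- unique(pmin(kmers, revcomp(kmers)))
  }
  structure(list(kmers = kmers, k = as.integer(k), id = id, length = L),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("k-mer profile%s: %d distinct %d-mers from %d bp\n",
              if (is.null(x$id)) "" else paste0(" of ", x$id),
              length(x$kmers), x$k, x$length))
  invisible(x)
}

#' Number of k-mers differing between two profiles
#'
#' The symmetric-difference cardinality of the two k-mer sets; with
#' `normalize = TRUE`, divided by the summed profile sizes.
#'
#' @param p,q [kmer_profile()] objects with equal `k`.
#' @param normalize Return `|p xor q| / (|p| + |q|)` instead of the raw
#'   count (default FALSE).
#' @return A single non-negative number.
#' @export
kmer_distance <- function(p, q, normalize = FALSE) {
  stopifnot(inherits(p, "kmer_profile"), inherits(q, "kmer_profile"))
  if (p$k != q$k) stopf("profiles built with different k (%d vs %d)", p$k, q$k)
  d <- length(setdiff(p$kmers, q$kmers)) + length(setdiff(q$kmers, p$kmers))
  if (normalize) {
    tot <- length(p$kmers) + length(q$kmers)
    if (tot == 0L) return(0)
    d <- d / tot
  }
  d
}

#' Pairwise k-mer distance matrix over a set of sequences
#'
#' @param seqs Named character vector (or named list) of sequences.
#' @inheritParams kmer_profile
#' @inheritParams kmer_distance
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k = 30L, drop_homopolymers = TRUE,
                                 canonical = FALSE, normalize = FALSE) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  profs <- lapply(names(seqs), function(nm)
    kmer_profile(seqs[[nm]], k = k, drop_homopolymers = drop_homopolymers,
                 canonical = canonical, id = nm))
  n <- length(profs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- kmer_distance(profs[[i]], profs[[j]],
                                        normalize = normalize)
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (Saitou-Nei selection criterion with
#' Studier-Keppler updates, as implemented in \pkg{ape}); negative
#' branch lengths are clamped to zero and the clamped total recorded in
#' the `"negative_length_clamped"` attribute.
#'
#' @param d Symmetric numeric matrix (zero diagonal) over >= 3 taxa.
#' @param tol Asymmetry tolerance (default 1e-8).
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stopf("at least 3 taxa required")
  if (max(abs(d - t(d))) > tol) stopf("distance matrix is not symmetric")
  tree <- ape::nj(d)
  neg <- tree$edge.length < 0
  deficit <- 0
  if (any(neg)) {
    deficit <- -sum(tree$edge.length[neg])
    msgf("clamped %d negative branch length(s) (total %.4g) to zero",
         sum(neg), deficit)
    tree$edge.length[neg] <- 0
  }
  attr(tree, "negative_length_clamped") <- deficit
  tree
}

#' Write a tree in Newick format
#'
#' Labels containing whitespace or Newick metacharacters are quoted.
#'
#' @param tree An \pkg{ape} `phylo` tree.
#' @param path Output file.
#' @return Invisibly, the Newick string.
#' @export
write_newick <- function(tree, path) {
  ## ape mangles labels containing whitespace/metacharacters; swap them
  ## for safe placeholders and substitute the quoted originals back in
  needs_quote <- grepl("[\\s():,;\\[\\]']", tree$tip.label, perl = TRUE)
  originals <- tree$tip.label[needs_quote]
  placeholders <- sprintf("xTRIQUOTEx%d", seq_along(originals))
  tree$tip.label[needs_quote] <- placeholders
  nwk <- ape::write.tree(tree)
  for (i in seq_along(originals))
    nwk <- sub(placeholders[i],
               paste0("'", gsub("'", "''", originals[i]), "'"),
               nwk, fixed = TRUE)
  writeLines(nwk, path)
  invisible(nwk)
}
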