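## SNP dissimilarity, principal-coordinates ordination, and flagging of
## accessions lying between the two germplasm pools (putative hybrids,
## candidates for exclusion from the pool representatives).

#' Pairwise SNP dissimilarity between accessions
#'
#' `d(i, j)` is the proportion of mismatching presence/absence calls
#' over the sites where both accessions have a non-missing call; pairs
#' sharing fewer than `min_shared` sites get an `NA` dissimilarity and
#' are flagged.
#'
#' @param gmat A `genotype_matrix` (1/0/NA).
#' @param min_shared Minimum co-typed sites per pair (default 1).
#' @return An object of class `dissimilarity_matrix`: the symmetric
#'   dissimilarity matrix `d` (values in `[0, 1]`, zero diagonal), the
#'   per-pair compared-site counts `shared`, and the flagged pairs.
#' @export
snp_dissimilarity <- function(gmat, min_shared = 1L) {
  if (ncol(gmat) < 2L) stopf("at least 2 accessions required")
  g <- unclass(gmat)
  typed <- !is.na(g)
  x <- g
  x[!typed] <- 0L
  storage.mode(x) <- "numeric"
  storage.mode(typed) <- "numeric"
  shared <- crossprod(typed)
  mism <- crossprod(x, typed) + crossprod(typed, x) - 2 * crossprod(x)
  d <- ifelse(shared > 0, mism / shared, NA_real_)
  diag(d) <- 0
  low <- which(shared < min_shared & upper.tri(shared), arr.ind = TRUE)
  flagged <- if (nrow(low) > 0)
    data.frame(acc1 = colnames(g)[low[, 1L]], acc2 = colnames(g)[low[, 2L]],
               shared = shared[low])
  else data.frame(acc1 = character(0), acc2 = character(0), shared = integer(0))
  if (nrow(flagged) > 0)
    msgf("%d pair(s) share fewer than %d typed sites", nrow(flagged), min_shared)
  structure(list(d = d, shared = shared, flagged_pairs = flagged),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("SNP dissimilarity over %d accessions (mean d = %.4f)\n",
              ncol(x$d), mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Principal-coordinates ordination of a dissimilarity matrix
#'
#' Classical metric multidimensional scaling: double-centred Gower
#' matrix, eigendecomposition, coordinates scaled by the square root of
#' each positive eigenvalue. Axes with negative eigenvalues are dropped
#' and their total magnitude reported. Missing dissimilarities are
#' imputed by the mean of the corresponding row and column means.
#'
#' @param diss A [snp_dissimilarity()] result or a symmetric matrix.
#' @param m Number of axes requested (default 2; truncated with a
#'   warning if fewer positive-eigenvalue axes exist).
#' @return An object of class `snp_ordination`: centred coordinates,
#'   eigenvalues, per-axis proportion of positive inertia, and the
#'   magnitude of dropped negative eigenvalues.
#' @export
pcoa_ordination <- function(diss, m = 2L) {
  d <- if (inherits(diss, "dissimilarity_matrix")) diss$d else as.matrix(diss)
  if (any(is.na(d))) {
    msgf("imputing %d missing dissimilarities by row/column means",
         sum(is.na(d)) / 2)
    rm_ <- rowMeans(d, na.rm = TRUE)
    for (idx in which(is.na(d)))
      d[idx] <- (rm_[(idx - 1L) %% nrow(d) + 1L] +
                   rm_[(idx - 1L) %/% nrow(d) + 1L]) / 2
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  n <- nrow(d)
  kmax <- n - 1L
  ## negative eigenvalues are expected for non-Euclidean dissimilarities
  ## and handled below; silence cmdscale's note about them
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = kmax, eig = TRUE))
  eig <- cs$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (m > npos) {
    warning(sprintf("only %d positive-eigenvalue axes available; truncating from %d",
                    npos, m), call. = FALSE)
    m <- npos
  }
  coords <- cs$points[, seq_len(m), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(m))
  pos_eig <- eig[seq_len(npos)]
  structure(list(coordinates = coords,
                 eigenvalues = pos_eig,
                 rel_inertia = pos_eig / sum(pos_eig),
                 negative_inertia = sum(abs(eig[eig < 0]))),
            class = "snp_ordination")
}

#' @export
print.snp_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d accessions, %d axes kept\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat(sprintf("  inertia: %s\n",
              paste(sprintf("axis%d %.1f%%", seq_len(ncol(x$coordinates)),
                            100 * x$rel_inertia[seq_len(ncol(x$coordinates))]),
                    collapse = ", ")))
  invisible(x)
}

#' Flag accessions lying between the two germplasm pools on axis 1
#'
#' Computes each pool's axis-1 coordinate envelope (optionally shrunk to
#' inner quantiles) and flags every accession whose axis-1 coordinate
#' falls strictly between the two envelopes. The output is a review
#' list: exclusion itself is an explicit user decision fed back to the
#' specificity analyses.
#'
#' @param ord A [pcoa_ordination()] result.
#' @param pools Named character vector accession -> pool (two labels;
#'   accessions without a pool label are still screened).
#' @param margin Quantile margin shrinking each envelope (default 0 =
#'   full range).
#' @return Data frame of flagged accessions with their axis-1
#'   coordinate and pool label (`NA` when unlabelled).
#' @export
flag_intermediates <- function(ord, pools, margin = 0) {
  stopifnot(inherits(ord, "snp_ordination"))
  if (length(pools) == 0L)
    return(data.frame(accession = character(0), axis1 = numeric(0),
                      pool = character(0)))
  ax1 <- ord$coordinates[, 1L]
  levels_p <- sort(unique(pools))
  if (length(levels_p) != 2L)
    stopf("exactly two pool labels required, got: %s",
          paste(levels_p, collapse = ", "))
  env <- lapply(levels_p, function(p) {
    v <- ax1[intersect(names(pools)[pools == p], names(ax1))]
    if (length(v) == 0L) stopf("pool '%s' has no ordinated accessions", p)
    stats::quantile(v, c(margin, 1 - margin), names = FALSE)
  })
  lo <- which.min(vapply(env, mean, numeric(1)))
  hi <- 3L - lo
  gap <- c(env[[lo]][2L], env[[hi]][1L])
  if (gap[1L] >= gap[2L]) {
    warning("pool envelopes overlap on axis 1; no accessions flagged",
            call. = FALSE)
    return(data.frame(accession = character(0), axis1 = numeric(0),
                      pool = character(0)))
  }
  between <- ax1 > gap[1L] & ax1 < gap[2L]
  data.frame(accession = names(ax1)[between],
             axis1 = unname(ax1[between]),
             pool = unname(pools[names(ax1)[between]]),
             row.names = NULL)
}
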