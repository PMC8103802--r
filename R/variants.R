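## Presence/absence genotype calling from per-site allele depths, and
## VCF ingestion.
##
## Calling rules for a polyploid accession at one site:
##   * missing when total depth < min_depth (default 30);
##   * variant present when the alternate allele is seen at least
##     min_alt_count times (default 2) AND at >= min_alt_freq frequency
##     (default 4 %);
##   * variant absent when no alternate read is seen, or a single
##     alternate read is seen at < max_err_freq frequency (default 1 %,
##     treated as sequencing error);
##   * anything else is ambiguous and coded missing.

#' Genotype-calling configuration
#'
#' @param min_depth Minimum total depth for a call (inclusive).
#' @param min_alt_count Minimum alternate reads for a presence call
#'   (inclusive).
#' @param min_alt_freq Minimum alternate frequency for a presence call
#'   (inclusive).
#' @param max_err_freq Frequency below which a single alternate read is
#'   treated as sequencing error (strict).
#' @param freq_denominator `"depth"` (default) computes frequencies
#'   against total site depth; `"refalt"` against ref + alt reads only.
#' @return An object of class `genotype_config`.
#' @export
genotype_config <- function(min_depth = 30L, min_alt_count = 2L,
                            min_alt_freq = 0.04, max_err_freq = 0.01,
                            freq_denominator = c("depth", "refalt")) {
  freq_denominator <- match.arg(freq_denominator)
  if (min_depth < 1L) stopf("min_depth must be >= 1")
  if (min_alt_count < 1L) stopf("min_alt_count must be >= 1")
  if (!(max_err_freq >= 0 && max_err_freq < min_alt_freq && min_alt_freq <= 1))
    stopf("need 0 <= max_err_freq < min_alt_freq <= 1")
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_count = as.integer(min_alt_count),
                 min_alt_freq = min_alt_freq, max_err_freq = max_err_freq,
                 freq_denominator = freq_denominator),
            class = "genotype_config")
}

## Vectorized core: 1 = present, 0 = absent, NA = missing.
#' @noRd
call_code <- function(alt_count, depth, cfg, ref_count = NULL) {
  n <- max(length(alt_count), length(depth))
  alt_count <- rep_len(alt_count, n)
  depth <- rep_len(depth, n)
  if (!is.null(ref_count)) ref_count <- rep_len(ref_count, n)
  denom <- if (cfg$freq_denominator == "refalt" && !is.null(ref_count))
    ref_count + alt_count else depth
  freq <- ifelse(denom > 0, alt_count / denom, 0)
  out <- rep(NA_integer_, length(alt_count))
  ok <- depth >= cfg$min_depth
  present <- ok & alt_count >= cfg$min_alt_count & freq >= cfg$min_alt_freq
  absent <- ok & !present &
    (alt_count == 0L | (alt_count == 1L & freq < cfg$max_err_freq))
  out[present] <- 1L
  out[absent] <- 0L
  out
}

#' Call one presence/absence/missing genotype from allele depths
#'
#' @param alt_count Alternate-allele read count(s).
#' @param depth Total read depth(s) at the site.
#' @param cfg A [genotype_config()].
#' @param ref_count Reference read count(s); only used when the
#'   configured frequency denominator is `"refalt"`.
#' @return Character vector over `"present"`, `"absent"`, `"missing"`.
#' @examples
#' call_genotype(2, 30)    # present (6.7 %)
#' call_genotype(1, 200)   # absent (0.5 %, error)
#' call_genotype(10, 29)   # missing (depth < 30)
#' @export
call_genotype <- function(alt_count, depth, cfg = genotype_config(),
                          ref_count = NULL) {
  if (any(alt_count < 0) || any(depth < 0) || any(alt_count > depth))
    stopf("need 0 <= alt_count <= depth")
  code <- call_code(alt_count, depth, cfg, ref_count)
  ifelse(is.na(code), "missing", ifelse(code == 1L, "present", "absent"))
}

#' Call a full genotype matrix from an allele-depth grid
#'
#' Applies [call_genotype()] element-wise to an `allele_depths` object
#' (from [simulate_allele_depths()] or [read_ad_vcf()]).
#'
#' @param depths An `allele_depths` object.
#' @param cfg A [genotype_config()].
#' @return An integer matrix (sites x accessions; 1 = present,
#'   0 = absent, NA = missing) of class `genotype_matrix`, with the site
#'   table attached as attribute `"sites"`.
#' @export
call_matrix <- function(depths, cfg = genotype_config()) {
  stopifnot(!is.null(depths$alt_count), !is.null(depths$depth))
  code <- call_code(as.vector(depths$alt_count), as.vector(depths$depth),
                    cfg, as.vector(depths$ref_count %||% NA))
  m <- matrix(code, nrow = nrow(depths$alt_count),
              dimnames = dimnames(depths$alt_count))
  structure(m, sites = depths$sites, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d sites x %d accessions\n", nrow(x), ncol(x)))
  tab <- table(factor(as.vector(x), levels = c(1L, 0L)), useNA = "always")
  cat(sprintf("  present %d, absent %d, missing %d\n",
              tab[[1L]], tab[[2L]], tab[[3L]]))
  invisible(x)
}

#' Read per-sample allele depths from a VCF
#'
#' Reads a VCF 4.x file with per-sample `AD` annotations, decomposes
#' multi-allelic records into one biallelic record per alternate allele,
#' and skips non-SNP records with a logged count. Total depth is taken
#' from `DP` when present, otherwise from the sum of allelic depths.
#'
#' @param path VCF file.
#' @param sample_ids Optional subset of samples to keep, in this order.
#' @return An `allele_depths` object (as [simulate_allele_depths()]).
#' @export
read_ad_vcf <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@gt) == 0 && nrow(fix) == 0 ||
      nrow(fix) == 0) {
    return(structure(list(
      sites = data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), key = character(0)),
      chrom = character(0), samples = sample_ids %||% character(0),
      depth = matrix(integer(0), 0, length(sample_ids %||% character(0))),
      ref_count = matrix(integer(0), 0, 0), alt_count = matrix(integer(0), 0, 0)),
      class = "allele_depths"))
  }
  fmt <- colnames(vcf@gt)[1L]
  samples <- colnames(vcf@gt)[-1L]
  if (!is.null(sample_ids)) {
    missing_s <- setdiff(sample_ids, samples)
    if (length(missing_s))
      stopf("samples not in VCF: %s", paste(missing_s, collapse = ", "))
    samples <- sample_ids
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stopf("VCF '%s' has no per-sample AD (allele depth) annotation", path)
  ad <- ad[, samples, drop = FALSE]
  has_dp <- any(grepl("\\bDP\\b", vcf@gt[, 1L]))
  dp <- if (has_dp) {
    d <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    d[, samples, drop = FALSE]
  } else NULL

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_full <- fix[, "ALT"]

  rows <- list()
  skipped <- 0L
  for (i in seq_along(pos)) {
    alts <- strsplit(alt_full[i], ",", fixed = TRUE)[[1L]]
    if (nchar(ref[i]) != 1L) { skipped <- skipped + 1L; next }
    adrow <- strsplit(ad[i, ], ",", fixed = TRUE)
    bad <- vapply(adrow, function(x) any(is.na(x)) || length(x) < 1L + length(alts),
                  logical(1))
    if (any(bad))
      stopf("record %s:%d lacks a complete AD field for sample '%s'",
            chrom[i], pos[i], samples[which(bad)[1L]])
    admat <- vapply(adrow, function(x) as.integer(x), integer(1L + length(alts)))
    admat <- matrix(admat, nrow = 1L + length(alts))
    depth_i <- if (!is.null(dp)) as.integer(dp[i, ]) else colSums(admat)
    for (k in seq_along(alts)) {
      a <- alts[k]
      if (nchar(a) != 1L || !(a %in% .BASES)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- list(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = a,
        refc = admat[1L, ], altc = admat[1L + k, ], depth = depth_i)
    }
  }
  if (skipped > 0L) msgf("skipped %d non-SNP allele(s)", skipped)
  nr <- length(rows)
  sites <- data.frame(
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"))
  chrom_out <- vapply(rows, `[[`, character(1), "chrom")
  sites$key <- if (nr > 0)
    site_key(chrom_out, sites$pos, sites$ref, sites$alt) else character(0)
  grab <- function(field) {
    m <- t(vapply(rows, `[[`, numeric(length(samples)), field))
    m <- matrix(as.integer(m), nrow = nr,
                dimnames = list(sites$key, samples))
    m
  }
  structure(list(sites = sites, chrom = chrom_out, samples = samples,
                 depth = grab("depth"), ref_count = grab("refc"),
                 alt_count = grab("altc")),
            class = "allele_depths")
}

#' Write / read a genotype matrix as TSV (1/0/NA coding)
#'
#' @param gmat A `genotype_matrix`.
#' @param path File path.
#' @return `read_genotype_matrix()` returns a `genotype_matrix`.
#' @export
write_genotype_matrix <- function(gmat, path) {
  df <- data.frame(site = rownames(gmat), as.data.frame(unclass(gmat)),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$site
  structure(m, class = c("genotype_matrix", "matrix"))
}

#' Subset reads sharing a k-mer with target sequences
#'
#' Retains exactly the reads that share at least one k-length substring
#' (on either strand of the read) with any target sequence, the read
#' subsetting used to restrict whole-genome reads to gene regions of
#' interest before mapping.
#'
#' @param reads Character vector of read sequences.
#' @param targets Character vector of target sequences.
#' @param k k-mer length (default 20).
#' @return The retained subset of `reads` (names preserved).
#' @export
filter_reads_by_kmer <- function(reads, targets, k = 20L) {
  if (k <= 0L) stopf("k must be positive")
  if (length(targets) == 0L || length(reads) == 0L)
    return(reads[integer(0)])
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }
  target_set <- unique(unlist(lapply(toupper(targets), kmers_of)))
  keep <- vapply(toupper(reads), function(r) {
    any(kmers_of(r) %in% target_set) ||
      any(kmers_of(revcomp(r)) %in% target_set)
  }, logical(1), USE.NAMES = FALSE)
  reads[keep]
}
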