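## Internal helpers shared across modules.

#' @noRd
site_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d_%s/%s", chrom, as.integer(pos), ref, alt)
}

## Round half away from zero at `digits` decimals. base::round() rounds
## half to even, which disagrees with conventionally printed tables.
#' @noRd
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @noRd
seq_to_vec <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' @noRd
vec_to_seq <- function(v) paste(v, collapse = "")

#' @noRd
revcomp <- function(s) {
  vapply(s, function(x) {
    vec_to_seq(rev(seq_to_vec(chartr("ACGTN", "TGCAN", x))))
  }, character(1), USE.NAMES = FALSE)
}

## FNV-1a 32-bit hash of a character scalar, as hex. Used for config
## provenance records; not cryptographic.
#' @noRd
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte; keep h as a double to avoid
    ## 32-bit signed overflow
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    ## 32-bit multiply by 16777619 without overflow, via split words
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## Recursively sort list names so the provenance hash is stable under
## key reordering in the config file.
#' @noRd
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else {
    x
  }
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
msgf <- function(fmt, ...) message(sprintf(fmt, ...))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
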