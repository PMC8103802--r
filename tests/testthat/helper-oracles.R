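## Independent brute-force oracles, deliberately written without reusing
## any package internals: explicit neighbour enumeration for NG86 sites,
## recursive pathway enumeration for NG86 differences, a scalar
## if/else chain for the genotype-coding rules, and naive set scans for
## k-mer profiles.

.oracle_bases <- c("A", "C", "G", "T")

oracle_aa <- function(codon) unname(as.character(Biostrings::GENETIC_CODE[codon]))

oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    viable <- 0L
    for (b in .oracle_bases) {
      if (b == substr(codon, pos, pos)) next
      nb <- codon
      substr(nb, pos, pos) <- b
      if (oracle_aa(nb) == "*") next
      viable <- viable + 1L
      if (oracle_aa(nb) == oracle_aa(codon)) syn <- syn + 1L
    }
    if (viable > 0L) s <- s + syn / viable
  }
  c(s = s, n = 3 - s)
}

## All stop-free substitution pathways from c1 to c2, as per-path
## (synonymous, nonsynonymous) step counts; averaged.
oracle_diffs <- function(c1, c2) {
  walk <- function(cur) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(dp) == 0L) return(list(c(0, 0)))
    out <- list()
    for (p in dp) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_aa(nxt) == "*") next
      step <- if (oracle_aa(nxt) == oracle_aa(cur)) c(1, 0) else c(0, 1)
      for (tail in walk(nxt)) out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths <- walk(c1)
  if (length(paths) == 0L) return(c(sd = NA_real_, nd = NA_real_))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

## Full NG86 + Jukes-Cantor Ks on two aligned gapless coding sequences.
oracle_ks <- function(s1, s2) {
  n_cod <- nchar(s1) / 3
  S <- Sd <- 0
  for (i in seq_len(n_cod)) {
    c1 <- substr(s1, 3 * i - 2, 3 * i)
    c2 <- substr(s2, 3 * i - 2, 3 * i)
    if (oracle_aa(c1) == "*" || oracle_aa(c2) == "*") next
    d <- oracle_diffs(c1, c2)
    if (any(is.na(d))) next
    S <- S + (oracle_sites(c1)[["s"]] + oracle_sites(c2)[["s"]]) / 2
    Sd <- Sd + d[["sd"]]
  }
  ps <- Sd / S
  list(S = S, Sd = Sd, ps = ps, Ks = -0.75 * log(1 - 4 / 3 * ps))
}

## The four stated genotype-coding rules, scalar and literal.
oracle_call <- function(alt, depth, min_depth = 30, min_alt = 2,
                        min_freq = 0.04, err_freq = 0.01) {
  if (depth < min_depth) return("missing")
  freq <- if (depth > 0) alt / depth else 0
  if (alt >= min_alt && freq >= min_freq) return("present")
  if (alt == 0) return("absent")
  if (alt == 1 && freq < err_freq) return("absent")
  "missing"
}

oracle_kmer_set <- function(seq, k, drop_homopolymers = TRUE) {
  out <- character(0)
  for (i in seq_len(nchar(seq) - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    if (grepl("N", km, fixed = TRUE)) next
    out <- c(out, km)
  }
  out <- unique(out)
  if (drop_homopolymers)
    out <- out[vapply(out, function(x)
      length(unique(strsplit(x, "")[[1]])) > 1L, logical(1))]
  out
}

oracle_kmer_dist <- function(s1, s2, k, drop_homopolymers = TRUE) {
  p <- oracle_kmer_set(s1, k, drop_homopolymers)
  q <- oracle_kmer_set(s2, k, drop_homopolymers)
  sum(!(p %in% q)) + sum(!(q %in% p))
}

random_dna <- function(n) paste(sample(.oracle_bases, n, replace = TRUE),
                                collapse = "")

random_sense_codons <- function(n) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}
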