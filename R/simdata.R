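## Founder-genome and polyploid-accession simulator.
##
## Three founder lineages (A, B, C) diverge on the fixed topology
## ((A,B),C) under a strict molecular clock with Jukes-Cantor
## substitutions (no indels). The monoploid reference is modelled as a
## distinct A-lineage individual: the A lineage splits again at
## t_split_ref into the reference haplotype and the panel A haplotype,
## mirroring a cultivar-derived reference that is close to, but not
## identical with, any sampled A haplotype. Accessions are haplotype
## multisets over the founders (e.g. a cultivar carrying 9 A, 2 B and
## 1 C copy); sequencing is emulated as negative-binomial site depths
## with binomial allele counts.

#' Simulation configuration for founder genomes and accession panels
#'
#' @param seed Integer seed; one seed yields bit-identical outputs.
#' @param genome_length Length in bases of the simulated genomic segment.
#' @param n_genes,gene_length Number and length (bases, multiple of 3) of
#'   simulated coding genes used for Ks dating.
#' @param mu Substitution rate per site per year.
#' @param t_split_ab,t_split_abc Split times in years for the (A,B)
#'   divergence and the ((A,B),C) divergence.
#' @param t_split_ref Pairwise divergence time (years) between the
#'   monoploid reference and the panel A haplotype, both descending from
#'   the A founder lineage.
#' @param pool_sizes Named integer vector: accessions per species class.
#' @param ploidy_spec Named list: per class, a named multiset over
#'   `c(A =, B =, C =)` giving haplotype copy numbers.
#' @param pool_labels Named character vector mapping each class to its
#'   germplasm pool (classes labelled `"hybrid"` are kept out of the
#'   two-pool origin analyses).
#' @param within_pool_theta Expected fraction of sites carrying a
#'   within-pool variant, per pool and lineage.
#' @param depth_mean,depth_dispersion Negative-binomial sequencing depth
#'   parameters (`depth_dispersion = 0` gives Poisson depths).
#' @param error_rate Per-read per-site sequencing error probability.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e5,
                       n_genes = 8L,
                       gene_length = 900L,
                       mu = 6.5e-9,
                       t_split_ab = 0.84e6,
                       t_split_abc = 1.29e6,
                       t_split_ref = 0.34e6,
                       pool_sizes = c(officinarum = 5L, robustum = 3L,
                                      spontaneum = 8L, cultivar = 1L),
                       ploidy_spec = list(
                         officinarum = c(A = 6L, B = 2L),
                         robustum = c(A = 6L, B = 2L),
                         spontaneum = c(C = 8L),
                         cultivar = c(A = 9L, B = 2L, C = 1L)),
                       pool_labels = c(officinarum = "offrob",
                                       robustum = "offrob",
                                       spontaneum = "spont",
                                       cultivar = "hybrid"),
                       within_pool_theta = 0.002,
                       depth_mean = 100,
                       depth_dispersion = 0.1,
                       error_rate = 1e-3) {
  if (genome_length <= 0) stopf("genome_length must be positive")
  if (gene_length %% 3L != 0L) stopf("gene_length must be a multiple of 3")
  if (t_split_ab < 0 || t_split_abc < t_split_ab)
    stopf("need t_split_abc >= t_split_ab >= 0")
  if (t_split_ref < 0 || t_split_ref / 2 > t_split_ab)
    stopf("need 0 <= t_split_ref/2 <= t_split_ab")
  for (r in c(mu = mu, within_pool_theta = within_pool_theta,
              error_rate = error_rate))
    if (r < 0 || r >= 1) stopf("rates must lie in [0, 1)")
  if (!setequal(names(pool_sizes), names(ploidy_spec)) ||
      !setequal(names(pool_sizes), names(pool_labels)))
    stopf("pool_sizes, ploidy_spec and pool_labels must name the same classes")
  for (cl in names(ploidy_spec)) {
    pl <- ploidy_spec[[cl]]
    if (length(pl) == 0L || sum(pl) == 0L)
      stopf("class '%s' has an empty haplotype multiset", cl)
    if (!all(names(pl) %in% c("A", "B", "C")))
      stopf("class '%s' names haplotypes outside A/B/C", cl)
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
                 mu = mu, t_split_ab = t_split_ab, t_split_abc = t_split_abc,
                 t_split_ref = t_split_ref, pool_sizes = pool_sizes,
                 ploidy_spec = ploidy_spec, pool_labels = pool_labels,
                 within_pool_theta = within_pool_theta, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, error_rate = error_rate),
            class = "sim_config")
}

## Apply Jukes-Cantor substitutions at the given positions (repeats are
## applied sequentially so multiple hits stay well-defined).
#' @noRd
mutate_positions <- function(v, positions) {
  while (length(positions)) {
    first <- !duplicated(positions)
    u <- positions[first]
    off <- sample.int(3L, length(u), replace = TRUE)
    v[u] <- .BASES[((match(v[u], .BASES) - 1L + off) %% 4L) + 1L]
    positions <- positions[!first]
  }
  v
}

#' @noRd
mutate_branch <- function(v, expected_subs) {
  n <- stats::rpois(1L, expected_subs)
  if (n == 0L) return(v)
  mutate_positions(v, sample.int(length(v), n, replace = TRUE))
}

## Codon-constrained evolution: substitutions never create a stop codon
## (a mutation whose target would be a stop is redirected uniformly among
## the viable alternatives), matching the viable-neighbour convention of
## the NG86 site counts.
#' @noRd
evolve_cds <- function(cds, expected_subs_per_site) {
  v <- seq_to_vec(cds)
  L <- length(v)
  code <- genetic_code()
  n <- stats::rpois(1L, expected_subs_per_site * L)
  if (n == 0L) return(cds)
  sites <- sample.int(L, n, replace = TRUE)
  for (s in sites) {
    cstart <- s - (s - 1L) %% 3L
    pos_in <- s - cstart + 1L
    cod <- v[cstart:(cstart + 2L)]
    cand <- setdiff(.BASES, v[s])
    ok <- vapply(cand, function(b) {
      cod2 <- cod
      cod2[pos_in] <- b
      code[[vec_to_seq(cod2)]] != "*"
    }, logical(1))
    viable <- cand[ok]
    if (length(viable))
      v[s] <- viable[sample.int(length(viable), 1L)]
  }
  vec_to_seq(v)
}

#' @noRd
random_sense_cds <- function(n_codons) {
  ng <- ng_tables()
  paste(sample(ng$codons[ng$sense], n_codons, replace = TRUE), collapse = "")
}

#' Simulate a pair of coding sequences diverged under the clock
#'
#' Draws a random ancestral coding sequence and evolves two descendants
#' independently for `t_split` years each, so the expected pairwise
#' divergence is `2 * t_split * mu` substitutions per site. Uses the
#' current RNG state.
#'
#' @param n_codons Number of codons.
#' @param t_split Split time in years.
#' @param mu Substitution rate per site per year.
#' @return A list with elements `seq1` and `seq2`.
#' @export
simulate_gene_pair <- function(n_codons, t_split, mu = 6.5e-9) {
  anc <- random_sense_cds(n_codons)
  list(seq1 = evolve_cds(anc, t_split * mu),
       seq2 = evolve_cds(anc, t_split * mu))
}

## Diff final lineage sequences against the reference: one registry row
## per (position, alternate allele), with the set of lineages carrying it.
#' @noRd
diff_registry <- function(ref, lineages) {
  diffs <- lapply(lineages, function(v) v != ref)
  pos_any <- which(Reduce(`|`, diffs))
  rows <- list()
  for (p in pos_any) {
    alts <- unique(vapply(names(lineages)[vapply(diffs, `[`, logical(1), p)],
                          function(l) lineages[[l]][p], character(1)))
    for (a in alts) {
      carrier <- vapply(lineages, function(v) v[p] == a, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, ref = ref[p], alt = a,
        in_A = carrier[["A"]], in_B = carrier[["B"]], in_C = carrier[["C"]])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      in_A = logical(0), in_B = logical(0), in_C = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$pos, out$alt), , drop = FALSE]
}

#' Simulate the three founder genomes and the monoploid reference
#'
#' Places Poisson substitutions on each branch of the fixed topology
#' ((A,B),C), with the reference as a second A-lineage descendant (see
#' [sim_config()]). Coding genes evolve on the same topology under the
#' stop-avoiding codon model. The truth registry lists, per (position,
#' alternate allele) relative to the reference, which lineages carry the
#' variant; re-diffing the emitted sequences reproduces it exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `founder_genomes`: sequences (reference,
#'   A, B, C), per-lineage gene CDS sets, the truth `registry` data
#'   frame, and the configuration.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  mu <- config$mu
  t_refhalf <- config$t_split_ref / 2
  branch_years <- c(ab_stem = config$t_split_abc - config$t_split_ab,
                    c_tip = config$t_split_abc,
                    b_tip = config$t_split_ab,
                    a_common = config$t_split_ab - t_refhalf,
                    a_tip = t_refhalf,
                    ref_tip = t_refhalf)
  expected <- branch_years * mu * L
  if (any(expected >= L))
    stopf("expected substitutions on branch '%s' (%.0f) reach the number of sites; saturation is not modelled",
          names(expected)[which.max(expected)], max(expected))
  anc <- sample(.BASES, L, replace = TRUE)
  ab_anc <- mutate_branch(anc, expected[["ab_stem"]])
  c_seq <- mutate_branch(anc, expected[["c_tip"]])
  b_seq <- mutate_branch(ab_anc, expected[["b_tip"]])
  a_anc <- mutate_branch(ab_anc, expected[["a_common"]])
  a_seq <- mutate_branch(a_anc, expected[["a_tip"]])
  ref_seq <- mutate_branch(a_anc, expected[["ref_tip"]])

  genes <- list(A = character(0), B = character(0), C = character(0))
  gene_rate <- function(years) years * mu
  if (config$n_genes > 0L) {
    for (g in seq_len(config$n_genes)) {
      anc_g <- random_sense_cds(config$gene_length %/% 3L)
      ab_g <- evolve_cds(anc_g, gene_rate(branch_years[["ab_stem"]]))
      genes$C[g] <- evolve_cds(anc_g, gene_rate(branch_years[["c_tip"]]))
      genes$B[g] <- evolve_cds(ab_g, gene_rate(branch_years[["b_tip"]]))
      genes$A[g] <- evolve_cds(ab_g, gene_rate(branch_years[["b_tip"]]))
    }
    for (l in names(genes)) names(genes[[l]]) <- sprintf("gene%02d", seq_len(config$n_genes))
  }

  registry <- diff_registry(ref_seq, list(A = a_seq, B = b_seq, C = c_seq))
  if (nrow(registry) > 0)
    registry$key <- site_key("chr1", registry$pos, registry$ref, registry$alt)
  else registry$key <- character(0)
  structure(list(
    sequences = list(reference = vec_to_seq(ref_seq), A = vec_to_seq(a_seq),
                     B = vec_to_seq(b_seq), C = vec_to_seq(c_seq)),
    genes = genes, registry = registry, config = config),
    class = "founder_genomes")
}

#' @export
print.founder_genomes <- function(x, ...) {
  cat(sprintf("Founder genomes A/B/C + reference (%d bp, %d genes)\n",
              x$config$genome_length, x$config$n_genes))
  cat(sprintf("  truth registry: %d alternate alleles at %d sites\n",
              nrow(x$registry), length(unique(x$registry$pos))))
  invisible(x)
}

#' Simulate polyploid accessions as haplotype multisets over the founders
#'
#' Each accession of a class carries the haplotype copies of its
#' `ploidy_spec` multiset. Within-pool polymorphism is added as extra
#' variant sites private to one pool and lineage, carried by a random
#' subset of that pool's copies; variant positions are drawn from sites
#' not already segregating between founders so the founder truth registry
#' stays exact.
#'
#' @param founders A [simulate_founders()] result.
#' @param config The same [sim_config()].
#' @return An object of class `accession_set`: accession and copy tables,
#'   the full variant site table with truth columns, a copy-level
#'   presence matrix and an accession-level dosage matrix.
#' @export
simulate_accessions <- function(founders, config) {
  stopifnot(inherits(founders, "founder_genomes"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- config$genome_length

  classes <- names(config$pool_sizes)
  acc_rows <- list()
  copy_rows <- list()
  for (cl in classes) {
    n_acc <- config$pool_sizes[[cl]]
    if (n_acc == 0L) next
    pl <- config$ploidy_spec[[cl]]
    if (sum(pl) == 0L) stopf("class '%s' has an empty haplotype multiset", cl)
    for (i in seq_len(n_acc)) {
      id <- sprintf("%s_%02d", cl, i)
      acc_rows[[id]] <- data.frame(accession = id, class = cl,
                                   pool = unname(config$pool_labels[[cl]]),
                                   n_copies = sum(pl))
      for (lin in names(pl)) {
        for (j in seq_len(pl[[lin]])) {
          copy_rows[[length(copy_rows) + 1L]] <- data.frame(
            copy = sprintf("%s_%s%d", id, lin, j), accession = id, lineage = lin)
        }
      }
    }
  }
  accessions <- do.call(rbind, acc_rows)
  rownames(accessions) <- NULL
  copies <- do.call(rbind, copy_rows)

  ## founder variant sites
  sites <- founders$registry
  if (nrow(sites) > 0) {
    sites$origin <- "founder"
    sites$wp_pool <- NA_character_
    sites$wp_lineage <- NA_character_
  } else {
    sites$origin <- character(0); sites$wp_pool <- character(0)
    sites$wp_lineage <- character(0)
  }

  ## within-pool variants, private to (pool, lineage) copy subsets
  ref_vec <- seq_to_vec(founders$sequences$reference)
  used_pos <- sites$pos
  wp_rows <- list()
  wp_carriers <- list()
  if (config$within_pool_theta > 0) {
    for (pool in unique(accessions$pool)) {
      pool_copies <- copies[copies$accession %in%
                              accessions$accession[accessions$pool == pool], ]
      for (lin in sort(unique(pool_copies$lineage))) {
        lin_copies <- pool_copies$copy[pool_copies$lineage == lin]
        lin_vec <- seq_to_vec(founders$sequences[[lin]])
        n_var <- stats::rpois(1L, config$within_pool_theta * L)
        for (v in seq_len(n_var)) {
          repeat {
            p <- sample.int(L, 1L)
            if (!(p %in% used_pos)) break
          }
          used_pos <- c(used_pos, p)
          cand <- setdiff(.BASES, c(ref_vec[p], lin_vec[p]))
          alt <- cand[sample.int(length(cand), 1L)]
          carriers <- lin_copies[stats::runif(length(lin_copies)) < 0.5]
          if (length(carriers) == 0L)
            carriers <- lin_copies[sample.int(length(lin_copies), 1L)]
          wp_rows[[length(wp_rows) + 1L]] <- data.frame(
            pos = p, ref = ref_vec[p], alt = alt,
            in_A = FALSE, in_B = FALSE, in_C = FALSE,
            key = site_key("chr1", p, ref_vec[p], alt),
            origin = "within_pool", wp_pool = pool, wp_lineage = lin)
          wp_carriers[[length(wp_rows)]] <- carriers
        }
      }
    }
  }
  if (length(wp_rows) > 0) sites <- rbind(sites, do.call(rbind, wp_rows))
  ord <- order(sites$pos, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  ## copy-level presence of each alternate allele
  presence <- matrix(FALSE, nrow = nrow(sites), ncol = nrow(copies),
                     dimnames = list(sites$key, copies$copy))
  lin_of_copy <- copies$lineage
  for (lin in c("A", "B", "C")) {
    rows <- sites$origin == "founder" & sites[[paste0("in_", lin)]]
    if (any(rows)) presence[rows, lin_of_copy == lin] <- TRUE
  }
  if (length(wp_rows) > 0) {
    wp_keys <- vapply(wp_rows, function(r) r$key, character(1))
    for (i in seq_along(wp_rows))
      presence[wp_keys[i], wp_carriers[[i]]] <- TRUE
  }

  ## accession-level alternate-allele dosage
  ind <- outer(copies$accession, accessions$accession, `==`)
  storage.mode(ind) <- "numeric"
  dosage <- presence %*% ind
  colnames(dosage) <- accessions$accession

  structure(list(accessions = accessions, copies = copies, sites = sites,
                 presence = presence, dosage = dosage, config = config),
            class = "accession_set")
}

#' @export
print.accession_set <- function(x, ...) {
  cat(sprintf("Accession set: %d accessions (%s), %d variant sites\n",
              nrow(x$accessions),
              paste(sprintf("%s=%d", names(table(x$accessions$class)),
                            table(x$accessions$class)), collapse = ", "),
              nrow(x$sites)))
  invisible(x)
}

#' Simulate per-site, per-accession allele depths
#'
#' Total depth per (site, accession) is negative-binomial with mean
#' `depth_mean` (Poisson when `depth_dispersion` is 0); alternate-allele
#' reads are binomial with success probability equal to the alternate
#' haplotype dosage over total copies, perturbed by the per-read error
#' rate.
#'
#' @param accessions A [simulate_accessions()] result.
#' @param config The same [sim_config()].
#' @return An object of class `allele_depths`: site table, sample ids
#'   and integer matrices `depth`, `ref_count`, `alt_count`.
#' @export
simulate_allele_depths <- function(accessions, config) {
  stopifnot(inherits(accessions, "accession_set"), inherits(config, "sim_config"))
  if (config$depth_mean <= 0) stopf("depth_mean must be positive")
  set.seed(config$seed + 2L)
  ns <- nrow(accessions$sites)
  na <- nrow(accessions$accessions)
  n <- ns * na
  depth <- if (config$depth_dispersion <= 0) {
    stats::rpois(n, config$depth_mean)
  } else {
    stats::rnbinom(n, mu = config$depth_mean, size = 1 / config$depth_dispersion)
  }
  depth <- matrix(depth, nrow = ns, ncol = na)
  p <- sweep(accessions$dosage, 2L, accessions$accessions$n_copies, "/")
  e <- config$error_rate
  p_eff <- p * (1 - e) + (1 - p) * e
  alt <- matrix(stats::rbinom(n, as.vector(depth), as.vector(p_eff)),
                nrow = ns, ncol = na)
  dimnames(depth) <- dimnames(alt) <-
    list(accessions$sites$key, accessions$accessions$accession)
  structure(list(sites = accessions$sites[, c("pos", "ref", "alt", "key")],
                 chrom = "chr1",
                 samples = accessions$accessions$accession,
                 depth = depth, ref_count = depth - alt, alt_count = alt),
            class = "allele_depths")
}

#' Materialize the haplotype sequences carried by one accession
#'
#' @param founders,accessions Simulator outputs.
#' @param accession_id Accession whose copies to materialize.
#' @return Named character vector, one sequence per haplotype copy.
#' @export
haplotype_sequences <- function(founders, accessions, accession_id) {
  cps <- accessions$copies[accessions$copies$accession == accession_id, ]
  if (nrow(cps) == 0L) stopf("unknown accession '%s'", accession_id)
  out <- character(nrow(cps))
  names(out) <- cps$copy
  wp <- accessions$sites$origin == "within_pool"
  for (i in seq_len(nrow(cps))) {
    v <- seq_to_vec(founders$sequences[[cps$lineage[i]]])
    carried <- wp & accessions$presence[, cps$copy[i]]
    if (any(carried))
      v[accessions$sites$pos[carried]] <- accessions$sites$alt[carried]
    out[i] <- vec_to_seq(v)
  }
  out
}

#' Build a haplotype panel from one accession's copies
#'
#' Uses the copies of the chosen accession (by default the one carrying
#' the most distinct lineages, i.e. the cultivar in the default
#' configuration) as the BAC-like haplotype panel: per variant site, each
#' copy's presence call, full coverage, and its lineage as group label.
#'
#' @param accessions A [simulate_accessions()] result.
#' @param accession_id Panel accession (default: most lineages).
#' @return A [haplotype_panel()].
#' @export
build_panel <- function(accessions, accession_id = NULL) {
  if (is.null(accession_id)) {
    n_lin <- tapply(accessions$copies$lineage, accessions$copies$accession,
                    function(x) length(unique(x)))
    accession_id <- names(n_lin)[which.max(n_lin)]
  }
  cps <- accessions$copies[accessions$copies$accession == accession_id, ]
  if (nrow(cps) == 0L) stopf("unknown accession '%s'", accession_id)
  present <- accessions$presence[, cps$copy, drop = FALSE]
  covered <- matrix(TRUE, nrow = nrow(present), ncol = ncol(present),
                    dimnames = dimnames(present))
  haplotype_panel(present, covered, stats::setNames(cps$lineage, cps$copy))
}

#' Write a simulated study to disk as standard plain-text formats
#'
#' Emits the monoploid reference FASTA, a multi-sample VCF with per-sample
#' depth and allele-depth (`DP:AD`) fields, the haplotype-panel TSV, the
#' accession metadata TSV, the truth-registry TSV and per-lineage gene
#' CDS FASTA.
#'
#' @param founders,accessions,depths Simulator outputs.
#' @param outdir Output directory (created if needed).
#' @param panel_accession Accession used for the haplotype panel
#'   (default as in [build_panel()]).
#' @return Invisibly, a named list of file paths.
#' @export
write_fixture <- function(founders, accessions, depths, outdir,
                          panel_accession = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory '%s'", outdir)
  paths <- list(
    reference = file.path(outdir, "reference.fa"),
    vcf = file.path(outdir, "variants.vcf"),
    panel = file.path(outdir, "panel.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    registry = file.path(outdir, "registry.tsv"),
    genes = file.path(outdir, "genes.fa"))

  refset <- Biostrings::DNAStringSet(c(chr1 = founders$sequences$reference))
  Biostrings::writeXStringSet(refset, paths$reference)

  if (length(founders$genes$A) > 0) {
    all_genes <- unlist(lapply(names(founders$genes), function(l)
      stats::setNames(founders$genes[[l]],
                      paste0(names(founders$genes[[l]]), "_", l))))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(all_genes), paths$genes)
  }

  ## VCF (records sorted by position; multi-allelic sites emitted as
  ## successive biallelic records)
  sts <- depths$sites
  ord <- order(sts$pos, sts$alt)
  samples <- depths$samples
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", founders$config$genome_length),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(ord, function(i) {
    cells <- sprintf("%d:%d,%d", depths$depth[i, ], depths$ref_count[i, ],
                     depths$alt_count[i, ])
    paste(c("chr1", sts$pos[i], sts$key[i], sts$ref[i], sts$alt[i],
            ".", ".", ".", "DP:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), paths$vcf)

  panel <- build_panel(accessions, panel_accession)
  write_haplotype_panel(panel, paths$panel)

  meta <- accessions$accessions[, c("accession", "class", "pool")]
  names(meta)[2] <- "species"
  write_tsv(meta, paths$metadata)

  write_tsv(accessions$sites, paths$registry)
  invisible(paths)
}
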