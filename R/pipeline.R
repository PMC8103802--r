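## End-to-end orchestration: simulate -> genotype -> ordinate ->
## origin -> Ks dating -> k-mer tree, with a provenance record so one
## seed plus one config reproduces a run byte for byte.

#' Default run configuration, validated and normalized
#'
#' Accepts a YAML file path or a nested list; fills every stage's
#' defaults, rejects unknown keys, and reports all type/range
#' violations at once.
#'
#' @param config Path to a YAML file, a nested list of overrides, or
#'   `NULL` for the full default configuration.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  defaults <- list(
    seed = 1L,
    stages = list(simulate = TRUE, genotype = TRUE, ordinate = TRUE,
                  origin = TRUE, ks = TRUE, kmer_tree = TRUE),
    sim = list(),         # sim_config() overrides
    genotype = list(),    # genotype_config() overrides
    specificity = list(), # specificity_config() overrides
    dating = list(mu = 6.5e-9, digits = 2),
    kmer = list(k = 30L, drop_homopolymers = TRUE, normalize = FALSE),
    ordination = list(axes = 2L, margin = 0),
    exclude = character(0),
    panel_accession = NULL)
  errors <- character(0)
  bad_keys <- setdiff(names(config), names(defaults))
  if (length(bad_keys))
    errors <- c(errors, sprintf("unknown key(s): %s",
                                paste(bad_keys, collapse = ", ")))
  merged <- defaults
  for (nm in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "sim" && nm != "genotype" && nm != "specificity") {
      sub_bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      if (length(sub_bad))
        errors <- c(errors, sprintf("unknown key(s) under '%s': %s", nm,
                                    paste(sub_bad, collapse = ", ")))
      merged[[nm]] <- utils::modifyList(defaults[[nm]],
                                        config[[nm]][setdiff(names(config[[nm]]), sub_bad)])
    } else {
      merged[[nm]] <- config[[nm]]
    }
  }
  ## range checks, accumulated so the user sees all problems at once
  check <- function(expr, msg) if (!isTRUE(expr)) errors <<- c(errors, msg)
  check(is.numeric(merged$seed) && length(merged$seed) == 1L,
        "seed must be a single integer")
  check(merged$dating$mu > 0, "dating$mu must be positive")
  check(merged$dating$digits >= 0, "dating$digits must be >= 0")
  check(merged$kmer$k >= 1, "kmer$k must be >= 1")
  check(merged$ordination$axes >= 1, "ordination$axes must be >= 1")
  check(merged$ordination$margin >= 0 && merged$ordination$margin < 0.5,
        "ordination$margin must lie in [0, 0.5)")
  ## constructors validate their own blocks; collect their messages too
  for (blk in c("sim", "genotype", "specificity")) {
    ctor <- switch(blk, sim = sim_config, genotype = genotype_config,
                   specificity = specificity_config)
    args <- merged[[blk]]
    if (blk == "sim") args$seed <- merged$seed
    res <- tryCatch(do.call(ctor, args), error = function(e)
      conditionMessage(e))
    if (is.character(res)) errors <- c(errors, sprintf("%s: %s", blk, res))
    else merged[[blk]] <- res
  }
  if (length(errors))
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  structure(merged, class = "run_config")
}

#' @noRd
config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  json <- jsonlite::toJSON(canonicalize(plain), auto_unbox = TRUE,
                           digits = NA, null = "null")
  fnv1a(as.character(json))
}

#' Run the full origin-inference pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs
#' and a run manifest (seed, configuration hash, file list) under
#' `outdir`. A stage failure aborts the run naming the stage; outputs
#' of completed stages are retained. Re-running with the same seed and
#' configuration reproduces the outputs exactly.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param outdir Run directory (created if needed).
#' @return Invisibly, a list of class `pipeline_run` with each stage's
#'   in-memory results and the summary.
#' @export
run_pipeline <- function(config = NULL, outdir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create run directory '%s'", outdir)
  res <- list(config = cfg)
  counts <- list()
  stage <- function(name, enabled, fn) {
    if (!enabled) return(NULL)
    tryCatch(fn(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  res$simulate <- stage("simulate", cfg$stages$simulate, function() {
    founders <- simulate_founders(cfg$sim)
    accessions <- simulate_accessions(founders, cfg$sim)
    depths <- simulate_allele_depths(accessions, cfg$sim)
    paths <- write_fixture(founders, accessions, depths,
                           file.path(outdir, "fixture"),
                           panel_accession = cfg$panel_accession)
    counts$variant_sites <<- nrow(accessions$sites)
    list(founders = founders, accessions = accessions, depths = depths,
         paths = paths)
  })

  res$genotype <- stage("genotype", cfg$stages$genotype, function() {
    if (is.null(res$simulate)) stopf("needs the simulate stage")
    depths <- read_ad_vcf(res$simulate$paths$vcf)
    gmat <- call_matrix(depths, cfg$genotype)
    write_genotype_matrix(gmat, file.path(outdir, "genotypes.tsv"))
    counts$calls_present <<- sum(gmat == 1L, na.rm = TRUE)
    counts$calls_missing <<- sum(is.na(gmat))
    gmat
  })

  meta <- if (!is.null(res$simulate)) res$simulate$accessions$accessions else NULL
  pool_map <- function() {
    keep <- meta$pool %in% setdiff(unique(meta$pool), c("hybrid", NA)) &
      !(meta$accession %in% cfg$exclude)
    stats::setNames(meta$pool[keep], meta$accession[keep])
  }

  res$ordinate <- stage("ordinate", cfg$stages$ordinate, function() {
    if (is.null(res$genotype)) stopf("needs the genotype stage")
    diss <- snp_dissimilarity(res$genotype)
    ord <- pcoa_ordination(diss, m = cfg$ordination$axes)
    flagged <- flag_intermediates(ord, pool_map(), margin = cfg$ordination$margin)
    write_tsv(data.frame(accession = rownames(ord$coordinates),
                         ord$coordinates),
              file.path(outdir, "ordination_coordinates.tsv"))
    write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                         eigenvalue = ord$eigenvalues,
                         rel_inertia = ord$rel_inertia),
              file.path(outdir, "ordination_eigenvalues.tsv"))
    write_tsv(flagged, file.path(outdir, "flagged_intermediates.tsv"))
    list(dissimilarity = diss, ordination = ord, flagged = flagged)
  })

  res$origin <- stage("origin", cfg$stages$origin, function() {
    if (is.null(res$genotype)) stopf("needs the genotype stage")
    panel <- build_panel(res$simulate$accessions, cfg$panel_accession)
    pools <- pool_map()
    grp <- group_specific_snps(panel, cfg$specificity)
    grp_origin <- group_snp_origin(grp, res$genotype, pools, cfg$specificity)
    pool_snps <- pool_specific_snps(res$genotype, pools, cfg$specificity)
    pool_tab <- pool_snps_on_haplotypes(pool_snps, panel)
    verdict <- infer_origin(grp_origin$table, pool_tab,
                            cfg$specificity$max_exceptions, grp_origin$snps)
    write_tsv(grp_origin$snps, file.path(outdir, "group_specific_snps.tsv"))
    write_tsv(pool_snps[pool_snps$label != "uninformative", , drop = FALSE],
              file.path(outdir, "pool_specific_snps.tsv"))
    write_tsv(as.data.frame(cbind(group = rownames(grp_origin$table),
                                  unclass(grp_origin$table))),
              file.path(outdir, "origin_table_groups.tsv"))
    write_tsv(as.data.frame(cbind(pool = rownames(pool_tab),
                                  unclass(pool_tab))),
              file.path(outdir, "origin_table_pools.tsv"))
    write_tsv(as.data.frame(verdict), file.path(outdir, "origin_verdicts.tsv"))
    counts$group_specific <<- sum(grepl("^group_", grp$label))
    counts$pool_specific <<- sum(pool_snps$label != "uninformative")
    list(group_snps = grp_origin$snps, group_table = grp_origin$table,
         pool_snps = pool_snps, pool_table = pool_tab, verdict = verdict)
  })

  res$ks <- stage("ks", cfg$stages$ks, function() {
    founders <- res$simulate$founders
    if (length(founders$genes$A) == 0L) stopf("no simulated genes")
    pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    rows <- list()
    ks_vals <- numeric(0)
    labels <- character(0)
    for (pr in pairs) {
      for (g in names(founders$genes[[pr[1L]]])) {
        aln <- codon_alignment(founders$genes[[pr[1L]]][[g]],
                               founders$genes[[pr[2L]]][[g]])
        kr <- ks_pairwise(aln)
        lab <- paste(pr, collapse = "-")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, pair = lab, S = kr$S, N = kr$N, Sd = kr$Sd, Nd = kr$Nd,
          ps = kr$ps, Ks = kr$Ks)
        ks_vals <- c(ks_vals, kr$Ks)
        labels <- c(labels, lab)
      }
    }
    per_pair <- do.call(rbind, rows)
    means <- group_mean_ks(ks_vals, labels)
    means$mya <- divergence_time(means$mean_ks, cfg$dating$mu,
                                 cfg$dating$digits)
    write_tsv(per_pair, file.path(outdir, "ks_pairwise.tsv"))
    write_tsv(means, file.path(outdir, "ks_summary.tsv"))
    list(per_pair = per_pair, summary = means)
  })

  res$kmer_tree <- stage("kmer_tree", cfg$stages$kmer_tree, function() {
    acc <- res$simulate$accessions
    panel_id <- cfg$panel_accession
    if (is.null(panel_id)) {
      n_lin <- tapply(acc$copies$lineage, acc$copies$accession,
                      function(x) length(unique(x)))
      panel_id <- names(n_lin)[which.max(n_lin)]
    }
    seqs <- haplotype_sequences(res$simulate$founders, acc, panel_id)
    d <- kmer_distance_matrix(seqs, k = cfg$kmer$k,
                              drop_homopolymers = cfg$kmer$drop_homopolymers,
                              normalize = cfg$kmer$normalize)
    utils::write.table(d, file.path(outdir, "kmer_distances.tsv"),
                       sep = "\t", quote = FALSE)
    tree <- nj_tree(d)
    nwk <- write_newick(tree, file.path(outdir, "kmer_tree.nwk"))
    list(distances = d, tree = tree, newick = nwk)
  })

  ## summary + provenance manifest
  summary <- list(
    seed = cfg$seed,
    counts = counts,
    verdicts = if (!is.null(res$origin))
      stats::setNames(res$origin$verdict$verdict, res$origin$verdict$group),
    dating = if (!is.null(res$ks))
      res$ks$summary[res$ks$summary$region == "pooled",
                     c("label", "n", "mean_ks", "mya")],
    tree = if (!is.null(res$kmer_tree)) res$kmer_tree$newick,
    flagged = if (!is.null(res$ordinate)) res$ordinate$flagged$accession)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  manifest <- list(
    package = "triorigin",
    version = as.character(utils::packageVersion("triorigin")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages_run = names(which(unlist(cfg$stages))),
    files = sort(list.files(outdir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$summary <- summary
  res$manifest <- manifest
  class(res) <- "pipeline_run"
  invisible(res)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$config$seed,
              x$manifest$config_hash))
  cat(sprintf("  stages: %s\n", paste(x$manifest$stages_run, collapse = ", ")))
  if (!is.null(x$summary$verdicts)) {
    cat("  verdicts: ",
        paste(sprintf("%s -> %s", names(x$summary$verdicts),
                      x$summary$verdicts), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$summary$dating)) {
    for (i in seq_len(nrow(x$summary$dating)))
      cat(sprintf("  %s: mean Ks %.4f -> %.2f Mya\n",
                  x$summary$dating$label[i], x$summary$dating$mean_ks[i],
                  x$summary$dating$mya[i]))
  }
  invisible(x)
}
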