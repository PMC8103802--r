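## Diagnostic-SNP classification: variants specific to haplotype groups
## (A/B/C) or to germplasm pools, reciprocal cross-tabulation, and the
## per-group origin verdict.
##
## Two complementary analyses mirror each other. The first takes SNPs
## specific to one haplotype group of the sequenced panel and asks which
## germplasm pool carries them; the second takes SNPs specific to one
## pool and asks which haplotype groups carry them. Agreement between
## the two assigns each group a founding pool.

#' Haplotype panel
#'
#' Per-haplotype variant presence calls with group labels and per-site
#' coverage masks, at reference coordinates (the role played by BAC
#' haplotype sequences aligned to a monoploid reference).
#'
#' @param present Logical matrix, sites x haplotypes: variant present.
#' @param covered Logical matrix, same shape: haplotype covers the site.
#' @param groups Named character vector mapping haplotype id to group
#'   (`"A"`, `"B"` or `"C"`); every group must have at least one
#'   haplotype.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(present, covered, groups) {
  if (!identical(dim(present), dim(covered)))
    stopf("present and covered matrices differ in shape")
  if (is.null(colnames(present))) colnames(present) <- names(groups)
  if (!setequal(colnames(present), names(groups)))
    stopf("group labels must name every haplotype column")
  groups <- groups[colnames(present)]
  if (!all(groups %in% c("A", "B", "C")))
    stopf("group labels must be A, B or C")
  missing_g <- setdiff(c("A", "B", "C"), unique(groups))
  if (length(missing_g))
    stopf("group '%s' has zero haplotypes", missing_g[1L])
  if (any(present & !covered))
    stopf("variant_present implies covered; %d cells violate this",
          sum(present & !covered))
  structure(list(present = present, covered = covered, groups = groups),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d sites x %d haplotypes (%s)\n",
              nrow(x$present), ncol(x$present),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a haplotype panel as a long-format TSV
#'
#' @param panel A [haplotype_panel()].
#' @param path File path.
#' @export
write_haplotype_panel <- function(panel, path) {
  long <- expand.grid(site = rownames(panel$present),
                      haplotype = colnames(panel$present),
                      stringsAsFactors = FALSE)
  long$group <- unname(panel$groups[long$haplotype])
  long$covered <- as.integer(panel$covered[cbind(long$site, long$haplotype)])
  long$present <- as.integer(panel$present[cbind(long$site, long$haplotype)])
  write_tsv(long, path)
  invisible(path)
}

#' @rdname write_haplotype_panel
#' @export
read_haplotype_panel <- function(path) {
  long <- read_tsv(path, colClasses = c(site = "character"))
  sites <- unique(long$site)
  haps <- unique(long$haplotype)
  shape <- list(sites, haps)
  present <- covered <- matrix(FALSE, length(sites), length(haps),
                               dimnames = shape)
  present[cbind(long$site, long$haplotype)] <- long$present == 1L
  covered[cbind(long$site, long$haplotype)] <- long$covered == 1L
  groups <- stats::setNames(long$group[!duplicated(long$haplotype)],
                            long$haplotype[!duplicated(long$haplotype)])
  haplotype_panel(present, covered, groups)
}

#' Specificity configuration
#'
#' @param min_carriers Minimum carrier accessions for a pool-specific
#'   call (default 2).
#' @param min_pool_data Minimum accessions with data required in each
#'   pool (default 5; relax to 3 for sparsely covered regions).
#' @param min_group_coverage Minimum covered haplotypes required per
#'   group for a site to be informative (default 1).
#' @param max_exceptions Contradicting SNPs tolerated by the per-group
#'   verdict (default 1).
#' @return An object of class `specificity_config`.
#' @export
specificity_config <- function(min_carriers = 2L, min_pool_data = 5L,
                               min_group_coverage = 1L, max_exceptions = 1L) {
  if (min_carriers < 1L || min_pool_data < 1L || min_group_coverage < 1L)
    stopf("thresholds must be >= 1")
  structure(list(min_carriers = as.integer(min_carriers),
                 min_pool_data = as.integer(min_pool_data),
                 min_group_coverage = as.integer(min_group_coverage),
                 max_exceptions = as.integer(max_exceptions)),
            class = "specificity_config")
}

## Per-group covered / carrier counts for every site.
#' @noRd
panel_counts <- function(panel) {
  out <- list()
  for (g in c("A", "B", "C")) {
    cols <- names(panel$groups)[panel$groups == g]
    out[[paste0("covered_", g)]] <-
      rowSums(panel$covered[, cols, drop = FALSE])
    out[[paste0("carriers_", g)]] <-
      rowSums((panel$present & panel$covered)[, cols, drop = FALSE])
  }
  as.data.frame(out)
}

#' Classify SNPs specific to one haplotype group
#'
#' A site is specific to group X when (1) at least `min_group_coverage`
#' haplotypes of every group cover the site, and (2) the variant is
#' present in at least one covered haplotype of group X and absent from
#' every covered haplotype of the other two groups. Uncovered haplotypes
#' do not veto a call, but the per-group coverage minimum must hold.
#'
#' @param panel A [haplotype_panel()].
#' @param cfg A [specificity_config()].
#' @return A data frame of class `specific_snp_set`: per site, the label
#'   (`group_A`/`group_B`/`group_C`/`uninformative`), per-group carrier
#'   and coverage counts, and the carrier fraction within the labelled
#'   group.
#' @export
group_specific_snps <- function(panel, cfg = specificity_config()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$present) == 0L) stopf("empty panel")
  cnt <- panel_counts(panel)
  covered_ok <- cnt$covered_A >= cfg$min_group_coverage &
    cnt$covered_B >= cfg$min_group_coverage &
    cnt$covered_C >= cfg$min_group_coverage
  carr <- cbind(A = cnt$carriers_A, B = cnt$carriers_B, C = cnt$carriers_C)
  n_groups_carrying <- rowSums(carr > 0L)
  label <- rep("uninformative", nrow(carr))
  sole <- covered_ok & n_groups_carrying == 1L
  which_g <- c("A", "B", "C")[max.col(carr, ties.method = "first")]
  label[sole] <- paste0("group_", which_g[sole])
  carrier_fraction <- rep(NA_real_, nrow(carr))
  cov <- cbind(A = cnt$covered_A, B = cnt$covered_B, C = cnt$covered_C)
  carrier_fraction[sole] <-
    carr[cbind(which(sole), match(which_g[sole], c("A", "B", "C")))] /
    cov[cbind(which(sole), match(which_g[sole], c("A", "B", "C")))]
  out <- data.frame(site = rownames(panel$present), label = label,
                    cnt, carrier_fraction = carrier_fraction,
                    row.names = NULL)
  class(out) <- c("specific_snp_set", "data.frame")
  out
}

## Carrier / with-data accession counts per pool for the given sites.
#' @noRd
pool_counts <- function(gmat, sites, pools) {
  levels_p <- sort(unique(pools))
  if (length(levels_p) != 2L)
    stopf("exactly two germplasm pools required, got: %s",
          paste(levels_p, collapse = ", "))
  for (p in levels_p)
    if (sum(pools == p) == 0L) stopf("pool '%s' has zero representatives", p)
  idx <- match(sites, rownames(gmat))
  res <- list(pools = levels_p)
  for (p in levels_p) {
    accs <- intersect(names(pools)[pools == p], colnames(gmat))
    sub <- gmat[, accs, drop = FALSE]
    carr <- rowSums(sub == 1L, na.rm = TRUE)
    dat <- rowSums(!is.na(sub))
    res[[paste0("carriers_", p)]] <- ifelse(is.na(idx), 0L, carr[idx])
    res[[paste0("data_", p)]] <- ifelse(is.na(idx), 0L, dat[idx])
  }
  res
}

## Shared pool-specificity rule: returns per-site origin label among the
## two pool names, "ancestral", or "uninformative".
#' @noRd
pool_rule <- function(pc, cfg, allow_ancestral = TRUE) {
  p1 <- pc$pools[1L]; p2 <- pc$pools[2L]
  c1 <- pc[[paste0("carriers_", p1)]]
  c2 <- pc[[paste0("carriers_", p2)]]
  d1 <- pc[[paste0("data_", p1)]]
  d2 <- pc[[paste0("data_", p2)]]
  label <- rep("uninformative", length(c1))
  enough <- d1 >= cfg$min_pool_data & d2 >= cfg$min_pool_data
  label[enough & c1 >= cfg$min_carriers & c2 == 0L] <- p1
  label[enough & c2 >= cfg$min_carriers & c1 == 0L] <- p2
  if (allow_ancestral)
    label[enough & c1 >= cfg$min_carriers & c2 >= cfg$min_carriers] <- "ancestral"
  label
}

#' Assign a germplasm-pool origin to group-specific SNPs
#'
#' For each group-specific SNP, counts carrier accessions and accessions
#' with data in each pool. The SNP is assigned to a pool when carried by
#' at least `min_carriers` accessions of that pool and by none of the
#' other, provided at least `min_pool_data` accessions of both pools
#' have data; carried by both pools, it is classed ancestral (predating
#' the pools' separation); otherwise uninformative. Results are
#' aggregated into a group x pool cross-tabulation.
#'
#' @param group_snps A [group_specific_snps()] result.
#' @param gmat A `genotype_matrix` covering the sites.
#' @param pools Named character vector mapping accession to pool
#'   (exactly two pool labels; accessions to exclude, e.g. flagged
#'   hybrids, are simply left out).
#' @param cfg A [specificity_config()].
#' @return A list with `snps` (the input plus per-pool counts and an
#'   `origin` column) and `table` (class `origin_table`: groups x
#'   {pool1, pool2, both-pools, total}).
#' @export
group_snp_origin <- function(group_snps, gmat, pools,
                             cfg = specificity_config()) {
  stopifnot(inherits(group_snps, "specific_snp_set"))
  grp <- group_snps[grepl("^group_", group_snps$label), , drop = FALSE]
  pc <- pool_counts(gmat, grp$site, pools)
  grp$origin <- pool_rule(pc, cfg, allow_ancestral = TRUE)
  for (p in pc$pools) {
    grp[[paste0("carriers_", p)]] <- pc[[paste0("carriers_", p)]]
    grp[[paste0("data_", p)]] <- pc[[paste0("data_", p)]]
  }
  tab <- matrix(0L, nrow = 3L, ncol = 4L,
                dimnames = list(c("A", "B", "C"),
                                c(pc$pools, "both_pools", "total")))
  for (g in c("A", "B", "C")) {
    sel <- grp$label == paste0("group_", g)
    tab[g, pc$pools[1L]] <- sum(sel & grp$origin == pc$pools[1L])
    tab[g, pc$pools[2L]] <- sum(sel & grp$origin == pc$pools[2L])
    tab[g, "both_pools"] <- sum(sel & grp$origin == "ancestral")
  }
  tab[, "total"] <- as.integer(rowSums(tab[, 1:3, drop = FALSE]))
  tab <- structure(tab, class = c("origin_table", "matrix"),
                   kind = "group_by_pool",
                   uninformative = sum(grp$origin == "uninformative"))
  list(snps = grp, table = tab)
}

#' Classify SNPs specific to one germplasm pool
#'
#' Symmetric rule over the two pools: a SNP is pool-specific when
#' carried by at least `min_carriers` accessions of one pool and absent
#' from all accessions of the other, with data in at least
#' `min_pool_data` accessions of both pools.
#'
#' @inheritParams group_snp_origin
#' @return A data frame of class `specific_snp_set`: per site, the pool
#'   label (or `uninformative`) and per-pool carrier/data counts.
#' @export
pool_specific_snps <- function(gmat, pools, cfg = specificity_config()) {
  pc <- pool_counts(gmat, rownames(gmat), pools)
  label <- pool_rule(pc, cfg, allow_ancestral = FALSE)
  out <- data.frame(site = rownames(gmat), label = label, row.names = NULL)
  for (p in pc$pools) {
    out[[paste0("carriers_", p)]] <- pc[[paste0("carriers_", p)]]
    out[[paste0("data_", p)]] <- pc[[paste0("data_", p)]]
  }
  class(out) <- c("specific_snp_set", "data.frame")
  out
}

#' Cross-tabulate pool-specific SNPs over the haplotype groups
#'
#' For each pool-specific SNP, determines which haplotype-group
#' combination of the panel carries it (present in at least one covered
#' haplotype of the group) and tabulates pools x {A, B, A-and-B, C,
#' other}. SNPs carried by no covered haplotype are excluded from the
#' table and reported via the `"absent_from_panel"` attribute.
#'
#' @param pool_snps A [pool_specific_snps()] result.
#' @param panel A [haplotype_panel()].
#' @return A matrix of class `origin_table` (kind `pool_by_group`), with
#'   per-SNP group combinations attached as attribute `"combinations"`.
#' @export
pool_snps_on_haplotypes <- function(pool_snps, panel) {
  stopifnot(inherits(pool_snps, "specific_snp_set"),
            inherits(panel, "haplotype_panel"))
  pool_levels <- sort(setdiff(unique(pool_snps$label),
                              c("uninformative", "ancestral")))
  snp <- pool_snps[pool_snps$label %in% pool_levels, , drop = FALSE]
  cnt <- panel_counts(panel)
  idx <- match(snp$site, rownames(panel$present))
  combo <- character(nrow(snp))
  for (i in seq_len(nrow(snp))) {
    if (is.na(idx[i])) { combo[i] <- "absent"; next }
    carr <- c(A = cnt$carriers_A[idx[i]], B = cnt$carriers_B[idx[i]],
              C = cnt$carriers_C[idx[i]]) > 0L
    combo[i] <- if (!any(carr)) "absent"
    else if (identical(unname(carr), c(TRUE, FALSE, FALSE))) "A"
    else if (identical(unname(carr), c(FALSE, TRUE, FALSE))) "B"
    else if (identical(unname(carr), c(TRUE, TRUE, FALSE))) "A_and_B"
    else if (identical(unname(carr), c(FALSE, FALSE, TRUE))) "C"
    else "other"
  }
  n_absent <- sum(combo == "absent")
  if (n_absent > 0L)
    msgf("%d pool-specific SNP(s) carried by no covered haplotype; excluded from the table",
         n_absent)
  cols <- c("A", "B", "A_and_B", "C", "other")
  tab <- matrix(0L, nrow = length(pool_levels), ncol = length(cols) + 1L,
                dimnames = list(pool_levels, c(cols, "total")))
  for (p in pool_levels) for (cc in cols)
    tab[p, cc] <- sum(snp$label == p & combo == cc)
  tab[, "total"] <- as.integer(rowSums(tab[, cols, drop = FALSE]))
  structure(tab, class = c("origin_table", "matrix"),
            kind = "pool_by_group", absent_from_panel = n_absent,
            combinations = stats::setNames(combo, snp$site))
}

#' @export
print.origin_table <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(if (identical(kind, "group_by_pool"))
    "Group-specific SNPs by carrying germplasm pool\n"
    else "Pool-specific SNPs by carrying haplotype group\n")
  print(unclass(x)[, , drop = FALSE])
  u <- attr(x, "uninformative")
  if (!is.null(u) && u > 0) cat(sprintf("(+ %d uninformative)\n", u))
  a <- attr(x, "absent_from_panel")
  if (!is.null(a) && a > 0) cat(sprintf("(+ %d absent from panel)\n", a))
  invisible(x)
}

#' Per-group origin verdict from the two reciprocal analyses
#'
#' Each haplotype group is assigned the germplasm pool with the strictly
#' greater supporting SNP count in each informative analysis, tolerating
#' up to `max_exceptions` contradicting SNPs; the analyses must agree.
#' An analysis with zero supporting SNPs for a group is treated as
#' uninformative for that group; ties, conflicts between analyses, or
#' more than `max_exceptions` contradictions give `unresolved`.
#' In the pool-by-group analysis, SNPs carried by both A and B
#' haplotypes support groups A and B alike.
#'
#' @param group_table `origin_table` from [group_snp_origin()].
#' @param pool_table `origin_table` from [pool_snps_on_haplotypes()].
#' @param max_exceptions Contradicting SNPs tolerated (default 1).
#' @param group_snps Optional classified SNP data frame (the `snps`
#'   element of [group_snp_origin()]); when given, contradicting sites
#'   are listed in the `"exceptions"` attribute.
#' @return A data frame of class `origin_verdict`: per group, the
#'   verdict pool (or `"unresolved"`), supports per analysis and the
#'   exception count.
#' @export
infer_origin <- function(group_table, pool_table, max_exceptions = 1L,
                         group_snps = NULL) {
  pools <- colnames(group_table)[1:2]
  one_analysis <- function(s1, s2) {
    if (s1 + s2 == 0L) return(list(verdict = NA_character_, exceptions = 0L))
    if (s1 == s2) return(list(verdict = "unresolved", exceptions = NA_integer_))
    maj <- if (s1 > s2) pools[1L] else pools[2L]
    minority <- min(s1, s2)
    if (minority > max_exceptions)
      return(list(verdict = "unresolved", exceptions = minority))
    list(verdict = maj, exceptions = minority)
  }
  rows <- list()
  exceptions <- list()
  for (g in c("A", "B", "C")) {
    s1 <- stats::setNames(as.integer(group_table[g, pools]), pools)
    cols <- if (g %in% c("A", "B")) c(g, "A_and_B") else g
    s2 <- vapply(pools, function(p)
      if (p %in% rownames(pool_table))
        sum(pool_table[p, intersect(cols, colnames(pool_table))]) else 0L,
      numeric(1))
    a1 <- one_analysis(s1[[1L]], s1[[2L]])
    a2 <- one_analysis(s2[[1L]], s2[[2L]])
    verdicts <- stats::na.omit(c(a1$verdict, a2$verdict))
    verdict <- if (length(verdicts) == 0L) "unresolved"
    else if (length(unique(verdicts)) == 1L) verdicts[[1L]]
    else "unresolved"
    n_exc <- sum(c(a1$exceptions, a2$exceptions), na.rm = TRUE)
    rows[[g]] <- data.frame(
      group = g, verdict = verdict,
      group_analysis_support = paste(s1, collapse = "/"),
      pool_analysis_support = paste(s2, collapse = "/"),
      n_exceptions = if (verdict == "unresolved") NA_integer_
                     else as.integer(n_exc))
    if (!is.null(group_snps) && !(verdict %in% c("unresolved"))) {
      other <- setdiff(pools, verdict)
      exceptions[[g]] <- group_snps$site[
        group_snps$label == paste0("group_", g) &
          group_snps$origin == other]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("origin_verdict", "data.frame"),
            exceptions = exceptions)
}

#' @export
print.origin_verdict <- function(x, ...) {
  cat("Haplotype-group origin verdicts\n")
  print.data.frame(x)
  exc <- attr(x, "exceptions")
  for (g in names(exc)) if (length(exc[[g]]) > 0)
    cat(sprintf("  group %s exceptions: %s\n", g,
                paste(exc[[g]], collapse = ", ")))
  invisible(x)
}
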