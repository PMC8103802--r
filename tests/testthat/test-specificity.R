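test_that("group-specificity rules behave on a constructed 12-haplotype panel", {
  panel <- toy_panel()
  res <- group_specific_snps(panel)
  lab <- stats::setNames(res$label, res$site)
  expect_identical(lab[["s_groupA"]], "group_A")      # 3/9 A carriers
  expect_identical(lab[["s_shared_AB"]], "uninformative")
  expect_identical(lab[["s_C_uncovered"]], "uninformative") # C has no data
  expect_identical(lab[["s_groupC"]], "group_C")
  expect_identical(lab[["s_invariant"]], "uninformative")
  expect_equal(res$carrier_fraction[res$site == "s_groupA"], 3 / 9)
  ## a panel missing a whole group is rejected
  bad <- panel$present[, 1:11]
  expect_error(haplotype_panel(bad, panel$covered[, 1:11],
                               panel$groups[1:11]), "zero haplotypes")
})

test_that("pool assignment of group-specific SNPs follows carrier and data rules", {
  panel <- toy_panel()
  grp <- group_specific_snps(panel)
  accs <- c(paste0("off", 1:5), paste0("spo", 1:5))
  pools <- stats::setNames(rep(c("offrob", "spont"), each = 5), accs)
  ## rows: s_groupA carried by 2 offrob; s_shared_AB irrelevant;
  ## s_C_uncovered irrelevant; s_groupC carried by 4 spont;
  ## s_invariant irrelevant
  gmat <- toy_matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0,
                       rep(0, 10),
                       rep(0, 10),
                       0, 0, 0, 0, 0, 1, 1, 1, 1, 0,
                       rep(0, 10)),
                     rownames(panel$present), accs)
  res <- group_snp_origin(grp, gmat, pools)
  org <- stats::setNames(res$snps$origin, res$snps$site)
  expect_identical(org[["s_groupA"]], "offrob")
  expect_identical(org[["s_groupC"]], "spont")
  expect_identical(unname(res$table["A", "offrob"]), 1L)
  expect_identical(unname(res$table["C", "spont"]), 1L)
  ## ancestral: carriers in both pools
  gmat2 <- gmat
  gmat2["s_groupA", c("spo1", "spo2")] <- 1L
  res2 <- group_snp_origin(grp, gmat2, pools)
  expect_identical(res2$snps$origin[res2$snps$site == "s_groupA"], "ancestral")
  expect_identical(unname(res2$table["A", "both_pools"]), 1L)
  ## insufficient data in one pool -> uninformative
  gmat3 <- gmat
  gmat3["s_groupA", c("off3", "off4")] <- NA_integer_  # 3 offrob with data < 5
  res3 <- group_snp_origin(grp, gmat3, pools)
  expect_identical(res3$snps$origin[res3$snps$site == "s_groupA"],
                   "uninformative")
  ## ...unless the sparse-region relaxation lowers min_pool_data to 3
  res4 <- group_snp_origin(grp, gmat3, pools,
                           specificity_config(min_pool_data = 3))
  expect_identical(res4$snps$origin[res4$snps$site == "s_groupA"], "offrob")
})

test_that("pool-specificity rules require carriers in one pool and absence in the other", {
  accs <- c(paste0("off", 1:5), paste0("spo", 1:5))
  pools <- stats::setNames(rep(c("offrob", "spont"), each = 5), accs)
  gmat <- toy_matrix(c(1, 1, 0, 0, 0, rep(0, 5),   # 2 offrob carriers
                       1, 0, 0, 0, 0, rep(0, 5),   # 1 carrier: below minimum
                       1, 1, 0, 0, 0, 1, 0, 0, 0, 0), # carrier in other pool
                     c("s1", "s2", "s3"), accs)
  res <- pool_specific_snps(gmat, pools)
  expect_identical(res$label, c("offrob", "uninformative", "uninformative"))
  expect_error(pool_specific_snps(gmat, pools[1:5]), "two germplasm pools")
})

test_that("pool-specific SNPs map onto haplotype-group combinations", {
  panel <- toy_panel()
  snps <- data.frame(
    site = c("s_groupC", "s_shared_AB", "s_groupA", "s_unknown"),
    label = c("spont", "offrob", "offrob", "spont"))
  class(snps) <- c("specific_snp_set", "data.frame")
  expect_message(tab <- pool_snps_on_haplotypes(snps, panel),
                 "carried by no covered haplotype")
  expect_identical(unname(tab["spont", "C"]), 1L)
  expect_identical(unname(tab["offrob", "A_and_B"]), 1L)
  expect_identical(unname(tab["offrob", "A"]), 1L)
  expect_identical(attr(tab, "absent_from_panel"), 1L)
  ## additivity: totals are row sums of the category columns
  expect_equal(unname(tab[, "total"]),
               unname(rowSums(tab[, c("A", "B", "A_and_B", "C", "other")])))
})

test_that("verdicts follow majority support with bounded exceptions", {
  mk_group_tab <- function(a, b, c2) {
    tab <- cbind(offrob = c(a[1], b[1], c2[1]),
                 spont = c(a[2], b[2], c2[2]),
                 both_pools = c(a[3], b[3], c2[3]))
    tab <- cbind(tab, total = rowSums(tab))
    rownames(tab) <- c("A", "B", "C")
    structure(tab, class = c("origin_table", "matrix"), kind = "group_by_pool")
  }
  mk_pool_tab <- function(offrob, spont) {
    tab <- rbind(offrob = offrob, spont = spont)
    colnames(tab) <- c("A", "B", "A_and_B", "C", "other")
    tab <- cbind(tab, total = rowSums(tab))
    structure(tab, class = c("origin_table", "matrix"), kind = "pool_by_group")
  }
  ## counts shaped like the published cross-tabs: A 29/0, B 28/1 (one
  ## exception), C 0/27
  g <- mk_group_tab(c(29, 0, 44), c(28, 1, 19), c(0, 27, 40))
  p <- mk_pool_tab(c(29, 28, 4, 0, 0), c(0, 1, 0, 27, 0))
  v <- infer_origin(g, p, max_exceptions = 1)
  expect_identical(v$verdict, c("offrob", "offrob", "spont"))
  expect_identical(v$n_exceptions, c(0L, 2L, 0L))  # one per analysis for B
  ## zero support in both analyses is unresolved
  g0 <- mk_group_tab(c(0, 0, 0), c(28, 1, 19), c(0, 27, 40))
  p0 <- mk_pool_tab(c(0, 28, 0, 0, 0), c(0, 1, 0, 27, 0))
  expect_identical(infer_origin(g0, p0)$verdict[1], "unresolved")
  ## too many contradictions -> unresolved
  g2 <- mk_group_tab(c(29, 5, 0), c(28, 1, 19), c(0, 27, 40))
  expect_identical(infer_origin(g2, p)$verdict[1], "unresolved")
  ## ties -> unresolved
  g3 <- mk_group_tab(c(3, 3, 0), c(28, 1, 19), c(0, 27, 40))
  p3 <- mk_pool_tab(c(3, 28, 0, 0, 0), c(3, 1, 0, 27, 0))
  expect_identical(infer_origin(g3, p3)$verdict[1], "unresolved")
})

test_that("no SNP is specific to two groups or two pools, and totals add up", {
  fx <- clean_sim(6)
  grp <- group_specific_snps(fx$panel)
  expect_lte(max(table(grp$site)), 1L)
  res <- group_snp_origin(grp, fx$gmat, fx$pools)
  tab <- res$table
  expect_equal(unname(tab[, "total"]),
               unname(rowSums(tab[, 1:3, drop = FALSE])))
  pool_snps <- pool_specific_snps(fx$gmat, fx$pools)
  expect_lte(max(table(pool_snps$site)), 1L)
})

test_that("raising thresholds never increases the specific-SNP count", {
  fx <- clean_sim(7, genome_length = 1e4)
  count_pool <- function(cfg) {
    res <- pool_specific_snps(fx$gmat, fx$pools, cfg)
    sum(res$label != "uninformative")
  }
  n_base <- count_pool(specificity_config())
  expect_lte(count_pool(specificity_config(min_carriers = 4)), n_base)
  expect_lte(count_pool(specificity_config(min_pool_data = 8)), n_base)
})

test_that("clean simulations are recovered with perfect precision and recall", {
  fx <- clean_sim(1)
  truth <- truth_labels(fx$accessions$sites)
  grp <- group_specific_snps(fx$panel)
  called_grp <- stats::setNames(grp$label, grp$site)[truth$key]
  for (g in c("group_A", "group_B", "group_C")) {
    expect_identical(sum(called_grp == g & truth$group != g), 0L)  # precision
    expect_identical(sum(called_grp != g & truth$group == g), 0L)  # recall
  }
  pool_snps <- pool_specific_snps(fx$gmat, fx$pools)
  called_pool <- stats::setNames(pool_snps$label, pool_snps$site)[truth$key]
  for (p in c("offrob", "spont")) {
    expect_identical(sum(called_pool == p & truth$pool != p), 0L)
    expect_identical(sum(called_pool != p & truth$pool == p), 0L)
  }
  res <- group_snp_origin(grp, fx$gmat, fx$pools)
  tab3 <- pool_snps_on_haplotypes(pool_snps, fx$panel)
  v <- infer_origin(res$table, tab3)
  expect_identical(stats::setNames(v$verdict, v$group),
                   c(A = "offrob", B = "offrob", C = "spont"))
})
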