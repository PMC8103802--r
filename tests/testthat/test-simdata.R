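test_that("founder divergence matches the molecular clock expectation", {
  cfg <- sim_config(seed = 42, genome_length = 1e5, n_genes = 0)
  f <- simulate_founders(cfg)
  a <- strsplit(f$sequences$A, "")[[1]]
  b <- strsplit(f$sequences$B, "")[[1]]
  observed <- sum(a != b)
  expected <- 2 * cfg$t_split_ab * cfg$mu * cfg$genome_length  # 1092
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
  ## C is farther from A than B is, by construction of the topology
  cc <- strsplit(f$sequences$C, "")[[1]]
  expect_gt(sum(a != cc), observed)
})

test_that("zero split times give identical founders and an empty registry", {
  cfg <- sim_config(seed = 3, genome_length = 5000, n_genes = 0,
                    t_split_ab = 0, t_split_abc = 0, t_split_ref = 0)
  f <- simulate_founders(cfg)
  expect_identical(f$sequences$A, f$sequences$B)
  expect_identical(f$sequences$A, f$sequences$C)
  expect_identical(f$sequences$A, f$sequences$reference)
  expect_identical(nrow(f$registry), 0L)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, genome_length = 8000, n_genes = 2)
  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1, f2)
  a1 <- simulate_accessions(f1, cfg)
  a2 <- simulate_accessions(f2, cfg)
  expect_identical(a1, a2)
  d1 <- simulate_allele_depths(a1, cfg)
  d2 <- simulate_allele_depths(a2, cfg)
  expect_identical(d1, d2)
})

test_that("re-diffing emitted founder sequences reproduces the registry", {
  cfg <- sim_config(seed = 17, genome_length = 3e4, n_genes = 0)
  f <- simulate_founders(cfg)
  ref <- strsplit(f$sequences$reference, "")[[1]]
  lin <- lapply(f$sequences[c("A", "B", "C")], function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (p in which(lin$A != ref | lin$B != ref | lin$C != ref)) {
    for (alt in sort(unique(setdiff(c(lin$A[p], lin$B[p], lin$C[p]), ref[p])))) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, ref = ref[p], alt = alt,
        in_A = lin$A[p] == alt, in_B = lin$B[p] == alt, in_C = lin$C[p] == alt)
    }
  }
  rediff <- do.call(rbind, rows)
  expect_equal(f$registry[, names(rediff)], rediff, ignore_attr = TRUE)
})

test_that("simulation rejects degenerate configurations", {
  expect_error(sim_config(genome_length = 0), "genome_length")
  expect_error(sim_config(gene_length = 100), "multiple of 3")
  expect_error(sim_config(t_split_ab = 2e6, t_split_abc = 1e6), "t_split_abc")
  expect_error(sim_config(error_rate = 1.2), "rates")
  expect_error(sim_config(ploidy_spec = list(
    officinarum = c(A = 6L, B = 2L), robustum = c(A = 6L, B = 2L),
    spontaneum = integer(0), cultivar = c(A = 9L, B = 2L, C = 1L))),
    "empty haplotype multiset")
  ## saturation: expected substitutions reach the site count
  cfg <- sim_config(seed = 1, genome_length = 100, n_genes = 0,
                    mu = 0.9, t_split_ab = 1, t_split_abc = 2, t_split_ref = 0)
  expect_error(simulate_founders(cfg), "saturation")
  cfg2 <- sim_config(seed = 1, depth_mean = 0)
  f <- simulate_founders(sim_config(seed = 1, genome_length = 1000, n_genes = 0))
  a <- simulate_accessions(f, f$config)
  expect_error(simulate_allele_depths(a, cfg2), "depth_mean")
})

test_that("accession haplotype content follows the class multiset", {
  fx <- clean_sim(5)
  s <- fx$accessions$sites
  truth <- truth_labels(s)
  dosage <- fx$accessions$dosage
  spont <- fx$accessions$accessions$accession[
    fx$accessions$accessions$class == "spontaneum"]
  ## spontaneum {C:8} never carries an allele private to A or B
  ab_rows <- truth$group %in% c("group_A", "group_B")
  expect_true(all(dosage[ab_rows, spont] == 0))
  ## the cultivar {A:9,B:2,C:1} carries alleles of all three lineages
  cult <- fx$accessions$accessions$accession[
    fx$accessions$accessions$class == "cultivar"]
  for (g in c("group_A", "group_B", "group_C"))
    expect_gt(sum(dosage[truth$group == g, cult]), 0)
  ## theta = 0: accessions of one class are identical in content
  off <- fx$accessions$accessions$accession[
    fx$accessions$accessions$class == "officinarum"]
  expect_true(all(dosage[, off[1]] == dosage[, off[2]]))
})

test_that("allele counts are binomial in the haplotype dosage", {
  ## 1 of 12 copies at Poisson depth 120: alt ~ Binomial(depth, 1/12)
  n_draws <- 2000L
  fake <- structure(list(
    sites = data.frame(pos = seq_len(n_draws), ref = "A", alt = "C",
                       key = paste0("chr1:", seq_len(n_draws), "_A/C")),
    accessions = data.frame(accession = "x", n_copies = 12L),
    dosage = matrix(1, n_draws, 1, dimnames = list(NULL, "x"))),
    class = "accession_set")
  cfg <- sim_config(seed = 8, depth_mean = 120, depth_dispersion = 0,
                    error_rate = 0)
  d <- simulate_allele_depths(fake, cfg)
  expect_equal(mean(d$alt_count), 10, tolerance = 0.05)
  expect_equal(stats::var(as.numeric(d$alt_count)),
               120 * (1 / 12) * (11 / 12) + (1 / 12)^2 * 120,
               tolerance = 0.15)
  ## dosage 0 -> never an alt read; dosage = all copies -> all alt reads
  fake$dosage[] <- 0
  expect_true(all(simulate_allele_depths(fake, cfg)$alt_count == 0))
  fake$dosage[] <- 12
  d2 <- simulate_allele_depths(fake, cfg)
  expect_true(all(d2$alt_count == d2$depth))
})

test_that("fixture files round-trip and are well-formed", {
  fx <- clean_sim(2, genome_length = 5000)
  out <- file.path(tempdir(), "fix_roundtrip")
  paths <- write_fixture(fx$founders, fx$accessions, fx$depths, out)
  ## VCF round-trips the simulated allele depths exactly
  back <- read_ad_vcf(paths$vcf)
  ord <- order(fx$depths$sites$pos, fx$depths$sites$alt)
  expect_equal(unname(back$depth), unname(fx$depths$depth[ord, ]),
               ignore_attr = TRUE)
  expect_equal(unname(back$alt_count), unname(fx$depths$alt_count[ord, ]),
               ignore_attr = TRUE)
  ## well-formed: single-base ref/alt, ascending 1-based positions
  body <- readLines(paths$vcf)
  body <- body[!startsWith(body, "#")]
  fields <- do.call(rbind, strsplit(body, "\t"))
  expect_true(all(nchar(fields[, 4]) == 1 & nchar(fields[, 5]) == 1))
  pos <- as.integer(fields[, 2])
  expect_true(all(pos >= 1) && !is.unsorted(pos))
  ## truth registry row count equals the planted variant count
  reg <- read.table(paths$registry, sep = "\t", header = TRUE)
  expect_identical(nrow(reg), nrow(fx$accessions$sites))
  ## panel TSV round-trips
  panel2 <- read_haplotype_panel(paths$panel)
  expect_equal(sort(rownames(panel2$present)), sort(rownames(fx$panel$present)))
  common <- rownames(fx$panel$present)
  expect_identical(panel2$present[common, colnames(fx$panel$present)],
                   fx$panel$present[common, ])
})
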