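## Fixture builders shared across test files. All fixtures are generated
## in code under fixed seeds; nothing is read from disk except what the
## tests themselves write to tempdirs.

## A clean study: no sequencing error, no within-pool polymorphism, so
## every call is decided by haplotype dosage alone.
clean_sim <- function(seed, genome_length = 2e4, n_genes = 0L, ...) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_genes = n_genes, within_pool_theta = 0,
                    error_rate = 0, ...)
  founders <- simulate_founders(cfg)
  accessions <- simulate_accessions(founders, cfg)
  depths <- simulate_allele_depths(accessions, cfg)
  gmat <- call_matrix(depths)
  pools <- stats::setNames(accessions$accessions$pool,
                           accessions$accessions$accession)
  pools <- pools[pools %in% c("offrob", "spont")]
  list(cfg = cfg, founders = founders, accessions = accessions,
       depths = depths, gmat = gmat, panel = build_panel(accessions),
       pools = pools)
}

## Truth labels for founder-registry alleles, reference-relative:
## carriers {A} -> group_A/offrob, {B} -> group_B/offrob,
## {C} -> group_C/spont, {A,B} -> offrob only, anything else -> none.
truth_labels <- function(sites) {
  grp <- rep("none", nrow(sites))
  grp[sites$in_A & !sites$in_B & !sites$in_C] <- "group_A"
  grp[!sites$in_A & sites$in_B & !sites$in_C] <- "group_B"
  grp[!sites$in_A & !sites$in_B & sites$in_C] <- "group_C"
  pool <- rep("none", nrow(sites))
  carries_ab <- (sites$in_A | sites$in_B) & !sites$in_C
  pool[carries_ab] <- "offrob"
  pool[!sites$in_A & !sites$in_B & sites$in_C] <- "spont"
  grp[sites$origin != "founder"] <- NA
  pool[sites$origin != "founder"] <- NA
  data.frame(key = sites$key, group = grp, pool = pool)
}

## Hand-built 12-haplotype panel (9 A, 2 B, 1 C) over explicit sites.
toy_panel <- function() {
  haps <- c(paste0("A", 1:9), "B1", "B2", "C1")
  groups <- stats::setNames(c(rep("A", 9), "B", "B", "C"), haps)
  sites <- c(
    "s_groupA",      # 3 of 9 A haplotypes carry, B/C covered & absent
    "s_shared_AB",   # one A and one B carrier
    "s_C_uncovered", # A-only pattern but the single C haplotype uncovered
    "s_groupC",      # only C carries
    "s_invariant")   # nobody carries
  present <- covered <- matrix(FALSE, length(sites), length(haps),
                               dimnames = list(sites, haps))
  covered[] <- TRUE
  present["s_groupA", c("A1", "A2", "A3")] <- TRUE
  present["s_shared_AB", c("A1", "B1")] <- TRUE
  present["s_C_uncovered", c("A4", "A5")] <- TRUE
  covered["s_C_uncovered", "C1"] <- FALSE
  present["s_groupC", "C1"] <- TRUE
  haplotype_panel(present, covered, groups)
}

## Genotype matrix built directly from call codes (1/0/NA), bypassing
## depth simulation, for specificity rule tests.
toy_matrix <- function(codes, sites, accessions) {
  m <- matrix(codes, nrow = length(sites), byrow = TRUE,
              dimnames = list(sites, accessions))
  structure(m, class = c("genotype_matrix", "matrix"))
}
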