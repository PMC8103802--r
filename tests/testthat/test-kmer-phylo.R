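test_that("k-mer profiles respect window counts and homopolymer filtering", {
  ## a pure homopolymer yields an empty profile under filtering
  p <- kmer_profile(strrep("A", 100), k = 30)
  expect_length(p$kmers, 0L)
  expect_gt(length(kmer_profile(strrep("A", 100), k = 30,
                                drop_homopolymers = FALSE)$kmers), 0L)
  ## L - k + 1 windows when all are distinct and non-homopolymeric
  set.seed(2)
  s <- random_dna(40)
  expect_length(kmer_profile(s, k = 30)$kmers, 11L)
  ## identical sequences give identical profiles; N windows are skipped
  expect_identical(kmer_profile(s, k = 30)$kmers, kmer_profile(s, k = 30)$kmers)
  sN <- paste0(substr(s, 1, 20), "N", substr(s, 22, 40))
  expect_length(kmer_profile(sN, k = 30)$kmers, 0L)
  ## k beyond the sequence length: empty profile, not an error
  expect_message(p0 <- kmer_profile("ACGT", k = 30), "exceeds")
  expect_length(p0$kmers, 0L)
  expect_error(kmer_profile(s, k = 0), "k must be")
})

test_that("profile distance equals the brute-force symmetric difference", {
  set.seed(9)
  for (i in 1:10) {
    s1 <- random_dna(300)
    s2 <- random_dna(300)
    d <- kmer_distance(kmer_profile(s1, k = 30), kmer_profile(s2, k = 30))
    expect_identical(d, oracle_kmer_dist(s1, s2, 30))
  }
  ## identity and disjointness
  p <- kmer_profile(random_dna(200), k = 30)
  expect_identical(kmer_distance(p, p), 0L)
  q <- kmer_profile(random_dna(200), k = 30)
  if (length(intersect(p$kmers, q$kmers)) == 0L)
    expect_identical(kmer_distance(p, q), length(p$kmers) + length(q$kmers))
  expect_error(kmer_distance(p, kmer_profile(random_dna(100), k = 20)),
               "different k")
})

test_that("one substitution in a non-repetitive sequence changes 2k k-mers", {
  set.seed(30)
  repeat {  # draw until all windows are distinct within each variant
    s1 <- random_dna(500)
    v <- strsplit(s1, "")[[1]]
    v[250] <- setdiff(c("A", "C", "G", "T"), v[250])[1]
    s2 <- paste(v, collapse = "")
    p1 <- kmer_profile(s1, k = 30)
    p2 <- kmer_profile(s2, k = 30)
    if (length(p1$kmers) == 471L && length(p2$kmers) == 471L) break
  }
  expect_identical(kmer_distance(p1, p2), 60L)
})

test_that("profile distance is a metric on random profiles", {
  set.seed(18)
  seqs <- replicate(5, random_dna(200))
  profs <- lapply(seqs, kmer_profile, k = 20)
  for (i in 1:5) for (j in 1:5) {
    dij <- kmer_distance(profs[[i]], profs[[j]])
    expect_identical(dij, kmer_distance(profs[[j]], profs[[i]])) # symmetry
    if (i == j) expect_identical(dij, 0L)
    for (l in 1:5)  # triangle inequality of symmetric-difference size
      expect_lte(dij, kmer_distance(profs[[i]], profs[[l]]) +
                   kmer_distance(profs[[l]], profs[[j]]))
  }
})

test_that("neighbour joining recovers additive trees exactly", {
  set.seed(4)
  ref <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:1):2,e:3);")
  d <- ape::cophenetic.phylo(ref)
  tr <- nj_tree(d)
  ## exact recovery: the tree-implied distances equal the input matrix
  dd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(dd, d, tolerance = 1e-10)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), ape::unroot(tr))), 0)
  ## taxon order does not change the unrooted topology
  perm <- c("d", "a", "e", "c", "b")
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
  ## three taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(d3)
  lens <- sort(tr3$edge.length)
  expect_equal(lens, sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2, (4 + 5 - 3) / 2)))
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
  d_asym <- d3; d_asym[1, 2] <- 9
  expect_error(nj_tree(d_asym), "not symmetric")
})

test_that("Newick output round-trips, quoting awkward labels", {
  ref <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:1):2,e:3);")
  d <- ape::cophenetic.phylo(ref)
  tr <- nj_tree(d)
  path <- file.path(tempdir(), "tree.nwk")
  nwk <- write_newick(tr, path)
  expect_match(nwk, ";$")
  back <- ape::read.tree(path)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  ## labels with spaces survive quoting
  tr$tip.label[1] <- "taxon one"
  nwk2 <- write_newick(tr, path)
  expect_match(nwk2, "'taxon one'", fixed = TRUE)
})

test_that("simulated haplotype segments cluster by founder lineage", {
  ## ((A,B),C) segments: A copies group together and C is outermost,
  ## and k-mer distance grows with divergence time
  ok <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      seed = 100 + s, genome_length = 25000, n_genes = 0,
      pool_sizes = c(officinarum = 0L, robustum = 0L, spontaneum = 0L,
                     cultivar = 1L),
      ploidy_spec = list(officinarum = c(A = 6L, B = 2L),
                         robustum = c(A = 6L, B = 2L),
                         spontaneum = c(C = 8L),
                         cultivar = c(A = 3L, B = 2L, C = 1L)))
    f <- simulate_founders(cfg)
    a <- simulate_accessions(f, cfg)
    seqs <- haplotype_sequences(f, a, "cultivar_01")
    d <- kmer_distance_matrix(seqs, k = 30)
    a_tips <- grep("_A", rownames(d), value = TRUE)
    b_tips <- grep("_B", rownames(d), value = TRUE)
    c_tip <- grep("_C", rownames(d), value = TRUE)
    expect_gt(mean(d[a_tips, c_tip]), mean(d[a_tips, b_tips]))
    tr <- nj_tree(d)
    rooted <- ape::root(tr, outgroup = c_tip, resolve.root = TRUE)
    ok <- ok + ape::is.monophyletic(rooted, a_tips)
  }
  expect_identical(ok, n_seeds)
})
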