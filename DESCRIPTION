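Package: triorigin
Title: Tracing Founding Ancestral Genomes in Polyploid Sugarcane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the germplasm-pool origin of haplotype groups coexisting in
    highly polyploid sugarcane (Saccharum spp.) genomes. Implements polyploid
    presence/absence genotype calling from per-site allele depths,
    haplotype-group- and germplasm-pool-specific SNP classification with
    reciprocal cross-tabulation and per-group origin verdicts, Nei-Gojobori
    (1986) synonymous-substitution (Ks) estimation on codon alignments with
    molecular-clock dating, alignment-free 30-mer distance phylogenies, and
    principal-coordinates ordination of SNP dissimilarities for hybrid
    screening. A founder-genome simulator generates diverging lineages,
    polyploid accession mixtures and allele-depth data so the whole inference
    chain can be exercised and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
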