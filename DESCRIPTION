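Package: haplodomain
Title: Gene-Set and Exon-Usage Analysis of Haplotype Effects on the Brain
    Transcriptome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for analysing the effect of humanized Klotho
    (KL) haplotypes on bulk brain RNA-seq: median-of-ratios normalization
    with covariate residualization, per-gene factorial linear models of age,
    sex and haplotype, ordered-haplotype trend models on Biodomain,
    subdomain, KEGG and KEGG-by-Biodomain intersection gene sets,
    Dirichlet-multinomial differential exon usage between FC and VS allele
    carriers, and cross-system effect-size concordance against a two-group
    (treated vs untreated) expression experiment. Includes a synthetic-data
    generator with known ground truth (cohort design, negative-binomial
    counts with injected set-level effects, Dirichlet-multinomial exon
    counts, paired organoid-style data) so every stage is testable without
    access to the original study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
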