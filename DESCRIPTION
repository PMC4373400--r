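Package: popanchor
Title: Population-Sequencing Marker Discovery, Ultra-Dense Linkage Maps
    and Genetic Anchoring of Assembly Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembly-free discovery of k-mer pair ("50+1-mer") SNP markers
    from whole-genome shotgun reads of two homozygous parents and a pooled
    doubled-haploid (DH) population, genotyping of low-coverage DH
    individuals against the marker panel, construction of ultra-dense
    genetic linkage maps (two-point LOD clustering, recombination-bin
    ordering, Kosambi map distances), and anchoring/validation of assembly
    scaffolds by nearest-neighbour genotype search, including mis-join
    (chimera) detection, collinearity checks and segregation-distortion
    scans. Ships k-mer frequency-spectrum analytics (error threshold, peak
    depth, genomic copy-number distribution), pairwise SNP-rate and
    deletion-interval estimation from depth tracks, and a fully seeded
    synthetic-data generator (parents, DH progeny, shotgun reads,
    genotype matrices, fragmented assemblies with planted chimeras) with
    complete ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
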