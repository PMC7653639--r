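Package: clonekit
Title: Clone Detection, Ploidy Inference and Apomixis Classification from
    Reduced-Representation Genotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting clonal lineages and inferring ploidy from
    ddRAD-style reduced-representation sequencing of plants. Converts
    per-locus allele read depths into diploidized genotype calls with
    depth and minor-allele-frequency filters, partitions samples into
    genetically homogeneous data sets by p-distance, identifies clones by
    pairwise heterozygous-locus similarity with duplicate-library
    threshold calibration, infers ploidy from minor-allele depth-fraction
    spectra (allele-balance peaks at 1/2, 1/3, 1/4, 1/5 and 2/5),
    performs flow-cytometry genome-size arithmetic and replicate quality
    control, and classifies taxa as sexual or apomictic from clone
    counts, localities, growth habit, male records and ploidy. Includes a
    synthetic data generator emulating clonal lineages, sexual sibships,
    polyploid allele dosage and negative-binomially dispersed locus
    depths, so the whole pipeline is testable without raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
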