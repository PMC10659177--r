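Package: superbarcode
Title: Super-Barcoding Marker Development and Hybrid Detection from
    Plastomes and 45S Ribosomal DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating closely related plant species from
    whole plastid genomes (plastomes) and complete 45S nuclear ribosomal
    DNA ("super-barcoding"). Scans multiple sequence alignments for SNPs
    and insertion/deletion events, designs codominant InDel, dominant
    allele-specific SNP and high-resolution-melting (HRM) style markers
    on conserved primer sites, predicts PCR products and genotypes
    samples in silico, measures per-site allele depths in sequencing
    reads to call nuclear ribosomal heterozygosity, and combines the
    maternally inherited plastome genotype with the biparentally
    inherited nrDNA state to classify samples into pure species and
    hybrids with an identified maternal parent. Includes a seeded
    simulator that generates reference sets, samples and read sets with
    planted variants and truth tables so the whole pipeline is testable
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
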