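Package: mirstack
Title: High-Confidence MicroRNA Annotation from Small RNA-Seq Read Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies microRNA hairpin loci as high confidence,
    insufficiently supported, or inconsistent with canonical Drosha/Dicer
    processing, from the pattern of exactly-mapped small RNA sequencing
    reads. Builds per-arm read stacks summed across datasets, infers star
    sequences from hairpin secondary structure, computes mature duplex
    3' overhangs, 5'-end homogeneity, folding free energy per nucleotide
    and mature pairing fraction, and evaluates five read-pattern and
    structure criteria with configurable thresholds. Includes a seeded
    synthetic locus generator for validation and TSV/GFF3 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
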