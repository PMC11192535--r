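Package: effectorscan
Title: Proteotranscriptomic Effector Discovery for Parasitoid Wasps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls venom-protein and teratocyte-effector genes from
    multi-tissue TPM expression tables combined with proteomic peptide
    evidence (N99 cumulative-abundance expression thresholding,
    tissue-specialization index, one-sided Z test for significantly high
    expression, in-silico tryptic digestion and exact peptide-to-protein
    matching), ranks gene-family domain expansions of a focal species
    against comparator genomes with robust-z outlier flagging, and
    computes parasitism-assay statistics (parasitism and emergence rates,
    oviposition preference index, enumeration-exact Wilcoxon signed-rank
    and Mann-Whitney U tests, superparasitism fold recovery). A synthetic
    data generator with planted ground truth emulates every input so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
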