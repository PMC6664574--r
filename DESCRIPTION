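Package: triplexmotif
Title: Triplex-Forming r-UC/r-AG Motif Analysis for lncRNAs and LINE Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans nucleotide sequences for short redundant pyrimidine (r-UC/TC)
    and purine (r-AG) motifs that can mediate RNA-dsDNA triplex formation via
    Hoogsteen or reverse Hoogsteen base pairing, and provides the downstream
    statistics used to characterise them: per-sequence occupancy, frequency and
    class ratio, motif-length distributions compared by Kolmogorov-Smirnov
    distance, cumulative overlapping-window ratios, and RepeatMasker-based LINE
    family and length-bin summaries with reproducible per-bin sampling.
    Includes a secondary-structure loop filter that restricts motifs to their
    single-stranded (triplex-accessible) portions, a paired-element comparison
    of sequence identity versus complete motif identity through an affine-gap
    global alignment, a kinetic Monte Carlo model of cooperative multi-site
    RNA-DNA binding yielding dissociation probabilities, and synthetic-data
    generators (motif-planted sequences, 5'-truncated LINE-1-like families,
    mutated sequence pairs, RepeatMasker and dot-bracket fixtures) so that the
    whole pipeline runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
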