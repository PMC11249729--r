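Package: codonramp
Title: Encoded Translation Speed and Evolutionary Turnover at Gene Termini
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon-level encoded translation speed at the
    5' and 3' ends of protein-coding genes. Computes per-codon speed profiles
    from ribosome residence times (RRT), the relative initial translation
    speed statistic (RIT), genome-wide terminal slowdown estimates,
    first-window codon-usage enrichment, and windowed terminal protein
    conservation scores from BLAST tabular output. Includes a synonymous
    recoder for designing slow/medium/fast reporter leaders with an optional
    ribosome collision site, and a synthetic-genome generator implementing a
    terminus-turnover ("young spandrel") model with closed-form expected
    effect sizes, so every stage of the pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
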