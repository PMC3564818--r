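Package: scdscan
Title: Census of S/T-Q Cluster Domains in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clusters of S/T-Q dipeptide motifs (the ATM/ATR and
    Tel1/Mec1 kinase consensus) in protein sequences under a parameterized
    cluster definition (at least k motifs within a span of W residues),
    sweeps definitions over a (k, W) grid, and quantifies how many
    cluster-containing proteins are expected by chance under a
    Poisson-process null with a Poisson-binomial significance test for the
    census size. Also provides hypergeometric overlap tests against
    external protein lists, term enrichment with Bonferroni and
    Benjamini-Hochberg correction, a log-normal goodness-of-fit test for
    census length distributions, position-specific frequency profiles of
    residues flanking phosphosites, and a fully seeded synthetic-data
    generator (proteomes, phosphosites, annotations) with recorded ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
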