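Package: paleoamp
Title: Authentication of Cloned Ancient-DNA Amplicon Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating short overlapping PCR amplicons recovered
    from degraded (ancient) DNA. Provides a synthetic clone-library simulator
    with post-mortem cytosine-deamination damage and numt (nuclear
    mitochondrial pseudogene) co-amplification; consensus calling across
    cloned amplifications with IUPAC ambiguity handling and replication
    validation; quantification of clone-versus-consensus damage spectra;
    multi-criterion discrimination of genuine mitochondrial sequences from
    numts (frequency, divergence, reading frame, third-codon-position
    composition, codon-position rate pattern, length-based preservation
    anchors); and likelihood-based topology confidence tests on fixed trees
    (partitioned GTR+I+Gamma site log-likelihoods, RELL bootstrap,
    Shimodaira-Hasegawa and approximately unbiased tests, harmonic-mean
    marginal likelihoods and Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
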