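Package: flphylo
Title: Phylogenetic Analysis of the Functional Load of Phonological Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes entropy-based functional load (FL) of phonological
    contrasts from segmented wordlists and studies its evolution on language
    phylogenies. Functional load is quantified as the drop in Shannon entropy
    of a distribution of string types when a contrast (e.g. vowel length,
    consonant manner, consonant place) is collapsed. The package extracts
    tonic-vowel plus post-tonic intervocalic-consonant domains from lexicons,
    computes unnormalized and normalized FL, measures phylogenetic signal
    with Blomberg's K and a tip-randomization permutation test aggregated
    over a sample of dated trees, and estimates phylogenetic Pearson
    correlations between FL variables under a Brownian-motion model.
    Includes a synthetic-data generator (Yule trees, Brownian traits, and
    lexicons with a tunable vowel-length/consonant-manner trade-off) so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
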