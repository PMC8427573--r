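Package: preydetect
Title: Species-Diagnostic Marker Design and Prey DNA Detection from
    Endpoint-PCR Intensity Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for molecular diet analysis of carnivores: screens
    aligned mitochondrial cytochrome b sequences for species-diagnostic
    marker loci, evaluates marker specificity from dual-dye (FAM/HEX)
    endpoint-PCR intensity plates with a passive-reference (ROX) channel,
    and calls prey species in predator scat samples using per-marker
    baselines and a minimum-k amplifying-marker rule.  Includes a
    synthetic-data generator (alignments with planted diagnostic sites,
    intensity plates with known ground truth) so the whole pipeline can
    be exercised and benchmarked without external data, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
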