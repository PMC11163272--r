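Package: amirephys
Title: Artificial miRNA Design and Extracellular Spike-Train Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing artificial microRNAs (amiRNAs) against a
    target transcript and for quantifying extracellular spike trains. The
    design side enumerates 23-nt duplex windows under a positional consensus
    with GC-content and homopolymer filters, scores 5' terminal duplex
    asymmetry from nearest-neighbor stacking free energies, screens
    candidates against a transcriptome by longest contiguous exact match,
    generates composition-preserving scrambled controls, and embeds guides
    into the miR-155 scaffold (5' arm, 21-nt antisense, loop, 19-nt sense
    with two central nucleotides deleted, 3' arm). The electrophysiology
    side band-pass filters raw traces, detects spikes at a standard-deviation
    threshold, clusters waveforms, classifies units by trough-to-peak
    duration, and computes rasters, firing rates, inter-spike intervals,
    autocorrelograms and a burstiness index. Seeded synthetic-data
    generators provide ground-truth transcriptomes, target genes and
    recordings for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
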