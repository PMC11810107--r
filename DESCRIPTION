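Package: compgrowth
Title: Size-Dependent Compensatory Growth Analysis for High-Content Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for size-dependent compensatory growth in
    proliferating mammalian cells, built around per-cell feature tables from
    fixed-cell high-content imaging and nuclear-area time-lapse tracks. The
    package provides an agent-based growth/division simulator with known
    ground truth (sizer-gated G1 exit, timer-like S and G2+M, size-dependent
    proteasome flux), automatic DNA/Geminin cell-cycle staging, a continuous
    cell-cycle axis from the density ridge of the DNA x log(Geminin)
    distribution, proteasome-flux statistics from paired proteasome-inhibitor
    wells (delta-K48-polyUb), superlinear size-scaling tests, cycloheximide
    chase and decomposition analyses, and growth-rate/cell-cycle-length
    inference from bulk time courses and single-cell tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
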