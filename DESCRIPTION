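Package: rnalayout
Title: Template-Based RNA Secondary Structure Layout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates 2D layouts for RNA secondary structures by transferring
    the layout of a similar, already-drawn template structure onto a target
    structure. Target and template (in dot-bracket notation) are converted to
    ordered rooted trees, a minimal tree edit mapping between them is computed
    with the Zhang-Shasha dynamic program, and the edit operations are replayed
    on the template drawing as local geometric modifications (circle
    redistribution of loops, subtree shifts, multibranch squeeze or rebuild),
    followed by stem straightening, top-level normalization and clash-rotation
    postprocessing. Includes readers and writers for a TSV layout exchange
    format, a minimal VARNA-style SVG subset, SVG and PostScript output with
    insert/relabel/shift color coding, an overlap (clash) counter, a random
    structure and layout generator for testing, and a two-phase map/draw
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    stats,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
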