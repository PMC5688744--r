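# rnalayout

Template-based drawing of RNA secondary structures.

## The problem

Secondary-structure diagrams of large RNAs — ribosomal RNAs above all — are
habitual: the community recognizes a molecule by the shape of its drawing, not
by any optimality criterion a de-novo layout engine could optimize for.
General drawing tools produce layouts that are geometrically fine but look
nothing like the accepted diagrams. When a well-drawn layout already exists
for a *similar* molecule, the sensible thing is to reuse it: keep everything
that is common, and modify the drawing only where the two structures differ.

`rnalayout` does exactly that. Given

* a **template**: a secondary structure (dot-bracket) plus its 2D layout, and
* a **target**: the secondary structure to be drawn,

it produces a layout for the target that deviates from the template as little
as the structural differences allow.

## The algorithm

1. **Tree representation.** A pseudoknot-free secondary structure maps to an
   ordered rooted tree: base pairs become inner nodes, unpaired residues
   leaves, and an artificial root holds the top-level elements together
   (`build_tree()`). Pseudoknots are first resolved to a maximum
   crossing-free pair subset (`remove_pseudoknots()`).
2. **Matching.** The ordered tree edit distance between template and target
   trees is computed with the Zhang–Shasha keyroot dynamic program
   (O(m²n²) time, O(mn) memory), together with a minimal edit script — the
   mapping realized as insert/update/delete operations (`ted()`). An
   exhaustive-enumeration oracle (`ted_bruteforce()`) verifies the DP on
   small trees.
3. **Layout transformation.** Each edit operation has a geometric
   counterpart (`transform_layout()`): a deleted pair pulls its subtree one
   `pair_step` back along the stem axis; an inserted pair pushes it out; an
   unpaired residue inserted into (or removed from) a loop redraws the local
   arc with equal spacing (`distribute_on_circle()`); an insertion between
   stacked pairs opens a bulge by shifting the sibling stem
   (`shift_subtree()`). Multibranch loops are special: small changes are
   *squeezed* into the existing gaps so no branch moves, larger ones rebuild
   the whole loop circle and rigidly rotate every branch into its new radial
   direction (`multibranch_update()`).
4. **Postprocessing.** Stems are straightened onto their axes
   (`straighten_stems()`), top-level spacing is normalized around edits
   (`normalize_top_level()`), and remaining steric clashes are reduced by
   trying a set of rigid subtree rotations and keeping the best
   (`resolve_clashes()`, `count_overlaps()`).

Residues in the result carry a status flag — `unchanged`, `shifted`
(blue), `relabeled` (green), `inserted` (red) — matching the color coding of
the SVG/PostScript writers.

## Worked example

```r
library(rnalayout)

# template: a random 60-nt structure drawn de novo
cfg <- generator_config(seed = 7, length = 60)
template_ss <- random_structure(cfg)
template <- baseline_layout(template_ss)
as_dotbracket(template_ss)
#> ..(((.......((((....)))).((....)))))......(((......)))......

# target: the same molecule with one stem shortened by two pairs
target_ss <- perturb_structure(template_ss,
                               list(kind = "del_pairs", stem = 2, n = 2))
as_dotbracket(target_ss)
#> ..(((.......((....)).((....)))))......(((......)))......

result <- transform_layout(template, target_ss)
print(result)
#> rna_template: 56 residues, 10 pairs; status:
#> unchanged   shifted relabeled  inserted
#>        48         4         4         0

attr(result, "script")
#> edit_script: distance 2, 2 deletions, 0 insertions, 47 updates (47 free)

count_overlaps(result)$count
#> [1] 0

write_svg(result, "target.svg", colored = TRUE)
```

The two deleted pairs cost edit distance 2; the four residues of the
shortened stem's hairpin moved (blue), four mapped pair residues changed
letters (green), nothing was inserted, and the drawing stays planar. Using
the shortened document as a template *for the original structure* recreates
the original drawing to within numerical noise — the Results vignette
(`vignettes/template-layouts.Rmd`) discusses this round-trip experiment and
every geometric rule in detail.

## Command line

A two-phase CLI mirrors the parser / mapper / visualizer architecture, so a
mapping can be computed once and redrawn repeatedly:

```sh
inst/cli/rnalayout map  --template-structure tpl.dbn --target-structure tgt.dbn --out m.map
inst/cli/rnalayout draw --template-structure tpl.dbn --target-structure tgt.dbn \
                        --template-layout tpl.tsv --map m.map --out tgt.svg --colored --overlaps
inst/cli/rnalayout generate --seed 7 --length 60 --out fixture
```

Template layouts are read from the native TSV exchange format
(`write_layout_tsv()`) or a minimal VARNA-style SVG subset
(`read_varna_svg()`); output is SVG, PostScript or TSV by extension.

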