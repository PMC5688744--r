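---
title: "Template-based RNA secondary structure layout: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based RNA secondary structure layout: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnalayout)
```

## The model

A pseudoknot-free RNA secondary structure is an ordered rooted tree: each
base pair is an inner node whose children are the pairs and unpaired
residues it immediately encloses, each unpaired residue is a leaf, and the
order of children is the 5'→3' order along the sequence. `rnalayout`
installs an artificial root unconditionally, whether or not the first and
last residues are paired. A structure whose ends are unpaired would
otherwise translate into a forest; unconditional rooting removes that case
split, and since both trees in a comparison gain the same extra node, no
mapping between them changes.

Pseudoknots cannot be represented in such a tree. Crossing pairs are
resolved beforehand by keeping a maximum-cardinality crossing-free subset,
computed by dynamic programming over sequence intervals; ties are broken by
preferring the pair with the smaller opening index. The choice of *which*
maximum subset to keep is a genuine free parameter of the problem — any
maximum subset yields a valid nested structure — and the smaller-opening
rule was fixed once for determinism.

## Matching: ordered tree edit distance

The mapping between template and target trees is a minimal-cost ordered
tree edit mapping (insertions, deletions, updates), computed with the
Zhang–Shasha keyroot-decomposition dynamic program in O(m²n²) worst-case
time and O(mn) memory. The backtrace is deterministic: at cost ties it
prefers an update over a delete+insert and maps leftmost template nodes
first, so the same input pair always yields the same script — a requirement
for reproducible layouts.

Edit costs are not dictated by the matching problem itself, so the package
fixes a scheme suited to layout transfer: insert = delete = 1, and updates
are free between nodes of the same kind (pair↔pair, leaf↔leaf) regardless
of nucleotide letters, cost 1 between kinds. Letters do not matter because
the layout machinery cares only about shape; a letter-only change is mapped
in place and color-coded "relabeled" rather than re-inserted. Kind-changing
updates (pair↔leaf) are permitted in the distance; the layout replay
decomposes them into delete + insert, because a pair (two residues) cannot
be relabeled into a single unpaired residue geometrically. The scheme is a
`cost_scheme()` object and can be replaced wholesale.

Correctness of the dynamic program is checked against an independent
oracle, `ted_bruteforce()`, which enumerates every valid mapping (partial
injections preserving ancestry and sibling order, verified through pre- and
postorder ranks) on trees of at most 10 nodes. The test suite and the
acceptance script compare the two on hundreds of random tree pairs.

## Layout transformation

The guiding principle is minimal interference: reuse template coordinates
wherever the mapping allows and modify the drawing only around edits.
Operations are replayed in a fixed order — deletions in postorder (children
before parents), insertions in target preorder (parents before children),
relabelings last — so every operation acts on an existing, well-positioned
neighbourhood.

Two primitives carry all the geometry:

* **Circle distribution** (`distribute_on_circle()`): place *n* residues on
  a circle through two anchor points so that the *n*+1 arc gaps are equal.
  The free parameter is the circle radius; it is solved by root-finding on
  the subtended central angle so that each gap's chord is as close as
  possible to `backbone_step`. When the anchors are too far apart for that
  spacing on any circle, the minimal circle through the anchors (a
  semicircular arc) is the fallback.
* **Subtree shift** (`shift_subtree()`): rigid translation of everything a
  node encloses.

From these: an inserted pair goes one `pair_step` beyond its parent along
the stem growth direction — the vector from the grandparent-pair midpoint
to the parent-pair midpoint; at a stem of length one, where no grandparent
pair exists, the vector from the enclosing loop's centre to the pair
midpoint is used instead — and the enclosed subtree shifts by the same
amount. An inserted loop residue triggers a redistribution of its local
unpaired run between the fixed flanking anchors. An insertion between
stacked pairs opens a bulge: the sibling stem shifts one `backbone_step`
along the axis and the new residue is placed on the outer side of its
strand. Deletions are the exact geometric inverses; the tests verify
insert-then-delete recovery to 1e-9.

### Multibranch loops

Hand-curated layouts of large RNAs compact their multibranch loops in ways
a circle redistribution would destroy, so loops with at least two emanating
stems are treated conservatively. If the net indel count in the loop is at
most 2 and the affected runs still fit between their fixed anchors with
per-gap spacing in [0.5, 2] × `backbone_step`, the change is *squeezed*:
only the unpaired residues between the neighbouring branches are re-spaced
and no branch anchor moves. Otherwise the loop is *rebuilt*: all residues
and branch anchor pairs are placed on a fresh circle (radius solved so the
chord angles close exactly), and each branch is rigidly rotated and
translated so its stem axis is radial at its new anchor — the rotation
propagates to every descendant. The "at most 2" threshold is a calibration
of the qualitative rule that only few added or removed bases justify
keeping the old anchors; both bounds are configurable in
`multibranch_update()`'s internals and recorded here as the package's
defaults.

### Top level

Children of the artificial root have no positioned parent, so the
parent/grandparent direction rule cannot apply there. A pair inserted at
the top level either extends an existing top-level stem — it takes over the
template's stem-start coordinates while the old stem shifts one `pair_step`
inward — or roots a brand-new branch, which is oriented perpendicular to
the local chain through its neighbours, with its bond lying along the chain
and downstream siblings shifting by `bond_length + backbone_step` to make
room. After all edits, gaps along the top-level chain that fall outside
[0.5, 2] × `backbone_step` are closed to one `backbone_step` by rigid
downstream translation. Inside `transform_layout()` this normalization is
restricted to gaps adjacent to actual top-level edits: a template whose
exterior was deliberately drawn with wide spacing keeps that spacing, in
line with the minimal-interference principle. The exported
`normalize_top_level()` applies the rule to the whole chain.

## Postprocessing

Because insertion directions come from parent/grandparent geometry, a
freshly extended stem can end up slightly bent. `straighten_stems()`
projects every maximal run of stacked pairs onto the line through its
outermost and innermost pair midpoints, with uniform `pair_step` spacing
and residues symmetric at `bond_length` about the axis. The outermost
(closest-to-root) pair anchors the stem — which end stays fixed is a free
choice; anchoring at the root side keeps the stem's attachment to the rest
of the drawing. The operation is idempotent.

Steric clashes can remain when template and target are dissimilar. An
overlap is a proper crossing between two drawn segments (hydrogen bond or
backbone link) sharing no residue; collinear overlaps of positive length
count once, and endpoint-to-endpoint touches never count (whether such
degenerate contacts should count is a convention; this one was fixed for
determinism). `resolve_clashes()` walks the minimal pair-rooted subtrees
containing clashing residues, outermost first, tries rotations of ±5° to
±60° about each subtree's anchor, and keeps the rotation with the fewest
global overlaps — never more than before. One pass only, without recursing
into already-rotated subtrees, which prevents oscillation. Clashes can
survive this heuristic; that is expected for very dissimilar inputs, and
`count_overlaps()` reports them.

A target structurally identical to its template short-circuits the whole
postprocessing phase, so template reuse is exactly the identity on
coordinates.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `backbone_step` | 8 layout units | distance between consecutive residues |
| `pair_step` | 8 | distance between stacked pairs along a stem |
| `bond_length` | 8 | distance between the two residues of a pair |
| squeeze threshold | 2 indels, [0.5, 2]×`backbone_step` | squeeze vs rebuild in multibranch loops |
| rotation candidates | ±5…±60° | clash-resolution attempts |

Layout units are arbitrary; equal defaults reflect the roughly uniform
spacing of habitual diagrams. All three are settable per document and from
the command line (`--backbone-step` sets all three).

## The fixture generator

`random_structure()` draws pseudoknot-free structures top-down: each
position is unpaired or opens a helix of 2–6 stacked pairs whose interior
is filled recursively, with branching probability 0.12 per position,
hairpin loops of at least 3 unpaired residues, and canonical (including
wobble) pair letters. `baseline_layout()` draws them de novo in the
habitual style — straight stems, loop residues on circles, branches radial,
the exterior on a circle — purely to manufacture template documents;
internal loops are drawn with the helix continuing straight through, and
loop gaps around bulky branches are widened using conservative subtree
extent estimates so that generated templates are planar (the suite checks
100 seeds).

What the generator does *not* emulate: thermodynamic plausibility of the
structures, the manual compaction of real CRW-style diagrams (which
violates the circular-loop convention on purpose), pseudoknots in
templates, and non-canonical pair annotations. Passing tests therefore
demonstrate the correctness of the tree matching and of each geometric
rule on clean radial drawings, not fidelity to any particular published
diagram.

## Numerical choices and degenerate inputs

Circle radii are solved with `uniroot` to 1e-12; chord-angle sums are
normalized to close rebuilt loops exactly. Status flags upgrade
monotonically (unchanged → shifted → relabeled → inserted) so a residue
keeps its strongest annotation. Coordinates in the text formats are written
as the shortest decimal of their 6-significant-digit rounding, making every
writer byte-deterministic; values below 1e-9 print as 0. Degenerate cases —
coincident anchors, a side direction parallel to the anchor line, deleting
the root — raise errors rather than guessing. Tiny loops whose chords
cannot close a circle fall back to the minimal enclosing radius.

## The round-trip experiment

The characteristic validation: take a drawn structure, delete part of a
stem, use the shortened molecule's generated layout as the template for the
*original* structure, and compare with the original drawing. Deletion and
insertion being exact inverses, the recovered coordinates match to within
numerical noise (the suite requires 0.1 × `backbone_step`; observed errors
are ~1e-15). When the middle step instead destroys whole hairpins so that a
multibranch loop must be rebuilt, the recreated layout is similar but not
identical — the rebuild's branch-placement rules need not match whatever
produced the original template. Both behaviours are exercised in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R` (problem sizes there: 200 random tree pairs of ≤ 8
nodes for the oracle, 100 fixture pairs of 50 nt for script validity, 200
fixtures of 36–60 nt for clash monotonicity, 100 baselines of 40–100 nt for
planarity — sizes chosen to keep the whole script near ten seconds on one
core while still covering every branch of the geometry).

## Known limitations

* Only "simple" base pairs are modelled; non-canonical pair classes and
  tertiary annotations are out of scope, as is drawing pseudoknots (they
  are removed, not drawn).
* The clash heuristic is a single greedy pass of rigid rotations; it
  reduces but does not guarantee zero overlaps.
* Stem straightening translates (does not re-rotate) the material hanging
  below a stem, so an extreme bend elsewhere can survive straightening.
* The squeeze/rebuild threshold is a fixed calibration; structures whose
  multibranch loops are heavily edited will see whole-loop rebuilds that
  discard the template's manual compaction.
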