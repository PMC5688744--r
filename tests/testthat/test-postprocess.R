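test_that("straighten_stems projects perturbed pairs back onto the axis", {
  doc <- hairpin_doc(npairs = 3L, nloop = 4L)
  lay <- doc$layout
  lay$x[c(2L, 9L)] <- lay$x[c(2L, 9L)] + 1.0       # kick the middle pair
  bent <- template_document(doc$structure, lay[, c("x", "y")])
  out <- straighten_stems(bent)
  mids <- t(sapply(1:3, function(k) c(mean(out$layout$x[c(k, 11L - k)]),
                                      mean(out$layout$y[c(k, 11L - k)]))))
  # midpoints collinear on the vertical axis with uniform pair_step spacing
  expect_lt(max(abs(mids[, 1L] - mids[1L, 1L])), 1e-9)
  expect_equal(diff(mids[, 2L]), rep(8, 2L), tolerance = 1e-9)
  # outermost pair anchors the stem
  expect_equal(out$layout$x[c(1L, 10L)], doc$layout$x[c(1L, 10L)], tolerance = 1e-12)
  expect_equal(out$layout$y[c(1L, 10L)], doc$layout$y[c(1L, 10L)], tolerance = 1e-12)
  # residues that moved are flagged
  expect_identical(out$layout$status[2L], "shifted")
})

test_that("straighten_stems is idempotent and leaves straight stems alone", {
  doc <- hairpin_doc(npairs = 4L, nloop = 5L)
  once <- straighten_stems(doc)
  expect_equal(once$layout$x, doc$layout$x, tolerance = 1e-12)
  expect_equal(once$layout$y, doc$layout$y, tolerance = 1e-12)
  expect_true(all(once$layout$status == "unchanged"))

  lay <- doc$layout
  lay$x[2L] <- lay$x[2L] + 2
  bent <- template_document(doc$structure, lay[, c("x", "y")])
  a <- straighten_stems(bent)
  b <- straighten_stems(a)
  expect_equal(b$layout$x, a$layout$x, tolerance = 1e-9)
  expect_equal(b$layout$y, a$layout$y, tolerance = 1e-9)
})

test_that("count_overlaps detects crossings and honours exclusions", {
  # crossing diagonals between non-adjacent backbone segments
  ss <- parse_dotbracket(c("ACGU", "...."))
  dq <- template_document(ss, data.frame(x = c(0, 2, 0, 2), y = c(0, 2, 2, 0)))
  expect_equal(count_overlaps(dq)$count, 1L)

  # consecutive backbone segments share a residue: never counted
  dz <- template_document(ss, data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 2, 3)))
  rep <- count_overlaps(dz)
  expect_false(any(rep$crossings$i1 == rep$crossings$i2))

  # square hairpin: planar, zero overlaps
  hp <- hairpin_doc(npairs = 2L, nloop = 4L)
  expect_equal(count_overlaps(hp)$count, 0L)
})

test_that("count_overlaps matches an independent brute-force checker", {
  set.seed(31)
  for (s in 1:8) {
    doc <- baseline_layout(random_structure(generator_config(seed = s, length = 40)))
    if (s %% 2L == 0L) {
      nd <- tree_nodes(doc)
      pairs <- nd$id[nd$kind == "PAIR" & nd$depth == 1L]
      if (length(pairs) > 0L) {
        doc <- rotate_doc_subtree(doc, pairs[1L], stats::runif(1, -pi / 2, pi / 2))
      }
    }
    expect_equal(count_overlaps(doc)$count, naive_overlap_count(doc))
  }
})

test_that("resolve_clashes fixes the constructed two-hairpin collision", {
  doc <- two_hairpin_collision(lean_deg = 30)
  before <- count_overlaps(doc)$count
  expect_gt(before, 0L)
  fixed <- resolve_clashes(doc)
  expect_equal(count_overlaps(fixed)$count, 0L)
})

test_that("resolve_clashes never increases the overlap count", {
  set.seed(97)
  for (s in 1:25) {
    doc <- baseline_layout(random_structure(generator_config(seed = 300 + s,
                                                             length = 45)))
    nd <- tree_nodes(doc)
    pairs <- nd$id[nd$kind == "PAIR"]
    if (length(pairs) == 0L) next
    v <- pairs[sample(length(pairs), 1L)]
    doc <- rotate_doc_subtree(doc, v, stats::runif(1, -pi, pi))
    before <- count_overlaps(doc)$count
    after <- count_overlaps(resolve_clashes(doc))$count
    expect_lte(after, before)
  }
  # clash-free layouts come back identical
  hp <- hairpin_doc()
  out <- resolve_clashes(hp)
  expect_identical(out$layout$x, hp$layout$x)
  expect_identical(out$layout$y, hp$layout$y)
})

test_that("normalize_top_level re-spaces only out-of-band gaps", {
  # three top-level leaves with a huge gap in the middle
  ss <- parse_dotbracket(c("ACGU", "...."))
  doc <- template_document(ss, data.frame(x = c(0, 8, 60, 68), y = c(0, 0, 0, 0)))
  out <- normalize_top_level(doc)
  gaps <- diff(out$layout$x)
  expect_true(all(gaps >= 0.5 * 8 - 1e-9 & gaps <= 2 * 8 + 1e-9))
  expect_equal(gaps[1L], 8)            # untouched gap keeps its spacing
  expect_equal(gaps[3L], 8)

  # already well-spaced chain unchanged
  ok <- template_document(ss, data.frame(x = c(0, 8, 17, 26), y = c(0, 0, 0, 0)))
  out2 <- normalize_top_level(ok)
  expect_identical(out2$layout$x, ok$layout$x)
})

test_that("normalize_top_level translates branches rigidly", {
  db <- "..((...)).."
  ss <- parse_dotbracket(c(strrep("A", nchar(db)), db))
  doc <- baseline_layout(ss)
  lay <- doc$layout
  span <- 3:10
  lay$x[span] <- lay$x[span] + 100       # tear the branch away
  torn <- template_document(ss, lay[, c("x", "y")])
  out <- normalize_top_level(torn)
  d0 <- dist(cbind(torn$layout$x[span], torn$layout$y[span]))
  d1 <- dist(cbind(out$layout$x[span], out$layout$y[span]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  expect_equal(nrow(out$layout), nrow(doc$layout))
})

test_that("top-level pair insertion handles both stem-extension and new-branch", {
  # case 1: extend an existing top-level stem
  doc <- hairpin_doc(npairs = 3L, nloop = 4L)
  out <- insert_pair_top_level(doc, pos = 1L, adopt = 1L)
  expect_equal(out$structure$length, 12L)
  # new pair takes the old stem-start coordinates
  expect_equal(c(out$layout$x[1L], out$layout$y[1L]),
               c(doc$layout$x[1L], doc$layout$y[1L]), tolerance = 1e-9)
  # old stem-start residues end exactly pair_step from their former spots
  expect_equal(sqrt((out$layout$x[2L] - doc$layout$x[1L])^2 +
                      (out$layout$y[2L] - doc$layout$y[1L])^2), 8,
               tolerance = 1e-9)

  # case 2: brand-new branch between two top-level leaves
  ss <- parse_dotbracket(c("ACGUAC", "......"))
  chain <- template_document(ss, data.frame(x = 8 * (0:5), y = rep(0, 6)))
  out2 <- insert_pair_top_level(chain, pos = 3L, adopt = 0L, letters = c("G", "C"))
  lay2 <- out2$layout
  expect_equal(out2$structure$length, 8L)
  # bond lies along the chain => branch axis perpendicular to it
  bond <- c(lay2$x[4L] - lay2$x[3L], lay2$y[4L] - lay2$y[3L])
  expect_lt(abs(atan2(bond[2L], bond[1L])), 1e-6)
  # upstream siblings unmoved, downstream shifted by bond + backbone step
  expect_equal(lay2$x[1:2], c(0, 8), tolerance = 1e-12)
  expect_equal(lay2$x[5:8], 8 * (2:5) + 16, tolerance = 1e-9)
})
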