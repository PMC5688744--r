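test_that("distribute_on_circle places symmetric, equally spaced points", {
  # n = 1: perpendicular bisector, requested side
  p <- distribute_on_circle(c(0, 0), c(4, 0), 1L, c(0, 1))
  expect_equal(p[1L, 1L], 2, tolerance = 1e-9)
  expect_gt(p[1L, 2L], 0)

  # n = 2: mirror symmetry about the bisector
  p2 <- distribute_on_circle(c(0, 0), c(4, 0), 2L, c(0, 1))
  expect_equal(p2[1L, 1L] + p2[2L, 1L], 4, tolerance = 1e-9)
  expect_equal(p2[1L, 2L], p2[2L, 2L], tolerance = 1e-9)

  # n = 0 and degenerate anchors
  expect_equal(nrow(distribute_on_circle(c(0, 0), c(1, 0), 0L, c(0, 1))), 0L)
  expect_error(distribute_on_circle(c(1, 1), c(1, 1), 2L, c(0, 1)), "oincident")
})

test_that("arc gaps are equal within 1e-6 across configurations", {
  set.seed(5)
  for (rep in 1:40) {
    a <- stats::runif(2, -20, 20)
    b <- a + stats::runif(2, -15, 15)
    if (sqrt(sum((b - a)^2)) < 1) next
    n <- sample(1:9, 1L)
    side <- c(-(b - a)[2L], (b - a)[1L]) * sample(c(-1, 1), 1L)
    pts <- distribute_on_circle(a, b, n, side, backbone_step = 8)
    ring <- rbind(a, pts, b)
    gaps <- sqrt(rowSums(diff(ring)^2))
    expect_lt(max(gaps) / min(gaps), 1 + 1e-6)
    # all points on the requested half-plane
    u <- (b - a) / sqrt(sum((b - a)^2))
    sperp <- side - sum(side * u) * u
    offs <- sweep(pts, 2L, a) %*% sperp
    expect_true(all(offs > 0))
  }
})

test_that("shift_subtree is a rigid motion confined to the subtree", {
  doc <- baseline_layout(random_structure(generator_config(seed = 2, length = 50)))
  nd <- tree_nodes(doc)
  v <- nd$id[nd$kind == "PAIR" & nd$depth == 1L][1L]
  span <- nd$i[v]:nd$j[v]

  moved <- shift_subtree(doc, v, c(3, -2))
  expect_equal(moved$layout$x[span], doc$layout$x[span] + 3)
  expect_equal(moved$layout$y[span], doc$layout$y[span] - 2)
  expect_identical(moved$layout$x[-span], doc$layout$x[-span])
  expect_identical(moved$layout$y[-span], doc$layout$y[-span])
  expect_true(all(moved$layout$status[span] == "shifted"))
  expect_true(all(moved$layout$status[-span] == "unchanged"))
  # intra-subtree distances preserved exactly
  d0 <- dist(cbind(doc$layout$x[span], doc$layout$y[span]))
  d1 <- dist(cbind(moved$layout$x[span], moved$layout$y[span]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)

  # zero vector: no movement, no flags
  same <- shift_subtree(doc, v, c(0, 0))
  expect_identical(same$layout$x, doc$layout$x)
  expect_true(all(same$layout$status == "unchanged"))
})

test_that("pair insertion extends a stem and shifts descendants by pair_step", {
  doc <- hairpin_doc(npairs = 3L, nloop = 4L)
  nd <- tree_nodes(doc)
  parent <- nd$id[nd$kind == "PAIR" & nd$i == 2L]   # middle pair
  out <- insert_pair_node(doc, parent, pos = 1L, adopt = 1L)
  expect_equal(out$structure$length, doc$structure$length + 2L)
  lay <- out$layout
  # stem remains straight and vertical; new pair midpoint one pair_step above parent
  mids_y <- sapply(1:4, function(k) mean(lay$y[c(k, out$structure$length + 1L - k)]))
  expect_equal(diff(mids_y), rep(8, 3L), tolerance = 1e-9)
  mids_x <- sapply(1:4, function(k) mean(lay$x[c(k, out$structure$length + 1L - k)]))
  expect_equal(mids_x, rep(0, 4L), tolerance = 1e-9)
  expect_equal(sum(lay$status == "inserted"), 2L)
  # descendants displaced by exactly pair_step along the stem axis
  old_loop <- doc$layout[4:7, ]
  new_loop <- lay[5:8, ]
  expect_equal(new_loop$x, old_loop$x, tolerance = 1e-9)
  expect_equal(new_loop$y, old_loop$y + 8, tolerance = 1e-9)
})

test_that("pair insert followed by delete restores all coordinates", {
  doc <- hairpin_doc(npairs = 3L, nloop = 4L)
  nd <- tree_nodes(doc)
  parent <- nd$id[nd$kind == "PAIR" & nd$i == 2L]
  ins <- insert_pair_node(doc, parent, pos = 1L, adopt = 1L)
  nd2 <- tree_nodes(ins)
  newpair <- nd2$id[nd2$kind == "PAIR" & nd2$i == 3L]
  back <- delete_node(ins, newpair)
  expect_equal(back$layout$x, doc$layout$x, tolerance = 1e-9)
  expect_equal(back$layout$y, doc$layout$y, tolerance = 1e-9)
})

test_that("loop insertion re-spaces the run with anchors fixed", {
  doc <- hairpin_doc(npairs = 2L, nloop = 3L)
  nd <- tree_nodes(doc)
  loop_pair <- nd$id[nd$kind == "PAIR" & nd$i == 2L]
  out <- insert_leaf_into_loop(doc, loop_pair, pos = 2L, letter = "A")
  expect_equal(out$structure$length, 8L)
  lay <- out$layout
  # anchors (closing pair residues) unmoved
  expect_equal(lay$x[c(2L, 7L)], doc$layout$x[c(2L, 6L)], tolerance = 1e-12)
  expect_equal(lay$y[c(2L, 7L)], doc$layout$y[c(2L, 6L)], tolerance = 1e-12)
  # the four loop residues now sit on one circle with equal gaps
  ring <- rbind(cbind(lay$x[2L], lay$y[2L]), cbind(lay$x[3:6], lay$y[3:6]),
                cbind(lay$x[7L], lay$y[7L]))
  gaps <- sqrt(rowSums(diff(ring)^2))
  expect_lt(max(gaps) / min(gaps), 1 + 1e-6)
  expect_equal(sum(lay$status == "inserted"), 1L)
  # 5'->3' order preserved: inserted letter at the requested slot
  expect_identical(lay$letter[4L], "A")
})

test_that("bulge insertion shifts the sibling stem and sits off the axis", {
  doc <- hairpin_doc(npairs = 3L, nloop = 4L)
  nd <- tree_nodes(doc)
  outer <- nd$id[nd$kind == "PAIR" & nd$i == 1L]
  out <- insert_leaf_new_bulge(doc, outer, pos = 1L, letter = "U")
  lay <- out$layout
  L <- out$structure$length
  expect_equal(L, 11L)
  # sibling subtree (old residues 2..9) moved exactly backbone_step up
  expect_equal(lay$y[3:10], doc$layout$y[2:9] + 8, tolerance = 1e-9)
  expect_equal(lay$x[3:10], doc$layout$x[2:9], tolerance = 1e-9)
  # bulge residue off the stem line (5' strand at x = -4)
  expect_gt(abs(lay$x[2L] - (-4)), 0.5)
  # backbone connected: consecutive gaps below 3 backbone steps
  gaps <- sqrt(diff(lay$x)^2 + diff(lay$y)^2)
  expect_lt(max(gaps), 3 * 8)
  # exact inverse: deleting the bulge residue restores the document
  nd2 <- tree_nodes(out)
  leaf <- nd2$id[nd2$kind == "LEAF" & nd2$i == 2L]
  back <- delete_node(out, leaf)
  expect_equal(back$layout$x, doc$layout$x, tolerance = 1e-9)
  expect_equal(back$layout$y, doc$layout$y, tolerance = 1e-9)
})

test_that("loop deletion shrinks the circle and keeps spacing equal", {
  doc <- hairpin_doc(npairs = 2L, nloop = 4L)
  nd <- tree_nodes(doc)
  leaf <- nd$id[nd$kind == "LEAF" & nd$i == 4L]
  out <- delete_node(doc, leaf)
  lay <- out$layout
  expect_equal(out$structure$length, 7L)
  ring <- rbind(cbind(lay$x[2L], lay$y[2L]), cbind(lay$x[3:5], lay$y[3:5]),
                cbind(lay$x[6L], lay$y[6L]))
  gaps <- sqrt(rowSums(diff(ring)^2))
  expect_lt(max(gaps) / min(gaps), 1 + 1e-6)
})

test_that("multibranch squeeze keeps branch anchors fixed", {
  db <- "((..((...))..((...))..))"
  ss <- parse_dotbracket(c(strrep("A", nchar(db)), db))
  doc <- baseline_layout(ss)
  nd <- tree_nodes(doc)
  loop <- nd$id[nd$kind == "PAIR" & nd$i == 2L]
  anchors <- c(5L, 11L, 14L, 20L)     # branch pair residues
  out <- multibranch_update(doc, loop, insert_pos = 2L, insert_letters = "G")
  expect_equal(out$structure$length, ss$length + 1L)
  # anchors identical before/after (their indices shift by the insertion)
  newpos <- ifelse(anchors >= 3L, anchors + 1L, anchors)
  expect_equal(out$layout$x[newpos], doc$layout$x[anchors], tolerance = 1e-12)
  expect_equal(out$layout$y[newpos], doc$layout$y[anchors], tolerance = 1e-12)
  expect_equal(sum(out$layout$status == "inserted"), 1L)
})

test_that("multibranch rebuild is rigid per branch with all elements on a circle", {
  db <- "((..((...))..((...))..))"
  ss <- parse_dotbracket(c(strrep("A", nchar(db)), db))
  doc <- baseline_layout(ss)
  nd <- tree_nodes(doc)
  loop <- nd$id[nd$kind == "PAIR" & nd$i == 2L]
  # six insertions force a rebuild
  out <- multibranch_update(doc, loop, insert_pos = rep(2L, 6L),
                            insert_letters = "U")
  lay <- out$layout
  # branch subtree internal distances preserved (branch 1 now spans 11..17)
  old_span <- 5:11
  new_span <- 11:17
  d0 <- dist(cbind(doc$layout$x[old_span], doc$layout$y[old_span]))
  d1 <- dist(cbind(lay$x[new_span], lay$y[new_span]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  # every loop element equidistant from the loop circle centre
  loop_res <- c(2L, 3:10, 11L, 17L, 18L, 19L, 20L, 26L, 27L, 28L, 29L)
  cen <- c(mean(lay$x[loop_res]), mean(lay$y[loop_res]))
  rr <- sqrt((lay$x[loop_res] - cen[1L])^2 + (lay$y[loop_res] - cen[2L])^2)
  expect_lt(max(rr) - min(rr), 1e-6 + diff(range(rr)) * 0)
  expect_lt(diff(range(rr)), 1e-6)
})
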