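# Layout modification operations: the visual counterparts of the tree edit
# operations. Inserting/removing a base pair shifts the subtree below it
# along the stem axis; inserting/removing an unpaired residue redraws the
# local loop arc (or creates/collapses a bulge); multibranch loops are either
# "squeezed" locally or rebuilt on a fresh circle with every branch rotated
# into its new radial direction.
#
# All operations exist in two forms: an internal ld_* function mutating the
# working document, and an exported wrapper on rna_template objects for
# direct use and testing.

# Direction in which a stem grows away from the root, evaluated at node v
# (used to place children of v). Primary rule: vector from the grandparent
# pair midpoint to the parent pair midpoint; for a stem of length 1 the
# vector from the enclosing loop's centre to the pair midpoint is used.
ld_growth_dir <- function(ld, v) {
  p <- ld$parent[v]
  if (ld$kind[v] == "PAIR" && !is.na(p) && ld$kind[p] == "PAIR" &&
      length(ld$children[[p]]) == 1L) {
    d <- ld_mid(ld, v) - ld_mid(ld, p)
    if (vnorm(d) > 1e-9) return(vunit(d))
  }
  if (ld$kind[v] == "PAIR" && !is.na(p)) {
    # enclosing loop centre: parent residues plus sibling anchor residues
    ctx <- ld$node_res[[p]]
    for (s in ld$children[[p]]) if (s != v) ctx <- c(ctx, ld$node_res[[s]])
    if (length(ctx) > 0L) {
      c0 <- c(mean(ld$res_x[ctx]), mean(ld$res_y[ctx]))
      d <- ld_mid(ld, v) - c0
      if (vnorm(d) > 1e-9) return(vunit(d))
    }
  }
  if (ld$kind[v] == "PAIR") {
    ch <- ld$children[[v]]
    pc <- ch[vapply(ch, function(c) ld$kind[c] == "PAIR", logical(1))]
    if (length(pc) > 0L) {
      d <- ld_mid(ld, pc[1L]) - ld_mid(ld, v)
      if (vnorm(d) > 1e-9) return(vunit(d))
    }
    rs <- ld$node_res[[v]]
    return(vperp(vunit(ld_pt(ld, rs[2L]) - ld_pt(ld, rs[1L]))))
  }
  stop("no growth direction at node ", v)
}

# previous / next residue around a node's child slot, by traversal
ld_flanks <- function(ld, P, pos) {
  kids <- ld$children[[P]]
  prev_res <- if (pos > 1L) {
    k <- kids[pos - 1L]
    rs <- ld$node_res[[k]]
    rs[length(rs)]
  } else if (ld$kind[P] == "PAIR") ld$node_res[[P]][1L] else NA_integer_
  next_res <- if (pos <= length(kids)) {
    rs <- ld$node_res[[kids[pos]]]
    rs[1L]
  } else if (ld$kind[P] == "PAIR") ld$node_res[[P]][2L] else NA_integer_
  c(prev_res, next_res)
}

# ---- subtree shift ----------------------------------------------------------

ld_shift_subtree <- function(ld, v, vec, include_self = TRUE) {
  ld_shift_res(ld, ld_span(ld, v, include_self), vec)
}

#' Shift a subtree rigidly
#'
#' Translates every residue of the subtree rooted at `node` by `vector`;
#' all other residues are untouched. Moved residues are flagged `"shifted"`
#' (a zero vector moves nothing and sets no flags).
#'
#' @param doc An [template_document()].
#' @param node Tree node id (see [tree_nodes()]).
#' @param vector Numeric length-2 displacement.
#' @return The updated `rna_template`.
#' @export
shift_subtree <- function(doc, node, vector) {
  ld <- ld_new(doc)
  ld_check_node(ld, node)
  ld_shift_subtree(ld, node, vector)
  ld_export(ld)
}

# ---- loop run respacing -----------------------------------------------------

# Re-space the maximal leaf run containing leaf node `v` (a child of P) on a
# circular arc between its flanking anchors. `fresh` residues keep their
# "inserted" status; old members that move are flagged "shifted".
ld_respace_run <- function(ld, P, v) {
  kids <- ld$children[[P]]
  pos <- match(v, kids)
  lo <- pos; hi <- pos
  while (lo > 1L && ld$kind[kids[lo - 1L]] == "LEAF") lo <- lo - 1L
  while (hi < length(kids) && ld$kind[kids[hi + 1L]] == "LEAF") hi <- hi + 1L
  run <- kids[lo:hi]
  run_res <- vapply(run, function(w) ld$node_res[[w]][1L], integer(1))
  fl <- ld_flanks(ld, P, lo)
  a_res <- fl[1L]
  fl2 <- ld_flanks(ld, P, hi + 1L)
  b_res <- fl2[2L]
  if (is.na(a_res) || is.na(b_res)) return(invisible(ld))   # top level: handled elsewhere
  a <- ld_pt(ld, a_res); b <- ld_pt(ld, b_res)
  old <- run_res[ld$res_status[run_res] != "inserted"]
  side <- NULL
  if (length(old) > 0L) {
    cen <- c(mean(ld$res_x[old]), mean(ld$res_y[old]))
    u <- vunit(b - a)
    off <- (cen - a) - sum((cen - a) * u) * u
    if (vnorm(off) > 1e-9) side <- off
  }
  if (is.null(side)) {
    # no usable old members: open toward the loop growth direction
    side <- tryCatch(ld_growth_dir(ld, P), error = function(e) vperp(vunit(b - a)))
  }
  pts <- distribute_on_circle(a, b, length(run_res), side, ld$geom$backbone_step)
  for (k in seq_along(run_res)) ld_move_res(ld, run_res[k], pts[k, ])
  invisible(ld)
}

# ---- pair insertion ---------------------------------------------------------

# Insert a PAIR node under P at child position pos, adopting `adopt_n`
# consecutive children starting there. Stem case: the new pair is placed one
# pair_step beyond the parent midpoint along the growth direction and the
# adopted subtree is shifted by the same amount.
ld_insert_pair <- function(ld, P, pos, adopt_n, letters = c("G", "C")) {
  stopifnot(ld$kind[P] == "PAIR")
  g <- ld$geom
  kids <- ld$children[[P]]
  adopt <- if (adopt_n > 0L) kids[pos:(pos + adopt_n - 1L)] else integer(0)
  if (adopt_n > 0L || length(kids) == 0L) {
    # stem-style insertion: anything the new pair encloses moves one
    # pair_step deeper along the stem axis
    d <- ld_growth_dir(ld, P)
    pm <- ld_mid(ld, P)
    new_mid <- pm + g$pair_step * d
    perp <- vperp(d)
    prs <- ld$node_res[[P]]
    s <- sign(sum((ld_pt(ld, prs[1L]) - pm) * perp))
    if (s == 0) s <- 1
    p1 <- new_mid + s * (g$bond_length / 2) * perp
    p2 <- new_mid - s * (g$bond_length / 2) * perp
    for (c in adopt) ld_shift_subtree(ld, c, g$pair_step * d)
  } else {
    # new branch inside a loop: bond placed on the local arc chord,
    # branch direction handled radially when children arrive
    fl <- ld_flanks(ld, P, pos)
    fl2 <- ld_flanks(ld, P, pos + adopt_n)
    a <- ld_pt(ld, fl[1L]); b <- ld_pt(ld, fl2[2L])
    mid <- (a + b) / 2
    t_hat <- if (vnorm(b - a) > 1e-9) vunit(b - a) else vperp(ld_growth_dir(ld, P))
    p1 <- mid - (g$bond_length / 2) * t_hat
    p2 <- mid + (g$bond_length / 2) * t_hat
  }
  r1 <- ld_add_res(ld, letters[1L], p1)
  r2 <- ld_add_res(ld, letters[2L], p2)
  ld_add_node(ld, "PAIR", paste0(letters[1L], letters[2L]), c(r1, r2), P, pos, adopt)
}

#' Insert a base pair into a stem
#'
#' Places a new pair one `pair_step` beyond the parent pair along the stem
#' growth direction (given by the parent and grandparent midpoints), with its
#' residues `bond_length` apart perpendicular to that direction, and shifts
#' the adopted descendant subtree by the same `pair_step` (Fig.-3a-style
#' operation). Insertion directly under the artificial root is handled by
#' [insert_pair_top_level()].
#'
#' @param doc An [template_document()].
#' @param parent Tree node id of the pair under which to insert.
#' @param pos Child position (1-based) at which the new pair is placed.
#' @param adopt Number of consecutive existing children (starting at `pos`)
#'   the new pair takes over as its own children.
#' @param letters Two residue letters for the new pair.
#' @return The updated `rna_template`.
#' @export
insert_pair_node <- function(doc, parent, pos = 1L, adopt = 1L,
                             letters = c("G", "C")) {
  ld <- ld_new(doc)
  ld_check_node(ld, parent)
  if (ld$kind[parent] == "ROOT") {
    stop("insertion at the top level is handled by insert_pair_top_level()")
  }
  ld_insert_pair(ld, parent, pos, adopt, letters)
  ld_export(ld)
}

# ---- leaf insertion ---------------------------------------------------------

# Insert a LEAF under P at position pos (P not ROOT, not multibranch).
ld_insert_leaf <- function(ld, P, pos, letter = "A") {
  stopifnot(ld$kind[P] == "PAIR")
  g <- ld$geom
  kids <- ld$children[[P]]
  near_leaf <- (pos > 1L && ld$kind[kids[pos - 1L]] == "LEAF") ||
    (pos <= length(kids) && ld$kind[kids[pos]] == "LEAF")
  bulge_new <- !near_leaf && length(kids) >= 1L &&
    all(vapply(kids, function(c) ld$kind[c] == "PAIR", logical(1)))
  Cn <- if (length(kids) > 0L) kids[vapply(kids, function(c) ld$kind[c] == "PAIR", logical(1))] else integer(0)
  if (bulge_new) {
    # new bulge between stacked pairs: make room by shifting the sibling
    # (stem continuation) subtree one backbone_step along the stem axis
    d <- ld_growth_dir(ld, P)
    ld_shift_subtree(ld, Cn[1L], g$backbone_step * d)
  }
  fl <- ld_flanks(ld, P, pos)          # flanks of the slot, before insertion
  a <- ld_pt(ld, fl[1L]); b <- ld_pt(ld, fl[2L])
  r <- ld_add_res(ld, letter, (a + b) / 2)
  v <- ld_add_node(ld, "LEAF", letter, r, P, pos)
  if (bulge_new) {
    # bulge side: away from the partner strand
    kids2 <- ld$children[[P]]
    five_p <- match(v, kids2) < match(Cn[1L], kids2)
    other <- if (five_p) c(ld$node_res[[P]][2L], ld$node_res[[Cn[1L]]][2L])
             else c(ld$node_res[[P]][1L], ld$node_res[[Cn[1L]]][1L])
    side <- (a + b) / 2 - c(mean(ld$res_x[other]), mean(ld$res_y[other]))
    if (vnorm(side) < 1e-9) side <- vperp(vunit(b - a))
    pt <- distribute_on_circle(a, b, 1L, side, g$backbone_step)
    ld$res_x[r] <- pt[1L, 1L]; ld$res_y[r] <- pt[1L, 2L]
  } else {
    ld_respace_run(ld, P, v)
  }
  v
}

#' Insert an unpaired residue into an existing loop
#'
#' All unpaired residues of the local loop run, plus the new one, are
#' redistributed on a circular arc between the flanking paired anchors
#' (which do not move); repositioned residues are flagged `"shifted"`, the
#' new one `"inserted"`. Multibranch loops are handled by
#' [multibranch_update()].
#'
#' @param doc An [template_document()].
#' @param parent Tree node id of the loop-closing pair.
#' @param pos Child position at which the new leaf is placed.
#' @param letter Residue letter.
#' @return The updated `rna_template`.
#' @export
insert_leaf_into_loop <- function(doc, parent, pos = 1L, letter = "A") {
  ld <- ld_new(doc)
  ld_check_node(ld, parent)
  if (ld$kind[parent] != "PAIR") stop("parent must be a PAIR node")
  if (ld_branchiness(ld, parent) >= 2L) {
    stop("parent is a multibranch loop; use multibranch_update()")
  }
  ld_insert_leaf(ld, parent, pos, letter)
  ld_export(ld)
}

#' Insert an unpaired residue into a stem, forming a new bulge
#'
#' The sibling subtree (the stem continuation) is shifted one
#' `backbone_step` along the stem axis to make room and the new residue is
#' placed on the bulge side of the strand via [distribute_on_circle()]
#' (Fig.-3b-style operation).
#'
#' @inheritParams insert_leaf_into_loop
#' @return The updated `rna_template`.
#' @export
insert_leaf_new_bulge <- function(doc, parent, pos = 1L, letter = "A") {
  insert_leaf_into_loop(doc, parent, pos, letter)
}

# ---- deletion ---------------------------------------------------------------

ld_delete_pair <- function(ld, v) {
  g <- ld$geom
  p <- ld$parent[v]
  d <- NULL
  if (!is.na(p) && ld$kind[p] == "PAIR") {
    dd <- ld_mid(ld, v) - ld_mid(ld, p)
    if (vnorm(dd) > 1e-9) d <- vunit(dd)
  }
  if (is.null(d)) {
    ch <- ld$children[[v]]
    pc <- ch[vapply(ch, function(c) ld$kind[c] == "PAIR", logical(1))]
    if (length(pc) > 0L) {
      dd <- ld_mid(ld, pc[1L]) - ld_mid(ld, v)
      if (vnorm(dd) > 1e-9) d <- vunit(dd)
    }
  }
  if (!is.null(d)) {
    for (c in ld$children[[v]]) ld_shift_subtree(ld, c, -g$pair_step * d)
  }
  ld_drop_node(ld, v)
}

ld_delete_leaf <- function(ld, v) {
  g <- ld$geom
  P <- ld$parent[v]
  kids <- ld$children[[P]]
  pos <- match(v, kids)
  rest <- kids[-pos]
  sole_leaf <- ld$kind[P] == "PAIR" && length(rest) == 1L &&
    ld$kind[rest[1L]] == "PAIR" &&
    !any(vapply(rest, function(c) ld$kind[c] == "LEAF", logical(1)))
  # a neighbouring leaf in the same run, to re-space after removal
  nb <- NULL
  if (pos > 1L && ld$kind[kids[pos - 1L]] == "LEAF") nb <- kids[pos - 1L]
  if (is.null(nb) && pos < length(kids) && ld$kind[kids[pos + 1L]] == "LEAF") {
    nb <- kids[pos + 1L]
  }
  ld_drop_node(ld, v)
  if (sole_leaf) {
    # bulge collapse: pull the sibling stem back onto the axis
    d <- ld_growth_dir(ld, P)
    ld_shift_subtree(ld, rest[1L], -g$backbone_step * d)
  } else if (!is.null(nb)) {
    ld_respace_run(ld, P, nb)
  }
  invisible(ld)
}

#' Delete a node (pair or unpaired residue) from the layout
#'
#' Exact inverse geometry of the corresponding insertion: removing a stem
#' pair shifts the descendants back by `pair_step`; removing a loop residue
#' re-spaces the remaining run on a smaller arc; removing the sole residue of
#' a bulge collapses it and pulls the sibling stem back onto the axis.
#'
#' @param doc An [template_document()].
#' @param node Tree node id to remove.
#' @return The updated `rna_template`.
#' @export
delete_node <- function(doc, node) {
  ld <- ld_new(doc)
  ld_check_node(ld, node)
  if (ld$kind[node] == "ROOT") stop("cannot delete the root")
  if (ld$kind[node] == "PAIR") {
    ld_delete_pair(ld, node)
  } else {
    P <- ld$parent[node]
    if (ld$kind[P] == "ROOT") {
      ld_drop_node(ld, node)
    } else {
      ld_delete_leaf(ld, node)
    }
  }
  ld_export(ld)
}

# ---- multibranch loops ------------------------------------------------------

# Ring of residues around a loop node (5'->3'), with chord lengths between
# consecutive ring members. For a PAIR loop the ring starts at its opening
# residue and the closing chord (j -> i) is the bond; for the ROOT "exterior
# loop" the closure is a fictitious backbone_step.
ld_loop_ring <- function(ld, loop) {
  g <- ld$geom
  res <- integer(0); pairof <- integer(0)   # node owning each ring residue
  if (ld$kind[loop] == "PAIR") {
    res <- ld$node_res[[loop]][1L]; pairof <- loop
  }
  for (c in ld$children[[loop]]) {
    rs <- ld$node_res[[c]]
    res <- c(res, rs)
    pairof <- c(pairof, rep(c, length(rs)))
  }
  if (ld$kind[loop] == "PAIR") {
    res <- c(res, ld$node_res[[loop]][2L]); pairof <- c(pairof, loop)
  }
  K <- length(res)
  chords <- numeric(K)
  for (k in seq_len(K)) {
    nxt <- if (k < K) k + 1L else 1L
    chords[k] <- if (pairof[k] == pairof[nxt] && ld$kind[pairof[k]] == "PAIR") {
      g$bond_length
    } else {
      g$backbone_step
    }
  }
  list(res = res, pairof = pairof, chords = chords)
}

# Rebuild a whole loop on a fresh circle: all unpaired residues and branch
# anchor pairs are placed with Algorithm-1-style spacing, then every branch
# subtree is rigidly rotated+translated so its stem axis is radial at its
# new anchor; the transform is applied to every descendant.
ld_rebuild_loop <- function(ld, loop) {
  ring <- ld_loop_ring(ld, loop)
  K <- length(ring$res)
  if (K < 3L) return(invisible(ld))
  r <- loop_circle_radius(ring$chords)
  alpha <- 2 * asin(pmin(1, ring$chords / (2 * r)))
  alpha <- alpha * (2 * pi / sum(alpha))       # exact closure
  old_pos <- cbind(ld$res_x[ring$res], ld$res_y[ring$res])
  if (ld$kind[loop] == "PAIR") {
    # anchor at the closing pair: its residues stay put (up to the radius
    # constraint); centre sits on the inward side of the bond
    a <- old_pos[1L, ]; b <- old_pos[K, ]
    m <- (a + b) / 2
    cen_old <- colMeans(old_pos)
    inward <- cen_old - m
    if (vnorm(inward) < 1e-9) inward <- ld_growth_dir(ld, loop)
    d_ab <- vnorm(b - a)
    h <- sqrt(max(r^2 - (d_ab / 2)^2, 0))
    # centre sits on the perpendicular bisector of the anchor bond, on the
    # side of the loop interior
    bis <- vperp(vunit(b - a))
    if (sum(bis * inward) < 0) bis <- -bis
    centre <- m + bis * h
    phi0 <- atan2(a[2L] - centre[2L], a[1L] - centre[1L])
    phiK <- atan2(b[2L] - centre[2L], b[1L] - centre[1L])
    cum <- cumsum(alpha[-K])
    # sweep direction: end angle must land on the closing residue
    err <- function(s) {
      d <- (phi0 + s * cum[K - 1L]) - phiK
      abs(atan2(sin(d), cos(d)))
    }
    s <- if (err(1) <= err(-1)) 1 else -1
    phi <- c(phi0, phi0 + s * cum)
  } else {
    centre <- colMeans(old_pos)
    if (any(!is.finite(centre))) centre <- c(0, 0)
    phi0 <- atan2(old_pos[1L, 2L] - centre[2L], old_pos[1L, 1L] - centre[1L])
    if (!is.finite(phi0)) phi0 <- pi / 2
    # orientation: keep the current winding of the ring
    s <- 0
    for (k in seq_len(K - 1L)) {
      u <- old_pos[k, ] - centre; w <- old_pos[k + 1L, ] - centre
      s <- s + (u[1L] * w[2L] - u[2L] * w[1L])
    }
    s <- if (s < 0) -1 else 1
    phi <- phi0 + s * c(0, cumsum(alpha[-K]))
  }
  new_pos <- cbind(centre[1L] + r * cos(phi), centre[2L] + r * sin(phi))
  # move ring residues; branch subtrees move rigidly with their anchor pair
  done <- logical(length(ring$res))
  for (k in seq_len(K)) {
    if (done[k]) next
    v <- ring$pairof[k]
    if (v == loop) next                     # anchored closing pair stays
    if (ld$kind[v] == "LEAF") {
      ld_move_res(ld, ring$res[k], new_pos[k, ])
      done[k] <- TRUE
    } else {
      k2 <- which(ring$pairof == v)         # the two anchor residues
      o1 <- old_pos[k2[1L], ]; o2 <- old_pos[k2[2L], ]
      n1 <- new_pos[k2[1L], ]; n2 <- new_pos[k2[2L], ]
      theta <- atan2(n2[2L] - n1[2L], n2[1L] - n1[1L]) -
        atan2(o2[2L] - o1[2L], o2[1L] - o1[1L])
      rs <- ld_span(ld, v, include_self = TRUE)
      ld_rotate_res(ld, rs, o1, theta)
      ld_shift_res(ld, rs, n1 - o1)
      done[k2] <- TRUE
    }
  }
  invisible(ld)
}

# Squeeze-or-rebuild decision and application after leaf indels in a
# multibranch loop. `touch` holds leaf nodes (children of the loop) whose
# runs changed; `net` is |insertions - deletions| in this loop.
ld_multibranch_fix <- function(ld, loop, touch, net) {
  g <- ld$geom
  kids <- ld$children[[loop]]
  touch <- touch[touch %in% kids]
  feasible <- net <= 2L
  if (feasible) {
    for (v in touch) {
      pos <- match(v, kids)
      lo <- pos; hi <- pos
      while (lo > 1L && ld$kind[kids[lo - 1L]] == "LEAF") lo <- lo - 1L
      while (hi < length(kids) && ld$kind[kids[hi + 1L]] == "LEAF") hi <- hi + 1L
      fl <- ld_flanks(ld, loop, lo); fl2 <- ld_flanks(ld, loop, hi + 1L)
      if (is.na(fl[1L]) || is.na(fl2[2L])) next
      D <- vnorm(ld_pt(ld, fl2[2L]) - ld_pt(ld, fl[1L]))
      nrun <- hi - lo + 1L
      gap <- D / (nrun + 1L)
      if (gap < 0.5 * g$backbone_step || gap > 2 * g$backbone_step) {
        feasible <- FALSE
        break
      }
    }
  }
  if (feasible) {
    for (v in touch) if (v %in% ld$children[[loop]]) ld_respace_run(ld, loop, v)
  } else {
    ld_rebuild_loop(ld, loop)
  }
  invisible(ld)
}

#' Update a multibranch loop after residue insertions/deletions
#'
#' Applies the requested unpaired-residue insertions and deletions to a loop
#' with at least two emanating stems. When the change is small (net indel
#' count at most 2 and the local spacing between the fixed branch anchors
#' stays within 0.5-2 backbone steps) only the affected runs of unpaired
#' residues are re-spaced on their local arc and no branch moves; otherwise
#' the whole loop is rebuilt on a fresh circle and every branch is rigidly
#' rotated into its new radial direction, the rotation propagating to all
#' descendants.
#'
#' @param doc An [template_document()].
#' @param loop Tree node id of the loop-closing pair (or the root).
#' @param insert_pos Child positions (1-based, referring to the child list
#'   after earlier insertions in the same call) receiving new unpaired
#'   residues.
#' @param insert_letters Letters for the inserted residues (recycled).
#' @param delete Tree node ids of existing leaf children to remove.
#' @return The updated `rna_template`.
#' @export
multibranch_update <- function(doc, loop, insert_pos = integer(0),
                               insert_letters = "A", delete = integer(0)) {
  ld <- ld_new(doc)
  ld_check_node(ld, loop)
  if (ld_branchiness(ld, loop) < 2L) stop("node is not a multibranch loop")
  insert_letters <- rep_len(insert_letters, length(insert_pos))
  touch <- integer(0)
  ndel <- 0L
  for (v in delete) {
    stopifnot(ld$kind[v] == "LEAF", ld$parent[v] == loop)
    kids <- ld$children[[loop]]
    pos <- match(v, kids)
    if (pos > 1L && ld$kind[kids[pos - 1L]] == "LEAF") touch <- c(touch, kids[pos - 1L])
    if (pos < length(kids) && ld$kind[kids[pos + 1L]] == "LEAF") touch <- c(touch, kids[pos + 1L])
    ld_drop_node(ld, v)
    ndel <- ndel + 1L
  }
  for (k in seq_along(insert_pos)) {
    r <- ld_add_res(ld, insert_letters[k], ld_mid(ld, loop))
    v <- ld_add_node(ld, "LEAF", insert_letters[k], r, loop, insert_pos[k])
    fl <- ld_flanks(ld, loop, insert_pos[k])
    if (!is.na(fl[1L]) && !is.na(fl[2L])) {
      p <- (ld_pt(ld, fl[1L]) + ld_pt(ld, fl[2L])) / 2
      ld$res_x[r] <- p[1L]; ld$res_y[r] <- p[2L]
    }
    touch <- c(touch, v)
  }
  ld_multibranch_fix(ld, loop, unique(touch), abs(length(insert_pos) - ndel))
  ld_export(ld)
}
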