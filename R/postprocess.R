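# Postprocessing of generated layouts: stem straightening, top-level special
# cases, and clash (overlap) counting/minimization.

# ---- stems ------------------------------------------------------------------

# Maximal runs of stacked pairs: chains v1 -> v2 -> ... where each v_{t+1} is
# the sole child of v_t and both are PAIR nodes. Returns a list of id vectors
# (outermost pair first).
ld_stems <- function(ld) {
  alive <- which(ld$alive)
  stacked_child <- function(v) {
    ch <- ld$children[[v]]
    if (length(ch) == 1L && ld$kind[ch] == "PAIR") ch else NA_integer_
  }
  is_start <- function(v) {
    if (ld$kind[v] != "PAIR") return(FALSE)
    p <- ld$parent[v]
    !(!is.na(p) && ld$kind[p] == "PAIR" && identical(stacked_child(p), v))
  }
  out <- list()
  for (v in alive) {
    if (!is_start(v)) next
    chain <- v
    w <- stacked_child(v)
    while (!is.na(w)) {
      chain <- c(chain, w)
      w <- stacked_child(w)
    }
    out[[length(out) + 1L]] <- chain
  }
  out
}

ld_straighten <- function(ld) {
  g <- ld$geom
  for (chain in ld_stems(ld)) {
    k <- length(chain)
    if (k < 2L) next
    mids <- t(vapply(chain, function(v) ld_mid(ld, v), numeric(2)))
    axis <- mids[k, ] - mids[1L, ]
    if (vnorm(axis) < 1e-9) {
      rs <- ld$node_res[[chain[1L]]]
      axis <- vperp(ld_pt(ld, rs[2L]) - ld_pt(ld, rs[1L]))
      if (vnorm(axis) < 1e-9) next
    }
    dir <- vunit(axis)
    perp <- vperp(dir)
    rs1 <- ld$node_res[[chain[1L]]]
    s <- sign(sum((ld_pt(ld, rs1[1L]) - mids[1L, ]) * perp))
    if (s == 0) s <- 1
    old_last <- mids[k, ]
    for (t in seq_len(k)) {
      m <- mids[1L, ] + (t - 1L) * g$pair_step * dir
      rs <- ld$node_res[[chain[t]]]
      ld_move_res(ld, rs[1L], m + s * (g$bond_length / 2) * perp)
      ld_move_res(ld, rs[2L], m - s * (g$bond_length / 2) * perp)
    }
    new_last <- mids[1L, ] + (k - 1L) * g$pair_step * dir
    delta <- new_last - old_last
    if (vnorm(delta) > 1e-9) {
      for (c in ld$children[[chain[k]]]) ld_shift_subtree(ld, c, delta)
    }
  }
  invisible(ld)
}

#' Straighten stems onto their axis
#'
#' For every maximal run of stacked pairs, pair midpoints are projected onto
#' the line through the outermost and innermost pair midpoints, spaced
#' uniformly at `pair_step`, with each pair's residues placed symmetrically
#' at `bond_length` about the axis. The outermost (closest-to-root) pair
#' anchors the stem and does not translate; whatever hangs below the stem is
#' shifted rigidly along. Residues moved by more than 1e-9 are flagged
#' `"shifted"`. The operation is idempotent.
#'
#' @param doc An [template_document()].
#' @return The updated `rna_template`.
#' @export
straighten_stems <- function(doc) {
  ld <- ld_new(doc)
  ld_straighten(ld)
  ld_export(ld)
}

# ---- overlap counting -------------------------------------------------------

# Segment table of a document: backbone segments between consecutive
# residues and bond segments between paired residues (1-based indices).
doc_segments <- function(doc) {
  L <- doc$structure$length
  lay <- doc$layout
  segs <- data.frame(r1 = seq_len(L - 1L), r2 = seq_len(L - 1L) + 1L,
                     kind = "backbone")
  p <- doc$structure$pairs
  if (nrow(p) > 0L) {
    segs <- rbind(segs, data.frame(r1 = p[, 1L], r2 = p[, 2L], kind = "bond"))
  }
  segs$x1 <- lay$x[segs$r1]; segs$y1 <- lay$y[segs$r1]
  segs$x2 <- lay$x[segs$r2]; segs$y2 <- lay$y[segs$r2]
  segs
}

#' Count overlaps (segment crossings) in a layout
#'
#' An overlap is a proper crossing between two drawn segments - hydrogen
#' bonds between paired residues or sugar-phosphate backbone links between
#' consecutive residues - that share no residue. Touching at a shared
#' residue never counts; a collinear overlap of positive length counts as
#' one crossing. All segment pairs are tested (brute force).
#'
#' @param doc An [template_document()].
#' @return An object of class `overlap_report`: `count` and `crossings`, a
#'   data frame with one row per crossing segment pair (residue indices and
#'   segment kinds).
#' @export
count_overlaps <- function(doc) {
  segs <- doc_segments(doc)
  n <- nrow(segs)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- idx[, 1L]; b <- idx[, 2L]
  share <- segs$r1[a] == segs$r1[b] | segs$r1[a] == segs$r2[b] |
    segs$r2[a] == segs$r1[b] | segs$r2[a] == segs$r2[b]
  a <- a[!share]; b <- b[!share]
  hit <- segments_cross(segs$x1[a], segs$y1[a], segs$x2[a], segs$y2[a],
                        segs$x1[b], segs$y1[b], segs$x2[b], segs$y2[b])
  cross <- data.frame(kind1 = segs$kind[a[hit]], i1 = segs$r1[a[hit]],
                      j1 = segs$r2[a[hit]], kind2 = segs$kind[b[hit]],
                      i2 = segs$r1[b[hit]], j2 = segs$r2[b[hit]])
  structure(list(count = nrow(cross), crossings = cross),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:", x$count, "crossing segment pairs\n")
  invisible(x)
}

# ---- clash resolution -------------------------------------------------------

DEFAULT_ROTATIONS <- c(-60, -45, -30, -20, -15, -10, -5, 5, 10, 15, 20, 30, 45, 60) * pi / 180

# deepest PAIR node whose span contains residue index r (1-based layout index)
doc_enclosing_pair <- function(doc, r) {
  tr <- doc$tree
  best <- NA_integer_; best_span <- Inf
  for (v in seq_len(tr$n)) {
    if (tr$kind[v] != "PAIR") next
    if (tr$i[v] <= r && r <= tr$j[v]) {
      span <- tr$j[v] - tr$i[v]
      if (span < best_span) { best <- v; best_span <- span }
    }
  }
  best
}

#' Minimize clashes by subtree rotation
#'
#' Every minimal pair-rooted subtree containing a clashing residue is tried,
#' outermost first, with a fixed candidate set of rigid rotations about its
#' anchor pair midpoint (+-5, 10, 15, 20, 30, 45, 60 degrees); the rotation
#' giving the lowest global overlap count is kept. The global count never
#' increases; subtrees nested inside an already-rotated subtree are skipped
#' in the same pass.
#'
#' @param doc An [template_document()].
#' @param rotations Candidate rotation angles in radians.
#' @return The updated `rna_template`.
#' @export
resolve_clashes <- function(doc, rotations = DEFAULT_ROTATIONS) {
  rep0 <- count_overlaps(doc)
  if (rep0$count == 0L) return(doc)
  clash_res <- unique(c(rep0$crossings$i1, rep0$crossings$j1,
                        rep0$crossings$i2, rep0$crossings$j2))
  cand <- unique(stats::na.omit(vapply(clash_res, function(r)
    doc_enclosing_pair(doc, r), integer(1))))
  if (length(cand) == 0L) return(doc)
  nd <- tree_nodes(doc)
  cand <- cand[order(nd$depth[cand])]
  rotated_spans <- list()
  best_doc <- doc
  best_count <- rep0$count
  for (v in cand) {
    iv <- c(best_doc$tree$i[v], best_doc$tree$j[v])
    nested <- any(vapply(rotated_spans, function(sp)
      iv[1L] >= sp[1L] && iv[2L] <= sp[2L], logical(1)))
    if (nested) next
    improved <- FALSE
    for (th in rotations) {
      ld <- ld_new(best_doc)
      anchor <- ld_mid(ld, v)
      ld_rotate_res(ld, ld_span(ld, v, include_self = TRUE), anchor, th)
      trial <- ld_export(ld)
      ct <- count_overlaps(trial)$count
      if (ct < best_count) {
        best_count <- ct
        best_doc <- trial
        improved <- TRUE
      }
      if (best_count == 0L) break
    }
    if (improved) rotated_spans[[length(rotated_spans) + 1L]] <- iv
    if (best_count == 0L) break
  }
  best_doc
}

# ---- top level --------------------------------------------------------------

# `dirty = NULL` re-spaces every out-of-band gap; a vector of node ids
# limits the pass to gaps adjacent to those elements (the transform pipeline
# normalizes only around actual top-level edits, interfering with inherited
# template spacing as little as possible).
ld_normalize_top <- function(ld, dirty = NULL) {
  g <- ld$geom
  kids <- ld$children[[ld$root]]
  if (length(kids) < 2L) return(invisible(ld))
  acc <- c(0, 0)
  prev_dir <- c(1, 0)
  for (k in 2L:length(kids)) {
    span <- ld_span(ld, kids[k], include_self = TRUE)
    if (vnorm(acc) > 1e-12) ld_shift_res(ld, span, acc)
    eligible <- is.null(dirty) || kids[k - 1L] %in% dirty || kids[k] %in% dirty
    u_res <- ld$node_res[[kids[k - 1L]]]
    u <- ld_pt(ld, u_res[length(u_res)])
    w_res <- ld$node_res[[kids[k]]][1L]
    w <- ld_pt(ld, w_res)
    gap <- vnorm(w - u)
    if (!eligible || (gap >= 0.5 * g$backbone_step && gap <= 2 * g$backbone_step)) {
      if (gap > 1e-9) prev_dir <- vunit(w - u)
      next
    }
    dir <- if (gap > 1e-9) vunit(w - u) else prev_dir
    delta <- (u + g$backbone_step * dir) - w
    ld_shift_res(ld, span, delta)
    acc <- acc + delta
    prev_dir <- dir
  }
  invisible(ld)
}

#' Normalize top-level spacing
#'
#' The children of the artificial root have no positioned parent, so indels
#' among them leave gaps or pile-ups that no loop operation repairs. This
#' pass walks the top-level chain 5' to 3' and, wherever the backbone gap
#' between consecutive top-level elements falls outside 0.5-2 backbone
#' steps, rigidly translates the downstream element (and, cumulatively,
#' everything after it) so the gap becomes one `backbone_step`.
#'
#' @param doc An [template_document()].
#' @return The updated `rna_template`.
#' @export
normalize_top_level <- function(doc) {
  ld <- ld_new(doc)
  ld_normalize_top(ld)
  ld_export(ld)
}

# chain direction around top-level child slot `pos`
ld_top_chain_dir <- function(ld, pos) {
  kids <- ld$children[[ld$root]]
  u <- if (pos > 1L) {
    rs <- ld$node_res[[kids[pos - 1L]]]
    ld_pt(ld, rs[length(rs)])
  } else NULL
  w <- if (pos <= length(kids)) ld_pt(ld, ld$node_res[[kids[pos]]][1L]) else NULL
  if (!is.null(u) && !is.null(w) && vnorm(w - u) > 1e-9) return(vunit(w - u))
  if (is.null(u) && !is.null(w) && pos + 1L <= length(kids)) {
    w2 <- ld_pt(ld, ld$node_res[[kids[pos + 1L]]][1L])
    if (vnorm(w2 - w) > 1e-9) return(vunit(w2 - w))
  }
  if (!is.null(u) && is.null(w) && pos >= 3L) {
    u2 <- ld_pt(ld, ld$node_res[[kids[pos - 2L]]][1L])
    if (vnorm(u - u2) > 1e-9) return(vunit(u - u2))
  }
  c(1, 0)
}

ld_insert_leaf_top <- function(ld, pos, letter = "A") {
  g <- ld$geom
  kids <- ld$children[[ld$root]]
  dir <- ld_top_chain_dir(ld, pos)
  p <- if (pos > 1L) {
    rs <- ld$node_res[[kids[pos - 1L]]]
    ld_pt(ld, rs[length(rs)]) + g$backbone_step * dir
  } else if (length(kids) > 0L) {
    ld_pt(ld, ld$node_res[[kids[1L]]][1L]) - g$backbone_step * dir
  } else {
    c(0, 0)
  }
  r <- ld_add_res(ld, letter, p)
  v <- ld_add_node(ld, "LEAF", letter, r, ld$root, pos)
  # make room: downstream top-level elements move one backbone_step on
  if (pos <= length(kids)) {
    for (k in ld$children[[ld$root]][(pos + 1L):(length(kids) + 1L)]) {
      ld_shift_subtree(ld, k, g$backbone_step * dir)
    }
  }
  v
}

ld_insert_pair_top <- function(ld, pos, adopt_n, letters = c("G", "C")) {
  g <- ld$geom
  kids <- ld$children[[ld$root]]
  adopt <- if (adopt_n > 0L) kids[pos:(pos + adopt_n - 1L)] else integer(0)
  stem_child <- adopt[vapply(adopt, function(c) ld$kind[c] == "PAIR", logical(1))]
  if (length(stem_child) >= 1L) {
    # case 1: extending an existing top-level stem. The new pair takes the
    # template stem-start position; the old stem shifts one pair_step inward.
    C <- stem_child[1L]
    crs <- ld$node_res[[C]]
    p1 <- ld_pt(ld, crs[1L]); p2 <- ld_pt(ld, crs[2L])
    inner <- ld_span(ld, C, include_self = FALSE)
    d <- NULL
    if (length(inner) > 0L) {
      cen <- c(mean(ld$res_x[inner]), mean(ld$res_y[inner]))
      dd <- cen - ld_mid(ld, C)
      if (vnorm(dd) > 1e-9) d <- vunit(dd)
    }
    if (is.null(d)) d <- vperp(vunit(p2 - p1))
    for (c in adopt) ld_shift_subtree(ld, c, g$pair_step * d)
  } else {
    # case 2: a brand-new branch. Bond along the chain, branch axis
    # perpendicular; downstream siblings move over by bond_length +
    # backbone_step.
    dir <- ld_top_chain_dir(ld, pos)
    base <- if (pos > 1L) {
      rs <- ld$node_res[[kids[pos - 1L]]]
      ld_pt(ld, rs[length(rs)]) + g$backbone_step * dir
    } else if (length(kids) > 0L) {
      ld_pt(ld, ld$node_res[[kids[1L]]][1L]) - (g$backbone_step + g$bond_length) * dir
    } else {
      c(0, 0)
    }
    p1 <- base
    p2 <- base + g$bond_length * dir
    if (pos <= length(kids)) {
      for (k in kids[pos:length(kids)]) {
        if (k %in% adopt) next
        ld_shift_subtree(ld, k, (g$bond_length + g$backbone_step) * dir)
      }
    }
  }
  r1 <- ld_add_res(ld, letters[1L], p1)
  r2 <- ld_add_res(ld, letters[2L], p2)
  ld_add_node(ld, "PAIR", paste0(letters[1L], letters[2L]), c(r1, r2),
              ld$root, pos, adopt)
}

#' Insert a base pair at the top level
#'
#' Children of the artificial root have no positioned ancestor, so the usual
#' parent/grandparent direction rule cannot apply. Two cases: when the new
#' pair extends an existing top-level stem (it adopts that stem), it takes
#' over the template stem-start coordinates and the old stem shifts one
#' `pair_step` inward; when it roots a brand-new branch, the branch is
#' oriented perpendicular to the local top-level chain (bond along the
#' chain) and downstream siblings shift by `bond_length + backbone_step`.
#'
#' @param doc An [template_document()].
#' @param pos Child position under the root (1-based).
#' @param adopt Number of consecutive existing top-level elements the new
#'   pair encloses.
#' @param letters Two residue letters.
#' @return The updated `rna_template`.
#' @export
insert_pair_top_level <- function(doc, pos = 1L, adopt = 0L,
                                  letters = c("G", "C")) {
  ld <- ld_new(doc)
  ld_insert_pair_top(ld, pos, adopt, letters)
  ld_export(ld)
}
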