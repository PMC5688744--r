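# Full pipeline: tree edit mapping -> ordered geometric replay on the
# template layout -> postprocessing. Deletions are applied first in
# postorder (children before parents), then insertions in target preorder
# (parents before children), then letter updates; geometric fixes for
# multibranch loops are grouped per loop and applied once after the
# structural phase.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transform a template layout into a target layout
#'
#' Computes (or accepts) the minimal tree edit mapping between the template
#' and target structures and replays it on the template drawing: each delete
#' removes a base (pair) and closes the freed space, each insert makes room
#' and places the new base (pair), updates relabel in place. Multibranch
#' loops are squeezed or rebuilt as needed. Unless the script is purely
#' relabeling, the result is then postprocessed (stem straightening,
#' top-level normalization, clash-rotation minimization); a target identical
#' in structure to the template returns the template coordinates untouched.
#'
#' @param template An [template_document()].
#' @param target_ss Target [rna_structure()] (pseudoknots are removed
#'   internally if present).
#' @param costs [cost_scheme()] for the tree edit distance.
#' @param map Optional precomputed result of [read_edit_script()]; when
#'   given, the mapping is reused instead of recomputing [ted()].
#' @param postprocess Run the postprocessing phase (default `TRUE`).
#' @return An `rna_template` for the target structure whose layout carries
#'   per-residue status flags (`unchanged`, `shifted`, `relabeled`,
#'   `inserted`). The edit script is attached as attribute `"script"`.
#' @export
transform_layout <- function(template, target_ss, costs = cost_scheme(),
                             map = NULL, postprocess = TRUE) {
  stopifnot(inherits(template, "rna_template"))
  if (has_crossing(target_ss)) target_ss <- remove_pseudoknots(target_ss)
  tgt_tree <- build_tree(target_ss)
  script <- if (is.null(map)) {
    ted(template$tree, tgt_tree, costs)
  } else {
    script_from_mapfile(map, template$tree, tgt_tree, costs)
  }
  ops <- script$ops
  # kind-changing updates have no pure-relabel geometry: replay them as
  # delete + insert (the tree mapping itself is unchanged)
  upd <- ops[ops$op == "UPD", ]
  kind_change <- upd[template$tree$kind[upd$tpl] != tgt_tree$kind[upd$tgt], ]
  dels <- sort(c(ops$tpl[ops$op == "DEL"], kind_change$tpl))
  ins_set <- c(ops$tgt[ops$op == "INS"], kind_change$tgt)
  ins <- intersect(tree_preorder(tgt_tree), ins_set)
  structural <- length(dels) > 0L || length(ins) > 0L

  ld <- ld_new(template)
  img <- integer(tgt_tree$n)              # target node -> working node
  keep <- !(script$mapping[, 1L] %in% dels)
  img[script$mapping[keep, 2L]] <- script$mapping[keep, 1L]
  dirty <- new.env(parent = emptyenv())   # loop node -> list(touch, nins, ndel)
  mark_dirty <- function(loop, touch, is_ins) {
    key <- as.character(loop)
    e <- dirty[[key]] %||% list(touch = integer(0), nins = 0L, ndel = 0L)
    e$touch <- unique(c(e$touch, touch))
    if (is_ins) e$nins <- e$nins + 1L else e$ndel <- e$ndel + 1L
    dirty[[key]] <- e
  }

  # --- deletions (postorder) ---
  top_dirty <- integer(0)     # top-level elements flanking a deletion/insert
  note_top <- function(v) {
    kids <- ld$children[[ld$root]]
    pos <- match(v, kids)
    if (!is.na(pos)) {
      top_dirty <<- c(top_dirty,
                      if (pos < length(kids)) kids[pos + 1L],
                      if (pos > 1L) kids[pos - 1L])
    }
  }
  for (v in dels) {
    if (v == ld$root) stop("edit script integrity error: root deletion")
    if (ld$parent[v] == ld$root) note_top(v)
    if (ld$kind[v] == "PAIR") {
      ld_delete_pair(ld, v)
    } else {
      P <- ld$parent[v]
      if (ld$kind[P] == "ROOT") {
        ld_drop_node(ld, v)
      } else if (ld_branchiness(ld, P) >= 2L) {
        kids <- ld$children[[P]]
        pos <- match(v, kids)
        nb <- c(if (pos > 1L && ld$kind[kids[pos - 1L]] == "LEAF") kids[pos - 1L],
                if (pos < length(kids) && ld$kind[kids[pos + 1L]] == "LEAF") kids[pos + 1L])
        ld_drop_node(ld, v)
        mark_dirty(P, nb, is_ins = FALSE)
      } else {
        ld_delete_leaf(ld, v)
      }
    }
  }

  # --- insertions (target preorder) ---
  rev_img <- function(w) {
    hit <- which(img == w)
    if (length(hit) != 1L) stop("edit script integrity error: unmapped working node")
    hit
  }
  tgt_desc <- function(anc, v) {
    while (!is.na(tgt_tree$parent[v])) {
      v <- tgt_tree$parent[v]
      if (v == anc) return(TRUE)
    }
    FALSE
  }
  for (v in ins) {
    pt_ <- tgt_tree$parent[v]
    P <- img[pt_]
    if (P == 0L) stop("edit script integrity error: unplaced parent")
    kids <- ld$children[[P]]
    corr <- vapply(kids, rev_img, integer(1))
    adopt <- vapply(corr, function(w) tgt_desc(v, w), logical(1))
    if (any(adopt)) {
      rng <- range(which(adopt))
      if (!all(adopt[rng[1L]:rng[2L]])) {
        stop("edit script integrity error: non-consecutive adoption")
      }
      pos <- rng[1L]
    } else {
      pos <- sum(vapply(corr, function(w) w < v && !tgt_desc(v, w), logical(1))) + 1L
    }
    n_adopt <- sum(adopt)
    if (tgt_tree$kind[v] == "PAIR") {
      lt <- c(substr(tgt_tree$letters[v], 1L, 1L), substr(tgt_tree$letters[v], 2L, 2L))
      if (ld$kind[P] == "ROOT") {
        w <- ld_insert_pair_top(ld, pos, n_adopt, lt)
      } else {
        w <- ld_insert_pair(ld, P, pos, n_adopt, lt)
        if (n_adopt == 0L && ld_branchiness(ld, P) >= 2L) {
          # a new branch changes the loop; let the multibranch pass decide
          mark_dirty(P, integer(0), is_ins = TRUE)
        }
      }
    } else {
      lt <- tgt_tree$letters[v]
      if (ld$kind[P] == "ROOT") {
        w <- ld_insert_leaf_top(ld, pos, lt)
      } else if (ld_branchiness(ld, P) >= 2L) {
        fl <- ld_flanks(ld, P, pos)    # before insertion: flanks of the slot
        p0 <- if (!anyNA(fl)) (ld_pt(ld, fl[1L]) + ld_pt(ld, fl[2L])) / 2
              else ld_mid(ld, P)
        r <- ld_add_res(ld, lt, p0)
        w <- ld_add_node(ld, "LEAF", lt, r, P, pos)
        mark_dirty(P, w, is_ins = TRUE)
      } else {
        w <- ld_insert_leaf(ld, P, pos, lt)
      }
    }
    img[v] <- w
  }

  # --- letter updates (relabels) ---
  for (r in which(ops$op == "UPD")) {
    a <- ops$tpl[r]; b <- ops$tgt[r]
    if (template$tree$kind[a] != tgt_tree$kind[b]) next   # replayed above
    if (template$tree$letters[a] == tgt_tree$letters[b]) next
    ld$letters[a] <- tgt_tree$letters[b]
    rs <- ld$node_res[[a]]
    new_l <- strsplit(tgt_tree$letters[b], "", fixed = TRUE)[[1L]]
    ld$res_letter[rs] <- new_l
    ld_set_status(ld, rs, "relabeled")
  }

  # --- grouped multibranch fixes ---
  for (key in ls(dirty)) {
    loop <- as.integer(key)
    if (!ld$alive[loop]) next
    e <- dirty[[key]]
    if (ld_branchiness(ld, loop) >= 2L) {
      ld_multibranch_fix(ld, loop, e$touch, abs(e$nins - e$ndel))
    } else if (ld$kind[loop] == "PAIR") {
      for (v in e$touch) {
        if (v %in% ld$children[[loop]]) ld_respace_run(ld, loop, v)
      }
    }
  }

  # --- postprocessing ---
  if (structural && postprocess) {
    ld_straighten(ld)
    ld_normalize_top(ld, dirty = top_dirty[ld$alive[top_dirty]])
    out <- ld_export(ld)
    out <- resolve_clashes(out)
  } else {
    out <- ld_export(ld)
  }
  if (!tree_isomorphic(out$tree, tgt_tree)) {
    stop("internal error: transformed tree does not match the target")
  }
  if (any(!is.finite(out$layout$x)) || any(!is.finite(out$layout$y))) {
    stop("internal error: non-finite coordinates in the result")
  }
  attr(out, "script") <- script
  out
}
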