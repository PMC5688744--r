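# Template documents: a secondary structure, its tree, and a 2D layout with
# per-residue status flags, kept mutually consistent.
#
# Internally the layout-modification operations run on a mutable "ldoc"
# (an environment holding node and residue tables with stable ids); the
# public rna_template object is an immutable snapshot.

STATUS_LEVELS <- c("unchanged", "shifted", "relabeled", "inserted")

default_geometry <- function(backbone_step = 8, pair_step = 8, bond_length = 8) {
  list(backbone_step = backbone_step, pair_step = pair_step,
       bond_length = bond_length)
}

#' Template document: structure + tree + layout
#'
#' Bundles a pseudoknot-free secondary structure, its ordered tree and a 2D
#' layout (one coordinate per residue, plus a status flag in
#' `unchanged`/`shifted`/`relabeled`/`inserted`).
#'
#' @param ss A pseudoknot-free [rna_structure()].
#' @param layout A data frame (or matrix) with columns `x`, `y` and one row
#'   per residue, optionally a `status` column.
#' @param backbone_step,pair_step,bond_length Geometry constants in layout
#'   units: distance between consecutive backbone residues, between stacked
#'   pairs along a stem, and between the two residues of a pair.
#' @return An object of class `rna_template` with elements `structure`,
#'   `tree`, `layout` (data frame `letter`, `x`, `y`, `partner`, `status`;
#'   `partner` is the 1-based paired index or `NA`) and `geom`.
#' @export
template_document <- function(ss, layout,
                              backbone_step = 8, pair_step = 8, bond_length = 8) {
  if (has_crossing(ss)) {
    stop("template structure has crossing pairs; run remove_pseudoknots() first")
  }
  layout <- as.data.frame(layout)
  if (nrow(layout) != ss$length) {
    stop("layout has ", nrow(layout), " rows for ", ss$length, " residues")
  }
  if (!all(c("x", "y") %in% names(layout))) stop("layout needs x and y columns")
  if (any(!is.finite(layout$x)) || any(!is.finite(layout$y))) {
    stop("layout contains non-finite coordinates")
  }
  status <- if ("status" %in% names(layout)) as.character(layout$status)
            else rep("unchanged", ss$length)
  if (!all(status %in% STATUS_LEVELS)) stop("unknown status value")
  partner <- rep(NA_integer_, ss$length)
  if (nrow(ss$pairs) > 0L) {
    partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  lay <- data.frame(letter = ss$sequence, x = as.numeric(layout$x),
                    y = as.numeric(layout$y), partner = partner,
                    status = status)
  structure(list(structure = ss, tree = build_tree(ss), layout = lay,
                 geom = default_geometry(backbone_step, pair_step, bond_length)),
            class = "rna_template")
}

#' @export
print.rna_template <- function(x, ...) {
  cat("rna_template: ", x$structure$length, " residues, ",
      nrow(x$structure$pairs), " pairs; status: ", sep = "")
  print(table(factor(x$layout$status, levels = STATUS_LEVELS)))
  invisible(x)
}

# ---- internal mutable document ---------------------------------------------

ld_new <- function(doc) {
  tree <- doc$tree
  ld <- new.env(parent = emptyenv())
  ld$kind <- tree$kind
  ld$letters <- tree$letters
  ld$parent <- tree$parent
  ld$children <- tree$children
  ld$root <- tree$root
  ld$alive <- rep(TRUE, tree$n)
  ld$node_res <- vector("list", tree$n)
  for (v in seq_len(tree$n)) {
    ld$node_res[[v]] <- switch(tree$kind[v],
                               PAIR = c(tree$i[v], tree$j[v]),
                               LEAF = tree$i[v],
                               integer(0))
  }
  ld$res_letter <- doc$layout$letter
  ld$res_x <- doc$layout$x
  ld$res_y <- doc$layout$y
  ld$res_status <- doc$layout$status
  ld$geom <- doc$geom
  ld
}

ld_pt <- function(ld, r) c(ld$res_x[r], ld$res_y[r])

ld_mid <- function(ld, v) {
  rs <- ld$node_res[[v]]
  c(mean(ld$res_x[rs]), mean(ld$res_y[rs]))
}

# residue ids of node v's subtree in 5'->3' order
ld_span <- function(ld, v, include_self = TRUE) {
  out <- integer(0)
  rec <- function(w, self) {
    rs <- ld$node_res[[w]]
    if (ld$kind[w] == "PAIR") {
      if (self) out[length(out) + 1L] <<- rs[1L]
      for (c in ld$children[[w]]) rec(c, TRUE)
      if (self) out[length(out) + 1L] <<- rs[2L]
    } else if (ld$kind[w] == "LEAF") {
      if (self) out[length(out) + 1L] <<- rs[1L]
    } else {
      for (c in ld$children[[w]]) rec(c, TRUE)
    }
  }
  rec(v, include_self)
  out
}

ld_traverse <- function(ld) ld_span(ld, ld$root)

ld_set_status <- function(ld, rs, status) {
  lvl <- match(status, STATUS_LEVELS)
  cur <- match(ld$res_status[rs], STATUS_LEVELS)
  up <- rs[cur < lvl]
  ld$res_status[up] <- status
  invisible(ld)
}

# rigid translation of a residue set; flags shifted when it actually moves
ld_shift_res <- function(ld, rs, vec, flag = TRUE) {
  if (length(rs) == 0L) return(invisible(ld))
  if (vnorm(vec) < 1e-12) return(invisible(ld))
  ld$res_x[rs] <- ld$res_x[rs] + vec[1L]
  ld$res_y[rs] <- ld$res_y[rs] + vec[2L]
  if (flag) ld_set_status(ld, rs, "shifted")
  invisible(ld)
}

# rigid rotation (and optional translation) about a point
ld_rotate_res <- function(ld, rs, centre, theta, translate = c(0, 0), flag = TRUE) {
  if (length(rs) == 0L) return(invisible(ld))
  x <- ld$res_x[rs] - centre[1L]; y <- ld$res_y[rs] - centre[2L]
  ld$res_x[rs] <- centre[1L] + cos(theta) * x - sin(theta) * y + translate[1L]
  ld$res_y[rs] <- centre[2L] + sin(theta) * x + cos(theta) * y + translate[2L]
  if (flag && (abs(theta) > 1e-12 || vnorm(translate) > 1e-12)) {
    ld_set_status(ld, rs, "shifted")
  }
  invisible(ld)
}

ld_move_res <- function(ld, r, p, flag = TRUE) {
  moved <- vnorm(c(ld$res_x[r] - p[1L], ld$res_y[r] - p[2L])) > 1e-9
  ld$res_x[r] <- p[1L]
  ld$res_y[r] <- p[2L]
  if (flag && moved) ld_set_status(ld, r, "shifted")
  invisible(ld)
}

# add a residue record, returns its id
ld_add_res <- function(ld, letter, p, status = "inserted") {
  r <- length(ld$res_letter) + 1L
  ld$res_letter[r] <- letter
  ld$res_x[r] <- p[1L]
  ld$res_y[r] <- p[2L]
  ld$res_status[r] <- status
  r
}

# add a node record under parent P at child position pos, returns node id
ld_add_node <- function(ld, kind, letters, res_ids, P, pos, adopt = integer(0)) {
  v <- length(ld$kind) + 1L
  ld$kind[v] <- kind
  ld$letters[v] <- letters
  ld$alive[v] <- TRUE
  ld$node_res[[v]] <- res_ids
  kids <- ld$children[[P]]
  if (length(adopt) > 0L) {
    stopifnot(all(diff(match(adopt, kids)) == 1L))
    kids <- setdiff(kids, adopt)
  }
  ld$children[[v]] <- adopt
  for (c in adopt) ld$parent[c] <- v
  ld$children[[P]] <- append(kids, v, after = pos - 1L)
  ld$parent[v] <- P
  v
}

# splice node v out of the tree (children take its place); residues of v are
# dropped from the document
ld_drop_node <- function(ld, v) {
  P <- ld$parent[v]
  kids <- ld$children[[v]]
  sib <- ld$children[[P]]
  pos <- match(v, sib)
  ld$children[[P]] <- append(sib[-pos], kids, after = pos - 1L)
  for (c in kids) ld$parent[c] <- P
  ld$alive[v] <- FALSE
  invisible(ld)
}

# number of non-leaf (PAIR) children
ld_branchiness <- function(ld, v) {
  sum(vapply(ld$children[[v]], function(c) ld$kind[c] == "PAIR", logical(1)))
}

# export the current state as an rna_template
ld_export <- function(ld) {
  ord <- ld_traverse(ld)
  L <- length(ord)
  res_of <- integer(length(ld$res_letter))
  res_of[ord] <- seq_len(L)
  pairs <- matrix(integer(0), ncol = 2L)
  for (v in which(ld$alive)) {
    if (ld$kind[v] == "PAIR") {
      rs <- ld$node_res[[v]]
      pairs <- rbind(pairs, c(res_of[rs[1L]], res_of[rs[2L]]))
    }
  }
  ss <- rna_structure(ld$res_letter[ord], pairs)
  lay <- data.frame(x = ld$res_x[ord], y = ld$res_y[ord],
                    status = ld$res_status[ord])
  doc <- template_document(ss, lay,
                           backbone_step = ld$geom$backbone_step,
                           pair_step = ld$geom$pair_step,
                           bond_length = ld$geom$bond_length)
  doc
}

# map a public tree node id (postorder in doc$tree) to the same id in a fresh
# ldoc (identical by construction)
ld_check_node <- function(ld, v) {
  if (v < 1L || v > length(ld$kind) || !ld$alive[v]) stop("unknown tree node ", v)
  v
}
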