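# Ordered tree edit distance between template and target trees.
#
# The distance and mapping are computed with the Zhang-Shasha keyroot
# decomposition dynamic program (O(m^2 n^2) worst-case time, O(mn) memory),
# with a deterministic backtrace that extracts a minimal valid mapping.
# A brute-force enumerator over all valid mappings serves as an independent
# oracle for small trees.

#' Edit cost scheme
#'
#' Default costs: insert = delete = 1; update is free between nodes of the
#' same kind (PAIR-PAIR or LEAF-LEAF) irrespective of nucleotide letters and
#' costs 1 between different kinds. Letter-only changes are therefore mapped
#' (and later color-coded as "relabeled") rather than re-inserted: the layout
#' machinery cares about shape, not sequence.
#'
#' @param insert,delete Non-negative scalar costs.
#' @param update Function `(kind_a, kind_b)` returning a non-negative cost;
#'   must be symmetric and zero on identical kinds.
#' @return A `cost_scheme` object.
#' @export
cost_scheme <- function(insert = 1, delete = 1,
                        update = function(kind_a, kind_b) ifelse(kind_a == kind_b, 0, 1)) {
  stopifnot(insert >= 0, delete >= 0)
  structure(list(insert = insert, delete = delete, update = update),
            class = "cost_scheme")
}

# Per-node cost vectors and the full update-cost matrix.
ted_costs <- function(t1, t2, costs) {
  del <- rep(costs$delete, t1$n)
  ins <- rep(costs$insert, t2$n)
  upd <- outer(t1$kind, t2$kind, costs$update)
  list(del = del, ins = ins, upd = upd)
}

# Keyroots: nodes whose leftmost leaf differs from their parent's (plus root).
zs_keyroots <- function(tree) {
  kr <- logical(tree$n)
  kr[tree$root] <- TRUE
  for (v in seq_len(tree$n)) {
    p <- tree$parent[v]
    if (!is.na(p) && tree$lml[v] != tree$lml[p]) kr[v] <- TRUE
  }
  which(kr)
}

# Forest-distance DP for one keyroot pair. Fills the treedist matrix `td`
# in place (environment trick) and returns the forest matrix for backtracing.
zs_forest <- function(t1, t2, k1, k2, cv, td) {
  l1 <- t1$lml; l2 <- t2$lml
  li <- l1[k1]; lj <- l2[k2]
  m <- k1 - li + 1L; n <- k2 - lj + 1L
  fd <- matrix(0, m + 1L, n + 1L)
  for (x in seq_len(m)) fd[x + 1L, 1L] <- fd[x, 1L] + cv$del[li + x - 1L]
  for (y in seq_len(n)) fd[1L, y + 1L] <- fd[1L, y] + cv$ins[lj + y - 1L]
  for (x in seq_len(m)) {
    vx <- li + x - 1L
    whole1 <- l1[vx] == li
    for (y in seq_len(n)) {
      vy <- lj + y - 1L
      dcost <- fd[x, y + 1L] + cv$del[vx]
      icost <- fd[x + 1L, y] + cv$ins[vy]
      if (whole1 && l2[vy] == lj) {
        mcost <- fd[x, y] + cv$upd[vx, vy]
        best <- min(dcost, icost, mcost)
      } else {
        mcost <- fd[l1[vx] - li + 1L, l2[vy] - lj + 1L] + td[vx, vy]
        best <- min(dcost, icost, mcost)
      }
      fd[x + 1L, y + 1L] <- best
    }
  }
  fd
}

# Backtrace one subtree pair, appending matched node pairs and queueing
# nested subtree pairs. Deterministic: match/diagonal is preferred over
# delete, delete over insert.
zs_backtrace <- function(t1, t2, k1, k2, cv, td, out) {
  eps <- 1e-9
  fd <- zs_forest(t1, t2, k1, k2, cv, td)
  l1 <- t1$lml; l2 <- t2$lml
  li <- l1[k1]; lj <- l2[k2]
  x <- k1 - li + 1L; y <- k2 - lj + 1L
  while (x > 0L || y > 0L) {
    vx <- li + x - 1L; vy <- lj + y - 1L
    if (x > 0L && y > 0L) {
      if (l1[vx] == li && l2[vy] == lj) {
        if (abs(fd[x + 1L, y + 1L] - (fd[x, y] + cv$upd[vx, vy])) < eps) {
          out$pairs[[length(out$pairs) + 1L]] <- c(vx, vy)
          x <- x - 1L; y <- y - 1L
          next
        }
      } else if (abs(fd[x + 1L, y + 1L] -
                     (fd[l1[vx] - li + 1L, l2[vy] - lj + 1L] + td[vx, vy])) < eps) {
        out$queue[[length(out$queue) + 1L]] <- c(vx, vy)
        x <- l1[vx] - li; y <- l2[vy] - lj
        next
      }
    }
    if (x > 0L && abs(fd[x + 1L, y + 1L] - (fd[x, y + 1L] + cv$del[vx])) < eps) {
      x <- x - 1L
    } else {
      y <- y - 1L
    }
  }
  invisible(NULL)
}

#' Tree edit distance with minimal edit script
#'
#' Computes the minimal-cost sequence of node insertions, deletions and
#' updates turning the template tree into the target tree, together with the
#' underlying valid mapping (a partial injection preserving ancestry and
#' left-to-right order). The Zhang-Shasha keyroot DP is used; the backtrace
#' prefers updates over delete+insert and maps leftmost template nodes first,
#' so the output is deterministic.
#'
#' @param template,target `rna_tree` objects (see [build_tree()]).
#' @param costs A [cost_scheme()].
#' @return An object of class `edit_script`: `distance`, `mapping` (two-column
#'   matrix of template/target node ids), and `ops`, a data frame of
#'   operations in application order (DELETEs in template postorder, INSERTs
#'   in target preorder, UPDATEs last) with columns `op`, `tpl`, `tgt`,
#'   `cost`.
#' @export
ted <- function(template, target, costs = cost_scheme()) {
  t1 <- template; t2 <- target
  cv <- ted_costs(t1, t2, costs)
  td <- matrix(NA_real_, t1$n, t2$n)
  kr1 <- zs_keyroots(t1); kr2 <- zs_keyroots(t2)
  for (k1 in kr1) for (k2 in kr2) {
    fd <- zs_forest(t1, t2, k1, k2, cv, td)
    # treedist entries for whole-subtree pairs sit on the forest matrix rim
    l1 <- t1$lml; l2 <- t2$lml
    li <- l1[k1]; lj <- l2[k2]
    for (x in seq_len(k1 - li + 1L)) {
      vx <- li + x - 1L
      if (l1[vx] != li) next
      for (y in seq_len(k2 - lj + 1L)) {
        vy <- lj + y - 1L
        if (l2[vy] != lj) next
        td[vx, vy] <- fd[x + 1L, y + 1L]
      }
    }
  }
  distance <- td[t1$n, t2$n]
  out <- new.env(parent = emptyenv())
  out$pairs <- list()
  out$queue <- list(c(t1$root, t2$root))
  while (length(out$queue) > 0L) {
    pr <- out$queue[[1L]]
    out$queue[[1L]] <- NULL
    zs_backtrace(t1, t2, pr[1L], pr[2L], cv, td, out)
  }
  mapping <- do.call(rbind, out$pairs)
  if (is.null(mapping)) mapping <- matrix(integer(0), ncol = 2L)
  mapping <- mapping[order(mapping[, 1L]), , drop = FALSE]
  build_edit_script(t1, t2, mapping, cv, distance)
}

# Assemble the ordered operation list from a mapping.
build_edit_script <- function(t1, t2, mapping, cv, distance) {
  mapped1 <- mapping[, 1L]; mapped2 <- mapping[, 2L]
  dels <- setdiff(seq_len(t1$n), mapped1)              # postorder = children first
  ins <- intersect(tree_preorder(t2), setdiff(seq_len(t2$n), mapped2))
  tgt_of <- integer(t1$n); tgt_of[mapped1] <- mapped2
  ops <- rbind(
    if (length(dels)) data.frame(op = "DEL", tpl = dels, tgt = NA_integer_,
                                 cost = cv$del[dels]),
    if (length(ins)) data.frame(op = "INS", tpl = NA_integer_, tgt = ins,
                                cost = cv$ins[ins]),
    if (nrow(mapping)) data.frame(op = "UPD", tpl = mapped1, tgt = mapped2,
                                  cost = cv$upd[cbind(mapped1, mapped2)])
  )
  if (is.null(ops)) ops <- data.frame(op = character(0), tpl = integer(0),
                                      tgt = integer(0), cost = numeric(0))
  rownames(ops) <- NULL
  structure(list(distance = distance, mapping = mapping, ops = ops,
                 t1_n = t1$n, t2_n = t2$n),
            class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  cat("edit_script: distance ", format(x$distance), ", ",
      sum(x$ops$op == "DEL"), " deletions, ", sum(x$ops$op == "INS"),
      " insertions, ", sum(x$ops$op == "UPD"), " updates (",
      sum(x$ops$op == "UPD" & x$ops$cost == 0), " free)\n", sep = "")
  invisible(x)
}

#' Brute-force tree edit distance (test oracle)
#'
#' Exhaustively enumerates every valid mapping (partial injection preserving
#' ancestry and sibling order, checked through pre/postorder ranks) between
#' two small trees and returns the minimal total cost. Independent of the
#' dynamic program in [ted()]; refuses trees above 10 nodes.
#'
#' @param t1,t2 `rna_tree` objects with at most 10 nodes each.
#' @param costs A [cost_scheme()].
#' @return The exact minimal edit cost (a number).
#' @export
ted_bruteforce <- function(t1, t2, costs = cost_scheme()) {
  if (t1$n > 10L || t2$n > 10L) stop("ted_bruteforce limited to trees of <= 10 nodes")
  cv <- ted_costs(t1, t2, costs)
  pre1 <- match(seq_len(t1$n), tree_preorder(t1))
  pre2 <- match(seq_len(t2$n), tree_preorder(t2))
  # postorder rank is the node id itself
  best <- sum(cv$del) + sum(cv$ins)
  n1 <- t1$n; n2 <- t2$n
  chosen <- integer(0)   # target ids chosen for template nodes 1..k (0 = deleted)
  rec <- function(k, cost, used2) {
    if (cost >= best) return()
    if (k > n1) {
      total <- cost + sum(cv$ins[setdiff(seq_len(n2), used2)])
      if (total < best) best <<- total
      return()
    }
    # option: delete template node k
    rec(k + 1L, cost + cv$del[k], used2)
    # option: map k to any compatible unused target node
    for (b in seq_len(n2)) {
      if (b %in% used2) next
      ok <- TRUE
      for (a in seq_along(chosen)) {
        b0 <- chosen[a]
        if (b0 == 0L) next
        if ((a < k) != (b0 < b)) { ok <- FALSE; break }
        if ((pre1[a] < pre1[k]) != (pre2[b0] < pre2[b])) { ok <- FALSE; break }
      }
      if (!ok) next
      chosen[k] <<- b
      rec(k + 1L, cost + cv$upd[k, b], c(used2, b))
      chosen[k] <<- 0L
    }
  }
  chosen <- integer(n1)
  rec(1L, 0, integer(0))
  best
}

# ---- script application -----------------------------------------------------

# Mutable tree helper: list of nodes with parent/children/kind/letters.
mut_tree <- function(tree) {
  list(kind = tree$kind, letters = tree$letters,
       parent = tree$parent, children = tree$children, root = tree$root,
       alive = rep(TRUE, tree$n))
}

# Splice node v out of a mutable tree: children take its place in order.
mut_delete <- function(mt, v) {
  p <- mt$parent[v]
  stopifnot(!is.na(p))
  kids <- mt$children[[v]]
  sib <- mt$children[[p]]
  pos <- match(v, sib)
  mt$children[[p]] <- append(sib[-pos], kids, after = pos - 1L)
  for (c in kids) mt$parent[c] <- p
  mt$alive[v] <- FALSE
  mt
}

#' Apply an edit script to the template tree
#'
#' Replays the script (deletions children-first, insertions parents-first,
#' updates last) and returns the resulting tree, which equals the target tree
#' of the [ted()] call that produced the script, up to ordered isomorphism.
#'
#' @param template The `rna_tree` the script was computed from.
#' @param script An `edit_script` from [ted()].
#' @param target The target `rna_tree` (supplies kinds/letters of inserted
#'   nodes; required because the script stores target node ids).
#' @return An `rna_tree`.
#' @export
apply_script <- function(template, script, target) {
  if (script$t1_n != template$n || script$t2_n != target$n) {
    stop("script does not belong to this template/target pair")
  }
  mt <- mut_tree(template)
  img <- integer(target$n)    # target node id -> current tree node id
  mapping <- script$mapping
  img[mapping[, 2L]] <- mapping[, 1L]
  # deletions, postorder (node ids are postorder ranks, so increasing order)
  for (v in sort(script$ops$tpl[script$ops$op == "DEL"])) {
    if (identical(mt$root, v)) stop("cannot delete the root")
    mt <- mut_delete(mt, v)
  }
  if (img[target$root] == 0L) stop("internal error: roots not mapped")
  # insertions, target preorder
  next_id <- length(mt$kind)
  tgt_desc <- function(anc, v) {    # is v a strict descendant of anc in target?
    while (!is.na(target$parent[v])) {
      v <- target$parent[v]
      if (v == anc) return(TRUE)
    }
    FALSE
  }
  tgt_precedes <- function(a, b) a < b && tgt_desc(b, a) == FALSE  # postorder + not desc => left
  ins_ids <- script$ops$tgt[script$ops$op == "INS"]
  for (v in ins_ids) {
    pt <- target$parent[v]
    P <- img[pt]
    if (P == 0L) stop("edit script integrity error: unplaced parent for inserted node")
    kids <- mt$children[[P]]
    corr <- vapply(kids, function(c) {
      w <- which(img == c)
      if (length(w) != 1L) stop("edit script integrity error: unmapped child")
      w
    }, integer(1))
    adopt <- vapply(corr, function(w) tgt_desc(v, w), logical(1))
    if (any(adopt)) {
      rng <- range(which(adopt))
      if (!all(adopt[rng[1L]:rng[2L]])) stop("edit script integrity error: non-consecutive adoption")
      pos <- rng[1L]
    } else {
      pos <- sum(vapply(corr, function(w) tgt_precedes(w, v), logical(1))) + 1L
    }
    next_id <- next_id + 1L
    mt$kind[next_id] <- target$kind[v]
    mt$letters[next_id] <- target$letters[v]
    mt$alive[next_id] <- TRUE
    adopted <- kids[adopt]
    mt$children[[next_id]] <- adopted
    for (c in adopted) mt$parent[c] <- next_id
    rest <- kids[!adopt]
    mt$children[[P]] <- append(rest, next_id,
                               after = pos - 1L)
    mt$parent[next_id] <- P
    img[v] <- next_id
  }
  # updates: take kind/letters from the target
  upd <- script$ops[script$ops$op == "UPD", ]
  for (r in seq_len(nrow(upd))) {
    w <- upd$tpl[r]                      # template ids survive deletes untouched
    mt$kind[w] <- target$kind[upd$tgt[r]]
    mt$letters[w] <- target$letters[upd$tgt[r]]
  }
  mut_to_tree(mt)
}

# Rebuild a static rna_tree (postorder arrays) from a mutable tree.
mut_to_tree <- function(mt) {
  kind <- character(0); letters <- character(0)
  parent_out <- integer(0); children_out <- list()
  order_id <- integer(length(mt$kind))   # old id -> new postorder id
  nid <- 0L
  rec <- function(v) {
    kid_new <- vapply(mt$children[[v]], rec, integer(1))
    nid <<- nid + 1L
    kind[nid] <<- mt$kind[v]
    letters[nid] <<- mt$letters[v]
    children_out[nid] <<- list(kid_new)
    parent_out[nid] <<- NA_integer_
    for (c in kid_new) parent_out[c] <<- nid
    order_id[v] <<- nid
    nid
  }
  root_new <- rec(mt$root)
  n <- nid
  # assign residue indices by traversal (PAIR: i on entry, j on exit)
  i_of <- rep(NA_integer_, n); j_of <- rep(NA_integer_, n)
  cursor <- 0L
  walk <- function(v) {
    if (kind[v] == "LEAF") {
      cursor <<- cursor + 1L; i_of[v] <<- cursor
    } else if (kind[v] == "PAIR") {
      cursor <<- cursor + 1L; i_of[v] <<- cursor
      for (c in children_out[[v]]) walk(c)
      cursor <<- cursor + 1L; j_of[v] <<- cursor
    } else {
      for (c in children_out[[v]]) walk(c)
    }
  }
  walk(root_new)
  lml <- integer(n)
  for (v in seq_len(n)) {
    ch <- children_out[[v]]
    lml[v] <- if (length(ch) == 0L) v else lml[ch[1L]]
  }
  structure(list(kind = kind, i = i_of, j = j_of, parent = parent_out,
                 children = children_out, letters = letters, lml = lml,
                 n = n, L = cursor, root = root_new),
            class = "rna_tree")
}

# ---- edit script text format ------------------------------------------------

#' Write / read the edit-script text format
#'
#' Line-oriented format enabling the two-phase mapper/visualizer CLI: a
#' header line `# teddist <distance> <template nodes> <target nodes>`, then
#' one operation per line: `DEL <tpl-id>`, `INS <tgt-id> <parent-id> <child-pos>`
#' or `UPD <tpl-id> <tgt-id>`. Node ids are 0-based postorder ranks. The
#' `<parent-id>` of an insertion is the template id of the mapped parent, or
#' the negated target id when the parent is itself inserted; `<child-pos>` is
#' the 0-based child position in the target tree.
#'
#' @param script An `edit_script`.
#' @param target The target `rna_tree` (for insertion parent bookkeeping).
#' @param path File path.
#' @return `read_edit_script` returns a list with `distance`, `mapping`,
#'   `dels`, `ins` (data frame), suitable for [transform_layout()]'s `map`
#'   argument after validation against the trees.
#' @export
write_edit_script <- function(script, target, path) {
  img <- integer(target$n)
  img[script$mapping[, 2L]] <- script$mapping[, 1L]
  lines <- sprintf("# teddist %s %d %d", fmt_num(script$distance),
                   script$t1_n, script$t2_n)
  ops <- script$ops
  for (r in seq_len(nrow(ops))) {
    o <- ops$op[r]
    if (o == "DEL") {
      lines <- c(lines, sprintf("DEL %d", ops$tpl[r] - 1L))
    } else if (o == "INS") {
      v <- ops$tgt[r]
      pt <- target$parent[v]
      pref <- if (img[pt] > 0L) img[pt] - 1L else -pt
      cpos <- match(v, target$children[[pt]]) - 1L
      lines <- c(lines, sprintf("INS %d %d %d", v - 1L, pref, cpos))
    } else {
      lines <- c(lines, sprintf("UPD %d %d", ops$tpl[r] - 1L, ops$tgt[r] - 1L))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1L], "# teddist")) {
    stop("edit script parse error: missing '# teddist' header")
  }
  hdr <- strsplit(lines[1L], " +")[[1L]]
  if (length(hdr) != 5L) stop("edit script parse error: malformed header")
  distance <- as.numeric(hdr[3L])
  t1_n <- as.integer(hdr[4L]); t2_n <- as.integer(hdr[5L])
  mapping <- matrix(integer(0), ncol = 2L)
  dels <- integer(0)
  ins <- data.frame(tgt = integer(0), parent = integer(0), pos = integer(0))
  for (ln in lines[-1L]) {
    f <- strsplit(ln, " +")[[1L]]
    if (f[1L] == "DEL" && length(f) == 2L) {
      dels <- c(dels, as.integer(f[2L]) + 1L)
    } else if (f[1L] == "INS" && length(f) == 4L) {
      ins <- rbind(ins, data.frame(tgt = as.integer(f[2L]) + 1L,
                                   parent = as.integer(f[3L]),
                                   pos = as.integer(f[4L]) + 1L))
    } else if (f[1L] == "UPD" && length(f) == 3L) {
      mapping <- rbind(mapping, as.integer(f[2L:3L]) + 1L)
    } else {
      stop("edit script parse error: bad line '", ln, "'")
    }
  }
  if (anyNA(mapping) || anyNA(dels) || anyNA(unlist(ins))) {
    stop("edit script parse error: malformed number")
  }
  list(distance = distance, mapping = mapping, dels = dels, ins = ins,
       t1_n = t1_n, t2_n = t2_n)
}

# Rebuild a full edit_script from a parsed map file plus the two trees.
script_from_mapfile <- function(parsed, template, target, costs = cost_scheme()) {
  if (parsed$t1_n != template$n || parsed$t2_n != target$n) {
    stop("edit script does not match the given trees")
  }
  cv <- ted_costs(template, target, costs)
  build_edit_script(template, target, parsed$mapping, cv, parsed$distance)
}
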