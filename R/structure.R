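# Secondary-structure model: dot-bracket parsing, pseudoknot resolution and
# the ordered rooted tree representation (inner nodes = base pairs, leaves =
# unpaired residues, artificial root always present).
#
# Residue indices are 1-based inside R; all file formats and the CLI use
# 0-based indices (converted at the I/O boundary).

BRACKET_LAYERS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

#' Secondary structure object
#'
#' Constructs a validated secondary structure from a residue sequence and a
#' base-pair set. Pairs may cross (pseudoknots) at this stage; run
#' [remove_pseudoknots()] before [build_tree()].
#'
#' @param sequence Character vector of single residue letters (IUPAC codes are
#'   typical but any letters are carried through verbatim).
#' @param pairs Two-column integer matrix of 1-based residue indices, one row
#'   per base pair, first column < second column. May have zero rows.
#' @return An object of class `rna_structure` with elements `sequence`,
#'   `pairs` (rows sorted by opening index) and `length`.
#' @export
rna_structure <- function(sequence, pairs) {
  sequence <- as.character(sequence)
  L <- length(sequence)
  if (L == 0L) stop("empty sequence")
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] >= pairs[, 2L])) stop("pair with i >= j")
    if (any(pairs < 1L) || any(pairs > L)) stop("pair index out of range")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx)) {
      stop("residue ", idx[duplicated(idx)][1L], " participates in more than one pair")
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  structure(list(sequence = sequence, pairs = pairs, length = L),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure: ", x$length, " residues, ", nrow(x$pairs), " pairs",
      if (has_crossing(x)) " (pseudoknotted)" else "", "\n", sep = "")
  if (x$length <= 120L) {
    cat(paste(x$sequence, collapse = ""), "\n")
    cat(as_dotbracket(x), "\n")
  }
  invisible(x)
}

# TRUE if any two pairs cross (i < k < j < l)
has_crossing <- function(ss) {
  p <- ss$pairs
  n <- nrow(p)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    i <- p[a, 1L]; j <- p[a, 2L]
    k <- p[(a + 1L):n, 1L]; l <- p[(a + 1L):n, 2L]
    if (any(k < j & j < l)) return(TRUE)   # rows sorted by opening index, i < k
  }
  FALSE
}

#' Parse a dot-bracket (Vienna/DBN) document
#'
#' Accepts an optional `>` header line, one sequence line and one structure
#' line of equal length. Matched brackets denote base pairs; the layers
#' `()`, `[]`, `{}`, `<>` are stack-matched independently, so crossing pairs
#' (pseudoknots) are retained in the result.
#'
#' @param text Either a file path or a character vector of lines (a single
#'   string containing newlines is split).
#' @return An [rna_structure()]; pairs from all bracket layers.
#' @export
parse_dotbracket <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(text), "\n", fixed = TRUE))
  }
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && startsWith(lines[1L], ">")) lines <- lines[-1L]
  if (length(lines) < 2L) stop("dot-bracket parse error: need a sequence line and a structure line")
  seq_line <- lines[1L]
  db_line <- lines[2L]
  if (nchar(seq_line) != nchar(db_line)) {
    stop("dot-bracket parse error: sequence length ", nchar(seq_line),
         " != structure length ", nchar(db_line))
  }
  sequence <- strsplit(seq_line, "", fixed = TRUE)[[1L]]
  db <- strsplit(db_line, "", fixed = TRUE)[[1L]]
  known <- c(".", unlist(BRACKET_LAYERS))
  bad <- which(!(db %in% known))
  if (length(bad) > 0L) {
    stop("dot-bracket parse error: unknown structure character '", db[bad[1L]],
         "' at index ", bad[1L] - 1L)
  }
  pairs <- matrix(integer(0), ncol = 2L)
  for (layer in BRACKET_LAYERS) {
    stack <- integer(0)
    for (k in seq_along(db)) {
      if (db[k] == layer[1L]) {
        stack <- c(stack, k)
      } else if (db[k] == layer[2L]) {
        if (length(stack) == 0L) {
          stop("dot-bracket parse error: unbalanced '", layer[2L],
               "' at index ", k - 1L)
        }
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L) {
      stop("dot-bracket parse error: unbalanced '", layer[1L],
           "' at index ", stack[1L] - 1L)
    }
  }
  rna_structure(sequence, pairs)
}

#' Serialize a structure to a dot-bracket string
#'
#' Crossing pairs are emitted on successive bracket layers (`()`, `[]`, `{}`,
#' `<>`); a crossing-free structure uses only `()`.
#'
#' @param ss An [rna_structure()].
#' @return A single dot-bracket string of length `ss$length`.
#' @export
as_dotbracket <- function(ss) {
  db <- rep(".", ss$length)
  p <- ss$pairs
  if (nrow(p) == 0L) return(paste(db, collapse = ""))
  layer_of <- integer(nrow(p))
  for (a in seq_len(nrow(p))) {
    used <- 0L
    repeat {
      cand <- used + 1L
      if (cand > length(BRACKET_LAYERS)) stop("too many crossing layers to serialize")
      clash <- FALSE
      if (a > 1L) {
        prev <- which(layer_of[seq_len(a - 1L)] == cand)
        for (b in prev) {
          i <- p[b, 1L]; j <- p[b, 2L]; k <- p[a, 1L]; l <- p[a, 2L]
          if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) { clash <- TRUE; break }
        }
      }
      if (!clash) { layer_of[a] <- cand; break }
      used <- cand
    }
  }
  for (a in seq_len(nrow(p))) {
    db[p[a, 1L]] <- BRACKET_LAYERS[[layer_of[a]]][1L]
    db[p[a, 2L]] <- BRACKET_LAYERS[[layer_of[a]]][2L]
  }
  paste(db, collapse = "")
}

#' Write a dot-bracket file
#'
#' @param ss An [rna_structure()].
#' @param path Output file path.
#' @param name Header written after `>` (default "structure").
#' @export
write_dotbracket <- function(ss, path, name = "structure") {
  writeLines(c(paste0(">", name),
               paste(ss$sequence, collapse = ""),
               as_dotbracket(ss)), path)
  invisible(path)
}

#' Remove pseudoknots (maximum crossing-free pair subset)
#'
#' Keeps a maximum-cardinality subset of the pairs such that no two retained
#' pairs cross; the residues of dropped pairs become unpaired. Computed by
#' interval dynamic programming over the nesting relation; ties are broken by
#' preferring the pair with the smaller opening index.
#'
#' @param ss An [rna_structure()], possibly with crossing pairs.
#' @return An [rna_structure()] with a crossing-free pair set.
#' @export
remove_pseudoknots <- function(ss) {
  p <- ss$pairs
  if (nrow(p) < 2L || !has_crossing(ss)) return(ss)
  # DP over sequence intervals: best[i,j] = max pairs selectable wholly within
  # [i, j] without crossings. Only pair endpoints matter, so compress
  # coordinates to the sorted endpoint list.
  pts <- sort(unique(as.vector(p)))
  np <- length(pts)
  pos <- match(p, pts)
  dim(pos) <- dim(p)
  open_at <- vector("list", np)   # pairs opening at compressed position
  for (a in seq_len(nrow(p))) {
    open_at[[pos[a, 1L]]] <- c(open_at[[pos[a, 1L]]], a)
  }
  best <- matrix(0L, np, np)      # [i, j] compressed interval, i <= j
  pick <- matrix(0L, np, np)      # pair chosen at (i, j) (0 = skip i)
  for (span in seq_len(np)) {
    for (i in seq_len(np - span + 1L)) {
      j <- i + span - 1L
      # option 1: leave position i unpaired inside this interval
      b <- if (i < j) best[i + 1L, j] else 0L
      ch <- 0L
      # option 2: use a pair opening at i and closing at k <= j
      for (a in open_at[[i]]) {
        k <- pos[a, 2L]
        if (k > j) next
        v <- 1L
        if (k > i + 1L) v <- v + best[i + 1L, k - 1L]
        if (k < j) v <- v + best[k + 1L, j]
        if (v >= b) { b <- v; ch <- a }  # >=: on ties prefer pairing at the smaller opening index
      }
      best[i, j] <- b
      pick[i, j] <- ch
    }
  }
  keep <- logical(nrow(p))
  stack_iv <- list(c(1L, np))
  while (length(stack_iv) > 0L) {
    iv <- stack_iv[[length(stack_iv)]]
    stack_iv[[length(stack_iv)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i > j) next
    a <- pick[i, j]
    if (a == 0L) {
      if (i < j) stack_iv[[length(stack_iv) + 1L]] <- c(i + 1L, j)
    } else {
      keep[a] <- TRUE
      k <- pos[a, 2L]
      if (k > i + 1L) stack_iv[[length(stack_iv) + 1L]] <- c(i + 1L, k - 1L)
      if (k < j) stack_iv[[length(stack_iv) + 1L]] <- c(k + 1L, j)
    }
  }
  rna_structure(ss$sequence, p[keep, , drop = FALSE])
}

#' Build the ordered rooted tree of a structure
#'
#' Inner (`PAIR`) nodes represent base pairs, leaves unpaired residues; an
#' artificial `ROOT` node always tops the tree, so a structure whose ends are
#' unpaired still yields a single tree rather than a forest. Children are
#' ordered by 5'-to-3' encounter order and a left-to-right depth-first
#' traversal visits residue indices in strictly increasing order (a `PAIR`
#' contributes its opening index on entry and its closing index on exit).
#'
#' Nodes are stored in postorder; node ids are postorder ranks (1-based).
#'
#' @param ss A pseudoknot-free [rna_structure()].
#' @return An object of class `rna_tree`: parallel vectors `kind`
#'   (`"ROOT"|"PAIR"|"LEAF"`), `i`, `j` (residue indices, `NA` where absent),
#'   `parent`, `lml` (leftmost-leaf descendant, for the edit-distance DP),
#'   a `children` list of id vectors, `letters` per node, `n` nodes and the
#'   residue count `L`.
#' @export
build_tree <- function(ss) {
  if (has_crossing(ss)) {
    stop("structure has crossing pairs; run remove_pseudoknots() first")
  }
  L <- ss$length
  partner <- integer(L)
  p <- ss$pairs
  if (nrow(p) > 0L) {
    partner[p[, 1L]] <- p[, 2L]
    partner[p[, 2L]] <- p[, 1L]
  }
  n_nodes <- nrow(p) + (L - 2L * nrow(p)) + 1L
  kind <- character(n_nodes); ii <- rep(NA_integer_, n_nodes)
  jj <- rep(NA_integer_, n_nodes); parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  letters <- character(n_nodes)
  nid <- 0L
  rec <- function(from, to) {   # returns ids of nodes spanning residues [from, to]
    ids <- integer(0)
    k <- from
    while (k <= to) {
      if (partner[k] == 0L) {
        nid <<- nid + 1L
        kind[nid] <<- "LEAF"; ii[nid] <<- k
        letters[nid] <<- ss$sequence[k]
        children[nid] <<- list(integer(0))
        ids <- c(ids, nid)
        k <- k + 1L
      } else {
        j <- partner[k]
        kids <- rec(k + 1L, j - 1L)
        nid <<- nid + 1L
        kind[nid] <<- "PAIR"; ii[nid] <<- k; jj[nid] <<- j
        letters[nid] <<- paste0(ss$sequence[k], ss$sequence[j])
        children[nid] <<- list(kids)
        parent[kids] <<- nid
        ids <- c(ids, nid)
        k <- j + 1L
      }
    }
    ids
  }
  top <- rec(1L, L)
  nid <- nid + 1L
  kind[nid] <- "ROOT"
  letters[nid] <- ""
  children[nid] <- list(top)
  parent[top] <- nid
  lml <- integer(n_nodes)
  for (v in seq_len(n_nodes)) {
    ch <- children[[v]]
    lml[v] <- if (length(ch) == 0L) v else lml[ch[1L]]
  }
  structure(list(kind = kind, i = ii, j = jj, parent = parent,
                 children = children, letters = letters, lml = lml,
                 n = n_nodes, L = L, root = n_nodes),
            class = "rna_tree")
}

#' @export
print.rna_tree <- function(x, ...) {
  cat("rna_tree: ", x$n, " nodes (", sum(x$kind == "PAIR"), " pairs, ",
      sum(x$kind == "LEAF"), " leaves), ", x$L, " residues\n", sep = "")
  invisible(x)
}

#' Summarize tree nodes
#'
#' @param tree An `rna_tree` (or a [template_document()], whose tree is used).
#' @return A data frame with one row per node: `id` (postorder rank), `kind`,
#'   `i`, `j` (1-based residue indices), `parent` and `depth` (root = 0).
#' @export
tree_nodes <- function(tree) {
  if (inherits(tree, "rna_template")) tree <- tree$tree
  depth <- integer(tree$n)
  for (v in rev(seq_len(tree$n))) {   # reverse postorder: parents before children
    p <- tree$parent[v]
    depth[v] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  data.frame(id = seq_len(tree$n), kind = tree$kind, i = tree$i, j = tree$j,
             parent = tree$parent, depth = depth)
}

# Residue indices covered by a node's subtree, in 5'->3' order.
tree_span <- function(tree, v, include_self = TRUE) {
  if (tree$kind[v] == "ROOT") return(seq_len(tree$L))
  if (tree$kind[v] == "LEAF") return(if (include_self) tree$i[v] else integer(0))
  if (include_self) tree$i[v]:tree$j[v] else
    if (tree$j[v] - tree$i[v] > 1L) (tree$i[v] + 1L):(tree$j[v] - 1L) else integer(0)
}

# Serialize a tree back to the structure it encodes (round-trip check).
tree_to_structure <- function(tree) {
  letters <- character(tree$L)
  pairs <- matrix(integer(0), ncol = 2L)
  for (v in seq_len(tree$n)) {
    if (tree$kind[v] == "LEAF") {
      letters[tree$i[v]] <- substr(tree$letters[v], 1L, 1L)
    } else if (tree$kind[v] == "PAIR") {
      letters[tree$i[v]] <- substr(tree$letters[v], 1L, 1L)
      letters[tree$j[v]] <- substr(tree$letters[v], 2L, 2L)
      pairs <- rbind(pairs, c(tree$i[v], tree$j[v]))
    }
  }
  rna_structure(letters, pairs)
}

# Preorder node ids (root first, children left to right).
tree_preorder <- function(tree) {
  out <- integer(tree$n)
  k <- 0L
  stack <- tree$root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    ch <- tree$children[[v]]
    if (length(ch) > 0L) stack <- c(stack, rev(ch))
  }
  out
}

#' Test ordered-tree isomorphism
#'
#' Two trees are considered identical when their shapes, node kinds and node
#' letters agree under the left-to-right ordering of children.
#'
#' @param t1,t2 `rna_tree` objects.
#' @param compare_letters Compare residue letters as well as kinds.
#' @return `TRUE` or `FALSE`.
#' @export
tree_isomorphic <- function(t1, t2, compare_letters = TRUE) {
  sig <- function(tree, v) {
    lab <- if (compare_letters) paste0(tree$kind[v], ":", tree$letters[v]) else tree$kind[v]
    kids <- vapply(tree$children[[v]], function(c) sig(tree, c), character(1))
    paste0(lab, "(", paste(kids, collapse = ","), ")")
  }
  sig(t1, t1$root) == sig(t2, t2$root)
}
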