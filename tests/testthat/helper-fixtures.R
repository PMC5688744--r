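# Shared test fixtures, all built in code.

# random small dot-bracket strings for tree-edit oracle tests
random_small_db <- function(max_len = 7L) {
  gen <- function(budget) {
    if (budget <= 0L) return("")
    if (budget >= 2L && stats::runif(1) < 0.4) {
      inner <- gen(budget - 2L)
      paste0("(", inner, ")", gen(budget - 2L - nchar(inner)))
    } else {
      paste0(".", gen(budget - 1L))
    }
  }
  s <- gen(sample(seq_len(max_len), 1L))
  if (nchar(s) < 1L) "." else s
}

tree_of <- function(db, letter = "A") {
  build_tree(parse_dotbracket(c(strrep(letter, nchar(db)), db)))
}

# a simple anchored hairpin document: stem of `npairs` going up, loop of
# `nloop` residues on a circle on top
hairpin_doc <- function(npairs = 3L, nloop = 4L, x0 = 0) {
  L <- 2L * npairs + nloop
  db <- paste0(strrep("(", npairs), strrep(".", nloop), strrep(")", npairs))
  ss <- parse_dotbracket(c(strrep("G", L), db))
  xy <- matrix(NA_real_, L, 2L)
  for (k in seq_len(npairs)) {
    xy[k, ] <- c(x0 - 4, (k - 1) * 8)
    xy[L + 1L - k, ] <- c(x0 + 4, (k - 1) * 8)
  }
  top <- (npairs - 1) * 8
  pts <- distribute_on_circle(c(x0 - 4, top), c(x0 + 4, top), nloop, c(0, 1), 8)
  xy[npairs + seq_len(nloop), ] <- pts
  template_document(ss, data.frame(x = xy[, 1L], y = xy[, 2L]))
}

# two parallel hairpins with the second leaned onto the first by `lean_deg`
# degrees about its stem base: a constructed steric clash that a rotation
# from the standard candidate set separates
two_hairpin_collision <- function(lean_deg = 30) {
  ss <- parse_dotbracket(c(strrep("G", 22), "(((....)))..(((....)))"))
  mk_hp <- function(x0) {
    xy <- matrix(NA_real_, 10L, 2L)
    for (k in 1:3) {
      xy[k, ] <- c(x0 - 4, (k - 1) * 8)
      xy[11L - k, ] <- c(x0 + 4, (k - 1) * 8)
    }
    xy[4:7, ] <- distribute_on_circle(c(x0 - 4, 16), c(x0 + 4, 16), 4L, c(0, 1), 8)
    xy
  }
  x0 <- 22
  xy <- rbind(mk_hp(0), matrix(c(x0 / 2 - 4, -8, x0 / 2 + 4, -8), 2L, 2L,
                               byrow = TRUE), mk_hp(x0))
  doc <- template_document(ss, data.frame(x = xy[, 1L], y = xy[, 2L]))
  nd <- tree_nodes(doc)
  h2 <- nd$id[nd$kind == "PAIR" & nd$i == 13L]
  rotate_doc_subtree(doc, h2, lean_deg * pi / 180)
}

# rigidly rotate a pair-rooted subtree about its anchor midpoint (test-side
# re-implementation on the public layout table, independent of the package
# internals)
rotate_doc_subtree <- function(doc, node, theta) {
  nd <- tree_nodes(doc)
  i <- nd$i[node]; j <- nd$j[node]
  span <- i:j
  lay <- doc$layout
  anchor <- c(mean(lay$x[c(i, j)]), mean(lay$y[c(i, j)]))
  x <- lay$x[span] - anchor[1L]; y <- lay$y[span] - anchor[2L]
  lay$x[span] <- anchor[1L] + cos(theta) * x - sin(theta) * y
  lay$y[span] <- anchor[2L] + sin(theta) * x + cos(theta) * y
  template_document(doc$structure, lay[, c("x", "y", "status")],
                    backbone_step = doc$geom$backbone_step,
                    pair_step = doc$geom$pair_step,
                    bond_length = doc$geom$bond_length)
}

# independent brute-force overlap count on the raw coordinate table; shares
# no code with count_overlaps()
naive_overlap_count <- function(doc) {
  lay <- doc$layout
  L <- nrow(lay)
  segs <- cbind(seq_len(L - 1L), seq_len(L - 1L) + 1L)
  if (nrow(doc$structure$pairs) > 0L) segs <- rbind(segs, doc$structure$pairs)
  inter <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    eps <- 1e-9
    if (abs(den) > eps) {
      t <- ((q1[1L] - p1[1L]) * d2[2L] - (q1[2L] - p1[2L]) * d2[1L]) / den
      u <- ((q1[1L] - p1[1L]) * d1[2L] - (q1[2L] - p1[2L]) * d1[1L]) / den
      tol <- eps
      if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(FALSE)
      # endpoint-to-endpoint touches do not count
      at_end <- function(v) abs(v) < 1e-6 || abs(v - 1) < 1e-6
      return(!(at_end(t) && at_end(u)))
    }
    # parallel: collinear overlap of positive length?
    cross <- (q1[1L] - p1[1L]) * d1[2L] - (q1[2L] - p1[2L]) * d1[1L]
    if (abs(cross) > eps) return(FALSE)
    tt <- sum(d1 * d1)
    if (tt < eps) return(FALSE)
    s1 <- sum((q1 - p1) * d1) / tt
    s2 <- sum((q2 - p1) * d1) / tt
    lo <- max(0, min(s1, s2)); hi <- min(1, max(s1, s2))
    (hi - lo) * sqrt(tt) > eps
  }
  count <- 0L
  n <- nrow(segs)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (length(intersect(segs[a, ], segs[b, ])) > 0L) next
      p1 <- c(lay$x[segs[a, 1L]], lay$y[segs[a, 1L]])
      p2 <- c(lay$x[segs[a, 2L]], lay$y[segs[a, 2L]])
      q1 <- c(lay$x[segs[b, 1L]], lay$y[segs[b, 1L]])
      q2 <- c(lay$x[segs[b, 2L]], lay$y[segs[b, 2L]])
      if (inter(p1, p2, q1, q2)) count <- count + 1L
    }
  }
  count
}

# brute-force maximum crossing-free pair subset size (subset enumeration)
max_noncrossing_bruteforce <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) return(0L)
  crosses <- function(a, b) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]; k <- pairs[b, 1L]; l <- pairs[b, 2L]
    (i < k && k < j && j < l) || (k < i && i < l && l < j)
  }
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    if (length(sel) > 1L) {
      for (a in seq_along(sel)[-1L]) {
        for (b in seq_len(a - 1L)) {
          if (crosses(sel[a], sel[b])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}
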