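# Test fixtures: seeded random secondary structures, a de-novo radial
# baseline layouter used to manufacture template drawings, and controlled
# stem/loop perturbations with known ground truth.

# run code under a private RNG stream, leaving the global state untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the random structure generator
#'
#' @param seed Integer seed; the same seed and configuration always produce
#'   the same structure.
#' @param length Total residue count (>= 4).
#' @param stem_min,stem_max Stem length range (stacked pairs per helix).
#' @param loop_min,loop_max Hairpin loop size range; `loop_min` >= 3 keeps
#'   hairpins sterically plausible.
#' @param branch_prob Per-position probability of opening a new branch.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, length = 60L, stem_min = 2L,
                             stem_max = 6L, loop_min = 3L, loop_max = 10L,
                             branch_prob = 0.12) {
  stopifnot(length >= 4L, stem_min >= 1L, stem_max >= stem_min,
            loop_min >= 3L, loop_max >= loop_min,
            branch_prob > 0, branch_prob < 1)
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
                 loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
                 branch_prob = branch_prob),
            class = "generator_config")
}

PAIR_TYPES <- matrix(c("G", "C", "C", "G", "A", "U", "U", "A", "G", "U", "U", "G"),
                     ncol = 2L, byrow = TRUE)

#' Generate a random pseudoknot-free secondary structure
#'
#' Structures are built top-down: positions become unpaired residues or open
#' a branch (a helix of `stem_min`-`stem_max` stacked pairs whose interior
#' is filled recursively), so hairpins, bulges, internal and multibranch
#' loops all occur. Hairpin loops always hold at least `loop_min >= 3`
#' unpaired residues. Letters are drawn from ACGU with canonical (including
#' wobble) pair types on paired positions.
#'
#' @param cfg A [generator_config()].
#' @return An [rna_structure()] of exactly `cfg$length` residues.
#' @export
random_structure <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  min_branch <- 2L * cfg$stem_min + cfg$loop_min
  pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  gen_run <- function(B) {
    out <- character(0)
    while (B > 0L) {
      if (B >= min_branch && stats::runif(1) < cfg$branch_prob) {
        Bb <- pick1(min_branch:B)
        out <- c(out, gen_branch(Bb))
        B <- B - Bb
      } else {
        out <- c(out, ".")
        B <- B - 1L
      }
    }
    paste(out, collapse = "")
  }
  gen_branch <- function(Bb) {
    s_hi <- min(cfg$stem_max, (Bb - cfg$loop_min) %/% 2L)
    s <- pick1(cfg$stem_min:max(cfg$stem_min, s_hi))
    inner <- Bb - 2L * s
    inner_str <- if (inner > cfg$loop_max && inner >= min_branch + 2L) {
      gen_run(inner)       # interior may branch again (multibranch / internal loops)
    } else {
      strrep(".", inner)   # hairpin loop, inner >= loop_min by construction
    }
    paste0(strrep("(", s), inner_str, strrep(")", s))
  }
  with_seed(cfg$seed, {
    db <- gen_run(cfg$length)
    ss0 <- parse_dotbracket(c(strrep("N", cfg$length), db))
    letters <- sample(c("A", "C", "G", "U"), cfg$length, replace = TRUE)
    p <- ss0$pairs
    if (nrow(p) > 0L) {
      ty <- sample(nrow(PAIR_TYPES), nrow(p), replace = TRUE)
      letters[p[, 1L]] <- PAIR_TYPES[ty, 1L]
      letters[p[, 2L]] <- PAIR_TYPES[ty, 2L]
    }
    rna_structure(letters, p)
  })
}

# ---- baseline radial layout -------------------------------------------------

#' De-novo radial baseline layout
#'
#' Draws a structure from scratch in the habitual style: stems straight with
#' uniform `pair_step` spacing, every loop's residues and branch anchors on
#' a circle, branches directed radially outward, the top level on an
#' exterior circle. Exists to manufacture template layouts for testing and
#' experimentation, not as a general-purpose drawing engine.
#'
#' @param ss A pseudoknot-free [rna_structure()].
#' @param backbone_step,pair_step,bond_length Geometry constants.
#' @return An [template_document()].
#' @export
baseline_layout <- function(ss, backbone_step = 8, pair_step = 8,
                            bond_length = 8) {
  tree <- build_tree(ss)
  g <- default_geometry(backbone_step, pair_step, bond_length)
  xy <- matrix(NA_real_, ss$length, 2L)
  # conservative per-branch extent estimates (lateral half-width and radial
  # depth, in layout units), used to widen loop gaps around bulky branches
  hw <- numeric(tree$n); dp <- numeric(tree$n)
  for (v in seq_len(tree$n)) {                 # postorder: children first
    if (tree$kind[v] != "PAIR") next
    kids <- tree$children[[v]]
    pk <- kids[vapply(kids, function(c) tree$kind[c] == "PAIR", logical(1))]
    nl <- length(kids) - length(pk)
    if (length(pk) == 0L) {                    # hairpin
      r <- loop_circle_radius(c(g$bond_length, rep(g$backbone_step, nl + 1L)))
      hw[v] <- max(g$bond_length / 2, r)
      dp[v] <- 2 * r
    } else if (length(pk) == 1L && nl == 0L) { # stacked pair
      hw[v] <- max(g$bond_length / 2, hw[pk])
      dp[v] <- g$pair_step + dp[pk]
    } else if (length(pk) == 1L) {             # internal loop / bulge
      r <- loop_circle_radius(c(g$bond_length, rep(g$backbone_step, nl + 2L),
                                g$bond_length))
      hw[v] <- max(r, hw[pk], g$bond_length / 2)
      dp[v] <- 2 * r + dp[pk]
    } else {                                   # multibranch
      nring <- nl + 2L * length(pk)
      r <- loop_circle_radius(c(g$bond_length, rep(g$backbone_step, nring)))
      hw[v] <- r + max(dp[pk])
      dp[v] <- 2 * r + max(dp[pk])
    }
  }
  node_chords <- function(kids, closing) {
    res <- integer(0); owner <- integer(0)
    for (c in kids) {
      rs <- switch(tree$kind[c], PAIR = c(tree$i[c], tree$j[c]), LEAF = tree$i[c])
      res <- c(res, rs); owner <- c(owner, rep(c, length(rs)))
    }
    list(res = res, owner = owner)
  }
  # internal loop / bulge (exactly one branch): the stem continues straight
  # through, leaf runs on circular arcs either side of the axis
  draw_internal <- function(v, axis) {
    kids <- tree$children[[v]]
    cpos <- which(vapply(kids, function(c) tree$kind[c] == "PAIR", logical(1)))
    ch <- kids[cpos]
    n5 <- cpos - 1L
    n3 <- length(kids) - cpos
    ring <- node_chords(kids)
    chords <- c(g$bond_length,
                rep(g$backbone_step, length(ring$res)),
                g$bond_length)       # parent bond, steps, child bond (approx.)
    r0 <- loop_circle_radius(chords)
    nmax <- max(n5, n3)
    r_fit <- if (nmax > 0L) {
      g$backbone_step / (2 * sin(pi / (2 * (nmax + 1L))))
    } else 0
    r <- max(r0, r_fit, g$bond_length / 2 + 1e-9)
    a <- xy[tree$i[v], ]; b <- xy[tree$j[v], ]
    m <- (a + b) / 2
    h <- sqrt(max(r^2 - sum((b - a)^2) / 4, 0))
    centre <- m + axis * h
    h2 <- sqrt(max(r^2 - g$bond_length^2 / 4, 0))
    child_mid <- centre + axis * h2
    perp <- vperp(axis)
    sgn <- sign(sum((a - m) * perp))
    if (sgn == 0) sgn <- 1
    xy[tree$i[ch], ] <<- child_mid + sgn * (g$bond_length / 2) * perp
    xy[tree$j[ch], ] <<- child_mid - sgn * (g$bond_length / 2) * perp
    place_arc <- function(from, to, leaves) {
      if (length(leaves) == 0L) return(invisible(NULL))
      pf <- atan2(from[2L] - centre[2L], from[1L] - centre[1L])
      pt_ <- atan2(to[2L] - centre[2L], to[1L] - centre[1L])
      d <- pt_ - pf
      d <- atan2(sin(d), cos(d))              # short way round
      phis <- pf + d * seq_along(leaves) / (length(leaves) + 1L)
      for (k in seq_along(leaves)) {
        xy[tree$i[leaves[k]], ] <<- centre + r * c(cos(phis[k]), sin(phis[k]))
      }
    }
    place_arc(xy[tree$i[v], ], xy[tree$i[ch], ],
              if (n5 > 0L) kids[seq_len(n5)] else integer(0))
    place_arc(xy[tree$j[ch], ], xy[tree$j[v], ],
              if (n3 > 0L) kids[cpos + seq_len(n3)] else integer(0))
    draw_stem(ch, axis)
    invisible(NULL)
  }
  # lay out the loop at `v` (a PAIR with anchored residues, or ROOT)
  draw_loop <- function(v, centre0, axis) {
    kids <- tree$children[[v]]
    n_pair <- sum(vapply(kids, function(c) tree$kind[c] == "PAIR", logical(1)))
    if (tree$kind[v] == "PAIR" && n_pair == 1L) {
      return(draw_internal(v, axis))
    }
    ring <- node_chords(kids)
    anchored <- tree$kind[v] == "PAIR"
    if (anchored) {
      ring$res <- c(tree$i[v], ring$res, tree$j[v])
      ring$owner <- c(v, ring$owner, v)
    }
    K <- length(ring$res)
    if (K == 0L) return(invisible(NULL))
    chords <- numeric(K)
    for (k in seq_len(K)) {
      nxt <- if (k < K) k + 1L else 1L
      same_pair <- ring$owner[k] == ring$owner[nxt] && tree$kind[ring$owner[k]] == "PAIR"
      chords[k] <- if (same_pair) g$bond_length else g$backbone_step
    }
    # widen the gaps flanking bulky branch anchors so neighbouring
    # subtrees cannot sweep into each other
    for (c in kids) {
      if (tree$kind[c] != "PAIR") next
      extra <- max(0, hw[c] - g$bond_length / 2)
      if (extra <= 0) next
      at <- which(ring$owner == c)
      before <- if (at[1L] > 1L) at[1L] - 1L else K
      chords[before] <- chords[before] + extra
      chords[at[2L]] <- chords[at[2L]] + extra
    }
    if (K == 1L) {                       # lone residue (only at top level)
      xy[ring$res, ] <<- matrix(centre0, 1L)
      return(invisible(NULL))
    }
    r <- loop_circle_radius(chords)
    alpha <- 2 * asin(pmin(1, chords / (2 * r)))
    alpha <- alpha * (2 * pi / sum(alpha))
    if (anchored) {
      a <- xy[tree$i[v], ]; b <- xy[tree$j[v], ]
      m <- (a + b) / 2
      h <- sqrt(max(r^2 - sum((b - a)^2) / 4, 0))
      centre <- m + axis * h
      phi0 <- atan2(a[2L] - centre[2L], a[1L] - centre[1L])
      # sweep so the arc midpoint points away from the stem
      far <- atan2(axis[2L], axis[1L])
      sweep_mid <- function(s) {
        d <- (phi0 + s * (2 * pi - alpha[K]) / 2) - far
        abs(atan2(sin(d), cos(d)))
      }
      s <- if (sweep_mid(1) <= sweep_mid(-1)) 1 else -1
    } else {
      centre <- centre0
      phi0 <- pi / 2
      s <- -1                            # top level drawn clockwise
    }
    phi <- phi0 + s * c(0, cumsum(alpha[-K]))
    pos <- cbind(centre[1L] + r * cos(phi), centre[2L] + r * sin(phi))
    for (k in seq_len(K)) {
      if (ring$owner[k] == v) next       # anchors already placed
      xy[ring$res[k], ] <<- pos[k, ]
    }
    for (c in kids) {
      if (tree$kind[c] != "PAIR") next
      mid <- (xy[tree$i[c], ] + xy[tree$j[c], ]) / 2
      out_dir <- mid - centre
      out_dir <- if (vnorm(out_dir) > 1e-9) vunit(out_dir) else axis
      draw_stem(c, out_dir)
    }
    invisible(NULL)
  }
  # continue a stem downward from pair `v` (whose residues are placed)
  draw_stem <- function(v, axis) {
    repeat {
      kids <- tree$children[[v]]
      if (length(kids) == 1L && tree$kind[kids] == "PAIR") {
        c <- kids
        mid <- (xy[tree$i[v], ] + xy[tree$j[v], ]) / 2 + g$pair_step * axis
        perp <- vperp(axis)
        sgn <- sign(sum((xy[tree$i[v], ] - (xy[tree$i[v], ] + xy[tree$j[v], ]) / 2) * perp))
        if (sgn == 0) sgn <- 1
        xy[tree$i[c], ] <<- mid + sgn * (g$bond_length / 2) * perp
        xy[tree$j[c], ] <<- mid - sgn * (g$bond_length / 2) * perp
        v <- c
      } else {
        if (length(kids) > 0L) draw_loop(v, NULL, axis)
        return(invisible(NULL))
      }
    }
  }
  root_kids <- tree$children[[tree$root]]
  if (length(root_kids) == 1L && tree$kind[root_kids] == "PAIR") {
    v <- root_kids
    xy[tree$i[v], ] <- c(-g$bond_length / 2, 0)
    xy[tree$j[v], ] <- c(g$bond_length / 2, 0)
    draw_stem(v, c(0, 1))
  } else {
    draw_loop(tree$root, c(0, 0), c(0, 1))
  }
  template_document(ss, data.frame(x = xy[, 1L], y = xy[, 2L]),
                    backbone_step = backbone_step, pair_step = pair_step,
                    bond_length = bond_length)
}

# ---- controlled perturbations ----------------------------------------------

# maximal stacked stems of a structure: list of k x 2 matrices of pair rows
# (outermost first), ordered by opening index
structure_stems <- function(ss) {
  p <- ss$pairs
  if (nrow(p) == 0L) return(list())
  stems <- list()
  used <- logical(nrow(p))
  key <- paste(p[, 1L], p[, 2L])
  for (a in seq_len(nrow(p))) {
    if (used[a]) next
    run <- a
    repeat {
      last <- run[length(run)]
      nxt <- match(paste(p[last, 1L] + 1L, p[last, 2L] - 1L), key)
      if (is.na(nxt)) break
      run <- c(run, nxt)
    }
    # only keep if `a` is not itself a continuation
    prev <- match(paste(p[a, 1L] - 1L, p[a, 2L] + 1L), key)
    if (!is.na(prev)) next
    used[run] <- TRUE
    stems[[length(stems) + 1L]] <- p[run, , drop = FALSE]
  }
  stems[order(vapply(stems, function(m) m[1L, 1L], integer(1)))]
}

# maximal unpaired runs: list of index vectors, 5'->3'
structure_loops <- function(ss) {
  partner <- rep(0L, ss$length)
  if (nrow(ss$pairs) > 0L) {
    partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  unp <- which(partner == 0L)
  if (length(unp) == 0L) return(list())
  split(unp, cumsum(c(1L, diff(unp) != 1L)))
}

#' Perturb a structure by stem/loop insertions and deletions
#'
#' Applies a list of indel specifications in order, re-enumerating stems
#' (maximal stacked helices, by opening index) and loops (maximal unpaired
#' runs) after each step. Supported specs:
#' `list(kind = "del_pairs", stem =, n =)` removes the outermost `n` pairs
#' of a stem (their residues disappear); `list(kind = "ins_pairs", stem =,
#' n =, letters =)` adds `n` pairs at the outer end; `list(kind =
#' "del_loop", loop =, n =)` removes the first `n` residues of an unpaired
#' run; `list(kind = "ins_loop", loop =, n =, letters =)` inserts `n`
#' residues at its start. Unspecified letters are drawn from the seeded
#' stream. The returned structure carries an `"undo"` attribute: applying it
#' with [perturb_structure()] restores the original structure exactly.
#'
#' @param ss An [rna_structure()].
#' @param ops List of specification lists (a single spec may be given bare).
#' @param seed Integer seed for any random letter choices.
#' @return The perturbed [rna_structure()] with attribute `"undo"`.
#' @export
perturb_structure <- function(ss, ops, seed = 1L) {
  if (!is.null(ops$kind)) ops <- list(ops)
  undo <- list()
  with_seed(seed, {
    for (op in ops) {
      res <- apply_perturb_op(ss, op)
      ss <- res$ss
      undo <- c(list(res$undo), undo)
    }
  })
  attr(ss, "undo") <- undo
  ss
}

apply_perturb_op <- function(ss, op) {
  drop_residues <- function(ss, idx) {
    idx <- sort(idx)
    old2new <- cumsum(!(seq_len(ss$length) %in% idx))
    p <- ss$pairs
    keepp <- !(p[, 1L] %in% idx | p[, 2L] %in% idx)
    p <- p[keepp, , drop = FALSE]
    p[] <- old2new[p]
    rna_structure(ss$sequence[-idx], p)
  }
  add_residues <- function(ss, at, letters, pair_with = NULL) {
    # insert letters so that they occupy positions at, at+1, ... in the new
    # structure; `at` is a vector aligned with letters, computed on the new
    # indexing and strictly increasing
    L_new <- ss$length + length(letters)
    newpos <- setdiff(seq_len(L_new), at)
    old2new <- newpos
    seqn <- character(L_new)
    seqn[newpos] <- ss$sequence
    seqn[at] <- letters
    p <- ss$pairs
    p[] <- old2new[p]
    if (!is.null(pair_with)) p <- rbind(p, pair_with)
    rna_structure(seqn, p)
  }
  if (op$kind == "del_pairs") {
    stems <- structure_stems(ss)
    st <- stems[[op$stem]]
    if (op$n > nrow(st)) stop("stem has only ", nrow(st), " pairs")
    rows <- st[seq_len(op$n), , drop = FALSE]
    letters <- cbind(ss$sequence[rows[, 1L]], ss$sequence[rows[, 2L]])
    list(ss = drop_residues(ss, as.vector(rows)),
         undo = list(kind = "ins_pairs", stem = op$stem, n = op$n,
                     letters = letters))
  } else if (op$kind == "ins_pairs") {
    stems <- structure_stems(ss)
    st <- stems[[op$stem]]
    i0 <- st[1L, 1L]; j0 <- st[1L, 2L]
    n <- op$n
    letters <- op$letters
    if (is.null(letters)) {
      ty <- sample(nrow(PAIR_TYPES), n, replace = TRUE)
      letters <- PAIR_TYPES[ty, , drop = FALSE]
    }
    # new pairs wrap the stem: openings right before i0, closings right after j0
    at_open <- i0 + seq_len(n) - 1L
    at_close <- j0 + n + seq_len(n)
    at <- c(at_open, rev(at_close))
    lt <- c(letters[, 1L], rev(letters[, 2L]))
    pair_with <- cbind(at_open, rev(at_close))
    list(ss = add_residues(ss, at, lt, pair_with),
         undo = list(kind = "del_pairs", stem = op$stem, n = n))
  } else if (op$kind == "del_loop") {
    loops <- structure_loops(ss)
    run <- loops[[op$loop]]
    if (op$n > length(run)) stop("loop has only ", length(run), " residues")
    idx <- run[seq_len(op$n)]
    list(ss = drop_residues(ss, idx),
         undo = list(kind = "ins_loop", loop = op$loop, n = op$n,
                     letters = ss$sequence[idx]))
  } else if (op$kind == "ins_loop") {
    loops <- structure_loops(ss)
    run <- loops[[op$loop]]
    letters <- op$letters
    if (is.null(letters)) letters <- sample(c("A", "C", "G", "U"), op$n, replace = TRUE)
    at <- run[1L] + seq_len(op$n) - 1L
    list(ss = add_residues(ss, at, letters),
         undo = list(kind = "del_loop", loop = op$loop, n = op$n))
  } else {
    stop("unknown perturbation kind '", op$kind, "'")
  }
}

# convenience: a seeded random (template document, target structure) pair
# with a bounded number of loop indels, used by property tests
random_fixture_pair <- function(seed, length = 60L, max_indels = 5L) {
  cfg <- generator_config(seed = seed, length = length)
  ss <- random_structure(cfg)
  doc <- baseline_layout(ss)
  loops <- structure_loops(ss)
  ops <- list()
  with_seed(seed + 1000003L, {
    n_ops <- sample(seq_len(max_indels), 1L)
    for (k in seq_len(n_ops)) {
      loops_now <- structure_loops(ss)
      if (length(loops_now) == 0L) break
      li <- sample(length(loops_now), 1L)
      if (stats::runif(1) < 0.5 && length(loops_now[[li]]) > 1L) {
        ops[[length(ops) + 1L]] <- list(kind = "del_loop", loop = li, n = 1L)
      } else {
        ops[[length(ops) + 1L]] <- list(kind = "ins_loop", loop = li, n = 1L)
      }
      ss <- apply_perturb_op(ss, ops[[length(ops)]])$ss
    }
  })
  list(template = doc, target = ss, n_ops = length(ops))
}
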