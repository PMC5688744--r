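test_that("the generator is seed-deterministic and honours its invariants", {
  cfg <- generator_config(seed = 5L, length = 80L)
  a <- random_structure(cfg)
  b <- random_structure(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$pairs, b$pairs)
  expect_equal(a$length, 80L)
  expect_false(rnalayout:::has_crossing(a))
  # global RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(random_structure(cfg))
  expect_identical(.Random.seed, before)
})

test_that("hairpin loops never fall below three unpaired residues", {
  min_loop <- Inf
  for (s in 1:1000) {
    ss <- random_structure(generator_config(seed = s, length = 40L))
    tr <- build_tree(ss)
    for (v in seq_len(tr$n)) {
      if (tr$kind[v] != "PAIR") next
      kids <- tr$children[[v]]
      if (length(kids) > 0L && all(tr$kind[kids] == "LEAF")) {
        min_loop <- min(min_loop, length(kids))
      }
    }
  }
  expect_gte(min_loop, 3L)
})

test_that("baseline layouts have straight stems and circular loops", {
  for (s in c(1, 5, 9)) {
    ss <- random_structure(generator_config(seed = s, length = 70L))
    doc <- baseline_layout(ss)
    lay <- doc$layout
    for (stem in rnalayout:::structure_stems(ss)) {
      if (nrow(stem) < 3L) next
      mids <- cbind((lay$x[stem[, 1L]] + lay$x[stem[, 2L]]) / 2,
                    (lay$y[stem[, 1L]] + lay$y[stem[, 2L]]) / 2)
      v <- mids[nrow(mids), ] - mids[1L, ]
      v <- v / sqrt(sum(v^2))
      offs <- sweep(mids, 2L, mids[1L, ]) %*% c(-v[2L], v[1L])
      expect_lt(max(abs(offs)), 1e-9)
    }
    tr <- build_tree(ss)
    for (v in seq_len(tr$n)) {
      if (tr$kind[v] != "PAIR") next
      kids <- tr$children[[v]]
      leaves <- kids[tr$kind[kids] == "LEAF"]
      if (length(leaves) < 3L) next
      pts <- cbind(lay$x[tr$i[leaves]], lay$y[tr$i[leaves]])
      anch <- rbind(c(lay$x[tr$i[v]], lay$y[tr$i[v]]),
                    c(lay$x[tr$j[v]], lay$y[tr$j[v]]))
      # loop residues and anchors equidistant from a common centre
      allp <- rbind(pts, anch)
      fit <- function(cen) sqrt(rowSums(sweep(allp, 2L, cen)^2))
      cen <- stats::optim(colMeans(allp), function(c0) stats::var(fit(c0)))$par
      rr <- fit(cen)
      expect_lt(diff(range(rr)) / mean(rr), 1e-4)
    }
  }
})

test_that("baseline layouts of random structures are planar", {
  for (s in 1:100) {
    len <- 40L + (s %% 61L)
    ss <- random_structure(generator_config(seed = s, length = len))
    expect_equal(count_overlaps(baseline_layout(ss))$count, 0L)
  }
})

test_that("perturbations apply exactly and invert", {
  ss <- random_structure(generator_config(seed = 21L, length = 70L))
  stems <- rnalayout:::structure_stems(ss)
  k <- which(vapply(stems, nrow, integer(1)) >= 5L)[1L]
  if (is.na(k)) k <- which.max(vapply(stems, nrow, integer(1)))
  n0 <- nrow(ss$pairs)

  del <- perturb_structure(ss, list(kind = "del_pairs", stem = k, n = 2L))
  expect_equal(nrow(del$pairs), n0 - 2L)
  expect_equal(del$length, ss$length - 4L)
  back <- perturb_structure(del, attr(del, "undo"))
  expect_identical(back$sequence, ss$sequence)
  expect_identical(back$pairs, ss$pairs)

  ins <- perturb_structure(ss, list(kind = "ins_loop", loop = 1L, n = 3L), seed = 5L)
  expect_equal(ins$length, ss$length + 3L)
  back2 <- perturb_structure(ins, attr(ins, "undo"))
  expect_identical(back2$sequence, ss$sequence)
  expect_identical(back2$pairs, ss$pairs)
})

test_that("pure stem shortening costs exactly one unit per removed pair", {
  for (s in c(11L, 19L)) {
    ss <- random_structure(generator_config(seed = s, length = 60L))
    stems <- rnalayout:::structure_stems(ss)
    k <- which(vapply(stems, nrow, integer(1)) >= 3L)[1L]
    tgt <- perturb_structure(ss, list(kind = "del_pairs", stem = k, n = 2L))
    expect_equal(ted(build_tree(ss), build_tree(tgt))$distance, 2)
  }
})

test_that("the full pipeline completes on seeded fixture pairs", {
  for (s in 1:50) {
    fx <- random_fixture_pair(s, length = 55L, max_indels = 5L)
    out <- transform_layout(fx$template, fx$target)
    expect_true(all(is.finite(out$layout$x)) && all(is.finite(out$layout$y)))
    sc <- attr(out, "script")
    tgt_tree <- build_tree(fx$target)
    ins_nodes <- sc$ops$tgt[sc$ops$op == "INS"]
    upd <- sc$ops[sc$ops$op == "UPD", ]
    kc <- upd$tgt[fx$template$tree$kind[upd$tpl] != tgt_tree$kind[upd$tgt]]
    expected <- sum(ifelse(tgt_tree$kind[c(ins_nodes, kc)] == "PAIR", 2L, 1L))
    expect_equal(sum(out$layout$status == "inserted"), expected)
  }
})
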