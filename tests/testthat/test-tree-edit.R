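test_that("ted on identical trees is zero with only free updates", {
  tr <- tree_of("((..))")
  s <- ted(tr, tr)
  expect_equal(s$distance, 0)
  expect_true(all(s$ops$op == "UPD"))
  expect_true(all(s$ops$cost == 0))
  expect_equal(nrow(s$mapping), tr$n)
})

test_that("ted handles the documented small examples", {
  # one PAIR vs one LEAF under the root: a single kind-changing update
  expect_equal(ted(tree_of("()"), tree_of("."))$distance, 1)
  # one pair deleted
  expect_equal(ted(tree_of("((.))"), tree_of("(.)"))$distance, 1)
  # insert-only: root vs root with k leaves
  one <- tree_of(".")
  five <- tree_of(".....")
  expect_equal(ted(one, five)$distance, 4)
  expect_equal(ted_bruteforce(one, five), 4)
})

test_that("brute-force oracle refuses oversized trees", {
  expect_error(ted_bruteforce(tree_of("((((((....))))))"), tree_of(".")), "10 nodes")
})

test_that("DP distance equals the brute-force oracle on random tree pairs", {
  set.seed(101)
  checked <- 0L
  while (checked < 200L) {
    t1 <- tree_of(random_small_db())
    t2 <- tree_of(random_small_db(), letter = "C")
    if (t1$n > 8L || t2$n > 8L) next
    checked <- checked + 1L
    s <- ted(t1, t2)
    expect_equal(s$distance, ted_bruteforce(t1, t2))
    expect_equal(sum(s$ops$cost), s$distance)
  }
})

test_that("ted is symmetric and satisfies the triangle inequality", {
  set.seed(17)
  for (rep in 1:25) {
    ta <- tree_of(random_small_db(9L))
    tb <- tree_of(random_small_db(9L))
    tc <- tree_of(random_small_db(9L))
    dab <- ted(ta, tb)$distance
    expect_equal(dab, ted(tb, ta)$distance)
    dac <- ted(ta, tc)$distance
    dcb <- ted(tc, tb)$distance
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("applying the script reproduces the target tree", {
  set.seed(23)
  for (rep in 1:60) {
    t1 <- tree_of(random_small_db(12L))
    t2 <- tree_of(random_small_db(12L), letter = "G")
    s <- ted(t1, t2)
    out <- apply_script(t1, s, t2)
    expect_true(tree_isomorphic(out, t2))
  }
  # empty effective script leaves the template unchanged
  tr <- tree_of("(..)")
  out <- apply_script(tr, ted(tr, tr), tr)
  expect_true(tree_isomorphic(out, tr))
})

test_that("deleting a pair splices its children into the parent", {
  t1 <- tree_of("((..))")
  t2 <- tree_of("(..)")
  s <- ted(t1, t2)
  expect_equal(s$distance, 1)
  expect_equal(sum(s$ops$op == "DEL"), 1L)
  out <- apply_script(t1, s, t2)
  expect_true(tree_isomorphic(out, t2))
})

test_that("custom cost schemes are honoured", {
  costs <- cost_scheme(insert = 2, delete = 3,
                       update = function(a, b) ifelse(a == b, 0, 5))
  t1 <- tree_of("(.)")
  t2 <- tree_of("(..)")
  s <- ted(t1, t2, costs)
  expect_equal(s$distance, 2)          # one leaf insertion at cost 2
  expect_equal(s$distance, ted_bruteforce(t1, t2, costs))
})

test_that("edit scripts survive the text format round trip", {
  t1 <- tree_of("((...))..")
  t2 <- tree_of("((....)).")
  s <- ted(t1, t2)
  path <- withr::local_tempfile(fileext = ".map")
  write_edit_script(s, t2, path)
  parsed <- read_edit_script(path)
  expect_equal(parsed$distance, s$distance)
  expect_identical(parsed$mapping, s$mapping)
  expect_setequal(parsed$dels, s$ops$tpl[s$ops$op == "DEL"])
})

test_that("a corrupted edit script is rejected", {
  t1 <- tree_of("((...))")
  t2 <- tree_of("((..))")
  s <- ted(t1, t2)
  path <- withr::local_tempfile(fileext = ".map")
  write_edit_script(s, t2, path)
  lines <- readLines(path)
  # drop a field from every non-header line in turn
  for (k in which(!startsWith(lines, "#"))) {
    broken <- lines
    broken[k] <- sub(" [^ ]+$", "", broken[k])
    p2 <- withr::local_tempfile(fileext = ".map")
    writeLines(broken, p2)
    expect_error(read_edit_script(p2), "parse error")
  }
  # remove the header
  p3 <- withr::local_tempfile(fileext = ".map")
  writeLines(lines[-1L], p3)
  expect_error(read_edit_script(p3), "header")
})
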