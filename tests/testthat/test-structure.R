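test_that("dot-bracket parsing matches stack semantics", {
  ss <- parse_dotbracket(c("GGAACC", "((..))"))
  expect_identical(ss$pairs, matrix(c(1L, 2L, 6L, 5L), ncol = 2L))
  expect_identical(ss$sequence, c("G", "G", "A", "A", "C", "C"))

  # independent bracket layers give crossing pairs, which are retained
  ss2 <- parse_dotbracket(c("ACGU", "([)]"))
  expect_identical(ss2$pairs, matrix(c(1L, 2L, 3L, 4L), ncol = 2L))

  # header line and trailing whitespace tolerated
  ss3 <- parse_dotbracket(c(">hdr", "GAC \r", "(.) "))
  expect_equal(nrow(ss3$pairs), 1L)
})

test_that("malformed dot-bracket input is rejected with positions", {
  expect_error(parse_dotbracket(c("GGC", "(()")), "unbalanced.*index 0")
  expect_error(parse_dotbracket(c("GGC", "())")), "unbalanced")
  expect_error(parse_dotbracket(c("GGCA", "(.)")), "length")
  expect_error(parse_dotbracket(c("GGC", "(x)")), "unknown structure character")
})

test_that("pseudoknot removal finds a maximum crossing-free subset", {
  # crossing pair: exactly one survives
  ss <- rna_structure(c("A", "C", "G", "U"), rbind(c(1, 3), c(2, 4)))
  expect_equal(nrow(remove_pseudoknots(ss)$pairs), 1L)

  # nested input untouched
  ss2 <- parse_dotbracket(c("GGAACC", "((..))"))
  expect_identical(remove_pseudoknots(ss2)$pairs, ss2$pairs)

  # documented example with tie-break: keep the smaller opening index
  ss3 <- rna_structure(rep("A", 10), rbind(c(1, 10), c(2, 5), c(3, 8)))
  out <- remove_pseudoknots(ss3)
  expect_equal(nrow(out$pairs), 2L)
  expect_true(all(c(1L, 2L) %in% out$pairs[, 1L]))
})

test_that("pseudoknot removal cardinality equals brute force on random inputs", {
  set.seed(61)
  for (rep in 1:60) {
    L <- sample(6:16, 1L)
    npair <- sample(2:min(8L, L %/% 2L), 1L)
    idx <- sample(L, 2L * npair)
    pairs <- matrix(idx, ncol = 2L)
    pairs <- t(apply(pairs, 1L, sort))
    ss <- rna_structure(rep("A", L), pairs)
    got <- nrow(remove_pseudoknots(ss)$pairs)
    expect_equal(got, max_noncrossing_bruteforce(ss$pairs))
  }
})

test_that("tree construction follows the pair nesting", {
  tr <- tree_of("((..))")
  expect_equal(sum(tr$kind == "PAIR"), 2L)
  expect_equal(sum(tr$kind == "LEAF"), 2L)
  expect_equal(tr$kind[tr$root], "ROOT")
  # ROOT -> PAIR(1,6) -> PAIR(2,5) -> two leaves
  top <- tr$children[[tr$root]]
  expect_length(top, 1L)
  expect_equal(c(tr$i[top], tr$j[top]), c(1L, 6L))

  tr2 <- tree_of(".().")
  top2 <- tr2$children[[tr2$root]]
  expect_identical(tr2$kind[top2], c("LEAF", "PAIR", "LEAF"))

  expect_error(build_tree(rna_structure(rep("A", 4), rbind(c(1, 3), c(2, 4)))),
               "remove_pseudoknots")
})

test_that("tree counts and traversal order hold on random structures", {
  set.seed(7)
  for (rep in 1:40) {
    db <- random_small_db(12L)
    ss <- parse_dotbracket(c(strrep("A", nchar(db)), db))
    tr <- build_tree(ss)
    expect_equal(sum(tr$kind == "PAIR"), nrow(ss$pairs))
    expect_equal(sum(tr$kind == "LEAF"), ss$length - 2L * nrow(ss$pairs))
    # left-to-right DFS visits residues in strictly increasing order
    visit <- integer(0)
    walk <- function(v) {
      if (tr$kind[v] == "LEAF") visit <<- c(visit, tr$i[v])
      if (tr$kind[v] == "PAIR") visit <<- c(visit, tr$i[v])
      for (c in tr$children[[v]]) walk(c)
      if (tr$kind[v] == "PAIR") visit <<- c(visit, tr$j[v])
    }
    walk(tr$root)
    expect_identical(visit, seq_len(ss$length))
    # round trip through serialization
    expect_identical(as_dotbracket(tree_to_structure(tr)), db)
  }
})

test_that("non-ACGU letters are carried through verbatim", {
  ss <- parse_dotbracket(c("GN-XU", "(...)"))
  expect_identical(ss$sequence[2:4], c("N", "-", "X"))
  tr <- build_tree(ss)
  expect_identical(tree_to_structure(tr)$sequence, ss$sequence)
})
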