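# phylo: p-distances, neighbor-joining, bootstrap, majority-rule collapse
# and clade assignment

test_that("p-distance matrix covers the trivial cases", {
  twenty <- "MKVLFDEGHSTWYQNPARCI"
  a <- ps("a", twenty)
  b <- ps("b", twenty)                       # identical -> 0
  # half differing: every odd position replaced (alternation deters gaps)
  half <- local({
    ch <- strsplit(twenty, "")[[1]]
    ch[seq(1, 19, by = 2)] <- "W"
    paste(ch, collapse = "")
  })
  c2 <- ps("c", half)
  D <- p_distance_matrix(list(a, b, c2))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.5)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), c("a", "b", "c")))
  expect_error(p_distance_matrix(list(a, b)), "3")
})

test_that("NJ solves the 3-taxon system in closed form", {
  D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # closed form: la = (dab+dac-dbc)/2 etc.
  expect_equal(el[c("a", "b", "c")], c(a = 0.1, b = 0.2, c = 0.3))
})

test_that("NJ recovers a 4-taxon additive topology (vs LS enumeration)", {
  t0 <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  D <- cophenetic(t0)[letters[1:4], letters[1:4]]
  tr <- neighbor_joining(D)
  expect_equal(phangorn::RF.dist(ape::unroot(t0), tr), 0)
  best <- oracle_best_topology(D)
  expect_equal(phangorn::RF.dist(best, tr), 0)
})

test_that("NJ joins the closest pair first and validates input", {
  D <- matrix(0.8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 0.05
  tr <- neighbor_joining(D)
  parts <- mipscan:::tree_bipartitions(tr)
  expect_true(any(vapply(parts, function(p) setequal(p, c("c", "d")),
                         logical(1L))))  # ab|cd split present
  Dbad <- D; Dbad[1, 2] <- 0.3
  expect_error(neighbor_joining(Dbad), "symmetric")
  expect_error(neighbor_joining(D[1:2, 1:2]), "3")
})

test_that("bootstrap: unanimous columns give 100%, seeds reproduce", {
  mat <- rbind(A = rep(c("A", "C"), 5), B = rep(c("A", "C"), 5),
               C = rep(c("C", "A"), 5), D = rep(c("C", "A"), 5))
  colnames(mat) <- NULL
  bt <- bootstrap_support(mat, n_reps = 200L, seed = 3L)
  parts <- mipscan:::tree_bipartitions(bt)
  expect_equal(unname(attr(parts, "support")), 100)

  b1 <- bootstrap_support(mat, n_reps = 50L, seed = 9L)
  b2 <- bootstrap_support(mat, n_reps = 50L, seed = 9L)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
})

test_that("bootstrap supports are invariant to leaf order", {
  with_seed_t(42L, {
    mat <- matrix(sample(c("A", "C", "G"), 5 * 40, replace = TRUE), nrow = 5,
                  dimnames = list(paste0("t", 1:5), NULL))
    mat[2, ] <- mat[1, ]; mat[2, 1:8] <- "G"  # give t1/t2 shared signal
  })
  sup_of <- function(m) {
    bt <- bootstrap_support(m, n_reps = 100L, seed = 5L)
    parts <- mipscan:::tree_bipartitions(bt)
    s <- attr(parts, "support")
    names(s) <- vapply(parts, paste, character(1L), collapse = "|")
    sort(s)
  }
  s1 <- sup_of(mat)
  s2 <- sup_of(mat[c(3, 1, 5, 2, 4), ])
  common <- intersect(names(s1), names(s2))
  expect_true(length(common) >= 1L)
  # same bipartitions receive statistically indistinguishable support; with
  # the same seed but permuted resampling order, allow small wobble
  expect_true(all(abs(s1[common] - s2[common]) <= 10))
})

test_that("majority-rule collapse contracts weak edges only", {
  tr <- ape::read.tree(text = "((a:1,b:1)100:1,(c:1,d:1)100:1,e:1);")
  kept <- majority_rule_collapse(tr, threshold = 50)
  expect_equal(sort(ape::write.tree(kept)), sort(ape::write.tree(tr)))

  tr2 <- ape::read.tree(text = "((a:1,b:1)40:1,(c:1,d:1)80:1,e:1);")
  col2 <- majority_rule_collapse(tr2, threshold = 50)
  expect_equal(length(col2$tip.label), 5L)
  parts <- mipscan:::tree_bipartitions(col2)
  expect_length(parts, 1L)  # only the cd edge survives
  expect_true(setequal(parts[[1L]], c("c", "d")))

  star <- majority_rule_collapse(tr2, threshold = 101)
  expect_equal(star$Nnode, 1L)

  # collapsed bipartition set is a subset of the original
  p_all <- names(mipscan:::tree_bipartitions(tr2))
  p_col <- names(mipscan:::tree_bipartitions(col2))
  expect_true(all(p_col %in% p_all))
})

test_that("assign_clades labels by smallest unanimous supported clade", {
  tr <- ape::read.tree(
    text = "((q:1,(d1:1,d2:1)90:1)95:1,((a1:1,b1:1)80:1,x:1)70:1,o:1);")
  labels <- c(d1 = "delta", d2 = "delta", a1 = "alpha", b1 = "beta")
  got <- assign_clades(tr, labels, support_threshold = 50)
  expect_equal(got[["q"]], "delta")
  expect_equal(got[["x"]], "unclassified")  # smallest labeled side is mixed
  expect_equal(got[["o"]], "unclassified")  # own branch outside labeled clades

  expect_error(assign_clades(tr, c(zz = "alpha")), "labeled")
})
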