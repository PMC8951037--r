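test_that("character scores match hand-derived cases on a balanced quartet", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  clade <- dollo_character_score(c("A", "B"), tr)
  expect_equal(clade, list(gains = 1L, losses = 0L, transitions = 1L))
  # {A,B,C}: gain at the root, one loss on D (brute-force verified)
  expect_equal(dollo_character_score(c("A", "B", "C"), tr)$transitions, 2L)
  expect_equal(dollo_brute(c("A", "B", "C"), tr), 2L)
  # {A,C}: gain at the root, losses on B and D
  expect_equal(dollo_character_score(c("A", "C"), tr)$transitions, 3L)
  expect_equal(dollo_brute(c("A", "C"), tr), 3L)
  expect_equal(dollo_character_score(character(), tr)$transitions, 0L)
  expect_error(dollo_character_score(c("A", "Z"), tr), "not in tree")
})

test_that("transitions equal 1 exactly when the present set is a clade", {
  set.seed(31)
  for (rep in 1:20) {
    tr <- ape::rtree(7)
    clades <- phangorn::Descendants(tr, 8:13, type = "tips")
    for (cl in clades) {
      expect_equal(dollo_character_score(tr$tip.label[cl], tr)$transitions, 1L)
    }
    # random non-empty sets: score 1 iff monophyletic
    for (k in 1:5) {
      s <- sample(tr$tip.label, sample(2:6, 1))
      sc <- dollo_character_score(s, tr)$transitions
      mono <- ape::is.monophyletic(tr, s)
      expect_equal(sc == 1L, mono)
    }
  }
})

test_that("vectorised scoring agrees with brute force on random trees", {
  set.seed(15)
  for (n in 4:6) {
    for (rep in 1:5) {
      tr <- ape::rtree(n)
      m <- random_pa(n, 40, taxa = tr$tip.label)
      p <- vapply(seq_len(ncol(m)), function(j)
        dollo_character_score(rownames(m)[m[, j] == 1L], tr)$transitions, integer(1))
      brute <- vapply(seq_len(ncol(m)), function(j)
        dollo_brute(rownames(m)[m[, j] == 1L], tr), integer(1))
      expect_identical(p, brute)
      expect_equal(dollo_tree_length(m, tr), sum(brute))
    }
  }
  expect_equal(dollo_tree_length(random_pa(5, 0), ape::rtree(5, tip.label = paste0("s", 1:5))), 0)
})

test_that("search finds the generating topology under perfect signal", {
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  cols <- list(c("A", "B"), c("C", "D"), c("A", "B", "C", "D"))
  m <- pa_matrix(sapply(rep(cols, 7), function(s)
    as.integer(c("O", "A", "B", "C", "D") %in% s)) |>
      `rownames<-`(c("O", "A", "B", "C", "D")))
  res <- dollo_search(m, outgroup = "O", n_jumbles = 3, seed = 1)
  expect_equal(res$score, 21)   # one gain per column
  expect_true(any(vapply(res$trees, function(t)
    isTRUE(ape::all.equal.phylo(t, tr, use.edge.length = FALSE)), logical(1))))
})

test_that("search is deterministic given a seed", {
  set.seed(99)
  m <- random_pa(6, 30)
  a <- dollo_search(m, outgroup = "s1", n_jumbles = 3, seed = 7)
  b <- dollo_search(m, outgroup = "s1", n_jumbles = 3, seed = 7)
  expect_equal(a$score, b$score)
  expect_equal(lapply(a$trees, ape::write.tree), lapply(b$trees, ape::write.tree))
})

test_that("heuristic search attains the exhaustive minimum", {
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    m <- random_pa(n, 30)
    ex <- dollo_search(m, outgroup = "s1", mode = "exhaustive")
    he <- dollo_search(m, outgroup = "s1", n_jumbles = 7, seed = rep)
    expect_equal(he$score, ex$score)
  }
  expect_error(dollo_search(random_pa(10, 5), "s1", mode = "exhaustive"), "heuristic")
})

test_that("bootstrap replicates resample columns with replacement, reproducibly", {
  m <- random_pa(5, 100)
  bs <- bootstrap_replicates(m, n_reps = 200, seed = 3)
  bs2 <- bootstrap_replicates(m, n_reps = 200, seed = 3)
  expect_identical(bs$indices, bs2$indices)
  r <- get_replicate(bs, 1)
  expect_equal(ncol(r), ncol(m))
  # every replicate column is an original column
  expect_true(all(bs$indices >= 1 & bs$indices <= ncol(m)))
  # single-column matrix: every replicate equals the original
  m1 <- m[, 1, drop = FALSE]
  bs1 <- bootstrap_replicates(m1, n_reps = 5, seed = 1)
  expect_identical(unname(pa_states(get_replicate(bs1, 3))), unname(pa_states(m1)))
  # mean per-column inclusion frequency ~ 1 - 1/e
  incl <- mean(apply(bs$indices, 1, function(i) length(unique(i)))) / ncol(m)
  expect_lt(abs(incl - (1 - exp(-1))), 0.02)
  expect_error(bootstrap_replicates(m, n_reps = 0), "n_reps")
})

test_that("majority consensus keeps clades above the strict threshold", {
  t1 <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  t2 <- ape::read.tree(text = "(O,((A,C),(B,D)));")
  # identical trees: same topology, all supports 1
  cons <- majority_consensus(rep(list(t1), 10))
  expect_true(ape::all.equal.phylo(cons, t1, use.edge.length = FALSE))
  expect_true(all(cons$node.label == 1))
  # 6/10 for one resolution: kept with support 0.6
  cons <- majority_consensus(c(rep(list(t1), 6), rep(list(t2), 4)))
  key <- clade_support(cons, c("A", "B"))
  expect_equal(key, 0.6)
  # exact 50/50: neither resolution kept, polytomy remains
  cons <- majority_consensus(c(rep(list(t1), 5), rep(list(t2), 5)))
  expect_gt(ape::Ntip(cons) + cons$Nnode, 0)
  expect_false(is_clade(cons, c("A", "B")))
  expect_false(is_clade(cons, c("A", "C")))
  expect_error(majority_consensus(list(t1, ape::rtree(4))), "leaf sets")
  # support values do not depend on input order
  set.seed(4)
  trees <- c(rep(list(t1), 7), rep(list(t2), 3))
  c1 <- majority_consensus(trees)
  c2 <- majority_consensus(rev(trees))
  expect_equal(sort(c1$node.label), sort(c2$node.label))
})

test_that("consensus topology matches ape's majority rule", {
  set.seed(8)
  trees <- lapply(1:9, function(i) ape::rtree(6, tip.label = paste0("s", 1:6)))
  cons <- majority_consensus(trees)
  ref <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  expect_equal(phangorn::RF.dist(cons, ref), 0)
})

test_that("NJ recovers the topology from exactly additive distances", {
  tr <- ape::read.tree(text = "(((A,B),C),(D,(E,F)));")
  m <- additive_matrix(tr, k_per_edge = sample(2:6, nrow(tr$edge), replace = TRUE))
  nj <- nj_tree(m)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), nj), 0)
  # identical rows join first: zero distance
  m2 <- pa_matrix(rbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L), c = c(0L, 1L, 0L),
                        d = c(0L, 1L, 1L)))
  nj2 <- nj_tree(m2)
  d <- ape::cophenetic.phylo(nj2)
  expect_equal(unname(d["a", "b"]), 0)
  expect_error(nj_tree(m2[1:2, ]), "3 taxa")
})
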