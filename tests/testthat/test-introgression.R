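test_that("quartet enumeration covers every 4-subset exactly once", {
  q11 <- enumerate_quartets(paste0("s", 1:11))
  expect_equal(ncol(q11), 330)
  expect_equal(ncol(enumerate_quartets(letters[1:4])), 1)
  expect_equal(ncol(enumerate_quartets(letters[1:5])), 5)
  expect_equal(anyDuplicated(apply(q11, 2, paste, collapse = ",")), 0)
  expect_error(enumerate_quartets(letters[1:3]), "at least 4")
})

test_that("pattern counts match direct per-column tallies", {
  set.seed(61)
  m <- random_pa(8, 200)
  quartets <- enumerate_quartets(rownames(m))
  for (i in sample(ncol(quartets), 10)) {
    q <- quartets[, i]
    expect_equal(quartet_pattern_counts(m, q), brute_quartet_counts(m, q))
  }
  # a column with 3 of 4 present is excluded
  taxa <- c("A", "B", "C", "D", "E")
  m2 <- pa_matrix(sapply(list(c("A", "B"), c("A", "B", "C"), c("A", "B", "C", "D")),
                         function(s) as.integer(taxa %in% s)) |> `rownames<-`(taxa))
  expect_equal(unname(quartet_pattern_counts(m2, c("A", "B", "C", "D"))), c(1L, 0L, 0L))
})

test_that("counts are invariant to taxon order within the quartet", {
  set.seed(62)
  m <- random_pa(6, 100)
  q <- c("s1", "s3", "s4", "s6")
  base <- quartet_pattern_counts(m, q)
  perm <- c("s4", "s1", "s6", "s3")   # pairs {s4,s1} = old ac pairing etc.
  got <- quartet_pattern_counts(m, perm)
  expect_equal(sort(unname(got)), sort(unname(base)))
  expect_equal(sum(got), sum(base))
})

test_that("the 2N - L identity ties parsimony length to direct counts", {
  set.seed(63)
  m <- random_pa(8, 150)
  quartets <- enumerate_quartets(rownames(m))
  for (i in sample(ncol(quartets), 8)) {
    q <- quartets[, i]
    counts <- quartet_pattern_counts(m, q)
    for (s in 1:3) {
      pc <- parsimony_crosscheck(m, q, s)
      expect_equal(pc$support, unname(counts[s]))
      expect_equal(pc$N, sum(counts))
    }
  }
  # all columns matching the split: L = N, support = N
  taxa <- c("A", "B", "C", "D")
  m2 <- pa_matrix(matrix(rep(c(1L, 1L, 0L, 0L), 10), 4,
                         dimnames = list(taxa, NULL)))
  pc <- parsimony_crosscheck(m2, taxa, 1)
  expect_equal(pc$L, pc$N)
  expect_equal(pc$support, 10L)
})

test_that("quartet Fitch lengths agree with phangorn's parsimony", {
  set.seed(64)
  m <- random_pa(7, 120)
  quartets <- enumerate_quartets(rownames(m))
  splits_nwk <- function(q, s) {
    o <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))[[s]]
    sprintf("((%s,%s),(%s,%s));", q[o[1]], q[o[2]], q[o[3]], q[o[4]])
  }
  for (i in sample(ncol(quartets), 5)) {
    q <- quartets[, i]
    pr <- unclass(m)[q, colSums(unclass(m)[q, ]) == 2, drop = FALSE]
    dat <- phangorn::phyDat(pr, type = "USER", levels = c(0, 1))
    for (s in 1:3) {
      ref <- phangorn::parsimony(ape::read.tree(text = splits_nwk(q, s)), dat)
      expect_equal(parsimony_crosscheck(m, q, s)$L, as.integer(ref))
    }
  }
})

test_that("accepted split follows the species tree and flags polytomies", {
  tr <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(accepted_split(tr, c("A", "B", "C", "D")), 1L)
  expect_equal(accepted_split(tr, c("A", "C", "B", "D")), 2L)   # ab|cd reordered
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_true(is.na(accepted_split(star, c("A", "B", "C", "D"))))
  # pruning first then splitting gives the same answer
  big <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),G));")
  q <- c("A", "C", "E", "G")
  pruned <- ape::keep.tip(big, q)
  expect_equal(accepted_split(big, q), accepted_split(pruned, q))
})

test_that("chi-square asymmetry test matches hand-computed values", {
  even <- asymmetry_chi2(50, 50)
  expect_equal(even$chi2, 0)
  expect_equal(even$p_raw, 1)
  skew <- asymmetry_chi2(60, 40)
  expect_equal(skew$chi2, 4)
  expect_equal(skew$p_raw, pchisq(4, 1, lower.tail = FALSE))
  one <- asymmetry_chi2(10, 0)
  expect_equal(one$chi2, 10)
  expect_equal(one$p_raw, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(asymmetry_chi2(0, 0), ">= 1")
})

test_that("Holm correction rejects per the step-down rule", {
  h <- holm_correction(c(0.01, 0.02, 0.2), alpha = 0.05)
  expect_equal(h$significant, c(TRUE, TRUE, FALSE))
  expect_equal(h$p_holm, c(0.03, 0.04, 0.2))
  single <- holm_correction(0.03)
  expect_equal(single$p_holm, 0.03)
  expect_true(single$significant)
  none <- holm_correction(rep(1, 5))
  expect_false(any(none$significant))
  empty <- holm_correction(numeric())
  expect_length(empty$p_holm, 0)
})

test_that("full quartet test output is consistent and order-invariant", {
  mod <- pulse_model_6tax()
  m <- simulate_matrix(mod, seed = 5)
  qt <- suppressWarnings(quartet_asymmetry_test(m, mod$tree))
  expect_equal(nrow(qt), choose(6, 4))
  tst <- qt[qt$testable, ]
  expect_true(all(tst$n_accepted + tst$n_alt1 + tst$n_alt2 <= ncol(m)))
  expect_true(all(abs(tst$expected_alt - (tst$n_alt1 + tst$n_alt2) / 2) < 1e-12))
  expect_true(all(tst$chi2[tst$n_alt1 == tst$n_alt2] == 0))
  expect_true(all(tst$p_holm >= tst$p_raw - 1e-12))
  expect_true(all(!is.na(tst$overrepresented_split[tst$significant])))
  # column shuffling does not change the outcome
  qt2 <- suppressWarnings(quartet_asymmetry_test(m[, sample(ncol(m))], mod$tree))
  expect_equal(qt2$chi2, qt$chi2)
  expect_equal(qt2$significant, qt$significant)
})

test_that("implicated pairs tally both pairs of the overrepresented split", {
  mod <- pulse_model_6tax()
  m <- simulate_matrix(mod, seed = 6)
  qt <- suppressWarnings(quartet_asymmetry_test(m, mod$tree))
  ip <- implicated_pairs(qt)
  expect_equal(sum(ip$n_quartets), 2 * sum(qt$significant))
  expect_true(all(diff(ip$n_quartets) <= 0))
  # no significant quartets: empty table
  empty <- qt[0, ]
  class(empty) <- class(qt)
  expect_equal(nrow(implicated_pairs(empty)), 0)
})
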