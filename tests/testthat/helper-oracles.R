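# Shared fixtures and independent oracles. Oracles deliberately use the
# dumbest correct algorithm (exhaustive enumeration) so they stay
# independent of the vectorised implementations they check.

# Bare integer states of a pa_matrix (drops class and metadata attributes)
# for content comparisons.
pa_states <- function(m) {
  matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

random_pa <- function(n_taxa, n_loci, taxa = paste0("s", seq_len(n_taxa))) {
  pa_matrix(matrix(sample(0:1, n_taxa * n_loci, replace = TRUE), n_taxa,
                   dimnames = list(taxa, NULL)))
}

# Minimal Dollo transitions by brute force: enumerate every assignment of
# internal-node states, keep those with at most one 0->1 gain (a state-1
# root implies the gain happened on the root stem and costs one
# transition), take the minimum transition count.
dollo_brute <- function(present, tree) {
  n <- length(tree$tip.label)
  k <- tree$Nnode
  tipstate <- as.integer(tree$tip.label %in% present)
  if (sum(tipstate) == 0) return(0L)
  root <- n + 1L
  E <- tree$edge
  best <- Inf
  for (code in 0:(2^k - 1)) {
    st <- c(tipstate, as.integer(intToBits(code))[seq_len(k)])
    changes <- sum(st[E[, 1]] != st[E[, 2]]) + st[root]
    gains <- sum(st[E[, 1]] == 0 & st[E[, 2]] == 1) + st[root]
    if (gains <= 1 && changes < best) best <- changes
  }
  as.integer(best)
}

# Vectorised variant scoring every pattern on a tree at once (same
# enumeration, used where the per-pattern loop would dominate runtime).
dollo_brute_all_patterns <- function(tree) {
  n <- length(tree$tip.label)
  k <- tree$Nnode
  root <- n + 1L
  E <- tree$edge
  n_pat <- 2^n
  pat <- t(sapply(0:(n_pat - 1), function(p) as.integer(intToBits(p))[seq_len(n)]))
  asg <- t(sapply(0:(2^k - 1), function(c) as.integer(intToBits(c))[seq_len(k)]))
  ST <- rbind(t(pat[rep(seq_len(n_pat), each = 2^k), , drop = FALSE]),
              t(asg[rep(seq_len(2^k), times = n_pat), , drop = FALSE]))
  changes <- colSums(ST[E[, 1], , drop = FALSE] != ST[E[, 2], , drop = FALSE]) + ST[root, ]
  gains <- colSums(ST[E[, 1], , drop = FALSE] == 0 & ST[E[, 2], , drop = FALSE] == 1) + ST[root, ]
  changes[gains > 1] <- Inf
  grp <- rep(seq_len(n_pat), each = 2^k)
  best <- tapply(changes, grp, min)
  best[1] <- 0   # all-absent pattern: no gain, no transitions
  as.integer(best)   # indexed by pattern code + 1 (bit i = tip i)
}

# Brute-force quartet vote counts at one branch: enumerate every
# one-per-cluster quadruple and every column.
brute_branch_votes <- function(P, A, B, C, D) {
  v <- c(0, 0, 0)
  for (col in seq_len(ncol(P))) {
    s <- P[, col]
    for (a in A) for (b in B) for (cc in C) for (d in D) {
      x <- s[c(a, b, cc, d)]
      if (sum(x) != 2) next
      if ((x[1] && x[2]) || (x[3] && x[4])) v[1] <- v[1] + 1
      else if ((x[1] && x[3]) || (x[2] && x[4])) v[2] <- v[2] + 1
      else v[3] <- v[3] + 1
    }
  }
  v
}

# Direct per-column tally of quartet-informative patterns.
brute_quartet_counts <- function(m, q) {
  v <- c(ab_cd = 0L, ac_bd = 0L, ad_bc = 0L)
  for (col in seq_len(ncol(m))) {
    x <- unclass(m)[q, col]
    if (sum(x) != 2) next
    if (x[1] && x[2]) v[1] <- v[1] + 1L
    else if (x[1] && x[3]) v[2] <- v[2] + 1L
    else if (x[1] && x[4]) v[3] <- v[3] + 1L
    else if (x[3] && x[4]) v[1] <- v[1] + 1L
    else if (x[2] && x[4]) v[2] <- v[2] + 1L
    else v[3] <- v[3] + 1L
  }
  v
}

# A matrix whose taxon-pair Hamming distances are exactly additive on
# `tree`: each edge contributes `k` identical columns marking the tips
# below it.
additive_matrix <- function(tree, k_per_edge) {
  n <- length(tree$tip.label)
  cols <- list()
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2]
    tips <- if (v <= n) v else phangorn::Descendants(tree, v, type = "tips")[[1]]
    col <- integer(n)
    col[tips] <- 1L
    cols <- c(cols, rep(list(col), k_per_edge[e]))
  }
  pa_matrix(matrix(unlist(cols), nrow = n, dimnames = list(tree$tip.label, NULL)))
}

quartet_model_4tax <- function(internal = 0.5, n_loci = 2000, ...) {
  tr <- ape::read.tree(text = sprintf("((A:1,B:1):%g,(C:1,D:1):%g);", internal, internal))
  sim_model(tr, n_loci = n_loci, ...)
}

pulse_model_6tax <- function(prob = 0.3, n_loci = 10000) {
  tr <- ape::read.tree(text = "(((((A:1,B:1):0.5,C:1.5):0.5,D:2):0.5,E:2.5):1,O:3.5);")
  sim_model(tr, pulses = data.frame(time = 0.5, donor = "C", recipient = "E",
                                    prob = prob),
            n_loci = n_loci)
}

# helpers for clade membership on consensus trees
is_clade <- function(tree, tips) {
  any(vapply(phangorn::Descendants(tree, length(tree$tip.label) + seq_len(tree$Nnode),
                                   type = "tips"),
             function(d) setequal(tree$tip.label[d], tips), logical(1)))
}
clade_support <- function(tree, tips) {
  nodes <- length(tree$tip.label) + seq_len(tree$Nnode)
  d <- phangorn::Descendants(tree, nodes, type = "tips")
  hit <- vapply(d, function(i) setequal(tree$tip.label[i], tips), logical(1))
  as.numeric(tree$node.label[hit][1])
}
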