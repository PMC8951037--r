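#' Dollo parsimony score of one presence/absence character
#'
#' Under the Dollo model an insertion arises exactly once (a single 0->1
#' gain, placed at the most recent common ancestor of the taxa carrying
#' it) and may be lost any number of times (1->0). The score is the
#' minimal number of state transitions under that constraint, with
#' ancestral absence at the root. A character whose present taxa form a
#' clade needs one transition (the gain); every extra transition is a
#' loss, and two or more transitions mark the character as discordant
#' with the tree.
#'
#' @param present_set character vector of tip labels carrying the
#'   insertion (may be empty).
#' @param tree a rooted `phylo` tree.
#' @return a list with integer components `gains` (0 or 1), `losses`, and
#'   `transitions = gains + losses`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' dollo_character_score(c("A", "B"), tr)$transitions   # a clade: 1
#' dollo_character_score(c("A", "C"), tr)$transitions   # needs 2 losses: 3
#' @export
dollo_character_score <- function(present_set, tree) {
  bad <- setdiff(present_set, tree$tip.label)
  if (length(bad)) stop("taxa not in tree: ", paste(bad, collapse = ", "))
  m <- matrix(as.integer(tree$tip.label %in% present_set), ncol = 1,
              dimnames = list(tree$tip.label, "x"))
  p <- dollo_profile(pa_matrix(m), tree)
  list(gains = p$gains[1], losses = p$losses[1], transitions = p$transitions[1])
}

# Vectorised Dollo scoring of every column of a complete matrix.
# Returns per-column gains, losses, transitions and the node (ape id) of
# the single gain (the MRCA of the present taxa; NA for all-absent).
#
# Mechanics: count present tips below each node (one matrix product);
# a node is in state 1 iff it descends from (or is) the gain node and has
# a present descendant. Losses are edges from a state-1 parent to a
# subtree with no present tip.
dollo_profile <- function(m, tree, weights = NULL) {
  if (!inherits(tree, "phylo") || !ape::is.rooted(tree))
    stop("`tree` must be a rooted phylo object")
  if (!setequal(rownames(m), tree$tip.label))
    stop("matrix taxa and tree tip labels differ")
  stopifnot_complete(m)
  P <- unclass(m)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nno <- ntip + tree$Nnode
  L <- ncol(P)
  if (L == 0L)
    return(list(gains = integer(), losses = integer(),
                transitions = integer(), mrca = integer()))
  desc <- phangorn::Descendants(tree, seq_len(nno), type = "tips")
  A <- matrix(0L, nno, ntip)
  for (i in seq_len(nno)) A[i, desc[[i]]] <- 1L
  C <- A %*% P                          # present tips below each node
  total <- colSums(P)
  S <- rowSums(A)                       # clade sizes
  totN <- matrix(total, nno, L, byrow = TRUE)
  full <- (C == totN) & totN > 0L
  Smask <- matrix(S, nno, L)
  Smask[!full] <- Inf
  mrca <- max.col(-t(Smask), ties.method = "first")   # smallest full clade
  E <- tree$edge
  Cu <- C[E[, 1], , drop = FALSE]
  Cv <- C[E[, 2], , drop = FALSE]
  totE <- matrix(total, nrow(E), L, byrow = TRUE)
  zero_child <- Cv == 0L
  below_mrca <- Cu > 0L & Cu < totE
  at_mrca <- matrix(mrca, nrow(E), L, byrow = TRUE) == E[, 1]
  losses <- colSums(zero_child & (below_mrca | at_mrca))
  gains <- as.integer(total > 0L)
  losses[gains == 0L] <- 0L
  mrca[gains == 0L] <- NA_integer_
  list(gains = gains, losses = as.integer(losses),
       transitions = gains + as.integer(losses), mrca = mrca)
}

#' Dollo tree length of a matrix
#'
#' Sum of [dollo_character_score()] transitions over all columns,
#' optionally weighted (used internally for collapsed duplicate columns).
#'
#' @param m a complete [pa_matrix()] whose taxa match the tree's tips.
#' @param tree a rooted `phylo`.
#' @param weights optional per-column multiplicities.
#' @return the total number of state transitions.
#' @export
dollo_tree_length <- function(m, tree, weights = NULL) {
  p <- dollo_profile(m, tree)
  if (is.null(weights)) sum(p$transitions) else sum(p$transitions * weights)
}

#' Search for most-parsimonious Dollo trees
#'
#' Searches rooted topologies with a fixed basal outgroup for the minimal
#' Dollo tree length. The heuristic mode runs stepwise addition once per
#' jumbled taxon order followed by nearest-neighbor-interchange
#' hill-climbing; the exhaustive mode scores every rooted topology and is
#' limited to 9 taxa. All distinct topologies attaining the best score
#' found are returned.
#'
#' @param m a complete [pa_matrix()].
#' @param outgroup tip label fixed as one of the root's two children;
#'   Dollo scoring requires a root, and the most divergent lineage plays
#'   this role.
#' @param n_jumbles number of random addition orders (heuristic mode).
#' @param seed optional integer seed; identical seeds give identical
#'   output.
#' @param mode `"heuristic"` or `"exhaustive"`.
#' @return a list with `trees` (list of rooted `phylo`, lexicographically
#'   sorted canonical newick order), `score` (minimal tree length), and
#'   `mode`.
#' @export
dollo_search <- function(m, outgroup, n_jumbles = 7, seed = NULL,
                         mode = c("heuristic", "exhaustive")) {
  mode <- match.arg(mode)
  taxa <- rownames(m)
  if (length(taxa) < 3) stop("need at least 3 taxa")
  if (!outgroup %in% taxa) stop("outgroup '", outgroup, "' not among taxa")
  if (!is.null(seed)) set.seed(seed)
  cm <- pa_collapse(m)
  if (mode == "exhaustive") {
    if (length(taxa) > 9)
      stop("exhaustive search supports at most 9 taxa; use mode = \"heuristic\"")
    return(dollo_exhaustive(cm, taxa, outgroup))
  }
  ingroup <- setdiff(taxa, outgroup)
  best_score <- Inf
  best <- list()
  best_keys <- character()
  for (j in seq_len(n_jumbles)) {
    ord <- if (length(ingroup) > 1) sample(ingroup) else ingroup
    tr <- stepwise_addition(cm, outgroup, ord)
    tr <- nni_hillclimb(cm, tr, outgroup)
    sc <- dollo_tree_length(cm$m[tr$tip.label, , drop = FALSE], tr, cm$weights)
    key <- canonical_newick(tr)
    if (sc < best_score) {
      best_score <- sc; best <- list(tr); best_keys <- key
    } else if (sc == best_score && !key %in% best_keys) {
      best <- c(best, list(tr)); best_keys <- c(best_keys, key)
    }
  }
  o <- order(best_keys)
  list(trees = best[o], score = best_score, mode = mode)
}

dollo_exhaustive <- function(cm, taxa, outgroup) {
  ingroup <- setdiff(taxa, outgroup)
  cand <- if (length(ingroup) == 1) {
    list(ape::read.tree(text = sprintf("(%s,%s);", outgroup, ingroup)))
  } else {
    sub <- phangorn::allTrees(length(ingroup), rooted = TRUE, tip.label = ingroup)
    lapply(sub, function(s) {
      core <- sub(";$", "", ape::write.tree(s))
      ape::read.tree(text = sprintf("(%s,%s);", outgroup, core))
    })
  }
  scores <- vapply(cand, function(tr)
    dollo_tree_length(cm$m[tr$tip.label, , drop = FALSE], tr, cm$weights), numeric(1))
  best <- which(scores == min(scores))
  keys <- vapply(cand[best], canonical_newick, "")
  o <- order(keys)
  list(trees = cand[best][o], score = min(scores), mode = "exhaustive")
}

stepwise_addition <- function(cm, outgroup, ord) {
  if (length(ord) < 2)
    return(ape::read.tree(text = sprintf("(%s,%s);", outgroup, ord)))
  tr <- ape::read.tree(text = sprintf("(%s,(%s,%s));", outgroup, ord[1], ord[2]))
  for (k in seq(3, length.out = length(ord) - 2)) {
    label <- ord[k]
    sub <- cm$m[c(tr$tip.label, label), , drop = FALSE]
    cands <- lapply(allowed_edges(tr, outgroup), function(e) add_tip(tr, e, label))
    scores <- vapply(cands, function(ct)
      dollo_tree_length(sub[ct$tip.label, , drop = FALSE], ct, cm$weights), numeric(1))
    tr <- cands[[which.min(scores)]]
  }
  tr
}

# Every edge except the outgroup's pendant edge (attaching there would
# displace the outgroup from the root).
allowed_edges <- function(tr, outgroup) {
  og <- match(outgroup, tr$tip.label)
  which(tr$edge[, 2] != og)
}

# Hill-climb through NNI neighborhoods. Equal-score (plateau) moves are
# allowed a bounded number of times, with visited topologies tracked to
# avoid cycling; plateaus of equally parsimonious rearrangements are
# common with binary characters and block a purely greedy climb.
nni_hillclimb <- function(cm, tr, outgroup, max_plateau = 25) {
  if (length(tr$tip.label) < 4) return(tr)
  score <- function(t) dollo_tree_length(cm$m[t$tip.label, , drop = FALSE], t, cm$weights)
  cur <- score(tr)
  visited <- canonical_newick(tr)
  plateau <- 0
  repeat {
    neigh <- lapply(phangorn::nni(ape::unroot(tr)), root_at_outgroup, outgroup = outgroup)
    scores <- vapply(neigh, score, numeric(1))
    best <- min(scores)
    if (best < cur) {
      tr <- neigh[[which.min(scores)]]
      cur <- best
      plateau <- 0
      visited <- c(visited, canonical_newick(tr))
    } else if (best == cur && plateau < max_plateau) {
      keys <- vapply(neigh[scores == best], canonical_newick, "")
      fresh <- which(!keys %in% visited)
      if (length(fresh) == 0) break
      tr <- neigh[scores == best][[fresh[1]]]
      plateau <- plateau + 1
      visited <- c(visited, keys[fresh[1]])
    } else break
  }
  tr
}

#' Bootstrap resampling of matrix columns
#'
#' Draws `n_reps` with-replacement column resamples of the matrix, each
#' preserving the original column count.
#'
#' @param m a [pa_matrix()] with at least one column.
#' @param n_reps number of replicates.
#' @param seed optional integer seed.
#' @return an object of class `bootstrap_set` holding the source matrix
#'   and an `n_reps` x `ncol(m)` matrix of sampled column indices; extract
#'   replicate matrices with [get_replicate()].
#' @export
bootstrap_replicates <- function(m, n_reps = 1000, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (ncol(m) < 1) stop("matrix has no columns")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(ncol(m), n_reps * ncol(m), replace = TRUE),
                nrow = n_reps)
  structure(list(matrix = m, indices = idx, n_reps = n_reps, seed = seed),
            class = "bootstrap_set")
}

#' @rdname bootstrap_replicates
#' @param bs a `bootstrap_set`.
#' @param i replicate number.
#' @export
get_replicate <- function(bs, i) {
  cols <- bs$indices[i, ]
  m <- unclass(bs$matrix)[, cols, drop = FALSE]
  colnames(m) <- make.unique(colnames(m))
  pa_matrix(m)
}

#' @export
print.bootstrap_set <- function(x, ...) {
  cat(sprintf("Bootstrap set: %d replicates of a %d x %d matrix (seed %s)\n",
              x$n_reps, nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Dollo bootstrap analysis
#'
#' Convenience wrapper: resamples columns, runs a Dollo search per
#' replicate and returns one best tree per replicate (ready for
#' [majority_consensus()]).
#'
#' @inheritParams dollo_search
#' @param n_reps number of bootstrap replicates.
#' @param n_jumbles addition orders per replicate search (1 keeps
#'   bootstrap analyses fast; raise for rugged datasets).
#' @return list of rooted `phylo` trees, one per replicate.
#' @export
dollo_bootstrap <- function(m, outgroup, n_reps = 100, seed = NULL, n_jumbles = 1) {
  bs <- bootstrap_replicates(m, n_reps = n_reps, seed = seed)
  lapply(seq_len(n_reps), function(i) {
    res <- dollo_search(get_replicate(bs, i), outgroup, n_jumbles = n_jumbles)
    res$trees[[1]]
  })
}

#' Majority-rule consensus of rooted trees
#'
#' Builds the tree containing exactly the clades present in strictly more
#' than `threshold` of the input trees (for `threshold >= 0.5` these are
#' mutually compatible). Each retained clade is annotated with its
#' frequency as a node label; unresolved regions collapse to polytomies.
#' A clade at exactly the threshold is excluded, matching PHYLIP's
#' majority rule with the "extended" option off.
#'
#' @param trees list of rooted `phylo` objects on an identical leaf set.
#' @param threshold clade-frequency threshold in \[0.5, 1).
#' @return a rooted `phylo`; `node.label` holds clade frequencies (the
#'   root's is 1).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (threshold < 0.5 || threshold >= 1)
    stop("threshold must be in [0.5, 1)")
  if (length(trees) == 0) stop("no trees given")
  taxa <- sort(trees[[1]]$tip.label)
  n <- length(trees)
  keys <- unlist(lapply(trees, function(tr) {
    if (!setequal(tr$tip.label, taxa)) stop("trees have differing leaf sets")
    vapply(clade_sets(tr), paste, "", collapse = "\r")
  }))
  tab <- table(keys)
  keep <- tab[tab / n > threshold]
  clades <- lapply(strsplit(names(keep), "\r", fixed = TRUE), identity)
  supports <- as.numeric(keep) / n
  out <- tree_from_clades(taxa, clades, supports)
  out$node.label <- as.numeric(out$node.label)
  root_id <- length(out$tip.label) + 1L
  out$node.label[1] <- max(out$node.label[1], 1, na.rm = TRUE)
  out
}

#' Neighbor-joining tree from the 01 matrix
#'
#' Computes normalized Hamming distances between taxon rows (fraction of
#' loci at which two taxa differ) and applies the Saitou-Nei
#' neighbor-joining algorithm. Negative estimated branch lengths are
#' clamped to zero with a warning.
#'
#' @param m a complete [pa_matrix()] with at least 3 taxa.
#' @return an unrooted `phylo` with branch lengths.
#' @export
nj_tree <- function(m) {
  if (nrow(m) < 3) stop("need at least 3 taxa")
  stopifnot_complete(m)
  d <- stats::dist(unclass(m), method = "manhattan") / ncol(m)
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
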