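#' Bipartition gene trees from an insertion matrix
#'
#' Each informative column (at least two taxa on each side) becomes an
#' incompletely resolved gene tree with exactly one internal edge
#' separating the insertion-bearing taxa from the rest, rendered as
#' `((p1,p2,...),(a1,a2,...));`. These are the inputs quartet-based
#' species-tree methods such as ASTRAL consume. Uninformative columns are
#' skipped and counted in attribute `"skipped"`.
#'
#' @param m a complete [pa_matrix()].
#' @return character vector of newick strings, one per informative
#'   column, named by locus id.
#' @export
bp_gene_trees <- function(m) {
  stopifnot_complete(m)
  np <- colSums(m)
  keep <- np >= 2L & (nrow(m) - np) >= 2L
  taxa <- rownames(m)
  out <- vapply(which(keep), function(j) {
    pres <- taxa[m[, j] == 1L]
    abs_ <- taxa[m[, j] == 0L]
    sprintf("((%s),(%s));", paste(pres, collapse = ","), paste(abs_, collapse = ","))
  }, "")
  names(out) <- colnames(m)[keep]
  attr(out, "skipped") <- sum(!keep)
  out
}

#' @rdname bp_gene_trees
#' @param trees vector as returned by `bp_gene_trees()`.
#' @param path output file, one newick per line.
#' @export
write_bp_gene_trees <- function(trees, path) {
  writeLines(trees, path)
  invisible(path)
}

#' Per-branch quartet support of a species tree
#'
#' For every internal branch of the (unrooted) species tree, taxa fall
#' into four clusters `A,B` (one endpoint) and `C,D` (the other). Each
#' informative column, read as the bipartition present/absent, casts
#' weighted votes: a quartet with one taxon drawn from each cluster
#' supports the arrangement that matches the column's split. The main
#' topology `AB|CD` pairs the clusters sharing an endpoint; `AC|BD` and
#' `AD|BC` are the alternates. Vote totals use the closed form
#' `|A∩S||B∩S||C\\S||D\\S| + |A\\S||B\\S||C∩S||D∩S|` (and permutations),
#' summed over columns, then normalized per branch — the quantities drawn
#' as pie charts on species-tree branches in retroelement studies.
#'
#' @param m a complete [pa_matrix()].
#' @param species_tree a binary `phylo` (rooted or unrooted) on the
#'   matrix taxa.
#' @return data frame with one row per internal branch: the four cluster
#'   memberships, vote totals, and fractions `q1` (main), `q2`, `q3`.
#' @export
branch_quartet_support <- function(m, species_tree) {
  stopifnot_complete(m)
  if (!setequal(rownames(m), species_tree$tip.label))
    stop("matrix taxa and tree tip labels differ")
  ut <- if (ape::is.rooted(species_tree)) ape::unroot(species_tree) else species_tree
  ntip <- length(ut$tip.label)
  deg <- tabulate(c(ut$edge[, 1], ut$edge[, 2]), nbins = ntip + ut$Nnode)
  if (any(deg[-seq_len(ntip)] > 3))
    stop("species tree has polytomies; branch clusters are not quartets")
  adj <- tree_adjacency(ut)
  P <- unclass(m)[ut$tip.label, , drop = FALSE]
  internal <- ut$edge[, 1] > ntip & ut$edge[, 2] > ntip
  rows <- lapply(which(internal), function(e) {
    u <- ut$edge[e, 1]; v <- ut$edge[e, 2]
    sideA <- setdiff(adj[[v]], u)     # clusters at v
    sideC <- setdiff(adj[[u]], v)     # clusters at u
    cl <- lapply(c(sideA, sideC), function(w) subtree_tips(adj, ut, w, blocked = if (w %in% sideA) v else u))
    names(cl) <- c("A", "B", "C", "D")
    cnt <- lapply(cl, function(tips) colSums(P[tips, , drop = FALSE]))
    siz <- lengths(cl)
    a <- cnt$A; b <- cnt$B; cc <- cnt$C; d <- cnt$D
    an <- siz["A"] - a; bn <- siz["B"] - b; cn <- siz["C"] - cc; dn <- siz["D"] - d
    v1 <- sum(a * b * cn * dn + an * bn * cc * d)   # AB|CD
    v2 <- sum(a * cc * bn * dn + an * cn * b * d)   # AC|BD
    v3 <- sum(a * d * bn * cn + an * dn * b * cc)   # AD|BC
    tot <- v1 + v2 + v3
    data.frame(
      branch = e,
      cluster_A = paste(sort(ut$tip.label[cl$A]), collapse = ","),
      cluster_B = paste(sort(ut$tip.label[cl$B]), collapse = ","),
      cluster_C = paste(sort(ut$tip.label[cl$C]), collapse = ","),
      cluster_D = paste(sort(ut$tip.label[cl$D]), collapse = ","),
      votes = tot,
      q1 = if (tot > 0) v1 / tot else NA_real_,
      q2 = if (tot > 0) v2 / tot else NA_real_,
      q3 = if (tot > 0) v3 / tot else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  out
}

#' Quartet agreement score of a candidate species tree
#'
#' Total number of resolved quartets, over all columns read as
#' bipartitions, that agree with the split the candidate tree induces on
#' the quartet's four taxa. This is the criterion quartet-based
#' species-tree methods maximize; it ranks candidate topologies (e.g.
#' Dollo and NJ trees) on the same footing.
#'
#' @param m a complete [pa_matrix()].
#' @param candidate_tree a `phylo` on the matrix taxa.
#' @return the total agreement count (a non-negative number).
#' @export
quartet_score <- function(m, candidate_tree) {
  stopifnot_complete(m)
  if (!setequal(rownames(m), candidate_tree$tip.label))
    stop("matrix taxa and tree tip labels differ")
  taxa <- sort(rownames(m))
  quartets <- enumerate_quartets(taxa)
  D <- quartet_distance_matrix(candidate_tree)
  total <- 0
  for (i in seq_len(ncol(quartets))) {
    q <- quartets[, i]
    acc <- accepted_split_from_dist(D, q)
    if (is.na(acc)) next
    counts <- quartet_pattern_counts(m, q)
    total <- total + counts[acc]
  }
  unname(total)
}
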