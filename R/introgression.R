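#' Enumerate all 4-taxon subsets
#'
#' @param taxa ordered character vector of at least 4 labels.
#' @return a 4 x C(n,4) character matrix, one quartet per column, in
#'   deterministic [utils::combn()] order.
#' @examples
#' ncol(enumerate_quartets(letters[1:11]))   # 330
#' @export
enumerate_quartets <- function(taxa) {
  if (length(taxa) < 4) stop("need at least 4 taxa")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  utils::combn(taxa, 4)
}

# Canonical split labels for a quartet q = (a,b,c,d) in the given order:
# split 1 = ab|cd, split 2 = ac|bd, split 3 = ad|bc.
split_label <- function(q, s) {
  pairs <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))[[s]]
  paste0(q[pairs[1]], q[pairs[2]], "|", q[pairs[3]], q[pairs[4]])
}

#' Count informative characters supporting each quartet split
#'
#' Restricts every column to the four taxa; a column with exactly two of
#' them carrying the insertion votes for the split uniting those two.
#' All other restricted patterns (0, 1, 3 or 4 present) are uninformative
#' for the quartet and excluded.
#'
#' @param m a complete [pa_matrix()].
#' @param q character vector of 4 taxon labels `(a, b, c, d)`.
#' @return integer vector `c(ab_cd, ac_bd, ad_bc)` of supporting-character
#'   counts.
#' @export
quartet_pattern_counts <- function(m, q) {
  stopifnot_complete(m)
  if (length(q) != 4 || !all(q %in% rownames(m)))
    stop("q must be 4 taxa present in the matrix")
  pa <- unclass(m)[q[1], ]; pb <- unclass(m)[q[2], ]
  pc_ <- unclass(m)[q[3], ]; pd <- unclass(m)[q[4], ]
  s <- pa + pb + pc_ + pd
  inf <- s == 2L
  c(ab_cd = sum(inf & pa & pb), ac_bd = sum(inf & pa & pc_),
    ad_bc = sum(inf & pa & pd)) +
    c(sum(inf & pc_ & pd & !pa), sum(inf & pb & pd & !pa), sum(inf & pb & pc_ & !pa))
}

#' Parsimony cross-check of quartet support
#'
#' Independent route to the same support count used in the original
#' PAUP*-based workflow: compute the Fitch parsimony length `L` of the
#' 4-taxon tree for a split over the `N` quartet-informative columns;
#' characters not supporting the split cost 2 steps instead of 1, so the
#' number not in support is `L - N` and the support is `N - (L - N) =
#' 2N - L`. This must equal the direct pattern count from
#' [quartet_pattern_counts()].
#'
#' @inheritParams quartet_pattern_counts
#' @param split 1, 2 or 3 selecting `ab|cd`, `ac|bd` or `ad|bc`.
#' @return list with `N` (informative characters), `L` (tree length) and
#'   `support = 2N - L`.
#' @export
parsimony_crosscheck <- function(m, q, split) {
  stopifnot_complete(m)
  stopifnot(split %in% 1:3)
  pr <- unclass(m)[q, , drop = FALSE]
  inf <- colSums(pr) == 2L
  pr <- pr[, inf, drop = FALSE]
  N <- ncol(pr)
  ord <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))[[split]]
  x <- pr[ord[1], ]; y <- pr[ord[2], ]; z <- pr[ord[3], ]; w <- pr[ord[4], ]
  # Fitch length on ((x,y),(z,w)): one step per unequal cherry, plus one
  # when both cherries are fixed and disagree.
  L <- sum((x != y) + (z != w) + (x == y & z == w & x != z))
  list(N = N, L = L, support = 2L * N - L)
}

# Topological leaf-to-leaf distances (every edge length 1); the induced
# quartet split follows from the four-point condition.
quartet_distance_matrix <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  stats::cophenetic(t2)
}

accepted_split_from_dist <- function(D, q) {
  s1 <- D[q[1], q[2]] + D[q[3], q[4]]
  s2 <- D[q[1], q[3]] + D[q[2], q[4]]
  s3 <- D[q[1], q[4]] + D[q[2], q[3]]
  s <- c(s1, s2, s3)
  if (sum(s == min(s)) > 1) return(NA_integer_)   # polytomy: unresolved
  which.min(s)
}

#' Split induced by a species tree on a quartet
#'
#' Prunes the species tree to the four taxa and returns which of the
#' three pairings it induces; quartets spanning a polytomy are flagged
#' untestable (`NA`).
#'
#' @param species_tree a `phylo` containing the four taxa.
#' @param q character vector of 4 taxon labels.
#' @return integer 1, 2 or 3 (`ab|cd`, `ac|bd`, `ad|bc` in the order of
#'   `q`), or `NA` if unresolved.
#' @export
accepted_split <- function(species_tree, q) {
  if (!all(q %in% species_tree$tip.label))
    stop("quartet taxa missing from species tree")
  accepted_split_from_dist(quartet_distance_matrix(species_tree), q)
}

#' Chi-square test of quartet asymmetry
#'
#' Under incomplete lineage sorting alone the characters not supporting
#' the species-tree split divide equally between the two alternate
#' splits; introgression between lineages united by one alternate split
#' inflates it. Pearson chi-square with 1 degree of freedom, expected
#' counts `(n_alt1 + n_alt2)/2` each, no continuity correction.
#'
#' @param n_alt1,n_alt2 non-negative counts for the two alternate splits
#'   (at least one positive).
#' @return list with `chi2` and `p_raw` (upper tail of chi-square(1)).
#' @examples
#' asymmetry_chi2(60, 40)   # chi2 = 4, p ~ 0.0455
#' @export
asymmetry_chi2 <- function(n_alt1, n_alt2) {
  if (n_alt1 + n_alt2 < 1) stop("n_alt1 + n_alt2 must be >= 1")
  e <- (n_alt1 + n_alt2) / 2
  chi2 <- (n_alt1 - e)^2 / e + (n_alt2 - e)^2 / e
  list(chi2 = chi2, p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Holm-Bonferroni correction
#'
#' Step-down family-wise error control: the i-th smallest p-value is
#' rejected while `p(i) <= alpha / (m - i + 1)`; adjusted p-values are the
#' running maximum of `(m - i + 1) p(i)`, capped at 1 (as in
#' [stats::p.adjust()], which performs the computation).
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param alpha family-wise error rate.
#' @return list with `p_holm` (adjusted p-values, input order) and
#'   `significant` (logical flags).
#' @export
holm_correction <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(list(p_holm = numeric(), significant = logical()))
  adj <- stats::p.adjust(p_values, method = "holm")
  list(p_holm = adj, significant = adj <= alpha)
}

#' Quartet asymmetry test for introgression
#'
#' For every 4-taxon subset: counts the informative characters supporting
#' each of the three splits, takes the species-tree split as "accepted",
#' tests the two alternate counts against an equal division with
#' [asymmetry_chi2()], and applies a Holm-Bonferroni correction across
#' all testable quartets. Quartets spanning a species-tree polytomy or
#' with zero alternate characters are untestable and excluded from the
#' correction. For significant quartets the overrepresented alternate
#' split and the two taxon pairs it unites (the candidate introgressing
#' pairs) are recorded. A warning is emitted when an alternate split has
#' more support than the accepted one (possible near anomaly zones).
#'
#' @param m a complete [pa_matrix()].
#' @param species_tree a resolved `phylo` on the matrix taxa (the
#'   accepted topology source, e.g. an ASTRAL-BP or Dollo tree).
#' @param alpha family-wise significance level.
#' @return an object of classes `quartet_test` and `data.frame`, one row
#'   per quartet (taxa lexicographic order): `taxa`, `n_accepted`,
#'   `n_alt1`, `n_alt2`, `accepted_split`, `expected_alt`, `chi2`,
#'   `p_raw`, `p_holm`, `significant`, `low_count`, `testable`,
#'   `overrepresented_split`, `pair1`, `pair2`.
#' @export
quartet_asymmetry_test <- function(m, species_tree, alpha = 0.05) {
  stopifnot_complete(m)
  if (!setequal(rownames(m), species_tree$tip.label))
    stop("matrix taxa and tree tip labels differ")
  taxa <- sort(rownames(m))
  quartets <- enumerate_quartets(taxa)
  D <- quartet_distance_matrix(species_tree)
  n_q <- ncol(quartets)
  rows <- vector("list", n_q)
  n_inverted <- 0L
  for (i in seq_len(n_q)) {
    q <- quartets[, i]
    counts <- quartet_pattern_counts(m, q)
    acc <- accepted_split_from_dist(D, q)
    row <- list(taxa = paste(q, collapse = ","),
                n_accepted = NA_integer_, n_alt1 = NA_integer_,
                n_alt2 = NA_integer_, accepted_split = NA_character_,
                expected_alt = NA_real_, chi2 = NA_real_, p_raw = NA_real_,
                p_holm = NA_real_, significant = FALSE, low_count = FALSE,
                testable = FALSE, overrepresented_split = NA_character_,
                pair1 = NA_character_, pair2 = NA_character_)
    if (!is.na(acc)) {
      alts <- setdiff(1:3, acc)
      row$n_accepted <- unname(counts[acc])
      row$n_alt1 <- unname(counts[alts[1]])
      row$n_alt2 <- unname(counts[alts[2]])
      row$accepted_split <- split_label(q, acc)
      if (any(counts[alts] > counts[acc])) n_inverted <- n_inverted + 1L
      if (row$n_alt1 + row$n_alt2 >= 1) {
        ch <- asymmetry_chi2(row$n_alt1, row$n_alt2)
        row$expected_alt <- (row$n_alt1 + row$n_alt2) / 2
        row$chi2 <- ch$chi2
        row$p_raw <- ch$p_raw
        row$testable <- TRUE
        row$low_count <- (row$n_alt1 + row$n_alt2) < 10
        ov <- alts[which.max(c(row$n_alt1, row$n_alt2))]
        row$overrepresented_split <- split_label(q, ov)
        pr <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))[[ov]]
        row$pair1 <- paste(sort(q[pr[1:2]]), collapse = "-")
        row$pair2 <- paste(sort(q[pr[3:4]]), collapse = "-")
      }
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n_untestable <- sum(!out$testable)
  if (n_untestable > 0)
    message(n_untestable, " quartet(s) untestable (polytomy or no alternate characters); excluded from Holm correction")
  if (n_inverted > 0)
    warning(n_inverted, " quartet(s) have an alternate split with more support than the accepted split")
  hc <- holm_correction(out$p_raw[out$testable], alpha)
  out$p_holm[out$testable] <- hc$p_holm
  out$significant[out$testable] <- hc$significant
  # non-significant quartets keep no overrepresentation call
  out$overrepresented_split[!out$significant] <- NA_character_
  out$pair1[!out$significant] <- NA_character_
  out$pair2[!out$significant] <- NA_character_
  out <- out[order(out$taxa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("quartet_test", "data.frame")
  out
}

#' Tally taxon pairs implicated by significant quartets
#'
#' For each significant quartet, both taxon pairs united by the
#' overrepresented alternate split are candidate introgressing pairs;
#' across many quartets the truly admixed pair accumulates the most
#' support. Counts therefore sum to twice the number of significant
#' quartets.
#'
#' @param results a `quartet_test` object.
#' @return data frame `pair`, `n_quartets`, sorted descending (ties by
#'   pair label).
#' @export
implicated_pairs <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(pair = character(), n_quartets = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(c(sig$pair1, sig$pair2))
  o <- order(-as.integer(tab), names(tab))
  data.frame(pair = names(tab)[o], n_quartets = as.integer(tab)[o],
             stringsAsFactors = FALSE)
}

#' @export
print.quartet_test <- function(x, ...) {
  cat(sprintf("Quartet asymmetry test: %d quartets, %d testable, %d significant at alpha = %g\n",
              nrow(x), sum(x$testable), sum(x$significant), attr(x, "alpha")))
  NextMethod()
}

#' Write quartet test results to TSV
#'
#' @param results a `quartet_test` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_quartet_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
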