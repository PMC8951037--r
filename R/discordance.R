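#' Classify loci as concordant or discordant with a species tree
#'
#' Scores every locus with [dollo_character_score()] against the rooted
#' tree; a locus needing 2 or more state transitions (the single gain plus
#' at least one loss) is discordant: its presence pattern is not a clade
#' and signals incomplete lineage sorting or introgression.
#'
#' @param m a complete, informative-filtered [pa_matrix()].
#' @param tree a rooted `phylo` on the matrix taxa.
#' @return data frame with columns `locus_id`, `transitions`,
#'   `discordant`.
#' @export
classify_loci <- function(m, tree) {
  p <- dollo_profile(m, tree)
  data.frame(locus_id = colnames(m),
             transitions = p$transitions,
             discordant = p$transitions >= 2L,
             stringsAsFactors = FALSE)
}

#' Attribute discordant loci to ancestral nodes
#'
#' Each discordant locus is attributed to the most recent common ancestor
#' of the species carrying the insertion: the ancestral population where
#' the underlying lineage-sorting (or introgression) event would have
#' occurred. Concordant loci are not attributed. All internal nodes are
#' reported, including zero-count ones.
#'
#' @inheritParams classify_loci
#' @return data frame with one row per internal node: `node` (ape node
#'   id), `clade` (comma-joined sorted tip labels), `n_loci`.
#' @export
attribute_mrca <- function(m, tree) {
  p <- dollo_profile(m, tree)
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  att <- p$mrca[p$transitions >= 2L]
  counts <- tabulate(att, nbins = ntip + tree$Nnode)[nodes]
  cl <- clade_sets(tree)
  data.frame(node = nodes,
             clade = vapply(cl, paste, "", collapse = ","),
             n_loci = counts,
             stringsAsFactors = FALSE)
}

#' Ranked table of discordant presence patterns
#'
#' Groups discordant loci by their exact presence pattern (a bitstring in
#' the matrix taxon order), ranks patterns by occurrence count
#' (descending; ties broken by pattern lexicographic order) and annotates
#' each with its node of attribution.
#'
#' @inheritParams classify_loci
#' @param top_k number of top patterns to return.
#' @return data frame with columns `pattern`, `present_taxa`, `count`,
#'   `node`, `clade`.
#' @export
pattern_table <- function(m, tree, top_k = 20) {
  if (top_k < 1) stop("top_k must be >= 1")
  p <- dollo_profile(m, tree)
  disc <- which(p$transitions >= 2L)
  if (length(disc) == 0)
    return(data.frame(pattern = character(), present_taxa = character(),
                      count = integer(), node = integer(), clade = character(),
                      stringsAsFactors = FALSE))
  pat <- apply(unclass(m)[, disc, drop = FALSE], 2, paste, collapse = "")
  tab <- table(pat)
  o <- order(-as.integer(tab), names(tab))
  pats <- names(tab)[o][seq_len(min(top_k, length(tab)))]
  first <- disc[match(pats, pat)]
  node <- p$mrca[first]
  cl <- clade_sets(tree)
  ntip <- length(tree$tip.label)
  present <- vapply(pats, function(s) {
    paste(rownames(m)[strsplit(s, "")[[1]] == "1"], collapse = ",")
  }, "")
  data.frame(pattern = pats, present_taxa = unname(present),
             count = as.integer(tab)[o][seq_along(pats)],
             node = node, clade = vapply(node - ntip, function(i) {
               paste(cl[[i]], collapse = ",")
             }, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full discordance report
#'
#' Combines [classify_loci()], [attribute_mrca()] and [pattern_table()]
#' into one report object.
#'
#' @inheritParams pattern_table
#' @return an object of class `discordance_report`: a list with
#'   `per_locus` (including each discordant locus's attributed node),
#'   `node_counts`, `pattern_table`, `n_discordant` and
#'   `frac_discordant`.
#' @export
discordance_report <- function(m, tree, top_k = 20) {
  p <- dollo_profile(m, tree)
  per_locus <- data.frame(locus_id = colnames(m),
                          pattern = apply(unclass(m), 2, paste, collapse = ""),
                          transitions = p$transitions,
                          discordant = p$transitions >= 2L,
                          attributed_node = ifelse(p$transitions >= 2L, p$mrca, NA_integer_),
                          stringsAsFactors = FALSE, row.names = NULL)
  out <- list(per_locus = per_locus,
              node_counts = attribute_mrca(m, tree),
              pattern_table = pattern_table(m, tree, top_k),
              n_discordant = sum(per_locus$discordant),
              frac_discordant = mean(per_locus$discordant),
              tree = tree)
  class(out) <- "discordance_report"
  out
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("Discordance report: %d / %d loci discordant (%.1f%%)\n",
              x$n_discordant, nrow(x$per_locus), 100 * x$frac_discordant))
  nz <- x$node_counts[x$node_counts$n_loci > 0, , drop = FALSE]
  if (nrow(nz)) {
    cat("Attributed loci per ancestral node:\n")
    for (i in order(-nz$n_loci)) {
      cat(sprintf("  node %d (%s): %d (%.1f%%)\n", nz$node[i], nz$clade[i],
                  nz$n_loci[i], 100 * nz$n_loci[i] / max(x$n_discordant, 1)))
    }
  }
  invisible(x)
}

#' Write a discordance report to TSV
#'
#' @param report a `discordance_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_discordance_tsv <- function(report, path) {
  utils::write.table(report$per_locus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
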