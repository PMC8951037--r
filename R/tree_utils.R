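# Small rooted-tree utilities shared by the Dollo search, consensus and
# discordance code. All operate on ape "phylo" objects.

# Insert a new tip by bisecting edge `edge` (row index of tree$edge).
# Topology-only: edge lengths, if any, are dropped.
add_tip <- function(tree, edge, label) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  E <- tree$edge
  E[E > n] <- E[E > n] + 1L          # shift internal ids to free tip id n+1
  new_tip <- n + 1L
  new_node <- n + m + 2L
  v <- E[edge, 2L]
  E[edge, 2L] <- new_node
  E <- rbind(E, c(new_node, v), c(new_node, new_tip))
  out <- list(edge = E, tip.label = c(tree$tip.label, label),
              Nnode = m + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

# Children of every node, as a list indexed by node id.
node_children <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# Newick string with children sorted recursively by smallest tip label;
# equal topologies map to equal strings regardless of input rotation.
canonical_newick <- function(tree) {
  n <- length(tree$tip.label)
  ch <- node_children(tree)
  rec <- function(node) {
    if (node <= n) return(list(str = tree$tip.label[node], key = tree$tip.label[node]))
    kids <- lapply(ch[[node]], rec)
    keys <- vapply(kids, `[[`, "", "key")
    o <- order(keys)
    list(str = paste0("(", paste(vapply(kids[o], `[[`, "", "str"), collapse = ","), ")"),
         key = keys[o][1])
  }
  paste0(rec(rec_root(tree))$str, ";")
}

rec_root <- function(tree) {
  length(tree$tip.label) + 1L
}

# Tip-label sets of every clade (internal node) of a rooted tree.
clade_sets <- function(tree) {
  n <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, n + seq_len(tree$Nnode), type = "tips")
  lapply(desc, function(i) sort(tree$tip.label[i]))
}

# Root an unrooted (or rooted) binary tree so that `outgroup` is one of the
# two children of the root.
root_at_outgroup <- function(tree, outgroup) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ape::root(ut, outgroup = outgroup, resolve.root = TRUE)
}

# Build a rooted tree from a set of mutually compatible clades (character
# vectors of tip labels). `supports` are attached as node labels in the
# same order as the clades used. The root clade (all taxa) is added if
# absent.
tree_from_clades <- function(taxa, clades, supports = NULL) {
  key <- vapply(clades, paste, "", collapse = "\r")
  root_key <- paste(sort(taxa), collapse = "\r")
  if (!root_key %in% key) {
    clades <- c(list(sort(taxa)), clades)
    supports <- c(NA_real_, supports)
    key <- c(root_key, key)
  }
  sizes <- lengths(clades)
  o <- order(-sizes)
  clades <- clades[o]; supports <- supports[o]
  build <- function(ci) {
    members <- clades[[ci]]
    inner <- which(vapply(seq_along(clades), function(j)
      j != ci && all(clades[[j]] %in% members), logical(1)))
    # maximal proper sub-clades become children
    maximal <- inner[vapply(inner, function(j)
      !any(vapply(inner, function(k)
        k != j && all(clades[[j]] %in% clades[[k]]), logical(1))), logical(1))]
    covered <- unlist(clades[maximal])
    singles <- setdiff(members, covered)
    parts <- c(lapply(maximal, build), as.list(singles))
    lab <- supports[ci]
    paste0("(", paste(unlist(parts), collapse = ","), ")",
           if (!is.na(lab)) format(lab, digits = 4) else "")
  }
  ape::read.tree(text = paste0(build(1L), ";"))
}

# Tip labels reachable from `start` without crossing node `blocked`,
# on the unrooted adjacency of `tree`.
subtree_tips <- function(adj, tree, start, blocked) {
  n <- length(tree$tip.label)
  seen <- c(blocked)
  stack <- start
  tips <- integer()
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x %in% seen) next
    seen <- c(seen, x)
    if (x <= n) tips <- c(tips, x) else stack <- c(stack, adj[[x]])
  }
  sort(tips)
}

tree_adjacency <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}
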