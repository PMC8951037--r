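#' Specify a coalescent simulation model
#'
#' A `sim_model` bundles a species tree with branch lengths in coalescent
#' units (time scaled by 2N generations; one haploid lineage is sampled
#' per species, so population sizes are absorbed into the branch
#' lengths), an optional list of instantaneous introgression pulses, and
#' the locus count. It drives [simulate_matrix()],
#' [simulate_genealogy()] and [simulate_genealogies()].
#'
#' Pulses are given forward in time: at `time` (coalescent units before
#' the present), a fraction `prob` of the recipient population's
#' ancestry traces to the donor population. `donor` and `recipient` name
#' any extant species; the pulse applies to the species-tree branch
#' ancestral to that species at `time` (both branches must exist then).
#'
#' @param species_tree a rooted, binary, ultrametric `phylo` with branch
#'   lengths in coalescent units.
#' @param pulses `NULL`, or a data frame with columns `time`, `donor`,
#'   `recipient`, `prob`.
#' @param n_loci number of insertion loci to simulate. The default
#'   matches the scale of genus-level SINE studies (~10^4 informative
#'   insertions).
#' @param condition_on_informative if `TRUE` (default), rejection-sample
#'   each locus until its presence pattern is phylogenetically
#'   informative (`min_present`/`min_absent` taxa on each side), matching
#'   the informativeness filter applied to real matrices.
#' @param min_present,min_absent informativeness thresholds used when
#'   conditioning.
#' @param seed optional integer seed stored with the model and used by
#'   default in the simulation functions.
#' @return an object of class `sim_model`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
#' mod <- sim_model(tr, n_loci = 100, seed = 1)
#' m <- simulate_matrix(mod)
#' @export
sim_model <- function(species_tree, pulses = NULL, n_loci = 10000,
                      condition_on_informative = TRUE,
                      min_present = 2, min_absent = 2, seed = NULL) {
  if (!inherits(species_tree, "phylo") || !ape::is.rooted(species_tree))
    stop("species_tree must be a rooted phylo object")
  if (!ape::is.binary(species_tree))
    stop("species_tree must be binary")
  if (is.null(species_tree$edge.length))
    stop("species_tree needs branch lengths in coalescent units")
  if (!ape::is.ultrametric(species_tree, tol = 1e-6))
    stop("species_tree must be ultrametric (tips at time 0)")
  if (n_loci < 1) stop("n_loci must be >= 1")
  S <- length(species_tree$tip.label)
  times <- c(rep(0, S), ape::branching.times(species_tree))
  if (!is.null(pulses)) {
    req <- c("time", "donor", "recipient", "prob")
    if (!all(req %in% names(pulses)))
      stop("pulses needs columns time, donor, recipient, prob")
    if (any(pulses$prob < 0 | pulses$prob > 1))
      stop("pulse prob must be in [0, 1]")
    root_time <- max(times)
    if (any(pulses$time >= root_time))
      stop("pulse time at or beyond the root")
    pulses$donor_node <- vapply(seq_len(nrow(pulses)), function(i)
      branch_at_time(species_tree, times, pulses$donor[i], pulses$time[i]), integer(1))
    pulses$recipient_node <- vapply(seq_len(nrow(pulses)), function(i)
      branch_at_time(species_tree, times, pulses$recipient[i], pulses$time[i]), integer(1))
    if (any(pulses$donor_node == pulses$recipient_node))
      stop("pulse donor and recipient are the same species-tree branch at that time")
  }
  structure(list(tree = species_tree, times = times, pulses = pulses,
                 n_loci = n_loci,
                 condition_on_informative = condition_on_informative,
                 min_present = min_present, min_absent = min_absent,
                 seed = seed),
            class = "sim_model")
}

# Species-tree node whose branch (node -> parent) spans time t on the
# lineage ancestral to `label`.
branch_at_time <- function(tree, times, label, t) {
  v <- match(label, tree$tip.label)
  if (is.na(v)) stop("unknown species in pulse: ", label)
  root <- length(tree$tip.label) + 1L
  repeat {
    if (v == root) stop("pulse time at or beyond the root for ", label)
    par <- tree$edge[tree$edge[, 2] == v, 1]
    if (times[v] <= t && t < times[par]) return(as.integer(v))
    v <- par
  }
}

#' @export
print.sim_model <- function(x, ...) {
  cat(sprintf("Coalescent simulation model: %d taxa, %d loci%s, %d pulse(s)\n",
              length(x$tree$tip.label), x$n_loci,
              if (x$condition_on_informative) " (conditioned informative)" else "",
              if (is.null(x$pulses)) 0L else nrow(x$pulses)))
  invisible(x)
}

# Shared marshalling of a sim_model into the C++ core's arguments.
msc_args <- function(model) {
  tree <- model$tree
  S <- length(tree$tip.label)
  nn <- S + tree$Nnode
  parent <- rep(-1L, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  ev <- data.frame(time = model$times[S + seq_len(tree$Nnode)],
                   type = 0L, a = S + seq_len(tree$Nnode) - 1L, b = -1L,
                   prob = 0)
  if (!is.null(model$pulses) && nrow(model$pulses) > 0) {
    pe <- data.frame(time = model$pulses$time, type = 1L,
                     a = model$pulses$recipient_node - 1L,
                     b = model$pulses$donor_node - 1L,
                     prob = model$pulses$prob)
    ev <- rbind(ev, pe)
  }
  ev <- ev[order(ev$time, ev$type), , drop = FALSE]   # pulses after a merge at equal time
  list(S = S, sp_parent = parent - 1L, sp_time = model$times, ev = ev)
}

run_msc <- function(model, n_loci, condition, return_trees, seed) {
  if (!is.null(seed)) set.seed(seed)
  a <- msc_args(model)
  sim_msc_cpp(n_loci, a$S, a$sp_parent, a$sp_time,
              a$ev$time, a$ev$type, a$ev$a, a$ev$b, a$ev$prob,
              condition, model$min_present, model$min_absent,
              return_trees, max_tries = 1000 * n_loci + 1e5)
}

#' Simulate a presence/absence matrix under the model
#'
#' Draws `model$n_loci` independent genealogies under the multispecies
#' coalescent (with any pulses), places one insertion on each, and
#' returns the resulting binary matrix. With
#' `condition_on_informative = TRUE` each locus is rejection-sampled
#' until informative. The generating model is attached as attribute
#' `"truth"`.
#'
#' @param model a [sim_model()].
#' @param seed integer seed (defaults to the model's); same seed, same
#'   matrix.
#' @return a [pa_matrix()] of dimension taxa x `n_loci`.
#' @export
simulate_matrix <- function(model, seed = model$seed) {
  res <- run_msc(model, model$n_loci, model$condition_on_informative,
                 return_trees = FALSE, seed = seed)
  m <- res$patterns
  rownames(m) <- model$tree$tip.label
  colnames(m) <- sprintf("locus_%05d", seq_len(ncol(m)))
  out <- pa_matrix(m)
  attr(out, "truth") <- model
  out
}

#' Simulate coalescent genealogies
#'
#' `simulate_genealogy()` draws one genealogy of the sampled lineages
#' (one per species); `simulate_genealogies()` draws `n` of them.
#' Genealogies are ultrametric `phylo` trees with branch lengths in
#' coalescent units, unconditioned on pattern informativeness.
#'
#' @param model a [sim_model()].
#' @param seed integer seed (defaults to the model's).
#' @return a `phylo` (or list of `phylo`).
#' @export
simulate_genealogy <- function(model, seed = model$seed) {
  simulate_genealogies(model, 1, seed = seed)[[1]]
}

#' @rdname simulate_genealogy
#' @param n number of genealogies.
#' @export
simulate_genealogies <- function(model, n, seed = model$seed) {
  res <- run_msc(model, n, condition = FALSE, return_trees = TRUE, seed = seed)
  S <- length(model$tree$tip.label)
  lapply(seq_len(n), function(j)
    phylo_from_parents(res$gparents[, j] + 1L, res$gtimes[, j],
                       model$tree$tip.label))
}

# Build an ape phylo from 1-based parent pointers (root's parent = 0) and
# node times; tips are nodes 1..S.
phylo_from_parents <- function(parent, times, tip_labels) {
  S <- length(tip_labels)
  nn <- length(parent)
  internal <- (S + 1):nn
  o <- internal[order(-times[internal])]        # root (oldest) first
  newid <- integer(nn)
  newid[seq_len(S)] <- seq_len(S)
  newid[o] <- S + seq_along(o)
  child <- seq_len(nn)[-which(parent == 0)]
  edge <- cbind(newid[parent[child]], newid[child])
  len <- times[parent[child]] - times[child]
  tr <- list(edge = edge, edge.length = len, tip.label = tip_labels,
             Nnode = nn - S)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Place a single insertion on a genealogy
#'
#' Chooses one branch with probability proportional to its duration and
#' returns the taxa descending from it: the homoplasy-free insertion
#' model (no losses, no parallel gains). If the genealogy carries a
#' `root.edge`, that stem is placeable too and yields the all-present
#' pattern.
#'
#' @param g a `phylo` genealogy with branch lengths.
#' @return character vector of tip labels carrying the insertion.
#' @export
simulate_locus <- function(g) {
  len <- g$edge.length
  stem <- if (!is.null(g$root.edge)) g$root.edge else 0
  r <- stats::runif(1, 0, sum(len) + stem)
  if (r >= sum(len)) return(sort(g$tip.label))
  e <- which(r < cumsum(len))[1]
  v <- g$edge[e, 2]
  if (v <= length(g$tip.label)) return(g$tip.label[v])
  sort(g$tip.label[phangorn::Descendants(g, v, type = "tips")[[1]]])
}

#' Demonstration species tree
#'
#' An 11-taxon ultrametric species tree in coalescent units with short
#' internal branches (0.5 units by default), the regime of a rapid
#' radiation in which incomplete lineage sorting is extensive — the
#' setting the package's methods target.
#'
#' @param internal internal branch length in coalescent units.
#' @return a rooted binary ultrametric `phylo` with tips `t01`..`t10`
#'   and outgroup `out`.
#' @export
demo_species_tree <- function(internal = 0.5) {
  d <- internal
  # ladder backbone joining three cherries and single tips at heights
  # h1, h1+d, h1+2d, ...; outgroup on a long stem
  h <- 1 + d * (0:5)               # heights of the six ingroup nodes
  root <- h[6] + 2
  nwk <- sprintf(paste0(
    "(((((((t01:%g,t02:%g):%g,t03:%g):%g,(t04:%g,t05:%g):%g):%g,t06:%g):%g,",
    "(t07:%g,t08:%g):%g):%g,(t09:%g,t10:%g):%g):%g,out:%g);"),
    1, 1, h[2] - 1, h[2],              # (t01,t02) at h1=1, +t03 at h2
    h[3] - h[2], 1, 1, h[3] - 1,       # cherry (t04,t05) at 1, joins at h3
    h[4] - h[3], h[4],                 # +t06 at h4
    h[5] - h[4], 1, 1, h[5] - 1,       # cherry (t07,t08) joins at h5
    h[6] - h[5], 1, 1, h[6] - 1,       # cherry (t09,t10) joins at h6
    root - h[6], root)                 # outgroup stem
  ape::read.tree(text = nwk)
}
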