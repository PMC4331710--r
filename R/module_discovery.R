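# Overlapping dense-module discovery in the predicted interaction network.
# The algorithm is a documented greedy seed-and-extend procedure in the spirit
# of overlapping dense-subgraph clustering: every edge seeds a candidate
# module that grows by the neighbor adding the most internal edges, as long as
# the density stays above the cutoff and the size below the cap. It is
# deliberately simple, fully deterministic and declared as such -- not a
# bit-for-bit reimplementation of any published clustering code.

#' Construct an isoform interaction network
#'
#' @param edges data frame with columns `isoform_a`, `isoform_b` (self-loops
#'   rejected); typically the low-confidence prediction set.
#' @param nodes optional node universe; defaults to the isoforms incident to
#'   an edge. Extra isolated nodes are allowed.
#' @return Object of class `iii_network`: list with `nodes`, `edges`
#'   (canonical pair data frame) and `adj` (named list of sorted neighbor
#'   vectors).
#' @export
iii_network <- function(edges, nodes = NULL) {
  cp <- canonical_pair(edges$isoform_a, edges$isoform_b)
  if (any(cp$a == cp$b))
    validation_error("network: self-loop edge on '%s'",
                     cp$a[cp$a == cp$b][1])
  keep <- !duplicated(pair_key(cp$a, cp$b))
  e <- data.frame(isoform_a = cp$a[keep], isoform_b = cp$b[keep],
                  stringsAsFactors = FALSE)
  incident <- unique(c(e$isoform_a, e$isoform_b))
  if (is.null(nodes)) {
    nodes <- sort(incident)
  } else {
    nodes <- sort(unique(as.character(nodes)))
    unknown <- setdiff(incident, nodes)
    if (length(unknown) > 0)
      validation_error("network: edge references unknown node '%s'",
                       unknown[1])
  }
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  if (nrow(e) > 0) {
    nb <- split(c(e$isoform_b, e$isoform_a), c(e$isoform_a, e$isoform_b))
    nb <- lapply(nb, sort)
    adj[names(nb)] <- nb
  }
  structure(list(nodes = nodes, edges = e, adj = adj),
            class = "iii_network")
}

#' Network from a prediction table
#' @param predictions an `iii_predictions` data frame; all rows (the
#'   low-confidence set including rescued pairs) become edges, excluding
#'   isoform self-pairs which cannot form network edges.
#' @return An `iii_network`.
#' @export
network_from_predictions <- function(predictions) {
  e <- predictions[predictions$isoform_a != predictions$isoform_b,
                   c("isoform_a", "isoform_b"), drop = FALSE]
  iii_network(e)
}

#' Density of a node subset
#'
#' Undirected simple-graph density: `2 E_in / (n (n - 1))` where `E_in` counts
#' edges with both endpoints in the subset. A clique has density 1.
#'
#' @param members character vector of >= 2 node ids.
#' @param network an `iii_network`.
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(members, network) {
  members <- unique(members)
  n <- length(members)
  if (n < 2) contract_error("graph_density: need at least 2 members")
  in_set <- members
  e_in <- sum(vapply(in_set, function(v)
    sum(network$adj[[v]] %in% in_set), integer(1))) / 2
  2 * e_in / (n * (n - 1))
}

#' Discover overlapping dense modules
#'
#' Greedy seed-and-extend: edges are processed as seeds in decreasing order of
#' degree sum (ties by canonical edge order). From a seed pair, the module
#' repeatedly absorbs the neighboring node with the most edges into the module
#' (ties by lexicographic node order), provided the resulting density stays
#' `>= min_density` and the size stays `<= max_size`. Grown modules of at
#' least `min_size` members are emitted unless their member set is a subset of
#' an already-emitted module. Because a node can join modules grown from many
#' seeds, modules may overlap.
#'
#' @param network an `iii_network`.
#' @param min_size minimum module size (default 3; must be >= 2).
#' @param max_size maximum module size (default 30).
#' @param min_density density cutoff in `(0, 1]` (default 0.7).
#' @param seed accepted for interface uniformity; the algorithm is
#'   deterministic and ignores it.
#' @return Object of class `iii_modules`: list of modules, each a list with
#'   `module_id`, `members` (sorted) and `density`.
#' @export
discover_modules <- function(network, min_size = 3L, max_size = 30L,
                             min_density = 0.7, seed = NULL) {
  if (min_size < 2) stop("discover_modules: min_size must be >= 2")
  if (max_size < min_size) stop("discover_modules: max_size < min_size")
  if (min_density <= 0 || min_density > 1)
    stop("discover_modules: min_density must lie in (0, 1]")
  e <- network$edges
  adj <- network$adj
  if (nrow(e) == 0) return(structure(list(), class = "iii_modules"))
  deg <- lengths(adj)
  seed_ord <- order(-(deg[e$isoform_a] + deg[e$isoform_b]),
                    e$isoform_a, e$isoform_b)
  kept <- list()
  kept_keys <- character(0)
  for (i in seed_ord) {
    members <- c(e$isoform_a[i], e$isoform_b[i])
    e_in <- 1L
    repeat {
      if (length(members) >= max_size) break
      cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                      members)
      if (length(cand) == 0) break
      gain <- vapply(cand, function(v) sum(adj[[v]] %in% members),
                     integer(1))
      # density of members+v is monotone in gain; ties by node order
      best <- cand[order(-gain, cand)][1]
      n_new <- length(members) + 1L
      dens_new <- 2 * (e_in + gain[[best]]) / (n_new * (n_new - 1))
      if (dens_new < min_density) break
      members <- c(members, best)
      e_in <- e_in + gain[[best]]
    }
    if (length(members) < min_size) next
    members <- sort(members)
    key <- paste(members, collapse = .KEY_SEP)
    if (key %in% kept_keys) next
    subset_of_kept <- any(vapply(kept, function(m)
      all(members %in% m$members), logical(1)))
    if (subset_of_kept) next
    dens <- 2 * e_in / (length(members) * (length(members) - 1))
    kept[[length(kept) + 1L]] <- list(members = members, density = dens)
    kept_keys <- c(kept_keys, key)
  }
  mods <- lapply(seq_along(kept), function(i)
    list(module_id = sprintf("M%04d", i), members = kept[[i]]$members,
         density = kept[[i]]$density))
  structure(mods, class = "iii_modules")
}

#' @export
print.iii_modules <- function(x, ...) {
  sizes <- vapply(x, function(m) length(m$members), integer(1))
  cat(sprintf("iii_modules: %d modules, mean size %.2f\n",
              length(x), if (length(x)) mean(sizes) else NA_real_))
  invisible(x)
}

#' Size-matched random modules
#'
#' Null model for module functionality: generates the same number of modules
#' with the same sizes as the input, each drawn uniformly without replacement
#' from the node universe, independently across modules. Densities are
#' recomputed on the network when one is supplied (and are typically far below
#' the discovery cutoff).
#'
#' @param modules an `iii_modules` list.
#' @param universe character vector of node ids to sample from.
#' @param seed integer seed (mandatory for reproducibility).
#' @param network optional `iii_network` for density recomputation.
#' @return An `iii_modules`-shaped list with ids `R0001`, `R0002`, ...
#' @export
randomize_modules <- function(modules, universe, seed, network = NULL) {
  universe <- unique(as.character(universe))
  sizes <- vapply(modules, function(m) length(m$members), integer(1))
  if (length(sizes) > 0 && max(sizes) > length(universe))
    contract_error("randomize_modules: universe (%d) smaller than module size %d",
                   length(universe), max(sizes))
  mods <- with_seed(seed, lapply(seq_along(sizes), function(i) {
    members <- sort(sample(universe, sizes[i], replace = FALSE))
    dens <- if (!is.null(network) && sizes[i] >= 2)
      graph_density(members, network) else NA_real_
    list(module_id = sprintf("R%04d", i), members = members, density = dens)
  }))
  structure(mods, class = "iii_modules")
}
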