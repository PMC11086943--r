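#' Best-of-N Louvain community detection with shuffled node orders
#'
#' Louvain is node-order dependent, so the detection is repeated
#' `n_shuffles` times on randomly permuted copies of the graph (each run
#' under a sub-seed derived deterministically from `seed`) and the partition
#' with the greatest modularity is returned. The connected-components
#' partition competes as a reference configuration, so a degenerate split
#' that merely ties the trivial partition at Q = 0 never wins; exact
#' modularity ties go to the partition with fewer communities, then to the
#' earliest run.
#'
#' @param g an undirected igraph; an edge attribute `weight`, when present,
#'   is used throughout.
#' @param n_shuffles number of shuffled restarts (default 1000).
#' @param seed master seed for the restart sub-seeds.
#' @return An object of class `partition`: list with `membership` (named
#'   integer vector over the graph's vertices), `modularity`, `n_shuffles`
#'   and `best_index` (1-based index of the winning restart).
#' @export
louvain_best_of <- function(g, n_shuffles = 1000L, seed = 1L) {
  stopifnot(igraph::vcount(g) > 0, n_shuffles >= 1)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))

  if (igraph::ecount(g) == 0) {
    warning("graph has no edges: every node becomes its own community (Q = 0)")
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- nm
    return(structure(
      list(membership = memb, modularity = 0,
           n_shuffles = as.integer(n_shuffles), best_index = NA_integer_),
      class = "partition"
    ))
  }

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_shuffles)
  best_q <- -Inf
  best_memb <- NULL
  best_idx <- NA_integer_
  best_nc <- Inf
  n <- igraph::vcount(g)
  consider <- function(memb, q, idx) {
    nc <- length(unique(memb))
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 && nc < best_nc)) {
      best_q <<- q
      best_memb <<- memb
      best_idx <<- idx
      best_nc <<- nc
    }
  }
  for (s in seq_len(n_shuffles)) {
    set.seed(sub_seeds[s])
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    memb <- igraph::membership(cl)[perm] # back to original vertex order
    consider(memb, igraph::modularity(g, memb, weights = w), s)
  }
  # coarse reference configurations compete too: when no Louvain partition
  # is strictly better than the connected-components (or trivial) split,
  # the coarser configuration wins the modularity tie
  comp <- igraph::components(g)$membership
  consider(comp, igraph::modularity(g, comp, weights = w), NA_integer_)
  best_memb <- as.integer(best_memb)
  names(best_memb) <- nm
  structure(
    list(membership = best_memb, modularity = best_q,
         n_shuffles = as.integer(n_shuffles), best_index = best_idx),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf(
    "partition: %d nodes, %d communities, Q = %.6f (best of %d shuffles)\n",
    length(x$membership), length(unique(x$membership)), x$modularity,
    x$n_shuffles
  ))
  invisible(x)
}

#' Newman-Girvan weighted modularity of a membership vector
#'
#' @param g undirected igraph (edge attribute `weight` used when present).
#' @param membership vector of community ids, either named by vertex or in
#'   vertex order, covering every vertex.
#' @return scalar modularity Q at resolution 1.
#' @export
modularity_q <- function(g, membership) {
  nm <- igraph::V(g)$name
  if (!is.null(names(membership)) && !is.null(nm)) {
    if (!all(nm %in% names(membership))) {
      stop("membership is missing some graph vertices")
    }
    membership <- membership[nm]
  } else if (length(membership) != igraph::vcount(g)) {
    stop("membership must cover every vertex")
  }
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  igraph::modularity(g, as.integer(factor(membership)), weights = w)
}

#' Two-phase majority label propagation on a retweet network
#'
#' Extends community labels from a set of permanently labeled seed nodes
#' (the verified users' communities) to the remaining nodes of an undirected
#' graph. A node adjacent to at least one seed node takes the label held by
#' the (weight-)majority of its seed neighbors; a node with no seed
#' neighbors takes the majority label of its already-labeled non-seed
#' neighbors. Updates are asynchronous, in a seeded random order, sweeping
#' until no label changes. Nodes never reached by any label stay unlabeled.
#' Majority ties keep the node's current label when it is among the tied
#' set, otherwise they are broken uniformly at random under the run seed.
#'
#' @param g undirected igraph (edge attribute `weight` used when present;
#'   set `weighted = FALSE` to ignore it).
#' @param seed_labels named vector (names = vertex names) of community ids
#'   for the permanently labeled nodes.
#' @param seed integer seed controlling sweep order and tie-breaks.
#' @param max_iter maximum sweeps (default 100).
#' @param weighted logical; weight neighbor votes by edge weight.
#' @return named character vector over all vertices; `NA` for unlabeled.
#' @export
propagate_labels <- function(g, seed_labels, seed = 1L, max_iter = 100L,
                             weighted = TRUE) {
  stopifnot(length(seed_labels) > 0, !is.null(names(seed_labels)))
  nm <- igraph::V(g)$name
  if (is.null(nm)) stop("graph vertices must be named")
  if (!all(names(seed_labels) %in% nm)) {
    stop("seed_labels contains nodes absent from the graph")
  }
  n <- igraph::vcount(g)
  labels <- rep(NA_character_, n)
  names(labels) <- nm
  labels[names(seed_labels)] <- as.character(seed_labels)
  is_seed <- !is.na(labels)

  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(1, nrow(el))
  }
  # adjacency lists with parallel weight lists
  adj <- vector("list", n)
  adjw <- vector("list", n)
  if (nrow(el) > 0) {
    from <- c(el[, 1], el[, 2])
    to <- c(el[, 2], el[, 1])
    ww <- c(w, w)
    o <- order(from)
    from <- from[o]; to <- to[o]; ww <- ww[o]
    runs <- split(seq_along(from), from)
    for (v in names(runs)) {
      vi <- as.integer(v)
      adj[[vi]] <- to[runs[[v]]]
      adjw[[vi]] <- ww[runs[[v]]]
    }
  }

  set.seed(seed)
  free <- which(!is_seed)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    changed <- 0L
    for (v in sample(free)) {
      nb <- adj[[v]]
      if (is.null(nb) || length(nb) == 0) next
      wv <- adjw[[v]]
      seed_nb <- is_seed[nb]
      if (any(seed_nb)) {
        votes <- tapply(wv[seed_nb], labels[nb[seed_nb]], sum)
      } else {
        lab_nb <- !is.na(labels[nb])
        if (!any(lab_nb)) next
        votes <- tapply(wv[lab_nb], labels[nb[lab_nb]], sum)
      }
      top <- names(votes)[votes == max(votes)]
      cur <- labels[v]
      if (!is.na(cur) && cur %in% top) next
      new <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
      if (is.na(cur) || new != cur) {
        labels[v] <- new
        changed <- changed + 1L
      }
    }
    if (changed == 0L) break
    if (iter >= max_iter) {
      warning(sprintf("label propagation did not converge in %d sweeps", max_iter))
      break
    }
  }
  labels
}
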