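#' Build the directed weighted retweet network of a dataset
#'
#' One directed edge per (retweeted author, retweeter) pair: the edge
#' `a -> b` with weight `w` means user `b` retweeted content authored by
#' user `a` a total of `w` times. Original posts contribute no edges. All
#' users of the dataset appear as vertices. The sum of edge weights equals
#' the number of retweet records retained at load.
#'
#' @param d an [echo_dataset()].
#' @return directed igraph with edge attribute `weight`.
#' @export
build_retweet_network <- function(d) {
  stopifnot(inherits(d, "echo_dataset"))
  p <- d$posts
  rt <- p[!is.na(p$retweeted_author_id), , drop = FALSE]
  users <- sort(unique(c(p$author_id,
                         p$retweeted_author_id[!is.na(p$retweeted_author_id)])))
  if (nrow(rt) == 0) {
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(users))
  }
  key <- paste(rt$retweeted_author_id, rt$author_id, sep = "\r")
  tab <- table(key)
  pair <- strsplit(names(tab), "\r", fixed = TRUE)
  el <- data.frame(
    from = vapply(pair, `[`, "", 1),
    to = vapply(pair, `[`, "", 2),
    weight = as.numeric(tab),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = data.frame(name = users))
}

#' Undirected simple view of a retweet network
#'
#' Collapses directions and parallel edges; weights of merged edges are
#' summed.
#'
#' @param rt a directed retweet network from [build_retweet_network()].
#' @return undirected igraph.
#' @export
rt_undirected <- function(rt) {
  igraph::as_undirected(rt, mode = "collapse",
                        edge.attr.comb = list(weight = "sum"))
}

# verified status per user: TRUE iff any authored post carries the flag;
# users never authoring a post count as unverified.
user_verified_map <- function(d) {
  p <- d$posts
  v <- tapply(p$author_verified, p$author_id, any)
  all_users <- sort(unique(c(p$author_id,
                             p$retweeted_author_id[!is.na(p$retweeted_author_id)])))
  out <- stats::setNames(rep(FALSE, length(all_users)), all_users)
  out[names(v)] <- as.logical(v)
  out
}

#' Build the verified-unverified bipartite retweet network
#'
#' Verified users form the top layer, unverified users the bottom layer; a
#' binary link connects a verified and an unverified user iff at least one
#' retweet connects them in either role. Retweets between two verified or
#' two unverified users are excluded (the count is reported via the
#' `"excluded"` attribute).
#'
#' @param d an [echo_dataset()].
#' @return a [bipartite_graph()] (top = verified users) with attribute
#'   `excluded` = number of same-layer retweet records.
#' @export
build_verified_bipartite <- function(d) {
  stopifnot(inherits(d, "echo_dataset"))
  ver <- user_verified_map(d)
  if (!any(ver)) stop("no verified users in the dataset")
  if (all(ver)) stop("no unverified users in the dataset")
  p <- d$posts
  rt <- p[!is.na(p$retweeted_author_id), , drop = FALSE]
  if (nrow(rt) == 0) stop("dataset has no retweets")
  a_ver <- ver[rt$author_id]
  r_ver <- ver[rt$retweeted_author_id]
  cross <- xor(a_ver, r_ver)
  excluded <- sum(!cross)
  rt <- rt[cross, , drop = FALSE]
  if (nrow(rt) == 0) stop("no cross-layer (verified-unverified) retweets")
  v_side <- ifelse(ver[rt$author_id], rt$author_id, rt$retweeted_author_id)
  u_side <- ifelse(ver[rt$author_id], rt$retweeted_author_id, rt$author_id)
  g <- bipartite_from_edges(v_side, u_side,
                            top_nodes = sort(names(ver)[ver]),
                            bottom_nodes = sort(names(ver)[!ver]))
  attr(g, "excluded") <- excluded
  g
}

#' Build the user-URL bipartite network
#'
#' A binary link connects a user and a canonical URL iff the user ever
#' shared it (in a tweet or retweet). URLs are canonicalized with
#' [canonicalize_url()]; unparseable URLs are dropped (count in the
#' `"dropped_urls"` attribute).
#'
#' @param d an [echo_dataset()].
#' @param url_map optional short-to-long URL mapping.
#' @return a [bipartite_graph()] (top = users, bottom = canonical URLs).
#' @export
build_user_url_bipartite <- function(d, url_map = NULL) {
  stopifnot(inherits(d, "echo_dataset"))
  p <- d$posts
  urls <- lapply(p$urls, unique)
  n_urls <- vapply(urls, length, 1L)
  if (sum(n_urls) == 0) stop("dataset has no URL-bearing posts")
  rows <- rep(seq_len(nrow(p)), n_urls)
  shares <- data.frame(
    user = p$author_id[rows],
    url = unlist(urls, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  canon <- canonicalize_url(shares$url, url_map = url_map)
  dropped <- sum(is.na(canon$canonical))
  shares$canonical <- canon$canonical
  shares <- shares[!is.na(shares$canonical), , drop = FALSE]
  if (nrow(shares) == 0) stop("no parseable URLs in the dataset")
  g <- bipartite_from_edges(shares$user, shares$canonical)
  attr(g, "dropped_urls") <- dropped
  g
}

#' Detect discursive communities (DiCo)
#'
#' The upper path of the pipeline: fit the BiCM on the
#' verified-vs-unverified bipartite retweet network, validate the projection
#' on the verified layer, run best-of-N Louvain on the validated verified
#' network, then extend the verified communities to all users by two-phase
#' majority label propagation on the undirected retweet network.
#'
#' @param d an [echo_dataset()].
#' @param n_shuffles Louvain restarts (default 1000).
#' @param alpha false discovery rate of the projection validation.
#' @param seed master seed; Louvain and propagation sub-seeds are derived
#'   from it.
#' @param min_frac communities holding less than this fraction of labeled
#'   users are flagged "minor".
#' @return object of class `dico_assignment`: list with `labels` (named
#'   vector user -> DiCo id, `NA` when unlabeled), `verified_partition`
#'   (the [louvain_best_of()] result), `projection`, `tallies` (per-DiCo
#'   users/tweets/retweets, overall and URL-bearing-only), `minor` (logical
#'   per community) and `params`.
#' @export
detect_dico <- function(d, n_shuffles = 1000L, alpha = 0.05, seed = 1L,
                        min_frac = 0.01) {
  g <- build_verified_bipartite(d)
  model <- fit_bicm(g)
  proj <- validate_projection(g, model, layer = "top", alpha = alpha)

  rt <- build_retweet_network(d)
  rtu <- rt_undirected(rt)
  all_users <- igraph::V(rt)$name
  labels <- stats::setNames(rep(NA_character_, length(all_users)), all_users)

  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2)
  if (igraph::ecount(proj$graph) == 0) {
    warning("validated verified projection is empty: no DiCo labels assigned")
    part <- NULL
  } else {
    core <- igraph::induced_subgraph(
      proj$graph, igraph::V(proj$graph)[igraph::degree(proj$graph) > 0]
    )
    part <- louvain_best_of(core, n_shuffles = n_shuffles, seed = sub[1])
    seeds <- stats::setNames(as.character(part$membership), names(part$membership))
    seeds <- seeds[names(seeds) %in% igraph::V(rtu)$name]
    if (length(seeds) > 0) {
      labels <- propagate_labels(rtu, seeds, seed = sub[2])
    }
  }

  tallies <- dico_tallies(d, labels)
  n_labeled <- sum(!is.na(labels))
  minor <- if (n_labeled > 0) {
    stats::setNames(tallies$users / n_labeled < min_frac, tallies$dico)
  } else {
    stats::setNames(logical(0), character(0))
  }
  structure(
    list(labels = labels, verified_partition = part, projection = proj,
         tallies = tallies, minor = minor,
         params = list(n_shuffles = n_shuffles, alpha = alpha, seed = seed,
                       min_frac = min_frac)),
    class = "dico_assignment"
  )
}

# per-DiCo tallies of users, tweets (original posts) and retweets, overall
# and restricted to URL-bearing posts
dico_tallies <- function(d, labels) {
  p <- d$posts
  lab <- unclass(labels)[p$author_id]
  is_rt <- !is.na(p$retweeted_author_id)
  has_url <- vapply(p$urls, length, 1L) > 0
  ids <- sort(unique(stats::na.omit(unclass(labels))))
  out <- lapply(ids, function(g) {
    users <- names(labels)[!is.na(labels) & labels == g]
    sel <- !is.na(lab) & lab == g
    data.frame(
      dico = g,
      users = length(users),
      tweets = sum(sel & !is_rt),
      retweets = sum(sel & is_rt),
      users_url = length(unique(p$author_id[sel & has_url])),
      tweets_url = sum(sel & !is_rt & has_url),
      retweets_url = sum(sel & is_rt & has_url),
      stringsAsFactors = FALSE
    )
  })
  if (length(out) == 0) {
    return(data.frame(dico = character(0), users = integer(0),
                      tweets = integer(0), retweets = integer(0),
                      users_url = integer(0), tweets_url = integer(0),
                      retweets_url = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect news engagement communities (NEC)
#'
#' The lower path of the pipeline: fit the BiCM on the user-URL bipartite
#' network, validate the projection on the user layer, and cluster the
#' validated users with best-of-N Louvain. NEC ids are integers `0, 1, ...`
#' assigned in decreasing order of community size.
#'
#' @inheritParams detect_dico
#' @param url_map optional short-to-long URL mapping.
#' @return object of class `nec_assignment`: list with `labels` (named
#'   vector user -> NEC id for validated users), `validated` (character
#'   vector of validated users), `projection`, `partition`, `tallies`
#'   (per-NEC user and URL-share counts) and `params`.
#' @export
detect_nec <- function(d, alpha = 0.05, n_shuffles = 1000L, seed = 1L,
                       url_map = NULL) {
  g <- build_user_url_bipartite(d, url_map = url_map)
  model <- fit_bicm(g)
  proj <- validate_projection(g, model, layer = "top", alpha = alpha)

  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 1)
  if (igraph::ecount(proj$graph) == 0) {
    warning("validated user-URL projection is empty: no NECs")
    return(structure(
      list(labels = stats::setNames(character(0), character(0)),
           validated = character(0), projection = proj, partition = NULL,
           tallies = data.frame(nec = integer(0), users = integer(0),
                                url_shares = integer(0)),
           params = list(alpha = alpha, n_shuffles = n_shuffles, seed = seed)),
      class = "nec_assignment"
    ))
  }
  core <- igraph::induced_subgraph(
    proj$graph, igraph::V(proj$graph)[igraph::degree(proj$graph) > 0]
  )
  part <- louvain_best_of(core, n_shuffles = n_shuffles, seed = sub[1])
  # NEC ids 0,1,... by decreasing community size (ties by community label)
  sizes <- sort(table(part$membership), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- stats::setNames(remap[as.character(part$membership)],
                            names(part$membership))

  p <- d$posts
  n_urls <- vapply(lapply(p$urls, unique), length, 1L)
  shares_by_user <- tapply(n_urls, p$author_id, sum)
  tallies <- do.call(rbind, lapply(sort(unique(labels)), function(id) {
    members <- names(labels)[labels == id]
    data.frame(
      nec = id, users = length(members),
      url_shares = sum(shares_by_user[members], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(labels = labels, validated = sort(names(labels)), projection = proj,
         partition = part, tallies = tallies,
         params = list(alpha = alpha, n_shuffles = n_shuffles, seed = seed)),
    class = "nec_assignment"
  )
}

#' Extract echo chambers from NEC, DiCo and retweet connectivity
#'
#' An echo chamber is a set of at least two users who (i) share a NEC,
#' (ii) share a DiCo and (iii) are weakly connected through retweets. Under
#' the default `nec_induced` rule, connectivity is evaluated on the retweet
#' subgraph induced by the (NEC, DiCo) co-members themselves; under
#' `dico_paths`, paths may run through any user of the same DiCo. Each
#' chamber inherits its NEC id (with a suffix when one NEC splits into
#' several components).
#'
#' @param dico a [detect_dico()] result.
#' @param nec a [detect_nec()] result.
#' @param rt the directed retweet network from [build_retweet_network()].
#' @param connectivity_mode `"nec_induced"` (default) or `"dico_paths"`.
#' @return object of class `echo_chambers`: list with `chambers` (list of
#'   per-chamber records: `id`, `nec`, `dico`, `members`,
#'   `avg_clustering`, `rt_generated`, `rt_received`) and `excluded`
#'   (users in a NEC+DiCo but in no chamber).
#' @export
detect_echo_chambers <- function(dico, nec, rt,
                                 connectivity_mode = c("nec_induced", "dico_paths")) {
  connectivity_mode <- match.arg(connectivity_mode)
  stopifnot(inherits(dico, "dico_assignment"), inherits(nec, "nec_assignment"))
  rtu <- rt_undirected(rt)
  users_rt <- igraph::V(rtu)$name
  chambers <- list()
  excluded <- character(0)

  nec_labels <- nec$labels
  dico_labels <- dico$labels
  for (nid in sort(unique(nec_labels))) {
    members_n <- names(nec_labels)[nec_labels == nid]
    dl <- unclass(dico_labels)[members_n]
    for (did in sort(unique(stats::na.omit(dl)))) {
      co <- members_n[!is.na(dl) & dl == did]
      in_rt <- co[co %in% users_rt]
      excluded <- c(excluded, setdiff(co, in_rt))
      if (length(in_rt) < 2) { excluded <- c(excluded, in_rt); next }
      if (connectivity_mode == "nec_induced") {
        sub <- igraph::induced_subgraph(rtu, in_rt)
        comp <- igraph::components(sub)$membership
      } else {
        dico_users <- names(dico_labels)[!is.na(dico_labels) & dico_labels == did]
        sub <- igraph::induced_subgraph(rtu, intersect(dico_users, users_rt))
        comp <- igraph::components(sub)$membership[in_rt]
      }
      groups <- split(names(comp), comp)
      groups <- groups[order(-vapply(groups, length, 1L))]
      kept <- Filter(function(m) length(m) >= 2, groups)
      excluded <- c(excluded,
                    unlist(Filter(function(m) length(m) < 2, groups),
                           use.names = FALSE))
      for (ci in seq_along(kept)) {
        members <- sort(kept[[ci]])
        id <- if (length(kept) == 1) as.character(nid) else {
          paste0(nid, ".", ci)
        }
        vol <- chamber_rt_volume(rt, members)
        chambers[[length(chambers) + 1]] <- list(
          id = id, nec = nid, dico = did, members = members,
          avg_clustering = average_clustering(rt, members),
          rt_generated = vol$generated, rt_received = vol$received
        )
      }
    }
  }
  structure(
    list(chambers = chambers, excluded = sort(unique(excluded)),
         connectivity_mode = connectivity_mode),
    class = "echo_chambers"
  )
}

chamber_rt_volume <- function(rt, members) {
  el <- igraph::as_data_frame(rt, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  list(
    generated = sum(el$weight[el$from %in% members]), # their content retweeted
    received = sum(el$weight[el$to %in% members])     # retweets they made
  )
}

#' @export
print.echo_chambers <- function(x, ...) {
  cat(sprintf("echo_chambers: %d chambers, %d users excluded\n",
              length(x$chambers), length(x$excluded)))
  for (ch in x$chambers) {
    cat(sprintf("  chamber %s (NEC %s, DiCo %s): %d members, clustering %.3f\n",
                ch$id, ch$nec, ch$dico, length(ch$members), ch$avg_clustering))
  }
  invisible(x)
}

#' Average undirected local clustering coefficient of a user set
#'
#' Mean over `nodes` of the local clustering coefficient on the undirected
#' simple view of the retweet network; nodes of degree < 2 contribute 0.
#'
#' @param rt retweet network (directed or undirected igraph).
#' @param nodes character vector of vertex names.
#' @return scalar in \[0, 1\].
#' @export
average_clustering <- function(rt, nodes) {
  if (length(nodes) == 0) stop("node set must be nonempty")
  g <- if (igraph::is_directed(rt)) rt_undirected(rt) else rt
  g <- igraph::simplify(g)
  missing_v <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing_v) > 0) {
    stop("nodes absent from the retweet network: ", paste(missing_v, collapse = ", "))
  }
  cc <- igraph::transitivity(g, type = "local", vids = nodes, isolates = "zero")
  mean(cc)
}

#' Aggregate the retweet flow between echo chambers
#'
#' Collapses the retweet network of the chambers' host discursive
#' community onto chamber ids; users of the DiCo outside any chamber are
#' pooled into sentinel node `-1`. An edge `A -> B` with weight `w` means
#' content authored in group `A` was retweeted `w` times by users of group
#' `B`; self-loops are kept; edges below `weight_min` are dropped.
#'
#' @param rt directed retweet network.
#' @param chambers a [detect_echo_chambers()] result (or its `chambers`
#'   list).
#' @param dico_labels named vector user -> DiCo id restricting the user
#'   universe to the chambers' host DiCo(s).
#' @param weight_min minimum edge weight kept (default 0; the headline
#'   figure uses 1000).
#' @return directed igraph over chamber ids plus `"-1"`.
#' @export
aggregate_flow <- function(rt, chambers, dico_labels, weight_min = 0) {
  if (inherits(chambers, "echo_chambers")) chambers <- chambers$chambers
  group <- character(0)
  host_dicos <- unique(vapply(chambers, function(ch) as.character(ch$dico), ""))
  for (ch in chambers) {
    group[ch$members] <- as.character(ch$id)
  }
  scope <- names(dico_labels)[!is.na(dico_labels) &
                                as.character(dico_labels) %in% host_dicos]
  rest <- setdiff(scope, names(group))
  group[rest] <- "-1"

  el <- igraph::as_data_frame(rt, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  el <- el[el$from %in% names(group) & el$to %in% names(group), , drop = FALSE]
  nodes <- sort(unique(c(vapply(chambers, function(ch) as.character(ch$id), ""), "-1")))
  if (nrow(el) == 0) {
    return(igraph::make_empty_graph(directed = TRUE) + igraph::vertices(nodes))
  }
  el$gf <- group[el$from]
  el$gt <- group[el$to]
  agg <- stats::aggregate(weight ~ gf + gt, data = el, FUN = sum)
  agg <- agg[agg$weight >= weight_min, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = agg$gf, to = agg$gt, weight = agg$weight),
    directed = TRUE, vertices = data.frame(name = nodes)
  )
}
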