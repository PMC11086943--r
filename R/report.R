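#' Percentage of URL-sharing users validated into NECs
#'
#' @param n_validated users with at least one validated projection edge.
#' @param n_nonvalidated URL-sharing users with none.
#' @return percentage on the 0-100 scale.
#' @export
validated_fraction <- function(n_validated, n_nonvalidated) {
  100 * n_validated / (n_validated + n_nonvalidated)
}

#' URL shares per account
#'
#' @param n_urls total URL shares attributed to a user class.
#' @param n_accounts number of accounts in the class.
#' @return shares per account.
#' @export
urls_per_account <- function(n_urls, n_accounts) {
  if (n_accounts == 0) return(NA_real_)
  n_urls / n_accounts
}

#' Users left in echo chambers after the connectivity and DiCo filters
#'
#' Validated NEC users minus those outside the weakly connected components
#' and those sitting in a different discursive community.
#'
#' @param n_validated NEC users.
#' @param n_outside_wcc users excluded by retweet connectivity.
#' @param n_other_dico users excluded for belonging to another DiCo.
#' @return user count.
#' @export
echo_chamber_user_count <- function(n_validated, n_outside_wcc, n_other_dico = 0) {
  n_validated - n_outside_wcc - n_other_dico
}

#' Share of all dataset users trapped in echo chambers
#'
#' @param n_echo users in echo chambers.
#' @param n_users all users in the dataset.
#' @return percentage on the 0-100 scale.
#' @export
echo_user_share <- function(n_echo, n_users) {
  100 * n_echo / n_users
}

#' Run the full echo-chamber detection pipeline
#'
#' Executes both detection paths (DiCo and NEC), intersects them with
#' retweet connectivity into echo chambers, aggregates the retweet flow and
#' (when trust labels are supplied) tallies news trustworthiness, then
#' writes all intermediates, a report and a checksum manifest to `out`.
#'
#' @param config list (or path handled by [echonet_cli()]) with elements:
#'   `posts` (path) or `dataset` (an [echo_dataset()]); optional `format`,
#'   `alpha` (default 0.05), `shuffles` (default 1000), `seed` (default 1),
#'   `connectivity` (default "nec_induced"), `url_map` (path to CSV
#'   `short,long`), `trust_labels` (path), `weight_min` (default 0), `out`
#'   (output directory; omit to skip writing).
#' @return the run report (list), invisibly when writing files.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(format = "auto", alpha = 0.05, shuffles = 1000L, seed = 1L,
         connectivity = "nec_induced", url_map = NULL, trust_labels = NULL,
         weight_min = 0, out = NULL),
    config
  )
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[echonet] stage %s ...", name))
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  d <- if (!is.null(cfg$dataset)) {
    cfg$dataset
  } else {
    stage("load", read_posts(cfg$posts, cfg$format))
  }
  url_map <- if (!is.null(cfg$url_map) && is.character(cfg$url_map)) {
    m <- utils::read.csv(cfg$url_map, stringsAsFactors = FALSE,
                         colClasses = "character")
    stats::setNames(m[[2]], m[[1]])
  } else {
    cfg$url_map
  }

  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max, 2)

  rt <- stage("retweet_network", build_retweet_network(d))
  dico <- stage("dico", detect_dico(d, n_shuffles = cfg$shuffles,
                                    alpha = cfg$alpha, seed = sub[1]))
  nec <- stage("nec", detect_nec(d, alpha = cfg$alpha,
                                 n_shuffles = cfg$shuffles, seed = sub[2],
                                 url_map = url_map))
  ec <- stage("echo_chambers",
              detect_echo_chambers(dico, nec, rt,
                                   connectivity_mode = cfg$connectivity))
  flow <- if (length(ec$chambers) > 0) {
    stage("flow", aggregate_flow(rt, ec, dico$labels,
                                 weight_min = cfg$weight_min))
  } else {
    NULL
  }

  trust_section <- "skipped (no trust labels supplied)"
  if (!is.null(cfg$trust_labels)) {
    labels <- if (is.character(cfg$trust_labels)) {
      read_trust_labels(cfg$trust_labels)
    } else {
      cfg$trust_labels
    }
    chamber_groups <- stats::setNames(character(0), character(0))
    for (ch in ec$chambers) chamber_groups[ch$members] <- "echo_chamber"
    dico_users <- names(dico$labels)[!is.na(dico$labels)]
    non_chamber <- setdiff(dico_users, names(chamber_groups))
    chamber_groups[non_chamber] <- "outside_chambers"
    trust_section <- if (length(chamber_groups) == 0) {
      "skipped (no grouped users)"
    } else {
      stage("trust", tally_trust(d, chamber_groups, labels, url_map = url_map))
    }
  }

  n_url_users <- length(unique(d$posts$author_id[
    vapply(d$posts$urls, length, 1L) > 0
  ]))
  n_validated <- length(nec$validated)
  chamber_users <- unique(unlist(lapply(ec$chambers, `[[`, "members")))

  report <- list(
    params = cfg[c("alpha", "shuffles", "seed", "connectivity", "weight_min")],
    dataset = d$counts,
    dico = list(
      tallies = dico$tallies,
      minor = as.list(dico$minor),
      unlabeled = sum(is.na(dico$labels)),
      fdr_threshold = dico$projection$threshold
    ),
    nec = list(
      tallies = nec$tallies,
      validated = n_validated,
      nonvalidated = n_url_users - n_validated,
      validated_pct = validated_fraction(n_validated, n_url_users - n_validated),
      fdr_threshold = nec$projection$threshold
    ),
    echo_chambers = list(
      n_chambers = length(ec$chambers),
      n_users = length(chamber_users),
      user_share_pct = echo_user_share(length(chamber_users), d$counts$users),
      excluded = length(ec$excluded),
      table = lapply(ec$chambers, function(ch) {
        list(id = ch$id, nec = ch$nec, dico = ch$dico,
             size = length(ch$members), avg_clustering = ch$avg_clustering,
             rt_generated = ch$rt_generated, rt_received = ch$rt_received)
      })
    ),
    flow = if (is.null(flow)) "skipped (no chambers)" else {
      list(nodes = igraph::V(flow)$name,
           edges = igraph::as_data_frame(flow, what = "edges"))
    },
    trust = trust_section,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(cfg$out)) {
    objs <- list(report = report, retweet_network = rt,
                 dico_labels = as.list(dico$labels),
                 nec_labels = as.list(nec$labels),
                 validated_dico_projection = dico$projection$graph,
                 validated_nec_projection = nec$projection$graph)
    if (!is.null(flow)) objs$flow <- flow
    write_outputs(objs, cfg$out)
    return(invisible(report))
  }
  report
}
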