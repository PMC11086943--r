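#' Configuration for the synthetic dataset generator
#'
#' Describes a community-structured retweet-and-URL-sharing world: `n_blocks`
#' planted discursive blocks, each with its own verified accounts, unverified
#' audience and URL pool; unverified users retweet verified users of their
#' own block at rate `p_in` and other blocks at rate `p_out`; within the
#' first `n_necs` blocks, `nec_users` users are planted as a news engagement
#' community oversampling a dedicated pool of `nec_pool` URLs, and are wired
#' into a random retweet spanning tree so the planted chamber is weakly
#' connected by construction.
#'
#' @param n_blocks number of planted blocks (default 2).
#' @param n_verified verified users per block (default 10).
#' @param n_unverified unverified users per block (default 400).
#' @param p_in within-block retweet probability per (unverified, verified)
#'   pair (default 0.3).
#' @param p_out cross-block retweet probability (default 0.01).
#' @param url_pool background URL pool size per block (default 100).
#' @param n_necs number of planted NECs, one per block, in blocks 1..n_necs
#'   (default 1).
#' @param nec_users users per planted NEC (default 8).
#' @param nec_pool shared-URL pool size per planted NEC (default 20).
#' @param nec_share_rate probability a NEC member shares each pool URL
#'   (default 0.8).
#' @param bg_share_rate expected background URL shares per user (default 1).
#' @param trust_mix length-3 probability vector over labels T, N, UNC for a
#'   block's background domains; recycled over blocks when a single vector
#'   is given (default c(0.5, 0.25, 0.25)).
#' @param seed master seed.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_blocks = 2L, n_verified = 10L,
                             n_unverified = 400L, p_in = 0.3, p_out = 0.01,
                             url_pool = 100L, n_necs = 1L, nec_users = 8L,
                             nec_pool = 20L, nec_share_rate = 0.8,
                             bg_share_rate = 1, trust_mix = c(0.5, 0.25, 0.25),
                             seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks), n_verified = as.integer(n_verified),
    n_unverified = as.integer(n_unverified), p_in = p_in, p_out = p_out,
    url_pool = as.integer(url_pool), n_necs = as.integer(n_necs),
    nec_users = as.integer(nec_users), nec_pool = as.integer(nec_pool),
    nec_share_rate = nec_share_rate, bg_share_rate = bg_share_rate,
    trust_mix = trust_mix, seed = as.integer(seed)
  )
  rates <- c(cfg$p_in, cfg$p_out, cfg$nec_share_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_blocks < 1 || cfg$n_verified < 1 || cfg$n_unverified < 1) {
    stop("block dimensions must be positive")
  }
  if (cfg$n_necs > cfg$n_blocks) stop("n_necs cannot exceed n_blocks")
  if (cfg$n_necs > 0 && cfg$nec_users > cfg$n_unverified) {
    stop("planted NEC larger than its block's unverified population")
  }
  if (abs(sum(cfg$trust_mix) - 1) > 1e-9 || length(cfg$trust_mix) != 3) {
    stop("trust_mix must be a length-3 probability vector")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic post dataset with planted ground truth
#'
#' Produces a dataset in the standard post-record schema together with the
#' planted structure: user-to-block (DiCo ground truth), planted NEC
#' memberships, and planted chamber memberships (NEC members, weakly
#' connected through an explicitly planted retweet spanning tree, all inside
#' one block). Byte-identical output under a fixed configuration and seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `dataset` (an [echo_dataset()]), `truth` (list:
#'   `dico` named user -> block, `nec` named user -> NEC id, `chambers`
#'   list of member vectors) and `trust_labels` (a domain trust table
#'   consistent with the generated URLs).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  B <- cfg$n_blocks

  ver <- lapply(seq_len(B), function(b) sprintf("v%d_%02d", b, seq_len(cfg$n_verified)))
  unv <- lapply(seq_len(B), function(b) sprintf("u%d_%03d", b, seq_len(cfg$n_unverified)))

  # per-block background domains, one per label slot, plus labels table
  doms <- lapply(seq_len(B), function(b) {
    c(T = sprintf("trusted%d.example", b),
      N = sprintf("untrusted%d.example", b),
      UNC = sprintf("gray%d.example", b))
  })
  nec_dom <- sprintf("necnews%d.example", seq_len(max(cfg$n_necs, 1)))
  trust <- data.frame(
    domain = c(unlist(doms, use.names = FALSE), if (cfg$n_necs > 0) nec_dom[seq_len(cfg$n_necs)]),
    label = c(rep(c("T", "N", "UNC"), B), rep("N", cfg$n_necs)),
    stringsAsFactors = FALSE
  )

  # background URL pools: each URL gets a label-bearing domain by trust_mix
  pools <- lapply(seq_len(B), function(b) {
    lab <- sample(c("T", "N", "UNC"), cfg$url_pool, replace = TRUE,
                  prob = cfg$trust_mix)
    sprintf("https://%s/a/%d-%d", doms[[b]][lab], b, seq_len(cfg$url_pool))
  })
  nec_pools <- lapply(seq_len(cfg$n_necs), function(k) {
    sprintf("https://%s/n/%d-%d", nec_dom[k], k, seq_len(cfg$nec_pool))
  })

  posts <- list()
  add <- function(author, verified, rt_author = NA_character_, urls = character(0)) {
    posts[[length(posts) + 1]] <<- list(
      author = author, verified = verified, rt = rt_author, urls = urls
    )
  }

  # each verified user authors one original post (fixes its verified flag)
  for (b in seq_len(B)) {
    for (v in ver[[b]]) add(v, TRUE, urls = sample(pools[[b]], 1))
  }

  # block-structured retweets: unverified u retweets verified v
  for (b in seq_len(B)) {
    for (c in seq_len(B)) {
      rate <- if (b == c) cfg$p_in else cfg$p_out
      pick <- which(matrix(stats::runif(cfg$n_unverified * cfg$n_verified),
                           cfg$n_unverified) < rate, arr.ind = TRUE)
      if (nrow(pick) > 0) {
        for (r in seq_len(nrow(pick))) {
          add(unv[[b]][pick[r, 1]], FALSE, rt_author = ver[[c]][pick[r, 2]])
        }
      }
    }
  }

  # background URL shares: ~bg_share_rate per unverified user
  for (b in seq_len(B)) {
    for (u in unv[[b]]) {
      n_sh <- stats::rpois(1, cfg$bg_share_rate)
      if (n_sh > 0) add(u, FALSE, urls = sample(pools[[b]], min(n_sh, cfg$url_pool)))
    }
  }

  # planted NECs: members oversample the common pool, and a random retweet
  # spanning tree makes each planted chamber weakly connected
  truth_nec <- stats::setNames(character(0), character(0))
  chambers <- list()
  for (k in seq_len(cfg$n_necs)) {
    members <- sample(unv[[k]], cfg$nec_users)
    truth_nec[members] <- as.character(k - 1L)
    for (u in members) {
      got <- nec_pools[[k]][stats::runif(cfg$nec_pool) < cfg$nec_share_rate]
      if (length(got) > 0) add(u, FALSE, urls = got)
    }
    ord <- sample(members)
    if (length(ord) > 1) {
      for (i in 2:length(ord)) {
        parent <- ord[sample.int(i - 1, 1)]
        add(ord[i], FALSE, rt_author = parent)
      }
    }
    chambers[[length(chambers) + 1]] <- sort(members)
  }

  n <- length(posts)
  df <- data.frame(
    post_id = sprintf("p%06d", seq_len(n)),
    author_id = vapply(posts, `[[`, "", "author"),
    author_verified = vapply(posts, `[[`, TRUE, "verified"),
    retweeted_author_id = vapply(posts, `[[`, "", "rt"),
    timestamp = sprintf("2021-09-%02dT%02d:%02d:00Z",
                        1 + (seq_len(n) %% 24), seq_len(n) %% 24,
                        seq_len(n) %% 60),
    stringsAsFactors = FALSE
  )
  df$urls <- lapply(posts, `[[`, "urls")

  truth_dico <- stats::setNames(
    rep(as.character(seq_len(B)), each = cfg$n_verified + cfg$n_unverified),
    unlist(lapply(seq_len(B), function(b) c(ver[[b]], unv[[b]])))
  )

  list(
    dataset = echo_dataset(df[c("post_id", "author_id", "author_verified",
                                "retweeted_author_id", "urls", "timestamp")]),
    truth = list(dico = truth_dico, nec = truth_nec, chambers = chambers),
    trust_labels = structure(stats::setNames(trust$label, trust$domain),
                             class = "trust_labels")
  )
}
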