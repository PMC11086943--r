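# Common multi-label public suffixes; single-label TLDs are handled by the
# default rule (registrable domain = last two labels). Deliberately a small
# embedded subset of the public-suffix list, extensible via `extra_suffixes`.
.multi_suffixes <- c(
  "co.uk", "org.uk", "ac.uk", "gov.uk", "me.uk", "net.uk", "ltd.uk", "plc.uk",
  "co.jp", "ne.jp", "or.jp", "ac.jp", "go.jp", "com.au", "net.au", "org.au",
  "edu.au", "gov.au", "id.au", "co.nz", "net.nz", "org.nz", "govt.nz",
  "co.in", "net.in", "org.in", "gen.in", "firm.in", "ind.in", "com.br",
  "net.br", "org.br", "gov.br", "com.mx", "com.ar", "com.cn", "net.cn",
  "org.cn", "gov.cn", "com.tw", "com.hk", "com.sg", "com.tr", "com.sa",
  "co.za", "org.za", "co.kr", "or.kr", "com.co", "com.ve", "com.pe",
  "com.eg", "co.id", "or.id", "com.my", "com.ph", "com.vn", "com.ua",
  "co.il", "org.il", "ac.il", "com.pl", "net.pl", "org.pl", "edu.pl"
)

# query parameters stripped during canonicalization (tracking junk)
.tracking_params <- "^(utm_|fbclid$|gclid$)"

#' Canonicalize a URL and extract its registrable domain
#'
#' Applies an optional short-to-long URL mapping (no live HTTP resolution),
#' lower-cases scheme and host, strips the fragment and tracking query
#' parameters (`utm_*`, `fbclid`, `gclid`), and extracts the registrable
#' domain with a public-suffix rule set (e.g. `news.site.co.uk` ->
#' `site.co.uk`). Unparseable URLs yield `NA` in both columns.
#'
#' @param urls character vector of URLs.
#' @param url_map optional named character vector (short URL -> long URL) or
#'   two-column data frame `short,long`.
#' @param extra_suffixes additional multi-label public suffixes.
#' @return data frame with columns `url` (input), `canonical`, `domain`.
#' @examples
#' canonicalize_url("HTTPS://Example.com/a?utm_source=x#frag")
#' @export
canonicalize_url <- function(urls, url_map = NULL, extra_suffixes = character(0)) {
  if (is.data.frame(url_map)) {
    url_map <- stats::setNames(as.character(url_map[[2]]), as.character(url_map[[1]]))
  }
  suffixes <- c(.multi_suffixes, extra_suffixes)
  out <- data.frame(url = as.character(urls), canonical = NA_character_,
                    domain = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    u <- trimws(out$url[r])
    if (!nzchar(u)) next
    if (!is.null(url_map) && u %in% names(url_map)) u <- url_map[[u]]
    parsed <- parse_url_parts(u)
    if (is.null(parsed)) next
    q <- parsed$query
    if (nzchar(q)) {
      parts <- strsplit(q, "&", fixed = TRUE)[[1]]
      keys <- sub("=.*$", "", parts)
      parts <- parts[!grepl(.tracking_params, tolower(keys))]
      q <- paste(parts, collapse = "&")
    }
    canonical <- paste0(parsed$scheme, "://", parsed$host,
                        if (nzchar(parsed$port)) paste0(":", parsed$port) else "",
                        parsed$path,
                        if (nzchar(q)) paste0("?", q) else "")
    out$canonical[r] <- canonical
    out$domain[r] <- registrable_domain(parsed$host, suffixes)
  }
  out
}

# Minimal URL splitter; scheme-less inputs get "https".
parse_url_parts <- function(u) {
  m <- regexec("^(?:([A-Za-z][A-Za-z0-9+.-]*)://)?([^/?#]+)([^?#]*)(?:\\?([^#]*))?(?:#.*)?$", u)
  g <- regmatches(u, m)[[1]]
  if (length(g) == 0 || !nzchar(g[3])) return(NULL)
  hostport <- tolower(g[3])
  host <- sub(":[0-9]+$", "", hostport)
  port <- if (grepl(":[0-9]+$", hostport)) sub("^.*:", "", hostport) else ""
  if (!grepl("^[a-z0-9.-]+$", host) || !grepl("\\.", host)) return(NULL)
  scheme <- if (nzchar(g[2])) tolower(g[2]) else "https"
  list(scheme = scheme, host = host, port = port,
       path = g[4], query = if (length(g) >= 5) g[5] else "")
}

registrable_domain <- function(host, suffixes = .multi_suffixes) {
  labels <- strsplit(host, ".", fixed = TRUE)[[1]]
  n <- length(labels)
  if (n < 2) return(host)
  two <- paste(labels[c(n - 1, n)], collapse = ".")
  if (two %in% suffixes && n >= 3) {
    return(paste(labels[c(n - 2, n - 1, n)], collapse = "."))
  }
  two
}

#' Tally trustworthy / untrustworthy / unclassified URL shares per group
#'
#' Every URL occurring in a post (tweet or retweet) by a grouped user
#' contributes one multiplicity-weighted count to the trust label of its
#' registrable domain in that user's group; distinct-URL counts are reported
#' alongside. Group-conditional share probabilities P(label | group) are
#' derived from the multiplicity-weighted counts.
#'
#' @param d an [echo_dataset()].
#' @param groups named vector user id -> group id; ungrouped users are
#'   ignored.
#' @param labels a [read_trust_labels()] table.
#' @param url_map optional short-to-long URL mapping (see
#'   [canonicalize_url()]).
#' @return object of class `trust_tally`: data frame with one row per group
#'   (plus a `"__all__"` row over all grouped users): multiplicity-weighted
#'   counts `T`, `N`, `UNC`, distinct counts `T_distinct`, `N_distinct`,
#'   `UNC_distinct`, ratio `NT_ratio` and probabilities `p_T`, `p_N`,
#'   `p_UNC` (NA for empty groups).
#' @export
tally_trust <- function(d, groups, labels, url_map = NULL) {
  stopifnot(inherits(d, "echo_dataset"), !is.null(names(groups)))
  p <- d$posts
  urls <- lapply(p$urls, unique) # identical URLs within one post count once
  n_urls <- vapply(urls, length, 1L)
  rows <- rep(seq_len(nrow(p)), n_urls)
  shares <- data.frame(
    user = p$author_id[rows],
    url = unlist(urls, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  shares <- shares[shares$user %in% names(groups), , drop = FALSE]
  grp_levels <- sort(unique(as.character(groups)))

  empty <- function(gid) data.frame(
    group = gid, T = 0, N = 0, UNC = 0,
    T_distinct = 0, N_distinct = 0, UNC_distinct = 0,
    NT_ratio = NA_real_, p_T = NA_real_, p_N = NA_real_, p_UNC = NA_real_,
    stringsAsFactors = FALSE
  )

  if (nrow(shares) > 0) {
    canon <- canonicalize_url(shares$url, url_map = url_map)
    shares$canonical <- canon$canonical
    shares$label <- trust_label_of(labels, canon$domain)
    dropped <- sum(is.na(shares$canonical))
    shares <- shares[!is.na(shares$canonical), , drop = FALSE]
    shares$group <- as.character(unclass(groups)[shares$user])
  } else {
    dropped <- 0L
    shares$canonical <- character(0)
    shares$label <- character(0)
    shares$group <- character(0)
  }

  one_group <- function(gid, sub) {
    if (nrow(sub) == 0) return(empty(gid))
    cnt <- table(factor(sub$label, levels = c("T", "N", "UNC")))
    dst <- table(factor(sub$label[!duplicated(sub$canonical)],
                        levels = c("T", "N", "UNC")))
    tot <- sum(cnt)
    data.frame(
      group = gid, T = as.numeric(cnt["T"]), N = as.numeric(cnt["N"]),
      UNC = as.numeric(cnt["UNC"]),
      T_distinct = as.numeric(dst["T"]), N_distinct = as.numeric(dst["N"]),
      UNC_distinct = as.numeric(dst["UNC"]),
      NT_ratio = if (cnt["T"] > 0) as.numeric(cnt["N"] / cnt["T"]) else NA_real_,
      p_T = as.numeric(cnt["T"] / tot), p_N = as.numeric(cnt["N"] / tot),
      p_UNC = as.numeric(cnt["UNC"] / tot),
      stringsAsFactors = FALSE
    )
  }

  res <- do.call(rbind, c(
    lapply(grp_levels, function(gid) {
      one_group(gid, shares[shares$group == gid, , drop = FALSE])
    }),
    list(one_group("__all__", shares))
  ))
  rownames(res) <- NULL
  attr(res, "dropped_urls") <- dropped
  class(res) <- c("trust_tally", "data.frame")
  res
}
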