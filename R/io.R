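#' Post dataset
#'
#' The canonical in-memory form of a post dataset: a data frame of post
#' records plus recomputable summary counts. One row per post with columns
#' `post_id`, `author_id`, `author_verified` (logical),
#' `retweeted_author_id` (`NA` for original posts), `urls` (list column of
#' character vectors) and `timestamp` (informational, never used by the
#' method).
#'
#' @param posts data frame as described above.
#' @param drops named integer vector of rows dropped at load, by reason.
#' @return object of class `echo_dataset`: list with `posts`, `counts`
#'   (users, verified_users, posts, retweets, url_posts) and `drops`.
#' @export
echo_dataset <- function(posts, drops = integer(0)) {
  need <- c("post_id", "author_id", "author_verified", "retweeted_author_id",
            "urls", "timestamp")
  missing_cols <- setdiff(need, names(posts))
  if (length(missing_cols) > 0) {
    stop("posts is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  posts <- posts[need]
  structure(
    list(posts = posts, counts = dataset_counts(posts), drops = drops),
    class = "echo_dataset"
  )
}

#' Summary counts of a post table
#'
#' @param posts post data frame (see [echo_dataset()]).
#' @return list of counts: `users`, `verified_users`, `posts`, `retweets`,
#'   `url_posts`.
#' @export
dataset_counts <- function(posts) {
  users <- unique(c(posts$author_id,
                    posts$retweeted_author_id[!is.na(posts$retweeted_author_id)]))
  verified <- unique(posts$author_id[posts$author_verified])
  list(
    users = length(users),
    verified_users = length(verified),
    posts = nrow(posts),
    retweets = sum(!is.na(posts$retweeted_author_id)),
    url_posts = sum(vapply(posts$urls, length, 1L) > 0)
  )
}

#' @export
print.echo_dataset <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "echo_dataset: %d posts (%d retweets, %d with URLs), %d users (%d verified)\n",
    c$posts, c$retweets, c$url_posts, c$users, c$verified_users
  ))
  if (sum(x$drops) > 0) {
    cat("  dropped at load:",
        paste(sprintf("%s=%d", names(x$drops), x$drops), collapse = ", "), "\n")
  }
  invisible(x)
}

post_row_template <- function(n) {
  data.frame(
    post_id = character(n), author_id = character(n),
    author_verified = logical(n), retweeted_author_id = character(n),
    timestamp = character(n), stringsAsFactors = FALSE
  )
}

#' Read post records from JSONL or CSV
#'
#' JSONL: one JSON object per line with fields `post_id`, `author_id`,
#' `author_verified`, optional `retweeted_author_id`, optional `urls`
#' (array), optional `timestamp`. CSV: same column names, comma-separated,
#' URLs joined by `"|"`.
#'
#' Malformed rows (unparseable, or missing `post_id`/`author_id`) are
#' skipped and counted; more than 50% malformed rows is a fatal format
#' error. Self-retweets (`retweeted_author_id == author_id`) and duplicated
#' `post_id`s are dropped with logged counts.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return an [echo_dataset()].
#' @export
read_posts <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read posts file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  drops <- c(malformed = 0L, self_retweet = 0L, duplicate_id = 0L)

  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("posts file is empty")
      posts <- post_row_template(0)
      posts$urls <- list()
      return(echo_dataset(posts[c("post_id", "author_id", "author_verified",
                                  "retweeted_author_id", "urls", "timestamp")],
                          drops))
    }
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE), error = function(e) NULL)
    })
    bad <- vapply(recs, function(r) {
      is.null(r) || !is.list(r) || is.null(r$post_id) || is.null(r$author_id)
    }, TRUE)
    drops["malformed"] <- sum(bad)
    if (sum(bad) > length(lines) / 2) {
      stop(sprintf("more than 50%% of rows are malformed (%d of %d)",
                   sum(bad), length(lines)))
    }
    recs <- recs[!bad]
    posts <- post_row_template(length(recs))
    posts$post_id <- vapply(recs, function(r) as.character(r$post_id), "")
    posts$author_id <- vapply(recs, function(r) as.character(r$author_id), "")
    posts$author_verified <- vapply(recs, function(r) {
      isTRUE(as.logical(r$author_verified))
    }, TRUE)
    posts$retweeted_author_id <- vapply(recs, function(r) {
      if (is.null(r$retweeted_author_id) || length(r$retweeted_author_id) == 0 ||
          is.na(r$retweeted_author_id)) NA_character_
      else as.character(r$retweeted_author_id)
    }, "")
    posts$timestamp <- vapply(recs, function(r) {
      if (is.null(r$timestamp)) NA_character_ else as.character(r$timestamp)
    }, "")
    posts$urls <- lapply(recs, function(r) {
      u <- r$urls
      if (is.null(u)) character(0) else as.character(u[!is.na(u) & nzchar(u)])
    })
  } else {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop("cannot parse posts CSV: ", conditionMessage(e))
    )
    if (nrow(df) == 0) {
      warning("posts file is empty")
      posts <- post_row_template(0)
      posts$urls <- list()
      return(echo_dataset(posts[c("post_id", "author_id", "author_verified",
                                  "retweeted_author_id", "urls", "timestamp")],
                          drops))
    }
    for (col in c("author_verified", "retweeted_author_id", "urls", "timestamp")) {
      if (!col %in% names(df)) df[[col]] <- NA_character_
    }
    bad <- is.na(df$post_id) | !nzchar(df$post_id) |
      is.na(df$author_id) | !nzchar(df$author_id)
    if (!all(c("post_id", "author_id") %in% names(df))) bad <- rep(TRUE, nrow(df))
    drops["malformed"] <- sum(bad)
    if (sum(bad) > nrow(df) / 2) {
      stop(sprintf("more than 50%% of rows are malformed (%d of %d)",
                   sum(bad), nrow(df)))
    }
    df <- df[!bad, , drop = FALSE]
    posts <- post_row_template(nrow(df))
    posts$post_id <- df$post_id
    posts$author_id <- df$author_id
    posts$author_verified <- toupper(trimws(df$author_verified)) %in% c("TRUE", "T", "1")
    posts$retweeted_author_id <- ifelse(
      is.na(df$retweeted_author_id) | !nzchar(df$retweeted_author_id),
      NA_character_, df$retweeted_author_id
    )
    posts$timestamp <- ifelse(is.na(df$timestamp) | !nzchar(df$timestamp),
                              NA_character_, df$timestamp)
    posts$urls <- lapply(df$urls, function(u) {
      if (is.na(u) || !nzchar(u)) character(0) else strsplit(u, "|", fixed = TRUE)[[1]]
    })
  }

  self <- !is.na(posts$retweeted_author_id) &
    posts$retweeted_author_id == posts$author_id
  drops["self_retweet"] <- sum(self)
  posts <- posts[!self, , drop = FALSE]

  dup <- duplicated(posts$post_id)
  drops["duplicate_id"] <- sum(dup)
  posts <- posts[!dup, , drop = FALSE]
  rownames(posts) <- NULL

  if (sum(drops) > 0) {
    message("read_posts: dropped ",
            paste(sprintf("%s=%d", names(drops), drops), collapse = ", "))
  }
  echo_dataset(posts, drops)
}

#' Write post records to JSONL or CSV
#'
#' Inverse of [read_posts()]: a write-then-read round trip reproduces the
#' dataset exactly.
#'
#' @param d an [echo_dataset()].
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(d, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  p <- d$posts
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(p)), function(r) {
      rec <- list(post_id = p$post_id[r], author_id = p$author_id[r],
                  author_verified = p$author_verified[r])
      if (!is.na(p$retweeted_author_id[r])) {
        rec$retweeted_author_id <- p$retweeted_author_id[r]
      }
      if (length(p$urls[[r]]) > 0) rec$urls <- I(p$urls[[r]])
      if (!is.na(p$timestamp[r])) rec$timestamp <- p$timestamp[r]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, "")
    writeLines(lines, path)
  } else {
    df <- p
    df$urls <- vapply(p$urls, paste, "", collapse = "|")
    df$author_verified <- ifelse(p$author_verified, "TRUE", "FALSE")
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(path)
}

#' Read a domain trust-label table
#'
#' CSV with columns `domain,label`; labels must be `T` (trustworthy), `N`
#' (not trustworthy) or `UNC` (unclassified). Domains are lower-cased;
#' duplicate domains keep the last row with a warning. Lookups of unknown
#' domains resolve to `UNC`.
#'
#' @param path CSV path.
#' @return object of class `trust_labels`: named character vector
#'   domain -> label.
#' @export
read_trust_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("domain", "label") %in% names(df))) {
    stop("trust-label CSV needs columns domain,label")
  }
  df$domain <- tolower(trimws(df$domain))
  df$label <- toupper(trimws(df$label))
  bad <- which(!df$label %in% c("T", "N", "UNC"))
  if (length(bad) > 0) {
    stop(sprintf("invalid trust label '%s' at row %d (must be T, N or UNC)",
                 df$label[bad[1]], bad[1]))
  }
  if (anyDuplicated(df$domain)) {
    warning("duplicate domains in trust-label table: last entry wins")
    df <- df[!duplicated(df$domain, fromLast = TRUE), , drop = FALSE]
  }
  structure(stats::setNames(df$label, df$domain), class = "trust_labels")
}

#' Look up trust labels for domains
#'
#' @param labels a [read_trust_labels()] table.
#' @param domains character vector of registrable domains.
#' @return character vector of labels; unknown domains map to `"UNC"`.
#' @export
trust_label_of <- function(labels, domains) {
  out <- unclass(labels)[tolower(domains)]
  out[is.na(out)] <- "UNC"
  unname(out)
}

#' Write graphs, partitions and reports with a checksum manifest
#'
#' igraph objects are written as GraphML plus a weighted edge-list CSV;
#' everything else is serialized as JSON. A `manifest.json` listing every
#' file with its MD5 checksum is written last. Two runs producing identical
#' objects produce identical checksums.
#'
#' @param objects named list; names become file stems.
#' @param out_dir output directory (created if needed).
#' @return data frame manifest (file, md5), invisibly.
#' @export
write_outputs <- function(objects, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  stopifnot(!is.null(names(objects)), all(nzchar(names(objects))))
  files <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (inherits(obj, "igraph")) {
      f1 <- file.path(out_dir, paste0(nm, ".graphml"))
      igraph::write_graph(obj, f1, format = "graphml")
      el <- igraph::as_data_frame(obj, what = "edges")
      if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
      f2 <- file.path(out_dir, paste0(nm, ".edges.csv"))
      utils::write.csv(el, f2, row.names = FALSE, quote = TRUE)
      files <- c(files, f1, f2)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", force = TRUE)
      files <- c(files, f)
    }
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
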