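#' Parse thread-text files into posts
#'
#' Reads one or more files in the dialect documented at [emit_threads()] and
#' returns a posts tibble. Reaction marks are mapped 推 -> like,
#' 噓/嘘 -> boo, → -> neutral. Malformed comment lines (wrong field
#' count, unknown mark, unparseable time) are skipped, counted and reported
#' in a warning; the count is attached as attribute `skipped`.
#'
#' @param source Character vector of file paths.
#' @return Posts tibble (`board_id`, `author`, `time`, `title`, `label`,
#'   `comments` list-column), with attribute `skipped` (number of malformed
#'   lines dropped).
#' @examples
#' cfg <- forum_config(n_users = 50, n_posts_per_layer = c(P = 5, H = 5, A = 2))
#' f <- tempfile(fileext = ".txt")
#' emit_threads(generate_forum(cfg)$posts, f)
#' posts <- parse_threads(f)
#' @export
parse_threads <- function(source) {
  lines <- character(0)
  for (path in source) {
    if (!file.exists(path)) {
      stop("cannot read '", path, "': no such file", call. = FALSE)
    }
    lines <- c(lines, readLines(path, encoding = "UTF-8", warn = FALSE))
  }
  starts <- grep("^==== ", lines)
  if (!length(starts)) {
    stop("no parseable posts found in input", call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  skipped <- 0L
  posts <- vector("list", length(starts))
  empty <- tibble::tibble(
    commenter = character(0), reaction = character(0),
    time = as.POSIXct(character(0), tz = TIME_TZ), text = character(0)
  )
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    board_id <- sub("^==== ", "", block[1])
    sep <- match("----", block)
    if (is.na(sep)) {
      skipped <- skipped + length(block)
      posts[k] <- list(NULL)
      next
    }
    header <- block[2:(sep - 1L)]
    kv <- strsplit(header, "\t", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) if (length(x) >= 2L) x[2L] else "", character(1))
    h <- setNames(vals, keys)
    ptime <- parse_time(h[["time"]])
    if (is.na(ptime) || is.null(h[["author"]])) {
      skipped <- skipped + length(block)
      posts[k] <- list(NULL)
      next
    }
    body <- if (sep < length(block)) block[(sep + 1L):length(block)] else character(0)
    cm <- empty
    if (length(body)) {
      is_cont <- startsWith(body, "\t")
      fields <- strsplit(body, "\t", fixed = TRUE)
      rows <- list()
      cur <- NULL
      for (i in seq_along(body)) {
        if (is_cont[i]) {
          if (is.null(cur)) {
            skipped <- skipped + 1L
          } else {
            cur$text <- paste0(cur$text, sub("^\t", "", body[i]))
          }
          next
        }
        f <- fields[[i]]
        mark <- f[1]
        if (length(f) < 3L || !mark %in% names(MARK_TO_REACTION)) {
          skipped <- skipped + 1L
          next
        }
        ctime <- parse_time(f[3])
        if (is.na(ctime)) {
          skipped <- skipped + 1L
          next
        }
        if (!is.null(cur)) rows[[length(rows) + 1L]] <- cur
        cur <- list(
          commenter = f[2],
          reaction = unname(MARK_TO_REACTION[[mark]]),
          time = ctime,
          text = if (length(f) >= 4L) f[4] else ""
        )
      }
      if (!is.null(cur)) rows[[length(rows) + 1L]] <- cur
      if (length(rows)) {
        cm <- tibble::tibble(
          commenter = vapply(rows, `[[`, character(1), "commenter"),
          reaction = vapply(rows, `[[`, character(1), "reaction"),
          time = as.POSIXct(vapply(rows, function(r) as.numeric(r$time), numeric(1)),
                            origin = "1970-01-01", tz = TIME_TZ),
          text = vapply(rows, `[[`, character(1), "text")
        )
      }
    }
    posts[[k]] <- tibble::tibble(
      board_id = board_id,
      author = h[["author"]],
      time = ptime,
      title = if (!is.null(h["title"]) && !is.na(h["title"])) h[["title"]] else "",
      label = if (!is.na(h["label"])) h[["label"]] else "unlabeled",
      comments = list(cm)
    )
  }
  posts <- posts[!vapply(posts, is.null, logical(1))]
  if (!length(posts)) {
    stop("no parseable posts found in input", call. = FALSE)
  }
  out <- dplyr::bind_rows(posts)
  if (skipped > 0L) {
    warning(skipped, " malformed line(s) skipped", call. = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Anonymize usernames
#'
#' Replaces every distinct raw username (authors and commenters) with a
#' distinct 6-character alphanumeric token (uppercase A-Z, 0-9). The mapping
#' is injective and fully determined by `seed`; raw names do not appear in
#' the output posts.
#'
#' @param posts Posts tibble.
#' @param seed Integer seed for token generation.
#' @return List with `posts` (tokenized) and `map` (tibble: user, token).
#' @export
anonymize <- function(posts, seed = 1L) {
  assert_posts(posts)
  users <- unique(c(posts$author,
                    unlist(lapply(posts$comments, `[[`, "commenter"))))
  n <- length(users)
  if (n > 36^6) {
    stop("token space exhausted: more than 36^6 distinct users", call. = FALSE)
  }
  local_seed_if(derive_seed(seed, "anonymize"))
  alphabet <- c(LETTERS, 0:9)
  tokens <- character(0)
  while (length(tokens) < n) {
    need <- n - length(tokens)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(alphabet, 6L, replace = TRUE), collapse = "")
    }, character(1))
    tokens <- head(unique(c(tokens, cand)), n)
  }
  map <- setNames(tokens, users)
  out <- posts
  out$author <- unname(map[out$author])
  out$comments <- lapply(out$comments, function(cm) {
    cm$commenter <- unname(map[cm$commenter])
    cm
  })
  list(posts = out, map = tibble::tibble(user = users, token = tokens))
}

#' Filter posts by keyword
#'
#' Retains posts whose title or any comment text contains the keyword
#' (substring match, case-insensitive for Latin script). The default keyword
#' is \dQuote{疫苗} (vaccine).
#'
#' @param posts Posts tibble.
#' @param keyword Non-empty filter string.
#' @return The retained posts; counts of retained/dropped are reported via
#'   `message()`.
#' @export
filter_vaccine_boards <- function(posts, keyword = "疫苗") {
  assert_posts(posts)
  if (!nzchar(keyword)) stop("`keyword` must be non-empty", call. = FALSE)
  hit_title <- grepl(keyword, posts$title, fixed = FALSE, ignore.case = TRUE)
  hit_body <- vapply(posts$comments, function(cm) {
    nrow(cm) > 0 && any(grepl(keyword, cm$text, ignore.case = TRUE))
  }, logical(1))
  keep <- hit_title | hit_body
  message("keyword filter: retained ", sum(keep), ", dropped ", sum(!keep))
  posts[keep, ]
}

#' Read a two-rater label table
#'
#' @param path CSV with columns `board_id`, `rater1`, `rater2`, `final`.
#' @return Tibble with those columns.
#' @export
read_label_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("board_id", "rater1", "rater2", "final")
  if (!all(needed %in% names(tbl))) {
    stop("label table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' Interrater agreement of board labels
#'
#' Percentage of boards on which the two raters agree, plus the disagreement
#' list for resolution.
#'
#' @param table Label table (see [read_label_table()]).
#' @return List: `percent` (0-100), `n_agree`, `n_total`, `disagreements`
#'   (tibble subset of `table`).
#' @examples
#' tbl <- tibble::tibble(board_id = c("a", "b"), rater1 = c("P", "P"),
#'                       rater2 = c("P", "A"), final = c("P", "P"))
#' interrater_agreement(tbl)$percent
#' @export
interrater_agreement <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("label table is empty", call. = FALSE)
  }
  agree <- table$rater1 == table$rater2
  list(
    percent = 100 * sum(agree) / nrow(table),
    n_agree = sum(agree),
    n_total = nrow(table),
    disagreements = tibble::as_tibble(table[!agree, ])
  )
}

#' Apply final board labels and drop excluded categories
#'
#' Joins the final (resolved) label onto each post and removes boards
#' labeled `neutral` or `irrelevant`, which are excluded from the analysis
#' network. Every post must appear in the table.
#'
#' @param posts Posts tibble.
#' @param table Label table (see [read_label_table()]).
#' @return Labeled posts restricted to the P/H/A analysis set, with
#'   attribute `excluded` (number of boards dropped).
#' @export
apply_final_labels <- function(posts, table) {
  assert_posts(posts)
  missing <- setdiff(posts$board_id, table$board_id)
  if (length(missing)) {
    stop("boards missing from label table: ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "",
         call. = FALSE)
  }
  lab <- setNames(table$final, table$board_id)
  out <- posts
  out$label <- unname(lab[out$board_id])
  keep <- out$label %in% LAYERS
  excluded <- sum(!keep)
  message("labels applied: retained ", sum(keep), ", excluded ", excluded,
          " neutral/irrelevant")
  out <- out[keep, ]
  attr(out, "excluded") <- excluded
  out
}
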