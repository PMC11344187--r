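#' Configuration for the synthetic forum generator
#'
#' Bundles every knob of the synthetic corpus: population size, per-layer
#' post counts, the power-law exponent of commenting activity, the
#' chambering probability (how likely a background user's comment lands on a
#' post of their own stance), reaction-mark rates, archetype fractions, and
#' the monthly time grid with optional burst months.
#'
#' Defaults mirror the structure of the studied forum: latent stance shares
#' follow the observed post split across the provaccination, hesitant and
#' antivaccination layers (1283:1322:387), commenting activity is heavy
#' tailed with exponent 2.3, and the 24 monthly periods span January 2021 to
#' December 2022 with burst months at periods 11 and 14 (November 2021 and
#' February 2022, the two observed surges).
#'
#' @param n_users Number of users.
#' @param n_posts_per_layer Named integer vector `c(P=,H=,A=)` of post counts.
#' @param activity_exponent Power-law exponent (> 1) of per-user comment
#'   counts.
#' @param activity_min Smallest per-user comment count (the x_min of the
#'   activity power law, default 1). Raising it produces a corpus of
#'   recurrent commenters, under which board-level cluster resampling is
#'   consistent for size-dependent statistics.
#' @param chambering Probability in `[0,1]` that a background user's comment
#'   targets a post of the user's own latent stance; the remaining mass is
#'   split evenly between the other two stances.
#' @param boo_rate,neutral_rate Probabilities of a comment carrying a boo or
#'   neutral mark (the rest are likes); their sum must be at most 1.
#' @param hardliner_fraction,spanner_fraction Fractions of users who comment
#'   only within their own stance (hardliners) or uniformly across stances
#'   (spanners); their sum must be at most 1.
#' @param stance_proportions Latent stance shares, normalized internally.
#' @param n_periods Number of monthly periods.
#' @param burst_periods Integer period indices with multiplied posting
#'   intensity.
#' @param burst_multiplier Posting-intensity multiplier for burst periods.
#' @param start Date of the first period (first of a month).
#' @param seed Integer root seed; every stochastic step derives a named
#'   stream from it, so a config fully determines a corpus.
#' @return A `forum_config` list.
#' @examples
#' cfg <- forum_config(n_users = 200, n_posts_per_layer = c(P = 20, H = 20, A = 8))
#' @export
forum_config <- function(n_users = 2000,
                         n_posts_per_layer = c(P = 257, H = 265, A = 78),
                         activity_exponent = 2.3,
                         activity_min = 1L,
                         chambering = 0.6,
                         boo_rate = 0.10,
                         neutral_rate = 0.25,
                         hardliner_fraction = 0.05,
                         spanner_fraction = 0.05,
                         stance_proportions = c(P = 1283, H = 1322, A = 387),
                         n_periods = 24,
                         burst_periods = c(11, 14),
                         burst_multiplier = 2,
                         start = "2021-01-01",
                         seed = 1L) {
  n_posts_per_layer <- as.integer(n_posts_per_layer)
  if (length(n_posts_per_layer) != 3L || any(n_posts_per_layer < 1L)) {
    stop("`n_posts_per_layer` must be three counts >= 1 (P, H, A)", call. = FALSE)
  }
  names(n_posts_per_layer) <- LAYERS
  if (n_users < 1L) stop("`n_users` must be positive", call. = FALSE)
  if (activity_exponent <= 1) stop("`activity_exponent` must be > 1", call. = FALSE)
  if (activity_min < 1L) stop("`activity_min` must be >= 1", call. = FALSE)
  probs <- c(chambering, boo_rate, neutral_rate, hardliner_fraction, spanner_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (boo_rate + neutral_rate > 1) {
    stop("`boo_rate` + `neutral_rate` must be <= 1", call. = FALSE)
  }
  if (hardliner_fraction + spanner_fraction > 1) {
    stop("`hardliner_fraction` + `spanner_fraction` must be <= 1", call. = FALSE)
  }
  if (n_periods < 1L) stop("`n_periods` must be positive", call. = FALSE)
  burst_periods <- as.integer(burst_periods)
  if (length(burst_periods) && any(burst_periods < 1L | burst_periods > n_periods)) {
    stop("`burst_periods` must be indices in 1..n_periods", call. = FALSE)
  }
  stance_proportions <- stance_proportions / sum(stance_proportions)
  names(stance_proportions) <- LAYERS
  structure(
    list(
      n_users = as.integer(n_users),
      n_posts_per_layer = n_posts_per_layer,
      activity_exponent = activity_exponent,
      activity_min = as.integer(activity_min),
      chambering = chambering,
      boo_rate = boo_rate,
      neutral_rate = neutral_rate,
      hardliner_fraction = hardliner_fraction,
      spanner_fraction = spanner_fraction,
      stance_proportions = stance_proportions,
      n_periods = as.integer(n_periods),
      burst_periods = burst_periods,
      burst_multiplier = burst_multiplier,
      start = start,
      seed = as.integer(seed)
    ),
    class = "forum_config"
  )
}

# Month boundaries of the configured periods: a POSIXct vector of length
# n_periods + 1.
period_boundaries <- function(config) {
  starts <- seq(
    as.POSIXct(paste(config$start, "00:00:00"), tz = TIME_TZ),
    by = "month", length.out = config$n_periods + 1L
  )
  starts
}

#' Generate the latent user population
#'
#' Draws each user's latent stance, commenting-activity weight (a discrete
#' power-law variate that becomes the user's comment count), and archetype:
#' hardliners comment only within their own stance, spanners uniformly across
#' stances, background users follow the chambering probability. Also
#' allocates each layer's posts over the monthly periods, with burst periods
#' receiving multiplied intensity.
#'
#' @param config A [forum_config()].
#' @return A `forum_truth` list with `users` (tibble: user, stance,
#'   archetype, activity) and `period_posts` (tibble: layer, period, n_posts).
#' @examples
#' truth <- generate_users(forum_config(n_users = 100))
#' table(truth$users$stance)
#' @export
generate_users <- function(config) {
  stopifnot(inherits(config, "forum_config"))
  local_seed_if(derive_seed(config$seed, "users"))
  n <- config$n_users
  user <- sprintf("u%05d", seq_len(n))
  stance <- sample(LAYERS, n, replace = TRUE, prob = config$stance_proportions)
  activity <- rpower_discrete(n, config$activity_exponent,
                              xmin = config$activity_min)
  archetype <- rep("background", n)
  n_hard <- round(config$hardliner_fraction * n)
  n_span <- round(config$spanner_fraction * n)
  special <- sample.int(n, n_hard + n_span)
  archetype[special[seq_len(n_hard)]] <- "hardliner"
  if (n_span > 0) archetype[special[n_hard + seq_len(n_span)]] <- "spanner"

  weights <- rep(1, config$n_periods)
  weights[config$burst_periods] <- config$burst_multiplier
  period_posts <- purrr::map_dfr(LAYERS, function(l) {
    counts <- as.vector(stats::rmultinom(1, config$n_posts_per_layer[[l]],
                                         prob = weights))
    tibble::tibble(layer = l, period = seq_len(config$n_periods), n_posts = counts)
  })

  structure(
    list(
      users = tibble::tibble(user = user, stance = stance,
                             archetype = archetype, activity = activity),
      period_posts = period_posts,
      config = config
    ),
    class = "forum_truth"
  )
}

# Pick the stance a single comment targets, given the commenter's latent
# stance and archetype.
target_stances <- function(stance, archetype, chambering) {
  n <- length(stance)
  out <- character(n)
  is_hard <- archetype == "hardliner"
  is_span <- archetype == "spanner"
  is_bg <- !is_hard & !is_span
  out[is_hard] <- stance[is_hard]
  if (any(is_span)) {
    out[is_span] <- sample(LAYERS, sum(is_span), replace = TRUE)
  }
  if (any(is_bg)) {
    own <- runif(sum(is_bg)) < chambering
    bg_stance <- stance[is_bg]
    res <- bg_stance
    if (any(!own)) {
      res[!own] <- vapply(bg_stance[!own], function(s) {
        sample(setdiff(LAYERS, s), 1L)
      }, character(1))
    }
    out[is_bg] <- res
  }
  out
}

#' Generate a stance-labeled synthetic corpus
#'
#' Materializes posts and comments from a [generate_users()] ground truth.
#' Post authors are drawn from the users of the post's stance, weighted by
#' activity; each user contributes exactly their activity weight in comments;
#' comment targets are chosen by preferential attachment to posts within the
#' selected stance (probability proportional to 1 + comments received so
#' far), which reproduces heavy-tailed indegrees. Timestamps are uniform
#' within the post's monthly period, and comments never precede their post.
#' Post titles carry the keyword \dQuote{疫苗} (vaccine) so synthetic
#' corpora pass the keyword filter unchanged.
#'
#' The output is byte-identical across calls with the same config.
#'
#' @param config A [forum_config()].
#' @param truth The matching [generate_users()] output.
#' @return A posts tibble: `board_id`, `author`, `time`, `title`, `label`,
#'   and a `comments` list-column of tibbles (`commenter`, `reaction`,
#'   `time`, `text`).
#' @examples
#' cfg <- forum_config(n_users = 100, n_posts_per_layer = c(P = 10, H = 10, A = 4))
#' posts <- generate_corpus(cfg, generate_users(cfg))
#' @export
generate_corpus <- function(config, truth) {
  stopifnot(inherits(config, "forum_config"), inherits(truth, "forum_truth"))
  if (!identical(truth$config, config)) {
    stop("`truth` was not generated from this `config`", call. = FALSE)
  }
  local_seed_if(derive_seed(config$seed, "corpus"))
  users <- truth$users
  bounds <- period_boundaries(config)

  # Posts: one row per board, authored within the post's stance.
  pp <- truth$period_posts[truth$period_posts$n_posts > 0, ]
  post_layer <- rep(pp$layer, pp$n_posts)
  post_period <- rep(pp$period, pp$n_posts)
  n_posts <- length(post_layer)
  post_author <- character(n_posts)
  for (l in LAYERS) {
    idx <- which(post_layer == l)
    pool <- users[users$stance == l, ]
    if (nrow(pool) == 0L) {
      stop("no users with stance ", l, "; increase `n_users`", call. = FALSE)
    }
    post_author[idx] <- sample(pool$user, length(idx), replace = TRUE,
                               prob = pool$activity)
  }
  p_start <- bounds[post_period]
  p_len <- as.numeric(bounds[post_period + 1L]) - as.numeric(p_start)
  # whole seconds: the thread-text dialect has second resolution
  post_time <- p_start + floor(runif(n_posts) * p_len)
  ord <- order(post_time)
  post_layer <- post_layer[ord]
  post_period <- post_period[ord]
  post_author <- post_author[ord]
  post_time <- post_time[ord]
  board_id <- sprintf("b%05d", seq_len(n_posts))

  # Comments: each user makes `activity` comments; stance per archetype,
  # post within stance by preferential attachment.
  commenter <- rep(users$user, users$activity)
  c_stance <- rep(users$stance, users$activity)
  c_arch <- rep(users$archetype, users$activity)
  perm <- sample.int(length(commenter))
  commenter <- commenter[perm]
  c_stance <- c_stance[perm]
  c_arch <- c_arch[perm]
  target <- target_stances(c_stance, c_arch, config$chambering)

  c_post <- integer(length(commenter))
  for (l in LAYERS) {
    cand <- which(post_layer == l)
    rows <- which(target == l)
    if (!length(rows)) next
    if (!length(cand)) {
      stop("no posts in layer ", l, " to receive comments", call. = FALSE)
    }
    w <- rep(1, length(cand))
    for (r in rows) {
      j <- sample.int(length(cand), 1L, prob = w)
      c_post[r] <- cand[j]
      w[j] <- w[j] + 1
    }
  }

  u <- runif(length(commenter))
  reaction <- ifelse(u < config$boo_rate, "boo",
                     ifelse(u < config$boo_rate + config$neutral_rate,
                            "neutral", "like"))
  t0 <- post_time[c_post]
  t_end <- bounds[post_period[c_post] + 1L]
  c_time <- t0 + floor(runif(length(commenter)) *
                         (as.numeric(t_end) - as.numeric(t0)))

  comment_tbl <- tibble::tibble(
    post = c_post, commenter = commenter, reaction = reaction,
    time = c_time, text = ""
  )
  comment_tbl <- comment_tbl[order(comment_tbl$post, comment_tbl$time), ]
  empty <- tibble::tibble(
    commenter = character(0), reaction = character(0),
    time = as.POSIXct(character(0), tz = TIME_TZ), text = character(0)
  )
  comments <- rep(list(empty), n_posts)
  if (nrow(comment_tbl)) {
    split_idx <- split(seq_len(nrow(comment_tbl)), comment_tbl$post)
    for (p in names(split_idx)) {
      comments[[as.integer(p)]] <-
        comment_tbl[split_idx[[p]], c("commenter", "reaction", "time", "text")]
    }
  }

  tibble::tibble(
    board_id = board_id,
    author = post_author,
    time = post_time,
    title = paste0("疫苗 thread ", board_id),
    label = post_layer,
    comments = comments
  )
}

#' Generate a full synthetic forum (users + corpus)
#'
#' @param config A [forum_config()].
#' @return List with `posts` (see [generate_corpus()]) and `truth` (see
#'   [generate_users()]).
#' @export
generate_forum <- function(config = forum_config()) {
  truth <- generate_users(config)
  list(posts = generate_corpus(config, truth), truth = truth)
}

#' Write the ground-truth user table as CSV
#'
#' @param truth A `forum_truth`.
#' @param path Output CSV path (columns user, stance, archetype, activity).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "forum_truth"))
  readr::write_csv(truth$users, path)
  invisible(path)
}

# Sanitize free text for the tab-delimited dialect.
sanitize_field <- function(x) gsub("[\t\r\n]+", " ", x)

# Wrap comment text into 39-character lines (the forum's line limit);
# continuation lines are re-joined by the parser.
wrap_comment_text <- function(text, width = 39L) {
  if (is.na(text) || !nchar(text)) {
    return("")
  }
  n <- nchar(text)
  starts <- seq(1L, n, by = width)
  substring(text, starts, pmin(starts + width - 1L, n))
}

#' Serialize posts in the thread-text dialect
#'
#' Writes one record per board to a single UTF-8 text file. Each record is a
#' header block followed by one line per comment:
#' \preformatted{==== <board_id>
#' author<TAB><author>
#' time<TAB><YYYY-MM-DD HH:MM:SS>
#' title<TAB><title>
#' label<TAB><P|H|A|neutral|irrelevant|unlabeled>
#' ----
#' <MARK><TAB><commenter><TAB><time><TAB><text, first 39 characters>
#' <TAB><continuation of text, 39 characters per line>}
#' Reaction marks are \dQuote{推} (like), \dQuote{噓} (boo) and
#' \dQuote{→} (neutral). Comment text is wrapped at 39 characters per
#' line, mirroring the forum's line limit; [parse_threads()] re-joins the
#' continuation lines, making `parse(emit(x))` the identity.
#'
#' @param posts Posts tibble (see [generate_corpus()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
emit_threads <- function(posts, path) {
  assert_posts(posts)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  lines <- character(0)
  for (i in seq_len(nrow(posts))) {
    cm <- posts$comments[[i]]
    rec <- c(
      paste0("==== ", posts$board_id[i]),
      paste0("author\t", sanitize_field(posts$author[i])),
      paste0("time\t", format_time(posts$time[i])),
      paste0("title\t", sanitize_field(posts$title[i])),
      paste0("label\t", posts$label[i]),
      "----"
    )
    if (nrow(cm)) {
      for (j in seq_len(nrow(cm))) {
        chunks <- wrap_comment_text(sanitize_field(cm$text[j]))
        rec <- c(rec,
                 paste0(REACTION_TO_MARK[[cm$reaction[j]]], "\t",
                        sanitize_field(cm$commenter[j]), "\t",
                        format_time(cm$time[j]), "\t", chunks[1]))
        if (length(chunks) > 1L) {
          rec <- c(rec, paste0("\t", chunks[-1]))
        }
      }
    }
    lines <- c(lines, rec)
  }
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
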