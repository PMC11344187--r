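# Brute-force oracles: every metric recomputed by direct enumeration of
# neighbor sets from the raw edge records, independent of the package's
# aggregation path.

LAYERS3 <- c("P", "H", "A")

bf_neighbors <- function(records, node, layer, direction) {
  r <- records[records$layer == layer, ]
  if (direction == "in") {
    unique(r$source[r$target == node])
  } else {
    unique(r$target[r$source == node])
  }
}

bf_layer_degree <- function(records, node, layer, direction) {
  length(bf_neighbors(records, node, layer, direction))
}

bf_cross_degree <- function(records, node, direction) {
  length(unique(unlist(lapply(LAYERS3, function(l) {
    bf_neighbors(records, node, l, direction)
  }))))
}

bf_layer_nodes <- function(records, layer) {
  r <- records[records$layer == layer, ]
  unique(c(r$source, r$target))
}

bf_layer_diversity <- function(records, layer, direction) {
  v <- bf_layer_nodes(records, layer)
  if (!length(v)) return(NA_real_)
  mean(vapply(v, bf_cross_degree, numeric(1), records = records,
              direction = direction))
}

# rank-then-Pearson Spearman, written from scratch
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (stats::sd(rx) * stats::sd(ry)) *
    length(rx) / (length(rx) - 1)
}

bf_entropy <- function(records, node) {
  counts <- vapply(LAYERS3, function(l) {
    bf_layer_degree(records, node, l, "in") +
      bf_layer_degree(records, node, l, "out")
  }, numeric(1))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts / tot
  -sum(ifelse(p > 0, p * log(p), 0))
}

# Random toy multilayer: <= 12 nodes, random parallel records.
random_toy_records <- function(seed, n_nodes = NULL, n_records = NULL) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(3:12, 1)
  if (is.null(n_records)) n_records <- sample(5:40, 1)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(nodes, n_records, replace = TRUE)
  tgt <- sample(nodes, n_records, replace = TRUE)
  keep <- src != tgt
  tibble::tibble(
    source = src[keep],
    target = tgt[keep],
    layer = sample(LAYERS3, sum(keep), replace = TRUE),
    weight = sample(c(2, 1, 0.2), sum(keep), replace = TRUE),
    reaction = sample(c("like", "boo", "neutral"), sum(keep), replace = TRUE),
    time = as.POSIXct("2021-01-01", tz = "UTC") +
      sample.int(86400 * 700, sum(keep)),
    board_id = sprintf("b%02d", sample.int(8, sum(keep), replace = TRUE))
  )
}

# Hand-built posts: one board with an author and a comments data frame.
make_post <- function(board_id, author, label, time = "2021-03-01 10:00:00",
                      title = "疫苗 test", comments = NULL) {
  if (is.null(comments)) {
    comments <- tibble::tibble(
      commenter = character(0), reaction = character(0),
      time = as.POSIXct(character(0), tz = "UTC"), text = character(0)
    )
  }
  tibble::tibble(
    board_id = board_id, author = author,
    time = as.POSIXct(time, tz = "UTC"),
    title = title, label = label, comments = list(comments)
  )
}

make_comments <- function(commenter, reaction = "like",
                          time = "2021-03-01 11:00:00", text = "") {
  n <- length(commenter)
  tibble::tibble(
    commenter = commenter,
    reaction = rep_len(reaction, n),
    time = rep_len(as.POSIXct(time, tz = "UTC"), n),
    text = rep_len(text, n)
  )
}

small_forum <- function(seed = 1, n_users = 60,
                        posts = c(P = 6, H = 6, A = 3), ...) {
  cfg <- forum_config(n_users = n_users, n_posts_per_layer = posts,
                      seed = seed, ...)
  generate_forum(cfg)
}

expect_posts_equal <- function(a, b) {
  attr(a, "skipped") <- NULL
  attr(b, "skipped") <- NULL
  expect_equal(as.data.frame(a[, setdiff(names(a), "comments")]),
               as.data.frame(b[, setdiff(names(b), "comments")]),
               ignore_attr = TRUE)
  for (i in seq_len(nrow(a))) {
    expect_equal(as.data.frame(a$comments[[i]]), as.data.frame(b$comments[[i]]),
                 ignore_attr = TRUE)
  }
}
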