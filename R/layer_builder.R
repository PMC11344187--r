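#' Assign a comment to a stance layer and weight
#'
#' Implements the flattening rule for a single comment on a labeled post:
#' likes and neutral comments join the post's own layer (weights 2 and 1);
#' boos (weight 0.2) are reassigned to the opposing camp. A boo on a
#' provaccination post goes to the antivaccination layer; a boo on an
#' antivaccination post is ambiguous (hesitant or provaccination) and is
#' assigned uniformly at random between P and H; symmetrically, a boo on a
#' hesitant post is assigned uniformly between P and A. Randomness comes
#' from the caller's RNG stream, so [flatten()] is deterministic given its
#' seed.
#'
#' @param post_label Vector of post labels, each one of `"P"`, `"H"`, `"A"`.
#' @param reaction Vector of `"like"`, `"boo"`, `"neutral"` (recycled
#'   against `post_label`).
#' @return Tibble with columns `layer` and `weight`, one row per comment.
#' @examples
#' assign_comment("P", "like")   # P, weight 2
#' assign_comment("P", "boo")    # A, weight 0.2
#' @export
assign_comment <- function(post_label, reaction) {
  n <- max(length(post_label), length(reaction))
  post_label <- rep_len(post_label, n)
  reaction <- rep_len(reaction, n)
  if (!all(post_label %in% LAYERS)) {
    stop("post labels must be P/H/A; exclude neutral/irrelevant boards first",
         call. = FALSE)
  }
  if (!all(reaction %in% REACTIONS)) {
    stop("unknown reaction type", call. = FALSE)
  }
  weight <- c(like = 2, neutral = 1, boo = 0.2)[reaction]
  layer <- post_label
  boo <- which(reaction == "boo")
  for (i in boo) {
    layer[i] <- switch(post_label[i],
      P = "A",
      A = sample(c("P", "H"), 1L),
      H = sample(c("P", "A"), 1L)
    )
  }
  tibble::tibble(layer = layer, weight = unname(weight))
}

#' Flatten labeled posts into directed edge records
#'
#' Produces one record per comment, directed commenter -> author (so an
#' author's indegree counts attention received), with the layer and weight
#' from [assign_comment()]. Self-comments (author commenting on their own
#' post) are excluded by default.
#'
#' @param posts Labeled posts tibble (all labels in P/H/A).
#' @param seed Integer seed for the boo-reassignment stream.
#' @param include_self Keep self-comments as self-loops? Default `FALSE`.
#' @return Tibble of edge records: `source`, `target`, `layer`, `weight`,
#'   `reaction`, `time`, `board_id`.
#' @examples
#' cfg <- forum_config(n_users = 50, n_posts_per_layer = c(P = 5, H = 5, A = 2))
#' records <- flatten(generate_forum(cfg)$posts, seed = 1)
#' @export
flatten <- function(posts, seed = 1L, include_self = FALSE) {
  assert_posts(posts)
  if (!all(posts$label %in% LAYERS)) {
    stop("all posts must be labeled P/H/A before flattening", call. = FALSE)
  }
  n_com <- vapply(posts$comments, nrow, integer(1))
  keep <- n_com > 0L
  if (!any(keep)) {
    return(empty_records())
  }
  cm <- dplyr::bind_rows(posts$comments[keep])
  rec <- tibble::tibble(
    source = cm$commenter,
    target = rep(posts$author[keep], n_com[keep]),
    post_label = rep(posts$label[keep], n_com[keep]),
    reaction = cm$reaction,
    time = cm$time,
    board_id = rep(posts$board_id[keep], n_com[keep])
  )
  if (!include_self) {
    rec <- rec[rec$source != rec$target, ]
  }
  local_seed_if(derive_seed(seed, "boo"))
  lw <- assign_comment(rec$post_label, rec$reaction)
  rec$layer <- lw$layer
  rec$weight <- lw$weight
  rec[, c("source", "target", "layer", "weight", "reaction", "time", "board_id")]
}

empty_records <- function() {
  tibble::tibble(
    source = character(0), target = character(0), layer = character(0),
    weight = numeric(0), reaction = character(0),
    time = as.POSIXct(character(0), tz = TIME_TZ), board_id = character(0)
  )
}

#' Aggregate edge records into the three-layer network
#'
#' Within each layer, parallel records with the same (source, target) pair
#' collapse into one directed edge carrying the summed weight, the comment
#' count, and the first/last comment time. Each layer's node set is exactly
#' the set of endpoints of its edges; the graphs are directed and
#' nonmirrored, so (u, v) and (v, u) are distinct edges.
#'
#' @param records Edge-record tibble from [flatten()] (may be empty).
#' @return A `multilayer_network`: list with `edges` (aggregated tibble),
#'   `n_records` (comment counts per layer), and `window` (time range).
#' @export
build_multilayer <- function(records) {
  dt <- data.table::as.data.table(records[, c("source", "target", "layer",
                                              "weight", "time")])
  if (nrow(dt)) {
    agg <- dt[, list(
      weight = sum(weight), count = .N,
      first_time = min(time), last_time = max(time)
    ), by = c("layer", "source", "target")]
    data.table::setorder(agg, layer, source, target)
  } else {
    agg <- data.table::data.table(
      layer = character(0), source = character(0), target = character(0),
      weight = numeric(0), count = integer(0),
      first_time = as.POSIXct(character(0), tz = TIME_TZ),
      last_time = as.POSIXct(character(0), tz = TIME_TZ)
    )
  }
  n_rec <- setNames(integer(length(LAYERS)), LAYERS)
  if (nrow(dt)) {
    tb <- table(dt$layer)
    n_rec[names(tb)] <- as.integer(tb)
  }
  structure(
    list(
      edges = tibble::as_tibble(agg),
      n_records = n_rec,
      window = if (nrow(dt)) range(dt$time) else
        as.POSIXct(character(0), tz = TIME_TZ)
    ),
    class = "multilayer_network"
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("Multilayer stance network (P/H/A)\n")
  for (l in LAYERS) {
    e <- x$edges[x$edges$layer == l, ]
    cat(sprintf("  %s: %d nodes, %d edges, %d comments\n",
                l, length(layer_nodes(x, l)), nrow(e), x$n_records[[l]]))
  }
  invisible(x)
}

#' Node set of one layer
#'
#' @param M A `multilayer_network`.
#' @param layer `"P"`, `"H"` or `"A"`.
#' @return Character vector of node ids (endpoints of the layer's edges).
#' @export
layer_nodes <- function(M, layer) {
  e <- M$edges[M$edges$layer == layer, ]
  unique(c(e$source, e$target))
}

#' Convert one layer to an igraph graph
#'
#' @param M A `multilayer_network`.
#' @param layer `"P"`, `"H"` or `"A"`.
#' @return A directed `igraph` graph with `weight` and `count` edge
#'   attributes.
#' @export
as_layer_igraph <- function(M, layer) {
  e <- M$edges[M$edges$layer == layer, ]
  igraph::graph_from_data_frame(
    e[, c("source", "target", "weight", "count")],
    directed = TRUE
  )
}

#' Cumulative temporal snapshots
#'
#' Builds the multilayer network restricted to records with `time <= t` for
#' each requested time point. Snapshots are cumulative: nodes and edges only
#' accumulate, and the snapshot at (or after) the last record time equals
#' the static network.
#'
#' @param records Edge-record tibble.
#' @param time_points Sorted ascending POSIXct vector.
#' @return List of `multilayer_network` objects, named by time point.
#' @export
snapshots <- function(records, time_points) {
  if (is.unsorted(time_points)) {
    stop("`time_points` must be sorted ascending", call. = FALSE)
  }
  out <- lapply(time_points, function(t) {
    build_multilayer(records[records$time <= t, ])
  })
  names(out) <- format_time(time_points)
  out
}

#' Write / read edge records as CSV
#'
#' Times are serialized in ISO-8601 (`YYYY-MM-DD HH:MM:SS`).
#'
#' @param records Edge-record tibble.
#' @param path CSV path.
#' @return `path` (write) or the records tibble (read).
#' @export
write_edge_records <- function(records, path) {
  out <- records
  out$time <- format_time(out$time)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_edge_records
#' @export
read_edge_records <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    layer = readr::col_character(), weight = readr::col_double(),
    reaction = readr::col_character(), time = readr::col_character(),
    .default = readr::col_character()
  ))
  tbl$time <- parse_time(tbl$time)
  tbl
}
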