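# Node-, layer- and network-level chambering statistics.
#
# All degree metrics are unweighted distinct-neighbor counts (the |N|
# semantics of in/outdegree): because build_multilayer() collapses parallel
# comments, an aggregated edge (u, v) contributes exactly one neighbor.

# Per-layer connection counts of every node as a nodes x layers matrix.
# basis "neighbors": distinct in-neighbors + distinct out-neighbors per layer.
# basis "comments":  raw comment multiplicities (aggregated `count`).
connection_matrix <- function(M, basis = c("neighbors", "comments")) {
  basis <- match.arg(basis)
  e <- M$edges
  nodes <- sort(unique(c(e$source, e$target)))
  mat <- matrix(0, nrow = length(nodes), ncol = length(LAYERS),
                dimnames = list(nodes, LAYERS))
  for (l in LAYERS) {
    el <- e[e$layer == l, ]
    if (!nrow(el)) next
    w <- if (basis == "comments") el$count else rep(1L, nrow(el))
    tin <- tapply(w, el$target, sum)
    tout <- tapply(w, el$source, sum)
    mat[names(tin), l] <- mat[names(tin), l] + as.numeric(tin)
    mat[names(tout), l] <- mat[names(tout), l] + as.numeric(tout)
  }
  mat
}

#' Within-layer degree
#'
#' Number of distinct in- or out-neighbors of each node in one layer; 0 for
#' nodes absent from the layer.
#'
#' @param M A `multilayer_network`.
#' @param layer `"P"`, `"H"` or `"A"`.
#' @param direction `"in"` (attention received) or `"out"` (comments given).
#' @param nodes Optional node ids to evaluate; default: the layer's nodes.
#' @return Named integer vector.
#' @examples
#' # degrees of every node of the hesitant layer:
#' # layer_degree(M, "H", "in")
#' @export
layer_degree <- function(M, layer, direction = c("in", "out"), nodes = NULL) {
  direction <- match.arg(direction)
  stopifnot(layer %in% LAYERS)
  e <- M$edges[M$edges$layer == layer, ]
  key <- if (direction == "in") e$target else e$source
  tab <- table(key)
  if (is.null(nodes)) nodes <- layer_nodes(M, layer)
  out <- setNames(integer(length(nodes)), nodes)
  hit <- intersect(nodes, names(tab))
  out[hit] <- as.integer(tab[hit])
  out
}

#' Cross-layer degree (diversity)
#'
#' Number of unique in- or out-neighbors of each node across the whole
#' multilayer network: the size of the union of the per-layer neighbor sets,
#' so a neighbor met in two layers counts once.
#'
#' @inheritParams layer_degree
#' @param nodes Optional node ids; default: all nodes of the network.
#' @return Named integer vector.
#' @export
cross_degree <- function(M, direction = c("in", "out"), nodes = NULL) {
  direction <- match.arg(direction)
  pairs <- unique(M$edges[, c("source", "target")])
  key <- if (direction == "in") pairs$target else pairs$source
  tab <- table(key)
  if (is.null(nodes)) nodes <- sort(unique(c(M$edges$source, M$edges$target)))
  out <- setNames(integer(length(nodes)), nodes)
  hit <- intersect(nodes, names(tab))
  out[hit] <- as.integer(tab[hit])
  out
}

#' Layer-level degree diversity
#'
#' Mean cross-layer degree ([cross_degree()]) over the nodes of one layer:
#' how broadly, on average, the layer's members receive from (`"in"`) or
#' reach into (`"out"`) the whole network.
#'
#' @inheritParams layer_degree
#' @return Numeric; `NA` (with a message) for an empty layer.
#' @export
layer_diversity <- function(M, layer, direction = c("in", "out")) {
  direction <- match.arg(direction)
  v <- layer_nodes(M, layer)
  if (!length(v)) {
    return(undefined_value(paste0("layer_diversity(", layer, ", ", direction,
                                  "): empty layer")))
  }
  mean(cross_degree(M, direction, nodes = v))
}

#' Spearman rank correlation of degrees between two layers
#'
#' Ranks the common nodes of two layers by their within-layer degree and
#' correlates the ranks (average ranks for ties). High values mean the same
#' users dominate both layers; low values across stance pairs indicate
#' polarization.
#'
#' @inheritParams layer_degree
#' @param layer_a,layer_b The two layers.
#' @return Correlation in `[-1, 1]`; `NA` (with a message) when fewer than
#'   two common nodes exist or a degree vector has zero variance.
#' @export
spearman_pair <- function(M, layer_a, layer_b, direction = c("in", "out")) {
  direction <- match.arg(direction)
  common <- intersect(layer_nodes(M, layer_a), layer_nodes(M, layer_b))
  if (length(common) < 2L) {
    return(undefined_value(paste0("spearman_pair(", layer_a, ",", layer_b,
                                  "): <2 common nodes")))
  }
  da <- layer_degree(M, layer_a, direction, nodes = common)
  db <- layer_degree(M, layer_b, direction, nodes = common)
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    return(undefined_value(paste0("spearman_pair(", layer_a, ",", layer_b,
                                  "): zero-variance degrees")))
  }
  unname(cor(da, db, method = "spearman"))
}

#' Percentage of overlapping nodes between two layers
#'
#' Defaults to the Jaccard form `100 * |A n B| / |A u B|`; the denominator
#' is configurable (`"min"`: the smaller layer; `"a"`/`"b"`: one layer).
#'
#' @inheritParams spearman_pair
#' @param denominator Denominator convention.
#' @return Percentage in `[0, 100]`; `NA` (with a message) when both layers
#'   are empty.
#' @export
layer_overlap <- function(M, layer_a, layer_b,
                          denominator = c("union", "min", "a", "b")) {
  denominator <- match.arg(denominator)
  va <- layer_nodes(M, layer_a)
  vb <- layer_nodes(M, layer_b)
  if (!length(va) && !length(vb)) {
    return(undefined_value(paste0("layer_overlap(", layer_a, ",", layer_b,
                                  "): both layers empty")))
  }
  den <- switch(denominator,
    union = length(union(va, vb)),
    min = min(length(va), length(vb)),
    a = length(va),
    b = length(vb)
  )
  if (den == 0L) {
    return(undefined_value(paste0("layer_overlap(", layer_a, ",", layer_b,
                                  "): empty denominator")))
  }
  100 * length(intersect(va, vb)) / den
}

#' Shannon participation entropy of nodes
#'
#' For each node, `p(l)` is the share of the node's connections (in plus
#' out) that fall in layer `l`; the entropy `H = -sum p(l) * log(p(l))`
#' (natural log, 0-probability terms contribute 0) measures how evenly the
#' node participates across the three stance layers: 0 for single-layer
#' nodes, `log(3)` for perfectly even participation.
#'
#' @param M A `multilayer_network`.
#' @param nodes Optional node ids; default: all nodes.
#' @param basis Count connections as distinct `"neighbors"` (default) or raw
#'   `"comments"`.
#' @return Named numeric vector; `NA` (with a message) for isolated nodes.
#' @export
node_entropy <- function(M, nodes = NULL, basis = c("neighbors", "comments")) {
  basis <- match.arg(basis)
  mat <- connection_matrix(M, basis)
  if (is.null(nodes)) nodes <- rownames(mat)
  out <- setNames(rep(NA_real_, length(nodes)), nodes)
  known <- intersect(nodes, rownames(mat))
  m <- mat[known, , drop = FALSE]
  tot <- rowSums(m)
  ok <- tot > 0
  if (any(ok)) {
    p <- m[ok, , drop = FALSE] / tot[ok]
    plogp <- ifelse(p > 0, p * log(p), 0)
    out[rownames(p)] <- -rowSums(plogp)
  }
  if (anyNA(out)) {
    message("undefined statistic: node_entropy for ", sum(is.na(out)),
            " isolated/unknown node(s) (NA)")
  }
  out
}

#' Select hardliners of a layer
#'
#' Among the layer's nodes with at least `min_activity` total connections
#' (all layers, both directions), returns the `k` lowest-entropy nodes —
#' users whose engagement is concentrated in a single stance. Ties are
#' broken by higher within-layer total degree, then by node id; fewer than
#' `k` rows are returned when the candidate pool is smaller.
#'
#' @inheritParams layer_degree
#' @param k Number of hardliners (default 30).
#' @param min_activity Minimum total connections to qualify (default 10);
#'   without a floor, every one-comment user ties at entropy 0.
#' @param basis Connection-count basis, see [node_entropy()].
#' @return Tibble: `node`, `entropy`, `total_connections`, `within_degree`,
#'   ordered by selection rank.
#' @export
select_hardliners <- function(M, layer, k = 30, min_activity = 10,
                              basis = c("neighbors", "comments")) {
  basis <- match.arg(basis)
  stopifnot(layer %in% LAYERS)
  v <- layer_nodes(M, layer)
  if (!length(v)) {
    return(tibble::tibble(node = character(0), entropy = numeric(0),
                          total_connections = numeric(0),
                          within_degree = numeric(0)))
  }
  mat <- connection_matrix(M, basis)
  tot <- rowSums(mat)[v]
  cand <- v[tot >= min_activity]
  if (!length(cand)) {
    message("select_hardliners: no candidates with >= ", min_activity,
            " connections in layer ", layer)
    return(tibble::tibble(node = character(0), entropy = numeric(0),
                          total_connections = numeric(0),
                          within_degree = numeric(0)))
  }
  ent <- node_entropy(M, nodes = cand, basis = basis)
  within <- layer_degree(M, layer, "in", nodes = cand) +
    layer_degree(M, layer, "out", nodes = cand)
  ord <- order(ent, -within, cand)
  sel <- head(ord, k)
  tibble::tibble(
    node = cand[sel],
    entropy = unname(ent[sel]),
    total_connections = unname(rowSums(mat)[cand[sel]]),
    within_degree = unname(within[sel])
  )
}

#' Select the most diverse (highly connected, cross-cutting) nodes
#'
#' Ranks nodes by total cross-layer degree (`cross_degree` in + out); ties
#' are broken by higher entropy (more even cross-layer participation), then
#' node id.
#'
#' @param M A `multilayer_network`.
#' @param k Number of nodes (default 50).
#' @return Tibble: `node`, `cross_in`, `cross_out`, `score`, `entropy`.
#' @export
select_diverse <- function(M, k = 50) {
  nodes <- sort(unique(c(M$edges$source, M$edges$target)))
  if (!length(nodes)) {
    return(tibble::tibble(node = character(0), cross_in = integer(0),
                          cross_out = integer(0), score = integer(0),
                          entropy = numeric(0)))
  }
  cin <- cross_degree(M, "in", nodes = nodes)
  cout <- cross_degree(M, "out", nodes = nodes)
  ent <- node_entropy(M, nodes = nodes)
  score <- cin + cout
  ord <- order(-score, -ent, nodes)
  sel <- head(ord, k)
  tibble::tibble(
    node = nodes[sel],
    cross_in = unname(cin[sel]),
    cross_out = unname(cout[sel]),
    score = unname(score[sel]),
    entropy = unname(ent[sel])
  )
}

#' Per-layer connection proportions of a node set
#'
#' For the given nodes, sums within-layer degree in the requested direction
#' per layer and normalizes to percentages (summing to 100). Used to
#' describe where the top diverse nodes receive and give comments.
#'
#' @inheritParams layer_degree
#' @param nodes Node ids.
#' @return Named numeric vector `c(P=, H=, A=)`; all-`NA` (with a message)
#'   when the nodes have no connections in that direction.
#' @export
layer_proportions <- function(M, nodes, direction = c("in", "out")) {
  direction <- match.arg(direction)
  sums <- vapply(LAYERS, function(l) {
    sum(layer_degree(M, l, direction, nodes = nodes))
  }, numeric(1))
  tot <- sum(sums)
  if (tot == 0) {
    undefined_value(paste0("layer_proportions(", direction, "): zero total"))
    return(setNames(rep(NA_real_, 3), LAYERS))
  }
  100 * sums / tot
}

#' Standardized within-layer degrees of a layer's hardliners
#'
#' Mean, over the layer's hardliners, of the within-layer degree divided by
#' the layer's mean degree in the same direction. A value above 1 means
#' hardliners are more active inside their layer than the average member.
#'
#' @inheritParams select_hardliners
#' @param hardliners Optional precomputed [select_hardliners()] result.
#' @return Tibble: `direction`, `mean_standardized`, `n_hardliners`.
#' @export
hardliner_degrees <- function(M, layer, k = 30, min_activity = 10,
                              hardliners = NULL) {
  if (is.null(hardliners)) {
    hardliners <- select_hardliners(M, layer, k = k, min_activity = min_activity)
  }
  if (!nrow(hardliners)) {
    undefined_value(paste0("hardliner_degrees(", layer, "): empty hardliner set"))
    return(tibble::tibble(direction = c("out", "in"),
                          mean_standardized = NA_real_,
                          n_hardliners = 0L))
  }
  v <- layer_nodes(M, layer)
  purrr::map_dfr(c("out", "in"), function(dir) {
    layer_mean <- mean(layer_degree(M, layer, dir, nodes = v))
    std <- if (layer_mean > 0) {
      mean(layer_degree(M, layer, dir, nodes = hardliners$node) / layer_mean)
    } else {
      undefined_value(paste0("hardliner_degrees(", layer, ", ", dir,
                             "): zero layer mean"))
    }
    tibble::tibble(direction = dir, mean_standardized = std,
                   n_hardliners = nrow(hardliners))
  })
}

#' Mean total degree per layer
#'
#' `2 * comments / nodes` per layer, the average-degree convention where
#' every comment is one directed edge contributing a stub at each endpoint.
#'
#' @param M A `multilayer_network`.
#' @return Named numeric vector `c(P=, H=, A=)` (`NA` for empty layers).
#' @export
mean_layer_degree <- function(M) {
  vapply(LAYERS, function(l) {
    n <- length(layer_nodes(M, l))
    if (n == 0L) NA_real_ else average_degree(n, M$n_records[[l]])
  }, numeric(1))
}

#' Evaluate a metric on cumulative snapshots
#'
#' Applies `metric` (a function of a `multilayer_network`, returning a
#' scalar or named vector) to the cumulative snapshot at every time point.
#' Undefined values surface as `NA` gaps; the final element equals the
#' static-network value once the last time point covers all records.
#'
#' @param records Edge-record tibble.
#' @param time_points Sorted ascending POSIXct vector.
#' @param metric Function of one `multilayer_network`.
#' @param ... Passed on to `metric`.
#' @return Tibble: `time`, `statistic`, `value`.
#' @export
metric_series <- function(records, time_points, metric, ...) {
  snaps <- snapshots(records, time_points)
  purrr::map_dfr(seq_along(snaps), function(i) {
    val <- metric(snaps[[i]], ...)
    nm <- names(val)
    if (is.null(nm)) nm <- rep("value", length(val))
    tibble::tibble(time = time_points[i], statistic = nm,
                   value = as.numeric(val))
  })
}
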