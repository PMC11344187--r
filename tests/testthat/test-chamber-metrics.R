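test_that("within-layer degree counts distinct neighbors", {
  star <- make_post("b1", "hub", "P",
                    comments = make_comments(paste0("u", 1:5)))
  M <- build_multilayer(flatten(star, seed = 1))
  expect_equal(unname(layer_degree(M, "P", "in", nodes = "hub")), 5)
  expect_equal(unname(layer_degree(M, "P", "out", nodes = "hub")), 0)
  # isolated / unknown node: 0 in every layer and direction
  expect_equal(unname(layer_degree(M, "H", "in", nodes = "ghost")), 0)
  # aggregated repeat comments count the neighbor once
  twice <- make_post("b2", "v", "H", comments = make_comments(c("u", "u")))
  M2 <- build_multilayer(flatten(twice, seed = 1))
  expect_equal(unname(layer_degree(M2, "H", "in", nodes = "v")), 1)
})

test_that("cross-layer degree is the union of per-layer neighbor sets", {
  rec <- tibble::tibble(
    source = c("u", "u", "a", "b", "c", "d", "e", "f"),
    target = c("v", "v", "v", "v", "v", "v", "v", "v"),
    layer = c("P", "H", "P", "P", "H", "H", "H", "A"),
    weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  M <- build_multilayer(rec)
  # u met in both P and H counts once; a,b | c,d,e | f are disjoint
  expect_equal(unname(cross_degree(M, "in", nodes = "v")), 7)
  rec2 <- rec[rec$source != "u", ]
  M2 <- build_multilayer(rec2)
  expect_equal(unname(cross_degree(M2, "in", nodes = "v")), 6)
})

test_that("all metrics match brute-force enumeration on random toy multilayers", {
  for (seed in 1:30) {
    rec <- random_toy_records(seed)
    M <- build_multilayer(rec)
    nodes <- sort(unique(c(rec$source, rec$target)))
    for (dir in c("in", "out")) {
      for (l in LAYERS3) {
        got <- layer_degree(M, l, dir, nodes = nodes)
        want <- vapply(nodes, bf_layer_degree, numeric(1), records = rec,
                       layer = l, direction = dir)
        expect_equal(unname(got), unname(want))
        expect_equal(suppressMessages(layer_diversity(M, l, dir)),
                     bf_layer_diversity(rec, l, dir))
      }
      got_cross <- cross_degree(M, dir, nodes = nodes)
      want_cross <- vapply(nodes, bf_cross_degree, numeric(1), records = rec,
                           direction = dir)
      expect_equal(unname(got_cross), unname(want_cross))
    }
    ent <- node_entropy(M, nodes = nodes)
    want_ent <- vapply(nodes, bf_entropy, numeric(1), records = rec)
    expect_equal(unname(ent), unname(want_ent))
    # pairwise spearman vs from-scratch rank-then-Pearson
    for (pair in list(c("P", "H"), c("P", "A"), c("H", "A"))) {
      common <- intersect(bf_layer_nodes(rec, pair[1]),
                          bf_layer_nodes(rec, pair[2]))
      for (dir in c("in", "out")) {
        got <- suppressMessages(spearman_pair(M, pair[1], pair[2], dir))
        if (length(common) < 2) {
          expect_true(is.na(got))
        } else {
          x <- vapply(common, bf_layer_degree, numeric(1), records = rec,
                      layer = pair[1], direction = dir)
          y <- vapply(common, bf_layer_degree, numeric(1), records = rec,
                      layer = pair[2], direction = dir)
          expect_equal(got, bf_spearman(x, y))
        }
      }
      got_ov <- suppressMessages(layer_overlap(M, pair[1], pair[2]))
      va <- bf_layer_nodes(rec, pair[1]); vb <- bf_layer_nodes(rec, pair[2])
      expect_equal(got_ov, 100 * length(intersect(va, vb)) / length(union(va, vb)))
    }
  }
})

test_that("entropy hits its closed-form values", {
  one_layer <- make_post("b1", "v", "P", comments = make_comments(c("a", "b")))
  M1 <- build_multilayer(flatten(one_layer, seed = 1))
  expect_equal(unname(node_entropy(M1, nodes = "v")), 0)

  # v receives from 2 distinct users in each layer: p = (1/3, 1/3, 1/3)
  rec <- tibble::tibble(
    source = c("a", "b", "c", "d", "e", "f"),
    target = "v",
    layer = rep(c("P", "H", "A"), each = 2),
    weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  expect_equal(unname(node_entropy(build_multilayer(rec), nodes = "v")), log(3))

  # p = (0.5, 0.25, 0.25) -> 1.5 * log(2)
  rec2 <- tibble::tibble(
    source = c("a", "b", "c", "d"),
    target = "v",
    layer = c("P", "P", "H", "A"),
    weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  expect_equal(unname(node_entropy(build_multilayer(rec2), nodes = "v")),
               1.5 * log(2))
  # isolated node: NA sentinel with a message
  expect_message(out <- node_entropy(build_multilayer(rec2), nodes = "ghost"),
                 "undefined")
  expect_true(is.na(out))
})

test_that("spearman endpoints and a hand-computed toy", {
  rec <- tibble::tibble(
    source = c(paste0("x", 1:3), paste0("y", 1:2), "z1"),
    target = rep(c("a", "b", "c"), times = c(3, 2, 1)),
    layer = "P", weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  # mirror the same structure in H -> identical degree vectors: rho = 1
  rec_h <- rec; rec_h$layer <- "H"
  M_same <- build_multilayer(rbind(rec, rec_h))
  expect_equal(spearman_pair(M_same, "P", "H", "in"), 1)
  # reverse the degree ranking in H: a gets 1, b gets 2, c gets 3
  # (fresh commenter ids so only a, b, c are common to both layers)
  rec_rev <- tibble::tibble(
    source = c("q1", "q2", "q3", "q4", "q5", "q6"),
    target = rep(c("a", "b", "c"), times = c(1, 2, 3)),
    layer = "H", weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  M_rev <- build_multilayer(rbind(rec, rec_rev))
  expect_equal(spearman_pair(M_rev, "P", "H", "in"), -1)
  # degree vectors (3,1,2) vs (2,1,3): rank-then-Pearson gives 0.5
  rec_toy <- tibble::tibble(
    source = c("r1", "r2", "r3", "r4", "r5", "r6"),
    target = c("a", "a", "b", "c", "c", "c"),
    layer = "H", weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  # P degrees: a=3, b=2, c=1; H degrees: a=2, b=1, c=3
  rec_p <- tibble::tibble(
    source = c("s1", "s2", "s3", "s4", "s5", "s6"),
    target = rep(c("a", "b", "c"), times = c(3, 2, 1)),
    layer = "P", weight = 2, reaction = "like",
    time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b1"
  )
  M_toy <- build_multilayer(rbind(rec_p, rec_toy))
  expect_equal(spearman_pair(M_toy, "P", "H", "in"),
               bf_spearman(c(3, 2, 1), c(2, 1, 3)))
})

test_that("overlap percentages for identical, disjoint and partial node sets", {
  mk <- function(sources, targets, layer) {
    tibble::tibble(source = sources, target = targets, layer = layer,
                   weight = 2, reaction = "like",
                   time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b")
  }
  M_same <- build_multilayer(rbind(mk("a", "b", "P"), mk("a", "b", "H")))
  expect_equal(layer_overlap(M_same, "P", "H"), 100)
  M_disj <- build_multilayer(rbind(mk("a", "b", "P"), mk("c", "d", "H")))
  expect_equal(layer_overlap(M_disj, "P", "H"), 0)
  # V^P = {1,2,3}, V^H = {3,4}: 1 common node, union of 4 -> 25
  M_part <- build_multilayer(rbind(mk(c("1", "2"), c("2", "3"), "P"),
                                   mk("3", "4", "H")))
  expect_equal(layer_overlap(M_part, "P", "H"), 25)
  expect_equal(layer_overlap(M_part, "P", "H", denominator = "min"), 50)
  expect_equal(layer_overlap(M_part, "P", "H", denominator = "a"), 100 / 3)
  expect_message(out <- layer_overlap(M_part, "A", "A"), "undefined")
  expect_true(is.na(out))
})

test_that("hardliner selection honors the activity floor and tie-breaks", {
  # five single-layer nodes (entropy 0) with different activity + one
  # multi-layer node: the k most active single-layer nodes win
  mk <- function(n_in, target, layer) {
    make_post(paste0("b_", target), target, layer,
              comments = make_comments(paste0(target, "_u", seq_len(n_in))))
  }
  posts <- dplyr::bind_rows(
    mk(6, "s1", "P"), mk(5, "s2", "P"), mk(4, "s3", "P"),
    mk(3, "s4", "P"), mk(2, "s5", "P"),
    # multi-layer node: receives in P and H -> entropy > 0
    make_post("b_m1", "m", "P", comments = make_comments(paste0("mp", 1:6))),
    make_post("b_m2", "m", "H", comments = make_comments(paste0("mh", 1:6)))
  )
  M <- build_multilayer(flatten(posts, seed = 1))
  sel <- select_hardliners(M, "P", k = 3, min_activity = 2)
  expect_equal(sel$node, c("s1", "s2", "s3"))
  expect_true(all(sel$entropy == 0))
  # k larger than pool: whole pool, still excluding low-activity users
  all_sel <- select_hardliners(M, "P", k = 100, min_activity = 2)
  expect_false("m" %in% head(all_sel$node, 5))
  expect_true(all(all_sel$total_connections >= 2))
})

test_that("diverse-node selection matches an exhaustive sort", {
  star <- make_post("b1", "hub", "P",
                    comments = make_comments(paste0("u", 1:7)))
  M <- build_multilayer(flatten(star, seed = 1))
  expect_equal(select_diverse(M, k = 1)$node, "hub")

  for (seed in 1:5) {
    rec <- random_toy_records(seed)
    M <- build_multilayer(rec)
    sel <- select_diverse(M, k = 4)
    nodes <- sort(unique(c(rec$source, rec$target)))
    score <- vapply(nodes, function(v) {
      bf_cross_degree(rec, v, "in") + bf_cross_degree(rec, v, "out")
    }, numeric(1))
    # the selected scores are the k largest scores
    expect_equal(sort(sel$score, decreasing = TRUE),
                 unname(head(sort(score, decreasing = TRUE), 4)))
  }
})

test_that("layer proportions normalize to 100 and match direct arithmetic", {
  mk <- function(sources, target, layer) {
    tibble::tibble(source = sources, target = target, layer = layer,
                   weight = 2, reaction = "like",
                   time = as.POSIXct("2021-06-01", tz = "UTC"), board_id = "b")
  }
  # v receives from 5 users in P, 3 in H, 2 in A
  rec <- rbind(mk(paste0("p", 1:5), "v", "P"),
               mk(paste0("h", 1:3), "v", "H"),
               mk(paste0("a", 1:2), "v", "A"))
  M <- build_multilayer(rec)
  expect_equal(layer_proportions(M, "v", "in"),
               c(P = 50, H = 30, A = 20))
  only_p <- build_multilayer(mk(paste0("p", 1:4), "v", "P"))
  expect_equal(layer_proportions(only_p, "v", "in"), c(P = 100, H = 0, A = 0))
  for (seed in 1:5) {
    rec <- random_toy_records(seed)
    M <- build_multilayer(rec)
    pr <- suppressMessages(layer_proportions(M, unique(rec$target), "in"))
    expect_equal(sum(pr), 100)
  }
  expect_message(out <- layer_proportions(M, "ghost", "out"), "undefined")
  expect_true(all(is.na(out)))
})

test_that("standardized hardliner degrees scale as designed", {
  # layer H: hardliner h receives from 4, others receive from 2 each
  posts <- dplyr::bind_rows(
    make_post("b1", "h", "H", comments = make_comments(paste0("u", 1:4))),
    make_post("b2", "w1", "H", comments = make_comments(paste0("x", 1:2))),
    make_post("b3", "w2", "H", comments = make_comments(paste0("y", 1:2)))
  )
  M <- build_multilayer(flatten(posts, seed = 1))
  hl <- tibble::tibble(node = "h", entropy = 0, total_connections = 4,
                       within_degree = 4)
  res <- hardliner_degrees(M, "H", hardliners = hl)
  v <- layer_nodes(M, "H")
  mean_in <- mean(layer_degree(M, "H", "in", nodes = v))
  expect_equal(res$mean_standardized[res$direction == "in"], 4 / mean_in)
  # a hardliner whose degree equals the layer mean standardizes to 1
  hl_mean <- tibble::tibble(node = "w1", entropy = 0, total_connections = 2,
                            within_degree = 2)
  res2 <- hardliner_degrees(M, "H", hardliners = hl_mean)
  expect_equal(res2$mean_standardized[res2$direction == "in"], 2 / mean_in)
})

test_that("metric bounds hold on random toys", {
  for (seed in 11:25) {
    rec <- random_toy_records(seed)
    M <- build_multilayer(rec)
    ent <- node_entropy(M)
    expect_true(all(ent >= 0 & ent <= log(3) + 1e-12, na.rm = TRUE))
    for (pair in list(c("P", "H"), c("P", "A"), c("H", "A"))) {
      ov <- suppressMessages(layer_overlap(M, pair[1], pair[2]))
      expect_true(is.na(ov) || (ov >= 0 && ov <= 100))
      sp <- suppressMessages(spearman_pair(M, pair[1], pair[2], "in"))
      expect_true(is.na(sp) || (sp >= -1 && sp <= 1))
    }
    # degree sandwich: max_l d^l <= d^M <= sum_l d^l
    nodes <- unique(c(rec$source, rec$target))
    for (dir in c("in", "out")) {
      per_layer <- sapply(LAYERS3, function(l) layer_degree(M, l, dir, nodes = nodes))
      cr <- cross_degree(M, dir, nodes = nodes)
      expect_true(all(apply(per_layer, 1, max) <= cr))
      expect_true(all(cr <= rowSums(per_layer)))
    }
  }
})

test_that("metric series evaluate on cumulative snapshots with NA gaps", {
  f <- small_forum(seed = 6)
  rec <- flatten(f$posts, seed = 3)
  end <- max(rec$time)
  static_val <- suppressMessages(layer_overlap(build_multilayer(rec), "P", "H"))
  single <- metric_series(rec, end, function(m) {
    c(overlap_PH = suppressMessages(layer_overlap(m, "P", "H")))
  })
  expect_equal(nrow(single), 1)
  expect_equal(single$value, static_val)

  grid <- month_grid(min(rec$time), max(rec$time))
  series <- metric_series(rec, grid, function(m) {
    c(nodes = length(unique(c(m$edges$source, m$edges$target))))
  })
  expect_true(all(diff(series$value) >= 0))
  expect_equal(utils::tail(series$value, 1),
               length(unique(c(rec$source, rec$target))))
})

test_that("undefined layer statistics surface as NA with messages", {
  rec <- random_toy_records(2)
  rec$layer <- "P"
  M <- build_multilayer(rec)
  expect_message(d <- layer_diversity(M, "A", "in"), "undefined")
  expect_true(is.na(d))
  expect_message(s <- spearman_pair(M, "P", "A", "in"), "undefined")
  expect_true(is.na(s))
  # single-layer network: diversity equals the within-layer mean degree
  v <- layer_nodes(M, "P")
  expect_equal(layer_diversity(M, "P", "in"),
               mean(layer_degree(M, "P", "in", nodes = v)))
})
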