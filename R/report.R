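# End-to-end orchestration: one config in, the full set of result tables out.

#' Monthly snapshot grid
#'
#' Calendar-month end points covering `[start, end]`: one time point at the
#' last instant of each month.
#'
#' @param start,end Dates or date strings.
#' @return POSIXct vector of month-end instants, sorted ascending.
#' @examples
#' length(month_grid("2021-01-01", "2022-12-31"))  # 24
#' @export
month_grid <- function(start, end) {
  s <- as.POSIXct(paste(format(as.Date(start), "%Y-%m-01"), "00:00:00"),
                  tz = TIME_TZ)
  e <- as.POSIXct(paste(format(as.Date(end)), "23:59:59"), tz = TIME_TZ)
  if (e <= s) stop("`end` must be after `start`", call. = FALSE)
  bounds <- seq(s, by = "month", length.out = 2L)
  pts <- s
  while (utils::tail(pts, 1) < e) {
    pts <- c(pts, seq(utils::tail(pts, 1), by = "month", length.out = 2L)[2])
  }
  utils::tail(pts, -1L) - 1  # last second of each covered month
}

#' Pipeline run configuration
#'
#' @param mode Input mode: `"synthetic"`, `"threads"` or `"edge_list"`.
#' @param forum A [forum_config()] (synthetic mode).
#' @param threads_path Thread-text file(s) (threads mode).
#' @param label_table_path Label-table CSV (threads mode; optional if the
#'   threads already carry P/H/A labels).
#' @param edge_list_path Edge-record CSV (edge-list mode).
#' @param keyword Keyword filter applied in threads mode (default
#'   \dQuote{疫苗}; `NULL` skips filtering).
#' @param start,end Time grid window; defaults to the record range.
#' @param k_diverse,k_hardliners,min_activity Metric parameters.
#' @param bootstrap_n Bootstrap replicates for the layer-summary CIs
#'   (0 skips the bootstrap).
#' @param powerlaw_boot Bootstrap replicates for power-law goodness of fit
#'   (0 skips the test).
#' @param series Compute monthly time series? Default `TRUE`.
#' @param seed Root seed; all stochastic steps derive named streams.
#' @param output_dir Optional directory for CSV outputs and the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "threads", "edge_list"),
                       forum = forum_config(),
                       threads_path = NULL,
                       label_table_path = NULL,
                       edge_list_path = NULL,
                       keyword = "疫苗",
                       start = NULL, end = NULL,
                       k_diverse = 50, k_hardliners = 30, min_activity = 10,
                       bootstrap_n = 0, powerlaw_boot = 0,
                       series = TRUE,
                       seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "threads" && is.null(threads_path)) {
    stop("threads mode requires `threads_path`", call. = FALSE)
  }
  if (mode == "edge_list" && is.null(edge_list_path)) {
    stop("edge_list mode requires `edge_list_path`", call. = FALSE)
  }
  if (!is.null(start) && !is.null(end) &&
      as.Date(end) <= as.Date(start)) {
    stop("`end` must be after `start`", call. = FALSE)
  }
  structure(
    list(mode = mode, forum = forum, threads_path = threads_path,
         label_table_path = label_table_path, edge_list_path = edge_list_path,
         keyword = keyword, start = start, end = end,
         k_diverse = k_diverse, k_hardliners = k_hardliners,
         min_activity = min_activity, bootstrap_n = bootstrap_n,
         powerlaw_boot = powerlaw_boot, series = series,
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the [run_config()] arguments; a `forum` mapping is
#' passed to [forum_config()].
#'
#' @param path YAML/JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$forum)) {
    raw$forum <- do.call(forum_config, raw$forum)
  }
  do.call(run_config, raw)
}

#' Corpus diagnostics
#'
#' Reports label coverage, the reaction-mark distribution, the timestamp
#' range (and the number of calendar months it spans), and duplicate board
#' ids (raised as a warning).
#'
#' @param posts Posts tibble.
#' @return List of diagnostics.
#' @export
validate_corpus <- function(posts) {
  assert_posts(posts)
  cm <- dplyr::bind_rows(posts$comments)
  dup <- unique(posts$board_id[duplicated(posts$board_id)])
  if (length(dup)) {
    warning("duplicated board id(s): ", paste(dup, collapse = ", "),
            call. = FALSE)
  }
  times <- c(posts$time, cm$time)
  months <- if (length(times)) {
    mo <- format(range(times), "%Y-%m")
    length(seq(as.Date(paste0(mo[1], "-01")), as.Date(paste0(mo[2], "-01")),
               by = "month"))
  } else {
    0L
  }
  n_unlabeled <- sum(!posts$label %in% c(LAYERS, "neutral", "irrelevant"))
  if (n_unlabeled > 0) {
    message(n_unlabeled, " post(s) without a final label")
  }
  list(
    n_posts = nrow(posts),
    n_comments = nrow(cm),
    label_counts = table(posts$label),
    n_unlabeled = n_unlabeled,
    reaction_counts = if (nrow(cm)) table(cm$reaction) else table(character(0)),
    time_range = if (length(times)) range(times) else NULL,
    n_months = months,
    duplicate_board_ids = dup
  )
}

#' Per-layer network summary
#'
#' Post, node and comment counts per layer with the mean total degree
#' (`2 * comments / nodes`).
#'
#' @param posts Labeled posts tibble.
#' @param M The `multilayer_network` built from the posts' records.
#' @return Tibble: `layer`, `n_posts`, `nodes`, `edges`, `mean_degree`.
#' @export
network_summary <- function(posts, M) {
  tibble::tibble(
    layer = LAYERS,
    n_posts = vapply(LAYERS, function(l) sum(posts$label == l), integer(1),
                     USE.NAMES = FALSE),
    nodes = vapply(LAYERS, function(l) length(layer_nodes(M, l)), integer(1),
                   USE.NAMES = FALSE),
    edges = unname(as.integer(M$n_records[LAYERS])),
    mean_degree = unname(mean_layer_degree(M))
  )
}

layer_pairs <- function() {
  list(c("P", "H"), c("P", "A"), c("H", "A"))
}

#' Run the full chambering analysis pipeline
#'
#' From a [run_config()], obtains posts (generated, parsed or loaded),
#' flattens them, builds the multilayer network and computes every result
#' surface: the per-layer network summary (with bootstrap CIs on the mean
#' degree when `bootstrap_n > 0`), pairwise Spearman rank correlations,
#' layer degree diversity, node-overlap percentages, the top-diverse-node
#' connection proportions, standardized hardliner degrees, per-layer
#' power-law fits, and (optionally) monthly time series of overlap,
#' diversity and mean entropy. A manifest echoes the config and seeds. With
#' `output_dir` set, every table is written as CSV plus a YAML manifest.
#'
#' The run is deterministic given the config.
#'
#' @param config A [run_config()].
#' @return A `chamber_report` list of tibbles (see Details) plus `network`
#'   (the `multilayer_network`), `records`, `posts` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  posts <- NULL
  records <- NULL
  if (config$mode == "synthetic") {
    forum <- generate_forum(config$forum)
    posts <- forum$posts
  } else if (config$mode == "threads") {
    posts <- parse_threads(config$threads_path)
    if (!is.null(config$keyword)) {
      posts <- filter_vaccine_boards(posts, config$keyword)
    }
    if (!is.null(config$label_table_path)) {
      posts <- apply_final_labels(posts, read_label_table(config$label_table_path))
    }
    if (!all(posts$label %in% LAYERS)) {
      stop("threads mode: posts remain without P/H/A labels; ",
           "supply `label_table_path`", call. = FALSE)
    }
  } else {
    records <- read_edge_records(config$edge_list_path)
  }
  if (is.null(records)) {
    records <- flatten(posts, seed = derive_seed(config$seed, "flatten"))
  }
  if (!nrow(records)) stop("no edge records to analyze", call. = FALSE)
  M <- build_multilayer(records)

  summary_tbl <- if (!is.null(posts)) {
    network_summary(posts, M)
  } else {
    tibble::tibble(
      layer = LAYERS, n_posts = NA_integer_,
      nodes = vapply(LAYERS, function(l) length(layer_nodes(M, l)), integer(1),
                     USE.NAMES = FALSE),
      edges = unname(as.integer(M$n_records[LAYERS])),
      mean_degree = unname(mean_layer_degree(M))
    )
  }
  if (config$bootstrap_n > 0 && !is.null(posts)) {
    bs <- bootstrap_metric(posts, mean_layer_degree,
                           n_replicates = config$bootstrap_n,
                           seed = derive_seed(config$seed, "bootstrap"))
    summary_tbl$mean_degree_ci <- format_ci(bs$boot_mean, bs$ci_lower,
                                            bs$ci_upper)
  }

  spearman_tbl <- purrr::map_dfr(layer_pairs(), function(pr) {
    purrr::map_dfr(c("in", "out"), function(dir) {
      tibble::tibble(
        layer_a = pr[1], layer_b = pr[2], direction = dir,
        spearman = suppressMessages(spearman_pair(M, pr[1], pr[2], dir))
      )
    })
  })

  diversity_tbl <- purrr::map_dfr(LAYERS, function(l) {
    tibble::tibble(
      layer = l,
      indegree_diversity = suppressMessages(layer_diversity(M, l, "in")),
      outdegree_diversity = suppressMessages(layer_diversity(M, l, "out"))
    )
  })

  overlap_tbl <- purrr::map_dfr(layer_pairs(), function(pr) {
    tibble::tibble(layer_a = pr[1], layer_b = pr[2],
                   overlap_pct = suppressMessages(layer_overlap(M, pr[1], pr[2])))
  })

  diverse <- select_diverse(M, k = config$k_diverse)
  diverse_prop <- tibble::as_tibble(rbind(
    data.frame(direction = "in",
               t(suppressMessages(layer_proportions(M, diverse$node, "in")))),
    data.frame(direction = "out",
               t(suppressMessages(layer_proportions(M, diverse$node, "out"))))
  ))

  hardliner_tbl <- purrr::map_dfr(LAYERS, function(l) {
    dplyr::mutate(
      suppressMessages(hardliner_degrees(M, l, k = config$k_hardliners,
                                         min_activity = config$min_activity)),
      layer = l, .before = 1
    )
  })

  powerlaw_tbl <- purrr::map_dfr(LAYERS, function(l) {
    v <- layer_nodes(M, l)
    deg <- layer_degree(M, l, "in", nodes = v) + layer_degree(M, l, "out", nodes = v)
    fit <- tryCatch(
      fit_power_law(deg, n_boot = config$powerlaw_boot,
                    seed = derive_seed(config$seed, paste0("plaw", l))),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      tibble::tibble(layer = l, exponent = NA_real_, xmin = NA_real_,
                     gof_p = NA_real_, n_tail = NA_integer_)
    } else {
      tibble::tibble(layer = l, exponent = fit$exponent, xmin = fit$xmin,
                     gof_p = fit$p_value, n_tail = fit$n_tail)
    }
  })

  series_tbl <- NULL
  if (isTRUE(config$series)) {
    rng <- range(records$time)
    grid <- month_grid(
      if (is.null(config$start)) as.Date(rng[1]) else config$start,
      if (is.null(config$end)) as.Date(rng[2]) else config$end
    )
    overlap_series <- metric_series(records, grid, function(m) {
      vapply(layer_pairs(), function(pr) {
        suppressMessages(layer_overlap(m, pr[1], pr[2]))
      }, numeric(1)) |>
        setNames(vapply(layer_pairs(), paste, character(1), collapse = "-"))
    })
    diversity_series <- metric_series(records, grid, function(m) {
      setNames(
        as.vector(vapply(LAYERS, function(l) {
          c(suppressMessages(layer_diversity(m, l, "in")),
            suppressMessages(layer_diversity(m, l, "out")))
        }, numeric(2))),
        as.vector(outer(c("in", "out"), LAYERS, function(d, l) paste0(l, "_", d)))
      )
    })
    entropy_series <- metric_series(records, grid, function(m) {
      ent <- suppressMessages(node_entropy(m))
      c(mean_entropy = if (length(ent)) mean(ent, na.rm = TRUE) else NA_real_)
    })
    series_tbl <- dplyr::bind_rows(
      dplyr::mutate(overlap_series, family = "overlap"),
      dplyr::mutate(diversity_series, family = "diversity"),
      dplyr::mutate(entropy_series, family = "entropy")
    )
  }

  manifest <- list(
    package = "stancenet",
    version = as.character(utils::packageVersion("stancenet")),
    mode = config$mode,
    seed = config$seed,
    k_diverse = config$k_diverse,
    k_hardliners = config$k_hardliners,
    min_activity = config$min_activity,
    bootstrap_n = config$bootstrap_n,
    tables = c("network_summary", "spearman_pairs", "layer_diversity",
               "node_overlap", "diverse_proportions", "hardliner_degrees",
               "powerlaw_fits", if (!is.null(series_tbl)) "series")
  )

  report <- structure(
    list(
      network_summary = summary_tbl,
      spearman_pairs = spearman_tbl,
      layer_diversity = diversity_tbl,
      node_overlap = overlap_tbl,
      diverse_proportions = diverse_prop,
      hardliner_degrees = hardliner_tbl,
      powerlaw_fits = powerlaw_tbl,
      series = series_tbl,
      network = M,
      records = records,
      posts = posts,
      manifest = manifest
    ),
    class = "chamber_report"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in manifest$tables) {
      readr::write_csv(report[[nm]], file.path(config$output_dir,
                                               paste0(nm, ".csv")))
    }
    yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  }
  report
}

#' @export
print.chamber_report <- function(x, ...) {
  cat("Chambering analysis report\n\n")
  cat("Network summary:\n")
  print(x$network_summary)
  cat("\nSpearman rank correlations (common nodes):\n")
  print(x$spearman_pairs)
  cat("\nLayer diversity (mean cross-layer degree):\n")
  print(x$layer_diversity)
  invisible(x)
}
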