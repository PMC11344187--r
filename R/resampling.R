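#' Bootstrap a network metric over board resamples
#'
#' Quantifies how board-classification variability propagates into a network
#' statistic: each replicate resamples the retained boards with replacement
#' (holding their number fixed), rebuilds the multilayer network from the
#' resampled boards' comments, and recomputes the metric. The comments are
#' flattened once (with a seed derived from `seed`), so the boo-reassignment
#' layer of every comment is held fixed across replicates; the replicate
#' stream itself is seed-deterministic.
#'
#' @param posts Labeled posts tibble (labels in P/H/A).
#' @param metric Function of a `multilayer_network` returning a scalar or a
#'   fixed-length named numeric vector (e.g. [mean_layer_degree()]).
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer root seed.
#' @param include_self Passed to [flatten()].
#' @return A `bootstrap_summary` tibble with one row per statistic:
#'   `statistic`, `estimate` (full-data value), `boot_mean`, `ci_lower`,
#'   `ci_upper` (percentile 2.5/97.5), `n_replicates`, `prop_undefined`,
#'   `flagged` (`TRUE` when the metric was undefined in more than half the
#'   replicates). The replicate matrix is attached as attribute
#'   `replicates`.
#' @export
bootstrap_metric <- function(posts, metric, n_replicates = 1000, seed = 1L,
                             include_self = FALSE) {
  assert_posts(posts)
  stopifnot(n_replicates >= 1)
  records <- flatten(posts, seed = derive_seed(seed, "flatten"),
                     include_self = include_self)
  full <- suppressMessages(metric(build_multilayer(records)))
  stat_names <- names(full)
  if (is.null(stat_names)) {
    stat_names <- if (length(full) == 1L) "statistic" else
      paste0("statistic", seq_along(full))
  }
  boards <- posts$board_id
  row_idx <- split(seq_len(nrow(records)),
                   factor(records$board_id, levels = boards))
  local_seed_if(derive_seed(seed, "bootstrap"))
  reps <- matrix(NA_real_, nrow = n_replicates, ncol = length(full),
                 dimnames = list(NULL, stat_names))
  for (b in seq_len(n_replicates)) {
    sel <- sample.int(length(boards), replace = TRUE)
    rows <- unlist(row_idx[sel], use.names = FALSE)
    val <- suppressMessages(metric(build_multilayer(records[rows, , drop = FALSE])))
    if (length(val) != length(full)) {
      stop("metric returned a value of varying length across replicates",
           call. = FALSE)
    }
    reps[b, ] <- as.numeric(val)
  }
  prop_na <- unname(colMeans(is.na(reps)))
  out <- tibble::tibble(
    statistic = stat_names,
    estimate = as.numeric(full),
    boot_mean = unname(colMeans(reps, na.rm = TRUE)),
    ci_lower = unname(apply(reps, 2, quantile, probs = 0.025, na.rm = TRUE)),
    ci_upper = unname(apply(reps, 2, quantile, probs = 0.975, na.rm = TRUE)),
    n_replicates = n_replicates,
    prop_undefined = prop_na,
    flagged = prop_na > 0.5
  )
  if (any(out$flagged)) {
    warning("metric undefined in >50% of replicates for: ",
            paste(out$statistic[out$flagged], collapse = ", "), call. = FALSE)
  }
  attr(out, "replicates") <- reps
  attr(out, "seed") <- seed
  class(out) <- c("bootstrap_summary", class(out))
  out
}

#' Format bootstrap summaries as report rows
#'
#' Renders each statistic as `"mean (low-high)"` with two-decimal rounding,
#' the table style of the reported results.
#'
#' @param summary A [bootstrap_metric()] result (or any tibble with
#'   `statistic`, `boot_mean`, `ci_lower`, `ci_upper`).
#' @return Tibble: `statistic`, `formatted`.
#' @examples
#' # format_summary(bootstrap_metric(posts, mean_layer_degree, 100))
#' @export
format_summary <- function(summary) {
  tibble::tibble(
    statistic = summary$statistic,
    formatted = format_ci(summary$boot_mean, summary$ci_lower, summary$ci_upper)
  )
}
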