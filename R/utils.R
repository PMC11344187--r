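# Internal helpers shared across modules.

# Undefined-statistic sentinel: metrics that are not defined on the given
# input (empty layer, zero variance, isolated node) return NA_real_ with an
# audit message rather than a silent 0.
undefined_value <- function(what) {
  message("undefined statistic: ", what, " (returning NA)")
  NA_real_
}

# Derive a named RNG stream from one root seed so that independent sources
# of randomness (user generation, boo reassignment, bootstrap, ...) do not
# share a stream. Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% (.Machine$integer.max - 1)) + 1L
}

# Seed the calling frame's RNG locally (restores global RNG state on exit).
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

#' Sample from a discrete power law
#'
#' Draws integers `x >= xmin` with probability proportional to
#' `x^(-exponent)`. For exponents of 1.5 and above, draws come from exact
#' inverse-CDF lookup on an explicit probability table truncated where the
#' remaining tail mass is negligible; for heavier tails (exponent below
#' 1.5), where no practical truncation point exists, the standard rounded
#' continuous-power-law approximation is used instead.
#'
#' @param n Number of draws.
#' @param exponent Power-law exponent, must be > 1.
#' @param xmin Smallest attainable value (default 1).
#' @return Integer vector of length `n`.
#' @examples
#' set.seed(1)
#' x <- rpower_discrete(1000, exponent = 2.3)
#' mean(x)
#' @export
rpower_discrete <- function(n, exponent, xmin = 1L) {
  stopifnot(n >= 0, exponent > 1, xmin >= 1)
  if (n == 0L) {
    return(integer(0))
  }
  if (exponent < 1.5) {
    # rounded continuous approximation (no truncation)
    u <- runif(n)
    return(as.integer(pmin(
      floor((xmin - 0.5) * (1 - u)^(-1 / (exponent - 1)) + 0.5),
      .Machine$integer.max / 2
    )))
  }
  cutoff <- if (exponent < 2) 1e6L else 1e5L
  support <- seq.int(xmin, max(cutoff, xmin + 1L))
  prob <- support^(-exponent)
  support[sample.int(length(support), n, replace = TRUE, prob = prob)]
}

#' Format a point estimate with its confidence interval
#'
#' Renders `mean (low-high)` with two-decimal rounding, the style used for
#' bootstrap summaries in the reported tables.
#'
#' @param estimate,lower,upper Numeric vectors (recycled to common length).
#' @return Character vector.
#' @examples
#' format_ci(4.2401, 4.2134, 4.2692)
#' @export
format_ci <- function(estimate, lower, upper) {
  sprintf("%.2f (%.2f-%.2f)", estimate, lower, upper)
}

#' Mean total degree of a layer from its node and edge counts
#'
#' For a layer where every comment is one directed edge, the average (total)
#' degree is `2 * edges / nodes`: each comment contributes one out-stub and
#' one in-stub.
#'
#' @param nodes Number of distinct users in the layer.
#' @param edges Number of comments (directed edge records) in the layer.
#' @return Numeric.
#' @examples
#' average_degree(11087, 23504)
#' @export
average_degree <- function(nodes, edges) {
  stopifnot(all(nodes > 0))
  2 * edges / nodes
}

# Fixed timestamp format of the thread-text dialect. All corpus times are
# local forum time stored without zone shifts (tz = "UTC" internally).
TIME_FORMAT <- "%Y-%m-%d %H:%M:%S"
TIME_TZ <- "UTC"

format_time <- function(x) format(x, TIME_FORMAT, tz = TIME_TZ)

parse_time <- function(x) as.POSIXct(x, format = TIME_FORMAT, tz = TIME_TZ)

assert_posts <- function(posts) {
  needed <- c("board_id", "author", "time", "title", "label", "comments")
  if (!is.data.frame(posts) || !all(needed %in% names(posts))) {
    stop(
      "`posts` must be a data frame with columns ",
      paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(posts)
}
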