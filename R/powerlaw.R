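#' Fit a discrete power law to a degree sample
#'
#' Estimates the tail exponent of `p(d) ~ d^-delta` by discrete maximum
#' likelihood, with the lower cutoff `x_min` selected by minimizing the
#' Kolmogorov-Smirnov distance between the fitted model and the empirical
#' tail (the standard plfit procedure, via [igraph::fit_power_law()]).
#' The goodness of fit is assessed by a semi-parametric bootstrap: each
#' replicate draws `n` values — tail values from the fitted power law,
#' below-cutoff values from the empirical body — refits (including the
#' `x_min` search) and records its KS distance; the p-value is the fraction
#' of replicates whose KS distance is at least the observed one. A small
#' p-value signals deviation from power-law behavior.
#'
#' @param degrees Integer vector of degree counts; zeros are dropped.
#' @param xmin Optional fixed lower cutoff; default: selected by KS search.
#' @param n_boot Bootstrap replicates for the p-value (default 100; 0 skips
#'   the test and returns `p_value = NA`).
#' @param seed Optional seed for the bootstrap.
#' @param min_n Minimum number of nonzero degrees required (default 50).
#' @return A `power_law_fit` list: `exponent`, `xmin`, `ks_stat`, `p_value`,
#'   `n`, `n_tail`, `n_boot`.
#' @examples
#' set.seed(7)
#' fit <- fit_power_law(rpower_discrete(2000, 2.3), n_boot = 20, seed = 1)
#' fit$exponent
#' @export
fit_power_law <- function(degrees, xmin = NULL, n_boot = 100, seed = NULL,
                          min_n = 50) {
  x <- as.integer(degrees[!is.na(degrees) & degrees > 0])
  if (length(x) < min_n) {
    stop("need at least ", min_n, " nonzero degrees to fit", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("degenerate degree sample: all values identical", call. = FALSE)
  }
  fit <- plfit_once(x, xmin = xmin)
  p_value <- NA_real_
  if (n_boot > 0) {
    local_seed_if(seed)
    n <- length(x)
    body <- x[x < fit$xmin]
    p_tail <- 1 - length(body) / n
    ks_boot <- vapply(seq_len(n_boot), function(b) {
      tail_n <- stats::rbinom(1, n, p_tail)
      draws <- c(
        if (tail_n > 0) rpower_discrete(tail_n, fit$alpha, xmin = fit$xmin),
        if (n - tail_n > 0) sample(body, n - tail_n, replace = TRUE)
      )
      plfit_once(draws, xmin = if (is.null(xmin)) NULL else xmin)$ks
    }, numeric(1))
    p_value <- mean(ks_boot >= fit$ks)
  }
  structure(
    list(
      exponent = fit$alpha, xmin = fit$xmin, ks_stat = fit$ks,
      p_value = p_value, n = length(x), n_tail = sum(x >= fit$xmin),
      n_boot = n_boot
    ),
    class = "power_law_fit"
  )
}

# One MLE fit; returns alpha, xmin, and the KS distance of the tail.
plfit_once <- function(x, xmin = NULL) {
  f <- if (is.null(xmin)) {
    igraph::fit_power_law(x, implementation = "plfit")
  } else {
    igraph::fit_power_law(x, xmin = xmin, implementation = "plfit")
  }
  list(alpha = f$alpha,
       xmin = if (is.null(xmin)) f$xmin else xmin,
       ks = f$KS.stat)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Discrete power-law fit: exponent %.3f (x_min = %d, tail n = %d)\n",
    x$exponent, as.integer(x$xmin), x$n_tail
  ))
  if (!is.na(x$p_value)) {
    cat(sprintf("  bootstrap GoF p = %.3f (%d replicates; small p => deviation)\n",
                x$p_value, x$n_boot))
  }
  invisible(x)
}
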