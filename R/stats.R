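## Shared statistics: two-sample tests and Benjamini-Hochberg FDR.

#' Two-sample test (Welch t or Mann-Whitney U)
#'
#' \code{method = "t"} runs Welch's two-sample t test with
#' Welch-Satterthwaite degrees of freedom; \code{method = "mwu"} runs the
#' two-sided Mann-Whitney U test with normal approximation and tie
#' correction. Degenerate inputs (all values identical across both samples,
#' or zero variance in both) return \code{p = 1} with \code{flagged = TRUE};
#' constant samples with different means return \code{p = 0} and an infinite
#' statistic, also flagged.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param method \code{"t"} or \code{"mwu"}.
#' @return A list of class \code{test_result}: \code{statistic},
#'   \code{p_value}, \code{method}, \code{n_a}, \code{n_b}, \code{df}
#'   (t only), \code{flagged}.
#' @export
two_sample_test <- function(x, y, method = c("t", "mwu")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L)
    stopf("both samples need at least 2 observations")
  res <- list(method = method, n_a = length(x), n_b = length(y),
              flagged = FALSE, df = NA_real_)
  if (method == "t") {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        res$statistic <- 0; res$p_value <- 1
      } else {
        res$statistic <- sign(mean(x) - mean(y)) * Inf; res$p_value <- 0
      }
      res$flagged <- TRUE
    } else {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      res$statistic <- unname(ht$statistic)
      res$p_value <- ht$p.value
      res$df <- unname(ht$parameter)
    }
  } else {
    if (length(unique(c(x, y))) == 1L) {
      res$statistic <- length(x) * length(y) / 2; res$p_value <- 1
      res$flagged <- TRUE
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = FALSE))
      res$statistic <- unname(ht$statistic)   # U for the first sample
      res$p_value <- if (is.nan(ht$p.value)) 1 else ht$p.value
    }
  }
  structure(res, class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (n = %d, %d)%s\n",
              if (x$method == "t") "Welch t" else "Mann-Whitney U",
              x$statistic, x$p_value, x$n_a, x$n_b,
              if (x$flagged) " [degenerate input]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Ranks the p-values and finds the largest \code{i} with
#' \code{p_(i) <= i * alpha / m}; all p-values up to that one are rejected.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return A list of class \code{fdr_result}: \code{p_sorted},
#'   \code{threshold} (the rejection threshold, 0 when nothing is rejected),
#'   \code{rejected} (indices into the input), \code{n_rejected},
#'   \code{alpha}.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L)
    return(structure(list(p_sorted = numeric(0), threshold = 0,
                          rejected = integer(0), n_rejected = 0L,
                          alpha = alpha),
                     class = "fdr_result"))
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * alpha / m)
  thr <- if (length(ok)) ps[max(ok)] else 0
  rejected <- if (length(ok)) which(p_values <= thr) else integer(0)
  structure(list(p_sorted = ps, threshold = thr, rejected = rejected,
                 n_rejected = length(rejected), alpha = alpha),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("BH-FDR at alpha = %g: %d of %d rejected (threshold %.4g)\n",
              x$alpha, x$n_rejected, length(x$p_sorted), x$threshold))
  invisible(x)
}
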