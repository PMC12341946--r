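#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene time-course fits
#'
#' Returns the long coefficient table — the stepwise-refined one when
#' [backward_stepwise()] has been run, the full-model one otherwise.
#'
#' @param x A `memory_fits` object.
#' @param ... Unused.
#' @return A tibble with one row per gene x term.
#' @export
tidy.memory_fits <- function(x, ...) {
  if (!is.null(x$final)) x$final else x$coef
}

#' One-row summary of a set of time-course fits
#'
#' @param x A `memory_fits` object.
#' @param ... Unused.
#' @return A tibble: `n_genes`, `n_terms`, `median_r2`, `df`, and the
#'   stepwise `alpha` when available.
#' @export
glance.memory_fits <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_terms = ncol(x$X),
    median_r2 = stats::median(x$genes$r2),
    df = x$genes$df[1],
    alpha = if (is.null(x$alpha)) NA_real_ else x$alpha
  )
}

#' Tidy a pipeline run into stage gene counts
#'
#' @param x A `memory_run` object.
#' @param ... Unused.
#' @return A tibble: `stage`, `n_genes` (telescoping counts).
#' @export
tidy.memory_run <- function(x, ...) {
  tibble::tibble(
    stage = c("input", "filtered", "time_significant"),
    n_genes = c(x$n_input, x$n_filtered, x$n_time_significant)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `memory_run` object.
#' @param ... Unused.
#' @return A tibble with stage counts, memory-class counts and (for
#'   simulated data) the memory-label recovery accuracy.
#' @export
glance.memory_run <- function(x, ...) {
  tab <- table(x$classes$memory_effect)
  cnt <- function(l) if (l %in% names(tab)) as.integer(tab[[l]]) else 0L
  tibble::tibble(
    n_input = x$n_input,
    n_filtered = x$n_filtered,
    n_time_significant = x$n_time_significant,
    memory_dampened = cnt("dampened"),
    memory_enhanced = cnt("enhanced"),
    memory_reversed = cnt("reversed"),
    memory_no_change = cnt("no_change"),
    memory_recovery = if (is.null(x$recovery)) NA_real_ else
      x$recovery$accuracy[x$recovery$effect == "memory"]
  )
}
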