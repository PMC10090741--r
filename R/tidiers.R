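#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multiverse grid
#'
#' Returns the per-window estimates as a plain tibble (one row per
#' country and baseline window).
#'
#' @param x An `mv_grid` from [run_multiverse()].
#' @param ... Unused.
#' @method tidy mv_grid
#' @export
tidy.mv_grid <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row-per-country summary of a multiverse grid
#'
#' @param x An `mv_grid` from [run_multiverse()].
#' @param ... Passed to [summarize_multiverse()].
#' @method glance mv_grid
#' @export
glance.mv_grid <- function(x, ...) {
  summarize_multiverse(x, ...)
}

#' Tidy a rank distribution: the rank-occurrence histogram
#'
#' @param x An `mv_rank` from [rank_distribution()].
#' @param ... Unused.
#' @method tidy mv_rank
#' @export
tidy.mv_rank <- function(x, ...) {
  x$histogram
}

#' One-row-per-country rank summary
#'
#' @param x An `mv_rank` from [rank_distribution()].
#' @param ... Unused.
#' @method glance mv_rank
#' @export
glance.mv_rank <- function(x, ...) {
  x$summary
}
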