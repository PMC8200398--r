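#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style accessors for teparypep results
#'
#' `tidy()` returns the per-row detail of a result (fragments of a digest,
#' per-item ratios of a chemical score); `glance()` returns a one-row (or
#' one-row-per-sample) summary.
#'
#' @param x A `tp_digest` or `tp_chemscore` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_teparypep
NULL
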