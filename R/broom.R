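#' Broom-style tidiers
#'
#' `tidy()` returns one row per statistical quantity; `glance()` a one-row
#' model summary, following the broom conventions.
#'
#' @param x An `lgt_te_test` (from `compare_te_density()`), a
#'   `codon_usage_comparison`, or an `lgt_pipeline_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name lgtscan-tidiers
NULL

#' @rdname lgtscan-tidiers
#' @export
tidy.lgt_te_test <- function(x, ...) {
  x$means %>%
    mutate(statistic = x$statistic, df = x$df, p.value = x$p.value,
           method = x$method)
}

#' @rdname lgtscan-tidiers
#' @export
glance.lgt_te_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         mean_lgt = x$means$mean[x$means$class == "LGT"],
         mean_other = x$means$mean[x$means$class == "Other"],
         method = x$method, low_expected = x$low_expected)
}

#' @rdname lgtscan-tidiers
#' @export
tidy.codon_usage_comparison <- function(x, ...) {
  x$per_codon
}

#' @rdname lgtscan-tidiers
#' @export
glance.codon_usage_comparison <- function(x, ...) {
  tibble(
    mean_fraction_diff = x$mean_fraction_diff,
    n_flagged_fraction = length(x$flagged_fraction),
    n_flagged_frequency = length(x$flagged_frequency)
  )
}

#' @rdname lgtscan-tidiers
#' @export
tidy.lgt_pipeline_result <- function(x, ...) {
  x$log
}

#' @rdname lgtscan-tidiers
#' @export
glance.lgt_pipeline_result <- function(x, ...) {
  out <- tibble(
    n_candidates = length(x$candidates),
    n_contaminants = length(x$contaminants),
    n_trees_supported = if (is.null(x$scan)) NA_integer_
                        else nrow(x$scan$per_tree)
  )
  dplyr::bind_cols(out, x$enumeration)
}
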