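#' Screen candidate LGT proteins against mobile-element proteins
#'
#' Two-stage filter over hits to a library of proteins borne by mobile
#' genetic elements (plasmids, prophages, bacterial viruses). The loose stage
#' keeps hits with e-value below `evalue_max` (the criterion defining the
#' study's 146-protein set); the strict stage additionally requires at least
#' 30% identity over at least half of both the query and the subject length
#' (the 32-protein criterion). Coverages are fractions in `[0, 1]`.
#'
#' @param hits Tibble with `query_id`, `subject_id`, `element_type`
#'   (`plasmid`, `prophage` or `virus`), `percent_identity`, `qcov`, `scov`,
#'   `evalue`.
#' @param stage `"loose"` or `"strict"`.
#' @param evalue_max E-value cut-off (strict inequality); the study's Methods
#'   state 0.001.
#' @param identity_min,qcov_min,scov_min Strict-stage thresholds (inclusive).
#' @return List with `passing` (filtered hit rows) and `best_hits` (one row
#'   per passing query: lowest e-value, ties broken by subject id).
#' @export
screen_mobile_hits <- function(hits, stage = c("strict", "loose"),
                               evalue_max = 0.001, identity_min = 30,
                               qcov_min = 0.5, scov_min = 0.5) {
  stage <- match.arg(stage)
  assert_columns(hits, c("query_id", "subject_id", "element_type",
                         "percent_identity", "qcov", "scov", "evalue"))
  if (any(hits$qcov < 0 | hits$qcov > 1 | hits$scov < 0 | hits$scov > 1)) {
    abort("coverages must be fractions in [0, 1]")
  }
  passing <- filter(hits, .data$evalue < evalue_max)
  if (stage == "strict") {
    passing <- filter(passing,
                      .data$percent_identity >= identity_min &
                        .data$qcov >= qcov_min & .data$scov >= scov_min)
  }
  best <- passing %>%
    group_by(.data$query_id) %>%
    arrange(.data$evalue, .data$subject_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  list(passing = passing, best_hits = best)
}

#' Element-type classification of mobile-element matches
#'
#' Each passing query is typed by the element carrying its best (lowest
#' e-value) hit, and the counts and percentages per element type are
#' reported.
#'
#' @param best_hits Per-query best-hit tibble from `screen_mobile_hits()`.
#' @return Tibble with `element_type`, `n`, `pct` covering plasmid, prophage
#'   and virus (zero rows included).
#' @export
classify_element_types <- function(best_hits) {
  types <- c("plasmid", "prophage", "virus")
  counts <- table(factor(best_hits$element_type, levels = types))
  total <- sum(counts)
  tibble(
    element_type = types,
    n = as.integer(counts),
    pct = if (total > 0) round_half_up(100 * as.integer(counts) / total, 1)
          else rep(NA_real_, length(types))
  )
}
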