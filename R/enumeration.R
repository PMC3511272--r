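#' Copy-number distributions of LGT genes
#'
#' The headline enumeration works on a distribution of copies-per-group (or
#' copies-per-tree): rows of (copies, number of groups, number of genes) plus
#' a count of unclustered singletons held separately. For exact copy buckets
#' the identity `n_genes == copies * n_groups` is enforced; the open `">8"`
#' bucket is exempt. Keeping singletons out of the rows preserves that
#' validation; display-shaped output merges them into the 1-copy row, the
#' convention used by the study's published table.
#'
#' @param rows Tibble with `copies` (integer-like or `">8"`), `n_groups`,
#'   `n_genes`.
#' @param singletons Number of unclustered single-copy genes.
#' @return Object of class `copy_distribution`.
#' @export
copy_distribution <- function(rows, singletons = 0L) {
  rows <- as_tibble(rows)
  assert_columns(rows, c("copies", "n_groups", "n_genes"))
  rows$copies <- as.character(rows$copies)
  if (any(rows$n_groups < 0) || any(rows$n_genes < 0) || singletons < 0) {
    abort("counts must be non-negative")
  }
  exact <- !rows$copies %in% ">8"
  k <- suppressWarnings(as.integer(rows$copies[exact]))
  if (anyNA(k)) abort("copies must be integers or '>8'")
  bad <- which(rows$n_genes[exact] != k * rows$n_groups[exact])
  if (length(bad) > 0) {
    abort(sprintf(
      "inconsistent bucket(s): copies %s have n_genes != copies * n_groups",
      paste(rows$copies[exact][bad], collapse = ", ")))
  }
  structure(list(rows = rows, singletons = as.integer(singletons)),
            class = "copy_distribution")
}

#' @rdname copy_distribution
#' @param copy_counts Integer vector of copies per group (or per tree);
#'   bucketed into 1..8 and ">8".
#' @export
copy_distribution_from_counts <- function(copy_counts, singletons = 0L) {
  copy_counts <- copy_counts[copy_counts > 0]
  bucket <- ifelse(copy_counts > 8, ">8", as.character(copy_counts))
  levels <- c(as.character(1:8), ">8")
  rows <- tibble(
    copies = levels,
    n_groups = as.integer(table(factor(bucket, levels = levels))),
    n_genes = vapply(levels, function(b) {
      as.integer(sum(copy_counts[bucket == b]))
    }, integer(1))
  ) %>% filter(.data$n_groups > 0)
  copy_distribution(rows, singletons)
}

#' @export
print.copy_distribution <- function(x, ...) {
  cat(sprintf("<copy_distribution> %d groups, %d grouped genes, %d singletons\n",
              sum(x$rows$n_groups), sum(x$rows$n_genes), x$singletons))
  print(x$rows)
  invisible(x)
}

#' @rdname copy_distribution
#' @param dist A `copy_distribution`.
#' @return `format_copy_distribution()`: display-shaped tibble with the
#'   singletons merged into the 1-copy gene count (table footnote
#'   convention) and a total row.
#' @export
format_copy_distribution <- function(dist) {
  stopifnot(inherits(dist, "copy_distribution"))
  rows <- dist$rows
  if (dist$singletons > 0) {
    if ("1" %in% rows$copies) {
      rows$n_genes[rows$copies == "1"] <-
        rows$n_genes[rows$copies == "1"] + dist$singletons
    } else {
      rows <- bind_rows(tibble(copies = "1", n_groups = 0L,
                               n_genes = dist$singletons), rows)
    }
  }
  bind_rows(rows, tibble(copies = "Total",
                         n_groups = sum(dist$rows$n_groups),
                         n_genes = total_lgt_genes(dist)))
}

#' Headline totals
#'
#' `total_lgt_genes()` counts all genes in a copy distribution including the
#' unclustered singletons; `total_phylo_supported()` counts genes over a
#' distribution built from per-tree copy numbers (no singleton bucket).
#' Both are linear under concatenation of distributions.
#'
#' @param dist A `copy_distribution`.
#' @return Integer total.
#' @export
total_lgt_genes <- function(dist) {
  stopifnot(inherits(dist, "copy_distribution"))
  as.integer(dist$singletons + sum(dist$rows$n_genes))
}

#' @rdname total_lgt_genes
#' @export
total_phylo_supported <- function(dist) {
  stopifnot(inherits(dist, "copy_distribution"))
  as.integer(sum(dist$rows$n_genes))
}

#' Percentage of a proteome
#'
#' `100 * n / proteome_size`, rounded half-up to two decimals — the precision
#' at which the study prints its proteome proportions.
#'
#' @param n Numerator count.
#' @param proteome_size Total protein-coding genes (> 0).
#' @return Percentage with 2 decimals.
#' @export
percent_of_proteome <- function(n, proteome_size) {
  if (any(proteome_size <= 0)) abort("proteome_size must be positive")
  round_half_up(100 * n / proteome_size, 2)
}

#' Duplication-cohort statistics
#'
#' Summarizes duplication-timing reports over the cohort of trees containing
#' genes from both nematodes: how many are duplicated (and the percentage of
#' the cohort), how many duplications started before the species split (as a
#' percentage of duplicated trees), and in how many of those duplications
#' also continued after the split (as a percentage of before-split trees).
#' Percentages are printed as integers, rounded half-up.
#'
#' @param reports Tibble of duplication reports with logical columns
#'   `both_species_present`, `duplicated`, `before_split`, `after_split`
#'   (e.g. `scan_gene_trees()$per_tree`). Alternatively pass the four
#'   `counts` directly.
#' @param counts Optional numeric vector
#'   `c(n_both_species, n_duplicated, n_before, n_after_given_before)`.
#' @return One-row tibble with the four counts and the three percentages
#'   (`pct_duplicated`, `pct_before`, `pct_after`).
#' @export
duplication_cohort_stats <- function(reports = NULL, counts = NULL) {
  if (is.null(counts)) {
    assert_columns(reports, c("both_species_present", "duplicated",
                              "before_split", "after_split"))
    cohort <- filter(reports, .data$both_species_present)
    counts <- c(
      nrow(cohort),
      sum(cohort$duplicated),
      sum(cohort$before_split),
      sum(cohort$after_split & cohort$before_split)
    )
  }
  if (length(counts) != 4) {
    abort("counts must be c(n_both_species, n_duplicated, n_before, n_after_given_before)")
  }
  n_both <- counts[1]; n_dup <- counts[2]
  n_before <- counts[3]; n_after <- counts[4]
  pct <- function(num, den) {
    if (den > 0) round_half_up(100 * num / den) else NA_real_
  }
  tibble(
    n_both_species = as.integer(n_both),
    n_duplicated = as.integer(n_dup),
    pct_duplicated = pct(n_dup, n_both),
    n_before = as.integer(n_before),
    pct_before = pct(n_before, n_dup),
    n_after_given_before = as.integer(n_after),
    pct_after = pct(n_after, n_before)
  )
}
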