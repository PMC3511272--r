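#' Clusters of LGT genes on scaffolds
#'
#' Single-linkage chaining of LGT-flagged genes along each scaffold: two
#' consecutive LGT genes (by start coordinate) belong to the same chain when
#' the gap between them — bp between the end of one and the start of the next
#' (`next_start - prev_end - 1`, negative gaps from overlapping models
#' clamped to 0) — is strictly less than `max_gap`. Chains of at least
#' `min_size` genes are reported.
#'
#' @param genes Tibble with `gene_id`, `scaffold_id`, `start`, `end`,
#'   `is_lgt` (1-based inclusive coordinates, GFF3 convention).
#' @param max_gap Maximum separation in bp (strict), default 50 kb.
#' @param min_size Minimum genes per reported cluster, default 3.
#' @return Tibble with one row per cluster: `cluster_id`, `scaffold_id`,
#'   `size`, `start`, `end` and list column `gene_ids` (ordered along the
#'   scaffold).
#' @export
detect_lgt_clusters <- function(genes, max_gap = 50000, min_size = 3) {
  assert_columns(genes, c("gene_id", "scaffold_id", "start", "end", "is_lgt"))
  lgt <- genes %>%
    filter(.data$is_lgt) %>%
    arrange(.data$scaffold_id, .data$start, .data$end, .data$gene_id)
  if (nrow(lgt) == 0) {
    return(tibble(cluster_id = character(0), scaffold_id = character(0),
                  size = integer(0), start = integer(0), end = integer(0),
                  gene_ids = list()))
  }
  lgt <- lgt %>%
    group_by(.data$scaffold_id) %>%
    mutate(gap = pmax(.data$start - lag(.data$end) - 1, 0),
           new_chain = is.na(.data$gap) | .data$gap >= max_gap,
           chain = cumsum(.data$new_chain)) %>%
    ungroup()
  clusters <- lgt %>%
    group_by(.data$scaffold_id, .data$chain) %>%
    summarise(size = n(), start = min(.data$start), end = max(.data$end),
              gene_ids = list(.data$gene_id), .groups = "drop") %>%
    filter(.data$size >= min_size) %>%
    arrange(.data$scaffold_id, .data$start) %>%
    mutate(cluster_id = sprintf("cluster_%03d", row_number())) %>%
    select("cluster_id", "scaffold_id", "size", "start", "end", "gene_ids")
  clusters
}

#' Transposable elements in gene-flanking windows
#'
#' Counts, for each gene, the transposable elements overlapping (by at least
#' 1 bp) the union of its two flanking windows `[start - window, start - 1]`
#' and `[end + 1, end + window]`, clipped at scaffold bounds. A TE touching
#' both flanks of a short gene counts once; a TE overlapping the gene body
#' counts if it also reaches a flank.
#'
#' @param genes Gene tibble (`gene_id`, `scaffold_id`, `start`, `end`, and
#'   `is_lgt` carried through if present).
#' @param tes TE tibble (`te_id`, `scaffold_id`, `start`, `end`).
#' @param scaffolds Tibble with `scaffold_id`, `length`.
#' @param window Flank width in bp; the study used 200, 500, 1000, 2000.
#' @return The gene tibble with an added integer column `n_te`.
#' @export
count_te_in_windows <- function(genes, tes, scaffolds, window) {
  assert_columns(genes, c("gene_id", "scaffold_id", "start", "end"))
  assert_columns(tes, c("te_id", "scaffold_id", "start", "end"))
  assert_columns(scaffolds, c("scaffold_id", "length"))
  g <- genes %>%
    left_join(scaffolds, by = "scaffold_id") %>%
    mutate(
      lf_start = pmax(.data$start - window, 1),
      lf_end = .data$start - 1,
      rf_start = .data$end + 1,
      rf_end = pmin(.data$end + window, .data$length)
    )
  count_one <- function(i) {
    t <- tes[tes$scaffold_id == g$scaffold_id[i], , drop = FALSE]
    if (nrow(t) == 0) return(0L)
    in_left <- g$lf_end[i] >= g$lf_start[i] &
      t$start <= g$lf_end[i] & t$end >= g$lf_start[i]
    in_right <- g$rf_end[i] >= g$rf_start[i] &
      t$start <= g$rf_end[i] & t$end >= g$rf_start[i]
    length(unique(t$te_id[in_left | in_right]))
  }
  genes$n_te <- vapply(seq_len(nrow(g)), count_one, integer(1))
  genes
}

#' Compare TE density around LGT genes and other genes
#'
#' The study reports a chi-square statistic with one degree of freedom per
#' window size; the test implemented here is the 2x2 contingency of gene
#' class (LGT vs other) against TE presence in the flanks (at least one TE
#' vs none), without continuity correction, which is the only 2x2 reading
#' consistent with df = 1. An alternative construction contrasting total TE
#' counts with gene counts per class is available as `method =
#' "count_total"`. Per-class means and standard errors of the TE counts are
#' reported alongside.
#'
#' @param lgt_counts,other_counts Integer vectors of per-gene TE counts for
#'   the two classes.
#' @param method `"presence"` (default) or `"count_total"`.
#' @return An object of class `lgt_te_test`: statistic, df, p.value, a
#'   per-class summary tibble (n, mean, se), the contingency table and a
#'   low-expected-count warning flag. `tidy()` and `glance()` methods are
#'   provided.
#' @export
compare_te_density <- function(lgt_counts, other_counts,
                               method = c("presence", "count_total")) {
  method <- match.arg(method)
  if (length(lgt_counts) == 0 || length(other_counts) == 0) {
    abort("both count vectors must be non-empty")
  }
  if (method == "presence") {
    tab <- rbind(
      LGT = c(with_te = sum(lgt_counts >= 1), without_te = sum(lgt_counts == 0)),
      Other = c(with_te = sum(other_counts >= 1),
                without_te = sum(other_counts == 0))
    )
  } else {
    tab <- rbind(
      LGT = c(te_total = sum(lgt_counts), genes = length(lgt_counts)),
      Other = c(te_total = sum(other_counts), genes = length(other_counts))
    )
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low_expected <- any(expected < 1)
  if (identical(lgt_counts, other_counts) || all(tab[1, ] == tab[2, ]) ||
      any(colSums(tab) == 0)) {
    # degenerate identical distributions: statistic 0 by definition
    stat <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  means <- tibble(
    class = c("LGT", "Other"),
    n = c(length(lgt_counts), length(other_counts)),
    mean = c(mean(lgt_counts), mean(other_counts)),
    se = c(sd(lgt_counts) / sqrt(length(lgt_counts)),
           sd(other_counts) / sqrt(length(other_counts)))
  )
  structure(
    list(statistic = stat, df = 1L, p.value = p, means = means,
         table = tab, method = method, low_expected = low_expected),
    class = "lgt_te_test"
  )
}

#' @export
print.lgt_te_test <- function(x, ...) {
  cat(sprintf("TE-density comparison (%s, X^2 df=1): statistic %.3f, p %.4g\n",
              x$method, x$statistic, x$p.value))
  print(x$means)
  if (x$low_expected) cat("warning: an expected cell count is < 1\n")
  invisible(x)
}

#' Table-3-shaped TE density report
#'
#' Runs `count_te_in_windows()` and `compare_te_density()` for each window
#' size and stacks the results into the layout of the study's TE-density
#' table: window, class, mean, SE, statistic, p.
#'
#' @inheritParams count_te_in_windows
#' @param windows Window sizes in bp.
#' @param method Passed to `compare_te_density()`.
#' @return Tibble with columns `window`, `class`, `n`, `mean`, `se`,
#'   `statistic`, `df`, `p.value`.
#' @export
te_density_report <- function(genes, tes, scaffolds,
                              windows = c(200, 500, 1000, 2000),
                              method = "presence") {
  bind_rows(lapply(windows, function(w) {
    counted <- count_te_in_windows(genes, tes, scaffolds, w)
    test <- compare_te_density(counted$n_te[counted$is_lgt],
                               counted$n_te[!counted$is_lgt],
                               method = method)
    test$means %>%
      mutate(window = w, statistic = test$statistic, df = test$df,
             p.value = test$p.value) %>%
      select("window", "class", "n", "mean", "se", "statistic", "df",
             "p.value")
  }))
}

#' Relative position of genes on scaffolds
#'
#' Distance of the gene midpoint to the nearest scaffold end, divided by the
#' scaffold length: 0 at a scaffold tip, 0.5 at the center. Used to ask
#' whether LGT genes pile up at scaffold ends.
#'
#' @inheritParams count_te_in_windows
#' @return The gene tibble with an added `rel_end_position` column in
#'   `[0, 0.5]`.
#' @export
scaffold_end_positions <- function(genes, scaffolds) {
  assert_columns(genes, c("gene_id", "scaffold_id", "start", "end"))
  genes %>%
    left_join(scaffolds, by = "scaffold_id") %>%
    mutate(mid = (.data$start + .data$end) / 2,
           rel_end_position = pmin(.data$mid, .data$length - .data$mid + 1) /
             .data$length) %>%
    select(-"mid", -"length")
}

#' @rdname scaffold_end_positions
#' @param n_bins Number of equal-width bins over `[0, 0.5]` for the
#'   chi-square comparison of binned position distributions (LGT vs other).
#' @return `compare_scaffold_end_positions()`: list with the binned
#'   contingency table, `statistic`, `df`, `p.value`.
#' @export
compare_scaffold_end_positions <- function(genes, scaffolds, n_bins = 5) {
  pos <- scaffold_end_positions(genes, scaffolds)
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  bin <- cut(pmin(pos$rel_end_position, 0.5), breaks, include.lowest = TRUE)
  tab <- table(ifelse(pos$is_lgt, "LGT", "Other"), bin)
  ct <- suppressWarnings(stats::chisq.test(tab))
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p.value = unname(ct$p.value))
}
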