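#' Exact-duplicate removal among proteins
#'
#' Within each set of proteins whose sequences are exactly identical
#' (full-length string identity, no substring containment), a single
#' representative is kept. Identical sequences necessarily share one length,
#' so the representative is the lexicographically smallest protein id; the
#' tie-break keeps runs reproducible.
#'
#' @param proteins Tibble with `protein_id`, `species`, `length`, `sequence`.
#' @return The input tibble with two added columns: `representative_id` (the
#'   surviving id for the record's sequence) and `is_representative`. Filter
#'   on `is_representative` for the non-redundant set.
#' @export
dedup_exact <- function(proteins) {
  assert_columns(proteins, c("protein_id", "sequence"))
  if (anyNA(proteins$sequence) || any(!nzchar(proteins$sequence))) {
    bad <- proteins$protein_id[is.na(proteins$sequence) |
                                 !nzchar(proteins$sequence)]
    abort(sprintf("missing sequence for protein(s): %s",
                  paste(bad, collapse = ", ")))
  }
  proteins %>%
    group_by(.data$sequence) %>%
    mutate(representative_id = min(.data$protein_id)) %>%
    ungroup() %>%
    mutate(is_representative = .data$protein_id == .data$representative_id)
}

#' Restriction of ortholog groups to the focal nematodes
#'
#' Groups containing any member outside the focal species (and optionally an
#' allowance list of other plant-parasitic nematode tags) are discarded: a
#' focal protein clustering with another metazoan species is taken as
#' evidence of vertical descent. Focal proteins belonging to no group at all
#' are reported separately as singletons.
#'
#' @param groups Tidy membership tibble (`group_id`, `species`, `protein_id`).
#' @param focal_species Species tags of the two root-knot nematodes,
#'   by default `c("Minc", "Mhap")`.
#' @param ppn_ok Additional species tags allowed inside a restricted group.
#' @param proteins Optional protein tibble; when given, focal proteins absent
#'   from every group are returned as `singletons`.
#' @param known_species Species tags considered resolvable. Defaults to all
#'   tags seen in `groups` plus `focal_species`; pass explicitly to catch
#'   typos in group files.
#' @return List with `groups` (memberships of retained groups),
#'   `discarded_group_ids`, and `singletons` (character vector of focal
#'   protein ids in no group; empty if `proteins` is `NULL`).
#' @export
select_restricted_groups <- function(groups,
                                     focal_species = c("Minc", "Mhap"),
                                     ppn_ok = character(),
                                     proteins = NULL,
                                     known_species = NULL) {
  assert_columns(groups, c("group_id", "species", "protein_id"))
  if (!is.null(known_species)) {
    unknown <- setdiff(unique(groups$species), known_species)
    if (length(unknown) > 0) {
      abort(sprintf("unknown species tag(s) in groups: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  allowed <- c(focal_species, ppn_ok)
  status <- groups %>%
    group_by(.data$group_id) %>%
    summarise(restricted = all(.data$species %in% allowed),
              has_focal = any(.data$species %in% focal_species),
              .groups = "drop")
  keep_ids <- status$group_id[status$restricted & status$has_focal]
  singletons <- character(0)
  if (!is.null(proteins)) {
    focal <- proteins$protein_id[proteins$species %in% focal_species]
    singletons <- sort(setdiff(focal, groups$protein_id))
  }
  list(
    groups = filter(groups, .data$group_id %in% keep_ids),
    discarded_group_ids = sort(setdiff(status$group_id, keep_ids)),
    singletons = singletons
  )
}

#' Representative protein of a restricted group
#'
#' The longest M. incognita member is the group's reference; groups with no
#' M. incognita member fall back to the longest M. hapla member. Length ties
#' break to the lexicographically smallest id.
#'
#' @param members Tibble of one group's members with `protein_id`, `species`,
#'   `length`.
#' @param primary,secondary Species tags tried in order.
#' @return One-row tibble (the representative member).
#' @export
choose_representative <- function(members, primary = "Minc",
                                  secondary = "Mhap") {
  assert_columns(members, c("protein_id", "species", "length"))
  pool <- filter(members, .data$species == primary)
  if (nrow(pool) == 0) pool <- filter(members, .data$species == secondary)
  if (nrow(pool) == 0) {
    abort(sprintf("group has neither %s nor %s member", primary, secondary))
  }
  pool %>%
    arrange(dplyr::desc(.data$length), .data$protein_id) %>%
    slice(1)
}

#' @rdname choose_representative
#' @param groups Tidy membership tibble.
#' @param proteins Protein tibble supplying lengths.
#' @return `choose_representatives()`: tibble with one row per group
#'   (`group_id` plus the representative's columns).
#' @export
choose_representatives <- function(groups, proteins, primary = "Minc",
                                   secondary = "Mhap") {
  joined <- groups %>%
    left_join(select(proteins, "protein_id", "length"), by = "protein_id")
  if (anyNA(joined$length)) {
    abort("some group members have no matching protein record")
  }
  joined %>%
    group_by(.data$group_id) %>%
    dplyr::group_modify(~ choose_representative(.x, primary, secondary)) %>%
    ungroup()
}

#' BLAST-filter configuration
#'
#' Thresholds of the non-metazoan top-hit vote and contamination filter.
#' Defaults are the study values: e-value cut-off 0.01, alignment covering at
#' least 30% of the query, vote over the 10 best hits with candidate status at
#' a non-metazoan fraction of at least 0.50, contaminant at more than 80%
#' identity over more than half of the query.
#'
#' @param evalue_max Maximum e-value for a hit to count.
#' @param qcov_min Minimum aligned fraction of the query length.
#' @param top_n Size of the best-hit window voted over.
#' @param vote_min Minimum non-metazoan fraction for candidate status
#'   (inclusive).
#' @param ppn_mode How plant-parasitic-nematode (and self) hits are excluded:
#'   `"skip"` removes them before the top-`top_n` window is taken (default,
#'   so the vote is over `top_n` informative hits when available);
#'   `"window"` takes the window first and drops PPN hits from both the
#'   numerator and the denominator afterwards.
#' @param contaminant_identity_min Identity (%) a hit must exceed (strictly)
#'   to flag contamination.
#' @param contaminant_qcov_min Query-length fraction a hit must exceed
#'   (strictly) to flag contamination.
#' @export
blast_filter_config <- function(evalue_max = 0.01, qcov_min = 0.30,
                                top_n = 10, vote_min = 0.50,
                                ppn_mode = c("skip", "window"),
                                contaminant_identity_min = 80,
                                contaminant_qcov_min = 0.5) {
  list(evalue_max = evalue_max, qcov_min = qcov_min, top_n = top_n,
       vote_min = vote_min, ppn_mode = match.arg(ppn_mode),
       contaminant_identity_min = contaminant_identity_min,
       contaminant_qcov_min = contaminant_qcov_min)
}

rank_hits <- function(hits) {
  ord <- if ("bitscore" %in% names(hits) && !all(is.na(hits$bitscore))) {
    order(hits$evalue, -hits$bitscore, hits$subject_id)
  } else {
    order(hits$evalue, hits$subject_id)
  }
  hits[ord, , drop = FALSE]
}

#' Non-metazoan BLAST vote
#'
#' For each query, hits failing the e-value or query-coverage thresholds are
#' dropped, hits to plant-parasitic nematodes (which include the two focal
#' species themselves) are excluded from the metazoan count, and the query is
#' called a candidate LGT when the fraction of non-metazoan (non-eumetazoan)
#' subjects among its `top_n` best remaining hits is at least `vote_min`.
#' Queries with fewer than `top_n` surviving hits are voted over the
#' available survivors; queries with none are reported as `no_hit` and are
#' dropped from the analysis downstream.
#'
#' @param hits BLAST hit tibble (`query_id`, `subject_id`, `subject_taxid`,
#'   `percent_identity`, `align_length_on_query`, `evalue`, optional
#'   `bitscore`).
#' @param proteins Protein tibble supplying `length` per query.
#' @param tax An `lgt_taxonomy`.
#' @param cfg A `blast_filter_config()`.
#' @return Tibble with one row per query: `query_id`, `status`
#'   (`"candidate"`, `"rejected"` or `"no_hit"`), `vote_fraction`,
#'   `n_hits_used`, `n_non_metazoan`, `reason`.
#' @export
vote_non_metazoan <- function(hits, proteins, tax,
                              cfg = blast_filter_config()) {
  assert_columns(hits, c("query_id", "subject_id", "subject_taxid",
                         "percent_identity", "align_length_on_query",
                         "evalue"))
  qlen <- setNames(proteins$length, proteins$protein_id)
  queries <- unique(c(hits$query_id, proteins$protein_id[
    proteins$protein_id %in% hits$query_id]))

  taxids <- unique(hits$subject_taxid)
  ppn_flag <- setNames(is_ppn(tax, taxids), taxids)
  met_flag <- setNames(is_eumetazoan(tax, taxids), taxids)

  decide <- function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    ql <- qlen[[q]]
    if (is.null(ql) || is.na(ql)) {
      abort(sprintf("no length known for query %s", q))
    }
    h <- h[h$evalue <= cfg$evalue_max &
             h$align_length_on_query >= cfg$qcov_min * ql, , drop = FALSE]
    if (nrow(h) == 0) {
      return(tibble(query_id = q, status = "no_hit",
                    vote_fraction = NA_real_, n_hits_used = 0L,
                    n_non_metazoan = 0L,
                    reason = "no hit passing e-value/coverage thresholds"))
    }
    h <- rank_hits(h)
    ppn <- ppn_flag[as.character(h$subject_taxid)]
    if (cfg$ppn_mode == "skip") {
      h <- h[!ppn, , drop = FALSE]
      h <- head(h, cfg$top_n)
    } else {
      h <- head(h, cfg$top_n)
      h <- h[!ppn_flag[as.character(h$subject_taxid)], , drop = FALSE]
    }
    if (nrow(h) == 0) {
      return(tibble(query_id = q, status = "no_hit",
                    vote_fraction = NA_real_, n_hits_used = 0L,
                    n_non_metazoan = 0L,
                    reason = "only PPN/self hits survived"))
    }
    non_met <- !met_flag[as.character(h$subject_taxid)]
    frac <- mean(non_met)
    cand <- frac >= cfg$vote_min
    tibble(query_id = q,
           status = if (cand) "candidate" else "rejected",
           vote_fraction = frac, n_hits_used = nrow(h),
           n_non_metazoan = sum(non_met),
           reason = sprintf("%d/%d non-metazoan hits",
                            sum(non_met), nrow(h)))
  }
  bind_rows(lapply(unique(hits$query_id), decide))
}

#' Contamination flag
#'
#' A query is flagged as a likely contaminant when any non-metazoan hit shows
#' more than 80% identity over more than half of the query length (both
#' strict inequalities): such near-identity is far above what an ancient
#' transfer would retain and matches the BLAST profile of assembled
#' contaminating sequence.
#'
#' @inheritParams vote_non_metazoan
#' @return Tibble with `query_id` and logical `contaminant` for every query
#'   appearing in `hits`.
#' @export
flag_contaminants <- function(hits, proteins, tax,
                              cfg = blast_filter_config()) {
  assert_columns(hits, c("query_id", "subject_taxid", "percent_identity",
                         "align_length_on_query"))
  qlen <- setNames(proteins$length, proteins$protein_id)
  taxids <- unique(hits$subject_taxid)
  met_flag <- setNames(is_eumetazoan(tax, taxids), taxids)
  hits %>%
    mutate(
      qlen = unname(qlen[.data$query_id]),
      strong = !met_flag[as.character(.data$subject_taxid)] &
        .data$percent_identity > cfg$contaminant_identity_min &
        .data$align_length_on_query > cfg$contaminant_qcov_min * .data$qlen
    ) %>%
    group_by(.data$query_id) %>%
    summarise(contaminant = any(.data$strong), .groups = "drop")
}

#' In-paralog counts from ortholog groups
#'
#' Per group, counts of M. incognita and M. hapla members and a duplication
#' classification. A group represents a species-specific (lineage-specific)
#' duplication when it holds at least three M. incognita or at least two
#' M. hapla genes; the asymmetric threshold corrects for the duplicated
#' structure of the M. incognita genome, and for the same reason 2:1
#' (Minc:Mhap) groups are discarded from the duplicated set rather than
#' counted.
#'
#' @param groups Tidy membership tibble.
#' @param lgt_ids Optional set of protein ids called LGT candidates; when
#'   given, the summary is also reported for groups containing at least one
#'   of them.
#' @param minc,mhap Species tags of the two focal nematodes.
#' @return List with `per_group` (group_id, n_minc, n_mhap, class) and
#'   `summary` (class counts, overall and for the LGT subset).
#'   Classes: `species-specific-duplication`, `discarded-2:1`,
#'   `not-duplicated`.
#' @export
count_inparalog_groups <- function(groups, lgt_ids = NULL,
                                   minc = "Minc", mhap = "Mhap") {
  assert_columns(groups, c("group_id", "species", "protein_id"))
  per_group <- groups %>%
    group_by(.data$group_id) %>%
    summarise(
      n_minc = sum(.data$species == minc),
      n_mhap = sum(.data$species == mhap),
      has_lgt = if (is.null(lgt_ids)) FALSE else
        any(.data$protein_id %in% lgt_ids),
      .groups = "drop"
    ) %>%
    mutate(class = case_when(
      .data$n_minc >= 3 | .data$n_mhap >= 2 ~ "species-specific-duplication",
      .data$n_minc == 2 & .data$n_mhap == 1 ~ "discarded-2:1",
      TRUE ~ "not-duplicated"
    ))
  summary <- per_group %>%
    count(.data$class, name = "n_groups_genome")
  if (!is.null(lgt_ids)) {
    lgt_summary <- per_group %>%
      filter(.data$has_lgt) %>%
      count(.data$class, name = "n_groups_lgt")
    summary <- left_join(summary, lgt_summary, by = "class") %>%
      mutate(n_groups_lgt = tidyr::replace_na(.data$n_groups_lgt, 0L))
  }
  list(per_group = per_group, summary = summary)
}
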