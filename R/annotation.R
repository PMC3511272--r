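#' GO terms from Pfam domain composition
#'
#' Assigns each protein the union of the GO terms mapped to its Pfam domains.
#' Proteins all of whose domains lack a mapping end up with an empty term set
#' and are tallied in the `unmapped_proteins` attribute.
#'
#' @param assignments Tibble with `protein_id`, `domain_id` (Pfam accession).
#' @param pfam2go Tibble with `domain_id`, `go_id` (see `read_pfam2go()`).
#' @return Tibble with distinct (`protein_id`, `go_id`) rows; attribute
#'   `unmapped_proteins` lists proteins with domains but no terms.
#' @export
pfam_to_go <- function(assignments, pfam2go) {
  assert_columns(assignments, c("protein_id", "domain_id"))
  assert_columns(pfam2go, c("domain_id", "go_id"))
  mapped <- assignments %>%
    inner_join(pfam2go, by = "domain_id",
               relationship = "many-to-many") %>%
    distinct(.data$protein_id, .data$go_id)
  unmapped <- setdiff(unique(assignments$protein_id), mapped$protein_id)
  attr(mapped, "unmapped_proteins") <- unmapped
  mapped
}

#' GO DAG from an is_a edge table
#'
#' Builds a validated directed acyclic graph of GO terms from a tabular
#' child-to-parent edge list (multiple parents allowed; `part_of` edges may
#' be merged into the table upstream and are then treated like `is_a`).
#'
#' @param edges Tibble with `term`, `parent` (`NA` for namespace roots) and
#'   `namespace` (one of biological_process, molecular_function,
#'   cellular_component).
#' @return Object of class `go_dag` with precomputed ancestor sets.
#' @export
go_dag <- function(edges) {
  assert_columns(edges, c("term", "parent", "namespace"))
  edges <- as_tibble(edges)
  terms <- unique(edges$term)
  unknown_parents <- setdiff(stats::na.omit(unique(edges$parent)), terms)
  if (length(unknown_parents) > 0) {
    abort(sprintf("edge parent(s) not defined as terms: %s",
                  paste(unknown_parents, collapse = ", ")))
  }
  parents_of <- lapply(split(edges$parent, edges$term), function(p) {
    unique(p[!is.na(p)])
  })
  # ancestors by memoized DFS; cycle detection on the stack
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(t, stack = character(0)) {
    if (t %in% stack) abort(sprintf("cycle in GO DAG at term %s", t))
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    ps <- parents_of[[t]]
    out <- unique(c(ps, unlist(lapply(ps, ancestors, stack = c(stack, t)))))
    anc_cache[[t]] <- out
    out
  }
  anc <- lapply(terms, ancestors)
  names(anc) <- terms
  ns <- edges %>% distinct(.data$term, .data$namespace)
  structure(
    list(edges = edges, terms = terms, ancestors = anc,
         namespace = setNames(ns$namespace, ns$term)),
    class = "go_dag"
  )
}

#' @rdname go_dag
#' @param dag A `go_dag`.
#' @param term A single term id.
#' @return `go_ancestors()`: character vector of (strict) ancestors.
#' @export
go_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  a <- dag$ancestors[[term]]
  if (is.null(a)) character(0) else a
}

#' Project GO terms onto a GO slim
#'
#' Maps each term to its slim ancestors within the DAG. A term already in the
#' slim maps to itself. With `mode = "most_specific"` (default) only the
#' minimal slim ancestors are kept: a slim ancestor is dropped when another
#' slim ancestor of the same term descends from it. `mode = "all"` keeps
#' every slim ancestor, mirroring bucket-style slim mappers. The result is
#' the union over the input terms; terms absent from the DAG (or with no
#' slim ancestor) are tallied in the `unmappable` attribute.
#'
#' @param terms Character vector of GO term ids.
#' @param dag A `go_dag`.
#' @param slim Character vector of slim term ids (subset of the DAG).
#' @param mode `"most_specific"` or `"all"`.
#' @return Character vector of slim terms (sorted, unique), with attribute
#'   `unmappable`.
#' @export
map_to_slim <- function(terms, dag, slim,
                        mode = c("most_specific", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dag, "go_dag"))
  bad_slim <- setdiff(slim, dag$terms)
  if (length(bad_slim) > 0) {
    abort(sprintf("slim term(s) absent from DAG: %s",
                  paste(bad_slim, collapse = ", ")))
  }
  unmappable <- character(0)
  mapped <- lapply(unique(terms), function(t) {
    if (!t %in% dag$terms) {
      unmappable <<- c(unmappable, t)
      return(character(0))
    }
    if (t %in% slim) return(t)
    anc_slim <- intersect(go_ancestors(dag, t), slim)
    if (length(anc_slim) == 0) {
      unmappable <<- c(unmappable, t)
      return(character(0))
    }
    if (mode == "all") return(anc_slim)
    keep <- vapply(anc_slim, function(s) {
      # drop s when another slim ancestor of t descends from it
      !any(vapply(setdiff(anc_slim, s), function(s2) {
        s %in% go_ancestors(dag, s2)
      }, logical(1)))
    }, logical(1))
    anc_slim[keep]
  })
  out <- sort(unique(unlist(mapped)))
  attr(out, "unmappable") <- unique(unmappable)
  out
}

#' @rdname map_to_slim
#' @param annotations Tibble with `protein_id`, `go_id`.
#' @return `map_annotations_to_slim()`: tibble of distinct
#'   (`protein_id`, `go_id`) rows with `go_id` in the slim.
#' @export
map_annotations_to_slim <- function(annotations, dag, slim,
                                    mode = c("most_specific", "all")) {
  assert_columns(annotations, c("protein_id", "go_id"))
  mode <- match.arg(mode)
  by_protein <- split(annotations$go_id, annotations$protein_id)
  rows <- lapply(names(by_protein), function(p) {
    slim_terms <- map_to_slim(by_protein[[p]], dag, slim, mode)
    if (length(slim_terms) == 0) return(NULL)
    tibble(protein_id = p, go_id = as.character(slim_terms))
  })
  distinct(bind_rows(rows))
}

#' Compare GO-slim term distributions between protein sets
#'
#' For each namespace and term, the percentage of annotated proteins carrying
#' the term in each set, the absolute difference and the difference rank.
#' Percentages are computed over proteins with at least one term in that
#' namespace and set — the "of annotated proteins" denominator — never over
#' whole proteomes, and a protein counts once per term however many original
#' terms collapsed onto it. No statistical test is attached: the comparison
#' is descriptive, ranking the most deviating terms.
#'
#' @param set_a,set_b Tibbles with `protein_id`, `go_id` (slim annotations;
#'   conventionally A = LGT set, B = whole proteome).
#' @param dag A `go_dag`, supplying each term's namespace.
#' @return Tibble with `namespace`, `go_id`, `n_a`, `pct_a`, `n_b`, `pct_b`,
#'   `diff`, and `rank` of the difference within the namespace.
#' @export
compare_go_distributions <- function(set_a, set_b, dag) {
  assert_columns(set_a, c("protein_id", "go_id"))
  assert_columns(set_b, c("protein_id", "go_id"))
  add_ns <- function(df) {
    mutate(df, namespace = unname(dag$namespace[.data$go_id]))
  }
  a <- add_ns(distinct(set_a))
  b <- add_ns(distinct(set_b))
  denom_a <- a %>% group_by(.data$namespace) %>%
    summarise(d_a = n_distinct(.data$protein_id), .groups = "drop")
  denom_b <- b %>% group_by(.data$namespace) %>%
    summarise(d_b = n_distinct(.data$protein_id), .groups = "drop")
  count_a <- a %>% count(.data$namespace, .data$go_id, name = "n_a")
  count_b <- b %>% count(.data$namespace, .data$go_id, name = "n_b")
  dplyr::full_join(count_a, count_b, by = c("namespace", "go_id")) %>%
    mutate(n_a = tidyr::replace_na(.data$n_a, 0L),
           n_b = tidyr::replace_na(.data$n_b, 0L)) %>%
    left_join(denom_a, by = "namespace") %>%
    left_join(denom_b, by = "namespace") %>%
    mutate(pct_a = 100 * .data$n_a / .data$d_a,
           pct_b = 100 * .data$n_b / .data$d_b,
           diff = abs(.data$pct_a - .data$pct_b)) %>%
    group_by(.data$namespace) %>%
    mutate(rank = rank(-.data$diff, ties.method = "first")) %>%
    ungroup() %>%
    arrange(.data$namespace, .data$rank) %>%
    select("namespace", "go_id", "n_a", "pct_a", "n_b", "pct_b", "diff",
           "rank")
}
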