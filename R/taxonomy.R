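#' Taxonomy trees and lineage queries
#'
#' The pipeline classifies every BLAST subject and every gene-tree leaf by its
#' position in an NCBI-style taxonomy: a table of nodes with integer taxids and
#' parent links. `lgt_taxonomy()` builds a validated taxonomy object from such
#' a table; `load_taxonomy()` reads one from a tab-separated file.
#'
#' Division labels (Bacteria, Archaea, Fungi, Plant, Metazoa, Protist, Other)
#' are resolved by walking from a taxon towards the root and stopping at the
#' nearest configured "anchor" taxid. Eukaryotes whose lineage carries no more
#' specific anchor fall back to Protist, which is deliberately not a
#' monophyletic label; non-eukaryotes without an anchor (e.g. viruses) are
#' labelled Other, never Protist.
#'
#' @param nodes A data frame with columns `taxid`, `parent_taxid`, `name` and
#'   optionally `rank` and `division`. The root is the single node whose
#'   parent equals itself (or is `NA`).
#' @param anchors Named integer vector mapping division labels to anchor
#'   taxids. The default follows NCBI: Bacteria 2, Archaea 2157, Fungi 4751,
#'   Plant 33090 (Viridiplantae), Metazoa 33208, with Eukaryota 2759 as the
#'   Protist fallback.
#' @param ppn_taxids Taxids whose descendants count as plant-parasitic
#'   nematodes (PPN): Tylenchida 6300, Triplonchida 211184, Dorylaimina
#'   211225 by default.
#' @param eumetazoa_taxid Taxid anchoring the metazoan-hit test (Eumetazoa,
#'   6072).
#' @return An object of class `lgt_taxonomy`.
#' @examples
#' tax <- lgt_taxonomy(tibble::tibble(
#'   taxid = c(1, 2759, 6072, 6300, 2),
#'   parent_taxid = c(1, 1, 2759, 6072, 1),
#'   name = c("root", "Eukaryota", "Eumetazoa", "Tylenchida", "Bacteria")
#' ))
#' is_descendant(tax, 6300, 6072)
#' @export
lgt_taxonomy <- function(nodes,
                         anchors = default_division_anchors(),
                         ppn_taxids = c(6300L, 211184L, 211225L),
                         eumetazoa_taxid = 6072L) {
  nodes <- as_tibble(nodes)
  assert_columns(nodes, c("taxid", "parent_taxid", "name"), "nodes")
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent_taxid <- as.integer(nodes$parent_taxid)

  dup <- nodes$taxid[duplicated(nodes$taxid)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate taxid(s): %s", paste(unique(dup), collapse = ", ")))
  }
  is_root <- is.na(nodes$parent_taxid) | nodes$parent_taxid == nodes$taxid
  if (sum(is_root) != 1) {
    abort(sprintf("taxonomy must have exactly one root, found %d", sum(is_root)))
  }
  orphan <- setdiff(nodes$parent_taxid[!is_root], nodes$taxid)
  if (length(orphan) > 0) {
    abort(sprintf("parent taxid(s) absent from table (orphan links): %s",
                  paste(orphan, collapse = ", ")))
  }

  parent <- setNames(nodes$parent_taxid, nodes$taxid)
  parent[is_root] <- NA_integer_

  # Cycle check: every node must reach the root.
  root <- nodes$taxid[is_root]
  for (t in nodes$taxid) {
    seen <- integer(0)
    cur <- t
    while (!is.na(parent[[as.character(cur)]])) {
      if (cur %in% seen) abort(sprintf("cycle in parent links at taxid %d", cur))
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }

  structure(
    list(
      nodes = nodes,
      parent = parent,
      root = root,
      anchors = anchors,
      ppn_taxids = as.integer(ppn_taxids),
      eumetazoa_taxid = as.integer(eumetazoa_taxid)
    ),
    class = "lgt_taxonomy"
  )
}

#' @rdname lgt_taxonomy
#' @export
default_division_anchors <- function() {
  c(Bacteria = 2L, Archaea = 2157L, Fungi = 4751L, Plant = 33090L,
    Metazoa = 33208L)
}

#' @rdname lgt_taxonomy
#' @param path Tab-separated file with columns taxid, parent_taxid, name and
#'   optionally rank and division.
#' @param ... Passed on to `lgt_taxonomy()`.
#' @export
load_taxonomy <- function(path, ...) {
  nodes <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  lgt_taxonomy(nodes, ...)
}

#' @rdname lgt_taxonomy
#' @param tax An `lgt_taxonomy` object.
#' @export
save_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "lgt_taxonomy"))
  write.table(tax$nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.lgt_taxonomy <- function(x, ...) {
  cat(sprintf("<lgt_taxonomy> %d nodes, root taxid %d\n",
              nrow(x$nodes), x$root))
  invisible(x)
}

check_known <- function(tax, taxid) {
  unknown <- setdiff(unique(taxid), tax$nodes$taxid)
  if (length(unknown) > 0) {
    abort(sprintf("unknown taxid(s): %s", paste(unknown, collapse = ", ")))
  }
}

#' Lineage of a taxon
#'
#' Taxids on the path from `taxid` up to the root, starting with `taxid`
#' itself.
#'
#' @param tax An `lgt_taxonomy`.
#' @param taxid A single taxid present in the taxonomy.
#' @return Integer vector of taxids.
#' @export
lineage <- function(tax, taxid) {
  check_known(tax, taxid)
  out <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    out <- c(out, cur)
    nxt <- tax$parent[[as.character(cur)]]
    if (is.na(nxt)) break
    cur <- nxt
  }
  out
}

#' Lineage-membership predicates
#'
#' `is_descendant()` reports whether `ancestor_taxid` lies on the path from
#' each `taxid` to the root; a taxon is a descendant of itself (matching NCBI
#' lineage conventions, so clade constraints phrased as "descendant of T"
#' include T). `is_ppn()` flags taxa under any of the configured
#' plant-parasitic-nematode lineages, and `is_eumetazoan()` flags taxa under
#' Eumetazoa. PPN taxa are themselves eumetazoans: the two predicates are
#' independent flags and are never merged.
#'
#' @param tax An `lgt_taxonomy`.
#' @param taxid Integer vector of taxids (all must be present in the tree).
#' @param ancestor_taxid Single candidate ancestor taxid.
#' @return Logical vector along `taxid`.
#' @export
is_descendant <- function(tax, taxid, ancestor_taxid) {
  check_known(tax, c(taxid, ancestor_taxid))
  ancestor_taxid <- as.integer(ancestor_taxid)
  vapply(as.integer(taxid), function(t) {
    ancestor_taxid %in% lineage(tax, t)
  }, logical(1))
}

#' @rdname is_descendant
#' @export
is_ppn <- function(tax, taxid) {
  check_known(tax, taxid)
  vapply(as.integer(taxid), function(t) {
    any(tax$ppn_taxids %in% lineage(tax, t))
  }, logical(1))
}

#' @rdname is_descendant
#' @export
is_eumetazoan <- function(tax, taxid) {
  is_descendant_any(tax, taxid, tax$eumetazoa_taxid)
}

# Vectorised is_descendant against a single ancestor, used in hot paths.
is_descendant_any <- function(tax, taxid, ancestor_taxid) {
  check_known(tax, taxid)
  vapply(as.integer(taxid), function(t) {
    ancestor_taxid %in% lineage(tax, t)
  }, logical(1))
}

#' Taxonomic division of a taxon
#'
#' Walks from the taxon towards the root and returns the division of the
#' nearest anchor taxid. Eukaryotes (lineage through taxid 2759) with no more
#' specific anchor are labelled `"Protist"`, the conventional catch-all for
#' non-metazoan, non-fungal, non-plant eukaryotes; taxa with no anchor at all
#' are labelled `"Other"`.
#'
#' @inheritParams is_descendant
#' @return Character vector of division labels along `taxid`.
#' @export
classify_division <- function(tax, taxid) {
  check_known(tax, taxid)
  anchor_label <- setNames(names(tax$anchors), tax$anchors)
  vapply(as.integer(taxid), function(t) {
    lin <- lineage(tax, t)
    for (a in lin) {
      hit <- anchor_label[as.character(a)]
      if (!is.na(hit)) return(unname(hit))
    }
    if (2759L %in% lin) "Protist" else "Other"
  }, character(1))
}

#' @rdname classify_division
#' @export
division_levels <- function() {
  c("Bacteria", "Fungi", "Protist", "Plant", "Archaea", "Metazoa", "Other")
}
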