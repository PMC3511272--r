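#' Configuration of the gene-tree topology scan
#'
#' @param focal_species Species tags whose presence defines the receiver
#'   clade (the two root-knot nematodes by default).
#' @param root_unrooted Midpoint-root trees that are read unrooted. Fusion
#'   trees are normally consumed rooted; the scan itself treats trees as
#'   rooted as given.
#' @export
tree_scan_config <- function(focal_species = c("Minc", "Mhap"),
                             root_unrooted = TRUE) {
  list(focal_species = focal_species, root_unrooted = root_unrooted)
}

# Descendant tip indices for every node of a phylo tree (tips included).
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  sets <- vector("list", n_all)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  # postorder guarantees children are accumulated before their parent
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]
    child <- po[k, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

tree_root <- function(tree) {
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

# Per-tip taxonomy flags for a species-tagged tree.
tip_flags <- function(tree, tax, species_taxids, focal_species) {
  assert_columns(species_taxids, c("species", "taxid"))
  sp <- species_of_label(tree$tip.label)
  idx <- match(sp, species_taxids$species)
  if (anyNA(idx)) {
    abort(sprintf("leaf taxid unresolvable for leaf/leaves: %s",
                  paste(tree$tip.label[is.na(idx)], collapse = ", ")))
  }
  taxid <- species_taxids$taxid[idx]
  u <- unique(taxid)
  ppn_u <- setNames(is_ppn(tax, u), u)
  met_u <- setNames(is_eumetazoan(tax, u), u)
  tibble(
    label = tree$tip.label, species = sp, taxid = taxid,
    ppn = unname(ppn_u[as.character(taxid)]),
    eumetazoan = unname(met_u[as.character(taxid)]),
    focal = sp %in% focal_species
  )
}

#' Scan a gene tree for LGT-compatible topologies
#'
#' Searches every internal node A whose child clades partition into a
#' receiver clade (only plant-parasitic nematode leaves, among them at least
#' one M. incognita or M. hapla sequence) and a donor clade (no eumetazoan
#' leaf), with the rest of the tree — the external clade — free of
#' plant-parasitic nematodes. Such a node is the minimal phylogenetic support
#' for a lateral transfer (grade `"A"`). Support is upgraded to `"A_plus_B"`
#' when the parent node B joins node A to an external clade containing at
#' least one non-metazoan leaf, which marks B as a duplication node and
#' therefore nests the nematode sequences inside non-metazoan diversity.
#'
#' Multifurcating nodes qualify when each child clade is individually
#' receiver-valid or donor-valid with at least one of each and no invalid
#' child. Trees with fewer than 3 leaves are not scanned (zero-row result).
#'
#' @param tree A rooted `phylo` tree with `species|protein_id` tip labels.
#' @param tax An `lgt_taxonomy`.
#' @param species_taxids Tibble mapping `species` tags to `taxid`.
#' @param cfg A `tree_scan_config()`.
#' @param tree_id Identifier recorded in the result.
#' @return A tibble of class `lgt_calls`, one row per matching node A:
#'   `tree_id`, `node`, `support`, `at_root`, `n_minc`, `n_mhap`, and list
#'   columns `receiver_leaves`, `donor_leaves`, `external_leaves`.
#' @export
match_lgt_pattern <- function(tree, tax, species_taxids,
                              cfg = tree_scan_config(), tree_id = "tree_1") {
  empty <- tibble(
    tree_id = character(0), node = integer(0), support = character(0),
    at_root = logical(0), n_minc = integer(0), n_mhap = integer(0),
    receiver_leaves = list(), donor_leaves = list(), external_leaves = list()
  )
  if (length(tree$tip.label) < 3) {
    return(structure(empty, class = c("lgt_calls", class(empty)),
                     scan_status = "no-scan"))
  }
  if (!ape::is.rooted(tree) && cfg$root_unrooted) {
    tree <- phangorn::midpoint(tree)
  }
  flags <- tip_flags(tree, tax, species_taxids, cfg$focal_species)
  sets <- node_tip_sets(tree)
  n_tip <- length(tree$tip.label)
  root <- tree_root(tree)
  all_tips <- seq_len(n_tip)

  calls <- list()
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    kids <- node_children(tree, node)
    recv_kids <- integer(0)
    donor_kids <- integer(0)
    ok <- TRUE
    for (kid in kids) {
      tipset <- sets[[kid]]
      receiver_ok <- all(flags$ppn[tipset])
      donor_ok <- !any(flags$eumetazoan[tipset])
      if (receiver_ok) {
        recv_kids <- c(recv_kids, kid)
      } else if (donor_ok) {
        donor_kids <- c(donor_kids, kid)
      } else {
        ok <- FALSE
        break
      }
    }
    if (!ok || length(recv_kids) == 0 || length(donor_kids) == 0) next
    receiver <- sort(unlist(sets[recv_kids]))
    if (!any(flags$focal[receiver])) next
    donor <- sort(unlist(sets[donor_kids]))
    external <- setdiff(all_tips, sets[[node]])
    if (any(flags$ppn[external])) next
    at_root <- node == root
    support <- if (!at_root && any(!flags$eumetazoan[external])) {
      "A_plus_B"
    } else {
      "A"
    }
    calls[[length(calls) + 1]] <- tibble(
      tree_id = tree_id, node = node, support = support, at_root = at_root,
      n_minc = sum(flags$species[receiver] == cfg$focal_species[1]),
      n_mhap = sum(flags$species[receiver] == cfg$focal_species[2]),
      receiver_leaves = list(tree$tip.label[receiver]),
      donor_leaves = list(tree$tip.label[donor]),
      external_leaves = list(tree$tip.label[external])
    )
  }
  out <- if (length(calls) == 0) empty else bind_rows(calls)
  structure(out, class = c("lgt_calls", class(empty)),
            tree = tree, scan_status = "scanned")
}

#' Support grade of an LGT call
#'
#' Recomputes the support grade from a call's external clade: `"A_plus_B"`
#' when node A has a parent (node B) and the external clade contains at least
#' one non-metazoan leaf; `"A"` otherwise, including when node A is the tree
#' root and no node B exists.
#'
#' @param calls An `lgt_calls` tibble.
#' @param tax An `lgt_taxonomy`.
#' @param species_taxids Species-to-taxid mapping tibble.
#' @return Character vector of grades along the rows of `calls`.
#' @export
classify_support <- function(calls, tax, species_taxids) {
  taxid_of <- setNames(species_taxids$taxid, species_taxids$species)
  vapply(seq_len(nrow(calls)), function(i) {
    if (calls$at_root[i]) return("A")
    ext <- calls$external_leaves[[i]]
    if (length(ext) == 0) return("A")
    taxids <- taxid_of[species_of_label(ext)]
    if (any(!is_eumetazoan(tax, taxids))) "A_plus_B" else "A"
  }, character(1))
}

#' Duplication nodes by species overlap
#'
#' An internal node of a (receiver) subtree is labelled a duplication node
#' when the species sets of at least two of its child clades intersect — the
#' classical species-overlap rule: a speciation node separates species, so
#' seeing the same species on both sides implies a gene duplication.
#'
#' @param tree A `phylo` tree with `species|protein_id` tip labels.
#' @return Integer vector of duplication node ids (phylo numbering).
#' @export
infer_duplication_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 2 || is.null(tree$edge)) return(integer(0))
  sp <- species_of_label(tree$tip.label)
  sets <- node_tip_sets(tree)
  out <- integer(0)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    kids <- node_children(tree, node)
    if (length(kids) < 2) next
    kid_species <- lapply(kids, function(k) unique(sp[sets[[k]]]))
    overlap <- FALSE
    for (i in seq_along(kid_species)) {
      for (j in seq_along(kid_species)) {
        if (i < j && length(intersect(kid_species[[i]],
                                      kid_species[[j]])) > 0) {
          overlap <- TRUE
        }
      }
    }
    if (overlap) out <- c(out, node)
  }
  out
}

#' Post-transfer duplication timing
#'
#' Classifies the duplication history of a receiver subtree. A gene counts as
#' duplicated when the subtree carries at least two M. hapla or at least
#' three M. incognita copies (the asymmetric threshold corrects for the
#' two-copy structure of the M. incognita genome). Duplication before the
#' speciation of the two nematodes is called when some node has both species
#' below it on at least two of its child clades (a duplication node prior to
#' the speciation nodes); duplication after the split is called when a
#' duplication node heads a single-species clade of at least 2 (M. hapla) or
#' at least 3 (M. incognita) leaves.
#'
#' @param tree A `phylo` tree; either the receiver subtree itself or a full
#'   gene tree together with `receiver_leaves`.
#' @param receiver_leaves Optional leaf labels delimiting the receiver clade.
#' @param minc,mhap Focal species tags.
#' @return One-row tibble: `n_minc`, `n_mhap`, `both_species_present`,
#'   `duplicated`, `before_split`, `after_split`.
#' @export
classify_duplication_timing <- function(tree, receiver_leaves = NULL,
                                        minc = "Minc", mhap = "Mhap") {
  labels <- if (is.null(receiver_leaves)) tree$tip.label else receiver_leaves
  sp <- species_of_label(labels)
  n_minc <- sum(sp == minc)
  n_mhap <- sum(sp == mhap)
  duplicated <- n_mhap >= 2 || n_minc >= 3
  before <- FALSE
  after <- FALSE
  if (length(labels) >= 2) {
    sub <- if (is.null(receiver_leaves) ||
               length(receiver_leaves) == length(tree$tip.label)) {
      tree
    } else {
      ape::keep.tip(tree, receiver_leaves)
    }
    sub_sp <- species_of_label(sub$tip.label)
    n_tip <- length(sub$tip.label)
    sets <- node_tip_sets(sub)
    for (node in (n_tip + 1):(n_tip + sub$Nnode)) {
      kids <- node_children(sub, node)
      kid_species <- lapply(kids, function(k) unique(sub_sp[sets[[k]]]))
      n_both <- sum(vapply(kid_species, function(s) {
        all(c(minc, mhap) %in% s)
      }, logical(1)))
      if (n_both >= 2) before <- TRUE
      clade_sp <- unique(sub_sp[sets[[node]]])
      clade_n <- length(sets[[node]])
      if (identical(clade_sp, mhap) && clade_n >= 2) after <- TRUE
      if (identical(clade_sp, minc) && clade_n >= 3) after <- TRUE
    }
  }
  tibble(
    n_minc = n_minc, n_mhap = n_mhap,
    both_species_present = n_minc >= 1 && n_mhap >= 1,
    duplicated = duplicated,
    before_split = duplicated && before,
    after_split = duplicated && after
  )
}

# Best call of a tree: strongest support, then most focal copies, then node.
best_call_per_tree <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  calls %>%
    mutate(.grade = ifelse(.data$support == "A_plus_B", 2L, 1L),
           .size = .data$n_minc + .data$n_mhap) %>%
    group_by(.data$tree_id) %>%
    arrange(dplyr::desc(.data$.grade), dplyr::desc(.data$.size),
            .data$node, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-".grade", -".size")
}

#' Scan a batch of gene trees
#'
#' Runs `match_lgt_pattern()` on every tree, keeps all calls, selects each
#' tree's best-supported call, and attaches its duplication-timing report.
#'
#' @param trees Tibble with `tree_id` and a `tree` list column of `phylo`
#'   objects (as returned by `read_gene_trees()`).
#' @inheritParams match_lgt_pattern
#' @return List with `calls` (all calls over all trees) and `per_tree` (one
#'   row per tree with a call: best support, copy numbers, duplication
#'   flags).
#' @export
scan_gene_trees <- function(trees, tax, species_taxids,
                            cfg = tree_scan_config()) {
  assert_columns(trees, c("tree_id", "tree"))
  all_calls <- bind_rows(lapply(seq_len(nrow(trees)), function(i) {
    match_lgt_pattern(trees$tree[[i]], tax, species_taxids, cfg,
                      tree_id = trees$tree_id[[i]])
  }))
  best <- best_call_per_tree(all_calls)
  if (nrow(best) > 0) {
    tree_of <- setNames(trees$tree, trees$tree_id)
    reports <- bind_rows(lapply(seq_len(nrow(best)), function(i) {
      classify_duplication_timing(
        tree_of[[best$tree_id[i]]], best$receiver_leaves[[i]],
        minc = cfg$focal_species[1], mhap = cfg$focal_species[2])
    }))
    per_tree <- dplyr::bind_cols(
      select(best, "tree_id", "node", "support", "receiver_leaves",
             "donor_leaves", "external_leaves"),
      select(reports, -"n_minc", -"n_mhap") # kept from best call columns
    ) %>%
      mutate(n_minc = best$n_minc, n_mhap = best$n_mhap)
  } else {
    per_tree <- tibble(
      tree_id = character(0), node = integer(0), support = character(0),
      receiver_leaves = list(), donor_leaves = list(),
      external_leaves = list(), both_species_present = logical(0),
      duplicated = logical(0), before_split = logical(0),
      after_split = logical(0), n_minc = integer(0), n_mhap = integer(0)
    )
  }
  list(calls = all_calls, per_tree = per_tree)
}

#' Donor-clade taxonomy summary
#'
#' For each taxonomic division, the number of trees whose best call's donor
#' clade contains at least one species of that division, and the number whose
#' donor clade contains only that division. A tree with a mixed donor clade
#' contributes to several "at least one" rows but to no "only" row.
#'
#' @param calls An `lgt_calls` tibble (typically `scan_gene_trees()$per_tree`
#'   or all calls; trees are deduplicated to their best call first).
#' @param tax An `lgt_taxonomy`.
#' @param species_taxids Species-to-taxid mapping tibble.
#' @return Tibble with `division`, `n_trees_any`, `n_trees_only` and the two
#'   corresponding percentages of calls summarized.
#' @export
summarize_donor_taxa <- function(calls, tax, species_taxids) {
  best <- if ("at_root" %in% names(calls)) best_call_per_tree(calls) else calls
  taxid_of <- setNames(species_taxids$taxid, species_taxids$species)
  n_trees <- nrow(best)
  div_sets <- lapply(seq_len(n_trees), function(i) {
    taxids <- taxid_of[species_of_label(best$donor_leaves[[i]])]
    unique(classify_division(tax, taxids))
  })
  divisions <- division_levels()
  out <- tibble(
    division = divisions,
    n_trees_any = vapply(divisions, function(d) {
      sum(vapply(div_sets, function(s) d %in% s, logical(1)))
    }, integer(1)),
    n_trees_only = vapply(divisions, function(d) {
      sum(vapply(div_sets, function(s) identical(s, d), logical(1)))
    }, integer(1))
  )
  if (n_trees > 0) {
    out <- mutate(out,
                  pct_any = round_half_up(100 * .data$n_trees_any / n_trees, 1),
                  pct_only = round_half_up(100 * .data$n_trees_only / n_trees, 1))
  } else {
    out <- mutate(out, pct_any = NA_real_, pct_only = NA_real_)
  }
  out
}
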