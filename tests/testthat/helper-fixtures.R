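# Shared fixtures and independent brute-force oracles. The oracles stay
# deliberately naive (path walks, quadratic loops, exhaustive enumeration)
# and never call the implementation paths they check.

fixture_tax <- function() lgt_taxonomy(sim_taxonomy_nodes())

fixture_species <- function() dplyr::select(sim_species_table(),
                                            species, taxid)

toy_tax <- function() {
  lgt_taxonomy(tibble::tibble(
    taxid = c(1, 6072, 6231, 6300, 2),
    parent_taxid = c(1, 1, 6072, 6231, 1),
    name = c("root", "Eumetazoa", "Nematoda", "Tylenchida", "Bacteria")
  ))
}

# random taxonomy with n nodes (node 1 is root, parents drawn among
# lower-numbered nodes)
random_taxonomy_nodes <- function(n) {
  tibble::tibble(
    taxid = seq_len(n),
    parent_taxid = c(1L, vapply(2:n, function(i) {
      sample.int(i - 1L, 1)
    }, integer(1))),
    name = paste0("node", seq_len(n))
  )
}

# independent ancestor oracle: walk the parent column of the raw table
oracle_is_descendant <- function(nodes, taxid, ancestor) {
  cur <- taxid
  repeat {
    if (cur == ancestor) return(TRUE)
    parent <- nodes$parent_taxid[nodes$taxid == cur]
    if (parent == cur) return(FALSE)
    cur <- parent
  }
}

# random species-labelled gene tree over a pool of species tags
random_species_tree <- function(n_leaves, pool, prob = NULL) {
  tr <- ape::rtree(n_leaves, br = NULL)
  sp <- sample(pool, n_leaves, replace = TRUE, prob = prob)
  tr$tip.label <- sprintf("%s|p%02d", sp, seq_len(n_leaves))
  tr
}

# brute-force LGT pattern enumerator: recomputes clade tip sets by walking
# the edge matrix recursively and checks the clade constraints with plain
# loops at every internal node
oracle_match_lgt <- function(tree, tax, species_taxids,
                             focal = c("Minc", "Mhap")) {
  n_tip <- length(tree$tip.label)
  sp <- sub("\\|.*$", "", tree$tip.label)
  taxid <- species_taxids$taxid[match(sp, species_taxids$species)]
  ppn <- vapply(taxid, function(t) {
    any(c(6300, 211184, 211225) %in% oracle_lineage(tax, t))
  }, logical(1))
  eumet <- vapply(taxid, function(t) {
    6072 %in% oracle_lineage(tax, t)
  }, logical(1))

  clade_tips <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, clade_tips))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  results <- list()
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    recv <- integer(0); donor <- integer(0); bad <- FALSE
    for (kid in kids) {
      tips <- clade_tips(kid)
      if (all(ppn[tips])) {
        recv <- c(recv, tips)
      } else if (!any(eumet[tips])) {
        donor <- c(donor, tips)
      } else {
        bad <- TRUE
      }
    }
    if (bad || length(recv) == 0 || length(donor) == 0) next
    if (!any(sp[recv] %in% focal)) next
    ext <- setdiff(seq_len(n_tip), clade_tips(node))
    if (any(ppn[ext])) next
    support <- if (node != root && any(!eumet[ext])) "A_plus_B" else "A"
    results[[length(results) + 1]] <- list(
      receiver = sort(tree$tip.label[recv]),
      donor = sort(tree$tip.label[donor]),
      support = support
    )
  }
  results
}

oracle_lineage <- function(tax, taxid) {
  nodes <- tax$nodes
  out <- c()
  cur <- taxid
  repeat {
    out <- c(out, cur)
    parent <- nodes$parent_taxid[nodes$taxid == cur]
    if (is.na(parent) || parent == cur) break
    cur <- parent
  }
  out
}

# canonical form of a call set for comparing scanner and oracle
call_signature <- function(receivers, donors, supports) {
  sig <- paste(
    vapply(receivers, paste, character(1), collapse = ","),
    vapply(donors, paste, character(1), collapse = ","),
    supports, sep = " / ")
  sort(sig)
}

# quadratic single-linkage chaining oracle for genomic clusters
oracle_clusters <- function(genes, max_gap = 50000, min_size = 3) {
  lgt <- genes[genes$is_lgt, ]
  out <- list()
  for (sc in unique(lgt$scaffold_id)) {
    g <- lgt[lgt$scaffold_id == sc, ]
    g <- g[order(g$start, g$end, g$gene_id), ]
    if (nrow(g) == 0) next
    chain <- g$gene_id[1]
    prev_end <- g$end[1]
    flush <- function(chain) {
      if (length(chain) >= min_size) out[[length(out) + 1]] <<- chain
    }
    for (i in seq_len(nrow(g))[-1]) {
      gap <- max(g$start[i] - prev_end - 1, 0)
      if (gap < max_gap) {
        chain <- c(chain, g$gene_id[i])
      } else {
        flush(chain)
        chain <- g$gene_id[i]
      }
      prev_end <- g$end[i]
    }
    flush(chain)
  }
  out
}

# naive O(n*m) TE-in-flanks counting oracle
oracle_te_count <- function(gene, tes, scaffold_len, window) {
  flanks <- list(
    c(max(gene$start - window, 1), gene$start - 1),
    c(gene$end + 1, min(gene$end + window, scaffold_len))
  )
  hit <- rep(FALSE, nrow(tes))
  for (i in seq_len(nrow(tes))) {
    if (tes$scaffold_id[i] != gene$scaffold_id) next
    for (f in flanks) {
      if (f[2] >= f[1] && tes$start[i] <= f[2] && tes$end[i] >= f[1]) {
        hit[i] <- TRUE
      }
    }
  }
  length(unique(tes$te_id[hit]))
}

# exhaustive ancestor-set oracle for GO slim projection
oracle_slim_map <- function(term, edges, slim, mode = "most_specific") {
  parents <- function(t) edges$parent[edges$term == t & !is.na(edges$parent)]
  ancestors <- function(t) {
    ps <- parents(t)
    unique(c(ps, unlist(lapply(ps, ancestors))))
  }
  if (term %in% slim) return(term)
  anc <- intersect(ancestors(term), slim)
  if (mode == "all" || length(anc) <= 1) return(sort(anc))
  keep <- vapply(anc, function(s) {
    !any(vapply(setdiff(anc, s), function(s2) s %in% ancestors(s2),
                logical(1)))
  }, logical(1))
  sort(anc[keep])
}
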