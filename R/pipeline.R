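#' Pipeline configuration
#'
#' Aggregates every stage threshold at the study's values: BLAST e-value
#' 0.01, query coverage 0.30, vote over the 10 best hits at a 0.50
#' non-metazoan fraction, contamination at >80% identity over >50% of the
#' query, genomic clusters of at least 3 LGT genes less than 50 kb apart, TE
#' windows of 200/500/1000/2000 bp, mobile-element thresholds of e < 0.001
#' and 30%/50%/50% identity/query/subject coverage, PPN lineages Tylenchida
#' 6300, Triplonchida 211184 and Dorylaimina 211225, and Eumetazoa 6072 as
#' the metazoan anchor.
#'
#' @param blast A `blast_filter_config()`.
#' @param tree A `tree_scan_config()`.
#' @param cluster_max_gap,cluster_min_size Genomic clustering parameters.
#' @param te_windows Flank window sizes in bp.
#' @param mobile_evalue_max,mobile_identity_min,mobile_qcov_min,mobile_scov_min
#'   Mobile-element screen thresholds.
#' @param focal_species Tags of the two root-knot nematodes.
#' @param ppn_taxids,eumetazoa_taxid Taxonomy anchors.
#' @param seed Seed recorded with the run.
#' @export
lgt_pipeline_config <- function(blast = blast_filter_config(),
                                tree = tree_scan_config(),
                                cluster_max_gap = 50000L,
                                cluster_min_size = 3L,
                                te_windows = c(200L, 500L, 1000L, 2000L),
                                mobile_evalue_max = 0.001,
                                mobile_identity_min = 30,
                                mobile_qcov_min = 0.5,
                                mobile_scov_min = 0.5,
                                focal_species = c("Minc", "Mhap"),
                                ppn_taxids = c(6300L, 211184L, 211225L),
                                eumetazoa_taxid = 6072L,
                                seed = 1L) {
  stopifnot(cluster_max_gap > 0, cluster_min_size >= 1,
            all(te_windows > 0), mobile_evalue_max > 0)
  as.list(environment())
}

#' @rdname lgt_pipeline_config
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname lgt_pipeline_config
#' @param config A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  int_fields <- c("cluster_max_gap", "cluster_min_size", "ppn_taxids",
                  "eumetazoa_taxid", "seed", "te_windows")
  for (f in int_fields) raw[[f]] <- as.integer(unlist(raw[[f]]))
  for (f in c("focal_species")) raw[[f]] <- as.character(unlist(raw[[f]]))
  raw$blast <- lapply(raw$blast, function(x) if (is.list(x)) unlist(x) else x)
  raw$tree$focal_species <- as.character(unlist(raw$tree$focal_species))
  raw
}

stage_cached <- function(output_dir, name, compute, reader = NULL,
                         writer = NULL) {
  if (is.null(output_dir)) return(compute())
  path <- file.path(output_dir, paste0(name, ".tsv"))
  if (file.exists(path) && !is.null(reader)) return(reader(path))
  value <- compute()
  if (!is.null(writer)) writer(value, path)
  value
}

#' Run the full LGT detection pipeline
#'
#' Executes the three detection steps and the downstream characterizations on
#' an input bundle (the structure returned by `simulate_lgt_study()` or
#' `read_lgt_bundle()`): redundancy removal, restriction of ortholog groups
#' to the two nematodes with representative selection, the non-metazoan BLAST
#' vote and contamination filter, the gene-tree topology scan with
#' duplication timing and donor summary, in-paralog counting, copy-number
#' enumeration, genomic context (clusters, TE density, scaffold ends, GC and
#' codon usage), GO-slim functional comparison, and the mobile-element
#' screen. A log tibble records each stage's input and output counts.
#'
#' @param bundle Input list with the components named as in
#'   `simulate_lgt_study()`. `trees`, `cds`, `domain_assignments` and
#'   `mobile_hits` are optional; stages lacking inputs are skipped.
#' @param config An `lgt_pipeline_config()`.
#' @param output_dir Optional directory: stage outputs are persisted as TSV
#'   and, when a stage's file already exists, it is reloaded instead of
#'   recomputed, which makes interrupted runs resumable.
#' @return Object of class `lgt_pipeline_result`.
#' @export
run_lgt_pipeline <- function(bundle, config = lgt_pipeline_config(),
                             output_dir = NULL) {
  required <- c("taxonomy", "species", "proteins", "groups", "blast_hits")
  missing <- setdiff(required, names(bundle))
  if (length(missing) > 0) {
    abort(sprintf("bundle is missing required input(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  tax <- bundle$taxonomy
  tax$ppn_taxids <- config$ppn_taxids
  tax$eumetazoa_taxid <- config$eumetazoa_taxid
  species_taxids <- select(bundle$species, "species", "taxid")
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1]] <<- tibble(stage = stage, n_in = n_in,
                                      n_out = n_out, detail = detail)
  }

  # stage 1: redundancy removal
  deduped <- dedup_exact(bundle$proteins)
  proteins <- filter(deduped, .data$is_representative)
  note("dedup_exact", nrow(bundle$proteins), nrow(proteins),
       "100%-identical records collapsed")

  # stage 1b: ortholog-group restriction and representatives
  restricted <- select_restricted_groups(
    bundle$groups, focal_species = config$focal_species,
    proteins = filter(proteins, .data$species %in% config$focal_species))
  reps <- choose_representatives(restricted$groups, proteins,
                                 primary = config$focal_species[1],
                                 secondary = config$focal_species[2])
  queries <- union(reps$protein_id, restricted$singletons)
  note("select_restricted_groups", n_distinct(bundle$groups$group_id),
       n_distinct(restricted$groups$group_id),
       sprintf("%d singletons", length(restricted$singletons)))
  note("queries", NA_integer_, length(queries),
       "group representatives + unclustered focal proteins")

  # stage 2: BLAST vote and contamination filter
  hits <- filter(bundle$blast_hits, .data$query_id %in% queries)
  votes <- vote_non_metazoan(hits, proteins, tax, config$blast)
  votes <- bind_rows(
    votes,
    tibble(query_id = setdiff(queries, votes$query_id), status = "no_hit",
           vote_fraction = NA_real_, n_hits_used = 0L, n_non_metazoan = 0L,
           reason = "no BLAST hit returned")
  )
  candidates0 <- votes$query_id[votes$status == "candidate"]
  note("vote_non_metazoan", length(queries), length(candidates0),
       sprintf("%d no_hit discarded", sum(votes$status == "no_hit")))

  contam <- flag_contaminants(filter(hits, .data$query_id %in% candidates0),
                              proteins, tax, config$blast)
  contaminants <- contam$query_id[contam$contaminant]
  candidates <- setdiff(candidates0, contaminants)
  note("flag_contaminants", length(candidates0), length(candidates),
       sprintf("%d contaminants removed", length(contaminants)))

  # stage 3: gene-tree topology scan
  scan <- NULL
  donor_summary <- NULL
  cohort <- NULL
  if (!is.null(bundle$trees)) {
    trees <- filter(bundle$trees, .data$tree_id %in% candidates)
    scan <- scan_gene_trees(trees, tax, species_taxids, config$tree)
    donor_summary <- summarize_donor_taxa(scan$per_tree, tax, species_taxids)
    cohort <- duplication_cohort_stats(scan$per_tree)
    note("scan_gene_trees", nrow(trees), nrow(scan$per_tree),
         "trees with an LGT-compatible topology")
  }

  # candidate gene copies: all focal members of candidate groups, plus
  # candidate singletons
  candidate_groups <- restricted$groups %>%
    semi_join(filter(reps, .data$protein_id %in% candidates), by = "group_id")
  lgt_copy_ids <- union(candidate_groups$protein_id,
                        intersect(candidates, restricted$singletons))

  # in-paralog counting and copy-number enumeration
  inparalogs <- count_inparalog_groups(restricted$groups,
                                       lgt_ids = lgt_copy_ids,
                                       minc = config$focal_species[1],
                                       mhap = config$focal_species[2])
  minc_tag <- config$focal_species[1]
  minc_per_group <- candidate_groups %>%
    group_by(.data$group_id) %>%
    summarise(n_minc = sum(.data$species == minc_tag), .groups = "drop")
  minc_singletons <- proteins %>%
    filter(.data$protein_id %in% intersect(candidates,
                                           restricted$singletons),
           .data$species == minc_tag)
  dist_blast <- copy_distribution_from_counts(
    minc_per_group$n_minc[minc_per_group$n_minc > 0],
    singletons = nrow(minc_singletons))
  proteome_size <- sum(bundle$proteins$species == minc_tag)
  enumeration <- tibble(
    total_lgt_genes = total_lgt_genes(dist_blast),
    pct_lgt_genes = percent_of_proteome(total_lgt_genes(dist_blast),
                                        proteome_size)
  )
  dist_phylo <- NULL
  if (!is.null(scan) && nrow(scan$per_tree) > 0) {
    phylo_counts <- scan$per_tree$n_minc[scan$per_tree$n_minc > 0]
    if (length(phylo_counts) > 0) {
      dist_phylo <- copy_distribution_from_counts(phylo_counts)
      enumeration$total_phylo_supported <- total_phylo_supported(dist_phylo)
      enumeration$pct_phylo_supported <- percent_of_proteome(
        total_phylo_supported(dist_phylo), proteome_size)
    }
  }

  # genomic context, using the pipeline's own LGT flags
  context <- NULL
  if (!is.null(bundle$genes)) {
    genes <- mutate(bundle$genes,
                    is_lgt = .data$gene_id %in% lgt_copy_ids)
    clusters <- detect_lgt_clusters(genes, config$cluster_max_gap,
                                    config$cluster_min_size)
    te_report <- te_density_report(genes, bundle$tes, bundle$scaffolds,
                                   windows = config$te_windows)
    end_positions <- compare_scaffold_end_positions(genes, bundle$scaffolds)
    gc <- NULL
    codon <- NULL
    if (!is.null(bundle$cds)) {
      is_lgt_cds <- bundle$cds$gene_id %in% lgt_copy_ids
      gc <- tibble(
        class = c("LGT", "Other"),
        mean_gc = c(mean(gc_content(bundle$cds$sequence[is_lgt_cds])),
                    mean(gc_content(bundle$cds$sequence[!is_lgt_cds])))
      )
      codon <- compare_codon_usage(
        codon_usage_table(bundle$cds$sequence[is_lgt_cds]),
        codon_usage_table(bundle$cds$sequence[!is_lgt_cds]))
    }
    context <- list(genes = genes, clusters = clusters,
                    te_report = te_report, end_positions = end_positions,
                    gc = gc, codon = codon)
    note("detect_lgt_clusters", sum(genes$is_lgt), nrow(clusters),
         "clusters of >=3 LGT genes")
  }

  # functional profile
  go <- NULL
  if (!is.null(bundle$domain_assignments) && !is.null(bundle$go_edges)) {
    dag <- go_dag(bundle$go_edges)
    ann <- pfam_to_go(bundle$domain_assignments, bundle$pfam2go)
    slim_ann <- map_annotations_to_slim(ann, dag, bundle$go_slim)
    set_lgt <- filter(slim_ann, .data$protein_id %in% lgt_copy_ids)
    go <- compare_go_distributions(set_lgt, slim_ann, dag)
    note("compare_go_distributions",
         n_distinct(slim_ann$protein_id), n_distinct(set_lgt$protein_id),
         "annotated proteins (all vs LGT)")
  }

  # mobile elements
  mobile <- NULL
  if (!is.null(bundle$mobile_hits) && nrow(bundle$mobile_hits) > 0) {
    mh <- filter(bundle$mobile_hits, .data$query_id %in% candidates)
    loose <- screen_mobile_hits(mh, "loose",
                                evalue_max = config$mobile_evalue_max)
    strict <- screen_mobile_hits(mh, "strict",
                                 evalue_max = config$mobile_evalue_max,
                                 identity_min = config$mobile_identity_min,
                                 qcov_min = config$mobile_qcov_min,
                                 scov_min = config$mobile_scov_min)
    mobile <- list(
      loose = loose, strict = strict,
      n_loose = n_distinct(loose$best_hits$query_id),
      n_strict = n_distinct(strict$best_hits$query_id),
      types = classify_element_types(strict$best_hits)
    )
    note("screen_mobile_hits", n_distinct(mh$query_id), mobile$n_strict,
         sprintf("%d loose-stage queries", mobile$n_loose))
  }

  result <- structure(
    list(
      config = config,
      proteins = proteins,
      restricted = restricted,
      representatives = reps,
      votes = votes,
      candidates = candidates,
      contaminants = contaminants,
      lgt_copy_ids = lgt_copy_ids,
      scan = scan,
      donor_summary = donor_summary,
      duplication_cohort = cohort,
      inparalogs = inparalogs,
      copy_distribution_blast = dist_blast,
      copy_distribution_phylo = dist_phylo,
      enumeration = enumeration,
      context = context,
      go = go,
      mobile = mobile,
      log = bind_rows(log)
    ),
    class = "lgt_pipeline_result"
  )
  if (!is.null(output_dir)) persist_pipeline_outputs(result, output_dir)
  result
}

persist_pipeline_outputs <- function(result, output_dir) {
  w <- function(df, name) {
    if (!is.null(df)) write_tsv_file(df, file.path(output_dir,
                                                   paste0(name, ".tsv")))
  }
  w(result$votes, "votes")
  w(tibble(query_id = result$candidates), "candidates")
  w(tibble(query_id = result$contaminants), "contaminants")
  if (!is.null(result$scan)) w(result$scan$per_tree, "lgt_calls")
  w(result$donor_summary, "donor_summary")
  w(result$duplication_cohort, "duplication_cohort")
  if (!is.null(result$context)) {
    w(result$context$clusters, "clusters")
    w(result$context$te_report, "te_density")
  }
  w(result$go, "go_comparison")
  if (!is.null(result$mobile)) w(result$mobile$types, "mobile_types")
  w(result$enumeration, "enumeration")
  w(result$log, "log")
  invisible(output_dir)
}

#' @export
print.lgt_pipeline_result <- function(x, ...) {
  cat("<lgt_pipeline_result>\n")
  cat(sprintf("  candidates: %d (contaminants removed: %d)\n",
              length(x$candidates), length(x$contaminants)))
  if (!is.null(x$scan)) {
    cat(sprintf("  trees with LGT-compatible topology: %d\n",
                nrow(x$scan$per_tree)))
  }
  print(x$enumeration)
  invisible(x)
}

#' Compare a pipeline run with the generator's ground truth
#'
#' Sensitivity and specificity of the candidate set against planted labels:
#' the fraction of planted LGT genes recovered as candidates, the fraction of
#' planted contaminants flagged, and the number of false-positive candidates
#' (candidates that are neither planted LGT nor planted contaminants).
#'
#' @param result An `lgt_pipeline_result`.
#' @param truth The generator's truth tibble.
#' @return One-row tibble with `n_lgt_truth`, `n_lgt_recovered`,
#'   `sensitivity_pct`, `n_contaminant_truth`, `n_contaminant_flagged`,
#'   `contaminant_recall_pct`, `n_false_positive`.
#' @export
evaluate_against_truth <- function(result, truth) {
  lgt_truth <- filter(truth, .data$is_lgt)
  ctm_truth <- filter(truth, .data$is_contaminant)
  recovered <- sum(lgt_truth$representative_id %in% result$candidates)
  flagged <- sum(ctm_truth$representative_id %in% result$contaminants)
  fp <- setdiff(result$candidates,
                c(lgt_truth$representative_id, ctm_truth$representative_id))
  tibble(
    n_lgt_truth = nrow(lgt_truth),
    n_lgt_recovered = recovered,
    sensitivity_pct = round_half_up(100 * recovered / nrow(lgt_truth), 2),
    n_contaminant_truth = nrow(ctm_truth),
    n_contaminant_flagged = flagged,
    contaminant_recall_pct =
      round_half_up(100 * flagged / max(nrow(ctm_truth), 1), 2),
    n_false_positive = length(fp)
  )
}
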