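small_cfg <- function(seed = 1) {
  lgt_sim_config(seed = seed, n_lgt = 20, n_vertical = 30,
                 n_contaminants = 3, n_clusters = 2L)
}

test_that("the generator is deterministic for a given seed", {
  s1 <- simulate_lgt_study(small_cfg(14))
  s2 <- simulate_lgt_study(small_cfg(14))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(s1$blast_hits, s2$blast_hits)
  expect_identical(lapply(s1$trees$tree, ape::write.tree),
                   lapply(s2$trees$tree, ape::write.tree))
  expect_identical(s1$tes, s2$tes)
  expect_identical(s1$cds, s2$cds)
  s3 <- simulate_lgt_study(small_cfg(15))
  expect_false(identical(s1$proteins$sequence, s3$proteins$sequence))
})

test_that("written bundles are byte-identical across runs and re-parse", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_lgt_bundle(simulate_lgt_study(small_cfg(14)), d1)
  write_lgt_bundle(simulate_lgt_study(small_cfg(14)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  b <- read_lgt_bundle(d1)
  sim <- simulate_lgt_study(small_cfg(14))
  expect_identical(
    dplyr::arrange(sim$proteins[, c("protein_id", "species", "length",
                                    "sequence")], protein_id),
    dplyr::arrange(b$proteins[, c("protein_id", "species", "length",
                                  "sequence")], protein_id))
  expect_identical(dplyr::arrange(sim$groups, group_id, protein_id),
                   dplyr::arrange(b$groups, group_id, protein_id))
  expect_equal(nrow(b$genes), nrow(sim$genes))
  expect_equal(nrow(b$tes), nrow(sim$tes))
  expect_identical(sim$cds, b$cds)
  expect_identical(sim$taxonomy$nodes$taxid, b$taxonomy$nodes$taxid)
  expect_identical(
    lapply(sim$trees$tree, ape::write.tree),
    lapply(b$trees$tree, ape::write.tree))
})

test_that("truth labels are mutually consistent", {
  sim <- simulate_lgt_study(small_cfg(33))
  t <- sim$truth
  # duplication timing implies the copy thresholds
  dup <- t[t$duplication_timing != "none" & t$both_species, ]
  expect_true(all(dup$n_copies_minc >= 3 | dup$n_copies_mhap >= 2))
  # LGT genes are grouped iff they have at least two focal copies (clustered
  # vertical genes are grouped with other metazoan species instead)
  lgt <- t[t$is_lgt, ]
  expect_equal(lgt$in_group, lgt$n_copies_minc + lgt$n_copies_mhap >= 2)
  # contaminants are single-copy and never carry trees
  ctm <- t[t$is_contaminant, ]
  expect_true(all(ctm$n_copies_minc + ctm$n_copies_mhap == 1))
  expect_true(all(!ctm$has_tree))
  # every LGT gene has a tree
  expect_true(all(t$has_tree[t$is_lgt]))
  # representative follows the longest-Minc rule
  for (gid in sample(t$gene_id[t$is_lgt], 5)) {
    members <- sim$proteins[sim$proteins$gene_id == gid &
                              !grepl("_redund$", sim$proteins$protein_id), ]
    expect_equal(t$representative_id[t$gene_id == gid],
                 choose_representative(members)$protein_id)
  }
})

test_that("truth-label marginals track the configured rates", {
  cfg <- lgt_sim_config(seed = 77, n_lgt = 400, n_vertical = 10,
                        n_contaminants = 2, n_clusters = 2L)
  sim <- simulate_lgt_study(cfg)
  t <- sim$truth[sim$truth$is_lgt, ]
  binom_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(t$both_species) - cfg$p_both_species),
            binom_tol(cfg$p_both_species, nrow(t)))
  cohort <- t[t$both_species, ]
  expect_lt(abs(mean(cohort$duplicated) - cfg$p_duplicated),
            binom_tol(cfg$p_duplicated, nrow(cohort)))
  dup <- cohort[cohort$duplicated, ]
  expect_lt(abs(mean(dup$duplication_timing %in% c("before", "both")) -
                  cfg$p_before),
            binom_tol(cfg$p_before, nrow(dup)))
})

test_that("every emitted file parses through the package readers", {
  d <- withr::local_tempdir()
  write_lgt_bundle(simulate_lgt_study(small_cfg(3)), d)
  expect_s3_class(load_taxonomy(file.path(d, "taxonomy.tsv")),
                  "lgt_taxonomy")
  expect_gt(nrow(read_proteome_fasta(file.path(d, "proteome.fasta"))), 0)
  expect_gt(nrow(read_orthomcl_groups(file.path(d, "groups.txt"))), 0)
  expect_gt(nrow(read_blast_hits(file.path(d, "blast_hits.tsv"))), 0)
  expect_gt(nrow(read_gene_trees(file.path(d, "trees.nwk"))), 0)
  ann <- read_genome_annotation(file.path(d, "genome.gff3"))
  expect_gt(nrow(ann$genes), 0)
  expect_gt(nrow(ann$tes), 0)
  expect_true(all(ann$genes$is_lgt %in% c(TRUE, FALSE)))
  expect_gt(nrow(read_cds_fasta(file.path(d, "cds.fasta"))), 0)
  expect_gt(nrow(read_pfam2go(file.path(d, "pfam2go.txt"))), 0)
})

test_that("generator rejects inconsistent configurations", {
  expect_error(lgt_sim_config(n_lgt = 5, n_clusters = 3,
                              cluster_size_range = c(3, 4)),
               "cluster specification")
  expect_error(lgt_sim_config(p_duplicated = 1.4), "probabilities")
})
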