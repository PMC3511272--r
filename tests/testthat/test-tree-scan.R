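scan_newick <- function(nwk, ...) {
  match_lgt_pattern(ape::read.tree(text = nwk), fixture_tax(),
                    fixture_species(), ...)
}

test_that("the three-clade pattern is matched with graded support", {
  # external clade metazoan -> minimal support A
  calls <- scan_newick("((Minc|m1,Ecol|e1),Hsap|h1);")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$support, "A")
  expect_equal(calls$receiver_leaves[[1]], "Minc|m1")
  expect_equal(calls$donor_leaves[[1]], "Ecol|e1")

  # non-metazoan in the external clade upgrades to A+B
  calls2 <- scan_newick("((Minc|m1,Ecol|e1),Bsub|b1);")
  expect_equal(calls2$support, "A_plus_B")

  # a human leaf poisons both receiver and donor clades
  expect_equal(nrow(scan_newick("((Minc|m1,Hsap|h1),Ecol|e1);")), 0)

  # node A at the tree root: no node B exists, support stays A
  calls3 <- scan_newick("((Minc|m1,Minc|m2),Ecol|e1);")
  expect_equal(calls3$support, "A")
  expect_true(calls3$at_root)

  # external clade may not contain plant-parasitic nematodes
  expect_equal(nrow(scan_newick("((Minc|m1,Ecol|e1),(Hsap|h1,Xind|x1));")), 0)

  # receiver may include other PPN, and must include a focal nematode
  calls4 <- scan_newick("(((Minc|m1,Xind|x1),Ecol|e1),Hsap|h1);")
  expect_equal(nrow(calls4), 1)
  expect_setequal(calls4$receiver_leaves[[1]], c("Minc|m1", "Xind|x1"))
  expect_equal(nrow(scan_newick("((Xind|x1,Ecol|e1),Hsap|h1);")), 0)

  # vertical-descent topology yields no call
  expect_equal(nrow(scan_newick(
    "((Minc|m1,Cele|c1),(Hsap|h1,Dmel|d1));")), 0)
})

test_that("calls partition the leaves and are rotation invariant", {
  nwk <- "(((Minc|m1,Mhap|h1),(Ecol|e1,Rsol|r1)),(Hsap|s1,Atha|a1));"
  calls <- scan_newick(nwk)
  expect_equal(nrow(calls), 1)
  parts <- c(calls$receiver_leaves[[1]], calls$donor_leaves[[1]],
             calls$external_leaves[[1]])
  expect_setequal(parts, ape::read.tree(text = nwk)$tip.label)
  expect_equal(length(parts), 6)

  rotated <- "((Atha|a1,Hsap|s1),((Rsol|r1,Ecol|e1),(Mhap|h1,Minc|m1)));"
  calls_rot <- scan_newick(rotated)
  expect_equal(
    call_signature(lapply(calls$receiver_leaves, sort),
                   lapply(calls$donor_leaves, sort), calls$support),
    call_signature(lapply(calls_rot$receiver_leaves, sort),
                   lapply(calls_rot$donor_leaves, sort), calls_rot$support)
  )
})

test_that("scanner agrees with the exhaustive-node oracle on random trees", {
  set.seed(99)
  tax <- fixture_tax()
  sp <- fixture_species()
  pool <- c("Minc", "Mhap", "Xind", "Cele", "Hsap", "Dmel", "Ecol", "Bsub",
            "Scer", "Atha")
  # weights favor receiver/donor species so that matching topologies occur
  weights <- c(4, 1, 1, 1, 1, 1, 4, 2, 2, 1)
  n_with_calls <- 0
  for (i in 1:60) {
    tr <- random_species_tree(sample(6:12, 1), pool, prob = weights)
    got <- match_lgt_pattern(tr, tax, sp)
    want <- oracle_match_lgt(tr, tax, sp)
    expect_equal(
      call_signature(lapply(got$receiver_leaves, sort),
                     lapply(got$donor_leaves, sort), got$support),
      call_signature(lapply(want, `[[`, "receiver"),
                     lapply(want, `[[`, "donor"),
                     vapply(want, `[[`, character(1), "support"))
    )
    if (nrow(got) > 0) n_with_calls <- n_with_calls + 1
  }
  expect_gt(n_with_calls, 0) # the comparison actually exercised matches
})

test_that("multifurcating nodes partition child clades", {
  calls <- scan_newick("((Minc|m1,Mhap|h1,Ecol|e1),Hsap|s1);")
  expect_equal(nrow(calls), 1)
  expect_setequal(calls$receiver_leaves[[1]], c("Minc|m1", "Mhap|h1"))
  # an invalid (mixed) child blocks the node
  expect_equal(nrow(scan_newick(
    "((Minc|m1,(Cele|c1,Ecol|e1),Bsub|b1),Hsap|s1);")), 0)
})

test_that("support grade recomputation matches the scanner", {
  tax <- fixture_tax(); sp <- fixture_species()
  for (nwk in c("((Minc|m1,Ecol|e1),Hsap|h1);",
                "((Minc|m1,Ecol|e1),Bsub|b1);",
                "((Minc|m1,Ecol|e1),(Bsub|b1,Hsap|h1));",
                "((Minc|m1,Minc|m2),Ecol|e1);")) {
    calls <- scan_newick(nwk)
    expect_equal(classify_support(calls, tax, sp), calls$support)
  }
})

test_that("species-overlap duplication nodes match exhaustive recomputation", {
  tr <- ape::read.tree(text = "((Minc|a,Mhap|b),(Minc|c,Mhap|d));")
  dup <- infer_duplication_nodes(tr)
  expect_equal(dup, 5L) # the root: both children hold {Minc, Mhap}

  expect_length(infer_duplication_nodes(
    ape::read.tree(text = "(Minc|a,Mhap|b);")), 0)

  set.seed(4)
  for (i in 1:30) {
    tr <- random_species_tree(sample(4:10, 1), c("Minc", "Mhap"))
    got <- infer_duplication_nodes(tr)
    # brute force: species sets of child clades via ape::extract.clade
    n_tip <- length(tr$tip.label)
    want <- integer(0)
    for (node in (n_tip + 1):(n_tip + tr$Nnode)) {
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      sets <- lapply(kids, function(k) {
        tips <- if (k <= n_tip) tr$tip.label[k]
                else ape::extract.clade(tr, k)$tip.label
        unique(sub("\\|.*$", "", tips))
      })
      if (length(intersect(sets[[1]], sets[[2]])) > 0) want <- c(want, node)
    }
    expect_equal(got, want)
  }
})

test_that("duplication timing follows the asymmetric copy thresholds", {
  timing <- function(nwk) {
    classify_duplication_timing(ape::read.tree(text = nwk))
  }
  # 2 Minc + 1 Mhap: below thresholds, not duplicated
  r <- timing("(Minc|a,(Minc|b,Mhap|c));")
  expect_false(r$duplicated)
  expect_false(r$before_split || r$after_split)

  # symmetric pre-speciation duplication
  r2 <- timing("((Minc|a,Mhap|b),(Minc|c,Mhap|d));")
  expect_true(r2$duplicated)
  expect_true(r2$before_split)
  expect_false(r2$after_split)

  # M. hapla restricted duplication after the split
  r3 <- timing("((Mhap|a,Mhap|b),Minc|c);")
  expect_true(r3$duplicated)
  expect_true(r3$after_split)
  expect_false(r3$before_split)

  # three M. incognita copies count; two do not
  expect_true(timing("(Mhap|z,((Minc|a,Minc|b),Minc|c));")$after_split)
  expect_false(timing("((Minc|a,Minc|b),Mhap|z);")$duplicated)

  # before + continued after
  r4 <- timing("((Minc|a,Mhap|b),(Minc|c,(Mhap|d,Mhap|e)));")
  expect_true(r4$before_split && r4$after_split)
})

test_that("donor summaries count trees by division membership", {
  tax <- fixture_tax(); sp <- fixture_species()
  trees <- tibble::tibble(
    tree_id = c("t1", "t2", "t3"),
    tree = list(
      ape::read.tree(text = "((Minc|m1,Ecol|e1),Hsap|h1);"),
      ape::read.tree(text = "((Minc|m2,(Ecol|e2,Afum|f1)),Hsap|h2);"),
      ape::read.tree(text = "((Minc|m3,Scer|s1),Hsap|h3);")
    )
  )
  scan <- scan_gene_trees(trees, tax, sp)
  ds <- summarize_donor_taxa(scan$per_tree, tax, sp)
  get <- function(div, col) unname(ds[[col]][ds$division == div])
  expect_equal(get("Bacteria", "n_trees_any"), 2L)
  expect_equal(get("Bacteria", "n_trees_only"), 1L)
  expect_equal(get("Fungi", "n_trees_any"), 2L)
  expect_equal(get("Fungi", "n_trees_only"), 1L)
  expect_equal(get("Plant", "n_trees_any"), 0L)
})

test_that("planted topologies are recovered and vertical trees stay silent", {
  sim <- simulate_lgt_study(lgt_sim_config(seed = 31, n_lgt = 30,
                                           n_vertical = 60,
                                           n_contaminants = 3,
                                           n_clusters = 2L))
  sp <- fixture_species()
  scan <- scan_gene_trees(sim$trees[, c("tree_id", "tree")], sim$taxonomy, sp)
  lgt_trees <- sim$truth$representative_id[sim$truth$is_lgt]
  vertical_trees <- setdiff(sim$trees$tree_id, lgt_trees)
  expect_setequal(intersect(scan$per_tree$tree_id, lgt_trees),
                  intersect(sim$trees$tree_id, lgt_trees))
  expect_length(intersect(scan$per_tree$tree_id, vertical_trees), 0)
  # planted support grade is recovered for every LGT tree
  m <- merge(scan$per_tree, sim$truth,
             by.x = "tree_id", by.y = "representative_id")
  expect_equal(m$support, m$support_planted)
  # planted copy numbers are recovered
  expect_equal(m$n_minc, m$n_copies_minc)
  expect_equal(m$n_mhap, m$n_copies_mhap)
})
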