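make_proteins <- function(ids, species, seqs) {
  tibble::tibble(protein_id = ids, species = species,
                 length = nchar(seqs), sequence = seqs)
}

test_that("exact-duplicate removal keeps one representative per sequence", {
  p <- make_proteins(c("b", "a", "c"), c("Minc", "Minc", "Mhap"),
                     c("MKL", "MKL", "MAA"))
  d <- dedup_exact(p)
  expect_equal(sort(d$protein_id[d$is_representative]), c("a", "c"))
  expect_equal(d$representative_id[d$protein_id == "b"], "a")

  # all-distinct input is untouched
  q <- make_proteins(c("x", "y"), c("Minc", "Minc"), c("MA", "MC"))
  expect_true(all(dedup_exact(q)$is_representative))

  expect_error(dedup_exact(make_proteins("z", "Minc", "")), "z")
})

test_that("dedup survivors equal brute-force grouping on random inputs", {
  set.seed(7)
  seqs <- sample(replicate(12, paste(sample(LETTERS[1:4], 6, TRUE),
                                     collapse = "")), 40, replace = TRUE)
  p <- make_proteins(sprintf("p%02d", 1:40), "Minc", seqs)
  d <- dedup_exact(p)
  # pairwise-comparison oracle
  survivors <- character(0)
  for (s in unique(seqs)) {
    ids <- p$protein_id[p$sequence == s]
    survivors <- c(survivors, sort(ids)[1])
  }
  expect_setequal(d$protein_id[d$is_representative], survivors)
})

test_that("group restriction keeps nematode-only groups and finds singletons", {
  groups <- tibble::tribble(
    ~group_id, ~species, ~protein_id,
    "g1", "Minc", "m1", "g1", "Minc", "m2", "g1", "Mhap", "h1",
    "g2", "Minc", "m3", "g2", "Cele", "c1",
    "g3", "Mhap", "h2", "g3", "Xind", "x1"
  )
  proteins <- make_proteins(c("m1", "m2", "m3", "h1", "h2", "m9"),
                            c("Minc", "Minc", "Minc", "Mhap", "Mhap", "Minc"),
                            rep("MK", 6))
  res <- select_restricted_groups(groups, proteins = proteins)
  expect_setequal(unique(res$groups$group_id), "g1")
  expect_setequal(res$discarded_group_ids, c("g2", "g3"))
  expect_setequal(res$singletons, "m9") # grouped proteins are not singletons
  res2 <- select_restricted_groups(groups, ppn_ok = "Xind",
                                   proteins = proteins)
  expect_setequal(unique(res2$groups$group_id), c("g1", "g3"))
  expect_error(select_restricted_groups(groups, known_species = c("Minc",
                                                                  "Mhap")),
               "unknown species")
})

test_that("restricted set equals a species-scan oracle on synthetic groups", {
  sim <- simulate_lgt_study(lgt_sim_config(seed = 21, n_lgt = 25,
                                           n_vertical = 40,
                                           n_contaminants = 3,
                                           n_clusters = 2L))
  res <- select_restricted_groups(sim$groups)
  by_group <- split(sim$groups$species, sim$groups$group_id)
  want <- names(by_group)[vapply(by_group, function(s) {
    all(s %in% c("Minc", "Mhap")) && any(s %in% c("Minc", "Mhap"))
  }, logical(1))]
  expect_setequal(unique(res$groups$group_id), want)
})

test_that("representative choice prefers the longest Minc protein", {
  members <- tibble::tibble(
    protein_id = c("A", "B", "C"), species = c("Minc", "Minc", "Mhap"),
    length = c(300, 200, 400)
  )
  expect_equal(choose_representative(members)$protein_id, "A")
  expect_equal(
    choose_representative(members[members$species == "Mhap", ])$protein_id,
    "C")
  ties <- tibble::tibble(protein_id = c("B", "A"),
                         species = "Minc", length = c(250, 250))
  expect_equal(choose_representative(ties)$protein_id, "A")
  expect_error(choose_representative(
    tibble::tibble(protein_id = "z", species = "Cele", length = 100)),
    "neither")
})

vote_fixture <- function(subjects, evalues = NULL, cov = NULL, qlen = 100) {
  sp <- sim_species_table()
  taxid_of <- setNames(sp$taxid, sp$species)
  n <- length(subjects)
  tibble::tibble(
    query_id = "q1",
    subject_id = sprintf("s%02d", seq_len(n)),
    subject_taxid = unname(taxid_of[subjects]),
    percent_identity = 35,
    align_length_on_query = if (is.null(cov)) rep(50, n) else cov,
    evalue = if (is.null(evalues)) seq(1e-30, 1e-10, length.out = n)
             else evalues,
    bitscore = seq(400, 100, length.out = n)
  )
}

test_that("the non-metazoan vote applies the inclusive 50% rule", {
  tax <- fixture_tax()
  proteins <- make_proteins("q1", "Minc", paste(rep("M", 100), collapse = ""))

  # exactly half non-metazoan of 10 -> candidate
  hits <- vote_fixture(c(rep("Ecol", 5), rep("Hsap", 5)))
  v <- vote_non_metazoan(hits, proteins, tax)
  expect_equal(v$status, "candidate")
  expect_equal(v$vote_fraction, 0.5)

  # two PPN hits at the best ranks are skipped before the window
  hits2 <- vote_fixture(c("Mhap", "Mhap", rep("Ecol", 4), rep("Hsap", 6)))
  v2 <- vote_non_metazoan(hits2, proteins, tax)
  expect_equal(v2$status, "rejected")
  expect_equal(v2$vote_fraction, 0.4)
  expect_equal(v2$n_hits_used, 10)

  # three surviving hits, all fungal -> candidate over the survivors
  hits3 <- vote_fixture(c("Scer", "Afum", "Scer"))
  v3 <- vote_non_metazoan(hits3, proteins, tax)
  expect_equal(v3$status, "candidate")
  expect_equal(v3$vote_fraction, 1.0)
  expect_equal(v3$n_hits_used, 3)

  # e-value and coverage thresholds remove hits; none left -> no_hit
  hits4 <- vote_fixture("Ecol", evalues = 0.5)
  expect_equal(vote_non_metazoan(hits4, proteins, tax)$status, "no_hit")
  hits5 <- vote_fixture("Ecol", cov = 10) # 10% of a 100 aa query
  expect_equal(vote_non_metazoan(hits5, proteins, tax)$status, "no_hit")
})

test_that("adding a non-metazoan hit never flips candidate to rejected", {
  tax <- fixture_tax()
  proteins <- make_proteins("q1", "Minc", paste(rep("M", 100), collapse = ""))
  set.seed(13)
  for (i in 1:25) {
    n_nm <- sample(0:8, 1); n_met <- sample(0:8, 1)
    if (n_nm + n_met == 0) next
    subjects <- sample(c(rep("Ecol", n_nm), rep("Hsap", n_met)))
    hits <- vote_fixture(subjects)
    before <- vote_non_metazoan(hits, proteins, tax)
    extra <- vote_fixture("Bsub", evalues = 1e-40)
    extra$subject_id <- "s_extra"
    after <- vote_non_metazoan(dplyr::bind_rows(extra, hits), proteins, tax)
    if (before$status == "candidate") {
      expect_equal(after$status, "candidate")
    }
  }
})

test_that("contamination requires >80% identity over >50% of the query", {
  tax <- fixture_tax()
  proteins <- make_proteins("q1", "Minc", paste(rep("M", 100), collapse = ""))
  base <- vote_fixture("Ecol")
  flag <- function(id, cov) {
    h <- base
    h$percent_identity <- id
    h$align_length_on_query <- cov
    flag_contaminants(h, proteins, tax)$contaminant
  }
  expect_true(flag(85, 60))
  expect_false(flag(85, 40))   # coverage fails
  expect_false(flag(80.0, 60)) # strictly more than 80 required
  expect_false(flag(85, 50))   # strictly more than half required
  # metazoan subject never flags
  h <- vote_fixture("Hsap"); h$percent_identity <- 99
  h$align_length_on_query <- 90
  expect_false(flag_contaminants(h, proteins, tax)$contaminant)
})

test_that("in-paralog classification applies the 2:1 discard rule", {
  groups <- tibble::tribble(
    ~group_id, ~species, ~protein_id,
    "g1", "Minc", "a1", "g1", "Minc", "a2", "g1", "Mhap", "a3",
    "g2", "Minc", "b1", "g2", "Minc", "b2", "g2", "Minc", "b3",
    "g3", "Mhap", "c1", "g3", "Mhap", "c2",
    "g4", "Minc", "d1", "g4", "Mhap", "d2"
  )
  res <- count_inparalog_groups(groups, lgt_ids = c("a1", "b1"))
  cls <- setNames(res$per_group$class, res$per_group$group_id)
  expect_equal(unname(cls["g1"]), "discarded-2:1")
  expect_equal(unname(cls["g2"]), "species-specific-duplication")
  expect_equal(unname(cls["g3"]), "species-specific-duplication")
  expect_equal(unname(cls["g4"]), "not-duplicated")
  lgt_dup <- res$summary$n_groups_lgt[
    res$summary$class == "species-specific-duplication"]
  expect_equal(lgt_dup, 1L)
})
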