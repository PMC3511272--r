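gene_row <- function(id, sc, start, end, lgt = TRUE) {
  tibble::tibble(gene_id = id, scaffold_id = sc, start = start, end = end,
                 strand = "+", is_lgt = lgt)
}

test_that("cluster chaining follows the strict 50 kb gap and min size", {
  genes <- dplyr::bind_rows(
    gene_row("a", "s1", 1, 1000),
    gene_row("b", "s1", 20000, 21000),
    gene_row("c", "s1", 60000, 61000)
  )
  cl <- detect_lgt_clusters(genes)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3L)
  expect_equal(cl$gene_ids[[1]], c("a", "b", "c"))

  # two genes only: below min size
  expect_equal(nrow(detect_lgt_clusters(genes[1:2, ])), 0)

  # a gap of exactly 50 kb breaks the chain (strict inequality)
  genes2 <- dplyr::bind_rows(
    gene_row("a", "s1", 1, 1000),
    gene_row("b", "s1", 51001, 52000), # gap = 50000, not < 50000
    gene_row("c", "s1", 60000, 61000)
  )
  expect_equal(nrow(detect_lgt_clusters(genes2)), 0)
  genes3 <- genes2
  genes3$start[2] <- 51000; genes3$end[2] <- 52000 # gap = 49999
  expect_equal(nrow(detect_lgt_clusters(genes3)), 1)

  # non-LGT genes never cluster
  genes$is_lgt <- FALSE
  expect_equal(nrow(detect_lgt_clusters(genes)), 0)
})

test_that("clusters equal the quadratic chaining oracle and ignore order", {
  set.seed(5)
  genes <- dplyr::bind_rows(lapply(1:200, function(i) {
    start <- sample(1:500000, 1)
    gene_row(sprintf("g%03d", i), sample(c("s1", "s2", "s3"), 1),
             start, start + sample(500:3000, 1), lgt = runif(1) < 0.7)
  }))
  got <- detect_lgt_clusters(genes)
  want <- oracle_clusters(genes)
  expect_equal(length(got$gene_ids), length(want))
  expect_setequal(vapply(got$gene_ids, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
  shuffled <- genes[sample(nrow(genes)), ]
  got2 <- detect_lgt_clusters(shuffled)
  expect_setequal(vapply(got2$gene_ids, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
  expect_lte(sum(got$size), sum(genes$is_lgt))
})

test_that("TE window counts match the naive overlap oracle and are monotone", {
  scaffolds <- tibble::tibble(scaffold_id = "s1", length = 100000L)
  gene <- gene_row("g1", "s1", 10000, 12000)
  tes <- tibble::tibble(
    te_id = c("t1", "t2", "t3", "t4"),
    scaffold_id = "s1",
    start = c(12010, 9000, 13950, 50000),
    end = c(12050, 9100, 14100, 50200)
  )
  counts <- vapply(c(200, 500, 1000, 2000), function(w) {
    count_te_in_windows(gene, tes, scaffolds, w)$n_te
  }, integer(1))
  # t1 within 200; t2 within 1000 (left); t3 straddles the 2000 flank edge
  expect_equal(counts, c(1L, 1L, 2L, 3L))
  expect_true(all(diff(counts) >= 0))

  # no TEs anywhere near
  far <- tibble::tibble(te_id = "t9", scaffold_id = "s1",
                        start = 90000, end = 90100)
  expect_equal(count_te_in_windows(gene, far, scaffolds, 2000)$n_te, 0L)

  # a TE spanning the whole gene and both flanks counts once
  spanning <- tibble::tibble(te_id = "t8", scaffold_id = "s1",
                             start = 9500, end = 12500)
  expect_equal(count_te_in_windows(gene, spanning, scaffolds, 500)$n_te, 1L)

  set.seed(11)
  genes <- dplyr::bind_rows(lapply(1:30, function(i) {
    s <- sample(5000:90000, 1)
    gene_row(sprintf("g%02d", i), "s1", s, s + 1500)
  }))
  tes_r <- tibble::tibble(
    te_id = sprintf("t%03d", 1:150), scaffold_id = "s1",
    start = sample(1:99000, 150, replace = TRUE)
  )
  tes_r$end <- tes_r$start + sample(50:900, 150, replace = TRUE)
  for (w in c(200, 2000)) {
    got <- count_te_in_windows(genes, tes_r, scaffolds, w)$n_te
    want <- vapply(seq_len(nrow(genes)), function(i) {
      oracle_te_count(genes[i, ], tes_r, 100000L, w)
    }, integer(1))
    expect_equal(got, want)
  }
})

test_that("TE-density chi-square behaves at the null and on fixed toys", {
  same <- c(0L, 1L, 2L, 0L, 1L)
  null_test <- compare_te_density(same, same)
  expect_equal(null_test$statistic, 0)
  expect_equal(null_test$p.value, 1)
  expect_equal(null_test$df, 1L)

  toy <- compare_te_density(c(0L, 1L, 2L), c(0L, 1L, 2L))
  expect_equal(toy$means$mean, c(1, 1))
  expect_equal(toy$means$se, c(0.577, 0.577), tolerance = 1e-3)

  # tidiers
  td <- tidy(compare_te_density(c(0L, 2L, 3L), c(0L, 0L, 1L)))
  expect_equal(nrow(td), 2)
  gl <- glance(compare_te_density(c(0L, 2L, 3L), c(0L, 0L, 1L)))
  expect_equal(gl$df, 1L)
  expect_error(compare_te_density(integer(0), 1L), "non-empty")
})

test_that("planted 2x TE enrichment is detected at larger windows", {
  set.seed(23)
  sim <- simulate_lgt_genome(n_lgt = 150, n_other = 150, seed = 23)
  report <- te_density_report(sim$genes, sim$tes, sim$scaffolds)
  wide <- tidyr::pivot_wider(report[, c("window", "class", "mean")],
                             names_from = "class", values_from = "mean")
  expect_true(all(wide$LGT[wide$window >= 500] >
                    wide$Other[wide$window >= 500]))
  # means grow with window size in both classes
  expect_true(all(diff(wide$LGT) >= 0))
  expect_true(all(diff(wide$Other) >= 0))
  expect_lt(report$p.value[report$window == 2000][1], 0.05)
})

test_that("scaffold end positions scale to [0, 0.5]", {
  scaffolds <- tibble::tibble(scaffold_id = "s1", length = 100000L)
  center <- scaffold_end_positions(gene_row("g1", "s1", 49500, 50500),
                                   scaffolds)
  expect_equal(center$rel_end_position, 0.5, tolerance = 1e-4)
  tip <- scaffold_end_positions(gene_row("g2", "s1", 1, 100), scaffolds)
  expect_lt(tip$rel_end_position, 0.01)

  set.seed(3)
  genes <- dplyr::bind_rows(lapply(1:300, function(i) {
    s <- sample(1:99000, 1)
    gene_row(sprintf("g%03d", i), "s1", s, min(s + 999, 100000),
             lgt = i <= 150)
  }))
  res <- compare_scaffold_end_positions(genes, scaffolds)
  expect_true(res$p.value > 0.001) # uniform placements: no end clustering
})

test_that("GC content counts letters and excludes N", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GCNN"), 100) # N dropped from the denominator
  expect_error(gc_content(""), "empty")
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, TRUE), collapse = "")
  chars <- strsplit(s, "")[[1]]
  want <- 100 * sum(chars %in% c("G", "C")) /
    sum(chars %in% c("A", "C", "G", "T"))
  expect_equal(gc_content(s), want)
})

test_that("codon usage tables normalize within amino-acid classes", {
  tab <- codon_usage_table("ATGATG")
  atg <- tab[tab$codon == "ATG", ]
  expect_equal(atg$occurrence, 2L)
  expect_equal(atg$fraction, 1)
  expect_equal(atg$frequency, 1)

  set.seed(8)
  cds <- vapply(1:20, function(i) {
    paste(sample(names(Biostrings::GENETIC_CODE), 300, TRUE), collapse = "")
  }, character(1))
  tab2 <- codon_usage_table(cds)
  sums <- tapply(tab2$fraction, tab2$amino_acid, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(tab2$frequency), 1, tolerance = 1e-12)
  expect_equal(sum(tab2$occurrence), 20 * 300)

  # trimming and N handling
  expect_warning(tab3 <- codon_usage_table("ATGAT"), "trimmed")
  expect_equal(sum(tab3$occurrence), 1L)
  tab4 <- codon_usage_table("ATGNNNTGG")
  expect_equal(sum(tab4$occurrence), 2L)
  expect_equal(attr(tab4, "skipped_codons"), 1L)
})

test_that("codon usage comparison computes per-class differences", {
  set.seed(8)
  cds <- vapply(1:10, function(i) {
    paste(sample(names(Biostrings::GENETIC_CODE), 300, TRUE), collapse = "")
  }, character(1))
  tab <- codon_usage_table(cds)
  self_cmp <- compare_codon_usage(tab, tab)
  expect_equal(self_cmp$mean_fraction_diff, 0)
  expect_true(all(self_cmp$per_codon$fraction_diff == 0, na.rm = TRUE))

  # hand-built two-codon class: fractions 0.6/0.4 vs 0.5/0.5
  a <- tab; b <- tab
  lys <- which(a$amino_acid == "K") # AAA, AAG
  a$fraction[lys] <- c(0.6, 0.4)
  b$fraction[lys] <- c(0.5, 0.5)
  cmp <- compare_codon_usage(a, b)
  expect_equal(cmp$per_codon$fraction_diff[lys], c(0.1, 0.1))
  k_row <- cmp$per_amino_acid[cmp$per_amino_acid$amino_acid == "K", ]
  expect_equal(k_row$mean_fraction_diff, 0.1)
  expect_true("K" %in% cmp$flagged_fraction)
  expect_equal(glance(cmp)$n_flagged_fraction, 1)
})
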