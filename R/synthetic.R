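#' Generator configuration for the synthetic miniature study
#'
#' The generator emits a fully consistent miniature of the study's inputs —
#' taxonomy, proteomes, ortholog groups, BLAST tables, gene trees, genome
#' annotation, CDS set, domain/GO tables, mobile-element hits — with
#' ground-truth labels. Defaults mirror the study's observed conditions: the
#' donor-division mix follows the reported donor-clade counts (Bacteria 72,
#' Protist 51, Fungi 21, Plant 19, Archaea 4 of 141 trees), 92/141 of LGT
#' trees contain both nematodes, 83% of those are duplicated, 79% of
#' duplications start before the species split and 72% of those continue
#' after it, 52/141 trees carry strong (A+B) support, and TE density around
#' LGT genes is doubled relative to other genes.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_lgt,n_vertical,n_contaminants Planted gene counts per class.
#' @param donor_mix Named weights over donor divisions.
#' @param p_both_species Probability an LGT gene is retained in both
#'   nematodes.
#' @param p_duplicated,p_before,p_after_given_before Duplication-timing
#'   probabilities within the both-species cohort.
#' @param p_strong Probability of planting an A+B (strong-support) topology.
#' @param p_root_call Probability the LGT node is the tree root (no external
#'   clade, support capped at A).
#' @param p_decoy_21 Probability a non-duplicated both-species gene is
#'   planted as the 2:1 Minc:Mhap configuration that the in-paralog filter
#'   must discard.
#' @param p_mixed_donor Probability a donor clade mixes a second division.
#' @param n_exact_duplicates Redundant (100% identical) protein records
#'   planted for the dedup stage.
#' @param frac_vertical_unclustered Fraction of vertical genes not clustered
#'   with other metazoans (they reach the BLAST vote and must be rejected).
#' @param frac_no_hit Fraction of unclustered vertical genes returning no
#'   usable BLAST hit.
#' @param te_rate Mean TEs planted in the 2 kb flanks of a non-LGT gene.
#' @param te_enrichment Multiplier on `te_rate` for LGT genes.
#' @param n_clusters,cluster_size_range Genomic clusters of LGT genes planted
#'   (count, and inclusive size range per cluster).
#' @param scaffold_length Scaffold length in bp.
#' @param cds_codon_range Codons per CDS (inclusive range).
#' @param codon_divergence Target mean per-amino-acid codon-fraction
#'   difference between the LGT and background codon profiles.
#' @param mobile_loose_frac,mobile_strict_frac Fractions of LGT genes with
#'   mobile-element hits at the loose stage, and of those passing the strict
#'   stage (defaults 146/609 and 32/146).
#' @param mobile_type_mix Element-type weights for best hits.
#' @export
lgt_sim_config <- function(seed = 1L,
                           n_lgt = 50L,
                           n_vertical = 200L,
                           n_contaminants = 10L,
                           donor_mix = c(Bacteria = 72, Protist = 51,
                                         Fungi = 21, Plant = 19, Archaea = 4),
                           p_both_species = 92 / 141,
                           p_duplicated = 0.83,
                           p_before = 0.79,
                           p_after_given_before = 43 / 60,
                           p_strong = 52 / 141,
                           p_root_call = 0.10,
                           p_decoy_21 = 0.25,
                           p_mixed_donor = 0.15,
                           n_exact_duplicates = 10L,
                           frac_vertical_unclustered = 0.30,
                           frac_no_hit = 0.05,
                           te_rate = 1.0,
                           te_enrichment = 2.0,
                           n_clusters = 3L,
                           cluster_size_range = c(3L, 5L),
                           scaffold_length = 300000L,
                           cds_codon_range = c(150L, 450L),
                           codon_divergence = 0.02,
                           mobile_loose_frac = 146 / 609,
                           mobile_strict_frac = 32 / 146,
                           mobile_type_mix = c(plasmid = 117, prophage = 19,
                                               virus = 10)) {
  probs <- c(p_both_species, p_duplicated, p_before, p_after_given_before,
             p_strong, p_root_call, p_decoy_21, p_mixed_donor,
             frac_vertical_unclustered, frac_no_hit,
             mobile_loose_frac, mobile_strict_frac)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  cfg <- as.list(environment())
  if (cfg$n_clusters * max(cfg$cluster_size_range) > cfg$n_lgt) {
    abort("cluster specification exceeds the number of LGT genes")
  }
  cfg
}

#' Fixture taxonomy and species tables
#'
#' The generator's fixed miniature taxonomy: the 16 metazoan study species
#' (including the two root-knot nematodes), two extra plant-parasitic
#' nematodes, donor species across the five divisions, and a virus node
#' exercising the Other label. `sim_species_table()` maps the species tags
#' used in record labels and tree leaves to taxids, roles and divisions.
#'
#' @return Tibbles: a node table consumable by `lgt_taxonomy()`, and the
#'   species table.
#' @export
sim_taxonomy_nodes <- function() {
  tibble(
    taxid = c(1L, 131567L, 2759L, 33208L, 6072L, 6231L, 6300L, 189290L,
              6306L, 6305L, 211184L, 183075L, 211225L, 61503L, 6236L, 6239L,
              6238L, 54126L, 6279L, 6656L, 7227L, 7091L, 7070L, 7711L, 9606L,
              10090L, 7739L, 7719L, 7668L, 6073L, 45351L, 10226L, 10228L,
              2L, 562L, 1423L, 305L, 382L, 2157L, 2190L, 2287L,
              4751L, 746128L, 4932L, 33090L, 3702L, 4530L,
              33634L, 4787L, 554915L, 44689L, 33630L, 5811L, 10239L),
    parent_taxid = c(1L, 1L, 131567L, 2759L, 33208L, 6072L, 6231L, 6300L,
                     189290L, 189290L, 6231L, 211184L, 6231L, 211225L, 6231L,
                     6236L, 6236L, 6231L, 6231L, 6072L, 6656L, 6656L, 6656L,
                     6072L, 7711L, 7711L, 7711L, 7711L, 6072L, 6072L, 6073L,
                     33208L, 10226L,
                     131567L, 2L, 2L, 2L, 2L, 131567L, 2157L, 2157L,
                     2759L, 4751L, 4751L, 2759L, 33090L, 33090L,
                     2759L, 33634L, 2759L, 554915L, 2759L, 33630L, 1L),
    name = c("root", "cellular organisms", "Eukaryota", "Metazoa",
             "Eumetazoa", "Nematoda", "Tylenchida", "Meloidogyne",
             "Meloidogyne incognita", "Meloidogyne hapla", "Triplonchida",
             "Paratrichodorus", "Dorylaimina", "Xiphinema index",
             "Rhabditida", "Caenorhabditis elegans",
             "Caenorhabditis briggsae", "Pristionchus pacificus",
             "Brugia malayi", "Arthropoda", "Drosophila melanogaster",
             "Bombyx mori", "Tribolium castaneum", "Chordata",
             "Homo sapiens", "Mus musculus", "Branchiostoma floridae",
             "Ciona intestinalis", "Strongylocentrotus purpuratus",
             "Cnidaria", "Nematostella vectensis", "Placozoa",
             "Trichoplax adhaerens",
             "Bacteria", "Escherichia coli", "Bacillus subtilis",
             "Ralstonia solanacearum", "Sinorhizobium meliloti", "Archaea",
             "Methanocaldococcus jannaschii", "Sulfolobus",
             "Fungi", "Aspergillus fumigatus", "Saccharomyces cerevisiae",
             "Viridiplantae", "Arabidopsis thaliana", "Oryza sativa",
             "Stramenopiles", "Phytophthora infestans", "Amoebozoa",
             "Dictyostelium discoideum", "Alveolata", "Toxoplasma gondii",
             "Viruses")
  )
}

#' @rdname sim_taxonomy_nodes
#' @export
sim_species_table <- function() {
  tibble(
    species = c("Minc", "Mhap", "Xind", "Ptri",
                "Cele", "Cbri", "Ppac", "Bmal", "Dmel", "Bmor", "Tcas",
                "Hsap", "Mmus", "Bflo", "Cint", "Spur", "Nvec", "Tadh",
                "Ecol", "Bsub", "Rsol", "Smel", "Mjan", "Ssol",
                "Afum", "Scer", "Atha", "Osat", "Pinf", "Ddis", "Tgon"),
    taxid = c(6306L, 6305L, 61503L, 183075L,
              6239L, 6238L, 54126L, 6279L, 7227L, 7091L, 7070L,
              9606L, 10090L, 7739L, 7719L, 7668L, 45351L, 10228L,
              562L, 1423L, 305L, 382L, 2190L, 2287L,
              746128L, 4932L, 3702L, 4530L, 4787L, 44689L, 5811L),
    role = c("focal", "focal", "ppn", "ppn",
             rep("metazoan", 14),
             rep("donor", 13)),
    division = c(rep("Metazoa", 18),
                 "Bacteria", "Bacteria", "Bacteria", "Bacteria",
                 "Archaea", "Archaea", "Fungi", "Fungi", "Plant", "Plant",
                 "Protist", "Protist", "Protist")
  )
}

donor_species_of <- function(division) {
  sp <- sim_species_table()
  sp$species[sp$role == "donor" & sp$division == division]
}

random_aa_seq <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(n, function(len) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}

# ---- gene plan -------------------------------------------------------------

sim_gene_plan <- function(cfg) {
  plan_lgt <- lapply(seq_len(cfg$n_lgt), function(i) {
    division <- sample(names(cfg$donor_mix), 1, prob = cfg$donor_mix)
    both <- runif(1) < cfg$p_both_species
    if (both) {
      duplicated <- runif(1) < cfg$p_duplicated
      if (duplicated) {
        before <- runif(1) < cfg$p_before
        after <- if (before) runif(1) < cfg$p_after_given_before else TRUE
        timing <- if (before && after) "both" else if (before) "before"
                  else "after"
        if (timing == "before") {
          nm <- 2L; nh <- 2L
        } else if (timing == "both") {
          if (runif(1) < 0.5) { nm <- 2L; nh <- 3L } else { nm <- 4L; nh <- 2L }
        } else {
          if (runif(1) < 0.5) { nm <- 1L; nh <- 2L } else { nm <- 3L; nh <- 1L }
        }
      } else {
        timing <- "none"
        if (runif(1) < cfg$p_decoy_21) { nm <- 2L; nh <- 1L }
        else { nm <- 1L; nh <- 1L }
      }
    } else {
      species <- if (runif(1) < 0.65) "Minc" else "Mhap"
      duplicated <- runif(1) < 0.4
      if (duplicated) {
        timing <- "after"
        nm <- if (species == "Minc") 3L else 0L
        nh <- if (species == "Mhap") 2L else 0L
      } else {
        timing <- "none"
        nm <- if (species == "Minc") 1L else 0L
        nh <- if (species == "Mhap") 1L else 0L
      }
    }
    at_root <- runif(1) < cfg$p_root_call
    strong <- !at_root && runif(1) < cfg$p_strong
    tibble(
      gene_id = sprintf("lgt%03d", i), class = "lgt",
      donor_division = division,
      mixed_donor = runif(1) < cfg$p_mixed_donor,
      both_species = both, duplicated = duplicated,
      duplication_timing = timing,
      n_copies_minc = nm, n_copies_mhap = nh,
      support_planted = if (strong) "A_plus_B" else "A",
      at_root = at_root
    )
  })
  plan_vrt <- tibble(
    gene_id = sprintf("vrt%03d", seq_len(cfg$n_vertical)), class = "vertical",
    donor_division = NA_character_, mixed_donor = FALSE,
    both_species = FALSE, duplicated = FALSE, duplication_timing = "none",
    n_copies_minc = 1L, n_copies_mhap = 0L,
    support_planted = NA_character_, at_root = FALSE
  )
  plan_vrt$unclustered <- runif(cfg$n_vertical) < cfg$frac_vertical_unclustered
  plan_vrt$no_hit <- plan_vrt$unclustered &
    runif(cfg$n_vertical) < cfg$frac_no_hit
  plan_ctm <- tibble(
    gene_id = sprintf("ctm%03d", seq_len(cfg$n_contaminants)),
    class = "contaminant",
    donor_division = "Bacteria", mixed_donor = FALSE,
    both_species = FALSE, duplicated = FALSE, duplication_timing = "none",
    n_copies_minc = 1L, n_copies_mhap = 0L,
    support_planted = NA_character_, at_root = FALSE
  )
  plan <- bind_rows(bind_rows(plan_lgt), plan_vrt, plan_ctm)
  plan$unclustered[is.na(plan$unclustered)] <- TRUE
  plan$no_hit[is.na(plan$no_hit)] <- FALSE
  plan
}

# ---- proteins and groups ---------------------------------------------------

sim_proteins <- function(plan, cfg) {
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    g <- plan[i, ]
    n_m <- g$n_copies_minc
    n_h <- g$n_copies_mhap
    ids <- c(if (n_m > 0) sprintf("%s_Minc_%d", g$gene_id, seq_len(n_m)),
             if (n_h > 0) sprintf("%s_Mhap_%d", g$gene_id, seq_len(n_h)))
    species <- c(rep("Minc", n_m), rep("Mhap", n_h))
    lens <- sample(150:600, length(ids), replace = TRUE)
    rows[[i]] <- tibble(protein_id = ids, species = species, length = lens,
                        gene_id = g$gene_id)
  }
  proteins <- bind_rows(rows)
  # homolog proteins of other metazoan species for clustered vertical genes
  vert <- plan %>% filter(.data$class == "vertical", !.data$unclustered)
  others <- sim_species_table() %>% filter(.data$role == "metazoan")
  extra <- lapply(vert$gene_id, function(gid) {
    partners <- sample(others$species, sample(1:3, 1))
    tibble(protein_id = sprintf("%s_%s_1", gid, partners),
           species = partners,
           length = sample(150:600, length(partners), replace = TRUE),
           gene_id = gid)
  })
  proteins <- bind_rows(proteins, bind_rows(extra))
  proteins$sequence <- random_aa_seq(proteins$length)

  # planted exact duplicates: identical sequence under a new id, removed at
  # the dedup stage (ids sort after the original, which therefore survives)
  dup_pool <- proteins %>% filter(.data$species %in% c("Minc", "Mhap"))
  dup_idx <- sample(seq_len(nrow(dup_pool)),
                    min(cfg$n_exact_duplicates, nrow(dup_pool)))
  dups <- dup_pool[dup_idx, ] %>%
    mutate(protein_id = paste0(.data$protein_id, "_redund"))
  bind_rows(proteins, dups)
}

sim_groups <- function(plan, proteins) {
  memberships <- proteins %>%
    filter(!grepl("_redund$", .data$protein_id)) %>%
    semi_join(
      bind_rows(
        plan %>% filter(.data$class == "lgt",
                        .data$n_copies_minc + .data$n_copies_mhap >= 2),
        plan %>% filter(.data$class == "vertical", !.data$unclustered)
      ),
      by = "gene_id"
    ) %>%
    mutate(group_id = paste0("grp_", .data$gene_id)) %>%
    select("group_id", "species", "protein_id")
  memberships
}

# ---- BLAST tables ----------------------------------------------------------

sim_blast <- function(plan, proteins, cfg) {
  sp <- sim_species_table()
  taxid_of <- setNames(sp$taxid, sp$species)
  metazoan_pool <- c("Hsap", "Cele", "Dmel", "Mmus", "Spur")
  reps <- sim_representatives(plan, proteins)

  make_hits <- function(q, subjects, identities, cov_frac, evalues, qlen) {
    tibble(
      query_id = q,
      subject_id = sprintf("%s_db_%d", subjects, seq_along(subjects)),
      subject_taxid = unname(taxid_of[subjects]),
      percent_identity = round(identities, 1),
      align_length_on_query = pmax(1L, as.integer(round(cov_frac * qlen))),
      evalue = evalues,
      bitscore = round(500 - 400 * seq_along(subjects) / length(subjects), 1)
    )
  }

  rows <- lapply(seq_len(nrow(plan)), function(i) {
    g <- plan[i, ]
    q <- reps$representative_id[reps$gene_id == g$gene_id]
    qlen <- proteins$length[proteins$protein_id == q]
    if (g$class == "vertical") {
      if (!g$unclustered || g$no_hit) return(NULL)
      n_nm <- sample(0:4, 1)
      donors <- sample(donor_species_of("Bacteria"), n_nm, replace = TRUE)
      mets <- sample(metazoan_pool, 10 - n_nm, replace = TRUE)
      subjects <- sample(c(donors, mets))
      return(make_hits(q, subjects, runif(10, 30, 60), runif(10, 0.4, 0.9),
                       sort(10^runif(10, -60, -3)), qlen))
    }
    donor_sp <- donor_species_of(g$donor_division)
    if (g$class == "contaminant") {
      subjects <- c(sample(donor_sp, 1),
                    sample(donor_sp, 9, replace = TRUE))
      identities <- c(runif(1, 96, 99), runif(9, 30, 40))
      cov <- c(runif(1, 0.85, 1.0), runif(9, 0.4, 0.9))
      ev <- sort(10^runif(10, -80, -10))
      return(make_hits(q, subjects, identities, cov, ev, qlen))
    }
    # lgt gene: a couple of self/PPN hits at the top, then a clean
    # majority (>= 80%) of non-metazoan hits among the next ten
    n_ppn <- sample(0:2, 1)
    n_nm <- sample(8:10, 1)
    ppn_subj <- if (n_ppn > 0) sample(c("Mhap", "Minc"), n_ppn,
                                      replace = TRUE) else character(0)
    nm_subj <- sample(donor_sp, n_nm, replace = TRUE)
    met_subj <- sample(metazoan_pool, 10 - n_nm, replace = TRUE)
    subjects <- c(ppn_subj, sample(c(nm_subj, met_subj)))
    n_tot <- length(subjects)
    identities <- c(runif(n_ppn, 60, 95), runif(n_tot - n_ppn, 28, 40))
    cov <- runif(n_tot, 0.4, 0.9)
    ev <- sort(10^runif(n_tot, -60, -5))
    h <- make_hits(q, subjects, identities, cov, ev, qlen)
    # one sub-threshold noise hit that the e-value filter must drop
    noise <- make_hits(q, sample(metazoan_pool, 1), runif(1, 25, 35),
                       runif(1, 0.4, 0.8), 0.5, qlen)
    bind_rows(h, noise)
  })
  bind_rows(rows)
}

sim_representatives <- function(plan, proteins) {
  originals <- proteins %>% filter(!grepl("_redund$", .data$protein_id))
  reps <- originals %>%
    filter(.data$species %in% c("Minc", "Mhap")) %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      pool <- d %>% filter(.data$species == "Minc")
      if (nrow(pool) == 0) pool <- d %>% filter(.data$species == "Mhap")
      pool %>% arrange(dplyr::desc(.data$length), .data$protein_id) %>% slice(1)
    }) %>%
    ungroup() %>%
    select("gene_id", representative_id = "protein_id")
  reps
}

# ---- gene trees ------------------------------------------------------------

receiver_newick <- function(g) {
  m <- function(k) sprintf("Minc|%s_Minc_%d", g$gene_id, k)
  h <- function(k) sprintf("Mhap|%s_Mhap_%d", g$gene_id, k)
  nm <- g$n_copies_minc; nh <- g$n_copies_mhap
  timing <- g$duplication_timing
  if (!g$both_species) {
    if (nm == 1 && nh == 0) return(m(1))
    if (nm == 0 && nh == 1) return(h(1))
    if (nm >= 3) return(sprintf("((%s,%s),%s)", m(1), m(2), m(3)))
    if (nh >= 2) return(sprintf("(%s,%s)", h(1), h(2)))
  }
  if (timing == "none") {
    if (nm == 2 && nh == 1) {
      return(sprintf("(%s,(%s,%s))", m(1), m(2), h(1)))
    }
    return(sprintf("(%s,%s)", m(1), h(1)))
  }
  if (timing == "before") {
    return(sprintf("((%s,%s),(%s,%s))", m(1), h(1), m(2), h(2)))
  }
  if (timing == "both") {
    if (nh == 3) {
      return(sprintf("((%s,%s),(%s,(%s,%s)))", m(1), h(1), m(2), h(2), h(3)))
    }
    return(sprintf("((%s,%s),((%s,(%s,%s)),%s))",
                   m(1), h(1), m(2), m(3), m(4), h(2)))
  }
  # after only
  if (nh == 2) return(sprintf("(%s,(%s,%s))", m(1), h(1), h(2)))
  sprintf("(%s,((%s,%s),%s))", h(1), m(1), m(2), m(3))
}

donor_newick <- function(g, min_k = 1) {
  pool <- donor_species_of(g$donor_division)
  k <- sample(min_k:3, 1)
  sp <- sample(pool, k, replace = TRUE)
  if (g$mixed_donor) {
    other_div <- sample(setdiff(c("Bacteria", "Fungi", "Plant", "Archaea",
                                  "Protist"), g$donor_division), 1)
    sp <- c(sp, sample(donor_species_of(other_div), 1))
  }
  leaves <- sprintf("%s|%s_%s_d%d", sp, g$gene_id, sp, seq_along(sp))
  while (length(leaves) > 1) {
    leaves <- c(sprintf("(%s,%s)", leaves[1], leaves[2]), leaves[-(1:2)])
  }
  leaves
}

external_newick <- function(g) {
  if (g$at_root) return(NA_character_)
  mets <- sample(c("Hsap", "Cele", "Dmel", "Spur"), 2)
  met_leaves <- sprintf("%s|%s_%s_e%d", mets, g$gene_id, mets,
                        seq_along(mets))
  if (identical(g$support_planted, "A_plus_B")) {
    nm_sp <- sample(c("Atha", "Scer", "Ddis", "Bsub"), 1)
    nm_leaf <- sprintf("%s|%s_%s_e9", nm_sp, g$gene_id, nm_sp)
    sprintf("(%s,(%s,%s))", nm_leaf, met_leaves[1], met_leaves[2])
  } else {
    sprintf("(%s,%s)", met_leaves[1], met_leaves[2])
  }
}

sim_trees <- function(plan, reps) {
  lgt <- plan %>% filter(.data$class == "lgt")
  vert <- plan %>% filter(.data$class == "vertical", .data$unclustered,
                          !.data$no_hit)
  rows <- list()
  for (i in seq_len(nrow(lgt))) {
    g <- lgt[i, ]
    # a rooted pattern needs >= 3 leaves: widen the donor clade when a
    # single-copy receiver sits at the root (no external clade)
    min_k <- if (g$at_root && g$n_copies_minc + g$n_copies_mhap < 2) 2 else 1
    rd <- sprintf("(%s,%s)", receiver_newick(g), donor_newick(g, min_k))
    ext <- external_newick(g)
    nwk <- if (is.na(ext)) paste0(rd, ";") else sprintf("(%s,%s);", rd, ext)
    rows[[length(rows) + 1]] <- tibble(
      tree_id = reps$representative_id[reps$gene_id == g$gene_id],
      gene_id = g$gene_id,
      tree = list(ape::read.tree(text = nwk))
    )
  }
  for (i in seq_len(nrow(vert))) {
    g <- vert[i, ]
    sisters <- sample(c("Cele", "Cbri", "Ppac"), 1)
    outs <- sample(c("Hsap", "Dmel", "Mmus", "Spur"), 2)
    nwk <- sprintf("((Minc|%s_Minc_1,%s|%s_%s_1),(%s|%s_%s_1,%s|%s_%s_1));",
                   g$gene_id, sisters, g$gene_id, sisters,
                   outs[1], g$gene_id, outs[1], outs[2], g$gene_id, outs[2])
    rows[[length(rows) + 1]] <- tibble(
      tree_id = reps$representative_id[reps$gene_id == g$gene_id],
      gene_id = g$gene_id,
      tree = list(ape::read.tree(text = nwk))
    )
  }
  bind_rows(rows)
}

# ---- genome ----------------------------------------------------------------

sim_genome <- function(plan, proteins, cfg) {
  minc <- proteins %>%
    filter(.data$species == "Minc", !grepl("_redund$", .data$protein_id)) %>%
    left_join(select(plan, "gene_id", "class"), by = "gene_id") %>%
    filter(.data$class %in% c("lgt", "vertical"))
  minc$is_lgt <- minc$class == "lgt"

  # plant clusters: whole LGT genes (all their Minc copies) are assigned to a
  # cluster until its planned size is reached
  sizes <- sample(seq(cfg$cluster_size_range[1], cfg$cluster_size_range[2]),
                  cfg$n_clusters, replace = TRUE)
  lgt_ids <- minc$protein_id[minc$is_lgt]
  cluster_assign <- rep(NA_integer_, nrow(minc))
  cursor <- 1
  for (k in seq_len(cfg$n_clusters)) {
    take <- lgt_ids[cursor:(cursor + sizes[k] - 1)]
    cluster_assign[minc$protein_id %in% take] <- k
    cursor <- cursor + sizes[k]
  }
  minc$cluster <- cluster_assign

  slot_spacing <- 60000L
  gene_rows <- list()
  scaffold_rows <- list()
  scaffold_n <- 0L

  # cluster scaffolds
  for (k in seq_len(cfg$n_clusters)) {
    scaffold_n <- scaffold_n + 1L
    sc <- sprintf("scaffold_%03d", scaffold_n)
    members <- minc[which(minc$cluster == k), , drop = FALSE]
    pos <- 10000L
    for (j in seq_len(nrow(members))) {
      len <- sample(1000:3000, 1)
      gene_rows[[length(gene_rows) + 1]] <- tibble(
        gene_id = members$protein_id[j], scaffold_id = sc,
        start = pos, end = pos + len - 1L, strand = "+",
        is_lgt = TRUE, in_cluster = TRUE
      )
      pos <- pos + len + sample(5000:20000, 1)
    }
    scaffold_rows[[length(scaffold_rows) + 1]] <-
      tibble(scaffold_id = sc, length = cfg$scaffold_length)
  }

  # scattered genes on shared scaffolds, one per 60 kb slot
  scattered <- minc[is.na(minc$cluster), , drop = FALSE]
  scattered <- scattered[sample(nrow(scattered)), , drop = FALSE]
  per_scaffold <- max(1L, (cfg$scaffold_length - 20000L) %/% slot_spacing)
  for (j in seq_len(nrow(scattered))) {
    slot <- (j - 1L) %% per_scaffold
    if (slot == 0L) {
      scaffold_n <- scaffold_n + 1L
      scaffold_rows[[length(scaffold_rows) + 1]] <-
        tibble(scaffold_id = sprintf("scaffold_%03d", scaffold_n),
               length = cfg$scaffold_length)
    }
    sc <- sprintf("scaffold_%03d", scaffold_n)
    len <- sample(1000:3000, 1)
    start <- 10000L + slot * slot_spacing + sample(0:2000, 1)
    gene_rows[[length(gene_rows) + 1]] <- tibble(
      gene_id = scattered$protein_id[j], scaffold_id = sc,
      start = start, end = start + len - 1L, strand = "+",
      is_lgt = scattered$is_lgt[j], in_cluster = FALSE
    )
  }
  genes <- bind_rows(gene_rows)
  scaffolds <- bind_rows(scaffold_rows)
  tes <- sim_tes(genes, scaffolds, cfg)
  list(genes = genes, tes = tes, scaffolds = scaffolds)
}

sim_tes <- function(genes, scaffolds, cfg) {
  rows <- list()
  scaffold_len <- setNames(scaffolds$length, scaffolds$scaffold_id)
  for (i in seq_len(nrow(genes))) {
    rate <- cfg$te_rate * if (genes$is_lgt[i]) cfg$te_enrichment else 1
    k <- rpois(1, rate)
    if (k == 0) next
    side <- sample(c(-1, 1), k, replace = TRUE)
    offset <- sample(1:1700, k, replace = TRUE)
    len <- sample(100:300, k, replace = TRUE)
    start <- ifelse(side > 0, genes$end[i] + offset,
                    genes$start[i] - offset - len)
    end <- start + len - 1L
    L <- scaffold_len[[genes$scaffold_id[i]]]
    keep <- start >= 1 & end <= L
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- tibble(
      te_id = sprintf("te_%s_%d", genes$gene_id[i], seq_len(sum(keep))),
      scaffold_id = genes$scaffold_id[i],
      start = as.integer(start[keep]), end = as.integer(end[keep])
    )
  }
  # light background independent of gene class
  for (s in seq_len(nrow(scaffolds))) {
    k <- rpois(1, scaffolds$length[s] / 2e5)
    if (k == 0) next
    start <- sample(seq_len(scaffolds$length[s] - 400L), k, replace = TRUE)
    rows[[length(rows) + 1]] <- tibble(
      te_id = sprintf("te_bg_%s_%d", scaffolds$scaffold_id[s], seq_len(k)),
      scaffold_id = scaffolds$scaffold_id[s],
      start = as.integer(start),
      end = as.integer(start + sample(100:300, k, replace = TRUE) - 1L)
    )
  }
  bind_rows(rows)
}

#' Synthetic genome with planted TE enrichment
#'
#' Stand-alone access to the generator's genome stage: `n_lgt` LGT-flagged
#' and `n_other` background genes are laid out on scaffolds (no two scattered
#' genes within the clustering distance), and transposable elements are
#' planted in their 2 kb flanks at a mean rate of `te_rate` per background
#' gene, multiplied by `te_enrichment` for LGT genes.
#'
#' @param n_lgt,n_other Genes per class.
#' @param te_rate,te_enrichment TE planting rate and LGT multiplier.
#' @param seed Integer seed.
#' @return List with `genes`, `tes`, `scaffolds` tibbles.
#' @export
simulate_lgt_genome <- function(n_lgt = 200, n_other = 200, te_rate = 1.0,
                                te_enrichment = 2.0, seed = 1L) {
  set.seed(seed)
  cfg <- lgt_sim_config(n_lgt = max(n_lgt, 3L), n_vertical = n_other,
                        te_rate = te_rate, te_enrichment = te_enrichment,
                        n_clusters = 0L)
  cfg$n_clusters <- 0L
  plan <- tibble(
    gene_id = c(sprintf("lgt%04d", seq_len(n_lgt)),
                sprintf("vrt%04d", seq_len(n_other))),
    class = rep(c("lgt", "vertical"), c(n_lgt, n_other))
  )
  proteins <- tibble(
    protein_id = paste0(plan$gene_id, "_Minc_1"),
    species = "Minc",
    length = 300L,
    gene_id = plan$gene_id
  )
  sim_genome(plan, proteins, cfg)
}

# ---- CDS and codon profiles ------------------------------------------------

sim_codon_profiles <- function(cfg) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code)
  base <- numeric(length(code))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    w <- stats::rexp(length(idx)) + 0.2
    base[idx] <- w / sum(w)
  }
  shifted <- base
  for (a in unique(aa)) {
    idx <- which(aa == a)
    if (length(idx) < 2) next
    delta <- rep(c(1, -1), length.out = length(idx))
    delta <- delta - mean(delta)
    if (all(delta == 0)) delta <- c(1, -1, rep(0, length(idx) - 2))
    cand <- base[idx] + delta * cfg$codon_divergence
    cand <- pmax(cand, 0.005)
    shifted[idx] <- cand / sum(cand)
  }
  aa_weight <- stats::rexp(length(unique(aa))) + 0.5
  names(aa_weight) <- unique(aa)
  aa_weight["*"] <- 0.02
  list(codons = names(code), aa = aa, base = base, shifted = shifted,
       aa_weight = aa_weight)
}

sim_cds <- function(genome_genes, truth_lgt_ids, cfg, profiles) {
  prob_for <- function(fracs, profiles) {
    w <- profiles$aa_weight[profiles$aa]
    p <- w * fracs
    p / sum(p)
  }
  p_base <- prob_for(profiles$base, profiles)
  p_lgt <- prob_for(profiles$shifted, profiles)
  n <- nrow(genome_genes)
  n_codons <- sample(seq(cfg$cds_codon_range[1], cfg$cds_codon_range[2]),
                     n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    p <- if (genome_genes$gene_id[i] %in% truth_lgt_ids) p_lgt else p_base
    paste(sample(profiles$codons, n_codons[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  tibble(gene_id = genome_genes$gene_id, sequence = seqs)
}

# ---- annotation fixtures ---------------------------------------------------

sim_go_fixture <- function() {
  edges <- tibble::tribble(
    ~term, ~parent, ~namespace,
    "GO:0008150", NA, "biological_process",
    "GO:0008152", "GO:0008150", "biological_process",
    "GO:0005975", "GO:0008152", "biological_process",
    "GO:0019538", "GO:0008152", "biological_process",
    "GO:0036211", "GO:0019538", "biological_process",
    "GO:0050789", "GO:0008150", "biological_process",
    "GO:0044245", "GO:0005975", "biological_process",
    "GO:0006468", "GO:0036211", "biological_process",
    "GO:0006508", "GO:0019538", "biological_process",
    "GO:0003674", NA, "molecular_function",
    "GO:0003824", "GO:0003674", "molecular_function",
    "GO:0016787", "GO:0003824", "molecular_function",
    "GO:0008233", "GO:0016787", "molecular_function",
    "GO:0004672", "GO:0003824", "molecular_function",
    "GO:0000166", "GO:0003674", "molecular_function",
    "GO:0003700", "GO:0003674", "molecular_function",
    "GO:0005575", NA, "cellular_component",
    "GO:0005576", "GO:0005575", "cellular_component",
    "GO:0005622", "GO:0005575", "cellular_component"
  )
  slim <- c("GO:0008152", "GO:0005975", "GO:0019538", "GO:0036211",
            "GO:0050789", "GO:0003824", "GO:0016787", "GO:0008233",
            "GO:0000166", "GO:0003700", "GO:0005576", "GO:0005622")
  domains <- tibble::tribble(
    ~domain_id, ~go_id, ~flavor,
    "PF00150", "GO:0044245", "lgt",      # glycoside-hydrolase-like
    "PF00082", "GO:0006508", "lgt",      # peptidase-like
    "PF00069", "GO:0006468", "lgt",      # kinase-like
    "PF00069", "GO:0004672", "lgt",
    "PF01357", "GO:0005576", "lgt",      # expansin-like, extracellular
    "PF00046", "GO:0003700", "background",
    "PF00076", "GO:0000166", "background",
    "PF00271", "GO:0000166", "background",
    "PF02798", "GO:0050789", "background",
    "PF00012", "GO:0005622", "background"
  )
  list(edges = edges, slim = slim, domains = domains)
}

sim_domain_assignments <- function(plan, proteins, fixture) {
  lgt_dom <- unique(fixture$domains$domain_id[fixture$domains$flavor == "lgt"])
  bg_dom <- unique(fixture$domains$domain_id[
    fixture$domains$flavor == "background"])
  focal <- proteins %>%
    filter(.data$species %in% c("Minc", "Mhap"),
           !grepl("_redund$", .data$protein_id)) %>%
    left_join(select(plan, "gene_id", "class"), by = "gene_id")
  rows <- lapply(seq_len(nrow(focal)), function(i) {
    if (runif(1) > 0.55) return(NULL) # roughly half the proteome has a domain
    is_lgt <- focal$class[i] == "lgt"
    pool_w <- if (is_lgt) c(rep(0.85 / length(lgt_dom), length(lgt_dom)),
                            rep(0.15 / length(bg_dom), length(bg_dom)))
              else c(rep(0.15 / length(lgt_dom), length(lgt_dom)),
                     rep(0.85 / length(bg_dom), length(bg_dom)))
    doms <- sample(c(lgt_dom, bg_dom), sample(1:2, 1), prob = pool_w)
    tibble(protein_id = focal$protein_id[i], domain_id = unique(doms))
  })
  bind_rows(rows)
}

# ---- mobile elements -------------------------------------------------------

sim_mobile_hits <- function(plan, reps, cfg) {
  lgt <- plan %>% filter(.data$class == "lgt")
  n_loose <- round(cfg$mobile_loose_frac * nrow(lgt))
  if (n_loose == 0) {
    return(tibble(query_id = character(0), subject_id = character(0),
                  element_type = character(0), percent_identity = numeric(0),
                  qcov = numeric(0), scov = numeric(0), evalue = numeric(0)))
  }
  loose_genes <- sample(lgt$gene_id, n_loose)
  n_strict <- round(cfg$mobile_strict_frac * n_loose)
  strict_genes <- sample(loose_genes, n_strict)
  types <- names(cfg$mobile_type_mix)
  rows <- lapply(loose_genes, function(gid) {
    q <- reps$representative_id[reps$gene_id == gid]
    strict <- gid %in% strict_genes
    type <- sample(types, 1, prob = cfg$mobile_type_mix)
    best <- tibble(
      query_id = q,
      subject_id = sprintf("aclame_%s_1", gid),
      element_type = type,
      percent_identity = if (strict) runif(1, 30, 40) else runif(1, 20, 28),
      qcov = if (strict) runif(1, 0.5, 0.9) else runif(1, 0.2, 0.45),
      scov = if (strict) runif(1, 0.5, 0.9) else runif(1, 0.2, 0.45),
      evalue = 10^runif(1, -40, -5)
    )
    extra <- tibble(
      query_id = q,
      subject_id = sprintf("aclame_%s_2", gid),
      element_type = sample(types, 1, prob = cfg$mobile_type_mix),
      percent_identity = runif(1, 20, 28),
      qcov = runif(1, 0.2, 0.45),
      scov = runif(1, 0.2, 0.45),
      evalue = best$evalue * 10^runif(1, 1, 3)
    )
    bind_rows(best, extra)
  })
  bind_rows(rows)
}

# ---- top-level generator ---------------------------------------------------

#' Generate a synthetic miniature study
#'
#' Produces, deterministically for a given seed, every input the pipeline
#' consumes plus a ground-truth table: see `lgt_sim_config()` for the planted
#' conditions. All emitted tables round-trip through the package's readers
#' and writers (`write_lgt_bundle()` / `read_lgt_bundle()`).
#'
#' @param cfg An `lgt_sim_config()`.
#' @return A list of class `lgt_sim` with elements `taxonomy`, `species`,
#'   `proteins`, `groups`, `blast_hits`, `trees`, `genes`, `tes`,
#'   `scaffolds`, `cds`, `domain_assignments`, `pfam2go`, `go_edges`,
#'   `go_slim`, `mobile_hits`, `truth` and `config`.
#' @export
simulate_lgt_study <- function(cfg = lgt_sim_config()) {
  set.seed(cfg$seed)
  tax <- lgt_taxonomy(sim_taxonomy_nodes())
  species <- sim_species_table()
  plan <- sim_gene_plan(cfg)
  proteins <- sim_proteins(plan, cfg)
  groups <- sim_groups(plan, proteins)
  reps <- sim_representatives(plan, proteins)
  blast <- sim_blast(plan, proteins, cfg)
  trees <- sim_trees(plan, reps)
  genome <- sim_genome(plan, proteins, cfg)
  profiles <- sim_codon_profiles(cfg)
  lgt_copy_ids <- genome$genes$gene_id[genome$genes$is_lgt]
  cds <- sim_cds(genome$genes, lgt_copy_ids, cfg, profiles)
  fixture <- sim_go_fixture()
  domains <- sim_domain_assignments(plan, proteins, fixture)
  mobile <- sim_mobile_hits(plan, reps, cfg)

  in_cluster_ids <- genome$genes$gene_id[genome$genes$in_cluster]
  truth <- plan %>%
    left_join(reps, by = "gene_id") %>%
    mutate(
      is_lgt = .data$class == "lgt",
      is_contaminant = .data$class == "contaminant",
      in_group = .data$gene_id %in% sub("^grp_", "", unique(groups$group_id)),
      has_tree = .data$gene_id %in% trees$gene_id,
      te_enriched = .data$is_lgt,
      in_cluster = vapply(.data$gene_id, function(gid) {
        any(startsWith(in_cluster_ids, paste0(gid, "_")))
      }, logical(1), USE.NAMES = FALSE),
      mobile_loose = .data$gene_id %in%
        sub("^aclame_(.*)_\\d+$", "\\1", mobile$subject_id)
    ) %>%
    select("gene_id", "class", "is_lgt", "is_contaminant", "donor_division",
           "both_species", "duplicated", "duplication_timing",
           "n_copies_minc", "n_copies_mhap", "support_planted", "at_root",
           "in_group", "has_tree", "in_cluster", "te_enriched",
           "mobile_loose", "representative_id")

  structure(
    list(taxonomy = tax, species = species, proteins = proteins,
         groups = groups, blast_hits = blast, trees = trees,
         genes = genome$genes, tes = genome$tes,
         scaffolds = genome$scaffolds, cds = cds,
         domain_assignments = domains, pfam2go = fixture$domains[, 1:2],
         go_edges = fixture$edges, go_slim = fixture$slim,
         mobile_hits = mobile, truth = truth, config = cfg),
    class = "lgt_sim"
  )
}

#' Synthetic receiver trees at set duplication rates
#'
#' Generates `n` full LGT gene trees whose receiver clades realize the given
#' duplication-timing probabilities (all trees contain both nematode
#' species), for calibration checks of the duplication-cohort statistics.
#'
#' @param n Number of trees.
#' @param p_duplicated,p_before,p_after_given_before Timing probabilities.
#' @param seed Integer seed.
#' @return Tibble with `tree_id`, `tree` (list of `phylo`), and the planted
#'   flags `duplicated`, `before_split`, `after_split`.
#' @export
simulate_receiver_trees <- function(n = 500,
                                    p_duplicated = 0.83,
                                    p_before = 0.79,
                                    p_after_given_before = 43 / 60,
                                    seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    duplicated <- runif(1) < p_duplicated
    before <- duplicated && runif(1) < p_before
    after <- duplicated && (!before || runif(1) < p_after_given_before)
    timing <- if (!duplicated) "none" else if (before && after) "both"
              else if (before) "before" else "after"
    copies <- switch(timing,
      none = c(1L, 1L),
      before = c(2L, 2L),
      both = if (runif(1) < 0.5) c(2L, 3L) else c(4L, 2L),
      after = if (runif(1) < 0.5) c(1L, 2L) else c(3L, 1L)
    )
    g <- tibble(gene_id = sprintf("cal%04d", i), both_species = TRUE,
                duplication_timing = timing,
                n_copies_minc = copies[1], n_copies_mhap = copies[2],
                donor_division = "Bacteria", mixed_donor = FALSE,
                at_root = FALSE, support_planted = "A")
    nwk <- sprintf("((%s,%s),%s);", receiver_newick(g), donor_newick(g),
                   external_newick(g))
    tibble(tree_id = g$gene_id, tree = list(ape::read.tree(text = nwk)),
           duplicated = duplicated, before_split = before,
           after_split = after)
  })
  bind_rows(rows)
}

#' Write / read a synthetic bundle as plain-text files
#'
#' One directory per bundle: proteome and CDS FASTA, ortholog groups, BLAST
#' TSV, Newick trees with an index, GFF3 genome annotation, domain and GO
#' tables, mobile-element hits, the truth table and the configuration.
#'
#' @param sim An `lgt_sim` bundle.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly; `read_lgt_bundle()` returns a list of
#'   the re-parsed components.
#' @export
write_lgt_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "lgt_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  save_taxonomy(sim$taxonomy, p("taxonomy.tsv"))
  write_tsv_file(sim$species, p("species.tsv"))
  write_proteome_fasta(sim$proteins, p("proteome.fasta"))
  write_orthomcl_groups(sim$groups, p("groups.txt"))
  write_blast_hits(sim$blast_hits, p("blast_hits.tsv"))
  write_gene_trees(sim$trees, p("trees.nwk"))
  write_tsv_file(select(sim$trees, "tree_id", "gene_id"), p("trees_index.tsv"))
  write_genome_annotation(sim$genes, sim$tes, sim$scaffolds, p("genome.gff3"))
  write_cds_fasta(sim$cds, p("cds.fasta"))
  write_tsv_file(sim$domain_assignments, p("domains.tsv"))
  write_pfam2go(sim$pfam2go, p("pfam2go.txt"))
  write_tsv_file(sim$go_edges, p("go_dag.tsv"))
  writeLines(sim$go_slim, p("go_slim.txt"))
  write_tsv_file(sim$mobile_hits, p("mobile_hits.tsv"))
  write_tsv_file(sim$truth, p("truth.tsv"))
  yaml::write_yaml(sim$config, p("config.yaml"))
  invisible(dir)
}

#' @rdname write_lgt_bundle
#' @export
read_lgt_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  trees <- read_gene_trees(p("trees.nwk"))
  index <- as_tibble(read.delim(p("trees_index.tsv")))
  trees$tree_id <- index$tree_id
  trees$gene_id <- index$gene_id
  annotation <- read_genome_annotation(p("genome.gff3"))
  list(
    taxonomy = load_taxonomy(p("taxonomy.tsv")),
    species = as_tibble(read.delim(p("species.tsv"))),
    proteins = read_proteome_fasta(p("proteome.fasta")),
    groups = read_orthomcl_groups(p("groups.txt")),
    blast_hits = read_blast_hits(p("blast_hits.tsv")),
    trees = trees,
    genes = annotation$genes,
    tes = annotation$tes,
    scaffolds = annotation$scaffolds,
    cds = read_cds_fasta(p("cds.fasta")),
    domain_assignments = as_tibble(read.delim(p("domains.tsv"))),
    pfam2go = read_pfam2go(p("pfam2go.txt")),
    go_edges = as_tibble(read.delim(p("go_dag.tsv"))),
    go_slim = readLines(p("go_slim.txt")),
    mobile_hits = as_tibble(read.delim(p("mobile_hits.tsv"))),
    truth = as_tibble(read.delim(p("truth.tsv")))
  )
}
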