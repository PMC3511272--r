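#' Readers and writers for the pipeline's file formats
#'
#' Proteome and CDS FASTA files are read with Biostrings; GFF3 with
#' rtracklayer; Newick gene trees with ape. Ortholog-group files, tabular
#' BLAST hits and pfam2go flat files use simple line formats parsed here.
#' Sequence records are tagged `species|protein_id` in FASTA headers and tree
#' leaf labels throughout.
#'
#' @param path Input file path.
#' @return `read_proteome_fasta()` returns a tibble with columns
#'   `protein_id`, `species`, `length`, `sequence`.
#' @name lgt_io
NULL

#' @rdname lgt_io
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  labels <- sub("\\s.*$", "", names(seqs))
  parts <- split_species_label(labels)
  tibble(
    protein_id = parts$protein_id,
    species = parts$species,
    length = Biostrings::width(seqs),
    sequence = unname(as.character(seqs))
  )
}

#' @rdname lgt_io
#' @param proteins Tibble with `protein_id`, `species`, `sequence`.
#' @export
write_proteome_fasta <- function(proteins, path) {
  assert_columns(proteins, c("protein_id", "species", "sequence"))
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- paste0(proteins$species, "|", proteins$protein_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname lgt_io
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    gene_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

#' @rdname lgt_io
#' @param cds Tibble with `gene_id`, `sequence`.
#' @export
write_cds_fasta <- function(cds, path) {
  assert_columns(cds, c("gene_id", "sequence"))
  set <- Biostrings::DNAStringSet(cds$sequence)
  names(set) <- cds$gene_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Ortholog group files
#'
#' One group per line in the OrthoMCL output convention:
#' `group_id: species|protein_id species|protein_id ...`. Parsed to a tidy
#' membership table with one row per (group, protein).
#'
#' @param path Group file path.
#' @return Tibble with columns `group_id`, `species`, `protein_id`.
#' @export
read_orthomcl_groups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(seq_along(lines), function(i) {
    line <- lines[[i]]
    m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3) {
      abort(sprintf("malformed group line %d: %s", i, line))
    }
    members <- strsplit(trimws(m[3]), "\\s+")[[1]]
    parts <- split_species_label(members)
    tibble(group_id = trimws(m[2]), species = parts$species,
           protein_id = parts$protein_id)
  })
  bind_rows(parsed)
}

#' @rdname read_orthomcl_groups
#' @param groups Membership tibble as returned by `read_orthomcl_groups()`.
#' @export
write_orthomcl_groups <- function(groups, path) {
  assert_columns(groups, c("group_id", "species", "protein_id"))
  by_group <- split(paste0(groups$species, "|", groups$protein_id),
                    groups$group_id)
  lines <- vapply(names(by_group), function(g) {
    paste0(g, ": ", paste(by_group[[g]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Tabular BLAST hits
#'
#' An outfmt-6-like tab-separated table with an added subject-taxonomy column.
#' The default column order is query_id, subject_id, subject_taxid,
#' percent_identity, align_length_on_query, evalue, bitscore; pass `columns`
#' to reorder for other dialects.
#'
#' @param path Hit table path.
#' @param columns Character vector naming the file's columns in order.
#' @return Tibble of hits.
#' @export
read_blast_hits <- function(path,
                            columns = c("query_id", "subject_id",
                                        "subject_taxid", "percent_identity",
                                        "align_length_on_query", "evalue",
                                        "bitscore")) {
  df <- read.delim(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != length(columns)) {
    abort(sprintf("expected %d columns, found %d in %s",
                  length(columns), ncol(df), path))
  }
  names(df) <- columns
  df <- as_tibble(df)
  num_cols <- intersect(
    c("subject_taxid", "percent_identity", "align_length_on_query",
      "evalue", "bitscore"), columns)
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && !anyNA(df[[cl]])) {
      bad <- which(is.na(v))[1]
      abort(sprintf("malformed value in column %s at line %d of %s",
                    cl, bad, path))
    }
    df[[cl]] <- v
  }
  df$subject_taxid <- as.integer(df$subject_taxid)
  df
}

#' @rdname read_blast_hits
#' @param hits Hit tibble.
#' @export
write_blast_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene trees with species-tagged leaves
#'
#' Newick files whose leaf labels follow the `species|protein_id` convention.
#' Multiple trees per file are supported; tree ids are taken from tree names
#' when present, else `tree_<i>`.
#'
#' @param path Newick file.
#' @return Tibble with columns `tree_id` and `tree` (list column of `phylo`).
#' @export
read_gene_trees <- function(path) {
  trees <- ape::read.tree(path)
  trees <- if (inherits(trees, "phylo")) list(trees) else unclass(trees)
  ids <- names(trees)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- paste0("tree_", seq_along(trees))
  }
  tibble(tree_id = ids, tree = unname(as.list(trees)))
}

#' @rdname read_gene_trees
#' @param trees Tibble with `tree_id` and `tree` columns.
#' @export
write_gene_trees <- function(trees, path) {
  assert_columns(trees, c("tree_id", "tree"))
  txt <- vapply(trees$tree, ape::write.tree, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Genome annotation (GFF3)
#'
#' Reads gene and transposable-element features from a GFF3 file via
#' rtracklayer and returns tidy interval tables in 1-based inclusive
#' coordinates. Which GFF3 `type` values count as genes and as TEs is
#' configurable. Scaffold lengths are taken from `##sequence-region`
#' directives when present, else from the maximum feature end per scaffold.
#'
#' @param path GFF3 file.
#' @param gene_types,te_types GFF3 feature types treated as genes / TEs.
#' @return List with tibbles `genes` (gene_id, scaffold_id, start, end,
#'   strand, is_lgt), `tes` (te_id, scaffold_id, start, end) and `scaffolds`
#'   (scaffold_id, length). The `is_lgt` flag is read from a `is_lgt=true`
#'   GFF3 attribute when present, else `FALSE`.
#' @export
read_genome_annotation <- function(path, gene_types = "gene",
                                   te_types = c("transposable_element",
                                                "repeat_region")) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$scaffold_id <- as.character(df$seqnames)

  ids <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))

  is_lgt <- rep(FALSE, nrow(df))
  if ("is_lgt" %in% names(df)) {
    is_lgt <- tolower(as.character(df$is_lgt)) %in% c("true", "1", "yes")
    is_lgt[is.na(is_lgt)] <- FALSE
  }

  genes <- tibble(
    gene_id = ids, scaffold_id = df$scaffold_id,
    start = df$start, end = df$end,
    strand = as.character(df$strand), is_lgt = is_lgt
  )[df$type %in% gene_types, ]
  tes <- tibble(
    te_id = ids, scaffold_id = df$scaffold_id,
    start = df$start, end = df$end
  )[df$type %in% te_types, ]

  seqinfo <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(seqinfo))) {
    scaffolds <- df %>%
      group_by(.data$scaffold_id) %>%
      summarise(length = max(.data$end), .groups = "drop")
  } else {
    scaffolds <- tibble(scaffold_id = names(seqinfo),
                        length = as.integer(seqinfo))
  }
  list(genes = genes, tes = tes, scaffolds = as_tibble(scaffolds))
}

#' @rdname read_genome_annotation
#' @param genes,tes,scaffolds Tibbles in the shapes returned by
#'   `read_genome_annotation()`.
#' @export
write_genome_annotation <- function(genes, tes, scaffolds, path) {
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      scaffolds$scaffold_id, scaffolds$length))
  gene_rows <- sprintf(
    "%s\tlgtscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;is_lgt=%s",
    genes$scaffold_id, genes$start, genes$end,
    ifelse(is.na(genes$strand) | genes$strand == "*", "+", genes$strand),
    genes$gene_id, ifelse(genes$is_lgt, "true", "false"))
  te_rows <- sprintf(
    "%s\tlgtscan\ttransposable_element\t%d\t%d\t.\t+\t.\tID=%s",
    tes$scaffold_id, tes$start, tes$end, tes$te_id)
  writeLines(c(header, gene_rows, te_rows), path)
  invisible(path)
}

#' pfam2go association files
#'
#' Flat-file lines of the form
#' `Pfam:PF00001 name > GO:description ; GO:0004930`. Comment lines starting
#' with `!` are skipped.
#'
#' @param path pfam2go file.
#' @return Tibble with columns `domain_id`, `go_id`.
#' @export
read_pfam2go <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parsed <- lapply(lines, function(line) {
    pf <- regmatches(line, regexpr("PF\\d{5}", line))
    gos <- regmatches(line, gregexpr("GO:\\d{7}", line))[[1]]
    if (length(pf) == 0 || length(gos) == 0) return(NULL)
    tibble(domain_id = pf, go_id = gos)
  })
  distinct(bind_rows(parsed))
}

#' @rdname read_pfam2go
#' @param pfam2go Tibble with `domain_id`, `go_id`.
#' @export
write_pfam2go <- function(pfam2go, path) {
  writeLines(sprintf("Pfam:%s %s > GO:term ; %s",
                     pfam2go$domain_id, tolower(pfam2go$domain_id),
                     pfam2go$go_id), path)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  # list columns (leaf sets, trees) are serialized as comma-joined strings
  df <- as.data.frame(df)
  for (cl in names(df)) {
    if (is.list(df[[cl]])) {
      df[[cl]] <- vapply(df[[cl]], function(x) {
        paste(as.character(unlist(x)), collapse = ",")
      }, character(1))
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
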