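#' GC content of coding sequences
#'
#' Percent G+C over the A/C/G/T letters of each sequence; `N` (and any other
#' ambiguity code) is excluded from both numerator and denominator.
#'
#' @param cds Character vector of nucleotide sequences (or a
#'   `DNAStringSet`).
#' @return Numeric vector of GC percentages.
#' @export
gc_content <- function(cds) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  if (length(cds) == 0) abort("no sequence given")
  vapply(cds, function(s) {
    if (is.na(s) || !nzchar(s)) abort("GC content undefined for empty sequence")
    chars <- strsplit(toupper(s), "")[[1]]
    acgt <- sum(chars %in% c("A", "C", "G", "T"))
    if (acgt == 0) abort("GC content undefined: no A/C/G/T letters")
    100 * sum(chars %in% c("G", "C")) / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Codon usage table
#'
#' Counts every codon over a set of coding sequences and reports, per codon:
#' `occurrence` (raw count), `fraction` (occurrence divided by the total
#' occurrences of codons encoding the same amino acid — sums to 1 within each
#' amino-acid class, stop codons forming a 21st class), and `frequency`
#' (occurrence divided by total codons — sums to 1 over the 64 codons).
#' Sequences whose length is not a multiple of 3 are trimmed to the last full
#' codon with a warning; codons containing a non-A/C/G/T letter are skipped
#' and tallied in the `skipped_codons` attribute.
#'
#' @param cds Character vector of CDS sequences (or a `DNAStringSet`).
#' @return Tibble of 64 rows: `codon`, `amino_acid` (one-letter, `*` for
#'   stop), `occurrence`, `fraction`, `frequency`. Amino-acid classes with
#'   zero occurrences get `fraction = NA`.
#' @export
codon_usage_table <- function(cds) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)

  cds <- toupper(cds)
  lens <- nchar(cds)
  remainder <- lens %% 3
  if (any(remainder != 0)) {
    warn(sprintf("%d sequence(s) not a multiple of 3; trailing bases trimmed",
                 sum(remainder != 0)))
    cds <- substr(cds, 1, lens - remainder)
  }
  all_codons <- unlist(lapply(cds[nchar(cds) > 0], function(s) {
    starts <- seq(1, nchar(s), by = 3)
    substring(s, starts, starts + 2)
  }))
  valid <- grepl("^[ACGT]{3}$", all_codons)
  skipped <- sum(!valid)
  counts <- table(factor(all_codons[valid], levels = codons))

  occurrence <- as.integer(counts)
  total <- sum(occurrence)
  aa <- unname(code)
  aa_total <- as.numeric(tapply(occurrence, aa, sum)[aa])
  out <- tibble(
    codon = codons,
    amino_acid = aa,
    occurrence = occurrence,
    fraction = ifelse(aa_total > 0, occurrence / aa_total, NA_real_),
    frequency = if (total > 0) occurrence / total else NA_real_
  )
  attr(out, "skipped_codons") <- skipped
  out
}

#' Compare two codon usage tables
#'
#' Per-codon absolute differences of the `fraction` column (usage among
#' synonymous codons, the scale on which the study reports its 2% average
#' difference) and of the `frequency` column, aggregated per amino-acid class
#' and globally. Classes in which any codon differs by more than `flag_above`
#' on either scale are flagged; whether the study's ">5%" flag refers to
#' fraction or frequency is ambiguous, so both are reported.
#'
#' @param table_a,table_b Codon usage tables from `codon_usage_table()`.
#' @param flag_above Flag threshold on the absolute difference (default
#'   0.05).
#' @return Object of class `codon_usage_comparison`: `per_codon` and
#'   `per_amino_acid` tibbles, `mean_fraction_diff` (mean over amino-acid
#'   classes of their mean per-codon fraction difference), and the flagged
#'   classes on each scale.
#' @export
compare_codon_usage <- function(table_a, table_b, flag_above = 0.05) {
  assert_columns(table_a, c("codon", "amino_acid", "fraction", "frequency"))
  assert_columns(table_b, c("codon", "amino_acid", "fraction", "frequency"))
  if (!identical(table_a$codon, table_b$codon)) {
    abort("codon tables must cover the same codons in the same order")
  }
  per_codon <- tibble(
    codon = table_a$codon,
    amino_acid = table_a$amino_acid,
    fraction_a = table_a$fraction,
    fraction_b = table_b$fraction,
    fraction_diff = abs(table_a$fraction - table_b$fraction),
    frequency_diff = abs(table_a$frequency - table_b$frequency)
  )
  per_aa <- per_codon %>%
    group_by(.data$amino_acid) %>%
    summarise(
      mean_fraction_diff = mean(.data$fraction_diff),
      max_fraction_diff = max(.data$fraction_diff),
      max_frequency_diff = max(.data$frequency_diff),
      .groups = "drop"
    ) %>%
    mutate(flag_fraction = !is.na(.data$max_fraction_diff) &
             .data$max_fraction_diff > flag_above,
           flag_frequency = .data$max_frequency_diff > flag_above)
  structure(
    list(
      per_codon = per_codon,
      per_amino_acid = per_aa,
      mean_fraction_diff = mean(per_aa$mean_fraction_diff, na.rm = TRUE),
      flagged_fraction = per_aa$amino_acid[per_aa$flag_fraction %in% TRUE],
      flagged_frequency = per_aa$amino_acid[per_aa$flag_frequency %in% TRUE]
    ),
    class = "codon_usage_comparison"
  )
}

#' @export
print.codon_usage_comparison <- function(x, ...) {
  cat(sprintf(
    "codon usage comparison: mean per-amino-acid fraction difference %.4f\n",
    x$mean_fraction_diff))
  if (length(x$flagged_fraction) > 0) {
    cat("classes with a codon fraction differing by more than the flag:",
        paste(x$flagged_fraction, collapse = ", "), "\n")
  }
  invisible(x)
}
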