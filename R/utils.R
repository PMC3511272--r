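# Shared internal helpers.

# Round half away from zero, matching how the headline percentages are
# printed (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Split "Species|protein" leaf/record labels into their two parts.
split_species_label <- function(label) {
  species <- sub("\\|.*$", "", label)
  protein <- sub("^[^|]*\\|", "", label)
  tibble(label = label, species = species, protein_id = protein)
}

species_of_label <- function(label) sub("\\|.*$", "", label)

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
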