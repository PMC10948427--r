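## Shared fixture builders for the suite. Everything is generated in code;
## randomness is always behind an explicit seed at the call site.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

## tiny gap-free three-isoform panel with a known shared core
tiny_panel <- function() {
  base <- "MAFAGILNDADITAALQGCQAADSFDHKKFFQMVGLKKKSADDVKKVFHILDKDKSGFIE"
  v2 <- sub("QGCQ", "QGCN", base)           # one in-core substitution
  v3 <- sub("KSGFIE", "KSGYIE", base)       # one C-terminal substitution
  allergen_panel(
    allergen_id = c("Tst a 1.0101", "Tst a 1.0201", "Tst b 1.0101"),
    sequence = c(base, v2, v3),
    species = c("Testus alpha", "Testus alpha", "Testus beta"))
}

tiny_alignment <- function(panel = tiny_panel())
  master_alignment(setNames(panel$sequence, panel$allergen_id))

## reactivity matrix from explicit per-peptide log2 values;
## `log2_values`: named list sample_id -> named numeric (peptide -> log2 I)
rmat_from_log2 <- function(log2_values, index) {
  rows <- list()
  for (sid in names(log2_values)) {
    key <- strsplit(sid, "|", fixed = TRUE)[[1]]
    vals <- log2_values[[sid]]
    rows[[sid]] <- data.frame(
      subject_id = key[1], timepoint = as.integer(key[2]), isotype = key[3],
      peptide = names(vals), intensity = 2^unname(vals))
  }
  reactivity_matrix(do.call(rbind, rows), index)
}

## background peptides guarantee a well-behaved per-sample median and MAD:
## n values spread around `center` with unit-ish scale
background_log2 <- function(peptides, center = 10) {
  stats::setNames(center + seq(-1, 1, length.out = length(peptides)),
                  peptides)
}

panel_fixture_paths <- function() {
  list(
    fasta = system.file("extdata", "parvalbumin_panel_synthetic.fasta",
                        package = "serotile", mustWork = TRUE),
    meta = system.file("extdata", "parvalbumin_panel_metadata.tsv",
                       package = "serotile", mustWork = TRUE))
}
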