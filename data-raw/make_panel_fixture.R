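## Builds the synthetic stand-in panel fixture under inst/extdata/.
##
## The 21 isoform names, species, completeness flags and initial-Met
## metadata transcribe the published design of the beta-parvalbumin array
## panel; the SEQUENCES are synthetic stand-ins (random homologous family),
## except for two printed peptides embedded verbatim so that coordinate and
## uniqueness queries can be exercised:
##   * "FIEEDELKLFLQNFSA" at residues 59-74 of Thu a 1.0101 (the full
##     16-mer minimal epitope at position 59);
##   * "LAAKSPADI" embedded only in Gad m 1.0201 (the uniquely-carried
##     minimal epitope), with "LAAKTPEDI" in Thu a 1.0101.
## Run from the package root: Rscript data-raw/make_panel_fixture.R

set.seed(20240305)
AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

meta <- data.frame(
  allergen_id = c("Clu h 1.0101", "Clu h 1.0201", "Clu h 1.0301",
                  "Cyp c 1.0101", "Cyp c 1.0201",
                  "Gad c 1.0101",
                  "Gad m 1.0101", "Gad m 1.0102", "Gad m 1.0201",
                  "Gad m 1.0202",
                  "Lat c 1.0101", "Lat c 1.0201",
                  "Lep w 1.0101",
                  "Onc m 1.0101", "Onc m 1.0201",
                  "Sal s 1.0101",
                  "Sar sa 1.0101",
                  "Seb m 1.0101", "Seb m 1.0201",
                  "Thu a 1.0101",
                  "Xip g 1.0101"),
  species = c(rep("Clupea harengus", 3), rep("Cyprinus carpio", 2),
              "Gadus callarias", rep("Gadus morhua", 4),
              rep("Lates calcarifer", 2), "Lepidorhombus whiffiagonis",
              rep("Oncorhynchus mykiss", 2), "Salmo salar",
              "Sardinops sagax", rep("Sebastes marinus", 2),
              "Thunnus albacares", "Xiphias gladius"),
  stringsAsFactors = FALSE)
meta$complete <- !meta$allergen_id %in% c("Onc m 1.0101", "Onc m 1.0201")
meta$includes_initial_met <-
  !meta$allergen_id %in% c("Gad c 1.0101", "Onc m 1.0101", "Onc m 1.0201")

L <- 109
base <- c("M", sample(AA, L - 1, replace = TRUE))

mutate <- function(s, rate = 0.08) {
  hit <- which(runif(length(s)) < rate)
  for (p in hit) s[p] <- sample(setdiff(AA, s[p]), 1)
  s
}
embed <- function(s, motif, at) {
  s[at:(at + nchar(motif) - 1)] <- strsplit(motif, "")[[1]]
  s
}

seqs <- character(nrow(meta))
for (i in seq_len(nrow(meta))) {
  s <- mutate(base)
  s[1] <- if (meta$includes_initial_met[i]) "M" else "A"
  id <- meta$allergen_id[i]
  if (id == "Thu a 1.0101") {
    s <- embed(s, "FIEEDELKLFLQNFSA", 59)
    s <- embed(s, "LAAKTPEDI", 33)
  }
  if (id == "Gad m 1.0201") s <- embed(s, "LAAKSPADI", 33)
  if (!meta$complete[i]) s <- s[1:80]  # incomplete records: truncated stand-in
  seqs[i] <- paste(s, collapse = "")
}

## the uniquely-carried peptide must really be unique to Gad m 1.0201
stopifnot(sum(grepl("LAAKSPADI", seqs, fixed = TRUE)) == 1)
stopifnot(grepl("LAAKSPADI", seqs[meta$allergen_id == "Gad m 1.0201"]))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
fa <- file("inst/extdata/parvalbumin_panel_synthetic.fasta", "w")
for (i in seq_len(nrow(meta))) {
  cat(">", meta$allergen_id[i], "\n", sep = "", file = fa)
  cat(seqs[i], "\n", sep = "", file = fa)
}
close(fa)
write.table(meta, "inst/extdata/parvalbumin_panel_metadata.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(meta), "records\n")
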