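## Allergen panel: reading, validation, exhaustive peptide tiling and the
## deduplicated unique-peptide index.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an allergen panel
#'
#' An allergen panel holds the isoform sequences represented on the array
#' together with completeness metadata. Records flagged incomplete (sequences
#' with undefined residues in the source database) are retained for
#' bookkeeping but are never tiled.
#'
#' @param allergen_id character vector of unique isoform names
#'   (e.g. `"Gad m 1.0201"`).
#' @param sequence character vector of uppercase amino-acid sequences over
#'   the 20 standard one-letter codes.
#' @param species character vector of source species names.
#' @param complete logical; is the database sequence complete? Incomplete
#'   records are excluded from tiling.
#' @param includes_initial_met logical; does the stored sequence carry the
#'   N-terminal methionine? This is metadata only: the stored sequence is
#'   exactly what gets tiled, so panels encode inclusion/exclusion of the
#'   initial Met by the sequence itself.
#' @return A `data.table` of class `allergen_panel` with one row per record.
#' @export
allergen_panel <- function(allergen_id, sequence,
                           species = NA_character_,
                           complete = TRUE,
                           includes_initial_met = TRUE) {
  panel <- data.table(
    allergen_id = as.character(allergen_id),
    species = as.character(species),
    sequence = toupper(as.character(sequence)),
    complete = as.logical(complete),
    includes_initial_met = as.logical(includes_initial_met)
  )
  dup <- panel$allergen_id[duplicated(panel$allergen_id)]
  if (length(dup) > 0L)
    stop("duplicate allergen ids: ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(panel))) {
    chars <- strsplit(panel$sequence[i], "")[[1]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L)
      stop(sprintf(
        "record '%s': invalid amino-acid character '%s' at position %d",
        panel$allergen_id[i], chars[bad[1]], bad[1]))
  }
  short <- panel$complete & nchar(panel$sequence) < 16L
  if (any(short))
    warning("complete records shorter than 16 residues: ",
            paste(panel$allergen_id[short], collapse = ", "))
  setattr(panel, "class", c("allergen_panel", class(panel)))
  panel[]
}

#' Read an allergen panel from FASTA plus metadata
#'
#' The FASTA description line (everything after `>`) is used verbatim as the
#' allergen id, so ids containing spaces (such as WHO/IUIS isoform names) are
#' supported. The metadata TSV must contain columns `allergen_id`, `species`,
#' `complete` and `includes_initial_met` and cover every FASTA record.
#'
#' @param fasta_path path to an (ungapped) amino-acid FASTA file.
#' @param metadata_path path to a tab-separated metadata table.
#' @return An [allergen_panel] in FASTA file order.
#' @export
read_panel <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- trimws(names(seqs))
  meta <- fread(metadata_path, sep = "\t", colClasses = list(
    character = c("allergen_id", "species")))
  need <- c("allergen_id", "species", "complete", "includes_initial_met")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L)
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(ids, meta$allergen_id)
  if (length(absent) > 0L)
    stop("no metadata for records: ", paste(absent, collapse = ", "))
  meta <- meta[match(ids, meta$allergen_id)]
  allergen_panel(
    allergen_id = ids,
    sequence = as.character(seqs),
    species = meta$species,
    complete = as.logical(meta$complete),
    includes_initial_met = as.logical(meta$includes_initial_met)
  )
}

#' Write an allergen panel to FASTA plus metadata
#'
#' Inverse of [read_panel()]; mainly used to persist synthetic panels.
#'
#' @param panel an [allergen_panel].
#' @param fasta_path,metadata_path output paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, fasta_path, metadata_path) {
  stopifnot(inherits(panel, "allergen_panel"))
  seqs <- Biostrings::AAStringSet(panel$sequence)
  names(seqs) <- panel$allergen_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  fwrite(panel[, .(allergen_id, species, complete, includes_initial_met)],
         metadata_path, sep = "\t")
  invisible(panel)
}

#' @export
print.allergen_panel <- function(x, ...) {
  cat(sprintf("allergen_panel: %d records (%d complete)\n",
              nrow(x), sum(x$complete)))
  NextMethod()
}

#' Tile one allergen into overlapping peptides
#'
#' Generates every k-mer of the record at the given start offset. With the
#' defaults (k = 16, offset = 1) this is the exhaustive overlapping design in
#' which adjacent peptides share 15 residues and a sequence of length L
#' yields L - 15 tiles. Incomplete records are refused: sequences with
#' undefined residues cannot be tiled faithfully.
#'
#' @param panel an [allergen_panel] (or a one-row subset).
#' @param allergen_id which record to tile; may be omitted for a one-row
#'   panel.
#' @param k tile length in residues (default 16).
#' @param offset step between consecutive tile starts (default 1).
#' @return `data.table` with columns `allergen_id`, `start_local` (1-based,
#'   tile covers `[start_local, start_local + k - 1]`), `sequence`; the tile
#'   length is recorded in attribute `k`.
#' @export
tile_allergen <- function(panel, allergen_id = NULL, k = 16L, offset = 1L) {
  stopifnot(inherits(panel, "allergen_panel"), k >= 1L, offset >= 1L)
  if (is.null(allergen_id)) {
    if (nrow(panel) != 1L)
      stop("allergen_id must be given for a multi-record panel")
    rec <- panel
  } else {
    sel <- panel[["allergen_id"]] == allergen_id
    rec <- panel[which(sel), ]
    if (nrow(rec) != 1L) stop("allergen not in panel: ", allergen_id)
  }
  if (!rec$complete)
    stop("record '", rec$allergen_id,
         "' is incomplete and cannot be tiled")
  len <- nchar(rec$sequence)
  if (len < k)
    stop("record '", rec$allergen_id, "' is shorter (", len,
         ") than the tile length (", k, ")")
  starts <- seq.int(1L, len - k + 1L, by = offset)
  tiles <- data.table(
    allergen_id = rec$allergen_id,
    start_local = as.integer(starts),
    sequence = substring(rec$sequence, starts, starts + k - 1L)
  )
  setattr(tiles, "k", as.integer(k))
  tiles[]
}

#' Tile all complete allergens of a panel
#'
#' Applies [tile_allergen()] to every complete record and, when a master
#' alignment is supplied, annotates each tile with the alignment column of
#' its first residue (`start_aligned`), the numbering used throughout
#' per-position figures and for homolog matching. Without an alignment
#' `start_aligned` is `NA`.
#'
#' @inheritParams tile_allergen
#' @param alignment optional [master_alignment] covering the panel.
#' @return `data.table` with columns `allergen_id`, `start_local`,
#'   `start_aligned`, `sequence`; attribute `k` records the tile length.
#' @export
tile_panel <- function(panel, alignment = NULL, k = 16L, offset = 1L) {
  stopifnot(inherits(panel, "allergen_panel"))
  comp <- panel[panel$complete == TRUE, ]
  if (nrow(comp) == 0L) stop("panel has no complete records")
  tiles <- rbindlist(lapply(comp$allergen_id, function(id)
    tile_allergen(panel, id, k = k, offset = offset)))
  if (is.null(alignment)) {
    tiles[, start_aligned := NA_integer_]
  } else {
    tiles[, start_aligned := local_to_aligned(alignment, .BY$allergen_id,
                                              start_local),
          by = allergen_id]
  }
  setcolorder(tiles, c("allergen_id", "start_local", "start_aligned",
                       "sequence"))
  setattr(tiles, "k", as.integer(k))
  tiles[]
}

#' Build the unique-peptide index
#'
#' Identical k-mers arising from different allergens (or positions) collapse
#' to a single unique peptide carrying the list of its occurrences. The sum
#' of occurrence-list lengths equals the total tile count, so no tile is lost
#' or double counted.
#'
#' @param tiles tile table from [tile_panel()] (or [tile_allergen()] output
#'   with a `start_aligned` column added); all tiles must share one k.
#' @return Object of class `peptide_index`: a list with elements
#'   `k`, `unique_sequences` (character vector, first-occurrence order),
#'   `occurrences` (`data.table` of `sequence`, `allergen_id`, `start_local`,
#'   `start_aligned`), and `n_unique`.
#' @export
build_peptide_index <- function(tiles) {
  stopifnot(is.data.frame(tiles), nrow(tiles) > 0L)
  tiles <- as.data.table(tiles)
  if (!"start_aligned" %in% names(tiles))
    tiles[, start_aligned := NA_integer_]
  ks <- unique(nchar(tiles$sequence))
  if (length(ks) != 1L)
    stop("tiles carry mixed peptide lengths: ",
         paste(sort(ks), collapse = ", "))
  occ <- tiles[, .(sequence, allergen_id, start_local, start_aligned)]
  idx <- structure(
    list(k = as.integer(ks),
         unique_sequences = unique(occ$sequence),
         occurrences = occ,
         n_unique = uniqueN(occ$sequence)),
    class = "peptide_index")
  idx
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf(
    "peptide_index: %d unique %d-mers, %d occurrences across %d allergens\n",
    x$n_unique, x$k, nrow(x$occurrences), uniqueN(x$occurrences$allergen_id)))
  invisible(x)
}

#' Export tiles or an index occurrence list as TSV
#'
#' @param tiles tile table or [build_peptide_index()] result.
#' @param path output path.
#' @return Invisibly, the written table.
#' @export
write_tiles <- function(tiles, path) {
  if (inherits(tiles, "peptide_index")) tiles <- tiles$occurrences
  out <- as.data.table(tiles)
  fwrite(out, path, sep = "\t")
  invisible(out)
}
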