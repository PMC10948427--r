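## Master alignment: coordinate mapping between allergen-local residue
## numbering and alignment-column numbering, plus per-column diversity.
##
## The alignment is an input (gapped FASTA), not computed here: pipelines of
## this kind fix one published alignment so that per-position numbering is
## stable across allergens and figures.

#' Construct a master alignment
#'
#' @param rows named character vector of equal-length gapped sequences;
#'   `-` (or `.`, normalised to `-`) marks a gap. Names are allergen ids.
#' @return Object of class `master_alignment`: list with `rows` (named
#'   character) and `column_count`.
#' @export
master_alignment <- function(rows) {
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("alignment rows must be named by allergen id")
  if (anyDuplicated(names(rows)))
    stop("duplicate allergen ids in alignment")
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in width: ",
         paste(range(widths), collapse = " vs "))
  structure(list(rows = rows, column_count = widths[[1]]),
            class = "master_alignment")
}

#' Read a master alignment from gapped FASTA
#'
#' @param path gapped FASTA file; full description lines are used as ids.
#' @return A [master_alignment].
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  rows <- as.character(seqs)
  names(rows) <- trimws(names(seqs))
  master_alignment(rows)
}

#' @export
print.master_alignment <- function(x, ...) {
  cat(sprintf("master_alignment: %d rows x %d columns\n",
              length(x$rows), x$column_count))
  invisible(x)
}

#' Check that an alignment matches a panel
#'
#' Ungapping each alignment row must reproduce the panel sequence exactly.
#'
#' @param alignment a [master_alignment].
#' @param panel an [allergen_panel]; only records present in the alignment
#'   are checked.
#' @return Invisibly `TRUE`; stops with the offending id otherwise.
#' @export
check_alignment <- function(alignment, panel) {
  stopifnot(inherits(alignment, "master_alignment"),
            inherits(panel, "allergen_panel"))
  shared <- intersect(names(alignment$rows), panel$allergen_id)
  for (id in shared) {
    ungapped <- gsub("-", "", alignment$rows[[id]], fixed = TRUE)
    ref <- panel$sequence[panel$allergen_id == id]
    if (!identical(ungapped, ref))
      stop("alignment row '", id, "' does not ungap to the panel sequence")
  }
  invisible(TRUE)
}

.alignment_row_chars <- function(alignment, allergen_id) {
  if (!allergen_id %in% names(alignment$rows))
    stop("allergen not in alignment: ", allergen_id)
  strsplit(alignment$rows[[allergen_id]], "")[[1]]
}

#' Map allergen-local positions to alignment columns
#'
#' Returns the 1-based alignment column holding the `local_pos`-th non-gap
#' residue of the given row. This is the coordinate system in which tile
#' start numbers are compared across allergens.
#'
#' @param alignment a [master_alignment].
#' @param allergen_id row to map on.
#' @param local_pos integer vector of 1-based residue positions.
#' @return Integer vector of alignment columns.
#' @seealso [aligned_to_local()] for the inverse.
#' @export
local_to_aligned <- function(alignment, allergen_id, local_pos) {
  chars <- .alignment_row_chars(alignment, allergen_id)
  nongap <- which(chars != "-")
  local_pos <- as.integer(local_pos)
  if (any(local_pos < 1L | local_pos > length(nongap)))
    stop("local position out of range 1..", length(nongap),
         " for '", allergen_id, "'")
  nongap[local_pos]
}

#' Map alignment columns to allergen-local positions
#'
#' Inverse of [local_to_aligned()]. Columns where the row carries a gap have
#' no local residue and map to `NA`.
#'
#' @inheritParams local_to_aligned
#' @param aligned_pos integer vector of 1-based alignment columns.
#' @return Integer vector of local positions (`NA` at gap columns).
#' @export
aligned_to_local <- function(alignment, allergen_id, aligned_pos) {
  chars <- .alignment_row_chars(alignment, allergen_id)
  aligned_pos <- as.integer(aligned_pos)
  if (any(aligned_pos < 1L | aligned_pos > length(chars)))
    stop("aligned position out of range 1..", length(chars))
  local_of_col <- cumsum(chars != "-")
  ifelse(chars[aligned_pos] == "-", NA_integer_,
         as.integer(local_of_col[aligned_pos]))
}

#' Per-column sequence diversity of the alignment
#'
#' For every alignment column, tabulates residues over non-gap rows and
#' reports the consensus residue (ties broken alphabetically), its frequency
#' among non-gap entries, and whether the column is flagged diverse, i.e.
#' the consensus frequency is strictly below `threshold`. All-gap columns
#' yield `NA` consensus and are never flagged.
#'
#' @param alignment a [master_alignment] with at least two rows.
#' @param threshold diversity cut-off on the consensus frequency
#'   (default 0.5: a column is diverse when the most prominent residue is
#'   carried by fewer than half the sequences).
#' @return `data.table` with columns `column`, `consensus_residue`,
#'   `consensus_frequency`, `diverse`.
#' @export
column_diversity_profile <- function(alignment, threshold = 0.5) {
  stopifnot(inherits(alignment, "master_alignment"))
  if (length(alignment$rows) < 2L)
    stop("diversity profile needs at least 2 alignment rows")
  mat <- do.call(rbind, strsplit(unname(alignment$rows), ""))
  res <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L)
      return(list(column = j, consensus_residue = NA_character_,
                  consensus_frequency = NA_real_, diverse = NA))
    tab <- table(col)
    tab <- tab[order(-tab, names(tab))]  # ties -> alphabetical
    freq <- as.numeric(tab[1]) / length(col)
    list(column = j, consensus_residue = names(tab)[1],
         consensus_frequency = freq, diverse = freq < threshold)
  })
  rbindlist(res)
}
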