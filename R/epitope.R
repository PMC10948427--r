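## Epitope deconvolution: runs of reactive tiles, minimal epitopes,
## homolog grouping at an aligned start, residue-level attribution of
## binding differences, isoallergen contrasts and the unique k-mer index.

#' Minimal epitope of a contiguous run of reactive tiles
#'
#' The minimal epitope is the stretch of residues covered by *all* reactive
#' tiles of a run: for tiles of length k starting at `first..last`
#' (contiguous), it spans `[last, first + k - 1]` and therefore has length
#' `k - (n_starts - 1)`. A run consisting of a single tile returns the full
#' k-mer; a run of k tiles narrows the epitope to a single residue.
#'
#' @param starts integer vector of reactive tile start positions. All tiles
#'   must share at least one residue (`max(starts) - min(starts) < k`);
#'   sets spanning more than one tile length have an empty intersection and
#'   must be split into runs first (see [call_segments()]).
#' @param sequence the allergen sequence the starts refer to.
#' @param k tile length (default 16).
#' @return List with `sequence` (the minimal epitope string), `start`,
#'   `end` (1-based inclusive local coordinates).
#' @export
minimal_epitope <- function(starts, sequence, k = 16L) {
  starts <- sort(unique(as.integer(starts)))
  if (length(starts) == 0L) stop("empty start set")
  first <- starts[1]; last <- starts[length(starts)]
  if (last - first >= k)
    stop("tiles share no common residue; not a single contiguous run - ",
         "split into runs first")
  if (first < 1L || last + k - 1L > nchar(sequence))
    stop("run extends beyond the sequence")
  list(sequence = substring(sequence, last, first + k - 1L),
       start = last, end = as.integer(first + k - 1L))
}

#' Deconvolve epitope segments from confirmed reactive calls
#'
#' Groups confirmed calls by sample and allergen, splits the reactive tile
#' start positions into maximal runs (runs are broken by gaps larger than
#' `max_gap + 1` starts; the default `max_gap = 0` requires strictly
#' consecutive starts), and reports one epitope segment per run with its
#' span (union of tile coverage) and minimal epitope (intersection of tile
#' coverage). With `max_gap > 0` the minimal span may be empty for long
#' gapped runs, in which case the minimal epitope is `NA`.
#'
#' @param calls a [call_reactive()] result.
#' @param index the matching [build_peptide_index()].
#' @param panel the [allergen_panel] (provides sequences for the minimal
#'   epitope strings).
#' @param alignment optional [master_alignment] to add aligned coordinates.
#' @param max_gap number of missing starts tolerated inside a run
#'   (default 0; 1 absorbs single failed spots).
#' @param use `"confirmed"` (default) or `"reactive"`: which calls seed
#'   segments.
#' @return `data.table` of class `epitope_segments`, one row per segment:
#'   sample key columns, `allergen_id`, `first_start`, `last_start`,
#'   `n_starts`, `span_start`, `span_end`, `minimal_start`, `minimal_end`,
#'   `minimal_epitope`, plus `span_start_aligned` / `minimal_start_aligned`
#'   when an alignment is given.
#' @export
call_segments <- function(calls, index, panel, alignment = NULL,
                          max_gap = 0L, use = c("confirmed", "reactive")) {
  use <- match.arg(use)
  stopifnot(inherits(index, "peptide_index"),
            inherits(panel, "allergen_panel"))
  k <- index$k
  sel <- if (use == "confirmed") calls[calls$confirmed == TRUE, ]
         else calls[calls$reactive == TRUE, ]
  empty <- data.table(
    sample_id = character(), subject_id = character(),
    timepoint = integer(), isotype = character(),
    allergen_id = character(), first_start = integer(),
    last_start = integer(), n_starts = integer(),
    span_start = integer(), span_end = integer(),
    minimal_start = integer(), minimal_end = integer(),
    minimal_epitope = character())
  if (nrow(sel) == 0L) return(empty)

  occ <- index$occurrences[sel, on = .(sequence = peptide),
                           allow.cartesian = TRUE]
  occ <- unique(occ[, .(sample_id, subject_id, timepoint, isotype,
                        allergen_id, start_local)])
  setorder(occ, sample_id, allergen_id, start_local)
  occ[, run_id := cumsum(c(1L, diff(start_local) > max_gap + 1L)),
      by = .(sample_id, allergen_id)]

  segs <- occ[, .(
    subject_id = subject_id[1], timepoint = timepoint[1],
    isotype = isotype[1],
    first_start = min(start_local), last_start = max(start_local),
    n_starts = uniqueN(start_local)),
    by = .(sample_id, allergen_id, run_id)]
  segs[, run_id := NULL]
  segs[, span_start := first_start]
  segs[, span_end := last_start + k - 1L]
  segs[, minimal_start := last_start]
  segs[, minimal_end := first_start + k - 1L]
  segs[minimal_end < minimal_start,
       c("minimal_start", "minimal_end") := .(NA_integer_, NA_integer_)]
  seq_of <- setNames(panel$sequence, panel$allergen_id)
  segs[, minimal_epitope := ifelse(
    is.na(minimal_start), NA_character_,
    substring(seq_of[allergen_id], minimal_start, minimal_end))]

  if (!is.null(alignment)) {
    segs[, span_start_aligned := local_to_aligned(alignment,
                                                  .BY$allergen_id, span_start),
         by = allergen_id]
    segs[, minimal_start_aligned := ifelse(
      is.na(minimal_start), NA_integer_,
      local_to_aligned(alignment, .BY$allergen_id,
                       ifelse(is.na(minimal_start), 1L, minimal_start))),
      by = allergen_id]
  }
  setcolorder(segs, c("sample_id", "subject_id", "timepoint", "isotype",
                      "allergen_id"))
  setattr(segs, "class", c("epitope_segments", class(segs)))
  setattr(segs, "k", k)
  segs[]
}

#' Group homologous tiles at one aligned start
#'
#' Collects, for every allergen in the alignment, the tile whose first
#' residue maps to the given master-alignment column (absent when the
#' allergen has a gap there or no such tile). Allergens carrying identical
#' tile sequences collapse into one representative with a member list —
#' species with identical peptides at a position appear only once.
#'
#' @param index a [build_peptide_index()] result.
#' @param alignment a [master_alignment].
#' @param aligned_start 1-based alignment column of the tile's first
#'   residue.
#' @return Object of class `homolog_group`: list with `aligned_start`, `k`,
#'   `members` (`data.table` of `allergen_id`, `start_local`, `sequence`)
#'   and `representatives` (`data.table` of `sequence`, `allergens`
#'   (list-column), `n_members`).
#' @export
group_homologs <- function(index, alignment, aligned_start) {
  stopifnot(inherits(index, "peptide_index"),
            inherits(alignment, "master_alignment"))
  aligned_start <- as.integer(aligned_start)
  if (aligned_start < 1L || aligned_start > alignment$column_count)
    stop("aligned_start out of range")
  occ <- index$occurrences
  members <- rbindlist(lapply(names(alignment$rows), function(id) {
    loc <- aligned_to_local(alignment, id, aligned_start)
    if (is.na(loc)) return(NULL)
    hit <- occ[occ$allergen_id == id & occ$start_local == loc, ]
    if (nrow(hit) == 0L) return(NULL)
    data.table(allergen_id = id, start_local = loc,
               sequence = hit$sequence[1])
  }))
  if (is.null(members) || nrow(members) == 0L)
    members <- data.table(allergen_id = character(),
                          start_local = integer(), sequence = character())
  reps <- members[, .(allergens = list(sort(allergen_id)),
                      n_members = .N), by = sequence]
  structure(list(aligned_start = aligned_start, k = index$k,
                 members = members, representatives = reps),
            class = "homolog_group")
}

#' @export
print.homolog_group <- function(x, ...) {
  cat(sprintf(
    "homolog_group at aligned start %d: %d members, %d representatives\n",
    x$aligned_start, nrow(x$members), nrow(x$representatives)))
  invisible(x)
}

#' Residue-level attribution of binding differences across homologs
#'
#' Given one sample's signals over the representatives of a homolog group,
#' scans every alignment column in the tile window and, for each residue
#' class with at least `min_class` representatives on both sides, computes
#' the effect as the difference of class means of the signal
#' (`mean(signal | residue) - mean(signal | other residues)`). Columns are
#' ranked by absolute effect; columns with `|effect| >= effect_cut` are
#' flagged. Because class sizes are tiny (at most the number of isoforms),
#' this is a ranking, not a formal test.
#'
#' @param group a [group_homologs()] result.
#' @param signals named numeric vector of signals (log2 intensities or
#'   z-scores) for one sample, named by representative peptide sequence or
#'   by allergen id.
#' @param alignment the [master_alignment] (provides per-column residues).
#' @param min_class minimum representatives per residue class (default 2).
#' @param effect_cut flagging threshold on `|effect|` in signal units
#'   (default 2, i.e. a four-fold intensity difference on the log2 scale).
#' @return `data.table` with columns `column` (alignment position),
#'   `residue` (class residue maximising `|effect|` at that column),
#'   `effect`, `n_class` / `n_other` (member-allergen counts of the class
#'   and its complement), `flagged`, sorted by decreasing `|effect|`; zero
#'   rows when no column has two eligible classes.
#' @export
residue_association <- function(group, signals, alignment,
                                min_class = 2L, effect_cut = 2) {
  stopifnot(inherits(group, "homolog_group"),
            inherits(alignment, "master_alignment"))
  reps <- group$representatives
  if (nrow(reps) < 3L)
    stop("need >= 3 representatives with signal; got ", nrow(reps))
  ## resolve signals: by representative sequence, else by allergen id
  if (all(reps$sequence %in% names(signals))) {
    sig <- signals[reps$sequence]
  } else {
    first_member <- vapply(reps$allergens, `[[`, character(1), 1L)
    if (!all(first_member %in% names(signals)))
      stop("signals must be named by representative sequence or allergen id")
    sig <- signals[first_member]
  }
  keep <- !is.na(sig)
  reps <- reps[keep]; sig <- unname(sig[keep])
  if (nrow(reps) < 3L) stop("fewer than 3 representatives carry a signal")

  ## per-column residues from the gapped row of each representative's first
  ## member (members of one representative share the tile sequence)
  cols <- seq.int(group$aligned_start, group$aligned_start + group$k - 1L)
  cols <- cols[cols <= alignment$column_count]
  res_mat <- vapply(seq_len(nrow(reps)), function(i) {
    row <- .alignment_row_chars(alignment, reps$allergens[[i]][1])
    row[cols]
  }, character(length(cols)))
  if (is.null(dim(res_mat))) res_mat <- matrix(res_mat, nrow = length(cols))

  nm <- reps$n_members
  out <- rbindlist(lapply(seq_along(cols), function(j) {
    rr <- res_mat[j, ]
    ok <- rr != "-"
    rr <- rr[ok]; ss <- sig[ok]; mm <- nm[ok]
    classes <- unique(rr)
    if (length(classes) < 2L) return(NULL)
    cand <- rbindlist(lapply(classes, function(a) {
      ## class sizes count member allergens (identical peptides carry all
      ## their members); means are over representatives, each measured once
      n1 <- sum(mm[rr == a]); n0 <- sum(mm[rr != a])
      if (n1 < min_class || n0 < min_class) return(NULL)
      data.table(column = cols[j], residue = a,
                 effect = mean(ss[rr == a]) - mean(ss[rr != a]),
                 n_class = n1, n_other = n0)
    }))
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand[which.max(abs(cand$effect))]
  }))
  if (is.null(out) || nrow(out) == 0L)
    return(data.table(column = integer(), residue = character(),
                      effect = numeric(), n_class = integer(),
                      n_other = integer(), flagged = logical()))
  out[, flagged := abs(effect) >= effect_cut]
  out <- out[order(-abs(effect))]
  out[]
}

#' Isoallergen-differential recognition
#'
#' For each pair of isoforms, compares reactivity at every aligned tile
#' start where both members carry a tile: a position is *discriminating* in
#' a sample when exactly one member's peptide is reactive there. The signal
#' difference (z of the first member minus z of the second) is reported for
#' every shared position, so antisymmetry under swapping the pair is
#' explicit.
#'
#' @param calls a [call_reactive()] result.
#' @param index the matching [build_peptide_index()].
#' @param panel the [allergen_panel] (pair members must be present).
#' @param pairs two-column `data.frame` (or matrix) of allergen id pairs.
#' @return `data.table` with columns `allergen_a`, `allergen_b`,
#'   `sample_id`, `aligned_start`, `z_a`, `z_b`, `reactive_a`,
#'   `reactive_b`, `diff` and `discriminating`.
#' @export
isoallergen_contrasts <- function(calls, index, panel, pairs) {
  stopifnot(inherits(index, "peptide_index"),
            inherits(panel, "allergen_panel"))
  pairs <- as.data.frame(pairs)
  occ <- index$occurrences[!is.na(index$occurrences$start_aligned), ]
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- as.character(pairs[r, 1]); b <- as.character(pairs[r, 2])
    for (id in c(a, b))
      if (!id %in% panel$allergen_id) stop("pair member not in panel: ", id)
    occ_a <- occ[occ$allergen_id == a, .(start_aligned, pep_a = sequence)]
    occ_b <- occ[occ$allergen_id == b, .(start_aligned, pep_b = sequence)]
    shared <- merge(occ_a, occ_b, by = "start_aligned")
    if (nrow(shared) == 0L) next
    ca <- calls[, .(sample_id, peptide, z, reactive)]
    ga <- ca[shared, on = .(peptide = pep_a), allow.cartesian = TRUE]
    setnames(ga, c("z", "reactive", "peptide"),
             c("z_a", "reactive_a", "pep_a"))
    gb <- ca[, .(sample_id, pep_b = peptide, z_b = z, reactive_b = reactive)]
    gg <- merge(ga, gb, by = c("sample_id", "pep_b"))
    gg[, `:=`(allergen_a = a, allergen_b = b,
              diff = z_a - z_b,
              discriminating = xor(reactive_a, reactive_b))]
    out[[length(out) + 1L]] <-
      gg[, .(allergen_a, allergen_b, sample_id, aligned_start = start_aligned,
             z_a, z_b, reactive_a, reactive_b, diff, discriminating)]
  }
  if (length(out) == 0L)
    return(data.table(allergen_a = character(), allergen_b = character(),
                      sample_id = character(), aligned_start = integer(),
                      z_a = numeric(), z_b = numeric(),
                      reactive_a = logical(), reactive_b = logical(),
                      diff = numeric(), discriminating = logical()))
  res <- rbindlist(out)
  setorder(res, allergen_a, allergen_b, sample_id, aligned_start)[]
  res
}

#' Index every k-mer of a panel by its carrier allergens
#'
#' Supports "uniquely found in" queries: which allergens contain a given
#' k-mer as a substring anywhere in their sequence.
#'
#' @param panel an [allergen_panel]; only complete records are indexed.
#' @param k k-mer length (default 9, a typical minimal-epitope length).
#' @return Object of class `kmer_index`: list with `k` and `map`
#'   (`data.table` of `kmer`, `allergen_id`, unique rows).
#' @export
unique_kmer_index <- function(panel, k = 9L) {
  stopifnot(inherits(panel, "allergen_panel"), k >= 1L)
  comp <- panel[panel$complete == TRUE, ]
  map <- rbindlist(lapply(seq_len(nrow(comp)), function(i) {
    s <- comp$sequence[i]
    if (nchar(s) < k) return(NULL)
    starts <- seq_len(nchar(s) - k + 1L)
    data.table(kmer = unique(substring(s, starts, starts + k - 1L)),
               allergen_id = comp$allergen_id[i])
  }))
  structure(list(k = as.integer(k), map = map), class = "kmer_index")
}

#' Query the carrier set of a k-mer
#'
#' @param kidx a [unique_kmer_index()] result.
#' @param kmer amino-acid string of length `kidx$k`.
#' @return Character vector of allergen ids containing the k-mer (possibly
#'   empty); a k-mer carried by exactly one allergen is unique to it.
#' @export
kmer_carriers <- function(kidx, kmer) {
  stopifnot(inherits(kidx, "kmer_index"))
  if (nchar(kmer) != kidx$k)
    stop("query length ", nchar(kmer), " != index k ", kidx$k)
  sort(kidx$map[["allergen_id"]][kidx$map[["kmer"]] == kmer])
}
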