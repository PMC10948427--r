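## Longitudinal analysis: stability of per-subject reactivity profiles
## across timepoints, and detection of induced (novel or greatly increased)
## reactivities.

#' Within- versus between-subject profile stability
#'
#' Computes the Pearson correlation of log2 reactivity profiles for every
#' pair of samples of one isotype over their shared (jointly observed)
#' peptides, and splits pairs into within-subject (two timepoints of the
#' same subject) and between-subject groups. Stable individual repertoires
#' show a higher mean within-subject than between-subject correlation.
#'
#' @param rmat a [reactivity_matrix()].
#' @param isotype isotype layer to analyse (default `"IgG"`).
#' @param min_shared minimum jointly observed peptides per pair (default
#'   3); pairs below it are skipped with a warning.
#' @return Object of class `stability_summary`: list with `pairs`
#'   (`data.table` of `sample_a`, `sample_b`, `type`, `r`, `n_shared`),
#'   `mean_within`, `mean_between`.
#' @export
stability_correlation <- function(rmat, isotype = "IgG", min_shared = 3L) {
  stopifnot(inherits(rmat, "reactivity_matrix"))
  sel <- rmat$samples[["isotype"]] == isotype
  keep <- rmat$samples[which(sel), ]
  if (nrow(keep) < 2L) stop("need >= 2 samples of isotype ", isotype)
  lg <- rmat$log2[keep$sample_id, , drop = FALSE]
  subj <- setNames(keep$subject_id, keep$sample_id)
  ids <- keep$sample_id
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) for (j in seq.int(i + 1L, length(ids))) {
    x <- lg[ids[i], ]; y <- lg[ids[j], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_shared) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.table(
      sample_a = ids[i], sample_b = ids[j],
      type = if (subj[ids[i]] == subj[ids[j]]) "within" else "between",
      r = cor(x[ok], y[ok]), n_shared = sum(ok))
  }
  if (n_skipped > 0L)
    warning(n_skipped, " sample pairs skipped (< ", min_shared,
            " shared peptides)")
  pairs <- rbindlist(rows)
  structure(list(
    pairs = pairs,
    mean_within = mean(pairs$r[pairs$type == "within"]),
    mean_between = mean(pairs$r[pairs$type == "between"])),
    class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf(
    "stability_summary: mean r within-subject %.3f (n=%d), between %.3f (n=%d)\n",
    x$mean_within, sum(x$pairs$type == "within"),
    x$mean_between, sum(x$pairs$type == "between")))
  invisible(x)
}

#' Detect induced reactivities across timepoints
#'
#' An induced reactivity is a peptide signal absent at all earlier
#' timepoints of a subject (robust z below `z_low`) that reaches the
#' reactivity threshold `z_cut` at a later timepoint with a log2 intensity
#' increase of at least `fold_min` over the baseline mean. A mere rise from
#' already-elevated baseline (baseline z above `z_low`) does not qualify:
#' that is an increase, not an induction. Only observed timepoints are
#' evaluated; missing samples are never imputed.
#'
#' Qualifying peptides are mapped to their tile occurrences and merged into
#' aligned-start windows per subject, isotype and allergen (starts within
#' `merge_gap + 1` columns join one window). When `calls` are supplied,
#' only peptides whose call at the induced timepoint is confirmed
#' contribute (the same multi-sample / multi-peptide criteria that guard
#' against single-spot artifacts), and each event carries the union of its
#' peptides' support tags.
#'
#' @param rmat a [reactivity_matrix()].
#' @param index the matching [build_peptide_index()].
#' @param z optional precomputed [robust_z()] matrix.
#' @param calls optional [call_reactive()] result used for confirmation
#'   filtering and support tags.
#' @param z_low baseline ceiling: all earlier timepoints must stay below
#'   this z (default 1).
#' @param z_cut induction threshold on z (default 3).
#' @param fold_min minimum log2 intensity increase over the baseline mean
#'   (default 2, i.e. four-fold).
#' @param merge_gap aligned-start gap tolerated within one event window
#'   (default 1).
#' @return `data.table` of class `induced_events`, one row per event:
#'   `subject_id`, `isotype`, `allergen_id`, `window_start`, `window_end`
#'   (aligned tile-start window), `first_induced_tp`, `log2_fold` (maximum
#'   over member peptides), `n_peptides`, `support` (comma-joined union of
#'   tags, `""` without `calls`). Attribute `peptide_events` holds the
#'   underlying per-peptide table.
#' @export
detect_induced <- function(rmat, index, z = NULL, calls = NULL,
                           z_low = 1, z_cut = 3, fold_min = 2,
                           merge_gap = 1L) {
  stopifnot(inherits(rmat, "reactivity_matrix"),
            inherits(index, "peptide_index"))
  if (is.null(z)) z <- robust_z(rmat)
  samples <- rmat$samples
  lg <- rmat$log2

  empty <- data.table(
    subject_id = character(), isotype = character(),
    allergen_id = character(), window_start = integer(),
    window_end = integer(), first_induced_tp = integer(),
    log2_fold = numeric(), n_peptides = integer(), support = character())

  ## per (subject, isotype): trajectories over observed timepoints
  pep_events <- list()
  grp <- split(samples, paste(samples$subject_id, samples$isotype, sep = "|"))
  for (g in grp) {
    if (nrow(g) < 2L) next
    g <- g[order(g$timepoint), ]
    zz <- z[g$sample_id, , drop = FALSE]
    ll <- lg[g$sample_id, , drop = FALSE]
    tps <- g$timepoint
    for (p in seq_len(ncol(zz))) {
      zt <- zz[, p]; lt <- ll[, p]
      obs <- which(!is.na(zt))
      if (length(obs) < 2L) next
      hit <- obs[zt[obs] >= z_cut]
      found <- FALSE
      for (h in hit) {
        earlier <- obs[obs < h]
        if (length(earlier) == 0L) next
        if (any(zt[earlier] >= z_low)) next
        fold <- lt[h] - mean(lt[earlier])
        if (fold < fold_min) next
        pep_events[[length(pep_events) + 1L]] <- data.table(
          subject_id = g$subject_id[1], isotype = g$isotype[1],
          peptide = colnames(zz)[p],
          first_induced_tp = tps[h], log2_fold = fold,
          sample_id = g$sample_id[h])
        found <- TRUE
        break  # report the first induced timepoint only
      }
    }
  }
  if (length(pep_events) == 0L) {
    setattr(empty, "class", c("induced_events", class(empty)))
    return(empty)
  }
  pe <- rbindlist(pep_events)

  ## confirmation filter + support tags from the calling layer
  if (!is.null(calls)) {
    cc <- calls[, .(sample_id, peptide, confirmed, support)]
    pe <- cc[pe, on = .(sample_id, peptide)]
    pe <- pe[confirmed == TRUE]
    if (nrow(pe) == 0L) {
      setattr(empty, "class", c("induced_events", class(empty)))
      return(empty)
    }
  } else {
    pe[, support := ""]
  }

  ## map to tile occurrences and merge into aligned-start windows
  occ <- index$occurrences[pe, on = .(sequence = peptide),
                           allow.cartesian = TRUE]
  occ <- occ[!is.na(start_aligned)]
  if (nrow(occ) == 0L) {
    setattr(empty, "class", c("induced_events", class(empty)))
    return(empty)
  }
  setorder(occ, subject_id, isotype, allergen_id, start_aligned)
  occ[, aligned_run := cumsum(c(1L, diff(start_aligned) > merge_gap + 1L)),
      by = .(subject_id, isotype, allergen_id)]
  events <- occ[, .(
    window_start = min(start_aligned), window_end = max(start_aligned),
    first_induced_tp = min(first_induced_tp),
    log2_fold = max(log2_fold),
    n_peptides = uniqueN(sequence),
    support = paste(sort(unique(unlist(strsplit(support[support != ""], ",")))),
                    collapse = ",")),
    by = .(subject_id, isotype, allergen_id, aligned_run)]
  events[, aligned_run := NULL]
  setattr(events, "class", c("induced_events", class(events)))
  setattr(events, "peptide_events", pe)
  events[]
}
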