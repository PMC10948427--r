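## Ground-truth recovery: run the standard pipeline on a synthetic cohort
## and score calls, epitope windows, key residues and induction events
## against the planted truth.

.interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0L, min(a2, b2) - max(a1, b1) + 1L)
  uni <- (a2 - a1 + 1L) + (b2 - b1 + 1L) - inter
  inter / uni
}

#' Run the standard calling pipeline on a synthetic cohort
#'
#' Chains matrix construction, robust z-scoring, reactive calling with
#' confirmation, epitope segment deconvolution and induction detection at
#' the given thresholds, then scores everything against the planted truth
#' with [evaluate_recovery()].
#'
#' @param cohort a [simulate_intensities()] / [simulate_cohort()] result.
#' @param z_cut,z_low,fold_min,overlap_min,effect_cut pipeline thresholds;
#'   see [call_reactive()], [detect_induced()], [residue_association()].
#' @return List with `rmat`, `z`, `calls`, `segments`, `induced` and
#'   `metrics` (the [evaluate_recovery()] result).
#' @export
run_recovery <- function(cohort, z_cut = 3, z_low = 1, fold_min = 2,
                         overlap_min = 8L, effect_cut = 2) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  index <- cohort$index
  rmat <- reactivity_matrix(cohort$intensities, index)
  z <- robust_z(rmat)
  calls <- call_reactive(rmat, index, z = z, z_cut = z_cut,
                         overlap_min = overlap_min)
  segments <- call_segments(calls, index, cohort$panel, cohort$alignment)
  induced <- detect_induced(rmat, index, z = z, calls = calls,
                            z_low = z_low, z_cut = z_cut,
                            fold_min = fold_min)
  metrics <- evaluate_recovery(cohort, rmat, calls, segments, induced,
                               effect_cut = effect_cut)
  list(rmat = rmat, z = z, calls = calls, segments = segments,
       induced = induced, metrics = metrics)
}

#' Score pipeline outputs against the planted truth
#'
#' Computes, on one isotype layer (default IgG, the layer carrying the
#' full planted affinities):
#'
#' * `call_precision` / `call_recall` of confirmed reactive calls against
#'   the cells with a planted effect;
#' * `window_recall` and `mean_window_jaccard`: fraction of planted
#'   epitopes whose minimal epitope is recovered by some segment of the
#'   subject (interval Jaccard of the minimal span with the planted window
#'   at least `min_jaccard`);
#' * `key_residue_accuracy`: fraction of key-residue epitopes for which
#'   [residue_association()] at the planted window ranks the planted
#'   column first and flags it;
#' * `induction_recall`, `induction_timepoint_accuracy` and
#'   `n_false_induction_events` (clusters of detected events not matching
#'   any planted induced window of the subject, cohort-wide).
#'
#' All metrics lie in `[0, 1]` except the false-event count; metrics whose
#' denominator is empty are `NA`.
#'
#' @param cohort the `synthetic_cohort`.
#' @param rmat,calls,segments,induced pipeline outputs over the cohort's
#'   intensity table.
#' @param isotype isotype layer to score (default `"IgG"`).
#' @param min_jaccard window-recovery threshold (default 0.5).
#' @param effect_cut flagging threshold forwarded to
#'   [residue_association()].
#' @return List of class `recovery_metrics` with the scalar metrics and
#'   `details` (per-epitope tables).
#' @export
evaluate_recovery <- function(cohort, rmat, calls, segments, induced,
                              isotype = "IgG", min_jaccard = 0.5,
                              effect_cut = 2) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- cohort$truth
  iso <- isotype
  k <- cohort$index$k
  w <- attr(truth, "params")$window_width
  n_tp <- cohort$params$timepoints

  ## --- confirmed-call precision / recall -------------------------------
  eff <- cohort$effects[cohort$effects$isotype == iso &
                          cohort$effects$effect > 0, ]
  truth_cells <- unique(paste(
    .sample_id(eff$subject_id, eff$timepoint, eff$isotype), eff$peptide))
  conf <- calls[calls$isotype == iso & calls$confirmed == TRUE, ]
  conf_cells <- unique(paste(conf$sample_id, conf$peptide))
  call_precision <- if (length(conf_cells) > 0L)
    mean(conf_cells %in% truth_cells) else NA_real_
  call_recall <- if (length(truth_cells) > 0L)
    mean(truth_cells %in% conf_cells) else NA_real_

  ## --- epitope-window recovery -----------------------------------------
  segs <- segments[segments$isotype == iso &
                     !is.na(segments$minimal_start), ]
  carriers_of <- function(ep) {
    ids <- cohort$panel$allergen_id
    if (!ep$is_key) return(ids)
    res <- substring(cohort$panel$sequence, ep$key_column, ep$key_column)
    ids[res == ep$required_residue]
  }
  ep_rows <- lapply(seq_len(nrow(truth)), function(i) {
    ep <- truth[i]
    active <- if (is.na(ep$induction_tp)) seq_len(n_tp) else
      seq.int(ep$induction_tp, n_tp)
    ss <- segs[segs$subject_id == ep$subject_id &
                 segs$timepoint %in% active &
                 segs$allergen_id %in% carriers_of(ep), ]
    bj <- if (nrow(ss) > 0L)
      max(vapply(seq_len(nrow(ss)), function(j)
        .interval_jaccard(ss$minimal_start[j], ss$minimal_end[j],
                          ep$window_start, ep$window_end), numeric(1)))
      else 0
    data.table(epitope_id = ep$epitope_id, subject_id = ep$subject_id,
               is_key = ep$is_key, induced = !is.na(ep$induction_tp),
               best_jaccard = bj, recovered = bj >= min_jaccard)
  })
  ep_tab <- rbindlist(ep_rows)
  window_recall <- mean(ep_tab$recovered)
  mean_window_jaccard <- mean(ep_tab$best_jaccard)

  ## --- key-residue attribution -----------------------------------------
  keys <- truth[truth$is_key == TRUE, ]
  key_tab <- NULL
  key_residue_accuracy <- NA_real_
  if (nrow(keys) > 0L) {
    key_rows <- lapply(seq_len(nrow(keys)), function(i) {
      ep <- keys[i]
      sid <- .sample_id(ep$subject_id, n_tp, iso)  # last timepoint: always active
      ok <- tryCatch({
        grp <- group_homologs(cohort$index, cohort$alignment,
                              ep$window_start)
        assoc <- residue_association(grp, rmat$log2[sid, ],
                                     cohort$alignment,
                                     effect_cut = effect_cut)
        nrow(assoc) > 0L && assoc$column[1] == ep$key_column &&
          assoc$flagged[1]
      }, error = function(e) FALSE)
      data.table(epitope_id = ep$epitope_id, key_column = ep$key_column,
                 identified = ok)
    })
    key_tab <- rbindlist(key_rows)
    key_residue_accuracy <- mean(key_tab$identified)
  }

  ## --- induction events -------------------------------------------------
  planted <- truth[!is.na(truth$induction_tp), ]
  det <- induced[induced$isotype == iso, ]
  induction_recall <- induction_timepoint_accuracy <- NA_real_
  n_false <- 0L
  ind_tab <- NULL
  ## cluster detected events per subject across allergens (overlapping or
  ## near-touching aligned start windows merge)
  clusters <- NULL
  if (nrow(det) > 0L) {
    dd <- as.data.table(det)[, .(subject_id, window_start, window_end,
                                 first_induced_tp)]
    setorder(dd, subject_id, window_start)
    dd[, cluster := {
      cm <- cummax(window_end)
      cumsum(c(TRUE, window_start[-1] > utils::head(cm, -1L) + 3L))
    }, by = subject_id]
    clusters <- dd[, .(window_start = min(window_start),
                       window_end = max(window_end),
                       first_induced_tp = min(first_induced_tp)),
                   by = .(subject_id, cluster)]
  }
  if (nrow(planted) > 0L) {
    ind_rows <- lapply(seq_len(nrow(planted)), function(i) {
      ep <- planted[i]
      exp_lo <- ep$window_start - (k - w)  # first covering tile start
      exp_hi <- ep$window_start
      hits <- det[det$subject_id == ep$subject_id &
                    det$window_start <= exp_hi + 1L &
                    det$window_end >= exp_lo - 1L, ]
      data.table(epitope_id = ep$epitope_id,
                 planted_tp = ep$induction_tp,
                 recovered = nrow(hits) > 0L,
                 tp_correct = nrow(hits) > 0L &&
                   any(hits$first_induced_tp == ep$induction_tp))
    })
    ind_tab <- rbindlist(ind_rows)
    induction_recall <- mean(ind_tab$recovered)
    if (any(ind_tab$recovered))
      induction_timepoint_accuracy <-
        mean(ind_tab$tp_correct[ind_tab$recovered])
  }
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    matched <- vapply(seq_len(nrow(clusters)), function(i) {
      cl <- clusters[i]
      pl <- planted[planted$subject_id == cl$subject_id, ]
      if (nrow(pl) == 0L) return(FALSE)
      any(pl$window_start - (k - w) - 1L <= cl$window_end &
            pl$window_start + 1L >= cl$window_start)
    }, logical(1))
    n_false <- sum(!matched)
  }

  structure(list(
    call_precision = call_precision,
    call_recall = call_recall,
    window_recall = window_recall,
    mean_window_jaccard = mean_window_jaccard,
    key_residue_accuracy = key_residue_accuracy,
    induction_recall = induction_recall,
    induction_timepoint_accuracy = induction_timepoint_accuracy,
    n_false_induction_events = n_false,
    isotype = iso,
    details = list(epitopes = ep_tab, keys = key_tab, induction = ind_tab)),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("recovery_metrics (", x$isotype, " layer)\n", sep = "")
  cat("  confirmed-call precision: ", fmt(x$call_precision),
      "  recall: ", fmt(x$call_recall), "\n", sep = "")
  cat("  epitope-window recall:    ", fmt(x$window_recall),
      "  mean Jaccard: ", fmt(x$mean_window_jaccard), "\n", sep = "")
  cat("  key-residue accuracy:     ", fmt(x$key_residue_accuracy), "\n",
      sep = "")
  cat("  induction recall:         ", fmt(x$induction_recall),
      "  timepoint accuracy: ", fmt(x$induction_timepoint_accuracy),
      "  false events: ", x$n_false_induction_events, "\n", sep = "")
  invisible(x)
}
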