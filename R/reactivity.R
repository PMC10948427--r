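## Reactivity: intensity ingestion, robust per-sample z-scores, and
## reactive-peptide calling with the multi-sample / multi-peptide
## confirmation criteria that distinguish specific binding from single-spot
## technical artifacts.

ISOTYPES <- c("IgG", "IgG4", "IgE")

.sample_id <- function(subject_id, timepoint, isotype)
  paste(subject_id, timepoint, isotype, sep = "|")

#' Construct a reactivity matrix from a long intensity table
#'
#' @param tab `data.frame` with columns `subject_id` (or `subject`),
#'   `timepoint` (integer 1-4), `isotype` (IgG / IgG4 / IgE), `peptide`
#'   (unique peptide sequence) and `intensity` (positive fluorescence
#'   units).
#' @param index a [build_peptide_index()] result used to resolve peptides;
#'   rows whose peptide is not in the index are quarantined with a warning
#'   and excluded from the matrix.
#' @param floor intensities at or below 0 are raised to this value before
#'   the log2 transform (default 1 fluorescence unit); negative intensities
#'   are an error.
#' @return Object of class `reactivity_matrix`: list with `raw` and `log2`
#'   matrices (samples x peptides, `NA` marks combinations absent from the
#'   table), `samples` (`data.table` of `sample_id`, `subject_id`,
#'   `timepoint`, `isotype`), `peptides` (character) and `quarantine`
#'   (`data.table` of excluded rows).
#' @export
reactivity_matrix <- function(tab, index, floor = 1) {
  stopifnot(inherits(index, "peptide_index"))
  tab <- as.data.table(tab)
  if ("subject" %in% names(tab) && !"subject_id" %in% names(tab))
    setnames(tab, "subject", "subject_id")
  need <- c("subject_id", "timepoint", "isotype", "peptide", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("intensity table missing columns: ", paste(miss, collapse = ", "))
  tab <- tab[, ..need]
  tab[, subject_id := as.character(subject_id)]
  tab[, timepoint := as.integer(timepoint)]
  if (any(is.na(tab$timepoint)) || any(!tab$timepoint %in% 1:4))
    stop("timepoint must be an integer in 1..4")
  if (any(!tab$isotype %in% ISOTYPES))
    stop("isotype must be one of: ", paste(ISOTYPES, collapse = ", "))
  if (any(!is.finite(tab$intensity)))
    stop("non-finite intensity values")
  if (any(tab$intensity < 0))
    stop("negative intensity values in ", sum(tab$intensity < 0), " rows")

  known <- tab$peptide %in% index$unique_sequences
  quarantine <- tab[!known]
  if (nrow(quarantine) > 0L) {
    warning(nrow(quarantine), " rows with peptides absent from the index ",
            "were quarantined (", uniqueN(quarantine$peptide),
            " distinct peptides)")
    tab <- tab[known]
  }
  if (nrow(tab) == 0L) stop("no rows left after quarantine")

  tab[, sample_id := .sample_id(subject_id, timepoint, isotype)]
  dups <- tab[, .N, by = .(sample_id, peptide)][N > 1L]
  if (nrow(dups) > 0L)
    stop("duplicate (sample, peptide) rows, e.g.: ",
         paste(utils::head(paste(dups$sample_id, dups$peptide), 5L),
               collapse = "; "))

  samples <- unique(tab[, .(sample_id, subject_id, timepoint, isotype)])
  setorder(samples, subject_id, isotype, timepoint)
  peptides <- index$unique_sequences[index$unique_sequences %in% tab$peptide]

  raw <- matrix(NA_real_, nrow(samples), length(peptides),
                dimnames = list(samples$sample_id, peptides))
  raw[cbind(match(tab$sample_id, samples$sample_id),
            match(tab$peptide, peptides))] <- tab$intensity
  lg <- log2(pmax(raw, floor))

  structure(list(raw = raw, log2 = lg, samples = samples,
                 peptides = peptides, floor = floor,
                 quarantine = quarantine),
            class = "reactivity_matrix")
}

#' Read a per-sample peptide intensity TSV
#'
#' Thin wrapper: reads the tab-separated intensity contract
#' (`subject_id`, `timepoint`, `isotype`, `peptide`, `intensity`) and builds
#' a [reactivity_matrix()].
#'
#' @param tsv_path path to the intensity table.
#' @inheritParams reactivity_matrix
#' @return A `reactivity_matrix`.
#' @export
read_intensity_table <- function(tsv_path, index, floor = 1) {
  tab <- fread(tsv_path, sep = "\t")
  reactivity_matrix(tab, index, floor = floor)
}

#' @export
print.reactivity_matrix <- function(x, ...) {
  cat(sprintf(
    "reactivity_matrix: %d samples x %d peptides (%d subjects, isotypes: %s)\n",
    nrow(x$raw), ncol(x$raw), uniqueN(x$samples$subject_id),
    paste(sort(unique(x$samples$isotype)), collapse = ", ")))
  invisible(x)
}

#' Robust per-sample z-scores
#'
#' Scales each sample's log2 intensities by its own median and median
#' absolute deviation: `z = (log2 I - median) / (1.4826 * MAD)`. Centring
#' and scaling within each sample makes calls invariant to scanner gain and
#' overall sample brightness.
#'
#' @param rmat a [reactivity_matrix()].
#' @param min_peptides minimum observed peptides per sample (default 8).
#' @return Numeric matrix of z-scores, same shape and dimnames as the log2
#'   layer.
#' @export
robust_z <- function(rmat, min_peptides = 8L) {
  stopifnot(inherits(rmat, "reactivity_matrix"))
  lg <- rmat$log2
  z <- lg
  for (i in seq_len(nrow(lg))) {
    x <- lg[i, ]
    obs <- x[!is.na(x)]
    if (length(obs) < min_peptides)
      stop("sample '", rownames(lg)[i], "' has only ", length(obs),
           " peptides (need >= ", min_peptides, ")")
    med <- median(obs)
    scale <- 1.4826 * median(abs(obs - med))
    if (scale == 0)
      stop("sample '", rownames(lg)[i], "' has zero MAD; consider a ",
           "pseudo-count or floor adjustment before calling")
    z[i, ] <- (x - med) / scale
  }
  z
}

#' Call reactive peptides with confirmation criteria
#'
#' A peptide is *reactive* in a sample when its robust z-score reaches
#' `z_cut`. A reactive call is *confirmed* — i.e. regarded as specific
#' antibody binding rather than a local artifact on the array surface —
#' when at least one of three independent lines of support holds:
#'
#' * `consecutive_sample`: the same peptide is reactive at two or more
#'   timepoints of the same subject and isotype (strictly adjacent
#'   timepoints if `require_adjacent`);
#' * `overlapping_peptide`: another reactive peptide of the same sample
#'   tiles the same allergen at a start within `k - overlap_min` residues,
#'   i.e. the two tiles share at least `overlap_min` residues;
#' * `homologous_peptide`: a different reactive peptide of the same sample
#'   starts at the same master-alignment column on another allergen.
#'
#' Reactive but unconfirmed calls are flagged `artifact_candidate`; the
#' classic example is a singular high signal in one peptide of one sample
#' with no overlapping or homologous support.
#'
#' @param rmat a [reactivity_matrix()].
#' @param index the [build_peptide_index()] the matrix was built against;
#'   its occurrences provide tile positions and aligned starts.
#' @param z optional precomputed z-score matrix from [robust_z()].
#' @param z_cut reactivity threshold on the robust z-score (default 3).
#' @param overlap_min minimum shared residues for overlapping-peptide
#'   support (default 8, half a 16-mer tile).
#' @param require_adjacent if `TRUE`, consecutive-sample support requires
#'   two timepoints differing by exactly 1; default `FALSE` (any two
#'   timepoints of the subject).
#' @return `data.table` of class `reactivity_calls` with one row per
#'   observed (sample, peptide) cell: `sample_id`, `subject_id`,
#'   `timepoint`, `isotype`, `peptide`, `z`, `reactive`, `confirmed`,
#'   `support` (comma-joined tags, `""` if none) and `artifact_candidate`.
#' @export
call_reactive <- function(rmat, index, z = NULL, z_cut = 3,
                          overlap_min = 8L, require_adjacent = FALSE) {
  stopifnot(inherits(rmat, "reactivity_matrix"),
            inherits(index, "peptide_index"))
  if (is.null(z)) z <- robust_z(rmat)
  k <- index$k

  calls <- data.table(
    sample_id = rep(rownames(z), ncol(z)),
    peptide = rep(colnames(z), each = nrow(z)),
    z = as.vector(z))
  calls <- calls[!is.na(z)]
  calls <- rmat$samples[calls, on = "sample_id"]
  calls[, reactive := z >= z_cut]

  rx <- calls[reactive == TRUE]
  tag_consecutive <- tag_overlap <- tag_homolog <- rx[0L]

  if (nrow(rx) > 0L) {
    ## (a) same peptide reactive at >= 2 timepoints of one subject+isotype
    grp <- rx[, .(tps = list(sort(unique(timepoint)))),
              by = .(subject_id, isotype, peptide)]
    ok <- vapply(grp$tps, function(tp) {
      if (length(tp) < 2L) return(FALSE)
      if (require_adjacent) any(diff(tp) == 1L) else TRUE
    }, logical(1))
    tag_consecutive <- rx[grp[ok], on = .(subject_id, isotype, peptide),
                          nomatch = NULL]

    ## occurrences of reactive peptides, per sample
    occ <- index$occurrences[rx, on = .(sequence = peptide),
                             allow.cartesian = TRUE]
    setnames(occ, "sequence", "peptide")

    ## (b) overlapping tiles (>= overlap_min shared residues) on the same
    ## allergen within one sample, from distinct peptides
    max_gap <- k - as.integer(overlap_min)
    ov <- occ[, {
      s <- start_local; p <- peptide
      supported <- vapply(seq_along(s), function(i)
        any(abs(s - s[i]) <= max_gap & p != p[i]), logical(1))
      .(peptide = unique(p[supported]))
    }, by = .(sample_id, allergen_id)]
    tag_overlap <- unique(ov[, .(sample_id, peptide)])

    ## (c) homologous tiles: same aligned start, different allergen, within
    ## one sample (distinct peptide sequences)
    ho <- occ[!is.na(start_aligned),
              .(n_pep = uniqueN(peptide), n_all = uniqueN(allergen_id)),
              by = .(sample_id, start_aligned, peptide)]
    ## recompute per (sample, start): a peptide is supported if another
    ## peptide shares the aligned start
    hs <- occ[!is.na(start_aligned)]
    hs <- hs[, .(n_pep = uniqueN(peptide)), by = .(sample_id, start_aligned)]
    hs <- hs[n_pep >= 2L]
    tag_homolog <- unique(
      occ[hs, on = .(sample_id, start_aligned)][, .(sample_id, peptide)])
  }

  calls[, support := ""]
  .add_tag <- function(keys, tag) {
    if (nrow(keys) == 0L) return()
    keys <- unique(keys[, .(sample_id, peptide)])
    calls[keys, on = .(sample_id, peptide),
          support := ifelse(support == "", tag, paste(support, tag, sep = ","))]
  }
  ## consecutive support tags every reactive call of the supported
  ## (subject, isotype, peptide) triple, one row per involved sample
  if (nrow(tag_consecutive) > 0L)
    .add_tag(tag_consecutive[, .(sample_id, peptide)], "consecutive_sample")
  .add_tag(tag_overlap, "overlapping_peptide")
  .add_tag(tag_homolog, "homologous_peptide")

  calls[, confirmed := reactive & support != ""]
  calls[reactive == FALSE, support := ""]
  calls[, artifact_candidate := reactive & !confirmed]
  setcolorder(calls, c("sample_id", "subject_id", "timepoint", "isotype",
                       "peptide", "z", "reactive", "confirmed", "support",
                       "artifact_candidate"))
  setattr(calls, "class", c("reactivity_calls", class(calls)))
  setattr(calls, "z_cut", z_cut)
  setattr(calls, "k", k)
  calls[]
}

#' Project peptide signals onto allergen residues
#'
#' Converts per-tile signals into a per-residue profile for one allergen:
#' each residue receives an aggregate (default the maximum) of the signals
#' of all tiles covering it; residues covered by no tile are `NA`.
#'
#' @param values named numeric vector of per-peptide signals (names are
#'   peptide sequences), e.g. one row of a z or log2 matrix.
#' @param index a [build_peptide_index()] result.
#' @param allergen_id allergen to project onto.
#' @param aggregate `"max"` or `"mean"` (default `"max"`).
#' @return Numeric vector over the allergen's residues.
#' @export
project_positions <- function(values, index, allergen_id,
                              aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(index, "peptide_index"))
  sel <- index$occurrences[["allergen_id"]] == allergen_id
  occ <- index$occurrences[which(sel), ]
  if (nrow(occ) == 0L) stop("no tiles for allergen: ", allergen_id)
  k <- index$k
  len <- max(occ$start_local) + k - 1L
  vals <- values[occ$sequence]
  prof <- rep(NA_real_, len)
  agg <- if (aggregate == "max") max else mean
  for (pos in seq_len(len)) {
    covering <- vals[occ$start_local <= pos & occ$start_local + k - 1L >= pos]
    covering <- covering[!is.na(covering)]
    if (length(covering) > 0L) prof[pos] <- agg(covering)
  }
  prof
}
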