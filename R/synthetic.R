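## Synthetic serology generator: an allergen family with planted
## polymorphic key columns, per-subject epitope repertoires with occasional
## induction events, key-residue-dependent cross-reactivity, multiplicative
## log-normal array noise, and recovery metrics against the planted truth.
##
## Defaults mirror the motivating study design: 19 complete ~109-residue
## homologs, 15 subjects, up to 4 longitudinal samples, 16-mer offset-1
## tiling.

#' Generate a synthetic homologous allergen panel
#'
#' Mutates a random base sequence independently per allergen at a fixed
#' per-site substitution rate, producing a gap-free family whose trivial
#' master alignment makes local and aligned coordinates coincide. A small
#' number of *key columns* is planted: positions at which the family splits
#' into two residue classes of at least `min_class` members each (the kind
#' of surface polymorphism that drives isoform-dependent epitope
#' recognition). Key columns are spaced at least 16 apart so that any
#' 16-mer tile window contains at most one.
#'
#' @param n_allergens number of isoforms (default 19).
#' @param length sequence length in residues (default 109).
#' @param substitution_rate per-site substitution probability per allergen,
#'   in `[0, 0.3]` (default 0.05).
#' @param n_key_columns planted polymorphic columns (default 6; capped by
#'   the spacing constraint and skipped when `n_allergens < 2 * min_class`).
#' @param min_class minimum allergens per residue class at a key column
#'   (default 3).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return Object of class `synthetic_panel`: list with `panel`
#'   (an [allergen_panel]), `alignment` (gap-free [master_alignment]) and
#'   `truth` (list: `base_sequence`, `key_columns` `data.table` of
#'   `column`, `base_residue`, `alt_residue`, `alt_carriers` list-column,
#'   `mutations` `data.table`, `params`).
#' @export
generate_panel <- function(n_allergens = 19L, length = 109L,
                           substitution_rate = 0.05, n_key_columns = 6L,
                           min_class = 3L, seed = 1L) {
  stopifnot(n_allergens >= 2L, length >= 32L)
  if (substitution_rate < 0 || substitution_rate > 0.3)
    stop("substitution_rate must be in [0, 0.3]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  base <- sample(AA_ALPHABET, length, replace = TRUE)

  ## key columns: interior (coverable by full tile runs), spacing >= 16
  avail <- seq.int(16L, length - 7L, by = 16L)
  if (n_allergens < 2L * min_class) n_key_columns <- 0L
  n_key <- min(as.integer(n_key_columns), base::length(avail))
  key_cols <- if (n_key > 0L) avail[seq_len(n_key)] else integer(0)

  key_tab <- rbindlist(lapply(key_cols, function(cc) {
    alt <- sample(setdiff(AA_ALPHABET, base[cc]), 1L)
    repeat {
      carriers <- which(runif(n_allergens) < 0.5)
      if (base::length(carriers) >= min_class &&
          n_allergens - base::length(carriers) >= min_class) break
    }
    data.table(column = cc, base_residue = base[cc], alt_residue = alt,
               alt_carriers = list(carriers))
  }))
  if (is.null(key_tab) || nrow(key_tab) == 0L)
    key_tab <- data.table(column = integer(), base_residue = character(),
                          alt_residue = character(), alt_carriers = list())

  seqs <- character(n_allergens)
  muts <- list()
  for (i in seq_len(n_allergens)) {
    s <- base
    ## random substitutions away from the planted key columns
    hit <- which(runif(length) < substitution_rate)
    hit <- setdiff(hit, key_cols)
    for (p in hit) {
      new <- sample(setdiff(AA_ALPHABET, s[p]), 1L)
      muts[[base::length(muts) + 1L]] <-
        data.table(allergen = i, pos = p, from = s[p], to = new)
      s[p] <- new
    }
    ## planted key-column polymorphism
    for (r in seq_len(nrow(key_tab)))
      if (i %in% key_tab$alt_carriers[[r]])
        s[key_tab$column[r]] <- key_tab$alt_residue[r]
    seqs[i] <- paste(s, collapse = "")
  }
  mutations <- if (base::length(muts) > 0L) rbindlist(muts) else
    data.table(allergen = integer(), pos = integer(),
               from = character(), to = character())

  ids <- sprintf("Syn p 1.%02d01", seq_len(n_allergens))
  panel <- allergen_panel(
    allergen_id = ids, sequence = seqs,
    species = sprintf("Synthetic fish %d", seq_len(n_allergens)),
    complete = TRUE, includes_initial_met = TRUE)
  alignment <- master_alignment(setNames(seqs, ids))
  key_tab[, alt_carriers := lapply(alt_carriers, function(x) ids[x])]

  structure(list(
    panel = panel, alignment = alignment,
    truth = list(base_sequence = paste(base, collapse = ""),
                 key_columns = key_tab, mutations = mutations,
                 params = list(n_allergens = n_allergens, length = length,
                               substitution_rate = substitution_rate,
                               seed = seed))),
    class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "synthetic_panel: %d allergens x %d residues, %d key columns, seed %s\n",
    nrow(x$panel), nchar(x$panel$sequence[1]),
    nrow(x$truth$key_columns), format(x$truth$params$seed)))
  invisible(x)
}

#' Simulate per-subject epitope repertoires
#'
#' Draws, for each subject, a set of epitope windows (without replacement,
#' separated by at least `min_separation` columns so reactive tile runs
#' stay distinct). A configurable fraction of epitopes is key-residue
#' dependent: only allergens carrying the base residue at the window's key
#' column react. A fraction is induced, i.e. absent at baseline and
#' switched on at a random timepoint of 2 or later; all other epitopes are
#' part of the stable baseline repertoire. Per-isotype affinities are in
#' log2 intensity units: IgG carries the full affinity, IgG4 a reduced
#' affinity for a subset of epitopes (most reactivity is IgG with only a
#' small IgG4 component).
#'
#' @param sim a [generate_panel()] result.
#' @param n_subjects number of subjects (default 15).
#' @param epitopes_per_subject epitopes per subject (default 3).
#' @param induction_fraction probability an epitope is induced rather than
#'   baseline (default 0.2).
#' @param key_fraction probability an epitope is key-residue dependent
#'   (default 1/3; requires planted key columns).
#' @param timepoints number of longitudinal samples, 2-4 (default 4).
#' @param affinity IgG epitope affinity in log2 units (default 3).
#' @param igg4_fraction probability an epitope also carries IgG4 activity
#'   (default 0.25).
#' @param igg4_factor IgG4 affinity as a fraction of the IgG affinity
#'   (default 0.5).
#' @param window_width epitope width in residues (default 9, a typical
#'   minimal-epitope length).
#' @param tile_k tile length the array uses (default 16).
#' @param min_separation minimum distance between window starts of one
#'   subject (default 17 columns, i.e. more than one tile length).
#' @param seed integer seed.
#' @return `data.table` of class `subject_truth`, one row per planted
#'   epitope: `subject_id`, `epitope_id`, `window_start`, `window_end`
#'   (aligned = local columns, gap-free panel), `is_key`, `key_column`,
#'   `required_residue` (`NA` for non-key epitopes), `induction_tp` (`NA`
#'   for baseline), `affinity_IgG`, `affinity_IgG4`.
#' @export
simulate_subjects <- function(sim, n_subjects = 15L,
                              epitopes_per_subject = 3L,
                              induction_fraction = 0.2,
                              key_fraction = 1 / 3,
                              timepoints = 4L, affinity = 3,
                              igg4_fraction = 0.25, igg4_factor = 0.5,
                              window_width = 9L, tile_k = 16L,
                              min_separation = 17L, seed = 1L) {
  stopifnot(inherits(sim, "synthetic_panel"),
            n_subjects >= 1L, epitopes_per_subject >= 1L,
            timepoints >= 2L, timepoints <= 4L, affinity > 0,
            window_width >= 1L, window_width <= tile_k)
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- nchar(sim$panel$sequence[1])
  w <- as.integer(window_width); k <- as.integer(tile_k)

  ## windows fully covered by a complete run of k-mers: [a, a + w - 1] with
  ## covering tile starts a - (k - w) .. a all inside 1..L-k+1
  cand <- seq.int(k - w + 1L, L - k + 1L)
  if (length(cand) < 1L) stop("sequences too short for the window design")
  key_tab <- sim$truth$key_columns
  key_of_start <- lapply(cand, function(a)
    key_tab$column[key_tab$column >= a & key_tab$column <= a + w - 1L])
  has_key <- lengths(key_of_start) > 0L

  draw_once <- function() {
    n_key_target <- if (any(has_key) && key_fraction > 0)
      rbinom(1L, epitopes_per_subject, key_fraction) else 0L
    chosen <- integer(0)
    pick <- function(pool) {
      pool <- sample(pool)
      for (a in pool)
        if (all(abs(a - chosen) >= min_separation)) return(a)
      NA_integer_
    }
    kinds <- logical(0)
    for (e in seq_len(epitopes_per_subject)) {
      want_key <- sum(kinds) < n_key_target
      a <- if (want_key) pick(cand[has_key]) else pick(cand[!has_key])
      if (is.na(a)) a <- pick(cand)  # fall back to any admissible start
      if (is.na(a)) return(NULL)
      chosen <- c(chosen, a)
      kinds <- c(kinds, has_key[match(a, cand)])
    }
    list(starts = chosen, is_key = kinds)
  }
  draw_repertoire <- function() {
    ## greedy placement can dead-end on short sequences; retry afresh
    for (try in 1:50) {
      rep_s <- draw_once()
      if (!is.null(rep_s)) return(rep_s)
    }
    stop("cannot place ", epitopes_per_subject,
         " separated epitope windows; reduce epitopes_per_subject ",
         "or min_separation")
  }

  rows <- list()
  for (s in seq_len(n_subjects)) {
    rep_s <- draw_repertoire()
    for (e in seq_along(rep_s$starts)) {
      a <- rep_s$starts[e]
      is_key <- rep_s$is_key[e]
      kc <- if (is_key) key_of_start[[match(a, cand)]][1] else NA_integer_
      rows[[length(rows) + 1L]] <- data.table(
        subject_id = sprintf("S%02d", s),
        epitope_id = sprintf("S%02d_e%d", s, e),
        window_start = a, window_end = a + w - 1L,
        is_key = is_key, key_column = kc,
        required_residue = if (is_key)
          key_tab$base_residue[key_tab$column == kc] else NA_character_,
        induction_tp = if (runif(1) < induction_fraction)
          sample(2:timepoints, 1L) else NA_integer_,
        affinity_IgG = affinity,
        affinity_IgG4 = if (runif(1) < igg4_fraction)
          affinity * igg4_factor else 0)
    }
  }
  truth <- rbindlist(rows)
  setattr(truth, "class", c("subject_truth", class(truth)))
  setattr(truth, "params", list(
    n_subjects = n_subjects, epitopes_per_subject = epitopes_per_subject,
    induction_fraction = induction_fraction, key_fraction = key_fraction,
    timepoints = timepoints, affinity = affinity,
    window_width = w, tile_k = k, seed = seed))
  truth[]
}

#' Deterministic planted log2 effects per peptide and sample
#'
#' Expands the planted repertoires into the noiseless signal component: a
#' unique peptide carries an epitope's affinity in a sample when the
#' epitope is active at the sample's timepoint and at least one of the
#' peptide's tile occurrences fully covers the epitope window on an
#' allergen that satisfies the key-residue requirement.
#'
#' @param sim a [generate_panel()] result.
#' @param truth a [simulate_subjects()] result.
#' @param index the panel's [build_peptide_index()].
#' @param timepoints timepoints to expand (default from the truth).
#' @return `data.table` with columns `subject_id`, `timepoint`, `isotype`,
#'   `peptide`, `effect` (log2 units), rows only where `effect > 0`.
#' @export
truth_effects <- function(sim, truth, index,
                          timepoints = attr(truth, "params")$timepoints) {
  stopifnot(inherits(sim, "synthetic_panel"),
            inherits(index, "peptide_index"))
  k <- index$k
  occ <- index$occurrences
  res_at <- function(allergens, column)
    substring(sim$panel$sequence[match(allergens, sim$panel$allergen_id)],
              column, column)
  out <- list()
  for (i in seq_len(nrow(truth))) {
    ep <- truth[i]
    hits <- occ[occ$start_local <= ep$window_start &
                  occ$start_local + k - 1L >= ep$window_end, ]
    if (ep$is_key)
      hits <- hits[res_at(hits$allergen_id, ep$key_column) ==
                     ep$required_residue, ]
    if (nrow(hits) == 0L) next
    peps <- unique(hits$sequence)
    active_tps <- if (is.na(ep$induction_tp)) seq_len(timepoints) else
      seq.int(ep$induction_tp, timepoints)
    for (iso in c("IgG", "IgG4")) {
      aff <- if (iso == "IgG") ep$affinity_IgG else ep$affinity_IgG4
      if (aff <= 0) next
      out[[length(out) + 1L]] <- CJ(
        timepoint = active_tps, peptide = peps)[
          , `:=`(subject_id = ep$subject_id, isotype = iso, effect = aff)]
    }
  }
  if (length(out) == 0L)
    return(data.table(subject_id = character(), timepoint = integer(),
                      isotype = character(), peptide = character(),
                      effect = numeric()))
  eff <- rbindlist(out, use.names = TRUE)
  eff <- eff[, .(effect = sum(effect)),
             by = .(subject_id, timepoint, isotype, peptide)]
  eff[]
}

#' Simulate longitudinal array intensities
#'
#' Realises the intensity table of the full cohort under a log-additive
#' signal model with multiplicative log-normal noise: for every sample
#' (subject x timepoint x isotype) and unique peptide,
#' `log2 I = baseline + planted effect + Normal(0, noise_sd)` and
#' `I = 2^log2`. Output follows the intensity TSV contract and is
#' byte-reproducible under a fixed seed.
#'
#' @param sim a [generate_panel()] result.
#' @param truth a [simulate_subjects()] result.
#' @param timepoints number of timepoints to realise (default from the
#'   truth).
#' @param noise_sd log2 noise standard deviation, > 0 (default 0.5).
#' @param baseline_log2 baseline log2 intensity (default 10, i.e. ~1000
#'   fluorescence units).
#' @param isotypes isotype layers to realise (default IgG and IgG4).
#' @param seed integer seed.
#' @return Object of class `synthetic_cohort`: list with `intensities`
#'   (long `data.table`: `subject_id`, `timepoint`, `isotype`, `peptide`,
#'   `intensity`), `effects` (from [truth_effects()]), `tiles`, `index`,
#'   `panel`, `alignment`, `truth` (the subject truth) and `params`.
#' @export
simulate_intensities <- function(sim, truth,
                                 timepoints = attr(truth, "params")$timepoints,
                                 noise_sd = 0.5, baseline_log2 = 10,
                                 isotypes = c("IgG", "IgG4"), seed = 1L) {
  stopifnot(inherits(sim, "synthetic_panel"), noise_sd > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tiles <- tile_panel(sim$panel, sim$alignment,
                      k = attr(truth, "params")$tile_k)
  index <- build_peptide_index(tiles)
  eff <- truth_effects(sim, truth, index, timepoints = timepoints)

  grid <- CJ(subject_id = unique(truth$subject_id),
             timepoint = seq_len(timepoints),
             isotype = isotypes,
             peptide = index$unique_sequences)
  grid <- eff[grid, on = .(subject_id, timepoint, isotype, peptide)]
  grid[is.na(effect), effect := 0]
  grid[, log2_intensity := baseline_log2 + effect +
         rnorm(.N, mean = 0, sd = noise_sd)]
  grid[, intensity := 2^log2_intensity]
  intensities <- grid[, .(subject_id, timepoint, isotype, peptide, intensity)]

  structure(list(
    intensities = intensities, effects = eff,
    tiles = tiles, index = index,
    panel = sim$panel, alignment = sim$alignment,
    sim = sim, truth = truth,
    params = list(timepoints = timepoints, noise_sd = noise_sd,
                  baseline_log2 = baseline_log2, isotypes = isotypes,
                  seed = seed)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d subjects x %d timepoints x %d isotypes, %d peptides, noise_sd %.2f\n",
    uniqueN(x$truth$subject_id), x$params$timepoints,
    length(x$params$isotypes), x$index$n_unique, x$params$noise_sd))
  invisible(x)
}

#' One-call cohort simulation
#'
#' Convenience wrapper chaining [generate_panel()], [simulate_subjects()]
#' and [simulate_intensities()] with a single master seed (sub-seeds are
#' derived deterministically from it).
#'
#' @param seed master integer seed.
#' @param ... arguments forwarded to the three stages by name; recognised
#'   names are those of the stage functions.
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(seed = 1L, ...) {
  args <- list(...)
  take <- function(fn, extra = list()) {
    keep <- intersect(names(args), names(formals(fn)))
    c(args[keep], extra)
  }
  seed <- as.integer(seed)
  sim <- do.call(generate_panel, take(generate_panel,
                                      list(seed = seed)))
  truth <- do.call(simulate_subjects,
                   c(list(sim = sim), take(simulate_subjects,
                                           list(seed = seed + 1L))))
  do.call(simulate_intensities,
          c(list(sim = sim, truth = truth),
            take(simulate_intensities, list(seed = seed + 2L))))
}

#' Serialise / restore planted truth as JSON
#'
#' @param truth a [simulate_subjects()] result.
#' @param path JSON output path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns
#'   the restored `subject_truth` table (parameters included).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "subject_truth"))
  jsonlite::write_json(
    list(params = attr(truth, "params"),
         epitopes = as.data.frame(truth)),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.table(obj$epitopes)
  truth[, window_start := as.integer(window_start)]
  truth[, window_end := as.integer(window_end)]
  truth[, key_column := as.integer(key_column)]
  truth[, induction_tp := as.integer(induction_tp)]
  if (!"required_residue" %in% names(truth))
    truth[, required_residue := NA_character_]
  truth[, required_residue := as.character(required_residue)]
  setattr(truth, "class", c("subject_truth", class(truth)))
  setattr(truth, "params", obj$params)
  truth[]
}

#' Write an intensity table in the TSV contract
#'
#' @param x a `synthetic_cohort` or a long intensity `data.frame`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_intensity_table <- function(x, path) {
  if (inherits(x, "synthetic_cohort")) x <- x$intensities
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}
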