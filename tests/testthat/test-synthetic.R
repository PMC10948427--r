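test_that("panel generation: rate bounds, rate-0 family, key-column structure", {
  expect_error(generate_panel(substitution_rate = 0.5), "substitution_rate")

  sim0 <- generate_panel(n_allergens = 5, length = 60, substitution_rate = 0,
                         n_key_columns = 0, seed = 2)
  expect_true(all(sim0$panel$sequence == sim0$panel$sequence[1]))
  idx0 <- build_peptide_index(tile_panel(sim0$panel, sim0$alignment))
  expect_equal(idx0$n_unique, 60 - 15)

  sim <- generate_panel(seed = 3)
  expect_equal(nrow(sim$panel), 19L)
  expect_true(all(nchar(sim$panel$sequence) == 109L))
  kc <- sim$truth$key_columns
  expect_gt(nrow(kc), 0L)
  ## key columns are spaced > 15 apart: at most one per tile window
  expect_true(all(diff(kc$column) > 15))
  ## both residue classes hold at least 3 allergens
  n_alt <- lengths(kc$alt_carriers)
  expect_true(all(n_alt >= 3 & 19 - n_alt >= 3))
  ## planted polymorphism is realised in the sequences
  for (i in seq_len(nrow(kc))) {
    res <- substring(sim$panel$sequence, kc$column[i], kc$column[i])
    carriers <- sim$panel$allergen_id[res == kc$alt_residue[i]]
    expect_setequal(carriers, kc$alt_carriers[[i]])
  }
})

test_that("generation is byte-deterministic under a fixed seed", {
  sim_a <- generate_panel(seed = 42)
  sim_b <- generate_panel(seed = 42)
  expect_identical(sim_a$panel$sequence, sim_b$panel$sequence)
  fa_a <- withr::local_tempfile(fileext = ".fasta")
  fa_b <- withr::local_tempfile(fileext = ".fasta")
  meta <- withr::local_tempfile(fileext = ".tsv")
  write_panel(sim_a$panel, fa_a, meta)
  write_panel(sim_b$panel, fa_b, meta)
  expect_identical(readLines(fa_a), readLines(fa_b))

  co_a <- simulate_cohort(seed = 42, n_subjects = 3)
  co_b <- simulate_cohort(seed = 42, n_subjects = 3)
  tsv_a <- withr::local_tempfile(fileext = ".tsv")
  tsv_b <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(co_a, tsv_a)
  write_intensity_table(co_b, tsv_b)
  expect_identical(readLines(tsv_a), readLines(tsv_b))
  ## and a different seed changes the realisation
  co_c <- simulate_cohort(seed = 43, n_subjects = 3)
  expect_false(identical(co_a$intensities$intensity,
                         co_c$intensities$intensity))
})

test_that("column diversity flags only mutated or key columns (truth bookkeeping)", {
  sim <- generate_panel(n_allergens = 12, length = 80,
                        substitution_rate = 0.05, seed = 8)
  prof <- column_diversity_profile(sim$alignment)
  changed <- sort(unique(c(sim$truth$mutations$pos, sim$truth$key_columns$column)))
  ## every column flagged diverse must have been touched by the generator
  expect_true(all(prof$column[prof$diverse] %in% changed))
  ## untouched columns have consensus frequency 1
  untouched <- setdiff(prof$column, changed)
  expect_true(all(prof$consensus_frequency[untouched] == 1))
})

test_that("subject truth: induction flags, interindividual variation, JSON round trip", {
  sim <- generate_panel(seed = 4)
  tr0 <- simulate_subjects(sim, n_subjects = 4, induction_fraction = 0,
                           seed = 5)
  expect_true(all(is.na(tr0$induction_tp)))

  tr <- simulate_subjects(sim, n_subjects = 8, induction_fraction = 0.5,
                          seed = 6)
  expect_true(any(!is.na(tr$induction_tp)))
  expect_true(all(tr$induction_tp[!is.na(tr$induction_tp)] >= 2))
  ## epitope windows of one subject never collide
  sep_ok <- tr[, .(ok = all(diff(sort(window_start)) >= 17)), by = subject_id]
  expect_true(all(sep_ok$ok))
  ## repertoires differ between subjects
  reps <- split(tr$window_start, tr$subject_id)
  expect_gt(length(unique(vapply(reps, paste, character(1), collapse = ","))), 1L)

  ## lossless JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, path)
  tr2 <- read_truth(path)
  expect_equal(as.data.frame(tr), as.data.frame(tr2))
  expect_equal(attr(tr2, "params")$n_subjects, 8)
})

test_that("planted effects elevate exactly the covering tiles", {
  sim <- generate_panel(n_allergens = 6, length = 80, substitution_rate = 0,
                        n_key_columns = 0, seed = 9)
  truth <- simulate_subjects(sim, n_subjects = 1, epitopes_per_subject = 1,
                             induction_fraction = 0, key_fraction = 0,
                             window_width = 9, seed = 10)
  idx <- build_peptide_index(tile_panel(sim$panel, sim$alignment))
  eff <- truth_effects(sim, truth, idx)
  a <- truth$window_start
  ## identical family: tiles collapse, the 8 covering starts remain
  got_starts <- sort(unique(
    idx$occurrences$start_local[idx$occurrences$sequence %in% eff$peptide]))
  expect_equal(got_starts, (a - 7):a)
  expect_true(all(eff$effect == 3))
  ## key-residue epitopes only elevate carriers of the required residue
  simk <- generate_panel(n_allergens = 12, length = 109, seed = 11)
  truthk <- simulate_subjects(simk, n_subjects = 3, epitopes_per_subject = 2,
                              key_fraction = 1, induction_fraction = 0,
                              seed = 12)
  expect_true(all(truthk$is_key))
  idxk <- build_peptide_index(tile_panel(simk$panel, simk$alignment))
  effk <- truth_effects(simk, truthk, idxk)
  ep <- truthk[1]
  res <- substring(simk$panel$sequence, ep$key_column, ep$key_column)
  non_carrier <- simk$panel$allergen_id[res != ep$required_residue][1]
  ## no elevated peptide is exclusive to a non-carrier at the window
  occ_nc <- idxk$occurrences[idxk$occurrences$allergen_id == non_carrier &
                               idxk$occurrences$start_local %in%
                                 (ep$window_start - 7):ep$window_start, ]
  sub_eff <- effk[effk$subject_id == ep$subject_id &
                    effk$isotype == "IgG", ]
  carrier_seqs <- substring(
    simk$panel$sequence[res == ep$required_residue],
    ep$window_start - 7, ep$window_start + 15)
  for (p in occ_nc$sequence) {
    if (p %in% sub_eff$peptide) {
      ## only legitimate if the same 16-mer also occurs on a carrier
      others <- idxk$occurrences[idxk$occurrences$sequence == p, ]
      carrier_hit <- any(substring(
        simk$panel$sequence[match(others$allergen_id,
                                  simk$panel$allergen_id)],
        ep$key_column, ep$key_column) == ep$required_residue)
      expect_true(carrier_hit)
    }
  }
})

test_that("recovery metrics: bounds, near-noiseless limit, noise monotonicity", {
  ## effectively noiseless: everything recovered
  co <- simulate_cohort(seed = 21, n_subjects = 4, noise_sd = 0.01)
  res <- run_recovery(co)
  m <- res$metrics
  for (v in c(m$call_precision, m$call_recall, m$window_recall,
              m$key_residue_accuracy, m$induction_recall)) {
    if (!is.na(v)) { expect_gte(v, 0); expect_lte(v, 1) }
  }
  expect_equal(m$call_precision, 1.0)
  expect_equal(m$call_recall, 1.0)
  expect_equal(m$window_recall, 1.0)
  expect_equal(m$n_false_induction_events, 0L)

  ## recovery does not improve when the noise grows (fixed seeds)
  co_hi <- simulate_cohort(seed = 21, n_subjects = 4, noise_sd = 2.0)
  res_hi <- run_recovery(co_hi)
  expect_lte(res_hi$metrics$call_recall, m$call_recall)
  expect_lte(res_hi$metrics$window_recall, m$window_recall)
})

test_that("a cohort without epitopes yields almost no confirmed calls", {
  sim <- generate_panel(n_allergens = 8, length = 80, seed = 31)
  idx <- build_peptide_index(tile_panel(sim$panel, sim$alignment))
  set.seed(33)
  tab <- data.table::CJ(subject_id = c("S1", "S2", "S3"), timepoint = 1:4,
                        isotype = "IgG", peptide = idx$unique_sequences)
  tab[, intensity := 2^(10 + rnorm(.N, 0, 0.5))]
  rmat <- reactivity_matrix(tab, idx)
  calls <- call_reactive(rmat, idx)
  ## pure-noise arrays: a robust 3-sigma cut confirms almost nothing
  expect_lt(sum(calls$confirmed) / nrow(calls), 0.001)
})
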