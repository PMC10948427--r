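## brute-force oracle: positions covered by every tile of the run
brute_minimal <- function(starts, k) {
  covered <- lapply(starts, function(s) s:(s + k - 1))
  Reduce(intersect, covered)
}

test_that("minimal epitope equals the covered-position intersection for all run lengths", {
  set.seed(33)
  seqlen <- 80
  s <- random_aa(seqlen)
  k <- 16
  for (n in 1:16) {
    starts <- 20:(20 + n - 1)
    me <- minimal_epitope(starts, s, k)
    want <- brute_minimal(starts, k)
    expect_equal(me$start, min(want))
    expect_equal(me$end, max(want))
    ## length formula k - (n - 1)
    expect_equal(nchar(me$sequence), k - (n - 1))
    expect_identical(me$sequence, substring(s, me$start, me$end))
  }
  ## single tile: the full 16-mer itself
  me1 <- minimal_epitope(40, s, 16)
  expect_identical(me1$sequence, substring(s, 40, 55))
  ## boundary: starts {s, s+15} leave a single shared residue
  me2 <- minimal_epitope(c(10, 25), random_aa(45), 16)
  expect_equal(nchar(me2$sequence), 1L)
  ## starts {s, s+7}: a 9-residue overlap string
  me3 <- minimal_epitope(c(10, 17), s, 16)
  expect_equal(nchar(me3$sequence), 9L)
  ## start sets wider than one tile share no residue and are refused
  expect_error(minimal_epitope(c(10, 26), s, 16), "split into runs")
})

test_that("the printed full-16-mer and unique-carrier peptides behave on the fixture", {
  paths <- panel_fixture_paths()
  panel <- read_panel(paths$fasta, paths$meta)
  thu <- panel$sequence[panel$allergen_id == "Thu a 1.0101"]
  me <- minimal_epitope(59, thu, 16)
  expect_identical(me$sequence, "FIEEDELKLFLQNFSA")
  ## "LAAKSPADI" is carried by exactly one isoform
  kidx <- unique_kmer_index(panel, k = 9)
  expect_identical(kmer_carriers(kidx, "LAAKSPADI"), "Gad m 1.0201")
  ## its near-twin in the tuna isoform is likewise present
  expect_true("Thu a 1.0101" %in% kmer_carriers(kidx, "LAAKTPEDI"))
})

test_that("k-mer index equals a brute-force substring scan", {
  set.seed(37)
  panel <- allergen_panel(
    allergen_id = sprintf("Scan %d.0101", 1:4),
    sequence = c(replicate(3, random_aa(40)), "AAAAAAAAAAAAAAAAAAAA"))
  k <- 6
  kidx <- unique_kmer_index(panel, k)
  all_kmers <- unique(kidx$map$kmer)
  for (km in sample(all_kmers, 25)) {
    brute <- panel$allergen_id[vapply(panel$sequence, grepl,
                                      logical(1), pattern = km,
                                      fixed = TRUE)]
    expect_setequal(kmer_carriers(kidx, km), brute)
  }
  ## a k-mer in every record has a full carrier set
  common <- allergen_panel(c("C 1.0101", "C 2.0101"),
                           c(paste0("MKLV", random_aa(20)),
                             paste0("MKLV", random_aa(20))))
  kc <- unique_kmer_index(common, 4)
  expect_equal(length(kmer_carriers(kc, "MKLV")), 2L)
  expect_error(kmer_carriers(kc, "MKLVA"), "length")
})

test_that("segment deconvolution splits runs and applies the length formula", {
  set.seed(3)
  panel <- allergen_panel("Seg 1.0101", random_aa(80))
  aln <- master_alignment(stats::setNames(panel$sequence, panel$allergen_id))
  index <- build_peptide_index(tile_panel(panel, aln))
  occ <- index$occurrences
  pep_at <- function(s) occ$sequence[occ$start_local == s][1]

  mk_calls <- function(starts) {
    vals <- background_log2(index$unique_sequences)
    vals[vapply(starts, pep_at, character(1))] <- 16
    rmat <- rmat_from_log2(list("A|1|IgG" = vals), index)
    call_reactive(rmat, index)
  }

  ## single reactive start, unconfirmed on its own: seeding from reactive
  ## calls gives one single-tile segment whose minimal epitope is the
  ## full 16-mer
  segs0 <- call_segments(mk_calls(40), index, panel, aln, use = "reactive")
  expect_equal(nrow(segs0), 1L)
  expect_equal(segs0$n_starts, 1L)
  expect_identical(segs0$minimal_epitope,
                   substring(panel$sequence[1], 40, 55))
  expect_equal(nchar(segs0$minimal_epitope), 16L)

  ## two adjacent confirmed tiles form one run
  segs1 <- call_segments(mk_calls(c(40, 41)), index, panel, aln)
  expect_equal(nrow(segs1), 1L)
  expect_equal(segs1$n_starts, 2L)

  ## contiguous run 40..50 (11 tiles): minimal length 16 - 10 = 6
  segs2 <- call_segments(mk_calls(40:50), index, panel, aln)
  expect_equal(nrow(segs2), 1L)
  expect_equal(segs2$first_start, 40L)
  expect_equal(segs2$last_start, 50L)
  expect_equal(nchar(segs2$minimal_epitope), 6L)
  expect_equal(segs2$minimal_start, 50L)
  expect_equal(segs2$minimal_end, 55L)
  expect_equal(segs2$span_start, 40L)
  expect_equal(segs2$span_end, 65L)

  ## two runs 40..47 and 60..62: minimal lengths 9 and 14
  segs3 <- call_segments(mk_calls(c(40:47, 60:62)), index, panel, aln)
  expect_equal(nrow(segs3), 2L)
  expect_equal(nchar(segs3$minimal_epitope), c(9L, 14L))
  ## segments partition the reactive start set
  expect_equal(sum(segs3$n_starts), length(c(40:47, 60:62)))

  ## gap tolerance 1 absorbs a single failed spot
  segs4 <- call_segments(mk_calls(c(40:43, 45:47)), index, panel, aln,
                         max_gap = 1)
  expect_equal(nrow(segs4), 1L)
  segs5 <- call_segments(mk_calls(c(40:43, 45:47)), index, panel, aln,
                         max_gap = 0)
  expect_equal(nrow(segs5), 2L)
})

test_that("homolog grouping collapses identical peptides and matches brute force", {
  ## identical family: one representative carrying all allergens
  sim0 <- generate_panel(n_allergens = 4, length = 60,
                         substitution_rate = 0, n_key_columns = 0, seed = 5)
  idx0 <- build_peptide_index(tile_panel(sim0$panel, sim0$alignment))
  g0 <- group_homologs(idx0, sim0$alignment, 20)
  expect_equal(nrow(g0$representatives), 1L)
  expect_equal(g0$representatives$n_members, 4L)

  ## one in-window substitution separates exactly one representative
  panel <- tiny_panel()
  aln <- tiny_alignment(panel)
  idx <- build_peptide_index(tile_panel(panel, aln))
  g <- group_homologs(idx, aln, 10)   # window 10..25 spans the variant column
  expect_equal(nrow(g$representatives), 2L)

  ## brute-force oracle on a mutated family: grouping by substring equality
  sim <- generate_panel(n_allergens = 10, length = 90,
                        substitution_rate = 0.08, seed = 7)
  idx2 <- build_peptide_index(tile_panel(sim$panel, sim$alignment))
  for (a_start in c(5, 30, 61)) {
    g2 <- group_homologs(idx2, sim$alignment, a_start)
    brute <- split(sim$panel$allergen_id,
                   substring(sim$panel$sequence, a_start, a_start + 15))
    expect_equal(nrow(g2$representatives), length(brute))
    for (i in seq_len(nrow(g2$representatives)))
      expect_setequal(g2$representatives$allergens[[i]],
                      brute[[g2$representatives$sequence[i]]])
  }
})

test_that("residue association recovers a constructed key residue and nothing else", {
  sim <- generate_panel(n_allergens = 12, length = 70,
                        substitution_rate = 0.02, n_key_columns = 3,
                        seed = 9)
  idx <- build_peptide_index(tile_panel(sim$panel, sim$alignment))
  kc <- sim$truth$key_columns[1]           # planted polymorphic column
  a_start <- kc$column - 5L                 # tile window contains the column
  g <- group_homologs(idx, sim$alignment, a_start)

  ## constructed truth: high signal iff the allergen carries the base residue
  res <- substring(sim$panel$sequence, kc$column, kc$column)
  hi <- sim$panel$allergen_id[res == kc$base_residue]
  sig <- stats::setNames(
    ifelse(vapply(g$representatives$allergens, function(x)
      any(x %in% hi), logical(1)), 13, 10),
    g$representatives$sequence)
  assoc <- residue_association(g, sig, sim$alignment)
  expect_gt(nrow(assoc), 0L)
  expect_equal(assoc$column[1], kc$column)
  expect_true(assoc$flagged[1])
  expect_equal(sum(assoc$flagged), 1L)
  expect_equal(abs(assoc$effect[1]), 3)

  ## constant signals: nothing flagged
  sig0 <- stats::setNames(rep(10, nrow(g$representatives)),
                          g$representatives$sequence)
  assoc0 <- residue_association(g, sig0, sim$alignment)
  expect_false(any(assoc0$flagged))

  ## relabelling invariance: permuting representatives with their signals
  perm <- sample(length(sig))
  assoc_p <- residue_association(g, sig[perm], sim$alignment)
  expect_equal(assoc_p, assoc)
})

test_that("isoallergen contrasts find one-sided reactivity and are antisymmetric", {
  ## two isoforms differing only in a C-terminal epitope region
  set.seed(43)
  core <- random_aa(60)
  tail_a <- random_aa(20)
  tail_b <- random_aa(20)
  panel <- allergen_panel(c("Iso 1.0101", "Iso 1.0201"),
                          c(paste0(core, tail_a), paste0(core, tail_b)))
  aln <- master_alignment(stats::setNames(panel$sequence, panel$allergen_id))
  idx <- build_peptide_index(tile_panel(panel, aln))
  occ <- idx$occurrences
  ## elevate the C-terminal tiles of isoform 2 only
  vals <- background_log2(idx$unique_sequences)
  cpeps <- occ$sequence[occ$allergen_id == "Iso 1.0201" & occ$start_local >= 61]
  vals[cpeps] <- 16
  rmat <- rmat_from_log2(list("A|1|IgG" = vals), idx)
  calls <- call_reactive(rmat, idx)
  cons <- isoallergen_contrasts(calls, idx, panel,
                                data.frame(a = "Iso 1.0101", b = "Iso 1.0201"))
  disc <- cons[cons$discriminating == TRUE, ]
  expect_gt(nrow(disc), 0L)
  expect_true(all(disc$aligned_start >= 61 - 15))
  expect_true(all(disc$reactive_b & !disc$reactive_a))
  ## swapping the pair flips the sign of the difference
  cons_sw <- isoallergen_contrasts(calls, idx, panel,
                                   data.frame(a = "Iso 1.0201", b = "Iso 1.0101"))
  m <- merge(cons[, c("aligned_start", "diff", "discriminating")],
             cons_sw[, c("aligned_start", "diff", "discriminating")],
             by = "aligned_start")
  expect_equal(m$diff.x, -m$diff.y)
  expect_equal(m$discriminating.x, m$discriminating.y)

  ## identical isoforms: no discriminating positions anywhere
  panel_eq <- allergen_panel(c("Eq 1.0101", "Eq 1.0201"), rep(random_aa(50), 2))
  aln_eq <- master_alignment(stats::setNames(panel_eq$sequence,
                                             panel_eq$allergen_id))
  idx_eq <- build_peptide_index(tile_panel(panel_eq, aln_eq))
  vals_eq <- background_log2(idx_eq$unique_sequences)
  vals_eq[idx_eq$unique_sequences[10]] <- 16
  rmat_eq <- rmat_from_log2(list("A|1|IgG" = vals_eq), idx_eq)
  calls_eq <- call_reactive(rmat_eq, idx_eq)
  cons_eq <- isoallergen_contrasts(calls_eq, idx_eq, panel_eq,
                                   data.frame(a = "Eq 1.0101", b = "Eq 1.0201"))
  expect_false(any(cons_eq$discriminating))
  expect_error(isoallergen_contrasts(calls_eq, idx_eq, panel_eq,
                                     data.frame(a = "Eq 1.0101", b = "Zz 9")),
               "not in panel")
})
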