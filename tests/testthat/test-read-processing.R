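test_that("pair joining honours the 6 bp minimum overlap", {
  # constructed exact 6-base shared block "ACGTAA"
  p6 <- data.frame(id = "r1", forward = "ACGTACGTAA",
                   reverse = revcomp("ACGTAAGGGG"), sample_id = "s1")
  j <- join_pairs(p6)
  expect_equal(j$sequence, "ACGTACGTAAGGGG")
  expect_equal(j$length, 14L)

  # the same construction with only a 5-base shared block stays unjoined
  p5 <- data.frame(id = "r1", forward = "ACGTACGTAA",
                   reverse = revcomp("CGTAAGGGGG"), sample_id = "s1")
  j5 <- join_pairs(p5)
  expect_equal(nrow(j5), 0)
  expect_equal(attr(j5, "n_unjoined"), 1L)
})

test_that("joining resolves overlap mismatches in favour of the forward read", {
  ref <- random_dna(1, 100)
  fwd <- substr(ref, 1, 60)
  rc_rev <- substr(ref, 41, 100)  # 20-base overlap
  rc_mut <- mutate_at(rc_rev, 5)  # inside the overlap (ref position 45)
  j <- join_pairs(data.frame(id = "r", forward = fwd,
                             reverse = revcomp(rc_mut), sample_id = "s"))
  expect_equal(j$sequence, ref)  # forward read wins
})

test_that("noiseless simulated pairs join back to their reference", {
  refs <- make_reference_sequences("g", 254, seed = 9)
  cfg <- sim_config(150, 0)
  counts <- matrix(7L, 1, 1, dimnames = list("s1", "g"))
  contigs <- join_pairs(counts_to_read_pairs(counts, refs, cfg))
  expect_equal(nrow(contigs), 7)
  expect_true(all(contigs$sequence == refs[["g"]]))
})

test_that("contaminant index deduplicates and validates k", {
  ctl <- as_contigs(rep(random_dna(2), each = 3), "reagent_01")
  idx <- contaminant_index(ctl)
  expect_length(idx$sequences, 2)

  empty <- contaminant_index(as_contigs(character(0)))
  expect_length(empty$sequences, 0)

  short <- as_contigs(substr(random_dna(1), 1, 20))
  expect_error(contaminant_index(short), "shortest control contig")
})

test_that("indexed contigs are retrievable through their own k-mers", {
  seqs <- random_dna(10)
  idx <- contaminant_index(as_contigs(seqs))
  m <- match_contaminant(seqs, idx)
  expect_true(all(m$matched))
  expect_true(all(m$identity == 1))
})

test_that("the 99%/250bp match rule behaves exactly at the boundary", {
  ctl_seq <- random_dna(1, 254)
  idx <- contaminant_index(as_contigs(ctl_seq))

  exact <- match_contaminant(ctl_seq, idx)
  expect_true(exact$matched)
  expect_equal(exact$identity, 1.0)
  expect_equal(exact$length, 254L)

  two <- match_contaminant(mutate_at(ctl_seq, c(30, 200)), idx)
  expect_true(two$matched)          # 252/254 ~ 0.992 >= 0.99
  three <- match_contaminant(mutate_at(ctl_seq, c(30, 120, 200)), idx)
  expect_false(three$matched)       # 251/254 ~ 0.988 < 0.99

  # a perfect 200 bp block is below the 250 bp floor
  block <- paste0(substr(ctl_seq, 1, 200), random_dna(1, 54))
  expect_false(match_contaminant(block, idx)$matched)

  # reverse complement orientation is caught, and can be disabled
  rc <- revcomp(ctl_seq)
  expect_true(match_contaminant(rc, idx)$matched)
  cfg_norc <- filter_config(check_reverse_complement = FALSE)
  expect_false(match_contaminant(rc, idx, cfg_norc)$matched)
})

test_that("filtering removes spiked copies and nothing else", {
  specimen_seqs <- random_dna(100)
  ctl_seqs <- random_dna(5)
  spiked <- sample(ctl_seqs, 40, replace = TRUE)
  contigs <- as_contigs(c(specimen_seqs, spiked), "s1")
  idx <- contaminant_index(as_contigs(ctl_seqs, "reagent_01"))

  f <- filter_contigs(contigs, idx)
  expect_equal(f$report$n_removed, 40)
  expect_setequal(f$retained$sequence, specimen_seqs)
  # order of retained contigs preserved
  expect_identical(f$retained$sequence,
                   contigs$sequence[contigs$sequence %in% specimen_seqs])
  # report tallies are consistent
  ps <- f$report$per_sample
  expect_equal(ps$input, ps$removed + ps$retained)

  # empty index removes nothing
  f0 <- filter_contigs(contigs, contaminant_index(as_contigs(character(0))))
  expect_equal(f0$report$n_removed, 0)

  # everything identical to a control contig is removed
  all_ctl <- as_contigs(rep(ctl_seqs[1], 10), "s1")
  expect_equal(filter_contigs(all_ctl, idx)$report$removed_fraction, 1)

  # byte-identical reports on identical inputs
  expect_identical(f$report, filter_contigs(contigs, idx)$report)
})

test_that("contaminant matching agrees with the brute-force oracle", {
  set.seed(404)
  for (rep in 1:6) {
    ctl <- random_dna(4)
    queries <- c(
      random_dna(3),                                    # unrelated
      vapply(1:3, function(i) {
        mutate_at(ctl[i], sample(254, sample(0:4, 1))) # near-boundary
      }, character(1)),
      revcomp(ctl[4]),                                  # orientation
      paste0(substr(ctl[1], 1, sample(150:253, 1)),     # short block
             random_dna(1, 100))
    )
    idx <- contaminant_index(as_contigs(ctl))
    got <- match_contaminant(queries, idx)$matched
    want <- vapply(queries, oracle_match, logical(1), controls = ctl)
    expect_identical(unname(got), unname(want))
  }
})

test_that("genus assignment applies the >97% rule with lexicographic ties", {
  refs <- make_reference_sequences(c("alpha", "beta"), 254, seed = 4)
  expect_equal(assign_genus(refs[["alpha"]], refs), "alpha")
  expect_equal(assign_genus(refs[["beta"]], refs), "beta")

  # ~98% identity (4 substitutions over 254) clears the threshold
  near <- mutate_at(refs[["alpha"]], c(40, 90, 140, 190))
  expect_equal(assign_genus(near, refs), "alpha")

  # ~95% identity (13 substitutions over 254) stays unassigned
  far <- mutate_at(refs[["alpha"]], seq(10, 250, by = 20))
  expect_equal(assign_genus(far, refs), "unassigned")

  # equidistant contig between two references: lexicographically first
  base <- random_dna(1, 254)
  tie_refs <- structure(c(zeta = mutate_at(base, 10),
                          eta = mutate_at(base, 200)),
                        class = "reference_set")
  expect_equal(assign_genus(base, tie_refs), "eta")
})

test_that("tabulation round-trips noiseless simulations exactly", {
  prof <- genus_profile(c(a = 0.5, b = 0.3, c = 0.2), "toy")
  gs <- group_spec(prof, 6, log(300), 0.3, 100)
  truth <- simulate_counts(gs, seed = 21)
  refs <- make_reference_sequences(c("a", "b", "c"), 254, seed = 21)
  cfg <- sim_config(150, 0)
  contigs <- join_pairs(counts_to_read_pairs(truth, refs, cfg))
  counts <- tabulate_counts(contigs, refs, sample_ids = rownames(truth))
  expect_equal(drop_unassigned(counts)[, colnames(truth)], truth)
  expect_true(all(counts[, "unassigned"] == 0))

  # permuting contig order leaves the matrix unchanged
  perm <- contigs[sample(nrow(contigs)), ]
  expect_equal(tabulate_counts(perm, refs, sample_ids = rownames(truth)),
               counts)

  # a sample with no retained contigs keeps an all-zero row
  counts2 <- tabulate_counts(contigs, refs,
                             sample_ids = c(rownames(truth), "ghost"))
  expect_true(all(counts2["ghost", ] == 0))
})
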