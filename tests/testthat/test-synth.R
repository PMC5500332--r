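test_that("reference sequences have the right length, alphabet and spacing", {
  one <- make_reference_sequences("g1", 254, seed = 1)
  expect_length(one, 1)
  expect_equal(nchar(one[["g1"]]), 254)
  expect_true(grepl("^[ACGT]+$", one[["g1"]]))

  again <- make_reference_sequences("g1", 254, seed = 1)
  expect_identical(unclass(one), unclass(again))

  refs <- make_reference_sequences(paste0("g", 1:30), 254, seed = 3)
  # brute-force pairwise identity below the 90% collision bound
  for (i in 1:29) {
    for (j in (i + 1):30) {
      expect_lt(oracle_string_identity(refs[[i]], refs[[j]]), 0.90)
    }
  }

  expect_error(make_reference_sequences(character(0)), "non-empty")
  expect_error(make_reference_sequences("g1", length = 200), "250")
  expect_error(make_reference_sequences(c("a", "a")), "unique")
})

test_that("simulated counts follow the Dirichlet-multinomial law", {
  prof <- genus_profile(c(a = 0.6, b = 0.3, c = 0.1), "toy")

  # zero-depth limit
  gs0 <- group_spec(prof, 5, -Inf, 0.1, 10)
  expect_true(all(simulate_counts(gs0, seed = 1) == 0))

  # law of large numbers: high dispersion, deep sampling
  gs <- group_spec(prof, 200, log(5e4), 0.1, 1e4)
  m <- simulate_counts(gs, seed = 2)
  props <- colMeans(m / rowSums(m))
  expect_true(all(abs(props - unclass(prof)) < 0.01))

  # determinism and seed sensitivity
  expect_identical(simulate_counts(gs, seed = 2), m)
  expect_false(identical(simulate_counts(gs, seed = 3), m))

  # genera outside the profile stay at zero
  m2 <- simulate_counts(group_spec(prof, 4, log(100), 0.2, 50), seed = 1,
                        genera = c("a", "b", "c", "zzz"))
  expect_true(all(m2[, "zzz"] == 0))
})

test_that("read pairs reconstruct counts and carry the error model", {
  refs <- make_reference_sequences(c("a", "b"), 254, seed = 5)
  cfg <- sim_config(read_length = 150, error_rate = 0)
  counts <- matrix(c(5L, 0L, 0L, 3L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("a", "b")))

  pairs <- counts_to_read_pairs(counts, refs, cfg, seed = 1)
  # conservation: one pair per count
  expect_equal(as.vector(table(pairs$sample_id)[c("s1", "s2")]), c(5, 3))
  # noiseless round trip through joining
  contigs <- join_pairs(pairs)
  expect_equal(nrow(contigs), 8)
  expect_true(all(contigs$sequence[contigs$sample_id == "s1"] ==
                    refs[["a"]]))
  expect_true(all(contigs$sequence[contigs$sample_id == "s2"] ==
                    refs[["b"]]))

  # all-zero row yields no reads for that sample
  zero <- matrix(0L, 1, 2, dimnames = list("empty", c("a", "b")))
  expect_equal(nrow(counts_to_read_pairs(zero, refs, cfg)), 0)

  # missing reference is an error naming the genus
  bad <- matrix(2L, 1, 1, dimnames = list("s1", "nova"))
  expect_error(counts_to_read_pairs(bad, refs, cfg), "nova")

  # substitution rate: observed mismatch fraction within 3 SD of the rate
  cfg_err <- sim_config(read_length = 150, error_rate = 0.01)
  many <- matrix(40L, 1, 1, dimnames = list("s1", "a"))
  p <- counts_to_read_pairs(many, refs, cfg_err, seed = 7)
  fwd_ref <- substr(refs[["a"]], 1, 150)
  mism <- vapply(p$forward, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(fwd_ref, "")[[1]])
  }, numeric(1))
  n_bases <- 40 * 150
  rate <- sum(mism) / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("contaminant spiking matches its profile and leaves controls pure", {
  profs <- default_profiles()
  genera <- c("x", names(profs$contaminant))
  refs <- make_reference_sequences(genera, 254, seed = 2)
  cfg <- sim_config(150, 0)
  counts <- matrix(10L, 50, 1, dimnames = list(sprintf("s%02d", 1:50), "x"))
  pairs <- counts_to_read_pairs(counts, refs, cfg, seed = 1)

  # load 0: specimens unchanged, controls empty
  none <- spike_contaminants(pairs, contaminant_spec(load = 0), refs, cfg,
                             seed = 1, reagent_load = 0, ntc_load = 0)
  expect_identical(nrow(none$specimens), nrow(pairs))
  expect_identical(nrow(none$controls), 0L)

  sp <- spike_contaminants(pairs, contaminant_spec(load = 100), refs, cfg,
                           seed = 1)
  spiked <- sp$specimens[!(sp$specimens$id %in% pairs$id), ]
  genus_of <- vapply(strsplit(spiked$id, "\\|"), `[`, character(1), 2)
  n <- nrow(spiked)
  for (g in c("Pseudomonas", "Escherichia")) {
    p_g <- unclass(profs$contaminant)[[g]]
    se <- sqrt(p_g * (1 - p_g) / n)
    expect_lt(abs(mean(genus_of == g) - p_g), 3 * se)
  }

  # controls contain only contaminant genera
  ctl_genus <- vapply(strsplit(sp$controls$id, "\\|"), `[`, character(1), 2)
  expect_true(all(ctl_genus %in% names(profs$contaminant)))
  expect_setequal(unique(substr(sp$controls$sample_id, 1, 3)),
                  c("rea", "NTC"))

  # determinism
  sp2 <- spike_contaminants(pairs, contaminant_spec(load = 100), refs, cfg,
                            seed = 1)
  expect_identical(sp, sp2)
})

test_that("the default design keeps NTC depth far below URT depth", {
  sim <- simulate_scenario(small_scenario(), seed = 11, level = "reads")
  urt_ids <- sim$metadata$sample_id[sim$metadata$site == "URT"]
  ntc_ids <- sim$metadata$sample_id[sim$metadata$site == "NTC"]
  urt_total <- sum(sim$pairs$sample_id %in% urt_ids)
  ntc_total <- sum(sim$controls$sample_id %in% ntc_ids)
  expect_gt(urt_total / length(urt_ids), 20 * ntc_total / length(ntc_ids))
})

test_that("provenance masking hides true genus labels from read ids", {
  refs <- make_reference_sequences(c("a", "b"), 254, seed = 5)
  cfg <- sim_config(150, 0)
  counts <- matrix(c(3L, 2L), 1, 2, dimnames = list("s1", c("a", "b")))
  masked <- counts_to_read_pairs(counts, refs, cfg, mask_provenance = TRUE)
  expect_false(any(grepl("\\|a\\||\\|b\\|", masked$id)))
})
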