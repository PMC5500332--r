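# Compact study fixture: URT anchors plus lung samples of known origin.
make_study <- function(seed = 1, n_urt = 6, n_bg = 4, n_uni = 6,
                       n_asp = 3) {
  prof <- default_profiles()
  genera <- profile_genus_union(prof[c("urt", "lung_unique",
                                       "lung_aspirate")])
  draw <- function(p, n, depth, disp, ids) {
    simulate_counts(group_spec(p, n, log(depth), 0.3, disp), seed = seed,
                    genera = genera, sample_ids = ids)
  }
  counts <- rbind(
    draw(prof$urt, n_urt, 5e4, 500, sprintf("URT_%02d", 1:n_urt)),
    draw(prof$urt, n_bg, 12, 20, sprintf("UL_bg%02d", 1:n_bg)),
    draw(prof$lung_unique, n_uni, 300, 20, sprintf("UL_un%02d", 1:n_uni)),
    draw(prof$lung_aspirate, n_asp, 2000, 100,
         sprintf("LL_as%02d", 1:n_asp))
  )
  metadata <- data.frame(
    sample_id = rownames(counts),
    site = c(rep("URT", n_urt), rep("UL", n_bg + n_uni), rep("LL", n_asp)),
    animal_id = NA_character_,
    role = "specimen",
    stringsAsFactors = FALSE
  )
  truth <- c(rep(NA, n_urt), rep("background", n_bg),
             rep("unique", n_uni), rep("aspirate", n_asp))
  list(counts = counts, metadata = metadata,
       truth = setNames(truth, rownames(counts)))
}

test_that("the background rule is a strict sub-50 total-count test", {
  st <- make_study()
  base <- st$counts
  lung <- st$metadata$sample_id[st$metadata$site %in% c("UL", "LL")]

  # force three diagnostic totals: 30, 50 and 0 reads
  probe <- base
  probe["UL_un01", ] <- 0L
  probe["UL_un01", "Streptococcus"] <- 30L
  probe["UL_un02", ] <- 0L
  probe["UL_un02", "Streptococcus"] <- 50L
  probe["UL_un03", ] <- 0L
  fit <- pneumotype(probe, st$metadata)
  expect_equal(unname(fit$labels["UL_un01"]), "background")
  expect_false(fit$labels[["UL_un02"]] == "background")  # boundary: 50 is not < 50
  expect_equal(unname(fit$labels["UL_un03"]), "background")

  # monotonicity: raising the threshold never shrinks the background group
  f50 <- pneumotype(base, st$metadata, background_threshold = 50)
  f500 <- pneumotype(base, st$metadata, background_threshold = 500)
  bg50 <- names(f50$labels)[f50$labels == "background"]
  bg500 <- names(f500$labels)[f500$labels == "background"]
  expect_true(all(bg50 %in% bg500))

  # background decision depends only on the sample's own total
  expect_setequal(bg50, lung[rowSums(base[lung, ]) < 50])
})

test_that("classification recovers the generating pneumotypes", {
  st <- make_study(seed = 5)
  fit <- pneumotype(st$counts, st$metadata)
  lung <- names(fit$labels)
  expect_setequal(lung,
                  st$metadata$sample_id[st$metadata$site %in% c("UL", "LL")])
  expect_false(any(is.na(fit$labels)))          # labels partition lung
  expect_gte(mean(fit$labels == st$truth[lung]), 0.95)
  expect_true(fit$converged)
  expect_lte(fit$iterations, fit$config$max_iter)

  # rerun determinism
  expect_identical(fit$labels, pneumotype(st$counts, st$metadata)$labels)
})

test_that("initial assignment uses the URT correlation threshold", {
  st <- make_study(seed = 9)
  # a depth-scaled copy of the URT representative correlates ~1
  lmat <- log2_transform(st$counts)
  urt_ids <- st$metadata$sample_id[st$metadata$site == "URT"]
  prof <- representative_profile(lmat, urt_ids)
  aspirate_like <- st$counts["LL_as01", ]
  expect_gte(correlation_to_profile(lmat["LL_as01", ], prof), 0.6)
  unique_like <- lmat["UL_un01", ]
  expect_lt(correlation_to_profile(unique_like, prof), 0.6)

  fit <- pneumotype(st$counts, st$metadata)
  expect_equal(unname(fit$labels["LL_as01"]), "aspirate")
  expect_equal(unname(fit$labels["UL_un01"]), "unique")
})

test_that("iteration stops at a fixed point and survives degenerate groups", {
  st <- make_study(seed = 3)
  fit <- pneumotype(st$counts, st$metadata)
  # refitting from the fitted labels is already stable after one pass
  expect_true(fit$converged)

  # all non-background samples from a single profile: one surviving group
  prof <- default_profiles()
  genera <- profile_genus_union(prof["lung_unique"])
  uni_only <- simulate_counts(
    group_spec(prof$lung_unique, 8, log(400), 0.3, 50), seed = 2,
    genera = genera, sample_ids = sprintf("UL_%02d", 1:8))
  urt <- simulate_counts(
    group_spec(prof$lung_unique, 3, log(5e4), 0.2, 500), seed = 3,
    genera = genera, sample_ids = sprintf("URT_%02d", 1:3))
  meta <- data.frame(
    sample_id = c(rownames(uni_only), rownames(urt)),
    site = c(rep("UL", 8), rep("URT", 3)),
    animal_id = NA, role = "specimen", stringsAsFactors = FALSE)
  fit1 <- pneumotype(rbind(uni_only, urt), meta)
  expect_true(fit1$converged)
  expect_lte(length(unique(fit1$labels)), 2)
})

test_that("a study of only background-depth lung samples is all background", {
  st <- make_study(n_bg = 6, n_uni = 1, n_asp = 1)
  counts <- st$counts
  lung <- st$metadata$sample_id[st$metadata$site %in% c("UL", "LL")]
  # push every lung sample under the floor
  counts[lung, ] <- 0L
  counts[lung, "Streptococcus"] <- 10L
  fit <- pneumotype(counts, st$metadata)
  expect_true(all(fit$labels == "background"))
  expect_equal(fit$iterations, 0L)
  expect_true(fit$converged)
})

test_that("classification requires lung samples and a URT anchor", {
  st <- make_study()
  no_lung <- st$metadata[st$metadata$site == "URT", ]
  expect_error(pneumotype(st$counts[no_lung$sample_id, ], no_lung),
               "no lung")
  no_urt <- st$metadata[st$metadata$site != "URT", ]
  expect_error(pneumotype(st$counts[no_urt$sample_id, ], no_urt),
               "URT")
})

test_that("predict labels new samples consistently with the fit", {
  st <- make_study(seed = 13)
  fit <- pneumotype(st$counts, st$metadata)
  relabelled <- predict(fit, st$counts[names(fit$labels), ])
  expect_gte(mean(relabelled == fit$labels), 0.9)

  st2 <- make_study(seed = 14)
  lung2 <- st2$metadata$sample_id[st2$metadata$site %in% c("UL", "LL")]
  pred2 <- predict(fit, st2$counts[lung2, ])
  expect_gte(mean(pred2 == st2$truth[lung2]), 0.8)
})

test_that("pneumotype methods print, summarise and plot without error", {
  st <- make_study()
  fit <- pneumotype(st$counts, st$metadata)
  expect_output(print(fit), "Pneumotype classification")
  expect_output(summary(fit), "Config")
  cf <- coef(fit)
  expect_equal(rownames(cf), colnames(drop_unassigned(st$counts)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
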