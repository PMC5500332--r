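#' Validate pipeline inputs
#'
#' Checks FASTQ pairing and metadata completeness before a run: every
#' listed sample must have both read files on disk, metadata must cover
#' every sample with a recognised site and role, and sample ids must be
#' unique. All violations are collected (not fail-on-first) and returned
#' as a structured list.
#'
#' @param metadata data.frame with columns `sample_id`, `site`,
#'   `animal_id`, `role`.
#' @param fastq_manifest optional data.frame with columns `sample_id`,
#'   `r1`, `r2` (paths); checked for existence and pairing.
#' @return list with `ok` (logical) and `errors` (character vector of
#'   line-referenced messages).
#' @export
validate_inputs <- function(metadata, fastq_manifest = NULL) {
  errors <- character()
  req <- c("sample_id", "site", "animal_id", "role")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    errors <- c(errors, paste("metadata missing column(s):",
                              paste(missing_cols, collapse = ", ")))
  } else {
    sites <- c("URT", "UL", "LL", "NTC", "reagent", "bedding", "chow",
               "water")
    roles <- c("specimen", "control", "environmental")
    bad_site <- which(!metadata$site %in% sites)
    for (i in bad_site) {
      errors <- c(errors, sprintf(
        "metadata row %d: unknown site '%s' (allowed: %s)", i,
        metadata$site[i], paste(sites, collapse = ", ")))
    }
    bad_role <- which(!metadata$role %in% roles)
    for (i in bad_role) {
      errors <- c(errors, sprintf(
        "metadata row %d: unknown role '%s' (allowed: %s)", i,
        metadata$role[i], paste(roles, collapse = ", ")))
    }
    dup <- metadata$sample_id[duplicated(metadata$sample_id)]
    if (length(dup) > 0) {
      errors <- c(errors, paste("duplicate sample id(s):",
                                paste(unique(dup), collapse = ", ")))
    }
  }
  if (!is.null(fastq_manifest)) {
    for (i in seq_len(nrow(fastq_manifest))) {
      sid <- fastq_manifest$sample_id[i]
      for (col in c("r1", "r2")) {
        p <- fastq_manifest[[col]][i]
        if (is.na(p) || !file.exists(p)) {
          errors <- c(errors, sprintf(
            "manifest row %d: sample '%s' missing %s file '%s'", i, sid,
            toupper(col), p))
        }
      }
      if (!is.null(metadata$sample_id) &&
          !sid %in% metadata$sample_id) {
        errors <- c(errors, sprintf(
          "manifest row %d: sample '%s' absent from metadata", i, sid))
      }
    }
  }
  list(ok = length(errors) == 0, errors = errors)
}

## Header-comment lines for every output table.
pipeline_header <- function(seed, cfg, extra = character()) {
  cfg_string <- paste(names(unlist(cfg)), unlist(cfg), sep = "=",
                      collapse = ";")
  chash <- substr(digest_string(cfg_string), 1, 12)
  c(paste0("pneumotyper ",
           as.character(utils::packageVersion("pneumotyper"))),
    paste0("seed=", seed, " config_hash=", chash),
    paste0("variants: overlap=pooled chao1=bias_corrected_at_F2_0 ",
           "correlation=pearson pseudocount=1"),
    extra)
}

## md5 of a string via a temp file (tools:: has no direct string digest).
digest_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> join -> decontaminate -> tabulate ->
#' classify -> community statistics -> diversity as one reproducible run,
#' writing every result as TSV with a header comment carrying the seed,
#' a config hash and the statistic-variant flags. Outputs: the filtered
#' genus count matrix, the decontamination filter report, pneumotype
#' labels, group abundance report (composition-table analogue), group
#' correlation matrix, group and environmental overlap matrices, an
#' alpha-diversity table, per-group rarefaction curves and a PERMANOVA
#' summary.
#'
#' @param scenario a `scenario` from [scenario_paper_default()].
#' @param outdir output directory (created if needed).
#' @param seed integer seed governing every stochastic stage.
#' @param cfg a [filter_config].
#' @param rarefaction_depth depth for the alpha-diversity Chao1 (default
#'   340 reads).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @return invisibly, a run manifest: list with `files` (paths +
#'   md5 checksums), `results` (all in-memory result objects), `seed`,
#'   `scenario`.
#' @export
run_pipeline <- function(scenario = scenario_paper_default(),
                         outdir = tempfile("pneumotyper_run_"),
                         seed = scenario$seed,
                         cfg = filter_config(),
                         rarefaction_depth = 340L,
                         n_permutations = 999L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- pipeline_header(seed, cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_scenario(scenario, seed = seed,
                                             level = "reads"))
  val <- validate_inputs(sim$metadata)
  if (!val$ok) {
    stop("pipeline stage 'validate' failed:\n  ",
         paste(val$errors, collapse = "\n  "))
  }

  contigs <- stage("join", join_pairs(sim$pairs, cfg))
  control_contigs <- stage("join", join_pairs(sim$controls, cfg))
  index <- stage("filter", contaminant_index(control_contigs, cfg))
  filt <- stage("filter", filter_contigs(contigs, index, cfg))

  specimen_ids <- sim$metadata$sample_id[sim$metadata$role %in%
                                           c("specimen", "environmental")]
  counts <- stage("tabulate",
                  tabulate_counts(filt$retained, sim$refs, cfg,
                                  sample_ids = specimen_ids))
  control_counts <- stage("tabulate",
                          tabulate_counts(control_contigs, sim$refs, cfg,
                                          sample_ids = sim$metadata$sample_id[
                                            sim$metadata$role == "control"]))
  all_counts <- rbind(counts, control_counts)

  fit <- stage("classify",
               pneumotype(all_counts, sim$metadata))

  cc <- drop_unassigned(counts)
  urt_ids <- sim$metadata$sample_id[sim$metadata$site == "URT"]
  groups <- list(
    lung_unique = names(fit$labels)[fit$labels == "unique"],
    lung_aspirate = names(fit$labels)[fit$labels == "aspirate"],
    URT = urt_ids
  )
  groups <- groups[lengths(groups) > 0]
  env_groups <- lapply(c(bedding = "bedding", chow = "chow",
                         water = "water"), function(s) {
    sim$metadata$sample_id[sim$metadata$site == s]
  })
  env_groups <- env_groups[lengths(env_groups) > 0]

  lmat <- log2_transform(cc)
  stats_out <- stage("stats", {
    corr <- matrix(NA_real_, length(groups), length(groups),
                   dimnames = list(names(groups), names(groups)))
    for (a in names(groups)) {
      for (b in names(groups)) {
        corr[a, b] <- group_correlation(lmat, groups[[a]],
                                        groups[[b]])$mean
      }
    }
    list(
      correlation = corr,
      overlap_groups = overlap_matrix(cc, groups),
      overlap_env = {
        om <- matrix(NA_real_, length(env_groups), length(groups),
                     dimnames = list(names(env_groups), names(groups)))
        for (e in names(env_groups)) {
          for (g in names(groups)) {
            om[e, g] <- overlap(cc, env_groups[[e]], groups[[g]])
          }
        }
        om
      },
      abundance = abundance_report(cc, groups)
    )
  })

  div_out <- stage("diversity", {
    alpha <- suppressWarnings(
      alpha_diversity_table(cc, groups, depth = rarefaction_depth,
                            seed = seed))
    curves <- do.call(rbind, lapply(names(groups), function(g) {
      pooled <- colSums(cc[groups[[g]], , drop = FALSE])
      depths <- unique(pmin(seq(20L, rarefaction_depth, by = 40L),
                            sum(pooled)))
      cv <- rarefaction_curve(pooled, depths, n_reps = 50L, seed = seed)
      cv$group <- g
      cv
    }))
    evaluable <- unlist(groups[names(groups) != "URT"], use.names = FALSE)
    evaluable <- evaluable[rowSums(cc[evaluable, , drop = FALSE]) > 0]
    lab <- fit$labels[evaluable]
    perm <- if (length(unique(lab)) >= 2 && all(table(lab) >= 2)) {
      fct <- data.frame(pneumotype = as.character(lab),
                        stringsAsFactors = FALSE)
      animal <- sim$metadata$animal_id[match(evaluable,
                                             sim$metadata$sample_id)]
      if (!anyNA(animal) && length(unique(animal)) >= 2 &&
          all(table(animal) >= 2)) {
        fct$animal <- animal
      }
      permanova_factors(bray_curtis_matrix(cc[evaluable, , drop = FALSE]),
                        fct, n_permutations = n_permutations, seed = seed)
    } else {
      NULL
    }
    list(alpha = alpha, curves = curves, permanova = perm)
  })

  # --- write the report bundle ---
  files <- character()
  emit <- function(x, fname, extra = character()) {
    p <- file.path(outdir, fname)
    write_tsv_commented(x, p, c(hdr, extra))
    files <<- c(files, p)
    p
  }
  counts_df <- data.frame(sample_id = rownames(all_counts), all_counts,
                          check.names = FALSE)
  emit(counts_df, "counts.tsv")
  emit(filt$report$per_sample, "filter_report.tsv",
       sprintf("overall_removed_fraction=%.6f",
               filt$report$removed_fraction))
  emit(fit$correlations, "pneumotype_labels.tsv",
       sprintf("converged=%s iterations=%d", fit$converged,
               fit$iterations))
  ab <- stats_out$abundance
  ab_df <- data.frame(genus = rownames(ab),
                      ifelse(is.na(unclass(ab)), "-",
                             format(round(unclass(ab), 2), trim = TRUE)),
                      check.names = FALSE)
  emit(ab_df, "abundance_report.tsv")
  emit(data.frame(group = rownames(stats_out$correlation),
                  round(stats_out$correlation, 3), check.names = FALSE),
       "correlation_table.tsv")
  emit(data.frame(group = rownames(stats_out$overlap_groups),
                  round(unclass(stats_out$overlap_groups), 1),
                  check.names = FALSE),
       "overlap_groups.tsv")
  emit(data.frame(source = rownames(stats_out$overlap_env),
                  round(stats_out$overlap_env, 1), check.names = FALSE),
       "overlap_environment.tsv")
  emit(div_out$alpha, "alpha_diversity.tsv")
  emit(div_out$curves, "rarefaction_curves.tsv")
  if (!is.null(div_out$permanova)) {
    emit(div_out$permanova, "permanova.tsv",
         sprintf("n_permutations=%d", n_permutations))
  }
  prof_mat <- coef(fit)
  emit(data.frame(genus = rownames(prof_mat), round(prof_mat, 4),
                  check.names = FALSE),
       "representative_profiles.tsv")

  manifest <- list(
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE),
    results = list(counts = all_counts, filter_report = filt$report,
                   fit = fit, stats = stats_out, diversity = div_out,
                   truth = sim$truth),
    seed = seed, scenario = scenario,
    version = as.character(utils::packageVersion("pneumotyper"))
  )
  # manifest on disk lists files relative to the bundle, so two runs of
  # the same seed are byte-identical wherever they land
  manifest_df <- data.frame(file = basename(files),
                            md5 = unname(tools::md5sum(files)),
                            stringsAsFactors = FALSE)
  write_tsv_commented(manifest_df, file.path(outdir, "manifest.tsv"), hdr)
  invisible(manifest)
}

#' Process real paired FASTQ data up to decontaminated counts
#'
#' Real-data mode: joins paired reads for every sample in the manifest,
#' builds the contaminant index from the samples whose metadata role is
#' `control`, filters specimen contigs, and — only when a per-contig
#' genus annotation is supplied (external taxonomy is out of scope) —
#' tabulates a genus count matrix. Without an annotation the run stops
#' after the filter stage and returns the retained contigs.
#'
#' @param fastq_manifest data.frame with columns `sample_id`, `r1`, `r2`.
#' @param metadata sample metadata (see [validate_inputs()]).
#' @param cfg a [filter_config].
#' @param genus_annotation optional data.frame with columns `id` (contig
#'   id) and `genus`.
#' @return list with `contigs`, `retained`, `report` and, when annotated,
#'   `counts`.
#' @export
process_fastq <- function(fastq_manifest, metadata,
                          cfg = filter_config(),
                          genus_annotation = NULL) {
  val <- validate_inputs(metadata, fastq_manifest)
  if (!val$ok) {
    stop("input validation failed:\n  ",
         paste(val$errors, collapse = "\n  "))
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(fastq_manifest)),
                                 function(i) {
    read_fastq_pairs(fastq_manifest$r1[i], fastq_manifest$r2[i],
                     fastq_manifest$sample_id[i])
  }))
  contigs <- join_pairs(pairs, cfg)
  roles <- metadata$role[match(contigs$sample_id, metadata$sample_id)]
  control_contigs <- contigs[roles == "control", , drop = FALSE]
  specimen_contigs <- contigs[roles != "control", , drop = FALSE]
  class(control_contigs) <- class(specimen_contigs) <-
    c("contigs", "data.frame")
  index <- contaminant_index(control_contigs, cfg)
  filt <- filter_contigs(specimen_contigs, index, cfg)
  out <- list(contigs = contigs, retained = filt$retained,
              report = filt$report)
  if (!is.null(genus_annotation)) {
    g <- genus_annotation$genus[match(filt$retained$id,
                                      genus_annotation$id)]
    g[is.na(g)] <- "unassigned"
    genera <- c(sort(unique(g[g != "unassigned"])), "unassigned")
    sample_ids <- unique(specimen_contigs$sample_id)
    tab <- table(factor(filt$retained$sample_id, levels = sample_ids),
                 factor(g, levels = genera))
    out$counts <- matrix(as.integer(tab), nrow = length(sample_ids),
                         dimnames = list(sample_ids, genera))
  }
  out
}
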