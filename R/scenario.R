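#' The default study scenario
#'
#' Encodes the study design the package emulates: 18 co-housed mice, each
#' contributing one URT (oropharyngeal) sample and two lung samples (upper
#' and lower lobe, pooled as "lung" downstream); 8 reagent controls and 3
#' no-template water controls carrying only reagent contamination; and 3
#' samples each of cage bedding, rodent chow and drinking water. Lung
#' samples are split 33/58/9 percent across the background / unique /
#' aspirate pneumotypes (12/21/3 of the 36 samples).
#'
#' Sequencing depths follow the study's qualitative structure — the URT
#' carries orders of magnitude more bacterial 16S template than the lung
#' (URT ~5e4 reads/sample against ~3e2 for lung-unique), lung-aspirate
#' samples carry more reads than other lung samples (~2e3), background
#' lung samples fall below the 50-read floor (~15), NTCs ~30 and reagent
#' controls ~800 reads. Dirichlet dispersions make the URT highly
#' reproducible (500) and lung-unique much more variable mouse-to-mouse
#' (20). All values are overridable via `...` or a scenario file.
#'
#' @param n_animals number of animals (default 18).
#' @param seed default seed recorded in the scenario.
#' @param ... scalar overrides for any element of the returned list.
#' @return a `scenario` object (a named list of design parameters).
#' @export
#' @examples
#' sc <- scenario_paper_default()
#' sc$urt_depth_log_mean
scenario_paper_default <- function(n_animals = 18L, seed = 1L, ...) {
  sc <- list(
    name = "paper_default",
    n_animals = as.integer(n_animals),
    seed = as.integer(seed),
    # depth laws (natural-log scale)
    urt_depth_log_mean = log(5e4), urt_depth_log_sd = 0.3,
    unique_depth_log_mean = log(300), unique_depth_log_sd = 0.5,
    aspirate_depth_log_mean = log(2000), aspirate_depth_log_sd = 0.4,
    background_depth_log_mean = log(15), background_depth_log_sd = 0.5,
    env_depth_log_mean = log(5000), env_depth_log_sd = 0.3,
    # Dirichlet dispersions
    urt_dispersion = 500, unique_dispersion = 20,
    aspirate_dispersion = 100, background_dispersion = 20,
    env_dispersion = 100,
    # pneumotype mix over lung samples (fractions)
    frac_background = 12 / 36, frac_unique = 21 / 36, frac_aspirate = 3 / 36,
    # controls and contamination
    n_reagent = 8L, n_ntc = 3L, n_env = 3L,
    contaminant_load = 100, reagent_load = 800, ntc_load = 30,
    # read-level parameters
    read_length = 150L, error_rate = 0.002, reference_length = 254L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown) > 0) {
    stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "))
  }
  sc[names(dots)] <- dots
  structure(sc, class = "scenario")
}

#' Read / write a scenario as a flat key-value text file
#'
#' Lines are `key = value`; unknown keys are rejected. Values are parsed
#' numerically where possible. `scenario_read()` applies the file on top
#' of [scenario_paper_default()].
#'
#' @param sc a `scenario` object.
#' @param path file path.
#' @return `scenario_read()` returns a `scenario`; `scenario_write()` the
#'   path, invisibly.
#' @export
scenario_write <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  keys <- names(sc)
  vals <- vapply(sc, function(v) as.character(v), character(1))
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

#' @rdname scenario_write
#' @export
scenario_read <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed scenario line(s): ",
         paste(which(bad), collapse = ", "))
  }
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(parsed) <- keys
  parsed$name <- NULL
  do.call(scenario_paper_default, parsed)
}

## Deterministic-count pneumotype truth for the lung samples, shuffled
## across animals/sites under the scenario seed.
lung_truth_labels <- function(sc, n_lung, seed) {
  n_bg <- round(sc$frac_background * n_lung)
  n_asp <- round(sc$frac_aspirate * n_lung)
  n_un <- n_lung - n_bg - n_asp
  labels <- c(rep("background", n_bg), rep("unique", n_un),
              rep("aspirate", n_asp))
  with_seed(seed, offset = 733L, sample(labels))
}

#' Simulate a full study from a scenario
#'
#' At `level = "counts"` returns the true (pre-sequencing) genus count
#' matrix for every specimen and environmental sample, together with the
#' sample metadata and the generating pneumotype of each lung sample. At
#' `level = "reads"` additionally draws reference sequences, expands
#' counts into error-bearing read pairs, spikes reagent contamination into
#' every specimen and emits reagent/NTC control read collections.
#'
#' @param sc a `scenario` (default [scenario_paper_default()]).
#' @param seed integer seed; defaults to the scenario's.
#' @param level `"counts"` or `"reads"`.
#' @param mask_provenance passed through to the read-level generators.
#' @return list with elements `counts`, `metadata`, `truth` and, at read
#'   level, `pairs`, `controls`, `refs`, `cfg`.
#' @export
simulate_scenario <- function(sc = scenario_paper_default(),
                              seed = sc$seed,
                              level = c("counts", "reads"),
                              mask_provenance = FALSE) {
  level <- match.arg(level)
  prof <- default_profiles()
  n <- sc$n_animals
  genera <- profile_genus_union(prof)

  urt_ids <- sprintf("URT_m%02d", seq_len(n))
  lung_ids <- c(sprintf("UL_m%02d", seq_len(n)), sprintf("LL_m%02d", seq_len(n)))
  lung_sites <- c(rep("UL", n), rep("LL", n))
  truth_lung <- lung_truth_labels(sc, length(lung_ids), seed)

  spec_for <- function(profile, ids, mean, sd, disp, name) {
    g <- group_spec(profile, length(ids), mean, sd, disp, name = name)
    simulate_counts(g, seed = seed + .group_seed_shift(name),
                    genera = genera, sample_ids = ids)
  }
  counts <- spec_for(prof$urt, urt_ids, sc$urt_depth_log_mean,
                     sc$urt_depth_log_sd, sc$urt_dispersion, "URT")
  lung_rows <- lapply(c("background", "unique", "aspirate"), function(pt) {
    ids <- lung_ids[truth_lung == pt]
    if (length(ids) == 0) return(NULL)
    par <- switch(pt,
      background = list(prof$urt, sc$background_depth_log_mean,
                        sc$background_depth_log_sd, sc$background_dispersion),
      unique = list(prof$lung_unique, sc$unique_depth_log_mean,
                    sc$unique_depth_log_sd, sc$unique_dispersion),
      aspirate = list(prof$lung_aspirate, sc$aspirate_depth_log_mean,
                      sc$aspirate_depth_log_sd, sc$aspirate_dispersion)
    )
    spec_for(par[[1]], ids, par[[2]], par[[3]], par[[4]], pt)
  })
  env_rows <- lapply(c("bedding", "chow", "water"), function(src) {
    ids <- sprintf("%s_%02d", src, seq_len(sc$n_env))
    spec_for(prof[[src]], ids, sc$env_depth_log_mean, sc$env_depth_log_sd,
             sc$env_dispersion, src)
  })
  counts <- do.call(rbind, c(list(counts), lung_rows, env_rows))
  counts <- counts[c(urt_ids, lung_ids,
                     rownames(counts)[!rownames(counts) %in%
                                        c(urt_ids, lung_ids)]), ,
                   drop = FALSE]

  env_ids <- unlist(lapply(c("bedding", "chow", "water"), function(src) {
    sprintf("%s_%02d", src, seq_len(sc$n_env))
  }))
  control_ids <- c(sprintf("reagent_%02d", seq_len(sc$n_reagent)),
                   sprintf("NTC_%02d", seq_len(sc$n_ntc)))
  metadata <- data.frame(
    sample_id = c(urt_ids, lung_ids, control_ids, env_ids),
    site = c(rep("URT", n), lung_sites,
             rep("reagent", sc$n_reagent), rep("NTC", sc$n_ntc),
             rep(c("bedding", "chow", "water"), each = sc$n_env)),
    animal_id = c(sprintf("m%02d", seq_len(n)),
                  rep(sprintf("m%02d", seq_len(n)), 2),
                  rep(NA_character_,
                      sc$n_reagent + sc$n_ntc + 3 * sc$n_env)),
    role = c(rep("specimen", n + 2 * n),
             rep("control", sc$n_reagent + sc$n_ntc),
             rep("environmental", 3 * sc$n_env)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = c(urt_ids, lung_ids, env_ids),
    group = c(rep("URT", n), truth_lung,
              rep(c("bedding", "chow", "water"), each = sc$n_env)),
    stringsAsFactors = FALSE
  )
  out <- list(counts = counts, metadata = metadata, truth = truth,
              scenario = sc, seed = seed)
  if (level == "counts") return(out)

  all_genera <- sort(unique(c(genera, names(prof$contaminant))))
  refs <- make_reference_sequences(all_genera, sc$reference_length,
                                   seed = seed)
  cfg <- sim_config(sc$read_length, sc$error_rate, sc$reference_length)
  pairs <- counts_to_read_pairs(counts, refs, cfg, seed = seed,
                                mask_provenance = mask_provenance)
  spiked <- spike_contaminants(
    pairs, contaminant_spec(prof$contaminant, sc$contaminant_load),
    refs, cfg, seed = seed, n_reagent = sc$n_reagent, n_ntc = sc$n_ntc,
    reagent_load = sc$reagent_load, ntc_load = sc$ntc_load,
    mask_provenance = mask_provenance
  )
  out$pairs <- spiked$specimens
  out$controls <- spiked$controls
  out$refs <- refs
  out$cfg <- cfg
  out
}

## Distinct seed shift per group so group draws are independent substreams.
.group_seed_shift <- function(name) {
  shifts <- c(URT = 11L, background = 23L, unique = 37L, aspirate = 53L,
              bedding = 67L, chow = 79L, water = 97L)
  if (name %in% names(shifts)) shifts[[name]] else 113L
}

#' Write a scenario's sample metadata as TSV
#'
#' Columns: sample_id, site (URT, UL, LL, NTC, reagent, bedding, chow,
#' water), animal_id, role (specimen, control, environmental).
#'
#' @param metadata metadata data.frame from [simulate_scenario()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @param path path to a metadata TSV.
#' @export
read_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
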