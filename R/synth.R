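#' Group specification for the community simulator
#'
#' Bundles a genus profile with the sampling law used to draw samples from
#' it: per-sample sequencing depths are log-normal
#' (`depth_log_mean`/`depth_log_sd` on the natural-log scale) and
#' per-sample genus compositions are Dirichlet with concentration
#' `dispersion * profile` — larger `dispersion` keeps samples closer to the
#' group mean profile.
#'
#' @param profile a [genus_profile].
#' @param n_samples number of samples to draw (>= 1).
#' @param depth_log_mean,depth_log_sd log-scale depth parameters.
#' @param dispersion Dirichlet concentration scaler (> 0).
#' @param name group label; defaults to the profile's label.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(profile, n_samples, depth_log_mean, depth_log_sd,
                       dispersion, name = attr(profile, "name")) {
  stopifnot(inherits(profile, "genus_profile"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.finite(depth_log_sd) || depth_log_sd < 0) {
    stop("depth_log_sd must be finite and non-negative")
  }
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("dispersion must be positive and finite")
  }
  structure(
    list(profile = profile, n_samples = as.integer(n_samples),
         depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
         dispersion = dispersion, name = name),
    class = "group_spec"
  )
}

#' Generate reference amplicon sequences for a set of genera
#'
#' Draws one random reference sequence per genus over {A,C,G,T} and
#' enforces pairwise identity < 90% between any two references (colliding
#' sequences are regenerated), so that genus assignment at the 97% identity
#' threshold is unambiguous. Sequence length defaults to the 254-bp V4
#' amplicon.
#'
#' @param genera character vector of unique genus names.
#' @param length sequence length in bp (>= 250, so that the 250-bp
#'   decontamination rule can apply to full-length matches).
#' @param seed integer seed; output is a pure function of
#'   `(genera, length, seed)`.
#' @return named character vector of sequences (class `reference_set`).
#' @export
#' @examples
#' refs <- make_reference_sequences(c("Streptococcus", "Pseudomonas"),
#'                                  254, seed = 1)
#' nchar(refs)
make_reference_sequences <- function(genera, length = 254L, seed = 1L) {
  if (length(genera) == 0) stop("genus list must be non-empty")
  if (anyDuplicated(genera)) stop("genus names must be unique")
  if (length < 250) {
    stop("reference length must be >= 250 bp (decontamination rule needs ",
         ">= 250 bp matches)")
  }
  bases <- c("A", "C", "G", "T")
  draw <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(bases, length, replace = TRUE), collapse = "")
    }, character(1))
  }
  with_seed(seed, offset = .seed_offsets[["references"]], {
    seqs <- draw(length(genera))
    repeat {
      pid <- .pairwise_identity_cpp(seqs)
      diag(pid) <- 0
      bad <- which(apply(pid, 1, max) >= 0.90)
      if (length(bad) == 0) break
      seqs[bad] <- draw(length(bad))
    }
    names(seqs) <- genera
    class(seqs) <- "reference_set"
    seqs
  })
}

## Dirichlet draw; genera with zero concentration get exact zeros.
rdirichlet_one <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(x)
  if (s == 0) x[pos] <- 1 / sum(pos) else x <- x / s
  x
}

#' Simulate a genus count matrix for one group
#'
#' Per sample: depth ~ round(LogNormal(depth_log_mean, depth_log_sd)),
#' composition ~ Dirichlet(dispersion * profile), counts ~
#' Multinomial(depth, composition). Deterministic per seed.
#'
#' @param spec a [group_spec].
#' @param seed integer seed.
#' @param genera column set of the returned matrix; defaults to the
#'   profile's genera. Genera absent from the profile get zero counts.
#' @param sample_ids optional row names; default `<name>_01` ...
#' @return integer matrix (samples x genera) with named dimensions.
#' @export
simulate_counts <- function(spec, seed = 1L, genera = NULL,
                            sample_ids = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  p <- unclass(spec$profile)
  if (is.null(genera)) genera <- names(p)
  prof <- stats::setNames(numeric(length(genera)), genera)
  shared <- intersect(names(p), genera)
  if (length(shared) < length(p)) {
    stop("profile genera missing from requested genus set: ",
         paste(setdiff(names(p), genera), collapse = ", "))
  }
  prof[shared] <- p[shared]
  n <- spec$n_samples
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("%s_%02d", spec$name, seq_len(n))
  }
  with_seed(seed, offset = .seed_offsets[["counts"]], {
    depths <- round(stats::rlnorm(n, spec$depth_log_mean, spec$depth_log_sd))
    out <- matrix(0L, nrow = n, ncol = length(genera),
                  dimnames = list(sample_ids, genera))
    alpha <- spec$dispersion * prof
    for (i in seq_len(n)) {
      if (depths[i] <= 0) next
      pi <- rdirichlet_one(alpha)
      out[i, ] <- as.integer(stats::rmultinom(1, size = depths[i], prob = pi))
    }
    out
  })
}

#' Simulator configuration for read-level output
#'
#' @param read_length length of each read in the pair; the pair must
#'   overlap by at least 6 bp over the reference
#'   (`2 * read_length - reference length >= 6`).
#' @param error_rate per-base substitution probability in `[0, 0.25)`.
#' @param reference_length amplicon length the reads are drawn from.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(read_length = 150L, error_rate = 0.002,
                       reference_length = 254L) {
  if (2L * read_length - reference_length < 6L) {
    stop("reads cannot overlap by the minimum 6 bp: ",
         "2*read_length - reference_length < 6")
  }
  if (error_rate < 0 || error_rate >= 0.25) {
    stop("error_rate must be in [0, 0.25)")
  }
  structure(list(read_length = as.integer(read_length),
                 error_rate = error_rate,
                 reference_length = as.integer(reference_length)),
            class = "sim_config")
}

## One mutated batch of identical read pairs for a genus in a sample.
## Provenance (true genus) is carried in the read id for test oracles only;
## mask_provenance replaces it so inference can be shown not to use it.
make_pairs_for_genus <- function(ref, count, sample_id, genus, cfg,
                                 mask_provenance = FALSE) {
  L <- cfg$read_length
  n <- nchar(ref)
  fwd <- substr(ref, 1L, L)
  rev <- revcomp(substr(ref, n - L + 1L, n))
  fwds <- .mutate_seqs_cpp(rep(fwd, count), cfg$error_rate)
  revs <- .mutate_seqs_cpp(rep(rev, count), cfg$error_rate)
  tag <- if (mask_provenance) "masked" else genus
  data.frame(
    id = sprintf("%s|%s|%d", sample_id, tag, seq_len(count)),
    forward = fwds, reverse = revs, sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Expand a genus count matrix into error-bearing read pairs
#'
#' For a count of c in cell (sample, genus), emits exactly c read pairs:
#' the forward read is the first `read_length` bases of the genus
#' reference, the reverse read the reverse complement of the last
#' `read_length` bases, and every base is independently substituted with
#' probability `error_rate`. Read ids carry the sample and true genus for
#' test oracles; inference never reads them (set `mask_provenance = TRUE`
#' to verify).
#'
#' @param counts integer matrix from [simulate_counts()].
#' @param refs [make_reference_sequences()] output covering every genus
#'   with a nonzero count.
#' @param cfg a [sim_config].
#' @param seed integer seed (per-sample substreams, so adding samples does
#'   not perturb earlier ones).
#' @param mask_provenance replace the true genus in read ids.
#' @return data.frame with columns `id`, `forward`, `reverse`, `sample_id`
#'   (class `read_pairs`).
#' @export
counts_to_read_pairs <- function(counts, refs, cfg, seed = 1L,
                                 mask_provenance = FALSE) {
  used <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(used, names(refs))
  if (length(missing) > 0) {
    stop("no reference sequence for genus: ",
         paste(missing, collapse = ", "))
  }
  chunks <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    sid <- rownames(counts)[i]
    row <- counts[i, ]
    nz <- which(row > 0)
    if (length(nz) == 0) {
      chunks[[i]] <- NULL
      next
    }
    chunks[[i]] <- with_seed(seed + i, offset = .seed_offsets[["reads"]], {
      do.call(rbind, lapply(nz, function(j) {
        g <- colnames(counts)[j]
        make_pairs_for_genus(refs[[g]], row[j], sid, g, cfg,
                             mask_provenance)
      }))
    })
  }
  out <- do.call(rbind, chunks)
  if (is.null(out)) {
    out <- data.frame(id = character(), forward = character(),
                      reverse = character(), sample_id = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Contaminant specification
#'
#' @param profile contaminant [genus_profile] (default: the reagent
#'   community dominated by Pseudomonas 53% / Escherichia 15%).
#' @param load expected contaminant read pairs spiked into each specimen
#'   sample (Poisson mean, >= 0).
#' @return an object of class `contaminant_spec`.
#' @export
contaminant_spec <- function(profile = default_profiles()$contaminant,
                             load = 100) {
  stopifnot(inherits(profile, "genus_profile"))
  if (load < 0) stop("contaminant load must be >= 0")
  structure(list(profile = profile, load = load),
            class = "contaminant_spec")
}

## Draw a contaminant read collection of Poisson(load) pairs for one sample.
spike_one_sample <- function(sample_id, spec, refs, cfg,
                             mask_provenance = FALSE) {
  n <- stats::rpois(1, spec$load)
  if (n == 0) return(NULL)
  p <- unclass(spec$profile)
  genus_draw <- as.integer(stats::rmultinom(1, n, p))
  chunks <- lapply(which(genus_draw > 0), function(j) {
    g <- names(p)[j]
    make_pairs_for_genus(refs[[g]], genus_draw[j], sample_id, g, cfg,
                         mask_provenance)
  })
  do.call(rbind, chunks)
}

#' Spike reagent contamination into specimens and emit control samples
#'
#' Every specimen sample gains Poisson(`spec$load`) contaminant read pairs
#' drawn from the contaminant profile. In addition, reagent-control and
#' no-template-control (NTC) samples are emitted containing ONLY
#' contaminant-derived reads, mirroring the negative controls sequenced
#' alongside tissue. Deterministic per seed.
#'
#' @param pairs specimen `read_pairs` from [counts_to_read_pairs()].
#' @param spec a [contaminant_spec].
#' @param refs references covering the contaminant genera.
#' @param cfg a [sim_config].
#' @param seed integer seed.
#' @param n_reagent,n_ntc number of reagent controls / NTCs.
#' @param reagent_load,ntc_load Poisson mean reads per control.
#' @param mask_provenance replace true genus in read ids.
#' @return list with elements `specimens` (augmented pairs) and `controls`
#'   (read pairs for samples `reagent_01`.. and `NTC_01`..).
#' @export
spike_contaminants <- function(pairs, spec, refs, cfg, seed = 1L,
                               n_reagent = 8L, n_ntc = 3L,
                               reagent_load = 800, ntc_load = 30,
                               mask_provenance = FALSE) {
  missing <- setdiff(names(spec$profile), names(refs))
  if (length(missing) > 0) {
    stop("no reference sequence for contaminant genus: ",
         paste(missing, collapse = ", "))
  }
  sample_ids <- unique(pairs$sample_id)
  spiked <- with_seed(seed, offset = .seed_offsets[["spike"]], {
    do.call(rbind, lapply(sample_ids, function(sid) {
      spike_one_sample(sid, spec, refs, cfg, mask_provenance)
    }))
  })
  control_ids <- c(sprintf("reagent_%02d", seq_len(n_reagent)),
                   sprintf("NTC_%02d", seq_len(n_ntc)))
  loads <- c(rep(reagent_load, n_reagent), rep(ntc_load, n_ntc))
  controls <- with_seed(seed + 1L, offset = .seed_offsets[["spike"]], {
    do.call(rbind, lapply(seq_along(control_ids), function(i) {
      cspec <- spec
      cspec$load <- loads[i]
      spike_one_sample(control_ids[i], cspec, refs, cfg, mask_provenance)
    }))
  })
  specimens <- rbind(pairs, spiked)
  rownames(specimens) <- NULL
  if (is.null(controls)) {
    controls <- pairs[0, ]
  } else {
    rownames(controls) <- NULL
  }
  class(specimens) <- class(controls) <- c("read_pairs", "data.frame")
  list(specimens = specimens, controls = controls)
}
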