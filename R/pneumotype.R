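#' Classify lung samples into pneumotypes
#'
#' Fits the three-way pneumotype classification of lung microbiome
#' samples:
#'
#' 1. **Background rule** — lung samples whose total retained read count
#'    falls strictly below `background_threshold` (default 50) are
#'    labelled `background`; their composition is indistinguishable from
#'    the no-template water controls, so they carry no evaluable
#'    community. A Bray-Curtis distance to the NTC centroid is reported
#'    as QC for each background sample but never gates the decision.
#' 2. **Initialisation** — every remaining lung sample is provisionally
#'    labelled `aspirate` when its Pearson correlation (log2 scale) to
#'    the URT representative microbiome reaches `corr_threshold`
#'    (default 0.6), else `unique`.
#' 3. **Iterative refinement** — the aspirate and unique representative
#'    profiles are recomputed from the current members and every sample
#'    is reassigned to the better-correlated profile (a two-group Pearson
#'    analogue of k-means), until the labels stabilise or `max_iter` is
#'    reached. Exact correlation ties go to `tie_policy` (default
#'    `"unique"`, the conservative choice that avoids inflating the
#'    URT-like group). If either group empties, iteration stops with the
#'    current labels.
#'
#' Upper- and lower-lobe samples (sites `UL`, `LL`) are pooled as
#' "lung"; URT, control and environmental samples never receive a
#' pneumotype label.
#'
#' @param counts genus count matrix (samples x genera) after
#'   decontamination; an `"unassigned"` column, if present, is dropped
#'   before classification.
#' @param metadata data.frame with columns `sample_id`, `site` (URT, UL,
#'   LL, NTC, reagent, bedding, chow, water) and `role`.
#' @param background_threshold read-count floor for the background rule.
#' @param corr_threshold initial URT-correlation threshold.
#' @param max_iter iteration cap (>= 1).
#' @param tie_policy label awarded on an exact correlation tie.
#' @param method correlation type for all comparisons.
#' @return an object of class `pneumotype`: a list with `labels` (named
#'   character vector over the lung samples), `iterations`, `converged`,
#'   `trace` (per-iteration label matrix), `correlations` (per-sample
#'   correlation to the final aspirate/unique/URT profiles), `profiles`
#'   (representative log2 profiles of the three groups), `ntc_qc`
#'   (Bray-Curtis to the NTC centroid for background samples), `totals`,
#'   and the configuration.
#' @export
#' @examples
#' sim <- simulate_scenario(scenario_paper_default(n_animals = 4), seed = 1)
#' fit <- pneumotype(sim$counts, sim$metadata)
#' table(fit$labels)
pneumotype <- function(counts, metadata,
                       background_threshold = 50,
                       corr_threshold = 0.6,
                       max_iter = 20L,
                       tie_policy = c("unique", "aspirate"),
                       method = c("pearson", "spearman")) {
  tie_policy <- match.arg(tie_policy)
  method <- match.arg(method)
  stopifnot(background_threshold >= 0, max_iter >= 1,
            corr_threshold > 0, corr_threshold < 1)
  counts <- drop_unassigned(counts)
  meta <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata missing for sample(s): ",
         paste(setdiff(rownames(counts), metadata$sample_id),
               collapse = ", "))
  }
  lung_ids <- meta$sample_id[meta$site %in% c("UL", "LL")]
  urt_ids <- meta$sample_id[meta$site == "URT"]
  ntc_ids <- meta$sample_id[meta$site == "NTC"]
  if (length(lung_ids) == 0) stop("no lung (UL/LL) samples to classify")
  if (length(urt_ids) == 0) stop("no URT samples to anchor initialisation")

  totals <- rowSums(counts[lung_ids, , drop = FALSE])
  labels <- stats::setNames(rep(NA_character_, length(lung_ids)), lung_ids)
  labels[totals < background_threshold] <- "background"
  active <- lung_ids[is.na(labels)]

  lmat <- log2_transform(counts)
  urt_prof <- representative_profile(lmat, urt_ids, "URT")

  iterations <- 0L
  converged <- TRUE
  trace <- NULL
  corr_asp <- corr_uni <- stats::setNames(rep(NA_real_, length(lung_ids)),
                                          lung_ids)
  asp_prof <- uni_prof <- NULL
  if (length(active) > 0) {
    corr_urt_init <- vapply(active, function(s) {
      correlation_to_profile(lmat[s, ], urt_prof, method)
    }, numeric(1))
    labels[active] <- ifelse(corr_urt_init >= corr_threshold,
                             "aspirate", "unique")
    trace <- matrix(labels[active], nrow = 1,
                    dimnames = list(NULL, active))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- it
      asp <- active[labels[active] == "aspirate"]
      uni <- active[labels[active] == "unique"]
      if (length(asp) == 0 || length(uni) == 0) {
        converged <- TRUE
        break
      }
      asp_prof <- representative_profile(lmat, asp, "aspirate")
      uni_prof <- representative_profile(lmat, uni, "unique")
      ca <- vapply(active, function(s) {
        correlation_to_profile(lmat[s, ], asp_prof, method)
      }, numeric(1))
      cu <- vapply(active, function(s) {
        correlation_to_profile(lmat[s, ], uni_prof, method)
      }, numeric(1))
      new_labels <- ifelse(ca > cu, "aspirate",
                           ifelse(cu > ca, "unique", tie_policy))
      corr_asp[active] <- ca
      corr_uni[active] <- cu
      trace <- rbind(trace, new_labels)
      if (all(new_labels == labels[active])) {
        converged <- TRUE
        break
      }
      labels[active] <- new_labels
    }
  }

  # final group profiles over the classified samples
  profiles <- list(URT = urt_prof)
  for (pt in c("aspirate", "unique")) {
    ids <- names(labels)[labels == pt]
    if (length(ids) > 0) {
      profiles[[pt]] <- representative_profile(lmat, ids, pt)
    }
  }
  corr_urt <- stats::setNames(rep(NA_real_, length(lung_ids)), lung_ids)
  for (s in lung_ids) {
    if (stats::sd(lmat[s, ]) > 0) {
      corr_urt[s] <- correlation_to_profile(lmat[s, ], urt_prof, method)
    }
  }

  # QC: Bray-Curtis of each background sample to the NTC centroid
  ntc_qc <- NULL
  bg <- names(labels)[labels == "background"]
  if (length(bg) > 0 && length(ntc_ids) > 0) {
    centroid <- colMeans(counts[ntc_ids, , drop = FALSE])
    ntc_qc <- vapply(bg, function(s) {
      x <- counts[s, ]
      if (sum(x) + sum(centroid) == 0) return(NA_real_)
      sum(abs(x - centroid)) / sum(x + centroid)
    }, numeric(1))
  }

  structure(
    list(labels = labels, iterations = iterations, converged = converged,
         trace = trace,
         correlations = data.frame(sample_id = lung_ids,
                                   total_reads = as.numeric(totals),
                                   corr_urt = as.numeric(corr_urt),
                                   corr_aspirate = as.numeric(corr_asp),
                                   corr_unique = as.numeric(corr_uni),
                                   label = as.character(labels),
                                   stringsAsFactors = FALSE),
         profiles = profiles, ntc_qc = ntc_qc, totals = totals,
         config = list(background_threshold = background_threshold,
                       corr_threshold = corr_threshold,
                       max_iter = max_iter, tie_policy = tie_policy,
                       method = method),
         genera = colnames(counts)),
    class = "pneumotype"
  )
}

#' @export
print.pneumotype <- function(x, ...) {
  cat("Pneumotype classification of", length(x$labels), "lung samples\n")
  tab <- table(factor(x$labels,
                      levels = c("background", "aspirate", "unique")))
  cat(sprintf("  %-10s %3d (%.0f%%)\n", names(tab), as.integer(tab),
              100 * as.integer(tab) / length(x$labels)), sep = "")
  cat("Converged:", x$converged, "after", x$iterations, "iteration(s)\n")
  invisible(x)
}

#' @export
summary.pneumotype <- function(object, ...) {
  cat("Pneumotype fit\n")
  print(object)
  cat("\nConfig: background <", object$config$background_threshold,
      "reads; initial URT correlation >=", object$config$corr_threshold,
      "; ties ->", object$config$tie_policy, "\n")
  cf <- object$correlations
  for (pt in c("aspirate", "unique")) {
    v <- cf$corr_urt[cf$label == pt]
    if (length(v) > 0) {
      cat(sprintf("  %s: mean correlation to URT profile %.2f\n", pt,
                  mean(v, na.rm = TRUE)))
    }
  }
  if (!is.null(object$ntc_qc)) {
    cat(sprintf("  background: median Bray-Curtis to NTC centroid %.2f\n",
                stats::median(object$ntc_qc, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
coef.pneumotype <- function(object, ...) {
  m <- do.call(cbind, lapply(object$profiles, as.numeric))
  rownames(m) <- object$genera
  m
}

#' Classify new samples with a fitted pneumotype model
#'
#' Applies the fitted background rule and the final representative
#' profiles to new count rows (columns matched by genus name; genera
#' unseen at fit time are ignored, missing genera treated as zero).
#'
#' @param object a [pneumotype] fit.
#' @param newdata count matrix of new samples.
#' @param ... unused.
#' @return named character vector of labels.
#' @export
predict.pneumotype <- function(object, newdata, ...) {
  newdata <- drop_unassigned(as.matrix(newdata))
  full <- matrix(0, nrow(newdata), length(object$genera),
                 dimnames = list(rownames(newdata), object$genera))
  shared <- intersect(colnames(newdata), object$genera)
  full[, shared] <- newdata[, shared]
  totals <- rowSums(full)
  lmat <- log2_transform(full)
  out <- stats::setNames(rep(NA_character_, nrow(full)), rownames(full))
  out[totals < object$config$background_threshold] <- "background"
  active <- names(out)[is.na(out)]
  asp <- object$profiles$aspirate
  uni <- object$profiles$unique
  for (s in active) {
    if (is.null(asp) || is.null(uni)) {
      cu <- correlation_to_profile(lmat[s, ], object$profiles$URT,
                                   object$config$method)
      out[s] <- if (cu >= object$config$corr_threshold) "aspirate" else
        "unique"
    } else {
      ca <- correlation_to_profile(lmat[s, ], asp, object$config$method)
      cu <- correlation_to_profile(lmat[s, ], uni, object$config$method)
      out[s] <- if (ca > cu) "aspirate" else if (cu > ca) "unique" else
        object$config$tie_policy
    }
  }
  out
}

#' Plot a pneumotype fit
#'
#' Scatter of each non-background lung sample's correlation to the final
#' aspirate profile against its correlation to the unique profile,
#' coloured by assigned label; background samples are omitted (they carry
#' no evaluable community).
#'
#' @param x a [pneumotype] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pneumotype <- function(x, ...) {
  cf <- x$correlations
  cf <- cf[cf$label != "background" & !is.na(cf$corr_aspirate), ]
  if (nrow(cf) == 0) {
    warning("no non-background samples to plot")
    return(invisible(x))
  }
  cols <- c(aspirate = "#1b9e77", unique = "#d95f02")
  graphics::plot(cf$corr_unique, cf$corr_aspirate,
                 col = cols[cf$label], pch = 19,
                 xlab = "correlation to unique profile",
                 ylab = "correlation to aspirate profile", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::legend("bottomleft", legend = names(cols), col = cols,
                   pch = 19, bty = "n")
  invisible(x)
}
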