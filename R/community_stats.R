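#' Normalise counts to per-sample proportions
#'
#' Each row is scaled to total 100%. All-zero rows are left at zero and
#' flagged in the `"zero_rows"` attribute.
#'
#' @param counts numeric matrix (samples x genera).
#' @return matrix of row percentages with attribute `zero_rows`.
#' @export
#' @examples
#' to_proportions(rbind(s1 = c(a = 10, b = 30)))
to_proportions <- function(counts) {
  totals <- rowSums(counts)
  out <- counts
  nz <- totals > 0
  out[nz, ] <- 100 * counts[nz, , drop = FALSE] / totals[nz]
  out[!nz, ] <- 0
  attr(out, "zero_rows") <- rownames(counts)[!nz]
  out
}

#' Log2-transform a count matrix
#'
#' Elementwise `log2(count + pseudocount)`. The default pseudocount of 1
#' keeps zero counts at 0 and preserves monotonicity; the published
#' transform does not state its handling of zeros.
#'
#' @param counts numeric matrix.
#' @param pseudocount additive constant (> 0).
#' @return matrix of the same shape.
#' @export
log2_transform <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  out <- log2(counts + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Representative microbiome of a group
#'
#' The per-genus arithmetic mean of log2-transformed counts over the
#' group's member samples; the basis of the correlation comparisons and
#' of pneumotype classification.
#'
#' @param log2_matrix matrix from [log2_transform()].
#' @param members sample ids (row names) of the group.
#' @param name group label.
#' @return named numeric vector over the full genus set (class
#'   `representative_profile`, attributes `name` and `n_samples`).
#' @export
representative_profile <- function(log2_matrix, members,
                                   name = "group") {
  if (length(members) == 0) stop("member set must be non-empty")
  missing <- setdiff(members, rownames(log2_matrix))
  if (length(missing) > 0) {
    stop("members not in matrix: ", paste(missing, collapse = ", "))
  }
  prof <- colMeans(log2_matrix[members, , drop = FALSE])
  structure(prof, name = name, n_samples = length(members),
            class = "representative_profile")
}

#' Correlate a sample against a representative microbiome
#'
#' Pearson (default) or Spearman correlation between a sample's log2
#' abundance vector and a group's representative profile, computed across
#' the full genus set.
#'
#' @param sample_log2 named numeric vector (one row of a log2 matrix).
#' @param profile a [representative_profile()].
#' @param method `"pearson"` or `"spearman"`.
#' @return a correlation coefficient in \[-1, 1\].
#' @export
correlation_to_profile <- function(sample_log2, profile,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(sort(names(sample_log2)), sort(names(profile)))) {
    stop("sample and profile must share the same genus set")
  }
  if (length(sample_log2) < 3) stop("need at least 3 genera")
  x <- sample_log2[names(profile)]
  if (stats::sd(x) == 0 || stats::sd(profile) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(as.numeric(x), as.numeric(profile), method = method)
}

#' Mean correlation of a group's members against a reference profile
#'
#' Computes, for every member of group A, its correlation to group B's
#' representative profile, and the mean of those values. In the
#' intra-group case (A = B) each member is compared against the profile
#' computed from all of A's members; set `leave_one_out = TRUE` to
#' exclude the member from its own reference profile instead.
#'
#' @param log2_matrix matrix from [log2_transform()].
#' @param members sample ids of group A.
#' @param ref_members sample ids defining the reference profile (group B;
#'   default the same as `members`).
#' @param method correlation type.
#' @param leave_one_out exclude each member from its own reference
#'   profile (intra-group case only).
#' @return list with `mean` and named `per_sample` correlations.
#' @export
group_correlation <- function(log2_matrix, members,
                              ref_members = members,
                              method = c("pearson", "spearman"),
                              leave_one_out = FALSE) {
  method <- match.arg(method)
  vals <- vapply(members, function(s) {
    ref <- ref_members
    if (leave_one_out && s %in% ref) {
      ref <- setdiff(ref, s)
      if (length(ref) == 0) stop("leave-one-out leaves an empty group")
    }
    prof <- representative_profile(log2_matrix, ref)
    correlation_to_profile(log2_matrix[s, ], prof, method)
  }, numeric(1))
  list(mean = mean(vals), per_sample = vals)
}

#' Percent overlap between two sample groups
#'
#' The community-sharing statistic: over the pooled samples P of groups A
#' and B, every genus detected in both groups contributes its total
#' pooled count multiplied by the fraction of pooled samples containing
#' it; the sum is divided by the total pooled count and expressed as a
#' percentage. The intra-group case (A = B) spans all detected genera, so
#' a group scores 100 only when every detected genus occurs in every
#' sample. With `method = "literal"` the alternative reading of the
#' published wording — per-genus average count rather than total — is
#' used; it scales values down by roughly the number of samples and is
#' retained for comparison only.
#'
#' @param counts count matrix (samples x genera).
#' @param members_a,members_b sample ids of the two groups (identical for
#'   intra-group overlap).
#' @param method `"pooled"` (default) or `"literal"`.
#' @return percent overlap in \[0, 100\].
#' @export
#' @examples
#' m <- rbind(s1 = c(a = 10, b = 0), s2 = c(a = 0, b = 10))
#' overlap(m, c("s1", "s2"), c("s1", "s2"))  # 50
overlap <- function(counts, members_a, members_b = members_a,
                    method = c("pooled", "literal")) {
  method <- match.arg(method)
  if (length(members_a) == 0 || length(members_b) == 0) {
    stop("both groups must be non-empty")
  }
  pooled <- union(members_a, members_b)
  sub <- counts[pooled, , drop = FALSE]
  n_p <- sum(sub)
  if (n_p == 0) stop("pooled samples contain no counts")
  det_a <- colnames(counts)[colSums(counts[members_a, , drop = FALSE] > 0) > 0]
  det_b <- colnames(counts)[colSums(counts[members_b, , drop = FALSE] > 0) > 0]
  shared <- intersect(det_a, det_b)
  if (length(shared) == 0) return(0)
  t_g <- colSums(sub[, shared, drop = FALSE])
  f_g <- colMeans(sub[, shared, drop = FALSE] > 0)
  if (method == "literal") t_g <- t_g / nrow(sub)
  100 * sum(t_g * f_g) / n_p
}

#' Overlap matrix across groups
#'
#' @param counts count matrix.
#' @param groups named list of sample-id vectors.
#' @param method passed to [overlap()].
#' @return symmetric matrix of percent overlaps (class `overlap_matrix`).
#' @export
overlap_matrix <- function(counts, groups, method = "pooled") {
  k <- length(groups)
  out <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                                names(groups)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- overlap(counts, groups[[i]], groups[[j]], method = method)
      out[i, j] <- out[j, i] <- v
    }
  }
  structure(out, method = method, class = c("overlap_matrix", "matrix"))
}

#' Group mean-abundance report at a display threshold
#'
#' Per group, the mean of per-sample proportion rows (percent). A genus is
#' listed when its mean abundance strictly exceeds the threshold in ANY
#' group; all other genera are suppressed. This mirrors the published
#' group-composition tables reported at the >1% level.
#'
#' @param counts count matrix.
#' @param groups named list of sample-id vectors.
#' @param threshold display threshold in percent (default 1).
#' @return matrix (genera x groups) of mean percentages, `NA` ("-" when
#'   printed) where a genus was not detected in that group; attribute
#'   `threshold`.
#' @export
abundance_report <- function(counts, groups, threshold = 1) {
  props <- to_proportions(counts)
  means <- vapply(groups, function(m) {
    colMeans(props[m, , drop = FALSE])
  }, numeric(ncol(counts)))
  keep <- apply(means > threshold, 1, any)
  out <- means[keep, , drop = FALSE]
  out[out == 0] <- NA_real_
  out <- out[order(rownames(out)), , drop = FALSE]
  structure(out, threshold = threshold, class = c("abundance_report",
                                                  "matrix"))
}

#' @export
print.abundance_report <- function(x, digits = 2, ...) {
  cat("Mean relative abundance (%) of genera >",
      attr(x, "threshold"), "% in any group\n")
  disp <- format(round(unclass(x), digits), nsmall = digits)
  disp[is.na(unclass(x))] <- "-"
  print(disp, quote = FALSE)
  invisible(x)
}
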