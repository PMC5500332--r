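#' Chao1 richness estimate for one sample
#'
#' Classic Chao1: `S_obs + F1^2 / (2 F2)` where `F1`/`F2` are the numbers
#' of singleton and doubleton genera. When no doubletons exist the
#' bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used (the
#' classic form is undefined at F2 = 0).
#'
#' @param x non-negative integer count vector for one sample.
#' @return list of class `chao1` with `S_obs`, `F1`, `F2`, `estimate`,
#'   `bias_corrected` (logical branch indicator).
#' @export
#' @examples
#' chao1(c(5, 5, 1, 1, 1, 1, 2, 2, 9, 4))$estimate  # 10 + 16/4 = 14
chao1 <- function(x) {
  if (any(x < 0) || any(x != floor(x))) {
    stop("counts must be non-negative integers")
  }
  if (sum(x) == 0) stop("Chao1 undefined for an all-zero sample")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    bc <- FALSE
  } else {
    est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    bc <- TRUE
  }
  structure(list(S_obs = s_obs, F1 = f1, F2 = f2, estimate = est,
                 bias_corrected = bc), class = "chao1")
}

#' @export
print.chao1 <- function(x, ...) {
  cat(sprintf("Chao1 = %.2f (S_obs %d, F1 %d, F2 %d%s)\n", x$estimate,
              x$S_obs, x$F1, x$F2,
              if (x$bias_corrected) ", bias-corrected" else ""))
  invisible(x)
}

#' Rarefy one sample to a fixed depth
#'
#' Subsamples reads without replacement to exactly `depth` reads;
#' deterministic per seed.
#'
#' @param x non-negative integer count vector (total >= depth).
#' @param depth target read depth.
#' @param seed integer seed.
#' @return integer vector of the same length and names, summing to
#'   `depth`.
#' @export
rarefy_counts <- function(x, depth, seed = 1L) {
  if (sum(x) < depth) {
    stop("sample total (", sum(x), ") below rarefaction depth (", depth,
         ")")
  }
  with_seed(seed, offset = .seed_offsets[["rarefy"]], {
    pool <- rep.int(seq_along(x), x)
    keep <- sample(pool, depth)
    out <- tabulate(keep, nbins = length(x))
    names(out) <- names(x)
    out
  })
}

#' Chao1 rarefaction curve for one sample
#'
#' At each depth, the mean and SD (sample standard deviation, n-1
#' denominator) of the Chao1 estimate over `n_reps` independent random
#' subsamplings. The published curves use 50 samplings up to a final
#' depth of 340 reads.
#'
#' @param x count vector.
#' @param depths increasing depths (all <= sample total).
#' @param n_reps random subsamplings per depth (default 50).
#' @param seed integer seed.
#' @return data.frame with columns `depth`, `mean`, `sd`, `n_reps`.
#' @export
rarefaction_curve <- function(x, depths = seq(20, 340, by = 40),
                              n_reps = 50L, seed = 1L) {
  if (max(depths) > sum(x)) {
    stop("maximum depth exceeds the sample total (", sum(x), ")")
  }
  rows <- lapply(seq_along(depths), function(i) {
    vals <- vapply(seq_len(n_reps), function(r) {
      chao1(rarefy_counts(x, depths[i],
                          seed = seed + 1000L * i + r))$estimate
    }, numeric(1))
    data.frame(depth = depths[i], mean = mean(vals),
               sd = if (n_reps > 1) stats::sd(vals) else 0,
               n_reps = n_reps)
  })
  do.call(rbind, rows)
}

#' Inverse Simpson diversity of one sample
#'
#' `1 / sum(p_i^2)` over genus proportions — the effective number of
#' equally abundant genera; the probability-based view is that it grows
#' as two randomly drawn reads become less likely to share a genus.
#'
#' @param x count (or proportion) vector with positive total.
#' @return diversity number >= 1.
#' @export
#' @examples
#' inverse_simpson(c(1, 1, 1, 1, 1))  # 5
inverse_simpson <- function(x) {
  tot <- sum(x)
  if (tot <= 0) stop("inverse Simpson undefined for a zero-total sample")
  p <- x / tot
  1 / sum(p^2)
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)` between two count rows.
#'
#' @param x,y non-negative vectors over the same genera.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (sum(x) + sum(y) == 0) stop("Bray-Curtis undefined for two zero rows")
  sum(abs(x - y)) / sum(x + y)
}

#' Bray-Curtis distance matrix
#'
#' @param counts count matrix (samples x genera); zero-total rows are not
#'   allowed.
#' @return a `dist` object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(counts) {
  if (any(rowSums(counts) == 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  }
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts),
                                       rownames(counts)))
  for (i in seq_len(n - 1)) {
    xi <- counts[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(xi, counts[j, ])
    }
  }
  stats::as.dist(d)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational analysis of variance: the total sum of squares of the
#' distance matrix is partitioned into among- and within-group parts,
#' giving the pseudo-F statistic
#' `F = (SS_among / (k - 1)) / (SS_within / (n - k))`. Significance is
#' assessed by permuting the group labels (`n_permutations` times,
#' default 999) and the p-value uses the add-one rule
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, so p is never
#' exactly zero. Deterministic per seed.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, each with >= 2
#'   members).
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return list of class `permanova` with `F`, `p_value`, `R2`,
#'   `n_permutations`, `df_among`, `df_within`.
#' @export
permanova <- function(d, labels, n_permutations = 999L, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match the distance matrix")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 members each")
  }
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  k <- length(tab)
  sw <- ss_within(labels)
  sa <- ss_total - sw
  f_obs <- (sa / (k - 1)) / (sw / (n - k))
  r2 <- sa / ss_total
  f_perm <- with_seed(seed, offset = .seed_offsets[["permanova"]], {
    vapply(seq_len(n_permutations), function(i) {
      lab <- sample(labels)
      swp <- ss_within(lab)
      ((ss_total - swp) / (k - 1)) / (swp / (n - k))
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(F = f_obs, p_value = p, R2 = r2,
                 n_permutations = as.integer(n_permutations),
                 df_among = k - 1L, df_within = n - k),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
    x$df_among, x$df_within, x$F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' One-factor PERMANOVA per factor
#'
#' Runs the one-factor procedure separately for each column of a factor
#' table and reports each factor's pseudo-F, R-squared and p-value side
#' by side; full multi-factor variance partitioning is deliberately not
#' attempted.
#'
#' @param d a `dist` or distance matrix.
#' @param factors data.frame of grouping columns (rows aligned with `d`).
#' @param n_permutations,seed passed to [permanova()].
#' @return data.frame with one row per factor: `factor`, `F`, `R2`,
#'   `p_value`.
#' @export
permanova_factors <- function(d, factors, n_permutations = 999L,
                              seed = 1L) {
  rows <- lapply(names(factors), function(f) {
    res <- permanova(d, factors[[f]], n_permutations, seed)
    data.frame(factor = f, F = res$F, R2 = res$R2,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group alpha diversity table
#'
#' Chao1 (after rarefying every sample to a common depth) and inverse
#' Simpson for each sample, with its group. Samples below the
#' rarefaction depth are skipped with a warning, so shallow samples do
#' not abort a group comparison.
#'
#' @param counts count matrix.
#' @param groups named list of sample-id vectors.
#' @param depth rarefaction depth for Chao1 (default 340 reads).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `group`,
#'   `chao1_rarefied` (NA when skipped), `inverse_simpson`.
#' @export
alpha_diversity_table <- function(counts, groups, depth = 340L,
                                  seed = 1L) {
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    do.call(rbind, lapply(ids, function(s) {
      x <- counts[s, ]
      ch <- if (sum(x) >= depth) {
        chao1(rarefy_counts(x, depth, seed = seed + sum(utf8ToInt(s))))$
          estimate
      } else {
        warning("sample ", s, " below rarefaction depth ", depth,
                "; Chao1 skipped", call. = FALSE)
        NA_real_
      }
      data.frame(sample_id = s, group = g, chao1_rarefied = ch,
                 inverse_simpson = if (sum(x) > 0) inverse_simpson(x)
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
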