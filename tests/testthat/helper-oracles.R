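# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (double loops, no shared code with the package
# internals) so that agreement is meaningful.

oracle_overlap <- function(counts, members_a, members_b) {
  pooled <- union(members_a, members_b)
  n_p <- 0
  for (s in pooled) n_p <- n_p + sum(counts[s, ])
  total <- 0
  for (g in colnames(counts)) {
    in_a <- FALSE
    for (s in members_a) if (counts[s, g] > 0) in_a <- TRUE
    in_b <- FALSE
    for (s in members_b) if (counts[s, g] > 0) in_b <- TRUE
    if (!(in_a && in_b)) next
    t_g <- 0
    n_with <- 0
    for (s in pooled) {
      t_g <- t_g + counts[s, g]
      if (counts[s, g] > 0) n_with <- n_with + 1
    }
    total <- total + t_g * (n_with / length(pooled))
  }
  100 * total / n_p
}

oracle_chao1 <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_inverse_simpson <- function(x) {
  p <- x / sum(x)
  1 / sum(p * p)
}

oracle_bray_curtis <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# Character-level identity of two equal-length strings.
oracle_string_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force contaminant matching: all ungapped offsets of query against
# every control sequence, both orientations; TRUE when any alignment of
# >= min_len columns reaches >= min_ident.
oracle_match <- function(query, controls, min_len = 250,
                         min_ident = 0.99, check_rc = TRUE) {
  queries <- query
  if (check_rc) queries <- c(query, oracle_revcomp(query))
  for (q in queries) {
    vq <- strsplit(q, "")[[1]]
    for (ctl in controls) {
      vc <- strsplit(ctl, "")[[1]]
      lq <- length(vq)
      lc <- length(vc)
      for (off in seq(-lq + 1, lc - 1)) {
        qs <- max(1, 1 - off)
        cs <- max(1, 1 + off)
        len <- min(lq - qs + 1, lc - cs + 1)
        if (len < min_len) next
        m <- sum(vq[qs:(qs + len - 1)] == vc[cs:(cs + len - 1)])
        if (m / len >= min_ident) return(TRUE)
      }
    }
  }
  FALSE
}

random_count_matrix <- function(n_samples, n_genera, max_count = 50,
                                zero_prob = 0.4) {
  m <- matrix(
    ifelse(stats::runif(n_samples * n_genera) < zero_prob, 0L,
           sample.int(max_count, n_samples * n_genera, replace = TRUE)),
    nrow = n_samples,
    dimnames = list(paste0("s", seq_len(n_samples)),
                    paste0("g", seq_len(n_genera)))
  )
  storage.mode(m) <- "integer"
  m
}

random_dna <- function(n, length = 254) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Substitute exactly k positions of a sequence.
mutate_at <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) {
    v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  }
  paste(v, collapse = "")
}
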