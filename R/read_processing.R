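#' Filtering configuration
#'
#' Houses the decontamination and assignment thresholds: specimen contigs
#' matching any negative-control contig at >= 99% identity over >= 250
#' aligned bases are removed; read pairs must overlap by >= 6 bp to join;
#' contigs are assigned to the reference genus with the highest identity
#' when that identity exceeds 97%.
#'
#' @param identity_threshold contaminant-match identity (default 0.99).
#' @param min_match_length minimum aligned bases for a contaminant match
#'   (default 250).
#' @param min_join_overlap minimum pair overlap in bp (default 6).
#' @param join_identity minimum identity inside the join overlap
#'   (default 0.9; the published rule states only the 6-bp minimum).
#' @param assign_identity_threshold genus-assignment identity; assignment
#'   requires identity strictly greater than this (default 0.97).
#' @param check_reverse_complement also match contigs in reverse
#'   complement orientation (default TRUE).
#' @param k k-mer size of the contaminant prefilter (default 31; any
#'   match of 250 bp or more at 99% identity contains an exact 31-mer).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(identity_threshold = 0.99,
                          min_match_length = 250L,
                          min_join_overlap = 6L,
                          join_identity = 0.9,
                          assign_identity_threshold = 0.97,
                          check_reverse_complement = TRUE,
                          k = 31L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            assign_identity_threshold > 0, assign_identity_threshold <= 1,
            join_identity > 0, join_identity <= 1,
            min_match_length >= 1, min_join_overlap >= 1, k >= 1)
  structure(list(identity_threshold = identity_threshold,
                 min_match_length = as.integer(min_match_length),
                 min_join_overlap = as.integer(min_join_overlap),
                 join_identity = join_identity,
                 assign_identity_threshold = assign_identity_threshold,
                 check_reverse_complement = isTRUE(check_reverse_complement),
                 k = as.integer(k)),
            class = "filter_config")
}

#' Join paired reads into contigs
#'
#' Merges each forward read with the reverse complement of its reverse
#' read over the largest suffix/prefix overlap of at least
#' `min_join_overlap` bases whose identity reaches `join_identity`;
#' mismatches inside the overlap are resolved in favour of the forward
#' read. Pairs with no qualifying overlap are returned unjoined (a value,
#' not an error).
#'
#' @param pairs a `read_pairs` data.frame (columns `id`, `forward`,
#'   `reverse`, `sample_id`).
#' @param cfg a [filter_config].
#' @return data.frame of class `contigs` with columns `id`, `sequence`,
#'   `sample_id`, `length`, plus attribute `n_unjoined`.
#' @export
#' @examples
#' p <- data.frame(id = "r1", forward = "ACGTACGTAA",
#'                 reverse = revcomp("ACGTAAGGGG"), sample_id = "s1")
#' join_pairs(p)$sequence
join_pairs <- function(pairs, cfg = filter_config()) {
  stopifnot(all(c("id", "forward", "reverse", "sample_id") %in%
                  names(pairs)))
  if (nrow(pairs) == 0) {
    out <- data.frame(id = character(), sequence = character(),
                      sample_id = character(), length = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_unjoined") <- 0L
    class(out) <- c("contigs", "data.frame")
    return(out)
  }
  if (any(!nzchar(pairs$forward)) || any(!nzchar(pairs$reverse))) {
    stop("reads must be non-empty")
  }
  res <- .join_pairs_cpp(pairs$forward, pairs$reverse,
                         cfg$min_join_overlap, cfg$join_identity)
  keep <- res$joined
  out <- data.frame(id = pairs$id[keep], sequence = res$contig[keep],
                    sample_id = pairs$sample_id[keep],
                    length = nchar(res$contig[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unjoined") <- sum(!keep)
  class(out) <- c("contigs", "data.frame")
  out
}

#' Build a contaminant index from negative-control contigs
#'
#' Deduplicates the control contig sequences and prepares the k-mer
#' prefilter used by [match_contaminant()]. By default contigs from both
#' reagent controls and NTC water controls belong in the index (the two
#' control types are processed identically).
#'
#' @param control_contigs a `contigs` data.frame (may have zero rows).
#' @param cfg a [filter_config]; supplies `k`.
#' @return an object of class `contaminant_index`.
#' @export
contaminant_index <- function(control_contigs, cfg = filter_config()) {
  seqs <- unique(control_contigs$sequence)
  if (length(seqs) > 0 && min(nchar(seqs)) < cfg$k) {
    stop("k (", cfg$k, ") exceeds the shortest control contig (",
         min(nchar(seqs)), " bp)")
  }
  structure(list(sequences = seqs, k = cfg$k,
                 n_input = nrow(control_contigs)),
            class = "contaminant_index")
}

#' @export
print.contaminant_index <- function(x, ...) {
  cat("Contaminant index:", length(x$sequences),
      "distinct control contigs (from", x$n_input, "input contigs), k =",
      x$k, "\n")
  invisible(x)
}

#' Match contigs against the contaminant index
#'
#' A contig matches when some indexed control contig aligns to it
#' (ungapped sliding alignment, both orientations when configured) with
#' alignment length >= `min_match_length` and identity (matching columns /
#' alignment columns) >= `identity_threshold`. Candidate controls are
#' retrieved through shared k-mers and then verified by alignment.
#'
#' @param contigs a `contigs` data.frame (or character vector of
#'   sequences).
#' @param index a [contaminant_index()].
#' @param cfg a [filter_config].
#' @param first_hit stop the candidate scan for a contig as soon as one
#'   control contig clears the thresholds (the match decision is
#'   unchanged; only the reported best reference may differ). Used by
#'   [filter_contigs()], where only the decision matters.
#' @return data.frame with one row per contig: `matched`, `ref` (index of
#'   the best examined control sequence, 0 if no candidate), `identity`,
#'   `length`.
#' @export
match_contaminant <- function(contigs, index, cfg = filter_config(),
                              first_hit = FALSE) {
  seqs <- if (is.data.frame(contigs)) contigs$sequence else contigs
  n <- length(seqs)
  if (n == 0 || length(index$sequences) == 0) {
    return(data.frame(matched = logical(n), ref = integer(n),
                      identity = rep(NA_real_, n), length = integer(n)))
  }
  uq <- unique(seqs)
  res <- .kmer_match_cpp(uq, index$sequences, index$k,
                         cfg$min_match_length, cfg$identity_threshold,
                         cfg$check_reverse_complement,
                         first_hit_exit = first_hit)
  i <- match(seqs, uq)
  data.frame(matched = res$matched[i], ref = res$ref[i],
             identity = res$identity[i], length = res$length[i])
}

#' Remove contigs matching reagent/NTC control contigs
#'
#' The in-silico decontamination step: specimen contigs matching any
#' control contig at >= 99% identity over >= 250 bp are removed; the
#' order of retained contigs is preserved.
#'
#' @param sample_contigs a `contigs` data.frame.
#' @param index a [contaminant_index()].
#' @param cfg a [filter_config].
#' @return list with `retained` (a `contigs` data.frame) and `report`
#'   (a `filter_report`: per-sample input/removed/retained tallies and the
#'   overall removed fraction).
#' @export
filter_contigs <- function(sample_contigs, index, cfg = filter_config()) {
  m <- match_contaminant(sample_contigs, index, cfg, first_hit = TRUE)
  removed <- m$matched
  retained <- sample_contigs[!removed, , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- c("contigs", "data.frame")
  samples <- unique(sample_contigs$sample_id)
  per_sample <- data.frame(
    sample_id = samples,
    input = as.integer(table(factor(sample_contigs$sample_id,
                                    levels = samples))),
    removed = as.integer(table(factor(sample_contigs$sample_id[removed],
                                      levels = samples))),
    stringsAsFactors = FALSE
  )
  per_sample$retained <- per_sample$input - per_sample$removed
  ref_tally <- table(m$ref[removed])
  report <- structure(
    list(per_sample = per_sample,
         n_input = nrow(sample_contigs),
         n_removed = sum(removed),
         removed_fraction = if (nrow(sample_contigs) == 0) 0 else
           sum(removed) / nrow(sample_contigs),
         per_reference = ref_tally),
    class = "filter_report"
  )
  list(retained = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Decontamination filter report\n")
  cat(sprintf("  contigs in: %d  removed: %d (%.1f%%)  retained: %d\n",
              x$n_input, x$n_removed, 100 * x$removed_fraction,
              x$n_input - x$n_removed))
  invisible(x)
}

#' Assign contigs to genera by reference matching
#'
#' Each contig is assigned to the reference genus with the highest
#' ungapped identity, provided that identity strictly exceeds
#' `assign_identity_threshold` (default 0.97); otherwise `"unassigned"`.
#' Ties at equal identity go to the lexicographically first genus.
#' Alignments shorter than 90% of the shortest reference are not
#' considered, so trivial short overlaps cannot assign.
#'
#' @param contigs a `contigs` data.frame or character vector.
#' @param refs a `reference_set` from [make_reference_sequences()].
#' @param cfg a [filter_config].
#' @return character vector of genus names (or `"unassigned"`).
#' @export
assign_genus <- function(contigs, refs, cfg = filter_config()) {
  if (length(refs) == 0) stop("reference set must be non-empty")
  seqs <- if (is.data.frame(contigs)) contigs$sequence else contigs
  if (length(seqs) == 0) return(character(0))
  ord <- order(names(refs))
  refs <- refs[ord]
  min_len <- max(cfg$k, floor(0.9 * min(nchar(refs))))
  uq <- unique(seqs)
  # first-hit exit is safe here: references are mutually < 90% identical,
  # so at most one can clear the 97% threshold for a given contig
  res <- .kmer_match_cpp(uq, unclass(refs), cfg$k, min_len,
                         cfg$assign_identity_threshold,
                         cfg$check_reverse_complement,
                         first_hit_exit = TRUE)
  i <- match(seqs, uq)
  out <- rep("unassigned", length(seqs))
  hit <- res$ref > 0 & !is.na(res$identity) &
    res$identity > cfg$assign_identity_threshold &
    res$length >= min_len
  out[hit[i]] <- names(refs)[res$ref[i][hit[i]]]
  out
}

#' Tabulate retained contigs into a genus count matrix
#'
#' Cell (sample, genus) counts the retained contigs of that sample
#' assigned to that genus. Contigs below the assignment threshold are
#' counted in a reserved `"unassigned"` column, which downstream
#' statistics exclude. Samples listed in `sample_ids` but having zero
#' retained contigs keep an all-zero row.
#'
#' @param contigs a `contigs` data.frame of retained contigs.
#' @param refs a `reference_set`.
#' @param cfg a [filter_config].
#' @param sample_ids row set of the output (default: samples present in
#'   `contigs`).
#' @return integer matrix (samples x genera) with an `"unassigned"`
#'   final column.
#' @export
tabulate_counts <- function(contigs, refs, cfg = filter_config(),
                            sample_ids = NULL) {
  genera <- c(sort(names(refs)), "unassigned")
  if (is.null(sample_ids)) sample_ids <- unique(contigs$sample_id)
  assigned <- assign_genus(contigs, refs, cfg)
  tab <- table(factor(contigs$sample_id, levels = sample_ids),
               factor(assigned, levels = genera))
  out <- matrix(as.integer(tab), nrow = length(sample_ids),
                dimnames = list(sample_ids, genera))
  out
}

#' Drop the reserved "unassigned" column from a count matrix
#'
#' @param counts matrix from [tabulate_counts()].
#' @return the matrix without the `"unassigned"` column.
#' @export
drop_unassigned <- function(counts) {
  counts[, colnames(counts) != "unassigned", drop = FALSE]
}

#' Write / read contigs as FASTA
#'
#' @param contigs a `contigs` data.frame.
#' @param path file path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  dna <- Biostrings::DNAStringSet(contigs$sequence)
  names(dna) <- paste(contigs$id, contigs$sample_id)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_contigs_fasta
#' @param sample_id sample id to attach when the FASTA headers carry none.
#' @export
read_contigs_fasta <- function(path, sample_id = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(dna), "\\s+")
  out <- data.frame(
    id = vapply(hdr, `[`, character(1), 1),
    sequence = as.character(dna),
    sample_id = if (is.null(sample_id)) {
      vapply(hdr, function(h) if (length(h) > 1) h[2] else NA_character_,
             character(1))
    } else {
      sample_id
    },
    stringsAsFactors = FALSE
  )
  out$length <- nchar(out$sequence)
  class(out) <- c("contigs", "data.frame")
  out
}
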