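#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAN"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  .revcomp_cpp(x)
}

## Run expr under a derived RNG stream, restoring the caller's RNG state.
## `offset` gives each operation its own substream of a global seed, so that
## e.g. adding samples to one stage does not perturb draws in another.
with_seed <- function(seed, expr, offset = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(expr)
}

## Fixed per-operation offsets for seed substreams.
.seed_offsets <- c(
  references = 101L,
  counts     = 211L,
  reads      = 307L,
  spike      = 401L,
  rarefy     = 503L,
  permanova  = 601L
)

#' Write paired reads as FASTQ
#'
#' Writes standard 4-line FASTQ with constant placeholder qualities
#' (phred+33, Q30). Files are suffixed `_R1.fastq` / `_R2.fastq`.
#'
#' @param pairs data.frame with columns `id`, `forward`, `reverse`.
#' @param prefix output path prefix (directory must exist).
#' @return invisibly, the two file paths written.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  stopifnot(all(c("id", "forward", "reverse") %in% names(pairs)))
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    seqs <- if (i == 1) pairs$forward else pairs$reverse
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- pairs$id
    qual <- Biostrings::BStringSet(vapply(
      nchar(seqs), function(n) strrep("?", n), character(1)
    ))
    Biostrings::writeXStringSet(dna, paths[i], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param r1,r2 paths to the forward and reverse FASTQ files.
#' @param sample_id sample identifier attached to every pair.
#' @return data.frame with columns `id`, `forward`, `reverse`, `sample_id`.
#' @export
read_fastq_pairs <- function(r1, r2, sample_id = NA_character_) {
  f <- Biostrings::readDNAStringSet(r1, format = "fastq")
  r <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(f) != length(r)) {
    stop("paired FASTQ files differ in record count: ", r1, " vs ", r2)
  }
  data.frame(
    id = sub("\\s.*$", "", names(f)),
    forward = as.character(f),
    reverse = as.character(r),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

## TSV writer used by the pipeline: every table carries a header comment
## with the seed, a config hash and the statistic-variant flags in force.
write_tsv_commented <- function(x, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Fast integer tabulation of genus labels into a named count vector.
tabulate_named <- function(labels, levels) {
  as.integer(table(factor(labels, levels = levels)))
}
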