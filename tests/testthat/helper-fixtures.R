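# Small shared fixtures built in code.

# A scaled-down scenario for end-to-end tests: same structure as the
# default study design, smaller depths so read-level stages stay fast.
small_scenario <- function(n_animals = 4, ...) {
  scenario_paper_default(
    n_animals = n_animals,
    urt_depth_log_mean = log(2000),
    env_depth_log_mean = log(1000),
    reagent_load = 300,
    ...
  )
}

# Read-pair table for `count` verbatim copies of a reference.
verbatim_pairs <- function(ref, count, sample_id, read_length = 150) {
  n <- nchar(ref)
  data.frame(
    id = sprintf("%s|fix|%d", sample_id, seq_len(count)),
    forward = substr(ref, 1, read_length),
    reverse = pneumotyper::revcomp(substr(ref, n - read_length + 1, n)),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

as_contigs <- function(sequences, sample_id = "s1",
                       ids = sprintf("c%d", seq_along(sequences))) {
  out <- data.frame(id = ids, sequence = sequences,
                    sample_id = rep_len(sample_id, length(sequences)),
                    length = nchar(sequences),
                    stringsAsFactors = FALSE)
  class(out) <- c("contigs", "data.frame")
  out
}
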