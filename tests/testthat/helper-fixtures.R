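# Fixtures built in code: count tables, FASTQ files, reads indices.

fixture_counts <- function() {
  count_table(c("A", "B", "C"), c(100, 200, 700))
}

random_count_table <- function(n, max_reads = 1e5, with_features = FALSE,
                               n_blanks = 0) {
  reads <- sample.int(max_reads, n, replace = TRUE)
  role <- c(rep("sample", n - n_blanks), rep("blank", n_blanks))
  count_table(sprintf("L%03d", seq_len(n)), reads,
              feature_count = if (with_features) {
                vapply(reads, function(r) sample.int(r + 1L, 1) - 1L, integer(1))
              } else NULL,
              role = role)
}

# Minimal reads_index for direct volume/projection tests.
index_from_p <- function(p, role = rep("sample", length(p))) {
  structure(data.frame(sample_id = sprintf("L%02d", seq_along(p)),
                       role = role, proportion = p, stringsAsFactors = FALSE),
            mode = "reads", class = c("reads_index", "data.frame"))
}

# Write n FASTQ records (optionally gzipped); returns the path.
write_fastq <- function(n, path = tempfile(fileext = ".fastq"), gz = FALSE,
                        truncate_lines = 0) {
  recs <- as.character(unlist(lapply(seq_len(n), function(i) {
    c(paste0("@read", i), "ACGTACGT", "+", "IIIIIIII")
  })))
  if (truncate_lines > 0) recs <- recs[seq_len(length(recs) - truncate_lines)]
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(recs, con)
  close(con)
  path
}

# Independent brute-force projection: explicit per-library mass bookkeeping.
# Each library has R_i = p_i reads produced by prior_volume_i nL in the first
# pool, i.e. a read yield per nL of R_i / prior_i; transferring v_i nL moves
# v_i * R_i / prior_i read-equivalents into the new pool.
brute_force_projection <- function(volume_nl, p, prior) {
  mass <- numeric(length(p))
  for (i in seq_along(p)) {
    yield_per_nl <- p[i] / prior[i]
    mass[i] <- volume_nl[i] * yield_per_nl
  }
  mass / sum(mass)
}
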