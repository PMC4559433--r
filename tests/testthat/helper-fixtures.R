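# Shared in-code fixtures.

make_msa <- function(...) {
  seqs <- c(...)
  msa(sprintf("s%02d", seq_along(seqs)), seqs)
}

# Minimal hand-rolled PDB writer for fixture files (the package itself
# never writes PDB).
pdb_lines <- function(df, record = "ATOM") {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    alt <- if (is.null(r$alt)) " " else r$alt
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            record, i, sprintf(" %-3s", r$atom), alt, r$resname, r$chain,
            r$resno, " ", r$x, r$y, r$z, 1.0, 0.0)
  }, character(1))
}

write_pdb_fixture <- function(df, path, record = "ATOM") {
  writeLines(c(pdb_lines(df, record), "END"), path)
  path
}

# A moderately peaked specificity profile over a few designed
# positions (a phage-display-like sequence preference).
specificity_truth_pwm <- function(n_positions = 4, peak = 0.2,
                                  peaks = c(10, 16, 3, 19)) {
  m <- matrix((1 - peak) / 19, nrow = 20, ncol = n_positions,
              dimnames = list(AA_ALPHABET, seq_len(n_positions)))
  for (j in seq_len(n_positions)) m[peaks[(j - 1) %% length(peaks) + 1], j] <- peak
  macrobench:::as_pwm(m)
}

# ddG fixture with the three planted curation violations.
curation_fixture <- function(seed = 401) {
  simulate_ddg_dataset(12, target_correlation = 0.7, seed = seed,
                       planted_violations = TRUE)
}
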