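# small in-code fixtures

chan_cols <- function(x) grep("^ch[0-9]+$", names(x), value = TRUE)

# a hand-sized peptide table over `nch` channels
tiny_peptides <- function(nch = 4) {
  ch <- sprintf("ch%02d", seq_len(nch))
  tb <- data.frame(
    peptide = c("AAA", "AAB", "BBB", "BBC", "SHARED"),
    protein_id = c("p1", "p1", "p2", "p2", "p1"),
    is_unique = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  set.seed(99)
  for (cc in ch) tb[[cc]] <- round(runif(nrow(tb), 10, 1000), 3)
  tb
}

# a two-species design with small groups, for matrix-level tests
mini_design <- function() {
  data.frame(
    channel = sprintf("ch%02d", 1:8),
    species = rep(c("americana", "virilis"), each = 4),
    status = rep(c("mated", "mated", "virgin", "virgin"), 2),
    replicate = rep(c(1, 2, 1, 2), 2),
    stringsAsFactors = FALSE
  )
}

# seeded random matrix with channel names
seeded_matrix <- function(nr, nc, seed = 1, named = TRUE) {
  set.seed(seed)
  m <- matrix(2^rnorm(nr * nc, 15, 2), nr, nc)
  if (named) {
    colnames(m) <- sprintf("ch%02d", seq_len(nc))
    rownames(m) <- sprintf("r%04d", seq_len(nr))
  }
  m
}
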