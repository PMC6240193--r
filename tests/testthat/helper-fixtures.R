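# Shared fixtures: tiny synthetic worlds and quick-to-train networks.

tiny_world <- function(seed = 7, n_ligands = 60, n_ba = 30,
                       n_proteins = max(12, ceiling(n_ligands / 12)),
                       protein_length = 400, ...) {
  make_world(n_ligands = n_ligands, n_ba = n_ba, n_proteins = n_proteins,
             protein_length = protein_length, seed = seed, ...)
}

# A small instance table mixing EL positives, proteome negatives and BA.
tiny_training_data <- function(seed = 7, with_ba = TRUE, context_mode = TRUE) {
  w <- tiny_world(seed)
  ts <- suppressMessages(
    synthetic_training_set(w, context_mode = context_mode, with_ba = with_ba))
  ts$world <- w
  ts
}

# One quickly trained network (few iterations; enough for interface tests).
quick_network <- function(data, context_mode = TRUE, hidden = 3,
                          iterations = 3, seed = 11) {
  cfg <- network_config(hidden_units = hidden, seed = seed,
                        iterations = iterations)
  suppressMessages(train_fold(data, cfg, context_mode = context_mode))
}

random_peptides <- function(n, lengths = 11:19, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  picked <- if (length(lengths) == 1) rep(lengths, n)
            else if (length(lengths) == n && n > 1) lengths
            else sample(lengths, n, replace = TRUE)
  vapply(picked, function(L)
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = ""),
    character(1))
}

expect_bitwise_equal <- function(a, b) expect_identical(a, b)
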