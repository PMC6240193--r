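# Ground-truth generator. Emulates the statistical structure the modelling
# assumes: a 9mer position-specific binding motif with anchors at
# P1/P4/P6/P9, a unimodal ligand length preference near 14-16, a terminal
# cleavage signal (proline enrichment at the second residue from either
# terminus when the flanking region on that side is >= 3), and source
# proteins that embed the ligands so that genuine context residues exist.

# Human-proteome-like residue frequencies (rounded literature values,
# renormalised); selectable as an alternative to the uniform background.
.HUMAN_BG <- local({
  f <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.036, G = 0.066,
         H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
         P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
         W = 0.012, Y = 0.027)
  (f / sum(f))[.AA20]
})

#' Construct a synthetic ground-truth world
#'
#' Builds, deterministically under \code{seed}, the generating parameters of
#' a synthetic immunopeptidome: a 9x20 binding-motif PSSM whose anchor
#' columns (P1, P4, P6, P9) concentrate most of their mass on a few
#' residues (P1 anchors are drawn from the hydrophobic set, as in real
#' class II grooves) while non-anchor columns sit near the background; a
#' length law over 11-19; and the terminal cleavage-signal probability.
#'
#' @param n_ligands,n_ba Number of eluted ligands / affinity peptides to
#'   emit.
#' @param n_proteins,protein_length Source proteome dimensions.
#' @param length_law Probability vector over lengths 11-19 (default
#'   unimodal with mode 15).
#' @param cleavage_prob Probability that the second residue from a terminus
#'   is proline when that side's flanking region is >= 3 (default 0.4).
#' @param anchor_positions Core anchor positions (default 1, 4, 6, 9).
#' @param anchors_per_position Number of permitted residues per anchor
#'   (default 2).
#' @param anchor_mass Total frequency mass on the permitted anchor residues
#'   (default 0.88).
#' @param background \code{"uniform"} or \code{"human"} residue background.
#' @param ba_noise_sd Additive noise on the affinity targets (default
#'   0.05).
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_world}.
#' @export
make_world <- function(n_ligands = 2000L, n_ba = 1000L, n_proteins = 500L,
                       protein_length = 3000L,
                       length_law = c(0.02, 0.06, 0.12, 0.20, 0.24, 0.18,
                                      0.10, 0.05, 0.03),
                       cleavage_prob = 0.4,
                       anchor_positions = c(1L, 4L, 6L, 9L),
                       anchors_per_position = 2L, anchor_mass = 0.88,
                       background = c("uniform", "human"),
                       ba_noise_sd = 0.05, seed = 42L) {
  if (length(length_law) != 9 || any(length_law < 0) ||
      abs(sum(length_law) - 1) > 1e-8)
    stop("length_law must be 9 non-negative probabilities summing to 1")
  if (cleavage_prob < 0 || cleavage_prob > 1)
    stop("cleavage_prob must lie in [0, 1]")
  if (is.character(background))
    background <- switch(match.arg(background),
                         uniform = setNames(rep(1 / 20, 20), .AA20),
                         human = .HUMAN_BG)
  if (length(background) != 20 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 20 positive frequencies summing to 1")
  set.seed(seed)
  pssm <- matrix(0, 9, 20, dimnames = list(paste0("P", 1:9), .AA20))
  anchor_res <- list()
  for (pos in 1:9) {
    if (pos %in% anchor_positions) {
      pool <- if (pos == 1L) .HYDROPHOBIC_DEFAULT else .AA20
      res <- sample(pool, anchors_per_position)
      f <- rep((1 - anchor_mass) / (20 - anchors_per_position), 20)
      f[match(res, .AA20)] <- anchor_mass / anchors_per_position
      pssm[pos, ] <- f
      anchor_res[[paste0("P", pos)]] <- res
    } else {
      f <- background * exp(rnorm(20, 0, 0.08))
      pssm[pos, ] <- f / sum(f)
    }
  }
  structure(list(pssm = pssm, length_law = setNames(length_law, 11:19),
                 cleavage_prob = cleavage_prob,
                 n_ligands = as.integer(n_ligands), n_ba = as.integer(n_ba),
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 anchor_positions = as.integer(anchor_positions),
                 anchor_residues = anchor_res, background = background,
                 ba_noise_sd = ba_noise_sd, seed = as.integer(seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d ligands, %d BA peptides, ",
                     "%d proteins x %d aa, cleavage_prob %.2f, seed %d\n"),
              x$n_ligands, x$n_ba, x$n_proteins, x$protein_length,
              x$cleavage_prob, x$seed))
  invisible(x)
}

.sample_residues <- function(n, prob) {
  .AA20[sample.int(20, n, replace = TRUE, prob = prob)]
}

#' Emit eluted ligands embedded in a synthetic proteome
#'
#' Each ligand is a PSSM-sampled 9mer core flanked by background-sampled
#' PFRs (with the proline cleavage rule applied at termini whose PFR is
#' >= 3), with length drawn from the length law, embedded at a recorded
#' position inside a generated source protein. The emitted table carries
#' the true core offset and the true protein context for oracle tests.
#'
#' @param world A [make_world()] object.
#' @return List with \code{ligands} (instance table with extra
#'   \code{true_offset} and \code{protein_start} columns) and
#'   \code{proteins} (named character vector).
#' @export
emit_ligands <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(world$seed + 1L)
  np <- world$n_proteins
  nl <- world$n_ligands
  lpp <- ceiling(nl / np)
  slot_w <- (world$protein_length - 6L) %/% lpp
  if (slot_w < 25L)
    stop("protein_length too small to host the requested ligands")
  prot <- lapply(seq_len(np), function(i)
    .sample_residues(world$protein_length, world$background))
  names(prot) <- sprintf("SYNPROT%04d", seq_len(np))
  lig_seq <- character(nl)
  pid <- integer(nl)
  start <- integer(nl)
  true_off <- integer(nl)
  for (i in seq_len(nl)) {
    p <- ((i - 1L) %% np) + 1L
    slot <- (i - 1L) %/% np
    L <- sample(11:19, 1L, prob = world$length_law)
    off <- sample.int(L - 8L, 1L) - 1L
    core <- .AA20[apply(world$pssm, 1, function(f) sample.int(20, 1L, prob = f))]
    pep <- c(.sample_residues(off, world$background), core,
             .sample_residues(L - 9L - off, world$background))
    if (off >= 3L && runif(1) < world$cleavage_prob) pep[2L] <- "P"
    if (L - 9L - off >= 3L && runif(1) < world$cleavage_prob) pep[L - 1L] <- "P"
    st <- 4L + slot * slot_w + sample.int(slot_w - L + 1L, 1L) - 1L
    prot[[p]][st:(st + L - 1L)] <- pep
    lig_seq[i] <- paste(pep, collapse = "")
    pid[i] <- p
    start[i] <- st
    true_off[i] <- off
  }
  proteins <- vapply(prot, paste, character(1), collapse = "")
  ligands <- data.frame(
    peptide = lig_seq, target = 1, data_type = "EL",
    context_up = .padded_flank(proteins[pid], start - 3L, start - 1L),
    context_down = .padded_flank(proteins[pid], start + nchar(lig_seq),
                                 start + nchar(lig_seq) + 2L),
    source_protein_id = names(proteins)[pid],
    true_offset = true_off, protein_start = start,
    stringsAsFactors = FALSE)
  list(ligands = ligands, proteins = proteins)
}

# Best-window log-odds score of a peptide against the world PSSM.
.motif_score <- function(pep_idx, lo) {
  L <- length(pep_idx)
  best <- -Inf
  for (off in 0:(L - 9L)) {
    s <- sum(lo[cbind(1:9, pep_idx[(off + 1L):(off + 9L)])])
    if (s > best) best <- s
  }
  best
}

#' Emit a synthetic binding-affinity peptide table
#'
#' Random background peptides (half of them with a PSSM-sampled core
#' planted at a random offset, so that genuine binders exist) are scored by
#' the summed log-odds of their best 9mer window against the world PSSM,
#' mapped through a logistic to \[0, 1\] targets, and perturbed with
#' clamped additive noise of sd \code{ba_noise_sd}. Affinity records carry
#' no context (\code{"XXX"}).
#'
#' @param world A [make_world()] object.
#' @param logistic_scale Divisor of the raw motif score inside the logistic
#'   (default 3).
#' @return Instance table with \code{data_type} \code{"BA"}.
#' @export
emit_ba <- function(world, logistic_scale = 3) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(world$seed + 2L)
  n <- world$n_ba
  lo <- log2(sweep(world$pssm, 2, world$background, "/"))
  pep <- character(n)
  for (i in seq_len(n)) {
    L <- sample(11:19, 1L, prob = world$length_law)
    p <- .sample_residues(L, world$background)
    if (i %% 2L == 0L) {
      off <- sample.int(L - 8L, 1L) - 1L
      p[(off + 1L):(off + 9L)] <-
        .AA20[apply(world$pssm, 1, function(f) sample.int(20, 1L, prob = f))]
    }
    pep[i] <- paste(p, collapse = "")
  }
  raw <- vapply(pep, function(s) .motif_score(.aa_index(s), lo), numeric(1),
                USE.NAMES = FALSE)
  target <- plogis(raw / logistic_scale)
  if (world$ba_noise_sd > 0)
    target <- pmin(pmax(target + rnorm(n, 0, world$ba_noise_sd), 0), 1)
  data.frame(peptide = pep, target = target, data_type = "BA",
             context_up = "XXX", context_down = "XXX",
             source_protein_id = NA_character_, stringsAsFactors = FALSE)
}

#' Assemble a full synthetic training set
#'
#' Convenience wrapper: emits ligands and affinity peptides, samples
#' random negatives from the synthetic proteome, and assigns common-motif
#' partitions across the combined data.
#'
#' @param world A [make_world()] object.
#' @param context_mode Record proteome context for the negatives?
#' @param with_ba Include the affinity peptides?
#' @param n_partitions Cross-validation partitions (default 5).
#' @return List with \code{data} (partitioned instance table),
#'   \code{ligands}, \code{proteins}.
#' @export
synthetic_training_set <- function(world, context_mode = TRUE,
                                   with_ba = TRUE, n_partitions = 5L) {
  em <- emit_ligands(world)
  set.seed(world$seed + 3L)
  negs <- sample_negatives(em$ligands[, c("peptide", "target", "data_type",
                                          "context_up", "context_down",
                                          "source_protein_id")],
                           em$proteins, context_mode = context_mode)
  cols <- c("peptide", "target", "data_type", "context_up", "context_down",
            "source_protein_id")
  data <- rbind(em$ligands[, cols], negs[, cols])
  if (with_ba) data <- rbind(data, emit_ba(world)[, cols])
  set.seed(world$seed + 4L)
  data$partition <- common_motif_partition(data$peptide, k = n_partitions)
  rownames(data) <- NULL
  list(data = data, ligands = em$ligands, proteins = em$proteins)
}
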