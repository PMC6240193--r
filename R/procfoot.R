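# Antigen-processing footprint analysis: peptide-flanking-region (PFR)
# annotation, 6x20 terminal processing matrices (3 source-protein context
# residues + 3 terminal ligand residues per side), Kullback-Leibler logo
# matrices, and matrix comparison by Pearson correlation with an exact
# permutation test.

#' Annotate ligands with PFR lengths and source-protein context
#'
#' Given each ligand's binding-core offset (typically the cross-validated
#' out-of-fold core of the EL model), computes the N- and C-side PFR lengths
#' and, where a record carries no context, looks the context up from the
#' first occurrence of the ligand in its source protein (padding with
#' \code{X} at protein boundaries). Ligands not found in their declared
#' source protein are excluded with a logged count.
#'
#' @param ligands Instance table of ligands.
#' @param core_offsets 0-based core offsets aligned with \code{ligands}
#'   rows.
#' @param proteins Named protein vector (or \code{AAStringSet}).
#' @return Data frame of class \code{pfr_annotation}: \code{peptide},
#'   \code{core_offset}, \code{n_pfr}, \code{c_pfr}, \code{context_up},
#'   \code{context_down}, \code{source_protein_id}.
#' @export
annotate_pfr <- function(ligands, core_offsets, proteins = NULL) {
  ligands <- .validate_table(ligands)
  stopifnot(length(core_offsets) == nrow(ligands))
  L <- nchar(ligands$peptide)
  if (any(core_offsets < 0 | core_offsets > L - 9))
    stop("core offset out of range")
  up <- ligands$context_up
  down <- ligands$context_down
  keep <- rep(TRUE, nrow(ligands))
  need <- is.na(up) | is.na(down)
  if (any(need)) {
    if (is.null(proteins))
      stop("context lookup requires 'proteins'")
    proteins <- .as_protein_vector(proteins)
    for (i in which(need)) {
      prot <- proteins[[ligands$source_protein_id[i]]]
      pos <- regexpr(ligands$peptide[i], prot, fixed = TRUE)[1]
      if (pos < 0) { keep[i] <- FALSE; next }
      up[i] <- .padded_flank(prot, pos - 3L, pos - 1L)
      down[i] <- .padded_flank(prot, pos + L[i], pos + L[i] + 2L)
    }
    if (any(!keep))
      .log_msg("excluded %d ligands not found in their source protein",
               sum(!keep))
  }
  out <- data.frame(peptide = ligands$peptide[keep],
                    core_offset = as.integer(core_offsets[keep]),
                    n_pfr = as.integer(core_offsets[keep]),
                    c_pfr = as.integer(L[keep] - 9L - core_offsets[keep]),
                    context_up = up[keep], context_down = down[keep],
                    source_protein_id = ligands$source_protein_id[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("pfr_annotation", "data.frame")
  out
}

# 6-column matrix of residue indices (0 = X) for one terminus.
# upstream:   ctx[-3], ctx[-2], ctx[-1], pep[1], pep[2], pep[3]
# downstream: pep[L-2], pep[L-1], pep[L], ctx[+1], ctx[+2], ctx[+3]
.term_idx <- function(ann, side) {
  n <- nrow(ann)
  idx <- matrix(0L, n, 6)
  for (i in seq_len(n)) {
    pep <- .aa_index(ann$peptide[i])
    L <- length(pep)
    if (side == "upstream") {
      idx[i, ] <- c(.aa_index(ann$context_up[i], "context"), pep[1:3])
    } else {
      idx[i, ] <- c(pep[(L - 2):L], .aa_index(ann$context_down[i], "context"))
    }
  }
  idx
}

.aa_background <- function(proteins) {
  ch <- unlist(strsplit(paste(proteins, collapse = ""), ""))
  cnt <- tabulate(match(ch, .AA20), nbins = 20L)
  setNames(cnt / sum(cnt), .AA20)
}

.pm_from_idx <- function(idx, side, background, pseudocount, min_pfr) {
  counts <- t(apply(idx, 2, function(col) tabulate(col[col > 0L], nbins = 20L)))
  dimnames(counts) <- list(paste0("pos", 1:6), .AA20)
  tot <- rowSums(counts)
  freq <- counts / tot
  lo <- log2(((counts + pseudocount) / (tot + 20 * pseudocount)) /
               rep(background, each = 6))
  structure(list(side = side, counts = counts, frequencies = freq,
                 log_odds = lo, background = background,
                 n_ligands = nrow(idx), min_pfr = min_pfr,
                 pseudocount = pseudocount),
            class = "processing_matrix")
}

#' Terminal processing matrix for one ligand terminus
#'
#' Combines the three terminal ligand residues and the three adjacent
#' source-protein context residues of every ligand whose PFR on that side
#' is at least \code{min_pfr} (default 3; shorter PFRs sit too close to the
#' MHC for proteases to leave a trimming signal). Counts exclude \code{X}
#' padding. Frequencies are raw per-position fractions; log-odds versus the
#' background use an add-\code{pseudocount} correction. The background is
#' computed from the source proteins of all ligands in the set unless given
#' explicitly.
#'
#' @param annotations A [annotate_pfr()] result.
#' @param side \code{"upstream"} (N terminus) or \code{"downstream"} (C
#'   terminus).
#' @param proteins Named protein vector used for the background (ignored
#'   when \code{background} is supplied).
#' @param min_pfr Minimum PFR length on the chosen side (default 3).
#' @param background Optional 20-vector of background residue frequencies.
#' @param pseudocount Add-one style pseudocount for the log-odds (default 1).
#' @return An object of class \code{processing_matrix} with fields
#'   \code{counts}, \code{frequencies}, \code{log_odds} (all 6x20),
#'   \code{background} and \code{n_ligands}.
#' @export
terminal_matrix <- function(annotations, side = c("upstream", "downstream"),
                            proteins = NULL, min_pfr = 3L,
                            background = NULL, pseudocount = 1) {
  side <- match.arg(side)
  pfr <- if (side == "upstream") annotations$n_pfr else annotations$c_pfr
  ann <- annotations[pfr >= min_pfr, , drop = FALSE]
  if (nrow(ann) == 0)
    stop(sprintf("no ligand passes the %s PFR >= %d filter", side, min_pfr))
  if (is.null(background)) {
    if (is.null(proteins))
      stop("supply 'proteins' (for the background) or 'background'")
    proteins <- .as_protein_vector(proteins)
    ids <- unique(ann$source_protein_id)
    ids <- ids[!is.na(ids) & ids %in% names(proteins)]
    if (length(ids) == 0)
      stop("no source proteins available for the background")
    background <- .aa_background(proteins[ids])
  }
  if (any(background <= 0)) stop("background contains zero frequencies")
  .pm_from_idx(.term_idx(ann, side), side, background, pseudocount, min_pfr)
}

#' @export
print.processing_matrix <- function(x, ...) {
  cat(sprintf("<processing_matrix> %s, %d ligands (PFR >= %d)\n",
              x$side, x$n_ligands, x$min_pfr))
  invisible(x)
}

#' Kullback-Leibler logo matrix
#'
#' Per position, letter heights are \code{f(a) * log2(f(a) / q(a))} (no
#' sequence weighting; negative per-residue terms are permitted) and the
#' position's information content is their sum. Identical foreground and
#' background give zero heights.
#'
#' @param frequencies Positions x 20 frequency matrix (rows sum to 1).
#' @param background Positive background 20-vector.
#' @return An object of class \code{logo_matrix} with \code{heights} and
#'   per-position \code{information}.
#' @export
kl_logo_matrix <- function(frequencies, background) {
  frequencies <- as.matrix(frequencies)
  if (any(abs(rowSums(frequencies) - 1) > 1e-6))
    stop("frequency rows must sum to 1")
  if (any(background <= 0))
    stop("background contains zero entries; pseudocount upstream")
  h <- frequencies * log2(sweep(frequencies, 2, background, "/"))
  h[frequencies == 0] <- 0
  structure(list(heights = h, information = rowSums(h),
                 background = background), class = "logo_matrix")
}

#' Per-PFR-length logo matrices for one terminus
#'
#' Groups ligands by PFR length (1-5 exact; 6 collects PFR >= 6) and builds,
#' per group, a KL logo matrix over the 3 context positions plus the
#' \code{min(PFR, 6)} PFR residues nearest the terminus. Empty groups are
#' skipped with a log line.
#'
#' @inheritParams terminal_matrix
#' @param background Background 20-vector (computed from \code{proteins} if
#'   absent).
#' @return Named list (\code{pfr_1} .. \code{pfr_6}) of \code{logo_matrix}
#'   objects.
#' @export
pfr_grouped_logos <- function(annotations, side = c("upstream", "downstream"),
                              proteins = NULL, background = NULL) {
  side <- match.arg(side)
  pfr <- if (side == "upstream") annotations$n_pfr else annotations$c_pfr
  if (is.null(background)) {
    proteins <- .as_protein_vector(proteins)
    background <- .aa_background(proteins)
  }
  out <- list()
  for (g in 1:6) {
    sel <- if (g < 6) pfr == g else pfr >= 6
    ann <- annotations[sel, , drop = FALSE]
    if (nrow(ann) == 0) {
      .log_msg("PFR group %d (%s) empty; skipped", g, side)
      next
    }
    npos <- 3L + g
    idx <- matrix(0L, nrow(ann), npos)
    for (i in seq_len(nrow(ann))) {
      pep <- .aa_index(ann$peptide[i])
      L <- length(pep)
      if (side == "upstream")
        idx[i, ] <- c(.aa_index(ann$context_up[i], "context"), pep[1:g])
      else
        idx[i, ] <- c(pep[(L - g + 1):L],
                      .aa_index(ann$context_down[i], "context"))
    }
    counts <- t(apply(idx, 2, function(col) tabulate(col[col > 0L], 20L)))
    freq <- counts / rowSums(counts)
    colnames(freq) <- .AA20
    out[[paste0("pfr_", g)]] <- kl_logo_matrix(freq, background)
  }
  out
}

#' Pearson correlation between two processing matrices
#'
#' Flattens the two 6x20 matrices (log-odds by default) and returns their
#' Pearson correlation coefficient; 1 is maximal similarity, 0 no
#' correlation.
#'
#' @param a,b \code{processing_matrix} objects for the same side.
#' @param space \code{"log_odds"} (default) or \code{"frequencies"}.
#' @param drop_residues Optional residues to remove before correlating
#'   (e.g. \code{"C"}, whose depletion in mass-spectrometry data is a
#'   technological artifact).
#' @return PCC in \[-1, 1\].
#' @export
matrix_pcc <- function(a, b, space = c("log_odds", "frequencies"),
                       drop_residues = NULL) {
  space <- match.arg(space)
  if (!identical(a$side, b$side)) stop("matrices are for different sides")
  ma <- a[[space]]
  mb <- b[[space]]
  if (!is.null(drop_residues)) {
    keep <- !colnames(ma) %in% drop_residues
    ma <- ma[, keep, drop = FALSE]
    mb <- mb[, keep, drop = FALSE]
  }
  va <- as.numeric(ma)
  vb <- as.numeric(mb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant matrix: correlation undefined")
  stats::cor(va, vb)
}

#' Exact permutation test for processing-matrix similarity
#'
#' Two null hypotheses are available. \code{null = "labels"} tests whether
#' the two ligand sets carry \emph{different} processing signals: the
#' ligand-set membership labels of the pooled annotations are shuffled and
#' both terminal matrices and their PCC recomputed per permutation (under
#' exchangeable sets the p-value is uniform). \code{null = "entries"} tests
#' whether the observed PCC differs from \emph{random}, i.e. from no
#' correlation at all: the 120 entries of one flattened matrix are permuted
#' and the correlation recomputed, which is the relevant null when asking
#' whether two data sets share a common processing signal. Either way,
#' \code{p = (1 + #\{perm PCC >= observed\}) / (1 + n_perm)}. A common
#' background (from the pooled source proteins unless supplied) is used
#' throughout so that only the permuted quantity varies.
#'
#' @param set_a,set_b [annotate_pfr()] results.
#' @param side \code{"upstream"} or \code{"downstream"}.
#' @param n_perm Number of permutations (>= 1).
#' @param proteins Named protein vector for the pooled background.
#' @param background Optional explicit background 20-vector.
#' @param min_pfr Minimum PFR length filter (default 3).
#' @param space Correlation space, as in [matrix_pcc()].
#' @param pseudocount Log-odds pseudocount (default 1).
#' @param null \code{"labels"} (set-difference null) or \code{"entries"}
#'   (no-correlation null).
#' @return List with \code{p_value}, \code{observed} PCC and the permuted
#'   \code{null} PCC vector.
#' @export
pcc_permutation_test <- function(set_a, set_b,
                                 side = c("upstream", "downstream"),
                                 n_perm = 999L, proteins = NULL,
                                 background = NULL, min_pfr = 3L,
                                 space = c("log_odds", "frequencies"),
                                 pseudocount = 1,
                                 null = c("labels", "entries")) {
  side <- match.arg(side)
  space <- match.arg(space)
  null <- match.arg(null)
  if (n_perm < 1) stop("n_perm must be >= 1")
  pfr_a <- if (side == "upstream") set_a$n_pfr else set_a$c_pfr
  pfr_b <- if (side == "upstream") set_b$n_pfr else set_b$c_pfr
  a <- set_a[pfr_a >= min_pfr, , drop = FALSE]
  b <- set_b[pfr_b >= min_pfr, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("a set has no ligand passing the PFR filter")
  if (is.null(background)) {
    if (is.null(proteins))
      stop("supply 'proteins' or 'background'")
    proteins <- .as_protein_vector(proteins)
    ids <- unique(c(a$source_protein_id, b$source_protein_id))
    ids <- ids[!is.na(ids) & ids %in% names(proteins)]
    background <- .aa_background(proteins[ids])
  }
  idx_a <- .term_idx(a, side)
  idx_b <- .term_idx(b, side)
  pcc_of <- function(ia, ib) {
    matrix_pcc(.pm_from_idx(ia, side, background, pseudocount, min_pfr),
               .pm_from_idx(ib, side, background, pseudocount, min_pfr),
               space = space)
  }
  observed <- pcc_of(idx_a, idx_b)
  perm <- numeric(n_perm)
  if (null == "labels") {
    pooled <- rbind(idx_a, idx_b)
    na <- nrow(idx_a)
    n <- nrow(pooled)
    for (i in seq_len(n_perm)) {
      sel <- sample.int(n, na)
      perm[i] <- pcc_of(pooled[sel, , drop = FALSE],
                        pooled[-sel, , drop = FALSE])
    }
  } else {
    va <- as.numeric(.pm_from_idx(idx_a, side, background, pseudocount,
                                  min_pfr)[[space]])
    vb <- as.numeric(.pm_from_idx(idx_b, side, background, pseudocount,
                                  min_pfr)[[space]])
    for (i in seq_len(n_perm))
      perm[i] <- stats::cor(va[sample.int(length(va))], vb)
  }
  list(p_value = (1 + sum(perm >= observed)) / (1 + n_perm),
       observed = observed, null = perm)
}
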