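# Benchmark metrics (AUC, AUC 0.1, PPV) and the two T cell epitope
# evaluation protocols.

.check_scored <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive out-scores
#' a random negative, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels aligned with \code{scores}.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- .check_scored(scores, labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

# ROC corner points (fpr, tpr) including (0,0); tie groups collapse to one
# point so that tied scores trace a diagonal segment.
.roc_points <- function(scores, labels) {
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  ord <- order(-scores, method = "radix")
  s <- scores[ord]
  l <- labels[ord]
  n <- length(s)
  last <- c(s[-n] != s[-1], TRUE)
  tp <- cumsum(l == 1L)[last]
  fp <- cumsum(l == 0L)[last]
  list(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

#' Partial AUC up to false positive rate 0.1
#'
#' Trapezoidal area under the ROC curve over FPR in \[0, 0.1\], divided by
#' 0.1 so a perfect classifier scores 1 (an uninformative one scores 0.05).
#'
#' @inheritParams auc
#' @param max_fpr Upper FPR integration limit (default 0.1).
#' @return Normalised partial AUC in \[0, 1\].
#' @export
auc01 <- function(scores, labels, max_fpr = 0.1) {
  labels <- .check_scored(scores, labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("AUC 0.1 needs at least one positive and one negative")
  roc <- .roc_points(scores, labels)
  fpr <- roc$fpr
  tpr <- roc$tpr
  area <- 0
  for (i in 2:length(fpr)) {
    x0 <- fpr[i - 1]; x1 <- fpr[i]
    y0 <- tpr[i - 1]; y1 <- tpr[i]
    if (x0 >= max_fpr) break
    if (x1 > max_fpr) {
      y1 <- y0 + (y1 - y0) * (max_fpr - x0) / (x1 - x0)
      x1 <- max_fpr
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / max_fpr
}

#' Positive predictive value on the top-N predictions
#'
#' Sorts all predictions and reports the fraction of true positives among
#' the top N, where N is the number of positives in the set. Ties are broken
#' by stable input order.
#'
#' @inheritParams auc
#' @return PPV in \[0, 1\].
#' @export
ppv <- function(scores, labels) {
  labels <- .check_scored(scores, labels)
  np <- sum(labels == 1L)
  if (np == 0L) stop("PPV needs at least one positive")
  ord <- order(-scores, method = "radix")
  mean(labels[ord[seq_len(np)]] == 1L)
}

#' Remove evaluation peptides sharing a 9mer with the training set
#'
#' Drops every evaluation peptide that shares an identical 9mer substring
#' with any training peptide; logs the removed count. Idempotent.
#'
#' @param eval_set Character vector or instance table to be filtered.
#' @param train_set Character vector or instance table defining the
#'   forbidden 9mers.
#' @return \code{eval_set} with overlapping entries removed.
#' @export
filter_9mer_overlap <- function(eval_set, train_set) {
  ev <- if (is.data.frame(eval_set)) eval_set$peptide else eval_set
  tr <- if (is.data.frame(train_set)) train_set$peptide else train_set
  tr9 <- unique(unlist(lapply(tr, .kmer_set)))
  keep <- vapply(ev, function(s) !any(.kmer_set(s) %in% tr9), logical(1),
                 USE.NAMES = FALSE)
  if (any(!keep))
    .log_msg("removed %d/%d evaluation peptides with 9mer overlap",
             sum(!keep), length(keep))
  if (is.data.frame(eval_set)) eval_set[keep, , drop = FALSE] else eval_set[keep]
}

.ensemble_scorer <- function(ensemble, head = "EL") {
  function(peptides) predict_ensemble(peptides, ensemble, head)$score
}

#' Per-protein epitope AUC (direct strategy)
#'
#' Digests the epitope's source protein into overlapping windows of the
#' epitope's length, scores them with the model's EL output, and computes
#' the AUC taking windows identical to the epitope as positives and all
#' other windows as negatives — excluding negatives that share a 9mer with
#' the epitope.
#'
#' @param epitope Epitope sequence (must occur in \code{protein}).
#' @param protein Source protein sequence (longer than the epitope).
#' @param ensemble Trained model ensemble (EL head is used).
#' @param score_fun Optional replacement scoring function
#'   (\code{character -> numeric}); overrides \code{ensemble}.
#' @return AUC for this epitope/protein pair.
#' @export
epitope_auc_direct <- function(epitope, protein, ensemble = NULL,
                               score_fun = NULL) {
  L <- nchar(epitope)
  np <- nchar(protein)
  if (np <= L) stop("protein must be longer than the epitope")
  win <- substring(protein, 1:(np - L + 1L), L:np)
  pos <- win == epitope
  if (!any(pos)) stop("epitope does not occur in the source protein")
  ep9 <- .kmer_set(epitope)
  shares <- vapply(win, function(s) any(.kmer_set(s) %in% ep9), logical(1),
                   USE.NAMES = FALSE)
  keep <- pos | !shares
  if (is.null(score_fun)) score_fun <- .ensemble_scorer(ensemble)
  auc(score_fun(win[keep]), as.integer(pos[keep]))
}

#' Per-protein epitope AUC (ligand-preference strategy)
#'
#' Scores every 13-21mer window of the source protein with the model, then
#' assigns each epitope-length window the average score of all 13-21mers
#' overlapping it by at least nine positions, and computes the AUC as in
#' [epitope_auc_direct()]. This rewards windows covered by well-scoring
#' natural-ligand candidates rather than requiring the epitope boundaries
#' themselves to look processed.
#'
#' @inheritParams epitope_auc_direct
#' @param min_overlap Minimum positional overlap between a 13-21mer and a
#'   window for it to contribute (default 9).
#' @return AUC for this epitope/protein pair.
#' @export
epitope_auc_ligand_preference <- function(epitope, protein, ensemble = NULL,
                                          score_fun = NULL,
                                          min_overlap = 9L) {
  L <- nchar(epitope)
  np <- nchar(protein)
  if (np <= L) stop("protein must be longer than the epitope")
  if (np < 13L) stop("protein shorter than 13: no 13-21mer support")
  win <- substring(protein, 1:(np - L + 1L), L:np)
  pos <- win == epitope
  if (!any(pos)) stop("epitope does not occur in the source protein")
  frag_start <- integer(0)
  frag_len <- integer(0)
  for (l in 13:21) {
    if (np >= l) {
      st <- 1:(np - l + 1L)
      frag_start <- c(frag_start, st)
      frag_len <- c(frag_len, rep(l, length(st)))
    }
  }
  frags <- substring(protein, frag_start, frag_start + frag_len - 1L)
  if (is.null(score_fun)) score_fun <- .ensemble_scorer(ensemble)
  fscore <- score_fun(frags)
  frag_end <- frag_start + frag_len - 1L
  wscore <- vapply(seq_along(win), function(i) {
    s <- i; e <- i + L - 1L
    ov <- pmin(e, frag_end) - pmax(s, frag_start) + 1L
    mean(fscore[ov >= min_overlap])
  }, numeric(1))
  ep9 <- .kmer_set(epitope)
  shares <- vapply(win, function(s) any(.kmer_set(s) %in% ep9), logical(1),
                   USE.NAMES = FALSE)
  keep <- pos | !shares
  auc(wscore[keep], as.integer(pos[keep]))
}

#' Load and validate an epitope benchmark table
#'
#' Expects columns \code{epitope} and \code{protein_id}; entries with
#' nonstandard residues are filtered with a logged count and epitopes
#' outside the 14-19 length range are rejected.
#'
#' @param table Data frame (or path to a whitespace-separated file with a
#'   header).
#' @param proteins Named protein vector (or \code{AAStringSet}) resolving
#'   \code{protein_id}.
#' @return Validated data frame with an attached \code{protein} column.
#' @export
epitope_benchmark <- function(table, proteins) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.table(table, header = TRUE, stringsAsFactors = FALSE)
  proteins <- .as_protein_vector(proteins)
  stopifnot(!is.null(table$epitope), !is.null(table$protein_id))
  names(table)[names(table) == "epitope"] <- "peptide"
  table <- .filter_nonstandard(table)
  names(table)[names(table) == "peptide"] <- "epitope"
  len <- nchar(table$epitope)
  if (any(len < 14L | len > 19L))
    stop(sprintf("%d epitopes outside the accepted 14-19 length range",
                 sum(len < 14L | len > 19L)))
  missing <- !table$protein_id %in% names(proteins)
  if (any(missing))
    stop(sprintf("%d epitopes reference unknown proteins", sum(missing)))
  table$protein <- unname(proteins[table$protein_id])
  table
}
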