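# Data preparation and cross-validation orchestration: random-negative
# enrichment from a source proteome, common-motif partitioning (no shared
# 9mer across folds), balanced mixed-data training, ensembling.

#' Transform IC50 binding affinities to [0, 1] targets
#'
#' \code{1 - log(IC50) / log(50000)}, clamped to \[0, 1\]: 1 nM maps to 1,
#' 50000 nM and weaker to 0. The standard transform of the NetMHCII model
#' lineage.
#'
#' @param ic50_nm Measured IC50 values in nanomolar.
#' @return Numeric targets in \[0, 1\].
#' @export
ba_transform <- function(ic50_nm) {
  pmin(pmax(1 - log(ic50_nm) / log(50000), 0), 1)
}

#' Sample random negatives from a source proteome
#'
#' For each length 11-19 draws the same number of random proteome
#' subsequences — five times the count of the most represented length among
#' the positives — labels them 0, and (when \code{context_mode} is on)
#' records their true flanking proteome residues as context. Flanks that run
#' over a protein boundary are padded with \code{X}.
#'
#' @param positives Instance table of positive EL ligands (lengths 11-19).
#' @param proteins Named character vector of protein sequences (or an
#'   \code{AAStringSet}).
#' @param context_mode Record genuine proteome context for the negatives?
#' @param ratio Negatives per length as a multiple of the modal positive
#'   length count (default 5).
#' @return Instance table of negatives (\code{target} 0, \code{data_type}
#'   \code{"EL"}).
#' @export
sample_negatives <- function(positives, proteins, context_mode = TRUE,
                             ratio = 5) {
  proteins <- .as_protein_vector(proteins)
  positives <- .validate_table(positives)
  len <- nchar(positives$peptide)
  if (any(len < 11 | len > 19))
    stop("positives must have lengths 11-19")
  counts <- tabulate(len - 10L, nbins = 9L)
  n_per_len <- ratio * max(counts)
  plen <- nchar(proteins)
  out <- vector("list", 9)
  for (l in 11:19) {
    w <- pmax(plen - l + 1L, 0L)
    if (sum(w) == 0)
      stop(sprintf("proteome has no protein of length >= %d", l))
    pid <- sample.int(length(proteins), n_per_len, replace = TRUE,
                      prob = w)
    start <- 1L + floor(runif(n_per_len) * w[pid])
    pep <- substr(proteins[pid], start, start + l - 1L)
    if (context_mode) {
      up <- .padded_flank(proteins[pid], start - 3L, start - 1L)
      down <- .padded_flank(proteins[pid], start + l, start + l + 2L)
    } else {
      up <- down <- rep("XXX", n_per_len)
    }
    out[[l - 10L]] <- data.frame(
      peptide = pep, target = 0, data_type = "EL", context_up = up,
      context_down = down, source_protein_id = names(proteins)[pid],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  .log_msg("sampled %d negatives (%d per length 11-19)", nrow(res), n_per_len)
  res
}

# Substring with X padding outside [1, nchar]; vectorised over sequences.
.padded_flank <- function(seqs, from, to) {
  n <- nchar(seqs)
  lpad <- pmax(1L - from, 0L)
  rpad <- pmax(to - n, 0L)
  body <- substr(seqs, pmax(from, 1L), pmin(to, n))
  paste0(strrep("X", lpad), body, strrep("X", rpad))
}

.kmer_set <- function(s, k = 9L) {
  L <- nchar(s)
  if (L < k) return(s)
  unique(substring(s, 1:(L - k + 1L), k:L))
}

#' Common-motif cross-validation partitioning
#'
#' Single-linkage clustering in which two peptides are linked iff they share
#' an identical 9mer substring; clusters (largest first) are assigned
#' greedily to the currently smallest partition. Guarantees that no 9mer is
#' shared between peptides in different partitions.
#'
#' @param peptides Character vector (or instance table).
#' @param k Number of partitions (default 5).
#' @param motif_length Linkage motif length (default 9).
#' @return Integer partition labels in \code{1..k}.
#' @export
common_motif_partition <- function(peptides, k = 5L, motif_length = 9L) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  n <- length(peptides)
  if (n < k) stop("need at least k peptides")
  km <- lapply(peptides, .kmer_set, k = motif_length)
  idx <- rep.int(seq_len(n), lengths(km))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (grp in split(idx, unlist(km))) {
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (j in grp[-1]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  ord <- order(-lengths(clusters), vapply(clusters, min, integer(1)))
  labels <- integer(n)
  psize <- integer(k)
  for (ci in ord) {
    p <- which.min(psize)
    labels[clusters[[ci]]] <- p
    psize[p] <- psize[p] + length(clusters[[ci]])
  }
  labels
}

#' Train one network on a training set
#'
#' Balanced mixed-data online training: each iteration performs N update
#' steps (N = training-set size) in which the data type is first drawn
#' uniformly at random (when both are present), then an instance uniformly
#' within that type; its core is aligned by the current network (burn-in
#' restriction on the first \code{burn_in_iterations} iterations) and one
#' gradient step is taken on the squared error of the matching output head.
#'
#' @param train Instance table with \code{peptide}, \code{target},
#'   \code{data_type} (and context columns when \code{context_mode}).
#' @param cfg A [network_config()].
#' @param context_mode Encode the 12x20 context block?
#' @param encoder An [encoder_config()].
#' @param pre,use_idx Internal: a precomputed feature bundle and the 0-based
#'   instance subset to train on (used by [cross_validate()] to avoid
#'   re-encoding per fold).
#' @return A trained \code{mhc2_network}; attribute \code{n_draws} records
#'   how many updates each data type received.
#' @export
train_fold <- function(train, cfg = network_config(), context_mode = TRUE,
                       encoder = encoder_config(), pre = NULL,
                       use_idx = NULL) {
  if (is.null(pre)) {
    train <- .validate_table(train, training = TRUE)
    if (nrow(train) == 0) stop("empty training set")
    pre <- .precompute(train, encoder, context_mode)
  }
  if (is.null(use_idx)) use_idx <- seq_along(pre$n_off) - 1L
  if (length(use_idx) == 0) stop("empty training set")
  set.seed(cfg$seed)
  w <- cpp_train(pre$features, pre$ctx_features, pre$col_start, pre$n_off,
                 pre$p1_hydro, pre$target, pre$head, as.integer(use_idx),
                 cfg$hidden_units, cfg$iterations, cfg$burn_in_iterations,
                 cfg$learning_rate, cfg$initial_weight_range)
  net <- structure(list(w1 = w$w1, b1 = w$b1, w2_ba = w$w2_ba,
                        b2_ba = w$b2_ba, w2_el = w$w2_el, b2_el = w$b2_el,
                        config = cfg, encoder = encoder,
                        context_mode = context_mode,
                        dim = nrow(w$w1)), class = "mhc2_network")
  attr(net, "n_draws") <- w$n_draws
  net
}

#' Cross-validation run configuration
#'
#' The ensemble size is \code{|seeds| x |hidden_sizes| x n_partitions}; the
#' conventional full setting (10 seeds, hidden sizes 2/10/20/40/60, 5
#' partitions) yields 250 networks.
#'
#' @param seeds Integer seeds.
#' @param hidden_sizes Hidden-layer sizes.
#' @param n_partitions Number of cross-validation partitions.
#' @param context_mode Train with context features?
#' @param iterations,burn_in_iterations,learning_rate,initial_weight_range
#'   Passed to each [network_config()].
#' @return An object of class \code{train_run_config}.
#' @export
run_config <- function(seeds = 1:10, hidden_sizes = c(2L, 10L, 20L, 40L, 60L),
                       n_partitions = 5L, context_mode = TRUE,
                       iterations = 400L, burn_in_iterations = 1L,
                       learning_rate = 0.05, initial_weight_range = 0.1) {
  structure(list(seeds = as.integer(seeds),
                 hidden_sizes = as.integer(hidden_sizes),
                 n_partitions = as.integer(n_partitions),
                 context_mode = context_mode,
                 iterations = as.integer(iterations),
                 burn_in_iterations = as.integer(burn_in_iterations),
                 learning_rate = learning_rate,
                 initial_weight_range = initial_weight_range,
                 balanced_mixing = TRUE),
            class = "train_run_config")
}

#' Ensemble size implied by a run configuration
#' @param cfg A [run_config()].
#' @return Integer: seeds x hidden sizes x partitions.
#' @export
ensemble_size <- function(cfg) {
  length(cfg$seeds) * length(cfg$hidden_sizes) * cfg$n_partitions
}

# Deterministic per-network seed; unique for seeds < ~2e5, hidden < 100,
# folds < 10.
.net_seed <- function(seed, hidden, fold) {
  as.integer((seed * 100L + hidden) * 10L + fold)
}

#' Cross-validated training of the full ensemble
#'
#' For each fold, trains \code{|seeds| x |hidden_sizes|} networks on the
#' other partitions and predicts the held-out one, so that every instance
#' receives exactly one out-of-fold score per output head. The out-of-fold
#' core reported for each instance is the one selected by the fold member
#' with the maximal EL prediction.
#'
#' @param data Instance table with a populated \code{partition} column
#'   (1-based labels from [common_motif_partition()]).
#' @param cfg A [run_config()].
#' @param encoder An [encoder_config()].
#' @return An object of class \code{mhc2_cv}: list with \code{predictions}
#'   (row-aligned data frame with \code{el_score}, \code{ba_score},
#'   \code{core_offset}, \code{core}, \code{fold}), \code{models} (all
#'   trained networks) and \code{run_cfg}.
#' @export
cross_validate <- function(data, cfg = run_config(),
                           encoder = encoder_config()) {
  data <- .validate_table(data, training = TRUE)
  if (is.null(data$partition) || any(is.na(data$partition)))
    stop("data must carry a complete 'partition' column")
  part <- as.integer(data$partition)
  k <- cfg$n_partitions
  if (!setequal(unique(part), seq_len(k)))
    stop("every partition 1..k must be non-empty")
  pre <- .precompute(data, encoder, cfg$context_mode)
  n <- nrow(data)
  el_score <- ba_score <- numeric(n)
  best_el <- rep(-Inf, n)
  core_off <- integer(n)
  models <- list()
  for (f in seq_len(k)) {
    train_idx <- which(part != f) - 1L
    test_idx0 <- which(part == f) - 1L
    test_rows <- which(part == f)
    n_nets <- 0L
    for (s in cfg$seeds) for (h in cfg$hidden_sizes) {
      ncfg <- network_config(h, .net_seed(s, h, f), cfg$iterations,
                             cfg$burn_in_iterations, cfg$learning_rate,
                             cfg$initial_weight_range)
      net <- train_fold(NULL, ncfg, cfg$context_mode, encoder, pre = pre,
                        use_idx = train_idx)
      attr(net, "fold") <- f
      attr(net, "base_seed") <- s
      attr(net, "train_rows") <- train_idx + 1L
      models[[length(models) + 1L]] <- net
      n_nets <- n_nets + 1L
      pr_el <- cpp_predict(pre$features, pre$ctx_features, pre$col_start,
                           pre$n_off, test_idx0, net$w1, net$b1, net$w2_el,
                           net$b2_el)
      pr_ba <- cpp_predict(pre$features, pre$ctx_features, pre$col_start,
                           pre$n_off, test_idx0, net$w1, net$b1, net$w2_ba,
                           net$b2_ba)
      el_score[test_rows] <- el_score[test_rows] + pr_el$score
      ba_score[test_rows] <- ba_score[test_rows] + pr_ba$score
      upd <- pr_el$score > best_el[test_rows]
      best_el[test_rows[upd]] <- pr_el$score[upd]
      core_off[test_rows[upd]] <- pr_el$offset[upd]
    }
    el_score[test_rows] <- el_score[test_rows] / n_nets
    ba_score[test_rows] <- ba_score[test_rows] / n_nets
    .log_msg("fold %d: trained %d networks on %d instances, scored %d",
             f, n_nets, length(train_idx), length(test_rows))
  }
  preds <- data.frame(peptide = data$peptide, data_type = data$data_type,
                      target = data$target, fold = part,
                      el_score = el_score, ba_score = ba_score,
                      core_offset = core_off,
                      core = substr(data$peptide, core_off + 1L,
                                    core_off + 9L),
                      stringsAsFactors = FALSE)
  structure(list(predictions = preds, models = models, run_cfg = cfg,
                 encoder = encoder), class = "mhc2_cv")
}

#' @export
print.mhc2_cv <- function(x, ...) {
  cat(sprintf("<mhc2_cv> %d networks, %d instances, %d folds\n",
              length(x$models), nrow(x$predictions),
              x$run_cfg$n_partitions))
  invisible(x)
}
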