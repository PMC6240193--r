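# The two-output shallow network. One hidden layer is shared between the
# binding-affinity (BA) and eluted-ligand (EL) data types; each data type
# has its own hidden-to-output weights, so information transfers through the
# shared input weights while the output scales stay type-specific.

#' Network hyper-parameters
#'
#' @param hidden_units Hidden-layer size. Ensembles conventionally combine
#'   2, 10, 20, 40 and 60 units.
#' @param seed Integer seed for weight initialisation and training draws.
#' @param iterations Training iterations (default 400, no early stopping).
#'   One iteration performs N stochastic updates, N = training-set size.
#' @param burn_in_iterations Initial iterations during which the core search
#'   only admits offsets whose P1 residue is hydrophobic (default 1).
#' @param learning_rate Online gradient-descent step size.
#' @param initial_weight_range Weights start uniform in +/- this value.
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(hidden_units = 10L, seed = 1L, iterations = 400L,
                           burn_in_iterations = 1L, learning_rate = 0.05,
                           initial_weight_range = 0.1) {
  if (iterations <= burn_in_iterations || burn_in_iterations < 0)
    stop("iterations must exceed burn_in_iterations >= 0")
  if (hidden_units < 1) stop("hidden_units must be positive")
  structure(list(hidden_units = as.integer(hidden_units),
                 seed = as.integer(seed),
                 iterations = as.integer(iterations),
                 burn_in_iterations = as.integer(burn_in_iterations),
                 learning_rate = learning_rate,
                 initial_weight_range = initial_weight_range),
            class = "network_config")
}

.feature_dim <- function(context_mode) 231L + if (context_mode) 240L else 0L

#' Initialise an untrained network
#'
#' Draws all weights uniformly in \code{+/- initial_weight_range} under the
#' configuration seed.
#'
#' @param encoder An [encoder_config()].
#' @param config A [network_config()].
#' @param context_mode Does the input include the 12x20 context block?
#' @return An object of class \code{mhc2_network}.
#' @export
new_network <- function(encoder = encoder_config(), config = network_config(),
                        context_mode = TRUE) {
  D <- .feature_dim(context_mode)
  h <- config$hidden_units
  set.seed(config$seed)
  r <- config$initial_weight_range
  structure(list(
    w1 = matrix(runif(D * h, -r, r), nrow = D, ncol = h),
    b1 = runif(h, -r, r),
    w2_ba = runif(h, -r, r), b2_ba = runif(1, -r, r),
    w2_el = runif(h, -r, r), b2_el = runif(1, -r, r),
    config = config, encoder = encoder, context_mode = context_mode,
    dim = D), class = "mhc2_network")
}

.head_weights <- function(m, head) {
  if (head == "BA") list(w2 = m$w2_ba, b2 = m$b2_ba)
  else list(w2 = m$w2_el, b2 = m$b2_el)
}

#' Forward pass of the two-output network
#'
#' Logistic-sigmoid hidden layer followed by the logistic output of the
#' selected head. Accepts an [encode_instance()] result or a raw feature
#' vector.
#'
#' @param x Encoded instance or numeric feature vector.
#' @param m An \code{mhc2_network}.
#' @param head \code{"EL"} or \code{"BA"}.
#' @return Prediction in (0, 1).
#' @export
forward_pass <- function(x, m, head = c("EL", "BA")) {
  head <- match.arg(head)
  if (inherits(x, "encoded_instance")) x <- x$features
  if (length(x) != m$dim)
    stop(sprintf("feature-length mismatch: got %d, model expects %d",
                 length(x), m$dim))
  hh <- plogis(drop(crossprod(m$w1, x)) + m$b1)
  hw <- .head_weights(m, head)
  plogis(sum(hw$w2 * hh) + hw$b2)
}

#' Select the binding core of a peptide under a model
#'
#' Evaluates the forward pass at every admissible core offset using the head
#' matching the instance's data type and returns the arg-max offset (ties go
#' to the smallest offset). While \code{iteration} is below the burn-in
#' count, only offsets whose P1 residue is hydrophobic are admitted; if no
#' such offset exists for a peptide, all offsets are admitted for it.
#'
#' @param p A [peptide_instance()] (length >= 9).
#' @param m An \code{mhc2_network}.
#' @param iteration Current training iteration (default \code{Inf}: burn-in
#'   over).
#' @return An object of class \code{core_alignment} with fields
#'   \code{offset} (0-based), \code{core}, \code{per_offset_scores} and
#'   \code{burn_in_active}.
#' @export
select_core <- function(p, m, iteration = Inf) {
  p <- .as_instance(p)
  L <- nchar(p$sequence)
  if (L < 9) stop("peptide shorter than the 9-residue core")
  df <- data.frame(peptide = p$sequence, target = p$target,
                   data_type = p$data_type, context_up = p$context_up,
                   context_down = p$context_down,
                   stringsAsFactors = FALSE)
  pre <- .precompute(df, m$encoder, m$context_mode)
  hw <- .head_weights(m, p$data_type)
  cvec <- if (m$context_mode) pre$ctx_features[, 1] else numeric(0)
  scores <- cpp_forward_cols(pre$features, seq_len(pre$n_off[1]) - 1L,
                             cvec, m$w1, m$b1, hw$w2, hw$b2)
  burn <- is.finite(iteration) && iteration < m$config$burn_in_iterations
  adm <- if (burn && any(pre$p1_hydro)) pre$p1_hydro else rep(TRUE, length(scores))
  cand <- which(adm)
  off <- cand[which.max(scores[cand])] - 1L
  structure(list(offset = off,
                 core = substr(p$sequence, off + 1L, off + 9L),
                 per_offset_scores = scores,
                 burn_in_active = burn), class = "core_alignment")
}

#' One online gradient step on a single instance
#'
#' Squared-error loss at the head matching the instance's data type,
#' back-propagated through the encoding of the selected core. The shared
#' input weights and the matching head's output weights move opposite the
#' gradient; the other head's output weights are untouched.
#'
#' @param p A [peptide_instance()].
#' @param m An \code{mhc2_network}.
#' @param alignment A \code{core_alignment} produced by [select_core()] on
#'   the current weights.
#' @return The updated \code{mhc2_network}.
#' @export
backward_update <- function(p, m, alignment) {
  p <- .as_instance(p)
  x <- encode_instance(p, alignment$offset, m$encoder, m$context_mode)$features
  lr <- m$config$learning_rate
  hh <- plogis(drop(crossprod(m$w1, x)) + m$b1)
  hw <- .head_weights(m, p$data_type)
  out <- plogis(sum(hw$w2 * hh) + hw$b2)
  d_out <- (out - p$target) * out * (1 - out)
  d_h <- d_out * hw$w2 * hh * (1 - hh)
  w2_new <- hw$w2 - lr * d_out * hh
  b2_new <- hw$b2 - lr * d_out
  m$w1 <- m$w1 - lr * tcrossprod(x, d_h)
  m$b1 <- m$b1 - lr * d_h
  if (p$data_type == "BA") { m$w2_ba <- w2_new; m$b2_ba <- b2_new }
  else { m$w2_el <- w2_new; m$b2_el <- b2_new }
  m
}

# Analytic gradient of L = 0.5 * (out - target)^2 wrt every weight block,
# at a fixed encoded input. Used by the finite-difference correctness tests
# and equals (w - backward_update(w)) / lr up to float round-off.
.gradient <- function(x, m, target, head) {
  if (inherits(x, "encoded_instance")) x <- x$features
  hh <- plogis(drop(crossprod(m$w1, x)) + m$b1)
  hw <- .head_weights(m, head)
  out <- plogis(sum(hw$w2 * hh) + hw$b2)
  d_out <- (out - target) * out * (1 - out)
  d_h <- d_out * hw$w2 * hh * (1 - hh)
  list(w1 = tcrossprod(x, d_h), b1 = d_h, w2 = d_out * hh, b2 = d_out)
}

#' Ensemble prediction for peptides
#'
#' Scores each peptide with every network in the ensemble (each network at
#' its own selected core) and averages the predictions. The reported core is
#' the one selected by the member with the maximal prediction.
#'
#' @param peptides Character vector of peptides, or an instance table with a
#'   \code{peptide} column (context columns are used when the ensemble was
#'   trained in context mode).
#' @param ensemble A list of \code{mhc2_network} objects (or an
#'   \code{mhc2_ensemble}).
#' @param head \code{"EL"} or \code{"BA"}.
#' @return Data frame with columns \code{peptide}, \code{score},
#'   \code{core}, \code{offset} (0-based).
#' @export
predict_ensemble <- function(peptides, ensemble, head = c("EL", "BA")) {
  head <- match.arg(head)
  nets <- if (inherits(ensemble, "mhc2_ensemble")) ensemble$networks else ensemble
  if (inherits(nets, "mhc2_network")) nets <- list(nets)
  if (length(nets) == 0) stop("empty ensemble")
  if (is.character(peptides))
    peptides <- data.frame(peptide = peptides, target = 0,
                           data_type = head, stringsAsFactors = FALSE)
  df <- .validate_table(peptides)
  ctxm <- nets[[1]]$context_mode
  if (!all(vapply(nets, function(n) n$context_mode, TRUE) == ctxm))
    stop("ensemble members disagree on context mode")
  pre <- .precompute(df, nets[[1]]$encoder, ctxm)
  idx <- seq_len(nrow(df)) - 1L
  acc <- numeric(nrow(df))
  best_score <- rep(-Inf, nrow(df))
  best_off <- integer(nrow(df))
  for (m in nets) {
    hw <- .head_weights(m, head)
    pr <- cpp_predict(pre$features, pre$ctx_features, pre$col_start,
                      pre$n_off, idx, m$w1, m$b1, hw$w2, hw$b2)
    acc <- acc + pr$score
    upd <- pr$score > best_score
    best_score[upd] <- pr$score[upd]
    best_off[upd] <- pr$offset[upd]
  }
  data.frame(peptide = df$peptide, score = acc / length(nets),
             core = substr(df$peptide, best_off + 1L, best_off + 9L),
             offset = best_off, stringsAsFactors = FALSE)
}

# ---- serialization ---------------------------------------------------------

.net_to_list <- function(m) {
  list(w1 = as.numeric(m$w1), b1 = m$b1, w2_ba = m$w2_ba, b2_ba = m$b2_ba,
       w2_el = m$w2_el, b2_el = m$b2_el,
       hidden_units = m$config$hidden_units, seed = m$config$seed,
       iterations = m$config$iterations,
       burn_in_iterations = m$config$burn_in_iterations,
       learning_rate = m$config$learning_rate,
       initial_weight_range = m$config$initial_weight_range,
       context_mode = m$context_mode, dim = m$dim)
}

.net_from_list <- function(l, encoder) {
  cfg <- network_config(l$hidden_units, l$seed, l$iterations,
                        l$burn_in_iterations, l$learning_rate,
                        l$initial_weight_range)
  structure(list(w1 = matrix(l$w1, nrow = l$dim, ncol = l$hidden_units),
                 b1 = l$b1, w2_ba = l$w2_ba, b2_ba = l$b2_ba,
                 w2_el = l$w2_el, b2_el = l$b2_el, config = cfg,
                 encoder = encoder, context_mode = l$context_mode,
                 dim = l$dim), class = "mhc2_network")
}

#' Save a model (network or ensemble) to a JSON container
#'
#' Writes a versioned flat JSON file recording the encoder configuration,
#' the alphabet order and all weight blocks at full floating-point
#' precision; [load_model()] round-trips bit-exactly.
#'
#' @param model An \code{mhc2_network}, a list of them, or an
#'   \code{mhc2_ensemble}.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  nets <- if (inherits(model, "mhc2_ensemble")) model$networks
          else if (inherits(model, "mhc2_network")) list(model)
          else model
  enc <- nets[[1]]$encoder
  obj <- list(format = "mhc2lig-model", version = 1L,
              alphabet = paste(.AA20, collapse = ""),
              encoder = list(substitution_matrix = enc$substitution_matrix,
                             scale = enc$scale,
                             hydrophobic_set = enc$hydrophobic_set,
                             core_length = enc$core_length,
                             pfr_window = enc$pfr_window,
                             context_block = enc$context_block),
              networks = lapply(nets, .net_to_list))
  # 17 significant digits guarantee IEEE-double round-trip exactness
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path JSON model file.
#' @return An \code{mhc2_ensemble} (list with element \code{networks}).
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "mhc2lig-model"))
    stop("not a mhc2lig model file")
  if (!identical(obj$alphabet, paste(.AA20, collapse = "")))
    stop("model alphabet does not match this package build")
  enc <- encoder_config(obj$encoder$substitution_matrix, obj$encoder$scale,
                        obj$encoder$hydrophobic_set,
                        obj$encoder$core_length, obj$encoder$pfr_window,
                        obj$encoder$context_block)
  nets <- lapply(obj$networks, .net_from_list, encoder = enc)
  structure(list(networks = nets, encoder = enc,
                 context_mode = nets[[1]]$context_mode),
            class = "mhc2_ensemble")
}
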