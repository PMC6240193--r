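# Residue alphabet and peptide feature encoding. Every matrix in the package
# (substitution rows, PSSMs, processing matrices, logo matrices) uses the
# same fixed 20-letter ordering returned by aa_alphabet().

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.HYDROPHOBIC_DEFAULT <- c("F", "I", "L", "M", "V", "W", "Y", "A")

#' The 20 standard amino acids in package order
#'
#' One-letter codes in the fixed ordering used for every residue-indexed
#' matrix in the package. The wildcard \code{"X"} is not part of the
#' alphabet; it encodes to an all-zero vector wherever it appears.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() .AA20

# Integer-code a peptide: 1..20 in alphabet order, 0 for the X wildcard.
# Unknown letters are an error naming the letter and its position.
.aa_index <- function(sequence, what = "peptide") {
  ch <- strsplit(sequence, "")[[1]]
  idx <- match(ch, .AA20)
  idx[ch == "X"] <- 0L
  bad <- which(is.na(idx))
  if (length(bad) > 0)
    stop(sprintf("unknown residue '%s' at position %d of %s '%s'",
                 ch[bad[1]], bad[1], what, sequence), call. = FALSE)
  idx
}

.subst_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(env[[name]]))
    stop(sprintf("unknown substitution matrix '%s'", name), call. = FALSE)
  env[[name]]
}

#' Encoder configuration
#'
#' Bundles the residue-encoding scheme shared by all model operations: a
#' 20x20 substitution matrix (rows divided by \code{scale}), the set of
#' residues treated as hydrophobic for the burn-in restricted P1 search, the
#' fixed 9-residue core length, the flanking-region window and the context
#' block size.
#'
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default \code{"BLOSUM50"}).
#' @param scale Positive divisor applied to the matrix entries (default 5).
#' @param hydrophobic_set Residues admitted at the P1 anchor during the
#'   burn-in training iteration.
#' @param core_length Binding-core length; fixed at 9 for MHC class II.
#' @param pfr_window Number of flank residues per side summarised into the
#'   peptide-flanking-region composition features (default 3).
#' @param context_block Number of source-protein context residues per side
#'   (default 3).
#' @return An object of class \code{encoder_config}.
#' @export
encoder_config <- function(substitution_matrix = "BLOSUM50", scale = 5,
                           hydrophobic_set = .HYDROPHOBIC_DEFAULT,
                           core_length = 9L, pfr_window = 3L,
                           context_block = 3L) {
  if (core_length != 9L) stop("core_length is fixed at 9")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  if (length(hydrophobic_set) == 0) stop("hydrophobic_set must be non-empty")
  if (!all(hydrophobic_set %in% .AA20))
    stop("hydrophobic_set contains letters outside the alphabet")
  m <- .subst_matrix(substitution_matrix)
  if (!all(.AA20 %in% rownames(m)))
    stop("substitution matrix does not cover the 20 standard residues")
  enc <- m[.AA20, .AA20] / scale
  structure(list(substitution_matrix = substitution_matrix, scale = scale,
                 hydrophobic_set = hydrophobic_set, core_length = 9L,
                 pfr_window = as.integer(pfr_window),
                 context_block = as.integer(context_block),
                 matrix = enc),
            class = "encoder_config")
}

#' Encode one residue as a 20-vector
#'
#' Returns the alphabet-ordered substitution-matrix row for the residue,
#' divided by the configured scale. The wildcard \code{"X"} returns the zero
#' vector.
#'
#' @param residue Single one-letter code.
#' @param config An [encoder_config()].
#' @return Named numeric vector of length 20.
#' @export
encode_residue <- function(residue, config = encoder_config()) {
  stopifnot(is.character(residue), nchar(residue) == 1)
  if (residue == "X") return(setNames(numeric(20), .AA20))
  if (!residue %in% .AA20)
    stop(sprintf("unknown residue '%s' at position 1", residue), call. = FALSE)
  config$matrix[residue, ]
}

#' One-hot length-bin encoding
#'
#' One neuron per peptide length 11 to 19. Lengths outside that range are an
#' error for training inputs; for prediction-only inputs the nearest bin is
#' used and a warning is logged.
#'
#' @param length Integer peptide length.
#' @param strict If \code{TRUE} (training), lengths outside 11-19 are
#'   rejected; if \code{FALSE}, they map to the nearest bin with a warning.
#' @return Numeric 9-vector summing to 1.
#' @export
encode_length_bins <- function(length, strict = TRUE) {
  length <- as.integer(length)
  if (length < 11L || length > 19L) {
    if (strict)
      stop(sprintf("peptide length %d outside the 11-19 training range", length),
           call. = FALSE)
    warning(sprintf("length %d mapped to nearest length bin", length),
            call. = FALSE)
    length <- min(max(length, 11L), 19L)
  }
  v <- numeric(9)
  v[length - 10L] <- 1
  v
}

#' Construct a peptide instance
#'
#' One training or prediction record: the peptide, its target value, the
#' data type (in vitro binding affinity \code{"BA"} or mass-spectrometry
#' eluted ligand \code{"EL"}), the three source-protein context residues on
#' either side (\code{"XXX"} when unknown), and bookkeeping fields.
#'
#' @param sequence Peptide string over the 20-letter alphabet (plus
#'   \code{X}).
#' @param target Real value in \[0, 1\]: transformed affinity for BA,
#'   1/0 label for EL.
#' @param data_type \code{"EL"} or \code{"BA"}.
#' @param context_up,context_down 3-letter context strings.
#' @param source_protein_id Optional source protein identifier.
#' @param partition Optional cross-validation partition (1-5).
#' @return An object of class \code{peptide_instance}.
#' @export
peptide_instance <- function(sequence, target, data_type = c("EL", "BA"),
                             context_up = "XXX", context_down = "XXX",
                             source_protein_id = NA_character_,
                             partition = NA_integer_) {
  data_type <- match.arg(data_type)
  .aa_index(sequence)
  if (nchar(context_up) != 3 || nchar(context_down) != 3)
    stop("context strings must have length 3")
  .aa_index(context_up, "context")
  .aa_index(context_down, "context")
  if (!is.numeric(target) || target < 0 || target > 1)
    stop("target must lie in [0, 1]")
  structure(list(sequence = sequence, target = target, data_type = data_type,
                 context_up = context_up, context_down = context_down,
                 source_protein_id = source_protein_id,
                 partition = partition),
            class = "peptide_instance")
}

.as_instance <- function(p) {
  if (inherits(p, "peptide_instance")) return(p)
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- as.list(p)
  }
  if (is.list(p) && !is.null(p$sequence) && is.null(p$peptide)) p$peptide <- p$sequence
  peptide_instance(p$peptide, p$target, p$data_type,
                   if (is.null(p$context_up) || is.na(p$context_up)) "XXX" else p$context_up,
                   if (is.null(p$context_down) || is.na(p$context_down)) "XXX" else p$context_down,
                   if (is.null(p$source_protein_id)) NA_character_ else p$source_protein_id,
                   if (is.null(p$partition)) NA_integer_ else p$partition)
}

# 12-residue context block codes for one instance: N-context(3),
# N-terminal peptide(3), C-context(3), C-terminal peptide(3). BA instances
# carry an all-zero block (wildcard context, per the training convention for
# affinity data whose source protein is unknown).
.ctx12 <- function(sequence, data_type, context_up, context_down) {
  if (data_type == "BA") return(integer(12))
  L <- nchar(sequence)
  pep <- .aa_index(sequence)
  c(.aa_index(context_up, "context"), pep[1:3],
    .aa_index(context_down, "context"), pep[(L - 2):L])
}

#' Encode a peptide instance at a candidate core offset
#'
#' Concatenates the 9x20 core block starting at \code{offset}, the
#' peptide-flanking-region composition and length features for both flanks,
#' the one-hot length bins, and (when \code{context_mode} is on) the four
#' 3-residue context blocks. BA instances always carry an all-zero context
#' block. The flat feature vector has the same length for every peptide
#' under one configuration.
#'
#' @param p A [peptide_instance()] (or coercible list / 1-row data frame).
#' @param offset 0-based core start, \code{0 <= offset <= length - 9}.
#' @param config An [encoder_config()].
#' @param context_mode Include the 12x20 context block?
#' @return An object of class \code{encoded_instance} with fields
#'   \code{features} (flat vector), \code{core_features} (9x20),
#'   \code{pfr_features}, \code{length_bins}, \code{context_features}
#'   (12x20 or NULL) and \code{offset}.
#' @export
encode_instance <- function(p, offset, config = encoder_config(),
                            context_mode = TRUE) {
  p <- .as_instance(p)
  L <- nchar(p$sequence)
  if (offset < 0 || offset > L - 9)
    stop(sprintf("offset %d out of range for a %d-mer", offset, L))
  pep <- .aa_index(p$sequence)
  ctx <- .ctx12(p$sequence, p$data_type, p$context_up, p$context_down)
  feats <- cpp_encode_features(pep, as.integer(offset), ctx, config$matrix,
                               context_mode, config$pfr_window)
  ctxf <- NULL
  if (context_mode)
    ctxf <- matrix(feats[232:471], nrow = 12, ncol = 20, byrow = TRUE,
                   dimnames = list(NULL, .AA20))
  structure(list(
    features = feats,
    core_features = matrix(feats[1:180], nrow = 9, ncol = 20, byrow = TRUE,
                           dimnames = list(paste0("P", 1:9), .AA20)),
    pfr_features = feats[181:222],
    length_bins = feats[223:231],
    context_features = ctxf,
    offset = as.integer(offset)), class = "encoded_instance")
}

#' @export
print.encoded_instance <- function(x, ...) {
  cat(sprintf("<encoded_instance> offset %d, %d features\n",
              x$offset, length(x$features)))
  invisible(x)
}

# Precompute the dense feature matrix for a whole instance table: one column
# per (peptide, offset) pair, plus the burn-in admissibility flags.
.precompute <- function(df, config, context_mode) {
  peps <- lapply(df$peptide, .aa_index)
  ctx <- t(mapply(.ctx12, df$peptide, df$data_type,
                  ifelse(is.na(df$context_up), "XXX", df$context_up),
                  ifelse(is.na(df$context_down), "XXX", df$context_down),
                  USE.NAMES = FALSE))
  if (nrow(df) == 1) ctx <- matrix(as.integer(ctx), nrow = 1)
  storage.mode(ctx) <- "integer"
  hydro <- .AA20 %in% config$hydrophobic_set
  pre <- cpp_precompute(peps, ctx, config$matrix, context_mode,
                        config$pfr_window, hydro)
  pre$head <- as.integer(df$data_type == "EL")
  pre$target <- as.numeric(df$target)
  pre
}

# Canonical columns of an instance table; validates and fills defaults.
.validate_table <- function(df, training = FALSE) {
  stopifnot(is.data.frame(df), nrow(df) > 0, !is.null(df$peptide))
  if (is.null(df$target)) df$target <- 0
  if (is.null(df$data_type)) df$data_type <- "EL"
  if (is.null(df$context_up)) df$context_up <- "XXX"
  if (is.null(df$context_down)) df$context_down <- "XXX"
  if (is.null(df$source_protein_id)) df$source_protein_id <- NA_character_
  if (!all(df$data_type %in% c("BA", "EL")))
    stop("data_type must be 'BA' or 'EL'")
  if (any(df$target < 0 | df$target > 1)) stop("targets must lie in [0, 1]")
  if (training) {
    len <- nchar(df$peptide)
    bad <- df$data_type == "EL" & (len < 11 | len > 19)
    if (any(bad))
      stop(sprintf("%d EL training peptides outside the 11-19 length range",
                   sum(bad)))
  }
  df
}

# Drop rows whose peptide (or context) contains letters outside the
# alphabet (e.g. post-translationally modified or ambiguous residues);
# logs the removed count.
.filter_nonstandard <- function(df) {
  ok <- vapply(df$peptide, function(s) {
    ch <- strsplit(s, "")[[1]]
    all(ch %in% c(.AA20, "X"))
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok))
    .log_msg("filtered %d entries with nonstandard residues", sum(!ok))
  df[ok, , drop = FALSE]
}
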