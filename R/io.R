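# Format round-tripping and run manifests. Peptide tables are
# whitespace-separated text with a documented header; proteins are FASTA
# (via Biostrings); models and manifests are JSON.

.as_protein_vector <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("PROT%04d", seq_along(x))
    return(x)
  }
  stop("proteins must be a named character vector or AAStringSet")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector (names truncated at the first
#'   whitespace).
#' @export
read_fasta <- function(path) {
  .as_protein_vector(Biostrings::readAAStringSet(path))
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector (or \code{AAStringSet}).
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  x <- Biostrings::AAStringSet(.as_protein_vector(proteins))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

.TABLE_COLS <- c("peptide", "target", "data_type", "context_up",
                 "context_down", "source_protein_id")

#' Read a peptide table
#'
#' Whitespace/TAB-separated text with columns \code{peptide target
#' data_type [context_up context_down [source_protein_id]]}; a header line
#' starting with \code{peptide} is recognised and optional. \code{-} marks
#' missing context (stored as \code{XXX}) or a missing source protein
#' (stored as \code{NA}).
#'
#' @param path Input file.
#' @return Instance table (data frame).
#' @export
read_peptide_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^\\s*peptide(\\s|$)", first)
  df <- utils::read.table(path, header = has_header,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!has_header) {
    if (!ncol(df) %in% c(3L, 5L, 6L))
      stop("peptide table must have 3, 5 or 6 columns")
    names(df) <- .TABLE_COLS[seq_len(ncol(df))]
  }
  df$target <- as.numeric(df$target)
  for (col in c("context_up", "context_down"))
    if (!is.null(df[[col]])) df[[col]][df[[col]] == "-"] <- "XXX"
  if (!is.null(df$source_protein_id))
    df$source_protein_id[df$source_protein_id == "-"] <- NA_character_
  df <- .filter_nonstandard(df)
  .validate_table(df)
}

#' Write a peptide table
#'
#' Writes the canonical columns with a header; numeric targets are fixed at
#' six decimals, missing source proteins become \code{-}. Reading the
#' result back yields the same table.
#'
#' @param df Instance table.
#' @param path Output file.
#' @export
write_peptide_table <- function(df, path) {
  df <- .validate_table(df)
  out <- data.frame(peptide = df$peptide,
                    target = sprintf("%.6f", df$target),
                    data_type = df$data_type,
                    context_up = df$context_up,
                    context_down = df$context_down,
                    source_protein_id = ifelse(is.na(df$source_protein_id),
                                               "-", df$source_protein_id),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Score a peptide table with both output heads
#'
#' @param peptides Character vector or instance table.
#' @param ensemble Trained ensemble (or list of networks).
#' @return Data frame with \code{peptide}, \code{core}, \code{el_score},
#'   \code{ba_score} (scores at each head's own selected core; the
#'   reported core is the EL one).
#' @export
predict_peptides <- function(peptides, ensemble) {
  el <- predict_ensemble(peptides, ensemble, head = "EL")
  ba <- predict_ensemble(peptides, ensemble, head = "BA")
  data.frame(peptide = el$peptide, core = el$core,
             el_score = el$score, ba_score = ba$score,
             stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, input-file digests, package
#' version and a timestamp next to a run's outputs, so that the run can be
#' replayed bit-exactly.
#'
#' @param path Output JSON file.
#' @param config Named list: the configuration snapshot.
#' @param seeds Integer seeds used.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @export
write_manifest <- function(path, config = list(), seeds = integer(0),
                           inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(package = "mhc2lig",
              version = as.character(utils::packageVersion("mhc2lig")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seeds = seeds, config = config, input_md5 = digests)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#' @param path Manifest JSON file.
#' @return Named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
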