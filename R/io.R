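# File formats: FASTA and a TSV efficacy-table dialect for sequences,
# JSON for fitted models and for evaluation metrics, TSV for cluster
# assignments.

#' Read siRNA sequences from FASTA or TSV
#'
#' FASTA input yields records with ids from the headers and no efficiency.
#' The TSV dialect is tab-separated with a header line and columns
#' `id`, `sequence`, and optionally `efficiency` (percent) and `label`.
#' Sequences are normalized (T to U, uppercased); duplicate ids, illegal
#' characters and empty files are distinct errors.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.fa`/`.fasta` vs anything else),
#'   `"fasta"` or `"tsv"`.
#' @param threshold optional efficacy threshold in percent; when given and
#'   an `efficiency` column is present, labels are derived from it.
#' @param inclusive passed to [sirna_set()]: efficacy at the threshold
#'   counts as effective when `TRUE` (default).
#' @return a `sirna_set`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "tsv"),
                           threshold = NULL, inclusive = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (file.size(path) == 0) {
    stop("empty input file: ", path, call. = FALSE)
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(ss))
    return(sirna_set(as.character(ss), id = ids))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no data rows in ", path, call. = FALSE)
  need <- c("id", "sequence")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("TSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sirna_set(
    tab$sequence, id = tab$id,
    efficiency = if ("efficiency" %in% names(tab)) tab$efficiency else NULL,
    label = if ("label" %in% names(tab)) tab$label else NULL,
    threshold = threshold, inclusive = inclusive
  )
}

#' Write siRNA records to FASTA or TSV
#'
#' @param records a `sirna_set`.
#' @param path output path.
#' @param format `"fasta"` or `"tsv"` (the dialect of [read_sequences()]).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(records, "sirna_set"))
  if (format == "fasta") {
    writeLines(paste0(">", records$id, "\n", records$seq), path)
  } else {
    out <- data.frame(id = records$id, sequence = records$seq,
                      efficiency = records$efficiency, label = records$label,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Serialize a Markov model to JSON
#'
#' The document records the order, length, pseudocount, the initial h-mer
#' distribution, and one row per (position, context, base) transition
#' probability. Probabilities are written at full double precision so a
#' model round-trips exactly.
#'
#' @param model a `markov_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markov_model <- function(model, path) {
  stopifnot(inherits(model, "markov_model"))
  rows <- do.call(rbind, lapply(names(model$transitions), function(j) {
    tr <- model$transitions[[j]]
    data.frame(position = as.integer(j),
               context = rep(rownames(tr), times = ncol(tr)),
               base = rep(colnames(tr), each = nrow(tr)),
               prob = as.vector(tr), stringsAsFactors = FALSE)
  }))
  rows <- rows[rows$prob > 0, , drop = FALSE]
  doc <- list(
    order = model$order, length = model$length,
    pseudocount = model$pseudocount,
    position_specific = model$position_specific,
    n_training = model$n_training,
    initial = as.list(model$initial[model$initial > 0]),
    transitions = rows
  )
  # 17 significant digits round-trip an IEEE double exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a Markov model from JSON
#'
#' @param path a JSON file written by [write_markov_model()].
#' @return a `markov_model`.
#' @export
read_markov_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- as.integer(doc$order)
  L <- as.integer(doc$length)
  kmers <- all_kmers(h)
  initial <- stats::setNames(numeric(length(kmers)), kmers)
  initial[names(doc$initial)] <- unlist(doc$initial)
  transitions <- lapply((h + 1):L, function(j) {
    tr <- matrix(0, nrow = length(kmers), ncol = 4,
                 dimnames = list(kmers, RNA_BASES))
    rows <- doc$transitions[doc$transitions$position == j, , drop = FALSE]
    if (nrow(rows) > 0) tr[cbind(rows$context, rows$base)] <- rows$prob
    tr
  })
  names(transitions) <- (h + 1):L
  structure(
    list(order = h, length = L, pseudocount = doc$pseudocount,
         position_specific = isTRUE(doc$position_specific),
         initial = initial, transitions = transitions,
         n_training = if (is.null(doc$n_training)) NA_integer_
                      else doc$n_training),
    class = "markov_model"
  )
}

#' Write cluster assignments as TSV
#'
#' Columns: `id`, `value`, `cluster_id` and (for labeled clusterings)
#' `cluster_label`.
#'
#' @param clustering a `mini_clustering`.
#' @param path output path.
#' @param ids optional sequence identifiers.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(clustering, path, ids = NULL) {
  utils::write.table(as.data.frame(clustering, ids = ids), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write evaluation metrics as JSON
#'
#' @param result an `evaluation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
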