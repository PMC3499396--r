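#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize nucleotide sequences to the RNA alphabet
#'
#' Uppercases the input and maps DNA thymine (`T`) to uracil (`U`).
#' Any character outside `{A, C, G, U}` after this mapping is an error:
#' ambiguity codes and gaps are not meaningful for the Markov models used
#' here, so they are rejected rather than silently dropped.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of the same length over the `{A,C,G,U}` alphabet.
#' @examples
#' normalize_sequence(c("uaauc", "TACCG"))
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be a character vector", call. = FALSE)
  out <- chartr("acgut", "ACGUU", seq)
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop(
      "illegal character(s) in sequence(s) ",
      paste(which(bad), collapse = ", "),
      ": only A, C, G, U/T are allowed",
      call. = FALSE
    )
  }
  out
}

#' Construct a set of siRNA records
#'
#' The central container is a plain `data.frame` with class `sirna_set`
#' and columns `id`, `seq`, `efficiency` (percent knockdown, may be `NA`)
#' and `label` (one of `"effective"`, `"ineffective"`, `"unknown"`).
#'
#' If `efficiency` is supplied together with `threshold`, labels are derived
#' as `effective` when efficiency is greater than or equal to the threshold
#' (the conventional cutoff for siRNA knockdown efficacy is 80 percent).
#'
#' @param seq character vector of sequences (normalized on construction).
#' @param id identifiers; defaults to `s1, s2, ...`. Must be unique.
#' @param efficiency optional numeric vector of knockdown percentages in
#'   `[0, 100]`.
#' @param label optional character vector of labels; ignored when derived
#'   from `efficiency` and `threshold`.
#' @param threshold optional efficacy threshold in percent; when given,
#'   labels are recomputed from `efficiency`.
#' @param inclusive logical; if `TRUE` (default) a sequence is effective when
#'   `efficiency >= threshold`, if `FALSE` strictly greater (the convention
#'   used for shRNA sensor scores).
#' @return a `data.frame` of class `sirna_set`.
#' @examples
#' sirna_set(c("UAAUC", "AACGA"), efficiency = c(92, 40), threshold = 80)
#' @export
sirna_set <- function(seq, id = NULL, efficiency = NULL, label = NULL,
                      threshold = NULL, inclusive = TRUE) {
  seq <- normalize_sequence(seq)
  n <- length(seq)
  if (is.null(id)) {
    id <- if (n == 0) character(0) else paste0("s", seq_len(n))
  }
  id <- as.character(id)
  if (length(id) != n) stop("`id` and `seq` lengths differ", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(efficiency)) {
    efficiency <- rep(NA_real_, n)
  } else {
    efficiency <- as.numeric(efficiency)
    if (length(efficiency) != n) stop("`efficiency` length mismatch", call. = FALSE)
    if (any(!is.na(efficiency) & (efficiency < 0 | efficiency > 100))) {
      stop("`efficiency` must be a percentage in [0, 100]", call. = FALSE)
    }
  }
  if (is.null(label)) label <- rep("unknown", n)
  label <- as.character(label)
  if (length(label) != n) stop("`label` length mismatch", call. = FALSE)
  if (!all(label %in% c("effective", "ineffective", "unknown"))) {
    stop("labels must be 'effective', 'ineffective' or 'unknown'", call. = FALSE)
  }
  if (!is.null(threshold)) {
    has_eff <- !is.na(efficiency)
    hit <- if (inclusive) efficiency >= threshold else efficiency > threshold
    label[has_eff] <- ifelse(hit[has_eff], "effective", "ineffective")
  }
  out <- data.frame(
    id = id, seq = seq, efficiency = efficiency, label = label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sirna_set", "data.frame")
  out
}

#' @export
print.sirna_set <- function(x, ...) {
  cat(sprintf(
    "sirna_set: %d sequence(s), length %s; %d effective / %d ineffective / %d unknown\n",
    nrow(x),
    paste(sort(unique(nchar(x$seq))), collapse = ","),
    sum(x$label == "effective"), sum(x$label == "ineffective"),
    sum(x$label == "unknown")
  ))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

# internal: split equal-length sequences into an n x L character matrix
seq_matrix <- function(seq) {
  L <- unique(nchar(seq))
  if (length(L) != 1) {
    stop("sequences have heterogeneous lengths: ",
         paste(sort(L), collapse = ", "), call. = FALSE)
  }
  matrix(unlist(strsplit(seq, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}
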