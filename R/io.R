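#' Read a delimited score table
#'
#' Score tables are delimited text files with a header and at least the
#' columns `label` (0/1) and `score` (decimal). The delimiter is sniffed
#' from the header (tab or comma). Malformed rows are rejected with their
#' line numbers.
#'
#' @param path Path to the score table.
#' @param orientation Score orientation passed to [scored_dataset()];
#'   `"lower_is_positive"` negates scores at ingest.
#' @return A [scored_dataset()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_scores(scored_dataset(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)), f)
#' read_scores(f)
#' @export
read_scores <- function(path,
                        orientation = c("higher_is_positive",
                                        "lower_is_positive")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("score file not found: '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("score file '", path, "' has no data rows", call. = FALSE)
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  li <- match("label", header)
  si <- match("score", header)
  if (is.na(li) || is.na(si))
    stop("score file must have header columns 'label' and 'score'",
         call. = FALSE)
  n <- length(lines) - 1L
  labels <- integer(n); scores <- numeric(n)
  for (r in seq_len(n)) {
    fields <- trimws(strsplit(lines[r + 1L], sep, fixed = TRUE)[[1]])
    if (length(fields) < max(li, si))
      stop("line ", r + 1L, ": expected at least ", max(li, si),
           " fields", call. = FALSE)
    lab <- suppressWarnings(as.numeric(fields[li]))
    sc <- suppressWarnings(as.numeric(fields[si]))
    if (is.na(lab) || !(lab %in% c(0, 1)))
      stop("line ", r + 1L, ": label '", fields[li],
           "' is not binary (0/1)", call. = FALSE)
    if (is.na(sc) || !is.finite(sc))
      stop("line ", r + 1L, ": score '", fields[si],
           "' is not a finite number", call. = FALSE)
    labels[r] <- as.integer(lab); scores[r] <- sc
  }
  scored_dataset(scores, labels, orientation = orientation)
}

#' Write a score table
#'
#' Writes the `label` and `score` columns of a dataset as a tab-delimited
#' table readable by [read_scores()].
#'
#' @param data A [scored_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(data, path) {
  if (!inherits(data, "scored_dataset"))
    stop("expected a 'scored_dataset' object", call. = FALSE)
  utils::write.table(
    data.frame(label = data$labels, score = data$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
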