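#' Read a plot-by-species table from delimited text
#'
#' First row holds species identifiers, first column holds plot identifiers,
#' body is numeric.  The delimiter is auto-detected (comma vs tab) unless
#' given.  Row order in the file defines sample order; nothing is reordered.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter single character, or `NULL` to auto-detect.
#' @return A [community_matrix()].
#' @export
read_community_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("community matrix file needs a header row and at least one plot",
         call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) >
                     0) "\t" else ","
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(parts[[1]])
  ## header may or may not carry a stub cell above the plot-id column;
  ## the first data row decides which layout is in use
  body <- parts[-1]
  widths <- lengths(body)
  species <- if (widths[1] == length(header)) header[-1] else header
  expected <- length(species) + 1L
  bad <- which(widths != expected)
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                 bad[1] + 1L, expected, widths[bad[1]]), call. = FALSE)
  plot_ids <- vapply(body, function(p) trimws(p[1]), character(1))
  vals <- vapply(body, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("non-numeric value in body of ", path, call. = FALSE)
    v
  }, numeric(length(species)))
  vals <- matrix(t(vals), nrow = length(plot_ids),
                 dimnames = list(plot_ids, species))
  community_matrix(vals)
}

#' Write a community matrix as delimited text
#'
#' @param m a [community_matrix()].
#' @param path output path.
#' @param delimiter field delimiter (default tab).
#' @export
write_community_matrix <- function(m, path, delimiter = "\t") {
  header <- paste(c("plot", colnames(m)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = delimiter), character(1))
  writeLines(c(header, rows), path)
  invisible(NULL)
}

#' Read a dense similarity matrix in CLUTO-style text format
#'
#' The format is a plain text file with n + 1 lines: the first line holds the
#' number of rows n, and each of the remaining n lines holds n
#' whitespace-separated similarity values.
#'
#' @param path path to the file.
#' @return A [similarity_matrix()].  A missing unit diagonal is coerced to 1
#'   with a warning; asymmetry beyond `1e-9` and values outside \[0, 1\] are
#'   errors.
#' @export
read_similarity_cluto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty similarity file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("first line must hold the number of rows", call. = FALSE)
  if (length(lines) - 1L != n)
    stop(sprintf("declared %d rows but found %d", n, length(lines) - 1L),
         call. = FALSE)
  vals <- lapply(lines[-1], function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  widths <- lengths(vals)
  if (any(widths != n))
    stop(sprintf("row %d has %d values, expected %d",
                 which(widths != n)[1], widths[widths != n][1], n),
         call. = FALSE)
  m <- do.call(rbind, vals)
  if (anyNA(m)) stop("non-numeric similarity value", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("similarity values outside [0, 1]",
                               call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9)
    stop("similarity matrix is asymmetric beyond tolerance 1e-9",
         call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-9)) {
    warning("diagonal not 1; coercing self-similarity to 1")
    diag(m) <- 1
  }
  similarity_matrix(m)
}

#' Write a similarity matrix in CLUTO-style dense text format
#'
#' Values are printed with a fixed number of decimals (default 6) so that a
#' write/read round trip reproduces the matrix to within half a unit of the
#' last printed digit.
#'
#' @param sim a [similarity_matrix()] (or coercible symmetric matrix).
#' @param path output path.
#' @param digits decimal places to print.
#' @export
write_similarity_cluto <- function(sim, path, digits = 6) {
  sim <- as_similarity(sim)
  if (nrow(sim) == 0) stop("empty similarity matrix", call. = FALSE)
  fmt <- paste0("%.", digits, "f")
  rows <- vapply(seq_len(nrow(sim)), function(i)
    paste(sprintf(fmt, sim[i, ]), collapse = " "), character(1))
  writeLines(c(as.character(nrow(sim)), rows), path)
  invisible(NULL)
}

#' Read a reference classification from two-column delimited text
#'
#' Each line pairs a class name with one indicative species; the delimiter is
#' auto-detected among tab and comma.
#'
#' @param path path to the file.
#' @return Named list mapping class name to a character vector of species
#'   identifiers (class `reference_classification`).
#' @export
read_reference_classes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty reference file: ", path, call. = FALSE)
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, delim, fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop(sprintf("line %d does not have two fields",
                 which(lengths(parts) != 2)[1]), call. = FALSE)
  cls <- trimws(vapply(parts, `[`, character(1), 1))
  sp <- trimws(vapply(parts, `[`, character(1), 2))
  if (cls[1] %in% c("class", "Class")) { # optional header
    sp <- sp[-1]; cls <- cls[-1]
  }
  out <- lapply(split(sp, factor(cls, levels = unique(cls))), unique)
  if (any(!lengths(out))) stop("empty reference class", call. = FALSE)
  structure(out, class = "reference_classification")
}

#' Write / read cluster labels as two-column TSV
#'
#' The file holds one `sample_id<TAB>cluster` line per sample, in sample
#' order.
#'
#' @param solution a [cluster_solution()] or bare label vector (named, or
#'   paired with `sample_ids`).
#' @param path file path.
#' @param sample_ids identifiers to write alongside unnamed labels.
#' @export
write_labels <- function(solution, path, sample_ids = NULL) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels
            else solution
  ids <- sample_ids %||% names(labels) %||% paste0("s", seq_along(labels))
  writeLines(c("sample_id\tcluster",
               paste(ids, as.integer(labels), sep = "\t")), path)
  invisible(NULL)
}

#' @rdname write_labels
#' @param expected_ids if given, the file must reference exactly these sample
#'   ids (any order is an error: file order defines sample order).
#' @return `read_labels` returns a named integer vector in file order.
#' @export
read_labels <- function(path, expected_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  labels <- stats::setNames(tab[[2]], tab[[1]])
  if (!is.null(expected_ids)) {
    unknown <- setdiff(names(labels), expected_ids)
    if (length(unknown))
      stop("labels reference unknown sample ids: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    if (!identical(names(labels), as.character(expected_ids)))
      stop("labels file does not match expected sample order", call. = FALSE)
  }
  labels
}
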