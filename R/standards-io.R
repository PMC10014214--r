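## Readers/writers for the toolkit's on-disk artifacts. All delimited files
## are tab-separated UTF-8; lines starting with '#' are comments.

#' Read a drug-indication association standard
#'
#' Parses a two-column tab-separated mapping file
#' (`drug_id<TAB>indication_id`, one association per line, `#` comments
#' allowed) into an [AssociationStandard-class]. Duplicate pairs are dropped
#' with a message giving the count.
#'
#' @param path path to the mapping TSV.
#' @param dialect file dialect; only `"two-column-tsv"` is defined.
#' @return An [AssociationStandard-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("d1\tD000001", "d2\tD000001", "d1\tD000002"), f)
#' readAssociationStandard(f)
#' @export
readAssociationStandard <- function(path, dialect = "two-column-tsv") {
  dialect <- match.arg(dialect, "two-column-tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("empty association file: ", path)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 2L
  if (any(bad))
    stop("malformed association line(s) (need >= 2 tab-separated fields): ",
         paste(idx[bad], collapse = ", "))
  AssociationStandard(
    drug_id = vapply(fields, `[[`, character(1), 1L),
    indication_id = vapply(fields, `[[`, character(1), 2L))
}

#' Write an association standard as a two-column TSV
#'
#' @param standard an [AssociationStandard-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeAssociationStandard <- function(standard, path) {
  stopifnot(is(standard, "AssociationStandard"))
  a <- associations(standard)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# drug_id\tindication_id", con)
  writeLines(paste(a$drug_id, a$indication_id, sep = "\t"), con)
  invisible(path)
}

#' Read a drug x protein signature matrix
#'
#' The expected layout is a header row `drug_id<TAB>prot1<TAB>prot2...`
#' followed by one row per drug: the drug id then one numeric score per
#' protein. Ragged rows and non-numeric scores are errors that name the
#' offending drug.
#'
#' @param path path to the signature TSV.
#' @return A [SignatureMatrix-class].
#' @export
readSignatureMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("signature file needs a header and at least one drug row: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  proteins <- header[-1L]
  p <- length(proteins)
  if (p < 1L) stop("header must list at least one protein id")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(rows, `[[`, character(1), 1L)
  widths <- vapply(rows, length, integer(1))
  if (any(widths != p + 1L))
    stop("ragged row(s) for drug(s): ",
         paste(ids[widths != p + 1L], collapse = ", "),
         " (expected ", p, " scores)")
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(p)))
  mat <- t(matrix(vals, nrow = p))
  if (anyNA(mat)) {
    bad <- ids[apply(is.na(mat), 1L, any)]
    stop("non-numeric score(s) for drug(s): ", paste(bad, collapse = ", "))
  }
  SignatureMatrix(mat, drug_ids = ids, protein_ids = proteins)
}

#' Write a signature matrix as TSV
#'
#' @param sig a [SignatureMatrix-class].
#' @param path output path.
#' @param digits significant digits written (default 15, enough for
#'   bit-faithful round trips of typical scores).
#' @return Invisibly, `path`.
#' @export
writeSignatureMatrix <- function(sig, path, digits = 15L) {
  stopifnot(is(sig, "SignatureMatrix"))
  m <- scores(sig)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("drug_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = digits, format = "g")),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a metric report to JSON or TSV
#'
#' JSON keeps the full structure (per-indication values, aggregates, null
#' control) and round-trips losslessly through [readMetricReport()]. TSV is
#' a flat export of the three tables stacked with a `section` column.
#'
#' @param report a [MetricReport-class].
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
writeMetricReport <- function(report, path, format = c("json", "tsv")) {
  stopifnot(is(report, "MetricReport"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(perIndication = perIndication(report),
                aggregate = aggregated(report),
                nullControl = nullControl(report))
    jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    pi <- perIndication(report)
    ag <- aggregated(report)
    nc <- nullControl(report)
    pad <- function(df, section) {
      if (!nrow(df)) return(NULL)
      cbind(section = section, df, stringsAsFactors = FALSE)
    }
    blocks <- list(pad(pi, "per_indication"), pad(ag, "aggregate"),
                   pad(nc, "null_control"))
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!length(blocks)) {
      writeLines("section\tmetric\tcutoff\tvalue", con)
    } else {
      for (b in seq_along(blocks)) {
        utils::write.table(blocks[[b]], con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = (b == 1L) ||
                             !identical(names(blocks[[b]]),
                                        names(blocks[[b - 1L]])))
      }
    }
  }
  invisible(path)
}

#' Read a JSON metric report written by [writeMetricReport()]
#'
#' @param path path to the JSON file.
#' @return A [MetricReport-class].
#' @export
readMetricReport <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(x, template) {
    if (is.null(x) || !length(x) || all(lengths(x) == 0L)) return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    if ("cutoff" %in% names(df)) df$cutoff <- as.integer(df$cutoff)
    df
  }
  MetricReport(
    perIndication = asDf(obj$perIndication,
                         data.frame(indication_id = character(),
                                    metric = character(),
                                    cutoff = integer(), value = numeric(),
                                    stringsAsFactors = FALSE)),
    aggregate = asDf(obj$aggregate, emptyMetricFrame()),
    nullControl = asDf(obj$nullControl, emptyMetricFrame()))
}
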