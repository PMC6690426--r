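#' Read a delimited survival table
#'
#' Reads a TSV or CSV with one row per patient and named columns for the
#' follow-up time, event indicator and group label, then validates it via
#' [survival_dataset()].  The delimiter is auto-detected from the header
#' line (tab wins over comma) unless forced.
#'
#' @param path file path.
#' @param time_col,event_col,group_col,id_col column names (defaults
#'   `"time"`, `"event"`, `"group"`; `id_col = NULL` for none).
#' @param sep field separator; `NULL` (default) auto-detects.
#' @return A validated [survival_dataset()].
#' @examples
#' toy <- system.file("extdata", "toy_cohort_synthetic.tsv",
#'                    package = "permlogrank")
#' read_survival_table(toy)
#' @export
read_survival_table <- function(path, time_col = "time",
                                event_col = "event", group_col = "group",
                                id_col = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "")
  as_survival_dataset(df, time_col = time_col, event_col = event_col,
                      group_col = group_col, id_col = id_col)
}

#' Read a clustering solution file
#'
#' A solution file has two columns: patient id and cluster label (header
#' optional, auto-detected).  The returned labels are named by patient id
#' so [compare_solutions()] can join on id.
#'
#' @param path file path.
#' @param sep separator; `NULL` auto-detects tab vs comma.
#' @return A named vector of cluster labels.
#' @export
read_solution <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[2])))
  df <- read.table(path, header = has_header, sep = sep,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("solution file needs two columns (id, cluster)")
  stats::setNames(df[[2]], as.character(df[[1]]))
}

#' Write a result object to JSON or TSV
#'
#' JSON output keeps full double precision (17 significant digits) and,
#' for stochastic results, records the seed and scheme so a run can be
#' reproduced bit-for-bit.  Given identical inputs and seed the written
#' file is byte-identical across runs.
#'
#' @param x a result object (`logrank_test`, `permutation_test`, a data
#'   frame such as the [fpr_curve()] output, or a plain list of scalars).
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  obj <- result_payload(x)
  if (format == "json") {
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                             null = "null", pretty = TRUE)
    writeLines(json, path)
  } else {
    df <- if (is.data.frame(obj)) obj
          else as.data.frame(lapply(obj[!vapply(obj, is.null, TRUE) &
                                          lengths(obj) == 1L], identity),
                             stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Strip classes/attributes down to something serialisable.
result_payload <- function(x) {
  if (is.data.frame(x)) {
    attr(x, "method") <- NULL; attr(x, "alpha") <- NULL
    return(x)
  }
  if (inherits(x, "logrank_test")) {
    return(list(statistic = x$statistic, df = x$df, ap = x$p.value,
                observed = as.list(x$observed),
                expected = as.list(x$expected),
                singular = x$singular))
  }
  if (inherits(x, "permutation_test")) {
    return(list(ep = x$p.value, b = x$b, B = x$B,
                ci_low = x$conf.int[1], ci_high = x$conf.int[2],
                statistic = x$statistic, df = x$df, ap = x$ap,
                scheme = x$scheme, imputations = x$imputations,
                seed = x$seed))
  }
  if (is.list(x)) return(x)
  stop("cannot serialise object of class ", paste(class(x), collapse = "/"))
}

#' Write a risk table as TSV
#'
#' @param x a [risk_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(x, path) {
  stopifnot(inherits(x, "risk_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
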