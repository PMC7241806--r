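#' Read a long-format replicate-level Cq table
#'
#' Reads a delimited text file with one qPCR well per row. The required
#' columns are `sample`, `group`, `plate`, `run`, `gene`, `replicate` and
#' `cq`; a `col_map` may rename them if the file uses different headers.
#' Missing Cq cells (empty field or `NA`) are preserved as `NA`, never
#' dropped: downstream modules decide how to treat missing wells.
#'
#' @param path path to a comma- or tab-delimited UTF-8 file with a header.
#' @param sep field delimiter; `NULL` (default) auto-detects `,` vs tab from
#'   the header line.
#' @param col_map named character vector mapping the canonical column names
#'   to the file's header names, e.g. `c(sample = "SampleID")`.
#' @return a `replicate_table`: a data.frame with columns `sample_id`,
#'   `group`, `plate_id`, `run_id`, `gene`, `replicate`, `cq`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,group,plate,run,gene,replicate,cq",
#'              "S1,control,P1,R1,ACTB,1,19.8"), f)
#' read_replicate_table(f)
#' @export
read_replicate_table <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path))
    stop_refstab(sprintf("file not found: %s", path), "refstab_io_error")
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  canon <- c("sample", "group", "plate", "run", "gene", "replicate", "cq")
  have <- canon
  if (!is.null(col_map)) have[match(names(col_map), canon)] <- col_map
  missing_cols <- setdiff(have, names(raw))
  if (length(missing_cols))
    stop_refstab(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "refstab_io_error")
  df <- data.frame(
    sample_id = raw[[have[1]]], group = raw[[have[2]]],
    plate_id = raw[[have[3]]], run_id = raw[[have[4]]],
    gene = raw[[have[5]]],
    replicate = raw[[have[6]]], cq = raw[[have[7]]],
    stringsAsFactors = FALSE)
  df$replicate <- parse_numeric_column(df$replicate, "replicate")
  df$cq <- parse_numeric_column(df$cq, "cq")
  if (any(!is.na(df$replicate) & (df$replicate < 1 |
                                  df$replicate != round(df$replicate))))
    stop_refstab("'replicate' must be a positive integer index",
                 "refstab_validation_error")
  df$replicate <- as.integer(df$replicate)
  validate_replicate_table(df)
}

# strict numeric parse: empty/NA -> NA, anything else must parse
parse_numeric_column <- function(x, name) {
  x[x %in% c("", "NA", "NaN")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop_refstab(sprintf("non-numeric '%s' value '%s' at data row %d",
                         name, x[bad[1]], bad[1]),
                 "refstab_validation_error")
  out
}

#' Validate (or construct) a replicate table
#'
#' Checks the `replicate_table` invariants: `(sample_id, gene, replicate)`
#' unique within a run, and every present Cq finite and positive.
#'
#' @param df data.frame with the replicate-table columns.
#' @return `df` with class `replicate_table`.
#' @export
validate_replicate_table <- function(df) {
  needed <- c("sample_id", "group", "plate_id", "run_id", "gene",
              "replicate", "cq")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop_refstab(sprintf("replicate table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "refstab_validation_error")
  key <- paste(df$run_id, df$sample_id, df$gene, df$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- df[dup, , drop = FALSE][1L, ]
    stop_refstab(sprintf(
      "duplicate (sample, gene, replicate) key: (%s, %s, %d) in run %s",
      d$sample_id, d$gene, d$replicate, d$run_id),
      "refstab_validation_error")
  }
  bad_cq <- which(!is.na(df$cq) & (!is.finite(df$cq) | df$cq <= 0))
  if (length(bad_cq))
    stop_refstab(sprintf("non-positive or non-finite Cq at row %d", bad_cq[1]),
                 "refstab_validation_error")
  class(df) <- c("replicate_table", "data.frame")
  df
}

#' Write a replicate table to delimited text
#'
#' Labels round-trip bit-exactly; Cq is written with enough digits to
#' round-trip to at least 6 decimals.
#'
#' @param x a `replicate_table`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_replicate_table <- function(x, path, sep = ",") {
  out <- data.frame(sample = x$sample_id, group = x$group, plate = x$plate_id,
                    run = x$run_id, gene = x$gene, replicate = x$replicate,
                    cq = ifelse(is.na(x$cq), "", sprintf("%.9g", x$cq)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-gene per-plate amplification efficiencies
#'
#' Reads a table with columns `gene`, `plate`, `efficiency`, and optionally
#' `nq` (quantification-threshold fluorescence) and `factor` (inter-plate
#' correction factor). The amplification efficiency E is the per-cycle
#' amplification factor and must lie in (1, 2]: 2 is perfect doubling and
#' values at or below 1 or above 2 are physically meaningless.
#'
#' @param path path to a delimited file with header.
#' @param sep field delimiter; `NULL` auto-detects.
#' @return an `efficiency_table` data.frame with columns `gene`, `plate_id`,
#'   `efficiency`, `nq`, `factor`.
#' @export
read_efficiency_table <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop_refstab(sprintf("file not found: %s", path), "refstab_io_error")
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c("gene", "plate", "efficiency"))
    if (!col %in% names(raw))
      stop_refstab(sprintf("efficiency table lacks column '%s'", col),
                   "refstab_io_error")
  df <- data.frame(
    gene = raw$gene, plate_id = raw$plate,
    efficiency = parse_numeric_column(raw$efficiency, "efficiency"),
    nq = if ("nq" %in% names(raw))
      parse_numeric_column(raw$nq, "nq") else NA_real_,
    factor = if ("factor" %in% names(raw))
      parse_numeric_column(raw$factor, "factor") else NA_real_,
    stringsAsFactors = FALSE)
  validate_efficiency_table(df)
}

#' Validate an efficiency table
#'
#' @param df data.frame with columns `gene`, `plate_id`, `efficiency` and
#'   optionally `nq`, `factor`.
#' @return `df` with class `efficiency_table`.
#' @export
validate_efficiency_table <- function(df) {
  if (!all(c("gene", "plate_id", "efficiency") %in% names(df)))
    stop_refstab("efficiency table needs gene, plate_id, efficiency",
                 "refstab_validation_error")
  if (is.null(df$nq)) df$nq <- NA_real_
  if (is.null(df$factor)) df$factor <- NA_real_
  bad <- which(is.na(df$efficiency) | df$efficiency <= 1 | df$efficiency > 2)
  if (length(bad))
    stop_refstab(sprintf(
      "efficiency %g for gene %s on plate %s outside (1, 2]",
      df$efficiency[bad[1]], df$gene[bad[1]], df$plate_id[bad[1]]),
      "refstab_validation_error")
  if (any(!is.na(df$nq) & df$nq <= 0))
    stop_refstab("quantification threshold nq must be > 0",
                 "refstab_validation_error")
  if (any(!is.na(df$factor) & df$factor <= 0))
    stop_refstab("plate correction factor must be > 0",
                 "refstab_validation_error")
  if (anyDuplicated(paste(df$gene, df$plate_id, sep = "\r")))
    stop_refstab("duplicate (gene, plate) efficiency record",
                 "refstab_validation_error")
  class(df) <- c("efficiency_table", "data.frame")
  df
}

#' Construct an RQ matrix container
#'
#' A samples-by-genes matrix of strictly positive relative quantities with
#' sample metadata. Internal constructor also used by the simulator and the
#' relative-quantification step.
#'
#' @param rq numeric matrix, rows = samples, columns = genes; entries > 0 or
#'   `NA`.
#' @param group character vector of treatment-group labels per sample.
#' @param plate optional character vector of plate labels per sample.
#' @param plate_corrected logical provenance flag.
#' @param rq_mode `"calibrator"` or `"nq"`.
#' @return an object of class `rq_matrix`.
#' @export
rq_matrix <- function(rq, group, plate = NULL, plate_corrected = FALSE,
                      rq_mode = c("calibrator", "nq")) {
  rq_mode <- match.arg(rq_mode)
  rq <- as.matrix(rq)
  if (is.null(rownames(rq)))
    stop_refstab("rq matrix needs sample rownames", "refstab_validation_error")
  if (is.null(colnames(rq)))
    stop_refstab("rq matrix needs gene colnames", "refstab_validation_error")
  if (any(!is.na(rq) & rq <= 0))
    stop_refstab("relative quantities must be > 0 or missing",
                 "refstab_validation_error")
  if (length(group) != nrow(rq))
    stop_refstab("one group label per sample required",
                 "refstab_validation_error")
  structure(list(rq = rq, group = as.character(group),
                 plate = if (is.null(plate)) NULL else as.character(plate),
                 plate_corrected = isTRUE(plate_corrected),
                 rq_mode = rq_mode),
            class = "rq_matrix")
}

#' @exportS3Method base::print
print.rq_matrix <- function(x, ...) {
  cat(sprintf("rq_matrix: %d samples x %d genes (%s mode%s)\n",
              nrow(x$rq), ncol(x$rq), x$rq_mode,
              if (x$plate_corrected) ", plate-corrected" else ""))
  cat("genes:", paste(colnames(x$rq), collapse = ", "), "\n")
  cat("groups:", paste(unique(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.replicate_table <- function(x, ...) {
  cat(sprintf(
    "replicate_table: %d wells, %d samples, %d genes, %d plate(s), %d run(s)\n",
    nrow(x), length(unique(x$sample_id)), length(unique(x$gene)),
    length(unique(x$plate_id)), length(unique(x$run_id))))
  NextMethod()
}

#' Serialize an analysis result to JSON
#'
#' All result objects in the package are plain lists/data.frames and
#' serialize losslessly to a single structured JSON document.
#'
#' @param x result object (list-like).
#' @param path output path.
#' @param ... passed to [jsonlite::write_json()].
#' @export
write_result_json <- function(x, path, ...) {
  x <- unclass_deep(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE, ...)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}
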