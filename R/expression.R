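#' Construct an expression matrix with sample metadata
#'
#' The central data container of the package: a genes x samples numeric
#' matrix together with per-sample metadata (condition label, time in
#' hours, replicate index). Gene identifiers are case-sensitive opaque
#' strings and must be unique; values must be finite.
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   columns = samples.
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `time_h`, `replicate`, one row per column of `values`.
#' @param normalized Logical flag marking per-gene Z-scored values.
#' @return An object of class `gt_expression`.
#' @export
expression_matrix <- function(values, samples, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have gene identifiers as rownames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0)
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  req <- c("sample_id", "condition", "time_h", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("`samples` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample metadata rows (", nrow(samples),
         ") do not match matrix columns (", ncol(values), ")")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata")
  if (!all(is.finite(samples$time_h)) || any(samples$time_h < 0))
    stop("time_h must be finite and non-negative")
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1L))
    stop("replicate indices must be positive integers")
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, samples = samples,
         normalized = isTRUE(normalized)),
    class = "gt_expression"
  )
}

#' @export
print.gt_expression <- function(x, ...) {
  cat("<gt_expression> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  conditions: ", paste(unique(x$samples$condition), collapse = ", "),
      "\n  time points (h): ",
      paste(sort(unique(x$samples$time_h)), collapse = ", "),
      "\n  normalized: ", x$normalized, "\n", sep = "")
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param x A `gt_expression` object.
#' @return Character vector of gene identifiers in row order.
#' @export
genes <- function(x) rownames(x$values)

#' Parse CONDITION_TIME_REPLICATE sample headers
#'
#' Sample columns are conventionally named like `"TM_12_2"`: condition
#' label, time in hours, replicate index, joined by underscores. The
#' condition label itself must not contain an underscore.
#'
#' @param headers Character vector of column headers.
#' @return Data frame with columns sample_id, condition, time_h, replicate.
#' @export
parse_sample_headers <- function(headers) {
  parts <- strsplit(headers, "_", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0)
    stop("malformed sample header(s), expected CONDITION_TIME_REPLICATE: ",
         paste(headers[bad], collapse = ", "))
  cond <- vapply(parts, `[`, "", 1L)
  time_h <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  repl <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(time_h) | is.na(repl))
  if (length(bad) > 0)
    stop("non-numeric time or replicate in sample header(s): ",
         paste(headers[bad], collapse = ", "))
  data.frame(sample_id = headers, condition = cond, time_h = time_h,
             replicate = repl, stringsAsFactors = FALSE)
}

#' Read an expression matrix from delimited text
#'
#' Expects a gene-identifier first column and one numeric column per
#' sample. Sample metadata is parsed from the headers
#' (CONDITION_TIME_REPLICATE) unless a sidecar metadata table is given.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param sep Field separator; inferred from the file extension
#'   (`.csv` gives `","`, anything else tab) when `NULL`.
#' @param samples Optional sidecar data frame overriding header parsing;
#'   must contain a `sample_id` column matching the file headers.
#' @return A `gt_expression` object.
#' @export
read_expression <- function(path, sep = NULL, samples = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2)
    stop("expression file needs a gene column plus at least one sample")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate gene row(s): ", paste(dup, collapse = ", "))
  headers <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(headers),
                 dimnames = list(ids, headers))
  for (j in seq_along(headers)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("non-numeric value '", df[[j + 1L]][i], "' at gene '", ids[i],
           "', column '", headers[j], "'")
    }
    vals[, j] <- v
  }
  if (is.null(samples)) {
    meta <- parse_sample_headers(headers)
  } else {
    if (!all(headers %in% samples$sample_id))
      stop("sidecar metadata missing sample(s): ",
           paste(setdiff(headers, samples$sample_id), collapse = ", "))
    meta <- samples[match(headers, samples$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  expression_matrix(vals, meta)
}

#' Write an expression matrix to delimited text
#'
#' @param x A `gt_expression` object.
#' @param path Output path; `.csv` extension selects comma separation.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
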