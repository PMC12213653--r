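#' Write a layout to a three-column TSV
#'
#' Coordinates are written with full double precision (`%.17g`) so that a
#' read/write round trip is lossless and downstream rasters are
#' bit-reproducible from the file.
#'
#' @param layout A `gt_layout` object (see [kk_layout()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout <- function(layout, path) {
  pos <- layout_positions(layout)
  if (!all(is.finite(pos)))
    stop("layout coordinates must be finite")
  lines <- c("gene\tx\ty",
             sprintf("%s\t%.17g\t%.17g", rownames(pos), pos[, 1], pos[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a layout from a three-column TSV
#'
#' @param path Path to a TSV with columns gene, x, y.
#' @return A `gt_layout` object. Coordinates outside the unit square are
#'   passed through unchanged with a warning.
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene", "x", "y") %in% names(df)))
    stop("layout file must have columns gene, x, y; found: ",
         paste(names(df), collapse = ", "))
  pos <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  if (anyNA(pos)) stop("non-numeric coordinate in layout file")
  rownames(pos) <- df$gene
  if (any(pos < 0 | pos > 1))
    warning("layout contains coordinates outside [0, 1]; kept as-is")
  gt_layout(pos)
}

#' Write named gene sets in GMT format
#'
#' One tab-delimited row per set: name, description, member genes. This is
#' the hand-off surface for external enrichment tools. Empty sets are
#' skipped with a warning.
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param path Output path.
#' @param description Second GMT column, recycled across sets.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, description = "geneterrain") {
  if (length(sets) > 0 && is.null(names(sets)))
    stop("gene sets must be named")
  keep <- vapply(sets, length, 1L) > 0
  if (any(!keep))
    warning("skipping empty gene set(s): ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    tok <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3) stop("GMT line with fewer than 3 fields")
    tok[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}
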