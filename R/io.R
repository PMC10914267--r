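# Tabular I/O for long-format phenotype tables.

#' Validate and normalise a phenotype table
#'
#' Coerces a data frame with columns `genotype`, `block`, `harvest`, `yield`
#' into the canonical long format used by every fitting function: factor
#' labels (harvest ordered by first appearance unless already a factor),
#' finite numeric yields, and no duplicated genotype-block-harvest triple.
#' Labels are opaque strings; codes such as `"G15"` are never coerced to
#' numbers.
#'
#' @param x a data frame.
#' @return the validated table, classed `phenotype_table`.
#' @export
as_phenotype_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("genotype", "block", "harvest", "yield")
  names(x) <- tolower(names(x))
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- x[, need, drop = FALSE]
  for (col in c("genotype", "block", "harvest")) {
    if (!is.factor(x[[col]])) {
      v <- as.character(x[[col]])
      x[[col]] <- factor(v, levels = unique(v))
    }
  }
  if (!is.numeric(x$yield)) {
    stop("`yield` must be numeric", call. = FALSE)
  }
  if (nrow(x) && any(!is.finite(x$yield))) {
    stop("`yield` contains non-finite values", call. = FALSE)
  }
  key <- paste(x$genotype, x$block, x$harvest, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (genotype, block, harvest) triple: (%s, %s, %s)",
                 d$genotype, d$block, d$harvest), call. = FALSE)
  }
  class(x) <- c("phenotype_table", "data.frame")
  x
}

#' Read a phenotype table from CSV
#'
#' Expects a delimited text file with header columns `genotype`, `block`,
#' `harvest`, `yield` (case-insensitive, any column order).  Harvest ordering
#' is taken from `harvest_levels` when supplied, otherwise from first
#' appearance in the file.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param harvest_levels optional character vector fixing the harvest order.
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path, delim = ",", harvest_levels = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  if ("yield" %in% names(raw) && !is.numeric(raw$yield)) {
    stop("`yield` column is not numeric", call. = FALSE)
  }
  tab <- as_phenotype_table(raw)
  if (!is.null(harvest_levels)) {
    bad <- setdiff(as.character(tab$harvest), harvest_levels)
    if (length(bad)) {
      stop("harvest labels absent from `harvest_levels`: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    tab$harvest <- factor(as.character(tab$harvest), levels = harvest_levels)
  }
  tab
}

#' Write a phenotype table to CSV
#'
#' @param table a `phenotype_table`.
#' @param path output file; written with header `genotype,block,harvest,yield`.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  table <- as_phenotype_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("Phenotype table: %d records, %d genotypes x %d blocks x %d harvests\n",
              nrow(x), nlevels(x$genotype), nlevels(x$block),
              nlevels(x$harvest)))
  NextMethod()
}
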