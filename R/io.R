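#' Read a genotype matrix from delimited text
#'
#' Expects a header row and a line-identifier first column; remaining
#' columns are numeric marker dosages (typically -1/+1 homozygote coding).
#'
#' @param path Path to a comma- (default) or otherwise-delimited text file.
#' @param sep Field separator.
#' @return Numeric matrix with line identifiers as row names.
#' @export
read_genotypes <- function(path, sep = ",") {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  M <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!vapply(d[-1], is.numeric, TRUE))
    stop("non-numeric genotype column(s): ", paste(names(d)[-1][bad], collapse = ", "))
  }
  rownames(M) <- ids
  M
}

#' Read a phenotype table from delimited text
#'
#' Same layout as [read_genotypes()]: identifier first column, one numeric
#' column per trait. When `align_to` identifiers are given, rows are
#' reordered to match and any missing line is reported by name.
#'
#' @inheritParams read_genotypes
#' @param align_to Optional identifier vector (e.g. genotype row names) to
#'   align rows against.
#' @return Numeric matrix (lines x traits) with identifiers as row names.
#' @export
read_phenotypes <- function(path, sep = ",", align_to = NULL) {
  M <- read_genotypes(path, sep = sep)
  if (!is.null(align_to)) {
    missing <- setdiff(align_to, rownames(M))
    if (length(missing)) {
      stop("phenotype records missing for line(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    M <- M[align_to, , drop = FALSE]
  }
  M
}

#' Write a matrix with identifiers as delimited text
#'
#' Counterpart of [read_genotypes()]/[read_phenotypes()]: writes the row
#' names as an `id` first column, comma-separated with a header row.
#'
#' @param x Matrix with row names.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_delimited <- function(x, path, sep = ",") {
  d <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
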