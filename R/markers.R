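#' Prepare a marker matrix for model fitting
#'
#' Validates and column-centers a lines x markers genotype matrix (homozygote
#' coding -1/+1, or any numeric dosage). Zero-variance (monomorphic) columns
#' are retained but flagged so downstream code can ignore them; centering
#' maps them to exact zeros.
#'
#' @param raw Numeric matrix, lines in rows, markers in columns. Row names
#'   are treated as line identifiers.
#' @return A centered numeric matrix with attributes `center` (the column
#'   means removed) and `zero_variance` (logical flag per column).
#' @export
prepare_markers <- function(raw) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("marker matrix must be numeric")
  if (anyNA(raw)) stop("marker matrix contains missing values")
  ctr <- colMeans(raw)
  W <- sweep(raw, 2, ctr)
  zv <- apply(W, 2, function(x) all(x == 0)) |
    (colSums(W^2) < 1e-12 * nrow(W))
  attr(W, "center") <- ctr
  attr(W, "zero_variance") <- as.logical(zv)
  W
}

#' Genomic relationship matrix
#'
#' VanRaden-style relationship matrix `K = W W' / c` from column-centered
#' genotypes `W`, with the scaling constant `c = sum_j mean(W_ij^2)` chosen
#' so that the diagonal of `K` averages exactly 1.
#'
#' @param markers Genotype matrix (lines x markers); centered internally via
#'   [prepare_markers()] if not already prepared.
#' @return A symmetric positive semi-definite n x n matrix with line
#'   identifiers as dimnames.
#' @export
grm <- function(markers) {
  W <- if (is.null(attr(markers, "center"))) prepare_markers(markers) else markers
  if (nrow(W) < 2) stop("at least two lines are required")
  cc <- sum(colMeans(W^2))
  if (cc <= 0) stop("no polymorphic markers: relationship matrix is degenerate")
  K <- tcrossprod(W) / cc
  dimnames(K) <- list(rownames(W), rownames(W))
  (K + t(K)) / 2
}
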