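#' Welch two-sample t-test on replicate summaries
#'
#' Thin wrapper around [stats::t.test()] (Welch, unequal variances) that
#' returns a tidy one-row comparison report, used to contrast replicate
#' means (or replicate variances) between two selection criteria.
#'
#' @param x,y Numeric vectors of replicate values (>= 2 each).
#' @param label Contrast label carried into the report.
#' @return A data.frame with `contrast`, `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, label = "x vs y") {
  if (length(x) < 2 || length(y) < 2) stop("at least two values per group are required")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(data.frame(contrast = label, statistic = 0,
                        df = length(x) + length(y) - 2, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    stop("degenerate comparison: both groups have zero variance")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(contrast = label, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Hotelling two-sample T-squared test
#'
#' Classic pooled-covariance two-sample test of mean-vector equality:
#' `T2 = (n1 n2 / (n1 + n2)) * d' S_pooled^-1 d`, converted to an F
#' statistic with `(t, n1 + n2 - t - 1)` degrees of freedom. At t = 1 the
#' statistic equals the square of the pooled two-sample t statistic.
#'
#' @param X,Y Numeric matrices (observations x traits) for the two groups.
#' @param label Contrast label.
#' @return A data.frame with `contrast`, `statistic` (T2), `f_statistic`,
#'   `df1`, `df2`, `p_value`.
#' @export
hotelling_t2 <- function(X, Y, label = "X vs Y") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("groups must have the same trait count")
  t_tr <- ncol(X); n1 <- nrow(X); n2 <- nrow(Y)
  if (n1 + n2 - 2 <= t_tr) stop("too few observations for the trait count")
  d <- colMeans(X) - colMeans(Y)
  Sp <- ((n1 - 1) * stats::cov(X) + (n2 - 1) * stats::cov(Y)) / (n1 + n2 - 2)
  qf <- tryCatch(as.numeric(t(d) %*% solve(Sp, d)),
                 error = function(e) stop("pooled covariance is singular"))
  T2 <- (n1 * n2 / (n1 + n2)) * qf
  Fstat <- (n1 + n2 - t_tr - 1) / ((n1 + n2 - 2) * t_tr) * T2
  p <- stats::pf(Fstat, t_tr, n1 + n2 - t_tr - 1, lower.tail = FALSE)
  data.frame(contrast = label, statistic = T2, f_statistic = Fstat,
             df1 = t_tr, df2 = n1 + n2 - t_tr - 1, p_value = p,
             stringsAsFactors = FALSE)
}

#' Overlap between two equally sized selections
#'
#' Reports how many (and what fraction of) lines selected by one criterion
#' are not selected by another.
#'
#' @param A,B Identifier vectors of equal length.
#' @return A list with `n_differing` (`|A \ B|`), `fraction`
#'   (`n_differing / |A|`) and `n` (selection size).
#' @examples
#' selection_overlap(sprintf("L%02d", 1:32),
#'                   c(sprintf("L%02d", 1:20), sprintf("M%02d", 1:12)))
#' @export
selection_overlap <- function(A, B) {
  if (length(A) != length(B)) stop("selections must have equal size")
  nd <- length(setdiff(A, B))
  list(n_differing = nd, fraction = nd / length(A), n = length(A))
}
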