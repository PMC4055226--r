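#' Row means of a fuzzy soft decision matrix
#'
#' The mean membership of each alternative across all parameters, used as
#' the per-row reference sequence of the grey relational analysis.
#'
#' @param x a `fuzzy_soft_set` or numeric membership matrix.
#' @return numeric vector of length `m`, named by object.
#' @export
row_means <- function(x) {
  rowMeans(as_membership_matrix(x))
}

as_membership_matrix <- function(x) {
  if (inherits(x, "fuzzy_soft_set")) x$memberships
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a fuzzy_soft_set or a numeric matrix", call. = FALSE)
}

#' Difference matrix against the row means
#'
#' @param x a `fuzzy_soft_set` or numeric matrix.
#' @param means numeric vector of row means (defaults to [row_means()]).
#' @return matrix of absolute deviations `|d_ij - mean_i|`.
#' @export
difference_matrix <- function(x, means = row_means(x)) {
  d <- as_membership_matrix(x)
  if (length(means) != nrow(d)) {
    stop("means must have one entry per object", call. = FALSE)
  }
  abs(d - means)
}

#' Grey mean relational degree matrix
#'
#' For each column of the difference matrix, with `a` its minimum and `b` its
#' maximum over the alternatives, the relational degree of entry `delta` is
#' `(a + rho * b) / (delta + rho * b)`. The distinguishing coefficient `rho`
#' compresses or expands the range of the coefficients. A degenerate column
#' (`b = 0`, every alternative sitting exactly on its row mean) is assigned
#' the constant 1, the continuous limit of the formula.
#'
#' @param delta non-negative matrix of difference information.
#' @param rho distinguishing coefficient in `(0, 1)`.
#' @return matrix of relational degrees in `(0, 1]`.
#' @export
grey_relational_matrix <- function(delta, rho = 0.5) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1) {
    stop("rho must lie strictly between 0 and 1", call. = FALSE)
  }
  delta <- as.matrix(delta)
  if (any(delta < 0)) stop("difference information must be non-negative",
                           call. = FALSE)
  r <- delta
  for (j in seq_len(ncol(delta))) {
    b <- max(delta[, j])
    if (b == 0) {
      r[, j] <- 1
    } else {
      a <- min(delta[, j])
      r[, j] <- (a + rho * b) / (delta[, j] + rho * b)
    }
  }
  r
}

#' Uncertainty degree of each parameter
#'
#' The q-order uncertainty degree of a parameter is the q-norm of its column
#' of grey relational degrees divided by the number of alternatives:
#' `DOI(e_j) = (1/m) * (sum_i r_ij^q)^(1/q)`. High uncertainty means the
#' parameter's memberships hug the row means and so discriminate poorly; its
#' evidence is discounted accordingly when masses are built. Values lie in
#' `(0, m^(1/q - 1)]` (for `q = 2`, at most `1/sqrt(m)`).
#'
#' @param relational matrix of grey relational degrees in `(0, 1]`.
#' @param q order of the norm, at least 1.
#' @return numeric vector of uncertainty degrees, one per column.
#' @export
uncertainty_degrees <- function(relational, q = 2) {
  if (!is.numeric(q) || length(q) != 1L || q < 1) {
    stop("q must be a number >= 1", call. = FALSE)
  }
  relational <- as.matrix(relational)
  m <- nrow(relational)
  apply(relational, 2, function(col) sum(col^q)^(1 / q) / m)
}

#' Information structure image of a fuzzy soft set
#'
#' Column-normalises the membership matrix so that each parameter's
#' memberships form a distribution over the alternatives. A parameter whose
#' column sums to zero supports no alternative at all and carries no
#' evidence; it is an error, and the caller must drop such parameters
#' explicitly before building masses.
#'
#' @param x a `fuzzy_soft_set` or numeric matrix.
#' @return matrix whose columns each sum to 1.
#' @export
information_structure_image <- function(x) {
  d <- as_membership_matrix(x)
  cs <- colSums(d)
  if (any(cs == 0)) {
    j <- which(cs == 0)[1L]
    lab <- if (!is.null(colnames(d))) colnames(d)[j] else paste0("column ", j)
    stop("parameter ", lab,
         " has zero total membership and carries no evidence; drop it first",
         call. = FALSE)
  }
  sweep(d, 2, cs, "/")
}

#' Grey relational analysis of a fuzzy soft decision matrix
#'
#' Runs the full chain: row means, difference matrix, grey relational
#' degrees, and per-parameter uncertainty degrees.
#'
#' @param x a `fuzzy_soft_set`.
#' @param rho distinguishing coefficient in `(0, 1)`.
#' @param q order of the uncertainty norm, at least 1.
#' @return an object of class `grey_result` with elements `row_means`,
#'   `delta`, `relational`, `doi`, `rho` and `q`.
#' @export
#' @examples
#' fss <- synth_fss(3, 5, seed = 1)
#' grey_analysis(fss)$doi
grey_analysis <- function(x, rho = 0.5, q = 2) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  means <- row_means(x)
  delta <- difference_matrix(x, means)
  relational <- grey_relational_matrix(delta, rho)
  doi <- uncertainty_degrees(relational, q)
  names(doi) <- fss_parameters(x)
  structure(list(row_means = means, delta = delta, relational = relational,
                 doi = doi, rho = rho, q = q),
            class = "grey_result")
}

#' @export
print.grey_result <- function(x, digits = 4, ...) {
  cat(sprintf("Grey relational analysis (rho = %g, q = %g)\n", x$rho, x$q))
  cat("Row means:\n")
  print(round(x$row_means, digits))
  cat("Uncertainty degrees:\n")
  print(round(x$doi, digits))
  invisible(x)
}
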