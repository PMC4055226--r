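#' Construct a fuzzy soft set
#'
#' A fuzzy soft set is a parameterised family of fuzzy subsets of a finite
#' universe: tabularly, an `m x n` matrix of membership degrees in `[0, 1]`
#' whose rows are objects (alternatives) and whose columns are parameters.
#'
#' @param memberships numeric matrix with values in `[0, 1]`; row and column
#'   names, when present, seed the object and parameter labels.
#' @param objects character vector of unique object labels (length `m`).
#' @param parameters character vector of unique parameter labels (length `n`).
#' @param sig_figs optional integer matrix of the same shape recording, per
#'   entry, the number of significant decimal digits of the value as written
#'   in its source text. Needed by [max_significant_figures()] and hence by
#'   the mean potentiality method; [read_fss()] and [synth_fss()] fill it in
#'   automatically.
#'
#' @return An object of class `fuzzy_soft_set`.
#' @seealso [read_fss()], [synth_fss()], [and_product()], [level_soft_set()]
#' @export
#' @examples
#' fss <- fuzzy_soft_set(matrix(c(0.85, 0.56, 0.71, 0.82), 2, 2),
#'                       objects = c("x1", "x2"), parameters = c("e1", "e2"))
#' fss
fuzzy_soft_set <- function(memberships,
                           objects = rownames(memberships),
                           parameters = colnames(memberships),
                           sig_figs = NULL) {
  memberships <- as.matrix(memberships)
  if (!is.numeric(memberships)) {
    stop("memberships must be a numeric matrix", call. = FALSE)
  }
  m <- nrow(memberships)
  n <- ncol(memberships)
  if (m < 1L || n < 1L) {
    stop("a fuzzy soft set needs at least one object and one parameter",
         call. = FALSE)
  }
  if (is.null(objects)) objects <- paste0("x", seq_len(m))
  if (is.null(parameters)) parameters <- paste0("e", seq_len(n))
  objects <- as.character(objects)
  parameters <- as.character(parameters)
  if (length(objects) != m || length(parameters) != n) {
    stop("label lengths do not match the matrix shape", call. = FALSE)
  }
  if (anyDuplicated(objects)) {
    stop("duplicate object label: ", objects[duplicated(objects)][1L],
         call. = FALSE)
  }
  if (anyDuplicated(parameters)) {
    stop("duplicate parameter label: ",
         parameters[duplicated(parameters)][1L], call. = FALSE)
  }
  if (anyNA(memberships)) stop("memberships contain NA", call. = FALSE)
  bad <- which(memberships < 0 | memberships > 1)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(memberships))
    stop(sprintf("membership %g at (%s, %s) is outside [0, 1]",
                 memberships[bad[1L]], objects[ij[1L]], parameters[ij[2L]]),
         call. = FALSE)
  }
  if (!is.null(sig_figs)) {
    sig_figs <- as.matrix(sig_figs)
    storage.mode(sig_figs) <- "integer"
    if (!identical(dim(sig_figs), dim(memberships))) {
      stop("sig_figs must have the same shape as memberships", call. = FALSE)
    }
    dimnames(sig_figs) <- list(objects, parameters)
  }
  dimnames(memberships) <- list(objects, parameters)
  structure(list(memberships = memberships, sig_figs = sig_figs),
            class = "fuzzy_soft_set")
}

#' @export
print.fuzzy_soft_set <- function(x, ...) {
  cat(sprintf("Fuzzy soft set: %d objects x %d parameters\n",
              nrow(x$memberships), ncol(x$memberships)))
  print(x$memberships, ...)
  invisible(x)
}

#' Accessors for fuzzy soft sets
#'
#' @param x a `fuzzy_soft_set`.
#' @return `memberships()` the membership matrix; `fss_objects()` and
#'   `fss_parameters()` the label vectors.
#' @export
memberships <- function(x) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  x$memberships
}

#' @rdname memberships
#' @export
fss_objects <- function(x) rownames(memberships(x))

#' @rdname memberships
#' @export
fss_parameters <- function(x) colnames(memberships(x))

#' Restrict a fuzzy soft set to a subset of its parameters
#'
#' @param x a `fuzzy_soft_set`.
#' @param parameters character vector of parameter labels to keep, in the
#'   requested order.
#' @return a `fuzzy_soft_set` over the same objects.
#' @export
select_parameters <- function(x, parameters) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  missing_p <- setdiff(parameters, fss_parameters(x))
  if (length(missing_p)) {
    stop("unknown parameter(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  fuzzy_soft_set(x$memberships[, parameters, drop = FALSE],
                 objects = fss_objects(x), parameters = parameters,
                 sig_figs = if (!is.null(x$sig_figs))
                   x$sig_figs[, parameters, drop = FALSE])
}

# align g's rows to f's object order; error if the universes differ
align_objects <- function(f, g) {
  of <- fss_objects(f)
  og <- fss_objects(g)
  if (!setequal(of, og) || length(of) != length(og)) {
    stop("fuzzy soft sets are defined over different object universes",
         call. = FALSE)
  }
  if (identical(of, og)) g else
    fuzzy_soft_set(g$memberships[of, , drop = FALSE],
                   objects = of, parameters = fss_parameters(g),
                   sig_figs = if (!is.null(g$sig_figs))
                     g$sig_figs[of, , drop = FALSE])
}

#' Fuzzy soft subset test
#'
#' `(F, A)` is a fuzzy soft subset of `(G, B)` when `A` is contained in `B`
#' and, for every shared parameter, `F`'s membership of each object does not
#' exceed `G`'s.
#'
#' @param f,g fuzzy soft sets over the same object universe.
#' @return `TRUE` or `FALSE`.
#' @export
is_fuzzy_subset <- function(f, g) {
  stopifnot(inherits(f, "fuzzy_soft_set"), inherits(g, "fuzzy_soft_set"))
  g <- align_objects(f, g)
  pf <- fss_parameters(f)
  if (!all(pf %in% fss_parameters(g))) return(FALSE)
  all(f$memberships <= g$memberships[, pf, drop = FALSE])
}

#' AND-product of two fuzzy soft sets
#'
#' Forms the fuzzy soft set on the Cartesian product of the two parameter
#' sets whose membership at pair `(a, b)` is the pointwise minimum of the two
#' input memberships. Pair columns are laid out row-major over `A x B` and
#' labelled `"(a,b)"`.
#'
#' @param f,g fuzzy soft sets over the same object universe.
#' @return a `fuzzy_soft_set` with `ncol(f) * ncol(g)` parameters.
#' @export
and_product <- function(f, g) {
  stopifnot(inherits(f, "fuzzy_soft_set"), inherits(g, "fuzzy_soft_set"))
  g <- align_objects(f, g)
  pa <- fss_parameters(f)
  pb <- fss_parameters(g)
  pairs <- expand.grid(b = pb, a = pa, stringsAsFactors = FALSE)[, c("a", "b")]
  mem <- matrix(0, nrow(f$memberships), nrow(pairs))
  sf <- NULL
  have_sf <- !is.null(f$sig_figs) && !is.null(g$sig_figs)
  if (have_sf) sf <- matrix(0L, nrow(f$memberships), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    va <- f$memberships[, pairs$a[k]]
    vb <- g$memberships[, pairs$b[k]]
    mem[, k] <- pmin(va, vb)
    if (have_sf) {
      # precision travels with whichever entry attains the minimum
      sa <- f$sig_figs[, pairs$a[k]]
      sb <- g$sig_figs[, pairs$b[k]]
      sf[, k] <- ifelse(va < vb, sa, ifelse(vb < va, sb, pmax(sa, sb)))
    }
  }
  fuzzy_soft_set(mem, objects = fss_objects(f),
                 parameters = sprintf("(%s,%s)", pairs$a, pairs$b),
                 sig_figs = sf)
}

#' Level soft set at a threshold
#'
#' Binarises a fuzzy soft set at threshold `t`: the indicator is 1 where the
#' membership is greater than or equal to `t`. Each object's choice value is
#' its indicator row sum.
#'
#' @param x a `fuzzy_soft_set`.
#' @param t threshold in `[0, 1]`.
#' @return an object of class `level_soft_set` with elements `indicator`,
#'   `threshold` and `choice_values`.
#' @export
level_soft_set <- function(x, t) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  ind <- (x$memberships >= t) * 1L
  structure(list(indicator = ind, threshold = t,
                 choice_values = rowSums(ind)),
            class = "level_soft_set")
}

#' @export
print.level_soft_set <- function(x, ...) {
  cat(sprintf("Level soft set at threshold %g\n", x$threshold))
  print(cbind(x$indicator, choice = x$choice_values), ...)
  invisible(x)
}

#' Row and column membership spreads
#'
#' For each parameter (column) the spread `alpha` is the difference between
#' its largest and smallest membership; for each object (row) the spread
#' `beta` is defined the same way across parameters. Both feed the mean
#' potentiality method's second threshold and its final tie-break.
#'
#' @param x a `fuzzy_soft_set`.
#' @return list with numeric vectors `alpha` (per parameter) and `beta`
#'   (per object).
#' @export
membership_ranges <- function(x) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  d <- x$memberships
  list(alpha = apply(d, 2, max) - apply(d, 2, min),
       beta  = apply(d, 1, max) - apply(d, 1, min))
}

# significant decimal digits of one non-negative decimal string:
# drop sign/point, strip leading zeros, count what remains
count_sig_figs <- function(s) {
  s <- sub("^\\+", "", trimws(s))
  digits <- gsub("[^0-9]", "", s)
  digits <- sub("^0+", "", digits)
  n <- nchar(digits)
  ifelse(n == 0L, 1L, n)
}

#' Maximum number of significant figures in a fuzzy soft set
#'
#' The mean potentiality method rounds its thresholds to the maximum number
#' of significant decimal digits found among the membership values as
#' written. That count is a property of the textual representation, so it is
#' recorded when a set is read from text ([read_fss()]) or generated
#' ([synth_fss()]); for sets built directly from numerics pass `override`.
#'
#' @param x a `fuzzy_soft_set`.
#' @param override optional positive integer to use instead of the recorded
#'   precision.
#' @return a positive integer.
#' @export
max_significant_figures <- function(x, override = NULL) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  if (!is.null(override)) {
    override <- as.integer(override)
    if (is.na(override) || override < 1L) {
      stop("override must be a positive integer", call. = FALSE)
    }
    return(override)
  }
  if (is.null(x$sig_figs)) {
    stop("no source precision recorded for this fuzzy soft set; ",
         "pass the number of significant figures explicitly",
         call. = FALSE)
  }
  max(x$sig_figs)
}

#' Round to a number of significant figures, half away from zero
#'
#' `signif()` rounds to even under IEEE ties; the decision procedures here
#' specify half-away-from-zero (0.625 at 2 significant figures is 0.63).
#'
#' @param x non-negative numeric vector.
#' @param rho positive integer number of significant figures.
#' @return `x` rounded to `rho` significant figures.
#' @export
round_sig <- function(x, rho) {
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 1L) stop("rho must be a positive integer",
                                   call. = FALSE)
  if (any(x < 0)) stop("round_sig expects non-negative values", call. = FALSE)
  out <- x
  nz <- x > 0
  if (any(nz)) {
    e <- floor(log10(x[nz]))
    scale <- 10^(rho - 1L - e)
    # nudge by a relative epsilon so values stored a hair below a tie
    # (0.626 * 50 = 31.299999...) still round half away from zero
    out[nz] <- floor(x[nz] * scale + 0.5 + 1e-9) / scale
  }
  out
}

#' Performance measure of a decision method
#'
#' Scores the alternative a method selects: the reciprocal of the summed
#' pairwise absolute spread of the optimum's memberships across the choice
#' parameters (unordered pairs), plus the optimum's total membership. Larger
#' is better. Undefined when the optimum's memberships are all equal.
#'
#' @param x a `fuzzy_soft_set` with at least two parameters.
#' @param optimal_object label of the selected optimal object.
#' @return the performance score, a positive number.
#' @export
performance_measure <- function(x, optimal_object) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  if (!optimal_object %in% fss_objects(x)) {
    stop("unknown object: ", optimal_object, call. = FALSE)
  }
  v <- x$memberships[optimal_object, ]
  if (length(v) < 2L) {
    stop("the performance measure needs at least two choice parameters",
         call. = FALSE)
  }
  s <- sum(abs(outer(v, v, "-"))) / 2  # unordered pairs i < j
  if (s == 0) {
    stop("performance measure undefined: the optimum's memberships are all equal",
         call. = FALSE)
  }
  1 / s + sum(v)
}
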