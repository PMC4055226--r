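#' Basic probability assignment over a frame of discernment
#'
#' A mass function maps subsets of a finite frame of mutually exclusive,
#' exhaustive alternatives to `[0, 1]`, assigning zero to the empty set and
#' summing to 1 over all focal sets. Arbitrary non-empty focal subsets are
#' supported, not just singletons and the full frame.
#'
#' @param frame character vector of distinct alternative labels (the frame
#'   of discernment, often written Theta).
#' @param subsets list of character vectors, each a non-empty subset of the
#'   frame: the focal sets.
#' @param masses numeric vector of the same length, non-negative, summing
#'   to 1 within `1e-9`.
#' @return an object of class `mass_function`.
#' @export
#' @examples
#' m1 <- mass_function(c("A1", "A2"),
#'                     list("A1", "A2", c("A1", "A2")), c(0.2, 0.5, 0.3))
#' belief(m1, "A1")
mass_function <- function(frame, subsets, masses) {
  frame <- as.character(frame)
  if (length(frame) < 1L || anyDuplicated(frame)) {
    stop("the frame must be a non-empty set of distinct labels", call. = FALSE)
  }
  if (!is.list(subsets)) subsets <- as.list(subsets)
  if (length(subsets) != length(masses)) {
    stop("subsets and masses must have the same length", call. = FALSE)
  }
  keys <- character(length(subsets))
  canon <- vector("list", length(subsets))
  for (k in seq_along(subsets)) {
    a <- unique(as.character(subsets[[k]]))
    if (length(a) == 0L) {
      stop("the empty set cannot be a focal set", call. = FALSE)
    }
    if (!all(a %in% frame)) {
      stop("focal set contains labels outside the frame: ",
           paste(setdiff(a, frame), collapse = ", "), call. = FALSE)
    }
    a <- frame[frame %in% a]  # canonical frame order
    canon[[k]] <- a
    keys[k] <- paste(a, collapse = "|")
  }
  masses <- as.numeric(masses)
  if (any(masses < -1e-12)) stop("masses must be non-negative", call. = FALSE)
  masses <- pmax(masses, 0)
  if (anyDuplicated(keys)) {
    agg <- tapply(masses, keys, sum)
    keep <- !duplicated(keys)
    canon <- canon[keep]
    keys <- keys[keep]
    masses <- as.numeric(agg[keys])
  }
  keep <- masses > 0
  canon <- canon[keep]
  keys <- keys[keep]
  masses <- masses[keep]
  if (abs(sum(masses) - 1) > 1e-9) {
    stop(sprintf("masses sum to %.12f, not 1", sum(masses)), call. = FALSE)
  }
  names(masses) <- keys
  structure(list(frame = frame, focal = canon, masses = masses),
            class = "mass_function")
}

#' Convenience constructor for singleton-plus-frame mass functions
#'
#' @param frame character vector of alternative labels.
#' @param singletons named numeric vector of masses on singletons (names in
#'   the frame); the remaining mass goes to the whole frame.
#' @return a `mass_function`.
#' @export
singleton_mass_function <- function(frame, singletons) {
  theta <- 1 - sum(singletons)
  if (theta < -1e-9) stop("singleton masses exceed 1", call. = FALSE)
  subsets <- c(as.list(names(singletons)), list(frame))
  mass_function(frame, subsets, c(unname(singletons), max(theta, 0)))
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  cat("Mass function on {", paste(x$frame, collapse = ", "), "}\n", sep = "")
  lab <- vapply(x$focal, function(a) {
    if (length(a) == length(x$frame)) "THETA"
    else paste0("{", paste(a, collapse = ","), "}")
  }, character(1))
  for (k in order(-x$masses)) {
    cat(sprintf("  %-20s %.*f\n", lab[k], digits, x$masses[k]))
  }
  invisible(x)
}

#' @rdname mass_function
#' @param x a `mass_function`.
#' @export
focal_sets <- function(x) {
  stopifnot(inherits(x, "mass_function"))
  x$focal
}

#' Mass assigned to one subset
#'
#' @param x a `mass_function`.
#' @param a character vector, a non-empty subset of the frame.
#' @return the stored mass of `a` (0 if `a` is not focal).
#' @export
mass <- function(x, a) {
  stopifnot(inherits(x, "mass_function"))
  a <- unique(as.character(a))
  if (!all(a %in% x$frame)) {
    stop("subset contains labels outside the frame", call. = FALSE)
  }
  key <- paste(x$frame[x$frame %in% a], collapse = "|")
  if (key %in% names(x$masses)) unname(x$masses[key]) else 0
}

#' Belief of a subset of the frame
#'
#' `Bel(A)` is the total mass of all focal sets contained in `A`; it is the
#' degree of support committed to `A`. `Bel` of the whole frame is 1 and of
#' the empty set 0; for a singleton, belief equals its mass.
#'
#' @param x a `mass_function`.
#' @param a character vector of frame labels (may be empty).
#' @return the belief value in `[0, 1]`.
#' @export
belief <- function(x, a) {
  stopifnot(inherits(x, "mass_function"))
  a <- unique(as.character(a))
  if (!all(a %in% x$frame)) {
    stop("subset contains labels outside the frame: ",
         paste(setdiff(a, x$frame), collapse = ", "), call. = FALSE)
  }
  if (length(a) == 0L) return(0)
  inside <- vapply(x$focal, function(b) all(b %in% a), logical(1))
  sum(x$masses[inside])
}

#' Dempster's rule for two mass functions
#'
#' Combines two independent bodies of evidence on the same frame by
#' intersecting every pair of focal sets. The mass falling on empty
#' intersections is the conflict `K`; the surviving products are
#' renormalised by `1/(1 - K)`. Total conflict (`K = 1`) means the evidence
#' is non-combinable and is an error.
#'
#' @param m1,m2 mass functions on the same frame.
#' @return an object of class `ds_combination`: list with `combined` (a
#'   `mass_function`) and `conflict` (`K` in `[0, 1)`).
#' @export
#' @examples
#' m1 <- singleton_mass_function(c("A1", "A2"), c(A1 = 0.2, A2 = 0.5))
#' m2 <- singleton_mass_function(c("A1", "A2"), c(A1 = 0.4, A2 = 0.3))
#' ds_combine(m1, m2)$conflict   # 0.26
ds_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  if (!identical(m1$frame, m2$frame)) {
    stop("mass functions are defined on different frames", call. = FALSE)
  }
  frame <- m1$frame
  acc <- new.env(parent = emptyenv())
  conflict <- 0
  for (i in seq_along(m1$focal)) {
    for (j in seq_along(m2$focal)) {
      p <- m1$masses[[i]] * m2$masses[[j]]
      if (p == 0) next
      inter <- intersect(m1$focal[[i]], m2$focal[[j]])
      if (length(inter) == 0L) {
        conflict <- conflict + p
      } else {
        key <- paste(frame[frame %in% inter], collapse = "|")
        acc[[key]] <- p + (if (is.null(acc[[key]])) 0 else acc[[key]])
      }
    }
  }
  if (conflict >= 1 - 1e-12) {
    stop("total conflict (K = 1): the evidence cannot be combined",
         call. = FALSE)
  }
  keys <- ls(acc)
  masses <- vapply(keys, function(k) acc[[k]], numeric(1)) / (1 - conflict)
  subsets <- strsplit(keys, "|", fixed = TRUE)
  structure(list(combined = mass_function(frame, subsets, masses),
                 conflict = conflict),
            class = "ds_combination")
}

#' @export
print.ds_combination <- function(x, ...) {
  cat(sprintf("Dempster combination, conflict K = %.4f\n", x$conflict))
  print(x$combined, ...)
  invisible(x)
}

#' Combine a list of mass functions
#'
#' Left-fold of [ds_combine()]; Dempster's rule is commutative and
#' associative, so the result is independent of the order of the list.
#'
#' @param masses non-empty list of mass functions on a shared frame.
#' @return the combined `mass_function`.
#' @export
ds_combine_all <- function(masses) {
  if (!is.list(masses) || length(masses) < 1L) {
    stop("need a non-empty list of mass functions", call. = FALSE)
  }
  out <- masses[[1L]]
  for (k in seq_along(masses)[-1L]) {
    out <- ds_combine(out, masses[[k]])$combined
  }
  out
}

#' Build per-parameter mass functions from grey analysis
#'
#' Turns each column of the information structure image into a basic
#' probability assignment: alternative `x_i` receives the normalised
#' membership discounted by the parameter's uncertainty,
#' `m_j({x_i}) = image_ij * (1 - DOI(e_j))`, and the whole frame absorbs the
#' remainder, which equals `DOI(e_j)` because image columns sum to 1. A
#' maximally uncertain parameter (`DOI = 1`) thus yields vacuous evidence.
#'
#' @param image column-normalised matrix from
#'   [information_structure_image()], with row names the alternatives.
#' @param doi numeric vector of uncertainty degrees in `(0, 1]`, one per
#'   column.
#' @return list of `mass_function`s, one per parameter, named by column.
#' @export
build_mass_functions <- function(image, doi) {
  image <- as.matrix(image)
  if (length(doi) != ncol(image)) {
    stop("doi must have one entry per image column", call. = FALSE)
  }
  if (any(doi <= 0 | doi > 1)) {
    stop("uncertainty degrees must lie in (0, 1]", call. = FALSE)
  }
  frame <- rownames(image)
  if (is.null(frame)) frame <- paste0("x", seq_len(nrow(image)))
  out <- lapply(seq_len(ncol(image)), function(j) {
    s <- image[, j] * (1 - doi[j])
    names(s) <- frame
    singleton_mass_function(frame, s)
  })
  names(out) <- colnames(image)
  out
}
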