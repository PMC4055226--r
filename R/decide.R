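#' Decision making by grey relational analysis and evidence combination
#'
#' The full pipeline: (1) take the membership matrix as the decision matrix;
#' (2) compute each alternative's row mean; (3) the difference matrix;
#' (4) grey mean relational degrees with distinguishing coefficient `rho`;
#' (5) the q-order uncertainty degree of each parameter; (6) the
#' column-normalised information structure image; (7) per-parameter mass
#' functions with singleton masses discounted by the parameter's
#' uncertainty; (8) Dempster combination of all parameter evidences;
#' (9) ranking of the alternatives by combined singleton mass (equal to the
#' belief of each singleton), ties grouped. The optimal set collects every
#' alternative attaining the maximum.
#'
#' @param x a `fuzzy_soft_set` of alternatives by parameters.
#' @param rho distinguishing coefficient in `(0, 1)`.
#' @param q order of the uncertainty norm, at least 1.
#' @return an object of class `gds_report`: combined singleton masses,
#'   residual whole-frame mass, mean input uncertainty, ranking (a list of
#'   tie groups, best first), the optimal set, and all intermediates.
#' @export
#' @examples
#' fss <- read_fss(system.file("extdata", "table3.csv", package = "greysoft"))
#' gds_decide(fss)
gds_decide <- function(x, rho = 0.5, q = 2) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  grey <- grey_analysis(x, rho = rho, q = q)
  image <- information_structure_image(x)
  masses <- build_mass_functions(image, grey$doi)
  combined <- ds_combine_all(masses)
  frame <- fss_objects(x)
  singleton <- vapply(frame, function(a) mass(combined, a), numeric(1))
  theta <- mass(combined, frame)
  ranking <- rank_groups(singleton)
  structure(list(method = "gds",
                 combined = singleton,
                 theta_mass = theta,
                 mean_doi = mean(grey$doi),
                 ranking = ranking,
                 optimal = ranking[[1L]],
                 intermediates = list(grey = grey, image = image,
                                      masses = masses,
                                      combined_mass = combined)),
            class = "gds_report")
}

# group labels by descending value, ties (within tol) in one group
rank_groups <- function(values, tol = 1e-9) {
  ord <- order(-values, names(values))
  groups <- list()
  for (i in ord) {
    g <- length(groups)
    if (g > 0L && abs(values[i] - values[[names(groups[[g]])[1L]]]) <= tol) {
      groups[[g]] <- c(groups[[g]], values[i])
    } else {
      groups[[g + 1L]] <- values[i]
    }
  }
  lapply(groups, names)
}

format_ranking <- function(ranking) {
  paste(vapply(ranking, function(g) paste(g, collapse = " ~ "), character(1)),
        collapse = " ≻ ")
}

#' @export
print.gds_report <- function(x, digits = 4, ...) {
  cat("Grey relational + Dempster-Shafer decision\n")
  cat("Combined singleton masses:\n")
  print(round(x$combined, digits))
  cat(sprintf("Residual whole-frame mass: %.*f (mean input uncertainty %.*f)\n",
              digits, x$theta_mass, digits, x$mean_doi))
  cat("Ranking:", format_ranking(x$ranking), "\n")
  cat("Optimal:", paste(x$optimal, collapse = ", "), "\n")
  invisible(x)
}

#' Mean potentiality decision method
#'
#' The level-soft-set baseline: (1) look for a normal parameter reduction
#' and work on the reduced set if one exists; (2) compute the mean
#' potentiality (the grand mean of all memberships) rounded to the maximum
#' number of significant figures `rho` among the entries; (3, 4) threshold
#' the set at that level and stop if one object has the unique maximum
#' choice value; (5-8) otherwise threshold at the rounded mean of the
#' per-parameter membership spreads and stop on a unique maximum; (9) break
#' any remaining tie by the smallest per-object spread `beta` among the tied
#' objects.
#'
#' @param x a `fuzzy_soft_set`.
#' @param sig_figs optional override for the significant-figure count used
#'   in rounding the thresholds (needed when `x` carries no source
#'   precision).
#' @param reduction logical; attempt the normal parameter reduction search
#'   of step 1 (default `TRUE`).
#' @param max_subset_size cap on the size of the dispensable parameter set
#'   searched for (default 3; the search is exhaustive over subsets).
#' @return an object of class `mp_report` recording every intermediate:
#'   the reduction (if any), `m_p` and its rounded value, first-level choice
#'   values, `alpha` and its rounded value, second-level choice values, the
#'   `beta` vector, the stage at which the decision resolved (4, 8 or 9) and
#'   the optimal set.
#' @export
mean_potentiality_decide <- function(x, sig_figs = NULL, reduction = TRUE,
                                     max_subset_size = 3L) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  rho <- max_significant_figures(x, override = sig_figs)
  reduced_to <- NULL
  if (isTRUE(reduction) && ncol(x$memberships) > 1L) {
    reduced_to <- normal_parameter_reduction(x, max_subset_size)
    if (!is.null(reduced_to)) x <- select_parameters(x, reduced_to)
  }
  d <- x$memberships
  mp <- mean(d)
  mp_rounded <- round_sig(mp, rho)
  level1 <- level_soft_set(x, mp_rounded)
  c1 <- level1$choice_values
  top1 <- names(c1)[c1 == max(c1)]
  ranges <- membership_ranges(x)
  if (length(top1) == 1L) {
    return(new_mp_report(reduced_to, rho, mp, mp_rounded, c1, ranges,
                         alpha = NULL, alpha_rounded = NULL, c2 = NULL,
                         stage = 4L, optimal = top1))
  }
  alpha <- mean(ranges$alpha)
  alpha_rounded <- round_sig(alpha, rho)
  level2 <- level_soft_set(x, alpha_rounded)
  c2 <- level2$choice_values
  top2 <- names(c2)[c2 == max(c2)]
  if (length(top2) == 1L) {
    return(new_mp_report(reduced_to, rho, mp, mp_rounded, c1, ranges,
                         alpha, alpha_rounded, c2, stage = 8L,
                         optimal = top2))
  }
  beta_tied <- ranges$beta[top2]
  optimal <- names(beta_tied)[beta_tied <= min(beta_tied) + 1e-12]
  new_mp_report(reduced_to, rho, mp, mp_rounded, c1, ranges,
                alpha, alpha_rounded, c2, stage = 9L, optimal = optimal)
}

new_mp_report <- function(reduced_to, rho, mp, mp_rounded, c1, ranges,
                          alpha, alpha_rounded, c2, stage, optimal) {
  structure(list(method = "mean_potentiality",
                 reduction = reduced_to, sig_figs = rho,
                 mp = mp, mp_rounded = mp_rounded,
                 choice_values = c1,
                 alpha = alpha, alpha_rounded = alpha_rounded,
                 choice_values2 = c2,
                 column_ranges = ranges$alpha, row_ranges = ranges$beta,
                 stage = stage, optimal = optimal),
            class = "mp_report")
}

#' @export
print.mp_report <- function(x, digits = 4, ...) {
  cat("Mean potentiality decision\n")
  if (!is.null(x$reduction)) {
    cat("Reduced to parameters:", paste(x$reduction, collapse = ", "), "\n")
  }
  cat(sprintf("Mean potentiality %.*f -> threshold %g; choice values: %s\n",
              digits, x$mp, x$mp_rounded,
              paste(x$choice_values, collapse = ", ")))
  if (!is.null(x$alpha)) {
    cat(sprintf("Mean column spread %.*f -> threshold %g; choice values: %s\n",
                digits, x$alpha, x$alpha_rounded,
                paste(x$choice_values2, collapse = ", ")))
  }
  cat(sprintf("Resolved at stage %d; optimal: %s\n", x$stage,
              paste(x$optimal, collapse = ", ")))
  invisible(x)
}

#' Normal parameter reduction
#'
#' Searches for a non-empty proper subset of the parameters whose per-object
#' membership sums are identical across all objects. Deleting such a
#' dispensable set shifts every object's total by the same constant and so
#' preserves the choice-value ordering. The search is exhaustive over
#' subsets of size up to `max_subset_size`, smallest first.
#'
#' @param x a `fuzzy_soft_set`.
#' @param max_subset_size largest dispensable-set size to try; capped at
#'   `n - 1` so the remaining set is non-empty.
#' @param tol numeric tolerance on the equality of the sums.
#' @return character vector of the remaining parameters, or `NULL` when no
#'   dispensable set exists.
#' @export
normal_parameter_reduction <- function(x, max_subset_size = 3L, tol = 1e-9) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  d <- x$memberships
  n <- ncol(d)
  if (n < 2L) return(NULL)
  max_subset_size <- min(as.integer(max_subset_size), n - 1L)
  params <- fss_parameters(x)
  for (k in seq_len(max_subset_size)) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      sums <- rowSums(d[, idx, drop = FALSE])
      if (max(sums) - min(sums) <= tol) {
        return(params[-idx])
      }
    }
  }
  NULL
}

#' Compare the two decision methods on one fuzzy soft set
#'
#' Runs both the grey relational + evidence pipeline and the mean
#' potentiality method, evaluates the performance measure at each method's
#' optimum, and reports which method scores higher (equal scores mean equal
#' performance, which is guaranteed when the optima coincide).
#'
#' @param x a `fuzzy_soft_set`.
#' @param rho,q parameters of [gds_decide()].
#' @param sig_figs,reduction,max_subset_size parameters of
#'   [mean_potentiality_decide()].
#' @return an object of class `method_comparison` with both optima, both
#'   performance values and the better method (`"gds"`, `"mp"` or
#'   `"same"`).
#' @export
compare_methods <- function(x, rho = 0.5, q = 2, sig_figs = NULL,
                            reduction = TRUE, max_subset_size = 3L) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  gds <- gds_decide(x, rho = rho, q = q)
  mp <- mean_potentiality_decide(x, sig_figs = sig_figs,
                                 reduction = reduction,
                                 max_subset_size = max_subset_size)
  if (length(gds$optimal) != 1L) {
    stop("the grey/evidence method returned a tied optimum (",
         paste(gds$optimal, collapse = ", "),
         "); the performance measure needs a unique optimal object",
         call. = FALSE)
  }
  if (length(mp$optimal) != 1L) {
    stop("the mean potentiality method returned a tied optimum (",
         paste(mp$optimal, collapse = ", "),
         "); the performance measure needs a unique optimal object",
         call. = FALSE)
  }
  perf_gds <- performance_measure(x, gds$optimal)
  perf_mp <- performance_measure(x, mp$optimal)
  better <- if (perf_gds > perf_mp) "gds"
            else if (perf_mp > perf_gds) "mp"
            else "same"
  structure(list(gds = gds, mp = mp,
                 gds_optimal = gds$optimal, mp_optimal = mp$optimal,
                 gds_performance = perf_gds, mp_performance = perf_mp,
                 better = better),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 4, ...) {
  cat("Method comparison\n")
  cat(sprintf("  grey/evidence:     optimum %s, performance %.*f\n",
              x$gds_optimal, digits, x$gds_performance))
  cat(sprintf("  mean potentiality: optimum %s, performance %.*f\n",
              x$mp_optimal, digits, x$mp_performance))
  cat("  better:", if (x$better == "same") "same performance" else x$better,
      "\n")
  invisible(x)
}
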