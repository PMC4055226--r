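#' Read a fuzzy soft set from delimited text
#'
#' The layout is comma-separated: a header row of parameter labels, a first
#' column of object labels, and membership values in `[0, 1]` in the body.
#' The number of significant decimal digits of each cell as written is
#' recorded so that the mean potentiality method can round its thresholds to
#' the source precision.
#'
#' @param path path to the file.
#' @return a `fuzzy_soft_set` with per-entry source precision.
#' @export
#' @examples
#' read_fss(system.file("extdata", "table3.csv", package = "greysoft"))
read_fss <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, row.names = NULL,
                         colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) < 2L) stop("expected an object-label column and at least ",
                           "one parameter column", call. = FALSE)
  objects <- raw[[1L]]
  parameters <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  if (anyNA(num)) {
    ij <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at (%s, %s)",
                 cells[ij[1L], ij[2L]], objects[ij[1L]], parameters[ij[2L]]),
         call. = FALSE)
  }
  bad <- which(num < 0 | num > 1)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(num))
    stop(sprintf("value %s at (%s, %s) is outside [0, 1]",
                 cells[ij[1L], ij[2L]], objects[ij[1L]], parameters[ij[2L]]),
         call. = FALSE)
  }
  sf <- matrix(count_sig_figs(cells), nrow(num), ncol(num))
  fuzzy_soft_set(num, objects = objects, parameters = parameters,
                 sig_figs = sf)
}

# minimal decimal text for a membership value (exact for values that came
# from short decimal strings)
format_membership <- function(v) {
  s <- sprintf("%.15f", v)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s
}

#' Write a fuzzy soft set as delimited text
#'
#' Inverse of [read_fss()]: values are written as minimal decimal strings,
#' so a write/read round trip reproduces the set exactly for values of
#' ordinary decimal precision.
#'
#' @param x a `fuzzy_soft_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fss <- function(x, path) {
  stopifnot(inherits(x, "fuzzy_soft_set"))
  d <- x$memberships
  body <- matrix(vapply(d, format_membership, character(1)),
                 nrow(d), ncol(d))
  df <- data.frame(object = fss_objects(x), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("object", fss_parameters(x))
  # pair labels like "(e1,s1)" contain commas, so labels must be quoted
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate a random fuzzy soft set
#'
#' Memberships are drawn independently and uniformly on `[0, 1]` and rounded
#' to `decimals` decimal places; object and parameter labels are
#' auto-generated as `x1..xm` and `e1..en`. The same seed always produces
#' the same set, and the caller's random-number state is left untouched.
#'
#' @param m number of objects (at least 1).
#' @param n number of parameters (at least 1).
#' @param seed non-negative integer seed.
#' @param decimals decimal places to round to (at least 1).
#' @return a `fuzzy_soft_set` with source precision recorded.
#' @export
synth_fss <- function(m, n, seed, decimals = 2L) {
  m <- as.integer(m); n <- as.integer(n); decimals <- as.integer(decimals)
  if (is.na(m) || m < 1L || is.na(n) || n < 1L) {
    stop("m and n must be positive integers", call. = FALSE)
  }
  if (is.na(decimals) || decimals < 1L) {
    stop("decimals must be a positive integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  vals <- round(stats::runif(m * n), decimals)
  text <- vapply(vals, format_membership, character(1))
  fuzzy_soft_set(matrix(vals, m, n),
                 objects = paste0("x", seq_len(m)),
                 parameters = paste0("e", seq_len(n)),
                 sig_figs = matrix(count_sig_figs(text), m, n))
}

# ---- report serialization ----------------------------------------------

display4 <- function(x) round(unclass(x), 4)

mass_function_to_list <- function(m) {
  keys <- vapply(m$focal, function(a) {
    if (length(a) == length(m$frame)) "THETA" else paste(a, collapse = ",")
  }, character(1))
  ord <- order(keys)
  out <- as.list(unname(m$masses)[ord])
  names(out) <- keys[ord]
  out
}

report_to_list <- function(report, intermediates = FALSE) {
  UseMethod("report_to_list")
}

#' @export
report_to_list.gds_report <- function(report, intermediates = FALSE) {
  out <- list(
    method = "gds",
    optimal = as.list(report$optimal),
    ranking = lapply(report$ranking, as.list),
    ranking_text = format_ranking(report$ranking),
    combined = as.list(report$combined),
    combined_display = as.list(display4(report$combined)),
    theta_mass = report$theta_mass,
    theta_mass_display = display4(report$theta_mass),
    mean_doi = report$mean_doi,
    mean_doi_display = display4(report$mean_doi))
  if (intermediates) {
    g <- report$intermediates$grey
    out$intermediates <- list(
      row_means = as.list(g$row_means),
      doi = as.list(g$doi),
      relational = apply(g$relational, 1, as.list),
      image = apply(report$intermediates$image, 1, as.list),
      masses = lapply(report$intermediates$masses, mass_function_to_list),
      combined_mass = mass_function_to_list(
        report$intermediates$combined_mass))
  }
  out
}

#' @export
report_to_list.mp_report <- function(report, intermediates = FALSE) {
  out <- list(
    method = "mean_potentiality",
    optimal = as.list(report$optimal),
    stage = report$stage,
    mp = report$mp, mp_rounded = report$mp_rounded,
    choice_values = as.list(report$choice_values))
  if (!is.null(report$reduction)) out$reduction <- as.list(report$reduction)
  if (!is.null(report$alpha)) {
    out$alpha <- report$alpha
    out$alpha_rounded <- report$alpha_rounded
    out$choice_values2 <- as.list(report$choice_values2)
  }
  if (intermediates) {
    out$intermediates <- list(column_ranges = as.list(report$column_ranges),
                              row_ranges = as.list(report$row_ranges))
  }
  out
}

#' @export
report_to_list.method_comparison <- function(report, intermediates = FALSE) {
  list(method = "compare",
       gds = report_to_list(report$gds, intermediates),
       mp = report_to_list(report$mp, intermediates),
       gds_performance = report$gds_performance,
       gds_performance_display = display4(report$gds_performance),
       mp_performance = report$mp_performance,
       mp_performance_display = display4(report$mp_performance),
       better = report$better)
}

#' Serialize a decision report to JSON
#'
#' Numbers are emitted at full double precision, alongside `*_display`
#' fields rounded to 4 decimals for human reading. Output is stable: keys
#' are emitted in a fixed order and repeated runs on the same input are
#' byte-identical.
#'
#' @param report a `gds_report`, `mp_report` or `method_comparison`.
#' @param path optional path; when given the JSON is written there.
#' @param intermediates include full intermediate matrices and masses.
#' @return the JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL, intermediates = FALSE) {
  json <- jsonlite::toJSON(report_to_list(report, intermediates),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
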