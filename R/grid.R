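#' Construct an APC grid of aggregated biomarker means
#'
#' An `apc_grid` holds mean biomarker values on an age-group x survey-year
#' lattice (a Lexis grid aggregated to 10-year age bands and yearly surveys),
#' together with a missingness mask. Unobserved cells are stored as `NA`.
#'
#' @param values numeric matrix, one row per age group, one column per survey
#'   year; `NA` marks unobserved cells, every observed cell must be finite.
#' @param age_lower,age_upper integer vectors of inclusive age-group bounds
#'   (e.g. 20 and 29 for the 20-29 band); groups must be pairwise disjoint
#'   and sorted ascending.
#' @param years integer vector of calendar survey years, strictly increasing.
#'   Years absent from the survey (e.g. 1974) are simply not listed.
#' @param biomarker,unit,sex character labels carried through to outputs
#'   (e.g. `"sbp"`, `"mmHg"`, `"men"`).
#' @param n_obs optional matrix of subject counts, same shape as `values`.
#' @return An object of class `apc_grid`.
#' @examples
#' g <- apc_grid(matrix(c(120, 130, 125, 135), 2, 2),
#'               age_lower = c(20, 30), age_upper = c(29, 39),
#'               years = c(2000, 2001), biomarker = "sbp", unit = "mmHg")
#' @export
apc_grid <- function(values, age_lower, age_upper, years,
                     biomarker = "biomarker", unit = "", sex = "",
                     n_obs = NULL) {
  values <- as.matrix(values)
  age_lower <- as.integer(age_lower)
  age_upper <- as.integer(age_upper)
  years <- as.integer(years)
  I <- length(age_lower)
  J <- length(years)
  if (length(age_upper) != I)
    stop("age_lower and age_upper must have the same length")
  if (!all(dim(values) == c(I, J)))
    stop("values must be a ", I, " x ", J, " matrix (age groups x years)")
  if (any(age_lower < 0))
    stop("age bounds must be non-negative")
  if (any(age_lower > age_upper))
    stop("each age group needs lower <= upper")
  if (I > 1) {
    if (any(diff(age_lower) <= 0))
      stop("age groups must be sorted ascending")
    if (any(age_upper[-I] >= age_lower[-1]))
      stop("age groups must be pairwise disjoint")
  }
  if (J > 1 && any(diff(years) <= 0))
    stop("years must be strictly increasing")
  obs <- !is.na(values)
  if (any(obs & !is.finite(values)))
    stop("observed cells must hold finite values")
  if (!is.null(n_obs)) {
    n_obs <- as.matrix(n_obs)
    if (!all(dim(n_obs) == dim(values)))
      stop("n_obs must have the same shape as values")
  }
  rownames(values) <- age_labels(age_lower, age_upper)
  colnames(values) <- years
  structure(
    list(values = values, age_lower = age_lower, age_upper = age_upper,
         years = years, biomarker = biomarker, unit = unit, sex = sex,
         n_obs = n_obs),
    class = "apc_grid")
}

age_labels <- function(lower, upper) paste0(lower, "-", upper)

#' @export
print.apc_grid <- function(x, ...) {
  cat("<apc_grid> ", x$biomarker,
      if (nzchar(x$unit)) paste0(" [", x$unit, "]"),
      if (nzchar(x$sex)) paste0(", ", x$sex), "\n", sep = "")
  cat("  ", nrow(x$values), " age groups (",
      paste(rownames(x$values)[c(1, nrow(x$values))], collapse = " .. "),
      "), ", length(x$years), " years (", x$years[1], "-",
      x$years[length(x$years)], ")\n", sep = "")
  cat("  ", sum(!is.na(x$values)), " observed / ",
      length(x$values), " cells\n", sep = "")
  invisible(x)
}

#' Birth-year span of an age group observed in a given survey year
#'
#' People aged `lower`..`upper` (inclusive, in whole years) in calendar year
#' `year` were born between `year - upper` and `year - lower`. For example
#' the 60-69 group surveyed in 1973 was born 1904-1913.
#'
#' @param age_lower,age_upper inclusive age bounds in whole years.
#' @param year calendar survey year; must exceed `age_upper`.
#' @return Integer vector `c(earliest, latest)` birth year.
#' @examples
#' cohort_birth_span(60, 69, 1973)  # 1904 1913
#' @export
cohort_birth_span <- function(age_lower, age_upper, year) {
  if (age_lower > age_upper) stop("age_lower must not exceed age_upper")
  if (age_lower < 0) stop("ages must be non-negative")
  if (year <= age_upper)
    stop("survey year must exceed the upper age bound")
  c(earliest = as.integer(year - age_upper),
    latest = as.integer(year - age_lower))
}

#' Map grid cells to one-year-shift birth cohorts
#'
#' Cohort levels are keyed by calendar birth span, not by positional index
#' arithmetic, so gaps in the survey years (a missing 1974, say) do not
#' corrupt the mapping. Level 1 is the oldest birth span present among the
#' observed cells; level K the youngest. Two cells share a level exactly when
#' they share a birth span, and every level is attached to at least one
#' observed cell.
#'
#' @param grid an [apc_grid].
#' @return An object of class `cohort_index`: a list with the per-cell level
#'   matrix `k` (NA for cells whose span is attached to no observed cell),
#'   per-level `birth_start` / `birth_end`, and the level count `K`.
#' @export
build_cohort_index <- function(grid) {
  stopifnot(inherits(grid, "apc_grid"))
  I <- length(grid$age_lower)
  J <- length(grid$years)
  # birth span of each cell: (year - upper age) .. (year - lower age)
  starts <- outer(-grid$age_upper, grid$years, `+`)
  ends <- outer(-grid$age_lower, grid$years, `+`)
  obs <- !is.na(grid$values)
  if (!any(obs)) stop("grid has no observed cells")
  spans <- unique(cbind(start = starts[obs], end = ends[obs]))
  spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
  key <- function(s, e) paste(s, e)
  lev_key <- key(spans[, 1], spans[, 2])
  k <- matrix(match(key(starts, ends), lev_key), I, J)
  structure(
    list(k = k, birth_start = as.integer(spans[, 1]),
         birth_end = as.integer(spans[, 2]), K = nrow(spans)),
    class = "cohort_index")
}

#' @export
print.cohort_index <- function(x, ...) {
  cat("<cohort_index> K = ", x$K, " birth cohorts, ",
      x$birth_start[1], "-", x$birth_end[1], " .. ",
      x$birth_start[x$K], "-", x$birth_end[x$K], "\n", sep = "")
  invisible(x)
}

#' Read APC grids from a long-format CSV table
#'
#' The file must carry one header row with columns
#' `sex,biomarker,unit,year,age_lower,age_upper,mean` (optionally `n`),
#' comma-separated, UTF-8. Rows absent from the file become unobserved cells.
#'
#' @param path path to the CSV file.
#' @return A named list of [apc_grid] objects, one per `sex:biomarker`
#'   combination present in the file.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, colClasses = "character",
                       fileEncoding = "UTF-8")
  need <- c("sex", "biomarker", "unit", "year", "age_lower", "age_upper", "mean")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & nzchar(d[[col]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric ", col, " at data row(s) ",
           paste(utils::head(unique(c(bad, which(is.na(v)))), 5), collapse = ", "))
    v
  }
  d$year <- num("year"); d$age_lower <- num("age_lower")
  d$age_upper <- num("age_upper"); d$mean <- num("mean")
  inv <- which(d$age_lower > d$age_upper)
  if (length(inv))
    stop("inverted age bounds at data row(s) ", paste(inv, collapse = ", "))
  key <- paste(d$sex, d$biomarker, d$year, d$age_lower, d$age_upper)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (sex, biomarker, year, age group) at data row(s) ",
         paste(dup, collapse = ", "))
  out <- list()
  for (grp in split(d, paste(d$sex, d$biomarker, sep = ":"))) {
    ages <- unique(grp[, c("age_lower", "age_upper")])
    ages <- ages[order(ages$age_lower), , drop = FALSE]
    years <- sort(unique(grp$year))
    vals <- matrix(NA_real_, nrow(ages), length(years))
    nmat <- if ("n" %in% names(d)) matrix(NA_real_, nrow(ages), length(years))
    i <- match(paste(grp$age_lower, grp$age_upper),
               paste(ages$age_lower, ages$age_upper))
    j <- match(grp$year, years)
    vals[cbind(i, j)] <- grp$mean
    if (!is.null(nmat) && any(nzchar(grp$n)))
      nmat[cbind(i, j)] <- suppressWarnings(as.numeric(grp$n))
    g <- apc_grid(vals, ages$age_lower, ages$age_upper, years,
                  biomarker = grp$biomarker[1], unit = grp$unit[1],
                  sex = grp$sex[1], n_obs = nmat)
    out[[paste(grp$sex[1], grp$biomarker[1], sep = ":")]] <- g
  }
  out
}

#' Write an APC grid as a long-format CSV table
#'
#' One row per observed cell, in the schema read back by [read_grid()].
#'
#' @param grid an [apc_grid] (or a list of them, concatenated to one file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  if (inherits(grid, "apc_grid")) grid <- list(grid)
  rows <- lapply(grid, function(g) {
    obs <- which(!is.na(g$values), arr.ind = TRUE)
    if (!nrow(obs)) return(NULL)
    d <- data.frame(
      sex = g$sex, biomarker = g$biomarker, unit = g$unit,
      year = g$years[obs[, 2]],
      age_lower = g$age_lower[obs[, 1]],
      age_upper = g$age_upper[obs[, 1]],
      mean = g$values[obs])
    if (!is.null(g$n_obs)) d$n <- g$n_obs[obs]
    d[order(d$year, d$age_lower), , drop = FALSE]
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(sex = character(), biomarker = character(),
                    unit = character(), year = integer(),
                    age_lower = integer(), age_upper = integer(),
                    mean = numeric())
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Direct age standardization of a grid
#'
#' Computes, for every survey year in which *all* age groups are observed,
#' the weighted mean of the age-specific values under a fixed standard set of
#' age weights (normalized to sum one). Years with any missing age group get
#' `NA`, mirroring how published age-standardized series leave blanks when an
#' age group was not surveyed; no renormalization over the observed groups is
#' attempted.
#'
#' @param grid an [apc_grid].
#' @param weights one non-negative weight per age group (default equal);
#'   normalized internally. The survey's own standard population is not
#'   published, so the weights are configurable.
#' @return A data.frame with columns `year` and `value`.
#' @export
age_standardize <- function(grid, weights = NULL) {
  stopifnot(inherits(grid, "apc_grid"))
  I <- length(grid$age_lower)
  if (is.null(weights)) weights <- rep(1, I)
  if (length(weights) != I)
    stop("need one weight per age group (", I, ")")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  value <- apply(grid$values, 2, function(col)
    if (anyNA(col)) NA_real_ else sum(w * col))
  data.frame(year = grid$years, value = unname(value))
}

#' Load the packaged age-standardized reference series
#'
#' Returns the transcription of the published yearly age-standardized
#' biomarker table (systolic blood pressure, serum glucose, triglyceride,
#' HDL cholesterol, BMI; men and women; 1973 and 1975-2018) shipped with the
#' package. Blank cells in the printed table are `NA`.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A data.frame with columns `year`, `sex`, `biomarker`, `value`.
#' @export
read_table1 <- function(path = system.file("extdata",
                                           "table1_age_standardized.csv",
                                           package = "apctrends")) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  d$value <- suppressWarnings(as.numeric(d$value))
  d
}
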