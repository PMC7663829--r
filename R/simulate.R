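#' Define an APC study design
#'
#' A design is the layout a grid lives on: the age bands, the survey years
#' actually conducted, and any individual (age group, year) cells known to be
#' missing within conducted years.
#'
#' @param age_lower,age_upper inclusive age-group bounds, as in [apc_grid()].
#' @param years calendar survey years, strictly increasing.
#' @param missing_cells optional data.frame with columns `age` (age-group
#'   index) and `year` (calendar year) listing unobserved cells.
#' @return An object of class `apc_design`.
#' @export
apc_design <- function(age_lower, age_upper, years, missing_cells = NULL) {
  skel <- apc_grid(matrix(0, length(age_lower), length(years)),
                   age_lower, age_upper, years)  # validates layout
  if (!is.null(missing_cells)) {
    stopifnot(all(c("age", "year") %in% names(missing_cells)))
    if (!all(missing_cells$year %in% years))
      stop("missing_cells refers to years outside the design")
    if (!all(missing_cells$age %in% seq_along(age_lower)))
      stop("missing_cells refers to age-group indices outside the design")
  }
  structure(list(age_lower = skel$age_lower, age_upper = skel$age_upper,
                 years = skel$years, missing_cells = missing_cells),
            class = "apc_design")
}

#' @export
print.apc_design <- function(x, ...) {
  cat("<apc_design> ", length(x$age_lower), " age groups x ",
      length(x$years), " years (", x$years[1], "-",
      x$years[length(x$years)], ")", sep = "")
  if (!is.null(x$missing_cells))
    cat(", ", nrow(x$missing_cells), " missing cells", sep = "")
  cat("\n")
  invisible(x)
}

# all-cells-observed-except-missing skeleton grid for a design
design_skeleton <- function(design, missing = design$missing_cells) {
  vals <- matrix(0, length(design$age_lower), length(design$years))
  if (!is.null(missing) && nrow(missing))
    vals[cbind(missing$age, match(missing$year, design$years))] <- NA
  if (all(is.na(vals))) stop("missing pattern covers every cell")
  apc_grid(vals, design$age_lower, design$age_upper, design$years)
}

#' Survey-shaped APC designs
#'
#' Emits layouts shaped like the public aggregates of the Japanese National
#' Health and Nutrition Survey: five 10-year age groups (20-29 .. 60-69) and
#' yearly surveys 1973-2018 with no survey in 1974. Blood-pressure and BMI
#' series span the whole period (45 survey years); HDL cholesterol starts in
#' 1989; serum glucose and triglyceride start in 1989 and were additionally
#' not measured in 2012 and 2016.
#'
#' @param marker one of `"sbp"`, `"bmi"`, `"hdl"`, `"sg"`, `"tg"`.
#' @return An [apc_design].
#' @examples
#' length(nhns_like_design("bmi")$years)  # 45
#' @export
nhns_like_design <- function(marker = c("sbp", "bmi", "hdl", "sg", "tg")) {
  marker <- match.arg(marker)
  years <- switch(marker,
    sbp = , bmi = c(1973L, 1975:2018),
    hdl = 1989:2018,
    sg = , tg = setdiff(1989:2018, c(2012L, 2016L)))
  apc_design(age_lower = seq(20L, 60L, 10L), age_upper = seq(29L, 69L, 10L),
             years = as.integer(years))
}

#' Ground-truth APC effects
#'
#' Bundles an intercept, sum-to-zero age/period/cohort effect vectors and an
#' observation noise standard deviation. Vectors are centered on
#' construction; the intercept absorbs the removed means, so every cell mean
#' is preserved.
#'
#' @param delta intercept, in biomarker units.
#' @param alpha,beta,gamma effect vectors (lengths I, J, K of the design).
#' @param sigma observation noise standard deviation, `>= 0`.
#' @param s_alpha,s_beta,s_gamma optional smoothness scales recorded for
#'   provenance (standard deviations of first differences).
#' @return An object of class `true_effects`.
#' @export
true_effects <- function(delta, alpha, beta, gamma, sigma,
                         s_alpha = NA_real_, s_beta = NA_real_,
                         s_gamma = NA_real_) {
  if (sigma < 0) stop("sigma must be non-negative")
  delta <- delta + mean(alpha) + mean(beta) + mean(gamma)
  structure(list(delta = delta,
                 alpha = alpha - mean(alpha),
                 beta = beta - mean(beta),
                 gamma = gamma - mean(gamma),
                 sigma = sigma,
                 s_alpha = s_alpha, s_beta = s_beta, s_gamma = s_gamma),
            class = "true_effects")
}

#' Draw ground-truth effects from first-order random walks
#'
#' Each effect vector is a cumulative sum of independent Normal(0, s^2)
#' increments, then centered to sum zero — the same smoothness structure the
#' model's RW1 priors encode, so credible-interval coverage on the fitted
#' cell means is directly interpretable.
#'
#' @param design an [apc_design].
#' @param s_alpha,s_beta,s_gamma non-negative standard deviations of the
#'   first differences of the age, period and cohort effects.
#' @param sigma observation noise standard deviation.
#' @param delta intercept.
#' @param seed integer seed (mandatory; same seed, same effects).
#' @return A [true_effects] object sized for the design.
#' @export
generate_effects <- function(design, s_alpha, s_beta, s_gamma,
                             sigma = 1, delta = 0, seed) {
  stopifnot(inherits(design, "apc_design"))
  if (missing(seed)) stop("seed is required")
  if (any(c(s_alpha, s_beta, s_gamma) < 0))
    stop("smoothness scales must be non-negative")
  if (sigma < 0) stop("sigma must be non-negative")
  # effects are sized to the full design; missing cells only mask draws
  idx <- build_cohort_index(design_skeleton(design, missing = NULL))
  I <- length(design$age_lower); J <- length(design$years); K <- idx$K
  rw <- function(n, s) cumsum(c(0, stats::rnorm(n - 1, 0, s)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  true_effects(delta = delta,
               alpha = rw(I, s_alpha), beta = rw(J, s_beta),
               gamma = rw(K, s_gamma), sigma = sigma,
               s_alpha = s_alpha, s_beta = s_beta, s_gamma = s_gamma)
}

.Random.seed_save <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an APC grid from known effects
#'
#' Each observed cell is drawn independently from
#' Normal(delta + alpha_i + beta_j + gamma_k, sigma^2); cells in the missing
#' pattern are left unobserved. At `sigma = 0` the grid equals the cell means
#' exactly.
#'
#' @param effects a [true_effects] object consistent with the design.
#' @param design an [apc_design].
#' @param missing cells to leave unobserved; defaults to the design's own
#'   `missing_cells`.
#' @param seed integer seed (mandatory).
#' @param biomarker,unit,sex labels for the resulting grid.
#' @return An [apc_grid].
#' @export
generate_grid <- function(effects, design, missing = design$missing_cells,
                          seed, biomarker = "synthetic", unit = "", sex = "") {
  stopifnot(inherits(effects, "true_effects"), inherits(design, "apc_design"))
  if (missing(seed)) stop("seed is required")
  skel <- design_skeleton(design, missing)
  idx <- build_cohort_index(design_skeleton(design, missing = NULL))
  I <- length(design$age_lower); J <- length(design$years)
  if (length(effects$alpha) != I || length(effects$beta) != J ||
      length(effects$gamma) != idx$K)
    stop("effects are inconsistent with the design (expected I=", I,
         ", J=", J, ", K=", idx$K, ")")
  lam <- effects$delta +
    outer(effects$alpha, effects$beta, `+`) +
    matrix(effects$gamma[idx$k], I, J)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noise <- matrix(stats::rnorm(I * J, 0, effects$sigma), I, J)
  vals <- lam + noise
  vals[is.na(skel$values)] <- NA
  apc_grid(vals, design$age_lower, design$age_upper, design$years,
           biomarker = biomarker, unit = unit, sex = sex)
}

#' Cell means implied by ground-truth effects
#'
#' @param effects a [true_effects] object.
#' @param design an [apc_design].
#' @return An I x J matrix of cell means delta + alpha_i + beta_j + gamma_k.
#' @export
true_cell_means <- function(effects, design) {
  idx <- build_cohort_index(design_skeleton(design, missing = NULL))
  I <- length(design$age_lower); J <- length(design$years)
  effects$delta + outer(effects$alpha, effects$beta, `+`) +
    matrix(effects$gamma[idx$k], I, J)
}

#' Write / read a ground-truth sidecar file
#'
#' JSON serialization of a [true_effects] object plus the seed that produced
#' it, for downstream recovery tests.
#'
#' @param effects a [true_effects] object.
#' @param path JSON path.
#' @param seed the seed used to generate the data (recorded for provenance).
#' @return `path` invisibly, or the reloaded [true_effects].
#' @export
write_truth <- function(effects, path, seed = NULL) {
  x <- unclass(effects)
  x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  true_effects(x$delta, x$alpha, x$beta, x$gamma, x$sigma,
               s_alpha = x$s_alpha, s_beta = x$s_beta, s_gamma = x$s_gamma)
}
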