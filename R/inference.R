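DRAWS_FORMAT <- "apctrends-draws-1"

# univariate slice sampler (Neal 2003, stepping out + shrinkage) on the
# log scale of a positive parameter; logf takes the log-parameter and must
# include the Jacobian
slice_sample_log <- function(theta0, logf, w = 1, max_steps = 50) {
  f0 <- logf(theta0)
  if (!is.finite(f0)) stop("slice sampler started outside the support")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- theta0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    theta1 <- stats::runif(1, L, R)
    if (logf(theta1) > z) return(theta1)
    if (theta1 < theta0) L <- theta1 else R <- theta1
  }
}

#' Fit the Bayesian APC model by blocked Gibbs sampling
#'
#' Draws from the posterior defined by [log_posterior()]: given the noise sd
#' and the three RW1 scales, the joint conditional of
#' `(delta, alpha, beta, gamma)` on the sum-to-zero subspace is multivariate
#' normal and is sampled exactly in one block; the four scale parameters are
#' then updated by univariate slice sampling under their half-normal
#' hyperpriors. Every stored draw satisfies the sum-to-zero constraint and,
#' when the spec standardizes, is back-transformed to the original
#' measurement scale.
#'
#' @param grid an [apc_grid] with at least 2 age groups and 2 years; every
#'   cohort level must be attached to at least one observed cell.
#' @param spec an [apc_model_spec].
#' @param chains number of independent chains (>= 2 for diagnostics).
#' @param iterations total iterations per chain, including warmup.
#' @param warmup iterations discarded per chain; `iterations > warmup`.
#' @param seed integer seed (mandatory; same inputs and seed give identical
#'   draws).
#' @param fixed optional named list fixing any of `sigma`, `s_alpha`,
#'   `s_beta`, `s_gamma` at positive values (on the original data scale);
#'   fixed parameters are not updated — used for oracle validation.
#' @param init_jitter sd of the per-chain log-normal jitter on initial
#'   scales.
#' @return An object of class `apc_draws`: the draw matrix (one row per
#'   retained draw, columns `delta`, `alpha[i]`, `beta[j]`, `gamma[k]`,
#'   `sigma`, `s_alpha`, `s_beta`, `s_gamma`), chain ids, level labels,
#'   convergence diagnostics (split R-hat and effective sample size per
#'   parameter), and provenance (seed, spec, grid digest).
#' @export
fit_apc <- function(grid, spec = apc_model_spec(), chains = 4,
                    iterations = 2000, warmup = 1000, seed,
                    fixed = NULL, init_jitter = 0.2) {
  stopifnot(inherits(grid, "apc_grid"), inherits(spec, "apc_model_spec"))
  if (missing(seed)) stop("seed is required")
  if (iterations <= warmup) stop("iterations must exceed warmup")
  if (length(grid$age_lower) < 2 || length(grid$years) < 2)
    stop("model fitting needs at least 2 age groups and 2 years")
  index <- build_cohort_index(grid)
  dm <- apc_design_matrices(grid, index)  # errors on unidentified levels

  y_raw <- dm$y
  if (spec$standardize) {
    ctr <- mean(y_raw); scl <- stats::sd(y_raw)
    if (!is.finite(scl) || scl == 0) scl <- 1
  } else {
    ctr <- 0; scl <- 1
  }
  y <- (y_raw - ctr) / scl
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), c("sigma", "s_alpha", "s_beta", "s_gamma"))
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
    if (any(unlist(fixed) <= 0)) stop("fixed scales must be positive")
    fixed <- lapply(fixed, function(v) v / scl)  # to the fitting scale
  }
  is_fixed <- function(p) !is.null(fixed[[p]])

  XtX <- crossprod(dm$X)
  Xty <- crossprod(dm$X, y)
  p <- ncol(dm$X)
  n_keep <- iterations - warmup
  P <- matrix(0, p, p)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)

  param_names <- c("delta", paste0("alpha[", seq_len(dm$I), "]"),
                   paste0("beta[", seq_len(dm$J), "]"),
                   paste0("gamma[", seq_len(dm$K), "]"),
                   "sigma", "s_alpha", "s_beta", "s_gamma")
  out <- matrix(NA_real_, chains * n_keep, length(param_names),
                dimnames = list(NULL, param_names))
  chain_id <- rep(seq_len(chains), each = n_keep)

  hn <- c(s_alpha = spec$scale_s_alpha, s_beta = spec$scale_s_beta,
          s_gamma = spec$scale_s_gamma, sigma = spec$scale_sigma)

  for (cc in seq_len(chains)) {
    set.seed(chain_seeds[cc])
    sc <- list(sigma = 1, s_alpha = 1, s_beta = 1, s_gamma = 1)
    for (pnm in names(sc)) {
      sc[[pnm]] <- if (is_fixed(pnm)) fixed[[pnm]]
                   else exp(stats::rnorm(1, 0, init_jitter))
    }
    u <- numeric(p)
    for (it in seq_len(iterations)) {
      # block 1: exact joint Gaussian draw of the effects given the scales
      P[dm$blocks$alpha, dm$blocks$alpha] <- dm$P_alpha / sc$s_alpha^2
      P[dm$blocks$beta, dm$blocks$beta] <- dm$P_beta / sc$s_beta^2
      P[dm$blocks$gamma, dm$blocks$gamma] <- dm$P_gamma / sc$s_gamma^2
      Q <- XtX / sc$sigma^2 + P
      R <- chol(Q)
      mu <- backsolve(R, backsolve(R, Xty / sc$sigma^2, transpose = TRUE))
      u <- drop(mu + backsolve(R, stats::rnorm(p)))

      # block 2: scales by slice sampling
      ef <- expand_coef(u, dm)
      if (!is_fixed("sigma")) {
        ss <- sum((y - drop(dm$X %*% u))^2)
        sc$sigma <- exp(slice_sample_log(log(sc$sigma), function(th) {
          s <- exp(th)
          -dm$n * th - ss / (2 * s^2) + half_normal_logpdf(s, hn["sigma"]) + th
        }))
      }
      for (enm in c("alpha", "beta", "gamma")) {
        pnm <- paste0("s_", enm)
        if (is_fixed(pnm)) next
        d2 <- sum(diff(ef[[enm]])^2)
        nd <- length(ef[[enm]]) - 1
        sc[[pnm]] <- exp(slice_sample_log(log(sc[[pnm]]), function(th) {
          s <- exp(th)
          -nd * th - d2 / (2 * s^2) + half_normal_logpdf(s, hn[pnm]) + th
        }))
      }

      if (it > warmup) {
        st <- recenter(parameter_state(
          delta = ctr + scl * ef$delta,
          alpha = scl * ef$alpha, beta = scl * ef$beta,
          gamma = scl * ef$gamma,
          sigma = scl * sc$sigma, s_alpha = scl * sc$s_alpha,
          s_beta = scl * sc$s_beta, s_gamma = scl * sc$s_gamma))
        out[(cc - 1) * n_keep + it - warmup, ] <-
          c(st$delta, st$alpha, st$beta, st$gamma,
            st$sigma, st$s_alpha, st$s_beta, st$s_gamma)
      }
    }
  }

  diag_df <- data.frame(parameter = param_names,
                        rhat = NA_real_, ess = NA_real_)
  for (pi in seq_along(param_names)) {
    m <- matrix(out[, pi], n_keep, chains)
    if (chains >= 2 && n_keep >= 4)
      diag_df$rhat[pi] <- tryCatch(rhat(m), error = function(e) NA_real_)
    if (n_keep >= 4)
      diag_df$ess[pi] <- tryCatch(ess(m), error = function(e) NA_real_)
  }
  converged <- all(is.na(diag_df$rhat) | diag_df$rhat <= 1.05)
  if (!converged)
    warning("possible non-convergence: max split R-hat = ",
            round(max(diag_df$rhat, na.rm = TRUE), 3))

  structure(
    list(draws = out, chain = chain_id, chains = chains,
         iterations = iterations, warmup = warmup, seed = seed,
         spec = unclass(spec),
         labels = list(age = rownames(grid$values), years = grid$years,
                       birth_start = index$birth_start,
                       birth_end = index$birth_end),
         dims = list(I = dm$I, J = dm$J, K = dm$K),
         scale = list(center = ctr, scale = scl),
         diagnostics = diag_df, converged = converged,
         grid_digest = grid_digest(grid),
         biomarker = grid$biomarker, unit = grid$unit, sex = grid$sex,
         format = DRAWS_FORMAT),
    class = "apc_draws")
}

grid_digest <- function(grid) {
  v <- grid$values
  sprintf("%dx%d:%d:%.10g", nrow(v), ncol(v), sum(!is.na(v)),
          sum(v, na.rm = TRUE))
}

#' @export
print.apc_draws <- function(x, ...) {
  cat("<apc_draws> ", x$chains, " chains x ",
      x$iterations - x$warmup, " retained draws, ",
      ncol(x$draws), " parameters (I=", x$dims$I, ", J=", x$dims$J,
      ", K=", x$dims$K, ")\n", sep = "")
  cat("  seed ", x$seed, "; max split R-hat ",
      round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "; min ESS ",
      round(min(x$diagnostics$ess, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half; R-hat compares between- and within-chain
#' variance across the split chains. Values near 1 are consistent with
#' convergence; values above ~1.05 indicate the chains have not mixed.
#'
#' @param x a matrix of draws (iterations x chains) or a list of equal-length
#'   numeric vectors, one per chain. At least 2 chains of at least 4 draws.
#' @return The scalar R-hat, or `NA` for constant chains (undefined).
#' @export
rhat <- function(x) {
  ch <- as_chain_matrix(x)
  if (ncol(ch) < 2) stop("R-hat needs at least 2 chains")
  if (nrow(ch) < 4) stop("R-hat needs at least 4 draws per chain")
  sp <- split_chains(ch)
  n <- nrow(sp); m <- ncol(sp)
  W <- mean(apply(sp, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(sp))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based effective sample size using cross-chain pooling and
#' Geyer's initial-monotone-sequence truncation. Approximately the number of
#' independent draws the chains are worth for estimating a posterior mean.
#'
#' @param x a numeric vector (one chain) or matrix / list of chains.
#' @return The scalar ESS, or `NA` for constant chains (undefined).
#' @export
ess <- function(x) {
  ch <- as_chain_matrix(x)
  if (nrow(ch) < 4) stop("ESS needs at least 4 draws")
  sp <- split_chains(ch)
  n <- nrow(sp); m <- ncol(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- if (m > 1) n * stats::var(colMeans(sp)) else 0
  var_plus <- (n - 1) / n * W + B / n
  # pooled autocovariance
  acov <- sapply(seq_len(m), function(j)
    stats::acf(sp[, j], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence over lag pairs (1,2),(3,4),...
  tau <- rho[1]  # lag-0 term
  prev <- Inf
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 2
  }
  m * n / max(tau, .Machine$double.eps)
}

as_chain_matrix <- function(x) {
  if (is.list(x) && !is.matrix(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1) stop("chains must have equal length")
    x <- do.call(cbind, x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

split_chains <- function(ch) {
  n <- nrow(ch)
  h <- n %/% 2
  cbind(ch[seq_len(h), , drop = FALSE],
        ch[(n - h + 1):n, , drop = FALSE])
}

#' Persist posterior draws
#'
#' `save_draws()` writes a columnar CSV (one row per chain x draw, one
#' column per scalar parameter, plus `chain` and `draw`) and a JSON
#' provenance sidecar (`<path>.meta.json`) holding the seed, model spec,
#' level labels, diagnostics and grid digest. `load_draws()` restores the
#' object and refuses files written under a different draws-format version.
#'
#' @param draws an [apc_draws] object.
#' @param path CSV path for the draw table.
#' @return `save_draws()` returns `path` invisibly; `load_draws()` returns
#'   the restored [apc_draws].
#' @export
save_draws <- function(draws, path) {
  stopifnot(inherits(draws, "apc_draws"))
  tab <- data.frame(chain = draws$chain,
                    draw = stats::ave(draws$chain, draws$chain,
                                      FUN = seq_along),
                    draws$draws, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- draws[setdiff(names(draws), c("draws", "chain"))]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_draws
#' @export
load_draws <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("draws table or provenance sidecar not found at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != DRAWS_FORMAT)
    stop("draws file format ", if (is.null(meta$format)) "<missing>"
         else meta$format, " does not match this package version (",
         DRAWS_FORMAT, ")")
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  obj <- c(list(draws = as.matrix(tab[, -(1:2), drop = FALSE]),
                chain = tab$chain),
           meta)
  obj$diagnostics <- as.data.frame(meta$diagnostics)
  class(obj) <- "apc_draws"
  obj
}
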