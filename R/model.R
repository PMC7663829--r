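#' Model specification for the Bayesian APC model
#'
#' The model for a grid of cell means is
#' `y_ij ~ Normal(lambda_ij, sigma^2)` with
#' `lambda_ij = delta + alpha_i + beta_j + gamma_k(i,j)`, sum-to-zero
#' constraints on each effect vector, first-order random-walk (RW1)
#' smoothing priors on consecutive effect levels, a flat prior on the
#' intercept, and half-normal hyperpriors on the three RW1 scales and on the
#' observation noise.
#'
#' With `standardize = TRUE` the response is centered and scaled by the mean
#' and standard deviation of the observed cells before fitting (the
#' half-normal scales then live on the standardized scale) and all draws are
#' back-transformed to the original measurement scale.
#'
#' @param scale_s_alpha,scale_s_beta,scale_s_gamma half-normal scale of the
#'   hyperprior on each RW1 smoothness standard deviation.
#' @param scale_sigma half-normal scale of the hyperprior on the noise sd.
#' @param standardize standardize the response internally before fitting.
#' @param constraint identifiability constraint; only `"recenter"`
#'   (sum-to-zero via recentering) is available.
#' @return An object of class `apc_model_spec`.
#' @export
apc_model_spec <- function(scale_s_alpha = 1, scale_s_beta = 1,
                           scale_s_gamma = 1, scale_sigma = 1,
                           standardize = TRUE,
                           constraint = "recenter") {
  scales <- c(scale_s_alpha, scale_s_beta, scale_s_gamma, scale_sigma)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("hyperprior scales must be positive and finite")
  constraint <- match.arg(constraint, "recenter")
  structure(list(scale_s_alpha = scale_s_alpha, scale_s_beta = scale_s_beta,
                 scale_s_gamma = scale_s_gamma, scale_sigma = scale_sigma,
                 standardize = standardize, constraint = constraint),
            class = "apc_model_spec")
}

#' @export
print.apc_model_spec <- function(x, ...) {
  cat("<apc_model_spec> RW1 priors, sum-to-zero constraint (",
      x$constraint, ")\n", sep = "")
  cat("  half-normal hyperprior scales: s_alpha ", x$scale_s_alpha,
      ", s_beta ", x$scale_s_beta, ", s_gamma ", x$scale_s_gamma,
      ", sigma ", x$scale_sigma, "\n", sep = "")
  cat("  standardize response: ", x$standardize, "\n", sep = "")
  invisible(x)
}

#' Bundle a full set of APC model parameters
#'
#' @param delta intercept.
#' @param alpha,beta,gamma age, period and cohort effect vectors.
#' @param sigma observation noise sd (> 0).
#' @param s_alpha,s_beta,s_gamma RW1 smoothness sds (> 0).
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(delta, alpha, beta, gamma, sigma,
                            s_alpha, s_beta, s_gamma) {
  if (any(c(sigma, s_alpha, s_beta, s_gamma) <= 0))
    stop("sigma and the smoothness scales must be positive")
  if (!all(is.finite(c(delta, alpha, beta, gamma))))
    stop("effects must be finite")
  structure(list(delta = delta, alpha = alpha, beta = beta, gamma = gamma,
                 sigma = sigma, s_alpha = s_alpha, s_beta = s_beta,
                 s_gamma = s_gamma),
            class = "parameter_state")
}

#' Linear predictor of one grid cell
#'
#' `lambda_ij = delta + alpha_i + beta_j + gamma_k`, where `k` is the cohort
#' level the index map assigns to cell `(i, j)`.
#'
#' @param state a [parameter_state].
#' @param i age-group index; `j` year index.
#' @param j year index.
#' @param index a [build_cohort_index()] map for the grid.
#' @return The scalar cell mean.
#' @export
linear_predictor <- function(state, i, j, index) {
  if (i < 1 || i > nrow(index$k) || j < 1 || j > ncol(index$k))
    stop("cell (", i, ", ", j, ") is outside the design")
  k <- index$k[i, j]
  if (is.na(k)) stop("cell (", i, ", ", j, ") has no cohort level")
  state$delta + state$alpha[i] + state$beta[j] + state$gamma[k]
}

# all cell means at once (NA where no cohort level)
cell_means <- function(state, index) {
  state$delta + outer(state$alpha, state$beta, `+`) +
    matrix(state$gamma[index$k], nrow(index$k), ncol(index$k))
}

#' Gaussian log-likelihood of a grid under a parameter state
#'
#' Sums `Normal(lambda_ij, sigma^2)` log-densities over the observed cells
#' only; unobserved cells contribute nothing (no imputation).
#'
#' @param state a [parameter_state].
#' @param grid an [apc_grid] with at least one observed cell.
#' @param index cohort index map for the grid.
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(state, grid, index) {
  if (state$sigma <= 0) stop("sigma must be positive")
  obs <- !is.na(grid$values)
  if (!any(obs)) stop("grid has no observed cells")
  lam <- cell_means(state, index)
  sum(stats::dnorm(grid$values[obs], lam[obs], state$sigma, log = TRUE))
}

half_normal_logpdf <- function(x, scale) {
  if (x <= 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

#' RW1 log-prior of a parameter state
#'
#' Sum over the three effect vectors of `Normal(0, s^2)` log-densities on
#' consecutive first differences, plus half-normal hyperprior log-densities
#' on the three smoothness scales and the noise sd. The intercept carries a
#' flat prior (constant contribution, taken as zero).
#'
#' @param state a [parameter_state].
#' @param spec an [apc_model_spec].
#' @return The scalar log-prior density (up to the flat-intercept constant).
#' @export
log_prior <- function(state, spec = apc_model_spec()) {
  if (any(c(state$s_alpha, state$s_beta, state$s_gamma, state$sigma) <= 0))
    stop("scales must be positive")
  rw1 <- function(e, s) sum(stats::dnorm(diff(e), 0, s, log = TRUE))
  rw1(state$alpha, state$s_alpha) +
    rw1(state$beta, state$s_beta) +
    rw1(state$gamma, state$s_gamma) +
    half_normal_logpdf(state$s_alpha, spec$scale_s_alpha) +
    half_normal_logpdf(state$s_beta, spec$scale_s_beta) +
    half_normal_logpdf(state$s_gamma, spec$scale_s_gamma) +
    half_normal_logpdf(state$sigma, spec$scale_sigma)
}

#' Joint log-posterior (unnormalized)
#'
#' @inheritParams log_likelihood
#' @param spec an [apc_model_spec].
#' @return `log_likelihood + log_prior`.
#' @export
log_posterior <- function(state, grid, index, spec = apc_model_spec()) {
  log_likelihood(state, grid, index) + log_prior(state, spec)
}

#' Recenter a parameter state onto the sum-to-zero constraint
#'
#' Subtracts the mean of each effect vector and absorbs the three means into
#' the intercept. Every cell mean `lambda_ij` — and hence the likelihood —
#' is unchanged; the operation is idempotent.
#'
#' @param state a [parameter_state].
#' @return The recentered [parameter_state].
#' @export
recenter <- function(state) {
  ma <- mean(state$alpha); mb <- mean(state$beta); mg <- mean(state$gamma)
  state$delta <- state$delta + ma + mb + mg
  state$alpha <- state$alpha - ma
  state$beta <- state$beta - mb
  state$gamma <- state$gamma - mg
  state
}

#' Shift linear trends between the three effects without changing the fit
#'
#' Applies the APC aliasing transformation with slope `w`: for each cohort
#' level add `w` times its earliest birth year, for each period subtract `w`
#' times the calendar year, for each age group add `w` times its upper age
#' bound, then recenter. Because birth year = year - upper age for every
#' cell, all cell means are exactly unchanged — the identification problem
#' in algebraic form. Only the smoothing priors distinguish the members of
#' this family.
#'
#' @param state a [parameter_state].
#' @param grid an [apc_grid] supplying ages and years.
#' @param index cohort index map supplying birth years.
#' @param w slope to reallocate.
#' @return The transformed, recentered [parameter_state].
#' @export
alias_transform <- function(state, grid, index, w) {
  # centered covariates: identical after recentering, numerically tighter
  b <- index$birth_start - mean(index$birth_start)
  y <- grid$years - mean(grid$years)
  u <- grid$age_upper - mean(grid$age_upper)
  state$gamma <- state$gamma + w * b
  state$beta <- state$beta - w * y
  state$alpha <- state$alpha + w * u
  recenter(state)
}

# --- sum-to-zero parameterization helpers ------------------------------

# orthonormal basis of {x : sum(x) = 0} in R^n
sum_zero_basis <- function(n) {
  qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# first-difference matrix, (n-1) x n
diff_matrix <- function(n) {
  D <- matrix(0, n - 1, n)
  D[cbind(seq_len(n - 1), seq_len(n - 1))] <- -1
  D[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  D
}

# constrained design pieces shared by the oracle and the sampler wrapper:
# y, X (n_obs x p) over (delta, u_alpha, u_beta, u_gamma) with effects = Z u,
# per-block penalty matrices Z' D'D Z, and bookkeeping
apc_design_matrices <- function(grid, index) {
  I <- length(grid$age_lower); J <- length(grid$years); K <- index$K
  obs <- which(!is.na(grid$values), arr.ind = TRUE)
  if (!nrow(obs)) stop("grid has no observed cells")
  kk <- index$k[obs]
  if (anyNA(kk)) stop("observed cell without a cohort level")
  if (!all(seq_len(K) %in% kk))
    stop("cohort level(s) with no observed cell: ",
         paste(setdiff(seq_len(K), kk), collapse = ", "))
  Za <- sum_zero_basis(I); Zb <- sum_zero_basis(J); Zg <- sum_zero_basis(K)
  n <- nrow(obs)
  X <- cbind(1, Za[obs[, 1], , drop = FALSE], Zb[obs[, 2], , drop = FALSE],
             Zg[kk, , drop = FALSE])
  pen <- function(Z) crossprod(diff_matrix(nrow(Z)) %*% Z)
  blocks <- list(delta = 1L, alpha = 1L + seq_len(I - 1),
                 beta = I + seq_len(J - 1),
                 gamma = I + J - 1L + seq_len(K - 1))
  list(y = grid$values[obs], X = X, obs = obs,
       Za = Za, Zb = Zb, Zg = Zg,
       P_alpha = pen(Za), P_beta = pen(Zb), P_gamma = pen(Zg),
       blocks = blocks, I = I, J = J, K = K, n = n)
}

# map a coefficient vector in the constrained basis back to named effects
expand_coef <- function(u, dm) {
  list(delta = u[1],
       alpha = drop(dm$Za %*% u[dm$blocks$alpha]),
       beta = drop(dm$Zb %*% u[dm$blocks$beta]),
       gamma = drop(dm$Zg %*% u[dm$blocks$gamma]))
}

#' Exact Gaussian posterior of the effects at fixed variances
#'
#' Given the noise sd and the three RW1 scales, the APC model is a Gaussian
#' linear model: the posterior of `(delta, alpha, beta, gamma)` under the
#' sum-to-zero constraint is multivariate normal with a closed form. This
#' serves as the ground-truth oracle against which the MCMC sampler is
#' validated. The computation solves the penalized normal equations on an
#' orthonormal sum-to-zero basis and maps the law back to the full
#' coordinates (where it is degenerate along the constraint).
#'
#' @param grid an [apc_grid]; every cohort level must have an observed cell.
#' @param index cohort index map for the grid.
#' @param sigma fixed observation noise sd.
#' @param s_alpha,s_beta,s_gamma fixed RW1 smoothness sds.
#' @return A list with posterior `mean` (named list: delta, alpha, beta,
#'   gamma), full-coordinate covariance `cov` (rows/cols named
#'   `delta, alpha[i], beta[j], gamma[k]`), and `sd` (named vector).
#' @export
posterior_given_variances <- function(grid, index, sigma,
                                      s_alpha, s_beta, s_gamma) {
  if (any(c(sigma, s_alpha, s_beta, s_gamma) <= 0))
    stop("variances must be fixed at positive values")
  dm <- apc_design_matrices(grid, index)
  P <- matrix(0, ncol(dm$X), ncol(dm$X))
  P[dm$blocks$alpha, dm$blocks$alpha] <- dm$P_alpha / s_alpha^2
  P[dm$blocks$beta, dm$blocks$beta] <- dm$P_beta / s_beta^2
  P[dm$blocks$gamma, dm$blocks$gamma] <- dm$P_gamma / s_gamma^2
  Q <- crossprod(dm$X) / sigma^2 + P
  R <- tryCatch(chol(Q), error = function(e)
    stop("singular penalized normal equations: some effect levels are ",
         "unidentified (", conditionMessage(e), ")"))
  b <- crossprod(dm$X, dm$y) / sigma^2
  mean_u <- backsolve(R, backsolve(R, b, transpose = TRUE))
  cov_u <- chol2inv(R)
  # back to full coordinates
  T <- matrix(0, 1 + dm$I + dm$J + dm$K, ncol(dm$X))
  T[1, 1] <- 1
  T[1 + seq_len(dm$I), dm$blocks$alpha] <- dm$Za
  T[1 + dm$I + seq_len(dm$J), dm$blocks$beta] <- dm$Zb
  T[1 + dm$I + dm$J + seq_len(dm$K), dm$blocks$gamma] <- dm$Zg
  mean_full <- drop(T %*% mean_u)
  cov_full <- T %*% cov_u %*% t(T)
  nms <- c("delta", paste0("alpha[", seq_len(dm$I), "]"),
           paste0("beta[", seq_len(dm$J), "]"),
           paste0("gamma[", seq_len(dm$K), "]"))
  names(mean_full) <- nms
  dimnames(cov_full) <- list(nms, nms)
  list(mean = list(delta = unname(mean_full[1]),
                   alpha = unname(mean_full[1 + seq_len(dm$I)]),
                   beta = unname(mean_full[1 + dm$I + seq_len(dm$J)]),
                   gamma = unname(mean_full[1 + dm$I + dm$J + seq_len(dm$K)])),
       mean_vector = mean_full,
       cov = cov_full,
       sd = sqrt(pmax(diag(cov_full), 0)))
}
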