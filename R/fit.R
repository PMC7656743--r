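# Maximum-likelihood fitting of the progressive multistate model to
# panel-observed transitions.
#
# Each cohort record contributes one panel observation (from, to, t, z, w);
# the likelihood is prod_i P(t_i; z_i)[from_i, to_i]^{w_i} with
# P(t; z) = exp(Q(z) t) and log-linear intensities
# q_rs(z) = exp(alpha_rs + beta_rs . z). Parameters are unconstrained on
# the log scale, so positivity holds by construction. Observations sharing
# a covariate pattern and interval are aggregated before optimisation:
# with categorical covariates the likelihood costs a handful of 4x4 matrix
# exponentials per evaluation regardless of cohort size.

ALPHA_FLOOR <- log(1e-12)

# design matrix from a covariate formula over the cohort columns;
# dummy coding: female = 1, alcohol ever = 1, paternal education reference
# college-or-higher; numeric (non-dummy) columns are centered
build_design <- function(cohort, covariates) {
  n <- nrow(cohort)
  if (is.null(covariates)) {
    return(list(X = matrix(0, n, 0), centers = numeric(0),
                means = numeric(0), formula = NULL))
  }
  stopifnot(inherits(covariates, "formula"))
  df <- cohort
  if ("sex" %in% names(df))
    df$sex <- factor(df$sex, levels = c("male", "female"))
  if ("paternal_edu_3level" %in% names(df))
    df$paternal_edu_3level <- factor(
      df$paternal_edu_3level,
      levels = c("college_or_higher", "high_school_or_lower", "unknown_NA"))
  mm <- stats::model.matrix(covariates, df)
  keep <- colnames(mm) != "(Intercept)"
  X <- mm[, keep, drop = FALSE]
  if (nrow(X) != n) stop("build_design: missing covariate values in cohort")
  is_dummy <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  centers <- ifelse(is_dummy, 0, colMeans(X))
  X <- sweep(X, 2, centers)
  list(X = X, centers = centers, means = colMeans(X), formula = covariates)
}

# aggregate panel observations into covariate-pattern cells
aggregate_panel <- function(X, t, from, to, w) {
  key <- do.call(paste, c(as.data.frame(cbind(X, t = t)), sep = "\r"))
  pat_id <- match(key, unique(key))
  first <- !duplicated(pat_id)
  patterns <- lapply(which(first), function(i) {
    list(z = X[i, ], t = t[i])
  })
  cell_key <- paste(pat_id, from, to, sep = "\r")
  agg <- rowsum(w, cell_key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  cells <- data.frame(pattern = as.integer(parts[, 1]),
                      from = as.integer(parts[, 2]),
                      to = as.integer(parts[, 3]),
                      w = as.vector(agg))
  # per-pattern cell index precomputed for the likelihood's inner loop
  cell_split <- lapply(seq_along(patterns), function(ip) {
    cc <- cells[cells$pattern == ip, , drop = FALSE]
    list(idx = cbind(cc$from, cc$to), w = cc$w)
  })
  list(patterns = patterns, cells = cells, cell_split = cell_split)
}

# parameter bookkeeping: free vector <-> (alpha[5], Beta[5 x p])
par_index <- function(frozen, p, shared) {
  labs <- transition_labels()
  idx_alpha <- rep(NA_integer_, 5)
  idx_alpha[!frozen] <- seq_len(sum(!frozen))
  k <- sum(!frozen)
  if (p == 0) {
    idx_beta <- matrix(integer(0), 0, 0)
  } else if (shared) {
    idx_beta <- matrix(rep(k + seq_len(p), each = 5), 5, p)
  } else {
    idx_beta <- matrix(k + seq_len(5 * p), 5, p, byrow = TRUE)
  }
  names(idx_alpha) <- labs
  list(alpha = idx_alpha, beta = idx_beta,
       npar = k + if (p == 0) 0 else if (shared) p else 5 * p)
}

unpack_par <- function(theta, pidx, frozen) {
  alpha <- rep(ALPHA_FLOOR, 5)
  alpha[!frozen] <- theta[pidx$alpha[!frozen]]
  p <- ncol(pidx$beta)
  Beta <- if (p > 0) matrix(theta[pidx$beta], 5, p) else matrix(0, 5, 0)
  # frozen transitions keep no covariate effect
  if (p > 0 && any(frozen)) Beta[frozen, ] <- 0
  list(alpha = alpha, Beta = Beta)
}

rates_at <- function(alpha, Beta, z) {
  eta <- alpha + if (ncol(Beta) > 0) as.vector(Beta %*% z) else 0
  q <- exp(eta)
  if (any(!is.finite(q))) stop("rates_at: non-finite intensity")
  q
}

# negative weighted log-likelihood over aggregated cells
panel_negloglik <- function(theta, agg, pidx, frozen) {
  pb <- unpack_par(theta, pidx, frozen)
  ll <- 0
  for (ip in seq_along(agg$patterns)) {
    pat <- agg$patterns[[ip]]
    q <- tryCatch(rates_at(pb$alpha, pb$Beta, pat$z), error = function(e) NULL)
    # reject absurd rates the line search may probe (overflow territory)
    if (is.null(q) || any(q > 1e6)) return(1e10)
    P <- tp_closed_rates(q, pat$t)
    if (is.null(P)) return(1e10)
    cc <- agg$cell_split[[ip]]
    pij <- P[cc$idx]
    if (any(!is.finite(pij)) || any(pij <= 0)) return(1e10)
    ll <- ll + sum(cc$w * log(pij))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

num_gradient <- function(f, x, ...) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- 1e-6 * (abs(x[i]) + 1e-4)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp, ...) - f(xm, ...)) / (2 * h)
  }
  g
}

#' Fit the progressive multistate Markov model to a cohort
#'
#' Maximum-likelihood estimation of the four-state progressive
#' continuous-time Markov model from single- (or mixed-) interval panel
#' observations, with optional log-linear covariate effects on the five
#' transition intensities.
#'
#' @param cohort Data.frame from [build_cohort()] (columns
#'   `baseline_state`, `end_state`, `interval_months`, covariates,
#'   `weight`), or any data.frame with those columns.
#' @param covariates `NULL` for the null (intercept-only) model, or a
#'   one-sided formula over cohort columns, e.g.
#'   `~ sex + baseline_grade + ever_alcohol_baseline + paternal_edu_3level`.
#'   Dummy coding: female = 1, ever alcohol = 1, paternal-education
#'   reference college-or-higher; numeric columns are centered.
#' @param shared_covariates If `TRUE`, one coefficient per design column
#'   shared across all transitions; default `FALSE` gives
#'   transition-specific coefficients.
#' @param control List: `reltol` (optimizer relative tolerance, 1e-12),
#'   `maxit` (500), `restarts` (max jittered restarts, 5), `jitter_sd`
#'   (0.3), `seed` (seed for restart jitter, 1).
#' @return An object of class `"retromsm"`: log-intensity intercepts
#'   (`alpha`), covariate coefficients (`beta`), covariance of the free
#'   parameters (inverse observed information), log-likelihood, AIC and
#'   convergence diagnostics. Transitions never observed directly have
#'   their intercept frozen at log(1e-12) (with a warning) instead of
#'   diverging.
#' @seealso [tir()], [tp_report()], [compare_models()], and the
#'   `print`, `summary`, `coef`, `vcov`, `logLik`, `predict`, `simulate`,
#'   `residuals`, `plot` methods.
#' @examples
#' cohort <- build_cohort(generate_table2_fixture())
#' fit <- msm_fit(cohort)
#' exp(coef(fit))  # fitted rates per month
#' @export
msm_fit <- function(cohort, covariates = NULL, shared_covariates = FALSE,
                    control = list()) {
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 500, restarts = 5,
                                 jitter_sd = 0.3, seed = 1L), control)
  stopifnot(nrow(cohort) > 0,
            all(c("baseline_state", "end_state", "interval_months")
                %in% names(cohort)))
  from <- as.integer(cohort$baseline_state)
  to <- as.integer(cohort$end_state)
  t <- as.numeric(cohort$interval_months)
  w <- if (is.null(cohort$weight)) rep(1, nrow(cohort)) else cohort$weight
  stopifnot(all(t > 0), all(w > 0))
  reach <- transition_structure()$reachable
  if (any(!reach[cbind(from, to)]))
    stop("msm_fit: data contain structurally impossible transitions")
  des <- build_design(cohort, covariates)
  agg <- aggregate_panel(des$X, t, from, to, w)
  # direct observed count per allowed transition decides freezing
  tr <- transition_structure()$transitions
  labs <- transition_labels()
  direct <- vapply(seq_len(5), function(k)
    sum(w[from == tr[k, 1] & to == tr[k, 2]]), numeric(1))
  names(direct) <- labs
  frozen <- direct == 0
  if (any(frozen))
    warning("msm_fit: no observed transitions for ",
            paste(labs[frozen], collapse = ", "),
            "; intercept frozen at log(1e-12)")
  if (all(frozen)) stop("msm_fit: no transitions observed at all")
  p <- ncol(des$X)
  pidx <- par_index(frozen, p, shared_covariates)

  # start values: invert the pooled empirical proportion matrix
  t0 <- stats::weighted.mean(t, w)
  tab <- rowsum(w, paste(from, to))
  Pn <- matrix(0, 4, 4)
  ij <- do.call(rbind, strsplit(rownames(tab), " "))
  Pn[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- tab
  Pn[4, 4] <- max(Pn[4, 4], 1)
  rs <- rowSums(Pn)
  empty_rows <- rs == 0
  Pn[empty_rows, ] <- diag(4)[empty_rows, ]
  Phat <- Pn / rowSums(Pn)
  alpha0 <- rep(log(0.01), 5)
  Q0 <- tryCatch(invert_single_interval(Phat, t0), error = function(e) NULL)
  if (!is.null(Q0)) {
    r0 <- pmax(intensity_rates(Q0), 1e-8)
    alpha0 <- log(r0)
  }
  theta0 <- numeric(pidx$npar)
  theta0[pidx$alpha[!frozen]] <- alpha0[!frozen]

  nll <- function(th) panel_negloglik(th, agg, pidx, frozen)
  best <- NULL
  restarts_used <- 0L
  set.seed(ctrl$seed)
  start <- theta0
  for (attempt in seq_len(ctrl$restarts + 1L)) {
    opt <- tryCatch(
      stats::optim(start, nll, method = "BFGS",
                   control = list(reltol = ctrl$reltol, maxit = ctrl$maxit)),
      error = function(e) NULL)
    ok <- !is.null(opt) && opt$convergence == 0 && is.finite(opt$value) &&
      opt$value < 1e9
    if (ok && (is.null(best) || opt$value < best$value - 1e-9)) best <- opt
    if (!is.null(best) && ok && attempt > 1) break
    if (!is.null(best) && attempt == 1) break
    restarts_used <- attempt
    start <- theta0 + stats::rnorm(pidx$npar, sd = ctrl$jitter_sd)
  }
  if (is.null(best))
    stop("msm_fit: optimisation failed to converge after ",
         ctrl$restarts, " restarts")
  theta <- best$par
  grad <- num_gradient(nll, theta)
  H <- stats::optimHess(theta, nll)
  V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  V <- (V + t(V)) / 2
  pb <- unpack_par(theta, pidx, frozen)
  dimnames(pb$Beta) <- list(labs, colnames(des$X))
  par_names <- character(pidx$npar)
  par_names[pidx$alpha[!frozen]] <- paste0("logq(", labs[!frozen], ")")
  if (p > 0) {
    if (shared_covariates) {
      par_names[pidx$beta[1, ]] <- colnames(des$X)
    } else {
      for (j in seq_len(p))
        par_names[pidx$beta[, j]] <- paste0(labs, ":", colnames(des$X)[j])
    }
  }
  names(theta) <- par_names
  dimnames(V) <- list(par_names, par_names)
  ll <- -best$value
  k <- pidx$npar
  structure(list(call = match.call(),
                 alpha = stats::setNames(pb$alpha, labs),
                 beta = pb$Beta,
                 frozen = stats::setNames(frozen, labs),
                 par = theta, vcov = V, pidx = pidx,
                 loglik = ll, npar = k, AIC = -2 * ll + 2 * k,
                 nobs = nrow(cohort), wsum = sum(w),
                 direct_counts = direct,
                 design = list(formula = des$formula,
                               colnames = colnames(des$X),
                               centers = des$centers, means = des$means),
                 shared_covariates = shared_covariates,
                 intervals = sort(unique(t)),
                 n_patterns = length(agg$patterns),
                 agg = agg,
                 convergence = list(code = best$convergence,
                                    grad_norm = max(abs(grad)),
                                    restarts = restarts_used,
                                    seed = ctrl$seed)),
            class = "retromsm")
}

# covariate profile handling: "means" (cohort means of the design columns,
# i.e. zeros for centered numeric columns), "zero", or a named numeric
# vector on the design-column scale
resolve_profile <- function(fit, z) {
  cn <- fit$design$colnames
  if (is.character(z) && length(z) == 1) {
    z <- switch(z,
                means = fit$design$means,
                zero = stats::setNames(rep(0, length(cn)), cn),
                stop("unknown covariate profile '", z, "'"))
  }
  if (length(cn) == 0) return(numeric(0))
  stopifnot(all(cn %in% names(z)))
  z[cn]
}

#' Fitted transition intensities at a covariate profile
#'
#' @param fit A [msm_fit()] object.
#' @param z Covariate profile: `"means"` (default), `"zero"`, or a named
#'   vector over the design columns (centered scale).
#' @return Named vector of the five rates per month.
#' @export
fitted_rates <- function(fit, z = "means") {
  zz <- resolve_profile(fit, z)
  rates_at(fit$alpha, fit$beta, zz)
}

#' Fitted intensity matrix at a covariate profile
#' @inheritParams fitted_rates
#' @return 4 x 4 intensity matrix.
#' @export
fitted_Q <- function(fit, z = "means") {
  q <- fitted_rates(fit, z)
  intensity_matrix(q[1], q[2], q[3], q[4], q[5])
}
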