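# Matrix-exponential transition probabilities for the progressive chain.
#
# Two routes are provided deliberately: a general scaling-and-squaring Pade
# matrix exponential (the path used in fitting) and the analytic spectral
# solution special to the progressive 4-state chain (used as an always-on
# cross-check in the test suite).

# Pade order-13 scaling-and-squaring (Higham 2005 coefficients).
expm_ss <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  if (any(!is.finite(A))) stop("expm_ss: non-finite matrix")
  nrmA <- max(colSums(abs(A)))  # 1-norm
  if (nrmA == 0) return(diag(n))
  # scaling: bring norm under theta_13 = 5.37
  s <- max(0L, ceiling(log2(nrmA / 5.371920351148152)))
  A <- A / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600,
         670442572800, 33522128640, 1323241920, 40840800,
         960960, 16380, 182, 1)
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  if (s > 0) for (i in seq_len(s)) E <- E %*% E
  E
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' General matrix-exponential route (scaling-and-squaring Pade). For a valid
#' progressive intensity matrix the result is row-stochastic and inherits the
#' upper-triangular zero pattern; tiny negative entries from floating point
#' are clipped at 0 and rows renormalised (within 1e-12).
#'
#' @param Q 4 x 4 intensity matrix (see [intensity_matrix()]).
#' @param t Nonnegative time (months).
#' @return 4 x 4 row-stochastic matrix, `P[i, j]` = probability of being in
#'   state j after t months given state i now.
#' @examples
#' Q <- intensity_matrix(0.004, 6e-4, 6e-4, 0.025, 0.025)
#' tpm(Q, 4)
#' @export
tpm <- function(Q, t) {
  if (length(t) != 1 || !is.finite(t) || t < 0) stop("tpm: t must be a single nonnegative number")
  check_intensity_matrix(Q)
  if (t == 0) return(diag(4))
  P <- expm_ss(Q * t)
  # enforce structural zeros and clip rounding noise
  P[lower.tri(P)] <- 0
  P[2, 3] <- 0
  P[P < 0 & P > -1e-12] <- 0
  P / rowSums(P)
}

# stable (exp(-a t) - exp(-b t)) / (b - a); limit t*exp(-a t) as b -> a.
# expm1 keeps the quotient accurate for any nonzero d, so only d == 0
# needs the limiting form.
exp_diff <- function(a, b, t) {
  d <- b - a
  ifelse(d == 0,
         t * exp(-a * t),
         exp(-a * t) * (-expm1(-d * t)) / d)
}

#' Closed-form transition probabilities for the progressive chain
#'
#' Analytic spectral solution of P(t) = exp(Qt) for the 4-state one-way
#' structure, with limiting forms when total exit rates coincide. Serves as
#' an independent oracle for [tpm()].
#'
#' @inheritParams tpm
#' @return 4 x 4 row-stochastic matrix.
#' @export
tpm_closed <- function(Q, t) {
  if (length(t) != 1 || !is.finite(t) || t < 0) stop("tpm_closed: t must be a single nonnegative number")
  check_intensity_matrix(Q)
  q12 <- Q[1, 2]; q13 <- Q[1, 3]; q14 <- Q[1, 4]
  q24 <- Q[2, 4]; q34 <- Q[3, 4]
  a1 <- q12 + q13 + q14
  P <- diag(4)
  P[1, 1] <- exp(-a1 * t)
  P[2, 2] <- exp(-q24 * t)
  P[3, 3] <- exp(-q34 * t)
  P[2, 4] <- -expm1(-q24 * t)
  P[3, 4] <- -expm1(-q34 * t)
  P[1, 2] <- q12 * exp_diff(a1, q24, t)
  P[1, 3] <- q13 * exp_diff(a1, q34, t)
  P[1, 4] <- 1 - P[1, 1] - P[1, 2] - P[1, 3]
  P
}

# analytic P(t) straight from the five rates, skipping matrix assembly and
# validation: the likelihood's hot path (exactness vs tpm() is covered by
# the oracle tests). Returns NULL on non-finite output.
tp_closed_rates <- function(q, t) {
  a1 <- q[1] + q[2] + q[3]
  p11 <- exp(-a1 * t); p22 <- exp(-q[4] * t); p33 <- exp(-q[5] * t)
  p12 <- q[1] * exp_diff(a1, q[4], t)
  p13 <- q[2] * exp_diff(a1, q[5], t)
  P <- matrix(c(p11, 0, 0, 0,
                p12, p22, 0, 0,
                p13, 0, p33, 0,
                1 - p11 - p12 - p13, 1 - p22, 1 - p33, 1), 4, 4)
  if (any(!is.finite(P))) return(NULL)
  P
}

#' Recover intensities from a single-interval transition-proportion matrix
#'
#' Direct algebraic inversion of the progressive-chain map Q -> P(t): with a
#' single common observation interval the five free probabilities determine
#' the five rates exactly. This is the saturated-model oracle: maximum
#' likelihood on single-interval, no-covariate panel data must reproduce it.
#'
#' @param P 4 x 4 row-stochastic matrix of observed transition proportions.
#' @param t Interval length (months), default 4.
#' @return 4 x 4 intensity matrix Q with `tpm(Q, t)` equal to `P`.
#' @details Fails with an informative error when `P` is not embeddable in a
#'   progressive chain (e.g. an implied rate would be negative beyond
#'   rounding noise, or a diagonal entry is not in (0, 1]).
#' @export
invert_single_interval <- function(P, t = 4) {
  stopifnot(is.matrix(P), all(dim(P) == 4), t > 0)
  if (max(abs(rowSums(P) - 1)) > 1e-8) stop("invert_single_interval: P rows must sum to 1")
  if (any(diag(P) <= 0)) stop("invert_single_interval: non-embeddable P (zero diagonal)")
  a1  <- -log(P[1, 1]) / t
  q24 <- -log(P[2, 2]) / t
  q34 <- -log(P[3, 3]) / t
  q12 <- if (P[1, 2] == 0) 0 else P[1, 2] / exp_diff(a1, q24, t)
  q13 <- if (P[1, 3] == 0) 0 else P[1, 3] / exp_diff(a1, q34, t)
  q14 <- a1 - q12 - q13
  q <- c(q12, q13, q14, q24, q34)
  if (any(q < -1e-8)) {
    stop("invert_single_interval: non-embeddable P (implied negative rate)")
  }
  q[q < 0] <- 0
  intensity_matrix(q[1], q[2], q[3], q[4], q[5])
}
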