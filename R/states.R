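#' Four-state progressive tobacco/ENDS use structure
#'
#' States encode ever-use of two products: 1 = never use, 2 = cigarette only,
#' 3 = ENDS only, 4 = cigarette and ENDS. Because states record initiation
#' ("even one puff"), they can only be entered, never left: the chain is
#' progressive (one-way) and state 4 is absorbing.
#'
#' @return A list with elements `n_states` (4), `labels`, `transitions`
#'   (a 5 x 2 integer matrix of the allowed instantaneous moves
#'   1->2, 1->3, 1->4, 2->4, 3->4) and `reachable` (4 x 4 logical matrix:
#'   can state j be occupied at a later time given state i now, including
#'   staying).
#' @examples
#' ts <- transition_structure()
#' ts$transitions
#' @export
transition_structure <- function() {
  trans <- cbind(from = c(1L, 1L, 1L, 2L, 3L),
                 to   = c(2L, 3L, 4L, 4L, 4L))
  reach <- diag(4) > 0
  reach[1, ] <- TRUE
  reach[2, 4] <- TRUE
  reach[3, 4] <- TRUE
  list(n_states = 4L,
       labels = c("never", "cigarette_only", "ends_only", "cig_and_ends"),
       transitions = trans,
       reachable = reach)
}

#' Labels of the five allowed transitions, e.g. "1->2"
#' @return Character vector of length 5.
#' @export
transition_labels <- function() {
  tr <- transition_structure()$transitions
  paste0(tr[, 1], "->", tr[, 2])
}

#' Ever-use state code from the two product flags
#'
#' The state is a pure function of (ever cigarette, ever ENDS):
#' (FALSE, FALSE) = 1, (TRUE, FALSE) = 2, (FALSE, TRUE) = 3,
#' (TRUE, TRUE) = 4. Vectorised.
#'
#' @param ever_cig,ever_ends Logical vectors.
#' @return Integer state codes in 1..4.
#' @export
use_state <- function(ever_cig, ever_ends) {
  stopifnot(is.logical(ever_cig), is.logical(ever_ends),
            length(ever_cig) == length(ever_ends))
  1L + as.integer(ever_cig) + 2L * as.integer(ever_ends)
}

#' Build an intensity matrix for the progressive chain
#'
#' Assembles the 4 x 4 transition intensity (TI) matrix Q from the five
#' allowed instantaneous rates (per month). Off-diagonal entries outside the
#' allowed set are structural zeros; each diagonal entry is minus the row's
#' exit rate, so rows sum to zero.
#'
#' @param q12,q13,q14,q24,q34 Nonnegative rates per month.
#' @return A 4 x 4 matrix of class "matrix".
#' @examples
#' Q <- intensity_matrix(0.004, 6e-4, 6e-4, 0.025, 0.025)
#' rowSums(Q)  # all zero
#' @export
intensity_matrix <- function(q12, q13, q14, q24, q34) {
  q <- c(q12, q13, q14, q24, q34)
  if (any(!is.finite(q))) stop("intensity_matrix: rates must be finite")
  if (any(q < 0)) stop("intensity_matrix: rates must be nonnegative")
  Q <- matrix(0, 4, 4)
  tr <- transition_structure()$transitions
  Q[tr] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

#' Extract the five allowed rates from an intensity matrix
#' @param Q 4 x 4 intensity matrix.
#' @return Named numeric vector (names "1->2", ..., "3->4").
#' @export
intensity_rates <- function(Q) {
  tr <- transition_structure()$transitions
  stats::setNames(Q[tr], transition_labels())
}

# validate Q structure; used internally before expensive operations
check_intensity_matrix <- function(Q, tol = 1e-8) {
  stopifnot(is.matrix(Q), all(dim(Q) == 4))
  if (any(!is.finite(Q))) stop("intensity matrix has non-finite entries")
  off <- Q; diag(off) <- 0
  tr <- transition_structure()$transitions
  allowed <- matrix(FALSE, 4, 4); allowed[tr] <- TRUE
  if (any(off[!allowed] != 0)) stop("intensity matrix has mass on disallowed transitions")
  if (any(off < 0)) stop("intensity matrix has negative off-diagonal entries")
  if (max(abs(rowSums(Q))) > tol * max(1, max(abs(Q))))
    stop("intensity matrix rows do not sum to 0")
  invisible(TRUE)
}
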