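#' Vectorize / unvectorize a matrix (column stacking)
#'
#' `vectorize` stacks the columns of a d x d matrix into a d^2 vector;
#' `unvectorize` is its inverse.  Under this convention
#' `vec(A X B) = (t(B) %x% A) vec(X)`.
#'
#' @param m square matrix.
#' @param v vector of square length.
#' @return vector / matrix.
#' @export
vectorize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  dim(m) <- NULL
  m
}

#' @rdname vectorize
#' @export
unvectorize <- function(v) {
  d <- sqrt(length(v))
  if (d != round(d)) stop("length is not a perfect square")
  matrix(v, as.integer(d), as.integer(d))
}

#' Choi matrix of a superpropagator
#'
#' Applies the involution (index reshuffle) that turns the matrix
#' representation T of a linear map into its Choi matrix
#' `C = sum_ij E_ij %x% Phi(E_ij)` in the column-stacking convention:
#' `C[(i,j),(i',j')] = T[(i,i'),(j,j')]`.  The involution is its own
#' inverse; the result is numerically symmetrized to Hermitian form.
#'
#' @param T a `superpropagator` or a bare d^2 x d^2 matrix.
#' @param hermitize symmetrize the result (default TRUE; the reshuffle of
#'   a Hermiticity-preserving map is Hermitian up to roundoff).
#' @return object of class `choi_matrix` (elements `matrix`, `d`).
#' @export
choi_from_map <- function(T, hermitize = TRUE) {
  Tm <- if (inherits(T, "superpropagator")) T$matrix else T
  D2 <- nrow(Tm)
  d <- as.integer(round(sqrt(D2)))
  if (d * d != D2 || ncol(Tm) != D2) stop("map matrix must be d^2 x d^2")
  Cm <- choi_involution(Tm, d)
  if (hermitize) Cm <- (Cm + Conj(t(Cm))) / 2
  structure(list(matrix = Cm, d = d), class = "choi_matrix")
}

## the raw index reshuffle (self-inverse)
choi_involution <- function(Tm, d) {
  A <- array(Tm, c(d, d, d, d))     # [i, i', j, j']
  Cm <- aperm(A, c(1, 3, 2, 4))     # [i, j, i', j']
  dim(Cm) <- c(d * d, d * d)
  Cm
}

#' Map matrix from a Choi matrix (inverse involution)
#'
#' @param C a `choi_matrix`.
#' @return d^2 x d^2 map matrix.
#' @export
map_from_choi <- function(C) {
  stopifnot(inherits(C, "choi_matrix"))
  choi_involution(C$matrix, C$d)
}

#' Kraus operators from a Choi matrix
#'
#' Eigendecomposes the (Hermitian) Choi matrix and reconstructs one Kraus
#' operator per retained eigenpair, `M_k = sqrt(lambda_k) unvec(u_k)`
#' (the first d entries of u_k are the first column of M_k, and so on).
#' Small negative eigenvalues (path-integral truncation noise) within
#' `repair_budget` are clamped to zero and the spectrum is rescaled to
#' preserve the trace; eigenvalues below `floor` (relative to the total
#' weight) are dropped.  Operators are ordered by descending weight with
#' a deterministic phase (largest-magnitude entry real positive).
#'
#' @param C a `choi_matrix` (or a `superpropagator`, converted first).
#' @param floor relative drop threshold for eigenvalues (default 1e-9).
#' @param repair_budget most negative tolerated Choi eigenvalue (default
#'   1e-6); larger violations raise an error reporting `cp_floor`.
#' @return object of class `kraus_set`: `operators` (list of d x d
#'   matrices), `weights` (descending eigenvalues), `tp_deficit`
#'   (operator norm of sum(M^H M) - I), `cp_floor` (most negative
#'   pre-repair eigenvalue), `d`.
#' @export
kraus_from_choi <- function(C, floor = 1e-9, repair_budget = 1e-6) {
  if (inherits(C, "superpropagator")) C <- choi_from_map(C)
  stopifnot(inherits(C, "choi_matrix"))
  e <- eigen(C$matrix, symmetric = TRUE)
  vals <- e$values
  cp_floor <- min(vals)
  if (cp_floor < -repair_budget)
    stop("Choi matrix is not completely positive within the repair budget: ",
         "min eigenvalue ", signif(cp_floor, 4))
  tr0 <- sum(vals)
  vals[vals < 0] <- 0
  keep <- which(vals > floor * tr0)
  if (!length(keep)) stop("no Kraus operators above the drop floor")
  vals_k <- vals[keep] * (tr0 / sum(vals[keep]))
  ops <- lapply(seq_along(keep), function(i) {
    M <- sqrt(vals_k[i]) * unvectorize(e$vectors[, keep[i]])
    imax <- which.max(Mod(M))
    ph <- M[imax] / Mod(M)[imax]
    M / ph
  })
  new_kraus_set(ops, vals_k, cp_floor, C$d)
}

new_kraus_set <- function(ops, weights, cp_floor, d) {
  S <- Reduce(`+`, lapply(ops, function(M) Conj(t(M)) %*% M))
  tp_deficit <- max(svd(S - diag(d), nu = 0, nv = 0)$d)
  structure(list(operators = ops, weights = weights,
                 tp_deficit = tp_deficit, cp_floor = cp_floor, d = d),
            class = "kraus_set")
}

#' Build a kraus_set directly from operator matrices
#'
#' @param ops list of d x d matrices.
#' @param weights optional weights (default: squared Frobenius norms,
#'   matching the Choi eigenvalues of the set).
#' @return `kraus_set`.
#' @export
kraus_set <- function(ops, weights = NULL) {
  d <- nrow(ops[[1]])
  if (is.null(weights))
    weights <- vapply(ops, function(M) sum(Mod(M)^2), numeric(1))
  new_kraus_set(ops, weights, cp_floor = 0, d = d)
}

#' @export
print.kraus_set <- function(x, ...) {
  cat("<kraus_set> d =", x$d, "with", length(x$operators), "operators\n")
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  cat("  tp_deficit:", signif(x$tp_deficit, 3),
      " cp_floor:", signif(x$cp_floor, 3), "\n")
  invisible(x)
}

#' Superpropagator matrix reconstructed from a Kraus set
#'
#' `T = sum_k Conj(M_k) %x% M_k` (column-stacking convention), the
#' operator-sum map acting on vectorized density matrices.
#'
#' @param K a `kraus_set`.
#' @return d^2 x d^2 map matrix.
#' @export
map_from_kraus <- function(K) {
  stopifnot(inherits(K, "kraus_set"))
  Reduce(`+`, lapply(K$operators, function(M) kronecker(Conj(M), M)))
}

#' CPTP diagnostics of a Kraus set
#'
#' @param K a `kraus_set`.
#' @return list with `tp_deficit`, `cp_floor`, `n_operators`,
#'   `max_singular_value` (must be <= 1 + 1e-8 for a CPTP map, which is
#'   contractive), and `contractive` (logical).
#' @export
validate_cptp <- function(K) {
  stopifnot(inherits(K, "kraus_set"))
  smax <- max(vapply(K$operators,
                     function(M) max(svd(M, nu = 0, nv = 0)$d), numeric(1)))
  list(tp_deficit = K$tp_deficit, cp_floor = K$cp_floor,
       n_operators = length(K$operators), max_singular_value = smax,
       contractive = smax <= 1 + 1e-8)
}

#' Count significantly contributing Kraus operators
#'
#' Number of operators whose weight exceeds `rel_threshold` of the total
#' weight.
#'
#' @param K a `kraus_set`.
#' @param rel_threshold fraction of the total weight (default 0.01).
#' @return integer count.
#' @export
count_significant <- function(K, rel_threshold = 0.01) {
  stopifnot(inherits(K, "kraus_set"),
            rel_threshold > 0, rel_threshold < 1)
  sum(K$weights / sum(K$weights) > rel_threshold)
}

#' Phase-align a sequence of Kraus sets along a trajectory
#'
#' Choi eigenvectors are defined only up to a phase (and up to mixing
#' within degenerate subspaces), so per-operator curves along a
#' trajectory can show arbitrary jumps.  This helper aligns each time
#' point's operators to the previous one by maximal-overlap phase fixing;
#' the weighted sum of the operator-sum representation is invariant.
#'
#' @param ksets list of `kraus_set` objects (consecutive time points).
#' @return list of `kraus_set` objects with aligned phases.
#' @export
align_kraus_trajectory <- function(ksets) {
  if (length(ksets) < 2) return(ksets)
  for (i in 2:length(ksets)) {
    prev <- ksets[[i - 1]]$operators
    cur <- ksets[[i]]$operators
    for (k in seq_along(cur)) {
      if (k > length(prev)) break
      ov <- sum(Conj(prev[[k]]) * cur[[k]])
      if (Mod(ov) > 1e-12)
        ksets[[i]]$operators[[k]] <- cur[[k]] * Conj(ov) / Mod(ov)
    }
  }
  ksets
}
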