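## Internal matrix-product-state machinery for the augmented path tensor.
##
## A chain is a list of sites ordered newest-first; each site is
## list(G = complex 3-d array (chi_left, phys, chi_right), time = integer
## path index).  The last site always carries the free initial index x_0 of
## the dynamical map; middle sites are the path variables inside the memory
## window.  The first and last bonds have dimension 1.

site3 <- function(G, time) list(G = G, time = time)

## truncated SVD split: returns U (left factor, isometry) and S V^H.
svd_trunc <- function(M, cutoff, chi_max = Inf) {
  sv <- svd(M)
  r <- sum(sv$d >= cutoff * sv$d[1])
  r <- max(1L, min(r, chi_max, length(sv$d)))
  list(U = sv$u[, seq_len(r), drop = FALSE],
       SVh = sv$d[seq_len(r)] * Conj(t(sv$v[, seq_len(r), drop = FALSE])))
}

## Apply a front-conditioned diagonal MPO: the physical value c of the
## chain's (already prepared) front site is broadcast down the chain and
## multiplies site s by the factor Mlist[[s]](c, x_s).  The front site must
## expose the broadcast copy as the slow part of its right bond, layout
## (a, c) with a = original bond (fast), c = front value (slow).  Sites
## beyond length(Mlist) are untouched; the broadcast bond terminates (is
## summed) at the last coupled site.  Truncation happens at every split.
zip_front_mpo <- function(chain, Mlist, chi_a, D2, cutoff, chi_max) {
  J <- length(Mlist)
  stopifnot(J >= 1, J <= length(chain))
  ## carry C (r, a, c), initialized to the identity on the composite bond
  C <- array(0i, c(chi_a * D2, chi_a, D2))
  for (cc in seq_len(D2))
    for (aa in seq_len(chi_a))
      C[aa + chi_a * (cc - 1L), aa, cc] <- 1
  for (s in seq_len(J)) {
    G <- chain[[s]]$G; dG <- dim(G)
    dC <- dim(C)
    ## T1[r, c, x, b] = sum_a C[r, a, c] G[a, x, b]
    Cp <- aperm(C, c(1, 3, 2))
    dim(Cp) <- c(dC[1] * dC[3], dC[2])
    T1 <- Cp %*% matrix(G, dG[1], dG[2] * dG[3])
    dim(T1) <- c(dC[1], dC[3], dG[2], dG[3])
    ## multiply factor M[c, x]
    T1 <- aperm(T1, c(2, 3, 1, 4))                  # (c, x, r, b)
    dim(T1) <- c(dC[3] * dG[2], dC[1] * dG[3])
    T1 <- T1 * as.vector(Mlist[[s]])
    dim(T1) <- c(dC[3], dG[2], dC[1], dG[3])        # (c, x, r, b)
    if (s < J) {
      T2 <- aperm(T1, c(3, 2, 4, 1))                # (r, x, b, c)
      dim(T2) <- c(dC[1] * dG[2], dG[3] * dC[3])
      dec <- svd_trunc(T2, cutoff, chi_max)
      r2 <- ncol(dec$U)
      chain[[s]]$G <- array(dec$U, c(dC[1], dG[2], r2))
      C <- array(dec$SVh, c(r2, dG[3], dC[3]))      # (r, b, c)
    } else {
      ## terminate the broadcast bond: sum over c
      dim(T1) <- c(dC[3], dG[2] * dC[1] * dG[3])
      T2 <- colSums(T1)
      dim(T2) <- c(dG[2], dC[1], dG[3])             # (x, r, b)
      chain[[s]]$G <- aperm(T2, c(2, 1, 3))
    }
  }
  chain
}

## right-to-left orthogonalization sweep (SVD-based, no truncation)
mps_sweep_rl <- function(chain) {
  S <- length(chain)
  if (S < 2) return(chain)
  for (s in S:2) {
    G <- chain[[s]]$G; dG <- dim(G)
    M <- matrix(G, dG[1], dG[2] * dG[3])
    sv <- svd(M)
    r <- length(sv$d)
    chain[[s]]$G <- array(Conj(t(sv$v)), c(r, dG[2], dG[3]))
    L <- sv$u * rep(sv$d, each = nrow(sv$u))        # U diag(d): (a, r)
    GL <- chain[[s - 1]]$G; dL <- dim(GL)
    GLm <- matrix(GL, dL[1] * dL[2], dL[3]) %*% L
    chain[[s - 1]]$G <- array(GLm, c(dL[1], dL[2], r))
  }
  chain
}

## left-to-right truncating SVD sweep
mps_sweep_lr <- function(chain, cutoff, chi_max = Inf) {
  S <- length(chain)
  if (S < 2) return(chain)
  for (s in 1:(S - 1)) {
    G <- chain[[s]]$G; dG <- dim(G)
    dec <- svd_trunc(matrix(G, dG[1] * dG[2], dG[3]), cutoff, chi_max)
    r <- ncol(dec$U)
    chain[[s]]$G <- array(dec$U, c(dG[1], dG[2], r))
    GR <- chain[[s + 1]]$G; dR <- dim(GR)
    GRm <- dec$SVh %*% matrix(GR, dR[1], dR[2] * dR[3])
    chain[[s + 1]]$G <- array(GRm, c(r, dR[2], dR[3]))
  }
  chain
}

## sum out (trace over) path variables that have left the memory window;
## the initial-index site (time 0) is never summed.
mps_prune <- function(chain, min_time) {
  repeat {
    drop <- which(vapply(chain, function(s)
      s$time > 0 && s$time < min_time, logical(1)))
    if (!length(drop)) return(chain)
    s <- drop[1]
    G <- chain[[s]]$G
    M <- colSums(aperm(G, c(2, 1, 3)), dims = 1)    # sum over phys -> (a, b)
    GL <- chain[[s - 1]]$G; dL <- dim(GL)
    GLm <- matrix(GL, dL[1] * dL[2], dL[3]) %*% M
    chain[[s - 1]]$G <- array(GLm, c(dL[1], dL[2], ncol(M)))
    chain[[s]] <- NULL
  }
}

## contract a chain into the map matrix T[x_front, x_0]
mps_contract_map <- function(chain) {
  S <- length(chain)
  G1 <- chain[[1]]$G; d1 <- dim(G1)
  A <- matrix(G1[1, , ], d1[2], d1[3])              # (x, b)
  if (S > 2) {
    for (s in 2:(S - 1)) {
      G <- chain[[s]]$G
      A <- A %*% colSums(aperm(G, c(2, 1, 3)), dims = 1)
    }
  }
  GL <- chain[[S]]$G; dL <- dim(GL)
  A %*% matrix(GL[, , 1], dL[1], dL[2])             # (x_front, x_0)
}

## largest bond dimension (diagnostic)
mps_max_bond <- function(chain) {
  max(vapply(chain, function(s) dim(s$G)[3], numeric(1)))
}
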