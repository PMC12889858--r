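# Independent oracles used to cross-check the package's solvers on small
# instances. They attack the same objectives by different numerical routes
# (accelerated proximal gradient, dense normal equations, exhaustive
# enumeration) and share no code with the solvers under test.

# Proximal-gradient (FISTA) solver for the variant objective
#   sum_m ||R(m) - A Phi(m)||_F^2 + gamma1 ||A||_1
#   + gamma2 sum_{i'} lambda_{i'} ||A - A_neighbor[[i']]||_F^2
# run to high precision. residuals/phis are lists over trials.
oracle_variant_pg <- function(residuals, phis, gamma1, gamma2, lambda,
                              neighbors, nonneg = FALSE, N, p,
                              max_iter = 200000L, tol = 1e-13) {
  S <- matrix(0, p, p)
  Rt <- matrix(0, N, p)
  for (m in seq_along(residuals)) {
    S <- S + phis[[m]] %*% t(phis[[m]])
    Rt <- Rt + residuals[[m]] %*% t(phis[[m]])
  }
  Lam <- if (length(lambda)) gamma2 * sum(lambda) else 0
  Nb <- matrix(0, N, p)
  for (i in seq_along(neighbors)) {
    Nb <- Nb + gamma2 * lambda[[i]] * neighbors[[i]]
  }
  gradf <- function(A) 2 * (A %*% S - Rt) + 2 * (Lam * A - Nb)
  smooth_obj <- function(A) {
    sum((A %*% S) * A) - 2 * sum(A * Rt) + Lam * sum(A^2) - 2 * sum(A * Nb)
  }
  L <- 2 * (max(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values)) + Lam)
  if (L <= 0) L <- 1
  step <- 1 / L
  shrink <- function(X, thr) {
    if (nonneg) pmax(X - thr, 0) else sign(X) * pmax(abs(X) - thr, 0)
  }
  A <- matrix(0, N, p)
  Z <- A
  tk <- 1
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    A_new <- shrink(Z - step * gradf(Z), step * gamma1)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- A_new + ((tk - 1) / t_new) * (A_new - A)
    A <- A_new
    tk <- t_new
    if (it %% 200L == 0L) {
      obj <- smooth_obj(A) + gamma1 * sum(abs(A))
      if (abs(obj_prev - obj) <= tol * max(1, abs(obj))) break
      obj_prev <- obj
    }
  }
  A
}

# Dense normal-equation solve of the trace objective with gamma4 = 0:
#   ||Y - A Phi||^2 + gamma3 * sum_t ||Phi_t - Phi_{t-1}||^2
# via the full (P*T) x (P*T) system, column-major vec.
oracle_trace_dense <- function(Y, A, gamma3) {
  P <- ncol(A)
  Tt <- ncol(Y)
  L <- diag(c(1, rep(2, max(0, Tt - 2)), 1))
  if (Tt >= 2) {
    idx <- seq_len(Tt - 1)
    L[cbind(idx, idx + 1)] <- -1
    L[cbind(idx + 1, idx)] <- -1
  }
  M <- kronecker(diag(Tt), crossprod(A)) + gamma3 * kronecker(L, diag(P))
  b <- as.vector(crossprod(A, Y))
  matrix(solve(M, b), P, Tt)
}

# All permutations of 1..n (recursive; for exhaustive assignment checks).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (perm in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force minimum-cost assignment over all permutations.
oracle_assignment <- function(cost) {
  P <- nrow(cost)
  best <- Inf
  best_perm <- NULL
  for (perm in all_permutations(P)) {
    v <- sum(cost[cbind(seq_len(P), perm)])
    if (v < best - 1e-15) {
      best <- v
      best_perm <- perm
    }
  }
  list(cost = best, perm = best_perm)
}
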