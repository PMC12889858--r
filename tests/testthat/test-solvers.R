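# Build a one-category random subproblem instance and solve it both with the
# package's coordinate descent and with the proximal-gradient oracle.
variant_instance <- function(seed, N = 4L, p = 2L, T = 6L, M = 2L,
                             n_neighbors = 2L) {
  set.seed(seed)
  residuals <- lapply(seq_len(M), function(m) matrix(rnorm(N * T), N, T))
  phis <- lapply(seq_len(M), function(m) matrix(rnorm(p * T), p, T))
  neighbors <- lapply(seq_len(n_neighbors), function(i) matrix(rnorm(N * p), N, p))
  lambda <- runif(n_neighbors, 0.2, 1)
  list(residuals = residuals, phis = phis, neighbors = neighbors,
       lambda = lambda, N = N, p = p)
}

solve_instance_cd <- function(inst, gamma1, gamma2, nonneg = FALSE) {
  S <- Reduce(`+`, lapply(inst$phis, function(P) P %*% t(P)))
  Rt <- Reduce(`+`, Map(function(R, P) R %*% t(P), inst$residuals, inst$phis))
  Lam <- gamma2 * sum(inst$lambda)
  B <- Rt
  for (i in seq_along(inst$neighbors)) {
    B <- B + gamma2 * inst$lambda[[i]] * inst$neighbors[[i]]
  }
  lcdecomp:::solve_variant_quad(S + diag(Lam, inst$p), B, gamma1, nonneg,
                                tol = 1e-12, max_iter = 5000L)
}

test_that("unpenalized variant update with orthonormal traces is the projection", {
  set.seed(1)
  N <- 5L; p <- 3L; T <- 12L
  Phi <- qr.Q(qr(matrix(rnorm(T * p), T, p)))  # orthonormal columns
  Phi <- t(Phi)                                # p x T, orthonormal rows
  R <- matrix(rnorm(N * T), N, T)
  inst <- list(residuals = list(R), phis = list(Phi), neighbors = list(),
               lambda = numeric(0), N = N, p = p)
  A <- solve_instance_cd(inst, gamma1 = 0, gamma2 = 0)
  expect_lt(max(abs(A - R %*% t(Phi))), 1e-8)
})

test_that("a large enough L1 weight zeroes the variant", {
  inst <- variant_instance(2, n_neighbors = 0L)
  S <- Reduce(`+`, lapply(inst$phis, function(P) P %*% t(P)))
  Rt <- Reduce(`+`, Map(function(R, P) R %*% t(P), inst$residuals, inst$phis))
  gamma1 <- 2 * max(abs(Rt)) + 1  # above the LASSO null threshold 2*max|b|
  A <- solve_instance_cd(inst, gamma1 = gamma1, gamma2 = 0)
  expect_true(all(A == 0))
})

test_that("coordinate descent matches the proximal-gradient oracle", {
  inst <- variant_instance(3, N = 3L, p = 2L, T = 6L, M = 2L)
  for (nonneg in c(FALSE, TRUE)) {
    A_cd <- solve_instance_cd(inst, gamma1 = 0.1, gamma2 = 0.3, nonneg = nonneg)
    A_pg <- oracle_variant_pg(inst$residuals, inst$phis, 0.1, 0.3, inst$lambda,
                              inst$neighbors, nonneg, inst$N, inst$p)
    expect_lt(max(abs(A_cd - A_pg)), 1e-6)
  }
})

test_that("sparsity increases monotonically with the L1 weight", {
  inst <- variant_instance(4, N = 8L, p = 3L, T = 10L, M = 3L)
  nnz <- vapply(c(0, 0.5, 2, 8, 32), function(g1) {
    sum(solve_instance_cd(inst, gamma1 = g1, gamma2 = 0.2) != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("unpenalized trace update with orthonormal loading is the projection", {
  set.seed(5)
  N <- 8L; P <- 3L; T <- 15L
  A <- qr.Q(qr(matrix(rnorm(N * P), N, P)))
  Y <- matrix(rnorm(N * T), N, T)
  cfg <- lcd_config(gamma3 = 0, gamma4 = 0)
  Phi <- update_trace(Y, A, cfg)$trace
  expect_lt(max(abs(Phi - t(A) %*% Y)), 1e-8)
})

test_that("trace update with gamma4 = 0 matches the dense normal-equation oracle", {
  set.seed(6)
  for (rep in 1:5) {
    N <- sample(3:8, 1); P <- sample(2:4, 1); T <- sample(5:12, 1)
    A <- matrix(rnorm(N * P), N, P)
    Y <- matrix(rnorm(N * T), N, T)
    g3 <- runif(1, 0.01, 2)
    Phi <- update_trace(Y, A, lcd_config(gamma3 = g3, gamma4 = 0))$trace
    expect_lt(max(abs(Phi - oracle_trace_dense(Y, A, g3))), 1e-6)
  }
})

test_that("strong smoothing flattens every trace row", {
  set.seed(7)
  N <- 6L; P <- 2L; T <- 30L
  A <- matrix(abs(rnorm(N * P)), N, P)
  Y <- matrix(rnorm(N * T), N, T) + 3
  Phi <- update_trace(Y, A, lcd_config(gamma3 = 1e6, gamma4 = 0))$trace
  for (j in seq_len(P)) {
    row <- Phi[j, ]
    expect_lt((max(row) - min(row)) / max(abs(row)), 1e-3)
  }
})

test_that("decorrelation surrogate never increases and is accepted or rolled back", {
  set.seed(8)
  N <- 10L; P <- 3L; T <- 25L
  A <- matrix(abs(rnorm(N * P)), N, P)
  Phi_true <- matrix(rnorm(P * T), P, T)
  Y <- A %*% Phi_true + 0.1 * matrix(rnorm(N * T), N, T)
  cfg <- lcd_config(gamma3 = 0.1, gamma4 = 0.5)
  warm <- update_trace(Y, A, lcd_config(gamma3 = 0.1, gamma4 = 0))$trace
  up <- update_trace(Y, A, cfg, trace0 = warm)
  expect_lte(up$surrogate_descent, 1e-8)
  true_obj <- function(P_) {
    lcdecomp:::trial_sse(Y, A, P_) +
      sum(lcdecomp:::trace_penalties(P_, cfg$gamma3, cfg$gamma4))
  }
  expect_lte(true_obj(up$trace), true_obj(warm) + 1e-10)
})

test_that("masked trace update agrees with the dense solver on complete data", {
  set.seed(9)
  N <- 6L; P <- 2L; T <- 10L
  A <- matrix(rnorm(N * P), N, P)
  Y <- matrix(rnorm(N * T), N, T)
  cfg <- lcd_config(gamma3 = 0.3, gamma4 = 0, mask_missing = TRUE)
  dense <- update_trace(Y, A, cfg)$trace
  Yna <- Y
  Yna[1, 1] <- Yna[1, 1]  # still complete; force masked path via NA round trip
  masked_path <- lcdecomp:::solve_trace_quad(Y, A, cfg$gamma3, matrix(0, P, P))
  expect_lt(max(abs(dense - masked_path)), 1e-8)
  # now actually mask a cell: solution should change only slightly and solve
  # the masked normal equations
  Yna[2, 3] <- NA
  Phi_m <- lcdecomp:::solve_trace_quad(Yna, A, cfg$gamma3, matrix(0, P, P))
  expect_equal(dim(Phi_m), c(P, T))
  expect_false(anyNA(Phi_m))
})

test_that("ill-posed variant subproblem returns the incumbent with a warning", {
  sim <- small_sim(seed = 10, M = 6L)
  cfg <- lcd_config(gamma2 = 0)
  init <- lcd_init(sim$trials, sim$labels, sim$specs, cfg)
  traces0 <- lapply(init$traces, function(tr) { tr[] <- 0; tr })
  expect_warning(
    slice <- update_component_variant("difficulty", 1L, sim$trials, sim$labels,
                                      sim$specs, init$tensors, traces0,
                                      build_label_graph(sim$specs$difficulty),
                                      cfg),
    "ill-posed")
  expect_equal(unname(slice), unname(matrix(init$tensors$difficulty[, , 1],
                                            ncol = sim$specs$difficulty$p)))
})
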