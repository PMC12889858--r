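test_that("objective history is non-increasing and subproblems descend", {
  sim <- small_sim(seed = 1)
  fit <- lcd_fit(sim$trials, sim$labels, sim$specs,
                 lcd_config(nonneg = TRUE, max_outer_iters = 10))
  oh <- fit$objective_history
  expect_true(all(diff(oh) <= 1e-8 * pmax(1, abs(oh[-length(oh)]))))
  expect_lte(fit$diagnostics$worst_component_ascent, 1e-8)
  expect_lte(fit$diagnostics$worst_surrogate_ascent, 1e-8)
})

test_that("single-trial, single-option model reduces to one sparse factorization", {
  set.seed(2)
  N <- 12L; T <- 30L
  specs <- list(category_spec("only", "x", p = 2L))
  labels <- data.frame(trial_id = "1", only = "x", stringsAsFactors = FALSE)
  u <- abs(matrix(rnorm(N * 2), N, 2))
  trials <- list(`1` = u %*% matrix(rnorm(2 * T), 2, T) +
                   0.05 * matrix(rnorm(N * T), N, T))
  fit <- lcd_fit(trials, labels, specs, lcd_config(gamma2 = 0, max_outer_iters = 15))
  oh <- fit$objective_history
  expect_true(all(diff(oh) <= 1e-8 * pmax(1, abs(oh[-length(oh)]))))
  expect_equal(length(fit$traces), 1L)
})

test_that("truth is a fixed point of the unpenalized alternation on noiseless data", {
  sim <- small_sim(seed = 3, noise_sigma = 0)
  cfg <- lcd_config(gamma1 = 0, gamma2 = 0, gamma3 = 0, gamma4 = 0,
                    nonneg = TRUE, max_outer_iters = 1)
  init <- list(tensors = sim$truth$tensors, traces = sim$truth$traces)
  fit <- lcd_fit(sim$trials, sim$labels, sim$specs, cfg, init = init)
  ynorm2 <- sum(vapply(sim$trials, function(Y) sum(Y^2), numeric(1)))
  expect_lt(fit$objective_history[1] / ynorm2, 1e-6)
  for (k in names(fit$tensors)) {
    expect_lt(max(abs(fit$tensors[[k]] - sim$truth$tensors[[k]])), 1e-3)
  }
})

test_that("strong variant coupling fuses the slices of a category", {
  sim <- small_sim(seed = 4, variant_jitter = 0.4)
  fit <- lcd_fit(sim$trials, sim$labels, sim$specs,
                 lcd_config(gamma2 = 1e6, nonneg = TRUE, max_outer_iters = 5))
  for (k in names(fit$tensors)) {
    ten <- fit$tensors[[k]]
    ref <- ten[, , 1]
    for (i in seq_len(dim(ten)[3])[-1]) {
      expect_lt(sqrt(sum((ten[, , i] - ref)^2)) / max(sqrt(sum(ref^2)), 1e-12),
                1e-3)
    }
  }
})

test_that("increasing the coupling weight shrinks within-category variant distance", {
  sim <- small_sim(seed = 5, variant_jitter = 0.4)
  mean_dist <- function(fit) {
    ds <- c()
    for (k in names(fit$tensors)) {
      ten <- fit$tensors[[k]]
      n_opt <- dim(ten)[3]
      if (n_opt < 2) next
      for (i in seq_len(n_opt - 1)) {
        for (j in seq.int(i + 1, n_opt)) {
          ds <- c(ds, sqrt(sum((ten[, , i] - ten[, , j])^2)))
        }
      }
    }
    mean(ds)
  }
  fits <- lapply(c(0, 0.5, 50), function(g2) {
    lcd_fit(sim$trials, sim$labels, sim$specs,
            lcd_config(gamma2 = g2, nonneg = TRUE, max_outer_iters = 6))
  })
  d <- vapply(fits, mean_dist, numeric(1))
  expect_true(all(diff(d) <= 1e-10))
})

test_that("nonnegativity is closed under the full alternation", {
  sim <- small_sim(seed = 6)
  fit <- lcd_fit(sim$trials, sim$labels, sim$specs,
                 lcd_config(nonneg = TRUE, max_outer_iters = 6))
  expect_true(all(unlist(fit$tensors) >= 0))
})

test_that("equal-label trials share identical loadings after the fit", {
  sim <- small_sim(seed = 7, M = 16L)
  fit <- lcd_fit(sim$trials, sim$labels, sim$specs,
                 lcd_config(nonneg = TRUE, max_outer_iters = 4))
  key <- apply(sim$labels[, c("difficulty", "choice")], 1, paste, collapse = "|")
  dup <- split(sim$labels$trial_id, key)
  dup <- Filter(function(x) length(x) > 1, dup)
  expect_gt(length(dup), 0)
  for (grp in dup) {
    A1 <- construct_loading(fit$tensors,
                            lcdecomp:::label_tuple(sim$labels, grp[[1]], fit$specs),
                            fit$specs)
    for (id in grp[-1]) {
      A2 <- construct_loading(fit$tensors,
                              lcdecomp:::label_tuple(sim$labels, id, fit$specs),
                              fit$specs)
      expect_identical(A1, A2)
    }
  }
})

test_that("normalization preserves reconstructions and is scale invariant", {
  st <- random_state(8)
  cfg <- lcd_config()
  before <- lapply(names(st$trials), function(id) {
    A <- construct_loading(st$tensors,
                           lcdecomp:::label_tuple(st$labels, id, st$specs),
                           st$specs)
    A %*% st$traces[[id]]
  })
  nz <- normalize_components(st$tensors, st$traces, st$labels, st$specs, cfg)
  after <- lapply(names(st$trials), function(id) {
    A <- construct_loading(nz$tensors,
                           lcdecomp:::label_tuple(st$labels, id, st$specs),
                           st$specs)
    A %*% nz$traces[[id]]
  })
  for (m in seq_along(before)) {
    expect_lt(max(abs(before[[m]] - after[[m]])), 1e-10)
  }
  # columns now L1-normalized
  for (k in names(nz$tensors)) {
    ten <- nz$tensors[[k]]
    for (i in seq_len(dim(ten)[3])) {
      for (j in seq_len(dim(ten)[2])) {
        expect_equal(sum(abs(ten[, j, i])), 1, tolerance = 1e-12)
      }
    }
  }
  # normalize(c * column) gives the same column for any c > 0, and an already
  # normalized nonnegative state is untouched
  sc <- st
  sc$tensors$choice[, 1, 1] <- 3.7 * st$tensors$choice[, 1, 1]
  nz2 <- normalize_components(sc$tensors, sc$traces, st$labels, st$specs, cfg)
  expect_equal(nz2$tensors$choice[, 1, 1], nz$tensors$choice[, 1, 1],
               tolerance = 1e-12)
  nz3 <- normalize_components(nz$tensors, nz$traces, st$labels, st$specs, cfg)
  expect_equal(nz3$tensors, nz$tensors, tolerance = 1e-12)
})

test_that("all-zero columns pass through normalization untouched", {
  st <- random_state(9)
  st$tensors$choice[, 1, 1] <- 0
  tr_before <- st$traces
  nz <- normalize_components(st$tensors, st$traces, st$labels, st$specs,
                             lcd_config())
  expect_true(all(nz$tensors$choice[, 1, 1] == 0))
})

test_that("an option carried by no trial is filled from its siblings with a warning", {
  sim <- small_sim(seed = 10, M = 10L)
  labels <- sim$labels
  labels$difficulty[labels$difficulty == "3"] <- "2"  # empty option 3
  warns <- capture_warnings(
    fit <- lcd_fit(sim$trials, labels, sim$specs,
                   lcd_config(nonneg = TRUE, max_outer_iters = 2)))
  expect_true(any(grepl("no trials", warns)))
  ten <- fit$tensors$difficulty
  expect_true(all(is.finite(ten)))
  expect_gt(sum(abs(ten[, , 3])), 0)
})

test_that("masked fits ignore NA cells and still descend", {
  sim <- small_sim(seed = 11, M = 8L)
  trials <- sim$trials
  for (id in names(trials)[1:3]) {
    idx <- cbind(sample(nrow(trials[[id]]), 15, replace = TRUE),
                 sample(ncol(trials[[id]]), 15, replace = TRUE))
    trials[[id]][idx] <- NA
  }
  cfg <- lcd_config(nonneg = TRUE, mask_missing = TRUE, max_outer_iters = 4)
  fit <- lcd_fit(trials, sim$labels, sim$specs, cfg)
  oh <- fit$objective_history
  expect_true(all(is.finite(oh)))
  expect_true(all(diff(oh) <= 1e-8 * pmax(1, abs(oh[-length(oh)]))))
  expect_false(anyNA(unlist(fit$traces)))
})

test_that("fits reject non-finite input up front", {
  sim <- small_sim(seed = 12, M = 4L)
  sim$trials[["1"]][1, 1] <- NaN
  expect_error(lcd_fit(sim$trials, sim$labels, sim$specs, lcd_config()),
               "NaN/Inf")
})
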