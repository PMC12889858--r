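#' Model configuration
#'
#' Collects the hyperparameters and numerical controls of the decomposition.
#' All penalty weights are nonnegative; see the methods vignette for the role
#' of each term and how the defaults were chosen.
#'
#' @param gamma1 Sparsity weight on component entries (L1 penalty).
#' @param gamma2 Variant-coupling weight: quadratic attraction between a
#'   category's variant slices, scaled by the label similarity graph.
#' @param gamma3 Temporal smoothness weight on first differences of each
#'   trace row.
#' @param gamma4 Within-trial trace decorrelation weight (normalized absolute
#'   Gram off-diagonals).
#' @param nonneg Constrain all component entries to be nonnegative.
#' @param norm_constant Each non-zero component column is rescaled so its
#'   absolute entries sum to this constant (traces are counter-scaled so
#'   reconstructions are preserved).
#' @param max_outer_iters Maximum number of outer alternating iterations.
#' @param tol Convergence tolerance on the relative change of the total
#'   objective between outer iterations.
#' @param seed Integer seed recorded with the fit (the fit itself is
#'   deterministic; the seed matters for helpers that simulate).
#' @param mask_missing Allow `NA` cells in trial matrices; masked cells are
#'   excluded from every data-fidelity term.
#' @param bandwidth Kernel bandwidth for ordinal label similarity graphs
#'   (on option values rescaled to `[0, 1]`).
#' @param inner_trace_iters Number of inner surrogate iterations in the trace
#'   update when `gamma4 > 0`.
#' @param cd_tol,cd_max_iter Coordinate-descent stopping rule for the
#'   component subproblems.
#'
#' @return A list of class `lcd_config`.
#' @export
lcd_config <- function(gamma1 = 0.1, gamma2 = 0.1, gamma3 = 0.1, gamma4 = 0.01,
                       nonneg = FALSE, norm_constant = 1,
                       max_outer_iters = 50L, tol = 1e-4, seed = 1L,
                       mask_missing = FALSE, bandwidth = 0.5,
                       inner_trace_iters = 5L, cd_tol = 1e-10,
                       cd_max_iter = 1000L) {
  cfg <- list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
              gamma4 = gamma4, nonneg = isTRUE(nonneg),
              norm_constant = norm_constant,
              max_outer_iters = as.integer(max_outer_iters), tol = tol,
              seed = as.integer(seed), mask_missing = isTRUE(mask_missing),
              bandwidth = bandwidth,
              inner_trace_iters = as.integer(inner_trace_iters),
              cd_tol = cd_tol, cd_max_iter = as.integer(cd_max_iter))
  for (g in c("gamma1", "gamma2", "gamma3", "gamma4")) {
    if (!is.numeric(cfg[[g]]) || length(cfg[[g]]) != 1L || cfg[[g]] < 0) {
      stop(g, " must be a single nonnegative number")
    }
  }
  if (cfg$norm_constant <= 0) stop("norm_constant must be positive")
  if (cfg$max_outer_iters < 1L) stop("max_outer_iters must be >= 1")
  if (cfg$tol <= 0) stop("tol must be positive")
  if (cfg$bandwidth <= 0) stop("bandwidth must be positive")
  structure(cfg, class = "lcd_config")
}

#' @export
print.lcd_config <- function(x, ...) {
  cat("<lcd_config>\n")
  cat(sprintf("  penalties: gamma1=%g (sparsity) gamma2=%g (variant coupling)\n",
              x$gamma1, x$gamma2))
  cat(sprintf("             gamma3=%g (smoothness) gamma4=%g (decorrelation)\n",
              x$gamma3, x$gamma4))
  cat(sprintf("  nonneg=%s  norm_constant=%g  max_outer_iters=%d  tol=%g\n",
              x$nonneg, x$norm_constant, x$max_outer_iters, x$tol))
  invisible(x)
}
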