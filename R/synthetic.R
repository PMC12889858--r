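#' Configuration of the synthetic-data generator
#'
#' Describes a labeled multi-trial dataset with known ground truth: sparse
#' nonnegative component variants that differ slightly across label options,
#' Gaussian-process traces whose kernel parameters are tied to label options,
#' and additive i.i.d. Gaussian observation noise. Defaults mirror the
#' benchmark protocol used throughout the package: two categories ("difficulty",
#' 5 ordinal options, and "choice", 2 categorical options), two components
#' each (P = 4), 250 trials of 500 time steps over 100 channels.
#'
#' @param N Number of channels.
#' @param M Number of trials.
#' @param T Time steps per trial.
#' @param categories List of category descriptors, each a list with `name`,
#'   `n_options`, `ordinal` (logical) and `p`.
#' @param sparsity Fraction of channels in each component's support.
#' @param variant_jitter Relative magnitude of the label-driven composition
#'   changes between a component's variants (0 = identical variants).
#' @param gp_lengthscale_range Interval (time steps) from which each
#'   (component, option) pair draws its squared-exponential GP length scale.
#' @param gp_amplitude_range Interval from which each (component, option) pair
#'   draws its GP amplitude.
#' @param trial_amplitude_jitter Half-width of the uniform per-(trial, row)
#'   amplitude multiplier `1 +/- jitter`, the trial-specific "free" variation
#'   on top of the label-tied kernel parameters.
#' @param label_tied_traces If `FALSE`, GP parameters are drawn per component
#'   only (not per option), so labels carry no information about the traces;
#'   used for null calibrations.
#' @param noise_sigma Standard deviation of the additive observation noise.
#' @param seed Integer seed; the same seed reproduces the dataset bitwise.
#' @return A list of class `lcd_sim_config`.
#' @export
lcd_sim_config <- function(N = 100L, M = 250L, T = 500L,
                           categories = list(
                             list(name = "difficulty", n_options = 5L,
                                  ordinal = TRUE, p = 2L),
                             list(name = "choice", n_options = 2L,
                                  ordinal = FALSE, p = 2L)),
                           sparsity = 0.15, variant_jitter = 0.2,
                           gp_lengthscale_range = c(0.02, 0.1) * T,
                           gp_amplitude_range = c(0.5, 1.5),
                           trial_amplitude_jitter = 0.3,
                           label_tied_traces = TRUE,
                           noise_sigma = 0.1, seed = 1L) {
  stopifnot(N >= 1, M >= 1, T >= 2, length(categories) >= 1)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (variant_jitter < 0) stop("variant_jitter must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  stopifnot(length(gp_lengthscale_range) == 2, all(gp_lengthscale_range > 0),
            length(gp_amplitude_range) == 2, all(gp_amplitude_range > 0))
  structure(list(N = as.integer(N), M = as.integer(M), T = as.integer(T),
                 categories = categories, sparsity = sparsity,
                 variant_jitter = variant_jitter,
                 gp_lengthscale_range = as.numeric(gp_lengthscale_range),
                 gp_amplitude_range = as.numeric(gp_amplitude_range),
                 trial_amplitude_jitter = trial_amplitude_jitter,
                 label_tied_traces = isTRUE(label_tied_traces),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "lcd_sim_config")
}

sim_category_specs <- function(config) {
  lapply(config$categories, function(cc) {
    opts <- as.character(seq_len(cc$n_options))
    category_spec(cc$name, opts, p = cc$p,
                  ordinal_values = if (isTRUE(cc$ordinal)) seq_len(cc$n_options))
  })
}

#' Draw one Gaussian-process trace
#'
#' Zero-mean draw with squared-exponential kernel
#' `k(t, t') = amplitude^2 * exp(-(t - t')^2 / (2 * lengthscale^2))` on the
#' integer time grid `1..T`, with `1e-6` diagonal jitter.
#'
#' @param T Number of time steps.
#' @param lengthscale,amplitude Positive kernel parameters (time steps /
#'   signal units).
#' @param chol_corr Optional pre-computed upper-triangular Cholesky factor of
#'   the unit-amplitude correlation matrix (for repeated draws at the same
#'   length scale).
#' @return Numeric vector of length `T`. Consumes `T` standard normals from
#'   the current RNG stream.
#' @export
sample_gp_trace <- function(T, lengthscale, amplitude, chol_corr = NULL) {
  stopifnot(lengthscale > 0, amplitude > 0 || amplitude == 0)
  if (is.null(chol_corr)) chol_corr <- gp_chol(T, lengthscale)
  z <- stats::rnorm(T)
  amplitude * as.vector(crossprod(chol_corr, z))
}

gp_chol <- function(T, lengthscale) {
  d <- outer(seq_len(T), seq_len(T), "-")
  K <- exp(-d^2 / (2 * lengthscale^2)) + diag(1e-6, T)
  chol(K)
}

#' Generate ground-truth component tensors
#'
#' Per category: each component draws a sparse nonnegative base pattern
#' (support of size `ceiling(sparsity * N)`, magnitudes uniform on
#' `[0.5, 1]`) and a perturbation target that adds and removes up to 20% of
#' the support and wiggles the surviving magnitudes. Variants are placed
#' between base and target: ordinal categories interpolate monotonically along
#' the option order; categorical options each draw an independent target. The
#' step size is `variant_jitter`, so variants coincide when it is zero. Every
#' variant column is L1-normalized.
#'
#' @param config An [lcd_sim_config()]. Uses the current RNG stream.
#' @return Named list of `N x p x n_options` arrays.
#' @export
generate_components <- function(config) {
  N <- config$N
  s_size <- ceiling(config$sparsity * N)
  jit <- config$variant_jitter
  out <- list()
  for (cc in config$categories) {
    n_opt <- cc$n_options
    ten <- array(0, dim = c(N, cc$p, n_opt),
                 dimnames = list(NULL, NULL, as.character(seq_len(n_opt))))
    for (j in seq_len(cc$p)) {
      support <- sample.int(N, s_size)
      base <- numeric(N)
      base[support] <- stats::runif(s_size, 0.5, 1)
      make_target <- function() {
        target <- base
        n_move <- max(1L, floor(0.2 * s_size / 2))
        rm_idx <- sample(support, min(n_move, s_size))
        target[rm_idx] <- 0
        outside <- setdiff(seq_len(N), support)
        if (length(outside) > 0) {
          add_idx <- sample(outside, min(n_move, length(outside)))
          target[add_idx] <- stats::runif(length(add_idx), 0.5, 1)
        }
        keep <- setdiff(support, rm_idx)
        target[keep] <- target[keep] * (1 + stats::runif(length(keep), -0.5, 0.5))
        target
      }
      if (isTRUE(cc$ordinal) && n_opt > 1L) {
        target <- make_target()
        alphas <- jit * (seq_len(n_opt) - 1) / (n_opt - 1)
        for (i in seq_len(n_opt)) {
          ten[, j, i] <- pmax(0, (1 - alphas[i]) * base + alphas[i] * target)
        }
      } else {
        for (i in seq_len(n_opt)) {
          target <- make_target()
          ten[, j, i] <- pmax(0, (1 - jit) * base + jit * target)
        }
      }
      for (i in seq_len(n_opt)) {
        sm <- sum(abs(ten[, j, i]))
        if (sm > 0) ten[, j, i] <- ten[, j, i] / sm
      }
    }
    out[[cc$name]] <- ten
  }
  out
}

#' Generate a labeled synthetic dataset with ground truth
#'
#' Assigns each trial a label uniformly at random over the product of option
#' spaces, draws per-trial Gaussian-process traces whose kernel parameters are
#' tied to the trial's option in the owning category (plus a per-trial
#' amplitude jitter), forms `Y = loading %*% trace + noise`, and returns both
#' the observations and the generating truth.
#'
#' @param config An [lcd_sim_config()].
#' @return List with `trials` (named list of `N x T` matrices), `labels`
#'   (data frame), `specs` (list of [category_spec()]), and `truth` (list with
#'   `tensors`, `traces`, `labels`).
#' @export
#' @examples
#' sim <- simulate_lcd_dataset(lcd_sim_config(N = 20, M = 6, T = 30, seed = 7))
#' dim(sim$trials[["1"]])
simulate_lcd_dataset <- function(config = lcd_sim_config()) {
  set.seed(config$seed)
  specs <- sim_category_specs(config)
  specs <- as_category_list(specs)
  layout <- trace_layout(specs)
  P <- attr(layout, "P")
  tensors <- generate_components(config)

  M <- config$M
  ids <- as.character(seq_len(M))
  labels <- data.frame(trial_id = ids, stringsAsFactors = FALSE)
  for (s in specs) {
    labels[[s$name]] <- sample(s$options, M, replace = TRUE)
  }

  # label-tied GP parameters per (trace row, option); in the label-free mode
  # the same parameters are shared by all options of a row
  ls_rng <- config$gp_lengthscale_range
  amp_rng <- config$gp_amplitude_range
  gp_par <- list()
  for (s in specs) {
    n_opt <- length(s$options)
    lsc <- matrix(0, s$p, n_opt)
    amp <- matrix(0, s$p, n_opt)
    for (j in seq_len(s$p)) {
      if (config$label_tied_traces) {
        lsc[j, ] <- stats::runif(n_opt, ls_rng[1], ls_rng[2])
        amp[j, ] <- stats::runif(n_opt, amp_rng[1], amp_rng[2])
      } else {
        lsc[j, ] <- stats::runif(1, ls_rng[1], ls_rng[2])
        amp[j, ] <- stats::runif(1, amp_rng[1], amp_rng[2])
      }
    }
    gp_par[[s$name]] <- list(lengthscale = lsc, amplitude = amp)
  }
  chol_cache <- new.env(parent = emptyenv())
  get_chol <- function(ell) {
    key <- sprintf("%.12g", ell)
    hit <- chol_cache[[key]]
    if (is.null(hit)) {
      hit <- gp_chol(config$T, ell)
      chol_cache[[key]] <- hit
    }
    hit
  }

  trials <- vector("list", M)
  traces <- vector("list", M)
  names(trials) <- names(traces) <- ids
  jit <- config$trial_amplitude_jitter
  for (m in seq_len(M)) {
    lab <- label_tuple(labels, ids[m], specs)
    Phi <- matrix(0, P, config$T)
    for (s in specs) {
      i <- option_index(s, lab[[s$name]])
      for (j in seq_len(s$p)) {
        ell <- gp_par[[s$name]]$lengthscale[j, i]
        amp <- gp_par[[s$name]]$amplitude[j, i] *
          stats::runif(1, 1 - jit, 1 + jit)
        Phi[layout[[s$name]][j], ] <- sample_gp_trace(config$T, ell, amp,
                                                      chol_corr = get_chol(ell))
      }
    }
    A <- construct_loading(tensors, lab, specs)
    Y <- A %*% Phi
    if (config$noise_sigma > 0) {
      Y <- Y + matrix(stats::rnorm(length(Y), sd = config$noise_sigma),
                      nrow(Y), ncol(Y))
    }
    trials[[m]] <- Y
    traces[[m]] <- Phi
  }

  list(trials = trials, labels = labels, specs = specs,
       truth = list(tensors = tensors, traces = traces, labels = labels),
       config = config)
}
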