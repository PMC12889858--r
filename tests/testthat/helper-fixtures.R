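# Small programmatic fixtures shared across test files.

# Two-category spec set used in most small tests.
small_specs <- function(p_a = 2L, p_b = 2L, n_a = 3L, n_b = 2L) {
  list(
    category_spec("difficulty", as.character(seq_len(n_a)), p = p_a,
                  ordinal_values = seq_len(n_a)),
    category_spec("choice", c("left", "right")[seq_len(n_b)], p = p_b)
  )
}

# Fully random dense model state for algebra/identity tests (no structure).
random_state <- function(seed, N = 6L, specs = small_specs(), M = 4L, T = 8L) {
  set.seed(seed)
  specs <- lcdecomp:::as_category_list(specs)
  layout <- lcdecomp:::trace_layout(specs)
  P <- attr(layout, "P")
  tensors <- lapply(specs, function(s) {
    array(rnorm(N * s$p * length(s$options)),
          dim = c(N, s$p, length(s$options)),
          dimnames = list(NULL, NULL, s$options))
  })
  names(tensors) <- names(specs)
  ids <- as.character(seq_len(M))
  labels <- data.frame(trial_id = ids, stringsAsFactors = FALSE)
  for (s in specs) labels[[s$name]] <- sample(s$options, M, replace = TRUE)
  traces <- lapply(ids, function(id) matrix(rnorm(P * T), P, T))
  names(traces) <- ids
  trials <- lapply(ids, function(id) {
    A <- construct_loading(tensors, lcdecomp:::label_tuple(labels, id, specs), specs)
    A %*% traces[[id]] + 0.1 * matrix(rnorm(N * T), N, T)
  })
  names(trials) <- ids
  list(specs = specs, tensors = tensors, traces = traces, labels = labels,
       trials = trials, layout = layout, P = P, N = N)
}

# Small labeled synthetic dataset (structured, nonnegative ground truth).
small_sim <- function(seed = 1, N = 20L, M = 12L, T = 40L, ...) {
  simulate_lcd_dataset(lcd_sim_config(
    N = N, M = M, T = T,
    categories = list(
      list(name = "difficulty", n_options = 3L, ordinal = TRUE, p = 1L),
      list(name = "choice", n_options = 2L, ordinal = FALSE, p = 1L)),
    seed = seed, ...))
}
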