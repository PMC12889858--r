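#' Initialize components and traces
#'
#' Deterministic spectral initialization: the singular vectors of the
#' horizontal concatenation of all trials are partitioned across categories in
#' declaration order (the first category takes the leading `p` vectors, the
#' next category the following ones, and so on), every variant slice of a
#' category starting identical. Traces are then initialized per trial by
#' ridge-stabilized least squares against the initial loadings. With
#' `nonneg = TRUE` the absolute values of the singular vectors are used.
#'
#' @param trials Named list of `N x T` trial matrices.
#' @param labels Label table (`trial_id` plus one column per category).
#' @param specs List of [category_spec()] objects.
#' @param config An [lcd_config()].
#' @return List with `tensors` (named list of `N x p x n_options` arrays) and
#'   `traces` (named list of `P x T` matrices).
#' @export
lcd_init <- function(trials, labels, specs, config = lcd_config()) {
  specs <- as_category_list(specs)
  trials <- validate_trials(trials, allow_na = config$mask_missing)
  validate_labels(labels, specs)
  layout <- trace_layout(specs)
  P <- attr(layout, "P")
  N <- nrow(trials[[1]])
  if (P > N) stop("total component budget P = ", P, " exceeds channel count N = ", N)

  X <- do.call(cbind, unname(trials))
  if (anyNA(X)) X[is.na(X)] <- 0
  sv <- svd(X, nu = P, nv = 0)
  U <- sv$u[, seq_len(P), drop = FALSE]
  # fix the SVD sign ambiguity: largest-magnitude entry positive
  for (j in seq_len(P)) {
    n_star <- which.max(abs(U[, j]))
    if (U[n_star, j] < 0) U[, j] <- -U[, j]
  }
  if (config$nonneg) U <- abs(U)
  # gauge: L1-normalize columns (zero columns cannot occur for nonzero data)
  cs <- colSums(abs(U))
  cs[cs == 0] <- 1
  U <- sweep(U, 2, cs / config$norm_constant, "/")

  tensors <- lapply(specs, function(s) {
    base <- U[, layout[[s$name]], drop = FALSE]
    ten <- array(0, dim = c(N, s$p, length(s$options)),
                 dimnames = list(NULL, NULL, s$options))
    for (i in seq_along(s$options)) ten[, , i] <- base
    ten
  })
  names(tensors) <- names(specs)

  traces <- lapply(names(trials), function(id) {
    lab <- label_tuple(labels, id, specs)
    A <- construct_loading(tensors, lab, specs)
    Y <- trials[[id]]
    if (anyNA(Y)) Y[is.na(Y)] <- 0
    solve(crossprod(A) + diag(1e-8, P), crossprod(A, Y))
  })
  names(traces) <- names(trials)
  list(tensors = tensors, traces = traces)
}
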