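#' Construct the per-trial loading matrix
#'
#' The loading matrix of a trial selects, for each category, the variant slice
#' matching the trial's label option, and concatenates the slices horizontally
#' in category declaration order. Trials with identical labels therefore share
#' identical loadings.
#'
#' @param tensors Named list (by category) of `N x p x n_options` component
#'   tensors, as returned by [lcd_init()] or [lcd_fit()].
#' @param label Named character vector or list with one option per category
#'   (names are category names), e.g. `c(difficulty = "3", choice = "left")`.
#' @param specs List of [category_spec()] objects in declaration order.
#'
#' @return An `N x P` numeric matrix with a `"provenance"` attribute, a data
#'   frame recording for each column its category, component index, and the
#'   selected variant slice.
#' @export
construct_loading <- function(tensors, label, specs) {
  specs <- as_category_list(specs)
  layout <- trace_layout(specs)
  P <- attr(layout, "P")
  Ns <- vapply(specs, function(s) dim(tensors[[s$name]])[1], integer(1))
  if (length(unique(Ns)) != 1L) {
    stop("component tensors disagree on channel count N: ",
         paste(Ns, collapse = ", "))
  }
  N <- Ns[[1]]
  A <- matrix(0, N, P)
  prov <- vector("list", length(specs))
  for (ci in seq_along(specs)) {
    s <- specs[[ci]]
    ten <- tensors[[s$name]]
    if (is.null(ten)) stop("no component tensor for category '", s$name, "'")
    if (dim(ten)[2] != s$p || dim(ten)[3] != length(s$options)) {
      stop("tensor for category '", s$name, "' has dims ",
           paste(dim(ten), collapse = "x"), ", expected N x ", s$p, " x ",
           length(s$options))
    }
    opt <- label[[s$name]]
    if (is.null(opt)) stop("label has no entry for category '", s$name, "'")
    i <- option_index(s, opt)
    A[, layout[[s$name]]] <- ten[, , i, drop = FALSE]
    prov[[ci]] <- data.frame(column = layout[[s$name]], category = s$name,
                             component = seq_len(s$p), slice = i,
                             option = s$options[i], stringsAsFactors = FALSE)
  }
  attr(A, "provenance") <- do.call(rbind, prov)
  A
}

#' Noiseless model prediction for one trial
#'
#' @param loading `N x P` loading matrix from [construct_loading()].
#' @param trace `P x T` trace matrix for the trial.
#' @return The `N x T` product `loading %*% trace`.
#' @export
reconstruct_trial <- function(loading, trace) {
  if (!is.matrix(loading) || !is.matrix(trace)) stop("loading and trace must be matrices")
  if (ncol(loading) != nrow(trace)) {
    stop("shape mismatch: loading has ", ncol(loading),
         " columns but trace has ", nrow(trace), " rows")
  }
  loading %*% trace
}

#' Residual of a trial with one category's contribution removed
#'
#' Subtracts from the observations the partial reconstruction by all
#' categories except `k`; what remains is the signal the category-`k` variant
#' update must explain. Masked (`NA`) cells propagate as `NA`.
#'
#' @param Y `N x T` observation matrix for the trial.
#' @param tensors Named list of component tensors.
#' @param trace `P x T` trace matrix for the trial.
#' @param label The trial's label tuple (named, one option per category).
#' @param specs List of [category_spec()] objects.
#' @param k Name of the category whose contribution is *kept out* of the
#'   subtraction.
#' @return `N x T` residual matrix.
#' @export
residual_for_category <- function(Y, tensors, trace, label, specs, k) {
  specs <- as_category_list(specs)
  if (!k %in% names(specs)) stop("unknown category '", k, "'")
  layout <- trace_layout(specs)
  if (is.null(trace)) stop("no trace available for this trial")
  R <- Y
  for (s in specs) {
    if (s$name == k) next
    i <- option_index(s, label[[s$name]])
    slice <- tensors[[s$name]][, , i, drop = TRUE]
    if (s$p == 1L) slice <- matrix(slice, ncol = 1L)
    R <- R - slice %*% trace[layout[[s$name]], , drop = FALSE]
  }
  R
}

# --- objective bookkeeping ---------------------------------------------------

# Squared-error fidelity of one trial, skipping masked cells.
trial_sse <- function(Y, loading, trace) {
  E <- Y - loading %*% trace
  sum(E * E, na.rm = TRUE)
}

# Trace penalties of one trial: gamma3 * sum of squared first differences +
# gamma4 * sum_{j != j'} |gram_jj'| / (||phi_j|| ||phi_j'||).
trace_penalties <- function(trace, gamma3, gamma4) {
  Tt <- ncol(trace)
  sm <- if (Tt >= 2L) {
    D <- trace[, -1L, drop = FALSE] - trace[, -Tt, drop = FALSE]
    sum(D * D)
  } else 0
  dec <- 0
  if (gamma4 > 0 && nrow(trace) > 1L) {
    C <- trace %*% t(trace)
    nrm <- sqrt(diag(C))
    Dn <- outer(nrm, nrm)
    ratio <- abs(C) / Dn
    ratio[Dn == 0] <- 0
    diag(ratio) <- 0
    dec <- sum(ratio)
  }
  c(smooth = gamma3 * sm, decor = gamma4 * dec)
}

# Total objective: sum over trials of masked squared error + gamma1 L1 on all
# variant slices + gamma2 * graph-weighted squared distances between variant
# pairs (each unordered pair once) + per-trial trace penalties.
lcd_objective <- function(trials, labels, specs, tensors, traces, graphs, config) {
  specs <- as_category_list(specs)
  fid <- 0; sm <- 0; dec <- 0
  for (id in names(trials)) {
    lab <- label_tuple(labels, id, specs)
    A <- construct_loading(tensors, lab, specs)
    fid <- fid + trial_sse(trials[[id]], A, traces[[id]])
    tp <- trace_penalties(traces[[id]], config$gamma3, config$gamma4)
    sm <- sm + tp[["smooth"]]
    dec <- dec + tp[["decor"]]
  }
  l1 <- 0; pair <- 0
  for (s in specs) {
    ten <- tensors[[s$name]]
    l1 <- l1 + sum(abs(ten))
    n_opt <- length(s$options)
    if (n_opt > 1L && config$gamma2 > 0) {
      lam <- graphs[[s$name]]
      for (i in seq_len(n_opt - 1L)) {
        for (j in seq.int(i + 1L, n_opt)) {
          if (lam[i, j] == 0) next
          Dv <- ten[, , i] - ten[, , j]
          pair <- pair + lam[i, j] * sum(Dv * Dv)
        }
      }
    }
  }
  parts <- c(fidelity = fid, l1 = config$gamma1 * l1,
             pair = config$gamma2 * pair, smooth = sm, decor = dec)
  list(total = sum(parts), parts = parts)
}
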