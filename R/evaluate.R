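#' Align estimated components with ground truth
#'
#' Because the decomposition is invariant to component permutation, estimated
#' and true components are aligned by optimal linear sum assignment before
#' scoring: each component is flattened to an N-vector (averaging its variant
#' slices, or comparing every variant when `per_variant = TRUE`), the
#' assignment cost is `1 - |pearson|`, and the optimal bijection is found by
#' maximum-weight bipartite matching. Constant (zero-variance) components get
#' correlation 0 with a warning.
#'
#' @param est_tensors,true_tensors Named lists of component tensors with the
#'   same categories, N, and total P.
#' @param est_traces,true_traces Optional named lists of per-trial trace
#'   matrices; when given, trace correlations of matched pairs (rows
#'   concatenated across trials) are reported too.
#' @param per_variant Flatten by stacking all variant slices instead of
#'   averaging them.
#' @return A list of class `lcd_match`: `permutation` (index of the true
#'   component matched to each estimated component), `component_correlations`,
#'   `trace_correlations` (or `NULL`), and their means.
#' @export
match_components <- function(est_tensors, true_tensors,
                             est_traces = NULL, true_traces = NULL,
                             per_variant = FALSE) {
  E <- flatten_tensors(est_tensors, per_variant)
  Tr <- flatten_tensors(true_tensors, per_variant)
  if (!all(dim(E) == dim(Tr))) {
    stop("estimated and true tensors disagree in shape (",
         paste(dim(E), collapse = "x"), " vs ", paste(dim(Tr), collapse = "x"), ")")
  }
  P <- ncol(E)
  R <- matrix(0, P, P)
  warned <- FALSE
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      r <- safe_cor(E[, i], Tr[, j])
      if (is.na(r)) {
        r <- 0
        warned <- TRUE
      }
      R[i, j] <- r
    }
  }
  if (warned) warning("constant component(s); their correlations are set to 0")
  # maximum-weight perfect matching on |corr|; the +1 shift keeps all edge
  # weights positive without changing the optimal assignment
  g <- igraph::graph_from_biadjacency_matrix(abs(R) + 1, weighted = TRUE)
  mt <- igraph::max_bipartite_match(g)
  perm <- mt$matching[seq_len(P)] - P
  comp_cor <- R[cbind(seq_len(P), perm)]

  trace_cor <- NULL
  if (!is.null(est_traces) && !is.null(true_traces)) {
    ids <- intersect(names(est_traces), names(true_traces))
    Ecat <- do.call(cbind, est_traces[ids])
    Tcat <- do.call(cbind, true_traces[ids])
    trace_cor <- vapply(seq_len(P), function(i) {
      r <- safe_cor(Ecat[i, ], Tcat[perm[i], ])
      if (is.na(r)) 0 else r
    }, numeric(1))
  }
  structure(
    list(permutation = as.integer(perm),
         component_correlations = comp_cor,
         trace_correlations = trace_cor,
         mean_component_corr = mean(comp_cor),
         mean_trace_corr = if (is.null(trace_cor)) NULL else mean(trace_cor)),
    class = "lcd_match"
  )
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Flatten a tensor list into an N x P matrix in global layout order.
flatten_tensors <- function(tensors, per_variant = FALSE) {
  cols <- list()
  for (k in names(tensors)) {
    ten <- tensors[[k]]
    for (j in seq_len(dim(ten)[2])) {
      cols[[length(cols) + 1L]] <- if (per_variant) {
        as.vector(ten[, j, ])
      } else {
        rowMeans(ten[, j, , drop = FALSE], dims = 1)
      }
    }
  }
  do.call(cbind, cols)
}

#' @export
print.lcd_match <- function(x, ...) {
  cat("<lcd_match>\n  permutation:", x$permutation, "\n")
  cat(sprintf("  mean component correlation: %.3f\n", x$mean_component_corr))
  if (!is.null(x$mean_trace_corr)) {
    cat(sprintf("  mean trace correlation:     %.3f\n", x$mean_trace_corr))
  }
  invisible(x)
}

#' Recovery metrics of a fit against ground truth
#'
#' Aligns fitted components with the truth, then reports per-component and
#' trace correlation distributions, per-trial reconstruction R-squared, and
#' summary means.
#'
#' @param fit An [lcd_fit()] result (or any list with `tensors`, `traces`,
#'   `labels`, `specs`).
#' @param truth Ground truth as returned in `simulate_lcd_dataset()$truth`.
#' @param trials The observed trial matrices (for reconstruction R-squared).
#' @param per_variant Passed to [match_components()].
#' @return A list of class `lcd_recovery`: the `match`, a `per_trial` data
#'   frame with reconstruction `r2`, and the summary means.
#' @export
recovery_metrics <- function(fit, truth, trials, per_variant = FALSE) {
  match <- match_components(fit$tensors, truth$tensors,
                            fit$traces, truth$traces, per_variant)
  specs <- as_category_list(fit$specs)
  labels <- if (!is.null(fit$labels)) fit$labels else truth$labels
  r2 <- vapply(names(trials), function(id) {
    lab <- label_tuple(labels, id, specs)
    A <- construct_loading(fit$tensors, lab, specs)
    Yhat <- A %*% fit$traces[[id]]
    Y <- trials[[id]]
    sse <- sum((Y - Yhat)^2, na.rm = TRUE)
    sst <- sum((Y - mean(Y, na.rm = TRUE))^2, na.rm = TRUE)
    if (sst == 0) return(NA_real_)
    1 - sse / sst
  }, numeric(1))
  structure(
    list(match = match,
         per_trial = data.frame(trial_id = names(trials), r2 = unname(r2),
                                stringsAsFactors = FALSE),
         mean_component_corr = match$mean_component_corr,
         mean_trace_corr = match$mean_trace_corr,
         mean_r2 = mean(r2, na.rm = TRUE)),
    class = "lcd_recovery"
  )
}

#' @export
print.lcd_recovery <- function(x, ...) {
  cat("<lcd_recovery>\n")
  cat(sprintf("  mean component correlation: %.3f\n", x$mean_component_corr))
  if (!is.null(x$mean_trace_corr)) {
    cat(sprintf("  mean trace correlation:     %.3f\n", x$mean_trace_corr))
  }
  cat(sprintf("  mean reconstruction R^2:    %.3f over %d trials\n",
              x$mean_r2, nrow(x$per_trial)))
  invisible(x)
}

# Total reconstruction R^2 of a (tensors, traces) state on a dataset.
reconstruction_score <- function(trials, labels, specs, tensors, traces) {
  sse <- 0; sst <- 0
  for (id in names(trials)) {
    lab <- label_tuple(labels, id, specs)
    A <- construct_loading(tensors, lab, specs)
    Y <- trials[[id]]
    Yhat <- A %*% traces[[id]]
    sse <- sse + sum((Y - Yhat)^2, na.rm = TRUE)
    mu <- mean(Y, na.rm = TRUE)
    sst <- sst + sum((Y - mu)^2, na.rm = TRUE)
  }
  1 - sse / sst
}

#' Permutation-null significance test
#'
#' Tests whether the fitted decomposition exploits genuine label information
#' by comparing its reconstruction score against a null distribution obtained
#' by shuffling the trial-to-label assignment. In `"rescore"` mode the
#' components are held fixed and only the traces are refit under each
#' permuted label table (the real score is computed through the identical
#' pipeline); `"refit"` mode runs the full fit on each permuted dataset. The
#' p-value uses the add-one rule `p = (1 + #{null >= real}) / (1 + n_perms)`,
#' so it can never be zero.
#'
#' @param trials,labels,specs The dataset.
#' @param config An [lcd_config()] used for fitting/rescoring.
#' @param n_perms Number of label permutations (>= 19).
#' @param mode `"rescore"` (default) or `"refit"`.
#' @param fit Optional pre-computed [lcd_fit()] on the real labels.
#' @param seed Seed for the permutation stream.
#' @return A list of class `lcd_perm_test`: `p_value`, `real_score`,
#'   `null_scores`, `mode`, `n_perms`.
#' @export
permutation_null_test <- function(trials, labels, specs, config = lcd_config(),
                                  n_perms = 99L, mode = c("rescore", "refit"),
                                  fit = NULL, seed = 1L) {
  mode <- match.arg(mode)
  specs <- as_category_list(specs)
  n_perms <- as.integer(n_perms)
  if (n_perms < 19L) stop("n_perms must be at least 19")
  if (is.null(fit)) fit <- lcd_fit(trials, labels, specs, config)

  score_with_labels <- function(lab_tab) {
    if (mode == "rescore") {
      traces <- fit$traces
      for (id in names(trials)) {
        lab <- label_tuple(lab_tab, id, specs)
        A <- construct_loading(fit$tensors, lab, specs)
        traces[[id]] <- update_trace(trials[[id]], A, config)$trace
      }
      reconstruction_score(trials, lab_tab, specs, fit$tensors, traces)
    } else {
      f <- lcd_fit(trials, lab_tab, specs, config)
      reconstruction_score(trials, lab_tab, specs, f$tensors, f$traces)
    }
  }

  real_score <- score_with_labels(labels)
  set.seed(seed)
  cat_cols <- vapply(specs, function(s) s$name, character(1))
  null_scores <- vapply(seq_len(n_perms), function(b) {
    perm <- sample.int(nrow(labels))
    lab_tab <- labels
    lab_tab[cat_cols] <- labels[perm, cat_cols, drop = FALSE]
    score_with_labels(lab_tab)
  }, numeric(1))
  p <- (1 + sum(null_scores >= real_score)) / (1 + n_perms)
  structure(list(p_value = p, real_score = real_score,
                 null_scores = null_scores, mode = mode, n_perms = n_perms),
            class = "lcd_perm_test")
}

#' @export
print.lcd_perm_test <- function(x, ...) {
  cat(sprintf("<lcd_perm_test> %s mode, %d permutations\n", x$mode, x$n_perms))
  cat(sprintf("  real reconstruction R^2: %.4f\n", x$real_score))
  cat(sprintf("  null R^2: median %.4f, max %.4f\n",
              stats::median(x$null_scores), max(x$null_scores)))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  invisible(x)
}
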