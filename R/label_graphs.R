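#' Build the label similarity graph of a category
#'
#' The graph weights `lambda[i, j] >= 0` couple a category's variant slices in
#' proportion to how similar their label options are; they scale the quadratic
#' attraction term of the variant update. Categorical categories get uniform
#' off-diagonal weights (every option equally similar); ordinal categories get
#' a Gaussian kernel on the option values rescaled to `[0, 1]`, so coupling
#' decays smoothly with ordinal distance and approaches the categorical graph
#' as `bandwidth` grows.
#'
#' @param spec A [category_spec()].
#' @param bandwidth Positive kernel bandwidth for ordinal categories, on the
#'   rescaled `[0, 1]` option scale. Default 0.5.
#' @return A symmetric `n_options x n_options` matrix with zero diagonal and
#'   nonnegative entries, of class `lcd_label_graph` (attributes carry the
#'   category name).
#' @export
#' @examples
#' build_label_graph(category_spec("choice", c("L", "R"), p = 1))
build_label_graph <- function(spec, bandwidth = 0.5) {
  stopifnot(inherits(spec, "lcd_category"))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop("bandwidth must be a positive number")
  }
  n <- length(spec$options)
  if (spec$ordinal) {
    if (is.null(spec$ordinal_values)) {
      stop("category '", spec$name, "' declared ordinal but has no ordinal_values")
    }
    v <- spec$ordinal_values
    rng <- diff(range(v))
    v <- if (rng > 0) (v - min(v)) / rng else rep(0, n)
    W <- exp(-outer(v, v, "-")^2 / (2 * bandwidth^2))
  } else {
    W <- matrix(1, n, n)
  }
  diag(W) <- 0
  dimnames(W) <- list(spec$options, spec$options)
  structure(W, category = spec$name, class = c("lcd_label_graph", "matrix", "array"))
}

#' Build (or override) the label graphs of all categories
#'
#' @param specs List of [category_spec()] objects.
#' @param bandwidth Passed to [build_label_graph()].
#' @param overrides Optional named list; each entry is either a numeric
#'   `n x n` matrix or a path to a headerless CSV matrix, replacing the
#'   built-in graph for that category (e.g. to match an externally defined
#'   similarity). Overrides are validated (symmetry, zero diagonal,
#'   nonnegativity).
#' @return Named list of graphs, one per category.
#' @export
label_graphs <- function(specs, bandwidth = 0.5, overrides = NULL) {
  specs <- as_category_list(specs)
  out <- lapply(specs, build_label_graph, bandwidth = bandwidth)
  for (nm in names(overrides)) {
    if (!nm %in% names(specs)) stop("graph override for unknown category '", nm, "'")
    W <- overrides[[nm]]
    if (is.character(W)) {
      W <- as.matrix(utils::read.csv(W, header = FALSE))
      dimnames(W) <- NULL
    }
    n <- length(specs[[nm]]$options)
    if (!is.matrix(W) || !all(dim(W) == n)) {
      stop("graph override for '", nm, "' must be a ", n, "x", n, " matrix")
    }
    W <- unname(W * 1.0)
    if (any(W < 0)) stop("graph override for '", nm, "' has negative weights")
    if (max(abs(W - t(W))) > 1e-12) stop("graph override for '", nm, "' is not symmetric")
    if (any(diag(W) != 0)) stop("graph override for '", nm, "' must have a zero diagonal")
    dimnames(W) <- list(specs[[nm]]$options, specs[[nm]]$options)
    out[[nm]] <- structure(W, category = nm,
                           class = c("lcd_label_graph", "matrix", "array"))
  }
  out
}
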