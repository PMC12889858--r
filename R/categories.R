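#' Declare a label category
#'
#' A category is one metadata axis of the experiment (e.g. task difficulty,
#' animal choice). Each trial carries exactly one *option* per category, and
#' each category owns a budget of `p` components whose channel memberships may
#' differ subtly between options (the component *variants*).
#'
#' @param name Category name (string); must be unique within a dataset and is
#'   used as the column name in label tables.
#' @param options Character vector of the category's option identifiers, in a
#'   fixed order. The i-th option selects the i-th variant slice of the
#'   category's component tensor.
#' @param p Integer component budget for this category (number of trace rows
#'   the category owns).
#' @param ordinal_values Optional numeric vector, one value per option, giving
#'   the option positions on an ordinal scale (e.g. difficulty levels). When
#'   supplied, the label similarity graph decays with ordinal distance instead
#'   of being uniform.
#' @param ordinal Logical; declare the category ordinal. Defaults to `TRUE`
#'   exactly when `ordinal_values` is supplied. Declaring `ordinal = TRUE`
#'   without values is a configuration error.
#'
#' @return An object of class `lcd_category`.
#' @export
#' @examples
#' category_spec("choice", c("left", "right"), p = 2)
#' category_spec("difficulty", as.character(1:5), p = 2, ordinal_values = 1:5)
category_spec <- function(name, options, p, ordinal_values = NULL,
                          ordinal = !is.null(ordinal_values)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  options <- as.character(options)
  if (length(options) < 1L) stop("category '", name, "' needs at least one option")
  if (anyDuplicated(options)) stop("category '", name, "' has duplicated options")
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("component budget p must be a positive integer")
  if (isTRUE(ordinal) && is.null(ordinal_values)) {
    stop("category '", name, "' declared ordinal but no ordinal_values given")
  }
  if (!is.null(ordinal_values)) {
    ordinal_values <- as.numeric(ordinal_values)
    if (length(ordinal_values) != length(options)) {
      stop("ordinal_values must have one entry per option")
    }
  }
  structure(
    list(name = name, options = options, p = p,
         ordinal = isTRUE(ordinal), ordinal_values = ordinal_values),
    class = "lcd_category"
  )
}

#' @export
print.lcd_category <- function(x, ...) {
  cat(sprintf("<lcd_category> %s: %d option(s) [%s], p = %d%s\n",
              x$name, length(x$options),
              paste(x$options, collapse = ", "), x$p,
              if (x$ordinal) ", ordinal" else ""))
  invisible(x)
}

# Trace-row layout: categories occupy contiguous blocks of 1..P in declaration
# order, so column semantics of the loading matrix are deterministic.
trace_layout <- function(specs) {
  specs <- as_category_list(specs)
  p <- vapply(specs, function(s) s$p, integer(1))
  ends <- cumsum(p)
  starts <- ends - p + 1L
  out <- Map(function(a, b) seq.int(a, b), starts, ends)
  names(out) <- vapply(specs, function(s) s$name, character(1))
  attr(out, "P") <- sum(p)
  out
}

as_category_list <- function(specs) {
  if (inherits(specs, "lcd_category")) specs <- list(specs)
  if (!is.list(specs) || !all(vapply(specs, inherits, logical(1), "lcd_category"))) {
    stop("specs must be a list of category_spec() objects")
  }
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicated category names: ", paste(nm[duplicated(nm)], collapse = ", "))
  names(specs) <- nm
  specs
}

# Map option identifier -> slice index (position in the declared option order).
option_index <- function(spec, option) {
  idx <- match(as.character(option), spec$options)
  if (anyNA(idx)) {
    stop("unknown option '", paste(option[is.na(idx)], collapse = "', '"),
         "' for category '", spec$name, "'")
  }
  idx
}

# Validate a label table against the declared categories: one column per
# category plus trial_id, every value a declared option.
validate_labels <- function(labels, specs) {
  specs <- as_category_list(specs)
  if (!is.data.frame(labels)) stop("labels must be a data.frame")
  if (!"trial_id" %in% names(labels)) stop("labels needs a trial_id column")
  for (s in specs) {
    if (!s$name %in% names(labels)) {
      stop("labels is missing a column for category '", s$name, "'")
    }
    vals <- as.character(labels[[s$name]])
    bad <- !vals %in% s$options
    if (any(bad)) {
      stop("trial '", labels$trial_id[which(bad)[1]], "' has unknown option '",
           vals[which(bad)[1]], "' in category '", s$name, "'")
    }
  }
  if (anyDuplicated(labels$trial_id)) stop("duplicated trial_id in label table")
  invisible(labels)
}

# Validate trial matrices: identical channel count, >= 2 time steps, finite
# (NA allowed only when the model is run with mask_missing).
validate_trials <- function(trials, allow_na = FALSE) {
  if (!is.list(trials) || length(trials) == 0L) stop("trials must be a non-empty list of matrices")
  if (is.null(names(trials)) || any(!nzchar(names(trials)))) {
    names(trials) <- as.character(seq_along(trials))
  }
  N <- nrow(trials[[1]])
  for (id in names(trials)) {
    Y <- trials[[id]]
    if (!is.matrix(Y) || !is.numeric(Y)) stop("trial '", id, "' is not a numeric matrix")
    if (nrow(Y) != N) {
      stop("trial '", id, "' has ", nrow(Y), " channels but the dataset has ", N)
    }
    if (ncol(Y) < 2L) stop("trial '", id, "' has fewer than 2 time steps")
    if (any(is.infinite(Y)) || any(is.nan(Y))) stop("trial '", id, "' contains NaN/Inf values")
    if (!allow_na && anyNA(Y)) {
      stop("trial '", id, "' contains missing values; set mask_missing = TRUE to model them")
    }
  }
  trials
}

# Per-trial label tuple as a named character vector in category order.
label_tuple <- function(labels, trial_id, specs) {
  specs <- as_category_list(specs)
  row <- labels[match(as.character(trial_id), as.character(labels$trial_id)), , drop = FALSE]
  if (nrow(row) != 1L || anyNA(row$trial_id)) stop("no label row for trial '", trial_id, "'")
  out <- vapply(specs, function(s) as.character(row[[s$name]]), character(1))
  names(out) <- names(specs)
  out
}
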