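#' Write a dataset bundle to disk
#'
#' The on-disk container is a directory holding Feather files (lossless for
#' doubles) plus plain-text metadata: `format.json` (schema version),
#' `categories.json` (category declarations), `labels.csv` (trial_id and one
#' column per category), `trials/trial_<id>.feather` (one file per trial,
#' first column the channel id, remaining columns the time steps), and an
#' optional `truth/` group with the generating tensors and traces.
#'
#' @param trials Named list of `N x T(m)` matrices.
#' @param labels Label table.
#' @param specs List of [category_spec()] objects.
#' @param path Directory to create (must not already contain a bundle unless
#'   `overwrite = TRUE`).
#' @param truth Optional ground-truth list (`tensors`, `traces`) as produced
#'   by [simulate_lcd_dataset()].
#' @param overwrite Replace an existing bundle.
#' @return `path`, invisibly.
#' @export
write_lcd_dataset <- function(trials, labels, specs, path, truth = NULL,
                              overwrite = FALSE) {
  specs <- as_category_list(specs)
  trials <- validate_trials(trials, allow_na = TRUE)
  validate_labels(labels, specs)
  extra <- setdiff(names(trials), as.character(labels$trial_id))
  if (length(extra)) stop("trials missing from label table: ", paste(extra, collapse = ", "))
  if (dir.exists(path)) {
    if (!overwrite && file.exists(file.path(path, "format.json"))) {
      stop("bundle already exists at ", path, " (use overwrite = TRUE)")
    }
  } else {
    dir.create(path, recursive = TRUE)
  }
  dir.create(file.path(path, "trials"), showWarnings = FALSE)

  jsonlite::write_json(list(format = "lcdecomp-bundle", version = "1"),
                       file.path(path, "format.json"), auto_unbox = TRUE)
  cats <- lapply(specs, function(s) {
    list(name = s$name, options = as.list(s$options), p = s$p,
         ordinal = s$ordinal,
         ordinal_values = if (is.null(s$ordinal_values)) NULL else as.list(s$ordinal_values))
  })
  jsonlite::write_json(unname(cats), file.path(path, "categories.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  lab_out <- labels
  lab_out$trial_id <- as.character(lab_out$trial_id)
  utils::write.csv(lab_out, file.path(path, "labels.csv"), row.names = FALSE)

  for (id in names(trials)) {
    arrow::write_feather(matrix_to_frame(trials[[id]]),
                         file.path(path, "trials", paste0("trial_", id, ".feather")))
  }

  if (!is.null(truth)) {
    dir.create(file.path(path, "truth"), showWarnings = FALSE)
    dir.create(file.path(path, "truth", "traces"), showWarnings = FALSE)
    for (k in names(truth$tensors)) {
      ten <- truth$tensors[[k]]
      flat <- matrix(ten, nrow = dim(ten)[1])
      colnames(flat) <- as.vector(outer(seq_len(dim(ten)[2]), seq_len(dim(ten)[3]),
                                        function(j, i) sprintf("c%d_o%d", j, i)))
      arrow::write_feather(as.data.frame(flat),
                           file.path(path, "truth", paste0("tensor_", k, ".feather")))
    }
    for (id in names(truth$traces)) {
      arrow::write_feather(matrix_to_frame(truth$traces[[id]]),
                           file.path(path, "truth", "traces", paste0("trial_", id, ".feather")))
    }
  }
  invisible(path)
}

matrix_to_frame <- function(Y) {
  df <- as.data.frame(Y)
  names(df) <- sprintf("t%d", seq_len(ncol(Y)))
  rid <- rownames(Y)
  if (is.null(rid)) rid <- as.character(seq_len(nrow(Y)))
  cbind(data.frame(channel = rid, stringsAsFactors = FALSE), df)
}

frame_to_matrix <- function(df) {
  ch <- as.character(df[[1]])
  Y <- as.matrix(df[, -1, drop = FALSE])
  dimnames(Y) <- list(ch, NULL)
  Y
}

#' Read a dataset bundle
#'
#' Inverse of [write_lcd_dataset()]; the round trip reproduces trial values
#' bitwise and labels exactly. Validates that every trial file has a label
#' row, that options are declared, and that all trials share the channel
#' count.
#'
#' @param path Bundle directory.
#' @return List with `trials`, `labels`, `specs`, and `truth` (or `NULL`).
#' @export
read_lcd_dataset <- function(path) {
  fmt_file <- file.path(path, "format.json")
  if (!file.exists(fmt_file)) stop("no dataset bundle at ", path)
  fmt <- jsonlite::read_json(fmt_file)
  if (!identical(fmt$format, "lcdecomp-bundle") || !identical(fmt$version, "1")) {
    stop("unsupported bundle format/version")
  }
  cats <- jsonlite::read_json(file.path(path, "categories.json"))
  specs <- lapply(cats, function(cc) {
    category_spec(cc$name, unlist(cc$options), p = cc$p,
                  ordinal_values = if (is.null(cc$ordinal_values)) NULL else unlist(cc$ordinal_values),
                  ordinal = isTRUE(cc$ordinal))
  })
  specs <- as_category_list(specs)
  labels <- utils::read.csv(file.path(path, "labels.csv"),
                            colClasses = "character", check.names = FALSE)
  validate_labels(labels, specs)

  files <- list.files(file.path(path, "trials"), pattern = "^trial_.*\\.feather$")
  ids <- sub("^trial_(.*)\\.feather$", "\\1", files)
  extra <- setdiff(ids, labels$trial_id)
  if (length(extra)) stop("trial '", extra[[1]], "' has no row in the label table")
  ord <- match(intersect(labels$trial_id, ids), ids)
  trials <- lapply(ord, function(i) {
    frame_to_matrix(arrow::read_feather(file.path(path, "trials", files[i])))
  })
  names(trials) <- ids[ord]
  Ns <- vapply(trials, nrow, integer(1))
  if (length(unique(Ns)) > 1L) {
    stop("trials disagree on channel count N: ", paste(unique(Ns), collapse = ", "))
  }

  truth <- NULL
  if (dir.exists(file.path(path, "truth"))) {
    tensors <- list()
    for (k in names(specs)) {
      f <- file.path(path, "truth", paste0("tensor_", k, ".feather"))
      if (!file.exists(f)) next
      flat <- as.matrix(arrow::read_feather(f))
      s <- specs[[k]]
      tensors[[k]] <- array(flat, dim = c(nrow(flat), s$p, length(s$options)),
                            dimnames = list(NULL, NULL, s$options))
    }
    tr_files <- list.files(file.path(path, "truth", "traces"),
                           pattern = "^trial_.*\\.feather$")
    traces <- lapply(tr_files, function(f) {
      M <- frame_to_matrix(arrow::read_feather(file.path(path, "truth", "traces", f)))
      dimnames(M) <- NULL
      M
    })
    names(traces) <- sub("^trial_(.*)\\.feather$", "\\1", tr_files)
    traces <- traces[names(trials)[names(trials) %in% names(traces)]]
    truth <- list(tensors = tensors, traces = traces, labels = labels)
  }
  list(trials = trials, labels = labels, specs = specs, truth = truth)
}
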