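#' Read a gaze trajectory from delimited text
#'
#' Expects a CSV with header `t,x,y,d` (extra columns `label`,
#' `disability`, `writer` are picked up as metadata). Validates strictly
#' increasing time, reporting the offending row.
#'
#' @param path file path.
#' @param y_down if `TRUE`, the file uses screen coordinates (y growing
#'   downward) and the y axis is flipped to the mathematical convention
#'   on ingestion.
#' @return A [raw_trajectory()].
#' @export
read_trajectory <- function(path, y_down = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "d")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_trajectory(): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      num <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(num))
      stop("read_trajectory(): non-numeric '", cn, "' at row ",
           if (length(bad)) bad[1] else NA, call. = FALSE)
    }
  }
  nonmono <- which(diff(df$t) <= 0)
  if (length(nonmono))
    stop("read_trajectory(): non-increasing t at row ", nonmono[1] + 1L,
         call. = FALSE)
  y <- if (y_down) -df$y else df$y
  raw_trajectory(df$t, df$x, y, df$d,
                 label = if ("label" %in% names(df)) df$label[1] else NULL,
                 disability = if ("disability" %in% names(df))
                   as.integer(df$disability[1]) else NULL,
                 writer = if ("writer" %in% names(df)) df$writer[1] else NULL)
}

#' Write a gaze trajectory to delimited text
#'
#' Inverse of [read_trajectory()]; samples round-trip within 1e-9.
#'
#' @param traj a [raw_trajectory()].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = format(traj$t, digits = 17, scientific = FALSE,
                              trim = TRUE),
                   x = format(traj$x, digits = 17, trim = TRUE),
                   y = format(traj$y, digits = 17, trim = TRUE),
                   d = format(traj$d, digits = 17, trim = TRUE))
  if (!is.null(attr(traj, "label"))) df$label <- attr(traj, "label")
  if (!is.null(attr(traj, "disability")))
    df$disability <- attr(traj, "disability")
  if (!is.null(attr(traj, "writer"))) df$writer <- attr(traj, "writer")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

EW_MODEL_SCHEMA <- 1L

#' Save / load a learned model
#'
#' The archive stores every probability table, the raw counts and
#' normal-fit sufficient statistics, the domain specifications and the
#' learning configuration, together with a schema version and a JSON
#' manifest. The round trip is bit-exact: posteriors computed before
#' saving equal posteriors computed after loading.
#'
#' @param model an `ew_model`.
#' @param path file path for the archive.
#' @return `save_model()` returns `path` invisibly; `load_model()`
#'   returns the `ew_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ew_model"))
  manifest <- jsonlite::toJSON(list(
    schema = EW_MODEL_SCHEMA,
    symbols = model$symbols,
    n_exemplars = sum(model$n_exemplars),
    alpha = model$config$alpha,
    smoothing = c(model$config$pos_kernel_order, model$config$pos_kernel_var,
                  model$config$vel_kernel_order, model$config$vel_kernel_var)),
    auto_unbox = TRUE)
  payload <- list(schema = EW_MODEL_SCHEMA, manifest = as.character(manifest),
                  model = model)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e)
                        stop("load_model(): unreadable or truncated archive: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(payload) || is.null(payload$schema) ||
      !identical(as.integer(payload$schema), EW_MODEL_SCHEMA))
    stop("load_model(): schema version mismatch", call. = FALSE)
  model <- payload$model
  if (!inherits(model, "ew_model"))
    stop("load_model(): archive does not contain a model", call. = FALSE)
  model
}
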