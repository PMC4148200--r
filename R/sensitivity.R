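#' Two-parameter sensitivity scan of the fit distance
#'
#' Re-simulates the gradient over a grid in two model parameters and records,
#' for each grid point, the fit distance between the re-simulated normalized
#' ventral window and a baseline gradient (by default the normalized
#' `mel_adjusted` wild-type output). Grid points whose geometry is infeasible
#' (e.g. a nucleus larger than its compartment) are recorded as error cells,
#' not propagated as failures.
#'
#' @param base A `dl_params` baseline parameter set.
#' @param param_x,param_y Names of the two scanned parameters.
#' @param values_x,values_y Numeric axis grids (non-empty).
#' @param baseline Normalized `dl_profile` to fit against; default: the
#'   normalized wild-type `mel_adjusted` gradient.
#' @param window Ventral window size (default 30).
#' @param ... Passed to [simulate_final_cycle()].
#' @return A `dl_sensitivity` object: `fit_matrix`
#'   (`length(values_y)` × `length(values_x)`, `NA` at error cells), `status`
#'   (character matrix, `"ok"` or the error message), axes, parameter names
#'   and `baseline_label`.
#' @export
sensitivity_scan <- function(base, param_x, values_x, param_y, values_y,
                             baseline = NULL, window = 30, ...) {
  stopifnot(inherits(base, "dl_params"),
            length(values_x) >= 1, length(values_y) >= 1)
  for (p in c(param_x, param_y))
    if (!p %in% PARAM_FIELDS)
      stop("unknown parameter '", p, "'; fields are: ",
           paste(PARAM_FIELDS, collapse = ", "), call. = FALSE)
  if (is.null(baseline))
    baseline <- as_normalized_profile(load_parameter_set("mel_adjusted"),
                                      window, ...)
  if (!baseline$normalized)
    baseline <- normalize_profile(baseline)

  nx <- length(values_x); ny <- length(values_y)
  fit <- matrix(NA_real_, ny, nx)
  status <- matrix("ok", ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      ov <- stats::setNames(list(values_x[j], values_y[i]),
                            c(param_x, param_y))
      res <- tryCatch({
        p_ij <- do.call(set_params, c(list(base), ov))
        prof <- as_normalized_profile(p_ij, window, ...)
        fit_distance(prof, baseline)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        status[i, j] <- conditionMessage(res)
      } else {
        fit[i, j] <- res
      }
    }
  }
  structure(list(param_x = param_x, param_y = param_y,
                 values_x = values_x, values_y = values_y,
                 fit_matrix = fit, status = status,
                 baseline_label = attr(base, "meta")$label %||% "custom"),
            class = "dl_sensitivity")
}

#' @export
print.dl_sensitivity <- function(x, ...) {
  n_err <- sum(x$status != "ok")
  cat("<dl_sensitivity> ", x$param_y, " x ", x$param_x, " grid (",
      nrow(x$fit_matrix), " x ", ncol(x$fit_matrix), "), fit range [",
      signif(min(x$fit_matrix, na.rm = TRUE), 4), ", ",
      signif(max(x$fit_matrix, na.rm = TRUE), 4), "]",
      if (n_err) paste0(", ", n_err, " error cells"), "\n", sep = "")
  invisible(x)
}

#' Contour levels for a sensitivity grid
#'
#' Evenly spaced levels `0, step, 2*step, ...` up to the maximum finite fit
#' value in the grid.
#'
#' @param grid A `dl_sensitivity` object (or numeric matrix).
#' @param step Level spacing (> 0); default 0.01.
#' @return Ordered numeric vector of levels.
#' @export
#' @examples
#' contour_levels(matrix(c(0, 0.035), 1), step = 0.01)  # 0 0.01 0.02 0.03
contour_levels <- function(grid, step = 0.01) {
  if (step <= 0) stop("contour step must be positive", call. = FALSE)
  m <- if (inherits(grid, "dl_sensitivity")) grid$fit_matrix else grid
  top <- max(m, na.rm = TRUE)
  seq(0, top, by = step)
}

#' Write a sensitivity grid as TSV
#'
#' Long format: columns `x`, `y`, `fit`, `status`.
#'
#' @param grid A `dl_sensitivity` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_tsv <- function(grid, path) {
  df <- expand.grid(x = grid$values_x, y = grid$values_y,
                    KEEP.OUT.ATTRS = FALSE)
  df$fit <- as.vector(t(grid$fit_matrix))
  df$status <- as.vector(t(grid$status))
  names(df)[1:2] <- c(grid$param_x, grid$param_y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
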