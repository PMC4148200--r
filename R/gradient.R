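#' Construct a gradient profile
#'
#' A gradient profile holds nuclear-Dl values indexed by nucleus position
#' relative to the ventral midline, optionally with per-embryo replicates and
#' their summary statistics.
#'
#' @param values Numeric vector of nuclear Dl values (raw or normalized).
#' @param positions Integer nucleus positions relative to the ventral midline;
#'   default `-floor(k/2) .. ceiling(k/2)-1` for `k` values (the 30-cell
#'   window runs -15..+14, the midline falling between the two centre nuclei).
#' @param normalized Logical flag.
#' @param replicates Optional matrix (positions × embryos) of per-embryo
#'   values.
#' @param mean,sd,n_embryos Optional per-position statistics; derived from
#'   `replicates` when those are given.
#' @return A `dl_profile` object.
#' @export
gradient_profile <- function(values, positions = NULL, normalized = FALSE,
                             replicates = NULL, mean = NULL, sd = NULL,
                             n_embryos = NULL) {
  values <- as.numeric(values)
  k <- length(values)
  if (is.null(positions))
    positions <- seq.int(-floor(k / 2), length.out = k)
  stopifnot(length(positions) == k)
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    stopifnot(nrow(replicates) == k)
    mean <- rowMeans(replicates)
    sd <- apply(replicates, 1, stats::sd)
    n_embryos <- ncol(replicates)
  }
  structure(list(positions = as.integer(positions), values = values,
                 normalized = isTRUE(normalized), replicates = replicates,
                 mean = mean, sd = sd, n_embryos = n_embryos),
            class = "dl_profile")
}

#' @export
print.dl_profile <- function(x, ...) {
  cat("<dl_profile> ", length(x$values), " positions [",
      min(x$positions), "..", max(x$positions), "], ",
      if (x$normalized) "normalized" else "raw",
      if (!is.null(x$n_embryos)) paste0(", ", x$n_embryos, " embryos"),
      "\n", sep = "")
  invisible(x)
}

#' Extract the most-ventral nucleus window
#'
#' Returns the `window` compartments whose centres are angularly closest to
#' the ventral midline, ordered by signed position. With the even default
#' window of 30, positions run -15..+14 (the midline falls between the two
#' centre nuclei; ties at the window edge resolve to the negative side).
#'
#' @param x A `dl_sim` result, or a numeric per-compartment nuclear profile
#'   (compartment 1 at the midline, ring order).
#' @param window Number of ventral nuclei to keep (default 30).
#' @return A `dl_profile` with `window` values.
#' @export
extract_ventral_window <- function(x, window = 30) {
  raw <- if (inherits(x, "dl_sim")) x$raw_nuclear_profile else as.numeric(x)
  n <- length(raw)
  if (window > n)
    stop("window (", window, ") exceeds the number of compartments (", n,
         ")", call. = FALSE)
  pos <- seq.int(-floor(window / 2), length.out = window)
  idx <- (pos %% n) + 1L       # ring wrap: negative positions at the far end
  gradient_profile(raw[idx], positions = pos, normalized = FALSE)
}

#' Normalize a gradient profile
#'
#' Min-max normalization (`method = "minmax"`, the default) maps the window
#' onto \[0, 1\]: `(v - min) / (max - min)`. Peak normalization
#' (`method = "peak"`) divides by the maximum, preserving the baseline; it is
#' the convention used when comparing gradient shapes across nuclear cycles.
#' Both are idempotent.
#'
#' @param profile A `dl_profile` or numeric vector.
#' @param method `"minmax"` or `"peak"`.
#' @return A normalized `dl_profile`.
#' @export
#' @examples
#' normalize_profile(gradient_profile(c(2, 4, 6)))$values  # 0 0.5 1
normalize_profile <- function(profile, method = c("minmax", "peak")) {
  method <- match.arg(method)
  p <- if (inherits(profile, "dl_profile")) profile
       else gradient_profile(profile)
  v <- p$values
  rng <- range(v)
  if (method == "minmax") {
    if (rng[2] <= rng[1])
      stop("cannot min-max normalize a constant profile", call. = FALSE)
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    if (rng[2] <= 0)
      stop("cannot peak-normalize a profile with non-positive maximum",
           call. = FALSE)
    v <- v / rng[2]
  }
  gradient_profile(v, positions = p$positions, normalized = TRUE,
                   replicates = p$replicates)
}

#' Fit distance between two normalized profiles
#'
#' The square root of the sum of squared per-nucleus differences,
#' \eqn{\sqrt{\sum_j (a_j - b_j)^2}} — the Euclidean metric on equal-length
#' profiles.
#'
#' @param sim,ref `dl_profile` objects or numeric vectors of equal length.
#' @return Non-negative fit distance (0 iff identical).
#' @export
#' @examples
#' fit_distance(rep(0, 30), rep(1, 30))  # sqrt(30)
fit_distance <- function(sim, ref) {
  a <- if (inherits(sim, "dl_profile")) sim$values else as.numeric(sim)
  b <- if (inherits(ref, "dl_profile")) ref$values else as.numeric(ref)
  if (length(a) != length(b))
    stop("profiles have different lengths (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Per-position confidence interval for a replicate cohort
#'
#' Student-t interval for the per-position mean:
#' `mean ± qt((1+level)/2, n-1) * sd / sqrt(n)`. Appropriate for the small
#' cohorts (n ≈ 5 embryos) typical of gradient quantifications.
#'
#' @param replicates Matrix (positions × embryos), or a `dl_profile` carrying
#'   replicates.
#' @param level Confidence level in (0, 1); default 0.99.
#' @return List with vectors `mean`, `lower`, `upper` and scalar `level`.
#' @export
confidence_interval <- function(replicates, level = 0.99) {
  if (inherits(replicates, "dl_profile")) replicates <- replicates$replicates
  stopifnot(!is.null(replicates), level > 0, level < 1)
  m <- as.matrix(replicates)
  n <- ncol(m)
  if (n < 2)
    stop("confidence interval needs at least 2 replicate embryos",
         call. = FALSE)
  mu <- rowMeans(m)
  se <- apply(m, 1, stats::sd) / sqrt(n)
  tq <- stats::qt((1 + level) / 2, df = n - 1)
  list(mean = mu, lower = mu - tq * se, upper = mu + tq * se, level = level)
}

#' Compare a simulation against a reference profile
#'
#' Runs the full pipeline — simulate (if given parameters), extract the
#' ventral window, min-max normalize — and scores the result against a
#' normalized reference: fit distance, per-position residuals, and whether
#' each simulated value lies inside the reference confidence interval (when
#' the reference carries replicates).
#'
#' @param sim A `dl_params`, fixture label, `dl_sim`, or `dl_profile`.
#' @param ref A `dl_profile` (normalized, or normalized here); if it carries
#'   replicates, a CI at `level` is computed on per-embryo profiles.
#' @param window Ventral window size (default 30).
#' @param level CI level (default 0.99).
#' @param ... Passed to [simulate_final_cycle()].
#' @return List with `fit`, `residuals`, `sim_profile`, `ref_profile`, and
#'   (with replicates) `inside_ci` and `ci`.
#' @export
compare_profiles <- function(sim, ref, window = 30, level = 0.99, ...) {
  sim_prof <- as_normalized_profile(sim, window, ...)
  ref_prof <- if (inherits(ref, "dl_profile") && ref$normalized) ref
              else normalize_profile(ref)
  fit <- fit_distance(sim_prof, ref_prof)
  res <- sim_prof$values - ref_prof$values
  out <- list(fit = fit, residuals = res, sim_profile = sim_prof,
              ref_profile = ref_prof)
  if (!is.null(ref_prof$replicates)) {
    ci <- confidence_interval(ref_prof$replicates, level)
    out$ci <- ci
    out$inside_ci <- sim_prof$values >= ci$lower & sim_prof$values <= ci$upper
  }
  out
}

as_normalized_profile <- function(x, window = 30, ...) {
  if (is.character(x)) x <- load_parameter_set(x)
  if (inherits(x, "dl_params")) x <- simulate_final_cycle(x, ...)
  if (inherits(x, "dl_sim")) x <- extract_ventral_window(x, window)
  if (!inherits(x, "dl_profile")) x <- gradient_profile(x)
  if (x$normalized) x else normalize_profile(x)
}

#' Read/write gradient profiles as TSV
#'
#' Columns: `position`, `value`, and optionally `sd`, `n`.
#'
#' @param profile A `dl_profile`.
#' @param path TSV file path.
#' @return `write_profile_tsv`: `path` invisibly; `read_profile_tsv`: a
#'   `dl_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(position = profile$positions, value = profile$values)
  if (!is.null(profile$sd)) df$sd <- profile$sd
  if (!is.null(profile$n_embryos)) df$n <- profile$n_embryos
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param normalized Flag recorded on the profile read back.
#' @export
read_profile_tsv <- function(path, normalized = FALSE) {
  df <- utils::read.delim(path)
  gradient_profile(df$value, positions = df$position,
                   normalized = normalized,
                   sd = df$sd, n_embryos = df$n[1])
}
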