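# Pseudo-experimental cohorts. The experimental pipeline this emulates:
# per-embryo nuclear-Dl intensity profiles over the 30 most ventral nuclei,
# ~5 replicate embryos per genotype, each embryo normalized on its own
# window before averaging, reported as mean +/- SD.

#' Generate a synthetic replicate-embryo cohort
#'
#' Each replicate is the base normalized profile plus independent zero-mean
#' Gaussian noise (`sd = noise_sd`), re-normalized per embryo (min-max on its
#' own window), mimicking per-embryo normalization before averaging in
#' experimental quantifications. Noise acts on the final normalized profile
#' only; imaging artifacts are out of scope.
#'
#' @param base A `dl_params`, fixture label, `dl_sim` or profile; reduced to
#'   a normalized ventral-window profile.
#' @param n_embryos Number of replicate embryos (default 5).
#' @param noise_sd Noise standard deviation in normalized units
#'   (default 0.05).
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @param window Ventral window size (default 30).
#' @param renormalize Min-max re-normalize each noisy replicate (default
#'   `TRUE`, matching the experimental per-embryo normalization). `FALSE`
#'   keeps the raw noisy replicates, whose expectation is exactly the base
#'   profile.
#' @return A `dl_cohort`: `profiles` (positions × embryos matrix), `mean`,
#'   `sd`, `base_label`, `noise_sd`, `seed`.
#' @export
#' @examples
#' \donttest{
#' co <- generate_cohort("mel_adjusted", n_embryos = 5, noise_sd = 0.05,
#'                       seed = 1)
#' dim(co$profiles)  # 30 x 5
#' }
generate_cohort <- function(base, n_embryos = 5, noise_sd = 0.05, seed = 1,
                            window = 30, renormalize = TRUE) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  stopifnot(n_embryos >= 1)
  base_prof <- as_normalized_profile(base, window)
  k <- length(base_prof$values)
  profiles <- with_seed(seed, {
    vapply(seq_len(n_embryos), function(i) {
      v <- base_prof$values + stats::rnorm(k, 0, noise_sd)
      if (noise_sd == 0 || !renormalize) return(v)
      (v - min(v)) / (max(v) - min(v))
    }, numeric(k))
  })
  label <- if (is.character(base)) base
           else if (inherits(base, "dl_params")) attr(base, "meta")$label
           else NA_character_
  structure(list(base_label = label, profiles = profiles,
                 positions = base_prof$positions,
                 mean = rowMeans(profiles),
                 sd = apply(profiles, 1, stats::sd),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dl_cohort")
}

#' @export
print.dl_cohort <- function(x, ...) {
  cat("<dl_cohort> base '", x$base_label, "', ", ncol(x$profiles),
      " embryos, noise sd ", x$noise_sd, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Convert a cohort to a gradient profile
#'
#' The cohort mean, min-max normalized over the window (averaging per-embryo
#' normalized replicates compresses their range, so the mean is re-normalized
#' the way published mean curves span 0 to 1), as a `dl_profile` carrying the
#' replicates (so [confidence_interval()] and [compare_profiles()] can use
#' them).
#'
#' @param cohort A `dl_cohort`.
#' @return A `dl_profile`.
#' @export
cohort_profile <- function(cohort) {
  stopifnot(inherits(cohort, "dl_cohort"))
  v <- cohort$mean
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  gradient_profile(v, positions = cohort$positions,
                   normalized = TRUE, replicates = cohort$profiles)
}

# Frozen generation recipe per reference label: best-fit generating fixture
# and a fixed seed. Regenerated deterministically on demand.
REFERENCE_RECIPES <- list(
  wt        = list(fixture = "mel_adjusted", seed = 101L),
  dl_het    = list(fixture = "dl_het_2",     seed = 102L),
  ssm       = list(fixture = "ssm_2",        seed = 103L),
  gyn       = list(fixture = "gyn_3",        seed = 104L),
  busckii   = list(fixture = "bus_3",        seed = 105L),
  simulans  = list(fixture = "sim_5",        seed = 106L),
  sechellia = list(fixture = "sec_5",        seed = 107L),
  yakuba    = list(fixture = "yak_3",        seed = 108L),
  santomea  = list(fixture = "san_3",        seed = 109L)
)

.reference_cache <- new.env(parent = emptyenv())

#' Frozen pseudo-experimental reference profile for a genotype or species
#'
#' A synthetic stand-in for the experimental quantification of each
#' genotype/species: a cohort of 5 replicate embryos generated once from the
#' best-fit packaged fixture for that label with `noise_sd = 0.05` and a
#' fixed per-label seed. Deterministic and stable across calls.
#'
#' @param label One of `wt`, `dl_het`, `ssm`, `gyn`, `busckii`, `simulans`,
#'   `sechellia`, `yakuba`, `santomea`.
#' @return A normalized `dl_profile` with `mean`, `sd`, `n_embryos` and the
#'   replicate matrix.
#' @export
#' @examples
#' \donttest{
#' ref <- reference_profile("wt")
#' ref$n_embryos  # 5
#' }
reference_profile <- function(label) {
  rec <- REFERENCE_RECIPES[[label]]
  if (is.null(rec))
    stop("unknown reference label '", label, "'; available: ",
         paste(names(REFERENCE_RECIPES), collapse = ", "), call. = FALSE)
  if (is.null(.reference_cache[[label]])) {
    cohort <- generate_cohort(rec$fixture, n_embryos = 5, noise_sd = 0.05,
                              seed = rec$seed)
    .reference_cache[[label]] <- cohort_profile(cohort)
  }
  .reference_cache[[label]]
}

#' Write a cohort to TSV files
#'
#' `path` receives the position × embryo replicate matrix; `stats_path`
#' (optional) receives per-position `mean`, `sd`, `n`.
#'
#' @param cohort A `dl_cohort`.
#' @param path Replicate-matrix TSV path.
#' @param stats_path Optional summary TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path, stats_path = NULL) {
  m <- as.data.frame(cohort$profiles)
  names(m) <- paste0("embryo_", seq_len(ncol(m)))
  utils::write.table(cbind(position = cohort$positions, m), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stats_path)) {
    df <- data.frame(position = cohort$positions, mean = cohort$mean,
                     sd = cohort$sd, n = ncol(cohort$profiles))
    utils::write.table(df, stats_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
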