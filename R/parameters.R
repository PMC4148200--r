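#' @useDynLib dlgradient, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# The 19 independent model parameters, in canonical order. Morphology (El, Er,
# Eh, Tn), Toll activation (R, S, xi), kinetics (Gamma, k_i, k_e, P_Cact,
# k_Deg, k_b), onset concentrations (Dl0, DlCact0, Cact0) and final-cycle
# nuclear geometry/timing (r, n, t).
PARAM_FIELDS <- c("El", "Er", "Eh", "Tn", "R", "S", "xi", "Gamma", "k_i",
                  "k_e", "P_Cact", "k_Deg", "k_b", "Dl0", "DlCact0", "Cact0",
                  "r", "n", "t")

#' Construct a model parameter set
#'
#' Bundles the 19 independent parameters of the compartmental Dorsal-gradient
#' model, plus optional species metadata, into a validated `dl_params` object.
#'
#' Lengths are in micrometres, time in minutes; rate constants and
#' concentrations are in model units (per minute, and arbitrary concentration
#' units, respectively).
#'
#' @param El Embryo half-length (µm).
#' @param Er Embryo radius (µm).
#' @param Eh Cortical-layer depth (µm); must satisfy `Eh < Er`.
#' @param Tn Total number of nuclei in the embryo.
#' @param R Toll-activation amplitude of the Dl-Cact dissociation rate.
#' @param S Toll-activation shape parameter.
#' @param xi Toll-activation shape exponent (dimensionless).
#' @param Gamma Inter-compartment transport rate constant applied to the three
#'   cytoplasmic species (per minute).
#' @param k_i,k_e Nuclear import and export rate constants.
#' @param P_Cact Cactus production rate.
#' @param k_Deg Free-Cactus degradation rate constant.
#' @param k_b Dl-Cact binding rate constant.
#' @param Dl0,DlCact0,Cact0 Cytoplasmic concentrations of free Dl, Dl-Cact
#'   complex and free Cact at the onset of the final nuclear cycle.
#' @param r Nuclear radius at the final cycle (µm).
#' @param n Number of nuclei around the dorso-ventral cross-section at the
#'   final cycle.
#' @param t Duration of the final-cycle interphase (minutes).
#' @param species,sna_arc_pct,final_cycle Optional metadata: species label,
#'   mesodermal *sna* percent arc-length (0-50), and last nuclear cycle index
#'   (13, 14 or 15).
#' @param label Optional fixture label.
#'
#' @return A `dl_params` object (named list of the 19 parameters with a
#'   `meta` attribute).
#' @seealso [load_parameter_set()] for the packaged published sets.
#' @export
#' @examples
#' p <- load_parameter_set("mel_adjusted")
#' p$Er
parameter_set <- function(El, Er, Eh, Tn, R, S, xi, Gamma, k_i, k_e, P_Cact,
                          k_Deg, k_b, Dl0, DlCact0, Cact0, r, n, t,
                          species = NA_character_, sna_arc_pct = NA_real_,
                          final_cycle = NA_integer_, label = NA_character_) {
  p <- mget(PARAM_FIELDS)
  p <- lapply(p, function(x) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("every model parameter must be a single finite number",
           call. = FALSE)
    as.numeric(x)
  })
  structure(p,
            meta = list(label = label, species = species,
                        sna_arc_pct = sna_arc_pct,
                        final_cycle = if (is.na(final_cycle)) NA_integer_
                                      else as.integer(final_cycle)),
            class = "dl_params") |> validate_params()
}

validate_params <- function(p) {
  pos <- c("El", "Er", "Eh", "Tn", "r", "n", "t")
  for (f in pos)
    if (p[[f]] <= 0) stop("parameter '", f, "' must be strictly positive",
                          call. = FALSE)
  nonneg <- c("R", "S", "xi", "Gamma", "k_i", "k_e", "P_Cact", "k_Deg",
              "k_b", "Dl0", "DlCact0", "Cact0")
  for (f in nonneg)
    if (p[[f]] < 0) stop("parameter '", f, "' must be non-negative",
                         call. = FALSE)
  if (p$Eh >= p$Er)
    stop("cortical depth Eh must be smaller than embryo radius Er",
         call. = FALSE)
  m <- attr(p, "meta")
  if (!is.na(m$sna_arc_pct) && (m$sna_arc_pct <= 0 || m$sna_arc_pct >= 50))
    stop("sna_arc_pct must lie in (0, 50)", call. = FALSE)
  if (!is.na(m$final_cycle) && !m$final_cycle %in% 13:15)
    stop("final_cycle must be 13, 14 or 15", call. = FALSE)
  p
}

#' @export
print.dl_params <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<dl_params>",
      if (!is.na(m$label)) paste0(" '", m$label, "'") else "",
      if (!is.na(m$species)) paste0(" [", m$species, "]") else "",
      "\n", sep = "")
  print(unlist(x))
  invisible(x)
}

fixture_dir <- function() {
  system.file("extdata", "parameter_sets", package = "dlgradient",
              mustWork = TRUE)
}

#' List the packaged parameter-set fixtures
#'
#' @return Character vector of fixture labels accepted by
#'   [load_parameter_set()].
#' @export
list_parameter_sets <- function() {
  sort(sub("\\.yaml$", "", list.files(fixture_dir(), pattern = "\\.yaml$")))
}

#' Load a packaged or user-supplied parameter set
#'
#' Packaged fixtures carry the published parameter vectors for
#' *D. melanogaster* wild type (`mel_original`, `mel_adjusted`), dosage and
#' ploidy mutants (`dl_het_1/2`, `ssm_1/2`, `gyn_1..3`) and six species
#' (`bus_1..3`, `sim_1..5`, `sec_1..5`, `yak_1..4`, `san_1..4`).
#'
#' @param name Fixture label (see [list_parameter_sets()]), or a path to a
#'   YAML/JSON file in the same schema (keys are the parameter field names).
#' @return A `dl_params` object.
#' @export
#' @examples
#' gyn <- load_parameter_set("gyn_3")
#' gyn$Er  # 117
load_parameter_set <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  path <- if (file.exists(name) && grepl("[/\\\\.]", name)) name
          else file.path(fixture_dir(), paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown parameter set '", name, "'; packaged fixtures are: ",
         paste(list_parameter_sets(), collapse = ", "), call. = FALSE)
  doc <- if (grepl("\\.json$", path)) jsonlite_read(path)
         else yaml::read_yaml(path)
  missing <- setdiff(PARAM_FIELDS, names(doc))
  if (length(missing))
    stop("parameter file '", path, "' is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(parameter_set, c(
    doc[PARAM_FIELDS],
    list(species = doc$species %||% NA_character_,
         sna_arc_pct = doc$sna_arc_pct %||% NA_real_,
         final_cycle = doc$final_cycle %||% NA_integer_,
         label = doc$label %||% sub("\\.(yaml|json)$", "", basename(path)))))
}

jsonlite_read <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading JSON parameter files requires the 'jsonlite' package",
         call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a parameter set to YAML
#'
#' Inverse of [load_parameter_set()]: the written file reloads to a
#' field-identical set.
#'
#' @param params A `dl_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "dl_params"))
  m <- attr(params, "meta")
  doc <- c(list(label = m$label, species = m$species,
                sna_arc_pct = m$sna_arc_pct, final_cycle = m$final_cycle),
           unclass(params))
  doc <- doc[!vapply(doc, function(x) length(x) == 1 && is.na(x), logical(1))]
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Modify fields of a parameter set
#'
#' @param params A `dl_params` object.
#' @param ... Named parameter overrides, e.g. `k_Deg = 4, Dl0 = 18`.
#' @return A revalidated `dl_params` object.
#' @export
#' @examples
#' dl_het <- set_params(load_parameter_set("mel_adjusted"),
#'                      k_Deg = 4, Dl0 = 18, DlCact0 = 15)
set_params <- function(params, ...) {
  stopifnot(inherits(params, "dl_params"))
  ov <- list(...)
  bad <- setdiff(names(ov), PARAM_FIELDS)
  if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         "; valid fields are: ", paste(PARAM_FIELDS, collapse = ", "),
         call. = FALSE)
  for (f in names(ov)) params[[f]] <- as.numeric(ov[[f]])
  validate_params(params)
}

#' Space-dependent Toll-driven Dl-Cact dissociation rate
#'
#' The Toll receptor activation gradient is represented solely by the
#' dissociation rate constant of the cytoplasmic Dl-Cact complex,
#' \eqn{k_D(\theta) = R \exp(-S \, |\theta/\pi|^{\xi})}, an even function of
#' the angle from the ventral midline that peaks at \eqn{\theta = 0} with
#' amplitude `R`, decays monotonically towards the dorsal midline, and whose
#' spatial range is governed by `S` and `xi`.
#'
#' @param theta Angular position(s) from the ventral midline, radians, in
#'   \eqn{[-\pi, \pi]}.
#' @param R Amplitude (maximum dissociation rate, per minute).
#' @param S Shape parameter (decay strength).
#' @param xi Shape exponent.
#' @return Numeric vector of dissociation rates, same length as `theta`.
#' @export
#' @examples
#' toll_dissociation_rate(0, R = 15000, S = 4000, xi = 2.5)  # = R
toll_dissociation_rate <- function(theta, R, S, xi) {
  if (R < 0 || S < 0)
    stop("Toll activation parameters R and S must be non-negative",
         call. = FALSE)
  if (any(abs(theta) > pi + 1e-12))
    stop("theta must lie within [-pi, pi]", call. = FALSE)
  R * exp(-S * abs(theta / pi)^xi)
}

#' Rescale the Toll amplitude by mesodermal arc-length
#'
#' Assuming the Toll activation amplitude `R` is linear in the percent
#' arc-length of the mesodermal *sna* domain, the species value is
#' `R_base * arc_species_pct / arc_base_pct`, truncated to an integer.
#'
#' @param R_base Baseline amplitude (e.g. 15000 for *D. melanogaster*).
#' @param arc_base_pct Baseline mesodermal arc-length, percent (> 0).
#' @param arc_species_pct Species mesodermal arc-length, percent (> 0).
#' @return Integer adjusted amplitude.
#' @export
#' @examples
#' scale_R_by_arclength(15000, 21, 17)  # 12142 (D. busckii)
#' scale_R_by_arclength(15000, 21, 27)  # 19285 (D. simulans)
#' scale_R_by_arclength(15000, 21, 26)  # 18571 (D. sechellia)
scale_R_by_arclength <- function(R_base, arc_base_pct, arc_species_pct) {
  if (arc_base_pct <= 0)
    stop("arc_base_pct must be strictly positive", call. = FALSE)
  if (R_base <= 0 || arc_species_pct <= 0)
    stop("R_base and arc_species_pct must be strictly positive",
         call. = FALSE)
  as.integer(trunc(R_base * arc_species_pct / arc_base_pct))
}

#' Sample random parameter sets within bounds
#'
#' Draws each parameter independently and uniformly within per-parameter
#' bounds, emulating random sampling within a published parameter-cloud range.
#' Unbounded fields are held at the values of `base`.
#'
#' @param ranges Named list of `c(low, high)` bounds; names must be parameter
#'   fields.
#' @param count Number of sets to draw.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param base Template `dl_params` supplying fields absent from `ranges`
#'   (default `mel_adjusted`).
#' @return A list of `count` `dl_params` objects.
#' @export
#' @examples
#' draws <- sample_parameter_sets(list(k_Deg = c(0.3, 5), k_b = c(0.005, 0.05)),
#'                                count = 3, seed = 1)
sample_parameter_sets <- function(ranges, count, seed,
                                  base = load_parameter_set("mel_adjusted")) {
  stopifnot(is.list(ranges), count >= 0)
  bad <- setdiff(names(ranges), PARAM_FIELDS)
  if (length(bad))
    stop("unknown parameter name(s) in ranges: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (f in names(ranges)) {
    rg <- ranges[[f]]
    if (length(rg) != 2L || rg[1] > rg[2])
      stop("range for '", f, "' must be c(low, high) with low <= high",
           call. = FALSE)
  }
  count <- as.integer(count)
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      ov <- lapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]))
      do.call(set_params, c(list(base), ov))
    })
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
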