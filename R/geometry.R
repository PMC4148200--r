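#' Build the ring compartment geometry for an embryo cross-section
#'
#' The cortical layer of the syncytial embryo is modeled as an annular
#' cylindrical shell (length `2*El`, outer radius `Er`, inner radius
#' `Er - Eh`) partitioned into `Tn` equal compartments, `n` of which form one
#' full dorso-ventral ring of circular trapezoids. Each compartment holds one
#' spherical nucleus of radius `r`.
#'
#' Compartment `j` (0-based index, stored 1-based in R vectors) is centred at
#' angle `theta_j = j * 2*pi/n` from the ventral midline, wrapped to
#' `(-pi, pi]`, so compartment 1 sits exactly on the midline and the ring is
#' periodic (compartment `n` is adjacent to compartment 1).
#'
#' @param params A `dl_params` object.
#' @return A `dl_geometry` list with elements `n_compartments`, `delta_theta`,
#'   `theta` (signed centre angles), `V_comp`, `V_nuc`, `A_nuc`, `V_cyt`
#'   (µm³ / µm²), and `w_arc`, the compartment arc width at mid-cortex radius
#'   `Er - Eh/2` (µm).
#' @export
#' @examples
#' g <- build_geometry(load_parameter_set("mel_adjusted"))
#' g$n_compartments   # 92
#' g$delta_theta      # 2*pi/92
build_geometry <- function(params) {
  stopifnot(inherits(params, "dl_params"))
  n <- as.integer(round(params$n))
  if (n < 3) stop("need at least 3 compartments on the ring", call. = FALSE)
  if (params$Eh >= params$Er)
    stop("cortical depth Eh must be smaller than embryo radius Er",
         call. = FALSE)
  shell <- 2 * params$El * pi * (params$Er^2 - (params$Er - params$Eh)^2)
  V_comp <- shell / params$Tn
  V_nuc <- 4 / 3 * pi * params$r^3
  if (V_nuc >= V_comp)
    stop("nucleus larger than compartment (V_nuc = ", signif(V_nuc, 6),
         " >= V_comp = ", signif(V_comp, 6), " um^3)", call. = FALSE)
  delta_theta <- 2 * pi / n
  theta <- (seq_len(n) - 1L) * delta_theta
  theta <- ifelse(theta > pi, theta - 2 * pi, theta)
  structure(list(
    n_compartments = n,
    delta_theta = delta_theta,
    theta = theta,
    V_comp = V_comp,
    V_nuc = V_nuc,
    A_nuc = 4 * pi * params$r^2,
    V_cyt = V_comp - V_nuc,
    w_arc = delta_theta * (params$Er - params$Eh / 2)
  ), class = "dl_geometry")
}

#' @export
print.dl_geometry <- function(x, ...) {
  cat("<dl_geometry> ", x$n_compartments, " compartments, V_comp = ",
      signif(x$V_comp, 6), " um^3, V_nuc = ", signif(x$V_nuc, 6),
      " um^3\n", sep = "")
  invisible(x)
}

#' Number of ring nuclei at an earlier nuclear cycle
#'
#' Nuclei double at each cleavage division, so the count along any one axis
#' grows by a factor of sqrt(2) per cycle. Going backwards from the final
#' cycle, `round(n_final * 2^(-(final_cycle - cycle)/2))`.
#'
#' @param n_final Ring nucleus count at the final cycle.
#' @param cycle Queried nuclear cycle index (≤ `final_cycle`).
#' @param final_cycle Final nuclear cycle index.
#' @return Integer nucleus count at `cycle`.
#' @export
#' @examples
#' nuclei_at_cycle(92, 10, 14)  # 23
#' nuclei_at_cycle(100, 13, 14) # 71
nuclei_at_cycle <- function(n_final, cycle, final_cycle) {
  if (any(cycle > final_cycle))
    stop("cycle must not exceed final_cycle", call. = FALSE)
  stopifnot(n_final >= 1)
  as.integer(round(n_final * 2^(-(final_cycle - cycle) / 2)))
}

#' Default per-cycle nuclear radius anchors
#'
#' Anchor radii interpolate linearly in time from `0.75 * r_final` at the
#' start of nc10 to `r_final` at the end of the final cycle. The final-cycle
#' gradient shape is insensitive to the early-cycle radii, so the defaults
#' only need plausibility; pass explicit anchors to override.
#'
#' @param r_final Final-cycle nuclear radius (µm).
#' @param start_cycle,final_cycle First and last simulated nuclear cycles.
#' @return Data frame with columns `cycle`, `r_start`, `r_end`.
#' @export
default_radius_profile <- function(r_final, start_cycle = 10,
                                   final_cycle = 14) {
  cycles <- start_cycle:final_cycle
  k <- length(cycles)
  anchors <- seq(0.75 * r_final, r_final, length.out = k + 1)
  data.frame(cycle = cycles, r_start = anchors[-(k + 1)], r_end = anchors[-1])
}

#' Nuclear radius at a time within a cycle's interphase
#'
#' Piecewise-linear interpolation between the cycle-start and cycle-end anchor
#' radii of `profile`. With `profile = NULL` ("constant" mode) returns
#' `r_const` at all times.
#'
#' @param time Minutes into the interphase.
#' @param cycle Nuclear cycle index.
#' @param profile Data frame as returned by [default_radius_profile()], or
#'   `NULL` for constant mode.
#' @param interphase Interphase duration of that cycle (minutes); required
#'   when `profile` is given.
#' @param r_const Radius returned in constant mode.
#' @return Nuclear radius (µm).
#' @export
nuclear_radius_at <- function(time, cycle, profile = NULL, interphase = NULL,
                              r_const = NULL) {
  if (is.null(profile)) {
    if (is.null(r_const)) stop("constant mode needs r_const", call. = FALSE)
    return(rep_len(r_const, length(time)))
  }
  stopifnot(!is.null(interphase))
  if (any(time < 0 | time > interphase + 1e-9))
    stop("time outside the interphase [0, ", interphase, "]", call. = FALSE)
  row <- profile[profile$cycle == cycle, ]
  if (nrow(row) != 1L)
    stop("radius profile has no anchors for cycle ", cycle, call. = FALSE)
  row$r_start + (row$r_end - row$r_start) * pmin(time / interphase, 1)
}

#' Write a geometry table to TSV
#'
#' One row per compartment: index (0-based), centre angle, compartment,
#' nuclear and cytoplasmic volumes and nuclear surface area.
#'
#' @param geom A `dl_geometry` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_geometry_tsv <- function(geom, path) {
  df <- data.frame(index = seq_len(geom$n_compartments) - 1L,
                   theta = geom$theta,
                   V_comp = geom$V_comp, V_nuc = geom$V_nuc,
                   A_nuc = geom$A_nuc, V_cyt = geom$V_cyt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
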