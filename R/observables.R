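#' Map from species trajectories to instrument signals
#'
#' FP (mP), anisotropy and in-cell ratio signals are modelled as affine in
#' the bound fraction of the fluorophore: the free substrate contributes
#' `r_free`, a fully bound/labeled fluorophore pool contributes `r_bound`.
#' Which species count as "bound" depends on the scheme: `PS` for the
#' direct scheme, `PSstar` and `PS` for the two-step scheme (a non-covalent
#' complex already tumbles slowly, so it is polarized like the product),
#' and `PI` for the competition scheme, where only the reporter is
#' fluorescent.
#'
#' @param r_free Signal of the unbound fluorescent substrate (mP or
#'   anisotropy units).
#' @param r_bound Signal of the bound/labeled substrate. A value below
#'   `r_free` is unusual for a polarization assay and triggers a warning
#'   (but is not an error).
#' @param bound_species Character vector of trajectory columns counted as
#'   bound.
#' @param r_free_fixed Logical; whether `r_free` was measured (e.g. from a
#'   zero-protein baseline) and should be held fixed in fits.
#' @return A list of class `slk_observable_map`.
#' @examples
#' observable_map(60, 220)                      # plate-reader FP
#' observable_map(0.05, 0.19, c("PSstar", "PS")) # stopped-flow anisotropy
#' @export
observable_map <- function(r_free, r_bound, bound_species = "PS",
                           r_free_fixed = TRUE) {
  stopifnot(is.numeric(r_free), is.numeric(r_bound),
            length(r_free) == 1L, length(r_bound) == 1L,
            is.character(bound_species), length(bound_species) >= 1L)
  if (r_bound < r_free)
    warning("r_bound < r_free: signal decreases upon binding")
  structure(list(r_free = as.numeric(r_free), r_bound = as.numeric(r_bound),
                 bound_species = bound_species,
                 r_free_fixed = isTRUE(r_free_fixed)),
            class = "slk_observable_map")
}

#' Convert a species trajectory to an instrument signal trace
#'
#' `signal(t) = r_free + (r_bound - r_free) * bound(t) / fluor_total`,
#' where `bound(t)` is the summed concentration of the map's bound species
#' and `fluor_total` is the total fluorophore concentration. When protein
#' is limiting, only part of the fluorophore is ever bound, which lowers
#' the final plateau — the feature that makes the substrate concentration
#' identifiable in global fits.
#'
#' @param traj An `slk_trajectory` (from the `simulate_*` functions).
#' @param map An [observable_map()].
#' @param fluor_total Total fluorophore concentration (M); defaults to the
#'   fluorescent species' initial concentration recorded in the trajectory
#'   (`S0`, or `I0` when the bound species is `PI`).
#' @param ... Annotations passed on to [trace()] (`trace_id`, `kind`, ...).
#' @return An [trace()] object.
#' @export
trajectory_to_signal <- function(traj, map, fluor_total = NULL, ...) {
  stopifnot(inherits(traj, "slk_trajectory"),
            inherits(map, "slk_observable_map"))
  missing_sp <- setdiff(map$bound_species, names(traj))
  if (length(missing_sp))
    stop("bound species not in trajectory: ",
         paste(missing_sp, collapse = ", "))
  ic <- attr(traj, "ic")
  if (is.null(fluor_total))
    fluor_total <- if (identical(map$bound_species, "PI")) ic$I0 else ic$S0
  if (!is.numeric(fluor_total) || fluor_total <= 0)
    stop("'fluor_total' must be > 0")
  bound <- rowSums(as.data.frame(traj)[, map$bound_species, drop = FALSE])
  sig <- map$r_free + (map$r_bound - map$r_free) * bound / fluor_total
  args <- list(...)
  # in the competition scheme the fluorescent species is the reporter I;
  # the trace's substrate_conc annotation always names the fluorophore
  defaults <- if (identical(map$bound_species, "PI"))
    list(protein_conc = ic$P0, substrate_conc = ic$I0,
         competitor_conc = ic$S0)
  else
    list(protein_conc = ic$P0, substrate_conc = ic$S0,
         competitor_conc = ic$I0)
  args <- modifyList(defaults, args)
  do.call(trace, c(list(time = traj$time, signal = sig), args))
}
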