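# Equilibrium bulk-water sampling: a rigid-body Metropolis Monte Carlo
# sampler for TIP4P/2005 water (Lennard-Jones on oxygen, charges on the two
# hydrogens and the planar M site, molecule-based spherical truncation on
# the O-O distance), run in the NVT ensemble at the model's 1-bar density.

# TIP4P/2005 liquid densities at 1 bar (g/cm^3), interpolated linearly
.TIP4P2005_RHO <- data.frame(
  t = c(250, 260, 272, 278, 298, 313, 323, 340),
  rho = c(0.9910, 0.9970, 0.9994, 1.0000, 0.9977, 0.9925, 0.9882, 0.9790))

#' 1-bar liquid density of TIP4P/2005 water
#'
#' @param temperature Temperature in K.
#' @return Density in g/cm^3 (linear interpolation of tabulated
#'   equation-of-state values).
#' @export
tip4p2005_density <- function(temperature) {
  stats::approx(.TIP4P2005_RHO$t, .TIP4P2005_RHO$rho, xout = temperature,
                rule = 2)$y
}

#' Sample equilibrium bulk TIP4P/2005 water by Monte Carlo
#'
#' Starts from a jittered-lattice box ([build_water_box()]) at the model's
#' 1-bar density for the requested temperature, equilibrates with
#' single-molecule translation/rotation moves (amplitudes auto-tuned toward
#' ~40% acceptance during the first half of equilibration, then frozen),
#' and records configurations every `sample_every` sweeps of the production
#' phase.
#'
#' @param n_molecules Number of molecules (default 360).
#' @param temperature Temperature in K.
#' @param density Mass density in g/cm^3; the model's 1-bar value for
#'   `temperature` when `NULL`.
#' @param n_equil,n_production Equilibration / production sweeps (one sweep
#'   is one attempted move per molecule).
#' @param sample_every Sampling stride in sweeps.
#' @param cutoff Molecule-based O-O truncation cutoff in nm (default 0.9).
#' @param seed Integer seed.
#' @return An [ensemble()] of water configurations with attributes
#'   `energy_trace` (kJ/mol per molecule, every 10 sweeps) and
#'   `acceptance`.
#' @export
simulate_bulk_water <- function(n_molecules = 360, temperature = 298,
                                density = NULL, n_equil = 1500,
                                n_production = 1000, sample_every = 50,
                                cutoff = 0.9, seed = 1) {
  if (is.null(density)) density <- tip4p2005_density(temperature)
  wb <- build_water_box(n_molecules, density = density, seed = seed)
  if (cutoff > min(wb$frame$box) / 2) {
    stop(sprintf(
      "cutoff %.2f nm exceeds half the box edge (%.2f nm); use more molecules",
      cutoff, min(wb$frame$box) / 2))
  }
  wmol <- water_molecules(wb$topology)
  o <- wb$frame$coords[wmol[, "O"], , drop = FALSE]
  h1 <- wb$frame$coords[wmol[, "H1"], , drop = FALSE] - o
  h2 <- wb$frame$coords[wmol[, "H2"], , drop = FALSE] - o
  out <- cpp_water_mc(o, h1, h2, wb$frame$box, temperature, cutoff,
                      as.integer(n_equil), as.integer(n_production),
                      as.integer(sample_every), as.integer(seed),
                      0.012, 0.25)
  if (!length(out$frames)) stop("no frames sampled; increase n_production")
  frames <- lapply(seq_along(out$frames), function(k) {
    frame(out$frames[[k]], wb$frame$box, time = k - 1)
  })
  ens <- ensemble(wb$topology, frames)
  attr(ens, "energy_trace") <- out$energy_trace
  attr(ens, "acceptance") <- out$acceptance
  ens
}

#' Mean hydrogen bonds per molecule in bulk water
#'
#' Donated-plus-accepted hydrogen bonds per water molecule (every bond
#' increments both partners), averaged over molecules and frames under the
#' given geometric criterion.
#'
#' @param ens A water [ensemble()] (no protein needed; all molecules count
#'   as bulk).
#' @param criterion An [hbond_criterion()].
#' @return Mean hydrogen bonds per molecule.
#' @export
bulk_water_hbonds <- function(ens, criterion = hbond_criterion()) {
  hydration_report(ens, criterion)$hb_bulk
}
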