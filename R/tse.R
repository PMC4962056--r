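# Transition-state-ensemble sampling: a C-alpha native-centric (Go-type)
# model annealed under a per-conformation Phi-value restraint.  Structures
# sampled at the low reference temperature at the end of each annealing
# cycle are retained as the TSE.

#' Go-model force-field parameters
#'
#' @param k_bond Bond stiffness, kJ/mol/nm^2.
#' @param k_angle Angle stiffness, kJ/mol/rad^2.
#' @param k_dihedral 1-cos dihedral amplitude, kJ/mol.
#' @param epsilon Native-contact well depth per native atom-pair contact,
#'   kJ/mol (a residue pair with w atom pairs gets a well of depth
#'   `w * epsilon`).
#' @param eps_rep,sigma_rep Non-native excluded-volume strength (kJ/mol)
#'   and radius (nm).
#' @param formed_factor A residue-pair contact counts as formed when the
#'   bead distance is within `formed_factor` times the native distance.
#' @param lambda Width (nm) of the logistic switching function used for the
#'   formed-ness inside the Phi restraint (reported Q and Phi always use
#'   the hard cutoff); gives intermediate Phi targets a usable gradient.
#' @param step_xyz,step_crank Monte Carlo move amplitudes (nm, rad), tuned
#'   for roughly 40% acceptance at the low reference temperature.
#' @return Named list of parameters.
#' @export
go_params <- function(k_bond = 2000, k_angle = 40, k_dihedral = 1,
                      epsilon = 6, eps_rep = 1, sigma_rep = 0.40,
                      formed_factor = 1.2, lambda = 0.025,
                      step_xyz = 0.025, step_crank = 0.6) {
  list(k_bond = k_bond, k_angle = k_angle, k_dihedral = k_dihedral,
       epsilon = epsilon, eps_rep = eps_rep, sigma_rep = sigma_rep,
       formed_factor = formed_factor, lambda = lambda,
       step_xyz = step_xyz, step_crank = step_crank, k_phi = 0)
}

#' Build a C-alpha Go-type model from a native structure
#'
#' One bead per residue at the C-alpha position; harmonic bonds, angles and
#' 1-cos dihedrals reproduce the native internal coordinates, and every
#' residue pair of the native-contact map receives an attractive 12-10 well
#' at the native bead distance with depth proportional to its native
#' atom-pair count.
#'
#' @param native List with `topology` and `frame`.
#' @param map A [native_contacts()] map of the same structure.
#' @param params A [go_params()] list.
#' @return Object of class `"go_model"`.
#' @export
build_go_model <- function(native, map, params = go_params()) {
  top <- native$topology
  a <- top$atoms
  res <- residue_table(top)
  res <- res[res$segment == "protein", , drop = FALSE]
  ca <- vapply(res$resid, function(r) {
    k <- which(a$resid == r & a$name == "CA")
    if (!length(k)) stop(sprintf("residue %d has no C-alpha atom", r))
    k[1]
  }, integer(1))
  coords <- native$frame$coords[ca, , drop = FALSE]
  bead_of <- match(map$residue_pairs$res_i, res$resid)
  bead_j <- match(map$residue_pairs$res_j, res$resid)
  rnat <- sqrt(rowSums((coords[bead_of, , drop = FALSE] -
                          coords[bead_j, , drop = FALSE])^2))
  structure(list(coords = coords, resid = res$resid,
                 resname = res$resname,
                 contacts = cbind(i = bead_of, j = bead_j),
                 rnat = rnat, weight = map$residue_pairs$n_pairs,
                 params = params),
            class = "go_model")
}

#' Go-model potential energy of a conformation
#'
#' @param model A [build_go_model()] model.
#' @param coords Bead coordinates (defaults to the model's native coords).
#' @return Energy in kJ/mol.
#' @export
go_energy <- function(model, coords = model$coords) {
  cpp_go_energy(model$coords, as.matrix(coords),
                matrix(as.integer(model$contacts - 1L), ncol = 2),
                model$rnat, as.numeric(model$weight), model$params)
}

#' Simulated-annealing schedule
#'
#' Each cycle ramps the temperature linearly from `t_high` down to `t_low`;
#' the conformation at the end of each cycle (sampled at `t_low`) is
#' retained, so the ensemble size equals `n_cycles`.
#'
#' @param n_cycles Number of annealing cycles (default 300).
#' @param steps_per_cycle Monte Carlo sweeps per cycle (default 5000; a
#'   sweep is one attempted move per bead).
#' @param t_low,t_high Temperature bounds in K.
#' @param restart_native Start every cycle from the native conformation
#'   (default), making the retained structures independent anneals; with
#'   `FALSE` each cycle continues from the previous one.
#' @return Named list.
#' @export
annealing_schedule <- function(n_cycles = 300, steps_per_cycle = 5000,
                               t_low = 272, t_high = 500,
                               restart_native = TRUE) {
  stopifnot(t_high > t_low, t_low > 0, n_cycles >= 1, steps_per_cycle >= 1)
  list(n_cycles = as.integer(n_cycles),
       steps_per_cycle = as.integer(steps_per_cycle),
       t_low = t_low, t_high = t_high,
       restart_native = isTRUE(restart_native))
}

#' Phi-restrained simulated annealing of a transition-state ensemble
#'
#' Metropolis Monte Carlo on the Go model with total energy
#' `E_go + k * sum_valid (Phi_i(conformation) - Phi_exp_i)^2`, annealed
#' between `t_high` and `t_low` each cycle; the per-conformation Phi of a
#' residue is the weighted fraction of its native residue-pair contacts
#' formed.  Experimental Phi-values outside `[0, 1]` (or flagged invalid)
#' are not restrained.
#'
#' @param model A [build_go_model()] model.
#' @param phi_exp A [phi_set()] of experimental Phi-values over the model's
#'   residues.
#' @param k Restraint constant in kJ/mol (default 50).
#' @param schedule An [annealing_schedule()].
#' @param seed Integer seed (the sampler is deterministic given the seed).
#' @return Object of class `"tse_result"`: `conformations` (an [ensemble()]
#'   of C-alpha beads), `q_values`, `phi_sim` (a [phi_set()], mean over
#'   retained conformations), `energy_trace` (per-cycle Go and restraint
#'   energies) and `acceptance`.
#' @export
anneal <- function(model, phi_exp, k = 50,
                   schedule = annealing_schedule(), seed = 1) {
  pe <- as.data.frame(phi_exp)
  pv <- rep(NA_real_, nrow(model$coords))
  m <- match(model$resid, pe$residue)
  ok <- !is.na(m) & pe$valid[m] & !is.na(pe$phi[m]) &
    pe$phi[m] >= 0 & pe$phi[m] <= 1
  pv[ok] <- pe$phi[m[ok]]
  if (!any(ok)) stop("phi_exp has no valid residue on this model")
  params <- model$params
  params$k_phi <- k
  out <- cpp_go_anneal(model$coords,
                       matrix(as.integer(model$contacts - 1L), ncol = 2),
                       model$rnat, as.numeric(model$weight), pv, params,
                       schedule$n_cycles, schedule$steps_per_cycle,
                       schedule$t_low, schedule$t_high, as.integer(seed),
                       isTRUE(schedule$restart_native))
  n10 <- max(3L, ceiling(0.1 * schedule$n_cycles))
  if (schedule$n_cycles >= 2 * n10) {
    a <- mean(out$e_phi[seq_len(n10)])
    b <- mean(out$e_phi[(schedule$n_cycles - n10 + 1):schedule$n_cycles])
    if (is.finite(a) && is.finite(b) && b > 1.2 * a + max(0.5, 0.01 * k)) {
      warning(sprintf(
        "restraint energy not decreasing (first %d cycles: %.3g, last %d: %.3g kJ/mol); consider more cycles or a larger k",
        n10, a, n10, b))
    }
  }
  # C-alpha bead topology for the retained conformations
  res <- model$resid
  top <- topology(name = rep("CA", length(res)), resid = res,
                  resname = model$resname, element = rep("C", length(res)))
  box <- apply(do.call(rbind, lapply(out$frames, function(f)
    apply(f, 2, max))), 2, max) + 2
  frames <- lapply(seq_along(out$frames), function(i) {
    f <- out$frames[[i]]
    frame(f - matrix(apply(f, 2, min) - 1, nrow(f), 3, byrow = TRUE),
          box, time = i - 1)
  })
  phi_mean <- colMeans(out$phi_sim)
  structure(list(
    conformations = ensemble(top, frames),
    q_values = out$q,
    phi_sim = phi_set(res, phi_mean, valid = !is.na(phi_mean)),
    energy_trace = data.frame(cycle = seq_len(schedule$n_cycles),
                              e_go = out$e_go, e_phi = out$e_phi),
    acceptance = out$acceptance), class = "tse_result")
}

#' @export
print.tse_result <- function(x, ...) {
  cat(sprintf(
    "TSE: %d retained conformations, mean Q = %.3f (sd %.3f), acceptance %.2f\n",
    length(x$q_values), mean(x$q_values), sd(x$q_values), x$acceptance))
  invisible(x)
}
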