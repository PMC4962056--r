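# Water-structure analyses: geometric hydrogen-bond detection with
# water-water / water-protein / protein-protein bookkeeping, first-shell
# (interface) vs bulk water classification, the unnormalised water-protein
# RDF, and the rotational-anisotropy profile <3cos^2(theta) - 1> * RDF(r)
# with its absolute integral.

#' Geometric hydrogen-bond criterion
#'
#' A donor-acceptor pair is hydrogen bonded when the donor-acceptor
#' minimum-image distance is at most `max_da_distance` and the
#' hydrogen-donor-acceptor angle is at most `max_hda_angle` for one of the
#' donor's hydrogens.  The defaults (0.35 nm, 30 degrees) are the common
#' MD-analysis convention; both are configurable.
#'
#' @param max_da_distance Donor-acceptor cutoff in nm.
#' @param max_hda_angle H-donor-acceptor cutoff in degrees, in (0, 90).
#' @return Object of class `"hbond_criterion"`.
#' @export
hbond_criterion <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  stopifnot(max_da_distance > 0, max_hda_angle > 0, max_hda_angle < 90)
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criterion")
}

# covalent H attachment distance (nm) used to pair hydrogens with donors
.H_BOND_LENGTH <- 0.125

# donor (heavy, hydrogen) pairs and acceptor atoms for one frame.
# Water oxygens donate via their two hydrogens and accept; protein N/O/S
# atoms donate when they carry a bound hydrogen and accept when they do not.
.hbond_sites <- function(fr, top) {
  a <- top$atoms
  if (!any(a$element == "H")) {
    stop("topology has no hydrogens; hydrogen-bond detection needs ",
         "all-atom input")
  }
  wmol <- water_molecules(top)
  dh <- NULL
  if (nrow(wmol)) {
    dh <- rbind(cbind(wmol[, "O"], wmol[, "H1"]),
                cbind(wmol[, "O"], wmol[, "H2"]))
  }
  acc <- wmol[, "O"]
  prot <- which(a$segment == "protein")
  if (length(prot)) {
    ph <- prot[a$element[prot] == "H"]
    pheavy <- prot[a$element[prot] %in% c("N", "O", "S")]
    has_h <- rep(FALSE, length(pheavy))
    if (length(ph) && length(pheavy)) {
      for (h in ph) {
        d <- min_image_distance(fr, rep(h, length(pheavy)), pheavy)
        k <- which.min(d)
        if (d[k] <= .H_BOND_LENGTH) {
          dh <- rbind(dh, c(pheavy[k], h))
          has_h[k] <- TRUE
        }
      }
    }
    acc <- c(acc, pheavy[!has_h])
  }
  list(dh = dh, acc = acc)
}

#' Detect hydrogen bonds in a frame
#'
#' @param fr A [frame()].
#' @param top The matching [topology()] (hydrogens required).
#' @param criterion An [hbond_criterion()].
#' @return Data frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (atom indices) and `category` (`"ww"`, `"wp"` or `"pp"`).
#' @export
detect_hbonds <- function(fr, top, criterion = hbond_criterion()) {
  s <- .hbond_sites(fr, top)
  if (is.null(s$dh) || !nrow(s$dh)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), category = character(0)))
  }
  hb <- cpp_hbonds(fr$coords, fr$box,
                   matrix(as.integer(s$dh - 1L), ncol = 2),
                   as.integer(s$acc - 1L),
                   criterion$max_da_distance, criterion$max_hda_angle)
  seg <- top$atoms$segment
  d <- hb[, 1] + 1L; h <- hb[, 2] + 1L; acp <- hb[, 3] + 1L
  dw <- seg[d] == "water"; aw <- seg[acp] == "water"
  category <- ifelse(dw & aw, "ww", ifelse(!dw & !aw, "pp", "wp"))
  data.frame(donor = d, hydrogen = h, acceptor = acp, category = category,
             stringsAsFactors = FALSE)
}

#' Partition water molecules into interface and bulk
#'
#' A water molecule is interface water when its oxygen lies within
#' `shell_cutoff` (minimum image) of the nearest protein heavy atom,
#' bulk water otherwise.  With no protein atoms all waters are bulk.
#'
#' @param fr A [frame()].
#' @param top The matching [topology()].
#' @param shell_cutoff First-shell cutoff in nm (default 0.4).
#' @return List with integer vectors `interface` and `bulk` (row indices
#'   into `water_molecules(top)`) and the `molecules` matrix itself.
#' @export
classify_waters <- function(fr, top, shell_cutoff = 0.4) {
  wmol <- water_molecules(top)
  heavy <- protein_heavy_atoms(top)
  if (!nrow(wmol)) {
    return(list(interface = integer(0), bulk = integer(0),
                molecules = wmol))
  }
  if (!length(heavy)) {
    return(list(interface = integer(0), bulk = seq_len(nrow(wmol)),
                molecules = wmol))
  }
  d <- cpp_min_dist_to_set(fr$coords, fr$box,
                           as.integer(wmol[, "O"] - 1L),
                           as.integer(heavy - 1L))
  list(interface = which(d <= shell_cutoff),
       bulk = which(d > shell_cutoff), molecules = wmol)
}

#' Ensemble-averaged hydrogen-bond report
#'
#' Per-molecule hydrogen-bond counts use the donated-plus-accepted
#' convention: every bond increments both partners by one.  Category means
#' are computed per frame (pooled over the molecules of that frame) and then
#' weight-averaged over frames; `hb_pp_total` and `hb_pw_total` are mean
#' per-frame bond counts.  The identity
#' `hb_total_interface = hb_ww_interface + hb_wp_interface` holds exactly.
#'
#' @param ens An [ensemble()] containing water.
#' @param criterion An [hbond_criterion()].
#' @param shell_cutoff First-shell cutoff in nm.
#' @return Object of class `"hydration_report"`.
#' @export
hydration_report <- function(ens, criterion = hbond_criterion(),
                             shell_cutoff = 0.4) {
  top <- ens$topology
  wmol <- water_molecules(top)
  if (!nrow(wmol)) stop("ensemble contains no water")
  nw <- nrow(wmol)
  mol_of <- integer(n_atoms(top))
  mol_of[as.vector(wmol)] <- rep(seq_len(nw), 3)

  nf <- n_frames(ens)
  per <- data.frame(n_int = numeric(nf), n_blk = numeric(nf),
                    ww_int = NA_real_, wp_int = NA_real_, tot_int = NA_real_,
                    blk = NA_real_, pp = numeric(nf), pw = numeric(nf))
  for (k in seq_len(nf)) {
    fr <- ens$frames[[k]]
    hb <- detect_hbonds(fr, top, criterion)
    cls <- classify_waters(fr, top, shell_cutoff)
    ww_count <- wp_count <- numeric(nw)
    if (nrow(hb)) {
      ww <- hb[hb$category == "ww", , drop = FALSE]
      if (nrow(ww)) {
        t1 <- table(factor(mol_of[ww$donor], levels = seq_len(nw)))
        t2 <- table(factor(mol_of[ww$acceptor], levels = seq_len(nw)))
        ww_count <- as.numeric(t1) + as.numeric(t2)
      }
      wp <- hb[hb$category == "wp", , drop = FALSE]
      if (nrow(wp)) {
        wpart <- ifelse(mol_of[wp$donor] > 0, mol_of[wp$donor],
                        mol_of[wp$acceptor])
        wp_count <- as.numeric(table(factor(wpart, levels = seq_len(nw))))
      }
      per$pp[k] <- sum(hb$category == "pp")
      per$pw[k] <- sum(hb$category == "wp")
    }
    per$n_int[k] <- length(cls$interface)
    per$n_blk[k] <- length(cls$bulk)
    if (length(cls$interface)) {
      per$ww_int[k] <- mean(ww_count[cls$interface])
      per$wp_int[k] <- mean(wp_count[cls$interface])
      per$tot_int[k] <- per$ww_int[k] + per$wp_int[k]
    }
    if (length(cls$bulk)) {
      per$blk[k] <- mean(ww_count[cls$bulk] + wp_count[cls$bulk])
    }
  }
  w <- ens$weights
  wmean <- function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  structure(list(
    n_interface_waters = sum(per$n_int * w),
    n_bulk_waters = sum(per$n_blk * w),
    hb_ww_interface = wmean(per$ww_int),
    hb_wp_interface = wmean(per$wp_int),
    hb_total_interface = wmean(per$ww_int) + wmean(per$wp_int),
    hb_bulk = wmean(per$blk),
    hb_pp_total = sum(per$pp * w),
    hb_pw_total = sum(per$pw * w),
    per_frame = per), class = "hydration_report")
}

#' @export
print.hydration_report <- function(x, ...) {
  cat("hydration report (ensemble averages)\n")
  cat(sprintf("  interface waters: %.1f   bulk waters: %.1f\n",
              x$n_interface_waters, x$n_bulk_waters))
  cat(sprintf("  H-bonds per interface water: %.3f (ww %.3f + wp %.3f)\n",
              x$hb_total_interface, x$hb_ww_interface, x$hb_wp_interface))
  cat(sprintf("  H-bonds per bulk water: %.3f\n", x$hb_bulk))
  cat(sprintf("  protein-protein bonds/frame: %.2f   protein-water: %.2f\n",
              x$hb_pp_total, x$hb_pw_total))
  invisible(x)
}

.rdf_accumulate <- function(ens, bin_width, r_max, do_aniso) {
  top <- ens$topology
  wmol <- water_molecules(top)
  if (!nrow(wmol)) stop("ensemble contains no water")
  prot <- protein_atoms(top)
  if (!length(prot)) stop("ensemble contains no protein atoms")
  nb <- ceiling(r_max / bin_width - 1e-9)
  counts <- s <- numeric(nb)
  for (k in seq_len(n_frames(ens))) {
    fr <- ens$frames[[k]]
    acc <- cpp_rdf_aniso(fr$coords, fr$box,
                         as.integer(wmol[, "O"] - 1L),
                         as.integer(wmol[, "H1"] - 1L),
                         as.integer(wmol[, "H2"] - 1L),
                         as.integer(prot - 1L), bin_width, r_max, do_aniso)
    counts <- counts + ens$weights[k] * acc$counts
    s <- s + ens$weights[k] * acc$s
  }
  list(bin_edges = seq(0, by = bin_width, length.out = nb + 1),
       counts = counts, s = s)
}

#' Unnormalised water-protein radial distribution function
#'
#' Histogram of water-oxygen to protein-atom minimum-image distances,
#' weight-averaged over frames (so the bin sum equals the mean number of
#' pairs within `r_max`).
#'
#' @param ens An [ensemble()] with water and protein.
#' @param bin_width Bin width in nm (default 0.01).
#' @param r_max Histogram range in nm (default 1.5).
#' @return List with `bin_edges` and per-bin `counts`.
#' @export
rdf_unnormalized <- function(ens, bin_width = 0.01, r_max = 1.5) {
  acc <- .rdf_accumulate(ens, bin_width, r_max, do_aniso = FALSE)
  list(bin_edges = acc$bin_edges, counts = acc$counts)
}

#' Water rotational-anisotropy profile
#'
#' For every (water oxygen, protein atom) pair at distance r, the
#' orientational order parameter 3cos^2(theta) - 1 is accumulated, where
#' theta is the angle between the oxygen-to-atom vector and the water-plane
#' normal (normalised cross product of the two O-H bond vectors).  The
#' profile is the per-bin mean multiplied by the unnormalised RDF of the
#' same bin; empty bins give zero.
#'
#' @inheritParams rdf_unnormalized
#' @return Object of class `"anisotropy_profile"`: `bin_edges`, `A`
#'   (per-bin anisotropy), `rdf`, `mean_orient` (per-bin mean of
#'   3cos^2-1), `bin_width` and `total` (the absolute integral).
#' @export
anisotropy_profile <- function(ens, bin_width = 0.01, r_max = 1.5) {
  acc <- .rdf_accumulate(ens, bin_width, r_max, do_aniso = TRUE)
  mean_orient <- ifelse(acc$counts > 0, acc$s / acc$counts, 0)
  A <- mean_orient * acc$counts
  structure(list(bin_edges = acc$bin_edges, A = A, rdf = acc$counts,
                 mean_orient = mean_orient, bin_width = bin_width,
                 total = sum(abs(A)) * bin_width),
            class = "anisotropy_profile")
}

#' Integrated absolute anisotropy
#'
#' Rectangle-rule integral of |A(r)| over the profile bins; reports the
#' overall orientational-order (rotational-entropy-loss) burden of the
#' hydration water.
#'
#' @param profile An [anisotropy_profile()].
#' @return Non-negative scalar (nm x pair-count units).
#' @export
total_anisotropy <- function(profile) {
  sum(abs(profile$A)) * profile$bin_width
}
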