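# Per-ensemble structural summaries: mass-weighted radius of gyration and
# Ramachandran-box secondary-structure populations (alpha / beta /
# polyproline II / coil).

#' Mass-weighted radius of gyration
#'
#' Rg over the protein atoms of a frame (nm).  No periodic wrapping is
#' applied: the protein is assumed whole in the frame.
#'
#' @param fr A [frame()].
#' @param top The matching [topology()].
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(fr, top) {
  sel <- protein_atoms(top)
  if (length(sel) < 2) stop("radius of gyration needs at least 2 protein atoms")
  m <- top$atoms$mass[sel]
  x <- fr$coords[sel, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

# torsion angle (degrees) for rows a-b-c-d of coordinate matrices
.torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
         n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m * n2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

#' Backbone dihedral angles of a frame
#'
#' @param fr A [frame()].
#' @param top The matching [topology()].
#' @return Data frame with `residue`, `phi`, `psi` (degrees; `NA` at the
#'   termini).
#' @export
backbone_dihedrals <- function(fr, top) {
  a <- top$atoms
  res <- residue_table(top)
  res <- res[res$segment == "protein", , drop = FALSE]
  idx_of <- function(r, nm) {
    k <- which(a$resid == r & a$name == nm)
    if (!length(k)) stop(sprintf("residue %d is missing backbone atom %s",
                                 r, nm))
    k[1]
  }
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    r <- res$resid[k]
    Ni <- fr$coords[idx_of(r, "N"), ]
    CAi <- fr$coords[idx_of(r, "CA"), ]
    Ci <- fr$coords[idx_of(r, "C"), ]
    if (k > 1) {
      phi[k] <- .torsion(fr$coords[idx_of(res$resid[k - 1], "C"), ],
                         Ni, CAi, Ci)
    }
    if (k < n) {
      psi[k] <- .torsion(Ni, CAi, Ci,
                         fr$coords[idx_of(res$resid[k + 1], "N"), ])
    }
  }
  data.frame(residue = res$resid, phi = phi, psi = psi)
}

#' Ramachandran region boxes
#'
#' Rectangular (phi, psi) boxes (degrees, half-open `[lo, hi)`) defining
#' the alpha, beta and polyproline-II classes; everything else is coil.
#' Defaults follow standard Ramachandran conventions: alpha
#' phi `[-100, -30)`, psi `[-80, -5)`; beta phi `[-180, -90)`, psi
#' `[90, 180]` or `[-180, -170)`; ppii phi `[-90, -20)`, psi `[120, 180)`.
#'
#' @param alpha,beta,ppii Each a list of boxes; a box is
#'   `c(phi_lo, phi_hi, psi_lo, psi_hi)`.
#' @return Object of class `"ramachandran_regions"`.
#' @export
ramachandran_regions <- function(
    alpha = list(c(-100, -30, -80, -5)),
    beta = list(c(-180, -90, 90, 180.001), c(-180, -90, -180, -170)),
    ppii = list(c(-90, -20, 120, 180.001))) {
  structure(list(alpha = alpha, beta = beta, ppii = ppii),
            class = "ramachandran_regions")
}

.in_boxes <- function(phi, psi, boxes) {
  for (b in boxes) {
    if (phi >= b[1] && phi < b[2] && psi >= b[3] && psi < b[4]) return(TRUE)
  }
  FALSE
}

#' Secondary-structure class per residue of a frame
#'
#' Dihedral-only classification by Ramachandran-box membership; terminal
#' residues (undefined phi or psi) are coil.
#'
#' @param fr A [frame()].
#' @param top The matching [topology()].
#' @param regions A [ramachandran_regions()] object.
#' @return Character vector (`"alpha"`, `"beta"`, `"ppii"`, `"coil"`), one
#'   entry per protein residue, named by residue id.
#' @export
classify_secondary_structure <- function(fr, top,
                                         regions = ramachandran_regions()) {
  dih <- backbone_dihedrals(fr, top)
  lab <- vapply(seq_len(nrow(dih)), function(k) {
    phi <- dih$phi[k]; psi <- dih$psi[k]
    if (is.na(phi) || is.na(psi)) return("coil")
    if (.in_boxes(phi, psi, regions$alpha)) return("alpha")
    if (.in_boxes(phi, psi, regions$beta)) return("beta")
    if (.in_boxes(phi, psi, regions$ppii)) return("ppii")
    "coil"
  }, character(1))
  setNames(lab, dih$residue)
}

#' Secondary-structure populations of an ensemble
#'
#' Weight-averaged per-residue frequencies of the alpha, beta,
#' polyproline-II and coil classes, plus their ensemble means over
#' residues.  Per residue the four fractions sum to one.
#'
#' @param ens An [ensemble()].
#' @param regions A [ramachandran_regions()] object.
#' @return Object of class `"ss_populations"`: `per_residue` (data frame
#'   with `residue`, `f_alpha`, `f_beta`, `f_ppii`, `f_coil`) and `means`
#'   (named numeric).
#' @export
ss_populations <- function(ens, regions = ramachandran_regions()) {
  top <- ens$topology
  lv <- c("alpha", "beta", "ppii", "coil")
  first <- classify_secondary_structure(ens$frames[[1]], top, regions)
  nres <- length(first)
  freq <- matrix(0, nres, 4, dimnames = list(names(first), lv))
  for (k in seq_len(n_frames(ens))) {
    lab <- if (k == 1) first else
      classify_secondary_structure(ens$frames[[k]], top, regions)
    for (j in seq_along(lv)) {
      freq[, j] <- freq[, j] + ens$weights[k] * (lab == lv[j])
    }
  }
  per <- data.frame(residue = as.integer(rownames(freq)),
                    f_alpha = freq[, "alpha"], f_beta = freq[, "beta"],
                    f_ppii = freq[, "ppii"], f_coil = freq[, "coil"],
                    row.names = NULL)
  structure(list(per_residue = per,
                 means = c(alpha = mean(per$f_alpha),
                           beta = mean(per$f_beta),
                           ppii = mean(per$f_ppii),
                           coil = mean(per$f_coil))),
            class = "ss_populations")
}

#' @export
print.ss_populations <- function(x, ...) {
  cat(sprintf(
    "secondary-structure populations: alpha %.1f%%, beta %.1f%%, ppii %.1f%%, coil %.1f%%\n",
    100 * x$means["alpha"], 100 * x$means["beta"], 100 * x$means["ppii"],
    100 * x$means["coil"]))
  invisible(x)
}
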