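# Synthetic-input generators: peptides with prescribed backbone dihedrals,
# jittered-lattice water boxes with exact rigid-model geometry, solvated
# systems, ensembles with prescribed per-contact formation probabilities,
# and ddG tables with an exact sample correlation.

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# canonical (phi, psi) for named backbone classes (degrees)
.DIHEDRAL_CLASSES <- list(alpha = c(-57, -47), beta = c(-135, 135),
                          ppii = c(-75, 145), coil = c(-90, 60))

# natural extension of reference frame: place D given A-B-C with bond |CD|,
# angle B-C-D and torsion A-B-C-D (radians)
.nerf <- function(A, B, C, bond, angle, torsion) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         -bond * sin(angle) * sin(torsion))
  C + bc * d[1] + m * d[2] + n * d[3]
}

#' Build an idealised peptide with prescribed backbone dihedrals
#'
#' Constructs an all-atom chain (backbone N, H, CA, C, O plus a C-beta for
#' every non-glycine residue) by natural-extension chain growth with
#' standard bond lengths and angles, trans peptide bonds, and the requested
#' (phi, psi) per residue.  Dihedral classes map to fixed canonical angles:
#' alpha (-57, -47), beta (-135, 135), ppii (-75, 145), coil (-90, 60).
#'
#' @param sequence One-letter amino-acid string, length >= 2.
#' @param dihedrals Either a class name (recycled), a character vector of
#'   class names (one per residue), or an n x 2 numeric matrix of
#'   (phi, psi) in degrees.
#' @param seed Integer seed (construction is deterministic; the seed is kept
#'   for interface uniformity with the other generators).
#' @return List with `topology` and `frame` (box encloses the chain with a
#'   2 nm margin).
#' @export
build_peptide <- function(sequence, dihedrals = "coil", seed = 1) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seq1)
  if (n < 2) stop("sequence must have at least 2 residues")
  if (!all(seq1 %in% names(.AA1))) {
    stop("unknown residue letter(s): ",
         paste(unique(seq1[!(seq1 %in% names(.AA1))]), collapse = ", "))
  }
  res3 <- unname(.AA1[seq1])
  if (is.character(dihedrals)) {
    cls <- rep_len(dihedrals, n)
    bad <- !(cls %in% names(.DIHEDRAL_CLASSES))
    if (any(bad)) stop("unknown dihedral class: ", cls[bad][1])
    phipsi <- t(vapply(cls, function(k) .DIHEDRAL_CLASSES[[k]], numeric(2)))
  } else {
    phipsi <- as.matrix(dihedrals)
    if (nrow(phipsi) != n || ncol(phipsi) != 2) {
      stop("dihedrals matrix must be n x 2 (phi, psi) in degrees")
    }
  }
  phi <- phipsi[, 1] * pi / 180
  psi <- phipsi[, 2] * pi / 180

  b_NCA <- 0.1458; b_CAC <- 0.1525; b_CN <- 0.1329
  b_CO <- 0.1229; b_NH <- 0.101; b_CACB <- 0.153
  a_NCAC <- 111.0 * pi / 180; a_CACN <- 116.2 * pi / 180
  a_CNCA <- 121.7 * pi / 180; a_CACO <- 120.5 * pi / 180
  a_CNH <- 119.0 * pi / 180; a_CCACB <- 110.1 * pi / 180
  omega <- pi

  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  C[1, ] <- CA[1, ] + b_CAC * c(-cos(a_NCAC), sin(a_NCAC), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], b_CN, a_CACN, psi[i])
    CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], b_NCA, a_CNCA, omega)
    C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], b_CAC, a_CNCA,
                        phi[i + 1])
  }
  # carbonyl O trans to the next amide N (virtual for the C-terminus)
  O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    nn <- if (i < n) N[i + 1, ] else
      .nerf(N[i, ], CA[i, ], C[i, ], b_CN, a_CACN, psi[i])
    O[i, ] <- .nerf(nn, CA[i, ], C[i, ], b_CO, a_CACO, pi)
  }
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    H[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ], b_NH, a_CNH, 0)
  }
  CB <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (res3[i] != "GLY") {
      CB[i, ] <- .nerf(N[i, ], C[i, ], CA[i, ], b_CACB, a_CCACB,
                       122.6 * pi / 180)
    }
  }

  name <- character(0); resid <- integer(0); elem <- character(0)
  coords <- NULL
  for (i in seq_len(n)) {
    nm <- c("N", if (i > 1) "H", "CA", if (res3[i] != "GLY") "CB", "C", "O")
    el <- c("N", if (i > 1) "H", "C", if (res3[i] != "GLY") "C", "C", "O")
    xyz <- rbind(N[i, ], if (i > 1) H[i, ], CA[i, ],
                 if (res3[i] != "GLY") CB[i, ], C[i, ], O[i, ])
    name <- c(name, nm); elem <- c(elem, el)
    resid <- c(resid, rep(i, length(nm)))
    coords <- rbind(coords, xyz)
  }
  # shift into the positive octant and box with margin
  coords <- sweep(coords, 2, apply(coords, 2, min)) + 1
  box <- apply(coords, 2, max) + 1
  top <- topology(name = name, resid = resid, resname = res3[resid],
                  element = elem)
  list(topology = top, frame = frame(coords, box))
}

# uniform random rotation matrices via unit quaternions
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a water box with exact rigid-model internal geometry
#'
#' Molecules are placed on a jittered cubic lattice with orientations drawn
#' uniformly on SO(3) (random unit quaternions), so the orientation
#' distribution is exactly isotropic.  Each molecule has the model's exact
#' internal geometry (tip4p2005: r_OH = 0.09572 nm, HOH angle 104.52 deg).
#'
#' @param n_molecules Number of water molecules.
#' @param box Box edge lengths (nm, scalar or length 3); computed from
#'   `density` when `NULL`.
#' @param density Mass density in g/cm^3 used when `box` is `NULL`
#'   (default 0.997).
#' @param seed Integer seed.
#' @param model Water model descriptor ([water_model()]).
#' @return List with `topology` and `frame`.
#' @export
build_water_box <- function(n_molecules, box = NULL, density = 0.997,
                            seed = 1, model = water_model()) {
  if (is.null(box)) {
    vol <- n_molecules * 18.01528 * 1.66053907e-3 / density   # nm^3
    box <- rep(vol^(1 / 3), 3)
  }
  box <- rep_len(as.numeric(box), 3)
  m <- ceiling(n_molecules^(1 / 3))
  a <- min(box) / m
  if (a < 0.265) stop("infeasible packing: lattice spacing below 0.265 nm")
  jitter <- min(0.025, (a - 0.255) / (2 * sqrt(3)))
  half <- model$angle_HOH / 2 * pi / 180
  h1_0 <- model$r_OH * c(sin(half), 0, cos(half))
  h2_0 <- model$r_OH * c(-sin(half), 0, cos(half))

  .with_seed(seed, {
    grid <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m),
                                  z = seq_len(m)))
    # scatter any vacancies uniformly so partial fillings stay bulk-like
    sites <- grid[sample(nrow(grid), n_molecules), , drop = FALSE]
    o <- sweep((sites - 0.5) * a, 2, rep(0, 3)) +
      matrix(runif(3 * n_molecules, -jitter, jitter), ncol = 3)
    coords <- matrix(NA_real_, 3 * n_molecules, 3)
    for (i in seq_len(n_molecules)) {
      R <- .random_rotation()
      coords[3 * i - 2, ] <- o[i, ]
      coords[3 * i - 1, ] <- o[i, ] + as.numeric(R %*% h1_0)
      coords[3 * i, ] <- o[i, ] + as.numeric(R %*% h2_0)
    }
    top <- topology(
      name = rep(c("OW", "HW1", "HW2"), n_molecules),
      resid = rep(seq_len(n_molecules), each = 3),
      resname = rep("SOL", 3L * n_molecules),
      element = rep(c("O", "H", "H"), n_molecules),
      water_model = model)
    list(topology = top, frame = frame(coords, box))
  })
}

#' Solvate a protein in a water box
#'
#' Builds a water box, centres the protein in it, and deletes every water
#' molecule whose oxygen lies within `clearance` of a protein heavy atom
#' (minimum image).  The combined topology is ordered protein-then-water.
#'
#' @param protein List with `topology` and `frame`, or `NULL`/zero-atom
#'   input to get a pure water box.
#' @param n_molecules,box,density,seed,model Passed to [build_water_box()].
#' @param clearance Deletion cutoff in nm (default 0.24).
#' @return List with `topology` and `frame`.
#' @export
solvate <- function(protein, n_molecules, box = NULL, density = 0.997,
                    seed = 1, model = water_model(), clearance = 0.24) {
  wb <- build_water_box(n_molecules, box = box, density = density,
                        seed = seed, model = model)
  if (is.null(protein) || n_atoms(protein$topology) == 0) return(wb)
  ptop <- protein$topology
  pc <- protein$frame$coords
  bx <- wb$frame$box
  span <- apply(pc, 2, function(v) diff(range(v)))
  if (any(span > bx)) stop("protein does not fit in the requested box")
  pc <- sweep(pc, 2, colMeans(pc)) + matrix(bx / 2, nrow(pc), 3, byrow = TRUE)

  heavy <- which(ptop$atoms$is_heavy)
  wmol <- water_molecules(wb$topology)
  all_coords <- rbind(pc, wb$frame$coords)
  offset <- nrow(pc)
  od <- cpp_min_dist_to_set(all_coords, bx,
                            as.integer(wmol[, "O"] + offset - 1L),
                            as.integer(heavy - 1L))
  keep <- which(od > clearance)
  keep_atoms <- as.vector(t(wmol[keep, , drop = FALSE]))

  wa <- wb$topology$atoms[keep_atoms, , drop = FALSE]
  nprot_res <- max(ptop$atoms$resid)
  new_resid <- c(ptop$atoms$resid,
                 nprot_res + match(wa$resid, unique(wa$resid)))
  top <- topology(
    name = c(ptop$atoms$name, wa$name),
    resid = new_resid,
    resname = c(ptop$atoms$resname, wa$resname),
    element = c(ptop$atoms$element, wa$element),
    water_model = model)
  coords <- rbind(pc, wb$frame$coords[keep_atoms, , drop = FALSE])
  list(topology = top, frame = frame(coords, bx))
}

#' Generate an ensemble with prescribed contact-formation probabilities
#'
#' Starting from a native structure, each frame independently realises each
#' native atom-pair contact with its prescribed probability.  Geometry is
#' perturbed by moving side-chain atoms on the sphere of fixed bond length
#' around their C-alpha (bond lengths are preserved); a stochastic local
#' search picks, per frame, side-chain directions realising the drawn
#' formed/broken pattern.
#'
#' @param native List with `topology` and `frame`.
#' @param contact_formation_p Scalar or per-contact probability in `[0, 1]`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param map Optional [native_contacts()] map (computed with defaults when
#'   `NULL`).
#' @param formation_cutoff Distance (nm) below which a contact counts as
#'   formed (defaults to the map cutoff).
#' @return An [ensemble()] with uniform weights.
#' @export
generate_ensemble <- function(native, contact_formation_p, n_frames,
                              seed = 1, map = NULL,
                              formation_cutoff = NULL) {
  if (is.null(map)) map <- native_contacts(native)
  nc <- nrow(map$atom_pairs)
  if (!nc) stop("native structure has no native contacts")
  p <- rep_len(contact_formation_p, nc)
  if (any(p < 0 | p > 1)) stop("contact probabilities must lie in [0, 1]")
  if (is.null(formation_cutoff)) formation_cutoff <- map$cutoff
  top <- native$topology
  box <- native$frame$box
  xyz0 <- native$frame$coords

  a <- top$atoms
  bb <- c("N", "CA", "C", "O", "H", "OXT", "H1", "H2", "H3")
  # movable side-chain atoms appearing in the map, with their anchor CA
  movers <- sort(unique(c(map$atom_pairs[, 1], map$atom_pairs[, 2])))
  movers <- movers[!(a$name[movers] %in% bb)]
  anchor <- vapply(movers, function(k) {
    ca <- which(a$resid == a$resid[k] & a$name == "CA")
    if (!length(ca)) stop("residue without CA cannot be perturbed")
    ca[1]
  }, integer(1))
  rad <- sqrt(rowSums((xyz0[movers, , drop = FALSE] -
                         xyz0[anchor, , drop = FALSE])^2))
  # contacts touching each movable atom
  touch <- lapply(movers, function(k) {
    which(map$atom_pairs[, 1] == k | map$atom_pairs[, 2] == k)
  })

  .with_seed(seed, {
    frames <- vector("list", n_frames)
    unresolved <- 0L
    for (f in seq_len(n_frames)) {
      want <- runif(nc) < p
      best_xyz <- NULL; best_tot <- Inf
      for (attempt in 1:4) {
        xyz <- xyz0
        if (attempt > 1) {
          # random restart: scatter the side chains before searching
          for (mi in seq_along(movers)) {
            u <- rnorm(3); u <- u / sqrt(sum(u^2))
            xyz[movers[mi], ] <- xyz[anchor[mi], ] + rad[mi] * u
          }
        }
        for (sweep_i in 1:50) {
          viol_total <- 0L
          for (mi in sample(seq_along(movers))) {
            k <- movers[mi]; ca <- anchor[mi]
            cids <- touch[[mi]]
            if (!length(cids)) next
            cur <- xyz[k, ] - xyz[ca, ]
            cand <- matrix(rnorm(3 * 24), ncol = 3)
            # half the pool explores locally around the current direction
            cand[1:8, ] <- sweep(0.35 * cand[1:8, ], 2, cur, "+")
            cand <- cand / sqrt(rowSums(cand^2)) * rad[mi]
            cand <- rbind(cur, xyz0[k, ] - xyz0[ca, ], cand)
            partners <- ifelse(map$atom_pairs[cids, 1] == k,
                               map$atom_pairs[cids, 2],
                               map$atom_pairs[cids, 1])
            pp <- xyz[partners, , drop = FALSE]
            best <- NULL; best_v <- Inf; best_m <- -Inf
            for (ci in seq_len(nrow(cand))) {
              pos <- xyz[ca, ] + cand[ci, ]
              d <- sqrt(rowSums(sweep(pp, 2, pos)^2))
              formed <- d <= formation_cutoff
              v <- sum(formed != want[cids])
              # margin from the cutoff, to leave room for later movers
              m <- min(ifelse(want[cids], formation_cutoff - d,
                              d - formation_cutoff))
              if (v < best_v || (v == best_v && m > best_m)) {
                best_v <- v; best_m <- m; best <- pos
              }
            }
            xyz[k, ] <- best
            viol_total <- viol_total + best_v
          }
          if (viol_total == 0L) break
        }
        if (viol_total < best_tot) {
          best_tot <- viol_total; best_xyz <- xyz
        }
        if (best_tot == 0L) break
      }
      if (best_tot > 0L) unresolved <- unresolved + 1L
      frames[[f]] <- frame(best_xyz, box, time = f - 1)
    }
    if (unresolved > 0L) {
      warning(sprintf(
        "%d of %d frames could not realise the full contact pattern",
        unresolved, n_frames))
    }
    ensemble(top, frames)
  })
}

#' Generate a ddG table with an exact sample correlation
#'
#' Produces per-mutant equilibrium (`ddG_DN`) and activation (`ddG_TSN`)
#' destabilisation free energies whose sample Pearson correlation equals
#' `target_r` exactly (constructive Gram-Schmidt orthogonalisation of two
#' Gaussian draws, then recombination).
#'
#' @param n_mutants Number of mutants (>= 3).
#' @param target_r Target Pearson correlation in `[-1, 1]`.
#' @param scale Spread of the energies (kJ/mol).
#' @param seed Integer seed.
#' @param residues Optional residue ids (defaults to `1:n_mutants`).
#' @return A `ddg_table` data frame with columns `residue`, `ddG_DN`,
#'   `ddG_TSN` (kJ/mol).
#' @export
generate_ddg_table <- function(n_mutants, target_r, scale = 4, seed = 1,
                               residues = NULL) {
  if (n_mutants < 3) stop("n_mutants must be at least 3")
  if (abs(target_r) > 1) stop("target_r must lie in [-1, 1]")
  if (is.null(residues)) residues <- seq_len(n_mutants)
  .with_seed(seed, {
    repeat {
      x <- rnorm(n_mutants)
      y <- rnorm(n_mutants)
      xc <- x - mean(x)
      if (sqrt(sum(xc^2)) < 1e-12) next
      u <- xc / sqrt(sum(xc^2))
      yc <- y - mean(y)
      yp <- yc - sum(yc * u) * u
      if (sqrt(sum(yp^2)) < 1e-12) next
      v <- yp / sqrt(sum(yp^2))
      z <- target_r * u + sqrt(1 - target_r^2) * v
      ddg_dn <- 6 + scale * u * sqrt(n_mutants)
      ddg_tsn <- 3 + 0.6 * scale * z * sqrt(n_mutants)
      out <- data.frame(residue = residues, ddG_DN = ddg_dn,
                        ddG_TSN = ddg_tsn)
      class(out) <- c("ddg_table", "data.frame")
      return(out)
    }
  })
}
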