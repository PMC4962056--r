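# Core containers: topology, frame, ensemble.
# Units: coordinates in nm, masses in amu, charges in e, time in ps.

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")
.AA1 <- setNames(names(.AA3), .AA3)

.WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP", "T4P", "SPC")
.ION_RESNAMES <- c("NA", "CL", "K", "MG", "ZN", "LI", "RB", "CS", "BR",
                   "F", "IOD", "NA+", "CL-", "K+")

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, NA. = 22.990, CL = 35.453,
                   K = 39.098, MG = 24.305, ZN = 65.38, FE = 55.845,
                   BR = 79.904, F = 18.998, I = 126.904, LI = 6.94)

.element_mass <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  m <- .ELEMENT_MASS[key]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

.guess_element <- function(name, resname) {
  name <- toupper(name)
  out <- character(length(name))
  ion <- resname %in% .ION_RESNAMES
  out[ion] <- sub("[+-]", "", resname[ion])
  stripped <- sub("^[0-9]+", "", name[!ion])
  out[!ion] <- substr(stripped, 1L, 1L)
  out
}

.classify_segment <- function(resname) {
  seg <- rep(NA_character_, length(resname))
  seg[resname %in% .WATER_RESNAMES] <- "water"
  seg[resname %in% .ION_RESNAMES] <- "ion"
  unknown <- is.na(seg) & !(resname %in% names(.AA3))
  if (any(unknown)) {
    warning("unknown residue class for: ",
            paste(unique(resname[unknown]), collapse = ", "),
            "; assigning segment 'protein'")
  }
  seg[is.na(seg)] <- "protein"
  seg
}

#' Water model descriptor
#'
#' Geometry (and, for the four-site model, charge placement) of the rigid
#' water model used by the generators and the water sampler.  Topologies
#' store the three real atoms (O, H1, H2); the massless M site of four-site
#' models is reconstructed on the fly where it is needed.
#'
#' @param name `"tip4p2005"` (default) or `"spc"`.
#' @return A list with `name`, `r_OH` (nm), `angle_HOH` (degrees), `n_sites`,
#'   and for tip4p2005 the O-M distance `d_OM` (nm) and site charges.
#' @export
water_model <- function(name = "tip4p2005") {
  name <- match.arg(name, c("tip4p2005", "spc"))
  if (name == "tip4p2005") {
    list(name = "tip4p2005", r_OH = 0.09572, angle_HOH = 104.52,
         n_sites = 4L, d_OM = 0.01546, q_H = 0.5564, q_M = -1.1128,
         sigma_O = 0.31589, epsilon_O = 0.7749)
  } else {
    list(name = "spc", r_OH = 0.1, angle_HOH = 109.47, n_sites = 3L,
         d_OM = 0, q_H = 0.41, q_M = -0.82,
         sigma_O = 0.3166, epsilon_O = 0.650)
  }
}

#' Build a molecular topology
#'
#' @param name,resid,resname Per-atom name, 1-based residue index and
#'   three-letter residue name (character/integer vectors of equal length).
#' @param element Element symbols; guessed from atom names when `NULL`.
#' @param segment Per-atom segment (`"protein"`, `"water"` or `"ion"`);
#'   classified from residue names when `NULL` (water: HOH/SOL/WAT/...,
#'   ions: NA/CL/...; unknown residues fall back to protein with a warning).
#' @param charge Optional per-atom charges (e).
#' @param water_model Water model descriptor, see [water_model()].
#' @return An object of class `"topology"`: a list with the per-atom table
#'   `$atoms` (name, element, resid, resname, segment, mass, charge,
#'   is_heavy) and `$water_model`.
#' @export
topology <- function(name, resid, resname, element = NULL, segment = NULL,
                     charge = NA_real_, water_model = hydrophi::water_model()) {
  n <- length(name)
  stopifnot(length(resid) == n, length(resname) == n)
  resname <- toupper(resname)
  if (is.null(element)) element <- .guess_element(name, resname)
  if (is.null(segment)) segment <- .classify_segment(resname)
  atoms <- data.frame(
    name = as.character(name), element = toupper(element),
    resid = as.integer(resid), resname = resname,
    segment = segment, mass = .element_mass(toupper(element)),
    charge = rep_len(charge, n),
    is_heavy = toupper(element) != "H",
    stringsAsFactors = FALSE)
  top <- structure(list(atoms = atoms, water_model = water_model),
                   class = "topology")
  validate_topology(top)
  top
}

#' @rdname topology
#' @param top A topology.
#' @export
validate_topology <- function(top) {
  a <- top$atoms
  stopifnot(all(a$mass > 0), all(a$segment %in% c("protein", "water", "ion")))
  wat <- a[a$segment == "water", , drop = FALSE]
  if (nrow(wat)) {
    per <- split(wat$element, wat$resid)
    ok <- vapply(per, function(e) {
      length(e) == 3L && sum(e == "O") == 1L && sum(e == "H") == 2L
    }, logical(1))
    if (!all(ok)) {
      stop("water residue(s) without exactly O,H,H atoms: ",
           paste(names(per)[!ok][seq_len(min(5, sum(!ok)))], collapse = ", "))
    }
  }
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("topology: %d atoms, %d residues (%d protein / %d water / %d ion atoms)\n",
              nrow(a), length(unique(a$resid)),
              sum(a$segment == "protein"), sum(a$segment == "water"),
              sum(a$segment == "ion")))
  invisible(x)
}

#' @rdname topology
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Residue table of a topology
#'
#' @param top A topology.
#' @return Data frame with one row per residue: `resid`, `resname`,
#'   `segment`, `first`, `last` (atom index range).
#' @export
residue_table <- function(top) {
  a <- top$atoms
  idx <- seq_len(nrow(a))
  first <- tapply(idx, a$resid, min)
  last <- tapply(idx, a$resid, max)
  ord <- order(as.integer(names(first)))
  data.frame(resid = as.integer(names(first))[ord],
             resname = a$resname[first[ord]],
             segment = a$segment[first[ord]],
             first = as.integer(first[ord]), last = as.integer(last[ord]),
             stringsAsFactors = FALSE)
}

# index helpers ------------------------------------------------------------

#' Atom index helpers
#'
#' `protein_atoms` / `protein_heavy_atoms` return atom indices of the
#' protein segment; `water_molecules` returns a matrix with one row per
#' water molecule and columns `O`, `H1`, `H2` (atom indices).
#'
#' @param top A [topology()].
#' @name atom-indices
#' @export
protein_atoms <- function(top) which(top$atoms$segment == "protein")

#' @rdname atom-indices
#' @export
protein_heavy_atoms <- function(top) {
  which(top$atoms$segment == "protein" & top$atoms$is_heavy)
}

#' @rdname atom-indices
#' @export
water_molecules <- function(top) {
  a <- top$atoms
  w <- which(a$segment == "water")
  if (!length(w)) {
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("O", "H1", "H2"))))
  }
  sp <- split(w, a$resid[w])
  out <- t(vapply(sp, function(ix) {
    o <- ix[a$element[ix] == "O"]
    h <- ix[a$element[ix] == "H"]
    c(o, h)
  }, integer(3)))
  colnames(out) <- c("O", "H1", "H2")
  out[order(out[, 1]), , drop = FALSE]
}

#' Coordinate frame
#'
#' @param coords Numeric n x 3 matrix of coordinates (nm).
#' @param box Orthorhombic box lengths, length-3 numeric (nm).
#' @param time Time stamp (ps).
#' @return Object of class `"frame"`.
#' @export
frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive orthorhombic edge lengths (nm)")
  }
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("frame: %d atoms, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Conformational ensemble
#'
#' A topology plus an ordered list of frames with per-frame statistical
#' weights (uniform by default, normalised to sum to one).
#'
#' @param topology A [topology()].
#' @param frames List of [frame()] objects sharing the topology atom count.
#' @param weights Optional non-negative per-frame weights.
#' @return Object of class `"ensemble"`.
#' @export
ensemble <- function(topology, frames, weights = NULL) {
  if (!length(frames)) stop("no frames")
  nat <- n_atoms(topology)
  for (f in frames) {
    if (nrow(f$coords) != nat) {
      stop(sprintf("frame has %d atoms but topology has %d",
                   nrow(f$coords), nat))
    }
  }
  if (is.null(weights)) weights <- rep(1, length(frames))
  if (length(weights) != length(frames) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be non-negative, one per frame, with positive sum")
  }
  structure(list(topology = topology, frames = frames,
                 weights = weights / sum(weights)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frames x %d atoms\n",
              length(x$frames), n_atoms(x$topology)))
  invisible(x)
}

#' @rdname ensemble
#' @param ens An ensemble.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Minimum-image distance between two atoms
#'
#' Euclidean distance under orthorhombic periodic boundary conditions.
#'
#' @param frame A [frame()].
#' @param i,j Atom indices (1-based); may be vectors of equal length.
#' @return Distance(s) in nm.
#' @export
min_image_distance <- function(frame, i, j) {
  n <- nrow(frame$coords)
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1 | i > n | j < 1 | j > n)) {
    stop(sprintf("atom index out of range 1..%d", n))
  }
  cpp_min_image_distance(frame$coords, frame$box, i - 1L, j - 1L)
}
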