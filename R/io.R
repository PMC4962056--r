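# Structure and trajectory I/O.  PDB files are read and written through
# bio3d; the GRO format (fixed-width, coordinates already in nm) is handled
# directly.  Coordinates are converted to nm at the I/O boundary
# (PDB records are in Angstrom).

.A2NM <- 0.1
.NM2A <- 10

# sequential residue indices from a vector that may restart or repeat
.sequential_resid <- function(resno, chain = NULL) {
  key <- if (is.null(chain)) as.character(resno) else paste(chain, resno)
  changed <- c(TRUE, key[-1] != key[-length(key)])
  cumsum(changed)
}

.default_box <- function(coords, margin = 2) {
  span <- apply(coords, 2, function(v) diff(range(v)))
  pmax(span + margin, margin)
}

.parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  f <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                    substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (anyNA(f)) stop("malformed CRYST1 record: ", cl[1])
  if (any(abs(f[4:6] - 90) > 1e-6)) {
    stop("triclinic boxes are not supported (CRYST1 angles != 90)")
  }
  f[1:3] * .A2NM
}

.read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("malformed GRO record at line 2: ", lines[2])
  if (length(lines) < nat + 3) {
    stop(sprintf("GRO file truncated: expected %d atom lines", nat))
  }
  al <- lines[3:(nat + 2)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- toupper(trimws(substr(al, 6, 10)))
  name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop(sprintf("malformed GRO record at line %d: %s", bad[1] + 2,
                 al[bad[1]]))
  }
  boxf <- suppressWarnings(as.numeric(strsplit(trimws(lines[nat + 3]),
                                               "[[:space:]]+")[[1]]))
  if (anyNA(boxf) || length(boxf) < 3) {
    stop("malformed GRO box line: ", lines[nat + 3])
  }
  if (length(boxf) > 3 && any(abs(boxf[-(1:3)]) > 1e-9)) {
    stop("triclinic boxes are not supported")
  }
  list(resno = resno, resname = resname, name = name,
       coords = cbind(x, y, z), box = boxf[1:3])
}

.gro_name_fix <- function(name) {
  # OW/HW1/HW2 style water names carry the element in the first character
  name
}

#' Read a molecular structure
#'
#' Reads a PDB (via bio3d) or GRO file into a topology plus a coordinate
#' frame.  Water (HOH/SOL/WAT/...) and ion (NA/CL/...) residues are assigned
#' to their segments by residue name; unrecognised residue names fall back
#' to the protein segment with a warning.  PDB files without a CRYST1 record
#' get an enclosing box with a 2 nm margin.
#'
#' @param path File path.
#' @param format `"pdb"` or `"gro"`; inferred from the file extension when
#'   missing.
#' @param water_model Water model descriptor attached to the topology.
#' @return A list with elements `topology` and `frame`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           water_model = hydrophi::water_model()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gro") {
    g <- .read_gro(path)
    resid <- .sequential_resid(g$resno)
    resname <- g$resname
    # normalise common water naming
    resname[resname %in% c("SOL", "WAT", "TIP", "T4P")] <- "SOL"
    top <- topology(name = g$name, resid = resid, resname = resname,
                    water_model = water_model)
    return(list(topology = top,
                frame = frame(g$coords, g$box)))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type %in% c("ATOM", "HETATM")
  a <- a[keep, , drop = FALSE]
  resid <- .sequential_resid(a$resno, a$chain)
  box <- .parse_cryst1(readLines(path))
  coords <- cbind(a$x, a$y, a$z) * .A2NM
  if (is.null(box)) box <- .default_box(coords)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- NULL
  } else {
    elem <- trimws(elem)
    miss <- !nzchar(elem) | is.na(elem)
    elem[miss] <- .guess_element(a$elety[miss], toupper(a$resid[miss]))
  }
  top <- topology(name = a$elety, resid = resid,
                  resname = toupper(a$resid), element = elem,
                  water_model = water_model)
  list(topology = top, frame = frame(coords, box))
}

.pdb_atom_lines <- function(top, fr) {
  a <- top$atoms
  xyz <- fr$coords * .NM2A
  resname <- a$resname
  sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)) %% 100000,
          ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
          resname, a$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3],
          1, 0, a$element)
}

#' Write a molecular structure
#'
#' @param top Topology.
#' @param fr Frame.
#' @param path Output path.
#' @param format `"pdb"` or `"gro"` (inferred from extension when missing).
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, fr, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (format == "gro") {
    a <- top$atoms
    lines <- c("written by hydrophi", sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000, a$resname, a$name,
                       seq_len(nrow(a)) %% 100000,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
               sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
    writeLines(lines, path)
    return(invisible(path))
  }
  box <- fr$box * .NM2A
  lines <- c(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90),
    .pdb_atom_lines(top, fr), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a conformational ensemble from a trajectory file
#'
#' Multi-model PDB files are read through bio3d; DCD through
#' [bio3d::read.dcd()].  XTC is not supported and raises an explicit error.
#' Frames get uniform weights.
#'
#' @param path Trajectory file.
#' @param top Topology describing the atoms (atom counts must match).
#' @param format `"pdb"`, `"dcd"` or `"xtc"`; inferred from extension when
#'   missing.
#' @return An [ensemble()].
#' @export
read_trajectory <- function(path, top, format = c("auto", "pdb", "dcd",
                                                  "xtc")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("pdb", "dcd", "xtc")) ext else "pdb"
  }
  if (format == "xtc") {
    stop("XTC reading is not supported; convert to DCD or multi-model PDB")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  nat <- n_atoms(top)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (!nrow(xyz)) stop("no frames")
    if (ncol(xyz) != 3L * nat) {
      stop(sprintf("trajectory has %d atoms but topology has %d",
                   ncol(xyz) %/% 3L, nat))
    }
    box <- .default_box(matrix(xyz[1, ], ncol = 3, byrow = TRUE) * .A2NM)
    frames <- lapply(seq_len(nrow(xyz)), function(k) {
      frame(matrix(xyz[k, ], ncol = 3, byrow = TRUE) * .A2NM, box,
            time = k - 1)
    })
    return(ensemble(top, frames))
  }
  lines <- readLines(path)
  if (!any(grepl("^(ATOM|HETATM)", lines))) stop("no frames")
  box <- .parse_cryst1(lines)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) { starts <- 0L; ends <- length(lines) + 1L }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    al <- lines[(starts[k] + 1):(ends[k] - 1)]
    al <- al[grepl("^(ATOM|HETATM)", al)]
    if (length(al) != nat) {
      stop(sprintf("trajectory frame %d has %d atoms but topology has %d",
                   k, length(al), nat))
    }
    coords <- cbind(as.numeric(substr(al, 31, 38)),
                    as.numeric(substr(al, 39, 46)),
                    as.numeric(substr(al, 47, 54))) * .A2NM
    if (anyNA(coords)) stop(sprintf("malformed ATOM record in frame %d", k))
    b <- if (is.null(box)) .default_box(coords) else box
    frames[[k]] <- frame(coords, b, time = k - 1)
  }
  if (!length(frames)) stop("no frames")
  ensemble(top, frames)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ens, path) {
  box <- ens$frames[[1]]$box * .NM2A
  out <- c(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90))
  for (k in seq_len(n_frames(ens))) {
    out <- c(out, sprintf("MODEL %8d", k),
             .pdb_atom_lines(ens$topology, ens$frames[[k]]), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
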