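# Fixtures and independent oracles shared across the test files.
# All fixtures are built in code; the oracles use plain R arithmetic and
# stay independent of the package's C++ kernels.

# minimum-image distance by explicit enumeration of the 27 periodic images
bf_min_image <- function(coords, box, i, j) {
  d <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    v <- coords[j, ] + c(sx, sy, sz) * box - coords[i, ]
    d <- min(d, sqrt(sum(v^2)))
  }
  d
}

# all-triples hydrogen-bond oracle over explicit donor-H pairs and acceptors
bf_hbonds <- function(fr, top, criterion = hbond_criterion()) {
  s <- hydrophi:::.hbond_sites(fr, top)
  out <- NULL
  mi_vec <- function(a, b) {
    v <- fr$coords[b, ] - fr$coords[a, ]
    v - fr$box * round(v / fr$box)
  }
  for (k in seq_len(nrow(s$dh))) {
    d <- s$dh[k, 1]; h <- s$dh[k, 2]
    vh <- mi_vec(d, h)
    for (a in s$acc) {
      if (a == d) next
      va <- mi_vec(d, a)
      r <- sqrt(sum(va^2))
      if (r == 0 || r > criterion$max_da_distance) next
      ang <- acos(min(1, max(-1, sum(vh * va) /
                               (sqrt(sum(vh^2)) * r)))) * 180 / pi
      if (ang <= criterion$max_hda_angle) out <- rbind(out, c(d, h, a))
    }
  }
  out
}

# mass-weighted radius of gyration straight from the definition
bf_rg <- function(coords, mass) {
  com <- colSums(coords * mass) / sum(mass)
  sqrt(sum(mass * rowSums(sweep(coords, 2, com)^2)) / sum(mass))
}

# a small solvated peptide; the box is the larger of the liquid-density box
# and the peptide extent, so small water counts still fit the chain
make_solvated <- function(seq = "AKVLE", dihedrals = "ppii",
                          n_water = 216, seed = 5) {
  pep <- build_peptide(seq, dihedrals)
  span <- max(apply(pep$frame$coords, 2, function(v) diff(range(v))))
  box <- max((n_water * 18.01528 * 1.66053907e-3 / 0.997)^(1 / 3),
             span + 0.4)
  solvate(pep, n_molecules = n_water, box = box, seed = seed)
}

# two waters with the donor O-H of the first pointing at the second oxygen
make_water_dimer <- function(d_oo = 0.28, box = c(3, 3, 3)) {
  g <- water_model()
  half <- g$angle_HOH * pi / 180 / 2
  ang <- g$angle_HOH * pi / 180
  co <- matrix(c(
    1, 1, 1,                                     # O1
    1 + g$r_OH, 1, 1,                            # H1 points at O2
    1 + g$r_OH * cos(ang), 1 + g$r_OH * sin(ang), 1,
    1 + d_oo, 1, 1,                              # O2
    1 + d_oo + g$r_OH * cos(half), 1 + g$r_OH * sin(half), 1,
    1 + d_oo + g$r_OH * cos(half), 1 - g$r_OH * sin(half), 1),
    ncol = 3, byrow = TRUE)
  top <- topology(name = rep(c("OW", "HW1", "HW2"), 2),
                  resid = rep(1:2, each = 3),
                  resname = rep("SOL", 6))
  list(topology = top, frame = frame(co, box))
}

# native 16-residue beta-hairpin with cross-strand side-chain contacts,
# used as the toy protein of the contact/Go-model tests (with C-beta-level
# side chains an idealised helix keeps all its C-betas beyond the 0.65 nm
# contact cutoff, so a hairpin is the minimal contact-bearing fold)
make_toy_native <- function() {
  strand <- c(-120, 125)
  dih <- rbind(matrix(rep(strand, 7), ncol = 2, byrow = TRUE),
               c(42, 86), c(95, -34),
               matrix(rep(strand, 7), ncol = 2, byrow = TRUE))
  build_peptide("AKVLEDIARNFKQLWS", dih)
}
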