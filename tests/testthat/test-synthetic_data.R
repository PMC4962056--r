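# Generators: peptides, water boxes, solvation, contact-probability
# ensembles, correlated ddG tables.

test_that("an all-alpha peptide classifies as alpha and has 0.38 nm CA-CA steps", {
  pep <- build_peptide("ACDEFGHIKLMN", "alpha")
  ss <- classify_secondary_structure(pep$frame, pep$topology)
  expect_true(all(ss[2:11] == "alpha"))   # interior residues
  ca <- which(pep$topology$atoms$name == "CA")
  d <- sqrt(rowSums((pep$frame$coords[ca[-1], ] -
                       pep$frame$coords[ca[-length(ca)], ])^2))
  expect_true(all(abs(d - 0.38) < 0.01))
})

test_that("peptide construction is deterministic and validates input", {
  a <- build_peptide("AKVLE", "ppii", seed = 3)
  b <- build_peptide("AKVLE", "ppii", seed = 3)
  expect_identical(a$frame$coords, b$frame$coords)
  expect_error(build_peptide("AXB"), "unknown residue letter")
  expect_error(build_peptide("A"), "at least 2")
})

test_that("prescribed dihedrals are realised within a degree", {
  tgt <- cbind(phi = c(NA, -70, -120, -60, NA),
               psi = c(NA, 150, 130, -40, NA))
  full <- tgt; full[is.na(full)] <- -90
  pep <- build_peptide("GAVLK", full)
  d <- backbone_dihedrals(pep$frame, pep$topology)
  expect_equal(d$phi[2:4], tgt[2:4, "phi"], tolerance = 1 / 60)
  expect_equal(d$psi[2:4], tgt[2:4, "psi"], tolerance = 1 / 60)
})

test_that("water boxes respect packing and exact model geometry", {
  wb <- build_water_box(216, box = 1.86, seed = 9)
  wm <- water_molecules(wb$topology)
  expect_equal(nrow(wm), 216)
  # O-O minimum-image separations
  pairs <- combn(wm[, "O"], 2)
  d <- min_image_distance(wb$frame, pairs[1, ], pairs[2, ])
  expect_gt(min(d), 0.25)
  # exact O-H bond lengths and HOH angle
  g <- water_model()
  d1 <- min_image_distance(wb$frame, wm[, "O"], wm[, "H1"])
  d2 <- min_image_distance(wb$frame, wm[, "O"], wm[, "H2"])
  expect_equal(d1, rep(g$r_OH, 216), tolerance = 1e-12)
  expect_equal(d2, rep(g$r_OH, 216), tolerance = 1e-12)
  hh <- min_image_distance(wb$frame, wm[, "H1"], wm[, "H2"])
  ang <- 2 * asin(hh / (2 * g$r_OH)) * 180 / pi
  expect_equal(ang, rep(g$angle_HOH, 216), tolerance = 1e-9)
  expect_error(build_water_box(216, box = 1.0), "infeasible packing")
})

test_that("water orientations are isotropic against any external direction", {
  n <- 3000
  wb <- build_water_box(n, seed = 4)
  wm <- water_molecules(wb$topology)
  v1 <- wb$frame$coords[wm[, "H1"], ] - wb$frame$coords[wm[, "O"], ]
  v2 <- wb$frame$coords[wm[, "H2"], ] - wb$frame$coords[wm[, "O"], ]
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  for (dir in list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))) {
    cth <- nrm %*% dir
    expect_lt(abs(mean(3 * cth^2 - 1)), 3 / sqrt(n))
  }
})

test_that("solvation removes exactly the overlapping waters", {
  pep <- build_peptide("AKVLE", "ppii")
  sys <- solvate(pep, n_molecules = 216, seed = 5, clearance = 0.24)
  top <- sys$topology
  heavy <- protein_heavy_atoms(top)
  wm <- water_molecules(top)
  # no retained oxygen within the clearance
  dmin <- vapply(wm[, "O"], function(o) {
    min(min_image_distance(sys$frame, rep(o, length(heavy)), heavy))
  }, numeric(1))
  expect_gt(min(dmin), 0.24)
  # brute-force overlap scan on the pristine box gives the deletion count
  wb <- build_water_box(216, seed = 5)
  pc <- pep$frame$coords
  pc <- sweep(pc, 2, colMeans(pc)) +
    matrix(wb$frame$box / 2, nrow(pc), 3, byrow = TRUE)
  wm0 <- water_molecules(wb$topology)
  co <- rbind(pc, wb$frame$coords)
  fr <- frame(co, wb$frame$box)
  hv0 <- which(pep$topology$atoms$is_heavy)
  del <- sum(vapply(wm0[, "O"] + nrow(pc), function(o) {
    min(min_image_distance(fr, rep(o, length(hv0)), hv0)) <= 0.24
  }, logical(1)))
  expect_equal(nrow(wm), 216 - del)
  # solvating nothing reproduces the plain water box
  expect_equal(solvate(NULL, 64, seed = 3)$frame$coords,
               build_water_box(64, seed = 3)$frame$coords)
})

test_that("generated ensembles hit the contact-formation limits exactly", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  expect_gt(nrow(map$atom_pairs), 5)
  e1 <- generate_ensemble(nat, 1, n_frames = 5, seed = 2, map = map)
  for (fr in e1$frames) {
    expect_equal(fraction_native_contacts(fr, map), 1)
  }
  e0 <- generate_ensemble(nat, 0, n_frames = 5, seed = 2, map = map)
  for (fr in e0$frames) {
    expect_equal(fraction_native_contacts(fr, map), 0)
  }
  expect_error(generate_ensemble(nat, 1.4, 2, map = map), "\\[0, 1\\]")
})

test_that("per-contact formation frequencies follow the prescribed probability", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  n <- 400
  ens <- generate_ensemble(nat, 0.5, n_frames = n, seed = 8, map = map)
  formed <- sapply(ens$frames, function(fr) {
    hydrophi:::.formed_flags(fr, map, map$cutoff)
  })
  freq <- rowMeans(formed)
  se <- sqrt(0.5 * 0.5 / n)
  expect_true(all(abs(freq - 0.5) <= 3 * se))
  # ensemble-mean Q matches the closed form (mean of the probabilities)
  qbar <- mean(sapply(ens$frames, fraction_native_contacts, map = map))
  expect_lt(abs(qbar - 0.5), 3 * se)
  # determinism
  ens2 <- generate_ensemble(nat, 0.5, n_frames = 3, seed = 8, map = map)
  expect_identical(ens2$frames[[1]]$coords, ens$frames[[1]]$coords)
})

test_that("ddG tables reproduce the target correlation constructively", {
  tab <- generate_ddg_table(30, 0.77, seed = 1)
  # independent correlation computation from the definition
  x <- tab$ddG_DN; y <- tab$ddG_TSN
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, 0.77, tolerance = 1e-10)
  # exact collinearity at r = 1
  tab1 <- generate_ddg_table(10, 1, seed = 2)
  expect_equal(abs(cor(tab1$ddG_DN, tab1$ddG_TSN)), 1, tolerance = 1e-12)
  expect_error(generate_ddg_table(2, 0.5), "at least 3")
  expect_error(generate_ddg_table(10, 1.2), "\\[-1, 1\\]")
})
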