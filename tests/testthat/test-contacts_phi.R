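# Native contacts, Q, Phi-values, the restraint pseudo-energy and
# Bronsted statistics.

test_that("native contacts apply the distance cutoff and neighbour exclusion", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  resid <- nat$topology$atoms$resid
  d <- min_image_distance(nat$frame, map$atom_pairs[, 1], map$atom_pairs[, 2])
  expect_true(all(d <= 0.65))
  expect_true(all(abs(resid[map$atom_pairs[, 1]] -
                        resid[map$atom_pairs[, 2]]) >= 2))
  expect_false(anyDuplicated(map$atom_pairs) > 0)
  # only side-chain heavy atoms take part
  nm <- nat$topology$atoms$name
  expect_true(all(nm[map$atom_pairs] == "CB"))
  # a 0.60 nm side-chain pair of residues i, i+3 is in; at 0.70 nm it is out
  mk_pair <- function(d) {
    top <- topology(name = rep(c("N", "CA", "C", "O", "CB"), 4),
                    resid = rep(1:4, each = 5),
                    resname = rep("ALA", 20))
    co <- matrix(rep(seq(0, by = 0.2, length.out = 20), 3), ncol = 3)
    co[, 2:3] <- 0
    cb1 <- 5; cb4 <- 20
    co[cb1, ] <- c(0, 2, 0)
    co[cb4, ] <- c(d, 2, 0)
    list(topology = top, frame = frame(co + 3, c(12, 12, 12)))
  }
  in_map <- native_contacts(mk_pair(0.60))
  expect_true(any(in_map$residue_pairs$res_i == 1 &
                    in_map$residue_pairs$res_j == 4))
  out_map <- native_contacts(mk_pair(0.70))
  expect_false(any(out_map$residue_pairs$res_i == 1 &
                     out_map$residue_pairs$res_j == 4))
  none <- native_contacts(nat, cutoff = 0.2)
  expect_equal(nrow(none$atom_pairs), 0)
  # a fully extended chain has no contacts at all
  ext <- build_peptide("AKVLEDIARN", "beta")
  expect_equal(nrow(native_contacts(ext)$atom_pairs), 0)
})

test_that("Q is 1 in the native frame, 0 when extended, 0.5 when half broken", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  expect_equal(fraction_native_contacts(nat$frame, map), 1)
  expect_error(
    fraction_native_contacts(nat$frame,
                             native_contacts(nat, cutoff = 0.2)),
    "empty")
  # break exactly half of the atom-pair contacts by construction
  nc <- nrow(map$atom_pairs)
  half <- nc %/% 2
  p <- c(rep(0, half), rep(1, nc - half))
  ens <- generate_ensemble(nat, p, n_frames = 1, seed = 4, map = map)
  expect_equal(fraction_native_contacts(ens$frames[[1]], map),
               (nc - half) / nc)
})

test_that("the contact-formation map is symmetric, bounded, and exact in limits", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  ens_nat <- ensemble(nat$topology, list(nat$frame, nat$frame))
  m <- contact_formation_map(ens_nat, map)
  expect_equal(m, t(m))
  expect_true(all(m[!is.na(m)] == 1))
  ens <- generate_ensemble(nat, 0.3, n_frames = 300, seed = 6, map = map)
  m <- contact_formation_map(ens, map)
  vals <- m[upper.tri(m)]
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 1))
  # per-entry binomial agreement at n = 300 (entries average >= 1 pair)
  se <- sqrt(0.3 * 0.7 / 300)
  expect_true(all(abs(vals - 0.3) <= 3.5 * se))
})

test_that("ensemble Phi-values hit the limits and the two-frame average", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  ens_nat <- ensemble(nat$topology, list(nat$frame))
  phi1 <- phi_from_ensemble(ens_nat, map)
  expect_true(all(phi1$phi[phi1$valid] == 1))
  # residues with no native contacts are flagged invalid
  with_contacts <- unique(c(map$residue_pairs$res_i, map$residue_pairs$res_j))
  expect_setequal(phi1$residue[phi1$valid], with_contacts)

  ens0 <- generate_ensemble(nat, 0, n_frames = 1, seed = 2, map = map)
  phi0 <- phi_from_ensemble(ens0, map)
  expect_true(all(phi0$phi[phi0$valid] == 0))

  mix <- ensemble(nat$topology, list(nat$frame, ens0$frames[[1]]))
  phim <- phi_from_ensemble(mix, map)
  expect_true(all(phim$phi[phim$valid] == 0.5))
})

test_that("Phi recovery and the contact-map marginalisation identity hold", {
  nat <- make_toy_native()
  map <- native_contacts(nat)
  n <- 300
  ens <- generate_ensemble(nat, 0.4, n_frames = n, seed = 10, map = map)
  phi <- phi_from_ensemble(ens, map)
  se <- sqrt(0.4 * 0.6 / n)
  expect_true(all(abs(phi$phi[phi$valid] - 0.4) <= 3.5 * se))
  # marginalising the residue-level map with atom-pair weights reproduces Phi
  m <- contact_formation_map(ens, map)
  rp <- map$residue_pairs
  for (r in phi$residue[phi$valid]) {
    sel <- rp$res_i == r | rp$res_j == r
    partner <- ifelse(rp$res_i[sel] == r, rp$res_j[sel], rp$res_i[sel])
    w <- rp$n_pairs[sel]
    expect_equal(sum(w * m[cbind(r, partner)]) / sum(w),
                 phi$phi[phi$residue == r], tolerance = 1e-12)
  }
})

test_that("the restraint energy is quadratic, selective and zero at agreement", {
  sim <- phi_set(1:4, c(0.5, 0.2, 0.9, 0.1))
  expect_equal(phi_restraint_energy(sim, sim, k = 7), 0)
  exp1 <- phi_set(1, 0.0)
  sim1 <- phi_set(1, 0.5)
  expect_equal(phi_restraint_energy(sim1, exp1, k = 1), 0.25)
  # residues with experimental Phi outside [0, 1] do not contribute
  expv <- structure(data.frame(residue = 1:2, phi = c(0.0, 1.7),
                               valid = c(TRUE, TRUE)),
                    class = c("phi_set", "data.frame"))
  simv <- phi_set(1:2, c(0.5, 0.3))
  expect_equal(phi_restraint_energy(simv, expv, k = 1), 0.25)
  expv$phi[2] <- -0.4
  expect_equal(phi_restraint_energy(simv, expv, k = 1), 0.25)
  # quadratic scaling: deviations scaled by c scale E by c^2
  exp4 <- phi_set(1:4, c(0.2, 0.4, 0.6, 0.8))
  dev <- c(0.1, -0.05, 0.2, -0.1)
  e1 <- phi_restraint_energy(phi_set(1:4, exp4$phi + dev), exp4, k = 3)
  e2 <- phi_restraint_energy(phi_set(1:4, exp4$phi + 2 * dev), exp4, k = 3)
  expect_equal(e2, 4 * e1, tolerance = 1e-12)
  expect_gte(e1, 0)
  expect_error(phi_restraint_energy(phi_set(1, NA, valid = FALSE), exp1),
               "no residue")
})

test_that("Phi from ddG tables follows the definition and the reliability floor", {
  tab <- structure(data.frame(residue = 1:3,
                              ddG_DN = c(5, 5, 1),
                              ddG_TSN = c(0, 5, 0.2)),
                   class = c("ddg_table", "data.frame"))
  phi <- phi_from_ddg(tab, min_ddg = 2.5)
  expect_equal(phi$phi[1], 1)    # TS destabilised like N
  expect_equal(phi$phi[2], 0)    # TS destabilised like D
  expect_false(phi$valid[3])     # |ddG_DN| below the floor
  # multi-mutant residues are averaged with a warning
  tab2 <- structure(data.frame(residue = c(1, 1), ddG_DN = c(5, 5),
                               ddG_TSN = c(0, 5)),
                    class = c("ddg_table", "data.frame"))
  expect_warning(phi2 <- phi_from_ddg(tab2), "averaging")
  expect_equal(phi2$phi, 0.5)
})

test_that("Bronsted statistics recover generator targets exactly", {
  lin <- structure(data.frame(residue = 1:5, ddG_DN = 1:5,
                              ddG_TSN = 0.3 * (1:5) + 1),
                   class = c("ddg_table", "data.frame"))
  b <- bronsted(lin)
  expect_equal(b$pearson_r, 1)
  expect_equal(b$slope, 0.3)
  for (r in c(0, 0.48, 0.77, 1)) {
    tab <- generate_ddg_table(30, r, seed = 1)
    expect_equal(bronsted(tab)$pearson_r, r, tolerance = 1e-10)
  }
  expect_error(bronsted(lin[1:2, ]), "at least 3")
  flat <- lin; flat$ddG_DN <- 2
  expect_error(bronsted(flat), "zero variance")
})

test_that("ddG tables and Phi sets round trip through TSV", {
  tab <- generate_ddg_table(12, 0.6, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ddg_table(tab, path)
  back <- read_ddg_table(path)
  expect_equal(back$ddG_DN, tab$ddG_DN, tolerance = 1e-12)
  phi <- phi_from_ddg(tab)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_phi_set(phi, p2)
  expect_equal(read_phi_set(p2)$phi, phi$phi, tolerance = 1e-12)
})
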