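# Hydrogen-bond detection, interface/bulk bookkeeping, RDF and the
# rotational-anisotropy profile.

test_that("an ideal water dimer gives exactly one ww bond, lost beyond the cutoff", {
  dim28 <- make_water_dimer(0.28)
  hb <- detect_hbonds(dim28$frame, dim28$topology)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$category, "ww")
  expect_equal(hb$donor, 1)
  expect_equal(hb$acceptor, 4)
  dim36 <- make_water_dimer(0.36)
  expect_equal(nrow(detect_hbonds(dim36$frame, dim36$topology)), 0)
  # hydrogen-free input is refused with advice
  top_noh <- topology(name = c("N", "CA"), resid = c(1, 1),
                      resname = c("ALA", "ALA"))
  fr <- frame(rbind(c(0, 0, 0), c(0.15, 0, 0)), c(3, 3, 3))
  expect_error(detect_hbonds(fr, top_noh), "all-atom")
})

test_that("detection matches the all-triples oracle on a dense random box", {
  wb <- build_water_box(50, seed = 13)
  got <- detect_hbonds(wb$frame, wb$topology)
  want <- bf_hbonds(wb$frame, wb$topology)
  expect_gt(nrow(got), 0)
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_equal(key(as.matrix(got[, 1:3])), key(want))
})

test_that("bond detection is invariant under rigid translation", {
  wb <- build_water_box(50, seed = 13)
  hb0 <- detect_hbonds(wb$frame, wb$topology)
  shifted <- frame(sweep(wb$frame$coords, 2, -c(0.71, 1.13, -0.37)),
                   wb$frame$box)
  hb1 <- detect_hbonds(shifted, wb$topology)
  expect_equal(hb0[order(hb0$donor, hb0$acceptor), ],
               hb1[order(hb1$donor, hb1$acceptor), ],
               ignore_attr = TRUE)
})

test_that("waters are split at the first-shell cutoff measured to heavy atoms", {
  g <- water_model()
  half <- g$angle_HOH * pi / 180 / 2
  mk <- function(d) {
    co <- rbind(c(1, 1, 1),                       # protein heavy atom
                c(1 + d, 1, 1),
                c(1 + d + g$r_OH * cos(half), 1 + g$r_OH * sin(half), 1),
                c(1 + d + g$r_OH * cos(half), 1 - g$r_OH * sin(half), 1))
    top <- topology(name = c("CA", "OW", "HW1", "HW2"),
                    resid = c(1, 2, 2, 2),
                    resname = c("ALA", "SOL", "SOL", "SOL"))
    list(frame = frame(co, c(4, 4, 4)), topology = top)
  }
  near <- mk(0.35)
  expect_equal(classify_waters(near$frame, near$topology)$interface, 1L)
  far <- mk(0.45)
  expect_equal(classify_waters(far$frame, far$topology)$bulk, 1L)
  # without protein everything is bulk
  wb <- build_water_box(8, box = 2, seed = 1)
  cls <- classify_waters(wb$frame, wb$topology)
  expect_equal(length(cls$interface), 0)
  expect_equal(length(cls$bulk), 8)
})

test_that("the hydration report matches manual enumeration on a hand fixture", {
  # protein carbonyl O (acceptor) + amide N-H (donor), one interface water
  # donating to the carbonyl and accepting from a second interface water
  g <- water_model()
  ang <- g$angle_HOH * pi / 180
  co <- rbind(
    c(1.0, 1.0, 1.0),                       # C    (protein)
    c(1.0, 1.123, 1.0),                     # O    acceptor
    c(2.2, 1.0, 1.0),                       # N    (protein)
    c(2.2, 1.101, 1.0),                     # H on N
    # W1: O at 0.28 above the carbonyl O, donating straight down
    c(1.0, 1.403, 1.0),
    c(1.0, 1.403 - g$r_OH, 1.0),
    c(1.0 + g$r_OH * sin(ang), 1.403 - g$r_OH * cos(ang), 1.0),
    # W2: O 0.28 above W1, donating straight down to W1
    c(1.0, 1.683, 1.0),
    c(1.0, 1.683 - g$r_OH, 1.0),
    c(1.0 + g$r_OH * sin(ang), 1.683 - g$r_OH * cos(ang), 1.0),
    # W3: far-away bulk water
    c(3.5, 3.5, 3.5),
    c(3.5 + g$r_OH, 3.5, 3.5),
    c(3.5 + g$r_OH * cos(ang), 3.5 + g$r_OH * sin(ang), 3.5))
  top <- topology(
    name = c("C", "O", "N", "H", rep(c("OW", "HW1", "HW2"), 3)),
    resid = c(1, 1, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5),
    resname = c("ALA", "ALA", "ALA", "ALA", rep("SOL", 9)))
  fr <- frame(co, c(5, 5, 5))
  hb <- detect_hbonds(fr, top)
  expect_equal(sort(hb$category), c("wp", "ww"))
  rep <- hydration_report(ensemble(top, list(fr)))
  # only W1 (0.28 nm from the carbonyl O) is inside the 0.4 nm shell
  expect_equal(rep$n_interface_waters, 1)
  expect_equal(rep$n_bulk_waters, 2)
  # W1: one wp (donated to the carbonyl) + one ww (accepted from W2)
  expect_equal(rep$hb_wp_interface, 1)
  expect_equal(rep$hb_ww_interface, 1)
  expect_identical(rep$hb_total_interface,
                   rep$hb_ww_interface + rep$hb_wp_interface)
  # W2 carries one ww bond, W3 none
  expect_equal(rep$hb_bulk, 0.5)
  expect_equal(rep$hb_pw_total, 1)
  expect_equal(rep$hb_pp_total, 0)
})

test_that("interface totals conserve ww + wp on arbitrary input and weights", {
  sys <- make_solvated(n_water = 216, seed = 6)
  ens <- ensemble(sys$topology, list(sys$frame))
  rep1 <- hydration_report(ens)
  expect_identical(rep1$hb_total_interface,
                   rep1$hb_ww_interface + rep1$hb_wp_interface)
  # duplicating every frame with renormalised weights changes nothing
  ens2 <- ensemble(sys$topology, list(sys$frame, sys$frame))
  rep2 <- hydration_report(ens2)
  for (f in c("hb_ww_interface", "hb_wp_interface", "hb_total_interface",
              "hb_bulk", "hb_pp_total", "hb_pw_total")) {
    expect_equal(rep1[[f]], rep2[[f]])
  }
})

test_that("the unnormalised RDF matches a direct pair loop", {
  # single pair at a known distance
  g <- water_model()
  half <- g$angle_HOH * pi / 180 / 2
  co <- rbind(c(1, 1, 1), c(1.30, 1, 1),
              c(1.30 + g$r_OH * cos(half), 1 + g$r_OH * sin(half), 1),
              c(1.30 + g$r_OH * cos(half), 1 - g$r_OH * sin(half), 1))
  top <- topology(name = c("CA", "OW", "HW1", "HW2"), resid = c(1, 2, 2, 2),
                  resname = c("ALA", "SOL", "SOL", "SOL"))
  ens <- ensemble(top, list(frame(co, c(4, 4, 4))))
  r <- rdf_unnormalized(ens, bin_width = 0.01, r_max = 1.0)
  expect_equal(sum(r$counts), 1)
  b <- which(r$counts == 1)
  expect_lt(abs((b - 0.5) * 0.01 - 0.30), 0.01)   # containing bin only

  sys <- make_solvated(n_water = 64, seed = 12)
  ens <- ensemble(sys$topology, list(sys$frame))
  got <- rdf_unnormalized(ens, 0.05, 0.8)
  wm <- water_molecules(sys$topology)
  prot <- protein_atoms(sys$topology)
  want <- numeric(length(got$counts))
  for (o in wm[, "O"]) for (p in prot) {
    d <- min_image_distance(sys$frame, o, p)
    if (d <= 0.8 && d > 0) {
      b <- min(ceiling(d / 0.05), length(want))
      want[b] <- want[b] + 1
    }
  }
  expect_equal(got$counts, want)
  expect_equal(sum(got$counts), sum(want))
})

test_that("the anisotropy profile matches explicit trigonometry", {
  # water normals aligned with the O->atom direction: 3cos^2-1 = 2
  g <- water_model()
  half <- g$angle_HOH * pi / 180 / 2
  s <- g$r_OH * sin(half); c0 <- g$r_OH * cos(half)
  co <- rbind(c(1, 1, 1.30),                     # protein atom above
              c(1, 1, 1),                        # O; normal = z
              c(1 + s, 1 + c0 * s / s * 0, 1),   # H1 in xy-plane
              c(1 - s, 1, 1))
  co[3, ] <- c(1 + s, 1 + 0.02, 1)
  co[4, ] <- c(1 - s, 1 + 0.02, 1)
  top <- topology(name = c("CA", "OW", "HW1", "HW2"), resid = c(1, 2, 2, 2),
                  resname = c("ALA", "SOL", "SOL", "SOL"))
  ens <- ensemble(top, list(frame(co, c(4, 4, 4))))
  prof <- anisotropy_profile(ens, 0.01, 1.0)
  b <- which(prof$rdf == 1)
  expect_equal(prof$mean_orient[b], 2, tolerance = 1e-10)
  expect_equal(prof$A[b], 2 * prof$rdf[b], tolerance = 1e-10)

  # 10-water fixture against a brute-force pair loop
  sys <- make_solvated(n_water = 27, seed = 3)
  ens <- ensemble(sys$topology, list(sys$frame))
  prof <- anisotropy_profile(ens, 0.05, 1.0)
  wm <- water_molecules(sys$topology)
  prot <- protein_atoms(sys$topology)
  nb <- length(prof$A)
  s_acc <- counts <- numeric(nb)
  fr <- sys$frame
  mi_vec <- function(a, b) {
    v <- fr$coords[b, ] - fr$coords[a, ]
    v - fr$box * round(v / fr$box)
  }
  for (k in seq_len(nrow(wm))) {
    v1 <- mi_vec(wm[k, "O"], wm[k, "H1"])
    v2 <- mi_vec(wm[k, "O"], wm[k, "H2"])
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    for (p in prot) {
      v <- mi_vec(wm[k, "O"], p)
      r <- sqrt(sum(v^2))
      if (r > 1.0 || r == 0) next
      b <- min(ceiling(r / 0.05), nb)
      cth <- sum(v * nrm) / r
      s_acc[b] <- s_acc[b] + 3 * cth^2 - 1
      counts[b] <- counts[b] + 1
    }
  }
  want_A <- ifelse(counts > 0, s_acc / counts, 0) * counts
  expect_equal(prof$A, want_A, tolerance = 1e-12)
  expect_equal(prof$rdf, counts)
  # bounds: per-pair orientation parameter in [-1, 2]
  expect_true(all(prof$mean_orient >= -1 - 1e-12 &
                    prof$mean_orient <= 2 + 1e-12))
  expect_true(all(abs(prof$A) <= 2 * prof$rdf + 1e-12))
})

test_that("the absolute integral follows the rectangle rule", {
  prof <- structure(list(A = c(2, 0, -1.5), rdf = c(1, 0, 1),
                         bin_width = 0.01,
                         bin_edges = seq(0, 0.03, by = 0.01)),
                    class = "anisotropy_profile")
  expect_equal(total_anisotropy(prof), (2 + 1.5) * 0.01)
  prof$A <- c(0, 0, 0)
  expect_equal(total_anisotropy(prof), 0)
  # agreement with independent quadrature on a computed profile
  sys <- make_solvated(n_water = 64, seed = 2)
  p <- anisotropy_profile(ensemble(sys$topology, list(sys$frame)), 0.02, 1.2)
  expect_equal(total_anisotropy(p), sum(abs(p$A)) * 0.02, tolerance = 1e-12)
  expect_gte(total_anisotropy(p), 0)
})

test_that("anisotropy of isotropic orientations vanishes with system size", {
  # single distant probe atom; random orientations at fixed O distances
  res <- vapply(c(100, 1000, 10000), function(n) {
    wb <- build_water_box(n, seed = n)
    top0 <- wb$topology
    co <- rbind(c(0.05, 0.05, 0.05), wb$frame$coords)
    top <- topology(name = c("CA", top0$atoms$name),
                    resid = c(1, top0$atoms$resid + 1),
                    resname = c("ALA", top0$atoms$resname))
    ens <- ensemble(top, list(frame(co, wb$frame$box)))
    prof <- anisotropy_profile(ens, 0.25, min(wb$frame$box) / 2)
    sum(abs(prof$A)) / sum(prof$rdf)   # mean |orientation| per pair
  }, numeric(1))
  expect_true(res[3] < res[1])
  # and the largest system is close to the isotropic null
  expect_lt(res[3], 3 / sqrt(10000 / 4))
})
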