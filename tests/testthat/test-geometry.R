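test_that("bond length and angle agree with a law-of-cosines oracle", {
  expect_equal(bond_length(c(0, 0, 0), c(1, 0, 0)), 1.0)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(42)
  for (rep in 1:25) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    # oracle: angle at b from the three side lengths
    ab <- sqrt(sum((a - b)^2)); cb <- sqrt(sum((c - b)^2))
    ac <- sqrt(sum((a - c)^2))
    oracle <- acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
    expect_lt(abs(bond_angle(a, b, c) - oracle), 1e-9)
  }
  expect_error(bond_length(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("dihedral matches an independent atan2-of-cross-products oracle", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(abs(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))), 180)
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  oracle <- function(a, b, c, d) {
    # project bond vectors onto the plane normal to b->c and take the
    # signed angle between the projections
    bc <- (c - b) / sqrt(sum((c - b)^2))
    v1 <- (a - b) - sum((a - b) * bc) * bc
    v2 <- (d - c) - sum((d - c) * bc) * bc
    ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    s <- sign(sum(cross(v1, v2) * bc))
    -s * ang * 180 / pi
  }
  set.seed(7)
  for (rep in 1:25) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3); d <- rnorm(3)
    expect_lt(abs(wrap_angle(dihedral(a, b, c, d) - oracle(a, b, c, d))), 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("place_next_atom inverts measurement and is rigid-motion equivariant", {
  expect_equal(place_next_atom(c(-1, 1, 0), c(-1, 0, 0), c(0, 0, 0), 1, 90, 0),
               c(0, 1, 0), tolerance = 1e-9)
  expect_equal(place_next_atom(c(-1, 1, 0), c(-1, 0, 0), c(0, 0, 0), 1, 90, 180),
               c(0, -1, 0), tolerance = 1e-9)
  set.seed(3)
  for (rep in 1:25) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    len <- runif(1, 0.9, 1.9); ang <- runif(1, 30, 150)
    tor <- runif(1, -179, 180)
    d <- place_next_atom(a, b, c, len, ang, tor)
    expect_lt(abs(bond_length(c, d) - len), 1e-6)
    expect_lt(abs(bond_angle(b, c, d) - ang), 1e-6)
    expect_lt(abs(wrap_angle(dihedral(a, b, c, d) - tor)), 1e-6)
    # equivariance under a random rotation + translation
    qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(qr_) < 0) qr_[, 1] <- -qr_[, 1]
    tr <- rnorm(3)
    d2 <- place_next_atom(qr_ %*% a + tr, qr_ %*% b + tr, qr_ %*% c + tr,
                          len, ang, tor)
    expect_equal(as.numeric(d2), as.numeric(qr_ %*% d + tr), tolerance = 1e-9)
  }
})

test_that("the ideal table covers the backbone and honors per-residue overrides", {
  expect_equal(ideal_value(ideal_tab, "N-CA"), 1.458)
  expect_equal(ideal_value(ideal_tab, "N-CA", "GLY"), 1.451)
  expect_equal(ideal_value(ideal_tab, "N-CA", "PRO"), 1.466)
  expect_equal(ideal_value(ideal_tab, "C-N", c("ALA", "PRO")), c(1.329, 1.341))
  expect_equal(ideal_value(ideal_tab, "N-CA-C", "GLY"), 112.5)
  expect_true(all(ideal_tab$bonds$value > 0.8 & ideal_tab$bonds$value < 2.0))
  expect_true(all(ideal_tab$angles$value > 90 & ideal_tab$angles$value < 180))
  expect_error(ideal_value(ideal_tab, "X-Y"), "unknown")
})

test_that("rebuilt O/H/CB atoms have exactly ideal local geometry", {
  pep <- make_ideal_peptide(c("ALA", "ALA"))
  expect_lt(max_geometry_dev(pep), 1e-6)
  a <- pep$atoms
  r1 <- a[a$residue_index == 1, ]
  g <- function(nm) as.numeric(r1[r1$name == nm, c("x", "y", "z")])
  # carbonyl O trans to the next N, in the peptide plane
  n2 <- as.numeric(a[a$residue_index == 2 & a$name == "N", c("x", "y", "z")])
  expect_equal(abs(dihedral(n2, g("CA"), g("C"), g("O"))), 180, tolerance = 1e-6)
  # Gly has no CB, Pro no amide H
  ag <- make_ideal_peptide(c("ALA", "GLY"))$atoms
  expect_false("CB" %in% ag$name[ag$residue_index == 2])
  ap <- make_ideal_peptide(c("ALA", "PRO"))$atoms
  expect_false("H" %in% ap$name[ap$residue_index == 2])
  # L chirality: improper dihedral N-C-CA-CB near -122 degrees
  expect_lt(dihedral(g("N"), g("C"), g("CA"), g("CB")), -100)
  expect_gt(dihedral(g("N"), g("C"), g("CA"), g("CB")), -145)
})

test_that("rebuilt CB falls near the deposited CB of a realistic fragment", {
  # synthetic stand-in for a high-resolution structure: a peptide chained
  # with bond lengths/angles jittered at crystallographic spreads
  # (0.02 A, 1.5 deg) and CB placed from jittered tetrahedral angles
  set.seed(19)
  n <- 6
  coords <- matrix(NA_real_, 3 * n, 3)
  coords[1:3, ] <- canonical_anchor("ALA", ideal_tab)
  phi <- runif(n, -140, -50); psi <- runif(n, -60, 150)
  jl <- function(nm) ideal_value(ideal_tab, nm) + rnorm(1, 0, 0.02)
  ja <- function(nm) ideal_value(ideal_tab, nm) + rnorm(1, 0, 1.5)
  for (t in 4:(3 * n)) {
    i <- (t + 2) %/% 3; kind <- (t - 1) %% 3
    prm <- switch(kind + 1,
      list(jl("C-N"), ja("CA-C-N"), psi[i - 1]),
      list(jl("N-CA"), ja("C-N-CA"), 180 + rnorm(1, 0, 3)),
      list(jl("CA-C"), ja("N-CA-C"), phi[i]))
    coords[t, ] <- place_next_atom(coords[t - 3, ], coords[t - 2, ],
                                   coords[t - 1, ], prm[[1]], prm[[2]], prm[[3]])
  }
  s <- protein_from_backbone(coords, rep("ALA", n))
  deposited_cb <- t(vapply(seq_len(n), function(i) {
    j <- 3 * (i - 1)
    protideal:::.place_cb(coords[j + 1, , drop = FALSE],
                          coords[j + 2, , drop = FALSE],
                          coords[j + 3, , drop = FALSE],
                          jl("CA-CB"), ja("N-CA-CB"), ja("C-CA-CB"))[1, ]
  }, numeric(3)))
  rebuilt <- rebuild_dependent_atoms(s, ideal_tab)
  cb <- atom_coords(rebuilt, "CB")
  expect_lt(max(sqrt(rowSums((cb - deposited_cb)^2))), 0.25)
})

test_that("build_from_torsions and extract_torsions are mutually inverse", {
  # alpha-helical poly-ALA round trip
  s <- make_ideal_peptide("AAAAA", phi = -57, psi = -47, omega = 180)
  t <- extract_torsions(s)
  expect_equal(t$phi[-1], rep(-57, 4), tolerance = 1e-6)
  expect_equal(t$psi[-5], rep(-47, 4), tolerance = 1e-6)
  expect_equal(abs(wrap_angle(t$omega[-5] - 180)), rep(0, 4), tolerance = 1e-6)
  expect_lt(max_geometry_dev(s), 1e-6)

  # cis peptide: CA atoms on the same side (short CA-CA distance)
  sc <- make_ideal_peptide("AA", omega = 0)
  ca <- atom_coords(sc, "CA")
  expect_lt(bond_length(ca[1, ], ca[2, ]), 3.2)
  st <- make_ideal_peptide("AA", omega = 180)
  cat2 <- atom_coords(st, "CA")
  expect_gt(bond_length(cat2[1, ], cat2[2, ]), 3.6)

  # random torsion round trip to 1e-6 degrees, with rebuild anchored on the
  # extracted frame reproducing coordinates to 1e-4 A
  set.seed(12)
  n <- 7
  tor <- data.frame(residue_index = 1:n, residue_type = "ALA",
                    phi = c(NA, runif(n - 1, -180, 180)),
                    psi = c(runif(n - 1, -180, 180), NA),
                    omega = c(sample(c(0, 180), n - 1, TRUE), NA))
  s2 <- build_from_torsions(rep("ALA", n), tor, ideal_tab)
  t2 <- extract_torsions(s2)
  expect_lt(max(abs(wrap_angle(t2$phi[-1] - tor$phi[-1]))), 1e-6)
  expect_lt(max(abs(wrap_angle(t2$psi[-n] - tor$psi[-n]))), 1e-6)
  expect_lt(max(abs(wrap_angle(t2$omega[-n] - tor$omega[-n]))), 1e-6)
  bb <- backbone_coords(s2)
  s3 <- build_from_torsions(rep("ALA", n), t2, ideal_tab,
                            anchor = rbind(bb$N[1, ], bb$CA[1, ], bb$C[1, ]))
  expect_lt(max(abs(atom_coords(s3, "CA") - atom_coords(s2, "CA"))), 1e-4)
  expect_error(build_from_torsions(rep("ALA", 3),
                                   data.frame(phi = c(NA, NA, -60),
                                              psi = c(-45, -45, NA),
                                              omega = c(180, 180, NA))),
               "undefined")
})
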