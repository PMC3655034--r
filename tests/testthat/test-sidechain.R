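test_that("chi grids have 2*floor(3 sigma / step) + 1 samples per dimension", {
  rot_ser <- get_rotamers(toy$rotamers, "SER")[1, ]
  g <- enumerate_chi("SER", rot_ser, step = 10, window_sigmas = 3)
  # sigma 11 -> floor(33/10) = 3 -> 7 samples
  expect_equal(nrow(g), 7L)
  expect_equal(sort(wrap_angle(g[, 1] - rot_ser$m1)), seq(-30, 30, 10))
  rot_leu <- get_rotamers(toy$rotamers, "LEU")[1, ]
  g2 <- enumerate_chi("LEU", rot_leu, step = 10, window_sigmas = 3)
  # sigma 10 and 11 -> 7 x 7 = 49 tuples
  expect_equal(nrow(g2), 49L)
  expect_equal(ncol(g2), 2L)
  expect_error(enumerate_chi("GLY", rot_ser), "no chi")
  # all samples wrapped into (-180, 180]
  rot_val <- get_rotamers(toy$rotamers, "VAL")
  gv <- enumerate_chi("VAL", rot_val[rot_val$m1 == 175, ][1, ],
                      step = 10, window_sigmas = 3)
  expect_true(all(gv > -180 & gv <= 180))
})

test_that("built side chains measure back their chi angles with ideal geometry", {
  for (case in list(list(aa = "LYS", chis = c(-65, 175, 175, 175)),
                    list(aa = "TRP", chis = c(-177, -105, NA, NA)),
                    list(aa = "THR", chis = c(62, NA, NA, NA)))) {
    k <- n_chi(case$aa)
    chis <- matrix(NA_real_, 3, 4); chis[2, ] <- case$chis
    pep <- make_ideal_peptide(c("ALA", case$aa, "ALA"), chis = chis)
    meas <- measure_chis(pep, 2)
    expect_equal(meas[seq_len(k)], case$chis[seq_len(k)], tolerance = 1e-6)
    # every built bond length/angle equals its topology value
    topo <- protideal:::.SC_TOPO[[case$aa]]
    a <- pep$atoms[pep$atoms$residue_index == 2, ]
    g <- function(nm) as.numeric(a[a$name == nm, c("x", "y", "z")])
    for (r in seq_len(nrow(topo))) {
      expect_lt(abs(bond_length(g(topo$c[r]), g(topo$name[r])) - topo$len[r]),
                1e-6)
      expect_lt(abs(bond_angle(g(topo$b[r]), g(topo$c[r]), g(topo$name[r])) -
                      topo$ang[r]), 1e-6)
    }
  }
})

test_that("arginine guanidinium torsions are rounded to 0 and 180", {
  chis <- matrix(NA_real_, 2, 4); chis[1, ] <- c(-65, 175, 180, 180)
  pep <- make_ideal_peptide(c("ARG", "ALA"), chis = chis)
  a <- pep$atoms[pep$atoms$residue_index == 1, ]
  g <- function(nm) as.numeric(a[a$name == nm, c("x", "y", "z")])
  expect_equal(dihedral(g("CD"), g("NE"), g("CZ"), g("NH1")), 0,
               tolerance = 1e-6)
  expect_equal(abs(dihedral(g("CD"), g("NE"), g("CZ"), g("NH2"))), 180,
               tolerance = 1e-6)
})

test_that("side chains at a rotamer mean are self-recovered within half a step", {
  chis <- matrix(NA_real_, 3, 4)
  chis[1, 1] <- 62            # SER g+ rotamer mean
  chis[2, 1:2] <- c(-65, 175) # LEU most common rotamer
  pep <- make_ideal_peptide(c("SER", "LEU", "ALA"), chis = chis)
  out <- idealize_sidechains(pep, pep, toy$rotamers, step = 10,
                             window_sigmas = 3)
  expect_equal(out$scores$chi1[1], 62, tolerance = 5)
  expect_equal(out$scores$chi1[2], -65, tolerance = 5)
  expect_equal(out$scores$chi2[2], 175, tolerance = 5)
  # the output passes the full geometry invariant (backbone + O/H/CB)
  expect_lt(max_geometry_dev(out$structure), 1e-6)
  # ALA/GLY are skipped
  expect_true(all(is.na(out$scores$chi1[3])))
})

test_that("residues are idealized independently of each other", {
  chis <- matrix(NA_real_, 4, 4)
  chis[2, 1] <- 62; chis[3, 1:2] <- c(-65, 175)
  pep <- make_ideal_peptide(c("ALA", "SER", "LEU", "ALA"), chis = chis)
  full <- idealize_sidechains(pep, pep, toy$rotamers)
  # corrupting residue 3's target side chain must not change residue 2
  tweaked <- pep
  sel <- tweaked$atoms$residue_index == 3 &
    !tweaked$atoms$name %in% c("N", "CA", "C", "O", "H", "CB")
  tweaked$atoms$x[sel] <- tweaked$atoms$x[sel] + 1.5
  part <- idealize_sidechains(pep, tweaked, toy$rotamers)
  expect_equal(part$scores[2, ], full$scores[2, ])
  # rerun determinism
  again <- idealize_sidechains(pep, pep, toy$rotamers)
  expect_identical(again$scores, full$scores)
})

test_that("the kept conformation attains the exhaustive maximum (1-residue oracle)", {
  chis <- matrix(NA_real_, 2, 4); chis[1, 1] <- 70
  pep <- make_ideal_peptide(c("SER", "ALA"), chis = chis)
  out <- idealize_sidechains(pep, pep, toy$rotamers, step = 10,
                             window_sigmas = 3)
  tor <- extract_torsions(pep)
  a <- pep$atoms[pep$atoms$residue_index == 1, ]
  g <- function(nm) as.numeric(a[a$name == nm, c("x", "y", "z")])
  tcoords <- rbind(OG = g("OG"))
  # independent enumeration through sidechain_score
  best <- -Inf
  for (rr in seq_len(nrow(get_rotamers(toy$rotamers, "SER")))) {
    rot <- get_rotamers(toy$rotamers, "SER")[rr, ]
    for (chi in enumerate_chi("SER", rot, 10, 3)[, 1]) {
      pos <- build_sidechain("SER", g("N"), g("CA"), g("CB"), chi)
      cand <- rbind(OG = pos$OG[1, ])
      sc <- sidechain_score(cand, tcoords, chi, measure_chis(pep, 1),
                            toy$rotamers, "SER", tor$phi[1], tor$psi[1])
      if (sc > best) best <- sc
    }
  }
  expect_equal(out$scores$score[1], best, tolerance = 1e-9)
})

test_that("missing target side chains fall back to free-energy-only placement", {
  pep <- make_ideal_peptide(c("ALA", "SER", "ALA"))  # no SER side chain built
  out <- idealize_sidechains(pep, pep, toy$rotamers)
  expect_true("OG" %in% out$structure$atoms$name)
  # score equals the pure chi log-odds of the chosen chi
  tor <- extract_torsions(out$structure)
  expect_equal(out$scores$score[2],
               chi_log_odds(toy$rotamers, "SER", tor$phi[2], tor$psi[2],
                            out$scores$chi1[2]),
               tolerance = 1e-9)
})
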