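test_that("bottleneck distance is the max over matched atoms", {
  p <- make_ideal_peptide("AAA")
  expect_equal(bottleneck_distance(p, p), 0)
  q <- p
  q$atoms$x[5] <- q$atoms$x[5] + 0.5
  expect_equal(bottleneck_distance(p, q), 0.5)
  set.seed(21)
  for (rep in 1:10) {
    a <- matrix(rnorm(30), 10, 3)
    b <- a + matrix(rnorm(30, 0, 0.3), 10, 3)
    expect_equal(bottleneck_distance(a, b),
                 max(sapply(1:10, function(i) sqrt(sum((a[i, ] - b[i, ])^2)))))
  }
  expect_error(bottleneck_distance(matrix(0, 2, 3), matrix(0, 3, 3)),
               "mismatched")
})

test_that("frame-fixed RMSD has no superposition and hand-checked values", {
  p <- make_ideal_peptide("AAA")
  expect_equal(rmsd_no_fit(p, p, "CA"), 0)
  # deviations 1 A and 2 A -> sqrt((1 + 4) / 2) = sqrt(2.5)
  a <- rbind(c(0, 0, 0), c(5, 0, 0))
  b <- rbind(c(1, 0, 0), c(5, 2, 0))
  expect_equal(rmsd_no_fit(a, b), sqrt(2.5))
  # a pure translation is NOT fitted away
  q <- p; q$atoms$x <- q$atoms$x + 1
  expect_equal(rmsd_no_fit(p, q), 1)
  expect_warning(r0 <- rmsd_no_fit(p, q, "OXT"), "empty")
  expect_equal(r0, 0)
})

test_that("score combination is additive, associative, and matches Eq-style pooling", {
  mk <- function(ss, n, lo = 0) {
    b <- score_breakdown()
    b$ss["ca"] <- ss; b$n["ca"] <- n; b$logodds <- lo
    b
  }
  # segment RMSDs 1.0 over 3 atoms and 2.0 over 1 atom ->
  # sqrt((3*1 + 1*4)/4) = sqrt(1.75)
  a <- mk(3 * 1.0^2, 3L); b <- mk(1 * 2.0^2, 1L)
  expect_equal(breakdown_rmsd(combine_breakdowns(a, b))[["ca"]], sqrt(1.75))
  # combining with an empty breakdown is the identity
  e <- score_breakdown()
  expect_equal(backbone_score(combine_breakdowns(a, e)), backbone_score(a))
  # associativity + equality with direct pooled RMSD on random triples
  set.seed(31)
  for (rep in 1:10) {
    devs <- list(rnorm(4)^2, rnorm(3)^2, rnorm(5)^2)
    bs <- lapply(devs, function(d) mk(sum(d), length(d), rnorm(1)))
    left <- combine_breakdowns(combine_breakdowns(bs[[1]], bs[[2]]), bs[[3]])
    right <- combine_breakdowns(bs[[1]], combine_breakdowns(bs[[2]], bs[[3]]))
    expect_equal(backbone_score(left), backbone_score(right), tolerance = 1e-12)
    pooled <- sqrt(mean(unlist(devs)))
    expect_equal(breakdown_rmsd(left)[["ca"]], pooled, tolerance = 1e-12)
  }
  a2 <- mk(1, 1L); a2$weights <- c(2, 1, 1, 1)
  expect_error(combine_breakdowns(a, a2), "weights")
})

test_that("backbone_score recovers S_f minus weighted distances", {
  b <- score_breakdown()
  b$logodds <- 3.2
  expect_equal(backbone_score(b), 3.2)
  b2 <- score_breakdown()
  b2$ss["ca"] <- 0.25; b2$n["ca"] <- 1L
  expect_equal(backbone_score(b2), -0.5)
  set.seed(8)
  for (rep in 1:10) {
    b3 <- score_breakdown(weights = runif(4, 0.5, 2))
    b3$logodds <- rnorm(1)
    b3$ss[] <- runif(4); b3$n[] <- sample(1:5, 4, TRUE)
    expect_equal(backbone_score(b3),
                 b3$logodds - sum(b3$weights * sqrt(b3$ss / b3$n)),
                 tolerance = 1e-12)
  }
})

test_that("Kabsch-Sander detection finds helix (i, i-4) bonds and nothing in strands", {
  helix <- make_ideal_peptide(strrep("A", 12))
  hb <- detect_hbonds(helix)
  expect_true(all(hb$donor - hb$acceptor == 4))
  expect_setequal(hb$donor, 5:12)
  expect_true(all(hb$energy < -0.5))
  # a fully extended single strand has no backbone hydrogen bonds
  ext <- make_ideal_peptide(strrep("A", 8), phi = -135, psi = 135)
  expect_equal(nrow(detect_hbonds(ext)), 0L)
  # proline never donates
  hp <- make_ideal_peptide(c("ALA", "ALA", "ALA", "ALA", "PRO",
                             "ALA", "ALA", "ALA", "ALA", "ALA",
                             "ALA", "ALA"))
  hbp <- detect_hbonds(hp)
  expect_false(5 %in% hbp$donor)
  expect_error(detect_hbonds(protein_from_backbone(
    atom_coords(helix, c("N", "CA", "C")), rep("ALA", 12))), "rebuilt")
})

test_that("sidechain score is zero-distance at the target and wrap-immune", {
  toy_rot <- structure(
    data.frame(aa = "SER", phi_bin = NA, psi_bin = NA, prob = 1,
               m1 = 60, m2 = NA, m3 = NA, m4 = NA,
               s1 = 10, s2 = NA, s3 = NA, s4 = NA, nchi = 1L),
    class = c("rotamer_table", "data.frame"), bbdep = FALSE)
  cand <- matrix(rnorm(6), 2, 3, dimnames = list(c("OG", "XX"), NULL))
  s_at <- sidechain_score(cand, cand, 60, 60, toy_rot, "SER")
  expect_equal(s_at, chi_log_odds(toy_rot, "SER", chis = 60))
  # a chi difference of 350 degrees counts as 10 degrees
  s350 <- sidechain_score(cand, cand, -175, 175, toy_rot, "SER")
  s10 <- sidechain_score(cand, cand, -175, -185, toy_rot, "SER")
  expect_equal(s350, s10, tolerance = 1e-12)
  expect_equal(sidechain_score(NULL, NULL, numeric(0), numeric(0),
                               toy_rot, "GLY"), 0)
})

test_that("the phi/psi distance uses wrapped angular differences", {
  seq4 <- rep("ALA", 4)
  mk4 <- function(phi2) {
    tor <- data.frame(residue_index = 1:4, residue_type = seq4,
                      phi = c(NA, phi2, -57, -57),
                      psi = c(-47, -47, -47, NA),
                      omega = c(180, 180, 180, NA))
    build_from_torsions(seq4, tor, ideal_tab)
  }
  target <- mk4(179)
  cand <- mk4(-179)
  b <- score_backbone_structure(cand, target, uniform_rama)
  # residue 2's phi differs by 2 degrees across the wrap, never 358
  expect_lt(b$ss[["phipsi"]], (5 * pi / 180)^2)
  # and feeding theta + 360 into the builder changes nothing at all
  cand2 <- mk4(-179 + 360)
  expect_equal(atom_coords(cand2), atom_coords(cand), tolerance = 1e-9,
               ignore_attr = TRUE)
})
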