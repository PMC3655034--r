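# Shared fixtures, built once per test run.

toy <- make_toy_tables(seed = 1L)

ideal_tab <- read_ideal_geometry()

# a 2-residue slightly non-ideal target for small DP problems
two_res_target <- perturb(make_ideal_peptide("AA"), sigma = 0.15, seed = 11)

# uniform (pseudocount-only) Ramachandran table
uniform_rama <- rama_table_from_angles(character(0), numeric(0), numeric(0),
                                       pseudocount = 1)

# measure every built bond length/angle of a backbone (+O/H/CB) against the
# ideal table; returns the largest absolute deviation
max_geometry_dev <- function(s, ideal = ideal_tab) {
  bb <- backbone_coords(s)
  n <- nrow(bb$N)
  seq3 <- bb$restype
  dev <- c(
    abs(bond_length(bb$N, bb$CA) - ideal_value(ideal, "N-CA", seq3)),
    abs(bond_length(bb$CA, bb$C) - ideal_value(ideal, "CA-C", seq3)),
    abs(bond_angle(bb$N, bb$CA, bb$C) - ideal_value(ideal, "N-CA-C", seq3)))
  if (n > 1L) {
    nx <- 2:n
    dev <- c(dev,
      abs(bond_length(bb$C[nx - 1, , drop = FALSE], bb$N[nx, , drop = FALSE]) -
            ideal_value(ideal, "C-N", seq3[nx])),
      abs(bond_angle(bb$CA[nx - 1, , drop = FALSE], bb$C[nx - 1, , drop = FALSE],
                     bb$N[nx, , drop = FALSE]) -
            ideal_value(ideal, "CA-C-N", seq3[nx - 1])),
      abs(bond_angle(bb$C[nx - 1, , drop = FALSE], bb$N[nx, , drop = FALSE],
                     bb$CA[nx, , drop = FALSE]) -
            ideal_value(ideal, "C-N-CA", seq3[nx])))
  }
  a <- s$atoms
  for (i in seq_len(n)) {
    ai <- a[a$residue_index == i, ]
    g <- function(nm) {
      r <- ai[ai$name == nm, c("x", "y", "z")]
      if (nrow(r) == 1L) as.numeric(r) else NULL
    }
    if (!is.null(g("CB"))) {
      dev <- c(dev,
        abs(bond_length(g("CA"), g("CB")) - ideal_value(ideal, "CA-CB", seq3[i])),
        abs(bond_angle(g("N"), g("CA"), g("CB")) - ideal_value(ideal, "N-CA-CB", seq3[i])),
        abs(bond_angle(g("C"), g("CA"), g("CB")) - ideal_value(ideal, "C-CA-CB", seq3[i])))
    }
    if (!is.null(g("O"))) {
      dev <- c(dev,
        abs(bond_length(g("C"), g("O")) - ideal_value(ideal, "C-O", seq3[i])),
        abs(bond_angle(g("CA"), g("C"), g("O")) - ideal_value(ideal, "CA-C-O", seq3[i])))
    }
    if (!is.null(g("H"))) {
      dev <- c(dev, abs(bond_length(g("N"), g("H")) - ideal_value(ideal, "N-H", seq3[i])))
    }
  }
  max(dev)
}

# all omega torsions of a structure, wrapped distance from {0, 180}
max_omega_dev <- function(s) {
  om <- extract_torsions(s)$omega
  om <- om[!is.na(om)]
  if (!length(om)) return(0)
  max(pmin(abs(wrap_angle(om)), abs(wrap_angle(om - 180))))
}

# independent brute-force enumeration over the DP's candidate sets, scoring
# every complete chain monolithically; returns the best score
brute_force_best <- function(target, r, eps, rama, ideal = ideal_tab,
                             cis_window = 30) {
  target <- prepare_target(target, ideal)
  seq3 <- sequence3(target)
  n3 <- 3L * length(seq3)
  hb <- detect_hbonds(target)
  stor <- extract_torsions(target)
  prefixes <- seed_candidates(target, r, eps, ideal)
  for (t in seq(4L, n3)) {
    i <- (t + 2L) %/% 3L
    om <- allowed_omegas(seq3[i], stor$omega[i - 1], cis_window)
    nxt <- list()
    for (p in prefixes) {
      cand <- extend_candidates(p, seq3, t, ideal, eps, omegas = om)
      for (j in seq_len(nrow(cand))) {
        nxt[[length(nxt) + 1L]] <- rbind(p, cand[j, ])
      }
    }
    prefixes <- nxt
  }
  best <- -Inf
  for (p in prefixes) {
    s <- rebuild_dependent_atoms(protein_from_backbone(p, seq3), ideal)
    sc <- backbone_score(score_backbone_structure(s, target, rama, hbonds = hb))
    if (sc > best) best <- sc
  }
  list(best = best, n_enumerated = length(prefixes))
}
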