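## Deterministic synthetic-structure generators: idealized poly-peptides
## with prescribed torsions, Gaussian coordinate perturbations, and toy
## probability tables — so every part of the method is testable with no
## external data.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Make an idealized peptide with prescribed torsions
#'
#' Builds the backbone with \code{\link{build_from_torsions}} (canonical
#' anchor at the origin) and, for chi-bearing residues with supplied chi
#' angles, attaches ideal side chains.
#'
#' @param sequence 3-letter vector or 1-letter string.
#' @param phi,psi,omega Backbone torsions in degrees, recycled over
#'   residues; defaults are alpha-helical (-57, -47, 180).
#' @param chis Optional matrix (n x 4) of chi angles; NA entries skipped.
#' @param ideal An \code{ideal_geometry} table.
#' @return A \code{protein}.
#' @export
make_ideal_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                               chis = NULL, ideal = read_ideal_geometry()) {
  seq3 <- as_seq3(sequence)
  n <- length(seq3)
  tor <- data.frame(residue_index = seq_len(n), residue_type = seq3,
                    phi = rep_len(phi, n), psi = rep_len(psi, n),
                    omega = rep_len(omega, n))
  tor$phi[1] <- NA; tor$psi[n] <- NA; tor$omega[n] <- NA
  s <- build_from_torsions(seq3, tor, ideal)
  if (!is.null(chis)) {
    chis <- matrix(chis, nrow = n, ncol = 4)
    atoms <- s$atoms
    for (i in seq_len(n)) {
      k <- n_chi(seq3[i])
      if (k == 0L || anyNA(chis[i, seq_len(k)])) next
      a <- atoms[atoms$residue_index == i, ]
      getc <- function(nm) as.numeric(a[a$name == nm, c("x", "y", "z")][1, ])
      pos <- build_sidechain(seq3[i], getc("N"), getc("CA"), getc("CB"),
                             chis[i, ])
      nm <- names(pos)
      atoms <- rbind(atoms, data.frame(
        serial = NA_integer_, name = nm, element = .element_of(nm),
        residue_index = i, residue_type = seq3[i],
        x = vapply(pos, function(p) p[1, 1], 0),
        y = vapply(pos, function(p) p[1, 2], 0),
        z = vapply(pos, function(p) p[1, 3], 0), stringsAsFactors = FALSE))
    }
    s <- protein(atoms, chain_id = s$chain_id, source_model = s$source_model)
  }
  s
}

#' Perturb a structure with Gaussian coordinate noise
#'
#' Adds i.i.d. N(0, sigma^2) noise to every coordinate — the standard
#' emulation of a non-ideal experimental target whose ideal ancestor is
#' known.
#'
#' @param s A \code{protein}.
#' @param sigma Noise standard deviation per coordinate (Angstrom).
#' @param seed Integer seed; the result is a deterministic function of
#'   (s, sigma, seed) and the global RNG state is left untouched.
#' @return The perturbed \code{protein}.
#' @export
perturb <- function(s, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(s)
  .with_seed(seed, {
    a <- s$atoms
    noise <- matrix(stats::rnorm(3L * nrow(a), 0, sigma), ncol = 3)
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
    protein(a, chain_id = s$chain_id, source_model = s$source_model)
  })
}

#' Make compact toy probability tables
#'
#' Builds a Ramachandran table from synthetic torsion samples concentrated
#' in the alpha-helix and beta-sheet basins (deterministic given the
#' seed), plus the packaged coarse rotamer table.  Helix/sheet queries
#' score well above loop-region queries by construction.
#'
#' @param seed Integer seed.
#' @param n_per_aa Torsion samples drawn per amino-acid type.
#' @param helix_frac Fraction of samples in the helix basin.
#' @param pseudocount Ramachandran pseudocount.
#' @return List with elements \code{rama} (a \code{rama_table}) and
#'   \code{rotamers} (a \code{rotamer_table}).
#' @export
make_toy_tables <- function(seed = 1L, n_per_aa = 20000L, helix_frac = 0.6,
                            pseudocount = 1) {
  samp <- .with_seed(seed, {
    out <- list()
    for (aa in AA3) {
      nh <- round(n_per_aa * helix_frac)
      ns <- n_per_aa - nh
      phi <- c(stats::rnorm(nh, -57, 8), stats::rnorm(ns, -120, 15))
      psi <- c(stats::rnorm(nh, -47, 8), stats::rnorm(ns, 130, 15))
      out[[aa]] <- data.frame(aa = aa, phi = wrap_angle(phi),
                              psi = wrap_angle(psi))
    }
    do.call(rbind, out)
  })
  list(rama = rama_table_from_angles(samp$aa, samp$phi, samp$psi, pseudocount),
       rotamers = read_rotamer_library())
}
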