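## Side-chain idealization: residue-by-residue exhaustive chi-grid search
## on a fixed idealized backbone.
##
## Side chains are built as internal-coordinate trees rooted at N/CA/CB:
## each heavy atom is placed from three predecessors with an ideal bond
## length and angle, and a torsion that is either a searched chi angle, a
## chi plus a fixed branch offset (e.g. the second methyl of Val), or a
## fixed value (planar rings; arginine's guanidinium torsions, which are
## rounded to 0/180).  Only chi torsions vary, so every built side chain
## satisfies the ideal-geometry invariant by construction.

## topology rows: name, a, b, c (predecessor atom names), len (A),
## ang (deg), tor ("chi<k>", "chi<k>+<off>", or a fixed number)
.sc_row <- function(name, a, b, c, len, ang, tor) {
  data.frame(name = name, a = a, b = b, c = c, len = len, ang = ang,
             tor = as.character(tor), stringsAsFactors = FALSE)
}

.SC_TOPO <- list(
  SER = rbind(.sc_row("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = rbind(.sc_row("SG", "N", "CA", "CB", 1.808, 114.4, "chi1")),
  THR = rbind(.sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
              .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")),
  VAL = rbind(.sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
              .sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1+120")),
  ILE = rbind(.sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
              .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120"),
              .sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.9, "chi2")),
  LEU = rbind(.sc_row("CG", "N", "CA", "CB", 1.530, 116.3, "chi1"),
              .sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
              .sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+120")),
  ASP = rbind(.sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
              .sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
              .sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  ASN = rbind(.sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
              .sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
              .sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = rbind(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
              .sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
              .sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
              .sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  GLN = rbind(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
              .sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
              .sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
              .sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  MET = rbind(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
              .sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
              .sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  LYS = rbind(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
              .sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
              .sc_row("CE", "CB", "CG", "CD", 1.508, 111.9, "chi3"),
              .sc_row("NZ", "CG", "CD", "CE", 1.489, 111.7, "chi4")),
  ARG = rbind(.sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
              .sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
              .sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, "chi3"),
              .sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4"),
              .sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
              .sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
  HIS = rbind(.sc_row("CG", "N", "CA", "CB", 1.497, 113.8, "chi1"),
              .sc_row("ND1", "CA", "CB", "CG", 1.371, 122.7, "chi2"),
              .sc_row("CD2", "CA", "CB", "CG", 1.356, 129.1, "chi2+180"),
              .sc_row("CE1", "CB", "CG", "ND1", 1.319, 109.3, "180"),
              .sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, "180")),
  PHE = rbind(.sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
              .sc_row("CD1", "CA", "CB", "CG", 1.384, 120.0, "chi2"),
              .sc_row("CD2", "CA", "CB", "CG", 1.384, 120.0, "chi2+180"),
              .sc_row("CE1", "CB", "CG", "CD1", 1.384, 120.0, "180"),
              .sc_row("CE2", "CB", "CG", "CD2", 1.384, 120.0, "180"),
              .sc_row("CZ", "CG", "CD1", "CE1", 1.384, 120.0, "0")),
  TYR = rbind(.sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
              .sc_row("CD1", "CA", "CB", "CG", 1.384, 120.0, "chi2"),
              .sc_row("CD2", "CA", "CB", "CG", 1.384, 120.0, "chi2+180"),
              .sc_row("CE1", "CB", "CG", "CD1", 1.384, 120.0, "180"),
              .sc_row("CE2", "CB", "CG", "CD2", 1.384, 120.0, "180"),
              .sc_row("CZ", "CG", "CD1", "CE1", 1.384, 120.0, "0"),
              .sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "180")),
  TRP = rbind(.sc_row("CG", "N", "CA", "CB", 1.498, 113.6, "chi1"),
              .sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
              .sc_row("CD2", "CA", "CB", "CG", 1.433, 126.8, "chi2+180"),
              .sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
              .sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
              .sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
              .sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
              .sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
              .sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0")),
  PRO = rbind(.sc_row("CG", "N", "CA", "CB", 1.492, 104.5, "chi1"),
              .sc_row("CD", "CA", "CB", "CG", 1.503, 106.1, "chi2"))
)

## chi-defining atom quadruples per residue type
.CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ"))
)

#' Side-chain heavy-atom names of a residue type
#'
#' @param restype 3-letter code.
#' @return Character vector of atom names beyond CB (empty for GLY/ALA).
#' @export
sidechain_atom_names <- function(restype) {
  topo <- .SC_TOPO[[toupper(restype)]]
  if (is.null(topo)) character(0) else topo$name
}

#' Measure the chi angles of one residue
#'
#' @param s A \code{protein}.
#' @param residue Residue index.
#' @return Numeric length-4 vector (NA beyond the residue's chi count or
#'   where defining atoms are missing).
#' @export
measure_chis <- function(s, residue) {
  out <- rep(NA_real_, 4)
  restype <- s$atoms$residue_type[match(residue, s$atoms$residue_index)]
  if (is.na(restype)) return(out)
  quads <- .CHI_ATOMS[[restype]]
  if (is.null(quads)) return(out)
  a <- s$atoms[s$atoms$residue_index == residue, ]
  getc <- function(nm) {
    r <- a[a$name == nm, c("x", "y", "z")]
    if (nrow(r) == 1L) as.numeric(r) else NULL
  }
  for (j in seq_along(quads)) {
    pts <- lapply(quads[[j]], getc)
    if (!any(vapply(pts, is.null, TRUE))) {
      out[j] <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
  }
  out
}

#' Build side-chain atoms for given chi tuples
#'
#' Places every heavy atom of the residue's side chain beyond CB with ideal
#' internal coordinates, vectorized over chi tuples.
#'
#' @param restype 3-letter code.
#' @param n,ca,cb Coordinates of the residue's N, CA and CB atoms.
#' @param chis Matrix of chi tuples (one per row; columns chi1..) or a
#'   single numeric vector.
#' @return Named list of coordinate matrices, one \code{nrow(chis)} x 3
#'   matrix per side-chain atom.
#' @export
build_sidechain <- function(restype, n, ca, cb, chis) {
  topo <- .SC_TOPO[[toupper(restype)]]
  if (is.null(topo)) return(list())
  if (!is.matrix(chis)) chis <- matrix(chis, nrow = 1)
  nt <- nrow(chis)
  rep_row <- function(v) matrix(v, nt, 3, byrow = TRUE)
  pos <- list(N = rep_row(n), CA = rep_row(ca), CB = rep_row(cb))
  for (r in seq_len(nrow(topo))) {
    tor <- topo$tor[r]
    tau <- if (grepl("^chi", tor)) {
      kk <- as.integer(substr(tor, 4, 4))
      off <- sub("^chi[0-9]", "", tor)
      chis[, kk] + if (nzchar(off)) as.numeric(off) else 0
    } else {
      rep(as.numeric(tor), nt)
    }
    pos[[topo$name[r]]] <- place_next_atom(pos[[topo$a[r]]], pos[[topo$b[r]]],
                                           pos[[topo$c[r]]], topo$len[r],
                                           topo$ang[r], tau)
  }
  pos[topo$name]
}

#' Enumerate the chi search grid of a rotamer
#'
#' Per chi dimension: samples centered on the rotamer mean, extending
#' \code{window_sigmas} standard deviations either side in steps of
#' \code{step} degrees (2*floor(halfwidth/step)+1 samples), wrapped to
#' (-180, 180].  The Cartesian product over dimensions is returned.
#'
#' @param restype 3-letter code (must have at least one chi).
#' @param rotamer One row of a \code{rotamer_table}.
#' @param step Grid spacing in degrees (default 10).
#' @param window_sigmas Half-width in standard deviations (default 3).
#' @return Matrix of chi tuples, one per row.
#' @export
enumerate_chi <- function(restype, rotamer, step = 10, window_sigmas = 3) {
  k <- n_chi(restype)
  if (k == 0L) stop("residue type ", restype, " has no chi angles")
  axes <- lapply(seq_len(k), function(j) {
    mu <- rotamer[[paste0("m", j)]]
    sig <- rotamer[[paste0("s", j)]]
    half <- window_sigmas * sig
    offs <- step * seq(-floor(half / step), floor(half / step))
    wrap_angle(mu + offs)
  })
  as.matrix(do.call(expand.grid, axes))
}

#' Idealize all side chains on a fixed idealized backbone
#'
#' Per residue, independently: enumerates the chi grid of every applicable
#' rotamer, builds each candidate's atoms with ideal geometry from the
#' backbone, scores with \code{\link{sidechain_score}} against the target's
#' side chain, and keeps the argmax (deterministic first-found
#' tie-breaking).  Residues whose target side chain is absent are scored by
#' the chi log-odds alone.
#'
#' @param backbone An idealized \code{protein} with N/CA/C (+O/H/CB; they
#'   are rebuilt if missing).
#' @param target A \code{protein} providing reference side-chain
#'   coordinates where present (pass NULL for pure free-energy placement).
#' @param rotamers A \code{rotamer_table}.
#' @param step Chi grid spacing (degrees).
#' @param window_sigmas Chi window half-width in standard deviations.
#' @param weights c(w1, w2) for the side-chain RMSD and chi-RMSD terms.
#' @param ideal An \code{ideal_geometry} table (for CB rebuilds).
#' @return A list: \code{structure} (the backbone plus all side-chain
#'   atoms), \code{scores} (per-residue data frame: residue_index,
#'   residue_type, score, chi1..chi4).
#' @export
idealize_sidechains <- function(backbone, target = NULL,
                                rotamers = read_rotamer_library(),
                                step = 10, window_sigmas = 3,
                                weights = c(1, 1),
                                ideal = read_ideal_geometry()) {
  s <- rebuild_dependent_atoms(backbone, ideal, replace = FALSE)
  tor <- extract_torsions(s)
  n <- n_residues(s)
  seq3 <- sequence3(s)
  out_atoms <- s$atoms[s$atoms$name %in% c("N", "CA", "C", "O", "H", "CB"), ]
  res_scores <- data.frame(residue_index = seq_len(n), residue_type = seq3,
                           score = 0, chi1 = NA_real_, chi2 = NA_real_,
                           chi3 = NA_real_, chi4 = NA_real_,
                           stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- n_chi(seq3[i])
    if (k == 0L) next
    a <- s$atoms[s$atoms$residue_index == i, ]
    getc <- function(nm) as.numeric(a[a$name == nm, c("x", "y", "z")][1, ])
    nc <- getc("N"); cac <- getc("CA"); cbc <- getc("CB")
    tchis <- if (!is.null(target)) measure_chis(target, i) else rep(NA_real_, 4)
    tcoords <- NULL
    if (!is.null(target)) {
      ta <- target$atoms[target$atoms$residue_index == i &
                           target$atoms$name %in% sidechain_atom_names(seq3[i]), ]
      if (nrow(ta) > 0L) {
        tcoords <- as.matrix(ta[, c("x", "y", "z")])
        rownames(tcoords) <- ta$name
      }
    }
    rot <- get_rotamers(rotamers, seq3[i], tor$phi[i], tor$psi[i])
    best <- NULL
    for (rr in seq_len(nrow(rot))) {
      tuples <- enumerate_chi(seq3[i], rot[rr, ], step, window_sigmas)
      pos <- build_sidechain(seq3[i], nc, cac, cbc, tuples)
      sf <- chi_log_odds(rotamers, seq3[i], tor$phi[i], tor$psi[i], tuples)
      d_sc <- numeric(nrow(tuples))
      if (!is.null(tcoords)) {
        cm <- intersect(names(pos), rownames(tcoords))
        if (length(cm) > 0L) {
          ssum <- 0
          for (nm in cm) {
            ssum <- ssum + .rownorm(pos[[nm]] -
              matrix(tcoords[nm, ], nrow(tuples), 3, byrow = TRUE))^2
          }
          d_sc <- sqrt(ssum / length(cm))
        }
      }
      d_chi <- numeric(nrow(tuples))
      ok <- !is.na(tchis[seq_len(k)])
      if (any(ok)) {
        dd <- wrap_angle(tuples[, which(ok), drop = FALSE] -
                           matrix(tchis[which(ok)], nrow(tuples),
                                  sum(ok), byrow = TRUE)) * pi / 180
        d_chi <- sqrt(rowMeans(dd^2))
      }
      sc <- sf - weights[1] * d_sc - weights[2] * d_chi
      jb <- which.max(sc)
      if (is.null(best) || sc[jb] > best$score) {
        best <- list(score = sc[jb], chis = tuples[jb, ],
                     pos = lapply(pos, function(p) p[jb, ]))
      }
    }
    res_scores$score[i] <- best$score
    res_scores[i, paste0("chi", seq_len(k))] <- best$chis[seq_len(k)]
    nm <- names(best$pos)
    out_atoms <- rbind(out_atoms, data.frame(
      serial = NA_integer_, name = nm, element = .element_of(nm),
      residue_index = i, residue_type = seq3[i],
      x = vapply(best$pos, `[`, 0, 1), y = vapply(best$pos, `[`, 0, 2),
      z = vapply(best$pos, `[`, 0, 3), stringsAsFactors = FALSE))
  }
  list(structure = protein(out_atoms, chain_id = s$chain_id,
                           source_model = s$source_model),
       scores = res_scores)
}
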