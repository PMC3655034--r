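## Internal-coordinate mathematics: measuring and imposing bond lengths,
## bond angles and dihedral angles; rebuilding dependent atoms (O, amide H,
## CB) from an N/CA/C trace; torsion <-> Cartesian conversion.
##
## All primitives are vectorized over rows: arguments may be length-3
## vectors or n x 3 matrices (recycled to a common number of rows).

.as_mat3 <- function(x) {
  if (is.null(dim(x))) return(matrix(x, ncol = 3L))
  if (ncol(x) == 3L) as.matrix(x) else matrix(as.numeric(x), ncol = 3L)
}

.recycle3 <- function(...) {
  ms <- lapply(list(...), .as_mat3)
  n <- max(vapply(ms, nrow, 1L))
  lapply(ms, function(m) if (nrow(m) == n) m else m[rep_len(seq_len(nrow(m)), n), , drop = FALSE])
}

.rownorm <- function(m) sqrt(rowSums(m * m))

.unit <- function(m) m / .rownorm(m)

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Bond length between two points
#'
#' @param a,b Coordinates: length-3 vectors or n x 3 matrices (rows are
#'   recycled to a common length).
#' @return Euclidean distance(s) in the input units (Angstrom throughout the
#'   package).
#' @export
bond_length <- function(a, b) {
  m <- .recycle3(a, b)
  d <- .rownorm(m[[2]] - m[[1]])
  if (any(d < 1e-12)) stop("degenerate geometry: coincident points")
  d
}

#' Bond angle at the middle point
#'
#' Interior angle a-b-c, measured at \code{b}.
#'
#' @param a,b,c Coordinates (vectors or matrices, rows recycled).
#' @return Angle(s) in degrees, in [0, 180].
#' @export
bond_angle <- function(a, b, c) {
  m <- .recycle3(a, b, c)
  u <- m[[1]] - m[[2]]
  v <- m[[3]] - m[[2]]
  nu <- .rownorm(u); nv <- .rownorm(v)
  if (any(nu < 1e-12) || any(nv < 1e-12)) {
    stop("degenerate geometry: coincident points in bond_angle()")
  }
  cs <- rowSums(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Signed dihedral (torsion) angle
#'
#' IUPAC convention: looking along b -> c, the angle is positive when d is
#' rotated clockwise relative to a.  Returned in (-180, 180].
#'
#' @param a,b,c,d Coordinates (vectors or matrices, rows recycled).
#' @return Dihedral angle(s) in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  m <- .recycle3(a, b, c, d)
  b1 <- m[[2]] - m[[1]]
  b2 <- m[[3]] - m[[2]]
  b3 <- m[[4]] - m[[3]]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (any(.rownorm(n1) < 1e-10) || any(.rownorm(n2) < 1e-10)) {
    stop("degenerate geometry: collinear points in dihedral()")
  }
  m1 <- .cross3(n1, .unit(b2))
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

#' Wrap angles to (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * round(x / 360)
  ifelse(w <= -180, w + 360, w)
}

#' Place an atom from three predecessors and internal coordinates
#'
#' Natural-extension (NeRF-style) construction: returns the point d with
#' \code{bond_length(c, d) == length}, \code{bond_angle(b, c, d) == angle}
#' and \code{dihedral(a, b, c, d) == torsion}.
#'
#' @param a,b,c Coordinates of the three predecessor atoms (vectors or
#'   matrices, rows recycled).
#' @param length Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees, in (0, 180).
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Coordinates of d (matrix if any input was a matrix).
#' @export
place_next_atom <- function(a, b, c, length, angle, torsion) {
  m <- .recycle3(a, b, c)
  n <- nrow(m[[1]])
  length <- rep_len(length, n)
  theta <- rep_len(angle, n) * pi / 180
  tau <- rep_len(torsion, n) * pi / 180
  bc <- m[[3]] - m[[2]]
  nbc <- .rownorm(bc)
  ab <- m[[2]] - m[[1]]
  nvec <- .cross3(ab, bc)
  if (any(nbc < 1e-12) || any(.rownorm(nvec) < 1e-10)) {
    stop("degenerate geometry: collinear predecessors in place_next_atom()")
  }
  bc <- bc / nbc
  nvec <- .unit(nvec)
  mvec <- .cross3(nvec, bc)
  d2 <- length * cbind(-cos(theta), sin(theta) * cos(tau), -sin(theta) * sin(tau))
  d <- m[[3]] + d2[, 1] * bc + d2[, 2] * mvec + d2[, 3] * nvec
  if (n == 1L && is.null(dim(a))) d[1, ] else d
}

## ---------------------------------------------------------------------------
## Ideal geometry table

#' Read an ideal-geometry table
#'
#' Loads mean ("ideal") bond lengths and bond angles from a tab-separated
#' key-value file.  The packaged default transcribes the standard
#' Engh-Huber stereochemical means, with per-residue overrides for Gly/Pro
#' (and Ala CA-CB).
#'
#' @param path Path to the table; default is the packaged file.
#' @return An object of class \code{ideal_geometry}: a list with
#'   \code{bonds} and \code{angles} lookup data frames.
#' @export
read_ideal_geometry <- function(path = system.file("extdata", "ideal_geometry.tsv",
                                                   package = "protideal")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "name", "restype", "value") %in% names(tab)))
  bonds <- tab[tab$kind == "bond", c("name", "restype", "value")]
  angles <- tab[tab$kind == "angle", c("name", "restype", "value")]
  if (any(bonds$value <= 0.8 | bonds$value >= 2.0)) {
    stop("ideal bond length outside (0.8, 2.0) Angstrom")
  }
  if (any(angles$value <= 90 | angles$value >= 180)) {
    stop("ideal bond angle outside (90, 180) degrees")
  }
  needed_b <- c("N-CA", "CA-C", "C-N", "C-O", "CA-CB", "N-H")
  needed_a <- c("N-CA-C", "CA-C-N", "C-N-CA", "CA-C-O", "C-N-H", "N-CA-CB", "C-CA-CB")
  if (!all(needed_b %in% bonds$name) || !all(needed_a %in% angles$name)) {
    stop("ideal geometry table is missing required bond/angle types")
  }
  structure(list(bonds = bonds, angles = angles), class = "ideal_geometry")
}

#' Look up an ideal bond length or angle
#'
#' @param ideal An \code{ideal_geometry} table.
#' @param name Bond/angle type, e.g. "N-CA" or "N-CA-C".
#' @param restype 3-letter residue type; overrides apply where tabulated.
#' @return Numeric value (Angstrom or degrees). Vectorized over
#'   \code{restype}.
#' @export
ideal_value <- function(ideal, name, restype = "*") {
  tab <- if (grepl("^[^-]+-[^-]+$", name)) ideal$bonds else ideal$angles
  rows <- tab[tab$name == name, ]
  if (nrow(rows) == 0L) stop("unknown bond/angle type: ", name)
  base <- rows$value[rows$restype == "*"]
  if (length(base) == 0L) stop("no default value for type: ", name)
  out <- rep(base, length(restype))
  over <- rows[rows$restype != "*", ]
  if (nrow(over) > 0L) {
    hit <- match(restype, over$restype)
    out[!is.na(hit)] <- over$value[hit[!is.na(hit)]]
  }
  out
}

## ---------------------------------------------------------------------------
## Dependent-atom reconstruction

## CB from N/CA/C by intersecting the two cones with the ideal N-CA-CB and
## C-CA-CB angles; the branch is chosen to give L-amino-acid chirality
## (dihedral(N, C, CA, CB) < 0, approximately -122 deg).
.place_cb <- function(n, ca, c, len, ang_n, ang_c) {
  m <- .recycle3(n, ca, c)
  nr <- nrow(m[[1]])
  len <- rep_len(len, nr)
  ang_n <- rep_len(ang_n, nr)
  ang_c <- rep_len(ang_c, nr)
  u <- .unit(m[[1]] - m[[2]])
  v <- .unit(m[[3]] - m[[2]])
  cu <- cos(ang_n * pi / 180)
  cv <- cos(ang_c * pi / 180)
  uv <- rowSums(u * v)
  det <- 1 - uv^2
  al <- (cu - cv * uv) / det
  be <- (cv - cu * uv) / det
  w_in <- al * u + be * v
  g2 <- 1 - rowSums(w_in * w_in)
  g2[g2 < 0] <- 0
  nvec <- .unit(.cross3(u, v))
  w <- w_in + sqrt(g2) * nvec
  cb <- m[[2]] + len * w
  flip <- dihedral(m[[1]], m[[3]], m[[2]], cb) > 0
  if (any(flip)) {
    w2 <- w_in[flip, , drop = FALSE] -
      sqrt(g2[flip]) * nvec[flip, , drop = FALSE]
    cb[flip, ] <- m[[2]][flip, , drop = FALSE] + len[flip] * w2
  }
  cb
}

## Carbonyl O of residue i: in the peptide plane, anti to the next N
## (terminal residue: anti to the own N, the only available neighbor).
.place_o <- function(ca, c, ref, ideal, restype = "*") {
  place_next_atom(ref, ca, c,
                  ideal_value(ideal, "C-O", restype),
                  ideal_value(ideal, "CA-C-O", restype),
                  180)
}

## Amide H of residue i: in the peptide plane, anti to the previous CA
## along the C(i-1)-N(i) bond (i.e. trans to the carbonyl O).  The
## N-terminal H uses the own CA/C as the only available neighbors.
.place_h <- function(ca_prev, c_prev, n, ideal) {
  place_next_atom(ca_prev, c_prev, n,
                  ideal_value(ideal, "N-H"),
                  ideal_value(ideal, "C-N-H"),
                  0)
}

#' Rebuild dependent backbone atoms from an N/CA/C trace
#'
#' Places the carbonyl O, the amide H and CB for every residue of a gapless
#' N/CA/C backbone, using ideal geometry: O in the peptide plane trans to
#' the next N; H in the peptide plane trans to the carbonyl O; CB by the
#' two-cone construction with L chirality.  Gly gets no CB; Pro gets no
#' amide H.  Terminal O/H are built from the only available neighbors.
#'
#' @param s A \code{protein} structure containing at least N, CA, C for
#'   every residue (other atoms are passed through untouched unless
#'   \code{replace = TRUE}).
#' @param ideal An \code{ideal_geometry} table.
#' @param replace If TRUE, existing O/H/CB atoms are dropped and rebuilt.
#' @return The structure with O, H and CB atoms present.
#' @export
rebuild_dependent_atoms <- function(s, ideal = read_ideal_geometry(), replace = TRUE) {
  bb <- backbone_coords(s)   # list of n x 3 matrices N, CA, C + restype
  n_res <- nrow(bb$N)
  if (n_res < 2L) stop("need at least 2 residues to rebuild dependent atoms")
  restype <- bb$restype
  ## O: residues 1..n-1 use next N; terminal uses own N
  o <- matrix(NA_real_, n_res, 3)
  o[-n_res, ] <- .place_o(bb$CA[-n_res, , drop = FALSE], bb$C[-n_res, , drop = FALSE],
                          bb$N[-1, , drop = FALSE], ideal, restype[-n_res])
  o[n_res, ] <- .place_o(bb$CA[n_res, ], bb$C[n_res, ], bb$N[n_res, ], ideal,
                         restype[n_res])
  ## H: residues 2..n use previous CA/C; N-terminal uses own CA/C
  h <- matrix(NA_real_, n_res, 3)
  if (n_res > 1L) {
    h[-1, ] <- .place_h(bb$CA[-n_res, , drop = FALSE], bb$C[-n_res, , drop = FALSE],
                        bb$N[-1, , drop = FALSE], ideal)
  }
  h[1, ] <- .place_h(bb$CA[1, ], bb$C[1, ], bb$N[1, ], ideal)
  ## CB for non-Gly
  cb <- .place_cb(bb$N, bb$CA, bb$C,
                  ideal_value(ideal, "CA-CB", restype),
                  ideal_value(ideal, "N-CA-CB", restype),
                  ideal_value(ideal, "C-CA-CB", restype))
  atoms <- s$atoms
  if (replace) atoms <- atoms[!(atoms$name %in% c("O", "H", "CB")), , drop = FALSE]
  add <- list()
  for (i in seq_len(n_res)) {
    ri <- unique(atoms$residue_index)[i]
    add[[length(add) + 1L]] <- data.frame(
      serial = NA_integer_,
      name = c("O", if (restype[i] != "PRO") "H", if (restype[i] != "GLY") "CB"),
      element = c("O", if (restype[i] != "PRO") "H", if (restype[i] != "GLY") "C"),
      residue_index = ri,
      residue_type = restype[i],
      x = c(o[i, 1], if (restype[i] != "PRO") h[i, 1], if (restype[i] != "GLY") cb[i, 1]),
      y = c(o[i, 2], if (restype[i] != "PRO") h[i, 2], if (restype[i] != "GLY") cb[i, 2]),
      z = c(o[i, 3], if (restype[i] != "PRO") h[i, 3], if (restype[i] != "GLY") cb[i, 3]),
      stringsAsFactors = FALSE)
  }
  add <- do.call(rbind, add)
  if (!replace) {
    have <- paste(atoms$residue_index, atoms$name)
    add <- add[!paste(add$residue_index, add$name) %in% have, , drop = FALSE]
  }
  atoms <- rbind(atoms, add)
  protein(atoms, chain_id = s$chain_id, source_model = s$source_model)
}

## ---------------------------------------------------------------------------
## Torsions <-> Cartesian

#' Extract backbone (and chi) torsions from a structure
#'
#' @param s A \code{protein} structure with a gapless N/CA/C backbone.
#' @param chi If TRUE, also measure side-chain chi angles for residues whose
#'   defining atoms are present.
#' @return A data frame of class \code{torsion_set} with one row per
#'   residue: \code{residue_index}, \code{residue_type}, \code{phi},
#'   \code{psi}, \code{omega} (degrees; NA where undefined: phi of the
#'   first, psi/omega of the last residue) and, if requested, \code{chi1}..
#'   \code{chi4}.
#' @export
extract_torsions <- function(s, chi = FALSE) {
  bb <- backbone_coords(s)
  n <- nrow(bb$N)
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n >= 2L) {
    idx <- 2:n
    phi[idx] <- dihedral(bb$C[idx - 1, , drop = FALSE], bb$N[idx, , drop = FALSE],
                         bb$CA[idx, , drop = FALSE], bb$C[idx, , drop = FALSE])
    idx <- 1:(n - 1)
    psi[idx] <- dihedral(bb$N[idx, , drop = FALSE], bb$CA[idx, , drop = FALSE],
                         bb$C[idx, , drop = FALSE], bb$N[idx + 1, , drop = FALSE])
    omega[idx] <- dihedral(bb$CA[idx, , drop = FALSE], bb$C[idx, , drop = FALSE],
                           bb$N[idx + 1, , drop = FALSE], bb$CA[idx + 1, , drop = FALSE])
  }
  out <- data.frame(residue_index = seq_len(n), residue_type = bb$restype,
                    phi = phi, psi = psi, omega = omega,
                    stringsAsFactors = FALSE)
  if (chi) {
    ch <- matrix(NA_real_, n, 4, dimnames = list(NULL, paste0("chi", 1:4)))
    for (i in seq_len(n)) {
      ch[i, ] <- measure_chis(s, i)
    }
    out <- cbind(out, as.data.frame(ch))
  }
  class(out) <- c("torsion_set", "data.frame")
  out
}

#' Build an idealized backbone from torsion angles
#'
#' The inverse of \code{\link{extract_torsions}} under ideal geometry: given
#' a sequence and per-residue (phi, psi, omega), chains N/CA/C atoms with
#' every bond length and angle at its ideal value.  O, H and CB are then
#' rebuilt.  The conformation is anchored by the coordinates of the first
#' three atoms (N1, CA1, C1).
#'
#' @param sequence Character vector of 3-letter residue types (or a single
#'   string of 1-letter codes).
#' @param torsions A \code{torsion_set} (only phi/psi/omega are used); phi
#'   of the first and psi/omega of the last residue may be NA.
#' @param ideal An \code{ideal_geometry} table.
#' @param anchor 3 x 3 matrix of coordinates for N1, CA1, C1; the default
#'   places the first residue in a canonical frame at the origin.  The
#'   anchor is used verbatim, so pass ideal-geometry points to obtain a
#'   fully ideal structure.
#' @param dependent If TRUE (default), rebuild O/H/CB.
#' @return A \code{protein} structure.
#' @export
build_from_torsions <- function(sequence, torsions, ideal = read_ideal_geometry(),
                                anchor = NULL, dependent = TRUE) {
  seq3 <- as_seq3(sequence)
  n <- length(seq3)
  tor <- as.data.frame(torsions)
  if (nrow(tor) != n) stop("torsion table and sequence lengths differ")
  if (n >= 2L) {
    if (any(is.na(tor$phi[2:n])) || any(is.na(tor$psi[1:(n - 1)])) ||
        any(is.na(tor$omega[1:(n - 1)]))) {
      stop("undefined mid-chain torsion in build_from_torsions()")
    }
  }
  if (is.null(anchor)) anchor <- canonical_anchor(seq3[1], ideal)
  coords <- matrix(NA_real_, 3 * n, 3)
  coords[1:3, ] <- as.matrix(anchor)
  for (t in seq(4L, length.out = max(0L, 3L * n - 3L))) {
    i <- (t + 2L) %/% 3L          # residue of atom t
    kind <- (t - 1L) %% 3L        # 0 = N, 1 = CA, 2 = C
    a <- coords[t - 3, ]; b <- coords[t - 2, ]; cc <- coords[t - 1, ]
    if (kind == 0L) {             # N(i) from N,CA,C of i-1; torsion = psi(i-1)
      coords[t, ] <- place_next_atom(a, b, cc,
                                     ideal_value(ideal, "C-N", seq3[i]),
                                     ideal_value(ideal, "CA-C-N", seq3[i - 1]),
                                     tor$psi[i - 1])
    } else if (kind == 1L) {      # CA(i); torsion = omega(i-1)
      coords[t, ] <- place_next_atom(a, b, cc,
                                     ideal_value(ideal, "N-CA", seq3[i]),
                                     ideal_value(ideal, "C-N-CA", seq3[i]),
                                     tor$omega[i - 1])
    } else {                      # C(i); torsion = phi(i)
      coords[t, ] <- place_next_atom(a, b, cc,
                                     ideal_value(ideal, "CA-C", seq3[i]),
                                     ideal_value(ideal, "N-CA-C", seq3[i]),
                                     tor$phi[i])
    }
  }
  s <- protein_from_backbone(coords, seq3)
  if (dependent) s <- rebuild_dependent_atoms(s, ideal) else s
}

#' Canonical anchor frame for the first residue
#'
#' N1 at the origin, CA1 on +x, C1 in the xy-plane, all at ideal geometry.
#'
#' @param restype 3-letter type of the first residue.
#' @param ideal An \code{ideal_geometry} table.
#' @return A 3 x 3 coordinate matrix (rows N1, CA1, C1).
#' @export
canonical_anchor <- function(restype = "ALA", ideal = read_ideal_geometry()) {
  b_nca <- ideal_value(ideal, "N-CA", restype)
  b_cac <- ideal_value(ideal, "CA-C", restype)
  a_ncac <- ideal_value(ideal, "N-CA-C", restype) * pi / 180
  rbind(c(0, 0, 0),
        c(b_nca, 0, 0),
        c(b_nca - b_cac * cos(a_ncac), b_cac * sin(a_ncac), 0))
}

## Rigid least-squares fit of an ideal anchor triad onto three observed
## points (Kabsch on 3 atoms); used to anchor rebuilt structures near a
## target's first residue.
#' Fit an ideal anchor triad onto three observed points
#'
#' Superposes the canonical ideal N1/CA1/C1 triad onto three given
#' coordinates by rigid-body least squares, so torsion-space rebuilds can
#' be anchored in a target's frame.
#'
#' @param obs 3 x 3 matrix of observed N1, CA1, C1 coordinates.
#' @param restype Residue type of the first residue.
#' @param ideal An \code{ideal_geometry} table.
#' @return A 3 x 3 anchor matrix with exactly ideal internal geometry.
#' @export
fit_anchor <- function(obs, restype = "ALA", ideal = read_ideal_geometry()) {
  ref <- canonical_anchor(restype, ideal)
  obs <- as.matrix(obs)
  cm_r <- colMeans(ref); cm_o <- colMeans(obs)
  a <- sweep(ref, 2, cm_r); b <- sweep(obs, 2, cm_o)
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t(rot %*% t(a)) + matrix(cm_o, 3, 3, byrow = TRUE)
}
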