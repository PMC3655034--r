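## Tail-grid dynamic program over idealized backbone candidates.
##
## Candidates are chained atom-by-atom (N, CA, C per residue) with EXACT
## ideal bond lengths and angles; only torsions vary.  Free torsions (phi
## at C atoms, psi at N atoms) are swept on a circle at arc spacing ~eps;
## the omega torsion at CA atoms is rounded to 0/180 so each CA has at most
## two candidates.  The DP state is the epsilon-grid cell signature of the
## last k atoms: prefixes sharing a tail signature are interchangeable
## (every score term of a later atom is a function of the tail alone, which
## is why k >= 5 is required), so only the best-scoring prefix per
## signature is kept, and the beam is then pruned to the top m prefixes.
##
## The epsilon lattice is used ONLY for tail keying/dedup; coordinates are
## never snapped to it, which preserves exact ideal geometry.

.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

## torsion sample grid for a full-circle sweep at arc spacing ~eps
.sweep_torsions <- function(radius, eps) {
  n <- max(4L, as.integer(ceiling(2 * pi * radius / eps)))
  seq(-180, 180 - 360 / n, length.out = n)
}

## deterministic off-axis reference point defining torsion zero for the
## atom-3 circle
.circle_ref <- function(p1, p2) {
  ax <- .unit(p2 - p1)
  ref <- matrix(rep(c(0, 0, 1), nrow(ax)), ncol = 3, byrow = TRUE)
  bad <- abs(ax[, 3]) > 0.99
  ref[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
  p1 + ref
}

## n_rows x 3 slice of prefix array A at atom j
.slice <- function(A, rows, j) {
  m <- A[rows, j, , drop = FALSE]
  dim(m) <- c(length(rows), 3L)
  m
}

#' Lattice anchor of a structure
#'
#' The minimum corner of the structure's bounding box; tail-grid cells are
#' indexed relative to this point.
#'
#' @param s A \code{protein}.
#' @return Length-3 numeric vector.
#' @export
lattice_anchor <- function(s) {
  m <- atom_coords(s)
  apply(m, 2, min)
}

.seed_atom1 <- function(center, r, eps, anchor) {
  lo <- floor((center - r - anchor) / eps)
  hi <- ceiling((center + r - anchor) / eps)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  pts <- sweep(as.matrix(g) * eps, 2, anchor, "+")
  pts <- pts[.rownorm(sweep(pts, 2, center)) <= r, , drop = FALSE]
  if (nrow(pts) == 0L) {   # never happens for r >= eps, kept as a guard
    pts <- matrix(anchor + eps * round((center - anchor) / eps), 1, 3)
  }
  pts
}

#' Seed 3-atom prefixes for the backbone search
#'
#' Atom 1 (N1): epsilon-lattice points within \code{r} of the target N1.
#' Atom 2 (CA1): points on the ideal N-CA sphere around each atom-1
#' candidate at arc spacing ~eps (Fibonacci sampling).  Atom 3 (C1): points
#' on the ideal-geometry circle around each (1,2) pair at arc spacing ~eps.
#' Every prefix has exactly ideal bond lengths and angles; the lattice is
#' used only for dedup keys, atoms are not snapped to it.
#'
#' @param target A \code{protein}; its first residue centers the search.
#' @param r Search-sphere radius for atom 1 (Angstrom).
#' @param eps Grid/arc spacing (Angstrom).
#' @param ideal An \code{ideal_geometry} table.
#' @param anchor Lattice anchor (default: target bounding-box corner).
#' @return List of 3 x 3 prefix coordinate matrices (rows N1, CA1, C1).
#' @export
seed_candidates <- function(target, r, eps, ideal = read_ideal_geometry(),
                            anchor = NULL) {
  if (eps <= 0) stop("eps must be positive")
  if (r < eps) stop("r must be at least eps")
  seq3 <- sequence3(target)
  bb <- backbone_coords(target)
  if (is.null(anchor)) anchor <- lattice_anchor(target)
  p1 <- .seed_atom1(bb$N[1, ], r, eps, anchor)
  rad <- ideal_value(ideal, "N-CA", seq3[1])
  n2 <- max(8L, as.integer(ceiling(4 * pi * rad^2 / eps^2)))
  dirs <- .fib_sphere(n2) * rad
  len3 <- ideal_value(ideal, "CA-C", seq3[1])
  ang3 <- ideal_value(ideal, "N-CA-C", seq3[1])
  taus <- .sweep_torsions(len3 * sin(ang3 * pi / 180), eps)
  out <- list()
  for (a in seq_len(nrow(p1))) {
    for (b in seq_len(n2)) {
      q1 <- p1[a, ]; q2 <- q1 + dirs[b, ]
      ref <- .circle_ref(matrix(q1, 1, 3), matrix(q2, 1, 3))
      q3 <- place_next_atom(ref[rep(1, length(taus)), , drop = FALSE],
                            matrix(q1, length(taus), 3, byrow = TRUE),
                            matrix(q2, length(taus), 3, byrow = TRUE),
                            len3, ang3, taus)
      for (cc in seq_len(nrow(q3))) {
        out[[length(out) + 1L]] <- rbind(q1, q2, q3[cc, ], deparse.level = 0)
      }
    }
  }
  out
}

## internal coordinates used when chaining atom t (t >= 3)
.atom_internal <- function(t, seq3, ideal) {
  i <- (t + 2L) %/% 3L
  kind <- (t - 1L) %% 3L
  if (kind == 0L) {        # N(i), torsion = psi(i-1), free sweep
    list(kind = "N", res = i,
         len = ideal_value(ideal, "C-N", seq3[i]),
         ang = ideal_value(ideal, "CA-C-N", seq3[i - 1]))
  } else if (kind == 1L) { # CA(i), torsion = omega(i-1), rounded to 0/180
    list(kind = "CA", res = i,
         len = ideal_value(ideal, "N-CA", seq3[i]),
         ang = ideal_value(ideal, "C-N-CA", seq3[i]))
  } else {                 # C(i), torsion = phi(i), free sweep
    list(kind = "C", res = i,
         len = ideal_value(ideal, "CA-C", seq3[i]),
         ang = ideal_value(ideal, "N-CA-C", seq3[i]))
  }
}

#' Omega values tried for a CA atom
#'
#' Trans (180) always; cis (0) additionally for proline, or when the
#' target's own omega lies within \code{cis_window} of 0.
#'
#' @param restype Residue type of the CA being placed.
#' @param target_omega The target's omega (degrees) preceding this CA, or
#'   NA.
#' @param cis_window Half-width in degrees of the cis detection window.
#' @return Numeric vector of omega values (180, optionally 0).
#' @export
allowed_omegas <- function(restype, target_omega, cis_window = 30) {
  cis <- identical(toupper(restype), "PRO") ||
    (!is.na(target_omega) && abs(wrap_angle(target_omega)) <= cis_window)
  if (cis) c(180, 0) else 180
}

#' Candidate coordinates for the next backbone atom of one prefix
#'
#' For C and N atoms: a full-circle torsion sweep at arc spacing ~eps on
#' the ideal-geometry circle around the previous atom.  For CA atoms: the
#' 1-2 points given by rounding omega to 180 (trans) and optionally 0
#' (cis).
#'
#' @param prefix (t-1) x 3 matrix of backbone coordinates generated so far.
#' @param seq3 Residue types of the chain (3-letter codes).
#' @param t Index (>= 4) of the atom to place (N1, CA1, C1, N2, ... order).
#' @param ideal An \code{ideal_geometry} table.
#' @param eps Arc spacing (Angstrom).
#' @param omegas Omega values to use at CA atoms (see
#'   \code{\link{allowed_omegas}}).
#' @return Matrix of candidate coordinates (one per row), each satisfying
#'   the ideal bond length and angle exactly.
#' @export
extend_candidates <- function(prefix, seq3, t, ideal = read_ideal_geometry(),
                              eps, omegas = 180) {
  stopifnot(t >= 4L, nrow(prefix) == t - 1L)
  ic <- .atom_internal(t, seq3, ideal)
  taus <- if (ic$kind == "CA") omegas else
    .sweep_torsions(ic$len * sin(ic$ang * pi / 180), eps)
  place_next_atom(matrix(prefix[t - 3L, ], length(taus), 3, byrow = TRUE),
                  matrix(prefix[t - 2L, ], length(taus), 3, byrow = TRUE),
                  matrix(prefix[t - 1L, ], length(taus), 3, byrow = TRUE),
                  ic$len, ic$ang, taus)
}

## ---------------------------------------------------------------------------
## The DP itself

## target-side data needed for incremental scoring
.dp_target_data <- function(target, hbonds) {
  tor <- extract_torsions(target)
  n <- nrow(tor)
  ca <- atom_coords(target, "CA")
  cbm <- matrix(NA_real_, n, 3)
  cbs <- atom_coords(target, "CB")
  key <- attr(cbs, "key")
  if (nrow(cbs) > 0L) cbm[key$residue_index, ] <- cbs
  hat <- attr(hbonds, "atoms")
  hpos <- opos <- matrix(NA_real_, n, 3)
  if (nrow(hat) > 0L) {
    for (r in seq_len(nrow(hat))) {
      pos <- atom_coords(target, hat$name[r], hat$residue_index[r])
      if (nrow(pos) == 1L) {
        if (hat$name[r] == "H") hpos[hat$residue_index[r], ] <- pos
        else opos[hat$residue_index[r], ] <- pos
      }
    }
  }
  list(n = n, seq3 = tor$residue_type, tor = tor, ca = ca, cb = cbm,
       h = hpos, o = opos,
       has_cb = !is.na(cbm[, 1]) & tor$residue_type != "GLY",
       has_h = !is.na(hpos[, 1]), has_o = !is.na(opos[, 1]))
}

#' Idealize a protein backbone by tail-grid dynamic programming
#'
#' Generates idealized backbone candidates atom-by-atom and keeps, at each
#' atom, only the best-scoring prefix per tail-grid signature, pruned to
#' the top \code{m} prefixes by prefix score.  Returns the best final
#' prefix with O/H/CB rebuilt.
#'
#' @param target A \code{protein}; all scoring distances are measured
#'   against it.  Missing O/H/CB atoms are filled in.
#' @param r Search-sphere radius for the first atom (Angstrom).
#' @param eps Grid size / arc spacing (Angstrom); tail signatures use cells
#'   of this size.
#' @param m Beam width: prefixes kept per atom (Inf = no beam pruning).
#' @param k Tail length in atoms; must be >= 5 so that the previous
#'   residue's phi/psi are functions of the tail.
#' @param rama A \code{rama_table} for the log-odds term.
#' @param weights Weights w1..w4 of the ca/cb/hb/phipsi distance terms.
#' @param ideal An \code{ideal_geometry} table.
#' @param hbonds Hydrogen bonds detected on the target (default: detected
#'   here); their H/O atom set is held fixed during scoring.
#' @param seed_structure Structure whose first residue centers the atom-1
#'   search sphere and whose omegas gate cis peptides (default: the
#'   target).  Iterative refinement passes the previous iterate here while
#'   scoring stays against the original target.
#' @param inject Optional idealized \code{protein} whose backbone prefixes
#'   are added to the beam at every atom and never pruned, guaranteeing
#'   the returned score is at least the injected structure's score.
#' @param cis_window Cis-peptide window (degrees) on the target omega.
#' @param tail_mode "grid" (default) keys tails by epsilon-cells; "exact"
#'   keys by exact coordinates so no two distinct prefixes ever merge
#'   (with \code{m = Inf} the DP is then exhaustive enumeration).
#' @param verbose Print beam sizes per atom.
#' @return A list of class \code{dp_result}: \code{structure} (idealized,
#'   with O/H/CB), \code{backbone} (N/CA/C only), \code{breakdown} (a
#'   \code{score_breakdown}), \code{score}, \code{beam_trace}.
#' @export
dp_idealize <- function(target, r = 1.6, eps = r / 5, m = 50000, k = 5L,
                        rama, weights = c(1, 1, 1, 1),
                        ideal = read_ideal_geometry(),
                        hbonds = NULL, seed_structure = NULL, inject = NULL,
                        cis_window = 30, tail_mode = c("grid", "exact"),
                        verbose = FALSE) {
  tail_mode <- match.arg(tail_mode)
  k <- as.integer(k)
  if (k < 5L) stop("k must be >= 5 (phi/psi of the previous residue must be tail-local)")
  if (eps <= 0) stop("eps must be positive")
  if (r < eps) stop("r must be at least eps")
  target <- prepare_target(target, ideal)
  n <- n_residues(target)
  if (n < 2L) stop("target must have at least 2 residues")
  if (is.null(hbonds)) hbonds <- detect_hbonds(target)
  if (is.null(seed_structure)) seed_structure <- target
  td <- .dp_target_data(target, hbonds)
  seq3 <- td$seq3
  stor <- extract_torsions(seed_structure)
  anchor <- lattice_anchor(target)
  w <- rep_len(as.numeric(weights), 4)
  names(w) <- SCORE_METRICS

  inj <- NULL
  if (!is.null(inject)) {
    bbi <- backbone_coords(inject)
    inj <- matrix(NA_real_, 3 * n, 3)
    inj[seq(1, 3 * n, 3), ] <- bbi$N
    inj[seq(2, 3 * n, 3), ] <- bbi$CA
    inj[seq(3, 3 * n, 3), ] <- bbi$C
  }

  rowkey <- function(mat) {
    if (tail_mode == "exact") {
      do.call(paste, c(as.data.frame(round(mat, 9)), sep = ","))
    } else {
      do.call(paste, c(as.data.frame(floor(
        sweep(mat, 2, rep(anchor, ncol(mat) / 3), "-") / eps)), sep = ","))
    }
  }

  ## beam state: A = n_e x t x 3 prefixes; comp = per-entry partial sums;
  ## cnt = per-metric counts (equal across entries at a given t);
  ## inj_row = beam row holding the injected prefix (always last)
  A <- NULL
  comp <- NULL   # list(lo, ca, cb, hb, pp), numeric vectors
  cnt <- c(ca = 0L, cb = 0L, hb = 0L, phipsi = 0L)
  inj_row <- NULL
  trace <- data.frame(t = integer(0), candidates = integer(0), kept = integer(0))

  score_of <- function(cp, cn) {
    cp$lo - w[["ca"]] * sqrt(cp$ca / max(cn[["ca"]], 1L)) -
      w[["cb"]] * sqrt(cp$cb / max(cn[["cb"]], 1L)) -
      w[["hb"]] * sqrt(cp$hb / max(cn[["hb"]], 1L)) -
      w[["phipsi"]] * sqrt(cp$pp / max(cn[["phipsi"]], 1L))
  }

  ## score increments for placing candidates D (rows) at atom t with
  ## parents pidx; returns list(inc = per-candidate sums, cnt_inc)
  make_inc <- function(t, D, pidx) {
    i <- (t + 2L) %/% 3L
    kind <- (t - 1L) %% 3L
    nc <- nrow(D)
    inc <- list(lo = numeric(nc), ca = numeric(nc), cb = numeric(nc),
                hb = numeric(nc), pp = numeric(nc))
    cnt_inc <- c(ca = 0L, cb = 0L, hb = 0L, phipsi = 0L)
    if (kind == 1L) {                        # CA(i)
      inc$ca <- .rownorm(D - matrix(td$ca[i, ], nc, 3, byrow = TRUE))^2
      cnt_inc["ca"] <- 1L
      if (i >= 3L && !is.na(td$tor$phi[i - 1]) && !is.na(td$tor$psi[i - 1])) {
        ## phi/psi of residue i-1 are functions of the parent tail
        ne <- dim(A)[1]
        phi <- dihedral(.slice(A, 1:ne, t - 5L), .slice(A, 1:ne, t - 4L),
                        .slice(A, 1:ne, t - 3L), .slice(A, 1:ne, t - 2L))
        psi <- dihedral(.slice(A, 1:ne, t - 4L), .slice(A, 1:ne, t - 3L),
                        .slice(A, 1:ne, t - 2L), .slice(A, 1:ne, t - 1L))
        lo <- rama_log_odds(rama, seq3[i - 1], phi, psi)
        pp <- (wrap_angle(phi - td$tor$phi[i - 1]) * pi / 180)^2 +
          (wrap_angle(psi - td$tor$psi[i - 1]) * pi / 180)^2
        inc$lo <- lo[pidx]
        inc$pp <- pp[pidx]
        cnt_inc["phipsi"] <- 2L
      }
    } else if (kind == 0L && t > 1L) {       # N(i): O(i-1), H(i)
      if (td$has_o[i - 1]) {
        o <- .place_o(.slice(A, pidx, t - 2L), .slice(A, pidx, t - 1L), D,
                      ideal, seq3[i - 1])
        inc$hb <- inc$hb + .rownorm(o - matrix(td$o[i - 1, ], nc, 3, byrow = TRUE))^2
        cnt_inc["hb"] <- cnt_inc["hb"] + 1L
      }
      if (td$has_h[i]) {
        h <- .place_h(.slice(A, pidx, t - 2L), .slice(A, pidx, t - 1L), D, ideal)
        inc$hb <- inc$hb + .rownorm(h - matrix(td$h[i, ], nc, 3, byrow = TRUE))^2
        cnt_inc["hb"] <- cnt_inc["hb"] + 1L
      }
    } else if (kind == 2L) {                 # C(i): CB, terminal O/H
      if (td$has_cb[i]) {
        cb <- .place_cb(.slice(A, pidx, t - 2L), .slice(A, pidx, t - 1L), D,
                        ideal_value(ideal, "CA-CB", seq3[i]),
                        ideal_value(ideal, "N-CA-CB", seq3[i]),
                        ideal_value(ideal, "C-CA-CB", seq3[i]))
        inc$cb <- .rownorm(cb - matrix(td$cb[i, ], nc, 3, byrow = TRUE))^2
        cnt_inc["cb"] <- 1L
      }
      if (i == 1L && td$has_h[1]) {          # N-terminal H (own CA/C rule)
        h <- .place_h(.slice(A, pidx, t - 1L), D, .slice(A, pidx, t - 2L), ideal)
        inc$hb <- inc$hb + .rownorm(h - matrix(td$h[1, ], nc, 3, byrow = TRUE))^2
        cnt_inc["hb"] <- cnt_inc["hb"] + 1L
      }
      if (i == n && td$has_o[n]) {           # C-terminal O (own N rule)
        o <- .place_o(.slice(A, pidx, t - 1L), D, .slice(A, pidx, t - 2L),
                      ideal, seq3[n])
        inc$hb <- inc$hb + .rownorm(o - matrix(td$o[n, ], nc, 3, byrow = TRUE))^2
        cnt_inc["hb"] <- cnt_inc["hb"] + 1L
      }
    }
    list(inc = inc, cnt_inc = cnt_inc)
  }

  ## candidate generation for atom t: returns list(D, pidx, inj_cand)
  gen <- function(t) {
    if (t == 1L) {
      D <- .seed_atom1(backbone_coords(seed_structure)$N[1, ], r, eps, anchor)
      pidx <- rep(1L, nrow(D))   # dummy
    } else if (t == 2L) {
      parents <- seq_len(dim(A)[1])
      rad <- ideal_value(ideal, "N-CA", seq3[1])
      n2 <- max(8L, as.integer(ceiling(4 * pi * rad^2 / eps^2)))
      dirs <- .fib_sphere(n2) * rad
      pidx <- rep(parents, each = n2)
      D <- .slice(A, pidx, 1L) + dirs[rep(seq_len(n2), length(parents)), ]
    } else if (t == 3L) {
      parents <- seq_len(dim(A)[1])
      ic <- .atom_internal(t, seq3, ideal)
      taus <- .sweep_torsions(ic$len * sin(ic$ang * pi / 180), eps)
      pidx <- rep(parents, each = length(taus))
      p1 <- .slice(A, pidx, 1L); p2 <- .slice(A, pidx, 2L)
      D <- place_next_atom(.circle_ref(p1, p2), p1, p2, ic$len, ic$ang,
                           rep(taus, length(parents)))
    } else {
      parents <- seq_len(dim(A)[1])
      ic <- .atom_internal(t, seq3, ideal)
      taus <- if (ic$kind == "CA") {
        allowed_omegas(seq3[ic$res], stor$omega[ic$res - 1], cis_window)
      } else {
        .sweep_torsions(ic$len * sin(ic$ang * pi / 180), eps)
      }
      pidx <- rep(parents, each = length(taus))
      D <- place_next_atom(.slice(A, pidx, t - 3L), .slice(A, pidx, t - 2L),
                           .slice(A, pidx, t - 1L), ic$len, ic$ang,
                           rep(taus, length(parents)))
    }
    inj_cand <- NA_integer_
    if (!is.null(inj)) {   # append the injected prefix's next atom
      D <- rbind(D, inj[t, ])
      pidx <- c(pidx, if (t == 1L) 1L else inj_row)
      inj_cand <- length(pidx)
    }
    list(D = D, pidx = pidx, inj_cand = inj_cand)
  }

  for (t in seq_len(3L * n)) {
    g <- gen(t)
    mi <- make_inc(t, g$D, g$pidx)
    ncand <- nrow(g$D)
    cp <- if (t == 1L) {
      mi$inc
    } else {
      list(lo = comp$lo[g$pidx] + mi$inc$lo, ca = comp$ca[g$pidx] + mi$inc$ca,
           cb = comp$cb[g$pidx] + mi$inc$cb, hb = comp$hb[g$pidx] + mi$inc$hb,
           pp = comp$pp[g$pidx] + mi$inc$pp)
    }
    cnt <- cnt + mi$cnt_inc
    scores <- score_of(cp, cnt)
    ## tail keys over the last min(k, t) atoms
    j0 <- max(1L, t - k + 1L)
    tail_mat <- g$D
    if (t > 1L && j0 < t) {
      prev <- A[g$pidx, j0:(t - 1L), , drop = FALSE]
      prev <- matrix(aperm(prev, c(1, 3, 2)), nrow = ncand)
      tail_mat <- cbind(prev, g$D)
    }
    keys <- rowkey(tail_mat)
    ord <- order(keys, -scores, g$pidx, method = "radix")
    ord <- ord[!duplicated(keys[ord])]
    ord <- ord[order(-scores[ord], keys[ord], method = "radix")]
    if (is.finite(m) && length(ord) > m) ord <- ord[seq_len(m)]
    if (!is.null(inj) && !(g$inj_cand %in% ord)) ord <- c(ord, g$inj_cand)
    n_keep <- length(ord)
    Anew <- array(NA_real_, c(n_keep, t, 3))
    if (t > 1L) Anew[, 1:(t - 1L), ] <- A[g$pidx[ord], , , drop = FALSE]
    Anew[, t, ] <- g$D[ord, , drop = FALSE]
    A <- Anew
    comp <- list(lo = cp$lo[ord], ca = cp$ca[ord], cb = cp$cb[ord],
                 hb = cp$hb[ord], pp = cp$pp[ord])
    if (!is.null(inj)) inj_row <- match(g$inj_cand, ord)
    trace <- rbind(trace, data.frame(t = t, candidates = ncand, kept = n_keep))
    if (verbose) {
      message(sprintf("atom %3d: %7d candidates -> %6d kept", t, ncand, n_keep))
    }
  }

  scores <- score_of(comp, cnt)
  best <- order(-scores)[1]
  coords <- A[best, , ]
  bb <- protein_from_backbone(coords, seq3)
  out <- rebuild_dependent_atoms(bb, ideal)
  breakdown <- score_breakdown(w)
  breakdown$logodds <- comp$lo[best]
  breakdown$ss <- c(ca = comp$ca[best], cb = comp$cb[best],
                    hb = comp$hb[best], phipsi = comp$pp[best])
  breakdown$n <- cnt
  structure(list(structure = out, backbone = bb, breakdown = breakdown,
                 score = scores[best], beam_trace = trace,
                 params = list(r = r, eps = eps, m = m, k = k, weights = w,
                               cis_window = cis_window, tail_mode = tail_mode)),
            class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("<dp_result> %d residues idealized, S_BB = %.4f\n",
              n_residues(x$structure), x$score))
  print(x$breakdown)
  invisible(x)
}

#' Fill in missing O/H/CB atoms of a target
#'
#' Deposited atoms are kept; only missing dependent atoms are rebuilt with
#' ideal geometry.
#'
#' @param target A \code{protein} with at least N/CA/C per residue.
#' @param ideal An \code{ideal_geometry} table.
#' @return The completed \code{protein}.
#' @export
prepare_target <- function(target, ideal = read_ideal_geometry()) {
  rebuild_dependent_atoms(target, ideal, replace = FALSE)
}
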