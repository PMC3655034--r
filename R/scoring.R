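## The backbone scoring function S_BB and side-chain scoring function S_SC,
## their distance metrics, the bottleneck distance, hydrogen-bond detection,
## and the additive score-combination operator.
##
## S_BB = S_f - w1*D_ca - w2*D_cb - w3*D_hb - w4*D_phipsi, where S_f is the
## Ramachandran log-odds sum and each D is a frame-fixed RMSD (no
## superposition: candidates are generated in the target's frame, which is
## what makes the score additive over chain segments).

SCORE_METRICS <- c("ca", "cb", "hb", "phipsi")

#' Create an (empty) score breakdown
#'
#' A \code{score_breakdown} carries the log-odds sum plus, per distance
#' metric (ca, cb, hb, phipsi), the running sum of squared deviations and
#' the count of contributing items — the partial sums that make the
#' backbone score additive over disjoint chain segments.
#'
#' @param weights Named (or positional) numeric weights w1..w4 for the
#'   ca, cb, hb and phipsi terms; default all 1.
#' @return An object of class \code{score_breakdown}.
#' @export
score_breakdown <- function(weights = c(ca = 1, cb = 1, hb = 1, phipsi = 1)) {
  w <- rep_len(as.numeric(weights), 4)
  names(w) <- SCORE_METRICS
  structure(list(logodds = 0,
                 ss = c(ca = 0, cb = 0, hb = 0, phipsi = 0),
                 n = c(ca = 0L, cb = 0L, hb = 0L, phipsi = 0L),
                 weights = w),
            class = "score_breakdown")
}

#' Add observations to a score breakdown
#'
#' @param b A \code{score_breakdown}.
#' @param metric One of "ca", "cb", "hb", "phipsi".
#' @param ss Sum of squared deviations to add.
#' @param n Number of items contributing to \code{ss}.
#' @param logodds Log-odds increment.
#' @return The updated breakdown.
#' @export
breakdown_add <- function(b, metric = NULL, ss = 0, n = 0L, logodds = 0) {
  if (!is.null(metric)) {
    b$ss[[metric]] <- b$ss[[metric]] + ss
    b$n[[metric]] <- b$n[[metric]] + as.integer(n)
  }
  b$logodds <- b$logodds + logodds
  b
}

#' Combine score breakdowns of disjoint chain segments
#'
#' Implements the additive property of the backbone score: squared-deviation
#' sums, counts and log-odds sums add, so the combined RMSDs equal
#' \code{sqrt((r1^2*n1 + r2^2*n2)/(n1+n2))}.
#'
#' @param a,b Breakdowns over disjoint segments (weights must agree).
#' @return The combined \code{score_breakdown}.
#' @export
combine_breakdowns <- function(a, b) {
  if (!isTRUE(all.equal(a$weights, b$weights))) {
    stop("cannot combine breakdowns with different weights")
  }
  a$logodds <- a$logodds + b$logodds
  a$ss <- a$ss + b$ss
  a$n <- a$n + b$n
  a
}

#' Per-metric RMSD values of a breakdown
#'
#' @param b A \code{score_breakdown}.
#' @return Named vector of RMSDs; a metric with no contributing items is 0
#'   (the neutral element of the score).
#' @export
breakdown_rmsd <- function(b) {
  ifelse(b$n > 0, sqrt(b$ss / pmax(b$n, 1L)), 0)
}

#' Backbone score of a breakdown
#'
#' \code{S_f - sum(w_a * D_a)} with the RMSDs recovered from the partial
#' sums.
#'
#' @param b A \code{score_breakdown}.
#' @return Numeric score.
#' @export
backbone_score <- function(b) {
  unname(b$logodds - sum(b$weights * breakdown_rmsd(b)))
}

#' @export
print.score_breakdown <- function(x, ...) {
  r <- breakdown_rmsd(x)
  cat(sprintf("<score_breakdown> S_f = %.4f | D_ca = %.4f  D_cb = %.4f  D_hb = %.4f  D_phipsi = %.4f | S_BB = %.4f\n",
              x$logodds, r["ca"], r["cb"], r["hb"], r["phipsi"],
              backbone_score(x)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Distance metrics

#' Bottleneck distance between two structures
#'
#' Maximum over matched atoms of the Euclidean distance.
#'
#' @param p,q \code{protein} structures (or plain coordinate matrices) with
#'   identical atom lists.
#' @return Distance in Angstrom.
#' @export
bottleneck_distance <- function(p, q) {
  mp <- if (inherits(p, "protein")) atom_coords(p) else .as_mat3(p)
  mq <- if (inherits(q, "protein")) atom_coords(q) else .as_mat3(q)
  if (nrow(mp) != nrow(mq)) stop("mismatched atom lists in bottleneck_distance()")
  if (inherits(p, "protein") && inherits(q, "protein")) {
    kp <- attr(mp, "key"); kq <- attr(mq, "key")
    if (!identical(paste(kp$residue_index, kp$name),
                   paste(kq$residue_index, kq$name))) {
      stop("mismatched atom identities in bottleneck_distance()")
    }
  }
  max(.rownorm(mp - mq))
}

#' Frame-fixed RMSD over selected atoms
#'
#' Root-mean-square deviation with NO superposition: both structures are
#' taken in the same (the target's) coordinate frame.
#'
#' @param p,q \code{protein} structures or coordinate matrices.
#' @param names Atom-name selection applied to both (e.g. "CA"); NULL = all.
#' @return RMSD in Angstrom; an empty selection yields 0 with a warning.
#' @export
rmsd_no_fit <- function(p, q, names = NULL) {
  mp <- if (inherits(p, "protein")) atom_coords(p, names) else .as_mat3(p)
  mq <- if (inherits(q, "protein")) atom_coords(q, names) else .as_mat3(q)
  if (nrow(mp) != nrow(mq)) stop("selections of unequal length in rmsd_no_fit()")
  if (nrow(mp) == 0L) {
    warning("empty atom selection; RMSD defined as 0")
    return(0)
  }
  sqrt(mean(.rownorm(mp - mq)^2))
}

## ---------------------------------------------------------------------------
## Hydrogen bonds (Kabsch-Sander electrostatic criterion)

#' Detect backbone hydrogen bonds (Kabsch-Sander)
#'
#' Computes the DSSP electrostatic energy
#' \code{E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)} kcal/mol for
#' every donor (amide N-H, never proline) / acceptor (carbonyl C=O) pair
#' with sequence separation of at least 2, and keeps pairs with
#' \code{E < cutoff}.
#'
#' @param s A \code{protein} with amide H and carbonyl O present (see
#'   \code{\link{rebuild_dependent_atoms}}).
#' @param cutoff Energy cutoff in kcal/mol (default -0.5).
#' @return An object of class \code{hbond_set}: data frame (donor,
#'   acceptor, energy) with the participating H/O atom table attached as
#'   attribute \code{"atoms"} (residue_index, name).
#' @export
detect_hbonds <- function(s, cutoff = -0.5) {
  a <- s$atoms
  res <- sort(unique(a$residue_index))
  get1 <- function(nm) {
    sel <- a[a$name == nm, ]
    m <- matrix(NA_real_, length(res), 3)
    m[match(sel$residue_index, res), ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  N <- get1("N"); H <- get1("H"); C <- get1("C"); O <- get1("O")
  if (all(is.na(O)) || all(is.na(H))) {
    stop("detect_hbonds() needs rebuilt O and H atoms")
  }
  restype <- a$residue_type[match(res, a$residue_index)]
  donors <- which(restype != "PRO" & !is.na(H[, 1]))
  acceptors <- which(!is.na(O[, 1]))
  pairs <- expand.grid(donor = donors, acceptor = acceptors)
  pairs <- pairs[abs(pairs$donor - pairs$acceptor) >= 2L, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(structure(data.frame(donor = integer(0), acceptor = integer(0),
                                energy = numeric(0)),
                     atoms = data.frame(residue_index = integer(0),
                                        name = character(0)),
                     class = c("hbond_set", "data.frame")))
  }
  d <- function(p, q) .rownorm(p - q)
  i <- pairs$donor; j <- pairs$acceptor
  e <- 0.084 * 332 * (1 / d(O[j, , drop = FALSE], N[i, , drop = FALSE]) +
                      1 / d(C[j, , drop = FALSE], H[i, , drop = FALSE]) -
                      1 / d(O[j, , drop = FALSE], H[i, , drop = FALSE]) -
                      1 / d(C[j, , drop = FALSE], N[i, , drop = FALSE]))
  keep <- e < cutoff
  out <- data.frame(donor = res[i[keep]], acceptor = res[j[keep]], energy = e[keep])
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  atoms <- unique(data.frame(
    residue_index = c(out$donor, out$acceptor),
    name = rep(c("H", "O"), c(nrow(out), nrow(out))),
    stringsAsFactors = FALSE))
  atoms <- atoms[order(atoms$residue_index, atoms$name), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(out, atoms = atoms, class = c("hbond_set", "data.frame"))
}

## ---------------------------------------------------------------------------
## Whole-structure backbone scoring (monolithic; the DP recomputes the same
## quantities incrementally and must agree with this to 1e-9)

#' Score a candidate backbone against a target (monolithic)
#'
#' Builds the full \code{score_breakdown} of a candidate structure in one
#' pass: Ramachandran log-odds and phi/psi deviations per interior residue,
#' CA and CB squared deviations, and squared deviations of the H/O atoms in
#' the target's hydrogen-bond set.  Both structures must cover the same
#' residues; CB/H/O atoms are taken from the structures as present (rebuild
#' them first for a fair comparison).
#'
#' @param candidate,target \code{protein} structures over the same residues.
#' @param rama A \code{rama_table}.
#' @param hbonds An \code{hbond_set} detected on the TARGET (its atom set is
#'   held fixed); NULL to detect it here.
#' @param weights Weights w1..w4.
#' @return A \code{score_breakdown}; use \code{\link{backbone_score}} on it.
#' @export
score_backbone_structure <- function(candidate, target, rama,
                                     hbonds = NULL, weights = c(1, 1, 1, 1)) {
  b <- score_breakdown(weights)
  tc <- extract_torsions(candidate)
  tt <- extract_torsions(target)
  ## CA term
  pc <- atom_coords(candidate, "CA"); pt <- atom_coords(target, "CA")
  b <- breakdown_add(b, "ca", sum(.rownorm(pc - pt)^2), nrow(pc))
  ## CB term (residues where the target has a CB)
  kc <- attr(atom_coords(candidate, "CB"), "key")
  ct <- atom_coords(target, "CB"); kt <- attr(ct, "key")
  common <- intersect(kc$residue_index, kt$residue_index)
  if (length(common) > 0L) {
    cc <- atom_coords(candidate, "CB", common)
    ct <- atom_coords(target, "CB", common)
    b <- breakdown_add(b, "cb", sum(.rownorm(cc - ct)^2), length(common))
  }
  ## hydrogen-bond atom term: the target's H-bond atom set, fixed
  if (is.null(hbonds)) hbonds <- detect_hbonds(target)
  hat <- attr(hbonds, "atoms")
  if (nrow(hat) > 0L) {
    for (r in seq_len(nrow(hat))) {
      cc <- atom_coords(candidate, hat$name[r], hat$residue_index[r])
      tt2 <- atom_coords(target, hat$name[r], hat$residue_index[r])
      if (nrow(cc) == 1L && nrow(tt2) == 1L) {
        b <- breakdown_add(b, "hb", sum((cc - tt2)^2), 1L)
      }
    }
  }
  ## log-odds + phi/psi deviations over interior residues; angular squared
  ## deviations are accumulated in radians so that all four distance
  ## metrics are commensurate under uniform weights
  ok <- !is.na(tc$phi) & !is.na(tc$psi) & !is.na(tt$phi) & !is.na(tt$psi)
  if (any(ok)) {
    for (i in which(ok)) {
      b <- breakdown_add(b, "phipsi",
                         (wrap_angle(tc$phi[i] - tt$phi[i]) * pi / 180)^2 +
                           (wrap_angle(tc$psi[i] - tt$psi[i]) * pi / 180)^2, 2L,
                         logodds = rama_log_odds(rama, tc$residue_type[i],
                                                 tc$phi[i], tc$psi[i]))
    }
  }
  b
}

## ---------------------------------------------------------------------------
## Side-chain scoring

#' Score an idealized side-chain conformation against the target
#'
#' \code{S_SC = S_f - w1 * D_sc - w2 * D_chi}: the chi log-odds score minus
#' the frame-fixed RMSD of the non-hydrogen side-chain atoms (over atoms
#' present in both) minus the RMSD of wrapped chi differences.
#'
#' @param cand_coords m x 3 matrix of candidate side-chain atom coordinates
#'   with atom names as rownames.
#' @param target_coords Matrix of the target residue's side-chain atoms
#'   (names as rownames); may be missing atoms or NULL, in which case the
#'   distance terms use only what is present.
#' @param cand_chis Candidate chi tuple (degrees).
#' @param target_chis Target chi tuple (NA components are skipped in D_chi).
#' @param table A \code{rotamer_table}.
#' @param aa Residue type.
#' @param phi,psi Backbone dihedrals for backbone-dependent libraries.
#' @param weights c(w1, w2).
#' @return Numeric score (0 for residues with no side chain).
#' @export
sidechain_score <- function(cand_coords, target_coords, cand_chis, target_chis,
                            table, aa, phi = NA, psi = NA, weights = c(1, 1)) {
  k <- n_chi(aa)
  if (k == 0L) return(0)
  sf <- chi_log_odds(table, aa, phi, psi, cand_chis)
  d_sc <- 0
  if (!is.null(target_coords) && nrow(target_coords) > 0L) {
    common <- intersect(rownames(cand_coords), rownames(target_coords))
    if (length(common) > 0L) {
      d_sc <- rmsd_no_fit(cand_coords[common, , drop = FALSE],
                          target_coords[common, , drop = FALSE])
    }
  }
  d_chi <- 0
  tk <- target_chis[seq_len(k)]
  ok <- !is.na(tk)
  if (any(ok)) {   # wrapped chi differences, in radians (commensurate units)
    d_chi <- sqrt(mean((wrap_angle(cand_chis[seq_len(k)][ok] - tk[ok]) * pi / 180)^2))
  }
  sf - weights[1] * d_sc - weights[2] * d_chi
}
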