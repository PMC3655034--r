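## Iterative refinement: alternate backbone and side-chain idealization
## while shrinking the search radius and grid by a constant factor, and the
## classic modelling front-end idealize() with its S3 methods.

#' Build the rounded-torsion baseline structure
#'
#' The naive idealization: measure the target's own torsions, round omega
#' to 0/180, rebuild with ideal geometry anchored (by rigid least squares)
#' on the target's first residue.  Useful as a baseline the optimized
#' idealization should beat.
#'
#' @param target A \code{protein}.
#' @param ideal An \code{ideal_geometry} table.
#' @return A \code{protein}.
#' @export
round_torsion_baseline <- function(target, ideal = read_ideal_geometry()) {
  tor <- extract_torsions(target)
  tor$omega <- ifelse(is.na(tor$omega), NA,
                      ifelse(abs(wrap_angle(tor$omega)) < 90, 0, 180))
  bb <- backbone_coords(target)
  anchor <- fit_anchor(rbind(bb$N[1, ], bb$CA[1, ], bb$C[1, ]),
                       tor$residue_type[1], ideal)
  build_from_torsions(tor$residue_type, tor, ideal, anchor = anchor)
}

#' Iteratively refine an idealized structure
#'
#' Iteration 1 runs the backbone DP at (r, eps); iteration j shrinks both
#' by \code{shrink^(j-1)} and re-seeds the candidate generation around the
#' previous iterate (which is also injected into the beam, so the backbone
#' score never decreases), while all scoring distances remain against the
#' ORIGINAL target.  After the final backbone pass, side chains are
#' idealized with the chi window and step shrunk by the same schedule.
#'
#' @param target A \code{protein}.
#' @param r,eps,m,k,weights,cis_window Backbone DP parameters (see
#'   \code{\link{dp_idealize}}).
#' @param rama A \code{rama_table}.
#' @param rotamers A \code{rotamer_table} (NULL skips side chains).
#' @param n_iter Number of backbone passes (>= 1).
#' @param shrink Per-iteration shrink factor in (0, 1).
#' @param chi_step,chi_window_sigmas Side-chain grid parameters before
#'   shrinking.
#' @param sc_weights Side-chain score weights c(w1, w2).
#' @param ideal An \code{ideal_geometry} table.
#' @param tol Early stop when the backbone score improves by less.
#' @param verbose Progress messages.
#' @return A list of class \code{refine_result}: \code{structure} (full,
#'   side chains included when a rotamer table was given),
#'   \code{backbone_result} (final \code{dp_result}), \code{iterations}
#'   (data frame: iter, r, eps, score), \code{sidechain_scores}.
#' @export
refine <- function(target, r = 1.6, eps = r / 5, m = 50000, k = 5L,
                   rama, rotamers = read_rotamer_library(),
                   weights = c(1, 1, 1, 1), n_iter = 3L, shrink = 0.5,
                   chi_step = 10, chi_window_sigmas = 3,
                   sc_weights = c(1, 1), ideal = read_ideal_geometry(),
                   cis_window = 30, tol = 1e-6, verbose = FALSE) {
  stopifnot(n_iter >= 1L, shrink > 0, shrink < 1)
  target <- prepare_target(target, ideal)
  hbonds <- detect_hbonds(target)
  incumbent <- NULL
  best <- NULL
  iters <- data.frame(iter = integer(0), r = numeric(0), eps = numeric(0),
                      score = numeric(0))
  last_shrink <- 1
  for (j in seq_len(n_iter)) {
    fac <- shrink^(j - 1)
    res <- dp_idealize(target, r = r * fac, eps = eps * fac, m = m, k = k,
                       rama = rama, weights = weights, ideal = ideal,
                       hbonds = hbonds,
                       seed_structure = if (is.null(incumbent)) target else incumbent,
                       inject = incumbent, cis_window = cis_window,
                       verbose = verbose)
    iters <- rbind(iters, data.frame(iter = j, r = r * fac, eps = eps * fac,
                                     score = res$score))
    if (verbose) message(sprintf("iteration %d: S_BB = %.6f", j, res$score))
    improved <- is.null(best) || res$score > best$score + tol
    if (is.null(best) || res$score >= best$score) {
      best <- res
      last_shrink <- fac
    }
    incumbent <- best$backbone
    if (!improved && j > 1L) break
  }
  sc <- NULL
  structure_out <- best$structure
  if (!is.null(rotamers)) {
    scr <- idealize_sidechains(best$backbone, target, rotamers,
                               step = chi_step * last_shrink,
                               window_sigmas = chi_window_sigmas * last_shrink,
                               weights = sc_weights, ideal = ideal)
    structure_out <- scr$structure
    sc <- scr$scores
  }
  structure(list(structure = structure_out, backbone_result = best,
                 iterations = iters, sidechain_scores = sc,
                 target = target),
            class = "refine_result")
}

## ---------------------------------------------------------------------------
## Modelling front-end

#' Idealize a protein structure
#'
#' The top-level fitter: finds a structure with ideal bond lengths and
#' angles (conformation fully determined by dihedral angles) that
#' maximizes the backbone score — Ramachandran log-odds minus weighted
#' frame-fixed RMSD penalties to the target — via the tail-grid dynamic
#' program, then idealizes side chains by exhaustive chi search, with
#' iterative shrink refinement.
#'
#' @param target A \code{protein} (see \code{\link{read_structure}}) or a
#'   path to a PDB file.
#' @param r Search radius for the first atom (Angstrom).
#' @param eps Discretization grid size (Angstrom); default r/5.
#' @param m Beam width of the dynamic program.
#' @param n_iter Refinement iterations (each shrinks r and eps by
#'   \code{shrink}).
#' @param shrink Refinement shrink factor.
#' @param rama A \code{rama_table}; default is a compact table trained on
#'   synthetic helix/sheet torsion samples (see
#'   \code{\link{make_toy_tables}}) — supply a table built from real
#'   structures with \code{\link{build_rama_table}} for production use.
#' @param rotamers A \code{rotamer_table}; NULL skips side-chain placement.
#' @param weights Backbone score weights w1..w4.
#' @param ... Further arguments passed to \code{\link{refine}}.
#' @return An object of class \code{idealization} with methods
#'   \code{print}, \code{summary}, \code{coef} (the fitted dihedral
#'   angles), \code{residuals} (per-atom deviations from the target),
#'   \code{fitted} (the idealized \code{protein}) and \code{plot}
#'   (Ramachandran before/after).
#' @export
idealize <- function(target, r = 1.6, eps = r / 5, m = 50000,
                     n_iter = 3L, shrink = 0.5,
                     rama = NULL, rotamers = read_rotamer_library(),
                     weights = c(1, 1, 1, 1), ...) {
  cl <- match.call()
  if (is.character(target)) target <- read_structure(target)
  if (is.null(rama)) rama <- make_toy_tables(seed = 1L)$rama
  rr <- refine(target, r = r, eps = eps, m = m, rama = rama,
               rotamers = rotamers, weights = weights, n_iter = n_iter,
               shrink = shrink, ...)
  ev <- evaluate_idealization(rr$target, rr$structure)
  structure(list(call = cl, target = rr$target, structure = rr$structure,
                 backbone_result = rr$backbone_result,
                 iterations = rr$iterations,
                 sidechain_scores = rr$sidechain_scores,
                 score = rr$backbone_result$score,
                 breakdown = rr$backbone_result$breakdown,
                 evaluation = ev, rama = rama),
            class = "idealization")
}

#' Compare a structure with its idealization
#'
#' Computes the report quantities: C-alpha RMSD, all-atom RMSD (over atoms
#' present in both), bottleneck distance of CA atoms, mean/max wrapped
#' phi/psi differences, and Kabsch-Sander hydrogen-bond counts before and
#' after.
#'
#' @param target,idealized \code{protein} structures over the same
#'   residues.
#' @param ideal An \code{ideal_geometry} table (used to complete missing
#'   O/H for hydrogen-bond counting).
#' @return A one-row data frame.
#' @export
evaluate_idealization <- function(target, idealized,
                                  ideal = read_ideal_geometry()) {
  target <- prepare_target(target, ideal)
  idealized <- prepare_target(idealized, ideal)
  ca_rmsd <- rmsd_no_fit(target, idealized, "CA")
  ## all-atom RMSD over atoms present in both (by residue/name)
  ka <- paste(target$atoms$residue_index, target$atoms$name)
  kb <- paste(idealized$atoms$residue_index, idealized$atoms$name)
  common <- intersect(ka, kb)
  pa <- as.matrix(target$atoms[match(common, ka), c("x", "y", "z")])
  pb <- as.matrix(idealized$atoms[match(common, kb), c("x", "y", "z")])
  aa_rmsd <- sqrt(mean(.rownorm(pa - pb)^2))
  tt <- extract_torsions(target); ti <- extract_torsions(idealized)
  dphi <- abs(wrap_angle(ti$phi - tt$phi)); dpsi <- abs(wrap_angle(ti$psi - tt$psi))
  dpp <- c(dphi[!is.na(dphi)], dpsi[!is.na(dpsi)])
  data.frame(
    n_residues = n_residues(target),
    ca_rmsd = ca_rmsd,
    allatom_rmsd = aa_rmsd,
    ca_bottleneck = bottleneck_distance(atom_coords(target, "CA"),
                                        atom_coords(idealized, "CA")),
    mean_dphipsi = if (length(dpp)) mean(dpp) else NA_real_,
    max_dphipsi = if (length(dpp)) max(dpp) else NA_real_,
    hbonds_target = nrow(detect_hbonds(target)),
    hbonds_idealized = nrow(detect_hbonds(idealized)))
}

#' @export
print.idealization <- function(x, ...) {
  cat("Protein structure idealization\n")
  cat(sprintf("  %d residues | S_BB = %.4f after %d iteration(s)\n",
              n_residues(x$structure), x$score, nrow(x$iterations)))
  cat(sprintf("  C-alpha RMSD to target: %.3f A | all-atom RMSD: %.3f A\n",
              x$evaluation$ca_rmsd, x$evaluation$allatom_rmsd))
  invisible(x)
}

#' @export
summary.idealization <- function(object, ...) {
  structure(list(obj = object), class = "summary.idealization")
}

#' @export
print.summary.idealization <- function(x, ...) {
  o <- x$obj
  print(o)
  cat("\nScore breakdown:\n")
  print(o$breakdown)
  cat("\nIterations:\n")
  print(o$iterations, row.names = FALSE)
  cat("\nEvaluation:\n")
  print(o$evaluation, row.names = FALSE)
  if (!is.null(o$sidechain_scores)) {
    scored <- o$sidechain_scores[n_chi(o$sidechain_scores$residue_type) > 0, ]
    if (nrow(scored) > 0L) {
      cat("\nSide-chain scores (chi-bearing residues):\n")
      print(scored, row.names = FALSE, digits = 4)
    }
  }
  invisible(x)
}

#' @export
coef.idealization <- function(object, ...) {
  extract_torsions(object$structure, chi = TRUE)
}

#' @export
fitted.idealization <- function(object, ...) object$structure

#' @export
residuals.idealization <- function(object, ...) {
  t <- object$target$atoms; i <- object$structure$atoms
  ka <- paste(t$residue_index, t$name)
  kb <- paste(i$residue_index, i$name)
  common <- intersect(ka, kb)
  pa <- as.matrix(t[match(common, ka), c("x", "y", "z")])
  pb <- as.matrix(i[match(common, kb), c("x", "y", "z")])
  data.frame(residue_index = t$residue_index[match(common, ka)],
             name = t$name[match(common, ka)],
             deviation = .rownorm(pb - pa))
}

#' @export
plot.idealization <- function(x, ...) {
  tt <- extract_torsions(x$target)
  ti <- extract_torsions(x$structure)
  ok <- !is.na(tt$phi) & !is.na(tt$psi)
  graphics::par(mfrow = c(1, 2))
  for (set in list(list(d = tt, main = "Target"),
                   list(d = ti, main = "Idealized"))) {
    graphics::plot(set$d$phi[ok], set$d$psi[ok], xlim = c(-180, 180),
                   ylim = c(-180, 180), pch = 19, cex = 0.7,
                   xlab = expression(Phi), ylab = expression(Psi),
                   main = set$main, ...)
    graphics::abline(h = 0, v = 0, col = "grey80")
  }
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
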