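## Probability tables behind the two free-energy scores: per-amino-acid
## Ramachandran grids (360 x 360, 1-degree bins over (-180, 180]^2) and
## chi-torsion rotamer statistics.
##
## A rama_table stores integer bin COUNTS plus the pseudocount; bin
## probabilities are always recomputed as (count + pc) / (n_aa + pc*360^2),
## which makes text serialization exact.

RAMA_NBIN <- 360L
RAMA_NULL <- 1 / (360 * 360)

## bin k covers [k, k+1) degrees, k = -180..179; angles outside (-180,180]
## are wrapped; +180 maps to the -180 bin.
#' Ramachandran bin index of an angle
#'
#' Half-open 1-degree bins: bin \code{k} covers \code{[k, k+1)} degrees.
#'
#' @param x Angle(s) in degrees.
#' @return Integer bin index in 1..360 (bin 1 starts at -180 degrees).
#' @export
rama_bin <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)   # wrap to [-180, 180)
  # the modulo guards against floating-point wrap landing a hair outside
  # [-180, 180), which would otherwise produce a 0 or 361 index (and a 0
  # silently DROPS the element in R matrix indexing)
  ((as.integer(floor(w)) + 180L) %% 360L) + 1L
}

#' Build a Ramachandran probability table from structures
#'
#' Counts (phi, psi) pairs per amino-acid type over all interior residues
#' of the supplied structures, adds a pseudocount to every one of the
#' 360 x 360 bins, and normalizes per type.
#'
#' @param structures A \code{protein} or list of them.
#' @param pseudocount Added to every bin (default 1) so all probabilities
#'   are positive.
#' @return An object of class \code{rama_table}.
#' @export
build_rama_table <- function(structures, pseudocount = 1) {
  if (inherits(structures, "protein")) structures <- list(structures)
  if (length(structures) == 0L) stop("no structures supplied")
  tor <- do.call(rbind, lapply(structures, function(s) {
    t <- extract_torsions(s)
    t[!is.na(t$phi) & !is.na(t$psi), c("residue_type", "phi", "psi")]
  }))
  if (nrow(tor) == 0L) stop("no defined (phi, psi) pairs in input")
  rama_table_from_angles(tor$residue_type, tor$phi, tor$psi, pseudocount)
}

#' Build a Ramachandran table from raw (phi, psi) samples
#'
#' @param aa 3-letter residue types of the samples.
#' @param phi,psi Angles in degrees.
#' @param pseudocount Added to every bin.
#' @return An object of class \code{rama_table}.
#' @export
rama_table_from_angles <- function(aa, phi, psi, pseudocount = 1) {
  stopifnot(length(aa) == length(phi), length(phi) == length(psi),
            pseudocount > 0)
  aa <- toupper(aa)
  counts <- list()
  for (type in unique(aa)) {
    sel <- aa == type
    flat <- rama_bin(phi[sel]) + RAMA_NBIN * (rama_bin(psi[sel]) - 1L)
    counts[[type]] <- matrix(tabulate(flat, RAMA_NBIN^2), RAMA_NBIN, RAMA_NBIN)
  }
  structure(list(counts = counts, pseudocount = pseudocount,
                 n_obs = vapply(counts, sum, 0)),
            class = "rama_table")
}

#' @export
print.rama_table <- function(x, ...) {
  cat(sprintf("<rama_table> %d amino-acid grid(s), %d observation(s), pseudocount %g\n",
              length(x$counts), sum(x$n_obs), x$pseudocount))
  invisible(x)
}

#' Bin probability from a Ramachandran table
#'
#' @param table A \code{rama_table}.
#' @param aa 3-letter residue type (scalar).
#' @param phi,psi Angles in degrees (vectorized).
#' @return Probabilities of the containing bins; types never observed get
#'   the uniform pseudocount-only grid (1/129600 per bin).
#' @export
rama_prob <- function(table, aa, phi, psi) {
  aa <- toupper(aa)
  pc <- table$pseudocount
  cnt <- table$counts[[aa]]
  n <- if (is.null(cnt)) 0 else table$n_obs[[aa]]
  denom <- n + pc * RAMA_NBIN^2
  base <- pc / denom
  if (is.null(cnt)) return(rep(base, length(phi)))
  (cnt[cbind(rama_bin(phi), rama_bin(psi))] + pc) / denom
}

#' Ramachandran log-odds score
#'
#' Natural log of the bin probability over the uniform null (1/129600 per
#' bin).  A uniform table scores 0 everywhere; a table with all mass in one
#' bin scores ln(129600) ~ 11.77 inside that bin.
#'
#' @param table A \code{rama_table}.
#' @param aa 3-letter residue type (scalar).
#' @param phi,psi Angles in degrees (vectorized); must be defined.
#' @return Log-odds score(s).
#' @export
rama_log_odds <- function(table, aa, phi, psi) {
  if (anyNA(phi) || anyNA(psi)) stop("undefined phi/psi in rama_log_odds()")
  log(rama_prob(table, aa, phi, psi) / RAMA_NULL)
}

#' Write a Ramachandran table to a text file
#'
#' Stores the integer bin counts sparsely plus the pseudocount; reading the
#' file back reproduces every probability exactly.
#'
#' @param table A \code{rama_table}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_rama_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rama_table pseudocount=%.17g", table$pseudocount), con)
  writeLines("aa\tphi_bin\tpsi_bin\tcount", con)
  for (aa in names(table$counts)) {
    m <- table$counts[[aa]]
    nz <- which(m > 0L, arr.ind = TRUE)
    if (nrow(nz) == 0L) {
      writeLines(sprintf("%s\t0\t0\t0", aa), con)   # record the type
    } else {
      writeLines(sprintf("%s\t%d\t%d\t%d", aa, nz[, 1], nz[, 2],
                         m[nz]), con)
    }
  }
  invisible(path)
}

#' Read a Ramachandran table written by \code{write_rama_table}
#'
#' @param path Input file.
#' @return A \code{rama_table}.
#' @export
read_rama_table <- function(path) {
  lines <- readLines(path)
  pc <- as.numeric(sub("# rama_table pseudocount=", "", lines[1], fixed = TRUE))
  tab <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  counts <- list()
  for (aa in unique(tab$aa)) {
    m <- matrix(0L, RAMA_NBIN, RAMA_NBIN)
    rows <- tab[tab$aa == aa & tab$count > 0L, ]
    if (nrow(rows) > 0L) m[cbind(rows$phi_bin, rows$psi_bin)] <- as.integer(rows$count)
    counts[[aa]] <- m
  }
  structure(list(counts = counts, pseudocount = pc,
                 n_obs = vapply(counts, sum, 0)),
            class = "rama_table")
}

## ---------------------------------------------------------------------------
## Rotamer tables

#' Read a rotamer library
#'
#' Two formats are supported: the backbone-dependent Dunbrack-lab text
#' format (whitespace-separated columns restype, Phi, Psi, Count, r1..r4,
#' Probabil, chi1..chi4 means, chi1..chi4 sigmas) and the packaged coarse
#' backbone-independent fallback (tab-separated aa/prob/chi/sig columns),
#' auto-detected from the header.
#'
#' @param path Library file; default is the packaged fallback table.
#' @return An object of class \code{rotamer_table}: a data frame of
#'   rotamers (aa, phi_bin, psi_bin, prob, m1..m4, s1..s4, nchi) with a
#'   \code{bbdep} attribute.
#' @export
read_rotamer_library <- function(path = system.file("extdata", "rotamer_fallback.tsv",
                                                    package = "protideal")) {
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (grepl("\t", first[1]) && grepl("^aa\t", first[1])) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    rot <- data.frame(aa = toupper(tab$aa), phi_bin = NA_real_, psi_bin = NA_real_,
                      prob = tab$prob,
                      m1 = tab$m1, m2 = tab$m2, m3 = tab$m3, m4 = tab$m4,
                      s1 = tab$s1, s2 = tab$s2, s3 = tab$s3, s4 = tab$s4,
                      stringsAsFactors = FALSE)
    bbdep <- FALSE
  } else {
    raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 17L) stop("unrecognized rotamer library format in '", path, "'")
    rot <- data.frame(aa = toupper(raw[[1]]), phi_bin = raw[[2]], psi_bin = raw[[3]],
                      prob = raw[[9]],
                      m1 = raw[[10]], m2 = raw[[11]], m3 = raw[[12]], m4 = raw[[13]],
                      s1 = raw[[14]], s2 = raw[[15]], s3 = raw[[16]], s4 = raw[[17]],
                      stringsAsFactors = FALSE)
    bbdep <- TRUE
  }
  bad <- !rot$aa %in% AA3
  if (any(bad)) stop("unknown residue type(s) in rotamer library: ",
                     paste(unique(rot$aa[bad]), collapse = ", "))
  rot$nchi <- n_chi(rot$aa)
  for (k in 1:4) {
    s <- rot[[paste0("s", k)]]
    if (any(rot$nchi >= k & (is.na(s) | s <= 0))) {
      stop("rotamer library has non-positive sigma for a used chi")
    }
  }
  structure(rot, class = c("rotamer_table", "data.frame"), bbdep = bbdep)
}

#' Number of chi angles per residue type
#'
#' @param aa 3-letter residue type(s).
#' @return Integer count(s) (0 for GLY/ALA, up to 4 for LYS/ARG; ARG's
#'   terminal guanidinium torsions are fixed at 0/180 and not counted).
#' @export
n_chi <- function(aa) {
  tab <- c(ALA = 0L, GLY = 0L, SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
           ILE = 2L, LEU = 2L, ASP = 2L, ASN = 2L, HIS = 2L, PHE = 2L,
           TYR = 2L, TRP = 2L, PRO = 2L, MET = 3L, GLU = 3L, GLN = 3L,
           LYS = 4L, ARG = 4L)
  out <- tab[toupper(aa)]
  if (anyNA(out)) stop("unknown residue type(s): ",
                       paste(unique(aa[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Rotamers applicable to a residue
#'
#' For a backbone-dependent library, rotamers of the nearest (phi, psi)
#' grid point; otherwise all rotamers of the type.  Probabilities are
#' renormalized to sum to 1 within the conditioning bin.
#'
#' @param table A \code{rotamer_table}.
#' @param aa 3-letter residue type.
#' @param phi,psi Backbone dihedrals of the residue (degrees); ignored for
#'   backbone-independent tables and may be NA.
#' @return Data frame of rotamers (prob, m1..m4, s1..s4, nchi).
#' @export
get_rotamers <- function(table, aa, phi = NA, psi = NA) {
  aa <- toupper(aa)
  if (n_chi(aa) == 0L) return(table[0, , drop = FALSE])
  rows <- table[table$aa == aa, , drop = FALSE]
  if (nrow(rows) == 0L) stop("residue type ", aa, " absent from rotamer library")
  if (isTRUE(attr(table, "bbdep")) && !is.na(phi) && !is.na(psi)) {
    dp <- abs(wrap_angle(rows$phi_bin - phi))
    ds <- abs(wrap_angle(rows$psi_bin - psi))
    d <- dp + ds
    rows <- rows[d == min(d), , drop = FALSE]
  }
  rows$prob <- rows$prob / sum(rows$prob)
  rows
}

#' Side-chain chi log-odds score
#'
#' Matches the chi tuple to the nearest rotamer (smallest sum of squared
#' wrapped per-chi differences from the rotamer means) and scores
#' \code{ln(p_rot * prod_j N(chi_j; m_j, s_j) / (1/360)^k)}: the rotamer
#' probability times independent Gaussian densities on each chi, against a
#' per-chi uniform null over (-180, 180].
#'
#' @param table A \code{rotamer_table}.
#' @param aa 3-letter residue type.
#' @param phi,psi Backbone dihedrals (degrees) for backbone-dependent
#'   libraries.
#' @param chis Numeric vector of chi angles (degrees), or a matrix with one
#'   tuple per row for vectorized evaluation.
#' @return Score(s); 0 for residues with no chi angles.
#' @export
chi_log_odds <- function(table, aa, phi = NA, psi = NA, chis = numeric(0)) {
  k <- n_chi(aa)
  if (k == 0L) return(if (is.matrix(chis)) rep(0, nrow(chis)) else 0)
  ch <- if (is.matrix(chis)) chis else matrix(chis, nrow = 1)
  if (ncol(ch) < k) stop("need ", k, " chi angle(s) for ", aa)
  ch <- ch[, seq_len(k), drop = FALSE]
  rows <- get_rotamers(table, aa, phi, psi)
  means <- as.matrix(rows[, paste0("m", seq_len(k)), drop = FALSE])
  sigs <- as.matrix(rows[, paste0("s", seq_len(k)), drop = FALSE])
  ## for each tuple, the best-matching rotamer under wrapped distance
  best <- numeric(nrow(ch))
  for (r in seq_len(nrow(rows))) {
    d <- wrap_angle(ch - matrix(means[r, ], nrow(ch), k, byrow = TRUE))
    ss <- rowSums(d^2)
    sc <- log(rows$prob[r]) +
      rowSums(stats::dnorm(d, 0, matrix(sigs[r, ], nrow(ch), k, byrow = TRUE),
                           log = TRUE)) - k * log(1 / 360)
    if (r == 1L) { best_ss <- ss; best <- sc } else {
      swap <- ss < best_ss
      best_ss[swap] <- ss[swap]
      best[swap] <- sc[swap]
    }
  }
  if (is.matrix(chis)) best else best[1]
}
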