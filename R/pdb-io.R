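## PDB reading/writing and the `protein` container.
##
## A `protein` is a list with:
##   atoms        data frame: serial, name, element, residue_index (1..n,
##                clean internal numbering), residue_type (3-letter), x, y, z
##   chain_id     chain label the atoms came from
##   source_model model number the atoms came from
##   renumbering  data frame mapping internal residue_index to the original
##                (resno, insert) labels, when read from a file
##
## Parsing and ATOM-record emission are delegated to bio3d; model/chain
## selection, altLoc resolution, completeness filtering and the
## longest-gapless-fragment policy live here.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Convert a sequence to 3-letter codes
#'
#' @param sequence Either a character vector of 3-letter codes or a single
#'   string of 1-letter codes.
#' @return Character vector of 3-letter residue types.
#' @export
as_seq3 <- function(sequence) {
  if (length(sequence) == 1L && !toupper(sequence) %in% AA3) {
    s1 <- strsplit(toupper(sequence), "")[[1]]
    idx <- match(s1, AA1)
    if (anyNA(idx)) stop("unknown 1-letter residue code(s): ",
                         paste(unique(s1[is.na(idx)]), collapse = ", "))
    return(AA3[idx])
  }
  s3 <- toupper(sequence)
  if (!all(s3 %in% AA3)) stop("unknown 3-letter residue code(s): ",
                              paste(unique(s3[!s3 %in% AA3]), collapse = ", "))
  s3
}

.element_of <- function(name) {
  e <- substr(gsub("[0-9']", "", name), 1, 1)
  ifelse(e %in% c("C", "N", "O", "S", "H"), e, "C")
}

#' Construct a protein structure
#'
#' @param atoms Data frame with columns name, residue_index, residue_type,
#'   x, y, z (serial and element are filled in when missing).  Atoms are
#'   re-ordered by residue and backbone-first atom order, and serials are
#'   renumbered 1..N.
#' @param chain_id Chain label.
#' @param source_model Source model number.
#' @param renumbering Optional mapping to original residue labels.
#' @return An object of class \code{protein}.
#' @export
protein <- function(atoms, chain_id = "A", source_model = 1L, renumbering = NULL) {
  req <- c("name", "residue_index", "residue_type", "x", "y", "z")
  if (!all(req %in% names(atoms))) stop("atoms is missing columns: ",
                                        paste(setdiff(req, names(atoms)), collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (is.null(atoms$element)) atoms$element <- .element_of(atoms$name)
  ord_name <- match(atoms$name, c("N", "CA", "C", "O", "H", "CB"))
  ord_name[is.na(ord_name)] <- 7L
  atoms <- atoms[order(atoms$residue_index, ord_name, atoms$name), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  ca_per_res <- tapply(atoms$name == "CA", atoms$residue_index, sum)
  if (any(ca_per_res != 1L)) stop("each residue must have exactly one CA atom")
  structure(list(atoms = atoms, chain_id = chain_id,
                 source_model = as.integer(source_model),
                 renumbering = renumbering),
            class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  n <- length(unique(x$atoms$residue_index))
  cat(sprintf("<protein> %d residues, %d atoms (chain %s, model %d)\n",
              n, nrow(x$atoms), x$chain_id, x$source_model))
  invisible(x)
}

#' Number of residues
#' @param s A \code{protein}.
#' @return Integer residue count.
#' @export
n_residues <- function(s) length(unique(s$atoms$residue_index))

#' Residue types in chain order
#' @param s A \code{protein}.
#' @return Character vector of 3-letter codes.
#' @export
sequence3 <- function(s) {
  a <- s$atoms
  a$residue_type[match(sort(unique(a$residue_index)), a$residue_index)]
}

#' Backbone coordinates as per-atom matrices
#'
#' @param s A \code{protein}.
#' @return List with n x 3 matrices \code{N}, \code{CA}, \code{C} and the
#'   residue type vector \code{restype}; errors if any residue lacks one of
#'   N/CA/C.
#' @export
backbone_coords <- function(s) {
  a <- s$atoms
  res <- sort(unique(a$residue_index))
  out <- list(restype = character(length(res)))
  for (nm in c("N", "CA", "C")) {
    sel <- a[a$name == nm, ]
    idx <- match(res, sel$residue_index)
    if (anyNA(idx)) stop("residue(s) missing backbone atom ", nm, ": ",
                         paste(res[is.na(idx)], collapse = ", "))
    out[[nm]] <- as.matrix(sel[idx, c("x", "y", "z")])
    dimnames(out[[nm]]) <- NULL
  }
  out$restype <- a$residue_type[match(res, a$residue_index)]
  out
}

#' Coordinates of selected atoms
#'
#' @param s A \code{protein}.
#' @param names Atom names to select (NULL = all atoms).
#' @param residues Residue indices to select (NULL = all).
#' @return m x 3 coordinate matrix, with a key data frame attached as
#'   attribute \code{"key"} (residue_index, name).
#' @export
atom_coords <- function(s, names = NULL, residues = NULL) {
  a <- s$atoms
  if (!is.null(names)) a <- a[a$name %in% names, , drop = FALSE]
  if (!is.null(residues)) a <- a[a$residue_index %in% residues, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  attr(m, "key") <- a[, c("residue_index", "name")]
  m
}

## Build a protein from a 3n x 3 backbone coordinate matrix (N,CA,C per
## residue) plus a sequence.
#' Assemble a protein from stacked backbone coordinates
#'
#' @param coords 3n x 3 matrix: rows are N1, CA1, C1, N2, ... in chain order.
#' @param seq3 Character vector of n 3-letter residue types.
#' @return A \code{protein} with backbone atoms only.
#' @export
protein_from_backbone <- function(coords, seq3) {
  n <- length(seq3)
  stopifnot(nrow(coords) == 3L * n)
  atoms <- data.frame(
    serial = seq_len(3L * n),
    name = rep(c("N", "CA", "C"), n),
    element = rep(c("N", "C", "C"), n),
    residue_index = rep(seq_len(n), each = 3L),
    residue_type = rep(seq3, each = 3L),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE)
  protein(atoms)
}

## ---------------------------------------------------------------------------

#' Read a protein structure from a PDB file
#'
#' Selects one model and one chain (by default the first of each), resolves
#' alternate locations to the highest-occupancy (then alphabetically first)
#' conformer, drops hydrogens and non-amino-acid records, reports residues
#' missing any of N/CA/C, and returns the longest gapless fragment,
#' renumbered 1..n (the original numbering is kept in
#' \code{$renumbering}).
#'
#' @param path PDB file.
#' @param model Model number to use (default: first).
#' @param chain Chain ID to use (default: first chain present).
#' @param min_fragment Minimum residue count for the returned fragment.
#' @return A \code{protein}.
#' @export
read_structure <- function(path, model = 1L, chain = NULL, min_fragment = 2L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in '", path, "'")
  ## model selection: bio3d stores models as rows of pdb$xyz
  if (model > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model) {
      stop("model ", model, " not present in '", path, "'")
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    a$x <- xyz[seq_len(nrow(pdb$atom)), 1][pdb$atom$type == "ATOM"]
    a$y <- xyz[seq_len(nrow(pdb$atom)), 2][pdb$atom$type == "ATOM"]
    a$z <- xyz[seq_len(nrow(pdb$atom)), 3][pdb$atom$type == "ATOM"]
  }
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain '", chain, "' not present in '", path, "'")
  a <- a[a$resid %in% AA3, , drop = FALSE]
  a <- a[.element_of(a$elety) != "H" & a$elety != "H", , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  ## altLoc: per (residue, atom name) keep highest occupancy, ties by
  ## alphabetic altLoc
  key <- paste(a$resno, a$insert, a$elety, sep = "\r")
  a <- a[order(key, -a$o, a$alt), , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$insert, a$elety, sep = "\r")), , drop = FALSE]
  ## original residue order
  rkey <- paste(a$resno, a$insert, sep = "\r")
  rlev <- unique(rkey[order(a$resno, a$insert)])
  ridx <- match(rkey, rlev)
  ## completeness: need N, CA, C
  has <- vapply(seq_along(rlev), function(i) {
    all(c("N", "CA", "C") %in% a$elety[ridx == i])
  }, logical(1))
  if (any(!has)) {
    message("dropping ", sum(!has),
            " residue(s) missing backbone atoms (N/CA/C): ",
            paste(gsub("\r", "", rlev[!has]), collapse = ", "))
  }
  keep_res <- which(has)
  if (length(keep_res) < 2L) stop("input too short: fewer than 2 complete residues")
  ## gapless fragments: consecutive complete residues whose peptide C-N
  ## distance is bond-like
  frag <- integer(length(keep_res)); frag[1] <- 1L
  for (j in seq_along(keep_res)[-1]) {
    i0 <- keep_res[j - 1]; i1 <- keep_res[j]
    c0 <- a[ridx == i0 & a$elety == "C", c("x", "y", "z")]
    n1 <- a[ridx == i1 & a$elety == "N", c("x", "y", "z")]
    d <- sqrt(sum((as.numeric(c0) - as.numeric(n1))^2))
    frag[j] <- if (d < 2.0) frag[j - 1] else frag[j - 1] + 1L
  }
  sizes <- table(frag)
  best <- as.integer(names(sizes)[which.max(sizes)])
  sel_res <- keep_res[frag == best]
  if (length(sel_res) < min_fragment) {
    stop("input too short: longest gapless fragment has ",
         length(sel_res), " residue(s)")
  }
  if (length(sel_res) < length(keep_res)) {
    message("chain break(s) detected; keeping longest gapless fragment of ",
            length(sel_res), " residues")
  }
  a <- a[ridx %in% sel_res, , drop = FALSE]
  new_idx <- match(match(paste(a$resno, a$insert, sep = "\r"), rlev), sel_res)
  renum <- data.frame(residue_index = seq_along(sel_res),
                      orig_resno = as.integer(sub("\r.*", "", rlev[sel_res])),
                      orig_insert = sub(".*\r", "", rlev[sel_res]),
                      stringsAsFactors = FALSE)
  atoms <- data.frame(serial = seq_len(nrow(a)),
                      name = a$elety,
                      element = ifelse(is.na(a$elesy) | a$elesy == "",
                                       .element_of(a$elety), a$elesy),
                      residue_index = new_idx,
                      residue_type = a$resid,
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  protein(atoms, chain_id = chain, source_model = model, renumbering = renum)
}

#' Write a protein structure to a PDB file
#'
#' Emits plain ATOM/TER records (occupancy 1.00, B 0.00) via bio3d, with
#' serials 1..N and the internal 1..n residue numbering.  Coordinates
#' round-trip through \code{\link{read_structure}} to 0.001 Angstrom (the
#' PDB fixed-point precision).
#'
#' @param s A \code{protein}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(s, path) {
  if (!inherits(s, "protein") || nrow(s$atoms) == 0L) {
    stop("write_structure() needs a non-empty protein structure")
  }
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = "ATOM",
                   eleno = a$serial,
                   elety = a$name,
                   resid = a$residue_type,
                   chain = rep(s$chain_id, nrow(a)),
                   resno = a$residue_index,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element,
                   end = TRUE)
  invisible(path)
}
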