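#' Read a (possibly multi-model) PDB structure
#'
#' Parses ATOM/HETATM records from a fixed-column PDB file.  Multi-model files
#' (MODEL/ENDMDL) are split into one structure per model.  Parsing is done with
#' [bio3d::read.pdb()] after a validation pass that reports malformed
#' coordinate fields with their line number.
#'
#' @param file Path to a PDB file.
#' @return A `structure3d` object (single model), or a list of `structure3d`
#'   objects of class `structure3d_ensemble` when the file holds several
#'   models.  A `structure3d` has an `atoms` data frame
#'   (`elety`, `resid`, `chain`, `resno`, `x`, `y`, `z`) and a `title`.
#' @export
read_structure <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0L) stop("empty structure: no ATOM/HETATM records in ", file)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed ATOM record (short line) at line ", i)
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      val <- suppressWarnings(as.numeric(substr(ln, cols[1], cols[2])))
      if (is.na(val)) stop("malformed coordinate field at line ", i, ": ", ln)
    }
  }
  multi <- sum(rec == "MODEL ") > 1L
  pdb <- bio3d::read.pdb(file, multi = multi, verbose = FALSE)
  title <- sub("^TITLE\\s+\\d*\\s*", "", lines[rec == "TITLE "][1])
  if (is.na(title)) title <- ""
  n_models <- if (multi) nrow(pdb$xyz) else 1L
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- if (multi) matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE) else
      matrix(pdb$xyz, ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      elety = pdb$atom$elety, resid = pdb$atom$resid, chain = pdb$atom$chain,
      resno = pdb$atom$resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      segid = if (!is.null(pdb$atom$segid)) pdb$atom$segid else "",
      stringsAsFactors = FALSE)
    if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
      stop("non-finite coordinates in ", file)
    structure(list(atoms = atoms, title = title), class = "structure3d")
  })
  if (n_models == 1L) models[[1]] else structure(models, class = "structure3d_ensemble")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Emits one CA pseudo-atom per bead, one MODEL/ENDMDL block per frame, in
#' fixed-column PDB layout.  The bead's domain label is written to the
#' segment identifier field, so domain assignments survive a round-trip.
#'
#' @param frames List of n-by-3 coordinate matrices (or one matrix).
#' @param chain A `cg_chain` giving residue identities and domain labels.
#' @param file Output path.
#' @export
write_ensemble <- function(frames, chain, file) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(inherits(chain, "cg_chain"))
  n <- nrow(chain$beads)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("frame length mismatch: expected ", n, " beads")
  aa3 <- names(.aa1_to_3)
  res3 <- .aa1_to_3[chain$beads$res]
  res3[is.na(res3)] <- "UNK"
  dom <- as.character(chain$beads$domain)
  dom[is.na(dom) | dom == ""] <- "X"
  ch_char <- if (is.null(chain$chain_id) || is.na(chain$chain_id)) "A"
             else substr(chain$chain_id, 1, 1)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   generated by cgsaxs (%d frames, %d beads)",
                     length(frames), n), con)
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
      seq_len(n), res3, ch_char, chain$beads$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, substr(dom, 1, 4))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(NULL)
}

#' Construct and validate a SAXS profile
#'
#' @param q Momentum transfer grid, 1/Angstrom, strictly increasing, q > 0.
#' @param I Intensities (arbitrary units), same length as `q`.
#' @param sigma Optional point-wise uncertainties, > 0.
#' @param label Free-text provenance label.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = NULL, label = "") {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I must have equal length")
  if (any(!is.finite(q)) || any(!is.finite(I))) stop("non-finite values in profile")
  if (any(q <= 0)) stop("q must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be positive")
  }
  structure(list(q = q, I = I, sigma = sigma, label = as.character(label)[1]),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("saxs_profile '%s': %d points, q in [%g, %g] 1/A, sigma %s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "absent" else "present"))
  invisible(x)
}

#' Read a 3-column SAXS profile (q, I, optional sigma)
#'
#' Whitespace-delimited text; lines starting with `#` are ignored.
#'
#' @param file Path to the `.dat` file.
#' @param q_unit `"A"` (1/Angstrom, default) or `"nm"` (1/nm, converted).
#' @param label Label stored on the profile (defaults to the file name).
#' @return A [saxs_profile].
#' @export
read_saxs <- function(file, q_unit = c("A", "nm"), label = basename(file)) {
  q_unit <- match.arg(q_unit)
  tab <- read.table(file, comment.char = "#", header = FALSE,
                    colClasses = "numeric")
  if (ncol(tab) < 2) stop("expected at least 2 columns (q, I) in ", file)
  q <- tab[[1]]
  if (q_unit == "nm") q <- q / 10
  saxs_profile(q, tab[[2]], sigma = if (ncol(tab) >= 3) tab[[3]] else NULL,
               label = label)
}

#' Write a SAXS profile in the 3-column dialect read by [read_saxs()]
#'
#' @param profile A [saxs_profile].
#' @param file Output path.
#' @export
write_saxs <- function(profile, file) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# cgsaxs SAXS profile: %s", profile$label), con)
  writeLines(sprintf("# q[1/A] I%s", if (is.null(profile$sigma)) "" else " sigma"), con)
  if (is.null(profile$sigma)) {
    writeLines(sprintf("%.8g %.8g", profile$q, profile$I), con)
  } else {
    writeLines(sprintf("%.8g %.8g %.8g", profile$q, profile$I, profile$sigma), con)
  }
  invisible(NULL)
}

# 1-letter -> 3-letter residue codes
.aa1_to_3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa3_to_1 <- setNames(names(.aa1_to_3), .aa1_to_3)
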