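# Domain-conformation analytics: centre-of-mass positions, inter-domain
# angles and dihedral, edge-domain distance, Kabsch superposition, averaged
# COM models and 2D frequency maps.

#' Centre of mass of a domain
#'
#' Equal-mass mean of the member bead positions.  Flexible beads (linkers,
#' tails) are excluded by default, so a domain whose range includes flagged
#' residues is represented by its folded core only.
#'
#' @param chain A `cg_chain` with domains defined.
#' @param coords n-by-3 coordinates (default: the chain's own).
#' @param label Domain label.
#' @param include_flexible Include flexible beads in the COM.
#' @return Length-3 position, Angstrom.
#' @export
domain_com <- function(chain, coords = NULL, label,
                       include_flexible = FALSE) {
  b <- chain$beads
  if (is.null(coords)) coords <- chain_coords(chain)
  sel <- b$domain == label
  if (!include_flexible) sel <- sel & !b$flexible
  if (!any(sel, na.rm = TRUE)) stop("empty domain: ", label)
  sel[is.na(sel)] <- FALSE
  colMeans(coords[sel, , drop = FALSE])
}

#' Angle at p2 between p1 and p3
#' @param p1,p2,p3 Length-3 positions.
#' @return Degrees, in the closed range 0..180.
#' @export
com_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector in angle")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Signed dihedral angle of four points
#'
#' Right-handed (IUPAC-style) convention via the atan2 formulation; result in
#' (-180, 180].  `convention = "left"` flips the sign, for pipelines whose
#' reference geometry is reported with the opposite handedness.
#'
#' @param p1,p2,p3,p4 Length-3 positions.
#' @param convention `"right"` (default) or `"left"`.
#' @return Degrees in (-180, 180].
#' @export
com_dihedral <- function(p1, p2, p3, p4, convention = c("right", "left")) {
  convention <- match.arg(convention)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sum(b2^2) == 0 || sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate dihedral (collinear points)")
  phi <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  if (convention == "left") phi <- -phi
  if (phi <= -180) phi <- phi + 360
  phi
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile[selection, ]` onto
#' `reference[selection, ]`, with reflection correction so the rotation is
#' proper (det = +1).
#'
#' @param reference,mobile n-by-3 coordinate matrices.
#' @param selection Row indices used for the fit (default all, >= 3).
#' @return List with `rotation` (3x3), `translation` (length 3; the fitted
#'   map is `x %*% t(rotation) + translation`), `rmsd` over the selection,
#'   and `transform(x)` applying the map to arbitrary coordinates.
#' @export
kabsch_superpose <- function(reference, mobile, selection = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  if (length(selection) < 3) stop("need at least 3 points to superpose")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection lengths differ")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- cb - as.vector(R %*% ca)
  transform <- function(x) sweep(as.matrix(x) %*% t(R), 2, translation, `+`)
  rmsd <- sqrt(mean(rowSums((transform(A) - B)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = transform)
}

#' Per-frame domain-conformation table
#'
#' For each frame: theta1 = angle a-(b)-(b') measured at the b COM,
#' theta2 = angle b-(b')-a' at the b' COM, phi = dihedral over the four
#' domain COMs (a, b, b', a'), and D = distance between the a and a' COMs.
#'
#' @param chain A `cg_chain` with domains defined.
#' @param frames List of n-by-3 coordinate matrices, or a `cg_trajectory`.
#' @param domains Character vector of the four domain labels, in chain order.
#' @param convention Dihedral sign convention, see [com_dihedral()].
#' @return A `geometry_table` data frame (`theta1`, `theta2`, `phi`, `d`)
#'   with a `summary` attribute holding mean and SD (N-1) per column.
#' @export
geometry_table <- function(chain, frames,
                           domains = c("a", "b", "bp", "ap"),
                           convention = "right") {
  if (inherits(frames, "cg_trajectory")) frames <- frames$frames
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, length(domains) == 4)
  rows <- lapply(frames, function(fr) {
    coms <- lapply(domains, function(d) domain_com(chain, fr, d))
    c(theta1 = com_angle(coms[[1]], coms[[2]], coms[[3]]),
      theta2 = com_angle(coms[[2]], coms[[3]], coms[[4]]),
      phi = com_dihedral(coms[[1]], coms[[2]], coms[[3]], coms[[4]],
                         convention = convention),
      d = sqrt(sum((coms[[1]] - coms[[4]])^2)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  summ <- data.frame(
    parameter = names(out),
    mean = vapply(out, mean, 0),
    sd = vapply(out, function(x) if (length(x) > 1) sd(x) else 0, 0))
  attr(out, "summary") <- summ
  class(out) <- c("geometry_table", "data.frame")
  out
}

#' Superposition-averaged domain-COM model
#'
#' Every frame is superposed onto the reference frame over the beads of the
#' anchor domains (default b and b'), then each domain's COM is averaged over
#' frames.  The per-domain spread is the RMS deviation of the per-frame COMs
#' about their average.
#'
#' @param chain A `cg_chain` with domains defined.
#' @param frames List of coordinate matrices or a `cg_trajectory`.
#' @param reference_frame Reference coordinates (default: the chain's own
#'   native coordinates).
#' @param anchor Domain labels whose beads define the superposition.
#' @param domains Domains whose COMs are reported.
#' @return An `averaged_model`: list with `com` (domain -> averaged position),
#'   `spread` (domain -> RMS COM deviation), `anchor`, `reference_frame`.
#' @export
averaged_com_model <- function(chain, frames, reference_frame = NULL,
                               anchor = c("b", "bp"),
                               domains = c("a", "b", "bp", "ap")) {
  if (inherits(frames, "cg_trajectory")) frames <- frames$frames
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  if (is.null(reference_frame)) reference_frame <- chain_coords(chain)
  b <- chain$beads
  sel <- which(b$domain %in% anchor & !b$flexible)
  if (length(sel) < 3) stop("anchor selection has fewer than 3 beads")
  per_frame <- lapply(frames, function(fr) {
    fit <- kabsch_superpose(reference_frame, fr, sel)
    fitted <- fit$transform(fr)
    vapply(domains, function(d) domain_com(chain, fitted, d), numeric(3))
  })
  arr <- simplify2array(per_frame)          # 3 x n_domain x n_frames
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  com <- apply(arr, c(1, 2), mean)
  colnames(com) <- domains
  spread <- vapply(seq_along(domains), function(j) {
    dev <- matrix(arr[, j, ], nrow = 3) - com[, j]
    sqrt(mean(colSums(dev^2)))
  }, 0)
  names(spread) <- domains
  structure(list(com = com, spread = spread, anchor = anchor,
                 reference_frame = reference_frame, n_frames = length(frames)),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("averaged_model over", x$n_frames, "frames (anchor:",
      paste(x$anchor, collapse = "+"), ")\n")
  print(round(t(x$com), 2))
  invisible(x)
}

#' Distance between averaged domain positions of two models
#'
#' @param modelA,modelB `averaged_model`s built against the same reference.
#' @param domain Domain label.
#' @return Euclidean distance, Angstrom.
#' @export
com_shift <- function(modelA, modelB, domain) {
  stopifnot(inherits(modelA, "averaged_model"), inherits(modelB, "averaged_model"))
  if (!domain %in% colnames(modelA$com) || !domain %in% colnames(modelB$com))
    stop("domain not present in both models: ", domain)
  sqrt(sum((modelA$com[, domain] - modelB$com[, domain])^2))
}

#' Paired 2D frequency maps and their difference
#'
#' Histograms two geometry parameters over a common grid for two model sets;
#' each map is normalized to total frequency 1, and the difference is
#' `mapA - mapB` (positive where set A is enriched).
#'
#' @param tableA,tableB `geometry_table`s.
#' @param pair Two column names, e.g. `c("theta2", "d")`.
#' @param bins Bin widths for the two parameters (e.g. degrees / Angstrom).
#' @return List with `x`, `y` bin edges, matrices `mapA`, `mapB`,
#'   `difference`.
#' @export
frequency_maps <- function(tableA, tableB, pair, bins) {
  stopifnot(length(pair) == 2, length(bins) == 2,
            all(pair %in% names(tableA)), all(pair %in% names(tableB)),
            nrow(tableA) > 0, nrow(tableB) > 0)
  if (any(bins <= 0)) stop("zero-width bins")
  lo <- vapply(pair, function(p) min(tableA[[p]], tableB[[p]]), 0)
  hi <- vapply(pair, function(p) max(tableA[[p]], tableB[[p]]), 0)
  xe <- seq(floor(lo[1] / bins[1]) * bins[1],
            ceiling(hi[1] / bins[1]) * bins[1] + bins[1] / 2, by = bins[1])
  ye <- seq(floor(lo[2] / bins[2]) * bins[2],
            ceiling(hi[2] / bins[2]) * bins[2] + bins[2] / 2, by = bins[2])
  hist2 <- function(tab) {
    ix <- findInterval(tab[[pair[1]]], xe, rightmost.closed = TRUE)
    iy <- findInterval(tab[[pair[2]]], ye, rightmost.closed = TRUE)
    m <- matrix(0, length(xe) - 1, length(ye) - 1)
    for (k in seq_along(ix)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
    m / sum(m)
  }
  mA <- hist2(tableA); mB <- hist2(tableB)
  list(x = xe, y = ye, mapA = mA, mapB = mB, difference = mA - mB)
}
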