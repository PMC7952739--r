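# Build the one-bead-per-residue coarse-grained model from a crystal
# structure: bead extraction, domain assignment, structure-based topology and
# charge assignment.

#' Build a C-alpha coarse-grained chain from a structure
#'
#' One bead per residue, placed at the CA position.  Charges are zero and
#' domains unassigned until [define_domains()] / [assign_charges()] run.
#' Alternate locations other than '' / 'A' are dropped.
#'
#' @param structure A `structure3d` from [read_structure()].
#' @param chain_id Chain to extract; `NULL` takes the first chain present.
#' @return A `cg_chain`: list with a `beads` data frame
#'   (`resno`, `res`, `x`, `y`, `z`, `charge`, `domain`, `flexible`, `unit`).
#' @export
build_cg_chain <- function(structure, chain_id = NULL) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[is.na(at$chain) | at$chain == chain_id | at$chain == "", , drop = FALSE]
  ca <- at[trimws(at$elety) == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms found for chain ", chain_id)
  if (anyDuplicated(ca$resno)) {
    dup <- unique(ca$resno[duplicated(ca$resno)])
    stop("duplicate residue numbers (altloc?): ", paste(dup, collapse = ", "))
  }
  res_all <- unique(at$resno)
  missing_ca <- setdiff(res_all, ca$resno)
  if (length(missing_ca))
    stop("residues without CA atoms: ", paste(missing_ca, collapse = ", "))
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  res1 <- .aa3_to_1[ca$resid]
  res1[is.na(res1)] <- "X"
  beads <- data.frame(
    resno = ca$resno, res = unname(res1),
    x = ca$x, y = ca$y, z = ca$z,
    charge = 0, domain = NA_character_, flexible = FALSE,
    unit = NA_integer_, stringsAsFactors = FALSE)
  structure(list(beads = beads, chain_id = chain_id), class = "cg_chain")
}

#' @export
print.cg_chain <- function(x, ...) {
  b <- x$beads
  cat(sprintf("cg_chain: %d beads (resno %d..%d), net charge %+g\n",
              nrow(b), min(b$resno), max(b$resno), sum(b$charge)))
  if (!all(is.na(b$domain))) {
    tab <- table(b$domain, useNA = "ifany")
    cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Domain definition for a multi-domain chain
#'
#' @param ranges Named list: domain label -> inclusive residue range
#'   `c(lo, hi)` (or a matrix of ranges, one row each).
#' @param flexible Residue numbers flagged flexible (inter-domain linkers,
#'   tails); these beads get no structure-based terms beyond backbone bonds.
#' @param units Optional named list mapping a "folded unit" id to the domain
#'   labels it groups (domains sharing a unit keep native contacts across
#'   their interface).  Default: one unit per domain.
#' @export
domain_definition <- function(ranges, flexible = integer(0), units = NULL) {
  stopifnot(is.list(ranges), !is.null(names(ranges)))
  ranges <- lapply(ranges, function(r) {
    r <- if (is.matrix(r)) r else matrix(r, ncol = 2, byrow = TRUE)
    if (any(r[, 1] > r[, 2])) stop("range lo > hi")
    r
  })
  # disjointness
  all_res <- unlist(lapply(ranges, function(r)
    unlist(apply(r, 1, function(rr) rr[1]:rr[2], simplify = FALSE))))
  if (anyDuplicated(all_res)) stop("domain ranges overlap")
  if (is.null(units)) units <- as.list(setNames(names(ranges), names(ranges)))
  structure(list(ranges = ranges, flexible = as.integer(flexible), units = units),
            class = "domain_definition")
}

#' Default ER-60 domain boundaries (mature-protein numbering)
#'
#' a = N-terminus..132, linker Gly133, b = 134..232, b' = 233..364,
#' linker Leu365, a' = 366..489, flexible C-tail 490..505.  b and b' share
#' one folded unit (their mutual arrangement is treated as fixed); the b/b'
#' split at 232/233 matters only for geometry and is configurable.
#'
#' @param bb_split Last residue of b; b' starts at `bb_split + 1`.
#' @export
er60_domains <- function(bb_split = 232L) {
  domain_definition(
    ranges = list(a = c(25, 132), linker1 = c(133, 133),
                  b = c(134, bb_split), bp = c(bb_split + 1L, 364),
                  linker2 = c(365, 365), ap = c(366, 489), ctail = c(490, 505)),
    flexible = c(133L, 365L, 490:505),
    units = list(a = "a", bb = c("b", "bp"), ap = "ap"))
}

#' Assign domain labels and flexibility flags to a chain
#'
#' @param chain A `cg_chain`.
#' @param boundaries A [domain_definition].
#' @return The chain with `domain`, `flexible` and `unit` columns filled.
#' @export
define_domains <- function(chain, boundaries) {
  stopifnot(inherits(chain, "cg_chain"), inherits(boundaries, "domain_definition"))
  b <- chain$beads
  b$domain <- NA_character_
  for (lab in names(boundaries$ranges)) {
    r <- boundaries$ranges[[lab]]
    for (k in seq_len(nrow(r))) {
      sel <- b$resno >= r[k, 1] & b$resno <= r[k, 2]
      b$domain[sel] <- lab
    }
  }
  covered <- unlist(lapply(boundaries$ranges, function(r)
    unlist(apply(r, 1, function(rr) rr[1]:rr[2], simplify = FALSE))))
  absent <- setdiff(range_ends(boundaries), b$resno)
  if (length(absent))
    stop("boundary residue(s) absent from chain: ", paste(absent, collapse = ", "))
  if (anyNA(b$domain)) {
    miss <- b$resno[is.na(b$domain)]
    stop("domain definition does not cover residues: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  b$flexible <- b$resno %in% boundaries$flexible
  unit_of_domain <- rep(NA_integer_, length(boundaries$ranges))
  names(unit_of_domain) <- names(boundaries$ranges)
  for (u in seq_along(boundaries$units))
    unit_of_domain[boundaries$units[[u]]] <- u
  b$unit <- unname(unit_of_domain[b$domain])
  b$unit[b$flexible] <- NA_integer_
  chain$beads <- b
  chain$definition <- boundaries
  chain
}

range_ends <- function(boundaries)
  unlist(lapply(boundaries$ranges, function(r) c(r[, 1], r[, 2])))

#' Build the structure-based (Go-type) topology from native coordinates
#'
#' Backbone bonds connect every neighbour pair at its native length.  Native
#' angles and dihedrals are added only where all member beads are
#' non-flexible; triples containing a flexible bead get a weak generic angle
#' (theta0 = 120 deg) that prevents chain collapse without referencing the
#' native structure.  Native contacts connect bead pairs in the same folded
#' unit with |i - j| >= 4 and native CA-CA distance <= `contact_cutoff`;
#' no contacts cross folded units and none involve a flexible bead.
#'
#' @param chain A `cg_chain` with domains defined.
#' @param contact_cutoff Native CA-CA distance cutoff in Angstrom (default 6.5).
#' @param params A [sim_params] supplying force constants.
#' @return A `cg_topology` with data frames `bonds`, `angles`, `dihedrals`,
#'   `contacts` and an excluded-volume exclusion key set.
#' @export
build_topology <- function(chain, contact_cutoff = 6.5, params = sim_params()) {
  stopifnot(inherits(chain, "cg_chain"))
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  b <- chain$beads
  if (all(is.na(b$domain))) stop("define_domains() must run before build_topology()")
  n <- nrow(b)
  xyz <- as.matrix(b[, c("x", "y", "z")])
  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  # bonds at native lengths for all neighbour pairs
  i <- seq_len(n - 1)
  bonds <- data.frame(i = i, j = i + 1,
                      r0 = sqrt(rowSums((xyz[i, , drop = FALSE] -
                                         xyz[i + 1, , drop = FALSE])^2)),
                      k = params$k_bond)

  # angles
  angles <- NULL
  if (n >= 3) {
    i <- seq_len(n - 2)
    flex3 <- b$flexible[i] | b$flexible[i + 1] | b$flexible[i + 2]
    th0 <- vapply(i, function(ii) .angle3(xyz[ii, ], xyz[ii + 1, ], xyz[ii + 2, ]), 0)
    angles <- data.frame(i = i, j = i + 1, k = i + 2,
                         theta0 = ifelse(flex3, 2 * pi / 3, th0),
                         k_theta = ifelse(flex3, params$k_angle_flex, params$k_angle),
                         type = ifelse(flex3, "generic", "native"))
  } else {
    angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                         theta0 = numeric(0), k_theta = numeric(0),
                         type = character(0))
  }

  # dihedrals only where all four members are non-flexible; quadruples whose
  # native internal angles are near-collinear are dropped (phi0 ill-defined)
  if (n >= 4) {
    i <- seq_len(n - 3)
    ok <- !(b$flexible[i] | b$flexible[i + 1] | b$flexible[i + 2] | b$flexible[i + 3])
    ang_ok <- th0 > 15 * pi / 180 & th0 < 165 * pi / 180
    ok <- ok & ang_ok[i] & ang_ok[i + 1]
    i <- i[ok]
  } else i <- integer(0)
  if (length(i)) {
    phi0 <- vapply(i, function(ii)
      .dihedral4(xyz[ii, ], xyz[ii + 1, ], xyz[ii + 2, ], xyz[ii + 3, ]), 0)
    dihedrals <- data.frame(i = i, j = i + 1, k = i + 2, l = i + 3,
                            phi0 = phi0, k_phi = params$k_dihedral)
  } else {
    dihedrals <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                            l = integer(0), phi0 = numeric(0), k_phi = numeric(0))
  }

  # native contacts: same folded unit, |i-j| >= 4, native distance <= cutoff
  eligible <- which(!b$flexible & !is.na(b$unit))
  contacts <- list()
  if (length(eligible) >= 2) {
    cut2 <- contact_cutoff^2
    for (ai in seq_along(eligible)) {
      ii <- eligible[ai]
      for (bi in seq_len(ai - 1L)) {
        jj <- eligible[bi]
        if (abs(ii - jj) < 4L) next
        if (b$unit[ii] != b$unit[jj]) next
        d2 <- sum((xyz[ii, ] - xyz[jj, ])^2)
        if (d2 <= cut2)
          contacts[[length(contacts) + 1L]] <- c(min(ii, jj), max(ii, jj), sqrt(d2))
      }
    }
  }
  contacts <- if (length(contacts)) {
    m <- do.call(rbind, contacts)
    data.frame(i = m[, 1], j = m[, 2], r0 = m[, 3], eps = params$eps_contact)
  } else data.frame(i = integer(0), j = integer(0), r0 = numeric(0), eps = numeric(0))
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL

  topo <- structure(list(
    n_beads = n, bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = contacts, contact_cutoff = contact_cutoff,
    hydro = matrix(numeric(0), ncol = 2)), class = "cg_topology")
  topo$excl_keys <- .exclusion_keys(topo, n)
  topo
}

# pairs excluded from the generic excluded-volume term: native-contact pairs
# (|i-j| <= 3 is excluded inside the compiled kernel already)
.exclusion_keys <- function(topo, n) {
  if (nrow(topo$contacts) == 0) return(numeric(0))
  i <- pmin(topo$contacts$i, topo$contacts$j) - 1
  j <- pmax(topo$contacts$i, topo$contacts$j) - 1
  sort(i * n + j)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(paste0("cg_topology: %d beads, %d bonds, %d angles",
                     " (%d native), %d dihedrals, %d native contacts\n"),
              x$n_beads, nrow(x$bonds), nrow(x$angles),
              sum(x$angles$type == "native"), nrow(x$dihedrals), nrow(x$contacts)))
  invisible(x)
}

#' Assign bead charges
#'
#' Flexible-loop beads always get their full titratable charge: +1 per Lys
#' (and Arg, if present in a loop), -1 per Asp/Glu.  Folded-region charges
#' depend on `mode`:
#' \describe{
#'   \item{`"loops-explicit+surface-proxy"`}{titratable beads (K/R +1, D/E -1)
#'     are charged only when solvent-exposed, using a burial proxy: a bead is
#'     buried when its CA has more than `burial_neighbors` neighbour CAs
#'     within `burial_radius` Angstrom.}
#'   \item{`"all-titratable"`}{every K/R gets +1 and every D/E -1.}
#' }
#' Histidine is left neutral (pH 7.4).
#'
#' @param chain A `cg_chain` with domains defined.
#' @param mode Charge mode, see above.
#' @param burial_neighbors,burial_radius Burial proxy parameters.
#' @return The chain with the `charge` column filled.
#' @export
assign_charges <- function(chain,
                           mode = c("loops-explicit+surface-proxy", "all-titratable"),
                           burial_neighbors = 14L, burial_radius = 10) {
  mode <- match.arg(mode)
  b <- chain$beads
  if (all(is.na(b$domain))) stop("define_domains() must run before assign_charges()")
  titr <- ifelse(b$res %in% c("K", "R"), 1,
                 ifelse(b$res %in% c("D", "E"), -1, 0))
  if (mode == "all-titratable") {
    b$charge <- titr
  } else {
    xyz <- as.matrix(b[, c("x", "y", "z")])
    d2 <- as.matrix(stats::dist(xyz))^2
    n_nb <- rowSums(d2 <= burial_radius^2) - 1L
    exposed <- n_nb <= burial_neighbors
    b$charge <- ifelse(b$flexible, titr, ifelse(exposed, titr, 0))
  }
  chain$beads <- b
  chain$charge_mode <- mode
  chain
}

#' Extract a bead coordinate matrix from a chain
#' @param chain A `cg_chain`.
#' @return n-by-3 numeric matrix.
#' @export
chain_coords <- function(chain) {
  stopifnot(inherits(chain, "cg_chain"))
  as.matrix(chain$beads[, c("x", "y", "z")])
}

# plain-R angle/dihedral helpers used when building native reference values
.angle3 <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
}

.dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2))
}
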