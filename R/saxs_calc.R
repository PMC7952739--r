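# Scattering math: Debye profiles from bead models, Guinier analysis, P(r),
# chi-square model-vs-data comparison and aggregate-corrected monomer
# extraction for slightly polydisperse samples.

#' Per-bead form factors
#'
#' `"uniform"` gives every bead amplitude 1 (the default; self-consistent
#' when the screening target is itself a bead-model profile).
#' `"per-residue"` scales amplitudes by residue electron counts relative to
#' the mean residue, a crude contrast proxy.
#'
#' @param chain A `cg_chain` (only needed for `"per-residue"`).
#' @param mode `"uniform"` or `"per-residue"`.
#' @param n Number of beads when no chain is given.
#' @return Positive numeric vector of amplitudes.
#' @export
form_factors <- function(chain = NULL, mode = c("uniform", "per-residue"),
                         n = NULL) {
  mode <- match.arg(mode)
  if (is.null(chain)) {
    if (is.null(n)) stop("need a chain or n")
    if (mode == "per-residue") stop("per-residue mode needs a chain")
    return(rep(1, n))
  }
  if (mode == "uniform") return(rep(1, nrow(chain$beads)))
  # approximate residue electron counts
  el <- c(G = 30, A = 38, S = 46, P = 52, V = 54, T = 54, C = 54, L = 62,
          I = 62, N = 60, D = 59, Q = 68, K = 71, E = 67, M = 70, H = 72,
          F = 78, R = 85, Y = 86, W = 98)
  f <- el[chain$beads$res]
  f[is.na(f)] <- mean(el)
  unname(f / mean(f))
}

#' Debye-formula SAXS profile of a bead model
#'
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' so that `I(0) = (sum f)^2`.  No hydration layer or excluded-volume solvent
#' term is applied.
#'
#' @param coords n-by-3 bead coordinates, Angstrom.
#' @param f Per-bead amplitudes (default uniform 1).
#' @param q q grid, 1/Angstrom, ascending, `q >= 0` allowed.
#' @param label Label for the returned profile.
#' @return A [saxs_profile] (points at `q = 0` are kept internally but the
#'   returned profile starts at the first positive q; use `keep_q0 = FALSE`).
#' @export
debye_profile <- function(coords, f = NULL, q, label = "model") {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1, ncol(coords) == 3)
  if (is.null(f)) f <- rep(1, nrow(coords))
  if (length(f) != nrow(coords)) stop("form factor length mismatch")
  if (any(f <= 0)) stop("form factors must be positive")
  q <- as.numeric(q)
  if (any(q < 0) || any(diff(q) <= 0)) stop("q must be ascending and >= 0")
  storage.mode(coords) <- "double"
  I <- cpp_debye(coords, as.numeric(f), q)
  pos <- q > 0
  saxs_profile(q[pos], I[pos], label = label)
}

#' Radius of gyration from coordinates
#'
#' @param coords n-by-3 matrix.
#' @param weights Optional per-bead weights (default equal).
#' @return Weighted RMS distance from the centre of mass, Angstrom.
#' @export
coordinate_rg <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1, ncol(coords) == 3)
  w <- if (is.null(weights)) rep(1, nrow(coords)) else as.numeric(weights)
  stopifnot(length(w) == nrow(coords), all(w > 0))
  w <- w / sum(w)
  com <- colSums(coords * w)
  sqrt(sum(w * rowSums((coords - matrix(com, nrow(coords), 3, byrow = TRUE))^2)))
}

#' Guinier fit of the low-q region
#'
#' Linear least squares of `ln I` against `q^2`, using
#' `I(q) = I(0) exp(-Rg^2 q^2 / 3)`.  The window is iterated: starting from
#' the full profile (or `q_max_start`), the fit is repeated with points
#' restricted to `q * Rg <= q_rg_max` until the window converges.
#'
#' @param profile A [saxs_profile].
#' @param q_rg_max Window limit on `q * Rg` (standard practice ~1.3).
#' @param q_max_start Initial upper q bound for the first fit.
#' @return List with `rg`, `i0`, the fitted window (`q_min`, `q_max`,
#'   `n_points`), and the fit object residual standard error.
#' @export
guinier_fit <- function(profile, q_rg_max = 1.3, q_max_start = 0.1) {
  stopifnot(inherits(profile, "saxs_profile"))
  q <- profile$q; I <- profile$I
  sel <- q <= q_max_start
  if (sum(sel) < 3) sel <- seq_len(min(length(q), 10L))
  rg_prev <- -Inf
  for (it in 1:50) {
    if (sum(sel) < 3) stop("fewer than 3 points in the Guinier window")
    if (any(I[sel] <= 0)) stop("non-positive intensities in the Guinier window")
    fit <- lm(log(I[sel]) ~ I(q[sel]^2))
    slope <- coef(fit)[[2]]
    if (slope >= 0) stop("non-decreasing profile in the Guinier window")
    rg <- sqrt(-3 * slope)
    sel_new <- q * rg <= q_rg_max
    if (identical(sel_new, sel) || abs(rg - rg_prev) < 1e-10) {
      sel <- sel_new
      break
    }
    rg_prev <- rg
    sel <- sel_new
  }
  if (sum(sel) < 3) stop("fewer than 3 points in the converged Guinier window")
  fit <- lm(log(I[sel]) ~ I(q[sel]^2))
  rg <- sqrt(-3 * coef(fit)[[2]])
  list(rg = rg, i0 = exp(coef(fit)[[1]]),
       q_min = min(q[sel]), q_max = max(q[sel]), n_points = sum(sel),
       sigma_resid = suppressWarnings(summary(fit)$sigma))
}

#' Pair distance distribution function from coordinates
#'
#' Weighted histogram of all pairwise distances, normalized to unit area.
#' The study-level P(r) from measured data (indirect transform) is out of
#' scope; this is the model-side quantity.
#'
#' @param coords n-by-3 matrix (n >= 2).
#' @param f Per-bead amplitudes (default 1).
#' @param bin Bin width in Angstrom.
#' @return List with `r` (bin centres), `p` (density, integrates to 1) and
#'   `dmax` (maximum pair distance).
#' @export
distance_distribution <- function(coords, f = NULL, bin = 1) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2, ncol(coords) == 3, bin > 0)
  if (is.null(f)) f <- rep(1, nrow(coords))
  storage.mode(coords) <- "double"
  # upper bound on dmax from the bounding box diagonal
  span <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  n_bins <- max(1L, ceiling(span / bin) + 1L)
  h <- cpp_pair_hist(coords, as.numeric(f), bin, n_bins)
  counts <- h$counts
  area <- sum(counts) * bin
  list(r = (seq_len(n_bins) - 0.5) * bin, p = counts / area, dmax = h$dmax)
}

#' Chi-square between a model and a target profile
#'
#' The model is linearly interpolated onto the target grid, an optimal
#' multiplicative scale `c` is applied in closed form, and
#' \deqn{\chi^2 = \frac{1}{N-1}\sum_k \left(\frac{c I_m(q_k) - I_t(q_k)}
#'  {\sigma_k}\right)^2.}
#' No additive offset is fitted unless `offset = TRUE`.
#'
#' @param model,target [saxs_profile]s; the target must carry `sigma`
#'   (unless `unit_weights = TRUE`).
#' @param q_max Restrict the comparison to `q <= q_max` (default 0.25).
#' @param unit_weights Use sigma = 1 when the target has no uncertainties.
#' @param offset Also fit an additive constant.
#' @return List with `chi2` and fitted `scale` (and `offset` if fitted).
#' @export
chi_square <- function(model, target, q_max = 0.25, unit_weights = FALSE,
                       offset = FALSE) {
  stopifnot(inherits(model, "saxs_profile"), inherits(target, "saxs_profile"))
  sel <- target$q <= q_max &
    target$q >= max(min(model$q), min(target$q)) &
    target$q <= max(model$q)
  if (sum(sel) < 2) stop("fewer than 2 overlapping points below q_max")
  qt <- target$q[sel]; It <- target$I[sel]
  if (is.null(target$sigma)) {
    if (!unit_weights)
      stop("target profile has no sigma; set unit_weights = TRUE to use ",
           "unweighted residuals")
    sg <- rep(1, length(qt))
  } else sg <- target$sigma[sel]
  Im <- stats::approx(model$q, model$I, xout = qt)$y
  if (offset) {
    w <- 1 / sg^2
    X <- cbind(Im, 1)
    fit <- stats::lm.wfit(X, It, w)
    cc <- fit$coefficients[1]; b <- fit$coefficients[2]
    chi2 <- sum(((cc * Im + b - It) / sg)^2) / (length(qt) - 1)
    return(list(chi2 = chi2, scale = unname(cc), offset = unname(b)))
  }
  cc <- sum(Im * It / sg^2) / sum(Im^2 / sg^2)
  chi2 <- sum(((cc * Im - It) / sg)^2) / (length(qt) - 1)
  list(chi2 = chi2, scale = cc)
}

#' Mixture composition (monomer plus oligomeric aggregates)
#'
#' @param order Oligomer order k (1 = monomer), integer >= 1.
#' @param weight_fraction Weight fractions, summing to 1.
#' @param molar_mass Molar masses, Da (defaults proportional to order).
#' @return A `mixture_spec` data frame.
#' @export
mixture_spec <- function(order, weight_fraction, molar_mass = NULL) {
  stopifnot(length(order) == length(weight_fraction), all(order >= 1))
  if (abs(sum(weight_fraction) - 1) > 1e-6)
    stop("weight fractions must sum to 1")
  if (any(weight_fraction < 0 | weight_fraction > 1))
    stop("weight fractions must lie in [0, 1]")
  if (is.null(molar_mass)) molar_mass <- order * 1
  structure(data.frame(order = as.integer(order),
                       weight_fraction = weight_fraction,
                       molar_mass = molar_mass),
            class = c("mixture_spec", "data.frame"))
}

#' Scattering of a weight-fraction mixture
#'
#' Components contribute in proportion to their number concentration
#' `w_k / M_k`; with per-particle profiles `I_k` (so `I_k(0)` grows as
#' `M_k^2`) the mixture is
#' \deqn{I(q) = \sum_k \frac{w_k}{M_k / M_1} I_k(q),}
#' which reduces to the monomer profile when only the monomer is present and
#' gives `I(0)` proportional to the weight-average molar mass, as for
#' scattering from a w/v mixture.
#'
#' @param component_profiles List of [saxs_profile]s, one per mixture row,
#'   on a common q grid.
#' @param spec A [mixture_spec].
#' @return A [saxs_profile].
#' @export
mixture_profile <- function(component_profiles, spec) {
  stopifnot(inherits(spec, "mixture_spec"),
            length(component_profiles) == nrow(spec))
  q <- component_profiles[[1]]$q
  for (p in component_profiles)
    if (length(p$q) != length(q) || any(abs(p$q - q) > 1e-9))
      stop("component profiles must share one q grid")
  rel_mass <- spec$molar_mass / spec$molar_mass[1]
  I <- Reduce(`+`, Map(function(p, w, m) w / m * p$I,
                       component_profiles, spec$weight_fraction, rel_mass))
  saxs_profile(q, I, label = "mixture")
}

#' Extract the monomer profile from a slightly aggregated sample
#'
#' Simplified aggregate correction: each oligomer k > 1 is modelled at the
#' Guinier level with forward intensity proportional to its mass-weighted
#' number concentration (`w_k M_k / M_1` relative to the monomer, i.e.
#' `w_k k` for k-mers of identical beads) and
#' `Rg_k = Rg_1 k^(1/3)` (density-preserving compact growth).  The modelled
#' aggregate contribution is subtracted from the observed profile and the
#' remainder rescaled by `1 / w_1`.  The monomer Rg used by the model is
#' refined once from the corrected profile.
#'
#' @param observed A [saxs_profile] with low-q coverage.
#' @param spec A [mixture_spec] whose first row is the monomer
#'   (weight fraction > 0.5).
#' @param monomer_rg_guess Initial monomer Rg, Angstrom; `NULL` fits it from
#'   the observed profile.
#' @return A [saxs_profile] of the monomer (same q grid and, when present,
#'   rescaled sigma).
#' @export
extract_monomer_profile <- function(observed, spec, monomer_rg_guess = NULL) {
  stopifnot(inherits(observed, "saxs_profile"), inherits(spec, "mixture_spec"))
  if (spec$order[1] != 1) stop("first mixture component must be the monomer")
  w1 <- spec$weight_fraction[1]
  if (w1 <= 0.5) stop("monomer fraction must exceed 0.5")
  if (nrow(spec) == 1) {
    message("mixture has no aggregates; returning the observed profile")
    return(observed)
  }
  gob <- guinier_fit(observed)
  rel <- spec$molar_mass / spec$molar_mass[1]
  # forward intensities per component: observed I(0) = a * sum_k w_k rel_k
  denom <- sum(spec$weight_fraction * rel)
  a <- gob$i0 / denom
  rg1 <- if (is.null(monomer_rg_guess)) gob$rg else monomer_rg_guess
  correct <- function(rg1) {
    agg <- rep(0, length(observed$q))
    for (k in seq_len(nrow(spec))[-1]) {
      rg_k <- rg1 * rel[k]^(1 / 3)
      agg <- agg + a * spec$weight_fraction[k] * rel[k] *
        exp(-rg_k^2 * observed$q^2 / 3)
    }
    I1 <- (observed$I - agg) / w1
    I1
  }
  I1 <- correct(rg1)
  ok <- I1 > 0
  if (sum(ok) >= 3) {
    g1 <- tryCatch(guinier_fit(saxs_profile(observed$q[ok], I1[ok])),
                   error = function(e) NULL)
    if (!is.null(g1)) I1 <- correct(g1$rg)
  }
  if (any(I1 <= 0))
    stop("aggregate correction produced non-positive intensities; ",
         "check the mixture specification")
  saxs_profile(observed$q, I1,
               sigma = if (!is.null(observed$sigma)) observed$sigma / w1,
               label = paste0(observed$label, " (monomer-extracted)"))
}
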