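# Score every trajectory snapshot against a target SAXS profile and select
# the model set by chi-square and radius-of-gyration windows.

#' Screening criteria
#'
#' @param chi2_max Upper chi-square bound (strict).
#' @param rg_min,rg_max Radius-of-gyration window, Angstrom (strict bounds).
#' @export
screening_criteria <- function(chi2_max, rg_min, rg_max) {
  stopifnot(chi2_max > 0, rg_min < rg_max)
  structure(list(chi2_max = chi2_max, rg_min = rg_min, rg_max = rg_max),
            class = "screening_criteria")
}

#' Score trajectory frames against a target profile
#'
#' For every frame the coordinate radius of gyration and the scale-fitted
#' chi-square against `target` are computed (via [debye_profile()] and
#' [chi_square()]).  Deterministic given its inputs.
#'
#' @param trajectory A `cg_trajectory`.
#' @param chain The `cg_chain` the trajectory samples.
#' @param target Target [saxs_profile] with uncertainties.
#' @param q Model q grid (default: the target grid up to `q_max`).
#' @param f Per-bead form factors (default uniform).
#' @param q_max Upper q bound used in the chi-square comparison.
#' @param rg_from `"coordinates"` (default, deterministic) or `"guinier"`
#'   (Guinier fit of the frame's computed profile).
#' @return A `screen_table` data frame: one row per frame with
#'   `run_id`, `step`, `rg`, `chi2`, `scale`.
#' @export
score_frames <- function(trajectory, chain, target, q = NULL, f = NULL,
                         q_max = 0.25, rg_from = c("coordinates", "guinier")) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  rg_from <- match.arg(rg_from)
  if (length(trajectory$frames) == 0) stop("empty trajectory")
  if (is.null(q)) q <- target$q[target$q <= q_max]
  if (is.null(f)) f <- rep(1, nrow(trajectory$frames[[1]]))
  rows <- lapply(seq_along(trajectory$frames), function(k) {
    fr <- trajectory$frames[[k]]
    prof <- tryCatch(debye_profile(fr, f, q),
                     error = function(e)
                       stop("frame ", k, ": ", conditionMessage(e)))
    cs <- tryCatch(chi_square(prof, target, q_max = q_max),
                   error = function(e)
                     stop("frame ", k, ": ", conditionMessage(e)))
    rg <- if (rg_from == "coordinates") coordinate_rg(fr, weights = f)
          else guinier_fit(prof)$rg
    data.frame(frame = k, run_id = trajectory$run_id[k],
               step = trajectory$steps[k], rg = rg,
               chi2 = cs$chi2, scale = cs$scale)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Select models meeting the screening criteria
#'
#' Strict inequalities on all three bounds:
#' `chi2 < chi2_max` and `rg_min < rg < rg_max`.
#'
#' @param table A `screen_table` from [score_frames()].
#' @param criteria A [screening_criteria].
#' @return Integer frame indices (stable order).  An empty selection is a
#'   valid outcome and is reported with a message.
#' @export
select_models <- function(table, criteria) {
  stopifnot(inherits(criteria, "screening_criteria"),
            all(c("rg", "chi2", "frame") %in% names(table)))
  idx <- table$frame[table$chi2 < criteria$chi2_max &
                       table$rg > criteria$rg_min &
                       table$rg < criteria$rg_max]
  if (length(idx) == 0)
    message("selection is empty under (chi2 < ", criteria$chi2_max,
            ", ", criteria$rg_min, " < Rg < ", criteria$rg_max, ")")
  as.integer(idx)
}

#' Subset a trajectory by frame indices
#' @param trajectory A `cg_trajectory`.
#' @param idx Frame indices (as returned by [select_models()]).
#' @export
subset_trajectory <- function(trajectory, idx) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  trajectory$frames <- trajectory$frames[idx]
  trajectory$steps <- trajectory$steps[idx]
  trajectory$run_id <- trajectory$run_id[idx]
  trajectory$kinetic <- trajectory$kinetic[idx]
  trajectory
}
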