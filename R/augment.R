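#' Augmentation parameters
#'
#' Distribution settings for the five kinematic augmentation operators:
#' magnitude offsets are drawn from N(0 deg, 5 deg) once per trial; magnitude
#' and time warps place `n_knots` knots drawn from N(1, 0.2) uniformly over
#' the cycle (endpoints included) and interpolate them with a natural cubic
#' spline.
#'
#' @param offset_mu,offset_sigma offset distribution (degrees).
#' @param knot_mu,knot_sigma warp-knot distribution (unitless).
#' @param n_knots number of warp knots (>= 4 for cubic-spline feasibility).
#' @param per_column if `TRUE`, draw an independent offset per angle column
#'   instead of one shared offset per trial.
#' @return list of class `augmentation_params`.
#' @export
augmentation_params <- function(offset_mu = 0, offset_sigma = 5,
                                knot_mu = 1, knot_sigma = 0.2,
                                n_knots = 7, per_column = FALSE) {
  stopifnot(offset_sigma >= 0, knot_sigma >= 0)
  if (n_knots < 4) stop("augmentation_params: need at least 4 knots")
  structure(list(offset_mu = offset_mu, offset_sigma = offset_sigma,
                 knot_mu = knot_mu, knot_sigma = knot_sigma,
                 n_knots = as.integer(n_knots), per_column = per_column),
            class = "augmentation_params")
}

#' Smooth random distortion vector
#'
#' Natural cubic spline through `n_knots` random values placed uniformly over
#' the trial's time span (endpoints included), evaluated at the trial's
#' sample times.
#'
#' @param trial a [kinematic_trial()].
#' @param params an [augmentation_params()].
#' @param knots optional fixed knot values (overrides the random draw; used
#'   for identity checks).
#' @return numeric distortion vector of length `n_samples(trial)`.
#' @keywords internal
distortion_vector <- function(trial, params, knots = NULL) {
  n <- n_samples(trial)
  if (n < params$n_knots) {
    stop("distortion_vector: trial shorter than the knot count")
  }
  if (is.null(knots)) {
    knots <- stats::rnorm(params$n_knots, params$knot_mu, params$knot_sigma)
  }
  xk <- seq(trial$time[1], trial$time[n], length.out = params$n_knots)
  stats::splinefun(xk, knots, method = "natural")(trial$time)
}

#' Magnitude offset augmentation
#'
#' Adds a single random offset, drawn from N(`offset_mu`, `offset_sigma`),
#' to every sample of every joint-angle column of the trial. The pelvis root
#' pose is left unchanged.
#'
#' @param trial a [kinematic_trial()].
#' @param params an [augmentation_params()].
#' @param delta optional fixed offset(s) in degrees (overrides the draw).
#' @return The augmented [kinematic_trial()].
#' @export
magnitude_offset <- function(trial, params = augmentation_params(), delta = NULL) {
  if (is.null(delta)) {
    k <- if (params$per_column) ncol(trial$angles) else 1L
    delta <- stats::rnorm(k, params$offset_mu, params$offset_sigma)
  }
  angles <- sweep(trial$angles, 2, rep_len(delta, ncol(trial$angles)), "+")
  out <- trial
  out$angles <- angles
  out$meta <- utils::modifyList(trial$meta, list(method = "offset"))
  out
}

#' Magnitude warp augmentation
#'
#' Multiplies every joint-angle column element-wise by the same smooth random
#' distortion vector (natural cubic spline through N(1, 0.2) knots).
#'
#' @inheritParams magnitude_offset
#' @param knots optional fixed knot values.
#' @return The augmented [kinematic_trial()].
#' @export
magnitude_warp <- function(trial, params = augmentation_params(), knots = NULL) {
  d <- distortion_vector(trial, params, knots)
  out <- trial
  out$angles <- trial$angles * d
  out$meta <- utils::modifyList(trial$meta, list(method = "mag_warp"))
  out
}

#' Combined magnitude warp then offset
#'
#' Applies [magnitude_warp()] first and [magnitude_offset()] second, drawing
#' from the RNG stream in that order.
#'
#' @inheritParams magnitude_offset
#' @return The augmented [kinematic_trial()].
#' @export
offset_and_warp <- function(trial, params = augmentation_params()) {
  warped <- magnitude_warp(trial, params)      # knots drawn first,
  out <- magnitude_offset(warped, params)      # then the offset
  out$meta$method <- "offset+mag_warp"
  out
}

#' Time warp augmentation
#'
#' A natural cubic spline through `n_knots` random values (N(1, 0.2)) is
#' evaluated at the n sample positions, cumulatively summed and divided by n
#' to give a monotone time-distortion vector `tau` of cycle fractions. All
#' joint-angle columns (and the pelvis root pose) are re-interpolated at
#' `tau`, with sample i of the source placed at fraction i/n so that constant
#' unit knots reproduce the input exactly. The output keeps the original
#' n-sample grid.
#'
#' @inheritParams magnitude_warp
#' @return The augmented [kinematic_trial()].
#' @export
time_warp <- function(trial, params = augmentation_params(), knots = NULL) {
  n <- n_samples(trial)
  s <- distortion_vector(trial, params, knots)
  tau <- pmin(cumsum(s) / n, 1)
  grid <- seq_len(n) / n
  warp_col <- function(y) stats::splinefun(grid, y, method = "natural")(tau)
  out <- trial
  out$angles <- vapply(seq_len(ncol(trial$angles)),
                       function(i) warp_col(trial$angles[, i]), numeric(n))
  colnames(out$angles) <- angle_columns()
  out$pelvis_pos <- vapply(1:3, function(i) warp_col(trial$pelvis_pos[, i]), numeric(n))
  out$pelvis_quat <- quat_normalize(
    vapply(1:4, function(i) warp_col(trial$pelvis_quat[, i]), numeric(n)))
  out$meta <- utils::modifyList(trial$meta, list(method = "time_warp"))
  out
}

#' Combined time warp then magnitude warp
#'
#' Applies [time_warp()] first and [magnitude_warp()] second, drawing from
#' the RNG stream in that order.
#'
#' @inheritParams magnitude_warp
#' @return The augmented [kinematic_trial()].
#' @export
time_and_magnitude_warp <- function(trial, params = augmentation_params()) {
  warped <- time_warp(trial, params)           # time knots drawn first,
  out <- magnitude_warp(warped, params)        # then the magnitude knots
  out$meta$method <- "time+mag_warp"
  out
}

#' Names of the five augmentation methods
#' @export
augmentation_methods <- function() {
  c("offset", "mag_warp", "offset+mag_warp", "time_warp", "time+mag_warp")
}

#' Augment a set of trials with all five methods
#'
#' Produces exactly 5 augmented trials per input trial (one per method), each
#' tagged with its method name and source index; deterministic under `seed`.
#' No physiological-plausibility filter is applied.
#'
#' @param trials non-empty list of [kinematic_trial()]s.
#' @param params an [augmentation_params()].
#' @param seed integer seed.
#' @param methods subset of [augmentation_methods()] to apply.
#' @return list of augmented trials of length `length(trials) * length(methods)`,
#'   ordered source-major then method.
#' @export
augment_dataset <- function(trials, params = augmentation_params(), seed = 1,
                            methods = augmentation_methods()) {
  if (length(trials) == 0) stop("augment_dataset: empty input")
  methods <- match.arg(methods, augmentation_methods(), several.ok = TRUE)
  set.seed(seed)
  fns <- list("offset" = magnitude_offset,
              "mag_warp" = magnitude_warp,
              "offset+mag_warp" = offset_and_warp,
              "time_warp" = time_warp,
              "time+mag_warp" = time_and_magnitude_warp)
  out <- vector("list", length(trials) * length(methods))
  k <- 0L
  for (i in seq_along(trials)) {
    for (m in methods) {
      k <- k + 1L
      aug <- fns[[m]](trials[[i]], params)
      aug$meta$source <- i
      aug$meta$provenance <- "synthetic"
      out[[k]] <- aug
    }
  }
  out
}
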