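# Drag-coefficient utilities and the tag-position comparison applied to
# externally produced (or synthetic) CFD outputs.

#' Drag coefficient from drag force
#'
#' `Cd = D / (0.5 * rho * U^2 * A)`: the dimensionless resistance of a body
#' in a fluid flow, from drag force `D` (N), fluid density `rho` (kg m^-3),
#' flow velocity `U` (m s^-1) and frontal area `A` (m^2). The default
#' density is sea water, 1028 kg m^-3.
#'
#' @param D Drag force in newtons (>= 0); vectorised.
#' @param rho Fluid density in kg m^-3 (> 0).
#' @param U Flow velocity in m s^-1 (> 0).
#' @param A Frontal area in m^2 (> 0); no default is meaningful — it must be
#'   measured for the body under study.
#' @return Dimensionless drag coefficient.
#' @seealso [drag_force()] for the inverse.
#' @export
drag_coefficient <- function(D, rho = 1028, U, A) {
  if (any(rho <= 0) || any(U <= 0) || any(A <= 0)) {
    stop("rho, U and A must be positive")
  }
  if (any(D < 0)) stop("drag force must be >= 0")
  D / (0.5 * rho * U^2 * A)
}

#' Drag force from drag coefficient (inverse of [drag_coefficient()])
#'
#' @param Cd Dimensionless drag coefficient (>= 0).
#' @param rho Fluid density in kg m^-3 (> 0).
#' @param U Flow velocity in m s^-1 (> 0).
#' @param A Frontal area in m^2 (> 0).
#' @return Drag force in newtons.
#' @export
drag_force <- function(Cd, rho = 1028, U, A) {
  if (any(rho <= 0) || any(U <= 0) || any(A <= 0)) {
    stop("rho, U and A must be positive")
  }
  if (any(Cd < 0)) stop("Cd must be >= 0")
  Cd * 0.5 * rho * U^2 * A
}

#' Standard CFD velocity grid (m s^-1)
#'
#' The realistic sea-turtle swimming-speed range over which solver runs are
#' typically requested.
#' @export
drag_velocity_grid <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2)

#' Generate synthetic drag-coefficient observations
#'
#' A stand-in for solver output when comparing attachment positions without
#' CFD runs: per-position intercepts and velocity slopes plus Gaussian noise.
#' The defaults emulate a bare carapace with Cd around 0.02 and tag-carrying
#' carapaces in the 0.05-0.06 range, ordered none < scute3 < scute1.
#'
#' @param intercepts Named numeric: Cd at zero velocity per position.
#' @param slopes Named numeric: Cd change per m s^-1 per position.
#' @param velocities Velocity grid (m s^-1).
#' @param noise_sd SD of Gaussian noise on Cd.
#' @param seed Integer seed.
#' @return Data frame with columns `position`, `velocity_ms`, `cd`.
#' @export
synth_drag_data <- function(
    intercepts = c(none = 0.020, scute1 = 0.060, scute3 = 0.048),
    slopes = c(none = 0.006, scute1 = 0.003, scute3 = 0.004),
    velocities = drag_velocity_grid,
    noise_sd = 0.0015, seed = 1L) {
  stopifnot(identical(sort(names(intercepts)), sort(names(slopes))))
  out <- expand.grid(position = names(intercepts), velocity_ms = velocities,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    out$cd <- intercepts[out$position] + slopes[out$position] * out$velocity_ms +
      stats::rnorm(nrow(out), 0, noise_sd)
  })
  out$cd <- pmax(out$cd, 0)
  rownames(out) <- NULL
  out
}

#' Read drag observations from CSV
#'
#' Accepts either precomputed coefficients (`position,velocity_ms,cd`) or raw
#' solver forces (`position,velocity_ms,drag_force_N,rho,area_m2`), in which
#' case [drag_coefficient()] is applied.
#'
#' @param path CSV file path.
#' @return Data frame with columns `position`, `velocity_ms`, `cd`.
#' @export
read_drag_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "velocity_ms") %in% names(df))) {
    stop("drag CSV needs 'position' and 'velocity_ms' columns")
  }
  if (!"cd" %in% names(df)) {
    needed <- c("drag_force_N", "rho", "area_m2")
    if (!all(needed %in% names(df))) {
      stop("drag CSV needs either 'cd' or ", paste(needed, collapse = ", "))
    }
    df$cd <- drag_coefficient(df$drag_force_N, df$rho, df$velocity_ms, df$area_m2)
  }
  df[, c("position", "velocity_ms", "cd")]
}

#' Compare drag coefficient across attachment positions
#'
#' Fits `cd ~ position * velocity` by least squares and reports
#' Tukey-adjusted pairwise position contrasts of the estimated marginal
#' means, plus the per-position velocity slopes. An unbalanced design
#' (unequal velocity grids per position) is flagged with a warning, not an
#' error.
#'
#' @param observations Data frame with columns `position`, `velocity_ms`,
#'   `cd` (e.g. from [read_drag_csv()] or [synth_drag_data()]).
#' @return A `drag_report`: the `ols_fit`, the contrast table, per-position
#'   slopes, and the marginal means.
#' @export
compare_drag <- function(observations) {
  stopifnot(all(c("position", "velocity_ms", "cd") %in% names(observations)))
  obs <- observations
  obs$position <- factor(obs$position)
  if (nlevels(obs$position) < 2) stop("need >= 2 positions to compare")
  n_vel <- tapply(obs$velocity_ms, obs$position, function(v) length(unique(v)))
  if (any(n_vel < 2)) stop("need >= 2 velocities per position")
  counts <- table(obs$position)
  if (length(unique(counts)) > 1) {
    warning("unbalanced design: unequal observation counts per position")
  }
  fit <- fit_ols(cd ~ position * velocity_ms, obs)
  contrasts <- pairwise_contrasts(fit, "position")
  # Per-position velocity slope via the interaction coefficients.
  co <- fit$coefficients
  base_slope <- co[["velocity_ms"]]
  slopes <- vapply(levels(obs$position), function(lv) {
    term <- paste0("position", lv, ":velocity_ms")
    base_slope + if (term %in% names(co)) co[[term]] else 0
  }, numeric(1))
  structure(
    list(fit = fit, contrasts = contrasts, slopes = slopes,
         emmeans = attr(contrasts, "emmeans")),
    class = "drag_report")
}

#' @export
print.drag_report <- function(x, ...) {
  cat("<drag_report> marginal mean Cd per position:\n")
  print(round(x$emmeans, 4))
  cat("velocity slopes (Cd per m s^-1):\n")
  print(round(x$slopes, 4))
  cat("pairwise contrasts (Tukey-adjusted):\n")
  print(x$contrasts, digits = 3)
  invisible(x)
}
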