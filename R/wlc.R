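#' Closed-form worm-like-chain mean squared radius of gyration
#'
#' For a worm-like chain of contour length `lc` and persistence length `lp`:
#' \deqn{\langle R_g^2\rangle = \frac{l_c l_p}{3} - l_p^2 +
#'   \frac{2 l_p^3}{l_c} - \frac{2 l_p^4}{l_c^2}\left(1 - e^{-l_c/l_p}\right)}
#' A series expansion is used for `lc/lp < 0.01` where the closed form loses
#' precision to cancellation; the rod limit is `lc^2/12`, the coil limit
#' `lc*lp/3`.
#'
#' @param lc contour length in nm (> 0), vectorized
#' @param lp persistence length in nm (> 0)
#' @return mean squared radius of gyration in nm^2
#' @examples
#' wlc_rg2(4000, 1000)        # 710623 nm^2 (Rg about 843 nm)
#' wlc_rg2(1, 1000)           # rod limit, about 1/12
#' @export
wlc_rg2 <- function(lc, lp) {
  if (any(!is.finite(lc)) || any(!is.finite(lp)) || any(lc <= 0) ||
      any(lp <= 0))
    stop("lc and lp must be positive and finite", call. = FALSE)
  x <- lc / lp
  out <- numeric(length(x))
  small <- x < 1e-2
  if (any(small)) {
    xs <- x[small]
    out[small] <- (lc[small]^2 / 12) *
      (1 - xs / 5 + xs^2 / 30 - xs^3 / 210)
  }
  if (any(!small)) {
    xb <- x[!small]
    lpb <- if (length(lp) > 1) lp[!small] else lp
    out[!small] <- lpb^2 *
      (xb / 3 - 1 + 2 / xb - (2 / xb^2) * (1 - exp(-xb)))
  }
  out
}

#' Time-averaged squared radius of gyration of one free filament
#'
#' Simulates an isolated bead-bond filament (no annealing) and returns the
#' sampling average of the bead radius of gyration squared together with a
#' standard error. The estimate is averaged over `n_replicates` independent
#' chains, each initialized from the exact equilibrium chain measure,
#' equilibrated for `equil_sweeps` Monte Carlo sweeps and then sampled every
#' `sample_every` sweeps for `n_sweeps` sweeps; the standard error is
#' computed across replicate means, which is valid regardless of the
#' autocorrelation within one trajectory.
#'
#' For a single trajectory (`n_replicates = 1`) the time average only
#' decorrelates over roughly `50 * n_beads^2` sweeps (local moves relax the
#' slowest bending modes diffusively); shorter runs trigger a warning.
#'
#' @param n_ulfs filament length in ULFs (>= 2)
#' @param params an [if_params()]; set `max_bond_angle` there to choose the
#'   stiffness
#' @param n_replicates number of independent chains
#' @param equil_sweeps equilibration sweeps per replicate
#' @param n_sweeps sampling sweeps per replicate
#' @param sample_every sampling stride in sweeps
#' @param seed optional integer seed
#' @return list with `rg2_mean`, `rg2_se` (nm^2), `contour_length` (mean
#'   instantaneous contour length, nm), `n_beads`, `acceptance`
#' @export
simulate_single_filament_rg <- function(n_ulfs, params = if_params(),
                                        n_replicates = 200,
                                        equil_sweeps = 100, n_sweeps = 200,
                                        sample_every = 50, seed = NULL) {
  stopifnot(n_ulfs >= 2)
  n_beads <- as.integer(n_ulfs * params$beads_per_ulf)
  if (!is.null(seed)) set.seed(seed)
  if (n_replicates == 1 && n_sweeps < 50 * n_beads^2)
    warning("single-trajectory average over fewer than 50*n_beads^2 sweeps ",
            "is unlikely to decorrelate; increase n_sweeps or n_replicates")
  res <- cpp_rg2_replicates(n_beads, params_for_cpp(params),
                            as.integer(n_replicates), equil_sweeps, n_sweeps,
                            sample_every)
  m <- mean(res$rg2)
  se <- if (n_replicates > 1) sd(res$rg2) / sqrt(n_replicates) else NA_real_
  list(rg2_mean = m, rg2_se = se,
       contour_length = mean(res$contour_length),
       n_beads = n_beads, acceptance = res$acceptance)
}

#' Simulate a persistence-length calibration curve
#'
#' Runs [simulate_single_filament_rg()] over a grid of filament lengths at a
#' given maximal bond angle and collects `(lc, <Rg^2>, se)` points, the raw
#' material of the worm-like-chain calibration.
#'
#' @param alpha maximal bond angle in degrees
#' @param ulf_grid filament lengths in ULFs (log-spaced 2-64 by default)
#' @param params base [if_params()]; its `max_bond_angle` is replaced by
#'   `alpha`
#' @param n_replicates replicates per grid point
#' @param equil_sweeps,n_sweeps,sample_every per-replicate Monte Carlo
#'   schedule, see [simulate_single_filament_rg()]
#' @param seed optional integer seed
#' @return a data frame of class `calibration_curve` with columns `lc_nm`,
#'   `rg2_nm2`, `rg2_se`, `n_beads`, `n_samples`; the bond angle is kept in
#'   attribute `alpha`
#' @export
calibrate_lp <- function(alpha, ulf_grid = c(2, 4, 8, 16, 32, 64),
                         params = if_params(), n_replicates = 200,
                         equil_sweeps = 100, n_sweeps = 200,
                         sample_every = 50, seed = NULL) {
  params$max_bond_angle <- alpha
  params$reaction_angle <- alpha
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(ulf_grid, function(u) {
    r <- simulate_single_filament_rg(u, params, n_replicates, equil_sweeps,
                                     n_sweeps, sample_every, seed = NULL)
    data.frame(lc_nm = r$contour_length, rg2_nm2 = r$rg2_mean,
               rg2_se = r$rg2_se, n_beads = r$n_beads,
               n_samples = n_replicates * floor(n_sweeps / sample_every))
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Fit the persistence length to a calibration curve
#'
#' Least-squares fit of the closed-form worm-like-chain expression
#' [wlc_rg2()] over `lp`, weighted by the per-point standard errors (points
#' with zero or missing standard error give an unweighted fit).
#'
#' By default the continuum expression is fitted directly to the simulated
#' bead averages, the conventional way such calibration curves are
#' compared. With `discrete_correction = TRUE` each simulated
#' point is first converted to its continuum equivalent by dividing out the
#' finite-bead factor `(N+1)/(N-1)` (the mean squared distance of N discrete
#' beads from their centroid exceeds that of a continuous filament of the
#' same contour length by exactly this factor in the rod limit); the
#' corrected fit recovers the tangent-correlation persistence length, which
#' is noticeably smaller because the short stiff chains then stop inflating
#' the fit.
#'
#' @param curve a data frame with columns `lc_nm`, `rg2_nm2`, `rg2_se` (from
#'   [calibrate_lp()] or [make_calibration_points()])
#' @param discrete_correction apply the finite-bead `(N+1)/(N-1)` correction
#'   before fitting (requires column `n_beads`; default `FALSE`)
#' @param interval search interval for `lp` in nm
#' @return list of class `lp_fit` with `lp` (nm), `lp_se` (approximate
#'   1-sigma from the profile curvature), `sse`, `n_points`
#' @examples
#' curve <- make_calibration_points(lp = 500, noise = 0)
#' fit_lp(curve)$lp   # 500, recovered exactly
#' @export
fit_lp <- function(curve, discrete_correction = FALSE,
                   interval = c(1, 1e6)) {
  stopifnot(all(c("lc_nm", "rg2_nm2", "rg2_se") %in% names(curve)))
  if (nrow(curve) < 3)
    stop("need at least 3 calibration points", call. = FALSE)
  if (max(curve$lc_nm) / min(curve$lc_nm) < 10)
    stop("calibration points must span at least one decade in lc",
         call. = FALSE)
  y <- curve$rg2_nm2
  se <- curve$rg2_se
  if (discrete_correction && !is.null(curve$n_beads)) {
    corr <- (curve$n_beads + 1) / (curve$n_beads - 1)
    y <- y / corr
    se <- se / corr
  }
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(y))
  sse <- function(loglp) {
    lp <- exp(loglp)
    sum(w * (y - wlc_rg2(curve$lc_nm, lp))^2)
  }
  opt <- optimize(sse, log(interval), tol = 1e-12)
  lp <- exp(opt$minimum)
  if (min(abs(log(lp / interval))) < 1e-3)
    stop("lp fit did not converge inside the search interval [",
         interval[1], ", ", interval[2], "] nm; sse = ", opt$objective,
         call. = FALSE)
  # 1-sigma from the curvature of the weighted SSE profile: var = 2 / d2SSE
  h <- 1e-4 * lp
  d2 <- (sse(log(lp + h)) - 2 * sse(log(lp)) + sse(log(lp - h))) /
    (h / lp)^2  # second derivative wrt log lp
  lp_se <- if (is.finite(d2) && d2 > 0) lp * sqrt(2 / d2) else NA_real_
  structure(list(lp = lp, lp_se = lp_se, sse = opt$objective,
                 n_points = nrow(curve)),
            class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("WLC fit: lp = %.4g nm (se %.2g, %d points, sse %.3g)\n",
              x$lp, x$lp_se, x$n_points, x$sse))
  invisible(x)
}
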