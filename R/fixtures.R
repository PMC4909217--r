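#' Synthetic traced-length dataset from stochastic coalescence
#'
#' Generates a deterministic stand-in for filament tracing data: integer ULF
#' counts are produced by a constant-kernel stochastic coalescence process
#' (random pairwise merging, the mean-field caricature of end-to-end
#' annealing) started from `round(n * target_mean_ulf)` monomers and stopped
#' at `n` clusters, then converted to traced lengths. The distributional
#' family is a fast stand-in for testing the analysis code, not a claim
#' about experimental data.
#'
#' @param n number of filaments to generate
#' @param target_mean_ulf target mean length in ULF units (>= 1)
#' @param seed optional integer seed
#' @param time_s,source labels forwarded to [length_distribution()]
#' @param params an [if_params()]
#' @return a [length_distribution()] whose sample mean ULF count is within
#'   sampling error of the target
#' @examples
#' d <- make_traced_lengths(500, 7.9, seed = 1)
#' summarize_lengths(d)$mean_ulf
#' @export
make_traced_lengths <- function(n, target_mean_ulf, seed = NULL,
                                time_s = NA_real_,
                                source = "synthetic-coalescence",
                                params = if_params()) {
  stopifnot(n >= 1, target_mean_ulf >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- round(n * target_mean_ulf)
  if (m < n) stop("infeasible target: fewer ULFs than filaments",
                  call. = FALSE)
  sizes <- rep(1L, m)
  len <- m
  while (len > n) {
    i <- sample.int(len, 1L)
    j <- sample.int(len - 1L, 1L)
    if (j >= i) j <- j + 1L
    sizes[i] <- sizes[i] + sizes[j]
    sizes[j] <- sizes[len]
    len <- len - 1L
  }
  length_distribution(sizes[seq_len(n)], time_s = time_s, source = source,
                      unit = "ulf", params = params)
}

#' Synthetic worm-like-chain calibration points
#'
#' Evaluates [wlc_rg2()] on a grid of contour lengths and perturbs the
#' values with multiplicative Gaussian noise; `noise = 0` gives exact
#' continuum points on which [fit_lp()] recovers `lp` to machine precision.
#'
#' @param lp persistence length in nm (> 0)
#' @param lc_grid contour lengths in nm
#' @param noise relative noise level (standard deviation of the
#'   multiplicative perturbation)
#' @param seed optional integer seed
#' @return a data frame of class `calibration_curve` with columns `lc_nm`,
#'   `rg2_nm2`, `rg2_se`
#' @examples
#' fit_lp(make_calibration_points(1000, noise = 0))$lp  # 1000
#' @export
make_calibration_points <- function(lp, lc_grid = 11 * 4 *
                                      c(2, 4, 8, 16, 32, 64),
                                    noise = 0, seed = NULL) {
  stopifnot(lp > 0, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  rg2 <- wlc_rg2(lc_grid, lp)
  if (noise > 0) rg2 <- rg2 * (1 + noise * rnorm(length(lc_grid)))
  out <- data.frame(lc_nm = lc_grid, rg2_nm2 = rg2,
                    rg2_se = noise * wlc_rg2(lc_grid, lp))
  attr(out, "lp_true") <- lp
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Two ULFs positioned with a prescribed gap and junction geometry
#'
#' Builds a two-filament system whose facing terminal beads are exactly
#' `gap` nm apart. The first ULF lies along +x; the second continues along a
#' direction rotated by `junction_angle` degrees in the xy-plane, so the
#' junction angle on the approaching side equals `junction_angle` (the other
#' junction angle is 0). A unit fixture for exercising reactive-pair
#' detection and the annealing acceptance geometry.
#'
#' @param gap end-to-end gap in nm (> 0)
#' @param junction_angle junction angle in degrees
#' @param params an [if_params()]
#' @param box optional [periodic_box()]; defaults to a 500 nm cube
#' @return an `if_system` with two straight ULFs
#' @examples
#' sys <- make_reactive_pair(11, 0)
#' nrow(detect_reactive_pairs(sys))  # 1
#' @export
make_reactive_pair <- function(gap, junction_angle = 0,
                               params = if_params(), box = NULL) {
  stopifnot(gap > 0)
  if (is.null(box)) box <- periodic_box(edge = 500)
  d <- params$bead_diameter
  bpu <- params$beads_per_ulf
  need <- (bpu - 1) * d * 2 + gap + 4 * d
  if (need > box$edge_nm)
    stop("impossible geometry: box too small for the requested gap",
         call. = FALSE)
  origin <- rep(box$edge_nm / 2, 3)
  a <- outer((0:(bpu - 1)) * d, c(1, 0, 0))          # along +x, ends at tailA
  tail_a <- a[bpu, ]
  th <- junction_angle * pi / 180
  dir_b <- c(cos(th), sin(th), 0)
  b0 <- tail_a + gap * dir_b
  b <- t(b0 + t(outer((0:(bpu - 1)) * d, dir_b)))
  coords <- sweep(rbind(a, b), 2, origin, "+")
  structure(list(coords = coords,
                 filaments = list(seq_len(bpu), bpu + seq_len(bpu)),
                 box = box, params = params, n0 = 2L, sweep_count = 0),
            class = "if_system")
}
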