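#' Initialize a system of free ULFs in a periodic box
#'
#' Places `n0` unit-length filaments (each `beads_per_ulf` beads) at uniform
#' random positions with uniform random orientations. By default the ULFs
#' are straight with bond length `1.0 * bead_diameter`; with
#' `init_shape = "equilibrium"` each ULF's internal shape is instead drawn
#' from the exact equilibrium chain measure (bond lengths with density
#' proportional to r^2 on the allowed interval, bending angles from the
#' configured angle measure). A near-rigid 4-bead ULF relaxes within a few
#' sweeps either way; the equilibrium draw matters mainly for the
#' `uniform_theta` angle measure, whose Jacobian acceptance factor unfreezes
#' exactly-straight chains only slowly.
#'
#' Coordinates are stored unwrapped; periodic wrapping is applied only when
#' distances between filament ends are queried.
#'
#' @param n0 initial number of ULFs (>= 1)
#' @param box a [periodic_box()]
#' @param params an [if_params()] object
#' @param seed optional integer seed for reproducibility
#' @param init_shape `"straight"` (default) or `"equilibrium"`
#' @return an object of class `if_system`: a list with elements `coords`
#'   (N x 3 matrix, nm), `filaments` (list of ordered bead-index vectors),
#'   `box`, `params`, `n0`, `sweep_count`
#' @examples
#' sys <- init_system(10, periodic_box(edge = 500), if_params(), seed = 1)
#' mean_ulf_length(sys)  # 1
#' @export
init_system <- function(n0, box, params = if_params(), seed = NULL,
                        init_shape = c("straight", "equilibrium")) {
  init_shape <- match.arg(init_shape)
  stopifnot(inherits(box, "periodic_box"), inherits(params, "if_params"))
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 1L) stop("n0 must be >= 1", call. = FALSE)
  bpu <- params$beads_per_ulf
  nbead <- n0 * bpu
  if (nbead > .Machine$integer.max / 4L)
    stop("system too large to index", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  coords <- matrix(0, nbead, 3)
  fil <- vector("list", n0)
  for (k in seq_len(n0)) {
    if (init_shape == "equilibrium") {
      shape <- cpp_sample_chain(bpu, params)
    } else {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      shape <- outer(0:(bpu - 1L) * params$bead_diameter, u)
    }
    origin <- runif(3, 0, box$edge_nm)
    idx <- ((k - 1L) * bpu + 1L):(k * bpu)
    coords[idx, ] <- sweep(shape, 2, origin, "+")
    fil[[k]] <- idx
  }
  structure(list(coords = coords, filaments = fil, box = box,
                 params = params, n0 = n0, sweep_count = 0),
            class = "if_system")
}

#' @export
print.if_system <- function(x, ...) {
  cat(sprintf(
    "IF assembly system: %d ULFs in %d filaments (<l_n> = %.3g), %s sweeps\n",
    x$n0, length(x$filaments), mean_ulf_length(x),
    format(x$sweep_count, big.mark = ",")))
  print(x$box)
  invisible(x)
}

#' Bead coordinates of one filament
#'
#' @param sys an `if_system`
#' @param i filament index
#' @return numeric matrix of bead positions in chain order (nm, unwrapped)
#' @export
filament_coords <- function(sys, i) {
  stopifnot(inherits(sys, "if_system"))
  sys$coords[sys$filaments[[i]], , drop = FALSE]
}

#' Number of ULFs in each filament
#'
#' @param sys an `if_system`
#' @return integer vector, one entry per filament
#' @export
filament_ulfs <- function(sys) {
  stopifnot(inherits(sys, "if_system"))
  vapply(sys$filaments, length, integer(1)) %/% sys$params$beads_per_ulf
}

#' Mean filament length in ULF units
#'
#' `<l_n>` = total ULFs / current filament count.
#'
#' @param sys an `if_system`
#' @return mean length in ULF units
#' @examples
#' # 1000 ULFs in 45 filaments give <l_n> = 22.2
#' @export
mean_ulf_length <- function(sys) {
  stopifnot(inherits(sys, "if_system"))
  if (length(sys$filaments) == 0L) stop("empty system", call. = FALSE)
  sys$n0 / length(sys$filaments)
}

#' Equivalent protein mass concentration of a system or ULF count
#'
#' Converts a number of ULFs in a volume to the protein concentration an
#' experiment at the same ULF density would use.
#'
#' @param n_ulfs number of ULFs
#' @param volume box volume in um^3
#' @param params an [if_params()] (supplies the ULF mass)
#' @return concentration in g/l
#' @examples
#' mass_concentration(1000, 28.0)   # about 0.10 g/l
#' mass_concentration(5832, 0.94)   # about 17.7 g/l
#' @export
mass_concentration <- function(n_ulfs, volume, params = if_params()) {
  stopifnot(volume > 0, n_ulfs >= 0)
  n_ulfs * params$ulf_mass_g / volume * 1e15
}

#' Number of ULFs equivalent to a concentration in a given volume
#'
#' Inverse of [mass_concentration()], rounded to the nearest integer.
#'
#' @param concentration concentration in g/l
#' @param volume box volume in um^3
#' @param params an [if_params()]
#' @return integer ULF count
#' @examples
#' ulfs_for_concentration(17.8, 0.94)  # close to 5832
#' @export
ulfs_for_concentration <- function(concentration, volume,
                                   params = if_params()) {
  stopifnot(concentration > 0, volume > 0)
  as.integer(round(concentration * volume / (params$ulf_mass_g * 1e15)))
}
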