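#' Minimum-image displacement between two points
#'
#' Displacement from `p` to `q` shifted by integer multiples of the box edge
#' per axis so that every component lies in `(-edge/2, edge/2]`.
#'
#' @param p,q numeric length-3 positions (nm)
#' @param box a [periodic_box()]
#' @return numeric length-3 displacement vector (nm)
#' @examples
#' b <- periodic_box(edge = 100)
#' minimum_image(c(1, 0, 0), c(99, 0, 0), b)  # c(-2, 0, 0)
#' @export
minimum_image <- function(p, q, box) {
  stopifnot(inherits(box, "periodic_box"))
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("coordinates must be finite", call. = FALSE)
  e <- box$edge_nm
  d <- q - p
  d - e * ceiling(d / e - 0.5)
}

#' Angle between two bond vectors
#'
#' @param b1,b2 numeric length-3 bond vectors
#' @return angle in degrees, in `[0, 180]`
#' @examples
#' bond_angle(c(1, 0, 0), c(1, 1, 0))  # 45
#' @export
bond_angle <- function(b1, b2) {
  n1 <- sqrt(sum(b1^2))
  n2 <- sqrt(sum(b2^2))
  if (n1 == 0 || n2 == 0) stop("bond vectors must be non-zero", call. = FALSE)
  cc <- sum(b1 * b2) / (n1 * n2)
  acos(min(1, max(-1, cc))) * 180 / pi
}

as_bead_matrix <- function(f) {
  m <- as.matrix(f)
  if (ncol(m) != 3L) stop("filament coordinates must have 3 columns", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Check a filament against the geometric constraints
#'
#' @param f a filament: numeric matrix of bead positions (rows, nm)
#' @param params an [if_params()] object
#' @return a data frame of violations with columns `index` (1-based bead
#'   index at which the offending bond or angle starts), `constraint`
#'   (`"bond_length"` or `"bond_angle"`) and `value` (the measured length in
#'   nm or angle in degrees); zero rows when the filament is valid
#' @examples
#' f <- cbind(x = c(0, 11, 22, 33), y = 0, z = 0)
#' validate_filament(f, if_params())  # no violations
#' @export
validate_filament <- function(f, params = if_params()) {
  m <- as_bead_matrix(f)
  n <- nrow(m)
  out <- data.frame(index = integer(), constraint = character(),
                    value = numeric())
  if (n < 2L) return(out)
  b <- diff(m)
  len <- sqrt(rowSums(b^2))
  bad <- which(len < params$bond_min | len > params$bond_max)
  if (length(bad))
    out <- rbind(out, data.frame(index = bad, constraint = "bond_length",
                                 value = len[bad]))
  if (n >= 3L) {
    dots <- rowSums(b[-nrow(b), , drop = FALSE] * b[-1, , drop = FALSE])
    cosang <- pmin(1, pmax(-1, dots / (len[-length(len)] * len[-1])))
    ang <- acos(cosang) * 180 / pi
    bad <- which(ang > params$max_bond_angle + 1e-9)
    if (length(bad))
      out <- rbind(out, data.frame(index = bad, constraint = "bond_angle",
                                   value = ang[bad]))
  }
  rownames(out) <- NULL
  out
}

#' Contour length of a filament
#'
#' @inheritParams validate_filament
#' @return sum of consecutive bead distances in nm
#' @examples
#' contour_length(cbind(c(0, 11, 22, 33), 0, 0))  # 33
#' @export
contour_length <- function(f) {
  m <- as_bead_matrix(f)
  if (nrow(m) < 2L) stop("a filament needs at least 2 beads", call. = FALSE)
  sum(sqrt(rowSums(diff(m)^2)))
}

#' Radius of gyration of a filament
#'
#' Root-mean-square distance of the beads from their centroid, computed on
#' unwrapped coordinates.
#'
#' @inheritParams validate_filament
#' @return radius of gyration in nm
#' @examples
#' radius_of_gyration(cbind(c(0, 1, 2, 3), 0, 0))  # sqrt(1.25)
#' @export
radius_of_gyration <- function(f) {
  m <- as_bead_matrix(f)
  ctr <- colMeans(m)
  sqrt(mean(rowSums((m - rep(ctr, each = nrow(m)))^2)))
}
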