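#' Convert a traced filament length to ULF units
#'
#' A single ULF traces at about 60 nm; on annealing, consecutive ULFs
#' interdigitate so each additional ULF adds the 42.7 nm axial repeat:
#' `i = (L - 60)/42.7 + 1`.
#'
#' @param length_nm traced filament length(s) in nm (>= 60)
#' @param params an [if_params()] (supplies the 60 nm / 42.7 nm constants)
#' @return filament length in ULF units (real; round at report time)
#' @examples
#' length_to_ulfs(353)    # 7.86, reported as 7.9
#' length_to_ulfs(2100)   # 48.8, reported as 49
#' @export
length_to_ulfs <- function(length_nm, params = if_params()) {
  if (any(length_nm < params$ulf_length_nm))
    stop("length below one ULF (", params$ulf_length_nm, " nm)",
         call. = FALSE)
  (length_nm - params$ulf_length_nm) / params$ulf_repeat_nm + 1
}

#' Convert a length in ULF units to a traced length in nm
#'
#' Exact inverse of [length_to_ulfs()]: `L = 60 + (i - 1) * 42.7`.
#'
#' @param i length in ULF units (>= 1)
#' @param params an [if_params()]
#' @return traced length in nm
#' @examples
#' ulfs_to_length(2)  # 102.7
#' @export
ulfs_to_length <- function(i, params = if_params()) {
  if (any(i < 1)) stop("a filament has at least 1 ULF", call. = FALSE)
  params$ulf_length_nm + (i - 1) * params$ulf_repeat_nm
}

#' A set of traced filament lengths
#'
#' Container for one time point of filament tracing (EM/AFM/TIRFM) or for a
#' simulated length distribution. Lengths are stored in nm; pass
#' `unit = "ulf"` to supply ULF counts, which are converted through
#' [ulfs_to_length()].
#'
#' @param lengths filament lengths (nm, or ULF units with `unit = "ulf"`)
#' @param time_s assembly time label in seconds (optional)
#' @param source free-text provenance, e.g. `"AFM"`, `"TIRFM"`,
#'   `"simulation"`
#' @param unit `"nm"` (default) or `"ulf"`
#' @param params an [if_params()]
#' @return object of class `length_distribution`
#' @examples
#' length_distribution(c(60, 102.7, 353), time_s = 600, source = "AFM")
#' @export
length_distribution <- function(lengths, time_s = NA_real_,
                                source = "simulation",
                                unit = c("nm", "ulf"),
                                params = if_params()) {
  unit <- match.arg(unit)
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1L) stop("no lengths given", call. = FALSE)
  if (any(!is.finite(lengths))) stop("lengths must be finite", call. = FALSE)
  if (unit == "ulf") lengths <- ulfs_to_length(lengths, params)
  if (any(lengths < params$ulf_length_nm - 1e-9))
    stop("every filament is at least one ULF (", params$ulf_length_nm,
         " nm)", call. = FALSE)
  structure(list(lengths_nm = lengths, time_s = time_s, source = source,
                 params = params),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  s <- summarize_lengths(x)
  cat(sprintf(
    "%d traced filaments (%s%s): <l> = %.3g um, <l_n> = %.3g ULF (SD %.3g)\n",
    s$n, x$source,
    if (is.finite(x$time_s)) sprintf(", t = %g s", x$time_s) else "",
    s$mean_length_um, s$mean_ulf, s$sd_ulf))
  invisible(x)
}

#' Summary statistics of a length distribution
#'
#' @param dist a [length_distribution()]
#' @return list with `n`, `mean_length_nm`, `mean_length_um`, `mean_ulf`
#'   (per-filament ULF counts averaged) and `sd_ulf`
#' @examples
#' summarize_lengths(length_distribution(c(60, 102.7)))  # mean ULF 1.5
#' @export
summarize_lengths <- function(dist) {
  stopifnot(inherits(dist, "length_distribution"))
  l <- dist$lengths_nm
  u <- length_to_ulfs(l, dist$params)
  list(n = length(l), mean_length_nm = mean(l),
       mean_length_um = mean(l) / 1000,
       mean_ulf = mean(u),
       sd_ulf = if (length(u) > 1) sd(u) else 0)
}

ulf_bins <- function(u, bin_width) {
  # left-closed right-open bins starting at 1 ULF
  lo <- 1 + bin_width * (0:ceiling((max(u) - 1 + 1e-9) / bin_width))
  k <- findInterval(u, lo, rightmost.closed = FALSE)
  nbin <- max(k)
  list(idx = k, lo = lo[seq_len(nbin)], hi = lo[seq_len(nbin)] + bin_width)
}

#' Number-weighted length histogram
#'
#' Fraction of filaments per ULF-unit bin. Bins are left-closed right-open
#' with width `bin_width` ULFs, the first bin starting at 1 ULF.
#'
#' @param dist a [length_distribution()]
#' @param bin_width bin width in ULF units (>= 1)
#' @return data frame with `bin_lo_ulf`, `bin_hi_ulf`, `count`, `fraction`;
#'   fractions sum to 1
#' @export
number_histogram <- function(dist, bin_width = 1) {
  stopifnot(inherits(dist, "length_distribution"), bin_width >= 1)
  u <- length_to_ulfs(dist$lengths_nm, dist$params)
  b <- ulf_bins(u, bin_width)
  cnt <- tabulate(b$idx, nbins = length(b$lo))
  data.frame(bin_lo_ulf = b$lo, bin_hi_ulf = b$hi, count = cnt,
             fraction = cnt / length(u))
}

#' Mass-weighted (total-length) histogram
#'
#' Each bin's fraction is the summed filament length in the bin divided by
#' the total filament length: the proportion of polymer mass residing in
#' each length class. Long filaments contribute little by number but a lot
#' by mass, so these fractions shift to longer bins whenever lengths are
#' heterogeneous.
#'
#' @inheritParams number_histogram
#' @return data frame with `bin_lo_ulf`, `bin_hi_ulf`, `total_length_nm`,
#'   `fraction`; fractions sum to 1
#' @export
mass_weighted_histogram <- function(dist, bin_width = 1) {
  stopifnot(inherits(dist, "length_distribution"), bin_width >= 1)
  l <- dist$lengths_nm
  u <- length_to_ulfs(l, dist$params)
  b <- ulf_bins(u, bin_width)
  tot <- vapply(seq_along(b$lo),
                function(k) sum(l[b$idx == k]), numeric(1))
  data.frame(bin_lo_ulf = b$lo, bin_hi_ulf = b$hi, total_length_nm = tot,
             fraction = tot / sum(l))
}

#' Mass fractions in persistence-length multiples
#'
#' Length-weighted fraction of total filament length falling in each bin
#' `[k*lp, (k+1)*lp)`. The fraction in bin 0 is the share of polymer mass in
#' filaments shorter than one persistence length.
#'
#' @param dist a [length_distribution()]
#' @param lp persistence length in nm (> 0)
#' @return data frame with `k` (bin index), `bin_lo_nm`, `bin_hi_nm`,
#'   `fraction`; fractions sum to 1
#' @examples
#' d <- length_distribution(c(0.5, 1.5, 3.5) * 1000)
#' lp_normalized_fractions(d, 1000)$fraction[1]  # 0.5/5.5
#' @export
lp_normalized_fractions <- function(dist, lp) {
  stopifnot(inherits(dist, "length_distribution"), lp > 0)
  l <- dist$lengths_nm
  k <- floor(l / lp)
  ks <- 0:max(k)
  tot <- vapply(ks, function(kk) sum(l[k == kk]), numeric(1))
  data.frame(k = ks, bin_lo_nm = ks * lp, bin_hi_nm = (ks + 1) * lp,
             fraction = tot / sum(l))
}

#' Concentration- and time-normalized elongation constant
#'
#' `(<l_n> - 1) / (c * t)`: the mean number of annealing steps per ULF,
#' normalized to 1 s of assembly at 1 g/l. Allows assembly speeds measured
#' under different regimes (and simulated kinetics) to be compared directly.
#'
#' @param mean_ulf mean filament length `<l_n>` in ULF units (>= 1)
#' @param c_gl protein concentration in g/l (> 0)
#' @param t_s assembly time in seconds (> 0)
#' @return elongation constant in ULF/(g/l)/s
#' @examples
#' elongation_constant(35, 0.1, 7200)     # vimentin, 2 h: 0.047
#' elongation_constant(3.7, 0.0025, 60)   # keratin, 1 min: 18
#' @export
elongation_constant <- function(mean_ulf, c_gl, t_s) {
  stopifnot(all(mean_ulf >= 1), all(c_gl > 0), all(t_s > 0))
  (mean_ulf - 1) / (c_gl * t_s)
}

#' Sweep count normalized to 1 g/l
#'
#' `c * sweeps`. Diffusion-limited end-to-end annealing makes the number of
#' sweeps to a given mean length inversely proportional to concentration,
#' so this product is approximately concentration-invariant.
#'
#' @param c_gl concentration in g/l (> 0)
#' @param sweeps sweep count
#' @return normalized sweeps in (g/l) * sweeps
#' @examples
#' normalized_sweeps(17.8, 4.30e6)  # about 77e6
#' @export
normalized_sweeps <- function(c_gl, sweeps) {
  stopifnot(all(c_gl > 0))
  c_gl * sweeps
}

#' Fold reduction of the filament number
#'
#' Ratio of total ULFs to the number of filaments they currently form: how
#' many times end-to-end annealing has reduced the particle count.
#'
#' @param total_ulfs total number of ULFs
#' @param n_filaments current filament count (>= 1)
#' @return the reduction factor
#' @examples
#' fold_reduction(300000, 9000)  # about 33
#' @export
fold_reduction <- function(total_ulfs, n_filaments) {
  stopifnot(all(n_filaments >= 1))
  total_ulfs / n_filaments
}

#' Length distribution of a simulated system
#'
#' Converts the per-filament ULF counts of an `if_system` into traced-length
#' equivalents via [ulfs_to_length()].
#'
#' @param sys an `if_system`
#' @param time_s optional time label in seconds
#' @return a [length_distribution()]
#' @export
system_length_distribution <- function(sys, time_s = NA_real_) {
  stopifnot(inherits(sys, "if_system"))
  length_distribution(filament_ulfs(sys), time_s = time_s,
                      source = "simulation", unit = "ulf",
                      params = sys$params)
}
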