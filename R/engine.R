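params_for_cpp <- function(params) {
  unclass(params)
}

rebuild_system <- function(sys, res, sweeps_added) {
  sys$coords <- res$coords
  sys$filaments <- res$filaments
  sys$sweep_count <- sys$sweep_count + sweeps_added
  sys
}

#' Attempt a single trial move on one bead
#'
#' Displaces the bead by `displacement` (or, when `NULL`, by a random vector
#' with uniform direction and magnitude uniform on `[0, max_displacement]`)
#' and accepts the move iff all bond-length and bond-angle constraints
#' touching the bead remain satisfied (plus, for the `uniform_theta` angle
#' measure, the geometric Jacobian acceptance factor). On rejection the
#' system is unchanged.
#'
#' @param sys an `if_system`
#' @param filament filament index
#' @param bead bead position within the filament (1-based)
#' @param displacement optional numeric length-3 displacement (nm); `NULL`
#'   draws a random trial displacement
#' @return list with `accepted` (logical) and `system` (possibly updated)
#' @export
trial_move <- function(sys, filament, bead, displacement = NULL) {
  stopifnot(inherits(sys, "if_system"))
  idx <- sys$filaments[[filament]]
  if (bead < 1L || bead > length(idx)) stop("no such bead", call. = FALSE)
  if (is.null(displacement)) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    displacement <- u * runif(1, 0, sys$params$max_displacement)
  }
  res <- cpp_trial_move(sys$coords[idx, , drop = FALSE], bead,
                        as.numeric(displacement), params_for_cpp(sys$params))
  if (res$accepted) sys$coords[idx, ] <- res$coords
  list(accepted = res$accepted, system = sys)
}

#' Run one Monte Carlo sweep
#'
#' Every bead attempts exactly one trial move, in a fresh random order; the
#' sweep counter advances by one. No annealing is attempted.
#'
#' @param sys an `if_system`
#' @return list with `acceptance` (fraction of accepted moves) and `system`
#' @export
sweep_system <- function(sys) {
  stopifnot(inherits(sys, "if_system"))
  res <- cpp_run_assembly(sys$coords, sys$filaments,
                          params_for_cpp(sys$params), sys$box$edge_nm,
                          sys$n0, 0L, 1, 0, sys$sweep_count, 0L)
  list(acceptance = res$trajectory$acceptance[nrow(res$trajectory)],
       system = rebuild_system(sys, res, 1))
}

#' Detect reactive end pairs
#'
#' All unordered pairs of ends of distinct filaments whose minimum-image
#' distance is below the reaction distance. Uses a periodic cell list with
#' cell size at least the reaction distance (falling back to an all-pairs
#' scan when the box is too small to hold 3 cells per axis).
#'
#' @param sys an `if_system`
#' @param method `"cell"` (default) or `"brute"` for the quadratic
#'   reference scan
#' @return data frame with columns `filament_a`, `end_a`, `filament_b`,
#'   `end_b` (ends labelled `"first"`/`"last"`) and `distance` (nm)
#' @export
detect_reactive_pairs <- function(sys, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(sys, "if_system"))
  nf <- length(sys$filaments)
  ends_bead <- unlist(lapply(sys$filaments, function(ix) ix[c(1L, length(ix))]))
  pos <- sys$coords[ends_bead, , drop = FALSE]
  grp <- rep(seq_len(nf), each = 2L)
  pairs <- cpp_detect_pairs(pos, grp, sys$box$edge_nm,
                            sys$params$reaction_distance,
                            method == "brute")
  lab <- rep(c("first", "last"), nf)
  if (nrow(pairs) == 0L)
    return(data.frame(filament_a = integer(), end_a = character(),
                      filament_b = integer(), end_b = character(),
                      distance = numeric()))
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    sqrt(sum(minimum_image(pos[pairs[k, 1], ], pos[pairs[k, 2], ],
                           sys$box)^2))
  }, numeric(1))
  out <- data.frame(filament_a = grp[pairs[, 1]], end_a = lab[pairs[, 1]],
                    filament_b = grp[pairs[, 2]], end_b = lab[pairs[, 2]],
                    distance = d)
  out[order(out$filament_a, out$filament_b), , drop = FALSE]
}

#' Attempt to anneal two filaments end-to-end
#'
#' Joins the two filaments by a single new bond between the named terminal
#' beads. The new bond is the minimum-image gap vector between the ends; the
#' merge is accepted iff its length lies within the allowed bond interval
#' and both junction angles are within the reaction angle. Bead positions
#' are not altered other than translating the absorbed filament into the
#' periodic image adjacent to its partner. ULF and bead counts are
#' conserved; on success the filament count decreases by one.
#'
#' @param sys an `if_system`
#' @param pair a list or one-row data frame with `filament_a`, `end_a`,
#'   `filament_b`, `end_b` as returned by [detect_reactive_pairs()]
#' @return list with `merged` (logical) and `system`
#' @export
anneal <- function(sys, pair) {
  stopifnot(inherits(sys, "if_system"))
  fa <- as.integer(pair$filament_a)
  fb <- as.integer(pair$filament_b)
  nf <- length(sys$filaments)
  if (is.na(fa) || is.na(fb) || fa < 1L || fb < 1L || fa > nf || fb > nf) {
    warning("stale pair: filament no longer exists; skipped")
    return(list(merged = FALSE, system = sys))
  }
  if (fa == fb) stop("self-annealing is forbidden", call. = FALSE)
  ia <- sys$filaments[[fa]]
  ib <- sys$filaments[[fb]]
  if (identical(pair$end_a, "first")) ia <- rev(ia)   # end a becomes tail
  if (identical(pair$end_b, "last")) ib <- rev(ib)    # end b becomes head
  pa <- sys$coords[ia[length(ia)], ]
  pb <- sys$coords[ib[1L], ]
  gap <- minimum_image(pa, pb, sys$box)
  glen <- sqrt(sum(gap^2))
  p <- sys$params
  ok <- glen >= p$bond_min && glen <= p$bond_max
  if (ok) {
    last_bond <- pa - sys$coords[ia[length(ia) - 1L], ]
    first_bond <- sys$coords[ib[2L], ] - pb
    ok <- bond_angle(last_bond, gap) <= p$reaction_angle &&
      bond_angle(gap, first_bond) <= p$reaction_angle
  }
  if (!ok) return(list(merged = FALSE, system = sys))
  shift <- (pa + gap) - pb
  sys$coords[ib, ] <- sweep(sys$coords[ib, , drop = FALSE], 2, shift, "+")
  sys$filaments[[fa]] <- c(ia, ib)
  sys$filaments[[fb]] <- NULL
  list(merged = TRUE, system = sys)
}

#' Run the assembly simulation
#'
#' Alternates Monte Carlo sweeps (one trial move per bead) with annealing
#' passes (detect reactive end pairs, attempt merges in random order, each
#' end reacting at most once per pass) until the mean filament length
#' reaches `target_mean_ulf` or `max_sweeps` sweeps have been performed.
#'
#' @param sys an `if_system`
#' @param target_mean_ulf stop once `<l_n>` reaches this value (optional)
#' @param max_sweeps hard sweep limit (required when no target is given)
#' @param record_every record a trajectory row every this many sweeps
#' @param react_every attempt an annealing pass every this many sweeps
#'   (default 1); 0 disables annealing
#' @param seed optional integer seed
#' @return list of class `if_run` with elements `system` (final state),
#'   `trajectory` (data frame: sweep, n_filaments, mean_ln, acceptance),
#'   `events` (one row per merge), `reached` (whether the target was hit)
#'   and `seed`
#' @examples
#' \donttest{
#' sys <- init_system(64, box_for_concentration(64, 17.8), seed = 1)
#' run <- run_assembly(sys, target_mean_ulf = 2, max_sweeps = 2e5, seed = 2)
#' tail(run$trajectory)
#' }
#' @export
run_assembly <- function(sys, target_mean_ulf = NULL, max_sweeps = NULL,
                         record_every = 10000, react_every = 1,
                         seed = NULL) {
  stopifnot(inherits(sys, "if_system"))
  if (is.null(target_mean_ulf) && is.null(max_sweeps))
    stop("give target_mean_ulf and/or max_sweeps", call. = FALSE)
  target_nfil <- 0L
  if (!is.null(target_mean_ulf)) {
    if (target_mean_ulf > sys$n0)
      stop("unreachable criterion: target mean length exceeds n0",
           call. = FALSE)
    target_nfil <- as.integer(floor(sys$n0 / target_mean_ulf))
  }
  if (is.null(max_sweeps)) max_sweeps <- Inf
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_assembly(sys$coords, sys$filaments,
                          params_for_cpp(sys$params), sys$box$edge_nm,
                          sys$n0, target_nfil, max_sweeps, record_every,
                          sys$sweep_count, as.integer(react_every))
  structure(list(system = rebuild_system(sys, res, res$sweeps_done),
                 trajectory = res$trajectory, events = res$events,
                 reached = res$reached, seed = seed),
            class = "if_run")
}

#' @export
print.if_run <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "Assembly run: %s sweeps, %d -> %d filaments (<l_n> %.3g -> %.3g)\n",
    format(max(tr$sweep) - min(tr$sweep), big.mark = ","),
    tr$n_filaments[1], tr$n_filaments[nrow(tr)],
    tr$mean_ln[1], tr$mean_ln[nrow(tr)]))
  invisible(x)
}

#' Convert sweep counts to approximate physical time
#'
#' One sweep corresponds to roughly 1 ns of real time (set by
#' `sweep_time_s`), a scale obtained by matching center-of-mass diffusion
#' against Brownian-dynamics simulations.
#'
#' @param sweeps number of sweeps (>= 0)
#' @param params an [if_params()]
#' @return time in seconds
#' @examples
#' sweeps_to_seconds(4.30e6)  # 0.0043 s
#' @export
sweeps_to_seconds <- function(sweeps, params = if_params()) {
  stopifnot(all(sweeps >= 0))
  sweeps * params$sweep_time_s
}
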