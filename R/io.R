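#' Load and validate a simulation run configuration
#'
#' Reads a YAML configuration describing one assembly simulation. Recognized
#' keys: the [if_params()] fields (`bead_diameter`, `max_bond_angle`,
#' `bond_min`, `bond_max`, `reaction_distance`, `reaction_angle`,
#' `max_displacement`, `beads_per_ulf`, `ulf_length_nm`, `ulf_repeat_nm`,
#' `sweep_time_s`, `ulf_mass_g`, `angle_measure`), exactly one box
#' specification (`edge_nm`, `volume_um3` or `concentration_gl`), `n0`,
#' stop criteria (`target_mean_ulf` and/or `max_sweeps`), `record_every`,
#' `react_every` and `seed`. Unknown keys are rejected; all offending keys
#' are reported at once.
#'
#' @param path path to a YAML file
#' @return a list of class `run_config` with elements `params`
#'   ([if_params()]), `box` ([periodic_box()]), `n0`, `target_mean_ulf`,
#'   `max_sweeps`, `record_every`, `react_every`, `seed`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  param_keys <- c("bead_diameter", "max_bond_angle", "bond_min", "bond_max",
                  "reaction_distance", "reaction_angle", "max_displacement",
                  "beads_per_ulf", "ulf_length_nm", "ulf_repeat_nm",
                  "sweep_time_s", "ulf_mass_g", "angle_measure")
  run_keys <- c("edge_nm", "volume_um3", "concentration_gl", "n0",
                "target_mean_ulf", "max_sweeps", "record_every",
                "react_every", "seed")
  problems <- character()
  unknown <- setdiff(names(raw), c(param_keys, run_keys))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  box_keys <- intersect(names(raw), c("edge_nm", "volume_um3",
                                      "concentration_gl"))
  if (length(box_keys) != 1L)
    problems <- c(problems, paste0(
      "exactly one of edge_nm / volume_um3 / concentration_gl required, got ",
      length(box_keys)))
  if (is.null(raw$n0) || !is.numeric(raw$n0) || raw$n0 < 1)
    problems <- c(problems, "n0 must be a positive count")
  if (is.null(raw$target_mean_ulf) && is.null(raw$max_sweeps))
    problems <- c(problems, "need target_mean_ulf and/or max_sweeps")
  for (k in intersect(names(raw), setdiff(param_keys, "angle_measure")))
    if (!is.numeric(raw[[k]]) || raw[[k]] <= 0)
      problems <- c(problems, paste0(k, " must be a positive number"))
  if (length(problems))
    stop("invalid config '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  params <- do.call(if_params, raw[intersect(names(raw), param_keys)])
  box <- if ("edge_nm" %in% names(raw)) {
    periodic_box(edge = raw$edge_nm)
  } else if ("volume_um3" %in% names(raw)) {
    periodic_box(volume = raw$volume_um3)
  } else {
    box_for_concentration(raw$n0, raw$concentration_gl, params)
  }
  structure(list(params = params, box = box, n0 = as.integer(raw$n0),
                 target_mean_ulf = raw$target_mean_ulf,
                 max_sweeps = raw$max_sweeps,
                 record_every = if (is.null(raw$record_every)) 10000
                                else raw$record_every,
                 react_every = if (is.null(raw$react_every)) 1L
                               else as.integer(raw$react_every),
                 seed = raw$seed),
            class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' Produces a file that [load_config()] reads back to an identical
#' configuration. The box is stored as `volume_um3`.
#'
#' @param config a `run_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config$params)
  out$volume_um3 <- config$box$volume_um3
  out$n0 <- config$n0
  for (k in c("target_mean_ulf", "max_sweeps", "seed"))
    if (!is.null(config[[k]])) out[[k]] <- config[[k]]
  out$record_every <- config$record_every
  out$react_every <- config$react_every
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a trajectory as annotated TSV
#'
#' The file starts with `#`-prefixed header lines (`key=value`; simulation
#' parameters and the seed when available) followed by a tab-separated table
#' with columns `sweep`, `n_filaments`, `mean_ln`, `acceptance`. The
#' round-trip is lossless.
#'
#' @param x an `if_run` from [run_assembly()] or a trajectory data frame
#' @param path output file
#' @param params optional [if_params()] recorded in the header
#' @param seed optional seed recorded in the header
#' @return `path`, invisibly
#' @export
write_trajectory <- function(x, path, params = NULL, seed = NULL) {
  if (inherits(x, "if_run")) {
    if (is.null(params)) params <- x$system$params
    if (is.null(seed)) seed <- x$seed
    x <- x$trajectory
  }
  stopifnot(is.data.frame(x),
            all(c("sweep", "n_filaments", "mean_ln") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ifsim trajectory", con)
  if (!is.null(params))
    for (k in names(unclass(params)))
      writeLines(sprintf("# %s=%s", k, format(params[[k]], digits = 17)), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x))
    writeLines(do.call(paste,
                       c(lapply(x, function(col) {
                         ifelse(is.na(col), "NA", fmt_num(col))
                       }), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns the trajectory data frame with the
#'   header key-value pairs in attribute `header`; a non-monotonic sweep
#'   column or a decreasing filament count is a parse error
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  header <- list()
  for (h in lines[hdr_idx]) {
    m <- regmatches(h, regexec("^#\\s*([^=[:space:]]+)=(.*)$", h))[[1]]
    if (length(m) == 3) header[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  if (!length(body)) stop("no table in trajectory file ", path, call. = FALSE)
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   na.strings = "NA")
  if (nrow(df)) {
    if (is.unsorted(df$sweep, strictly = TRUE)) {
      bad <- which(diff(df$sweep) <= 0)[1] + 1L
      stop("trajectory sweeps not strictly increasing at data row ", bad,
           " of ", path, call. = FALSE)
    }
    if (any(diff(df$n_filaments) > 0)) {
      bad <- which(diff(df$n_filaments) > 0)[1] + 1L
      stop("filament count increases at data row ", bad, " of ", path,
           call. = FALSE)
    }
  }
  attr(df, "header") <- header
  df
}

#' Write / read a traced-length table
#'
#' Tab-separated columns `length_nm` (required), `time_s` and `source`
#' (optional); lines starting with `#` are ignored on read.
#'
#' @param dist a [length_distribution()]
#' @param path file path
#' @return `path` invisibly; `read_lengths` returns a
#'   [length_distribution()]
#' @export
write_lengths <- function(dist, path) {
  stopifnot(inherits(dist, "length_distribution"))
  df <- data.frame(length_nm = dist$lengths_nm, time_s = dist$time_s,
                   source = dist$source)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ifsim traced filament lengths (nm)", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lengths
#' @export
read_lengths <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!"length_nm" %in% names(df))
    stop("column 'length_nm' missing in ", path, call. = FALSE)
  length_distribution(df$length_nm,
                      time_s = if ("time_s" %in% names(df)) df$time_s[1]
                               else NA_real_,
                      source = if ("source" %in% names(df)) df$source[1]
                               else "file")
}

#' Write a per-bead snapshot of the system
#'
#' `"tsv"` writes one row per bead (`filament_id`, `bead_index`, `x_nm`,
#' `y_nm`, `z_nm`) with parameters and sweep count in `#` header lines;
#' `"xyz"` writes a molecular-viewer XYZ file with one pseudo-atom per bead.
#'
#' @param sys an `if_system`
#' @param path output file
#' @param format `"tsv"` or `"xyz"`
#' @return `path`, invisibly
#' @export
write_snapshot <- function(sys, path, format = c("tsv", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(sys, "if_system"))
  fid <- rep(seq_along(sys$filaments),
             vapply(sys$filaments, length, integer(1)))
  ord <- unlist(sys$filaments)
  bead <- unlist(lapply(sys$filaments, seq_along))
  m <- sys$coords[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("# ifsim snapshot", con)
    for (k in names(unclass(sys$params)))
      writeLines(sprintf("# %s=%s", k,
                         format(sys$params[[k]], digits = 17)), con)
    writeLines(sprintf("# sweep_count=%s", fmt_num(sys$sweep_count)), con)
    writeLines(sprintf("# box_edge_nm=%s", fmt_num(sys$box$edge_nm)), con)
    writeLines("filament_id\tbead_index\tx_nm\ty_nm\tz_nm", con)
    writeLines(sprintf("%d\t%d\t%s\t%s\t%s", fid, bead,
                       fmt_num(m[, 1]), fmt_num(m[, 2]), fmt_num(m[, 3])),
               con)
  } else {
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("ifsim snapshot sweep=%s", fmt_num(sys$sweep_count)),
               con)
    writeLines(sprintf("C %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
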