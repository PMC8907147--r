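#' Read and write energy trajectories as TSV
#'
#' The on-disk dialect is a tab-separated table with header
#' `time  replica  s  V_R  V_1 ... V_N` (energies in kJ/mol, one row per
#' stored frame), preceded by a single comment line
#' `#offsets<TAB>E_1<TAB>...<TAB>E_N` carrying the offsets in force during
#' production. Numbers are written with 10 significant digits, so a
#' write-read round trip reproduces every field exactly at that decimal
#' precision.
#'
#' @param traj An [energy_trajectory()].
#' @param path File path.
#' @return `write_energy_trajectory`: the path, invisibly.
#'   `read_energy_trajectory`: an [energy_trajectory()].
#' @export
write_energy_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "energy_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#offsets", sprintf("%.10g", traj_offsets(traj))),
                   collapse = "\t"), con)
  writeLines(paste(names(traj), collapse = "\t"), con)
  if (nrow(traj)) {
    rows <- apply(as.matrix(traj), 1L, function(r)
      paste(sprintf("%.10g", r), collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_energy_trajectory
#' @export
read_energy_trajectory <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path)
  ln <- 1L
  offsets <- NULL
  if (startsWith(lines[1L], "#offsets")) {
    offsets <- as.numeric(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L])
    ln <- 2L
  }
  if (length(lines) < ln) stop("missing header in ", path)
  header <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
  need <- c("time", "replica", "s", "V_R")
  if (!identical(header[1:4], need))
    stop("malformed header at line ", ln, " of ", path,
         " (expected 'time replica s V_R V_1 ...')")
  ncols <- length(header)
  n_states <- ncols - 4L
  if (n_states < 1L) stop("header at line ", ln, " lists no V_i columns")
  if (is.null(offsets)) offsets <- rep(0, n_states)
  if (length(offsets) != n_states)
    stop("offsets line lists ", length(offsets), " values for ",
         n_states, " states in ", path)
  body <- lines[-seq_len(ln)]
  if (!length(body)) {
    fr <- as.data.frame(matrix(numeric(0), 0L, ncols,
                               dimnames = list(NULL, header)))
    return(energy_trajectory(fr, offsets))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncols)
  if (length(bad))
    stop("line ", ln + bad[1L], " of ", path, " has ",
         lengths(parts)[bad[1L]], " fields, expected ", ncols)
  mat <- matrix(as.numeric(unlist(parts)), ncol = ncols, byrow = TRUE)
  if (anyNA(mat)) {
    badrow <- which(apply(is.na(mat), 1L, any))[1L]
    stop("non-numeric field at line ", ln + badrow, " of ", path)
  }
  fr <- as.data.frame(mat)
  names(fr) <- header
  energy_trajectory(fr, offsets)
}

#' Write an exchange log as TSV
#'
#' Columns: `step  i  j  p  accepted` (plus the maximal-contributor state on
#' each side, `mc_i`, `mc_j`).
#'
#' @param exchanges Exchange data frame from [run_reeds()].
#' @param path File path.
#' @export
write_exchange_log <- function(exchanges, path) {
  utils::write.table(exchanges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A run is described by one structured config (YAML on disk): the toy
#' system, thermodynamic settings, stage lengths, the start-state mode
#' (`SSM`: replicas seeded with per-state optimized coordinates in an
#' alternating manner; `1SS`: one shared start), and the seed.
#' `default_run_config()` returns the documented defaults;
#' `read_run_config()`/`write_run_config()` handle the YAML form.
#'
#' @param system List describing the toy system: either
#'   `list(preset = "benchmark")`, `list(preset = "bottleneck")`, or
#'   `list(n_states =, dimension =, seed =)` for a randomly generated
#'   system.
#' @param temperature Temperature in K.
#' @param seed Integer seed for the whole run.
#' @param start_mode `"SSM"` or `"1SS"`.
#' @param steps Named list of stage lengths (MC steps): `explore`,
#'   `state_opt`, `peoe`, `opt_base`, `rebalance`, `production`.
#' @param production_discard Equilibration fraction dropped in the analysis
#'   stage.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(system = list(preset = "benchmark"),
                               temperature = 300, seed = 1L,
                               start_mode = "SSM",
                               steps = list(explore = 4000L,
                                            state_opt = 2000L,
                                            peoe = 6000L,
                                            opt_base = 3000L,
                                            rebalance = 3000L,
                                            production = 40000L),
                               production_discard = 0) {
  structure(
    list(system = system, temperature = temperature, seed = as.integer(seed),
         start_mode = match.arg(start_mode, c("SSM", "1SS")),
         steps = steps, production_discard = production_discard),
    class = "run_config"
  )
}

#' @rdname default_run_config
#' @param path Path of the YAML config file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (nm == "steps") {
      for (s in names(raw$steps)) cfg$steps[[s]] <- raw$steps[[s]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  if (!is.null(raw$start_mode))
    cfg$start_mode <- match.arg(raw$start_mode, c("SSM", "1SS"))
  validate_run_config(cfg)
}

#' @rdname default_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$temperature > 0)
  for (s in c("explore", "state_opt", "peoe", "opt_base", "rebalance",
              "production")) {
    v <- cfg$steps[[s]]
    if (is.null(v) || !is.numeric(v) || v < 1)
      stop("config: steps$", s, " must be a positive step count")
  }
  if (!is.null(cfg$system$n_states) && cfg$system$n_states < 2)
    stop("config: system needs at least 2 end states")
  cfg
}

#' Build the end states described by a run config
#'
#' @param system The `system` entry of a run config.
#' @return List of `end_state` objects.
#' @export
states_from_config <- function(system) {
  if (!is.null(system$preset)) {
    return(switch(match.arg(system$preset, c("benchmark", "bottleneck")),
                  benchmark = toy_benchmark(),
                  bottleneck = toy_bottleneck()))
  }
  if (!is.null(system$states)) {
    return(lapply(seq_along(system$states), function(i) {
      st <- system$states[[i]]
      harmonic_state(st$force_constants, st$minimum,
                     shift = if (is.null(st$shift)) 0 else st$shift,
                     id = if (is.null(st$id)) paste0("S", i) else st$id)
    }))
  }
  make_toy_system(toy_system_spec(
    n_states = system$n_states %||% 5L,
    dimension = system$dimension %||% 1L,
    seed = system$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
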