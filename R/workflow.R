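#' Production run with fixed reference-state parameters
#'
#' Stage 4 entry point: a replica-exchange run on the optimized ladder and
#' offsets, whose s = 1 frames feed the free-energy estimator.
#'
#' @param states List of end states.
#' @param s_values Optimized ladder.
#' @param offsets Optimized offsets.
#' @param configurations Starting configurations (typically the final
#'   configurations of the optimization stage).
#' @param thermo A [thermo_context()].
#' @param n_steps MC steps per replica.
#' @param exchange_interval Steps between exchange attempts.
#' @param seed Integer seed.
#' @return A `reeds_run`.
#' @export
produce <- function(states, s_values, offsets, configurations = NULL,
                    thermo = thermo_context(), n_steps = 40000L,
                    exchange_interval = 20L, seed = NULL) {
  ens <- replica_ensemble(states, s_values, offsets = offsets,
                          configurations = configurations, thermo = thermo)
  run_reeds(ens, n_steps, exchange_interval, seed = seed)
}

#' Analyse a production run
#'
#' Computes the pairwise free-energy matrix from the s = 1 replica together
#' with the sampling report.
#'
#' @param run A `reeds_run` (or an s = 1 [energy_trajectory()]).
#' @param thermo A [thermo_context()].
#' @param thresholds Optional [threshold_set()] for the occurrence metrics.
#' @param discard_fraction Equilibration fraction to drop.
#' @param environment_label Label stored in the result.
#' @return List with `free_energy` ([zwanzig_multistate()] result) and
#'   `report` ([sampling_report()]).
#' @export
analyze_production <- function(run, thermo = thermo_context(),
                               thresholds = NULL, discard_fraction = 0,
                               environment_label = "toy") {
  traj <- physical_trajectory(run)
  fe <- zwanzig_multistate(traj, thermo, discard_fraction,
                           environment_label = environment_label)
  rep <- sampling_report(discard_equilibration(traj, discard_fraction),
                         thresholds)
  list(free_energy = fe, report = rep)
}

#' Run the complete four-stage workflow
#'
#' Executes parameter exploration, parameter optimization, production and
#' analysis for the system described by a run config, writing every stage's
#' outputs into `out_dir` as plain TSV/text plus a JSON run ledger listing
#' each produced file with its checksum. Identical config and seed give
#' byte-identical outputs. A stage failure is recorded in the ledger and
#' downstream stages are skipped. Completed stages are resumable: with
#' `resume = TRUE`, stages whose snapshot is already in `out_dir` are
#' loaded instead of re-run.
#'
#' @param config A `run_config` (see [default_run_config()]) or the path of
#'   a YAML config file.
#' @param out_dir Run directory (created if needed).
#' @param resume Reuse completed stage snapshots found in `out_dir`.
#' @param stop_after Last stage to execute (default: run everything).
#' @return The run ledger (list of class `run_ledger`), invisibly:
#'   per-stage status, produced files with checksums, seed and timing.
#' @export
run_workflow <- function(config = default_run_config(),
                         out_dir = tempfile("reeds_run_"),
                         resume = FALSE,
                         stop_after = c("analysis", "exploration",
                                        "optimization", "production")) {
  stop_after <- match.arg(stop_after)
  stage_rank <- c(exploration = 1, optimization = 2, production = 3,
                  analysis = 4)
  wanted <- function(stage) stage_rank[[stage]] <= stage_rank[[stop_after]]
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thermo <- thermo_context(config$temperature)
  states <- states_from_config(config$system)
  n <- length(states)
  t0 <- Sys.time()

  ledger <- list(package_version = as.character(utils::packageVersion("reedsim")),
                 seed = config$seed, out_dir = out_dir,
                 stages = list(), files = list())
  note <- function(stage, status, reason = NULL) {
    ledger$stages[[stage]] <<- list(status = status, reason = reason)
  }
  emit <- function(path) {
    ledger$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }
  snapshot <- function(stage) file.path(out_dir, paste0("stage_", stage, ".rds"))
  run_stage <- function(stage, fn) {
    if (resume && file.exists(snapshot(stage))) {
      note(stage, "resumed")
      return(readRDS(snapshot(stage)))
    }
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      note(stage, "failed", conditionMessage(out))
      return(NULL)
    }
    saveRDS(out, snapshot(stage))
    note(stage, "completed")
    out
  }

  expl <- run_stage("exploration", function() {
    res <- explore_parameters(states, thermo,
                              n_steps_explore = config$steps$explore,
                              n_steps_stateopt = config$steps$state_opt,
                              n_steps_peoe = config$steps$peoe,
                              seed = config$seed,
                              start_mode = config$start_mode)
    writeLines(sprintf("%.10g", res$lower_bound),
               file.path(out_dir, "lower_bound.txt"))
    utils::write.table(
      data.frame(state = seq_len(n),
                 offset = res$peoe$offsets,
                 offset_vs_state1 = res$peoe$offsets - res$peoe$offsets[1L],
                 spread = res$peoe$spread),
      file.path(out_dir, "offsets_peoe.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    coords <- do.call(rbind, res$state_configurations)
    utils::write.table(coords, file.path(out_dir, "state_coordinates.txt"),
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    res
  })
  if (!is.null(expl))
    for (f in c("lower_bound.txt", "offsets_peoe.tsv", "state_coordinates.txt"))
      emit(file.path(out_dir, f))

  opt <- NULL
  if (!is.null(expl) && wanted("optimization")) {
    opt <- run_stage("optimization", function() {
      starts <- start_configurations(config$start_mode,
                                     length(expl$s_values),
                                     expl$state_configurations)
      res <- run_optimization(states, expl$s_values, expl$offsets,
                              configurations = starts, thermo = thermo,
                              schedule = optimization_schedule(config$steps$opt_base),
                              rebalance_steps = config$steps$rebalance)
      utils::write.table(
        data.frame(s = as.numeric(res$s_values)),
        file.path(out_dir, "s_distribution.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(state = seq_len(n), offset = res$offsets),
        file.path(out_dir, "offsets_final.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$history, file.path(out_dir, "optimization_history.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
    if (!is.null(opt))
      for (f in c("s_distribution.tsv", "offsets_final.tsv",
                  "optimization_history.tsv"))
        emit(file.path(out_dir, f))
  } else if (is.null(expl)) note("optimization", "skipped", "exploration failed")

  prod <- NULL
  if (!is.null(opt) && wanted("production")) {
    prod <- run_stage("production", function() {
      run <- produce(states, opt$s_values, opt$offsets,
                     configurations = opt$configurations, thermo = thermo,
                     n_steps = config$steps$production)
      write_energy_trajectory(run$trajectory,
                              file.path(out_dir, "production_energies.tsv"))
      write_exchange_log(run$exchanges,
                         file.path(out_dir, "production_exchanges.tsv"))
      run
    })
    if (!is.null(prod))
      for (f in c("production_energies.tsv", "production_exchanges.tsv"))
        emit(file.path(out_dir, f))
  } else if (is.null(opt) && wanted("production"))
    note("production", "skipped", "optimization not available")

  if (!is.null(prod) && wanted("analysis")) {
    ana <- run_stage("analysis", function() {
      res <- analyze_production(prod, thermo,
                                thresholds = expl$thresholds,
                                discard_fraction = config$production_discard)
      utils::write.table(
        as.data.frame(res$free_energy$dG),
        file.path(out_dir, "free_energy_dG.tsv"),
        sep = "\t", quote = FALSE, row.names = TRUE)
      utils::write.table(
        as.data.frame(res$free_energy$uncertainty),
        file.path(out_dir, "free_energy_uncertainty.tsv"),
        sep = "\t", quote = FALSE, row.names = TRUE)
      utils::write.table(
        data.frame(state = seq_len(n), f_mc = res$report$f_mc,
                   f_occur = res$report$f_occur),
        file.path(out_dir, "sampling_report.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
    if (!is.null(ana))
      for (f in c("free_energy_dG.tsv", "free_energy_uncertainty.tsv",
                  "sampling_report.tsv"))
        emit(file.path(out_dir, f))
  } else if (is.null(prod) && wanted("analysis"))
    note("analysis", "skipped", "production not available")

  ledger$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(ledger) <- "run_ledger"
  jsonlite::write_json(
    list(package_version = ledger$package_version, seed = ledger$seed,
         stages = lapply(ledger$stages, function(st)
           st[!vapply(st, is.null, logical(1))]),
         files = ledger$files, wall_clock_s = ledger$wall_clock_s),
    file.path(out_dir, "run_ledger.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(ledger)
}

#' Assign starting configurations to replicas
#'
#' `SSM` (starting-state mixing) seeds replica r with the optimized
#' coordinates of state `((r - 1) mod N) + 1`, cycling over the states when
#' replicas outnumber them; `1SS` gives every replica the same single start.
#'
#' @param mode `"SSM"` or `"1SS"`.
#' @param n_replicas Number of ladder levels.
#' @param state_configurations List of per-state configurations (SSM), or a
#'   single configuration (1SS).
#' @return d x n_replicas matrix of starting configurations.
#' @export
start_configurations <- function(mode, n_replicas, state_configurations) {
  mode <- match.arg(mode, c("SSM", "1SS"))
  if (mode == "1SS") {
    conf <- if (is.list(state_configurations)) state_configurations[[1L]]
            else state_configurations
    return(matrix(conf, nrow = length(conf), ncol = n_replicas))
  }
  stopifnot(is.list(state_configurations), length(state_configurations) >= 1L)
  n <- length(state_configurations)
  do.call(cbind, lapply(seq_len(n_replicas), function(r) {
    state_configurations[[(r - 1L) %% n + 1L]]
  }))
}

#' @export
print.run_ledger <- function(x, ...) {
  cat("<run_ledger>", x$out_dir, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s%s\n", nm, x$stages[[nm]]$status,
                if (!is.null(x$stages[[nm]]$reason))
                  paste0(" (", x$stages[[nm]]$reason, ")") else ""))
  cat(sprintf("  %d files, %.1f s\n", length(x$files), x$wall_clock_s))
  invisible(x)
}
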