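#' Experiment configuration
#'
#' Bundles everything needed to reproduce a thermal-reconstruction
#' experiment: the system (an [integral_table()] or an FCIDUMP path),
#' ground-state mode, sampling mode, shot budgets, inverse-temperature
#' grid, repetition count and the master seed.  Per-repetition sampling
#' seeds are derived from the master seed by a counter scheme and recorded
#' in the results, so a run is fully reproducible from the configuration
#' alone.
#'
#' @param system an [integral_table()] or a path to an FCIDUMP file.
#' @param gs_mode ground-state preparation(s): subset of
#'   `c("exact", "vqe")`.
#' @param sampling `"finite"` (SIC-POVM shots) or `"infinite"` (exact
#'   expectations).
#' @param shots integer vector of shot budgets (finite sampling only).
#' @param beta inverse-temperature grid in 1/Hartree.
#' @param repetitions repetitions per (gs_mode, shots) cell.
#' @param seed master seed.
#' @param metric_tol,branch_tol,imag_tol tolerances passed to [solve_gep()].
#' @param errors per-element standard-error mode for
#'   [estimate_matrix_elements()].
#' @return an object of class `qeom_config`.
#' @export
qeom_config <- function(system,
                        gs_mode = "exact",
                        sampling = c("finite", "infinite"),
                        shots = c(1e4, 1e5, 1e6),
                        beta = c(0, 1, 2, 5, 10, 20, 40, 60, 80, 100),
                        repetitions = 100L,
                        seed = 42L,
                        metric_tol = 1e-8,
                        branch_tol = 1e-10,
                        imag_tol = 1e-6,
                        errors = "none") {
  if (is.character(system)) system <- read_fcidump(system)
  if (!inherits(system, "integral_table"))
    stop_arg("system must be an integral_table or an FCIDUMP path")
  sampling <- match.arg(sampling)
  stopifnot(all(gs_mode %in% c("exact", "vqe")), length(gs_mode) >= 1L)
  if (sampling == "finite" && (!length(shots) || any(shots < 1)))
    stop_arg("shot budgets must be positive")
  if (!length(beta)) stop_arg("beta grid must be non-empty")
  if (repetitions < 1L) stop_arg("repetitions must be at least 1")
  structure(list(system = system, gs_mode = gs_mode, sampling = sampling,
                 shots = as.integer(shots), beta = as.numeric(beta),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), metric_tol = metric_tol,
                 branch_tol = branch_tol, imag_tol = imag_tol,
                 errors = errors),
            class = "qeom_config")
}

#' @export
print.qeom_config <- function(x, ...) {
  cat(sprintf(paste0("<qeom_config: CAS(%d,%d), gs {%s}, %s sampling%s, ",
                     "%d beta points, %d reps, seed %d>\n"),
              x$system$n_electrons, x$system$n_spatial_orbitals,
              paste(x$gs_mode, collapse = ","), x$sampling,
              if (x$sampling == "finite")
                paste0(", S {", paste(x$shots, collapse = ","), "}") else "",
              length(x$beta), x$repetitions, x$seed))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys: one of `fcidump` (path), `synthetic`
#' (`orbitals`, `electrons`, `seed`) or `polyene` (`sites`); plus
#' `gs_mode`, `sampling`, `shots`, `beta` (vector, or string
#' `"from:to:n"`), `repetitions`, `seed`, `metric_tol`.
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  system <- if (!is.null(y$fcidump)) read_fcidump(y$fcidump)
    else if (!is.null(y$synthetic))
      synthesize_integrals(y$synthetic$orbitals, y$synthetic$electrons,
                           y$synthetic$seed %||% 1L)
    else if (!is.null(y$polyene)) polyene_pi_integrals(y$polyene$sites)
    else stop_arg("config must name a system (fcidump/synthetic/polyene)")
  beta <- y$beta %||% c(0, 1, 2, 5, 10, 20, 40, 60, 80, 100)
  if (is.character(beta)) {
    p <- as.numeric(strsplit(beta, ":")[[1]])
    beta <- seq(p[1], p[2], length.out = p[3])
  }
  qeom_config(system,
              gs_mode = y$gs_mode %||% "exact",
              sampling = y$sampling %||% "finite",
              shots = y$shots %||% c(1e4, 1e5, 1e6),
              beta = beta,
              repetitions = y$repetitions %||% 100L,
              seed = y$seed %||% 42L,
              metric_tol = y$metric_tol %||% 1e-8)
}

#' Run the full thermal-reconstruction experiment
#'
#' For every repetition x shot budget x ground-state mode: prepare the
#' ground state; draw one SIC-POVM sample set and estimate all EOM matrix
#' elements from it (or take exact expectations in infinite mode); solve
#' the generalized eigenvalue problem; reconstruct the excited states;
#' assemble the Gibbs ensemble from the ground state plus retained
#' solutions at every `beta`; and score it against the exact
#' particle-number-sector Gibbs state by trace distance and absolute
#' thermal-energy difference.  A degenerate GEP yields a flagged record
#' (metrics `NA`) and the run continues.
#'
#' @param config a [qeom_config()].
#' @param quiet suppress progress messages.
#' @return a tibble of class `qeom_runs`, one row per
#'   (gs_mode, shots, repetition, beta), with columns `gs_mode`,
#'   `sampling`, `shots`, `rep`, `sample_seed`, `beta`, `trace_distance`,
#'   `delta_e`, `e0_estimate`, `metric_rank`, `n_retained`, `flagged`.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  tab <- config$system
  H <- qubit_hamiltonian(tab)
  Hd <- pauli_dense(H)
  sector <- exact_eigenstates(H, tab$n_electrons)
  basis <- excitation_basis(tab$n_electrons, tab$n_spatial_orbitals)
  obs <- build_eom_observables(H, basis)
  refs <- lapply(config$beta, function(b) sector_gibbs(sector, b))
  ref_e <- vapply(refs, thermal_energy, numeric(1), H = Hd)
  ground <- list()
  for (gm in config$gs_mode) {
    ground[[gm]] <- if (gm == "exact")
      list(state = sector$states[, 1], energy = sector$energies[1])
    else {
      fit <- vqe_optimize(tab, seed = config$seed)
      list(state = fit$state, energy = fit$energy)
    }
  }
  budgets <- if (config$sampling == "finite") config$shots else NA_integer_
  reps <- if (config$sampling == "finite") config$repetitions else 1L
  rows <- list()
  counter <- 0L
  for (gm in config$gs_mode) {
    gs <- ground[[gm]]
    for (S in budgets) {
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        sseed <- config$seed + counter
        sys <- if (config$sampling == "finite") {
          smp <- sample_outcomes(gs$state, canonical_sic(), S, sseed,
                                 state_id = gm)
          estimate_matrix_elements(obs, smp, errors = config$errors)
        } else {
          evaluate_exact(obs, gs$state)
        }
        solved <- tryCatch(
          solve_gep(sys, metric_tol = config$metric_tol,
                    branch_tol = config$branch_tol,
                    imag_tol = config$imag_tol),
          error = function(e) e)
        if (inherits(solved, "error")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            gs_mode = gm, sampling = config$sampling, shots = S, rep = r,
            sample_seed = sseed, beta = config$beta,
            trace_distance = NA_real_, delta_e = NA_real_,
            e0_estimate = sys$e0, metric_rank = NA_integer_,
            n_retained = 0L, flagged = TRUE)
          if (!quiet) message("GEP degenerate; cell skipped: ",
                              conditionMessage(solved))
          next
        }
        states <- suppressMessages(
          reconstruct_excited_states(gs$state, basis, solved))
        kept <- attr(states, "kept")
        ens_energies <- c(gs$energy,
                          gs$energy + solved$excitation_energies[kept])
        ens_states <- c(list(gs$state), states)
        td <- de <- numeric(length(config$beta))
        for (bi in seq_along(config$beta)) {
          ens <- thermal_state(ens_energies, ens_states, config$beta[bi])
          td[bi] <- trace_distance(ens, refs[[bi]])
          de[bi] <- abs(thermal_energy(ens, Hd) - ref_e[bi])
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gs_mode = gm, sampling = config$sampling, shots = S, rep = r,
          sample_seed = sseed, beta = config$beta,
          trace_distance = td, delta_e = de,
          e0_estimate = sys$e0, metric_rank = solved$metric_rank,
          n_retained = length(kept), flagged = length(solved$flags) > 0L)
        if (!quiet) message(sprintf("done: gs %s, S %s, rep %d", gm,
                                    format(S), r))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qeom_runs", class(out))
  attr(out, "config") <- config
  out
}

#' Summarize repeated runs
#'
#' Per (gs_mode, sampling, shots, beta) cell: the median and the central
#' 99.7-percentile interval (0.15th to 99.85th percentile, as order
#' statistics of the repetitions) of the trace distance and the
#' thermal-energy error.  Flagged (degenerate) repetitions are excluded
#' from the statistics but counted in `n_flagged`.
#'
#' @param records a `qeom_runs` tibble from [run_experiment()].
#' @return a tibble of class `qeom_summary`.
#' @export
summarize_runs <- function(records) {
  q <- function(x, p) stats::quantile(x, p, type = 1, names = FALSE, na.rm = TRUE)
  out <- records |>
    dplyr::group_by(.data$gs_mode, .data$sampling, .data$shots, .data$beta) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_flagged = sum(.data$flagged),
      td_median = stats::median(.data$trace_distance, na.rm = TRUE),
      td_lo = q(.data$trace_distance, 0.0015),
      td_hi = q(.data$trace_distance, 0.9985),
      de_median = stats::median(.data$delta_e, na.rm = TRUE),
      de_lo = q(.data$delta_e, 0.0015),
      de_hi = q(.data$delta_e, 0.9985),
      .groups = "drop")
  class(out) <- c("qeom_summary", class(out))
  out
}

#' @rdname summarize_runs
#' @param x a `qeom_runs` tibble.
#' @param ... unused.
#' @method glance qeom_runs
#' @export
glance.qeom_runs <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_records = nrow(x),
    n_cells = nrow(dplyr::distinct(x, .data$gs_mode, .data$shots, .data$beta)),
    n_flagged = sum(x$flagged),
    seed = if (!is.null(cfg)) cfg$seed else NA_integer_)
}
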