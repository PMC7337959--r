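# Shared IO (CSV/JSON/YAML), run manifests and the end-to-end synthetic-study
# pipeline. CSV dialect: comma-separated, header required, UTF-8, '.'
# decimal; units are encoded in column names (time_s, extension_um, ...).

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read cleavage time courses from CSV
#'
#' Expects columns `replicate`, `time_s`, `sc`, `oc`, `lin`; one
#' [cleavage_time_course()] is returned per replicate label.
#'
#' @param path CSV path.
#' @param fractions Logical; `TRUE` if the abundances are fractions, `FALSE`
#'   for raw counts.
#' @return Named list of `cleavage_time_course` objects.
#' @export
read_time_course_csv <- function(path, fractions = TRUE) {
  df <- utils::read.csv(path)
  check_columns(df, c("replicate", "time_s", "sc", "oc", "lin"), path)
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_s), ]
    cleavage_time_course(d$time_s, d$sc, d$oc, d$lin,
                         replicate_id = as.character(d$replicate[1]),
                         is_fraction = fractions)
  })
}

#' Write cleavage time courses to CSV
#' @param tcs List of [cleavage_time_course()]s.
#' @param path Output CSV path.
#' @export
write_time_course_csv <- function(tcs, path) {
  if (inherits(tcs, "cleavage_time_course")) tcs <- list(tcs)
  rows <- lapply(tcs, function(tc) {
    data.frame(replicate = attr(tc, "replicate_id"), time_s = tc$time_s,
               sc = tc$sc, oc = tc$oc, lin = tc$lin)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a bead trace from CSV
#'
#' Expects columns `time_s`, `extension_um`, `magnet_turns` and optionally
#' `force_pN`.
#'
#' @param path CSV path.
#' @param trace_id Label; defaults to the file name.
#' @param sample_rate Sampling rate in Hz; inferred from the time grid when
#'   `NULL`.
#' @return A [bead_trace()].
#' @export
read_trace_csv <- function(path, trace_id = NULL, sample_rate = NULL) {
  df <- utils::read.csv(path)
  check_columns(df, c("time_s", "extension_um", "magnet_turns"), path)
  if (is.null(trace_id)) trace_id <- sub("\\.csv$", "", basename(path))
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(df$time_s))
  force <- if ("force_pN" %in% names(df)) df$force_pN[1] else 0.3
  bead_trace(df$time_s, df$extension_um, df$magnet_turns,
             trace_id = trace_id, sample_rate = sample_rate, force = force)
}

#' Write a bead trace to CSV
#' @param trace A [bead_trace()].
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              extension_um = trace$extension_um,
                              magnet_turns = trace$magnet_turns),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a rotation curve from CSV
#'
#' Expects columns `turns`, `extension_um`.
#'
#' @param path CSV path.
#' @param curve_id Label; defaults to the file name.
#' @param condition `"reference"` or `"rloop_trapped"`.
#' @param rotation_rate Turns per second.
#' @return A [rotation_curve()].
#' @export
read_rotation_curve_csv <- function(path, curve_id = NULL,
                                    condition = "reference",
                                    rotation_rate = 1) {
  df <- utils::read.csv(path)
  check_columns(df, c("turns", "extension_um"), path)
  if (is.null(curve_id)) curve_id <- sub("\\.csv$", "", basename(path))
  rotation_curve(df$turns, df$extension_um, curve_id = curve_id,
                 condition = condition, rotation_rate = rotation_rate)
}

#' Write a rotation curve to CSV
#' @param curve A [rotation_curve()].
#' @param path Output CSV path.
#' @export
write_rotation_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(turns = curve$magnet_turns,
                              extension_um = curve$extension_um),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an emission spectrum from CSV
#'
#' Expects columns `wavelength_nm`, `intensity`.
#'
#' @param path CSV path.
#' @param excitation_nm Excitation wavelength of the scan.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path, excitation_nm) {
  df <- utils::read.csv(path)
  check_columns(df, c("wavelength_nm", "intensity"), path)
  emission_spectrum(df$wavelength_nm, df$intensity, excitation_nm)
}

#' Write detected dwell events to CSV
#' @param events Event data frame from [detect_rloop_events()].
#' @param path Output CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read dwell events from CSV
#' @param path CSV path written by [write_events_csv()].
#' @return Event data frame.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("trace_id", "kind", "dwell_s", "censored"), path)
  df
}

#' Read a rotation protocol from a YAML or JSON file
#'
#' Expects fields `target_turns`, `hold` and optionally `rate`,
#' `start_turns`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [rotation_protocol()].
#' @export
read_protocol <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$target_turns) || is.null(cfg$hold)) {
    stop(path, ": protocol needs target_turns and hold")
  }
  rotation_protocol(unlist(cfg$target_turns), unlist(cfg$hold),
                    rate = cfg$rate %||% 10,
                    start_turns = cfg$start_turns %||% 0)
}

# deterministic fingerprint of a configuration list (FNV-1a over the
# deparsed structure); for provenance only, not cryptographic
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build a run manifest
#'
#' Provenance record embedded in every pipeline report: command, a
#' deterministic configuration fingerprint, seeds, paths, package version
#' and timestamp. Two runs with the same manifest (seeds included)
#' reproduce identical numeric outputs.
#'
#' @param command Command or stage name.
#' @param config Configuration list.
#' @param seed Integer seed(s).
#' @param inputs,outputs Character vectors of paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed, inputs = character(),
                         outputs = character()) {
  structure(list(command = command, config_hash = config_hash(config),
                 seed = seed, inputs = inputs, outputs = outputs,
                 package_version = as.character(utils::packageVersion("rloopkin")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' Run the end-to-end synthetic study pipeline
#'
#' Chains simulate -> analyze -> fit -> report for the requested stages,
#' generating synthetic data with ground-truth sidecars and analysing them
#' with the package's own estimators. Stages: `"cleavage"` (simulate
#' replicate cleavage time courses, fit, average), `"dwells"` (simulate
#' cycling traces, detect events, fit dwell survival), `"rloopsize"`
#' (simulate reference and trapped rotation curves, pairwise sizing,
#' turns-to-bp), `"fret"` (simulate spectra at two FRET efficiencies,
#' compute ratio_A). All randomness derives from `config$seed`.
#'
#' @param config Nested configuration list, or path to a YAML/JSON file.
#'   Top-level fields: `seed` (default 1), `stages` (character vector,
#'   possibly empty), and optional per-stage parameter blocks `cleavage`
#'   (`n_replicates`, `variant`, `rates`, `counts_per_lane`, `times`),
#'   `dwells` (`n_cycles`, `formation`, `dissociation`), `rloopsize`
#'   (`n_reference`, `n_rloop`, `trapped_turns`, `fulllength_bp`),
#'   `fret` (`efficiency_high`, `efficiency_low`).
#' @param out_dir Optional directory; when given, per-stage CSVs and a
#'   consolidated JSON report are written there.
#' @return List of class `rloop_report` with `manifest` plus one element per
#'   executed stage, each carrying both estimates and generator truth.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- as.integer(config$seed %||% 1)
  stages <- config$stages %||% character()
  known <- c("cleavage", "dwells", "rloopsize", "fret")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(manifest = run_manifest("run", config, seed,
                                         outputs = out_dir %||% character()))
  if ("cleavage" %in% stages) {
    report$cleavage <- pipeline_cleavage(config, seed, out_dir)
  }
  if ("dwells" %in% stages) {
    report$dwells <- pipeline_dwells(config, seed, out_dir)
  }
  if ("rloopsize" %in% stages) {
    report$rloopsize <- pipeline_rloopsize(config, seed, out_dir)
  }
  if ("fret" %in% stages) {
    report$fret <- pipeline_fret(config, seed, out_dir)
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "rloop_report")
}

pipeline_cleavage <- function(config, seed, out_dir) {
  p <- config$cleavage %||% list()
  n_rep <- p$n_replicates %||% 3
  cl <- list()
  for (f in c("variant", "rates", "counts_per_lane", "times")) {
    if (!is.null(p[[f]])) cl[[f]] <- if (f == "rates") unlist(p[[f]]) else
      p[[f]]
  }
  scfg <- synth_config(seed = seed, cleavage = cl)
  sims <- lapply(seq_len(n_rep), function(i) {
    gen_time_course(scfg, replicate_id = paste0("rep", i), seed_offset = i)
  })
  spec <- kinetic_model_spec(scfg$cleavage$variant)
  fits <- lapply(sims, function(s) fit_time_course(s$time_course, spec))
  avg <- average_fits(fits)
  if (!is.null(out_dir)) {
    write_time_course_csv(lapply(sims, `[[`, "time_course"),
                          file.path(out_dir, "cleavage_time_courses.csv"))
  }
  list(averaged = avg$averaged, n_converged = avg$n_converged,
       truth = as.list(scfg$cleavage$rates), variant = scfg$cleavage$variant)
}

pipeline_dwells <- function(config, seed, out_dir) {
  p <- config$dwells %||% list()
  n_cycles <- p$n_cycles %||% 40
  dw <- list()
  if (!is.null(p$formation)) dw$formation <- p$formation
  if (!is.null(p$dissociation)) dw$dissociation <- p$dissociation
  scfg <- synth_config(seed = seed, dwell = dw)
  sim <- gen_bead_trace(scfg, n_cycles = n_cycles, seed_offset = 101)
  sm <- smooth_trace(sim$trace)
  step_um <- scfg$trace$rloop_turns * scfg$trace$um_per_turn
  events <- detect_rloop_events(sm, sim$protocol, expected_step = step_um,
                                um_per_turn = scfg$trace$um_per_turn)
  fits <- lapply(c("formation", "dissociation"), function(kind) {
    d <- events$dwell_s[events$kind == kind & !events$censored]
    if (length(d) < 10) return(NULL)
    curve <- survival_curve(d)
    f1 <- fit_exponential(curve, 1)
    f <- if (length(d) >= 19) {
      f2 <- try(fit_exponential(curve, 2), silent = TRUE)
      if (inherits(f2, "try-error")) f1 else select_model(f1, f2)
    } else f1
    list(kind = kind, n = f$n, n_components = f$n_components,
         tau = as.list(f$tau), slow_fraction = f$slow_fraction,
         mean_dwell = f$mean_dwell)
  })
  fits <- Filter(Negate(is.null), fits)
  names(fits) <- vapply(fits, `[[`, character(1), "kind")
  if (!is.null(out_dir)) {
    write_events_csv(events, file.path(out_dir, "dwell_events.csv"))
  }
  list(fits = fits, n_events = nrow(events),
       truth = scfg$dwell, truth_events = sim$truth)
}

pipeline_rloopsize <- function(config, seed, out_dir) {
  p <- config$rloopsize %||% list()
  n_ref <- p$n_reference %||% 20
  n_rl <- p$n_rloop %||% 22
  trapped <- p$trapped_turns %||% 1.9
  fulllength_bp <- p$fulllength_bp %||% 20
  scfg <- synth_config(seed = seed)
  full_turns <- scfg$trace$full_rloop_turns
  refs <- gen_rotation_curve_set(scfg, n_ref, 0, "ref", seed_offset = 200)
  rls <- gen_rotation_curve_set(scfg, n_rl, trapped, "rloop",
                                seed_offset = 300)
  est <- aggregate_shifts(refs, rls)
  # independent full-length condition sets the turns-per-bp calibration,
  # mirroring calibration against conditions with complete R-loops
  cal_curves <- gen_rotation_curve_set(scfg, n_rl, full_turns, "cal",
                                       seed_offset = 400)
  cal_est <- aggregate_shifts(refs, cal_curves)
  est <- turns_to_bp(est, fulllength_estimates = cal_est$mean_turns,
                     fulllength_bp = fulllength_bp,
                     calibration_set = "full_length_synthetic")
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(shift_turns = est$pairwise_shifts),
                     file.path(out_dir, "pairwise_shifts.csv"),
                     row.names = FALSE)
  }
  list(mean_turns = est$mean_turns, sd_turns = est$sd_turns,
       n_pairs = est$n_pairs, bp = est$bp,
       calibration_mean_turns = cal_est$mean_turns,
       truth_trapped_turns = trapped)
}

pipeline_fret <- function(config, seed, out_dir) {
  p <- config$fret %||% list()
  e_hi <- p$efficiency_high %||% 0.8
  e_lo <- p$efficiency_low %||% 0.2
  scfg <- synth_config(seed = seed)
  hi <- gen_spectra(scfg, fret_efficiency = e_hi, seed_offset = 401)
  lo <- gen_spectra(scfg, fret_efficiency = e_lo, seed_offset = 402)
  r_hi <- ratio_a(hi$ex530, hi$ex630, donor_only = hi$donor_only)
  r_lo <- ratio_a(lo$ex530, lo$ex630, donor_only = lo$donor_only)
  list(ratio_a_high = r_hi$value, ratio_a_low = r_lo$value,
       truth = list(efficiency_high = e_hi, efficiency_low = e_lo))
}

report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(report)
}

#' @export
print.rloop_report <- function(x, ...) {
  stages <- setdiff(names(x), "manifest")
  cat(sprintf("<rloop_report> %s stages: %s\n",
              length(stages), paste(stages, collapse = ", ")))
  if ("cleavage" %in% stages) {
    cat("  cleavage:\n"); print(x$cleavage$averaged, row.names = FALSE)
  }
  if ("dwells" %in% stages) {
    for (f in x$dwells$fits) {
      cat(sprintf("  %s dwells: %d-component fit, mean %.3g s (N = %d)\n",
                  f$kind, f$n_components, f$mean_dwell, f$n))
    }
  }
  if ("rloopsize" %in% stages) {
    cat(sprintf("  R-loop size: %.3g +/- %.2g turns -> %.3g bp (%d pairs)\n",
                x$rloopsize$mean_turns, x$rloopsize$sd_turns, x$rloopsize$bp,
                x$rloopsize$n_pairs))
  }
  if ("fret" %in% stages) {
    cat(sprintf("  ratio_A: high-FRET %.3f, low-FRET %.3f\n",
                x$fret$ratio_a_high, x$fret$ratio_a_low))
  }
  invisible(x)
}
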