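#' Write a sweep to plain-text files
#'
#' One TSV per sweep (columns `time_s`, `voltage_mV`, `current_pA`) plus a
#' sidecar `<path>.meta` file in DCF (key: value) format carrying the
#' condition, blocker concentration, seed and protocol, so a sweep
#' round-trips losslessly through text.
#'
#' @param sweep A `sweep` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep"))
  p <- sweep$protocol
  d <- data.frame(
    time_s = (seq_along(sweep$current_pA) - 1) / p$sample_rate_Hz,
    voltage_mV = protocol_voltage(p),
    current_pA = sweep$current_pA)
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    condition = sweep$condition,
    blocker_mM = sweep$blocker_mM,
    seed = sweep$seed,
    kind = p$kind,
    hold_voltage_mV = p$hold_voltage_mV,
    ramp_start_mV = p$ramp_start_mV,
    ramp_end_mV = p$ramp_end_mV,
    duration_s = p$duration_s,
    sample_rate_Hz = p$sample_rate_Hz,
    filter_cutoff_Hz = p$filter_cutoff_Hz)
  write.dcf(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a sweep written by [write_sweep()]
#'
#' @param path TSV path (with its `.meta` sidecar alongside).
#' @return A `sweep` object.
#' @export
read_sweep <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop(sprintf("sweep file or metadata missing for '%s'", path))
  }
  m <- as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE)
  num <- function(k) as.numeric(m[[k]][1])
  protocol <- voltage_protocol(kind = m$kind[1],
                               hold_voltage_mV = num("hold_voltage_mV"),
                               ramp_start_mV = num("ramp_start_mV"),
                               ramp_end_mV = num("ramp_end_mV"),
                               duration_s = num("duration_s"),
                               sample_rate_Hz = num("sample_rate_Hz"),
                               filter_cutoff_Hz = num("filter_cutoff_Hz"))
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "numeric"),
    error = function(e) stop(sprintf("corrupted sweep file '%s': %s",
                                     path, conditionMessage(e))))
  if (nrow(d) != protocol$n_samples) {
    stop(sprintf("sweep file '%s': %d rows but protocol expects %d",
                 path, nrow(d), protocol$n_samples))
  }
  structure(list(current_pA = d$current_pA,
                 protocol = protocol,
                 condition = m$condition[1],
                 blocker_mM = num("blocker_mM"),
                 seed = num("seed")),
            class = "sweep")
}

#' Write a sweep ensemble with controls and a manifest
#'
#' Simulates `n_sweeps` single-channel sweeps plus paired control sweeps
#' (channel closed throughout) from one fixture, writes each as TSV + sidecar
#' under `dir`, and writes `manifest.tsv` listing sweep/control pairings.
#' Controls are paired "closest in time": control k is the no-opening sweep
#' generated adjacent to sweep k.
#'
#' @param fixture A [gating_fixture()] or registry name.
#' @param protocol A [voltage_protocol()].
#' @param n_sweeps Number of experimental sweeps.
#' @param seed Base seed; sweep k uses `seed + 2k`, its control `seed + 2k + 1`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_sweepset <- function(fixture, protocol, n_sweeps, seed, dir) {
  if (is.character(fixture)) fixture <- fixture_registry(fixture)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n_sweeps), function(k) {
    sw <- simulate_sweep(fixture, protocol, seed + 2L * k)
    ct <- make_control_sweep(fixture, protocol, seed + 2L * k + 1L)
    sf <- sprintf("sweep_%04d.tsv", k)
    cf <- sprintf("control_%04d.tsv", k)
    write_sweep(sw, file.path(dir, sf))
    write_sweep(ct, file.path(dir, cf))
    data.frame(sweep_file = sf, control_file = cf,
               condition = fixture$name, seed = seed + 2L * k)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read a sweep ensemble from a manifest
#'
#' @param manifest_path Path to a `manifest.tsv` written by
#'   [write_sweepset()]. Rows whose control file is missing are dropped with
#'   a warning (an orphan sweep cannot be leak-subtracted).
#' @return List with `sweeps` and `controls` (parallel lists of `sweep`
#'   objects) and the `manifest` data frame of retained rows.
#' @export
read_sweepset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest '%s' does not exist", manifest_path))
  }
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(man) == 0) {
    return(list(sweeps = list(), controls = list(), manifest = man))
  }
  dir <- dirname(manifest_path)
  ok <- file.exists(file.path(dir, man$control_file))
  if (any(!ok)) {
    warning(sprintf("%d sweep(s) without a control; excluded", sum(!ok)))
    man <- man[ok, , drop = FALSE]
  }
  sweeps <- lapply(file.path(dir, man$sweep_file), read_sweep)
  controls <- lapply(file.path(dir, man$control_file), read_sweep)
  list(sweeps = sweeps, controls = controls, manifest = man)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param fixtures Character vector of gating-fixture registry names.
#' @param n_sweeps Sweeps per fixture.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param protocol A [voltage_protocol()] for the single-channel stage.
#' @param threshold_pA Event/noise threshold (pA).
#' @param bin_mV I-V bin width (mV).
#' @param leak_threshold Permeance threshold for the pore-sizing stage.
#' @param block_concentrations_mM Blocker concentrations for the block stage.
#' @param block_noise_fraction CV of the block-stage multiplicative noise.
#' @param stages Subset of
#'   `c("simulate", "events", "iv", "block", "surfpot", "poresize")`.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(fixtures = c("WT-150", "E920A-150"),
                       n_sweeps = 50, seed = 1,
                       protocol = ramp_protocol(),
                       threshold_pA = 3, bin_mV = 5,
                       leak_threshold = 0.02,
                       block_concentrations_mM = c(0.3, 1, 3, 10, 30),
                       block_noise_fraction = 0.02,
                       stages = c("simulate", "events", "iv", "block",
                                  "surfpot", "poresize"),
                       out_dir = tempfile("trpa1pore_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (f in fixtures) fixture_registry(f)   # fail fast on unknown names
  structure(list(fixtures = fixtures, n_sweeps = n_sweeps, seed = seed,
                 protocol = protocol, threshold_pA = threshold_pA,
                 bin_mV = bin_mV, leak_threshold = leak_threshold,
                 block_concentrations_mM = block_concentrations_mM,
                 block_noise_fraction = block_noise_fraction,
                 stages = stages, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[setdiff(names(config), "out_dir")], file = tf)
  unname(tools::md5sum(tf))
}

write_stage_table <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order -- simulate, event
#' detection/amplitude histograms, averaged I-V + slope conductances, block
#' fitting, surface potentials, pore sizing -- writing each stage's table
#' under `config$out_dir` (every table carries the config hash in a header
#' comment). Identical configs reproduce identical deterministic outputs.
#'
#' @param config A [run_config()].
#' @return An object of class `results_bundle`: list of per-stage results
#'   plus `provenance` (config hash, package version, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ensembles <- NULL
  if ("simulate" %in% config$stages) {
    ensembles <- stage("simulate", {
      out <- list()
      for (j in seq_along(config$fixtures)) {
        fx <- config$fixtures[j]
        dir <- file.path(config$out_dir, "sweeps", fx)
        write_sweepset(fx, config$protocol, config$n_sweeps,
                       seed = config$seed + 10000L * j, dir = dir)
        out[[fx]] <- read_sweepset(file.path(dir, "manifest.tsv"))
      }
      out
    })
    res$sweeps <- lapply(ensembles, function(e) nrow(e$manifest))
  }
  if ("events" %in% config$stages) {
    res$events <- stage("events", {
      if (is.null(ensembles)) stop("'events' requires the 'simulate' stage")
      tabs <- lapply(names(ensembles), function(fx) {
        e <- ensembles[[fx]]
        evs <- do.call(rbind, lapply(seq_along(e$sweeps), function(k) {
          ev <- detect_events(subtract_leak(e$sweeps[[k]], e$controls[[k]]),
                              threshold_pA = config$threshold_pA)
          if (nrow(ev)) ev$sweep <- k
          ev
        }))
        evs$condition <- if (nrow(evs)) fx else character(0)
        evs
      })
      all_ev <- do.call(rbind, tabs)
      write_stage_table(all_ev, file.path(config$out_dir, "events.tsv"), hash)
      all_ev
    })
  }
  if ("iv" %in% config$stages) {
    res$iv <- stage("iv", {
      if (is.null(ensembles)) stop("'iv' requires the 'simulate' stage")
      if (config$protocol$kind != "ramp") stop("'iv' requires a ramp protocol")
      out <- lapply(names(ensembles), function(fx) {
        e <- ensembles[[fx]]
        iv <- average_open_iv(e$sweeps, e$controls,
                              threshold_pA = config$threshold_pA,
                              bin_mV = config$bin_mV)
        iv$condition <- fx
        iv
      })
      names(out) <- names(ensembles)
      write_stage_table(do.call(rbind, out),
                        file.path(config$out_dir, "iv.tsv"), hash)
      lapply(out, slope_conductance)
    })
  }
  if ("block" %in% config$stages) {
    res$block <- stage("block", {
      truth <- fixture_registry("Ba-WT")
      ds <- simulate_block_dataset(truth, 5000,
                                   config$block_concentrations_mM,
                                   noise_fraction = config$block_noise_fraction,
                                   seed = config$seed + 777L)
      fit <- fit_block_model(ds, z = truth$z)
      write_stage_table(
        data.frame(parameter = c("K_out_mM", "K_through_mM", "delta",
                                 "hill_n", "KD0_mM"),
                   estimate = c(fit$params$K_out_mM, fit$params$K_through_mM,
                                fit$params$delta, fit$params$hill_n,
                                fit$KD0_mM),
                   se = c(fit$se, fit$KD0_se_mM)),
        file.path(config$out_dir, "block_fit.tsv"), hash)
      fit
    })
  }
  if ("surfpot" %in% config$stages) {
    res$surfpot <- stage("surfpot", {
      dphi_g <- delta_phi_from_conductance_ratio(0.54, 1, z = 1)
      dphi_kd <- delta_phi_from_kd_ratio(3, 1, z = 2)
      four <- debye_huckel_potential(
        charge_geometry(z = rep(-1, 4), r_A = rep(11, 4)))
      d <- data.frame(
        quantity = c("delta_phi_conductance_mV", "delta_phi_kd_ratio_mV",
                     "four_charge_potential_mV", "debye_length_150mM_A"),
        value = c(dphi_g, dphi_kd, four, debye_length(150)))
      write_stage_table(d, file.path(config$out_dir, "surfpot.tsv"), hash)
      d
    })
  }
  if ("poresize" %in% config$stages) {
    res$poresize <- stage("poresize", {
      specs <- cation_panel_specs()
      diam <- vapply(specs, cation_diameter, numeric(1))
      names(diam) <- names(specs)
      pt <- classify_permeation(wt_panel_currents(),
                                leak_threshold = config$leak_threshold)
      cut <- estimate_cutoff(pt, diam)
      d <- data.frame(name = pt$name, diameter_A = diam[pt$name],
                      relative_current = pt$relative_current,
                      blocker = pt$blocker,
                      classification = pt$classification)
      write_stage_table(d, file.path(config$out_dir, "poresize.tsv"), hash)
      list(table = d, cutoff = cut)
    })
  }
  structure(list(results = res,
                 provenance = list(
                   config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("trpa1pore")),
                   seed = config$seed)),
            class = "results_bundle")
}
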