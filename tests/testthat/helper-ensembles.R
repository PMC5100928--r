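# shared simulation helpers and independent oracles

# simulate paired sweep/control ensembles from a fixture
make_ensemble <- function(fixture, protocol, n, base_seed,
                          large_only = FALSE) {
  if (is.character(fixture)) fixture <- fixture_registry(fixture)
  if (large_only) fixture <- only_large_openings(fixture)
  list(
    sweeps = lapply(seq_len(n), function(k) {
      simulate_sweep(fixture, protocol, seed = base_seed + 2L * k)
    }),
    controls = lapply(seq_len(n), function(k) {
      make_control_sweep(fixture, protocol, seed = base_seed + 2L * k + 1L)
    })
  )
}

# pool detected events over an ensemble of leak-subtracted sweeps
pool_events <- function(ens, threshold_pA = 3) {
  do.call(rbind, lapply(seq_along(ens$sweeps), function(k) {
    detect_events(subtract_leak(ens$sweeps[[k]], ens$controls[[k]]),
                  threshold_pA = threshold_pA)
  }))
}

# pool per-point open-channel amplitudes over an ensemble
pool_points <- function(ens, threshold_pA = 3) {
  unlist(lapply(seq_along(ens$sweeps), function(k) {
    corr <- subtract_leak(ens$sweeps[[k]], ens$controls[[k]])
    open_point_amplitudes(corr, detect_events(corr,
                                              threshold_pA = threshold_pA))
  }), use.names = FALSE)
}

# brute-force per-sample event scan: the oracle detect_events must match
brute_force_events <- function(x, threshold_pA, min_n) {
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE; s <- 0L
  for (i in seq_along(x)) {
    if (abs(x[i]) >= threshold_pA) {
      if (!in_run) { in_run <- TRUE; s <- i }
    } else if (in_run) {
      if (i - s >= min_n) { starts <- c(starts, s); ends <- c(ends, i - 1L) }
      in_run <- FALSE
    }
  }
  if (in_run && length(x) - s + 1L >= min_n) {
    starts <- c(starts, s); ends <- c(ends, length(x))
  }
  data.frame(start = starts, end = ends,
             amplitude_pA = vapply(seq_along(starts), function(j) {
               mean(x[starts[j]:ends[j]])
             }, numeric(1)))
}

# exhaustive grid search over block-model parameters: the oracle
# fit_block_model must beat or match on noiseless data
grid_search_block <- function(dataset, z, K_grid, delta_grid, n_grid) {
  v_norm <- attr(dataset, "normalization_voltage_mV")
  best <- list(sse = Inf)
  for (ko in K_grid) for (kt in K_grid) {
    for (dl in delta_grid) for (hn in n_grid) {
      p <- block_model_params(ko, kt, dl, z = z, hill_n = hn)
      pred <- trpa1pore:::predict_norm_curve(p, dataset$concentration_mM,
                                             dataset$voltage_mV, v_norm, 0)
      sse <- sum((dataset$norm_current - pred)^2)
      if (sse < best$sse) {
        best <- list(sse = sse, K_out = ko, K_through = kt,
                     delta = dl, hill_n = hn)
      }
    }
  }
  best
}
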