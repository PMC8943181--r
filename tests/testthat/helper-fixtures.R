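# Shared fixtures: tiny series, configs and hand-built summaries.

# Constant-concentration series with the standard four-segment protocol.
constant_series <- function(values, duration = 30, op_id = "const") {
  nm <- names(values)
  t <- seq(0, 90 + duration - 1)
  conc <- matrix(rep(values, each = length(t)), length(t),
                 length(values), dimnames = list(NULL, nm))
  ion_series(op_id, t, conc,
             list(blank_pre = c(0, 30), calib = c(30, 60),
                  operation = c(60, 60 + duration),
                  blank_post = c(60 + duration, 90 + duration)))
}

# Two-compound simulator config with controllable noise.
tiny_config <- function(emission = c(A = 30, B = 10), sd_frac = 1,
                        noise = 0.5, ...) {
  sim_config(emission_mean_ppb = emission,
             emission_sd_ppb = sd_frac * emission,
             noise_sd_ppb = noise, ...)
}

tiny_design <- function(op_id = "op1", duration = 120, ...) {
  operation_design(op_id, duration = duration, ...)
}

# Build an operation_summary directly (for stats-module tests where the
# response values, not the raw series, are under control).
make_summary <- function(op_id, ses = "without_ses", approach = "open",
                         location = "surgeon_level", response = 100,
                         argmax_fractions = NULL, max_ppb = NULL) {
  if (is.null(argmax_fractions)) argmax_fractions <- 0.5
  nch <- length(argmax_fractions)
  if (is.null(max_ppb)) max_ppb <- rep(1, nch)
  structure(list(
    op_id = op_id,
    design = operation_design(op_id, approach = approach, ses = ses,
                              location = location, duration = 600),
    channel_stats = data.frame(channel = paste0("ch", seq_len(nch)),
                               mean_ppb = rep(response, nch),
                               max_ppb = max_ppb,
                               argmax_time_fraction = argmax_fractions,
                               stringsAsFactors = FALSE),
    total_voc_mean_ppb = response,
    total_voc_max_ppb = max(max_ppb),
    harmful_total_mean_ppb = response,
    harmful_total_max_ppb = max(max_ppb)
  ), class = "operation_summary")
}

# Simulate n operations with randomized SES and summarize them (no blank /
# calibration processing; the raw simulated record is summarized).
simulate_study <- function(n, config, duration = 120, seed = 1,
                           registry = NULL) {
  ses <- randomize_operations(n, 4, seed = seed)
  lapply(seq_len(n), function(i) {
    d <- operation_design(sprintf("op%02d", i),
                          approach = if (i %% 2 == 1) "open" else "minimally_invasive",
                          ses = ses[i],
                          location = if (i %% 4 %in% c(1, 2)) "surgeon_level"
                                     else "room_air",
                          duration = duration)
    sim <- simulate_operation(d, config, seed = seed * 10000 + i)
    summarize_operation(sim$series, d, registry)
  })
}
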