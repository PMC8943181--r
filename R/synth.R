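# Synthetic operating-room air: blocked randomization, cautery-plume
# concentration series with known ground truth, paired breath series.

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe one operation's design and measurement protocol
#'
#' Records the randomized and observational factors of one operation —
#' smoke-evacuation-system (SES) use, surgical approach, measurement
#' location — together with the operation duration and the instrument
#' protocol windows (pre-operation blank, standard-gas calibration, closing
#' blank), as half-open `[start, end)` windows in seconds from record start.
#'
#' Defaults follow the measurement protocol of a 1-min blank and 1-min
#' calibration before the operation: blank `[0, 60)`, calibration
#' `[60, 120)`, operation `[120, 120 + duration)`, closing blank of 90 s.
#'
#' @param op_id Operation identifier.
#' @param approach `"open"` or `"minimally_invasive"`.
#' @param ses `"with_ses"` or `"without_ses"`.
#' @param location `"surgeon_level"` or `"room_air"`.
#' @param duration Operation length in seconds (> 0).
#' @param blank_pre_window,calib_window,blank_post_window Optional
#'   `c(start, end)` windows (seconds); defaults derived from `duration`.
#' @return An `operation_design` list.
#' @export
operation_design <- function(op_id, approach = c("open", "minimally_invasive"),
                             ses = c("without_ses", "with_ses"),
                             location = c("surgeon_level", "room_air"),
                             duration = 3600,
                             blank_pre_window = c(0, 60),
                             calib_window = c(60, 120),
                             blank_post_window = NULL) {
  approach <- match.arg(approach)
  ses <- match.arg(ses)
  location <- match.arg(location)
  if (!is.numeric(duration) || duration <= 0) {
    stop("parameter error: duration must be > 0")
  }
  op_start <- calib_window[2]
  if (is.null(blank_post_window)) {
    blank_post_window <- c(op_start + duration, op_start + duration + 90)
  }
  d <- structure(list(op_id = as.character(op_id), approach = approach,
                      ses = ses, location = location, duration = duration,
                      blank_pre_window = as.numeric(blank_pre_window),
                      calib_window = as.numeric(calib_window),
                      blank_post_window = as.numeric(blank_post_window)),
                 class = "operation_design")
  wins <- design_segments(d)
  ends <- vapply(wins, `[`, 0, 2)
  starts <- vapply(wins, `[`, 0, 1)
  ord <- c("blank_pre", "calib", "operation", "blank_post")
  if (any(starts[ord][-1] < ends[ord][-length(ord)])) {
    stop("parameter error: protocol windows must be disjoint and ordered ",
         "blank_pre, calib, operation, blank_post")
  }
  d
}

# Segment list (for ion_series) implied by a design.
design_segments <- function(design) {
  op_start <- design$calib_window[2]
  list(blank_pre = design$blank_pre_window,
       calib = design$calib_window,
       operation = c(op_start, op_start + design$duration),
       blank_post = design$blank_post_window)
}

#' Simulator configuration for synthetic OR air
#'
#' Parameters of the generative model used for synthetic operations: cautery
#' activations arrive as a homogeneous Poisson process during the operation;
#' each activation releases, per compound, a log-normally distributed
#' concentration amplitude that decays exponentially with the first-order
#' ventilation clearance constant `ventilation_rate_k` (laminar-flow OR air
#' exchange, no spatial modelling). SES use, measurement in room air, and
#' open (vs minimally invasive) approach act multiplicatively on emission
#' amplitudes. An anesthetic-gas/ambient background adds per-compound
#' constant offsets; instrument noise is Gaussian; the instrument's true
#' sensitivity (`calib_true_factor`, measured/true) scales the whole record
#' and is what single-point calibration must undo.
#'
#' @param emission_mean_ppb Named numeric vector: expected per-event amplitude
#'   (ppb) per compound; names define the channels.
#' @param emission_sd_ppb Per-event amplitude standard deviation(s); default
#'   twice the mean (heavy-tailed maxima).
#' @param event_rate Cautery activations per minute.
#' @param ventilation_rate_k First-order clearance constant, 1/s.
#' @param ses_attenuation Multiplicative emission factor in \\[0, 1\\] applied
#'   when `ses = "with_ses"`.
#' @param room_dilution Multiplicative factor in \\[0, 1\\] applied when
#'   `location = "room_air"`.
#' @param open_vs_mis_factor Multiplicative factor applied when
#'   `approach = "open"`.
#' @param background_ppb Per-compound constant background (scalar recycled).
#' @param noise_sd_ppb Gaussian instrument noise standard deviation.
#' @param calib_true_factor Instrument sensitivity (measured/true) per
#'   compound (scalar recycled).
#' @param calib_standard_ppb True concentration of the calibration standard
#'   per compound (scalar recycled).
#' @param sample_period Sampling interval in seconds (instrument runs at 1 Hz).
#' @param seed Default seed carried in the config (may be overridden per call).
#' @return A `sim_config` list.
#' @export
sim_config <- function(emission_mean_ppb,
                       emission_sd_ppb = 2 * emission_mean_ppb,
                       event_rate = 2,
                       ventilation_rate_k = 0.02,
                       ses_attenuation = 0.5,
                       room_dilution = 0.5,
                       open_vs_mis_factor = 1.3,
                       background_ppb = 0,
                       noise_sd_ppb = 0.5,
                       calib_true_factor = 1,
                       calib_standard_ppb = 100,
                       sample_period = 1,
                       seed = NULL) {
  if (is.null(names(emission_mean_ppb)) ||
      any(!nzchar(names(emission_mean_ppb)))) {
    stop("parameter error: emission_mean_ppb must be a named vector")
  }
  nm <- names(emission_mean_ppb)
  expand <- function(x) {
    x <- if (length(x) == 1) rep(x, length(nm)) else x
    if (length(x) != length(nm)) {
      stop("parameter error: per-compound parameter of wrong length")
    }
    stats::setNames(as.numeric(x), nm)
  }
  cfg <- list(compounds = nm,
              emission_mean_ppb = expand(emission_mean_ppb),
              emission_sd_ppb = expand(emission_sd_ppb),
              event_rate = event_rate,
              ventilation_rate_k = ventilation_rate_k,
              ses_attenuation = ses_attenuation,
              room_dilution = room_dilution,
              open_vs_mis_factor = open_vs_mis_factor,
              background_ppb = expand(background_ppb),
              noise_sd_ppb = noise_sd_ppb,
              calib_true_factor = expand(calib_true_factor),
              calib_standard_ppb = expand(calib_standard_ppb),
              sample_period = sample_period,
              seed = seed)
  with(cfg, {
    if (event_rate < 0 || ventilation_rate_k < 0 || noise_sd_ppb < 0 ||
        any(emission_mean_ppb < 0) || any(emission_sd_ppb < 0) ||
        any(background_ppb < 0) || open_vs_mis_factor < 0) {
      stop("parameter error: rates, factors and amplitudes must be >= 0")
    }
    if (ses_attenuation < 0 || ses_attenuation > 1 ||
        room_dilution < 0 || room_dilution > 1) {
      stop("parameter error: ses_attenuation and room_dilution must be in [0, 1]")
    }
    if (sample_period <= 0) stop("parameter error: sample_period must be > 0")
  })
  structure(cfg, class = "sim_config")
}

#' Simulator configuration anchored to a compound registry
#'
#' Builds a [sim_config()] whose channels are the registry compounds and
#' whose per-event emission amplitudes are chosen so that the model's
#' stationary operation-segment mean (at surgeon level, open approach scaled
#' out, no SES) approximates each compound's panel average concentration.
#' The anesthetic carrier gases sevoflurane and desflurane are modelled as
#' constant background rather than cautery emissions.
#'
#' @param registry A `compound_table`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_from_registry <- function(registry, ...) {
  stopifnot(inherits(registry, "compound_table"))
  args <- list(...)
  event_rate <- if (!is.null(args$event_rate)) args$event_rate else 2
  k <- if (!is.null(args$ventilation_rate_k)) args$ventilation_rate_k else 0.02
  bg <- stats::setNames(rep(0, nrow(registry)), registry$name)
  anesthetic <- c("Sevoflurane", "Desflurane")
  bg[intersect(anesthetic, registry$name)] <-
    registry$avg_ppb_paper[match(intersect(anesthetic, registry$name),
                                 registry$name)]
  # stationary mean of the plume model is rate * E[A] / k above background
  target <- pmax(registry$avg_ppb_paper - bg, 0)
  emission <- stats::setNames(target * k / (event_rate / 60), registry$name)
  defaults <- list(emission_mean_ppb = emission, background_ppb = bg)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Blocked 1:1 randomization of SES use
#'
#' Permuted-block randomization: within every complete block of
#' `block_size` consecutive operations, exactly half are assigned
#' `"with_ses"` and half `"without_ses"`, in random order.
#'
#' @param n Number of operations (>= 0).
#' @param block_size Block length; must be even (default 4).
#' @param seed Optional RNG seed for a reproducible sequence.
#' @return Character vector of length `n` with values `"with_ses"` /
#'   `"without_ses"`.
#' @export
randomize_operations <- function(n, block_size = 4, seed = NULL) {
  if (n < 0) stop("parameter error: n must be >= 0")
  if (block_size <= 0 || block_size %% 2 != 0) {
    stop("parameter error: block_size must be a positive even number")
  }
  if (n == 0) return(character(0))
  with_seed(seed, {
    n_blocks <- ceiling(n / block_size)
    out <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(c("with_ses", "without_ses"), block_size / 2))
    }))
    out[seq_len(n)]
  })
}

# Design-dependent multiplicative emission factor.
design_factor <- function(design, config) {
  f <- 1
  if (design$ses == "with_ses") f <- f * config$ses_attenuation
  if (design$location == "room_air") f <- f * config$room_dilution
  if (design$approach == "open") f <- f * config$open_vs_mis_factor
  f
}

# Log-normal parameters from mean m > 0 and sd s >= 0.
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Noiseless plume matrix (n_t x n_compounds) at absolute times t for events
# at ev_times with amplitude matrix amps (n_events x n_compounds).
plume_signal <- function(t, ev_times, amps, k) {
  if (length(ev_times) == 0) {
    return(matrix(0, length(t), ncol(amps)))
  }
  dt <- outer(t, ev_times, "-")
  decay <- ifelse(dt >= 0, exp(-k * dt), 0)
  decay %*% amps
}

#' Simulate one operation's concentration record
#'
#' Generates a measured `ion_ts` for the given design under the plume model
#' of [sim_config()]: concentration at time `t` in the operation segment is
#' `background + sum over events e with t_e <= t of A_e * f(design) *
#' exp(-k (t - t_e))`, where `f` multiplies the SES attenuation, room-air
#' dilution and open-approach factors applicable to the design. Blank
#' windows contain background only; the calibration window contains the
#' standard concentration. The whole record is scaled by the instrument
#' sensitivity `calib_true_factor` and Gaussian noise is added — so blank
#' subtraction and calibration recover the true plume.
#'
#' @param design An [operation_design()].
#' @param config A [sim_config()].
#' @param seed Optional seed (overrides `config$seed`). Identical
#'   (design, config, seed) give bit-identical output.
#' @return List with `series` (measured `ion_ts`) and `truth` (`sim_truth`:
#'   realized event times and per-event amplitudes, design factor, analytic
#'   expected operation-segment mean per compound, realized noiseless
#'   operation maximum per compound, all in true — background-inclusive —
#'   units).
#' @export
simulate_operation <- function(design, config, seed = NULL) {
  stopifnot(inherits(design, "operation_design"), inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  segs <- design_segments(design)
  total <- max(vapply(segs, `[`, 0, 2))
  sp <- config$sample_period
  t <- seq(0, total - sp, by = sp)
  if (segs$operation[2] > total || any(vapply(segs, `[`, 0, 1) < 0)) {
    stop("parameter error: design windows must fit within the record")
  }
  nm <- config$compounds
  nC <- length(nm)
  k <- config$ventilation_rate_k
  f <- design_factor(design, config)
  op_w <- segs$operation

  with_seed(seed, {
    rate_s <- config$event_rate / 60
    n_ev <- stats::rpois(1, rate_s * design$duration)
    ev_times <- sort(stats::runif(n_ev, op_w[1], op_w[2]))
    amps <- matrix(0, n_ev, nC, dimnames = list(NULL, nm))
    for (j in seq_len(nC)) {
      m <- config$emission_mean_ppb[[j]]
      s <- config$emission_sd_ppb[[j]]
      if (m <= 0) next
      amps[, j] <- if (s <= 0) rep(m, n_ev) else {
        p <- lnorm_params(m, s)
        stats::rlnorm(n_ev, p$meanlog, p$sdlog)
      }
    }

    true_conc <- matrix(rep(config$background_ppb, each = length(t)),
                        length(t), nC, dimnames = list(NULL, nm))
    in_op <- t >= op_w[1] & t < op_w[2]
    true_conc[in_op, ] <- true_conc[in_op, , drop = FALSE] +
      plume_signal(t[in_op], ev_times, amps, k) * f
    in_cal <- t >= segs$calib[1] & t < segs$calib[2]
    true_conc[in_cal, ] <- matrix(rep(config$calib_standard_ppb,
                                      each = sum(in_cal)), sum(in_cal), nC)

    measured <- sweep(true_conc, 2, config$calib_true_factor, "*")
    if (config$noise_sd_ppb > 0) {
      measured <- measured + matrix(stats::rnorm(length(measured), 0,
                                                 config$noise_sd_ppb),
                                    nrow(measured))
    }

    # analytic expectation of the operation-segment mean (true units)
    Tdur <- design$duration
    lam_term <- if (k > 0) {
      (1 - (1 - exp(-k * Tdur)) / (k * Tdur)) / k
    } else {
      Tdur / 2
    }
    expected_mean <- config$background_ppb +
      f * rate_s * config$emission_mean_ppb * lam_term
    op_true <- true_conc[in_op, , drop = FALSE]
    truth <- structure(list(
      op_id = design$op_id,
      event_times = ev_times,
      event_amps = amps,
      design_factor = f,
      expected_mean_ppb = expected_mean,
      noiseless_max_ppb = apply(op_true, 2, max),
      seed = seed
    ), class = "sim_truth")

    series <- ion_series(design$op_id, t, measured, segs)
    list(series = series, truth = truth)
  })
}

#' Simulate a paired inhale/exhale breath record
#'
#' The inhaled-air record follows the plume model (no design factors); the
#' exhaled-air expectation equals the inhaled expectation times
#' `1 - uptake_fraction` per compound, with independent instrument noise on
#' both records. Both series carry a pre-operation blank window and an
#' operation window.
#'
#' @param config A [sim_config()].
#' @param uptake_fraction Named (or scalar, recycled) fraction(s) in
#'   \\[0, 1\\]: proportion of each inhaled compound retained by the body.
#' @param duration Operation window length in seconds.
#' @param seed Optional seed.
#' @return List with `inhale`, `exhale` (`ion_ts`) and `truth` (`sim_truth`
#'   with the uptake fractions and expected inhale mean).
#' @export
simulate_breath_pair <- function(config, uptake_fraction, duration = 300,
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  nm <- config$compounds
  u <- if (length(uptake_fraction) == 1) {
    stats::setNames(rep(uptake_fraction, length(nm)), nm)
  } else {
    uptake_fraction[nm]
  }
  if (any(is.na(u)) || any(u < 0) || any(u > 1)) {
    stop("parameter error: uptake fractions must be in [0, 1] for every compound")
  }
  if (is.null(seed)) seed <- config$seed
  sp <- config$sample_period
  segs <- list(blank_pre = c(0, 60), operation = c(60, 60 + duration))
  t <- seq(0, 60 + duration - sp, by = sp)
  in_op <- t >= 60
  k <- config$ventilation_rate_k

  with_seed(seed, {
    rate_s <- config$event_rate / 60
    n_ev <- stats::rpois(1, rate_s * duration)
    ev_times <- sort(stats::runif(n_ev, 60, 60 + duration))
    amps <- matrix(0, n_ev, length(nm), dimnames = list(NULL, nm))
    for (j in seq_along(nm)) {
      m <- config$emission_mean_ppb[[j]]
      s <- config$emission_sd_ppb[[j]]
      if (m <= 0) next
      amps[, j] <- if (s <= 0) rep(m, n_ev) else {
        p <- lnorm_params(m, s)
        stats::rlnorm(n_ev, p$meanlog, p$sdlog)
      }
    }
    signal <- matrix(rep(config$background_ppb, each = length(t)),
                     length(t), length(nm), dimnames = list(NULL, nm))
    signal[in_op, ] <- signal[in_op, , drop = FALSE] +
      plume_signal(t[in_op], ev_times, amps, k)
    noise <- function() {
      if (config$noise_sd_ppb > 0) {
        matrix(stats::rnorm(length(signal), 0, config$noise_sd_ppb),
               nrow(signal))
      } else 0
    }
    inhale_conc <- signal + noise()
    exhale_conc <- sweep(signal, 2, 1 - u, "*") + noise()
    op_signal <- signal[in_op, , drop = FALSE]
    truth <- structure(list(
      op_id = "breath",
      event_times = ev_times,
      event_amps = amps,
      uptake_fraction = u,
      inhale_mean_noiseless_ppb = colMeans(op_signal),
      seed = seed
    ), class = "sim_truth")
    list(inhale = ion_series("breath_in", t, inhale_conc, segs),
         exhale = ion_series("breath_ex", t, exhale_conc, segs),
         truth = truth)
  })
}
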