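# Inhaled dose, breath uptake, exposure-limit screening, cigarette equivalence.

.gas_constant <- 8.31446  # J / (mol K) = L kPa / (mol K)

#' Exposure model parameters
#'
#' Breathing and gas-state parameters for converting air concentrations to
#' inhaled mass. Defaults are the conventional assumptions for OR personnel:
#' minute ventilation 5 L/min and operation duration 120 min. The ideal-gas
#' molar volume is derived as R*T/P; at the default 25 degC and 101.325 kPa
#' this is 24.47 L/mol, essentially the industrial-hygiene convention figure
#' of 24.45 L/mol (the two differ by < 0.1%).
#'
#' @param minute_ventilation Inhaled air volume, L/min.
#' @param duration Exposure duration, min.
#' @param temperature Air temperature, K.
#' @param pressure Air pressure, kPa.
#' @return An `exposure_params` list with derived `molar_volume` (L/mol).
#' @export
exposure_params <- function(minute_ventilation = 5, duration = 120,
                            temperature = 298.15, pressure = 101.325) {
  if (minute_ventilation <= 0 || duration < 0 || temperature <= 0 ||
      pressure <= 0) {
    stop("parameter error: exposure parameters must be positive")
  }
  structure(list(minute_ventilation = minute_ventilation,
                 duration = duration,
                 temperature = temperature,
                 pressure = pressure,
                 molar_volume = .gas_constant * temperature / pressure),
            class = "exposure_params")
}

#' Convert a volume mixing ratio to mass concentration
#'
#' Ideal-gas conversion of ppb (by volume) to micrograms per cubic metre:
#' `ug/m3 = ppb * MW / Vm` with `Vm` the molar volume in L/mol.
#'
#' @param ppb Concentration in ppb by volume (vectorised, >= 0).
#' @param mw Molecular weight, g/mol (> 0).
#' @param params An [exposure_params()].
#' @return Mass concentration in ug/m3.
#' @examples
#' ppb_to_mass_conc(136, 44.05)  # acetaldehyde, ~245 ug/m3
#' @export
ppb_to_mass_conc <- function(ppb, mw, params = exposure_params()) {
  if (any(mw <= 0)) stop("parameter error: molecular weight must be > 0")
  if (any(ppb < 0)) stop("parameter error: ppb must be >= 0")
  ppb * mw / params$molar_volume
}

#' Inverse of [ppb_to_mass_conc()]
#' @param ugm3 Mass concentration in ug/m3.
#' @inheritParams ppb_to_mass_conc
#' @return Concentration in ppb by volume.
#' @export
mass_conc_to_ppb <- function(ugm3, mw, params = exposure_params()) {
  if (any(mw <= 0)) stop("parameter error: molecular weight must be > 0")
  ugm3 * params$molar_volume / mw
}

#' Inhaled mass of a compound over one operation
#'
#' Mass inhaled at a constant mean concentration: moles of air breathed are
#' `minute_ventilation * duration / molar_volume`; multiplying by the mixing
#' ratio and the molecular weight gives
#' `dose_ug = ppb * 1e-9 * (MV * duration / Vm) * MW * 1e6`.
#' At the defaults (5 L/min, 120 min), 136 ppb of acetaldehyde (44.05 g/mol)
#' gives 147 ug per operation.
#'
#' @param mean_ppb Mean breath-inlet concentration over the operation, ppb.
#' @param mw Molecular weight, g/mol.
#' @param params An [exposure_params()].
#' @return Inhaled mass in ug.
#' @export
inhaled_dose <- function(mean_ppb, mw, params = exposure_params()) {
  if (any(mean_ppb < 0)) stop("parameter error: mean_ppb must be >= 0")
  if (any(mw <= 0)) stop("parameter error: molecular weight must be > 0")
  air_mol <- params$minute_ventilation * params$duration / params$molar_volume
  mean_ppb * 1e-9 * air_mol * mw * 1e6
}

#' Breath uptake of a compound
#'
#' Uptake is the difference between inhaled and exhaled breath
#' concentrations: `uptake_ppb = mean(inhale) - mean(exhale)` over the
#' operation segment, and `uptake_fraction = uptake_ppb / mean(inhale)`,
#' clipped to \\[0, 1\\] (noise can push the raw ratio outside; the `clipped`
#' flag records when this happened). When the inhaled mean is not positive
#' the fraction is undefined (`NA`) but the absolute uptake is still
#' returned.
#'
#' @param inhale,exhale `ion_ts` objects containing `compound`.
#' @param compound Channel name to evaluate.
#' @return List with `compound`, `inhale_mean_ppb`, `uptake_ppb`,
#'   `uptake_fraction`, `clipped`.
#' @export
uptake_fraction <- function(inhale, exhale, compound) {
  for (s in list(inhale, exhale)) {
    if (!compound %in% channels(s)) {
      stop("lookup error: compound '", compound, "' not in series '",
           s$op_id, "'")
    }
  }
  mi <- mean(inhale$conc[segment_index(inhale, "operation"), compound])
  me <- mean(exhale$conc[segment_index(exhale, "operation"), compound])
  up <- mi - me
  if (mi <= 0) {
    return(list(compound = compound, inhale_mean_ppb = mi, uptake_ppb = up,
                uptake_fraction = NA_real_, clipped = FALSE))
  }
  frac_raw <- up / mi
  frac <- min(max(frac_raw, 0), 1)
  list(compound = compound, inhale_mean_ppb = mi, uptake_ppb = up,
       uptake_fraction = frac, clipped = frac != frac_raw)
}

#' Cigarette-equivalent inhaled dose
#'
#' Divides an inhaled mass by the per-cigarette emitted mass of the compound
#' where a reference exists (acetaldehyde: 2000 ug/cigarette; 1,3-butadiene:
#' 130 ug/cigarette). Compounds without a reference return `NA`.
#'
#' @param dose_ug Inhaled mass in ug (>= 0).
#' @param compound Compound name (panel labels such as
#'   `"1,3-butadiene/1-Butyne"` are matched on the contained reference name).
#' @return Dimensionless cigarette count, or `NA` if no reference.
#' @examples
#' cigarette_equivalents(146, "Acetaldehyde")  # ~0.073 cigarettes
#' @export
cigarette_equivalents <- function(dose_ug, compound) {
  if (any(dose_ug < 0)) stop("parameter error: dose must be >= 0")
  hit <- which(vapply(.cigarette_reference$key, grepl, TRUE,
                      x = tolower(compound), fixed = TRUE))
  if (length(hit) == 0) return(NA_real_)
  dose_ug / .cigarette_reference$ug_per_cigarette[hit[1]]
}

#' Screen maximum concentrations against permissible exposure limits
#'
#' Flags every panel compound whose maximum observed concentration strictly
#' exceeds its applicable (most stringent OSHA/NIOSH) limit. Compounds
#' without an assessed limit are listed but never flagged. Compounds whose
#' transcribed limit carries the `limit_suspect` flag (unit-scale ambiguity
#' in the source table) are evaluated like the others but collected in a
#' separate suspect-limit section of the printed report, with a note that
#' the source study nonetheless names methanol among the compounds exceeding
#' limits.
#'
#' @param maxima Named numeric vector of per-compound maximum concentrations
#'   (ppb), or an `operation_summary` (its per-channel maxima are used).
#' @param registry A `compound_table`.
#' @return An `exceedance_report` data.frame with columns `compound`,
#'   `max_ppb`, `limit_ppb` (NA = unassessed), `exceeds`, `limit_suspect`,
#'   plus a `notes` attribute printed with the report.
#' @export
exceedance_report <- function(maxima, registry) {
  stopifnot(inherits(registry, "compound_table"))
  if (inherits(maxima, "operation_summary")) {
    maxima <- stats::setNames(maxima$channel_stats$max_ppb,
                              maxima$channel_stats$channel)
  }
  if (is.null(names(maxima))) {
    stop("parameter error: maxima must be named by compound")
  }
  common <- intersect(registry$name, names(maxima))
  if (length(common) == 0) {
    stop("parameter error: no panel compounds present in maxima")
  }
  reg <- registry[match(common, registry$name), ]
  lim <- applicable_limit(reg)
  mx <- maxima[common]
  out <- data.frame(compound = common,
                    max_ppb = unname(mx),
                    limit_ppb = unname(lim),
                    exceeds = !is.na(lim) & unname(mx) > unname(lim),
                    limit_suspect = reg$limit_suspect,
                    stringsAsFactors = FALSE)
  notes <- character(0)
  suspects <- out$compound[out$limit_suspect]
  if (length(suspects) > 0) {
    notes <- c(notes, paste0(
      "Suspect limits (unit scale doubtful, transcribed verbatim from the ",
      "source table): ", paste(suspects, collapse = ", "), ". ",
      "The methanol cell prints 4200 and the ethanol cell 100,0000; ",
      "regulatory limits for both are conventionally quoted in ppm, so the ",
      "ppb reading here may understate or overstate the true limit. ",
      "Note the source study names methanol among the compounds exceeding ",
      "exposure limits even though the transcribed 4200 ppb limit is not ",
      "exceeded by the recorded maximum."))
  }
  structure(out, class = c("exceedance_report", "data.frame"), notes = notes)
}

#' @export
print.exceedance_report <- function(x, ...) {
  flagged <- x$compound[x$exceeds]
  cat("Exposure-limit exceedance screen (", nrow(x), " compounds)\n", sep = "")
  cat("exceeding:", if (length(flagged)) paste(flagged, collapse = ", ")
      else "none", "\n")
  unassessed <- x$compound[is.na(x$limit_ppb)]
  if (length(unassessed) > 0) {
    cat("unassessed (no OSHA/NIOSH limit):",
        paste(unassessed, collapse = ", "), "\n")
  }
  for (n in attr(x, "notes")) cat(strwrap(n, 78), sep = "\n")
  invisible(x)
}

#' Per-compound dose table for an operation
#'
#' Combines [inhaled_dose()] and [cigarette_equivalents()] over a set of
#' per-compound mean concentrations using registry molecular weights.
#'
#' @param mean_ppb Named numeric vector of mean concentrations (ppb).
#' @param registry A `compound_table` supplying molecular weights.
#' @param params An [exposure_params()].
#' @return data.frame with compound, mean_ppb, mw_g_mol, inhaled_mass_ug,
#'   cigarette_equivalents (NA where no reference exists).
#' @export
dose_table <- function(mean_ppb, registry, params = exposure_params()) {
  stopifnot(inherits(registry, "compound_table"))
  common <- intersect(registry$name, names(mean_ppb))
  if (length(common) == 0) {
    stop("parameter error: no panel compounds present in mean_ppb")
  }
  mw <- registry$mw_g_mol[match(common, registry$name)]
  conc <- pmax(mean_ppb[common], 0)  # negative blank-subtracted means -> 0 dose
  dose <- inhaled_dose(unname(conc), mw, params)
  data.frame(compound = common,
             mean_ppb = unname(mean_ppb[common]),
             mw_g_mol = mw,
             inhaled_mass_ug = dose,
             cigarette_equivalents = vapply(seq_along(common), function(i) {
               cigarette_equivalents(dose[i], common[i])
             }, numeric(1)),
             stringsAsFactors = FALSE)
}
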