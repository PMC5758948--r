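# Process-chemistry metrics: soluble-COD stabilization, free ammonia
# nitrogen equilibrium, and ammonia/VFA inhibition diagnostics.

#' Soluble-COD stabilization rate
#'
#' Percent reduction of soluble chemical oxygen demand (CODS) over the
#' digestion period, `(CODsi - CODsf) / CODsi * 100`. Negative values are
#' meaningful — they indicate net accumulation of hydrolysed organics in an
#' inhibited digester — and are returned unclipped; use [clip_for_display()]
#' only in reporting layers.
#'
#' @param cods_initial Initial soluble COD, mg/L; must be > 0.
#' @param cods_final Final soluble COD, mg/L; must be >= 0.
#' @return Stabilization rate in percent (may be negative).
#' @examples
#' cods_stabilization(100, 30)     # 70
#' cods_stabilization(100, 363.42) # -263.42, an inhibited digester
#' @export
cods_stabilization <- function(cods_initial, cods_final) {
  if (any(cods_initial <= 0)) {
    stop("cods_stabilization() is undefined for initial CODS <= 0",
         call. = FALSE)
  }
  if (any(cods_final < 0)) {
    stop("final CODS must be nonnegative", call. = FALSE)
  }
  (cods_initial - cods_final) / cods_initial * 100
}

#' Floor negative stabilization rates at zero for display
#'
#' Inhibited digesters can show negative CODS stabilization; figures
#' conventionally display these as zero while tables keep the signed value.
#' This helper is for plotting/report layers only and must never feed the
#' S/N analysis, which operates on the signed values.
#'
#' @param cods Stabilization rate(s) in percent.
#' @return `pmax(cods, 0)`.
#' @export
clip_for_display <- function(cods) {
  pmax(cods, 0)
}

#' Convert Celsius to Kelvin
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) {
  temp_c + 273.15
}

#' Free ammonia nitrogen from total ammonia, pH and temperature
#'
#' Computes the unionized (free) ammonia fraction of total ammonia nitrogen
#' from the NH3/NH4+ acid-base equilibrium:
#' `FAN = TAN * (1 + 10^(-pH) * 10^(0.09018 + 2729.92/T))^(-1)`,
#' with T in Kelvin. The temperature term is the van't Hoff form of the
#' ammonium pKa, so FAN rises steeply with both pH and temperature: at
#' mesophilic temperature a pH shift from 7 to 8 raises FAN roughly
#' nine-fold. FAN is the inhibitory ammonia species in anaerobic digesters.
#'
#' @param tan Total ammonia nitrogen, mg/L (>= 0).
#' @param ph pH of the digestate.
#' @param temp_k Process temperature in Kelvin (> 0); use
#'   [celsius_to_kelvin()] when starting from deg C.
#' @return Free ammonia nitrogen in mg/L, bounded by `0 <= FAN <= TAN`.
#' @examples
#' free_ammonia(1000, 8.0, celsius_to_kelvin(36))  # ~107 mg/L
#' @export
free_ammonia <- function(tan, ph, temp_k) {
  if (any(tan < 0)) stop("TAN must be nonnegative", call. = FALSE)
  if (any(temp_k <= 0)) stop("temperature must be positive Kelvin",
                             call. = FALSE)
  tan / (1 + 10^(-ph) * 10^(0.09018 + 2729.92 / temp_k))
}

#' Default inhibition-diagnostic thresholds
#'
#' Literature thresholds for ammonia and volatile-fatty-acid stress in
#' anaerobic digesters. All are configurable because they are regime- and
#' substrate-dependent:
#' * `fan_mesophilic`: FAN (mg/L) toxic to mesophilic chicken-manure
#'   fermentation when the digester runs at high total solids
#'   (`ts_for_fan_mesophilic`, %).
#' * `fan_thermophilic`: FAN (mg/L) above which thermophilic digestion is
#'   inhibited.
#' * `acetate_limit` (mg/L) together with `propionate_acetate_ratio`:
#'   acetate above the limit with propionate:acetate above the ratio is a
#'   digester-failure signal.
#' * `tvfa_rapid` (mg/L): rapid VFA accumulation warning.
#' * `tvfa_ph_suppression` (mg/L): TVFA level that drags pH down and stalls
#'   methanogenesis.
#' * `tan_undesirable`: TAN band (mg/L) reported as undesirable for stable
#'   digestion.
#'
#' @param fan_mesophilic,ts_for_fan_mesophilic,fan_thermophilic,acetate_limit,propionate_acetate_ratio,tvfa_rapid,tvfa_ph_suppression,tan_undesirable
#'   Numeric overrides, see description.
#' @return Named list of thresholds.
#' @export
ad_thresholds <- function(fan_mesophilic = 250,
                          ts_for_fan_mesophilic = 10,
                          fan_thermophilic = 700,
                          acetate_limit = 800,
                          propionate_acetate_ratio = 1.4,
                          tvfa_rapid = 5000,
                          tvfa_ph_suppression = 12000,
                          tan_undesirable = c(1700, 14000)) {
  list(fan_mesophilic = fan_mesophilic,
       ts_for_fan_mesophilic = ts_for_fan_mesophilic,
       fan_thermophilic = fan_thermophilic,
       acetate_limit = acetate_limit,
       propionate_acetate_ratio = propionate_acetate_ratio,
       tvfa_rapid = tvfa_rapid,
       tvfa_ph_suppression = tvfa_ph_suppression,
       tan_undesirable = tan_undesirable)
}

#' Screen a kinetics series for ammonia/VFA inhibition signals
#'
#' Scans a time series of digester measurements against the [ad_thresholds()]
#' rules and reports which flags fired, at which record, with the triggering
#' value and threshold. A series strictly below every threshold raises no
#' flag.
#'
#' @param series Data frame with columns `tan_mg_l`, `fan_mg_l`,
#'   `tvfa_mg_l`, `acetic_mg_l`, `propionic_mg_l` (additional columns are
#'   ignored).
#' @param ts_pct Total-solids level of the digester (%), used by the
#'   mesophilic FAN rule.
#' @param regime `"mesophilic"` or `"thermophilic"`.
#' @param thresholds Threshold set from [ad_thresholds()].
#' @return A data frame of class `diagnostics_report`: one row per flag with
#'   columns `flag`, `raised`, `record`, `value`, `threshold`.
#' @export
diagnose_series <- function(series, ts_pct,
                            regime = c("mesophilic", "thermophilic"),
                            thresholds = ad_thresholds()) {
  regime <- match.arg(regime)
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("diagnose_series() needs a nonempty kinetics series", call. = FALSE)
  }
  need <- c("tan_mg_l", "fan_mg_l", "tvfa_mg_l", "acetic_mg_l",
            "propionic_mg_l")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols)) {
    stop("kinetics series lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  th <- thresholds
  rows <- list()
  flag_first <- function(name, hits, values, threshold) {
    idx <- which(hits)[1]
    rows[[name]] <<- data.frame(
      flag = name,
      raised = !is.na(idx),
      record = if (is.na(idx)) NA_integer_ else idx,
      value = if (is.na(idx)) NA_real_ else values[idx],
      threshold = threshold,
      stringsAsFactors = FALSE)
  }

  meso_hits <- regime == "mesophilic" & ts_pct >= th$ts_for_fan_mesophilic &
    series$fan_mg_l > th$fan_mesophilic
  flag_first("fan_mesophilic_toxic", meso_hits, series$fan_mg_l,
             th$fan_mesophilic)

  thermo_hits <- regime == "thermophilic" &
    series$fan_mg_l > th$fan_thermophilic
  flag_first("fan_thermophilic_inhibition", thermo_hits, series$fan_mg_l,
             th$fan_thermophilic)

  tan_hits <- series$tan_mg_l >= th$tan_undesirable[1] &
    series$tan_mg_l <= th$tan_undesirable[2]
  flag_first("tan_undesirable_range", tan_hits, series$tan_mg_l,
             th$tan_undesirable[1])

  ratio <- ifelse(series$acetic_mg_l > 0,
                  series$propionic_mg_l / series$acetic_mg_l, 0)
  pa_hits <- series$acetic_mg_l > th$acetate_limit &
    ratio > th$propionate_acetate_ratio
  flag_first("acetate_propionate_failure", pa_hits, ratio,
             th$propionate_acetate_ratio)

  flag_first("tvfa_rapid_increase", series$tvfa_mg_l > th$tvfa_rapid,
             series$tvfa_mg_l, th$tvfa_rapid)
  flag_first("tvfa_ph_suppression",
             series$tvfa_mg_l > th$tvfa_ph_suppression,
             series$tvfa_mg_l, th$tvfa_ph_suppression)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("diagnostics_report", "data.frame"))
}
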