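# Taguchi signal-to-noise ratio analysis: per-run S/N, factor-level mean
# S/N, ranges, factor ranking, and optimal-level selection.

#' Larger-the-better signal-to-noise ratio
#'
#' `S/N_LTB = -10 log10( (1/n) * sum(1/y_i^2) )` in dB. Because the
#' measurements enter squared, the sign of a negative response is discarded:
#' a CODS removal of -263.42% yields the same S/N as +263.42%, which inflates
#' the apparent quality of an inhibited run. The default `negative_policy =
#' "literal"` reproduces that behaviour (with a warning); `"exclude"` drops
#' negative values, `"floor"` replaces them with a small positive `eps`.
#'
#' @param values Nonempty numeric vector of measurements; no value may be 0.
#' @param negative_policy How to treat negative measurements; see above.
#' @param eps Replacement value under `negative_policy = "floor"`.
#' @return S/N ratio in dB.
#' @examples
#' snr_ltb(140.11)      # 42.93 dB
#' snr_ltb(c(100, 200)) # 42.04 dB
#' @export
snr_ltb <- function(values, negative_policy = c("literal", "exclude",
                                                "floor"),
                    eps = 1e-6) {
  negative_policy <- match.arg(negative_policy)
  if (length(values) == 0L) stop("empty measurement vector", call. = FALSE)
  if (any(values == 0)) {
    stop("S/N (larger-the-better) is undefined for zero measurements",
         call. = FALSE)
  }
  if (any(values < 0)) {
    warning("negative measurements in larger-the-better S/N: squaring ",
            "discards the sign and can overstate quality (policy = '",
            negative_policy, "')", call. = FALSE)
    values <- switch(negative_policy,
                     literal = values,
                     exclude = values[values > 0],
                     floor = ifelse(values < 0, eps, values))
    if (length(values) == 0L) {
      stop("all measurements excluded as negative", call. = FALSE)
    }
  }
  -10 * log10(mean(1 / values^2))
}

#' Larger-the-better S/N from a reported mean and standard deviation
#'
#' When replicate-level data are summarized as mean +/- SD (triplicates),
#' the per-run S/N can be reconstructed through the second-moment
#' approximation
#' `20 log10(m) - 10 log10(1 + 3 (s/m)^2)`,
#' which matches the exact triplicate S/N to about +/- 0.02 dB for
#' coefficients of variation up to ~12% when `s` is the n-denominator
#' (population) standard deviation of the replicates — the convention the
#' packaged run table follows. With `sd = 0` it reduces to the
#' single-measurement formula `20 log10(m)`.
#'
#' @param mean Reported mean response (> 0; pass the absolute value for
#'   sign-discarded negative responses).
#' @param sd Reported standard deviation (>= 0).
#' @return Approximate S/N ratio in dB.
#' @examples
#' snr_ltb_from_moments(167.39, 16.92) # 44.34 dB
#' @export
snr_ltb_from_moments <- function(mean, sd = 0) {
  if (any(mean <= 0)) {
    stop("moment-based S/N requires a positive mean", call. = FALSE)
  }
  if (any(sd < 0)) stop("sd must be nonnegative", call. = FALSE)
  20 * log10(mean) - 10 * log10(1 + 3 * (sd / mean)^2)
}

#' Smaller-the-better signal-to-noise ratio
#'
#' `S/N_STB = -10 log10( (1/n) * sum(y_i^2) )` in dB.
#'
#' @param values Nonempty numeric vector of measurements.
#' @return S/N ratio in dB.
#' @export
snr_stb <- function(values) {
  if (length(values) == 0L) stop("empty measurement vector", call. = FALSE)
  -10 * log10(mean(values^2))
}

#' Nominal-the-best signal-to-noise ratio
#'
#' `S/N_NTB = 10 log10( mean^2 / variance )` in dB.
#'
#' @param values Numeric vector with at least two values and nonzero
#'   variance.
#' @return S/N ratio in dB.
#' @export
snr_ntb <- function(values) {
  if (length(values) < 2L) {
    stop("nominal-the-best S/N needs at least two measurements",
         call. = FALSE)
  }
  v <- stats::var(values)
  if (v == 0) stop("nominal-the-best S/N is undefined at zero variance",
                   call. = FALSE)
  10 * log10(mean(values)^2 / v)
}

#' Per-run S/N table from a run table
#'
#' Computes the larger-the-better S/N for every run and response of a run
#' table. With `source = "moments"` the S/N is reconstructed from the
#' reported mean and SD via [snr_ltb_from_moments()] (absolute value of the
#' mean for sign-discarded negative responses); with `source = "columns"`
#' the table's own `snr_*` columns are used verbatim when present.
#'
#' @param run_table A run table as returned by [load_run_table()].
#' @param source `"columns"` (default when `snr_*` columns exist) or
#'   `"moments"`.
#' @return Data frame with `run_id` and one dB column per response
#'   (`bgp`, `bmp`, `cods`).
#' @export
snr_table <- function(run_table, source = c("columns", "moments")) {
  source <- match.arg(source)
  responses <- c(bgp = "bgp_mean_ml_gvs", bmp = "bmp_mean_ml_gvs",
                 cods = "cods_mean_pct")
  snr_cols <- c(bgp = "snr_bgp_db", bmp = "snr_bmp_db", cods = "snr_cods_db")
  out <- data.frame(run_id = run_table$run_id)
  if (source == "columns" && !all(snr_cols %in% names(run_table))) {
    source <- "moments"
  }
  for (r in names(responses)) {
    if (source == "columns") {
      out[[r]] <- run_table[[snr_cols[r]]]
    } else {
      m <- run_table[[responses[r]]]
      s <- run_table[[switch(r, bgp = "bgp_sd", bmp = "bmp_sd",
                             cods = "cods_sd")]]
      out[[r]] <- snr_ltb_from_moments(abs(m), s)
    }
  }
  out
}

#' Mean S/N of the runs at one factor level
#'
#' Averages the per-run S/N over the three runs where `factor` sits at
#' `level` — the balanced-design estimate of that level's effect on the
#' response.
#'
#' @param snr Data frame from [snr_table()] (column `run_id` plus response
#'   columns).
#' @param design An `l9_design`.
#' @param factor Factor letter, e.g. `"B"`.
#' @param level Level index in 1..3.
#' @param response Response column name in `snr`.
#' @return Mean S/N in dB.
#' @export
level_mean_snr <- function(snr, design, factor, level, response) {
  lev_col <- paste0(factor, "_level")
  if (!lev_col %in% names(design)) {
    stop(sprintf("unknown factor '%s'", factor), call. = FALSE)
  }
  runs <- design$run_id[design[[lev_col]] == level]
  if (length(runs) != 3L) {
    stop(sprintf("level %s of factor %s does not select 3 runs",
                 level, factor), call. = FALSE)
  }
  vals <- snr[[response]][match(runs, snr$run_id)]
  if (anyNA(vals)) {
    stop("S/N table is missing runs required for this level mean",
         call. = FALSE)
  }
  mean(vals)
}

#' Factor-effects table: level means, ranges, ranks, best levels
#'
#' For each factor and response, averages the per-run S/N at each of the
#' three levels, takes the range (max - min) of the level means, ranks the
#' factors by descending range (rank 1 = most influential; ties broken by
#' factor order), and records the level attaining the maximum mean (ties go
#' to the lowest level index).
#'
#' @param snr Data frame from [snr_table()].
#' @param design An `l9_design`.
#' @param responses Response columns of `snr` to analyse; defaults to all
#'   non-`run_id` columns.
#' @return An object of class `factor_effects`: a data frame with one row
#'   per response x factor holding `level1..level3` means (dB), `range`,
#'   `rank` and `best_level`.
#' @export
effects_table <- function(snr, design,
                          responses = setdiff(names(snr), "run_id")) {
  lev <- design_levels(design)
  factors <- sub("_level$", "", colnames(lev))
  if (nrow(snr) != 9L || anyNA(snr[responses])) {
    stop("effects_table() needs a complete 9-run S/N table", call. = FALSE)
  }
  rows <- list()
  for (resp in responses) {
    means <- t(vapply(factors, function(f) {
      vapply(1:3, function(l) level_mean_snr(snr, design, f, l, resp),
             numeric(1))
    }, numeric(3)))
    rng <- apply(means, 1L, max) - apply(means, 1L, min)
    # ties broken by factor order A < B < C < D
    rnk <- rank(-rng, ties.method = "first")
    best <- apply(means, 1L, which.max)
    rows[[resp]] <- data.frame(
      response = resp, factor = factors,
      level1 = means[, 1], level2 = means[, 2], level3 = means[, 3],
      range = rng, rank = rnk, best_level = as.integer(best),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("factor_effects", "data.frame"))
}

#' @export
print.factor_effects <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, ...)
  invisible(x)
}

#' Optimal formulation for one response
#'
#' Per-factor argmax of the level-mean S/N: the factor-level combination
#' predicted to maximize the response. Ties resolve to the lowest level
#' index.
#'
#' @param effects A `factor_effects` table from [effects_table()].
#' @param response Response name present in `effects`.
#' @return Named integer vector of best level indices with attribute
#'   `designation` (also returned by [designation()] on the result).
#' @examples
#' # on the packaged study this returns A2B1C2D1 for biogas yield
#' @export
optimal_formulation <- function(effects, response) {
  sub <- effects[effects$response == response, ]
  if (nrow(sub) == 0L) {
    stop(sprintf("response '%s' not present in effects table", response),
         call. = FALSE)
  }
  lv <- sub$best_level
  names(lv) <- sub$factor
  attr(lv, "designation") <- designation(lv, sub$factor)
  lv
}
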