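# Additive main-effects response surrogate and Derringer-type desirability
# optimization over all 81 candidate formulations.

#' Fit an additive main-effects model to the nine run means
#'
#' The surrogate stores, per response, the grand mean of the nine run means
#' and the three level means of each factor (on the raw response scale, not
#' in dB). By the balance of the orthogonal array, the mean of any factor's
#' level means equals the grand mean, so the additive prediction telescopes
#' to the grand mean when averaged over all 81 formulations.
#'
#' @param run_means Numeric vector of 9 run means, ordered by `run_id`.
#' @param design An `l9_design` from [build_l9()].
#' @return An object of class `main_effects_model`.
#' @export
fit_main_effects <- function(run_means, design) {
  lev <- design_levels(design)
  if (length(run_means) != 9L || anyNA(run_means)) {
    stop("fit_main_effects() needs the 9 complete run means", call. = FALSE)
  }
  validate_design(design)
  grand <- mean(run_means)
  level_means <- t(vapply(seq_len(ncol(lev)), function(j) {
    vapply(1:3, function(l) mean(run_means[lev[, j] == l]), numeric(1))
  }, numeric(3)))
  rownames(level_means) <- sub("_level$", "", colnames(lev))
  structure(list(grand_mean = grand, level_means = level_means),
            class = "main_effects_model")
}

#' Predict a response for any formulation
#'
#' Additive main-effects prediction:
#' `grand mean + sum over factors of (level mean at the formulation - grand
#' mean)`. Valid for any of the 81 level combinations, including the 72 not
#' run.
#'
#' @param model A `main_effects_model` from [fit_main_effects()].
#' @param formulation Integer vector of level indices (one per factor, in
#'   1..3), or a designation string such as `"A2B1C2D1"`.
#' @return Predicted response on the raw scale.
#' @export
predict_response <- function(model, formulation) {
  if (is.character(formulation)) formulation <- parse_designation(formulation)
  lm_ <- model$level_means
  if (length(formulation) != nrow(lm_) ||
      any(formulation < 1L | formulation > ncol(lm_))) {
    stop("formulation must give one level index in 1..3 per factor",
         call. = FALSE)
  }
  contrib <- vapply(seq_len(nrow(lm_)), function(j) {
    lm_[j, formulation[j]] - model$grand_mean
  }, numeric(1))
  model$grand_mean + sum(contrib)
}

#' One-sided larger-is-better desirability
#'
#' Derringer-Suich ramp for a maximize goal:
#' `d = clip((y - L)/(U - L), 0, 1)^w`. `d = 0` at or below the lower bound
#' `L`, `d = 1` at or above the upper bound `U`, with exponent `w`
#' controlling the ramp curvature.
#'
#' @param y Response value(s).
#' @param lower,upper Bounds with `upper > lower`.
#' @param weight Positive ramp exponent (default 1 = linear).
#' @return Desirability in `[0, 1]`.
#' @examples
#' desirability(150, 100, 200)            # 0.5
#' desirability(150, 100, 200, weight = 2) # 0.25
#' @export
desirability <- function(y, lower, upper, weight = 1) {
  if (upper <= lower) stop("desirability bounds require upper > lower",
                           call. = FALSE)
  if (weight <= 0) stop("desirability weight must be positive",
                        call. = FALSE)
  d <- pmin(pmax((y - lower) / (upper - lower), 0), 1)
  d^weight
}

#' Build a desirability specification for one response
#'
#' @param lower,upper Desirability bounds; defaults are filled from observed
#'   data by [optimize_desirability()] when `NULL`.
#' @param weight Ramp exponent (> 0).
#' @param importance Relative importance in the weighted geometric mean
#'   (> 0); a common rescaling of all importances leaves the ranking
#'   unchanged.
#' @return Named list spec.
#' @export
desirability_spec <- function(lower = NULL, upper = NULL, weight = 1,
                              importance = 1) {
  if (weight <= 0 || importance <= 0) {
    stop("weight and importance must be positive", call. = FALSE)
  }
  list(lower = lower, upper = upper, weight = weight,
       importance = importance)
}

#' Rank all 81 formulations by overall desirability
#'
#' Evaluates every level combination of the four factors with the additive
#' surrogate of each response, scores each response with its one-sided
#' desirability ramp, and combines them into the overall desirability
#' `D = (prod d_i^imp_i)^(1/sum imp_i)` (weighted geometric mean; `D = 0`
#' whenever any `d_i = 0`). Bounds default to the observed min/max of the
#' run means per response, which makes `D = 1` attainable exactly when a
#' formulation is predicted to beat every observed response maximum.
#'
#' @param models Named list of `main_effects_model`s, one per response.
#' @param specs Named list of [desirability_spec()]s with the same names;
#'   defaults to equal-importance linear ramps for all responses.
#' @param observed_ranges Named list of `c(min, max)` per response, used to
#'   fill any `NULL` spec bounds; build it from the run table with
#'   [run_means_ranges()].
#' @return Data frame of class `desirability_ranking`: 81 rows with
#'   `designation`, level columns, one predicted and one desirability column
#'   per response, and `overall_d`, sorted by decreasing `overall_d`
#'   (ties in lexicographic designation order).
#' @export
optimize_desirability <- function(models, specs = NULL,
                                  observed_ranges = NULL) {
  responses <- names(models)
  if (is.null(responses) || any(responses == "")) {
    stop("models must be a named list keyed by response", call. = FALSE)
  }
  if (is.null(specs)) {
    specs <- stats::setNames(
      replicate(length(responses), desirability_spec(), simplify = FALSE),
      responses)
  }
  factors <- rownames(models[[1]]$level_means)
  grid <- expand.grid(rep(list(1:3), length(factors)))
  names(grid) <- factors

  out <- data.frame(
    designation = apply(grid, 1L, designation, factor_names = factors),
    stringsAsFactors = FALSE)
  for (f in factors) out[[paste0(f, "_level")]] <- grid[[f]]

  log_d_sum <- numeric(nrow(grid))
  imp_total <- 0
  zero_mask <- logical(nrow(grid))
  for (resp in responses) {
    pred <- apply(grid, 1L, function(fm) {
      predict_response(models[[resp]], as.integer(fm))
    })
    spec <- specs[[resp]]
    bounds <- c(spec$lower, spec$upper)
    if (is.null(spec$lower) || is.null(spec$upper)) {
      if (is.null(observed_ranges) || is.null(observed_ranges[[resp]])) {
        stop(sprintf(
          "no bounds for response '%s': give spec bounds or observed_ranges",
          resp), call. = FALSE)
      }
      rng <- observed_ranges[[resp]]
      spec$lower <- if (is.null(spec$lower)) rng[1] else spec$lower
      spec$upper <- if (is.null(spec$upper)) rng[2] else spec$upper
    }
    # a response observed at a single value cannot discriminate between
    # formulations; it contributes neutrally to the geometric mean
    d <- if (spec$upper == spec$lower) {
      rep(1, length(pred))
    } else {
      desirability(pred, spec$lower, spec$upper, spec$weight)
    }
    out[[paste0("pred_", resp)]] <- pred
    out[[paste0("d_", resp)]] <- d
    zero_mask <- zero_mask | d == 0
    log_d_sum <- log_d_sum + spec$importance * log(pmax(d, .Machine$double.xmin))
    imp_total <- imp_total + spec$importance
  }
  out$overall_d <- ifelse(zero_mask, 0, exp(log_d_sum / imp_total))

  ord <- order(-out$overall_d, out$designation)
  out <- out[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("desirability_ranking", "data.frame"))
}

#' Observed min/max run means per response, for desirability bounds
#'
#' @param run_table A run table as returned by [load_run_table()].
#' @return Named list of `c(min, max)` for responses `bgp`, `bmp`, `cods`.
#' @export
run_means_ranges <- function(run_table) {
  list(bgp = range(run_table$bgp_mean_ml_gvs),
       bmp = range(run_table$bmp_mean_ml_gvs),
       cods = range(run_table$cods_mean_pct))
}
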