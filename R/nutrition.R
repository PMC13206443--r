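# Nutritional suitability model: per-meal RDA adequacy, Atwater
# macronutrient energy-ratio balance, an energy-density penalty, and
# their weighted composite S_nutrition.

#' Default daily RDA table
#'
#' General-adult daily reference values (kcal for calories, grams
#' otherwise), divided by meals-per-day to give per-meal targets.
#' Editable: supply any positive named vector covering the modeled
#' nutrients.
#'
#' @return Named numeric vector over the 5 nutrient dimensions.
#' @export
default_rda <- function() {
  c(calories = 2000, protein = 50, fat = 70, carbohydrates = 260,
    fiber = 28)
}

#' Nutrition scoring configuration
#'
#' Bundles the Atwater energy-conversion factors (protein 4,
#' carbohydrate 4, fat 9 kcal/g), the target macronutrient energy split
#' (30% protein / 40% carbohydrate / 30% fat), the energy-density
#' threshold tau (kcal/g) and penalty rate kappa, the component weights
#' (0.5, 0.3, 0.2) and meals per day (3).
#'
#' @param atwater Named kcal/g factors for protein, carbohydrates, fat.
#' @param target_ratios Named target energy shares summing to 1.
#' @param tau Energy-density threshold, kcal/g (> 0).
#' @param kappa Exponential penalty rate above tau (> 0).
#' @param weights Length-3 weights (adequacy, ratio, density), sum 1.
#' @param meals_per_day Meals the daily RDA is split across.
#' @param modeled Nutrients entering the adequacy mean.
#' @return Object of class `nutrition_config`.
#' @export
nutrition_config <- function(atwater = c(protein = 4, carbohydrates = 4,
                                         fat = 9),
                             target_ratios = c(protein = 0.30,
                                               carbohydrates = 0.40,
                                               fat = 0.30),
                             tau = 1.5, kappa = 1.0,
                             weights = c(0.5, 0.3, 0.2),
                             meals_per_day = 3,
                             modeled = c("calories", "protein", "fat",
                                         "carbohydrates", "fiber")) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop_config("weights", "sum to 1")
  if (length(weights) != 3) stop_config("weights", "have length 3")
  if (abs(sum(target_ratios) - 1) > 1e-9)
    stop_config("target_ratios", "sum to 1")
  if (tau <= 0) stop_config("tau", "be > 0")
  if (kappa <= 0) stop_config("kappa", "be > 0")
  if (meals_per_day < 1) stop_config("meals_per_day", "be >= 1")
  structure(list(atwater = atwater, target_ratios = target_ratios,
                 tau = tau, kappa = kappa, weights = weights,
                 meals_per_day = meals_per_day, modeled = modeled),
            class = "nutrition_config")
}

#' Per-nutrient adequacy against the per-meal target
#'
#' `A_m = min(1, n_m / T_m)` with `T_m = RDA_m / meals_per_day`; capped
#' at 1 so moderate excess is not penalized.
#'
#' @param n_m Nutrient amount in the recipe (>= 0).
#' @param rda_m Daily RDA value (> 0).
#' @param meals_per_day Meals the daily value is split across.
#' @return Adequacy in \[0, 1\].
#' @export
adequacy <- function(n_m, rda_m, meals_per_day = 3) {
  if (any(rda_m <= 0)) stop("RDA values must be > 0", call. = FALSE)
  if (any(n_m < 0)) stop("nutrient amount must be >= 0", call. = FALSE)
  pmin(1, n_m / (rda_m / meals_per_day))
}

#' Aggregate adequacy: mean over the modeled nutrients
#'
#' @param a_m Numeric vector of per-nutrient adequacies.
#' @return Mean adequacy in \[0, 1\].
#' @export
aggregate_adequacy <- function(a_m) {
  if (length(a_m) == 0)
    stop_config("modeled nutrient set", "be non-empty")
  mean(a_m)
}

#' Macronutrient energy ratios via Atwater factors
#'
#' `R_i = atwater_i * grams_i / sum_j atwater_j * grams_j` over protein,
#' carbohydrates and fat. The denominator is the macro-derived energy,
#' not the stored calories field, so the ratios always sum to 1.
#'
#' @param n A nutrient vector (needs protein, carbohydrates, fat).
#' @param cfg A `nutrition_config`.
#' @return Named numeric vector (protein, carbohydrates, fat), sum 1.
#' @export
energy_ratios <- function(n, cfg = nutrition_config()) {
  macros <- names(cfg$atwater)
  energy <- cfg$atwater * as.numeric(n[macros])
  total <- sum(energy)
  if (total <= 0)
    stop("energy ratios undefined: all macronutrients are zero",
         call. = FALSE)
  energy / total
}

#' Ratio-balance score
#'
#' Mean over the three macros of `1 - |R_i - R_i_target|`; 1 exactly at
#' the target split.
#'
#' @param ratios Named ratios from [energy_ratios()].
#' @param cfg A `nutrition_config`.
#' @return Score in \[0, 1\].
#' @export
ratio_balance <- function(ratios, cfg = nutrition_config()) {
  tg <- cfg$target_ratios[names(cfg$atwater)]
  mean(1 - abs(as.numeric(ratios[names(cfg$atwater)]) - as.numeric(tg)))
}

#' Energy density and its satiety score
#'
#' `ED = calories / mass` (kcal/g); the score is 1 up to the threshold
#' tau and decays as `exp(-kappa * (ED - tau))` above it (continuous at
#' tau).
#'
#' @param calories Recipe calories (kcal).
#' @param mass_g Recipe mass in grams (> 0).
#' @param cfg A `nutrition_config`.
#' @return List with `ed` (kcal/g) and `score` in \[0, 1\].
#' @export
energy_density_score <- function(calories, mass_g,
                                 cfg = nutrition_config()) {
  if (mass_g <= 0) stop("mass must be > 0", call. = FALSE)
  ed <- calories / mass_g
  score <- if (ed <= cfg$tau) 1 else exp(-cfg$kappa * (ed - cfg$tau))
  list(ed = ed, score = score)
}

#' Composite nutritional suitability score
#'
#' `S_nutrition = w1 * A_abs + w2 * A_ratio + w3 * A_ED` with weights
#' from the configuration (default 0.5 / 0.3 / 0.2).
#'
#' @param a_abs,a_ratio,a_ed Component scores in \[0, 1\].
#' @param cfg A `nutrition_config`.
#' @return Score in \[0, 1\].
#' @export
composite_score <- function(a_abs, a_ratio, a_ed,
                            cfg = nutrition_config()) {
  if (abs(sum(cfg$weights) - 1) > 1e-9)
    stop_config("weights", "sum to 1")
  w <- cfg$weights
  w[1] * a_abs + w[2] * a_ratio + w[3] * a_ed
}

#' Full nutritional breakdown of a recipe
#'
#' Computes every component of the suitability model: per-nutrient
#' adequacies, their mean, energy ratios and balance, energy density
#' and its score, and the weighted composite.
#'
#' @param r A `recipe`.
#' @param rda Daily RDA table (named vector).
#' @param cfg A `nutrition_config`.
#' @return List of class `nutrition_breakdown` with elements `a_m`,
#'   `a_abs`, `ratios`, `a_ratio`, `ed`, `a_ed`, `s_nutrition`.
#' @export
nutrition_breakdown <- function(r, rda = default_rda(),
                                cfg = nutrition_config()) {
  m <- intersect(cfg$modeled, names(r$nutrients))
  if (length(m) == 0) stop_config("modeled nutrient set", "be non-empty")
  a_m <- stats::setNames(
    vapply(m, function(nm) adequacy(r$nutrients[[nm]], rda[[nm]],
                                    cfg$meals_per_day), numeric(1)), m)
  a_abs <- aggregate_adequacy(a_m)
  ratios <- tryCatch(energy_ratios(r$nutrients, cfg), error = function(e) NULL)
  a_ratio <- if (is.null(ratios)) 0 else ratio_balance(ratios, cfg)
  edl <- energy_density_score(r$nutrients[["calories"]], r$total_mass_g, cfg)
  structure(list(a_m = a_m, a_abs = a_abs, ratios = ratios,
                 a_ratio = a_ratio, ed = edl$ed, a_ed = edl$score,
                 s_nutrition = composite_score(a_abs, a_ratio, edl$score,
                                               cfg)),
            class = "nutrition_breakdown")
}

#' @export
print.nutrition_breakdown <- function(x, ...) {
  cat(sprintf(
    "<nutrition_breakdown> A_abs=%.3f A_ratio=%.3f ED=%.2f A_ED=%.3f S=%.3f\n",
    x$a_abs, x$a_ratio, x$ed, x$a_ed, x$s_nutrition))
  invisible(x)
}
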