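#' Caffeine intake scenario
#'
#' @param content Caffeine content of the grains, %w/w (0, 100].
#' @param coffee_mass_per_cup Coffee mass per cup, mg. The default of 80 mg
#'   is carried through verbatim from the consumption scenario this package
#'   reproduces; it is unusually low for a real cup of brewed coffee (a
#'   typical serving uses several grams of grounds), so override it for
#'   realistic exposure estimates.
#' @param cups_per_day Cups per day.
#' @param days_per_week Days per week (default 7).
#' @return An `intake_scenario` object.
#' @examples
#' intake_scenario()
#' @export
intake_scenario <- function(content = 1.3, coffee_mass_per_cup = 80,
                            cups_per_day = 1, days_per_week = 7) {
  assert_scalar_number(content, "content", lower = 0, upper = 100,
                       strict_lower = TRUE)
  assert_scalar_number(coffee_mass_per_cup, "coffee_mass_per_cup",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(cups_per_day, "cups_per_day", lower = 0, strict_lower = TRUE)
  assert_scalar_number(days_per_week, "days_per_week", lower = 1)
  structure(
    list(content = content, coffee_mass_per_cup = coffee_mass_per_cup,
         cups_per_day = cups_per_day, days_per_week = days_per_week),
    class = "intake_scenario"
  )
}

#' Daily caffeine intake
#'
#' `content/100 * coffee_mass_per_cup * cups_per_day`, in mg/day.
#'
#' @param scenario An [intake_scenario()].
#' @return Intake in mg/day.
#' @examples
#' daily_intake(intake_scenario()) # 1.04
#' @export
daily_intake <- function(scenario = intake_scenario()) {
  stopifnot(inherits(scenario, "intake_scenario"))
  (scenario$content / 100) * scenario$coffee_mass_per_cup * scenario$cups_per_day
}

#' Weekly caffeine intake
#'
#' Daily intake times days per week; the conventional report rounds to two
#' significant figures, so both values are returned.
#'
#' @param scenario An [intake_scenario()].
#' @return Tibble with `weekly_mg` (exact) and `weekly_mg_2sf` (rounded to
#'   2 significant figures).
#' @examples
#' weekly_intake(intake_scenario()) # 7.28, reported 7.3
#' @export
weekly_intake <- function(scenario = intake_scenario()) {
  w <- daily_intake(scenario) * scenario$days_per_week
  tibble::tibble(weekly_mg = w, weekly_mg_2sf = signif(w, 2))
}

#' High-caffeine labelling check for beverages
#'
#' EU practice requires beverages with more than 150 mg/L caffeine to be
#' labelled "high caffeine content"; coffee, tea and cocoa are exempt from
#' the rule, which is noted in the result.
#'
#' @param beverage_conc Beverage caffeine concentration(s), mg/L (>= 0).
#' @return Tibble with `beverage_conc_mg_L`, `high_caffeine` (strictly above
#'   150 mg/L) and `note`.
#' @examples
#' label_check(c(150, 151))
#' @export
label_check <- function(beverage_conc) {
  if (any(beverage_conc < 0)) {
    abort("`beverage_conc` must be non-negative.",
          class = "caffval_invalid_argument")
  }
  tibble::tibble(
    beverage_conc_mg_L = beverage_conc,
    high_caffeine = beverage_conc > 150,
    note = "coffee, tea and cocoa are exempt from the 150 mg/L labelling rule"
  )
}
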