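# Labeling economics: convert labeling/review counts and rates into
# person-years and savings. All operations are exact closed-form arithmetic.
# The work calendar is 8 h/day, 21 days/month, 12 months/year, so one
# person-year is 2,016 working hours.

#' Describe a labeling-cost scenario
#'
#' The default is the reference campaign used throughout: 100,000 images,
#' three labelers at 10 minutes per image, 10% human-labeled, and the other
#' 90% reviewed at 20 seconds per image by three reviewers.
#'
#' @param n_images Number of images in the dataset.
#' @param n_labelers Labelers working on each image.
#' @param minutes_per_label Minutes one person spends labeling one image.
#' @param n_reviewers Reviewers checking each auto-labeled image.
#' @param seconds_per_review Seconds one person spends reviewing one image.
#' @param frac_labeled Fraction of images labeled by humans, in `[0, 1]`;
#'   the remainder is auto-labeled and only reviewed.
#' @param hours_per_day,days_per_month,months_per_year The work calendar.
#' @return A `cost_scenario` list.
#' @examples
#' s <- cost_scenario()
#' full_labeling_cost(s)   # 24.8 person-years (floors to the headline 24)
#' al_scenario_cost(s)     # 3.224 person-years (prints as 3.2)
#' saving_percent(full_labeling_cost(s), al_scenario_cost(s)) # ~87
#' @export
cost_scenario <- function(n_images = 100000,
                          n_labelers = 3,
                          minutes_per_label = 10,
                          n_reviewers = 3,
                          seconds_per_review = 20,
                          frac_labeled = 0.1,
                          hours_per_day = 8,
                          days_per_month = 21,
                          months_per_year = 12) {
  if (n_images < 0 || n_labelers < 0 || minutes_per_label < 0 ||
      n_reviewers < 0 || seconds_per_review < 0) {
    stop_config("counts and rates must be nonnegative")
  }
  if (frac_labeled < 0 || frac_labeled > 1) stop_config("frac_labeled must lie in [0, 1]")
  if (hours_per_day <= 0 || days_per_month <= 0 || months_per_year <= 0) {
    stop_config("calendar constants must be positive")
  }
  structure(
    list(n_images = n_images, n_labelers = n_labelers,
         minutes_per_label = minutes_per_label, n_reviewers = n_reviewers,
         seconds_per_review = seconds_per_review, frac_labeled = frac_labeled,
         hours_per_day = hours_per_day, days_per_month = days_per_month,
         months_per_year = months_per_year),
    class = "cost_scenario"
  )
}

#' Convert total working minutes to person-years
#'
#' @param total_minutes Total person-minutes of work.
#' @param scenario A [cost_scenario()] supplying the work calendar.
#' @return Person-years as an unrounded real number (2,016 working hours per
#'   year under the default calendar).
#' @export
person_years <- function(total_minutes, scenario = cost_scenario()) {
  if (total_minutes < 0) stop_usage("total_minutes must be nonnegative")
  total_minutes / 60 /
    (scenario$hours_per_day * scenario$days_per_month * scenario$months_per_year)
}

#' Person-years to label the whole dataset by hand
#'
#' `n_images * n_labelers * minutes_per_label` through the work calendar.
#' The reference scenario (100,000 images, 3 labelers, 10 min) gives 24.8,
#' i.e. a headline of 24 person-years.
#'
#' @param s A [cost_scenario()].
#' @return Unrounded person-years.
#' @export
full_labeling_cost <- function(s) {
  person_years(s$n_images * s$n_labelers * s$minutes_per_label, s)
}

#' Person-years under the active-learning scenario
#'
#' Humans label `frac_labeled` of the images at the full labeling rate; the
#' rest is auto-labeled and reviewed at `seconds_per_review` per reviewer:
#' \deqn{py(f N L m + (1-f) N R s / 60)}
#'
#' @param s A [cost_scenario()].
#' @return Unrounded person-years (3.224 for the reference scenario, printed
#'   as 3.2).
#' @export
al_scenario_cost <- function(s) {
  label_min <- s$frac_labeled * s$n_images * s$n_labelers * s$minutes_per_label
  review_min <- (1 - s$frac_labeled) * s$n_images * s$n_reviewers *
    s$seconds_per_review / 60
  person_years(label_min + review_min, s)
}

#' Percent of person-time saved by active learning
#'
#' `100 * (1 - al / full)`, computed on the unrounded person-years. The
#' reference scenario gives 87% with three reviewers and 89% with one.
#'
#' @param full Person-years of full labeling (must be positive).
#' @param al Person-years of the AL scenario.
#' @return Percent saved (unrounded; can be negative if AL costs more).
#' @export
saving_percent <- function(full, al) {
  if (full <= 0) stop_usage("saving is undefined for a zero-cost full labeling")
  100 * (1 - al / full)
}

#' Percent reduction in labeling effort from the labeled fraction
#'
#' `100 * (1 - frac_labeled)`, rounded to integer percent — the count-based
#' effort reduction relative to labeling everything (or relative to a
#' baseline fraction when `frac_labeled` is a ratio of fractions).
#'
#' @param frac_labeled Fraction labeled, in `[0, 1]`.
#' @return Integer percent.
#' @examples
#' effort_reduction_percent(400 / 5525)  # 93
#' effort_reduction_percent(16 / 36)     # 56
#' @export
effort_reduction_percent <- function(frac_labeled) {
  if (frac_labeled < 0 || frac_labeled > 1) stop_usage("frac_labeled must lie in [0, 1]")
  round(100 * (1 - frac_labeled))
}

#' Rounded display summary of a cost scenario
#'
#' Applies the reporting conventions: full-labeling person-years floored to
#' an integer (the headline figure), scenario person-years to one decimal,
#' savings to integer percent computed on the unrounded values.
#'
#' @param s A [cost_scenario()].
#' @return A one-row tibble: `full_person_years` (floored),
#'   `full_person_years_exact`, `al_person_years` (1 decimal),
#'   `al_person_years_exact`, `saving_pct` (integer),
#'   `effort_reduction_pct`.
#' @export
cost_summary <- function(s) {
  full <- full_labeling_cost(s)
  al <- al_scenario_cost(s)
  tibble::tibble(
    full_person_years = floor(full),
    full_person_years_exact = full,
    al_person_years = round(al, 1),
    al_person_years_exact = al,
    saving_pct = round(saving_percent(full, al)),
    effort_reduction_pct = effort_reduction_percent(s$frac_labeled)
  )
}
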