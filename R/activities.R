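#' Activity label set
#'
#' The seven activity classes recognised by the platform: four static
#' postures and walking in three speed bands (very low < 1.5 km/h,
#' low 1.5-3.0 km/h, medium 3.0-4.5 km/h).
#'
#' @return Character vector of the seven class labels, in canonical order.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c("standing", "sitting", "bending", "lying",
    "walk_very_low", "walk_low", "walk_medium")
}

#' Walking speed bands
#'
#' Nominal speed bands (km/h) for the three walking classes. The band
#' midpoint is used as the nominal translation speed by the synthetic
#' landmark generator.
#'
#' @return A data.frame with columns `label`, `low_kmh`, `high_kmh`.
#' @export
walking_speed_bands <- function() {
  data.frame(
    label    = c("walk_very_low", "walk_low", "walk_medium"),
    low_kmh  = c(0.0, 1.5, 3.0),
    high_kmh = c(1.5, 3.0, 4.5),
    stringsAsFactors = FALSE
  )
}

#' MET lookup table
#'
#' Builds the activity-to-MET mapping used for energy-expenditure
#' quantification. One MET is the resting energy cost, 1 kcal per kg of
#' body weight per hour. Defaults are the compendium-derived values the
#' platform ships with: standing 1.2, sitting 1.0, bending 0.9, lying 1.0,
#' walking 1.9 / 2.6 / 3.4 for the very-low / low / medium speed bands.
#'
#' @param values Named numeric vector overriding any subset of the default
#'   MET values; names must be activity labels.
#' @return An object of class `met_table`: a named numeric vector over the
#'   seven activity classes.
#' @export
#' @examples
#' met_table()
#' met_table(c(standing = 1.3))
met_table <- function(values = NULL) {
  tab <- c(standing = 1.2, sitting = 1.0, bending = 0.9, lying = 1.0,
           walk_very_low = 1.9, walk_low = 2.6, walk_medium = 3.4)
  if (!is.null(values)) {
    if (is.null(names(values)) || !all(names(values) %in% names(tab)))
      stop("'values' must be named with activity labels: ",
           paste(setdiff(names(values), names(tab)), collapse = ", "))
    tab[names(values)] <- values
  }
  if (any(tab <= 0)) stop("MET values must be positive")
  walk <- tab[c("walk_very_low", "walk_low", "walk_medium")]
  if (any(diff(walk) <= 0))
    stop("walking MET values must increase strictly with speed band")
  structure(tab, class = "met_table")
}

#' @export
print.met_table <- function(x, ...) {
  cat("MET lookup table (kcal/kg/h):\n")
  print(unclass(x))
  invisible(x)
}

#' Look up the MET value of an activity
#'
#' @param activity One of the seven activity labels.
#' @param table A [met_table()].
#' @return The MET value (dimensionless multiple of resting energy cost).
#' @export
#' @examples
#' met_of("standing")            # 1.2
#' met_of("walk_medium")         # 3.4
met_of <- function(activity, table = met_table()) {
  if (!inherits(table, "met_table")) table <- met_table(table)
  if (length(activity) != 1L || !activity %in% names(table))
    stop("unknown activity label: ", paste(activity, collapse = ", "))
  unname(table[[activity]])
}

#' Subject profile
#'
#' Anthropometric record of one monitored subject. BMI is derived from
#' weight and height when not supplied; when both are given they must be
#' mutually consistent (within 0.5 kg/m^2).
#'
#' @param id Opaque subject identifier.
#' @param weight Body weight in kg (> 0).
#' @param height Stature in m (> 0). If missing and `bmi` is given, height
#'   is derived as `sqrt(weight / bmi)`.
#' @param age Age in years (optional).
#' @param gender Free-text gender (optional).
#' @param bmi Body mass index in kg/m^2 (optional; derived if absent).
#' @return An object of class `subject_profile`.
#' @export
#' @examples
#' subject_profile("u1", weight = 81, bmi = 27.06)
subject_profile <- function(id, weight, height = NULL, age = NA_real_,
                            gender = NA_character_, bmi = NULL) {
  stopifnot_scalar_num(weight, "weight", 0, strict = TRUE)
  if (is.null(height)) {
    if (is.null(bmi)) stop("supply 'height' or 'bmi'")
    height <- sqrt(weight / bmi)
  }
  stopifnot_scalar_num(height, "height", 0, strict = TRUE)
  derived <- weight / height^2
  if (is.null(bmi)) bmi <- derived
  else if (abs(bmi - derived) > 0.5)
    stop(sprintf("bmi %.2f inconsistent with weight/height^2 = %.2f",
                 bmi, derived))
  structure(list(id = as.character(id), weight = weight, height = height,
                 age = age, gender = gender, bmi = bmi),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject %s: %.1f kg, %.2f m, BMI %.2f\n",
              x$id, x$weight, x$height, x$bmi))
  invisible(x)
}

#' Packaged study cohort
#'
#' The eleven-subject cohort the packaged validation protocols are run on:
#' ageing adults (65-73 y) with weights 52-83 kg. Heights are derived from
#' weight and BMI.
#'
#' @return A list of [subject_profile()] objects.
#' @export
study_subjects <- function() {
  tab <- data.frame(
    id     = as.character(1:11),
    gender = c("male", "female", "female", "male", "male", "female",
               "female", "male", "female", "male", "male"),
    age    = c(67, 71, 70, 70, 65, 68, 68, 69, 65, 69, 73),
    weight = c(81, 55, 59, 75, 66, 61, 52, 83, 54, 78, 70),
    bmi    = c(27.06, 23.19, 23.04, 27.54, 21.30, 26.40, 18.42, 31.23,
               20.83, 28.65, 23.66),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(tab)), function(i)
    subject_profile(tab$id[i], weight = tab$weight[i], age = tab$age[i],
                    gender = tab$gender[i], bmi = tab$bmi[i]))
}
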