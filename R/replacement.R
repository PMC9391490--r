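# Replacement-rate and longevity estimators for tooth families.
#
# The replacement rate of a tooth position is the age (in days of dentine
# deposition) of the functional tooth at the moment its successor began
# depositing dentine: functional line count minus replacement line count.
# When the replacement tooth is lost, its age is estimated from the height
# of the resorption pit it eroded into the functional tooth base, or from
# the radial extent of its dentine.

#' Construct a tooth record
#'
#' One tooth's chronology and measurement flags.
#'
#' @param taxon Taxon name.
#' @param specimen_id Specimen identifier.
#' @param element Jaw element: `"maxilla"`, `"dentary"`, or `"premaxilla"`.
#' @param position_label Tooth-position label, e.g. `"mx09"`.
#' @param age_days Integer age in days (total von Ebner line count).
#' @param age_is_minimum `TRUE` when the count is a lower bound (e.g. crown
#'   apex missing, so apical lines are unrecorded).
#' @param crown_height Optional crown height (TH) in micrometres.
#' @param rp_height Optional resorption-pit height in micrometres.
#' @param ankylosed Is the tooth fused to the jawbone (functional)?
#' @param shed Was the tooth shed? (A shed tooth cannot be ankylosed.)
#'
#' @return An object of class `tooth_record`.
#' @export
tooth_record <- function(taxon, specimen_id, element = "maxilla",
                         position_label = NA_character_,
                         age_days, age_is_minimum = FALSE,
                         crown_height = NULL, rp_height = NULL,
                         ankylosed = FALSE, shed = FALSE) {
  if (!element %in% c("maxilla", "dentary", "premaxilla")) {
    tc_stop("invalid_record", "element must be maxilla, dentary or premaxilla")
  }
  if (!is_scalar_number(age_days) || age_days < 0) {
    tc_stop("invalid_record", "age_days must be a non-negative number")
  }
  if (!is.null(rp_height) && (!is_scalar_number(rp_height) || rp_height < 0)) {
    tc_stop("invalid_record", "rp_height must be non-negative when present")
  }
  if (!is_flag(age_is_minimum) || !is_flag(ankylosed) || !is_flag(shed)) {
    tc_stop("invalid_record", "flags must be single TRUE/FALSE values")
  }
  if (shed && ankylosed) {
    tc_stop("invalid_record", "a shed tooth cannot be ankylosed")
  }
  structure(
    list(taxon = taxon, specimen_id = specimen_id, element = element,
         position_label = position_label,
         age_days = as.integer(round_half_up(age_days)),
         age_is_minimum = age_is_minimum,
         crown_height = crown_height, rp_height = rp_height,
         ankylosed = ankylosed, shed = shed),
    class = "tooth_record"
  )
}

#' Construct a tooth family
#'
#' A tooth family is a functional tooth together with the replacement
#' tooth/teeth developing lingually at the same jaw position. Replacement
#' teeth are ordered oldest first (the immediate successor) to youngest
#' last; every replacement must be younger than the functional tooth.
#'
#' @param functional A [tooth_record()] for the functional tooth.
#' @param replacements List of [tooth_record()]s, oldest to youngest; may be
#'   empty.
#' @param family_id Optional identifier.
#' @return An object of class `tooth_family`.
#' @export
tooth_family <- function(functional, replacements = list(), family_id = NA_character_) {
  stopifnot(inherits(functional, "tooth_record"))
  if (inherits(replacements, "tooth_record")) replacements <- list(replacements)
  ages <- vapply(replacements, function(r) {
    stopifnot(inherits(r, "tooth_record"))
    r$age_days
  }, numeric(1))
  if (any(ages >= functional$age_days)) {
    tc_stop("inconsistent_family",
            "every replacement tooth must be younger than the functional tooth")
  }
  if (length(ages) > 1L && any(diff(ages) >= 0)) {
    tc_stop("inconsistent_family",
            "replacements must be strictly decreasing in age (oldest first)")
  }
  structure(
    list(family_id = family_id, functional = functional, replacements = replacements),
    class = "tooth_family"
  )
}

#' Construct an apex profile
#'
#' Cumulative crown height at each von Ebner line, measured down the
#' exterior edge of the functional tooth from the crown apex: entry `i` is
#' the height (micrometres) spanned by the first `i` lines counted from the
#' apex. This is the substrate on which an estimated replacement-tooth
#' height is overlaid to convert it into a line count.
#'
#' @param cumulative_heights Non-negative, monotone non-decreasing numeric
#'   vector of heights in micrometres.
#' @param tooth_id Optional tooth identifier.
#' @return An object of class `apex_profile`.
#' @export
apex_profile <- function(cumulative_heights, tooth_id = NA_character_) {
  h <- as.numeric(cumulative_heights)
  if (length(h) == 0L || anyNA(h) || any(h < 0) || any(diff(h) < 0)) {
    tc_stop("invalid_profile",
            "cumulative_heights must be non-negative and monotone non-decreasing")
  }
  structure(list(tooth_id = tooth_id, cumulative_heights = h),
            class = "apex_profile")
}

#' Direct replacement rate from two line counts
#'
#' @param functional_age Functional tooth age in days.
#' @param replacement_age Immediate replacement tooth age in days; must be
#'   strictly less than `functional_age`.
#' @return A `replacement_estimate` with `method = "direct"`.
#' @examples
#' replacement_rate_direct(459, 354)  # Dimetrodon-style: 105 days
#' @export
replacement_rate_direct <- function(functional_age, replacement_age) {
  if (!is_scalar_number(functional_age) || !is_scalar_number(replacement_age) ||
      replacement_age < 0) {
    tc_stop("invalid_measurement", "ages must be non-negative numbers")
  }
  if (replacement_age >= functional_age) {
    tc_stop("inconsistent_family",
            "replacement tooth must be younger than the functional tooth")
  }
  replacement_estimate(
    rate_days = functional_age - replacement_age,
    method = "direct", is_minimum = FALSE,
    replacement_age_used = replacement_age
  )
}

replacement_estimate <- function(rate_days, method, is_minimum,
                                 replacement_age_used) {
  method <- match.arg(method, c("direct", "rp_height", "dentine_extent", "minimum"))
  if (method == "minimum") is_minimum <- TRUE
  structure(
    list(rate_days = as.integer(round_half_up(rate_days)),
         method = method, is_minimum = is_minimum,
         replacement_age_used = as.integer(round_half_up(replacement_age_used))),
    class = "replacement_estimate"
  )
}

#' @export
print.replacement_estimate <- function(x, ...) {
  cat(sprintf("<replacement_estimate> %s%d days (method: %s, replacement age used: %d)\n",
              if (x$is_minimum) ">= " else "", x$rate_days, x$method,
              x$replacement_age_used))
  invisible(x)
}

#' Estimated replacement-tooth height from a resorption pit
#'
#' The developing replacement tooth erodes a resorption pit (RP) into the
#' functional tooth base; the replacement crown height is approximated as
#' two-thirds of the RP height.
#'
#' @param rp_height Resorption-pit height in micrometres (non-negative).
#' @return Estimated replacement-tooth height in micrometres.
#' @export
estimated_replacement_height <- function(rp_height) {
  if (!is_scalar_number(rp_height) || rp_height < 0) {
    tc_stop("invalid_measurement", "rp_height must be a non-negative number")
  }
  (2 / 3) * rp_height
}

#' Count increment lines from the apex down to a height
#'
#' Number of von Ebner lines whose cumulative height from the crown apex is
#' less than or equal to `height` (inclusive at equality: the last line
#' within the encompassed area counts). A height beyond the profile returns
#' the full line count.
#'
#' @param profile An [apex_profile()].
#' @param height Overlay height in micrometres (non-negative).
#' @return Integer line count.
#' @export
count_lines_from_apex <- function(profile, height) {
  stopifnot(inherits(profile, "apex_profile"))
  if (!is_scalar_number(height) || height < 0) {
    tc_stop("invalid_measurement", "height must be a non-negative number")
  }
  sum(profile$cumulative_heights <= height)
}

#' Estimate a lost replacement tooth's age from the resorption pit
#'
#' Composition of [estimated_replacement_height()] and
#' [count_lines_from_apex()]: the two-thirds-RP height is overlaid on the
#' exterior edge of the functional tooth and converted to a line count,
#' i.e. an age in days.
#'
#' @inheritParams count_lines_from_apex
#' @param rp_height Resorption-pit height in micrometres.
#' @return Estimated replacement-tooth age in days.
#' @export
estimate_missing_replacement_age <- function(profile, rp_height) {
  count_lines_from_apex(profile, estimated_replacement_height(rp_height))
}

#' Replacement age from radial dentine extent
#'
#' When a replacement tooth's lines cannot be traced continuously, its age
#' is estimated as its radial dentine extent divided by the functional
#' tooth's mean line width (days = micrometres / (micrometres per day)).
#'
#' @param radial_extent Radial dentine extent in micrometres (> 0).
#' @param mean_width Functional tooth mean line width in micrometres/day (> 0).
#' @return Estimated age in integer days (round half up).
#' @export
dentine_extent_age <- function(radial_extent, mean_width) {
  if (!is_scalar_number(radial_extent) || radial_extent <= 0 ||
      !is_scalar_number(mean_width) || mean_width <= 0) {
    tc_stop("invalid_measurement", "radial_extent and mean_width must be positive")
  }
  as.integer(round_half_up(radial_extent / mean_width))
}

#' Replacement rate for a tooth family
#'
#' Dispatches among the estimators by what the family preserves:
#' \itemize{
#'   \item an intact replacement tooth with a measured age: direct
#'     subtraction against the oldest (immediate successor) replacement;
#'   \item no replacement tooth but a resorption pit and an apex profile:
#'     the two-thirds-RP-height estimator;
#'   \item neither: a minimum rate equal to the functional tooth's age
#'     (the replacement, if any, had not begun depositing dentine when the
#'     record ends), flagged `is_minimum`.
#' }
#' The `is_minimum` flag is also set whenever the functional tooth's own
#' age is a minimum (crown apex missing).
#'
#' @param family A [tooth_family()].
#' @param profile Optional [apex_profile()] of the functional tooth,
#'   required for the resorption-pit method.
#' @return A `replacement_estimate`.
#' @examples
#' f <- tooth_record("Haptodus", "s1", age_days = 152)
#' replacement_rate_for_family(tooth_family(f))  # minimum: >= 152 days
#' @export
replacement_rate_for_family <- function(family, profile = NULL) {
  stopifnot(inherits(family, "tooth_family"))
  fun <- family$functional
  if (length(family$replacements) > 0L) {
    immediate <- family$replacements[[1L]]  # oldest = immediate successor
    est <- replacement_rate_direct(fun$age_days, immediate$age_days)
    est$is_minimum <- est$is_minimum || fun$age_is_minimum
    return(est)
  }
  if (!is.null(fun$rp_height)) {
    if (is.null(profile)) {
      tc_stop("missing_profile",
              "resorption-pit estimation requires an apex profile of the functional tooth")
    }
    rep_age <- estimate_missing_replacement_age(profile, fun$rp_height)
    return(replacement_estimate(
      rate_days = fun$age_days - rep_age,
      method = "rp_height",
      is_minimum = fun$age_is_minimum,
      replacement_age_used = rep_age
    ))
  }
  replacement_estimate(
    rate_days = fun$age_days, method = "minimum",
    is_minimum = TRUE, replacement_age_used = 0
  )
}

#' Functional period of a tooth
#'
#' Days a tooth spends in function: from initial attachment (ankylosis) to
#' shedding, computed as the shed tooth's age minus the mean age at
#' attachment across the attachment-stage teeth supplied.
#'
#' @param shed_age Age in days of a shed tooth.
#' @param attachment_ages Non-empty numeric vector of ages of teeth caught
#'   at the attachment stage; each must be below `shed_age`.
#' @return Integer days (round half up).
#' @examples
#' functional_period(227, c(106, 135))  # 107
#' @export
functional_period <- function(shed_age, attachment_ages) {
  if (!is_scalar_number(shed_age) || length(attachment_ages) == 0L ||
      !is.numeric(attachment_ages) || anyNA(attachment_ages)) {
    tc_stop("invalid_input", "need a shed age and at least one attachment age")
  }
  if (any(attachment_ages >= shed_age)) {
    tc_stop("invalid_input", "shed_age must exceed every attachment age")
  }
  as.integer(round_half_up(shed_age - mean(attachment_ages)))
}

#' Tooth longevity
#'
#' Longevity of the functional tooth: its total age in days (line count),
#' with a minimum flag when the count is a lower bound.
#'
#' @param family A [tooth_family()].
#' @return A list with `days` and `is_minimum`.
#' @export
tooth_longevity <- function(family) {
  stopifnot(inherits(family, "tooth_family"))
  list(days = family$functional$age_days,
       is_minimum = family$functional$age_is_minimum)
}
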