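# Risk scoring: CTCAE severity-group x frequency-class penalties plus
# interaction penalties per arm, reconciled drug-vs-comparator.

#' Frequency class of an adverse-event percentage
#'
#' Maps the highest single-AE frequency within a severity group onto the
#' product-label frequency classes: `"zero"` (no event at all), `"below_0.1"`
#' (rare/very rare), `"0.1_to_1"` (less common), `"1_to_10"` (common) and
#' `"10_plus"` (very common, 10% and above). Bands are half-open with the
#' lower bound included.
#'
#' @param percent Frequency in percent, in \[0, 100\].
#' @return The class name.
#' @export
#' @examples
#' frequency_class(0.5) # "0.1_to_1"
#' frequency_class(10)  # "10_plus"
frequency_class <- function(percent) {
  check_scalar_number(percent, "percent", lower = 0, upper = 100)
  if (percent == 0) "zero"
  else if (percent < 0.1) "below_0.1"
  else if (percent < 1) "0.1_to_1"
  else if (percent < 10) "1_to_10"
  else "10_plus"
}

# rows: frequency classes; columns: severity groups
.severity_table <- matrix(
  c(   0,     0,    0,     # zero
      -1,     0,    0,     # below_0.1
      -2,    -1,   -0.5,   # 0.1_to_1
      -3,    -2,   -1,     # 1_to_10
      -4,    -2.5, -1.5),  # 10_plus
  nrow = 5, byrow = TRUE,
  dimnames = list(.enums$frequency_class,
                  c("grades_4_5", "grade_3", "grades_1_2")))

.interaction_table <- c(frequent_or_serious = -2.0, occasional_or_clinical = -1.5,
                        dose_change = -1.0, unlikely_or_none = 0,
                        no_information = -1.0)

#' Penalty points for one severity group
#'
#' The adverse-event penalty for a CTCAE severity group given the frequency
#' class of its worst event: life-threatening/disabling/fatal events
#' (grades 4+5) are penalized even when rare, down to -4.0 when very common;
#' severe events (grade 3) down to -2.5; mild/moderate events (grades 1+2)
#' down to -1.5. Events rarer than 0.1% carry no penalty outside the top
#' severity group.
#'
#' @param group `"grades_4_5"`, `"grade_3"` or `"grades_1_2"`.
#' @param class A frequency class name (see [frequency_class()]).
#' @return Points, \eqn{\le 0}.
#' @export
severity_points <- function(group, class) {
  if (!group %in% colnames(.severity_table))
    abort_validation(paste("must be one of:",
                           paste(colnames(.severity_table), collapse = ", ")),
                     "group")
  check_enum(class, "frequency_class", "class")
  .severity_table[class, group]
}

#' Penalty points for the drug-interaction class
#'
#' Interaction information is usually taken from the product label since
#' trials rarely register interactions. Absence of information is itself
#' penalized (-1.0), the same as interactions requiring dose changes.
#'
#' @param class An interaction class name (see [arm_risk_profile()]).
#' @return Points, \eqn{\le 0}.
#' @export
interaction_points <- function(class) {
  check_enum(class, "interaction_class", "class")
  .interaction_table[[class]]
}

#' Risk point sum of one arm
#'
#' Adds the three severity-group penalties (each computed from the arm's
#' worst-event frequency via [frequency_class()] and [severity_points()]) and
#' the interaction penalty. The minimum is -10.0.
#'
#' @param profile An [arm_risk_profile()].
#' @return Points in \[-10, 0\].
#' @export
arm_sum <- function(profile) {
  stopifnot(inherits(profile, "evita_arm"))
  severity_points("grades_4_5", frequency_class(profile$grade_4_5_freq)) +
    severity_points("grade_3", frequency_class(profile$grade_3_freq)) +
    severity_points("grades_1_2", frequency_class(profile$grade_1_2_freq)) +
    interaction_points(profile$interaction_class)
}

arm_breakdown <- function(profile) {
  classes <- c(grades_4_5 = frequency_class(profile$grade_4_5_freq),
               grade_3 = frequency_class(profile$grade_3_freq),
               grades_1_2 = frequency_class(profile$grade_1_2_freq))
  data.frame(
    component = c(names(classes), "interaction"),
    class = c(unname(classes), profile$interaction_class),
    points = c(vapply(names(classes),
                      function(g) severity_points(g, classes[[g]]), numeric(1)),
               interaction_points(profile$interaction_class)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Comparative risk score of drug versus comparator
#'
#' The drug's inherently non-positive risk sum is set against the
#' comparator's: `net = arm_sum(drug) - arm_sum(comparator)`. A drug with a
#' cleaner adverse-event and interaction profile than its comparator can
#' therefore earn a positive risk score. Resolution is the frequency class,
#' not the raw percentage: arms whose worst events fall in the same class
#' contribute nothing to the net score.
#'
#' @param drug,comparator [arm_risk_profile()] objects.
#' @return An object of class `evita_risk` with `drug_sum`, `comparator_sum`,
#'   `net_score` (in \[-10, +10\]) and a side-by-side `breakdown` data frame.
#' @export
#' @examples
#' a <- arm_risk_profile("drug", 5, 50, 60, "occasional_or_clinical")
#' b <- arm_risk_profile("placebo", 5, 50, 60, "unlikely_or_none")
#' risk_score(a, b)$net_score # -1.5
risk_score <- function(drug, comparator) {
  stopifnot(inherits(drug, "evita_arm"), inherits(comparator, "evita_arm"))
  ds <- arm_sum(drug)
  cs <- arm_sum(comparator)
  bd <- arm_breakdown(drug)
  bc <- arm_breakdown(comparator)
  breakdown <- data.frame(
    component = bd$component,
    drug_class = bd$class, drug_points = bd$points,
    comparator_class = bc$class, comparator_points = bc$points,
    stringsAsFactors = FALSE)
  structure(
    list(drug_sum = ds, comparator_sum = cs, net_score = ds - cs,
         drug_label = drug$arm_label, comparator_label = comparator$arm_label,
         breakdown = breakdown),
    class = "evita_risk")
}

#' @export
print.evita_risk <- function(x, ...) {
  cat(sprintf("Risk: %g point(s) [%s %g vs %s %g]\n", x$net_score,
              x$drug_label, x$drug_sum, x$comparator_label, x$comparator_sum))
  invisible(x)
}
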