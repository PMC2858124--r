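# Efficiency scoring: base points by result direction, trial count and
# outcome level, and the NNT strength modifier by therapeutic aim.

# Base-point table. Non-inferiority/equivalence points are stored as exact
# fractions (5/3, 5/6) so the patient-relevant cell is exactly twice the
# surrogate cell; they print as 1.67 / 0.83.
.tab_superiority <- c(0, 5.0, 7.5)       # n = 0, 1, >=2 (patient-relevant)
.tab_noninf     <- c(0, 5 / 3, 2.5)      # magnitude; sign from net direction

count_cat <- function(n) min(n, 2L) + 1L # index into the 3-row tables

#' Efficiency base points from trial counts
#'
#' Sums the efficiency-table points for a set of same-outcome-level trials:
#' superiority contributes +5.0 (one trial) or +7.5 (two or more),
#' inferiority the mirror negatives; non-inferiority/equivalence trials
#' attenuate whichever direction the other trials establish (-1.67/-2.5
#' against superiority, +1.67/+2.5 against inferiority, 0 when there is no
#' directional evidence to attenuate). All magnitudes are halved when the
#' evidence is drawn from surrogate-outcome trials. When both superiority and
#' inferiority trials are present, both contribute and the attenuation
#' follows the sign of their sum.
#'
#' @param n_sup,n_noninf,n_inf Non-negative trial counts by result direction
#'   (failed superiority trials count towards none of them).
#' @param level `"patient_relevant"` or `"surrogate"`.
#' @return Base point sum in \[-7.5, +7.5\].
#' @export
#' @examples
#' base_points(1, 0, 0, "patient_relevant") # +5
#' base_points(0, 2, 1, "surrogate")        # -2.5 + 1.25 = -1.25
base_points <- function(n_sup, n_noninf, n_inf, level) {
  stopifnot(n_sup >= 0, n_noninf >= 0, n_inf >= 0)
  check_enum(level, "outcome_level", "level")
  s <- .tab_superiority[count_cat(n_sup)]
  i <- -.tab_superiority[count_cat(n_inf)]
  net <- s + i
  n <- if (n_noninf == 0L || net == 0) 0
       else -sign(net) * .tab_noninf[count_cat(n_noninf)]
  total <- s + i + n
  if (level == "surrogate") total <- total / 2
  total
}

#' Annualize a number needed to treat
#'
#' Converts an NNT observed over a trial of the given duration into a
#' per-year NNT, assuming the absolute risk reduction accrues linearly over
#' time: ARR per year = ARR / years, hence NNT per year = NNT x years.
#'
#' @param nnt NNT over the trial duration (>= 1).
#' @param duration_years Trial duration in years (> 0).
#' @return The per-year NNT.
#' @export
#' @examples
#' annualize_nnt(2.6, 1.5) # 3.9
annualize_nnt <- function(nnt, duration_years) {
  check_scalar_number(nnt, "nnt", lower = 1)
  check_scalar_number(duration_years, "duration_years", lower = 0,
                      lower_open = TRUE)
  nnt * duration_years
}

.modifier_bands <- list(
  prevention = list(breaks = c(20, 50, 100, 175, 300, 500, 1000),
                    factors = c(2.0, 1.75, 1.5, 1.25, 1.0, 0.75, 0.5, 0.25)),
  treatment  = list(breaks = c(3, 10),
                    factors = c(2.0, 1.5, 1.0))
)

#' Strength-of-effect modifier from the annualized NNT
#'
#' Looks up the factor that scales the efficiency base sum by therapeutic
#' strength. Treatment aims use three bands (NNT/year < 3 doubles the score,
#' 3 to < 10 gives 1.5, >= 10 leaves it unchanged); prevention aims use eight
#' bands from 2.0 (NNT/year < 20) down to 0.25 (>= 1000), so a weak
#' preventive effect can shrink the score. Bands are half-open with the
#' printed lower bound included (an NNT of exactly 10 under a treatment aim
#' falls in the >= 10 band, factor 1.0).
#'
#' @param aim `"prevention"` or `"treatment"`.
#' @param nnt_per_year Annualized NNT (>= 1); see [annualize_nnt()].
#' @return The modifier factor.
#' @export
#' @examples
#' modifier_lookup("treatment", 3.9)   # 1.5
#' modifier_lookup("prevention", 1000) # 0.25
modifier_lookup <- function(aim, nnt_per_year) {
  check_enum(aim, "therapeutic_aim", "aim")
  check_scalar_number(nnt_per_year, "nnt_per_year", lower = 1)
  bands <- .modifier_bands[[aim]]
  bands$factors[[findInterval(nnt_per_year, bands$breaks) + 1L]]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

apply_rounding <- function(x, rounding) {
  switch(rounding, none = x, half_up_integer = round_half_away(x),
         stop("unknown rounding mode: ", rounding))
}

#' Efficiency score of the included evidence
#'
#' Counts the included trials by result direction, takes the base points from
#' [base_points()] at the evidence's outcome level, and scales the signed sum
#' by the NNT strength modifier when the pivotal superiority evidence
#' provides an NNT (the smallest annualized NNT among superiority trials;
#' without any NNT the sum is left unmodified). A rounding policy
#' (`"none"` or `"half_up_integer"`) maps the raw score to the reported one.
#'
#' @param included_trials List of trials that survived [filter_trials()]
#'   (so they share one outcome level).
#' @param context The [therapeutic_context()] (supplies the aim for the
#'   modifier table).
#' @param rounding Rounding policy for the reported score.
#' @return An object of class `evita_efficiency` with counts, `base_sum`,
#'   `modifier` (`NA` when no NNT was available), `raw_score`,
#'   `reported_score` and `notes`.
#' @export
efficiency_score <- function(included_trials, context, rounding = "none") {
  stopifnot(is.list(included_trials), inherits(context, "evita_context"))
  check_enum(rounding, "rounding", "rounding")
  results <- vapply(included_trials, `[[`, character(1), "result")
  levels <- vapply(included_trials, `[[`, character(1), "outcome_level")
  notes <- character()

  n_sup <- sum(results == "superiority")
  n_noninf <- sum(results == "non_inferiority_or_equivalence")
  n_inf <- sum(results == "inferiority")
  n_nosig <- sum(results == "no_significant_difference")
  if (n_nosig > 0L)
    notes <- c(notes, sprintf(
      "%d trial(s) without significant difference contribute 0 points", n_nosig))

  level <- if (length(levels) == 0L || any(levels == "patient_relevant"))
    "patient_relevant" else "surrogate"
  base_sum <- base_points(n_sup, n_noninf, n_inf, level)

  # pivotal strength of effect: smallest annualized NNT among superiority trials
  modifier <- NA_real_
  sup_trials <- included_trials[results == "superiority"]
  nnts <- numeric()
  for (trial in sup_trials) {
    nnt <- trial$nnt
    if (is.null(nnt) && !is.null(trial$arr)) nnt <- 1 / trial$arr
    if (is.null(nnt)) next
    if (!is.null(trial$duration_years)) {
      nnts <- c(nnts, annualize_nnt(nnt, trial$duration_years))
    } else {
      nnts <- c(nnts, nnt)
      notes <- c(notes, sprintf(
        "trial %s: no duration given, NNT %.3g taken as per-year", trial$trial_id, nnt))
    }
  }
  if (length(nnts)) {
    nnt_year <- min(nnts)
    modifier <- modifier_lookup(context$therapeutic_aim, max(1, nnt_year))
    notes <- c(notes, sprintf(
      "modifier %.2f from annualized NNT %.3g (%s aim)", modifier, nnt_year,
      context$therapeutic_aim))
  } else {
    notes <- c(notes, "no NNT/ARR available: efficiency score not modified")
  }

  raw <- base_sum * (if (is.na(modifier)) 1 else modifier)
  reported <- apply_rounding(raw, rounding)
  if (reported != raw)
    notes <- c(notes, sprintf("rounded %.4g to %.4g (%s)", raw, reported, rounding))

  structure(
    list(n_superiority = n_sup, n_noninferiority = n_noninf,
         n_inferiority = n_inf,
         n_no_significant_difference = n_nosig,
         outcome_level_used = level, base_sum = base_sum, modifier = modifier,
         raw_score = raw, reported_score = reported, rounding = rounding,
         notes = notes),
    class = "evita_efficiency")
}

#' @export
print.evita_efficiency <- function(x, ...) {
  cat(sprintf(
    "Efficiency: %g point(s) [%s outcomes; %d sup / %d non-inf / %d inf; base %.4g%s]\n",
    x$reported_score, x$outcome_level_used, x$n_superiority,
    x$n_noninferiority, x$n_inferiority, x$base_sum,
    if (is.na(x$modifier)) "" else sprintf(", modifier %.2f", x$modifier)))
  invisible(x)
}
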