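# The assessment pipeline: filter -> classify -> efficiency + risk ->
# combined score with color band, or the explicit "not assessable" verdict.

#' Combine efficiency and risk into the total score
#'
#' The total is the reported efficiency score plus the net risk score. The
#' result is asserted to lie within the enumerable bounds of the scoring
#' tables, \[-25, +25\]; a value outside them would indicate a table
#' implementation bug, not bad input.
#'
#' @param efficiency An `evita_efficiency` (or a bare number).
#' @param risk An `evita_risk` (or a bare number).
#' @return The total score.
#' @export
#' @examples
#' combine_scores(7.5, -1.5) # 6
combine_scores <- function(efficiency, risk) {
  e <- if (inherits(efficiency, "evita_efficiency")) efficiency$reported_score
       else efficiency
  r <- if (inherits(risk, "evita_risk")) risk$net_score else risk
  total <- e + r
  if (total < -25 - 1e-9 || total > 25 + 1e-9)
    stop("internal consistency error: total score ", total,
         " outside [-25, 25]")
  total
}

#' Color band of a total score
#'
#' Scores are presented as a color-coded bar rather than a bare number:
#' green for clearly positive totals (a likely innovation), red for clearly
#' negative ones, and yellow for values around zero, which are considered
#' inconclusive. The width of the yellow band is presentation-layer
#' configuration; the default half-width is 2 points.
#'
#' @param total The combined score.
#' @param yellow_half_width Half-width of the yellow band (>= 0).
#' @return `"green"`, `"yellow"` or `"red"`.
#' @export
#' @examples
#' color_band(6)  # "green"
#' color_band(-1) # "yellow"
color_band <- function(total, yellow_half_width = 2) {
  check_scalar_number(total, "total")
  check_scalar_number(yellow_half_width, "yellow_half_width", lower = 0)
  if (abs(total) <= yellow_half_width) "yellow"
  else if (total > 0) "green"
  else "red"
}

#' Attainable score bounds, by exhaustive enumeration
#'
#' Enumerates every admissible combination of the scoring tables rather than
#' trusting a hard-coded constant: all trial-count categories (0, 1, >= 2 per
#' result direction) at both outcome levels, every strength-modifier factor
#' of both therapeutic aims (and the no-NNT case), and every frequency-class
#' and interaction-class combination for both arms. Returns the minimum and
#' maximum total score, which evaluate to -25 and +25.
#'
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
score_bounds <- function() {
  counts <- expand.grid(n_sup = 0:2, n_noninf = 0:2, n_inf = 0:2)
  base <- numeric(0)
  for (level in .enums$outcome_level)
    base <- c(base, mapply(base_points, counts$n_sup, counts$n_noninf,
                           counts$n_inf, MoreArgs = list(level = level)))
  modifiers <- unique(c(1, .modifier_bands$prevention$factors,
                        .modifier_bands$treatment$factors))
  eff <- as.vector(outer(base, modifiers))

  grid <- expand.grid(g45 = .enums$frequency_class,
                      g3 = .enums$frequency_class,
                      g12 = .enums$frequency_class,
                      int = .enums$interaction_class,
                      stringsAsFactors = FALSE)
  arm_sums <- .severity_table[grid$g45, "grades_4_5"] +
    .severity_table[grid$g3, "grade_3"] +
    .severity_table[grid$g12, "grades_1_2"] +
    .interaction_table[grid$int]
  net <- as.vector(outer(arm_sums, arm_sums, `-`))

  c(min = min(eff) + min(net), max = max(eff) + max(net))
}

#' Score a drug-indication dossier
#'
#' Runs the full assessment pipeline on a dossier: screens the trials
#' ([filter_trials()]), classifies the trial setting
#' ([classify_trial_setting()]), scores efficiency ([efficiency_score()]) and
#' the comparative risk profile ([risk_score()]), and combines them into the
#' total with its color band. When no trial survives screening the verdict is
#' `"not_assessable"` and no numeric score is produced — an explicit
#' assessment result in its own right, rendered as a yield sign.
#'
#' @param dossier An `evita_dossier` from [read_dossier()],
#'   [assessment_dossier()] or [synthetic_dossier()].
#' @param rounding Override the dossier's rounding option (`"none"` or
#'   `"half_up_integer"`).
#' @param yellow_half_width Override the dossier's yellow-band half-width.
#' @return An object of class `evita_result`: `context`, `setting`,
#'   `efficiency`, `risk`, `total` (the latter three `NULL` when not
#'   assessable), `band` (`"green"`, `"yellow"`, `"red"` or
#'   `"not_assessable"`) and `options`.
#' @export
#' @examples
#' res <- evita(read_dossier(evita_fixture("lenalidomide_mm")))
#' res$total # 6
#' summary(res)
evita <- function(dossier, rounding = NULL, yellow_half_width = NULL) {
  stopifnot(inherits(dossier, "evita_dossier"))
  opts <- dossier$options
  if (!is.null(rounding))
    opts$rounding <- check_enum(rounding, "rounding", "rounding")
  if (!is.null(yellow_half_width))
    opts$yellow_half_width <- check_scalar_number(
      yellow_half_width, "yellow_half_width", lower = 0)

  screened <- filter_trials(dossier$trials, dossier$context)
  setting <- classify_trial_setting(screened$included, dossier$context,
                                    screened$excluded)

  if (setting$value == "NA") {
    result <- list(context = dossier$context, setting = setting,
                   efficiency = NULL, risk = NULL, total = NULL,
                   band = "not_assessable", options = opts)
    return(structure(result, class = "evita_result"))
  }

  eff <- efficiency_score(screened$included, dossier$context,
                          rounding = opts$rounding)
  risk <- risk_score(dossier$drug_risk, dossier$comparator_risk)
  total <- combine_scores(eff, risk)
  structure(
    list(context = dossier$context, setting = setting, efficiency = eff,
         risk = risk, total = total,
         band = color_band(total, opts$yellow_half_width), options = opts),
    class = "evita_result")
}

#' @export
print.evita_result <- function(x, ...) {
  cat(sprintf("EVITA assessment: %s - %s\n", x$context$drug_name,
              x$context$indication))
  cat(sprintf("  aim %s | disease category %s | trial setting %s\n",
              x$context$therapeutic_aim, x$context$disease_category,
              x$setting$value))
  if (x$band == "not_assessable") {
    cat("  score: N/A (calculation not available; no eligible trial)\n")
  } else {
    cat(sprintf("  efficiency %+g | risk %+g | total %+g [%s]\n",
                x$efficiency$reported_score, x$risk$net_score, x$total, x$band))
  }
  invisible(x)
}

#' @export
summary.evita_result <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$setting$excluded_trials)) {
    cat("Excluded trials:\n")
    for (i in seq_len(nrow(x$setting$excluded_trials)))
      cat(sprintf("  - %s: %s\n", x$setting$excluded_trials$trial_id[i],
                  x$setting$excluded_trials$reason[i]))
  }
  if (length(x$setting$included_trials))
    cat("Included trials:", paste(x$setting$included_trials, collapse = ", "),
        "\n")
  if (!is.null(x$efficiency)) {
    print(x$efficiency)
    for (note in x$efficiency$notes) cat("  note:", note, "\n")
    print(x$risk)
    print(x$risk$breakdown)
  }
  invisible(x)
}

.band_colors <- c(green = "#2e8b57", yellow = "#e6b800", red = "#c0392b")

#' Plot an assessment as the color-coded score bar
#'
#' Draws the horizontal score bar on the fixed -25 to +25 axis so bar
#' positions are comparable across drugs, or the yield-sign glyph (triangle
#' with a question mark) for a not-assessable verdict.
#'
#' @param x An `evita_result`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.evita_result <- function(x, ...) {
  op <- graphics::par(mar = c(3, 1, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-25, 25), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s (%s, aim %s, category %s)",
                                x$context$drug_name, x$setting$value,
                                x$context$therapeutic_aim,
                                x$context$disease_category))
  graphics::axis(1, at = seq(-25, 25, 5))
  graphics::abline(v = 0, lty = 2, col = "grey40")
  if (x$band == "not_assessable") {
    graphics::polygon(c(-4, 4, 0), c(0.2, 0.2, 0.8), border = "#c0392b",
                      col = "white", lwd = 3)
    graphics::text(0, 0.42, "?", cex = 2.5)
    graphics::mtext("N/A: calculation not available", side = 1, line = 2)
  } else {
    graphics::rect(min(0, x$total), 0.3, max(0, x$total), 0.7,
                   col = .band_colors[[x$band]], border = NA)
    graphics::text(x$total, 0.8, sprintf("%+g", x$total))
  }
  invisible(x)
}
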