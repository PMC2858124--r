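# Report rendering: machine-readable JSON with the full audit trail, and
# HTML / SVG presentations of the color-coded score bar (or the yield sign
# for a not-assessable verdict).

REPORT_SCHEMA_VERSION <- 1L

result_to_list <- function(result) {
  stopifnot(inherits(result, "evita_result"))
  out <- list(
    schema = "evita_report", schema_version = REPORT_SCHEMA_VERSION,
    context = drop_null(unclass(result$context)),
    trial_setting = list(
      value = result$setting$value,
      included_trials = as.list(result$setting$included_trials),
      excluded_trials = lapply(seq_len(nrow(result$setting$excluded_trials)),
        function(i) list(trial_id = result$setting$excluded_trials$trial_id[i],
                         reason = result$setting$excluded_trials$reason[i]))),
    band = result$band,
    options = result$options)
  if (result$band != "not_assessable") {
    eff <- result$efficiency
    out$efficiency <- list(
      n_superiority = eff$n_superiority,
      n_noninferiority = eff$n_noninferiority,
      n_inferiority = eff$n_inferiority,
      n_no_significant_difference = eff$n_no_significant_difference,
      outcome_level_used = eff$outcome_level_used,
      base_sum = eff$base_sum,
      modifier = if (is.na(eff$modifier)) NULL else eff$modifier,
      raw_score = eff$raw_score, reported_score = eff$reported_score,
      rounding = eff$rounding, notes = as.list(eff$notes))
    risk <- result$risk
    out$risk <- list(
      drug_sum = risk$drug_sum, comparator_sum = risk$comparator_sum,
      net_score = risk$net_score,
      breakdown = lapply(seq_len(nrow(risk$breakdown)), function(i)
        as.list(risk$breakdown[i, ])))
    out$total <- result$total
  }
  out
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_svg <- function(result) {
  # 500x120 canvas; score axis -25..+25 mapped to x in [20, 480]
  xpos <- function(v) 20 + (v + 25) / 50 * 460
  header <- sprintf(
    '<text x="250" y="18" text-anchor="middle" font-size="13" font-family="sans-serif">%s — %s | aim: %s | disease category %s | setting %s</text>',
    svg_escape(result$context$drug_name), svg_escape(result$context$indication),
    result$context$therapeutic_aim, result$context$disease_category,
    result$setting$value)
  axis <- paste0(
    sprintf('<line x1="%g" y1="80" x2="%g" y2="80" stroke="black"/>',
            xpos(-25), xpos(25)),
    paste(sprintf(
      '<line x1="%g" y1="77" x2="%g" y2="83" stroke="black"/><text x="%g" y="97" text-anchor="middle" font-size="9" font-family="sans-serif">%d</text>',
      xpos(seq(-25, 25, 5)), xpos(seq(-25, 25, 5)), xpos(seq(-25, 25, 5)),
      seq(-25L, 25L, 5L)), collapse = ""))
  body <- if (result$band == "not_assessable") {
    sprintf(paste0(
      '<polygon points="%g,40 %g,40 %g,72" fill="white" stroke="#c0392b" stroke-width="5"/>',
      '<text x="%g" y="62" text-anchor="middle" font-size="20" font-family="sans-serif">?</text>',
      '<text x="%g" y="36" text-anchor="middle" font-size="11" font-family="sans-serif">N/A — calculation not available</text>'),
      xpos(0) - 22, xpos(0) + 22, xpos(0), xpos(0), xpos(0))
  } else {
    x0 <- xpos(min(0, result$total))
    x1 <- xpos(max(0, result$total))
    sprintf(paste0(
      '<rect x="%g" y="55" width="%g" height="20" fill="%s"/>',
      '<text x="%g" y="50" text-anchor="middle" font-size="12" font-family="sans-serif">%+g</text>'),
      x0, max(x1 - x0, 0.5), .band_colors[[result$band]],
      xpos(result$total), result$total)
  }
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="500" height="120" viewBox="0 0 500 120">',
         header, axis,
         sprintf('<line x1="%g" y1="50" x2="%g" y2="80" stroke="grey" stroke-dasharray="3,3"/>',
                 xpos(0), xpos(0)),
         body, '</svg>')
}

render_html <- function(result) {
  rows <- if (result$band == "not_assessable") {
    "<p><strong>Verdict:</strong> N/A — EVITA calculation not available (no eligible trial).</p>"
  } else {
    sprintf(paste0(
      "<p><strong>Efficiency score:</strong> %+g (base %.4g%s)</p>",
      "<p><strong>Risk score:</strong> %+g (drug %g vs comparator %g)</p>",
      "<p><strong>Total:</strong> %+g — band <span style=\"color:%s\">%s</span></p>"),
      result$efficiency$reported_score, result$efficiency$base_sum,
      if (is.na(result$efficiency$modifier)) ""
      else sprintf(" &times; modifier %.2f", result$efficiency$modifier),
      result$risk$net_score, result$risk$drug_sum, result$risk$comparator_sum,
      result$total, .band_colors[[result$band]], result$band)
  }
  excl <- result$setting$excluded_trials
  audit <- if (nrow(excl)) paste0(
    "<h2>Excluded trials</h2><ul>",
    paste(sprintf("<li>%s: %s</li>", svg_escape(excl$trial_id),
                  svg_escape(excl$reason)), collapse = ""),
    "</ul>") else ""
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><title>EVITA: ",
    svg_escape(result$context$drug_name), "</title></head><body>",
    sprintf("<h1>EVITA assessment: %s</h1>", svg_escape(result$context$drug_name)),
    sprintf("<p>%s | therapeutic aim: %s | disease category %s | trial setting %s</p>",
            svg_escape(result$context$indication),
            result$context$therapeutic_aim, result$context$disease_category,
            result$setting$value),
    render_svg(result), rows, audit, "</body></html>")
}

#' Render an assessment report
#'
#' Produces the report document as a single string: `"json"` carries every
#' intermediate value and the complete inclusion/exclusion audit trail;
#' `"html"` and `"svg"` show the color-coded score bar on the fixed -25..+25
#' axis (or the yield-sign glyph for a not-assessable verdict) together with
#' the aim and disease-category annotations.
#'
#' @param result An `evita_result` from [evita()].
#' @param format `"json"`, `"html"` or `"svg"`.
#' @return A character scalar with the document.
#' @seealso [write_report()]
#' @export
render_report <- function(result, format = c("json", "html", "svg")) {
  stopifnot(inherits(result, "evita_result"))
  format <- match.arg(format)
  switch(format,
    json = as.character(jsonlite::toJSON(result_to_list(result),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)),
    html = render_html(result),
    svg = render_svg(result))
}

#' Write an assessment report to a file
#'
#' @param result An `evita_result`.
#' @param path Output path; the format defaults to the file extension.
#' @param format Report format, `"json"`, `"html"` or `"svg"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path,
                         format = c("json", "html", "svg")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("json", "html", "svg")) ext else "json"
  } else {
    format <- match.arg(format)
  }
  writeLines(render_report(result, format), path)
  invisible(path)
}
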