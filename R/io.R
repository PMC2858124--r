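# Dossier file I/O. One YAML or JSON document per drug-indication pair,
# carrying a schema tag and version so future revisions of the format can be
# detected on load.

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

dossier_to_list <- function(dossier) {
  trial_to_list <- function(tr) {
    jd <- tr$jadad
    if (inherits(jd, "evita_jadad")) jd <- unclass(jd)
    drop_null(list(
      trial_id = tr$trial_id, comparator_kind = tr$comparator_kind,
      outcome_level = tr$outcome_level, result = tr$result, jadad = jd,
      duration_years = tr$duration_years, nnt = tr$nnt, arr = tr$arr,
      duplicate_protocol_key = tr$duplicate_protocol_key,
      exclusion_note = tr$exclusion_note))
  }
  arm_to_list <- function(a) unclass(a)
  list(
    schema = dossier$schema, schema_version = dossier$schema_version,
    context = drop_null(unclass(dossier$context)),
    trials = lapply(dossier$trials, trial_to_list),
    drug_risk = arm_to_list(dossier$drug_risk),
    comparator_risk = arm_to_list(dossier$comparator_risk),
    options = dossier$options)
}

dossier_from_list <- function(x, source = "<dossier>") {
  if (!is.list(x)) abort_validation("document is not a mapping/object")
  if (is.null(x$schema) || !identical(as.character(x$schema), DOSSIER_SCHEMA))
    abort_validation(sprintf("schema must be \"%s\"", DOSSIER_SCHEMA), "schema")
  if (is.null(x$schema_version) ||
      as.integer(x$schema_version) != DOSSIER_SCHEMA_VERSION)
    abort_validation(sprintf("unsupported schema_version (expected %d)",
                             DOSSIER_SCHEMA_VERSION), "schema_version")
  ctx <- x$context
  if (is.null(ctx)) abort_validation("missing", "context")
  context <- therapeutic_context(
    drug_name = ctx$drug_name, indication = ctx$indication,
    therapeutic_aim = ctx$therapeutic_aim,
    disease_category = ctx$disease_category,
    established_therapies = unlist(ctx$established_therapies) %||% character(),
    atc_code = ctx$atc_code)
  trial_from_list <- function(tr) {
    jd <- tr$jadad
    if (is.list(jd))
      jd <- jadad_items(
        randomization_mentioned = jd$randomization_mentioned %||% FALSE,
        randomization_appropriate = jd$randomization_appropriate %||% "not_described",
        blinding_mentioned = jd$blinding_mentioned %||% FALSE,
        blinding_appropriate = jd$blinding_appropriate %||% "not_described",
        withdrawals_described = jd$withdrawals_described %||% FALSE)
    trial_record(
      trial_id = tr$trial_id, comparator_kind = tr$comparator_kind,
      outcome_level = tr$outcome_level, result = tr$result, jadad = jd,
      duration_years = tr$duration_years, nnt = tr$nnt, arr = tr$arr,
      duplicate_protocol_key = tr$duplicate_protocol_key,
      exclusion_note = tr$exclusion_note)
  }
  arm_from_list <- function(a, field) {
    if (is.null(a)) abort_validation("missing", field)
    arm_risk_profile(
      arm_label = a$arm_label, grade_4_5_freq = a$grade_4_5_freq,
      grade_3_freq = a$grade_3_freq, grade_1_2_freq = a$grade_1_2_freq,
      interaction_class = a$interaction_class)
  }
  assessment_dossier(
    context = context,
    trials = lapply(x$trials %||% list(), trial_from_list),
    drug_risk = arm_from_list(x$drug_risk, "drug_risk"),
    comparator_risk = arm_from_list(x$comparator_risk, "comparator_risk"),
    options = x$options %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
}

#' Read an assessment dossier from a YAML or JSON file
#'
#' Loads and fully validates a dossier document. The format is inferred from
#' the file extension (`.json` for JSON, anything else is parsed as YAML,
#' which is a superset of JSON). Every domain invariant is re-checked on
#' load; violations raise a classed validation error naming the offending
#' field and the admissible values.
#'
#' @param path Path to the dossier file.
#' @return An `evita_dossier` object.
#' @seealso [write_dossier()], [evita_fixture()]
#' @export
read_dossier <- function(path) {
  if (!file.exists(path)) stop("dossier file not found: ", path)
  x <- if (guess_format(path) == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  dossier_from_list(x, source = path)
}

#' Write an assessment dossier to a YAML or JSON file
#'
#' The inverse of [read_dossier()]: writes a document that re-reads to a
#' structurally equal dossier. Format is inferred from the extension.
#'
#' @param dossier An `evita_dossier`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_dossier <- function(dossier, path) {
  stopifnot(inherits(dossier, "evita_dossier"))
  x <- dossier_to_list(dossier)
  if (guess_format(path) == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 12L)
  }
  invisible(path)
}

#' Path to a bundled example dossier
#'
#' The package ships the four worked drug evaluations as dossier fixtures:
#' `"lenalidomide_mm"` (relapsed/refractory multiple myeloma),
#' `"pioglitazone_dm2_2001"` and `"pioglitazone_dm2_2005"` (type-2 diabetes,
#' evaluated at two time points), `"bupropion_depression"` (major
#' depression) and `"zoledronic_pmo"` (postmenopausal osteoporosis; rated
#' not assessable).
#'
#' @param name Fixture name (with or without the `.yaml` extension). With no
#'   arguments, returns the available fixture names.
#' @return A file path, or a character vector of names.
#' @export
#' @examples
#' evita_fixture()
#' d <- read_dossier(evita_fixture("bupropion_depression"))
evita_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "evita")
  if (is.null(name))
    return(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
  file <- if (grepl("\\.(yaml|yml|json)$", name)) name else paste0(name, ".yaml")
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("no bundled dossier named '", name, "'; see evita_fixture()")
  path
}
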