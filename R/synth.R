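# Synthetic dossier generator: random but always-valid assessment dossiers
# for property testing and pipeline exercise. Deterministic per seed and
# isolated from the caller's RNG state.

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample1 <- function(x) x[[sample.int(length(x), 1L)]]

synth_freq <- function() {
  # hit every frequency class with positive probability, incl. exact zero
  switch(sample1(.enums$frequency_class),
         zero = 0,
         `below_0.1` = stats::runif(1, 0.001, 0.099),
         `0.1_to_1` = stats::runif(1, 0.1, 0.99),
         `1_to_10` = stats::runif(1, 1, 9.9),
         `10_plus` = stats::runif(1, 10, 95))
}

synth_arm <- function(label) {
  arm_risk_profile(
    arm_label = label,
    grade_4_5_freq = synth_freq(), grade_3_freq = synth_freq(),
    grade_1_2_freq = synth_freq(),
    interaction_class = sample1(.enums$interaction_class))
}

synth_jadad <- function() {
  rand_m <- stats::runif(1) < 0.8
  blind_m <- stats::runif(1) < 0.7
  jadad_items(
    randomization_mentioned = rand_m,
    randomization_appropriate = if (rand_m) sample1(.enums$appropriateness)
                                else "not_described",
    blinding_mentioned = blind_m,
    blinding_appropriate = if (blind_m) sample1(.enums$appropriateness)
                           else "not_described",
    withdrawals_described = stats::runif(1) < 0.7)
}

synth_trial <- function(i, dup_key) {
  nnt <- NULL; arr <- NULL; duration <- NULL
  u <- stats::runif(1)
  if (u < 0.5) {
    nnt <- round(stats::runif(1, 1, 50), 2)
    duration <- round(stats::runif(1, 0.25, 5), 2)
    if (stats::runif(1) < 0.3) arr <- round(1 / nnt, 6)
  }
  trial_record(
    trial_id = sprintf("TRIAL-%03d", i),
    comparator_kind = sample1(.enums$comparator_kind),
    outcome_level = sample1(.enums$outcome_level),
    result = sample1(.enums$result),
    jadad = if (stats::runif(1) < 0.7) synth_jadad()
            else sample.int(6L, 1L) - 1L,
    duration_years = duration, nnt = nnt, arr = arr,
    duplicate_protocol_key = if (stats::runif(1) < 0.15) dup_key else NULL)
}

#' Generate a random, valid assessment dossier
#'
#' Produces a structurally valid dossier with randomized context, trials and
#' risk profiles. Every enumerated field value is drawn with positive
#' probability (including trials that will be excluded on quality or
#' comparator grounds, twin-protocol pairs, and exact-zero adverse-event
#' frequencies), so the generator exercises every branch of the screening and
#' scoring rules. Output is deterministic for a fixed `(seed, n_trials)` pair
#' and the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_trials Number of trial records (>= 0; 0 forces a not-assessable
#'   verdict).
#' @return An `evita_dossier`.
#' @export
#' @examples
#' d <- synthetic_dossier(seed = 1, n_trials = 3)
#' evita(d)
synthetic_dossier <- function(seed, n_trials = 3L) {
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed)))
    stop("seed must be a single integer")
  if (!(is.numeric(n_trials) && length(n_trials) == 1L && n_trials >= 0 &&
        n_trials == as.integer(n_trials)))
    stop("n_trials must be a non-negative integer")
  n_trials <- as.integer(n_trials)
  with_preserved_rng(seed, {
    n_est <- sample.int(4L, 1L) - 1L
    context <- therapeutic_context(
      drug_name = sprintf("synthvir-%04d", sample.int(9999L, 1L)),
      atc_code = if (stats::runif(1) < 0.5)
        paste0(sample(LETTERS, 1), sprintf("%02d", sample.int(16L, 1L)),
               sample(LETTERS, 1), sample(LETTERS, 1),
               sprintf("%02d", sample.int(99L, 1L))) else NULL,
      indication = sprintf("synthetic indication %02d", sample.int(99L, 1L)),
      therapeutic_aim = sample1(.enums$therapeutic_aim),
      disease_category = sample1(.enums$disease_category),
      established_therapies = if (n_est > 0L)
        sprintf("established therapy %d", seq_len(n_est)) else character())
    dup_key <- sprintf("protocol-%03d", sample.int(999L, 1L))
    trials <- lapply(seq_len(n_trials), synth_trial, dup_key = dup_key)
    assessment_dossier(
      context = context, trials = trials,
      drug_risk = synth_arm(context$drug_name),
      comparator_risk = synth_arm("comparator"),
      options = list(rounding = sample1(.enums$rounding),
                     yellow_half_width = 2))
  })
}
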