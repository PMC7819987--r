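#' Study configuration
#'
#' Bundles everything [runStudy()] needs.  Two entry modes: `"table"` runs
#' on a patient-level cohort table (supplied or simulated), `"image"`
#' derives the sign, volumes and expansion calls from baseline/follow-up CT
#' volumes first and then proceeds identically.
#'
#' @param mode `"table"` or `"image"`.
#' @param cohort optional `CohortTable`; when `NULL` in table mode, a cohort
#'   is simulated from `params`.
#' @param params a [cohortParams()] list used when simulating.
#' @param imageManifest image-mode input: data.frame with columns
#'   `baselineNifti`, `followupNifti` plus the baseline covariate columns
#'   (and `id`).
#' @param covariates propensity-model covariates; default
#'   [baselineCovariates()].
#' @param caliper matching caliper on the propensity-score scale.
#' @param seed integer seed (mandatory); drives simulation and match order.
#' @param subgroups named list of predefined stratification factors; each
#'   element is a function of the cohort returning a binary vector.  The
#'   default set: sex, age 65 or older, moderate/severe GCS, baseline
#'   volume of 10 mL or more, time to CT of 3 h or more, coagulopathy.
#' @param segmentation a [segmentationConfig()] for image mode.
#' @return list of class `StudyConfig`
#' @export
studyConfig <- function(mode = c("table", "image"), cohort = NULL,
                        params = cohortParams(), imageManifest = NULL,
                        covariates = baselineCovariates(), caliper = 0.05,
                        seed = 1L, subgroups = defaultSubgroups(),
                        segmentation = segmentationConfig()) {
  mode <- match.arg(mode)
  if (is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory")
  if (mode == "image" && is.null(imageManifest))
    stop("image mode requires an imageManifest")
  structure(list(mode = mode, cohort = cohort, params = params,
                 imageManifest = imageManifest, covariates = covariates,
                 caliper = caliper, seed = as.integer(seed),
                 subgroups = subgroups, segmentation = segmentation),
            class = c("StudyConfig", "list"))
}

#' Predefined subgroup definitions
#'
#' @return named list of functions mapping a cohort table to binary vectors
#' @export
defaultSubgroups <- function() {
  list(male = function(d) d$male,
       age_ge_65 = function(d) as.numeric(d$age >= 65),
       gcs_moderate_severe = function(d) as.numeric(d$gcs != "mild"),
       volume_ge_10ml = function(d) as.numeric(d$baseline_volume >= 10),
       time_to_ct_ge_3h = function(d) as.numeric(d$time_to_ct >= 3),
       coagulopathy = function(d) d$coagulopathy)
}

# pre-match effect rows + PS matching + matched conditional estimate for one
# cohort; shared by the primary analysis and the >= 3 hematoma sensitivity
# analysis
analyseCohort <- function(cohort, covariates, caliper, seed,
                          minPairs = 10L, label = "primary") {
  ps <- estimatePropensity(cohort, covariates)
  effects <- rbind(
    adjustedOR(cohort, adjustment = "none"),
    adjustedOR(cohort, adjustment = "sex_age"),
    adjustedOR(cohort, adjustment = "individual_confounders",
               confounders = covariates),
    adjustedOR(cohort, adjustment = "ps_covariate", ps = ps$scores))
  matched <- greedyMatch(ps$scores, cohort$sign == 1, caliper = caliper,
                         seed = seed, ids = cohort$id)
  pr <- matchedPairs(matched)
  if (nrow(pr) < minPairs)
    stop(sprintf(
      "matching produced only %d pair(s) (< %d) in the %s analysis; %d treated unmatched at caliper %.3g",
      nrow(pr), minPairs, label, length(unmatchedTreated(matched)), caliper))
  tOut <- cohort$expanded[match(pr$treated, cohort$id)]
  cOut <- cohort$expanded[match(pr$control, cohort$id)]
  cond <- matchedConditionalOR(tOut, cOut)
  eff <- cond$effect
  eff$nUsed <- nrow(pr)
  effects <- rbind(effects, eff)
  list(effects = effects, matched = matched, ps = ps,
       mcnemar = cond$mcnemar,
       matchedOutcome = list(treated = tOut, control = cOut))
}

# image-mode front end: detect sign + volumes per scan pair, build the
# cohort table columns the statistical half expects
cohortFromImages <- function(manifest, cfg) {
  need <- c("id", "baselineNifti", "followupNifti")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0L)
    stop("imageManifest is missing columns: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    vol <- readCTVolume(manifest$baselineNifti[i])
    seg <- segmentHematomas(vol, cfg)
    ev <- detectFuzzySign(vol, seg, cfg)
    fvol <- readCTVolume(manifest$followupNifti[i])
    fseg <- segmentHematomas(fvol, cfg)
    data.frame(id = manifest$id[i],
               baseline_volume = totalHematomaVolume(seg),
               followup_volume = totalHematomaVolume(fseg),
               n_hematomas = nrow(hematomaComponents(seg)),
               sign = as.integer(signCall(ev)))
  })
  img <- do.call(rbind, rows)
  img$multiple_hematomas <- as.integer(img$n_hematomas >= 3L)
  img$expanded <- as.integer(
    classifyExpansion(img$baseline_volume, img$followup_volume)$expanded)
  covars <- manifest[, setdiff(names(manifest), c(need, names(img))),
                     drop = FALSE]
  cbind(img, covars)
}

#' Run the full matched-cohort study replica
#'
#' Applies the eligibility filters, estimates the sign propensity score,
#' computes the effect of the sign on expansion under five schemes (crude,
#' sex/age-adjusted, adjusted for all individual confounders,
#' propensity-score adjusted, and the pair-stratified conditional estimate
#' after 1:1 caliper matching), repeats the analysis restricted to patients
#' with three or more hematomas, runs the predefined subgroup/interaction
#' analyses on the matched sample, and compares the sign against multiple
#' hematomas, time to baseline CT (inverted: shorter delay = higher risk)
#' and baseline volume by ROC on the pre-matched cohort.
#'
#' @param config a [studyConfig()].
#' @return a [StudyReport-class]
#' @examples
#' \donttest{
#' rep <- runStudy(studyConfig(params = cohortParams(nPatients = 482),
#'                             seed = 11))
#' effectTable(rep)
#' }
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  cohort <- switch(config$mode,
                   table = if (!is.null(config$cohort)) config$cohort else
                     generateCohort(config$params, seed = config$seed),
                   image = cohortFromImages(config$imageManifest,
                                            config$segmentation))
  need <- unique(c(config$covariates, "id", "sign", "expanded",
                   "multiple_hematomas"))
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L)
    stop("cohort is missing required columns: ", paste(miss, collapse = ", "))
  nScreened <- nrow(cohort)
  cohort <- applyEligibility(cohort)
  elig <- attr(cohort, "eligibility")
  elig <- rbind(data.frame(criterion = "screened", excluded = 0L,
                           remaining = nScreened), elig)

  main <- analyseCohort(cohort, config$covariates, config$caliper,
                        seed = config$seed, label = "primary")

  sens <- tryCatch({
    sub <- cohort[cohort$multiple_hematomas == 1L, , drop = FALSE]
    analyseCohort(sub, config$covariates, config$caliper,
                  seed = config$seed + 1L, minPairs = 10L,
                  label = "multiple-hematoma sensitivity")$effects
  }, error = function(e)
    effectRow("sensitivity_unavailable", NA, NA, NA, NA, 0L,
              note = conditionMessage(e)))

  pr <- matchedPairs(main$matched)
  msel <- c(match(pr$treated, cohort$id), match(pr$control, cohort$id))
  msample <- cohort[msel, , drop = FALSE]
  factors <- lapply(config$subgroups, function(f) f(msample))
  sg <- subgroupInteraction(msample, factors)

  balance <- balanceReport(cohort, main$matched, config$covariates)

  roc <- rbind(
    rocAuc(cohort$sign, cohort$expanded, label = "multihematoma_fuzzy_sign"),
    rocAuc(cohort$multiple_hematomas, cohort$expanded,
           label = "multiple_hematomas"),
    rocAuc(-cohort$time_to_ct, cohort$expanded,
           label = "time_to_baseline_ct_inverted"),
    rocAuc(cohort$baseline_volume, cohort$expanded,
           label = "baseline_volume"))

  expandedMatchedT <- main$matchedOutcome$treated
  expandedMatchedC <- main$matchedOutcome$control
  summary_ <- list(
    nEligible = nrow(cohort),
    signPrevalencePct = 100 * mean(cohort$sign),
    expansionIncidencePct = 100 * mean(cohort$expanded),
    nPairs = nrow(pr),
    matchedExpansionIncidencePct =
      100 * mean(c(expandedMatchedT, expandedMatchedC)),
    matchedSignExpansionPct = 100 * mean(expandedMatchedT),
    matchedNoSignExpansionPct = 100 * mean(expandedMatchedC))

  new("StudyReport", eligibility = elig, balance = balance,
      effects = main$effects, sensitivity = sens,
      subgroups = sg$estimates, interactions = sg$interactions,
      roc = roc,
      matching = list(nPairs = nrow(pr),
                      nUnmatchedTreated = length(
                        unmatchedTreated(main$matched)),
                      caliper = config$caliper,
                      mcnemar = main$mcnemar),
      cohortSummary = summary_)
}

#' @rdname effectTable
setMethod("effectTable", "StudyReport", function(object) object@effects)

#' @rdname balanceTable
setMethod("balanceTable", "StudyReport", function(object) object@balance)

setMethod("show", "StudyReport", function(object) {
  s <- object@cohortSummary
  cat(sprintf(
    "StudyReport: %d eligible patients, sign prevalence %.1f%%, expansion %.1f%%\n",
    s$nEligible, s$signPrevalencePct, s$expansionIncidencePct))
  cat(sprintf("  %d matched pairs (caliper %.3g); McNemar chi2 %.2f\n",
              object@matching$nPairs, object@matching$caliper,
              object@matching$mcnemar$statistic))
  print(object@effects[, c("method", "oddsRatio", "ciLow", "ciHigh",
                           "pValue", "nUsed")], digits = 3)
  cat("ROC (pre-matched cohort):\n")
  print(object@roc, digits = 3)
})

#' Serialise a StudyReport to JSON (plus plot-ready CSVs)
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(eligibility = report@eligibility, balance = report@balance,
              effects = report@effects, sensitivity = report@sensitivity,
              subgroups = report@subgroups,
              interactions = report@interactions, roc = report@roc,
              matching = report@matching,
              cohortSummary = report@cohortSummary)
  path <- file.path(dir, "study_report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  utils::write.csv(report@balance, file.path(dir, "balance_love_plot.csv"),
                   row.names = FALSE)
  utils::write.csv(report@effects, file.path(dir, "effects.csv"),
                   row.names = FALSE)
  utils::write.csv(report@roc, file.path(dir, "roc_auc.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Load a StudyReport written by [writeStudyReport()]
#'
#' @param path path to `study_report.json`.
#' @return a [StudyReport-class]
#' @export
readStudyReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDF <- function(v) as.data.frame(v, stringsAsFactors = FALSE)
  new("StudyReport", eligibility = asDF(x$eligibility),
      balance = asDF(x$balance), effects = asDF(x$effects),
      sensitivity = asDF(x$sensitivity), subgroups = asDF(x$subgroups),
      interactions = asDF(x$interactions), roc = asDF(x$roc),
      matching = x$matching, cohortSummary = x$cohortSummary)
}

#' Headline statistics from the packaged printed-count fixture
#'
#' Recomputes the study's headline proportions (sign prevalence, expansion
#' incidence, matched-group expansion proportions) and the matched 2x2
#' summaries from a table of published counts.  The packaged fixture
#' (`system.file("extdata", "printed_study_counts.csv", package =
#' "fuzzyct")`) holds the development- and validation-cohort counts as
#' printed.
#'
#' @param path CSV with columns `cohort`, `quantity`, `count`; defaults to
#'   the packaged fixture.
#' @return named list of percentages and derived statistics
#' @export
summarizeFixture <- function(path = system.file("extdata",
                                                "printed_study_counts.csv",
                                                package = "fuzzyct")) {
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cohort", "quantity", "count") %in% names(counts)))
    stop("malformed fixture: need cohort, quantity, count columns")
  get <- function(cohort, quantity) {
    v <- counts$count[counts$cohort == cohort & counts$quantity == quantity]
    if (length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("malformed fixture: missing count %s/%s",
                   cohort, quantity))
    v
  }
  devN <- get("development", "patients")
  valN <- get("validation", "patients")
  vmPairs <- get("validation_matched", "pairs")
  vmSignExp <- get("validation_matched", "sign_expanded")
  vmNoExp <- get("validation_matched", "nosign_expanded")
  dmPairs <- get("development_matched", "pairs")
  or <- oddsRatio2x2(vmSignExp, vmPairs - vmSignExp,
                     vmNoExp, vmPairs - vmNoExp,
                     method = "validation_matched_2x2")
  auc <- (vmSignExp / (vmSignExp + vmNoExp) +
            (vmPairs - vmNoExp) / (2 * vmPairs - vmSignExp - vmNoExp)) / 2
  list(
    sign_prevalence_pct = 100 * get("development", "fuzzy_sign") / devN,
    development_expansion_pct = 100 * get("development", "expansion") / devN,
    validation_expansion_pct = 100 * get("validation", "expansion") / valN,
    validation_matched_sign_expansion_pct = 100 * vmSignExp / vmPairs,
    validation_matched_nosign_expansion_pct = 100 * vmNoExp / vmPairs,
    development_matched_sign_expansion_pct =
      100 * get("development_matched", "sign_expanded") / dmPairs,
    development_matched_nosign_expansion_pct =
      100 * get("development_matched", "nosign_expanded") / dmPairs,
    validation_matched_or = or$oddsRatio,
    validation_matched_sign_auc = auc)
}
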