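#' Cohort generation configuration
#'
#' Describes one synthetic case-control cohort: class sizes, scenario
#' (training cases carry the full marker effect, validation cases the
#' attenuated effect and 1:1 matched controls), stratum mixes for
#' radiographic finding, tumor stage and histology (cases only), and the
#' common pairwise correlation of log marker levels.
#'
#' @param n_cases,n_controls Positive class sizes. The validation scenario is
#'   individually matched, so it requires `n_controls == n_cases`.
#' @param scenario `"training"` or `"validation"`.
#' @param finding_mix Named proportions over findings (`nodule`, `mass`,
#'   `other`) for cases; must sum to 1. Training-scenario subjects, drawn
#'   outside a radiographic workup, get `NA` findings and the mix is ignored.
#' @param stage_mix,histology_mix Named proportions over stage / histology
#'   labels for cases (controls have none); each must sum to 1.
#' @param correlation Common pairwise correlation of log marker levels, in
#'   `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @seealso [training_config()], [validation_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_cases, n_controls,
                          scenario = c("training", "validation"),
                          finding_mix = c(nodule = 1),
                          stage_mix = c(IA = 1),
                          histology_mix = c(Adenocarcinoma = 1),
                          correlation = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_cases > 0, n_controls > 0)
  if (scenario == "validation" && n_cases != n_controls)
    stop("validation scenario emits 1:1 matched pairs; n_controls must equal n_cases")
  check_mix <- function(mix, what) {
    if (is.null(names(mix)) || any(!nzchar(names(mix))))
      stop(what, " must be a named proportion vector")
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      stop(what, " must be non-negative and sum to 1")
    mix
  }
  if (!is.numeric(correlation) || correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         scenario = scenario,
         finding_mix = check_mix(finding_mix, "finding_mix"),
         stage_mix = check_mix(stage_mix, "stage_mix"),
         histology_mix = check_mix(histology_mix, "histology_mix"),
         correlation = correlation, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default training-study configuration
#'
#' 95 early-stage NSCLC cases versus 186 healthy smoker controls; all cases
#' stage I, histology mix at the training-study frequencies; no radiographic
#' finding (subjects were not selected by imaging).
#'
#' @param seed Integer RNG seed.
#' @param correlation Common log-level correlation (default 0).
#' @return A [cohort_config()].
#' @export
training_config <- function(seed = 1L, correlation = 0) {
  cohort_config(
    n_cases = 95, n_controls = 186, scenario = "training",
    finding_mix = c(nodule = 1),
    stage_mix = c(I = 1),
    histology_mix = c(Adenocarcinoma = 63, BAC = 4, `Squamous cell` = 15,
                      `Large cell` = 6, NSCLC = 4, Neuroendocrine = 2,
                      Adenosquamous = 1) / 95,
    correlation = correlation, seed = seed)
}

#' Default validation-study configuration for one finding stratum
#'
#' 1:1 individually matched case-control pairs at the validation-study sizes
#' and stage/histology frequencies: 119 pairs with a pulmonary nodule
#' (< 3 cm), 50 pairs with a mass (> 3 cm), or 28 pairs with other suspicious
#' findings (pleural mass, hilar, infiltrate).
#'
#' @param finding `"nodule"`, `"mass"` or `"other"`.
#' @param seed Integer RNG seed.
#' @param correlation Common log-level correlation (default 0).
#' @return A [cohort_config()].
#' @export
validation_config <- function(finding = c("nodule", "mass", "other"),
                              seed = 1L, correlation = 0) {
  finding <- match.arg(finding)
  cfg <- switch(finding,
    nodule = list(
      n = 119,
      stage = c(I = 5, IA = 51, IB = 15, II = 10, III = 19, IV = 14,
                `NA` = 5) / 119,
      histology = c(Adenocarcinoma = 57, BAC = 20, `Squamous cell` = 25,
                    `Large cell` = 4, NSCLC = 2, Neuroendocrine = 2,
                    `Small cell` = 5, Adenosquamous = 4) / 119),
    mass = list(
      n = 50,
      stage = c(I = 16, II = 4, III = 16, IV = 10, `NA` = 4) / 50,
      histology = c(Adenocarcinoma = 24, BAC = 3, `Squamous cell` = 9,
                    `Large cell` = 4, NSCLC = 6, `Small cell` = 4) / 50),
    other = list(
      n = 28,
      stage = c(I = 9, II = 3, III = 3, IV = 8, `NA` = 5) / 28,
      histology = c(Adenocarcinoma = 12, BAC = 2, `Squamous cell` = 7,
                    `Large cell` = 1, NSCLC = 1, `Small cell` = 5) / 28))
  cohort_config(
    n_cases = cfg$n, n_controls = cfg$n, scenario = "validation",
    finding_mix = stats::setNames(1, finding),
    stage_mix = cfg$stage, histology_mix = cfg$histology,
    correlation = correlation, seed = seed)
}

# draw n log-level vectors ~ MVN(mu + shift, Sigma) given marker specs and a
# common pairwise correlation; returns an n x p matrix of concentrations
draw_levels <- function(n, specs, shift, correlation) {
  p <- length(specs)
  sig <- vapply(specs, `[[`, numeric(1), "sigma")
  mu <- vapply(specs, `[[`, numeric(1), "mu_control")
  corr <- matrix(correlation, p, p)
  diag(corr) <- 1
  sigma <- corr * tcrossprod(sig)
  ru <- chol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  loglev <- sweep(z %*% ru, 2L, mu + shift * sig, `+`)
  colnames(loglev) <- vapply(specs, `[[`, character(1), "name")
  exp(loglev)
}

# scenario-typical demographics (age mean/sd, pack-years mean/sd, P(male))
.demog <- list(
  training = list(case = list(age = c(66.5, 9.6), py = c(44.5, 21.3), pm = 34 / 95),
                  control = list(age = c(62.3, 11.8), py = c(37.4, 21.5), pm = 107 / 186)),
  validation = list(case = list(age = c(64.4, 5.3), py = c(55.3, 40.9), pm = 69 / 119),
                    control = NULL))  # matched: derived from the paired case

#' Generate a synthetic case-control cohort
#'
#' Draws log-normal marker levels (multivariate normal on the log scale with
#' a common pairwise correlation): controls at each marker's control mean,
#' cases shifted by `delta * sigma` where `delta` is the scenario-specific
#' standardized effect of the [marker_spec()]. Stage and histology labels are
#' apportioned to cases at exactly the configured frequencies
#' (largest-remainder rounding, then random assignment); controls carry
#' neither. In the validation scenario each case receives one individually
#' matched control with identical finding and gender, age within +/- 5 years
#' and pack-years within +/- 20 (the matching caliper).
#'
#' @param config A [cohort_config()].
#' @param markers List of [marker_spec()] objects (at least one).
#' @return A `data.frame`, one row per subject: `subject_id`, `label`
#'   (`case`/`control`), `finding`, `stage`, `histology`, `gender`, `age`,
#'   `pack_years`, `match_id`, then one concentration column per marker.
#' @export
generate_cohort <- function(config, markers) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(markers) < 1L) stop("at least one marker_spec is required")
  stopifnot(all(vapply(markers, inherits, logical(1), "marker_spec")))
  marker_names <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(marker_names)) stop("duplicate marker names")
  scen <- config$scenario
  m <- config$n_cases
  n0 <- config$n_controls

  with_seed(config$seed, {
    delta <- vapply(markers, `[[`, numeric(1),
                    if (scen == "training") "delta_train" else "delta_valid")
    case_lev <- draw_levels(m, markers, delta, config$correlation)
    ctrl_lev <- draw_levels(n0, markers, 0, config$correlation)

    # exact stratum counts for cases, shuffled over rows
    apportion <- function(mix, n) {
      counts <- alloc_counts(n, mix)
      sample(rep(names(counts), counts))
    }
    stage <- apportion(config$stage_mix, m)
    histology <- apportion(config$histology_mix, m)
    stage[stage == "NA"] <- NA_character_
    finding <- if (scen == "validation") apportion(config$finding_mix, m)
               else rep(NA_character_, m)

    dcase <- .demog[[scen]]$case
    case_age <- round(pmin(90, pmax(40, rnorm(m, dcase$age[1], dcase$age[2]))))
    case_py <- round(pmax(0, rnorm(m, dcase$py[1], dcase$py[2])), 1)
    case_gender <- ifelse(runif(m) < dcase$pm, "M", "F")

    case_df <- data.frame(
      subject_id = sprintf("case_%04d", seq_len(m)),
      label = "case", finding = finding, stage = stage,
      histology = histology, gender = case_gender, age = case_age,
      pack_years = case_py,
      match_id = if (scen == "validation") sprintf("pair_%04d", seq_len(m))
                 else NA_character_,
      stringsAsFactors = FALSE)

    if (scen == "validation") {
      # matched control generated from its case: shared finding and gender,
      # age and pack-years inside the caliper
      ctrl_df <- data.frame(
        subject_id = sprintf("ctrl_%04d", seq_len(n0)),
        label = "control", finding = finding, stage = NA_character_,
        histology = NA_character_, gender = case_gender,
        age = round(pmin(90, pmax(40, case_age + runif(n0, -3, 3)))),
        pack_years = round(pmax(0, case_py + runif(n0, -15, 15)), 1),
        match_id = sprintf("pair_%04d", seq_len(n0)),
        stringsAsFactors = FALSE)
      bad <- abs(ctrl_df$age - case_df$age) > 5 |
        abs(ctrl_df$pack_years - case_df$pack_years) > 20
      if (any(bad))
        stop("matching infeasible within caliper for stratum '",
             ctrl_df$finding[which(bad)[1]], "' (pair ",
             ctrl_df$match_id[which(bad)[1]], ")")
    } else {
      dctrl <- .demog[[scen]]$control
      ctrl_df <- data.frame(
        subject_id = sprintf("ctrl_%04d", seq_len(n0)),
        label = "control", finding = NA_character_, stage = NA_character_,
        histology = NA_character_,
        gender = ifelse(runif(n0) < dctrl$pm, "M", "F"),
        age = round(pmin(90, pmax(40, rnorm(n0, dctrl$age[1], dctrl$age[2])))),
        pack_years = round(pmax(0, rnorm(n0, dctrl$py[1], dctrl$py[2])), 1),
        match_id = NA_character_,
        stringsAsFactors = FALSE)
    }

    out <- rbind(cbind(case_df, as.data.frame(case_lev)),
                 cbind(ctrl_df, as.data.frame(ctrl_lev)))
    rownames(out) <- NULL
    out
  })
}

#' Generate a clotting-time stability series
#'
#' Emulates the pre-analytical experiment: serum from `n_donors` healthy
#' donors assayed after clotting for 0.5, 4 or 24 h. The 0.5 h level is the
#' donor's baseline draw from the marker's control distribution; later
#' timepoints are `baseline * drift_t * exp(noise)` with log-normal
#' measurement noise.
#'
#' @param markers List of [marker_spec()] objects.
#' @param n_donors Number of donors (>= 1).
#' @param noise_sd SD of the log-scale measurement noise at the 4 h and 24 h
#'   timepoints (0 = deterministic drift).
#' @param seed Integer RNG seed.
#' @return Long-format `data.frame` with columns `donor`, `marker`, `time_h`
#'   (0.5, 4, 24) and `level`; exactly three rows per donor per marker.
#' @export
generate_clotting_series <- function(markers, n_donors = 6, noise_sd = 0.05,
                                     seed = 1L) {
  stopifnot(n_donors >= 1, noise_sd >= 0)
  stopifnot(all(vapply(markers, inherits, logical(1), "marker_spec")))
  with_seed(seed, {
    rows <- lapply(markers, function(sp) {
      base <- exp(rnorm(n_donors, sp$mu_control, sp$sigma))
      noise <- function() exp(rnorm(n_donors, 0, noise_sd))
      data.frame(
        donor = rep(sprintf("donor_%02d", seq_len(n_donors)), times = 3),
        marker = sp$name,
        time_h = rep(c(0.5, 4, 24), each = n_donors),
        level = c(base, base * sp$drift_4h * noise(),
                  base * sp$drift_24h * noise()),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
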