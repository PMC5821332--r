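#' Default generating parameters for synthetic outcome rates
#'
#' Each synthetic outcome is generated as
#' `intercept + beta_black * pct_black + beta_miss * (MISS/100) + noise`,
#' clamped to its valid range. Intercepts sit near published national rates
#' for 2014-era US births; effect directions mirror the associations the
#' instrument was built to detect (integration raises physiologic-birth and
#' breastfeeding rates and lowers intervention and adverse-outcome rates),
#' with magnitudes chosen to give moderate state-level correlations.
#' Units: percentages of births, except neonatal mortality (per 1000).
#'
#' @return Tibble: `outcome`, `intercept`, `beta_black`, `beta_miss`,
#'   `noise_sd`, `lo`, `hi`.
#' @export
default_outcome_params <- function() {
  tibble::tribble(
    ~outcome,             ~intercept, ~beta_black, ~beta_miss, ~noise_sd, ~lo, ~hi,
    "svb",                 68,   -0.10,  15,   4,    0, 100,
    "vbac",                10,   -0.04,   8,   2.5,  0, 100,
    "induction",           25,    0.02,  -6,   3.5,  0, 100,
    "ptb",                  8.5,  0.06,  -3,   1,    0, 100,
    "lbw",                  7,    0.05,  -2,   0.8,  0, 100,
    "cesarean",            33,    0.08,  -8,   3,    0, 100,
    "neonatal_mortality",   4.5,  0.035, -2.5, 0.7,  0, 50,
    "bf_birth",            72,   -0.15,  20,   5,    0, 100,
    "bf_6mo",              45,   -0.12,  15,   6,    0, 100
  )
}

#' Configuration for the synthetic jurisdiction generator
#'
#' The generator emulates a cross-section of jurisdictions in which a
#' single latent integration level theta in \[0, 1\] drives both the
#' regulatory item responses (hence the composite score) and the midwifery
#' workforce, while outcome rates follow the two-block structure of the
#' ecological analysis (a race-composition effect plus an integration
#' effect plus noise). Profiles and vital records consume independent
#' random streams: changing one block's seed leaves the other block's
#' output identical.
#'
#' @param n_jurisdictions Number of jurisdictions (default 51, the 50
#'   states plus DC).
#' @param seed Master seed; the two stream seeds are derived from it
#'   deterministically and can be overridden individually.
#' @param seed_profiles,seed_vitals Stream seeds.
#' @param latent_shape Beta shape parameters for theta.
#' @param discrimination Steepness of the ordered-categorical response rule
#'   (> 0); larger values tie item responses more tightly to theta.
#' @param black_shape Beta shape parameters for the proportion of
#'   non-Hispanic Black births (scaled to percent).
#' @param births_range Annual births drawn log-uniformly over this range.
#' @param workforce_rate Expected midwives per 1000 births at theta = 1,
#'   named for the two credential groups.
#' @param outcome_params As [default_outcome_params()].
#' @return List of class `miss_sim_config`.
#' @export
sim_config <- function(n_jurisdictions = 51, seed = 1L,
                       seed_profiles = NULL, seed_vitals = NULL,
                       latent_shape = c(4, 6), discrimination = 4,
                       black_shape = c(1.6, 8.4),
                       births_range = c(6000, 500000),
                       workforce_rate = c(cnm_cm = 1.5, cpm = 0.6),
                       outcome_params = default_outcome_params()) {
  if (n_jurisdictions < 4) stop("need at least 4 jurisdictions", call. = FALSE)
  if (discrimination <= 0) stop("discrimination must be > 0", call. = FALSE)
  if (any(outcome_params$noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  missing_oc <- setdiff(unname(miss_outcomes), outcome_params$outcome)
  if (length(missing_oc) > 0) {
    stop("outcome_params missing: ", paste(missing_oc, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(
    list(
      n_jurisdictions = as.integer(n_jurisdictions),
      seed = seed,
      seed_profiles = as.integer(seed_profiles %||% (abs(seed) %% 1000000000L)),
      seed_vitals = as.integer(seed_vitals %||%
                                 ((abs(seed) + 104729L) %% 1000000000L)),
      latent_shape = latent_shape,
      discrimination = discrimination,
      black_shape = black_shape,
      births_range = births_range,
      workforce_rate = workforce_rate,
      outcome_params = outcome_params
    ),
    class = "miss_sim_config"
  )
}

sim_jurisdiction_codes <- function(n) {
  if (n == 51L) miss_jurisdictions else sprintf("J%03d", seq_len(n))
}

#' Simulate regulatory profiles from a latent integration level
#'
#' Each jurisdiction draws a latent integration level theta from a Beta
#' distribution; each rubric item's response is then drawn from an ordered
#' categorical rule (a latent-threshold / cumulative-logit model): with K
#' options ordered by favourability rank and equally spaced thresholds
#' `tau_k = (k - 1) / K`, the probability of reaching at least option k is
#' `plogis(discrimination * (theta - tau_k))`, so higher-ranked options
#' become monotonically more likely as theta grows. At extreme
#' discrimination the response degenerates to the top option when theta is
#' 1 and the bottom option when theta is 0.
#'
#' @param config A [sim_config()].
#' @param rubric A [miss_rubric()].
#' @return Profiles tibble (`jurisdiction`, `item_id`, `option_code`) with
#'   the latent draw attached as attribute `theta` (a tibble of
#'   `jurisdiction`, `theta`). Deterministic given the config's profile
#'   seed.
#' @export
simulate_profiles <- function(config, rubric) {
  stopifnot(inherits(config, "miss_sim_config"), inherits(rubric, "miss_rubric"))
  n <- config$n_jurisdictions
  jur <- sim_jurisdiction_codes(n)
  set.seed(config$seed_profiles)
  theta <- stats::rbeta(n, config$latent_shape[1], config$latent_shape[2])

  per_item <- split(rubric$options, factor(rubric$options$item_id,
                                           levels = rubric$items$item_id))
  rows <- purrr::map(rubric$items$item_id, function(id) {
    oi <- per_item[[id]]
    oi <- oi[order(oi$raw_rank), ]
    K <- nrow(oi)
    u <- stats::runif(n)
    idx <- rep(1L, n)
    for (k in 2:K) {
      tau <- (k - 1) / K
      s_k <- stats::plogis(config$discrimination * (theta - tau))
      idx <- idx + as.integer(u < s_k)
    }
    tibble::tibble(jurisdiction = jur, item_id = id, option_code = oi$code[idx])
  }) |> purrr::list_rbind() |>
    dplyr::arrange(.data$jurisdiction, .data$item_id)
  attr(rows, "theta") <- tibble::tibble(jurisdiction = jur, theta = theta)
  rows
}

#' Simulate vital and workforce records given composite scores
#'
#' Births are log-uniform over the configured range; the percent of
#' non-Hispanic Black births is Beta-distributed; midwife headcounts are
#' Poisson with mean `workforce_rate * theta * births / 1000`; births by
#' attendant and setting are Binomial draws whose success probabilities
#' rise with theta (hospital midwifery dominated by CNMs/CMs, community
#' births by CPMs); and each outcome follows its row of the config's
#' `outcome_params`: intercept + beta_black * pct_black +
#' beta_miss * (MISS/100) + Normal noise, clamped to the outcome's valid
#' range. Clamping is logged, and a warning recommends reparameterising if
#' it affects more than 10% of draws for an outcome.
#'
#' @param config A [sim_config()].
#' @param scores A `miss_scores` tibble for the same jurisdictions.
#' @param theta Optional tibble (`jurisdiction`, `theta`); taken from the
#'   scores' profile attribute when the scores came from
#'   [simulate_profiles()], else approximated by `total / target`.
#' @return A vital-records tibble (see [read_vitals()] for the column
#'   dictionary). Deterministic given the config's vitals seed.
#' @export
simulate_vitals <- function(config, scores, theta = NULL) {
  stopifnot(inherits(config, "miss_sim_config"))
  scores <- dplyr::arrange(tibble::as_tibble(scores), .data$jurisdiction)
  n <- nrow(scores)
  if (n != config$n_jurisdictions) {
    stop("scores have ", n, " jurisdictions but config expects ",
         config$n_jurisdictions, call. = FALSE)
  }
  if (is.null(theta)) {
    theta_tbl <- tibble::tibble(jurisdiction = scores$jurisdiction,
                                theta = scores$total / 100)
  } else {
    theta_tbl <- tibble::as_tibble(theta)
  }
  th <- theta_tbl$theta[match(scores$jurisdiction, theta_tbl$jurisdiction)]
  if (anyNA(th)) stop("theta missing for some jurisdictions", call. = FALSE)

  set.seed(config$seed_vitals)
  births <- round(exp(stats::runif(n, log(config$births_range[1]),
                                   log(config$births_range[2]))))
  pct_black <- 100 * stats::rbeta(n, config$black_shape[1], config$black_shape[2])
  mw_cnm <- stats::rpois(n, config$workforce_rate[["cnm_cm"]] * th * births / 1000)
  mw_cpm <- stats::rpois(n, config$workforce_rate[["cpm"]] * th * births / 1000)

  # attendant-by-setting probabilities, monotone in theta; community births
  # sit near the observed ~1.5% of US births at mid-range integration
  p_cells <- cbind(
    bas_cnm_cm_hospital = 0.03 + 0.09 * th,
    bas_cpm_hospital = rep(2e-4, n),
    bas_cnm_cm_home = 5e-4 + 0.0015 * th,
    bas_cpm_home = 0.002 + 0.010 * th,
    bas_cnm_cm_birth_center = 0.001 + 0.004 * th,
    bas_cpm_birth_center = 0.001 + 0.006 * th
  )
  cells <- apply(p_cells, 2, function(p) stats::rbinom(n, births, p))
  cells <- matrix(cells, nrow = n, dimnames = list(NULL, colnames(p_cells)))

  m <- scores$total / 100
  op <- config$outcome_params
  outcome_cols <- list()
  for (i in seq_len(nrow(op))) {
    y <- op$intercept[i] + op$beta_black[i] * pct_black +
      op$beta_miss[i] * m + stats::rnorm(n, 0, op$noise_sd[i])
    clamped <- y < op$lo[i] | y > op$hi[i]
    if (mean(clamped) > 0.10) {
      warning(sprintf(
        "outcome '%s': %.0f%% of draws clamped to [%g, %g]; consider changing its parameters",
        op$outcome[i], 100 * mean(clamped), op$lo[i], op$hi[i]), call. = FALSE)
    }
    outcome_cols[[op$outcome[i]]] <- pmin(pmax(y, op$lo[i]), op$hi[i])
  }

  community <- cells[, "bas_cnm_cm_home"] + cells[, "bas_cpm_home"] +
    cells[, "bas_cnm_cm_birth_center"] + cells[, "bas_cpm_birth_center"]
  out <- tibble::tibble(
    jurisdiction = scores$jurisdiction,
    year = 2014L,
    births_total = as.integer(births),
    midwives_cnm_cm = mw_cnm,
    midwives_cpm = mw_cpm,
    tibble::as_tibble(cells),
    pct_black_births = pct_black,
    community_birth_rate = 100 * community / births,
    tibble::as_tibble(outcome_cols)
  )
  validate_vitals(out)
  out
}

#' Run the whole synthetic study
#'
#' Profiles, scoring, ranking, quartiles and vital records in one call;
#' the standard entry point for calibration experiments and examples.
#'
#' @param config A [sim_config()].
#' @param rubric Defaults to the packaged [canonical_rubric()].
#' @return List with `profiles`, `scores` (ranked, with quartiles),
#'   `records`, `theta`, `config`.
#' @export
simulate_study <- function(config = sim_config(), rubric = canonical_rubric()) {
  profiles <- simulate_profiles(config, rubric)
  scores <- score_profiles(profiles, rubric) |>
    rank_jurisdictions() |>
    assign_quartiles()
  theta <- attr(profiles, "theta")
  records <- simulate_vitals(config, scores, theta = theta)
  list(profiles = profiles, scores = scores, records = records,
       theta = theta, config = config)
}
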