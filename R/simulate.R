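#' Synthetic cohort generator configuration
#'
#' Configures the generator that emulates the statistical structure the
#' analysis pipeline assumes: three orthogonal latent vulnerability factors
#' drive indicator co-occurrence through a threshold (probit) link whose
#' loadings default to the reference vulnerability-type pattern; family
#' structures, within-family prevalence and persistence states are drawn per
#' indicator; and SUDI risk factors are coupled to the latent factors through
#' logistic models whose default coefficient signs match the direction of the
#' reported associations (positive chaotic/socioeconomic effects for smoking,
#' surface sharing and excess bedding; negative for prone position and
#' solitary sleep; Indigenous status positive on chaotic and socioeconomic
#' and negative on psychosocial).
#'
#' Base rates are chosen to represent a high-adversity SUDI cohort (average
#' indicator prevalence about 0.18). The generator makes no attempt to
#' reproduce the confidential study cohort's observed medians or shift
#' estimates, which are data-dependent.
#'
#' @param n_families Number of families to generate.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param sole_parent_probability Probability a family has a single parent.
#' @param sibling_mean Mean of the Poisson sibling-count distribution.
#' @param planted_loadings 32 x 3 loading matrix of the latent structure
#'   (rows named by indicator id); default [svf_reference_loadings()].
#' @param indicator_base_rates Named length-32 vector of marginal presence
#'   probabilities.
#' @param persistence_transition Probabilities of `past`, `current`,
#'   `persistent` given presence, for longitudinal indicators.
#' @param risk_effects Tibble of per-level logistic coefficients for the risk
#'   factors: columns `column`, `level`, `intercept`, `chaotic`,
#'   `socioeconomic`, `psychosocial`. Reference levels have implicit linear
#'   predictor 0 (baseline-category logit for three-level factors).
#' @param risk_missing_rate Probability each risk-factor cell is missing
#'   completely at random (emulating the 95-100% completeness of routinely
#'   collected risk-factor data).
#' @param link `"probit"` (threshold model; planted loadings then equal the
#'   tetrachoric structure) or `"logistic"`.
#' @return A list of class `svf_generator_config`.
#' @export
svf_generator_config <- function(n_families = 500,
                                 seed = 1L,
                                 sole_parent_probability = 0.35,
                                 sibling_mean = 1.5,
                                 planted_loadings = svf_reference_loadings(),
                                 indicator_base_rates = svf_default_base_rates(),
                                 persistence_transition = c(past = 0.3, current = 0.5, persistent = 0.2),
                                 risk_effects = svf_default_risk_effects(),
                                 risk_missing_rate = 0.02,
                                 link = c("probit", "logistic")) {
  link <- match.arg(link)
  stopifnot(n_families >= 1)
  probs <- c(
    sole_parent_probability, indicator_base_rates,
    persistence_transition, risk_missing_rate
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(persistence_transition) - 1) > 1e-8) {
    stop("persistence_transition must sum to 1", call. = FALSE)
  }
  cfg <- list(
    n_families = as.integer(n_families),
    seed = as.integer(seed),
    sole_parent_probability = sole_parent_probability,
    sibling_mean = sibling_mean,
    planted_loadings = planted_loadings,
    indicator_base_rates = indicator_base_rates,
    persistence_transition = persistence_transition,
    risk_effects = risk_effects,
    risk_missing_rate = risk_missing_rate,
    link = link
  )
  class(cfg) <- "svf_generator_config"
  cfg
}

#' Default marginal indicator prevalences of the synthetic cohort
#'
#' @return Named numeric vector over the 32 operational indicator ids.
#' @export
svf_default_base_rates <- function() {
  c(
    material_hardship = 0.30, low_status_occupation = 0.25,
    unemployment = 0.20, long_term_unemployment = 0.12,
    homelessness = 0.08, marginal_homelessness = 0.10,
    overcrowding = 0.15, transience = 0.25,
    chronic_illness_parents = 0.20, chronic_illness_siblings = 0.10,
    mental_ill_health = 0.30, alcohol_misuse = 0.20,
    substance_abuse = 0.25, sibling_death = 0.05,
    stillbirth = 0.05, miscarriages_terminations = 0.15,
    limited_access_care = 0.30, criminal_offending = 0.20,
    long_term_criminal_offending = 0.15, victim_of_crime = 0.12,
    domestic_violence = 0.25, domestic_violence_previous = 0.15,
    child_abuse_neglect = 0.25, risky_behaviours = 0.05,
    lack_of_transport = 0.15, geographic_isolation = 0.15,
    limited_social_support = 0.25, multiple_partners = 0.30,
    children_not_in_care = 0.10, stressful_life_events = 0.35,
    parental_history_abuse = 0.15, parental_history_juvenile_offending = 0.10
  )
}

#' Default latent-factor coefficients of the risk-factor models
#'
#' @return Tibble with columns `column`, `level`, `intercept`, `chaotic`,
#'   `socioeconomic`, `psychosocial`.
#' @export
svf_default_risk_effects <- function() {
  tibble(
    column = c(
      "rf_indigenous", "rf_area_ses", "rf_area_ses", "rf_smoking",
      "rf_sga", "rf_sga", "rf_preterm", "rf_breastfeeding",
      "rf_sleep_position", "rf_sleep_position", "rf_surface_sharing",
      "rf_solitary_sleep", "rf_soft_surface", "rf_pillows", "rf_excess_bedding"
    ),
    level = c(
      "yes", "moderate", "low", "yes", "p11_25", "le10", "yes", "yes",
      "side", "prone", "yes", "yes", "yes", "yes", "yes"
    ),
    intercept = c(
      -0.85, -0.10, -0.20, 0.00, -1.73, -1.73, -1.39, -0.40,
      -1.73, -1.39, -0.28, -0.85, -1.39, -0.85, 0.00
    ),
    chaotic = c(
      0.35, 0.15, 0.25, 0.45, 0.20, 0.05, -0.10, -0.10,
      0.00, -0.35, 0.50, -0.50, 0.05, 0.05, 0.40
    ),
    socioeconomic = c(
      0.70, 0.40, 0.60, 0.50, 0.05, 0.00, 0.15, -0.20,
      0.10, -0.35, 0.30, -0.45, -0.10, 0.00, 0.10
    ),
    psychosocial = c(
      -0.45, 0.00, 0.00, 0.00, 0.10, 0.05, 0.00, -0.15,
      0.10, -0.15, -0.25, 0.10, -0.10, 0.05, 0.00
    )
  )
}

#' Generate a synthetic cohort of families
#'
#' Draws, per family: three independent standard-normal latent vulnerability
#' factors; indicator presence through the configured link on the planted
#' loadings and base rates (probit default: presence is a thresholded latent
#' variable with unit variance, so the planted loadings are the tetrachoric
#' structure and the marginal prevalence equals the configured base rate);
#' family structure; affected persons, persistence states, event counts,
#' occupational percentiles and remoteness classes per the indicator's
#' scoring method; and the risk-factor panel through logistic models on the
#' latent factors. Solitary sleep is structurally not applicable for
#' surface-sharing families and recorded as `NA`.
#'
#' The generated tibble carries the generator truth (latent draws, planted
#' loadings, risk effects and config) in its `"truth"` attribute for
#' parameter-recovery tests.
#'
#' @param cfg A [svf_generator_config()].
#' @param ledger Indicator ledger; defaults to the packaged ledger.
#' @return A cohort tibble, one row per family, in the cohort table schema
#'   accepted by [svf_score()], with `rf_*` risk-factor columns.
#' @export
svf_simulate <- function(cfg = svf_generator_config(), ledger = svf_ledger()) {
  stopifnot(inherits(cfg, "svf_generator_config"))
  ind <- svf_indicators(ledger)
  ids <- ind$id
  L <- cfg$planted_loadings[ids, , drop = FALSE]
  rates <- cfg$indicator_base_rates[ids]
  if (any(is.na(rates))) {
    stop("indicator_base_rates must cover every operational indicator",
      call. = FALSE
    )
  }
  n <- cfg$n_families
  set.seed(cfg$seed)

  z <- matrix(stats::rnorm(n * 3), n, 3,
    dimnames = list(NULL, c("chaotic", "socioeconomic", "psychosocial"))
  )
  n_parents <- ifelse(stats::runif(n) < cfg$sole_parent_probability, 1L, 2L)
  n_siblings <- stats::rpois(n, cfg$sibling_mean)

  eta <- z %*% t(L) # n x 32 systematic component
  present <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    lam2 <- sum(L[j, ]^2)
    if (cfg$link == "probit") {
      resid_sd <- sqrt(max(1 - lam2, 1e-6))
      u <- eta[, j] + stats::rnorm(n, sd = resid_sd)
      present[, j] <- as.integer(u > stats::qnorm(1 - rates[j]))
    } else {
      pr <- stats::plogis(stats::qlogis(rates[j]) + 1.7 * eta[, j])
      present[, j] <- stats::rbinom(n, 1, pr)
    }
  }
  # a sibling-level indicator requires a sibling
  present[, "chronic_illness_siblings"] <-
    present[, "chronic_illness_siblings"] * as.integer(n_siblings > 0)

  cohort <- tibble(
    family_id = sprintf("f%05d", seq_len(n)),
    n_parents = n_parents,
    n_siblings = as.integer(n_siblings)
  )
  pt <- cfg$persistence_transition
  for (j in seq_along(ids)) {
    id <- ids[j]
    pres <- present[, j] == 1L
    method <- ind$method[j]
    if (method %in% c("BINARY_1", "BINARY_2")) {
      cohort[[paste0(id, "__present")]] <- as.integer(pres)
    }
    if (method %in% c("PARENT_WEIGHTED", "PARENT_WEIGHTED_LONGITUDINAL")) {
      both <- stats::runif(n) < 0.3
      aff <- ifelse(!pres, 0L, ifelse(n_parents == 1L, 1L, ifelse(both, 2L, 1L)))
      cohort[[paste0(id, "__parents")]] <- as.integer(aff)
    }
    if (method == "SIBLING_WEIGHTED") {
      extra <- stats::rpois(n, 0.4)
      aff <- ifelse(pres, pmin(n_siblings, 1L + extra), 0L)
      cohort[[paste0(id, "__siblings")]] <- as.integer(aff)
    }
    if (method %in% c("LONGITUDINAL", "PARENT_WEIGHTED_LONGITUDINAL")) {
      state <- sample(names(pt), n, replace = TRUE, prob = pt)
      cohort[[paste0(id, "__temporal")]] <- ifelse(pres, state, "absent")
    }
    if (method == "EVENT_PREVALENCE") {
      k <- 1L + stats::rpois(n, 0.5)
      cohort[[paste0(id, "__count")]] <- as.integer(ifelse(pres, k, 0L))
    }
    if (method == "CONTINUOUS_OCCUPATION") {
      pct <- ifelse(pres,
        stats::runif(n, 0, 0.25),
        stats::runif(n, 0.2501, 1)
      )
      cohort[[paste0(id, "__percentile")]] <- pct
    }
    if (method == "REMOTENESS_WEIGHTED") {
      cls <- sample(c("outer_regional", "remote_or_very_remote"), n,
        replace = TRUE, prob = c(0.65, 0.35)
      )
      cohort[[paste0(id, "__remoteness")]] <- ifelse(pres, cls, "none")
    }
  }

  # risk factors: baseline-category logit on the latent factors
  eff <- cfg$risk_effects
  panel <- svf_risk_panel()
  for (i in seq_len(nrow(panel))) {
    col <- panel$column[i]
    lev <- panel$levels[[i]]
    rowset <- eff[eff$column == col, , drop = FALSE]
    etas <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    for (r in seq_len(nrow(rowset))) {
      lv <- rowset$level[r]
      beta <- as.numeric(rowset[r, c("chaotic", "socioeconomic", "psychosocial")])
      etas[, lv] <- rowset$intercept[r] + as.vector(z %*% beta)
    }
    expeta <- exp(etas)
    pr <- expeta / rowSums(expeta)
    u <- stats::runif(n)
    cum <- t(apply(pr, 1, cumsum))
    pick <- lev[max.col(u < cum, ties.method = "first")]
    cohort[[col]] <- pick
  }
  # structural not-applicable and MCAR missingness
  sharing <- cohort$rf_surface_sharing == "yes"
  cohort$rf_solitary_sleep[sharing] <- NA_character_
  if (cfg$risk_missing_rate > 0) {
    for (col in panel$column) {
      miss <- stats::runif(n) < cfg$risk_missing_rate
      if (col == "rf_solitary_sleep") miss <- miss & !sharing
      cohort[[col]][miss] <- NA_character_
    }
  }

  attr(cohort, "truth") <- list(
    z = z,
    planted_loadings = L,
    base_rates = rates,
    risk_effects = eff,
    config = cfg
  )
  cohort
}

#' Named test fixtures
#'
#' Three reproducible cohorts used throughout the test-suite and
#' documentation: `tiny`, six hand-specified families whose expected scores
#' are attached as an `"expected"` attribute sidecar; `null`, a generated
#' cohort with zero planted loadings and zero risk-factor coupling (no factor
#' structure, for calibration studies); and `reference`, the default
#' generator with its planted three-factor structure.
#'
#' @param name One of `"tiny"`, `"null"`, `"reference"`.
#' @param seed Seed for the generated fixtures.
#' @param n_families Cohort size for the generated fixtures.
#' @return A cohort tibble; for `tiny`, with an `"expected"` attribute tibble
#'   of hand-computed `simple` and `weighted` scores.
#' @export
svf_fixture <- function(name = c("tiny", "null", "reference"), seed = 1L,
                        n_families = if (name == "reference") 2000L else 500L) {
  name <- match.arg(name)
  if (name == "tiny") {
    return(tiny_fixture())
  }
  if (name == "null") {
    zero_L <- svf_reference_loadings() * 0
    eff <- svf_default_risk_effects()
    eff$chaotic <- eff$socioeconomic <- eff$psychosocial <- 0
    cfg <- svf_generator_config(
      n_families = n_families, seed = seed,
      planted_loadings = zero_L, risk_effects = eff,
      risk_missing_rate = 0
    )
    return(svf_simulate(cfg))
  }
  svf_simulate(svf_generator_config(n_families = n_families, seed = seed))
}

# Six hand-specified families with hand-computed scores:
#   f1 all absent ................................. simple 0,  weighted 0
#   f2 every indicator maximal .................... simple 32, weighted 63
#   f3 worked toy family (couple, 2 siblings; one parent mental ill-health,
#      past transience, one stillbirth) ........... simple 3,  weighted 3
#   f4 sole parent, substance abuse ............... simple 1,  weighted 2
#   f5 couple, one parent substance abuse ......... simple 1,  weighted 1
#   f6 occupation at the 25th percentile + one
#      access-to-care event ....................... simple 2,  weighted 1.25
tiny_fixture <- function() {
  ledger <- svf_ledger()
  ind <- svf_indicators(ledger)
  cohort <- svf_empty_cohort(6, ledger)
  cohort$n_parents <- c(2L, 2L, 2L, 1L, 2L, 2L)
  cohort$n_siblings <- c(0L, 2L, 2L, 0L, 0L, 0L)

  # f2: maximal state on every indicator
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    switch(ind$method[i],
      BINARY_1 = ,
      BINARY_2 = {
        cohort[[paste0(id, "__present")]][2] <- 1
      },
      PARENT_WEIGHTED = {
        cohort[[paste0(id, "__parents")]][2] <- 2
      },
      SIBLING_WEIGHTED = {
        cohort[[paste0(id, "__siblings")]][2] <- 2
      },
      LONGITUDINAL = {
        cohort[[paste0(id, "__temporal")]][2] <- "persistent"
      },
      PARENT_WEIGHTED_LONGITUDINAL = {
        cohort[[paste0(id, "__parents")]][2] <- 2
        cohort[[paste0(id, "__temporal")]][2] <- "persistent"
      },
      EVENT_PREVALENCE = {
        cohort[[paste0(id, "__count")]][2] <- 3
      },
      CONTINUOUS_OCCUPATION = {
        cohort[[paste0(id, "__percentile")]][2] <- 0
      },
      REMOTENESS_WEIGHTED = {
        cohort[[paste0(id, "__remoteness")]][2] <- "remote_or_very_remote"
      }
    )
  }
  # f3: toy worked family
  cohort$mental_ill_health__parents[3] <- 1
  cohort$transience__temporal[3] <- "past"
  cohort$stillbirth__count[3] <- 1
  # f4, f5: premise-two pair
  cohort$substance_abuse__parents[4] <- 1
  cohort$substance_abuse__parents[5] <- 1
  # f6: occupation exactly at the cut, one limited-access event
  cohort$low_status_occupation__percentile[6] <- 0.25
  cohort$limited_access_care__count[6] <- 1

  attr(cohort, "expected") <- tibble(
    family_id = paste0("f", 1:6),
    simple = c(0L, 32L, 3L, 1L, 1L, 2L),
    weighted = c(0, 63, 3, 2, 1, 1.25)
  )
  cohort
}
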