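#' Simulation configuration for a synthetic screening cohort
#'
#' Defaults emulate the study conditions: 22\% impairment prevalence, a one
#' SD general-ability deficit in the impaired group, ages 67--93 centred
#' near 76 with a 0.27 age-impairment correlation, per-instrument lognormal
#' total response times matching the published moments (ARW 47.421/11.619,
#' DCCS 36.049/14.909, PSM 73/34 seconds), and monotone missingness ramps
#' for the two stopping-rule instruments (MFS up to 50\%, NSM up to 90\% at
#' the last item).
#'
#' @param n patients.
#' @param prevalence impairment probability in (0, 1).
#' @param ability_gap mean general-ability deficit of the impaired group, in
#'   SD units (>= 0).
#' @param age_cor target point-biserial correlation between age and the
#'   impairment label.
#' @param age_mean,age_sd,age_range age distribution (truncated normal,
#'   years).
#' @param rt_moments named list of \code{c(mean, sd)} pairs (seconds) for
#'   DCCS, PSM, ARW.
#' @param miss_max named vector: missing probability at the last item for
#'   MFS and NSM (ramps linearly from 0 at the first item).
#' @param seed integer seed.
#' @return A list of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n = 86L, prevalence = 0.22, ability_gap = 1.0,
                              age_cor = 0.27, age_mean = 76, age_sd = 6,
                              age_range = c(67, 93),
                              rt_moments = list(ARW = c(47.421, 11.619),
                                                DCCS = c(36.049, 14.909),
                                                PSM = c(73, 34)),
                              miss_max = c(MFS = 0.5, NSM = 0.9),
                              seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, ability_gap >= 0,
            all(vapply(rt_moments, function(m) all(m > 0), TRUE)))
  structure(list(n = as.integer(n), prevalence = prevalence,
                 ability_gap = ability_gap, age_cor = age_cor,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 rt_moments = rt_moments, miss_max = miss_max,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Default item bank for the five instruments
#'
#' One 2PL item set per instrument at the fixed item counts (30, 12, 50,
#' 30, 144; 266 items in total), with discriminations a ~ LogNormal(0, 0.5),
#' difficulties b ~ N(0, 1) and domain loadings lambda drawn uniformly in
#' [0.5, 0.9].
#'
#' @param seed integer seed.
#' @param instruments instrument subset (default all five).
#' @return List with \code{items} (data frame: \code{a}, \code{b},
#'   \code{domain} factor) and \code{lambda} (named vector).
#' @export
generate_default_item_bank <- function(seed = 1L,
                                       instruments = instrument_names()) {
  sp <- instrument_specs()
  sp <- sp[sp$name %in% instruments, ]
  set.seed(seed)
  J <- sum(sp$n_items)
  items <- data.frame(
    a = exp(stats::rnorm(J, 0, 0.5)),
    b = stats::rnorm(J, 0, 1),
    domain = factor(rep(sp$name, sp$n_items), levels = sp$name))
  lambda <- stats::setNames(stats::runif(nrow(sp), 0.5, 0.9), sp$name)
  list(items = items, lambda = lambda)
}

# lognormal parameters from a target mean and sd (moment matching)
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# truncated-normal quantile function via the probability-integral transform
qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

#' Generate a synthetic screening cohort
#'
#' Label-first scheme: the impairment label is Bernoulli(prevalence); the
#' general ability is then drawn as
#' \eqn{\theta_g \sim N(\mu_0 - \mathrm{gap}\cdot\mathrm{impaired},\,1)}
#' with \eqn{\mu_0 = \mathrm{gap}\cdot\mathrm{prevalence}} so the marginal
#' mean stays at 0. Domain abilities and responses follow the higher-order
#' 2PL generator. Age is tied to the impairment propensity through a
#' Gaussian copula calibrated so the point-biserial age-impairment
#' correlation hits the configured target. Total response times are
#' lognormal with the configured moments; MFS/NSM missingness is a
#' per-patient stopping point, giving per-item missing rates that increase
#' monotonically along the ramp. Demographics are sampled from the
#' published category frequencies.
#'
#' @param config a \code{\link{cohort_sim_config}}.
#' @param bank item bank from \code{\link{generate_default_item_bank}}
#'   (default: bank generated from \code{config$seed}).
#' @return List with \code{cohort} (a \code{\link{cog_cohort}}) and
#'   \code{latents} (true \code{theta_g}, \code{theta_d}).
#' @export
generate_cohort <- function(config = cohort_sim_config(), bank = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (is.null(bank)) bank <- generate_default_item_bank(config$seed)
  n <- config$n
  set.seed(config$seed + 1L)

  # label and age through a Gaussian copula on the impairment propensity
  z1 <- stats::rnorm(n)
  impaired <- as.integer(z1 < stats::qnorm(config$prevalence))
  pb_factor <- stats::dnorm(stats::qnorm(config$prevalence)) /
    sqrt(config$prevalence * (1 - config$prevalence))
  rho_z <- min(max(-config$age_cor / pb_factor, -0.99), 0.99)
  z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
  age <- round(qtruncnorm(stats::pnorm(z2), config$age_mean, config$age_sd,
                          config$age_range[1], config$age_range[2]))

  # abilities: impaired group shifted down by the gap, marginal mean 0
  mu0 <- config$ability_gap * config$prevalence
  theta_g <- stats::rnorm(n, mu0 - config$ability_gap * impaired, 1)
  lambda <- bank$lambda
  D <- length(lambda)
  theta_d <- sapply(seq_len(D), function(d)
    lambda[d] * theta_g + sqrt(1 - lambda[d]^2) * stats::rnorm(n))
  theta_d <- matrix(theta_d, nrow = n,
                    dimnames = list(NULL, names(lambda)))

  items <- bank$items
  dom_i <- as.integer(items$domain)
  Th <- theta_d[, dom_i, drop = FALSE]
  p <- stats::plogis(sweep(Th, 2, items$a, `*`) -
                       rep(items$a * items$b, each = n))
  y <- matrix(stats::rbinom(n * nrow(items), 1L, p), nrow = n)

  sp <- instrument_specs()
  responses <- list()
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]
    m <- y[, dom_i == which(levels(items$domain) == nm), drop = FALSE]
    if (sp$allows_missing[i]) {
      ramp <- config$miss_max[[nm]] * (seq_len(ncol(m)) - 1) / (ncol(m) - 1)
      u <- stats::runif(n)
      drop_mask <- outer(u, ramp, `<`)      # monotone stopping per patient
      m[drop_mask] <- NA_integer_
    }
    responses[[nm]] <- m
  }

  rt <- as.data.frame(lapply(config$rt_moments[rt_instruments()], function(ms) {
    lp <- lognormal_params(ms[1], ms[2])
    stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
  }))
  names(rt) <- rt_instruments()

  demo_freq <- list(
    gender = c(F = 60, M = 26),
    race = c(A = 4, B = 11, U = 1, W = 70),
    income = c(`2` = 2, `3` = 3, `4` = 3, `5` = 8, `6` = 10, `7` = 12,
               `8` = 21, `9` = 26, D = 1),
    education = c(`4` = 5, `6` = 10, `7` = 3, `8` = 23, `9` = 32,
                  `10` = 5, `11` = 6, `777` = 2))
  demo <- lapply(demo_freq, function(f)
    sample(names(f), n, replace = TRUE, prob = f / sum(f)))

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    impaired = impaired, age = as.integer(age),
    gender = demo$gender, race = demo$race,
    income = demo$income, education = demo$education,
    stringsAsFactors = FALSE)
  list(cohort = cog_cohort(patients, responses, rt),
       latents = list(theta_g = theta_g, theta_d = theta_d))
}

#' End-to-end benchmark fixture from a synthetic cohort
#'
#' Generates a cohort, fits the two-domain (DCCS, PSM) and five-domain
#' higher-order IRT models (short chains by default), refits the five
#' composite models on the generated labels, assembles the full per-patient
#' score bundle, and builds feature matrices for all sixteen spaces.
#'
#' @param config a \code{\link{cohort_sim_config}}.
#' @param n_iter,n_burn chain controls for the IRT fits.
#' @return List with \code{cohort}, \code{latents}, \code{bundle} (data
#'   frame), \code{features} (named list of matrices), \code{fits} (the two
#'   \code{hoirt} objects) and \code{composites} (fitted models).
#' @export
make_benchmark_fixture <- function(config = cohort_sim_config(),
                                   n_iter = 800L, n_burn = 300L) {
  gen <- generate_cohort(config)
  fx <- make_benchmark_fixture_from(
    gen$cohort,
    list(hoirt = list(n_iter = n_iter, n_burn = n_burn),
         seed = config$seed))
  c(list(cohort = gen$cohort, latents = gen$latents), fx)
}
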