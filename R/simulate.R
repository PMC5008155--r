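#' Simulation parameters for the synthetic social population
#'
#' Defaults describe a plural-breeding, bi-philopatric mongoose-like study
#' population: several stable social groups in which 1-10 adult females enter
#' oestrus synchronously per breeding attempt, each guarded by one or more
#' males, with promiscuous paternity (the principal guard holds a baseline
#' paternity share, other in-group males sneak matings, and a small fraction
#' of sires are extra-group), litters of about three pups per female, and
#' adult maturity at one year. Kin-avoidance is tunable: candidate weights
#' decay as exp(-beta * r), with `beta_guard` acting on guard choice and
#' `beta_paternity` on sire choice, so that beta = 0 recovers exact random
#' mating within the group.
#'
#' @param n_groups number of social groups
#' @param founders_per_group founders per sex per group (mutually unrelated)
#' @param attempts_per_group observed breeding attempts per group
#' @param burnin_attempts_per_group pre-observation attempts per group: the
#'   same breeding process runs, and offspring enter the pedigree with
#'   parentage assignments (attempt unknown), but no behavioural tables are
#'   emitted. This mirrors a study whose observation window sits on top of a
#'   deeper multi-generation pedigree, so that most adults alive during the
#'   window have assigned parents
#' @param attempt_interval_days days between a group's attempts
#' @param oestrus_to_birth_days gestation lag from oestrus start to birth
#'   (within the 40-80 day attribution window)
#' @param p_female_in_oestrus probability an adult female joins an attempt
#' @param guard_extra_lambda each oestrous female has 1 + Poisson(lambda)
#'   guards (capped by the number of adult males)
#' @param litter_mean mean pups per oestrous female (Poisson)
#' @param beta_guard,beta_paternity kin-avoidance strengths (>= 0)
#' @param p_guard_paternity_base baseline probability that the principal
#'   guard sires the first-conceived pup of a litter (at equal relatedness)
#' @param litter_sire_concentration probability that each later pup of a
#'   female's litter reuses the previous pup's sire rather than drawing a
#'   fresh one (within-litter paternity is concentrated in promiscuous
#'   plural breeders)
#' @param p_extra_group_sire probability a freshly drawn sire is extra-group
#' @param maturity_days adult threshold in days
#' @param gamma_mass body-mass slope on F (g per unit F)
#' @param mass_intercept,mass_age_slope yearling mass model: grams at age 0
#'   and g/day
#' @param gamma_survival,survival_intercept,survival_rainfall_slope logit
#'   model of survival to 1 year
#' @param rainfall_mean,rainfall_sd gamma-distributed mean daily rainfall
#'   (mm) in the 30 days before birth
#' @param re_sd_mass named vector of random-effect SDs (g) for
#'   group/attempt/mother/father/individual in the mass model
#' @param residual_sd_mass residual SD (g) of single mass records
#' @param re_sd_survival named vector of logit-scale random-effect SDs for
#'   group/attempt/mother/father in the survival model
#' @param mass_records_mean mean number of yearling mass records per survivor
#' @param p_adult_death per-attempt-interval adult death probability
#' @param max_group_adults carrying capacity; random adults beyond it leave
#' @param founder_age_range_days founder ages (days) at the first attempt
#' @param assignment_confidence parentage confidence attached to all emitted
#'   assignments
#' @param founders_natal whether founders count as natal to their group
#'   (FALSE: groups formed by immigrant cohorts)
#' @param seed integer seed
#' @return object of class `sim_params`
#' @export
sim_params <- function(n_groups = 6L,
                       founders_per_group = 5L,
                       attempts_per_group = 12L,
                       burnin_attempts_per_group = 8L,
                       attempt_interval_days = 91,
                       oestrus_to_birth_days = 60,
                       p_female_in_oestrus = 0.7,
                       guard_extra_lambda = 0.4,
                       litter_mean = 3,
                       beta_guard = 0,
                       beta_paternity = 0,
                       p_guard_paternity_base = 0.3,
                       litter_sire_concentration = 0.75,
                       p_extra_group_sire = 0.1,
                       maturity_days = 365,
                       gamma_mass = -347.9,
                       mass_intercept = 807.5,
                       mass_age_slope = 1.15,
                       gamma_survival = -0.03,
                       survival_intercept = -1.31,
                       survival_rainfall_slope = 0.20,
                       rainfall_mean = 2.5,
                       rainfall_sd = 1.25,
                       re_sd_mass = c(group = 30, attempt = 40, mother = 40,
                                      father = 30, individual = 50),
                       residual_sd_mass = 90,
                       re_sd_survival = c(group = 0.3, attempt = 0.3,
                                          mother = 0.3, father = 0.3),
                       mass_records_mean = 3.7,
                       p_adult_death = 0.07,
                       max_group_adults = 24L,
                       founder_age_range_days = c(400, 1800),
                       assignment_confidence = 1.0,
                       founders_natal = FALSE,
                       seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$p_female_in_oestrus, p$p_guard_paternity_base,
             p$litter_sire_concentration, p$p_extra_group_sire,
             p$p_adult_death, p$assignment_confidence)
  stopifnot(all(probs >= 0 & probs <= 1),
            p$beta_guard >= 0, is.finite(p$beta_guard),
            p$beta_paternity >= 0, is.finite(p$beta_paternity),
            p$litter_mean > 0, p$n_groups >= 1, p$founders_per_group >= 1)
  structure(p, class = "sim_params")
}

#' Simulate a synthetic study population
#'
#' Forward-time generator emitting every canonical table of a
#' [study_dataset()] plus a truth record of the generative parameters and
#' realized quantities. Groups are founded by unrelated adults; offspring are
#' philopatric, so pedigree relatedness accumulates within groups over the
#' simulated attempts. Output is deterministic for a fixed seed.
#'
#' @param params a [sim_params()] object
#' @return list with `dataset` (a `study_dataset`) and `truth` (list:
#'   `params`, realized counts, realized mean sire-dam relatedness, mean F
#'   of pups, number of skipped attempts)
#' @export
simulate_population <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  local_seed(params$seed, simulate_population_impl(params))
}

simulate_population_impl <- function(p) {
  t0 <- as.Date("2003-01-01")  # observation window start
  t_start <- t0 - p$burnin_attempts_per_group * p$attempt_interval_days
  n_found <- p$n_groups * p$founders_per_group * 2L
  n_max <- n_found +
    p$n_groups * (p$attempts_per_group + p$burnin_attempts_per_group) *
    ceiling(10 * p$litter_mean)

  # individual state (grown in place)
  id <- character(n_max); dam <- rep(NA_character_, n_max)
  sire <- rep(NA_character_, n_max); sex <- character(n_max)
  birth <- rep(t0, n_max); natal <- rep(NA_character_, n_max)
  group <- character(n_max); alive <- logical(n_max)
  Fcoef <- numeric(n_max)
  u_mass_mother <- stats::rnorm(n_max, 0, p$re_sd_mass[["mother"]])
  u_mass_father <- stats::rnorm(n_max, 0, p$re_sd_mass[["father"]])
  u_mass_ind <- stats::rnorm(n_max, 0, p$re_sd_mass[["individual"]])
  u_surv_mother <- stats::rnorm(n_max, 0, p$re_sd_survival[["mother"]])
  u_surv_father <- stats::rnorm(n_max, 0, p$re_sd_survival[["father"]])
  K <- matrix(0, n_max, n_max)  # kinship f
  n <- 0L

  groups <- paste0("G", seq_len(p$n_groups))
  u_mass_group <- stats::setNames(stats::rnorm(p$n_groups, 0,
                                               p$re_sd_mass[["group"]]), groups)
  u_surv_group <- stats::setNames(stats::rnorm(p$n_groups, 0,
                                               p$re_sd_survival[["group"]]),
                                  groups)

  add_ind <- function(d, s, sx, bd, gr, nat) {
    n <<- n + 1L
    if (n > nrow(K)) stop("simulation exceeded preallocated population size")
    i <- n
    id[i] <<- sprintf("M%05d", i)
    dam[i] <<- d; sire[i] <<- s; sex[i] <<- sx
    birth[i] <<- bd; natal[i] <<- nat; group[i] <<- gr; alive[i] <<- TRUE
    if (is.na(d)) {
      K[i, i] <<- 0.5
      Fcoef[i] <<- 0
    } else {
      di <- match(d, id[seq_len(i - 1L)])
      si <- match(s, id[seq_len(i - 1L)])
      j <- seq_len(i - 1L)
      row <- (K[di, j] + K[si, j]) / 2
      K[i, j] <<- row; K[j, i] <<- row
      K[i, i] <<- (1 + K[di, si]) / 2
      Fcoef[i] <<- K[di, si]
    }
    id[i]
  }

  # founders
  for (g in groups) {
    for (sx in c("F", "M")) {
      for (k in seq_len(p$founders_per_group)) {
        age0 <- stats::runif(1, p$founder_age_range_days[1],
                             p$founder_age_range_days[2])
        add_ind(NA, NA, sx, t_start - round(age0), g,
                if (p$founders_natal) g else NA_character_)
      }
    }
  }

  # attempt schedule (burn-in then observed), interleaved across groups
  sched <- expand.grid(g = seq_len(p$n_groups),
                       k = seq_len(p$attempts_per_group +
                                     p$burnin_attempts_per_group))
  sched$date <- t_start + (sched$k - 1L) * p$attempt_interval_days +
    (sched$g - 1L) * 10
  sched$observed <- sched$k > p$burnin_attempts_per_group
  sched <- sched[order(sched$date, sched$g), ]

  membership <- list(); attempts <- list()
  par_off <- par_at <- par_dam <- par_sire <- character(0)
  gu_at <- gu_g <- gu_f <- character(0); gu_days <- integer(0)
  out_id <- character(0); out_age <- integer(0); out_mass <- numeric(0)
  out_surv <- logical(0)
  n_skipped <- 0L
  at_counter <- 0L
  sire_dam_r <- numeric(0)

  for (row in seq_len(nrow(sched))) {
    g <- groups[sched$g[row]]
    d <- sched$date[row]
    obs <- sched$observed[row]
    live <- which(alive[seq_len(n)] & group[seq_len(n)] == g)

    # deaths over the preceding interval, then carrying capacity
    age <- as.numeric(d - birth[live])
    adults <- live[age > p$maturity_days]
    die <- adults[stats::runif(length(adults)) < p$p_adult_death]
    alive[die] <- FALSE
    adults <- setdiff(adults, die)
    if (length(adults) > p$max_group_adults) {
      out <- sample(adults, length(adults) - p$max_group_adults)
      alive[out] <- FALSE
      adults <- setdiff(adults, out)
    }
    fem <- adults[sex[adults] == "F"]
    mal <- adults[sex[adults] == "M"]
    oestrus <- fem[stats::runif(length(fem)) < p$p_female_in_oestrus]
    if (!length(oestrus) || !length(mal)) {
      if (obs) n_skipped <- n_skipped + 1L
      next
    }

    at_id <- if (obs) {
      at_counter <- at_counter + 1L
      sprintf("AT%04d", at_counter)
    } else NA_character_
    rain <- stats::rgamma(1, shape = (p$rainfall_mean / p$rainfall_sd)^2,
                          rate = p$rainfall_mean / p$rainfall_sd^2)
    u_mass_at <- stats::rnorm(1, 0, p$re_sd_mass[["attempt"]])
    u_surv_at <- stats::rnorm(1, 0, p$re_sd_survival[["attempt"]])
    birth_date <- d + p$oestrus_to_birth_days

    if (obs)
      membership[[length(membership) + 1L]] <- data.frame(
        group_id = g, attempt_id = at_id, individual_id = id[adults],
        sex = sex[adults],
        is_natal = !is.na(natal[adults]) & natal[adults] == g,
        stringsAsFactors = FALSE)

    # extra-group adult males (potential sneak sires)
    eg_live <- which(alive[seq_len(n)] & group[seq_len(n)] != g &
                       sex[seq_len(n)] == "M")
    eg_mal <- eg_live[as.numeric(d - birth[eg_live]) > p$maturity_days]

    n_pups_total <- 0L
    for (f in oestrus) {
      r_to_males <- 2 * K[f, mal]
      # guards: weighted without replacement, weight exp(-beta_guard * r)
      n_g <- min(1L + stats::rpois(1, p$guard_extra_lambda), length(mal))
      w_g <- exp(-p$beta_guard * r_to_males)
      gsel <- if (length(mal) == 1L) mal else
        mal[sample.int(length(mal), n_g, prob = w_g)]
      days <- pmin(1L + stats::rpois(n_g, 1), 5L)
      if (obs) {
        gu_at <- c(gu_at, rep(at_id, n_g)); gu_g <- c(gu_g, id[gsel])
        gu_f <- c(gu_f, rep(id[f], n_g)); gu_days <- c(gu_days, days)
      }
      principal <- gsel[which.max(days)]

      # paternity weights for within-group sires
      w_p <- exp(-p$beta_paternity * r_to_males)
      if (length(mal) > 1L && p$p_guard_paternity_base > 0 &&
          p$p_guard_paternity_base < 1) {
        boost <- p$p_guard_paternity_base * (length(mal) - 1) /
          (1 - p$p_guard_paternity_base)
        w_p[mal == principal] <- w_p[mal == principal] * boost
      }

      n_pups <- stats::rpois(1, p$litter_mean)
      prev_sire <- NA_integer_
      for (pup in seq_len(n_pups)) {
        s_idx <- if (!is.na(prev_sire) &&
                     stats::runif(1) < p$litter_sire_concentration) {
          prev_sire
        } else if (length(eg_mal) > 0 &&
                   stats::runif(1) < p$p_extra_group_sire) {
          w_e <- exp(-p$beta_paternity * 2 * K[f, eg_mal])
          if (length(eg_mal) == 1L) eg_mal else
            eg_mal[sample.int(length(eg_mal), 1L, prob = w_e)]
        } else {
          if (length(mal) == 1L) mal else
            mal[sample.int(length(mal), 1L, prob = w_p)]
        }
        prev_sire <- s_idx
        pup_id <- add_ind(id[f], id[s_idx], if (stats::runif(1) < 0.5) "F" else "M",
                          birth_date, g, g)
        pi <- n
        if (obs) sire_dam_r <- c(sire_dam_r, 2 * K[f, s_idx])
        n_pups_total <- n_pups_total + 1L
        par_off <- c(par_off, pup_id); par_at <- c(par_at, at_id)
        par_dam <- c(par_dam, id[f]); par_sire <- c(par_sire, id[s_idx])

        eta <- p$survival_intercept + p$gamma_survival * Fcoef[pi] +
          p$survival_rainfall_slope * rain +
          u_surv_group[[g]] + u_surv_at +
          u_surv_mother[f] + u_surv_father[s_idx]
        surv <- stats::runif(1) < stats::plogis(eta)
        if (!surv) alive[pi] <- FALSE

        if (!obs) {
          # pre-observation pups enter pedigree and parentage only
        } else if (surv) {
          n_rec <- 1L + stats::rpois(1, max(p$mass_records_mean - 1, 0))
          ages <- sort(sample(350:370, n_rec, replace = TRUE))
          mass <- p$mass_intercept + p$mass_age_slope * ages +
            p$gamma_mass * Fcoef[pi] +
            u_mass_group[[g]] + u_mass_at + u_mass_mother[f] +
            u_mass_father[s_idx] + u_mass_ind[pi] +
            stats::rnorm(n_rec, 0, p$residual_sd_mass)
          out_id <- c(out_id, rep(pup_id, n_rec))
          out_age <- c(out_age, ages)
          out_mass <- c(out_mass, round(mass, 1))
          out_surv <- c(out_surv, rep(TRUE, n_rec))
        } else {
          out_id <- c(out_id, pup_id); out_age <- c(out_age, NA_integer_)
          out_mass <- c(out_mass, NA_real_); out_surv <- c(out_surv, FALSE)
        }
      }
    }

    if (obs)
      attempts[[length(attempts) + 1L]] <- data.frame(
        attempt_id = at_id, group_id = g, oestrus_start_date = d,
        birth_date = birth_date, rainfall_30d = round(rain, 3),
        group_size_adults = length(adults), n_pups_born = n_pups_total,
        stringsAsFactors = FALSE)
  }

  keep <- seq_len(n)
  ped_df <- data.frame(id = id[keep], dam = dam[keep], sire = sire[keep],
                       sex = sex[keep], birth_date = birth[keep],
                       natal_group = natal[keep], stringsAsFactors = FALSE)
  ds <- study_dataset(validate_pedigree(ped_df),
                      do.call(rbind, membership),
                      do.call(rbind, attempts),
                      data.frame(offspring_id = par_off, attempt_id = par_at,
                                 dam_id = par_dam, sire_id = par_sire,
                                 dam_confidence = p$assignment_confidence,
                                 sire_confidence = p$assignment_confidence,
                                 stringsAsFactors = FALSE),
                      data.frame(attempt_id = gu_at, guard_id = gu_g,
                                 female_id = gu_f, n_days_guarding = gu_days,
                                 stringsAsFactors = FALSE),
                      data.frame(individual_id = out_id, age_days = out_age,
                                 body_mass_g = out_mass,
                                 survived_to_1yr = out_surv,
                                 stringsAsFactors = FALSE),
                      quiet = TRUE)
  pups <- !is.na(dam[keep])
  truth <- list(params = unclass(p),
                n_individuals = n,
                n_founders = n_found,
                n_pups = sum(pups),
                n_attempts_emitted = at_counter,
                n_skipped_attempts = n_skipped,
                realized_mean_sire_dam_r = mean(sire_dam_r),
                mean_pup_F = mean(Fcoef[keep][pups]),
                pup_F = stats::setNames(Fcoef[keep][pups], id[keep][pups]))
  list(dataset = ds, truth = truth)
}

#' Realized bookkeeping quantities of a simulated (or real) dataset
#'
#' Recomputes, from the emitted tables alone, the realized quantities used by
#' parameter-recovery tests: table row counts, the realized mean sire-dam
#' relatedness over assigned parent pairs, and the distribution of offspring
#' inbreeding coefficients.
#'
#' @param dataset a `study_dataset`
#' @return list of counts and realized summaries
#' @export
truth_report <- function(dataset) {
  ped <- dataset$pedigree
  A <- relatedness_matrix(ped)
  par <- dataset$parentage
  ok <- !is.na(par$dam_id) & !is.na(par$sire_id)
  r_pairs <- relatedness(A, par$dam_id[ok], par$sire_id[ok])
  Ftab <- inbreeding(ped, A / 2)
  offF <- Ftab$F[Ftab$parents_known]
  list(n_individuals = nrow(ped),
       n_rows = vapply(dataset, nrow, 0L),
       realized_mean_sire_dam_r = mean(r_pairs),
       mean_offspring_F = mean(offF),
       prop_offspring_F_positive = mean(offF > 0),
       n_offspring = length(offF))
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", x$n_groups, "groups x", x$attempts_per_group,
      "attempts;", "beta_guard =", x$beta_guard,
      "beta_paternity =", x$beta_paternity, "seed =", x$seed, "\n")
  invisible(x)
}
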