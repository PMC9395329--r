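# Synthetic cohort: per-dog demographics, eight 1-5 behavior/performance
# scores, and ground-truth abundance profiles with optional planted
# species -> trait effects.

#' The eight behavior/performance traits
#'
#' Motivation, aggression, cowardice/hesitation, sociability, general
#' obedience, obedience specificity (one trainer vs many), stress level and
#' job performance, each scored 1-5.
#'
#' @return Character vector of trait column names.
#' @export
dog_traits <- function() {
  c("obedience", "obedience_specific", "motivation", "aggression",
    "cowardice", "sociability", "stress_level", "job_performance")
}

#' Specify a planted microbiome effect on a trait
#'
#' Dogs whose trait score is at or above `threshold` ("high" group) have the
#' affected SGBs' per-dog log-abundances shifted by
#' `direction * effect_size` standard deviations of the generator's per-dog
#' log-normal spread, before renormalization.
#'
#' @param trait one of [dog_traits()] or `"gi_issues"`.
#' @param sgbs character vector of affected SGB ids.
#' @param effect_size shift in units of the per-dog log-abundance SD.
#' @param direction `+1` or `-1`, recycled over `sgbs`.
#' @param threshold score at or above which a dog counts as "high".
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(trait, sgbs, effect_size, direction = 1,
                        threshold = 3) {
  if (!trait %in% c(dog_traits(), "gi_issues")) {
    stop("unknown trait: ", trait)
  }
  stopifnot(length(sgbs) >= 1, is.numeric(effect_size))
  structure(list(trait = trait, sgbs = sgbs, effect_size = effect_size,
                 direction = rep_len(direction, length(sgbs)),
                 threshold = threshold),
            class = "effect_spec")
}

#' Configuration of the cohort generator
#'
#' Defaults emulate the demographic structure of a working-dog program
#' cohort: 11.8% puppies (< 1 year), 53.4% female, ages centred near 3.8
#' years (SD 2.4) in 0.5-12, BCS centred on 5, 11.3% sterilized, 10.3% with
#' chronic GI issues, breeds dominated by Malinois.
#'
#' @param puppy_fraction fraction of dogs younger than 1 year.
#' @param female_fraction fraction of females.
#' @param sterilized_fraction fraction sterilized.
#' @param gi_fraction fraction with recurrent GI issues.
#' @param diet_fraction fraction on a special (hypoallergenic) diet.
#' @param sigma per-dog log-normal SD of species abundances; the unit in
#'   which planted effect sizes are expressed.
#' @param alpha Dirichlet-like concentration of the catalog-level base
#'   abundances (rank-abundance curve).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(puppy_fraction = 0.118, female_fraction = 0.534,
                          sterilized_fraction = 0.113, gi_fraction = 0.103,
                          diet_fraction = 0.067, sigma = 1, alpha = 0.5) {
  stopifnot(puppy_fraction >= 0, puppy_fraction < 1, sigma > 0, alpha > 0)
  structure(list(puppy_fraction = puppy_fraction,
                 female_fraction = female_fraction,
                 sterilized_fraction = sterilized_fraction,
                 gi_fraction = gi_fraction, diet_fraction = diet_fraction,
                 sigma = sigma, alpha = alpha),
            class = "cohort_config")
}

BREED_POOL <- c("Malinois" = 0.435, "Belgian/Dutch Shepherd" = 0.185,
                "GSD" = 0.129, "Corgi" = 0.097, "Labrador" = 0.064,
                "Other" = 0.090)
JOB_POOL <- c("Tracking" = 0.295, "Breeding" = 0.188,
              "Scent detection" = 0.147, "Bite work" = 0.131,
              "Search and Rescue" = 0.123, "Failed" = 0.116)

#' Generate a synthetic cohort with ground-truth abundance profiles
#'
#' Trait scores come from latent standard Gaussians discretized into five
#' equal-probability bins. Per-dog species abundances are
#' `normalize(b_g * exp(sigma * z_gd + shift_gd))` with catalog-level base
#' abundances `b_g ~ Gamma(alpha)` and per-dog noise `z ~ N(0,1)`; each
#' [effect_spec()] adds `direction * effect_size * sigma` to the affected
#' SGBs' log-abundances for dogs in the spec's high group, before
#' renormalization. With no effects, abundances are independent of all
#' metadata.
#'
#' @param catalog an `sgb_catalog` (defines the SGB ids).
#' @param n_dogs cohort size (>= 10); the emulated study cohort is 134.
#' @param effects list of [effect_spec()]s.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return List with `metadata` (data.frame, one row per dog) and `truths`
#'   (n_dogs x n_sgbs matrix of relative abundances, rows summing to 1).
#' @export
generate_cohort <- function(catalog, n_dogs = 134, effects = list(),
                            config = cohort_config(), seed = 1) {
  stopifnot(inherits(catalog, "sgb_catalog"), n_dogs >= 10)
  ids <- catalog$taxonomy$sgb_id
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    missing_sgb <- setdiff(e$sgbs, ids)
    if (length(missing_sgb) > 0) {
      stop("effect on SGB(s) absent from the catalog: ",
           paste(missing_sgb, collapse = ", "))
    }
  }
  set.seed(seed)

  n_puppy <- round(config$puppy_fraction * n_dogs)
  is_puppy <- seq_len(n_dogs) %in% sample.int(n_dogs, n_puppy)
  age <- numeric(n_dogs)
  age[is_puppy] <- round(stats::runif(n_puppy, 0.5, 1 - 1e-3), 2)
  # adult ages: log-normal matched to mean 3.8y, SD 2.4y, clipped to [1, 12]
  sdlog <- sqrt(log(1 + (2.4 / 3.8)^2))
  meanlog <- log(3.8) - sdlog^2 / 2
  age[!is_puppy] <- round(pmin(12, pmax(1, stats::rlnorm(
    n_dogs - n_puppy, meanlog, sdlog))), 1)

  metadata <- data.frame(
    dog_id = sprintf("dog_%03d", seq_len(n_dogs)),
    age = age,
    sex = ifelse(stats::runif(n_dogs) < config$female_fraction,
                 "female", "male"),
    breed = sample(names(BREED_POOL), n_dogs, replace = TRUE,
                   prob = BREED_POOL),
    job = sample(names(JOB_POOL), n_dogs, replace = TRUE, prob = JOB_POOL),
    sterilized = stats::runif(n_dogs) < config$sterilized_fraction,
    bcs = pmin(9, pmax(1, round(stats::rnorm(n_dogs, 5, 0.6) * 2) / 2)),
    gi_issues = stats::runif(n_dogs) < config$gi_fraction,
    special_diet = stats::runif(n_dogs) < config$diet_fraction,
    stringsAsFactors = FALSE)

  # latent-Gaussian trait scores, five equal-probability bins
  cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))
  for (tr in dog_traits()) {
    z <- stats::rnorm(n_dogs)
    metadata[[tr]] <- as.integer(findInterval(z, cuts) + 1L)
  }

  # ground-truth abundances
  n_sgbs <- length(ids)
  b <- stats::rgamma(n_sgbs, shape = config$alpha, rate = 1)
  b[b == 0] <- min(b[b > 0], 1e-12)
  z <- matrix(stats::rnorm(n_dogs * n_sgbs), n_dogs, n_sgbs)
  logw <- matrix(log(b), n_dogs, n_sgbs, byrow = TRUE) + config$sigma * z
  for (e in effects) {
    sc <- metadata[[e$trait]]
    high <- if (is.logical(sc)) sc else sc >= e$threshold
    j <- match(e$sgbs, ids)
    logw[high, j] <- logw[high, j] +
      matrix(e$direction * e$effect_size * config$sigma,
             sum(high), length(j), byrow = TRUE)
  }
  w <- exp(logw)
  truths <- w / rowSums(w)
  dimnames(truths) <- list(metadata$dog_id, ids)

  list(metadata = metadata, truths = truths)
}
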