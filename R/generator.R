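# Synthetic presbycusis cohort generator.
#
# Generative model per participant:
#   threshold(ear, freq) = baseline[freq] + slope * (age - 60)
#                          + person effect + tilt effect(freq)
#                          + ear effect + residual(freq)
# with an optional unilateral asymmetry offset, then 5-dB quantization and
# clipping to the audiometer range [-10, 120] dB HL. The tilt effect is a
# person-level audiogram-slope deviation (flat vs steeply sloping loss)
# with zero mean across the four octave-spaced frequencies, so it shifts
# individual frequencies without moving the pure-tone average.

#' Configuration of the synthetic cohort generator
#'
#' @param n Number of participants (> 0).
#' @param community Community label written into every record.
#' @param age_mean,age_sd Mean and sd (years) of the latent normal age
#'   distribution, truncated to `[age_min, age_max]`.
#' @param age_min,age_max Age range; `age_min` must be >= 60.
#' @param prop_female Fraction of female participants in `[0, 1]`.
#' @param baseline Length-4 vector of mean thresholds (dB HL) at age 60 for
#'   0.5, 1, 2, 4 kHz; must be non-decreasing with frequency (sloping
#'   presbycusis audiogram).
#' @param age_slope Common hearing-decline slope (dB per year of age above
#'   60) applied at every frequency.
#' @param person_sd Between-person random effect sd (dB), shared by both
#'   ears and all frequencies.
#' @param tilt_sd Between-person audiogram-slope sd (dB per octave): each
#'   participant's loss deviates from the population slope by a linear
#'   trend in log2 frequency, centered so the four-frequency mean (and
#'   hence PTA and severity) is unchanged. Captures the flat-to-steep
#'   spectrum of presbycusis configurations.
#' @param ear_sd Between-ear random effect sd (dB), shared by the four
#'   frequencies of one ear.
#' @param resid_sd Residual sd (dB) per frequency; a scalar is recycled to
#'   length 4.
#' @param p_asym Probability that a participant receives an extra unilateral
#'   offset, creating asymmetrical hearing loss.
#' @param asym_min,asym_max Uniform range (dB) of the unilateral offset;
#'   `asym_min` must exceed 20 so injected cases meet the asymmetry
#'   definition (worse-minus-better PTA > 20 dB HL).
#' @param seed Default seed used by [generate_cohort] when none is given.
#' @return A `generator_config` object (list).
#' @export
generator_config <- function(n,
                             community = "synthetic",
                             age_mean = 71.4, age_sd = 5.3,
                             age_min = 60, age_max = 92,
                             prop_female = 0.57,
                             baseline = c(25, 31, 38, 51),
                             age_slope = 0.601,
                             person_sd = 10,
                             tilt_sd = 3,
                             ear_sd = 4,
                             resid_sd = c(5, 4, 2.5, 6),
                             p_asym = 0.035,
                             asym_min = 25, asym_max = 45,
                             seed = 1L) {
  if (length(resid_sd) == 1L) resid_sd <- rep(resid_sd, 4L)
  cfg <- list(n = as.integer(n), community = as.character(community),
              age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max,
              prop_female = prop_female,
              baseline = as.numeric(baseline), age_slope = age_slope,
              person_sd = person_sd, tilt_sd = tilt_sd, ear_sd = ear_sd,
              resid_sd = as.numeric(resid_sd),
              p_asym = p_asym, asym_min = asym_min, asym_max = asym_max,
              seed = as.integer(seed))
  if (cfg$n <= 0L) stop("n must be positive", call. = FALSE)
  if (cfg$age_min < 60) stop("age_min must be >= 60", call. = FALSE)
  if (cfg$age_max < cfg$age_min) stop("age_max must be >= age_min", call. = FALSE)
  if (cfg$prop_female < 0 || cfg$prop_female > 1 ||
      cfg$p_asym < 0 || cfg$p_asym > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(cfg$age_sd, cfg$person_sd, cfg$tilt_sd, cfg$ear_sd,
            cfg$resid_sd) < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  if (length(cfg$baseline) != 4L || is.unsorted(cfg$baseline))
    stop("baseline must be four non-decreasing thresholds", call. = FALSE)
  if (cfg$asym_min <= 20)
    stop("asym_min must exceed 20 dB so injected cases are asymmetric",
         call. = FALSE)
  if (cfg$asym_max < cfg$asym_min)
    stop("asym_max must be >= asym_min", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Cohort generator config '%s': n = %d, age %g/%g on [%g, %g]\n",
              x$community, x$n, x$age_mean, x$age_sd, x$age_min, x$age_max))
  cat(sprintf("  baseline at 60 yrs: %s dB HL; slope %g dB/yr\n",
              paste(x$baseline, collapse = "/"), x$age_slope))
  cat(sprintf("  sds person %g, tilt %g/oct, ear %g, residual %s; asymmetry p = %g on [%g, %g] dB\n",
              x$person_sd, x$tilt_sd, x$ear_sd,
              paste(x$resid_sd, collapse = "/"),
              x$p_asym, x$asym_min, x$asym_max))
  invisible(x)
}

# Truncated-normal sampling via the inverse CDF, so the number of RNG draws
# is fixed and cohorts are reproducible regardless of truncation mass.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.round5 <- function(x) 5 * round(x / 5)

#' Generate a synthetic audiometric cohort
#'
#' Draws ages from a truncated normal, assigns sex, and builds bilateral
#' audiograms from the additive random-effects model described in
#' [generator_config]. A fraction `p_asym` of participants receives a
#' uniform unilateral offset on one randomly chosen ear. Thresholds are
#' rounded to the nearest 5 dB and clipped to [-10, 120] dB HL. The same
#' config and seed always produce the identical cohort.
#'
#' @param cfg A [generator_config].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A [cohort] with generator provenance.
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- cfg$n
  age <- as.integer(round(.rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                                      cfg$age_min, cfg$age_max)))
  age <- pmin(pmax(age, as.integer(cfg$age_min)), as.integer(cfg$age_max))
  sex <- ifelse(stats::runif(n) < cfg$prop_female, "female", "male")
  person <- stats::rnorm(n, 0, cfg$person_sd)
  tilt <- stats::rnorm(n, 0, cfg$tilt_sd)
  ear_l <- stats::rnorm(n, 0, cfg$ear_sd)
  ear_r <- stats::rnorm(n, 0, cfg$ear_sd)
  asym <- stats::runif(n) < cfg$p_asym
  asym_left <- stats::runif(n) < 0.5
  offset <- stats::runif(n, cfg$asym_min, cfg$asym_max) * asym

  # octave positions of 0.5/1/2/4 kHz, centered so the tilt leaves PTA fixed
  oct <- log2(tone_frequencies()) - mean(log2(tone_frequencies()))
  mu <- outer(cfg$age_slope * (age - 60) + person, rep(1, 4)) +
    outer(rep(1, n), cfg$baseline) + outer(tilt, oct)
  resid_l <- matrix(stats::rnorm(4L * n, 0, rep(cfg$resid_sd, each = n)), n, 4)
  resid_r <- matrix(stats::rnorm(4L * n, 0, rep(cfg$resid_sd, each = n)), n, 4)
  left <- mu + ear_l + resid_l + offset * asym_left
  right <- mu + ear_r + resid_r + offset * !asym_left

  quantize <- function(m) pmin(pmax(.round5(m), .db_range[1]), .db_range[2])
  left <- quantize(left)
  right <- quantize(right)

  df <- data.frame(id = sprintf("%s-%05d", cfg$community, seq_len(n)),
                   community = cfg$community, age = age, sex = sex,
                   stringsAsFactors = FALSE)
  df[c("l500", "l1000", "l2000", "l4000")] <- left
  df[c("r500", "r1000", "r2000", "r4000")] <- right
  cohort(df, provenance = list(source = "generator", config = unclass(cfg),
                               seed = as.integer(seed)))
}

#' Calibrated community generator profiles
#'
#' Returns named [generator_config]s whose free parameters (baselines,
#' random-effect sds, asymmetry rates) are calibrated so that generated
#' cohorts match the descriptive structure of the two study communities:
#' a younger community ("communityA", n = 1261, age 71.4 +/- 5.3 on
#' [60, 92], ~3.7% asymmetric, worse-ear moderate-to-profound prevalence
#' ~70.7%) and an older, more heterogeneous one ("communityB", n = 532, age
#' 76.5 +/- 10.2 on [60, 104], ~10.4% asymmetric, worse-ear prevalence
#' ~62.0%), with a common hearing-decline slope of 0.601 dB per year of
#' age. Calibrated values are stored in `inst/extdata/profiles.yaml`
#' (produced by `scripts/calibrate_profiles.R`), not hard-coded.
#'
#' @param path Optional path to a profiles YAML file; defaults to the one
#'   shipped with the package.
#' @return Named list of [generator_config] objects.
#' @export
default_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "profiles.yaml", package = "tonescreen",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) do.call(generator_config, p))
}

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_generator_config] returns a [generator_config];
#'   `write_generator_config` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}

#' @param cfg A [generator_config].
#' @rdname read_generator_config
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
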