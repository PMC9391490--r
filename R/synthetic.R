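# Synthetic dentine growth: seeded generators for teeth, tooth families and
# jaw-level replacement schedules with known ground truth, so every
# estimator in the package can be validated by parameter recovery. The
# generator emulates daily apposition (one increment per day), resorption
# pit growth on the functional tooth, line dropout, oblique-section width
# inflation, and measurement jitter.

#' Growth parameters for the synthetic dentine generator
#'
#' Defaults describe a mid-band polyphyodont tooth: lognormal daily widths
#' with mean 12 micrometres/day and coefficient of variation 0.2, a linear
#' crown (constant 10 micrometres of apical height per increment line), and
#' resorption-pit growth of 15 micrometres/day since replacement-tooth
#' initiation. With a linear crown, pit growth at 1.5 times the height per
#' increment makes the two-thirds-pit-height estimator exactly unbiased,
#' which is the intended geometry of that estimator; set
#' `rp_growth_per_day` away from `1.5 * height_per_increment` to study its
#' behaviour under mis-specified pit geometry.
#'
#' @param mean_daily_width Mean daily increment width, micrometres/day; must
#'   lie in (0, 30].
#' @param width_cv Coefficient of variation of daily widths (>= 0).
#' @param width_distribution `"lognormal"` or `"truncated-normal"`.
#' @param height_per_increment Either a single number (constant apical
#'   height contribution per line, micrometres) or a function
#'   `f(i)` returning the contribution of line `i` (counted from the apex);
#'   contributions must be positive.
#' @param true_replacement_interval True replacement interval in days (> 0).
#' @param rp_growth_per_day Resorption-pit height growth, micrometres/day.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(mean_daily_width = 12,
                          width_cv = 0.2,
                          width_distribution = c("lognormal", "truncated-normal"),
                          height_per_increment = 10,
                          true_replacement_interval = 105,
                          rp_growth_per_day = 15) {
  width_distribution <- match.arg(width_distribution)
  if (!is_scalar_number(mean_daily_width) || mean_daily_width <= 0 ||
      mean_daily_width > 30) {
    tc_stop("configuration_error", "mean_daily_width must be in (0, 30] um/day")
  }
  if (!is_scalar_number(width_cv) || width_cv < 0) {
    tc_stop("configuration_error", "width_cv must be >= 0")
  }
  if (!is_scalar_number(true_replacement_interval) || true_replacement_interval <= 0) {
    tc_stop("configuration_error", "true_replacement_interval must be > 0")
  }
  if (!is_scalar_number(rp_growth_per_day) || rp_growth_per_day <= 0) {
    tc_stop("configuration_error", "rp_growth_per_day must be > 0")
  }
  if (!is.function(height_per_increment) &&
      (!is_scalar_number(height_per_increment) || height_per_increment <= 0)) {
    tc_stop("configuration_error",
            "height_per_increment must be a positive number or a function of line index")
  }
  structure(
    list(mean_daily_width = mean_daily_width, width_cv = width_cv,
         width_distribution = width_distribution,
         height_per_increment = height_per_increment,
         true_replacement_interval = true_replacement_interval,
         rp_growth_per_day = rp_growth_per_day),
    class = "growth_params"
  )
}

#' Decelerating apical growth profile
#'
#' A pluggable alternative to the default linear crown: per-line apical
#' height contributions decay geometrically with line index, emulating a
#' tooth whose apical extension slows as the crown completes.
#'
#' @param initial First-line contribution in micrometres.
#' @param decay Per-line decay factor in (0, 1].
#' @return A function of the line index, usable as `height_per_increment`.
#' @export
decelerating_height <- function(initial = 15, decay = 0.995) {
  stopifnot(initial > 0, decay > 0, decay <= 1)
  function(i) initial * decay^(i - 1)
}

#' Measurement-noise parameters
#'
#' @param missed_line_prob Probability in \[0, 1) that an interior line
#'   boundary is missed (adjacent increments merge).
#' @param obliquity_angle Sectioning obliquity in degrees, `0 <= angle < 90`;
#'   apparent positions scale by `1/cos(angle)`.
#' @param position_jitter_sd Standard deviation (micrometres) of measurement
#'   jitter on boundary positions.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(missed_line_prob = 0, obliquity_angle = 0,
                         position_jitter_sd = 0) {
  if (!is_scalar_number(missed_line_prob) || missed_line_prob < 0 ||
      missed_line_prob >= 1) {
    tc_stop("configuration_error", "missed_line_prob must be in [0, 1)")
  }
  if (!is_scalar_number(obliquity_angle) || obliquity_angle < 0 ||
      obliquity_angle >= 90) {
    tc_stop("configuration_error", "obliquity_angle must be in [0, 90) degrees")
  }
  if (!is_scalar_number(position_jitter_sd) || position_jitter_sd < 0) {
    tc_stop("configuration_error", "position_jitter_sd must be >= 0")
  }
  structure(
    list(missed_line_prob = missed_line_prob, obliquity_angle = obliquity_angle,
         position_jitter_sd = position_jitter_sd),
    class = "noise_params"
  )
}

draw_widths <- function(params, n) {
  m <- params$mean_daily_width
  cv <- params$width_cv
  if (cv == 0) return(rep(m, n))
  if (params$width_distribution == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(m) - sdlog^2 / 2
    stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  } else {
    w <- stats::rnorm(n, mean = m, sd = cv * m)
    # reject non-positive draws; a width is a physical thickness
    while (any(w <= 0)) {
      bad <- w <= 0
      w[bad] <- stats::rnorm(sum(bad), mean = m, sd = cv * m)
    }
    w
  }
}

height_contributions <- function(params, n) {
  h <- params$height_per_increment
  if (is.function(h)) {
    out <- vapply(seq_len(n), h, numeric(1))
    if (any(out <= 0) || any(diff(cumsum(out)) < 0)) {
      tc_stop("configuration_error", "height_per_increment must return positive values")
    }
    out
  } else {
    rep(h, n)
  }
}

#' Simulate one tooth
#'
#' Generates a tooth of known age: `age_days` daily increments with i.i.d.
#' widths from the configured distribution, the matching transect of
#' boundary positions (pulp cavity outward), and the apex profile of
#' cumulative crown heights (apex downward).
#'
#' @param params A [growth_params()].
#' @param age_days Integer age in days (>= 1).
#' @param seed Integer seed; identical `params`, `age_days` and `seed` give
#'   bit-identical output.
#' @param tooth_id Identifier for the emitted transect/profile.
#' @return List with `transect` ([increment_transect()]), `profile`
#'   ([apex_profile()]), and `truth` (list: `true_age_days`,
#'   `true_mean_width`, `seed`).
#' @export
simulate_tooth <- function(params, age_days, seed, tooth_id = "synthetic") {
  stopifnot(inherits(params, "growth_params"))
  if (!is_scalar_number(age_days) || age_days < 1) {
    tc_stop("configuration_error", "age_days must be >= 1")
  }
  age_days <- as.integer(age_days)
  set.seed(as.integer(seed))
  widths <- draw_widths(params, age_days)
  transect <- increment_transect(tooth_id, "TR", c(0, cumsum(widths)))
  profile <- apex_profile(cumsum(height_contributions(params, age_days)),
                          tooth_id = tooth_id)
  list(
    transect = transect,
    profile = profile,
    truth = list(true_age_days = age_days,
                 true_mean_width = params$mean_daily_width,
                 seed = as.integer(seed))
  )
}

#' Apply sectioning and measurement noise to a transect
#'
#' In order: (1) each interior boundary is independently missed with
#' probability `missed_line_prob`, merging the adjacent increments;
#' (2) all positions are inflated by `1/cos(obliquity_angle)`, the apparent
#' widening of an obliquely cut section; (3) Gaussian jitter of standard
#' deviation `position_jitter_sd` is added to each boundary, clamped to the
#' midpoints between neighbouring boundaries so the strict ordering is
#' preserved. Gap intervals are carried through the same scaling.
#'
#' @param transect An [increment_transect()].
#' @param noise A [noise_params()].
#' @param seed Integer seed.
#' @return A new [increment_transect()].
#' @export
apply_section_noise <- function(transect, noise, seed) {
  stopifnot(inherits(transect, "increment_transect"), inherits(noise, "noise_params"))
  set.seed(as.integer(seed))
  pos <- transect$boundary_positions
  n <- length(pos)
  if (noise$missed_line_prob > 0 && n > 2L) {
    interior <- 2:(n - 1L)
    drop <- stats::runif(length(interior)) < noise$missed_line_prob
    if (any(drop)) pos <- pos[-interior[drop]]
  }
  scale <- 1 / cos(noise$obliquity_angle * pi / 180)
  pos <- pos * scale
  gaps <- transect$gaps
  if (nrow(gaps) > 0L) {
    gaps$start_um <- gaps$start_um * scale
    gaps$end_um <- gaps$end_um * scale
  }
  if (noise$position_jitter_sd > 0 && length(pos) > 2L) {
    jit <- pos + stats::rnorm(length(pos), sd = noise$position_jitter_sd)
    m <- length(pos)
    lo <- c(-Inf, (pos[-m] + pos[-1L]) / 2)
    hi <- c((pos[-m] + pos[-1L]) / 2, Inf)
    eps <- 1e-9 * max(1, diff(range(pos)))
    pos <- pmin(pmax(jit, lo + eps), hi - eps)
  }
  increment_transect(transect$tooth_id, transect$plane, pos,
                     gaps = if (nrow(gaps) > 0L) gaps else NULL)
}

#' Simulate a tooth family with known replacement interval
#'
#' The functional tooth is observed at `observation_day`; its replacement
#' began depositing dentine `true_replacement_interval` days ago, so the
#' replacement tooth's age is `observation_day - interval` and the
#' resorption pit has grown linearly at `rp_growth_per_day` since
#' initiation. Direct subtraction of the emitted ages recovers the interval
#' exactly (conservation, pre-noise).
#'
#' @param params A [growth_params()].
#' @param observation_day Day of observation; must exceed the replacement
#'   interval.
#' @param seed Integer seed.
#' @param taxon Taxon label for the emitted records.
#' @return List with `family` ([tooth_family()]), `profile` (functional
#'   tooth [apex_profile()]), `transects` (functional and replacement
#'   [increment_transect()]s), and `truth` (list: `true_age_days`,
#'   `true_replacement_rate`, `true_replacement_age`, `rp_height`,
#'   `true_mean_width`, `seed`).
#' @export
simulate_family <- function(params, observation_day, seed, taxon = "synthetic") {
  stopifnot(inherits(params, "growth_params"))
  interval <- params$true_replacement_interval
  if (!is_scalar_number(observation_day) || observation_day <= interval) {
    tc_stop("configuration_error",
            "observation_day must exceed the true replacement interval")
  }
  observation_day <- as.integer(observation_day)
  rep_age <- observation_day - as.integer(round_half_up(interval))
  fun_sim <- simulate_tooth(params, observation_day, seed = seed,
                            tooth_id = paste0(taxon, "_functional"))
  rep_sim <- simulate_tooth(params, rep_age, seed = as.integer(seed) + 1L,
                            tooth_id = paste0(taxon, "_replacement"))
  rp_height <- params$rp_growth_per_day * rep_age
  functional <- tooth_record(taxon, "sim", position_label = "p01",
                             age_days = observation_day,
                             rp_height = rp_height, ankylosed = TRUE)
  replacement <- tooth_record(taxon, "sim", position_label = "p01",
                              age_days = rep_age)
  fam <- tooth_family(functional, list(replacement),
                      family_id = paste0(taxon, "_fam"))
  list(
    family = fam,
    profile = fun_sim$profile,
    transects = list(functional = fun_sim$transect,
                     replacement = rep_sim$transect),
    truth = list(true_age_days = observation_day,
                 true_replacement_rate = as.integer(round_half_up(interval)),
                 true_replacement_age = rep_age,
                 rp_height = rp_height,
                 true_mean_width = params$mean_daily_width,
                 seed = as.integer(seed))
  )
}

#' Simulate a jaw-level replacement wave
#'
#' Polyphyodont replacement runs as a wave in alternating tooth positions:
#' odd and even positions replace in events offset by half the interval, so
#' no two adjacent positions are ever simultaneously toothless. Each
#' replacement event puts a position into the `"gap"` state (old tooth
#' shed, successor unattached) and then the `"new"` state (successor
#' attached but newly so) before returning to `"functional"`.
#'
#' @param n_positions Number of tooth positions along the jaw (>= 2).
#' @param interval Replacement interval in days.
#' @param duration Days to simulate.
#' @param seed Integer seed (the schedule is deterministic; the seed is
#'   recorded for schema compatibility with the other generators).
#' @param gap_days Days a position stays in the gap state after shedding;
#'   default one tenth of the interval, at least 1 and below `interval / 2`
#'   so adjacency is preserved.
#' @return List with `occupancy` (character matrix, positions x days,
#'   values `"functional"`, `"gap"`, `"new"`) and `events` (data frame of
#'   position, day).
#' @export
simulate_replacement_wave <- function(n_positions, interval, duration, seed = 1L,
                                      gap_days = NULL) {
  if (!is_scalar_number(n_positions) || n_positions < 2L) {
    tc_stop("configuration_error", "n_positions must be >= 2")
  }
  if (!is_scalar_number(interval) || interval < 2) {
    tc_stop("configuration_error", "interval must be >= 2 days")
  }
  n_positions <- as.integer(n_positions)
  interval <- as.integer(round_half_up(interval))
  duration <- as.integer(duration)
  if (is.null(gap_days)) gap_days <- max(1L, as.integer(round_half_up(interval / 10)))
  gap_days <- min(gap_days, as.integer(floor(interval / 2)) - 1L)
  gap_days <- max(gap_days, 1L)
  new_days <- gap_days
  occ <- matrix("functional", nrow = n_positions, ncol = duration)
  events <- list()
  half <- as.integer(round_half_up(interval / 2))
  for (p in seq_len(n_positions)) {
    offset <- if (p %% 2L == 1L) 0L else half
    event_days <- seq.int(from = interval + offset, by = interval,
                          length.out = max(0L, (duration - offset) %/% interval))
    event_days <- event_days[event_days <= duration]
    for (d in event_days) {
      events[[length(events) + 1L]] <- data.frame(position = p, day = d)
      gap_span <- d:min(duration, d + gap_days - 1L)
      occ[p, gap_span] <- "gap"
      new_start <- d + gap_days
      if (new_start <= duration) {
        occ[p, new_start:min(duration, new_start + new_days - 1L)] <- "new"
      }
    }
  }
  list(occupancy = occ,
       events = if (length(events) > 0L) do.call(rbind, events) else
         data.frame(position = integer(0), day = integer(0)),
       seed = as.integer(seed))
}

#' Estimator recovery experiment
#'
#' Runs the paper-style validation of the replacement-rate estimators on
#' simulated tooth families with known truth: for every condition in
#' `param_grid` and every estimator (`direct`, `rp_height`,
#' `dentine_extent`), simulates `n_reps` families, applies the estimator to
#' the noisy observables, and reports bias and root-mean-square error of
#' the recovered rate against the true interval.
#'
#' @param param_grid Data frame of conditions; recognised columns (all
#'   optional) `missed_line_prob`, `obliquity_angle`, `position_jitter_sd`,
#'   `width_cv`, `interval`, `observation_day`. Omitted columns take the
#'   defaults of [growth_params()] / [noise_params()].
#' @param n_reps Replicates per condition.
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @return Data frame with columns `condition`, the grid columns,
#'   `estimator`, `bias`, `rmse`, `n`.
#' @export
recovery_experiment <- function(param_grid = data.frame(missed_line_prob = 0),
                                n_reps = 50L, seed = 1L) {
  stopifnot(is.data.frame(param_grid), nrow(param_grid) >= 1L)
  seed <- as.integer(seed)
  grab <- function(row, col, default) {
    if (col %in% names(param_grid)) param_grid[[col]][row] else default
  }
  out <- list()
  for (cond in seq_len(nrow(param_grid))) {
    interval <- grab(cond, "interval", 105)
    obs_day <- grab(cond, "observation_day", round(interval * 1.6))
    params <- growth_params(
      width_cv = grab(cond, "width_cv", 0.2),
      true_replacement_interval = interval
    )
    noise <- noise_params(
      missed_line_prob = grab(cond, "missed_line_prob", 0),
      obliquity_angle = grab(cond, "obliquity_angle", 0),
      position_jitter_sd = grab(cond, "position_jitter_sd", 0)
    )
    errs <- matrix(NA_real_, nrow = n_reps, ncol = 3,
                   dimnames = list(NULL, c("direct", "rp_height", "dentine_extent")))
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + 7919L * (cond - 1L) + 13L * r
      sim <- simulate_family(params, obs_day, seed = rep_seed)
      tr_f <- apply_section_noise(sim$transects$functional, noise,
                                  seed = rep_seed + 1L)
      tr_r <- apply_section_noise(sim$transects$replacement, noise,
                                  seed = rep_seed + 2L)
      age_f <- tooth_age_days(count_total_increments(tr_f))
      age_r <- tooth_age_days(count_total_increments(tr_r))
      truth <- sim$truth$true_replacement_rate
      errs[r, "direct"] <- (age_f - age_r) - truth
      rp_age <- estimate_missing_replacement_age(sim$profile, sim$truth$rp_height)
      errs[r, "rp_height"] <- (age_f - rp_age) - truth
      # dentine extent of the replacement tooth, read off its noisy transect,
      # against the functional tooth's measured mean width (corrected for the
      # known obliquity, as an analyst with oriented sections would)
      mw <- deoblique_width(mean_increment_width(tr_f), noise$obliquity_angle)
      extent <- deoblique_width(diff(range(tr_r$boundary_positions)),
                                noise$obliquity_angle)
      de_age <- dentine_extent_age(extent, mw)
      errs[r, "dentine_extent"] <- (age_f - de_age) - truth
    }
    for (est in colnames(errs)) {
      row <- param_grid[cond, , drop = FALSE]
      rownames(row) <- NULL
      out[[length(out) + 1L]] <- cbind(
        data.frame(condition = cond), row,
        data.frame(estimator = est,
                   bias = mean(errs[, est]),
                   rmse = sqrt(mean(errs[, est]^2)),
                   n = n_reps)
      )
    }
  }
  do.call(rbind, out)
}
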