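#' Synthetic odor-class profile
#'
#' A class profile describes one odor class as seen by a metal-oxide sensor
#' array: the mean steady-state load voltage per sensor (its signature
#' pattern), the per-sensor dispersion of that steady state across repeated
#' exposures, the pre-exposure baseline voltage, and a first-order response
#' time constant. Sensor voltage rises during exposure, so the signature is
#' elementwise at least the baseline.
#'
#' @param mean_signature numeric length-N vector of steady-state voltages (V).
#' @param dispersion numeric length-N vector of standard deviations (V).
#' @param baseline numeric length-N vector of pre-exposure voltages (V).
#' @param tau response time constant (seconds).
#' @param name class name.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(mean_signature, dispersion, baseline, tau,
                          name = "class") {
  mean_signature <- as.numeric(mean_signature)
  dispersion <- as.numeric(dispersion)
  baseline <- as.numeric(baseline)
  N <- length(mean_signature)
  if (length(dispersion) != N || length(baseline) != N)
    stop("mean_signature, dispersion and baseline must share length")
  if (any(dispersion < 0)) stop("dispersion must be nonnegative")
  if (tau <= 0) stop("tau must be positive")
  if (any(mean_signature < baseline))
    stop("mean_signature must be >= baseline elementwise")
  structure(list(mean_signature = mean_signature, dispersion = dispersion,
                 baseline = baseline, tau = tau, name = name),
            class = "class_profile")
}

#' Synthetic generator configuration
#'
#' @param trained_profiles list of [class_profile()]s for the trained classes.
#' @param irrelevant_profiles list of [class_profile()]s for out-of-training
#'   classes (generated rows are flagged irrelevant).
#' @param reps_per_class replicate measurements per class.
#' @param noise_model only `"gaussian"` is supported.
#' @param separation_margin nonnegative margin, in units of per-sensor
#'   dispersion, requested between irrelevant samples and trained-class
#'   hyperboxes (enforced by [enforce_separation()]).
#' @param seed integer generation seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(trained_profiles, irrelevant_profiles = list(),
                             reps_per_class = 20L, noise_model = "gaussian",
                             separation_margin = 0, seed = 1L) {
  if (reps_per_class < 1) stop("reps_per_class must be >= 1")
  if (!identical(noise_model, "gaussian"))
    stop("only the gaussian noise model is supported")
  if (separation_margin < 0) stop("separation_margin must be >= 0")
  all_prof <- c(trained_profiles, irrelevant_profiles)
  if (length(all_prof) == 0) stop("need at least one profile")
  ns <- vapply(all_prof, function(p) length(p$mean_signature), integer(1))
  if (length(unique(ns)) != 1) stop("all profiles must share n_sensors")
  structure(list(n_sensors = ns[1], trained_profiles = trained_profiles,
                 irrelevant_profiles = irrelevant_profiles,
                 reps_per_class = as.integer(reps_per_class),
                 noise_model = noise_model,
                 separation_margin = separation_margin,
                 seed = as.integer(seed), separation = NULL),
            class = "generator_config")
}

#' Default synthetic e-nose design
#'
#' Emulates the structure of an 8-sensor, 12-class fruit-odor experiment:
#' 4 fruit types (banana, sapodilla, pineapple, mango) at 3 ripeness states
#' each, 20 replicate measurements per class (240 rows in total). The 9
#' banana/sapodilla/pineapple classes are the trained classes; the 3 mango
#' classes are irrelevant (out-of-training). Signature patterns are stylized:
#' sensors 1-2 sit near 0.2-0.3 V with little class variation, sensors 3-8
#' carry distinct class-varying responses on a 0-5 V scale (sensors powered
#' at 5 V bound plausible outputs), with ripeness scaling the VOC response.
#'
#' @param reps_per_class replicates per class (default 20).
#' @param seed generation seed.
#' @param separation_margin margin requested for irrelevant classes (default
#'   3 dispersions; applied by [enforce_separation()], not here).
#' @return a `generator_config` with 12 profiles over 8 sensors.
#' @export
default_design <- function(reps_per_class = 20L, seed = 1L,
                           separation_margin = 3) {
  fruit_base <- list(
    banana    = c(1.0, 2.2, 1.4, 3.0, 2.0, 1.2),
    sapodilla = c(1.8, 3.1, 2.2, 1.0, 1.4, 3.0),
    pineapple = c(3.3, 1.7, 1.1, 2.4, 3.2, 1.6),
    mango     = c(2.6, 1.2, 3.2, 1.5, 2.8, 2.1))
  ripeness <- c(unripe = 0.65, ripe = 1.0, rotten = 1.25)
  baseline <- c(0.10, 0.10, rep(0.30, 6))
  dispersion <- c(0.02, 0.02, rep(0.08, 6))
  mk <- function(fruit, state, i_state) {
    low <- 0.18 + 0.02 * i_state + 0.01 * match(fruit, names(fruit_base))
    sig <- c(low, low + 0.04,
             pmin(4.6, 0.3 + fruit_base[[fruit]] * ripeness[[state]]))
    class_profile(sig, dispersion, baseline, tau = 20,
                  name = paste(state, fruit))
  }
  profs <- list()
  for (fruit in names(fruit_base))
    for (i in seq_along(ripeness))
      profs[[length(profs) + 1]] <- mk(fruit, names(ripeness)[i], i)
  generator_config(trained_profiles = profs[1:9],
                   irrelevant_profiles = profs[10:12],
                   reps_per_class = reps_per_class,
                   separation_margin = separation_margin, seed = seed)
}

#' Simulate raw sensor voltage time series for one exposure
#'
#' Each sensor follows a first-order rise
#' `baseline + (steady - baseline) * (1 - exp(-t / tau))` plus i.i.d.
#' Gaussian noise with the profile's per-sensor dispersion, sampled at
#' `rate` samples per second for `duration` seconds.
#'
#' @param profile a [class_profile()].
#' @param duration exposure length (seconds), > 0.
#' @param rate sampling rate (samples/second), > 0.
#' @param seed integer seed.
#' @return numeric matrix, rows = time points, columns = sensors; time stamps
#'   in the `"time"` attribute.
#' @export
generate_time_series <- function(profile, duration, rate, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (rate <= 0) stop("rate must be positive")
  n <- max(1L, floor(duration * rate))
  t <- seq_len(n) / rate
  N <- length(profile$mean_signature)
  rise <- 1 - exp(-t / profile$tau)
  series <- with_seed(seed, {
    m <- outer(rise, profile$mean_signature - profile$baseline) +
      matrix(profile$baseline, n, N, byrow = TRUE)
    m + matrix(stats::rnorm(n * N, 0, rep(profile$dispersion, each = n)), n, N)
  })
  colnames(series) <- paste0("sensor_", seq_len(N))
  attr(series, "time") <- t
  series
}

#' Reduce a sensor time series to steady-state features
#'
#' Averages the trailing `window` fraction of samples per sensor, emulating
#' the steady-state plateau averaging used to build signature patterns.
#'
#' @param series matrix from [generate_time_series()] (rows = time points).
#' @param window trailing fraction of samples to average, in (0, 1].
#' @return numeric length-N feature vector.
#' @export
steady_state_features <- function(series, window = 0.2) {
  if (is.null(dim(series)) || nrow(series) == 0)
    stop("input error: empty series")
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  n <- nrow(series)
  keep <- seq.int(n - max(1L, ceiling(window * n)) + 1L, n)
  colMeans(series[keep, , drop = FALSE])
}

# Does row x violate the separation requirement against the trained boxes?
# Separation holds iff for EVERY trained class there is at least one sensor
# on which x lies outside that class's [V, Q] interval by at least
# margin * dispersion of that sensor.
row_separated <- function(x, Q, V, margin, dispersion) {
  for (m in seq_len(nrow(Q))) {
    exceed <- pmax(V[m, ] - x, x - Q[m, ])
    if (!any(exceed >= margin * dispersion)) return(FALSE)
  }
  TRUE
}

#' Generate a steady-state feature dataset from a configuration
#'
#' Emits `reps_per_class` rows per profile with features
#' `mean_signature + N(0, dispersion)`; rows from irrelevant profiles carry
#' the `irrelevant` flag. When the configuration carries a separation
#' constraint (from [enforce_separation()]), irrelevant rows violating it are
#' resampled (up to 1000 attempts per row). Output is a pure function of the
#' configuration and its seed.
#'
#' @param cfg a `generator_config`.
#' @return a `labeled_dataset` (trained classes labeled `1..M_trained`, then
#'   irrelevant classes) with the `irrelevant` flag set.
#' @export
generate_features <- function(cfg) {
  profs <- c(cfg$trained_profiles, cfg$irrelevant_profiles)
  n_tr <- length(cfg$trained_profiles)
  R <- cfg$reps_per_class
  N <- cfg$n_sensors
  sep <- cfg$separation
  with_seed(cfg$seed, {
    rows <- vector("list", length(profs))
    for (p in seq_along(profs)) {
      pr <- profs[[p]]
      block <- matrix(pr$mean_signature, R, N, byrow = TRUE) +
        matrix(stats::rnorm(R * N, 0, rep(pr$dispersion, each = R)), R, N)
      if (!is.null(sep) && p > n_tr) {
        for (r in seq_len(R)) {
          tries <- 0L
          while (!row_separated(block[r, ], sep$Q, sep$V, sep$margin,
                                pr$dispersion)) {
            tries <- tries + 1L
            if (tries > 1000L)
              stop("separation error: cannot place irrelevant sample outside ",
                   "trained hyperboxes in 1000 attempts")
            block[r, ] <- pr$mean_signature +
              stats::rnorm(N, 0, pr$dispersion)
          }
        }
      }
      rows[[p]] <- block
    }
    labeled_dataset(do.call(rbind, rows), rep(seq_along(profs), each = R),
                    class_names = vapply(profs, `[[`, "", "name"),
                    irrelevant = rep(seq_along(profs) > n_tr, each = R))
  })
}

#' Shift irrelevant profiles outside the trained-class hyperboxes
#'
#' Rewrites each irrelevant profile so that every sample it generates falls
#' outside every trained-class axis-aligned min-max box on at least one
#' sensor, by at least `margin` dispersions. Each irrelevant profile gets a
#' designated sensor whose mean is moved above the largest trained-class
#' maximum on that sensor by `(margin + 4)` dispersions, and the returned
#' configuration records the boxes and margin so [generate_features()]
#' resamples any residual violating rows. The shift is verified by a trial
#' generation; failure to separate within 1000 attempts per row is an error.
#'
#' @param cfg a `generator_config` with `separation_margin > 0`.
#' @param trained_boxes a fitted [fit_mmm()] model, or a list with `Q`
#'   (class-by-sensor maxima) and `V` (minima) for the trained classes.
#' @param margin overrides `cfg$separation_margin` if given.
#' @return a `generator_config` with shifted irrelevant profiles and an
#'   active separation constraint.
#' @export
enforce_separation <- function(cfg, trained_boxes,
                               margin = cfg$separation_margin) {
  if (margin <= 0)
    stop("separation error: separation_margin must be > 0")
  if (length(cfg$irrelevant_profiles) == 0)
    stop("no irrelevant profiles to separate")
  Q <- trained_boxes$Q
  V <- trained_boxes$V
  if (is.null(Q) || is.null(V)) stop("trained_boxes must supply Q and V")
  sensors <- 3:cfg$n_sensors  # keep the low-response sensors 1-2 untouched
  for (i in seq_along(cfg$irrelevant_profiles)) {
    pr <- cfg$irrelevant_profiles[[i]]
    s <- sensors[1 + (i - 1) %% length(sensors)]
    pr$mean_signature[s] <- max(Q[, s]) + (margin + 4) * pr$dispersion[s]
    cfg$irrelevant_profiles[[i]] <- pr
  }
  cfg$separation_margin <- margin
  cfg$separation <- list(Q = Q, V = V, margin = margin)
  ds <- generate_features(cfg)  # errors if separation is unachievable
  irr <- ds$features[ds$irrelevant, , drop = FALSE]
  disp <- cfg$irrelevant_profiles[[1]]$dispersion
  ok <- apply(irr, 1, row_separated, Q = Q, V = V, margin = margin,
              dispersion = disp)
  if (!all(ok)) stop("separation error: verification failed")
  cfg
}

#' Serialize / restore a generator configuration as YAML
#'
#' @param cfg a `generator_config`.
#' @param path YAML file path.
#' @return `config_to_yaml` returns `path` invisibly; `config_from_yaml`
#'   returns a `generator_config`.
#' @export
config_to_yaml <- function(cfg, path) {
  ser_prof <- function(p) list(mean_signature = p$mean_signature,
                               dispersion = p$dispersion,
                               baseline = p$baseline, tau = p$tau,
                               name = p$name)
  x <- list(n_sensors = cfg$n_sensors,
            trained_profiles = lapply(cfg$trained_profiles, ser_prof),
            irrelevant_profiles = lapply(cfg$irrelevant_profiles, ser_prof),
            reps_per_class = cfg$reps_per_class,
            noise_model = cfg$noise_model,
            separation_margin = cfg$separation_margin, seed = cfg$seed)
  if (!is.null(cfg$separation))
    x$separation <- list(Q = apply(cfg$separation$Q, 1, identity,
                                   simplify = FALSE),
                         V = apply(cfg$separation$V, 1, identity,
                                   simplify = FALSE),
                         margin = cfg$separation$margin)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  de_prof <- function(p) class_profile(p$mean_signature, p$dispersion,
                                       p$baseline, p$tau, p$name)
  cfg <- generator_config(lapply(x$trained_profiles, de_prof),
                          lapply(x$irrelevant_profiles, de_prof),
                          reps_per_class = x$reps_per_class,
                          noise_model = x$noise_model,
                          separation_margin = x$separation_margin,
                          seed = x$seed)
  if (!is.null(x$separation))
    cfg$separation <- list(Q = do.call(rbind, x$separation$Q),
                           V = do.call(rbind, x$separation$V),
                           margin = x$separation$margin)
  cfg
}
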