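#' Configuration for the synthetic breath-cohort generator
#'
#' Defaults mirror the structure of a two-group pediatric breath study:
#' 48 cases / 56 controls, 2,315 m/z features of which 375 carry group
#' effects (179 up in cases, 196 down) with |log2| effects in 0.15-1.1,
#' recordings of at least three exhalation plateaus at 0.5 s per scan.
#'
#' @param n_case,n_control Group sizes.
#' @param n_features Total number of m/z features (satellites included).
#' @param n_differential Number of features with a planted group effect.
#' @param n_up Number of planted effects that are positive in cases; the
#'   remaining `n_differential - n_up` are negative.
#' @param effect_range Interval of |log2 effect|.
#' @param scan_period Seconds per scan.
#' @param n_exhalations Number of exhalation plateaus per recording (>= 3).
#' @param exhalation_s,break_s Plateau length and inter-exhalation pause (s).
#' @param recording_duration Total recording length (s); derived from the
#'   breathing maneuver when `NULL`.
#' @param resolving_power Mass resolving power (FWHM definition) of the
#'   simulated analyzer; sets Gaussian peak widths.
#' @param noise_sd_log2 Subject-level log2 multiplicative noise SD.
#' @param n_batches,batch_sd_log2 Latent batch structure: number of batches
#'   and the SD of per-feature batch log2 shifts.
#' @param isotope_fraction,adduct_fraction Fractions of features that are
#'   13C isotopologue / adduct-or-loss satellites of other features.
#' @param baseline_mean,baseline_sd Feature baseline log2 abundance.
#' @param noise_floor Mean of the exponential per-grid-point baseline noise
#'   in raw recordings (counts).
#' @param scan_jitter_sd Per-scan multiplicative log-normal jitter SD.
#' @param add_isotopes Whether [simulate_recording()] adds natural-abundance
#'   13C peaks for features without an explicit isotope satellite.
#' @param rng_seed Master seed; every sub-stream derives from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_case = 48, n_control = 56, n_features = 2315,
                       n_differential = 375, n_up = 179,
                       effect_range = c(0.15, 1.1),
                       scan_period = 0.5, n_exhalations = 3,
                       exhalation_s = 8, break_s = 8,
                       recording_duration = NULL,
                       resolving_power = 30000,
                       noise_sd_log2 = 0.3,
                       n_batches = 4, batch_sd_log2 = 0.2,
                       isotope_fraction = 0.08, adduct_fraction = 0.04,
                       baseline_mean = 12, baseline_sd = 1.5,
                       noise_floor = 2, scan_jitter_sd = 0.05,
                       add_isotopes = TRUE, rng_seed = 1L) {
  if (is.null(recording_duration))
    recording_duration <- 6 + n_exhalations * (exhalation_s + break_s)
  cfg <- list(
    n_case = n_case, n_control = n_control, n_features = n_features,
    n_differential = n_differential, n_up = n_up,
    effect_range = effect_range, scan_period = scan_period,
    n_exhalations = n_exhalations, exhalation_s = exhalation_s,
    break_s = break_s, recording_duration = recording_duration,
    resolving_power = resolving_power, noise_sd_log2 = noise_sd_log2,
    n_batches = n_batches, batch_sd_log2 = batch_sd_log2,
    isotope_fraction = isotope_fraction, adduct_fraction = adduct_fraction,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_floor = noise_floor, scan_jitter_sd = scan_jitter_sd,
    add_isotopes = add_isotopes, rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    if (n_case < 1 || n_control < 1) stop("group sizes must be >= 1")
    if (n_differential > n_features) stop("n_differential > n_features")
    if (n_up > n_differential) stop("n_up > n_differential")
    if (scan_period <= 0) stop("scan_period must be > 0")
    if (n_exhalations < 3) stop("need at least 3 exhalations")
    if (noise_sd_log2 < 0 || batch_sd_log2 < 0) stop("SDs must be >= 0")
    if (effect_range[1] <= 0 || diff(effect_range) < 0)
      stop("invalid effect_range")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group breath cohort with known ground truth
#'
#' Per-subject true log2 feature abundances are
#' baseline + group effect (differential features, +/- half the effect per
#' group) + batch shift + subject-level Gaussian noise (the log2-scale
#' counterpart of multiplicative noise). Satellite features (13C
#' isotopologues and adduct/loss ions) track their parent's subject values
#' with a fixed log2 intensity ratio plus small independent noise, so that
#' correlation-based satellite grouping is recoverable downstream.
#'
#' @param config A [sim_config()].
#' @return list with `cohort` (data.frame: sample_id, group, batch),
#'   `abundances` (samples x features log2 matrix) and `truth` (class
#'   `ground_truth`: feature_mz, carbon counts, `differential` data.frame
#'   of feature index + signed log2 effect (case minus control),
#'   `satellite_map` data.frame, batch assignment and per-feature batch
#'   effects, group labels).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  p <- config$n_features
  n <- config$n_case + config$n_control

  n_iso <- round(config$isotope_fraction * p)
  n_add <- round(config$adduct_fraction * p)
  n_prim <- p - n_iso - n_add
  if (n_prim < 1) stop("satellite fractions leave no primary features")

  prim_mz <- sort(stats::runif(n_prim, 60, 480))
  carbon <- pmax(1L, stats::rpois(n_prim, 8))
  # satellites reference primary features
  d <- .mass_deltas()
  iso_parent <- sample.int(n_prim, n_iso)
  add_parent <- sample.int(n_prim, n_add)
  add_kind <- sample(c("adduct", "neutral_loss"), n_add, replace = TRUE)
  sat_mz <- c(prim_mz[iso_parent] + d[["C13"]],
              prim_mz[add_parent] + ifelse(add_kind == "adduct",
                                           d[["H2O"]], -d[["H2O"]]))
  feature_mz <- c(prim_mz, sat_mz)
  sat_feature <- n_prim + seq_len(n_iso + n_add)
  satellite_map <- data.frame(
    feature = sat_feature,
    parent = c(iso_parent, add_parent),
    relation = c(rep("isotope_13C", n_iso), add_kind),
    log2_ratio = c(log2(pmin(0.9, carbon[iso_parent] * 0.0107)),
                   log2(stats::runif(n_add, 0.1, 0.5))),
    stringsAsFactors = FALSE
  )

  # planted effects live on primary features; satellites inherit via parents
  diff_idx <- sample.int(n_prim, min(config$n_differential, n_prim))
  n_up_eff <- min(config$n_up, length(diff_idx))
  sgn <- rep(c(1, -1), c(n_up_eff, length(diff_idx) - n_up_eff))
  effects <- sgn * stats::runif(length(diff_idx),
                                config$effect_range[1], config$effect_range[2])
  effect_vec <- numeric(n_prim)
  effect_vec[diff_idx] <- effects

  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  batch <- sample(rep_len(seq_len(config$n_batches), n))
  batch_eff <- matrix(stats::rnorm(n_prim * config$n_batches,
                                   sd = config$batch_sd_log2),
                      n_prim, config$n_batches)

  baseline <- stats::rnorm(n_prim, config$baseline_mean, config$baseline_sd)
  A_prim <- matrix(baseline, n, n_prim, byrow = TRUE) +
    outer(ifelse(group == "case", 0.5, -0.5), effect_vec) +
    t(batch_eff[, batch, drop = FALSE]) +
    matrix(stats::rnorm(n * n_prim, sd = config$noise_sd_log2), n, n_prim)

  A_sat <- A_prim[, satellite_map$parent, drop = FALSE] +
    matrix(satellite_map$log2_ratio, n, nrow(satellite_map), byrow = TRUE) +
    matrix(stats::rnorm(n * nrow(satellite_map), sd = 0.05), n,
           nrow(satellite_map))
  A <- cbind(A_prim, A_sat)
  sample_id <- sprintf("S%03d", seq_len(n))
  dimnames(A) <- list(sample_id, sprintf("F%04d", seq_len(p)))

  truth <- structure(list(
    feature_mz = feature_mz,
    carbon = c(carbon, rep(NA_integer_, length(sat_feature))),
    differential = data.frame(feature = diff_idx, effect = effects),
    satellite_map = satellite_map,
    batch_assignment = batch,
    batch_effects = batch_eff,
    group_labels = group
  ), class = "ground_truth")
  list(
    cohort = data.frame(sample_id = sample_id, group = group, batch = batch,
                        stringsAsFactors = FALSE),
    abundances = A,
    truth = truth
  )
}

# trapezoidal plateau profile in [0, 1]: 1 s linear rise/fall
.exhalation_profile <- function(times, config) {
  prof <- numeric(length(times))
  windows <- .exhalation_windows(config)
  for (k in seq_len(nrow(windows))) {
    t0 <- windows$start[k]; t1 <- windows$end[k]
    ramp <- 1
    in_w <- times >= t0 & times <= t1
    x <- times[in_w]
    prof[in_w] <- pmin(1, pmin(x - t0, t1 - x) / ramp)
  }
  prof
}

.exhalation_windows <- function(config) {
  lead_in <- 3
  starts <- lead_in +
    (seq_len(config$n_exhalations) - 1) * (config$exhalation_s + config$break_s)
  data.frame(start = starts, end = starts + config$exhalation_s)
}

#' Simulate one raw breath recording
#'
#' Scans at `scan_period` spacing over the recording. During exhalation
#' windows each feature contributes a Gaussian m/z peak with
#' sigma = mz / (resolving_power * 2.355), scaled by the subject's linear
#' abundance (peak area = abundance x plateau factor) times a trapezoidal
#' plateau profile. Natural-abundance 13C peaks are added for features with
#' a known carbon count (unless the feature already has an explicit isotope
#' satellite), and exponential baseline noise is present on every scan.
#'
#' @param abundances Per-feature log2 abundances for one subject (as from
#'   a row of [simulate_cohort()]'s matrix), or linear abundances when
#'   `log2_scale = FALSE`.
#' @param feature_mz Feature m/z values (Th), same length.
#' @param config A [sim_config()].
#' @param carbon Optional per-feature carbon counts for 13C peak generation.
#' @param skip_isotope_for Feature indices that already have an explicit
#'   isotopologue feature (no extra 13C peak is drawn for those).
#' @param sample_id,polarity Metadata carried on the result.
#' @param log2_scale Whether `abundances` are log2 (default) or linear.
#' @param seed Seed for the recording's noise streams.
#' @return A `scan_series`: list with `scans` (list of lists `time`, `mz`,
#'   `intensity`), `polarity`, `sample_id`.
#' @export
simulate_recording <- function(abundances, feature_mz, config = sim_config(),
                               carbon = NULL, skip_isotope_for = integer(),
                               sample_id = "S001", polarity = "pos",
                               log2_scale = TRUE, seed = config$rng_seed) {
  stopifnot(length(abundances) == length(feature_mz))
  a <- unname(if (log2_scale) 2^abundances else abundances)
  if (any(!is.finite(a)) || any(a < 0)) stop("abundances must be finite and >= 0")
  set.seed(seed)
  d13 <- .mass_deltas()[["C13"]]

  mz <- feature_mz
  amp <- a
  if (config$add_isotopes && !is.null(carbon)) {
    extra <- which(!is.na(carbon) & !(seq_along(mz) %in% skip_isotope_for))
    if (length(extra)) {
      mz <- c(mz, feature_mz[extra] + d13)
      amp <- c(amp, a[extra] * pmin(0.9, carbon[extra] * 0.0107))
    }
  }
  keep <- mz >= 50 & mz <= 500
  mz <- mz[keep]; amp <- amp[keep]

  sigma <- mz / (config$resolving_power * 2.355)
  # local profile grid per peak: +/- 5 sigma at sigma/3 spacing
  grids <- lapply(seq_along(mz), function(i)
    seq(mz[i] - 5 * sigma[i], mz[i] + 5 * sigma[i], by = sigma[i] / 3))
  glen <- lengths(grids)
  gall <- unlist(grids)
  ord <- order(gall)
  gall <- gall[ord]
  peak_of <- rep.int(seq_along(mz), glen)[ord]
  dens <- stats::dnorm(gall, mz[peak_of], sigma[peak_of])
  in_range <- gall >= 50 & gall <= 500
  gall <- gall[in_range]; peak_of <- peak_of[in_range]; dens <- dens[in_range]

  times <- seq(0, config$recording_duration, by = config$scan_period)
  prof <- .exhalation_profile(times, config)
  scans <- vector("list", length(times))
  for (s in seq_along(times)) {
    jitter <- exp(stats::rnorm(1, sd = config$scan_jitter_sd))
    intensity <- dens * amp[peak_of] * prof[s] * jitter
    if (config$noise_floor > 0)
      intensity <- intensity +
        stats::rexp(length(gall), rate = 1 / config$noise_floor)
    scans[[s]] <- list(time = times[s], mz = gall, intensity = intensity)
  }
  structure(list(scans = scans, polarity = polarity, sample_id = sample_id),
            class = "scan_series")
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- list(
    feature_mz = as.numeric(x$feature_mz),
    carbon = as.integer(x$carbon),
    differential = if (length(x$differential))
      data.frame(feature = as.integer(x$differential$feature),
                 effect = as.numeric(x$differential$effect))
      else data.frame(feature = integer(), effect = numeric()),
    satellite_map = if (length(x$satellite_map))
      data.frame(feature = as.integer(x$satellite_map$feature),
                 parent = as.integer(x$satellite_map$parent),
                 relation = as.character(x$satellite_map$relation),
                 log2_ratio = as.numeric(x$satellite_map$log2_ratio),
                 stringsAsFactors = FALSE)
      else data.frame(feature = integer(), parent = integer(),
                      relation = character(), log2_ratio = numeric()),
    batch_assignment = as.integer(x$batch_assignment),
    batch_effects = matrix(as.numeric(x$batch_effects$data),
                           x$batch_effects$nrow, x$batch_effects$ncol),
    group_labels = as.character(x$group_labels)
  )
  structure(tr, class = "ground_truth")
}

#' Write / read ground truth as JSON (lossless round trip)
#'
#' @param truth A `ground_truth` object from [simulate_cohort()].
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- list(
    feature_mz = truth$feature_mz,
    carbon = truth$carbon,
    differential = truth$differential,
    satellite_map = truth$satellite_map,
    batch_assignment = truth$batch_assignment,
    batch_effects = list(data = as.numeric(truth$batch_effects),
                         nrow = nrow(truth$batch_effects),
                         ncol = ncol(truth$batch_effects)),
    group_labels = truth$group_labels
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a recording as a plain TSV scan table
#'
#' Long format with columns `scan_index`, `time_s`, `mz`, `intensity`.
#'
#' @param scan_series A `scan_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan_series, path) {
  tab <- do.call(rbind, lapply(seq_along(scan_series$scans), function(i) {
    sc <- scan_series$scans[[i]]
    data.frame(scan_index = i, time_s = sc$time, mz = sc$mz,
               intensity = sc$intensity)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV scan table written by [write_scan_tsv()]
#'
#' @param path Input file.
#' @param sample_id,polarity Metadata for the resulting series.
#' @return A `scan_series`.
#' @export
read_scan_tsv <- function(path, sample_id = basename(path), polarity = "pos") {
  tab <- utils::read.delim(path)
  stopifnot(all(c("scan_index", "time_s", "mz", "intensity") %in% names(tab)))
  scans <- lapply(split(tab, tab$scan_index), function(s) {
    o <- order(s$mz)
    list(time = s$time_s[1], mz = s$mz[o], intensity = s$intensity[o])
  })
  scans <- scans[order(vapply(scans, `[[`, 0, "time"))]
  structure(list(scans = unname(scans), polarity = polarity,
                 sample_id = sample_id), class = "scan_series")
}

#' Total ion current trace of a recording
#'
#' @param scan_series A `scan_series`.
#' @return Numeric vector, one summed intensity per scan.
#' @export
tic_trace <- function(scan_series) {
  vapply(scan_series$scans, function(s) sum(s$intensity), 0)
}
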