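#' The standard resampling grid
#'
#' Uniform m/z axis with step 0.0005 Th over 50-500 Th (900,001 points),
#' onto which every raw scan is interpolated.
#'
#' @return Numeric vector of grid m/z values.
#' @export
standard_grid <- function() seq(50, 500, by = 0.0005)

.GRID_STEP <- 0.0005

#' Resample one scan onto the standard m/z grid
#'
#' Linear interpolation; zero outside the scan's m/z support. Centroided
#' input (isolated sticks) is effectively rasterized by the same rule.
#'
#' @param scan List with ascending `mz` and `intensity` vectors.
#' @param grid Target grid (default [standard_grid()]).
#' @return Numeric vector of intensities on the grid.
#' @export
resample_spectrum <- function(scan, grid = standard_grid()) {
  mz <- scan$mz
  if (length(mz) == 0) return(numeric(length(grid)))
  if (is.unsorted(mz, strictly = FALSE)) stop("scan m/z array not ascending")
  if (length(mz) == 1)
    return(ifelse(abs(grid - mz) <= .GRID_STEP / 2, scan$intensity[1], 0))
  stats::approx(mz, scan$intensity, xout = grid, yleft = 0, yright = 0,
                ties = "ordered")$y
}

#' Detect exhalation windows from a TIC trace
#'
#' Scans whose TIC exceeds `median(TIC) + k_mad * MAD(TIC)` form candidate
#' windows; gaps of up to 2 scans are bridged, and windows shorter than
#' `min_duration_s` are dropped. Works when exhalations occupy a minority
#' of the recording (so that the median sits on the baseline), which the
#' breathing maneuver of repeated exhalations with pauses guarantees.
#'
#' @param tic TIC per scan (>= 20 scans).
#' @param scan_period Seconds per scan.
#' @param min_duration_s Minimum window duration (default 3 s).
#' @param k_mad Threshold multiplier (default 3).
#' @return list with `segments` (data.frame `start`, `end`; half-open scan
#'   index intervals), `tic`, and `warn_few` (TRUE when fewer than 3
#'   windows were found, flagging a non-compliant maneuver).
#' @export
detect_exhalations <- function(tic, scan_period, min_duration_s = 3, k_mad = 3) {
  if (length(tic) < 20) stop("need at least 20 scans")
  thr <- stats::median(tic) + k_mad * stats::mad(tic)
  above <- tic > thr
  # bridge gaps of <= 2 scans
  idx <- which(above)
  if (length(idx)) {
    gaps <- which(diff(idx) > 1 & diff(idx) <= 3)
    for (g in gaps) above[idx[g]:idx[g + 1]] <- TRUE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * scan_period >= min_duration_s
  segments <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  list(segments = segments, tic = tic, warn_few = nrow(segments) < 3)
}

#' Average resampled spectrum over exhalation scans
#'
#' Pointwise mean over all scans inside the detected segments, computed as
#' a running sum so only one resampled spectrum is held at a time.
#'
#' @param scan_series A `scan_series`.
#' @param segments data.frame `start`,`end` (half-open scan indices).
#' @param grid Resampling grid.
#' @return Numeric vector: the average exhalation spectrum on the grid.
#' @export
average_exhalation_spectrum <- function(scan_series, segments,
                                        grid = standard_grid()) {
  stopifnot(nrow(segments) >= 1)
  scan_idx <- unlist(lapply(seq_len(nrow(segments)), function(k)
    seq(segments$start[k], segments$end[k] - 1L)))
  scan_idx <- unique(scan_idx)
  acc <- numeric(length(grid))
  for (i in scan_idx)
    acc <- acc + resample_spectrum(scan_series$scans[[i]], grid)
  acc / length(scan_idx)
}

#' Pick peaks on an averaged spectrum
#'
#' Local maxima exceeding a rolling median plus `snr_k` rolling MADs
#' (window `window_Th` wide) are apexes; peak bounds extend to the nearest
#' flanking local minima and the area is the trapezoidal integral of the
#' grid between the bounds.
#'
#' @param spectrum Intensities on `grid`.
#' @param grid The m/z grid.
#' @param snr_k Threshold multiplier (default 5).
#' @param window_Th Rolling-statistics window in Th (default 1).
#' @return data.frame: `apex_mz`, `left_mz`, `right_mz`, `area`,
#'   `apex_intensity`.
#' @export
pick_peaks <- function(spectrum, grid = standard_grid(), snr_k = 5,
                       window_Th = 1) {
  n <- length(spectrum)
  stopifnot(length(grid) == n)
  step <- if (n > 1) grid[2] - grid[1] else .GRID_STEP
  k <- max(3L, round(window_Th / step))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  base <- stats::runmed(spectrum, k, endrule = "median")
  madr <- 1.4826 * stats::runmed(abs(spectrum - base), k, endrule = "median")
  thr <- base + snr_k * madr
  x <- spectrum
  apex <- which(x > thr)
  apex <- apex[apex > 1 & apex < n]
  apex <- apex[x[apex] > x[apex - 1] & x[apex] >= x[apex + 1]]
  if (!length(apex))
    return(data.frame(apex_mz = numeric(), left_mz = numeric(),
                      right_mz = numeric(), area = numeric(),
                      apex_intensity = numeric()))
  res <- lapply(apex, function(a) {
    l <- a
    while (l > 1 && x[l - 1] < x[l]) l <- l - 1
    r <- a
    while (r < n && x[r + 1] < x[r]) r <- r + 1
    area <- sum((x[l:(r - 1)] + x[(l + 1):r]) / 2) * step
    c(grid[a], grid[l], grid[r], area, x[a])
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("apex_mz", "left_mz", "right_mz", "area", "apex_intensity")
  # keep the stronger apex when two apexes share a bound region
  out <- out[order(out$apex_mz), ]
  rownames(out) <- NULL
  out
}

#' Process one recording into a peak table
#'
#' TIC computation, exhalation detection, exhalation-averaged spectrum and
#' peak picking in one pass, with per-sample QC.
#'
#' @param scan_series A `scan_series`.
#' @param min_duration_s,k_mad Exhalation-detection parameters.
#' @param snr_k,window_Th Peak-picking parameters.
#' @param grid Resampling grid.
#' @return list with `peaks` (see [pick_peaks()]) and `qc`
#'   (n_scans, n_exhalations, n_peaks, warn_few).
#' @export
process_recording <- function(scan_series, min_duration_s = 3, k_mad = 3,
                              snr_k = 5, window_Th = 1,
                              grid = standard_grid()) {
  tic <- tic_trace(scan_series)
  scan_period <- if (length(scan_series$scans) > 1)
    scan_series$scans[[2]]$time - scan_series$scans[[1]]$time else 0.5
  ex <- detect_exhalations(tic, scan_period, min_duration_s, k_mad)
  if (nrow(ex$segments) == 0)
    return(list(peaks = pick_peaks(numeric(length(grid)), grid),
                qc = data.frame(sample_id = scan_series$sample_id,
                                n_scans = length(tic), n_exhalations = 0L,
                                n_peaks = 0L, warn_few = TRUE)))
  avg <- average_exhalation_spectrum(scan_series, ex$segments, grid)
  peaks <- pick_peaks(avg, grid, snr_k, window_Th)
  list(peaks = peaks,
       qc = data.frame(sample_id = scan_series$sample_id,
                       n_scans = length(tic),
                       n_exhalations = nrow(ex$segments),
                       n_peaks = nrow(peaks), warn_few = ex$warn_few))
}

#' Align per-sample peak tables into a feature matrix
#'
#' Apex m/z values of all samples are pooled, sorted and chained into
#' clusters (a new cluster starts where the gap to the previous apex
#' exceeds `tol_ppm`); the consensus feature m/z is the intensity-weighted
#' mean. Features present in fewer than `presence_fraction` of samples are
#' dropped; absent cells stay `NA` for the normalization step to impute.
#'
#' @param peak_tables Named list of [pick_peaks()] tables (>= 2 samples).
#' @param tol_ppm Cluster gap tolerance in ppm (> 0).
#' @param presence_fraction Minimum fraction of samples a feature must
#'   appear in.
#' @return list: `values` (samples x features raw areas, NA where absent),
#'   `feature_mz` (ascending), `sample_ids`.
#' @export
align_features <- function(peak_tables, tol_ppm = 10, presence_fraction = 0.7) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  stopifnot(length(peak_tables) >= 2)
  if (is.null(names(peak_tables)))
    names(peak_tables) <- sprintf("S%03d", seq_along(peak_tables))
  all <- do.call(rbind, lapply(names(peak_tables), function(id) {
    pt <- peak_tables[[id]]
    if (!nrow(pt)) return(NULL)
    data.frame(sample = id, mz = pt$apex_mz, area = pt$area)
  }))
  if (is.null(all) || !nrow(all)) stop("no peaks to align")
  o <- order(all$mz)
  all <- all[o, ]
  gap_ppm <- c(Inf, diff(all$mz) / all$mz[-nrow(all)] * 1e6)
  cluster <- cumsum(gap_ppm > tol_ppm)
  n_samp <- length(peak_tables)
  feats <- lapply(split(all, cluster), function(cl) {
    if (length(unique(cl$sample)) / n_samp < presence_fraction) return(NULL)
    areas <- tapply(cl$area, cl$sample, sum)
    list(mz = sum(cl$mz * cl$area) / sum(cl$area), areas = areas)
  })
  feats <- feats[!vapply(feats, is.null, TRUE)]
  if (!length(feats)) stop("no features pass the presence filter")
  fmz <- unname(vapply(feats, `[[`, 0, "mz"))
  ord <- order(fmz)
  values <- matrix(NA_real_, n_samp, length(feats),
                   dimnames = list(names(peak_tables), NULL))
  for (j in seq_along(ord)) {
    a <- feats[[ord[j]]]$areas
    values[names(a), j] <- a
  }
  list(values = values, feature_mz = fmz[ord],
       sample_ids = names(peak_tables))
}

#' TIC-normalize, impute zeros/missings, and log2-transform
#'
#' Each sample's feature areas are divided by the sample's total picked-peak
#' area; zero or missing cells are replaced by half the sample's smallest
#' positive normalized value; the result is log2-transformed.
#'
#' @param aligned Output of [align_features()] (or any list with `values`,
#'   `feature_mz`, `sample_ids`).
#' @param polarity Carried through as metadata.
#' @return A `breath_profile`: list with log2 `values` (samples x features),
#'   `feature_mz`, `sample_ids`, `polarity`.
#' @export
normalize_and_log <- function(aligned, polarity = "pos") {
  v <- aligned$values
  stopifnot(all(v >= 0, na.rm = TRUE))
  out <- t(apply(v, 1, function(row) {
    tot <- sum(row, na.rm = TRUE)
    if (tot <= 0) stop("sample with zero total ion current")
    nr <- row / tot
    posmin <- min(nr[nr > 0], na.rm = TRUE)
    nr[is.na(nr) | nr == 0] <- posmin / 2
    log2(nr)
  }))
  structure(list(values = out, feature_mz = aligned$feature_mz,
                 sample_ids = aligned$sample_ids, polarity = polarity),
            class = "breath_profile")
}

#' Full preprocessing: recordings to breath-profile matrix
#'
#' @param recordings List of `scan_series` objects (one per sample).
#' @param tol_ppm,presence_fraction Alignment parameters.
#' @param ... Passed to [process_recording()].
#' @return list with `profile` (a `breath_profile`) and `qc` (per-sample
#'   data.frame).
#' @export
preprocess_cohort <- function(recordings, tol_ppm = 10,
                              presence_fraction = 0.7, ...) {
  res <- lapply(recordings, process_recording, ...)
  names(res) <- vapply(recordings, `[[`, "", "sample_id")
  qc <- do.call(rbind, lapply(res, `[[`, "qc"))
  aligned <- align_features(lapply(res, `[[`, "peaks"), tol_ppm,
                            presence_fraction)
  pol <- unique(vapply(recordings, `[[`, "", "polarity"))
  list(profile = normalize_and_log(aligned, polarity = pol[1]), qc = qc)
}

#' Write a breath-profile matrix (and features sidecar) as TSV
#'
#' @param profile A `breath_profile`.
#' @param path Matrix TSV path (samples in rows, header of consensus m/z);
#'   a `<path>.features.tsv` sidecar holds the feature m/z values.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  m <- profile$values
  colnames(m) <- sprintf("%.5f", profile$feature_mz)
  df <- data.frame(sample_id = profile$sample_ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(feature = seq_along(profile$feature_mz),
                     mz = profile$feature_mz, polarity = profile$polarity)
  utils::write.table(side, paste0(path, ".features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a breath-profile matrix TSV written by [write_profile_tsv()]
#'
#' @param path Matrix TSV path.
#' @return A `breath_profile`.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side_path <- paste0(path, ".features.tsv")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  if (file.exists(side_path)) {
    side <- utils::read.delim(side_path)
    fmz <- side$mz
    pol <- as.character(side$polarity[1])
  } else {
    fmz <- as.numeric(colnames(v))
    pol <- "pos"
  }
  structure(list(values = v, feature_mz = fmz, sample_ids = df$sample_id,
                 polarity = pol), class = "breath_profile")
}
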