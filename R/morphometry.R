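#' Morphometry parameters
#'
#' Defaults follow the published quantification protocol: 1.5 um ROI
#' diameter, peaks deeper than 35 um excluded, peaks retained within a
#' 15 um depth range of each other. The plateau definition (flat-top run
#' of at least `plateau_min_width` samples within `plateau_tolerance` of
#' the profile maximum) is this package's operationalization of
#' "plateau as opposed to bell-shaped"; both knobs are exposed.
#'
#' @param roi_diameter_um ROI diameter in um.
#' @param depth_limit_um peaks deeper than this are excluded.
#' @param cluster_range_um width of the depth window used to select
#'   mutually close peaks.
#' @param plateau_tolerance fraction of the (baseline-subtracted) maximum
#'   defining the flat top, in (0, 1).
#' @param plateau_min_width minimum flat-top run length (samples) to call
#'   a plateau.
#' @param recenter_radius_um lateral search radius when re-centering an
#'   ROI seed on the local intensity maximum.
#' @return list of class `"morph_params"`.
#' @export
morph_params <- function(roi_diameter_um = 1.5,
                         depth_limit_um = 35,
                         cluster_range_um = 15,
                         plateau_tolerance = 0.05,
                         plateau_min_width = 4L,
                         recenter_radius_um = 1) {
  stopifnot(roi_diameter_um > 0, depth_limit_um > 0, cluster_range_um > 0,
            plateau_tolerance > 0, plateau_tolerance < 1,
            plateau_min_width >= 1, recenter_radius_um >= 0)
  structure(list(roi_diameter_um = roi_diameter_um,
                 depth_limit_um = depth_limit_um,
                 cluster_range_um = cluster_range_um,
                 plateau_tolerance = plateau_tolerance,
                 plateau_min_width = as.integer(plateau_min_width),
                 recenter_radius_um = recenter_radius_um),
            class = "morph_params")
}

#' Extract an axial intensity profile under a circular ROI
#'
#' For every z-slice, records the maximum intensity inside a disk of
#' `roi_diameter_um` centered on the ROI seed. The seed is first
#' re-centered within `recenter_radius_um` so that the profile peak is
#' the highest attainable locally, mirroring manual ROI placement that
#' maximizes the measured signal.
#'
#' @param stack numeric array `[x, y, z]`.
#' @param roi_seed numeric length-2, `(x, y)` in um.
#' @param params [morph_params()].
#' @param pixel_size_um,z_step_um voxel geometry (um).
#' @param roi_id,glomerulus_id carried through to the output.
#' @return list of class `"intensity_profile"` with `roi_id`,
#'   `glomerulus_id`, `z` (um, strictly increasing, shallowest slice at
#'   z = 0) and `intensity` (one value per slice).
#' @export
extract_profile <- function(stack, roi_seed, params = morph_params(),
                            pixel_size_um, z_step_um,
                            roi_id = NA_character_, glomerulus_id = NA) {
  d <- dim(stack)
  ix <- round(roi_seed[1] / pixel_size_um)
  iy <- round(roi_seed[2] / pixel_size_um)
  if (ix < 0 || iy < 0 || ix > d[1] - 1L || iy > d[2] - 1L)
    stop("ROI seed (", roi_seed[1], ", ", roi_seed[2],
         ") um lies outside the image")

  r_px <- (params$roi_diameter_um / 2) / pixel_size_um
  search_px <- floor(params$recenter_radius_um / pixel_size_um)
  off <- expand.grid(dx = -ceiling(r_px):ceiling(r_px),
                     dy = -ceiling(r_px):ceiling(r_px))
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, , drop = FALSE]

  best <- NULL; best_peak <- -Inf
  for (sx in -search_px:search_px) for (sy in -search_px:search_px) {
    if (sx^2 + sy^2 > search_px^2) next
    cx <- ix + sx; cy <- iy + sy
    px <- cx + off$dx; py <- cy + off$dy
    keep <- px >= 0L & px < d[1] & py >= 0L & py < d[2]
    if (!any(keep)) next
    px <- px[keep] + 1L; py <- py[keep] + 1L
    prof <- vapply(seq_len(d[3]),
                   function(k) max(stack[cbind(px, py, k)]), numeric(1))
    if (max(prof) > best_peak) { best_peak <- max(prof); best <- prof }
  }

  structure(list(roi_id = roi_id, glomerulus_id = glomerulus_id,
                 z = (seq_len(d[3]) - 1L) * z_step_um,
                 intensity = best),
            class = "intensity_profile")
}

#' Classify a profile's peak as bell-shaped or plateau
#'
#' The peak is the global maximum of the profile. The shape is `plateau`
#' when the longest run of consecutive samples at or above
#' `(1 - plateau_tolerance)` of the maximum reaches `plateau_min_width`
#' samples, `bell` otherwise. With `baseline = "lower_quantile"` the 20%
#' lower quantile of the profile is subtracted first, so a constant
#' background offset does not flatten the relative variation of dim
#' cells. All-zero profiles are flagged `no_signal` and excluded
#' downstream.
#'
#' @param profile an `"intensity_profile"` (needs >= 3 samples).
#' @param params [morph_params()].
#' @param baseline `"none"` (default) or `"lower_quantile"`.
#' @return one-row data.frame: `roi_id`, `glomerulus_id`, `peak_z`,
#'   `peak_value`, `shape` (`"bell"`, `"plateau"` or `"no_signal"`), and
#'   `top1`..`top3` (the three highest profile values, descending).
#' @export
classify_peak_shape <- function(profile, params = morph_params(),
                                baseline = c("none", "lower_quantile")) {
  baseline <- match.arg(baseline)
  v <- profile$intensity
  if (length(v) < 3L) stop("profile needs at least 3 samples")
  top3 <- sort(v, decreasing = TRUE)[1:3]
  imax <- which.max(v)
  rec <- data.frame(roi_id = profile$roi_id,
                    glomerulus_id = profile$glomerulus_id,
                    peak_z = profile$z[imax], peak_value = v[imax],
                    shape = "bell", top1 = top3[1], top2 = top3[2],
                    top3 = top3[3], stringsAsFactors = FALSE)
  if (all(v == 0)) { rec$shape <- "no_signal"; return(rec) }
  b <- if (baseline == "lower_quantile")
    stats::quantile(v, 0.2, names = FALSE) else 0
  w <- v - b
  thr <- (1 - params$plateau_tolerance) * max(w)
  runs <- rle(w >= thr)
  longest <- max(c(0L, runs$lengths[runs$values]))
  if (longest >= params$plateau_min_width) rec$shape <- "plateau"
  rec
}

#' Depth and range filtering of peak records
#'
#' Drops plateau-shaped and no-signal peaks, then peaks deeper than
#' `depth_limit_um`, then retains the peaks falling in the densest
#' `cluster_range_um`-wide depth window. Candidate windows are anchored
#' at each remaining peak depth (the window `[d, d + range]` for every
#' depth `d`), which makes the rule order-independent; ties are broken
#' toward the window with the smaller mean depth.
#'
#' @param peaks data.frame of peak records ([classify_peak_shape()] rows).
#' @param params [morph_params()].
#' @return the retained subset (possibly empty, with a warning).
#' @export
filter_peaks <- function(peaks, params = morph_params()) {
  stopifnot(nrow(peaks) >= 1L)
  keep <- peaks[peaks$shape == "bell", , drop = FALSE]
  keep <- keep[keep$peak_z <= params$depth_limit_um, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no peaks survive shape/depth filtering")
    return(keep)
  }
  d <- keep$peak_z
  best_idx <- NULL; best_n <- -1L; best_mean <- Inf
  for (a in sort(unique(d))) {
    inside <- which(d >= a & d <= a + params$cluster_range_um)
    m <- mean(d[inside])
    if (length(inside) > best_n ||
        (length(inside) == best_n && m < best_mean)) {
      best_idx <- inside; best_n <- length(inside); best_mean <- m
    }
  }
  keep[best_idx, , drop = FALSE]
}

#' Two-class split of peak intensities at the largest gap
#'
#' Sorts the values and places the dim/bright boundary at the largest
#' adjacent gap. The split is accepted only when that gap strictly
#' exceeds every other adjacent gap — the separation between the lowest
#' bright and the highest dim value is then greater than any
#' within-group separation. Otherwise the sample is flagged (no clear
#' two-population structure) and no labels are emitted. With
#' `log = TRUE` gaps are measured on the log scale, appropriate when the
#' two populations differ multiplicatively (fluorescence intensities
#' spread by depth attenuation); labels are reported in the input order
#' and are invariant to input permutation and to positive rescaling.
#'
#' @param max_values numeric vector of per-cell peak intensities
#'   (length >= 2, positive when `log = TRUE`).
#' @param log measure gaps on the log scale.
#' @return list with `accepted` (logical), `labels` (character
#'   `"bright"`/`"dim"` in input order, or NULL when not accepted),
#'   `boundary` (midpoint of the separating gap, on the data scale),
#'   `gap` (the separating gap, on the gap scale).
#' @export
split_bright_dim <- function(max_values, log = FALSE) {
  n <- length(max_values)
  if (n < 2L) stop("need at least 2 values to split")
  v <- if (log) base::log(max_values) else max_values
  ord <- order(v, decreasing = TRUE)
  s <- v[ord]
  gaps <- s[-n] - s[-1L]
  k <- which.max(gaps)
  unique_max <- gaps[k] > 0 && sum(gaps == gaps[k]) == 1L
  if (!unique_max)
    return(list(accepted = FALSE, labels = NULL, boundary = NA_real_,
                gap = if (all(gaps == 0)) 0 else gaps[k]))
  labels <- character(n)
  labels[ord[seq_len(k)]] <- "bright"
  labels[ord[(k + 1L):n]] <- "dim"
  boundary <- (s[k] + s[k + 1L]) / 2
  if (log) boundary <- exp(boundary)
  list(accepted = TRUE, labels = labels, boundary = boundary, gap = gaps[k])
}

#' Per-glomerulus composition of bright and dim cells
#'
#' @param calls data.frame with columns `glomerulus_id`, `roi_id`,
#'   `class` (`"bright"`/`"dim"`) and `max_value`.
#' @return one-row data.frame: counts, percentages (denominator
#'   bright + dim) and per-class mean intensities (NA when a class is
#'   absent).
#' @export
summarize_glomerulus <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  nb <- sum(calls$class == "bright"); nd <- sum(calls$class == "dim")
  tot <- nb + nd
  data.frame(
    glomerulus_id = calls$glomerulus_id[1],
    n_bright = nb, n_dim = nd,
    pct_bright = if (tot > 0) 100 * nb / tot else NA_real_,
    pct_dim    = if (tot > 0) 100 * nd / tot else NA_real_,
    mean_bright = if (nb > 0) mean(calls$max_value[calls$class == "bright"])
                  else NA_real_,
    mean_dim    = if (nd > 0) mean(calls$max_value[calls$class == "dim"])
                  else NA_real_,
    stringsAsFactors = FALSE)
}

#' Welch's two-sample t-test (two-tailed, unpaired)
#'
#' Direct implementation of the unequal-variance t statistic with
#' Welch-Satterthwaite degrees of freedom, as applied to per-glomerulus
#' bright vs dim mean intensities.
#'
#' @param a,b numeric vectors, each of length >= 2 with finite variance.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 observations")
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  if (va + vb == 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_,
                p = if (d == 0) 1 else 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Full morphometry chain over a set of synthetic or real stacks
#'
#' Runs profile extraction, peak-shape QC, depth/range filtering, the
#' gap-based bright/dim split (on the log scale), and per-glomerulus
#' composition, then pools composition across glomeruli and applies
#' Welch's t-test to the per-glomerulus bright vs dim means.
#'
#' @param stacks list of numeric arrays `[x, y, z]`.
#' @param rois data.frame of ROI seeds (`glomerulus_id`, `roi_id`,
#'   `x_um`, `y_um`); `glomerulus_id` indexes into `stacks`.
#' @param pixel_size_um,z_step_um voxel geometry.
#' @param params [morph_params()].
#' @return list: `peaks` (all peak records), `calls` (classified cells),
#'   `compositions` (per glomerulus), `pooled_pct_dim`,
#'   `pooled_pct_bright`, `welch` (test on per-glomerulus class means).
#' @export
morphometry_pipeline <- function(stacks, rois, pixel_size_um, z_step_um,
                                 params = morph_params()) {
  peak_list <- list(); call_list <- list(); comp_list <- list()
  for (g in sort(unique(rois$glomerulus_id))) {
    rg <- rois[rois$glomerulus_id == g, , drop = FALSE]
    recs <- do.call(rbind, lapply(seq_len(nrow(rg)), function(i) {
      pr <- extract_profile(stacks[[g]], c(rg$x_um[i], rg$y_um[i]), params,
                            pixel_size_um, z_step_um,
                            roi_id = rg$roi_id[i], glomerulus_id = g)
      classify_peak_shape(pr, params, baseline = "lower_quantile")
    }))
    peak_list[[as.character(g)]] <- recs
    kept <- suppressWarnings(filter_peaks(recs, params))
    if (nrow(kept) < 2L) next
    sp <- split_bright_dim(kept$peak_value, log = TRUE)
    if (!sp$accepted) next
    calls <- data.frame(glomerulus_id = g, roi_id = kept$roi_id,
                        class = sp$labels, max_value = kept$peak_value,
                        stringsAsFactors = FALSE)
    call_list[[as.character(g)]] <- calls
    comp_list[[as.character(g)]] <- summarize_glomerulus(calls)
  }
  peaks <- do.call(rbind, peak_list)
  calls <- do.call(rbind, call_list)
  comps <- do.call(rbind, comp_list)
  pooled_dim <- if (!is.null(comps))
    100 * sum(comps$n_dim) / sum(comps$n_dim + comps$n_bright) else NA_real_
  welch <- NULL
  if (!is.null(comps)) {
    ok <- stats::complete.cases(comps[, c("mean_bright", "mean_dim")])
    if (sum(ok) >= 2L)
      welch <- welch_t_test(comps$mean_bright[ok], comps$mean_dim[ok])
  }
  list(peaks = peaks, calls = calls, compositions = comps,
       pooled_pct_dim = pooled_dim, pooled_pct_bright = 100 - pooled_dim,
       welch = welch)
}
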