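#' Gate configuration for cytometry preprocessing and classification
#'
#' Debris are removed with an absolute forward-scatter floor (the
#' synthetic debris occupy the bottom of the scatter range by
#' construction; real polygon gates from an acquisition GUI are not
#' machine-readable, so a scalar floor is the documented stand-in).
#' Doublets are removed with a ceiling on the area/height ratio. Optional
#' fixed intensity thresholds, given on the log-intensity scale, override
#' automatic estimation for fully reproducible runs.
#'
#' @param scatter_floor events with `scatter_a` below this are debris.
#' @param doublet_ratio_max events with `area_height_ratio` above this
#'   are doublets.
#' @param neg_dim_cut,dim_bright_cut optional fixed thresholds on
#'   `log(tdt)`; when both are set they must be ordered.
#' @param marker_cutoff default positivity cutoff for marker channels
#'   (raw intensity units).
#' @return list of class `"gate_config"`.
#' @export
gate_config <- function(scatter_floor = 400, doublet_ratio_max = 1.5,
                        neg_dim_cut = NULL, dim_bright_cut = NULL,
                        marker_cutoff = 100) {
  if (!is.null(neg_dim_cut) && !is.null(dim_bright_cut) &&
      !(neg_dim_cut < dim_bright_cut))
    stop("thresholds must be ordered: neg_dim_cut < dim_bright_cut")
  structure(list(scatter_floor = scatter_floor,
                 doublet_ratio_max = doublet_ratio_max,
                 neg_dim_cut = neg_dim_cut, dim_bright_cut = dim_bright_cut,
                 marker_cutoff = marker_cutoff),
            class = "gate_config")
}

#' Remove debris and doublets from an event table
#'
#' @param events data.frame with at least `scatter_a` and
#'   `area_height_ratio` columns.
#' @param gates [gate_config()].
#' @return the retained subset, with attributes `n_input`, `n_debris`,
#'   `n_doublets` recording provenance counts.
#' @export
gate_events <- function(events, gates = gate_config()) {
  req <- c("scatter_a", "area_height_ratio")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols))
    stop("event table lacks required channel(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(events) == 0L) return(events)
  debris <- events$scatter_a < gates$scatter_floor
  doublet <- !debris & events$area_height_ratio > gates$doublet_ratio_max
  out <- events[!debris & !doublet, , drop = FALSE]
  attr(out, "n_input") <- nrow(events)
  attr(out, "n_debris") <- sum(debris)
  attr(out, "n_doublets") <- sum(doublet)
  out
}

#' Estimate negative/dim and dim/bright thresholds from log intensities
#'
#' Kernel-density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of the log-intensity distribution; the two cuts are placed
#' at the deepest density minima between the three highest modes. When
#' fewer than three modes are found the configured fixed thresholds are
#' used; with no override available an error is raised, since a
#' negative/dim/bright classification is then not identifiable.
#'
#' @param log_intensities numeric vector of log-scale intensities
#'   (>= 100 values recommended).
#' @param gates optional [gate_config()] carrying fixed threshold
#'   overrides (returned as-is when both are set).
#' @return numeric length-2: `c(neg_dim_cut, dim_bright_cut)` on the
#'   log-intensity scale.
#' @export
estimate_thresholds <- function(log_intensities, gates = NULL) {
  override <- !is.null(gates) && !is.null(gates$neg_dim_cut) &&
    !is.null(gates$dim_bright_cut)
  if (override)
    return(c(neg_dim_cut = gates$neg_dim_cut,
             dim_bright_cut = gates$dim_bright_cut))
  d <- stats::density(log_intensities)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 3L)
    stop("classification not possible: fewer than 3 density modes and ",
         "no fixed-threshold override")
  modes <- is_max[order(y[is_max], decreasing = TRUE)][1:3]
  modes <- sort(modes)
  valley <- function(i, j) {
    seg <- i:j
    d$x[seg[which.min(y[seg])]]
  }
  c(neg_dim_cut = valley(modes[1], modes[2]),
    dim_bright_cut = valley(modes[2], modes[3]))
}

#' Classify gated events and summarize population composition
#'
#' Labels each event negative / dim / bright by interval membership of
#' `log(tdt)` against the two cuts, then reports counts, subpopulation
#' percentages with the reporter-positive pool as denominator (the
#' convention used for the published composition figures), the positive
#' fraction of all gated events, and per-class median raw intensities.
#'
#' @param gated gated event table (needs a `tdt` column).
#' @param cuts numeric length-2 `(neg_dim, dim_bright)` on the
#'   log-intensity scale, as returned by [estimate_thresholds()].
#' @return one-row data.frame of class counts and statistics, with the
#'   per-event labels attached as attribute `"labels"`.
#' @export
classify_and_summarize <- function(gated, cuts) {
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2])
  lt <- log(gated$tdt)
  lab <- ifelse(lt < cuts[1], "negative",
                ifelse(lt < cuts[2], "dim", "bright"))
  n_neg <- sum(lab == "negative"); n_dim <- sum(lab == "dim")
  n_bright <- sum(lab == "bright")
  n_pos <- n_dim + n_bright
  med <- function(cl) if (any(lab == cl))
    stats::median(gated$tdt[lab == cl]) else NA_real_
  out <- data.frame(
    n_gated = nrow(gated), n_negative = n_neg, n_dim = n_dim,
    n_bright = n_bright,
    pct_dim_of_positive = if (n_pos > 0) 100 * n_dim / n_pos else NA_real_,
    pct_bright_of_positive = if (n_pos > 0) 100 * n_bright / n_pos
                             else NA_real_,
    pct_positive_of_total = if (nrow(gated) > 0)
      100 * n_pos / nrow(gated) else NA_real_,
    median_negative = med("negative"), median_dim = med("dim"),
    median_bright = med("bright"))
  attr(out, "labels") <- lab
  out
}

#' Marker-channel positivity
#'
#' @param events event table.
#' @param channel channel column name (e.g. `"ehd3"`).
#' @param cutoff positivity cutoff in raw intensity units.
#' @return percentage of events at or above the cutoff (`NA` for an
#'   empty table).
#' @export
marker_positivity <- function(events, channel, cutoff) {
  if (!channel %in% names(events))
    stop("channel '", channel, "' not present in event table")
  if (nrow(events) == 0L) return(NA_real_)
  100 * mean(events[[channel]] >= cutoff)
}

#' Full cytometry chain: gate, estimate thresholds, classify
#'
#' @param events raw event table from [gen_facs_events()] or a delimited
#'   file read with [read.delim()].
#' @param gates [gate_config()].
#' @return list with `gated`, `cuts` (log scale), and `stats` (the
#'   [classify_and_summarize()] row).
#' @export
cytometry_pipeline <- function(events, gates = gate_config()) {
  gated <- gate_events(events, gates)
  cuts <- estimate_thresholds(log(gated$tdt), gates)
  stats <- classify_and_summarize(gated, cuts)
  list(gated = gated, cuts = cuts, stats = stats)
}
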