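#' Generate a synthetic flow-cytometry event table
#'
#' Draws events from a three-component (negative / dim / bright)
#' log-normal reporter-intensity mixture with bright log-mean above dim
#' log-mean, plus configurable contaminants: debris (bottom-range forward
#' scatter, reporter-negative) and doublets (area/height ratio above 1.5
#' by construction, otherwise ordinary cells). Marker channels (an
#' Ehd3-like endothelial marker and a WT1-like podocyte marker) are
#' positive per the configured fractions, independently of reporter
#' class.
#'
#' @param cfg a [sim_config()] object; `cfg$cytometry` holds the mixture
#'   weights, intensity model and contaminant fractions.
#' @param seed integer seed; fully determines the output.
#' @return list with `events` (data.frame: `event_id`, `scatter_a`,
#'   `scatter_b`, `area_height_ratio`, `tdt`, `ehd3`, `wt1`) and `truth`
#'   (data.frame: `event_id`, `class` in negative/dim/bright,
#'   `is_debris`, `is_doublet`, `ehd3_positive`, `wt1_positive`).
#' @examples
#' sim <- gen_facs_events(sim_config("WT", cytometry.n_events = 500L), seed = 1)
#' table(sim$truth$class)
#' @export
gen_facs_events <- function(cfg, seed) {
  cy <- cfg$cytometry
  if (cy$debris_fraction < 0 || cy$doublet_fraction < 0)
    stop("contaminant fractions must be non-negative")
  set.seed(as.integer(seed))
  n <- as.integer(cy$n_events)
  empty <- list(
    events = data.frame(event_id = integer(), scatter_a = numeric(),
                        scatter_b = numeric(), area_height_ratio = numeric(),
                        tdt = numeric(), ehd3 = numeric(), wt1 = numeric()),
    truth = data.frame(event_id = integer(), class = character(),
                       is_debris = logical(), is_doublet = logical(),
                       ehd3_positive = logical(), wt1_positive = logical(),
                       stringsAsFactors = FALSE))
  if (n == 0L) return(empty)

  u <- stats::runif(n)
  is_debris <- u < cy$debris_fraction
  is_doublet <- !is_debris & u < cy$debris_fraction + cy$doublet_fraction

  p_pos <- cy$positive_fraction
  cls <- sample(c("negative", "dim", "bright"), n, replace = TRUE,
                prob = c(1 - p_pos, p_pos * cy$dim_fraction,
                         p_pos * (1 - cy$dim_fraction)))
  cls[is_debris] <- "negative"

  ml <- c(negative = cy$neg_meanlog, dim = cy$dim_meanlog,
          bright = cy$bright_meanlog)
  sl <- c(negative = cy$neg_sdlog, dim = cy$dim_sdlog,
          bright = cy$bright_sdlog)
  tdt <- stats::rlnorm(n, ml[cls], sl[cls])

  scatter_a <- stats::rlnorm(n, log(1200), 0.15)
  scatter_b <- stats::rlnorm(n, log(900), 0.18)
  scatter_a[is_debris] <- stats::runif(sum(is_debris), 30, 250)
  scatter_b[is_debris] <- stats::runif(sum(is_debris), 30, 250)
  ratio <- pmax(stats::rnorm(n, 1.0, 0.08), 0.7)
  ratio[is_doublet] <- stats::runif(sum(is_doublet), 1.7, 2.3)

  mpf <- cy$marker_positive_fraction
  ehd3_pos <- stats::runif(n) < mpf[["ehd3"]]
  wt1_pos <- stats::runif(n) < mpf[["wt1"]]
  ehd3 <- stats::rlnorm(n,
    ifelse(ehd3_pos, cy$marker_pos_meanlog, cy$marker_neg_meanlog),
    ifelse(ehd3_pos, cy$marker_pos_sdlog, cy$marker_neg_sdlog))
  wt1 <- stats::rlnorm(n,
    ifelse(wt1_pos, cy$marker_pos_meanlog, cy$marker_neg_meanlog),
    ifelse(wt1_pos, cy$marker_pos_sdlog, cy$marker_neg_sdlog))

  list(
    events = data.frame(event_id = seq_len(n), scatter_a = scatter_a,
                        scatter_b = scatter_b, area_height_ratio = ratio,
                        tdt = tdt, ehd3 = ehd3, wt1 = wt1),
    truth = data.frame(event_id = seq_len(n), class = cls,
                       is_debris = is_debris, is_doublet = is_doublet,
                       ehd3_positive = ehd3_pos, wt1_positive = wt1_pos,
                       stringsAsFactors = FALSE))
}
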