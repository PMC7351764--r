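#' Generate synthetic confocal z-stacks of reporter-positive cells
#'
#' Renders one 12-bit z-stack per glomerulus. Each cell is a 3D Gaussian
#' blob whose peak amplitude is drawn from its class-conditional
#' log-normal intensity model and attenuated by `exp(-z / L)` with `L` the
#' depth-attenuation length. A configurable fraction of cells is placed
#' deeper than the morphometry depth limit, and a fraction is rendered
#' saturated (clipped at the 4095 ceiling) so their axial profile shows a
#' plateau instead of a bell. Poisson-Gaussian noise is added last.
#'
#' Dim/bright class labels are allocated across glomeruli by largest
#' remainder, so the realized dim fraction matches `dim_fraction` as
#' closely as integer counts permit; which cells within a glomerulus are
#' dim is random. Cell centers are snapped to voxel centers.
#'
#' @param cfg a [sim_config()] object.
#' @param seed integer seed; fully determines the output.
#' @return A list with:
#'   \describe{
#'     \item{stacks}{list (one per glomerulus) of numeric arrays
#'       `[x, y, z]`, intensities in `[0, 4095]`.}
#'     \item{truth}{data.frame with one row per cell: `glomerulus_id`,
#'       `roi_id`, `class` (`"dim"`/`"bright"`), `x_um`, `y_um`, `z_um`,
#'       `amplitude` (true attenuated peak before clipping),
#'       `is_plateau`, `is_deep`.}
#'     \item{rois}{data.frame of ROI seed coordinates (`glomerulus_id`,
#'       `roi_id`, `x_um`, `y_um`), the cell positions with sub-micron
#'       lateral jitter, as a human would seed ROIs.}
#'     \item{pixel_size_um, z_step_um}{voxel geometry.}
#'   }
#' @examples
#' sim <- gen_image_stack(sim_config("WT", imaging.n_glomeruli = 1L), seed = 1)
#' dim(sim$stacks[[1]])
#' @export
gen_image_stack <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  im <- cfg$imaging
  if (im$z_step_um <= 0 || im$stack_depth_um <= 0 || im$img_size_px <= 0 ||
      im$pixel_size_um <= 0)
    stop("stack dimensions and z_step must be positive")
  set.seed(as.integer(seed))

  nxy <- as.integer(im$img_size_px)
  nz  <- as.integer(floor(im$stack_depth_um / im$z_step_um)) + 1L
  ng  <- as.integer(im$n_glomeruli)
  ncell <- as.integer(im$cells_per_glomerulus)

  # deterministic dim-count allocation across glomeruli (largest remainder)
  total <- ng * ncell
  dim_counts <- integer(ng)
  if (total > 0L && ncell > 0L) {
    target <- im$dim_fraction * ncell
    base <- floor(target)
    dim_counts <- rep.int(as.integer(base), ng)
    extra <- round(im$dim_fraction * total) - sum(dim_counts)
    if (extra > 0L) dim_counts[seq_len(min(extra, ng))] <-
        dim_counts[seq_len(min(extra, ng))] + 1L
  }

  margin_um <- 5
  lo <- margin_um
  hi <- (nxy - 1L) * im$pixel_size_um - margin_um

  stacks <- vector("list", ng)
  truth_rows <- list()
  roi_rows <- list()

  for (g in seq_len(ng)) {
    stk <- array(0, dim = c(nxy, nxy, nz))
    if (ncell > 0L) {
      pos <- place_cells(ncell, lo, hi, im$min_separation_um)
      is_deep <- stats::runif(ncell) < im$deep_cell_fraction
      z_um <- ifelse(is_deep,
                     stats::runif(ncell, im$deep_z_min_um,
                                  min(im$deep_z_max_um, im$stack_depth_um - 2)),
                     stats::runif(ncell, im$z_min_um, im$z_max_um))
      # snap to voxel centers
      ix <- round(pos$x / im$pixel_size_um)
      iy <- round(pos$y / im$pixel_size_um)
      iz <- pmin(pmax(round(z_um / im$z_step_um), 0L), nz - 1L)
      x_um <- ix * im$pixel_size_um
      y_um <- iy * im$pixel_size_um
      z_um <- iz * im$z_step_um

      cls <- rep("bright", ncell)
      cls[sample.int(ncell, dim_counts[g])] <- "dim"
      ml <- ifelse(cls == "dim", cfg$intensity$dim_meanlog,
                   cfg$intensity$bright_meanlog)
      sl <- ifelse(cls == "dim", cfg$intensity$dim_sdlog,
                   cfg$intensity$bright_sdlog)
      amp0 <- stats::rlnorm(ncell, ml, sl)
      atten <- exp(-z_um / im$depth_attenuation_um)
      amp <- amp0 * atten
      # saturation artifacts: clip any cell's recorded signal, regardless of
      # class, so shape-QC exclusion stays composition-neutral
      is_plateau <- stats::runif(ncell) < im$plateau_artifact_fraction
      amp[is_plateau] <- pmax(amp[is_plateau], 4095 * 1.5)

      for (i in seq_len(ncell)) {
        stk <- add_blob(stk, ix[i], iy[i], iz[i], amp[i],
                        im$blob_sigma_xy_um / im$pixel_size_um,
                        im$blob_sigma_z_um / im$z_step_um)
      }
      stk[stk > 4095] <- 4095

      jit <- matrix(stats::runif(2L * ncell, -0.4, 0.4), ncol = 2L)
      truth_rows[[g]] <- data.frame(
        glomerulus_id = g,
        roi_id = sprintf("g%02d_c%02d", g, seq_len(ncell)),
        class = cls, x_um = x_um, y_um = y_um, z_um = z_um,
        amplitude = amp, is_plateau = is_plateau, is_deep = is_deep,
        stringsAsFactors = FALSE)
      roi_rows[[g]] <- data.frame(
        glomerulus_id = g,
        roi_id = truth_rows[[g]]$roi_id,
        x_um = pmin(pmax(x_um + jit[, 1], 0), (nxy - 1L) * im$pixel_size_um),
        y_um = pmin(pmax(y_um + jit[, 2], 0), (nxy - 1L) * im$pixel_size_um),
        stringsAsFactors = FALSE)
    }
    if (isTRUE(im$noise)) {
      stk <- stk + im$background
      stk <- stats::rpois(length(stk), lambda = stk) +
        stats::rnorm(length(stk), 0, im$read_noise_sd)
      stk <- array(round(pmin(pmax(stk, 0), 4095)), dim = c(nxy, nxy, nz))
    }
    stacks[[g]] <- stk
  }

  empty_truth <- data.frame(
    glomerulus_id = integer(), roi_id = character(), class = character(),
    x_um = numeric(), y_um = numeric(), z_um = numeric(),
    amplitude = numeric(), is_plateau = logical(), is_deep = logical(),
    stringsAsFactors = FALSE)
  empty_roi <- data.frame(
    glomerulus_id = integer(), roi_id = character(),
    x_um = numeric(), y_um = numeric(), stringsAsFactors = FALSE)

  list(
    stacks = stacks,
    truth = if (length(truth_rows)) do.call(rbind, truth_rows) else empty_truth,
    rois  = if (length(roi_rows)) do.call(rbind, roi_rows) else empty_roi,
    pixel_size_um = im$pixel_size_um,
    z_step_um = im$z_step_um
  )
}

# rejection-sample ncell lateral positions with pairwise min separation
place_cells <- function(ncell, lo, hi, min_sep) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < ncell && tries < 20000L) {
    tries <- tries + 1L
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < ncell)
    stop("could not place ", ncell, " cells with min separation ", min_sep,
         " um in the field; enlarge img_size_px or reduce separation")
  list(x = xs, y = ys)
}

# add a 3D Gaussian blob (sigmas in voxel units) on a local support window
add_blob <- function(stk, ix, iy, iz, amp, sxy, sz) {
  d <- dim(stk)
  rx <- ceiling(4 * sxy); rz <- ceiling(4 * sz)
  xr <- max(0L, ix - rx):min(d[1] - 1L, ix + rx)
  yr <- max(0L, iy - rx):min(d[2] - 1L, iy + rx)
  zr <- max(0L, iz - rz):min(d[3] - 1L, iz + rz)
  gx <- exp(-(xr - ix)^2 / (2 * sxy^2))
  gy <- exp(-(yr - iy)^2 / (2 * sxy^2))
  gz <- exp(-(zr - iz)^2 / (2 * sz^2))
  blob <- amp * outer(outer(gx, gy), gz)
  blob <- pmin(blob, 4095)  # detector ceiling applies to the ideal signal
  stk[xr + 1L, yr + 1L, zr + 1L] <- stk[xr + 1L, yr + 1L, zr + 1L] + blob
  stk
}

#' Write a stack as multi-page TIFF plus a TSV sidecar of ROI seeds
#'
#' One TIFF page per z-slice; the 12-bit data is stored in a 16-bit
#' container. Values round-trip exactly through [read_stack_tiff()].
#'
#' @param stack numeric array `[x, y, z]`, values in `[0, 4095]`.
#' @param rois data.frame of ROI seeds (`glomerulus_id`, `roi_id`, `x_um`,
#'   `y_um`) or NULL to skip the sidecar.
#' @param tiff_path,roi_path output paths.
#' @return `tiff_path`, invisibly.
#' @export
write_stack_tiff <- function(stack, rois, tiff_path, roi_path = NULL) {
  pages <- lapply(seq_len(dim(stack)[3]), function(k)
    t(stack[, , k]) / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  if (!is.null(rois) && !is.null(roi_path))
    utils::write.table(rois, roi_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tiff_path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param tiff_path path to the TIFF file.
#' @return numeric array `[x, y, z]` with integer intensities.
#' @export
read_stack_tiff <- function(tiff_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) * 65535
  round(arr)
}
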