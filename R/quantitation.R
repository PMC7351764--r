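#' Relative qPCR quantification by the 2^-ddCt (Livak) method
#'
#' For each sample, dCt = mean Ct(target) - mean Ct(reference);
#' ddCt = dCt - dCt(calibrator); fold = 2^-ddCt. Replicate Ct values
#' are averaged arithmetically before differencing by default; with
#' `per_replicate = TRUE` fold changes are computed per replicate pair
#' and then averaged (requires equal replicate counts per gene within a
#' sample). Amplification efficiency is fixed at 2.
#'
#' @param ct data.frame with columns `sample_id`, `gene_id`, `ct`
#'   (cycles, one row per replicate; Ct in (0, 45)).
#' @param target,reference gene ids (reference is the housekeeping
#'   gene, e.g. GAPDH).
#' @param calibrator sample id whose fold change is 1 by definition.
#' @param per_replicate average per-replicate folds instead of averaging
#'   Ct first.
#' @return data.frame: `sample_id`, `delta_ct`, `delta_delta_ct`,
#'   `fold`.
#' @export
ddct <- function(ct, target, reference, calibrator, per_replicate = FALSE) {
  req <- c("sample_id", "gene_id", "ct")
  if (!all(req %in% names(ct)))
    stop("Ct table needs columns: ", paste(req, collapse = ", "))
  if (any(ct$ct <= 0 | ct$ct >= 45))
    stop("Ct values must lie in (0, 45) cycles")
  samples <- unique(ct$sample_id)
  for (g in c(target, reference)) {
    have <- unique(ct$sample_id[ct$gene_id == g])
    if (!setequal(have, samples) || !g %in% ct$gene_id)
      stop("gene '", g, "' must be measured in every sample")
  }
  if (!calibrator %in% samples)
    stop("calibrator sample '", calibrator, "' not present")

  dct_of <- function(s) {
    tc <- ct$ct[ct$sample_id == s & ct$gene_id == target]
    rc <- ct$ct[ct$sample_id == s & ct$gene_id == reference]
    if (per_replicate) {
      if (length(tc) != length(rc))
        stop("per_replicate = TRUE needs equal replicate counts (sample '",
             s, "')")
      tc - rc
    } else mean(tc) - mean(rc)
  }
  dct_cal <- mean(dct_of(calibrator))
  res <- lapply(samples, function(s) {
    d <- dct_of(s)
    dd <- d - dct_cal
    data.frame(sample_id = s, delta_ct = mean(d),
               delta_delta_ct = mean(dd), fold = mean(2^-dd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Housekeeping-normalized densitometry ratio
#'
#' Target band pixel density divided by the matched housekeeping band
#' (beta-actin by convention); invariant to global exposure scaling.
#'
#' @param target,housekeeping positive numeric vectors of band pixel
#'   densities (recycled pairwise).
#' @return numeric vector of ratios.
#' @export
densitometry_ratio <- function(target, housekeeping) {
  if (any(housekeeping <= 0)) stop("housekeeping densities must be > 0")
  if (any(target <= 0)) stop("target densities must be > 0")
  target / housekeeping
}

#' Group summary of densitometry ratios
#'
#' @param rec data.frame with `sample_id`, `target`, `housekeeping`, and
#'   optionally `group`.
#' @return data.frame of per-group mean and SD of the normalized ratio
#'   (single group `"all"` when no group column is present).
#' @export
densitometry_summary <- function(rec) {
  ratio <- densitometry_ratio(rec$target, rec$housekeeping)
  grp <- if ("group" %in% names(rec)) rec$group else rep("all", nrow(rec))
  agg <- lapply(split(ratio, grp), function(v)
    data.frame(mean_ratio = mean(v), sd_ratio = stats::sd(v), n = length(v)))
  out <- do.call(rbind, agg)
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "mean_ratio", "sd_ratio", "n")]
}
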