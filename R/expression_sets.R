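#' Library-size and length normalization
#'
#' CPM = 1e6 * count / library_size;
#' RPKM = 1e9 * count / (library_size * length_bp).
#'
#' @param counts genes x samples count matrix (non-negative, rownames =
#'   gene ids).
#' @param lengths named numeric vector of gene lengths in bp (required
#'   for RPKM; may be NULL for CPM only).
#' @return list with `cpm` and (when lengths are supplied) `rpkm`
#'   matrices.
#' @export
cpm_rpkm <- function(counts, lengths = NULL) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  out <- list(cpm = cpm)
  if (!is.null(lengths)) {
    if (any(lengths[rownames(counts)] <= 0) ||
        anyNA(lengths[rownames(counts)]))
      stop("gene lengths must be positive for every gene")
    out$rpkm <- cpm / (lengths[rownames(counts)] / 1e3)
  }
  out
}

#' Stand-in differential-expression test for synthetic runs
#'
#' Per-gene Welch t-test on log2(CPM + 0.5) between two groups, with
#' Benjamini-Hochberg adjustment and a log2 fold change of group mean
#' CPM (0.5 pseudocount). This is deliberately a simple t-based
#' stand-in, not an exact negative-binomial test: its output schema
#' (gene_id, log2fc, p_value, adj_p, log_cpm) matches externally
#' produced DGE tables so either source feeds the downstream set algebra
#' interchangeably.
#'
#' @param counts genes x samples count matrix.
#' @param sample_groups named character vector sample -> group.
#' @param contrast character length-2 `(X, Y)`; fold changes are X over
#'   Y (positive = higher in X).
#' @return data.frame of class `"dge_table"`: `gene_id`, `log2fc`,
#'   `p_value`, `adj_p`, `log_cpm` (mean log2 CPM across all samples of
#'   the contrast), `contrast`.
#' @export
simple_de <- function(counts, sample_groups, contrast) {
  stopifnot(length(contrast) == 2L)
  sx <- names(sample_groups)[sample_groups == contrast[1]]
  sy <- names(sample_groups)[sample_groups == contrast[2]]
  if (length(sx) < 2L || length(sy) < 2L)
    stop("each contrast group needs >= 2 replicates")
  cpm <- cpm_rpkm(counts[, c(sx, sy), drop = FALSE])$cpm
  lx <- log2(cpm[, sx, drop = FALSE] + 0.5)
  ly <- log2(cpm[, sy, drop = FALSE] + 0.5)
  mx <- rowMeans(lx); my <- rowMeans(ly)
  vx <- apply(lx, 1, stats::var) / length(sx)
  vy <- apply(ly, 1, stats::var) / length(sy)
  t <- (mx - my) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(sx) - 1) + vy^2 / (length(sy) - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[!is.finite(t)] <- NA_real_
  p[mx == my] <- ifelse(is.na(p[mx == my]), 1, p[mx == my])
  out <- data.frame(
    gene_id = rownames(counts),
    log2fc = log2((rowMeans(cpm[, sx, drop = FALSE]) + 0.5) /
                  (rowMeans(cpm[, sy, drop = FALSE]) + 0.5)),
    p_value = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    log_cpm = rowMeans(log2(cpm + 0.5)),
    contrast = paste(contrast, collapse = "_vs_"),
    stringsAsFactors = FALSE)
  class(out) <- c("dge_table", "data.frame")
  out
}

#' Significance cutoff policy for DGE tables
#'
#' `venn` mode applies all three published cutoffs (p < 0.05,
#' logCPM > 1, |log2FC| >= 1.5); `p_only` mode applies the p cutoff
#' alone, as used for the inverse-regulation table whose entries include
#' fold changes below 1.5.
#'
#' @param p_max p-value cutoff.
#' @param log_cpm_min minimum logCPM (venn mode).
#' @param abs_log2fc_min minimum |log2 fold change| (venn mode). The
#'   published threshold "logFC > 1.5" is read on the log2 scale, the
#'   scale DGE tools report.
#' @param mode `"venn"` or `"p_only"`.
#' @return list of class `"cutoff_policy"`.
#' @export
cutoff_policy <- function(p_max = 0.05, log_cpm_min = 1,
                          abs_log2fc_min = 1.5,
                          mode = c("venn", "p_only")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(p_max), is.finite(log_cpm_min),
            is.finite(abs_log2fc_min))
  structure(list(p_max = p_max, log_cpm_min = log_cpm_min,
                 abs_log2fc_min = abs_log2fc_min, mode = mode),
            class = "cutoff_policy")
}

#' Label genes up / down / ns under a cutoff policy
#'
#' @param table a DGE table (`gene_id`, `log2fc`, `p_value`, and
#'   `log_cpm` when the policy is in venn mode).
#' @param policy a [cutoff_policy()].
#' @return named character vector (`names` = gene ids) with values
#'   `"up"`, `"down"`, `"ns"`.
#' @export
apply_cutoffs <- function(table, policy = cutoff_policy()) {
  req <- c("gene_id", "log2fc", "p_value")
  if (policy$mode == "venn") req <- c(req, "log_cpm")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("DGE table lacks column(s) required by mode '", policy$mode,
         "': ", paste(missing_cols, collapse = ", "))
  sig_p <- !is.na(table$p_value) & table$p_value < policy$p_max
  if (policy$mode == "venn") {
    sig <- sig_p & table$log_cpm > policy$log_cpm_min &
      abs(table$log2fc) >= policy$abs_log2fc_min
  } else {
    sig <- sig_p & table$log2fc != 0
  }
  lab <- rep("ns", nrow(table))
  lab[sig & table$log2fc > 0] <- "up"
  lab[sig & table$log2fc < 0] <- "down"
  stats::setNames(lab, table$gene_id)
}

#' Venn decomposition of two labelled contrasts
#'
#' Partitions the shared gene universe into the regions of a
#' four-circle up/down Venn diagram: commonly up, commonly down,
#' up/down in one contrast only, discordant (up in one and down in the
#' other), and not significant. Per-contrast totals are re-derived from
#' the regions and checked against direct counts.
#'
#' @param labelsX,labelsY named `"up"`/`"down"`/`"ns"` vectors over the
#'   same gene universe ([apply_cutoffs()] output).
#' @return list with `counts` (named integer vector over regions),
#'   `genes` (gene id list per region), and `margins`
#'   (`total_X`, `total_Y` significant-gene totals).
#' @export
venn_decompose <- function(labelsX, labelsY) {
  gx <- sort(names(labelsX)); gy <- sort(names(labelsY))
  if (!identical(gx, gy)) {
    offenders <- c(setdiff(gx, gy), setdiff(gy, gx))
    stop("label sets cover different gene universes; offending genes: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ...")
  }
  x <- labelsX[gx]; y <- labelsY[gx]
  genes <- list(
    up_both = gx[x == "up" & y == "up"],
    down_both = gx[x == "down" & y == "down"],
    up_X_only = gx[x == "up" & y == "ns"],
    up_Y_only = gx[x == "ns" & y == "up"],
    down_X_only = gx[x == "down" & y == "ns"],
    down_Y_only = gx[x == "ns" & y == "down"],
    discordant = gx[(x == "up" & y == "down") | (x == "down" & y == "up")],
    ns = gx[x == "ns" & y == "ns"])
  counts <- vapply(genes, length, integer(1))
  if (sum(counts) != length(gx))
    stop("internal error: Venn regions do not partition the universe")
  total_X <- counts[["up_both"]] + counts[["down_both"]] +
    counts[["up_X_only"]] + counts[["down_X_only"]] + counts[["discordant"]]
  total_Y <- counts[["up_both"]] + counts[["down_both"]] +
    counts[["up_Y_only"]] + counts[["down_Y_only"]] + counts[["discordant"]]
  if (total_X != sum(x != "ns") || total_Y != sum(y != "ns"))
    stop("internal error: Venn margins do not reconstruct totals")
  list(counts = counts, genes = genes,
       margins = c(total_X = total_X, total_Y = total_Y))
}

#' Inversely regulated genes between two contrasts
#'
#' Genes significant in both contrasts with opposite fold-change signs.
#' Uses the p-only policy by default, matching the published
#' inverse-regulation table whose entries include |FC| below the Venn
#' fold-change cutoff. Symmetric in its two inputs (fold pairs swap).
#'
#' @param tableA,tableB DGE tables over a shared gene universe.
#' @param policy a [cutoff_policy()]; the fold-change/CPM terms are
#'   ignored unless the policy is in venn mode.
#' @return data.frame sorted by gene id: `gene_id`, `fc_A`, `p_A`,
#'   `fc_B`, `p_B`.
#' @export
find_inverse_regulated <- function(tableA, tableB,
                                   policy = cutoff_policy(mode = "p_only")) {
  la <- apply_cutoffs(tableA, policy)
  lb <- apply_cutoffs(tableB, policy)
  shared <- intersect(names(la), names(lb))
  la <- la[shared]; lb <- lb[shared]
  inv <- shared[(la == "up" & lb == "down") | (la == "down" & lb == "up")]
  inv <- sort(inv)
  ia <- match(inv, tableA$gene_id); ib <- match(inv, tableB$gene_id)
  data.frame(gene_id = inv,
             fc_A = tableA$log2fc[ia], p_A = tableA$p_value[ia],
             fc_B = tableB$log2fc[ib], p_B = tableB$p_value[ib],
             stringsAsFactors = FALSE)
}

#' Transcripts solely expressed in one group
#'
#' A gene is X-only when its expression is at or above `tau` in every
#' replicate of group X and below `tau` in every replicate of group Y
#' (and symmetrically for Y-only).
#'
#' @param expr genes x samples expression matrix on the scale `tau`
#'   refers to (RPKM by convention).
#' @param sample_groups named character vector sample -> group.
#' @param groups character length-2 `(X, Y)`.
#' @param tau expression threshold (default RPKM 1).
#' @return list with `x_only` and `y_only` gene id vectors.
#' @export
solely_expressed <- function(expr, sample_groups, groups, tau = 1) {
  stopifnot(length(groups) == 2L)
  sx <- names(sample_groups)[sample_groups == groups[1]]
  sy <- names(sample_groups)[sample_groups == groups[2]]
  if (!length(sx) || !length(sy))
    stop("both groups need at least one replicate")
  ex <- expr[, sx, drop = FALSE]; ey <- expr[, sy, drop = FALSE]
  x_all <- rowSums(ex >= tau) == length(sx)
  y_all <- rowSums(ey >= tau) == length(sy)
  x_none <- rowSums(ex < tau) == length(sx)
  y_none <- rowSums(ey < tau) == length(sy)
  list(x_only = rownames(expr)[x_all & y_none],
       y_only = rownames(expr)[y_all & x_none])
}
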