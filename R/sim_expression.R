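#' Generate a synthetic expression count matrix with planted effects
#'
#' Negative-binomial counts for the four sorted GEC groups (WT_dim,
#' WT_bright, AS_dim, AS_bright) x replicates, with gene-wise baseline
#' means drawn log-normally. Planted structure, recorded in the ground
#' truth, covers the calls the downstream set algebra must recover:
#' \itemize{
#'   \item DE genes in contrast A (WT bright over dim) and contrast B
#'     (AS bright over dim), half up / half down at `de_log2fc`;
#'   \item inversely regulated genes, whose bright-over-dim fold change
#'     flips sign between WT and AS;
#'   \item solely expressed genes, with near-zero means in every
#'     replicate of the excluded subpopulation (both genotypes).
#' }
#'
#' @param cfg a [sim_config()] object; `cfg$expression` holds the layout.
#' @param seed integer seed; fully determines the output.
#' @return list with `counts` (genes x samples integer matrix), `lengths`
#'   (named vector, bp), `sample_groups` (named character vector
#'   sample -> group), and `truth` (data.frame: `gene_id`, `status` in
#'   \{null, up_A, down_A, up_B, down_B, inverse, dim_only, bright_only\},
#'   `fc_A`, `fc_B` planted log2 fold changes, `base_mean` the gene's
#'   baseline mean), and `mu` (genes x groups matrix of true NB means).
#' @export
gen_expression <- function(cfg, seed) {
  ex <- cfg$expression
  if (length(ex$groups) < 2L || ex$n_replicates < 2L)
    stop("expression layout needs >= 2 groups and >= 2 replicates")
  set.seed(as.integer(seed))
  ng <- as.integer(ex$n_genes)
  genes <- sprintf("gene%05d", seq_len(ng))
  groups <- ex$groups
  reps <- as.integer(ex$n_replicates)
  samples <- as.vector(t(outer(groups, seq_len(reps), paste, sep = "_r")))
  sample_groups <- stats::setNames(rep(groups, each = reps), samples)

  base <- stats::rlnorm(ng, ex$mean_meanlog, ex$mean_sdlog)
  mu <- matrix(base, nrow = ng, ncol = length(groups),
               dimnames = list(genes, groups))

  status <- rep("null", ng)
  fc_A <- numeric(ng); fc_B <- numeric(ng)
  n_de <- round(ex$de_fraction * ng)
  n_inv <- round(ex$inverse_fraction * ng)
  n_sol <- as.integer(ex$solely_expressed_count)
  pool <- sample.int(ng)   # disjoint planted-effect gene blocks
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }

  if (n_de > 0) {
    ia <- take(n_de)
    sgn <- rep(c(1, -1), length.out = n_de)
    status[ia] <- ifelse(sgn > 0, "up_A", "down_A")
    fc_A[ia] <- sgn * ex$de_log2fc
    ib <- take(n_de)
    sgn <- rep(c(1, -1), length.out = n_de)
    status[ib] <- ifelse(sgn > 0, "up_B", "down_B")
    fc_B[ib] <- sgn * ex$de_log2fc
  }
  if (n_inv > 0) {
    ii <- take(n_inv)
    sgn <- rep(c(1, -1), length.out = n_inv)
    status[ii] <- "inverse"
    fc_A[ii] <- sgn * ex$de_log2fc
    fc_B[ii] <- -sgn * ex$de_log2fc
  }
  sol_dim <- integer(0); sol_bright <- integer(0)
  if (n_sol > 0) {
    sol_dim <- take(ceiling(n_sol / 2))
    sol_bright <- take(floor(n_sol / 2))
    status[sol_dim] <- "dim_only"
    status[sol_bright] <- "bright_only"
  }

  # apply planted fold changes symmetrically around the baseline
  has_fc_A <- fc_A != 0
  if (any(has_fc_A)) {
    mu[has_fc_A, "WT_bright"] <- mu[has_fc_A, "WT_bright"] * 2^(fc_A[has_fc_A] / 2)
    mu[has_fc_A, "WT_dim"]    <- mu[has_fc_A, "WT_dim"] * 2^(-fc_A[has_fc_A] / 2)
  }
  has_fc_B <- fc_B != 0
  if (any(has_fc_B)) {
    mu[has_fc_B, "AS_bright"] <- mu[has_fc_B, "AS_bright"] * 2^(fc_B[has_fc_B] / 2)
    mu[has_fc_B, "AS_dim"]    <- mu[has_fc_B, "AS_dim"] * 2^(-fc_B[has_fc_B] / 2)
  }
  bright_groups <- grep("bright", groups, value = TRUE)
  dim_groups <- grep("dim", groups, value = TRUE)
  mu[sol_dim, bright_groups] <- 0.001
  mu[sol_dim, dim_groups] <- pmax(mu[sol_dim, dim_groups], 80)
  mu[sol_bright, dim_groups] <- 0.001
  mu[sol_bright, bright_groups] <- pmax(mu[sol_bright, bright_groups], 80)

  counts <- matrix(0L, nrow = ng, ncol = length(samples),
                   dimnames = list(genes, samples))
  for (s in samples)
    counts[, s] <- stats::rnbinom(ng, mu = mu[, sample_groups[[s]]],
                                  size = 1 / ex$nb_dispersion)

  lengths <- stats::setNames(
    round(stats::runif(ng, ex$length_min_bp, ex$length_max_bp)), genes)

  list(counts = counts, lengths = lengths, sample_groups = sample_groups,
       truth = data.frame(gene_id = genes, status = status,
                          fc_A = fc_A, fc_B = fc_B, base_mean = base,
                          stringsAsFactors = FALSE),
       mu = mu)
}
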