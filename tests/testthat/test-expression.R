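test_that("CPM and RPKM normalization formulas", {
  counts <- matrix(c(100, 0, 0,
                     10, 40, 50), ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  lens <- c(g1 = 1000, g2 = 500, g3 = 2000)
  norm <- cpm_rpkm(counts, lens)
  # a gene holding all of a sample's counts
  expect_equal(norm$cpm["g1", "s1"], 1e6)
  # hand arithmetic: count 10, library 1e6, length 1000 bp -> RPKM 10
  big <- matrix(c(10, 1e6 - 10), ncol = 1,
                dimnames = list(c("a", "b"), "s"))
  expect_equal(cpm_rpkm(big, c(a = 1000, b = 1000))$rpkm["a", "s"], 10)
  # scale invariance: doubling a sample's counts leaves CPM unchanged
  doubled <- counts; doubled[, "s2"] <- doubled[, "s2"] * 2
  expect_equal(cpm_rpkm(doubled)$cpm[, "s2"], norm$cpm[, "s2"])
  expect_error(cpm_rpkm(matrix(0, 2, 1,
                               dimnames = list(c("a", "b"), "s"))),
               "library size")
})

test_that("stand-in DE: null contrast, planted recovery, schema", {
  ex <- gen_expression(sim_config("WT", expression.n_genes = 400L), seed = 2)
  # identical groups (copied columns) give log2fc 0 everywhere
  dup <- cbind(ex$counts, ex$counts)
  colnames(dup) <- paste0("s", seq_len(ncol(dup)))
  grp <- stats::setNames(rep(c("X", "Y"), each = ncol(ex$counts)),
                         colnames(dup))
  de0 <- simple_de(dup, grp, c("X", "Y"))
  expect_true(all(de0$log2fc == 0))
  expect_named(de0, c("gene_id", "log2fc", "p_value", "adj_p", "log_cpm",
                      "contrast"))
  expect_error(simple_de(ex$counts[, 1, drop = FALSE],
                         c(WT_dim_r1 = "WT_dim"), c("WT_dim", "WT_bright")),
               "2 replicates")
})

test_that("planted 4-fold genes are recovered with few false calls", {
  cfg <- sim_config("WT", expression.n_genes = 5000L,
                    expression.de_fraction = 0.04)
  ex <- gen_expression(cfg, seed = 1)
  de <- simple_de(ex$counts, ex$sample_groups, c("WT_bright", "WT_dim"))
  lab <- apply_cutoffs(de, cutoff_policy())
  tr <- ex$truth
  planted <- tr$gene_id[tr$fc_A != 0]
  calls <- names(lab)[lab != "ns"]
  expect_gte(mean(planted %in% calls), 0.90)
  false_calls <- sum(calls %in% tr$gene_id[tr$status == "null"])
  expect_lte(false_calls, 0.10 * length(calls))
  # recovered direction matches the planted sign
  hit <- intersect(planted, calls)
  expect_true(all((lab[hit] == "up") ==
                    (tr$fc_A[match(hit, tr$gene_id)] > 0)))
})

test_that("BH adjustment equals the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  set.seed(5)
  p2 <- runif(200)^2
  expect_equal(stats::p.adjust(p2, "BH"), oracle_bh(p2))
  ex <- gen_expression(sim_config("WT", expression.n_genes = 300L), seed = 3)
  de <- simple_de(ex$counts, ex$sample_groups, c("WT_bright", "WT_dim"))
  ok <- !is.na(de$p_value)
  expect_equal(de$adj_p[ok], oracle_bh(de$p_value[ok]))
  expect_true(all(de$adj_p[ok] >= de$p_value[ok]))
})

test_that("cutoff labelling matches an independent row-wise predicate", {
  expect_equal(unname(apply_cutoffs(
    data.frame(gene_id = "g", log2fc = 2, p_value = 0.01, log_cpm = 3),
    cutoff_policy())), "up")
  low_cpm <- data.frame(gene_id = "g", log2fc = 2, p_value = 0.01,
                        log_cpm = 0.5)
  expect_equal(unname(apply_cutoffs(low_cpm, cutoff_policy())), "ns")
  expect_equal(unname(apply_cutoffs(low_cpm,
                                    cutoff_policy(mode = "p_only"))), "up")
  expect_error(apply_cutoffs(data.frame(gene_id = "g", log2fc = 1,
                                        p_value = 0.5), cutoff_policy()),
               "log_cpm")

  set.seed(11)
  tab <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                    log2fc = rnorm(1000, 0, 2),
                    p_value = runif(1000),
                    log_cpm = rnorm(1000, 2, 2))
  pol <- cutoff_policy()
  lab <- apply_cutoffs(tab, pol)
  predicate <- function(fc, p, cpm) {  # independently coded rule
    if (p >= 0.05 || cpm <= 1 || abs(fc) < 1.5) "ns"
    else if (fc > 0) "up" else "down"
  }
  expected <- mapply(predicate, tab$log2fc, tab$p_value, tab$log_cpm)
  expect_equal(unname(lab), unname(expected))

  # venn mode is at least as strict as p_only
  lab_p <- apply_cutoffs(tab, cutoff_policy(mode = "p_only"))
  expect_true(all(names(lab)[lab != "ns"] %in% names(lab_p)[lab_p != "ns"]))
})

test_that("Venn decomposition partitions the universe and keeps margins", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(7)
  lx <- stats::setNames(sample(c("up", "down", "ns"), 200, TRUE,
                               prob = c(.2, .2, .6)), genes)
  ly <- stats::setNames(sample(c("up", "down", "ns"), 200, TRUE,
                               prob = c(.15, .25, .6)), genes)
  vd <- venn_decompose(lx, ly)
  expect_equal(sum(vd$counts), 200)
  expect_equal(unname(vd$margins["total_X"]), sum(lx != "ns"))
  expect_equal(unname(vd$margins["total_Y"]), sum(ly != "ns"))

  # identical labels put everything in the shared regions
  vd2 <- venn_decompose(lx, lx)
  expect_equal(unname(vd2$counts["up_X_only"]), 0L)
  expect_equal(unname(vd2$counts["down_Y_only"]), 0L)
  expect_equal(unname(vd2$counts["up_both"]), sum(lx == "up"))

  # disjoint significant sets share nothing
  la <- stats::setNames(rep(c("up", "ns"), c(20, 180)), genes)
  lb <- stats::setNames(rep(c("ns", "down"), c(180, 20)), genes)
  vd3 <- venn_decompose(la, lb)
  expect_equal(unname(vd3$counts["up_both"] + vd3$counts["down_both"]), 0L)

  expect_error(venn_decompose(lx[1:100], ly), "different gene universes")
})

test_that("inverse regulation: reference list is recovered in full", {
  ref <- reference_inverse_table()
  expect_equal(nrow(ref), 26L)
  expect_equal(sum(ref$fc_wt > 0), 11L)
  expect_equal(sum(ref$fc_wt < 0), 15L)
  tabA <- data.frame(gene_id = ref$gene_id, log2fc = ref$fc_wt,
                     p_value = ref$p_wt)
  tabB <- data.frame(gene_id = ref$gene_id, log2fc = ref$fc_as,
                     p_value = ref$p_as)
  inv <- find_inverse_regulated(tabA, tabB)
  expect_setequal(inv$gene_id, ref$gene_id)
  arg1 <- inv[inv$gene_id == "Arg1", ]
  expect_equal(arg1$fc_A, 3.398)
  expect_equal(arg1$fc_B, -1.715)
  expect_equal(arg1$p_B, 0.0008)

  # concordant significant genes are not flagged
  tabC <- tabA; tabC$log2fc <- abs(tabC$log2fc)
  tabD <- tabB; tabD$log2fc <- abs(tabD$log2fc)
  expect_equal(nrow(find_inverse_regulated(tabC, tabD)), 0L)

  # symmetry: swapping inputs swaps the fold pairs
  swapped <- find_inverse_regulated(tabB, tabA)
  expect_equal(swapped$gene_id, inv$gene_id)
  expect_equal(swapped$fc_A, inv$fc_B)
  expect_equal(swapped$fc_B, inv$fc_A)
})

test_that("solely expressed calls: clean cases and planted recovery", {
  expr <- rbind(x_only = c(5, 6, 7, 0, 0, 0.2),
                shared = c(3, 3, 3, 4, 4, 4),
                y_only = c(0, 0.5, 0, 2, 2, 3))
  colnames(expr) <- paste0("s", 1:6)
  grp <- stats::setNames(rep(c("X", "Y"), each = 3), colnames(expr))
  sole <- solely_expressed(expr, grp, c("X", "Y"), tau = 1)
  expect_equal(sole$x_only, "x_only")
  expect_equal(sole$y_only, "y_only")

  ex <- gen_expression(sim_config("WT"), seed = 1)
  rpkm <- cpm_rpkm(ex$counts, ex$lengths)$rpkm
  found <- solely_expressed(rpkm, ex$sample_groups, c("WT_dim", "WT_bright"))
  tr <- ex$truth
  expect_setequal(found$x_only, tr$gene_id[tr$status == "dim_only"])
  expect_setequal(found$y_only, tr$gene_id[tr$status == "bright_only"])
})

test_that("stand-in DE holds its nominal size on asymptotic null data", {
  set.seed(12)
  ng <- 4000; nrep <- 10
  mu <- rlnorm(ng, log(100), 1)
  counts <- sapply(seq_len(2 * nrep), function(i)
    rnbinom(ng, mu = mu, size = 1 / 0.04))
  dimnames(counts) <- list(sprintf("g%04d", seq_len(ng)),
                           sprintf("s%02d", seq_len(2 * nrep)))
  grp <- stats::setNames(rep(c("A", "B"), each = nrep), colnames(counts))
  de <- simple_de(counts, grp, c("A", "B"))
  rate <- mean(de$p_value < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / ng))
})
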