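#' Derive a per-stage random seed from the master seed
#'
#' Deterministic substream derivation: a polynomial hash of the stage
#' name is mixed with the master seed modulo 2^31 - 1, so adding stages
#' never perturbs the draws of existing ones.
#'
#' @param master_seed integer master seed.
#' @param stage_name character stage identifier.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage_name) {
  h <- 0
  for (ch in utf8ToInt(stage_name)) h <- (h * 31 + ch) %% 1000003
  as.integer(1 + (abs(as.numeric(master_seed)) * 7919 + h * 104729) %%
               (2^31 - 3))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# merge a parsed config file (preset + section overrides + gates) into
# a sim_config and a gate_config
load_run_config <- function(config, preset) {
  overrides <- list()
  gates <- gate_config()
  if (!is.null(config)) {
    raw <- if (is.character(config)) {
      if (!file.exists(config)) stop("config file not found: ", config)
      yaml::read_yaml(config)
    } else config
    if (!is.null(raw$gates)) {
      gates <- do.call(gate_config, raw$gates)
      raw$gates <- NULL
    }
    raw$preset <- NULL
    overrides <- raw
  }
  cfg <- do.call(sim_config, c(list(preset = preset), overrides))
  list(cfg = cfg, gates = gates)
}

#' Validate a pipeline configuration file without running it
#'
#' Parses the YAML configuration, applies it over the defaults, and
#' returns typed findings (level, field, message) covering range bounds,
#' layout invariants and gate threshold ordering. An empty list means
#' the configuration is valid.
#'
#' @param config_path path to a YAML configuration file.
#' @return list of findings as in [validate_sim_config()].
#' @export
validate_config <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path)
  raw <- yaml::read_yaml(config_path)
  findings <- list()
  gates_raw <- raw$gates
  if (!is.null(gates_raw)) {
    ok <- tryCatch({ do.call(gate_config, gates_raw); TRUE },
                   error = function(e) e$message)
    if (!isTRUE(ok))
      findings[[length(findings) + 1L]] <- list(
        level = "error", field = "gates", message = ok)
    raw$gates <- NULL
  }
  preset <- raw$preset
  raw$preset <- NULL
  base <- tryCatch(sim_config(preset), error = function(e) NULL)
  if (is.null(base)) {
    findings[[length(findings) + 1L]] <- list(
      level = "error", field = "preset",
      message = paste0("unknown preset '", preset, "'"))
    return(findings)
  }
  merged <- tryCatch(apply_overrides(unclass(base), raw),
                     error = function(e) e$message)
  if (is.character(merged)) {
    findings[[length(findings) + 1L]] <- list(
      level = "error", field = "(overrides)", message = merged)
    return(findings)
  }
  c(findings, validate_sim_config(merged))
}

#' Run the full synthetic study end to end
#'
#' Simulates and analyzes the complete experiment: wild-type imaging
#' stacks through the morphometry chain; wild-type and Alport cytometry
#' through gating, threshold estimation and classification; a planted
#' expression experiment through the stand-in DE test, Venn
#' decomposition, inverse-regulation and sole-expression calls; and
#' over-representation of the AS-bright up-regulated set against a
#' seeded synthetic annotation. Writes TSV outputs, a plain-text report
#' and a YAML run manifest (config snapshot, per-stage seeds, file
#' digests, package version, timestamp) under `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds derive from it via
#'   [stage_seed()], so reruns with the same seed and configuration are
#'   bit-identical.
#' @param config optional YAML file (or pre-parsed list) of overrides
#'   applied on top of both presets; may carry a `gates:` section.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- load_run_config(config, "WT")
  as_ <- load_run_config(config, "AS")
  seeds <- vapply(c("imaging", "facs_wt", "facs_as", "expression",
                    "annotation"),
                  function(s) stage_seed(seed, s), integer(1))
  files <- character(0)
  keep <- function(path) { files <<- c(files, path); path }

  # --- imaging morphometry (wild type) ---
  sim_img <- gen_image_stack(wt$cfg, seeds[["imaging"]])
  morph <- morphometry_pipeline(sim_img$stacks, sim_img$rois,
                                sim_img$pixel_size_um, sim_img$z_step_um)
  keep(write_tsv(morph$compositions, file.path(out_dir, "morph_composition.tsv")))
  keep(write_tsv(morph$calls, file.path(out_dir, "morph_calls.tsv")))

  # --- cytometry (both genotypes) ---
  facs <- list(
    WT = cytometry_pipeline(
      gen_facs_events(wt$cfg, seeds[["facs_wt"]])$events, wt$gates),
    AS = cytometry_pipeline(
      gen_facs_events(as_$cfg, seeds[["facs_as"]])$events, as_$gates))
  facs_stats <- do.call(rbind, lapply(names(facs), function(nm)
    cbind(genotype = nm, facs[[nm]]$stats)))
  keep(write_tsv(facs_stats, file.path(out_dir, "facs_composition.tsv")))

  # --- expression set algebra ---
  ex <- gen_expression(wt$cfg, seeds[["expression"]])
  contrasts <- list(A = c("WT_bright", "WT_dim"),
                    B = c("AS_bright", "AS_dim"),
                    C = c("AS_bright", "WT_bright"),
                    D = c("AS_dim", "WT_dim"))
  dge <- lapply(contrasts, function(ct)
    simple_de(ex$counts, ex$sample_groups, ct))
  for (nm in names(dge))
    keep(write_tsv(dge[[nm]], file.path(out_dir,
                                        paste0("dge_", nm, ".tsv"))))
  pol <- cutoff_policy()
  venn <- venn_decompose(apply_cutoffs(dge$C, pol), apply_cutoffs(dge$D, pol))
  keep(write_tsv(data.frame(region = names(venn$counts),
                            n = as.integer(venn$counts)),
                 file.path(out_dir, "venn_C_vs_D.tsv")))
  inverse <- find_inverse_regulated(dge$A, dge$B)
  keep(write_tsv(inverse, file.path(out_dir, "inverse_regulated.tsv")))
  rpkm <- cpm_rpkm(ex$counts, ex$lengths)$rpkm
  sole <- solely_expressed(rpkm, ex$sample_groups, c("WT_dim", "WT_bright"))
  keep(write_tsv(data.frame(
    gene_id = c(sole$x_only, sole$y_only),
    side = rep(c("dim_only", "bright_only"),
               c(length(sole$x_only), length(sole$y_only)))),
    file.path(out_dir, "solely_expressed.tsv")))

  # --- over-representation against a seeded synthetic annotation ---
  set.seed(seeds[["annotation"]])
  universe <- rownames(ex$counts)
  ann <- split(universe, sample(sprintf("TERM%03d", 1:40),
                                length(universe), replace = TRUE))
  hits <- venn$genes$up_X_only
  enr <- if (length(hits)) enrich(hits, universe, ann) else
    enrich(character(0), universe, ann)
  keep(write_tsv(enr, file.path(out_dir, "enrichment.tsv")))

  # --- report ---
  report <- c(
    "GEC subpopulation synthetic study report",
    "========================================",
    "",
    sprintf("Imaging morphometry (WT): pooled dim %.1f%% / bright %.1f%% over %d cells in %d glomeruli",
            morph$pooled_pct_dim, morph$pooled_pct_bright,
            sum(morph$compositions$n_dim + morph$compositions$n_bright),
            nrow(morph$compositions)),
    if (!is.null(morph$welch))
      sprintf("Welch t (bright vs dim per-glomerulus means): t = %.2f, df = %.1f, p = %.3g",
              morph$welch$t, morph$welch$df, morph$welch$p) else
      "Welch t: not computed",
    "",
    sprintf("FACS composition WT: dim %.1f%% / bright %.1f%% of positives (positives %.1f%% of gated)",
            facs$WT$stats$pct_dim_of_positive,
            facs$WT$stats$pct_bright_of_positive,
            facs$WT$stats$pct_positive_of_total),
    sprintf("FACS composition AS: dim %.1f%% / bright %.1f%% of positives (positives %.1f%% of gated)",
            facs$AS$stats$pct_dim_of_positive,
            facs$AS$stats$pct_bright_of_positive,
            facs$AS$stats$pct_positive_of_total),
    "",
    "Venn regions (AS-over-WT bright vs dim contrasts):",
    paste(sprintf("  %-12s %d", names(venn$counts), venn$counts),
          collapse = "\n"),
    "",
    sprintf("Inversely regulated genes (WT vs AS bright-over-dim): %d",
            nrow(inverse)),
    sprintf("Solely expressed (WT): dim-only %d, bright-only %d",
            length(sole$x_only), length(sole$y_only)),
    "",
    sprintf("Top enrichment terms tested: %d (smallest adj. p = %.3g)",
            nrow(enr), if (nrow(enr)) min(enr$adj_p) else NA))
  report_path <- file.path(out_dir, "report.txt")
  writeLines(report, report_path)
  keep(report_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gecpop")),
    master_seed = as.integer(seed),
    stage_seeds = as.list(seeds),
    config = list(WT = unclass(wt$cfg), AS = unclass(as_$cfg)),
    files = as.list(stats::setNames(
      unname(tools::md5sum(sort(files))), basename(sort(files)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
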