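#' Default configuration of the coverage-reduction pipeline
#'
#' Returns the full configuration list used by [run_pipeline()], with
#' the standard study conditions: the calibration threshold grid, the
#' 10,000-1,000,000 read subsampling ladder with five replicates and
#' 99% confidence limits, the 10-read / 0.1% detection rule, a mock
#' community simulated at its full sequencing depth with the default
#' sister-species leak, and a ten-sample synthetic panel spanning the
#' richness range of real coverage-reduction panels (4-138 species).
#'
#' @param ... named overrides, merged (recursively for the nested
#'   sections) over the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1234,
    thresholds = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
    min_reads = 10,
    min_frac = 0.1,
    depths = c(1e4, 2.5e4, 5e4, 1e5, 2.5e5, 5e5, 1e6),
    n_replicates = 5,
    ci_level = 0.99,
    mock = list(depth = 4969245, leak_p = 0.007,
                unclassified_rate = 0),
    study = list(panel = "packaged", pool_size = 300, sigma = 1),
    betadiv = list(ordination = "nmds", dims = 2, n_perm = 999),
    recovery = list(read_length = 125, n_genes = 100,
                    gene_length = 1000, reduced_depth = 1e6))
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

.load_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("config must be a file path or a named list", call. = FALSE)
  do.call(default_config, config)
}

.validate_config <- function(cfg) {
  if (!is_count(cfg$mock$depth) || cfg$mock$depth <= 0)
    stop("config: mock$depth must be a positive integer", call. = FALSE)
  bad <- cfg$depths[cfg$depths > cfg$mock$depth]
  if (length(bad))
    stop("config: subsampling depth ",
         paste(format(bad, big.mark = ",", scientific = FALSE),
               collapse = ", "),
         " exceeds the simulated mock depth of ",
         format(cfg$mock$depth, big.mark = ",", scientific = FALSE),
         call. = FALSE)
  if (cfg$n_replicates < 2)
    stop("config: n_replicates must be >= 2", call. = FALSE)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("config: ci_level must be in (0, 1)", call. = FALSE)
  if (anyDuplicated(cfg$thresholds))
    stop("config: duplicate thresholds", call. = FALSE)
  if (!cfg$betadiv$ordination %in% c("nmds", "pcoa"))
    stop("config: betadiv$ordination must be 'nmds' or 'pcoa'",
         call. = FALSE)
  invisible(cfg)
}

# The synthetic analogue of the real ten-sample panel: richness and
# depth targets taken from the packaged study-panel summary table.
.packaged_panel <- function(cfg) {
  t2 <- load_fixture("table2")
  study_design(t2$sample, richness = t2$n_species, depth = t2$n_reads,
               sigma = cfg$study$sigma)
}

#' Run the end-to-end coverage-reduction study
#'
#' Orchestrates every stage on synthetic and packaged inputs:
#' detection-threshold calibration on the packaged mock benchmark;
#' simulation of the mock community and of a multi-sample panel;
#' replicated subsampling; expected-versus-observed and
#' full-versus-reduced abundance correlations; alpha-diversity depth
#' curves; beta-diversity Procrustes stability; and gene-recovery
#' summaries. Each stage writes a tab-delimited table into `out_dir`,
#' together with a manifest of every parameter and seed (sufficient to
#' reproduce the run) and a log with per-stage timings.
#'
#' @param config `NULL` for defaults, a named list of overrides, or the
#'   path to a YAML file of overrides (see [default_config()]).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages?
#' @return `out_dir`, invisibly.
#' @seealso [report_tables()]
#' @export
run_pipeline <- function(config = NULL, out_dir, quiet = FALSE) {
  cfg <- .validate_config(.load_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("stage %-12s done in %.1fs", name,
                proc.time()[["elapsed"]] - t0))
    res
  }
  seeds <- derive_seeds(cfg$seed, 6)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## 1. threshold calibration on the packaged mock benchmark.
  ## The abundance table censors values below 0.1%, so only thresholds
  ## >= 0.1% are recomputable from it; the full grid is scored from the
  ## packaged confusion counts, with F1 recomputed per row, and the
  ## recomputable rows are cross-checked against the abundance column.
  sweep <- stage("calibrate", {
    t1 <- load_fixture("table1")
    sw <- sweep_from_confusion(t1$threshold, t1$tp, t1$fp, t1$fn)
    write_sweep_tsv(sw, file.path(out_dir, "threshold_sweep.tsv"))
    obs <- abundance_vector(fixture_column("nt"), basis = "classified",
                            sample_id = "mock_nt")
    recomp <- cfg$thresholds[cfg$thresholds >= 0.1]
    if (length(recomp)) {
      sw_nt <- threshold_sweep(obs, mock_spec(), recomp)
      write_sweep_tsv(sw_nt,
                      file.path(out_dir, "threshold_sweep_nt.tsv"))
      chk <- merge(as.data.frame(sw), as.data.frame(sw_nt),
                   by = "threshold")
      if (nrow(chk) && any(chk$tp.x != chk$tp.y |
                             chk$fp.x != chk$fp.y))
        warning("abundance-column sweep disagrees with the packaged ",
                "confusion counts", call. = FALSE)
    }
    sw
  })
  best <- best_threshold(sweep)
  say("selected detection threshold: ", best, "%")

  ## 2. simulate the mock community at full depth
  mock_prof <- stage("simulate", {
    model <- default_misclass_model(
      mock_spec()$species, leak_p = cfg$mock$leak_p,
      unclassified_rate = cfg$mock$unclassified_rate)
    p <- simulate_profile(mock_spec(), model, depth = cfg$mock$depth,
                          seed = seeds[[1]], sample_id = "mock_sim")
    write_bracken_tsv(p, file.path(out_dir, "mock_profile.tsv"))
    p
  })

  ## 3. expected vs observed abundance across the depth ladder
  stage("abundance", {
    decl <- declared_abundances(mock_spec())
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        depth = cfg$depths)
    cell_seeds <- derive_seeds(seeds[[2]], nrow(grid))
    ab_rows <- list(); cor_rows <- list()
    for (i in seq_len(nrow(grid))) {
      sub <- subsample_profile(mock_prof, grid$depth[i],
                               seed = cell_seeds[[i]])
      obs <- relative_abundances(sub, basis = "classified")
      species <- union(names(decl), names(obs))
      ab_rows[[i]] <- data.frame(
        depth = grid$depth[i], replicate = grid$replicate[i],
        species = species,
        expected = ifelse(species %in% names(decl),
                          unclass(decl)[species], 0),
        observed = ifelse(species %in% names(obs),
                          unclass(obs)[species], 0))
      cor_rows[[i]] <- data.frame(
        comparison = "expected_vs_observed", sample = "mock_sim",
        depth = grid$depth[i], replicate = grid$replicate[i],
        method = "pearson",
        correlation = abundance_correlation(decl, obs,
                                            method = "pearson"))
    }
    tsv(do.call(rbind, ab_rows), "fig3_abundance.tsv")
    .pipeline_cache$expected_cor <- do.call(rbind, cor_rows)
  })

  ## 4. synthetic multi-sample panel: diversity + full-vs-reduced
  study_profs <- stage("study", {
    design <- .packaged_panel(cfg)
    simulate_study(design, seed = seeds[[3]],
                   pool_size = cfg$study$pool_size)
  })
  stage("diversity", {
    div_rows <- list(); cor_rows <- list(); k <- 0L
    for (prof in study_profs) {
      full_ab <- relative_abundances(prof, basis = "classified")
      depths_ok <- cfg$depths[cfg$depths <= total_reads(prof)]
      grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          depth = depths_ok)
      cell_seeds <- derive_seeds(seeds[[4]] + k, nrow(grid))
      for (i in seq_len(nrow(grid))) {
        sub <- subsample_profile(prof, grid$depth[i],
                                 seed = cell_seeds[[i]])
        div <- profile_diversity(sub, cfg$min_reads, cfg$min_frac)
        div_rows[[length(div_rows) + 1L]] <- data.frame(
          sample = prof$sample_id, depth = grid$depth[i],
          replicate = grid$replicate[i],
          observed_taxa = div[["observed_taxa"]],
          shannon = div[["shannon"]], pielou = div[["pielou"]])
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          comparison = "full_vs_reduced", sample = prof$sample_id,
          depth = grid$depth[i], replicate = grid$replicate[i],
          method = "spearman",
          correlation = abundance_correlation(
            full_ab, relative_abundances(sub, basis = "classified"),
            method = "spearman"))
      }
      k <- k + 1L
    }
    tsv(do.call(rbind, div_rows), "fig5_diversity.tsv")
    tsv(rbind(.pipeline_cache$expected_cor, do.call(rbind, cor_rows)),
        "correlation.tsv")
  })

  ## 5. beta-diversity stability (Procrustes between full and reduced)
  stage("betadiv", {
    ord_full <- ordinate(bray_curtis(study_profs,
                                     cfg$min_reads, cfg$min_frac),
                         method = cfg$betadiv$ordination,
                         dims = cfg$betadiv$dims, seed = seeds[[5]])
    rows <- list()
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        depth = cfg$depths)
    cell_seeds <- derive_seeds(seeds[[5]], 2L * nrow(grid))
    for (i in seq_len(nrow(grid))) {
      dep <- grid$depth[i]
      keep <- vapply(study_profs,
                     function(p) total_reads(p) >= dep, logical(1))
      if (sum(keep) < cfg$betadiv$dims + 2) next
      reduced <- lapply(study_profs[keep], subsample_profile,
                        depth = dep, seed = cell_seeds[[i]])
      ord_red <- tryCatch(
        ordinate(bray_curtis(reduced, cfg$min_reads, cfg$min_frac),
                 method = cfg$betadiv$ordination,
                 dims = cfg$betadiv$dims,
                 seed = cell_seeds[[nrow(grid) + i]]),
        error = function(e) NULL)
      if (is.null(ord_red)) next
      full_sub <- structure(list(
        coordinates = ord_full$coordinates[names(study_profs)[keep], ,
                                           drop = FALSE],
        method = ord_full$method, stress = ord_full$stress),
        class = "ordination")
      pt <- protest(full_sub, ord_red, n_perm = cfg$betadiv$n_perm,
                    seed = cell_seeds[[nrow(grid) + i]])
      rows[[length(rows) + 1L]] <- data.frame(
        depth = dep, replicate = grid$replicate[i],
        n_samples = sum(keep), correlation = pt$correlation,
        p_value = pt$p_value)
    }
    tsv(do.call(rbind, rows), "fig6_procrustes.tsv")
  })

  ## 6. gene recovery at full vs reduced depth
  stage("recovery", {
    gs <- mock_genome_sizes()
    rec <- cfg$recovery
    full <- simulate_recovery(mock_spec(), cfg$mock$depth, gs,
                              rec$read_length, rec$n_genes,
                              rec$gene_length, seed = seeds[[6]])
    red <- simulate_recovery(mock_spec(), rec$reduced_depth, gs,
                             rec$read_length, rec$n_genes,
                             rec$gene_length, seed = seeds[[6]])
    both <- rbind(cbind(depth_label = "full",
                        depth = cfg$mock$depth, full),
                  cbind(depth_label = "reduced",
                        depth = rec$reduced_depth, red))
    both$reconstructed <- both$complete + both$fragmented
    both$declared <- mock_spec()$declared[both$species]
    tsv(both, "fig7_recovery.tsv")
  })

  ## manifest: everything needed to reproduce the run
  manifest <- c(
    tool = paste0("shallowmeta ",
                  as.character(utils::packageVersion("shallowmeta"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    thresholds = paste(cfg$thresholds, collapse = ","),
    min_reads = cfg$min_reads, min_frac = cfg$min_frac,
    depths = paste(format(cfg$depths, scientific = FALSE,
                          trim = TRUE), collapse = ","),
    n_replicates = cfg$n_replicates, ci_level = cfg$ci_level,
    best_threshold = best,
    mock_depth = cfg$mock$depth, mock_leak_p = cfg$mock$leak_p,
    mock_unclassified_rate = cfg$mock$unclassified_rate,
    study_pool_size = cfg$study$pool_size,
    study_sigma = cfg$study$sigma,
    betadiv_ordination = cfg$betadiv$ordination,
    betadiv_dims = cfg$betadiv$dims,
    betadiv_n_perm = cfg$betadiv$n_perm,
    recovery_read_length = cfg$recovery$read_length,
    recovery_n_genes = cfg$recovery$n_genes,
    recovery_gene_length = cfg$recovery$gene_length,
    recovery_reduced_depth = cfg$recovery$reduced_depth)
  writeLines(paste0(names(manifest), "=", unname(manifest)),
             file.path(out_dir, "manifest.txt"))
  say("pipeline complete: ", out_dir)
  invisible(out_dir)
}

# scratch space for passing the expected-vs-observed correlations
# between the abundance and diversity stages of one run
.pipeline_cache <- new.env(parent = emptyenv())

#' Bundle per-figure summary tables from a pipeline run
#'
#' Reads the stage outputs of [run_pipeline()] and returns (and writes)
#' one tidy table per figure analogue: `fig3_correlation` (expected vs
#' observed, per depth and replicate), `fig5_diversity` (per sample,
#' depth and replicate), `fig6_procrustes` (per depth and replicate)
#' and `fig7_recovery` (per species and depth). Missing stage outputs
#' produce a warning and a partial report.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param write write `report_*.tsv` files back into `out_dir`?
#' @return Named list of data frames (invisibly those that exist).
#' @export
report_tables <- function(out_dir, write = TRUE) {
  stopifnot(dir.exists(out_dir))
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) {
      warning("missing stage output: ", f, call. = FALSE)
      return(NULL)
    }
    utils::read.delim(p, sep = "\t", stringsAsFactors = FALSE)
  }
  cors <- rd("correlation.tsv")
  out <- list(
    fig3_correlation = if (!is.null(cors))
      cors[cors$comparison == "expected_vs_observed", ],
    fig4_correlation = if (!is.null(cors))
      cors[cors$comparison == "full_vs_reduced", ],
    fig5_diversity = rd("fig5_diversity.tsv"),
    fig6_procrustes = rd("fig6_procrustes.tsv"),
    fig7_recovery = rd("fig7_recovery.tsv"))
  out <- out[!vapply(out, is.null, logical(1))]
  if (write)
    for (nm in names(out))
      utils::write.table(out[[nm]],
                         file.path(out_dir,
                                   paste0("report_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
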