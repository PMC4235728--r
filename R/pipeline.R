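#' Configuration for a full two-method comparison run
#'
#' Exactly one of `simulate = TRUE` (a synthetic dataset is generated from
#' `spec`) or a triple of input paths (`peaks_path`, `pyro_path`,
#' `metadata_path`) must be supplied.
#'
#' @param simulate generate the inputs with [simulate_dataset()].
#' @param spec [community_spec()] used when simulating.
#' @param peaks_path,pyro_path,metadata_path input files for a real run.
#' @param params [filter_params()] for ARISA processing.
#' @param scheme [binning_scheme()].
#' @param replicate_threshold replicate QC similarity threshold.
#' @param min_count rare-OTU threshold for the sequencing table (default 3:
#'   singletons and doubletons removed).
#' @param n_perm_anosim,n_perm_procrustes,n_perm_mantel permutation counts.
#' @param seed master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, spec = community_spec(),
                       peaks_path = NULL, pyro_path = NULL, metadata_path = NULL,
                       params = filter_params(), scheme = binning_scheme(),
                       replicate_threshold = 0.8, min_count = 3,
                       n_perm_anosim = 9999, n_perm_procrustes = 1000,
                       n_perm_mantel = 999, seed = 17) {
  have_paths <- !is.null(peaks_path) || !is.null(pyro_path) || !is.null(metadata_path)
  if (simulate && have_paths) config_error("supply either simulate = TRUE or input paths, not both")
  if (!simulate && (is.null(peaks_path) || is.null(pyro_path) || is.null(metadata_path))) {
    config_error("a real run needs peaks_path, pyro_path and metadata_path")
  }
  structure(list(simulate = simulate, spec = spec, peaks_path = peaks_path,
                 pyro_path = pyro_path, metadata_path = metadata_path,
                 params = params, scheme = scheme,
                 replicate_threshold = replicate_threshold,
                 min_count = min_count, n_perm_anosim = n_perm_anosim,
                 n_perm_procrustes = n_perm_procrustes,
                 n_perm_mantel = n_perm_mantel, seed = seed),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stage_error(stage, conditionMessage(e))
  })
}

#' Run the full ARISA vs sequencing comparison
#'
#' Executes the stages in fixed order: ingest (or simulate), ARISA
#' processing, rare-OTU removal, alpha diversity with pairwise group t-tests,
#' Bray-Curtis distance matrices, within-group similarity with between-method
#' tests, global and pairwise ANOSIM, 3-axis PCoA for both methods,
#' Procrustes with Monte-Carlo significance, and the similarity-vector
#' correlation. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @return A `comparison_report` list (see [render_report()]).
#' @export
run_comparison <- function(config = run_config()) {
  if (config$simulate) {
    sim <- run_stage("simulate", simulate_dataset(config$spec, seed = config$seed))
    peaks <- sim$peaks
    pyro_raw <- sim$pyro
    meta <- sim$metadata
  } else {
    peaks <- run_stage("ingest", read_peak_table(config$peaks_path))
    pyro_raw <- run_stage("ingest", read_otu_table(config$pyro_path, "read_count"))
    meta <- run_stage("ingest", read_metadata(config$metadata_path))
  }
  arisa <- run_stage("process_arisa",
                     process_arisa(peaks, config$params, config$scheme,
                                   config$replicate_threshold))
  pyro <- run_stage("tables", remove_rare_otus(pyro_raw, config$min_count))
  run_stage("tables", groups_for(meta, rownames(pyro)))
  tables <- list(arisa = arisa$otu_table, pyro = pyro)

  alpha <- run_stage("alpha", lapply(tables, function(t) {
    obs <- observed_otus(t, meta)
    h <- shannon(t)
    grp <- groups_for(meta, rownames(t))
    per_sample <- data.frame(sample_id = rownames(t), group = grp,
                             observed_otus = obs$per_sample, shannon_h = h)
    rownames(per_sample) <- NULL
    agg <- do.call(rbind, lapply(unique(grp), function(g) {
      i <- grp == g
      data.frame(group = g, n = sum(i),
                 total_otus = obs$per_group[[g]],
                 mean_otus = mean(obs$per_sample[i]), sd_otus = stats::sd(obs$per_sample[i]),
                 mean_shannon = mean(h[i]), sd_shannon = stats::sd(h[i]))
    }))
    pairs <- utils::combn(unique(grp), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- grp == pairs[1, k]; j <- grp == pairs[2, k]
      t_obs <- welch_t_test(obs$per_sample[i], obs$per_sample[j])
      t_h <- welch_t_test(h[i], h[j])
      data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                 p_otus = t_obs$p, p_shannon = t_h$p)
    }))
    tests$p_otus_bonferroni <- bonferroni(tests$p_otus, nrow(tests))
    tests$p_shannon_bonferroni <- bonferroni(tests$p_shannon, nrow(tests))
    list(per_sample = per_sample, per_group = agg, group_tests = tests)
  }))

  dists <- run_stage("beta", lapply(tables, distance_matrix))
  # align the two matrices on the common sample set, same order
  common <- intersect(rownames(dists$arisa), rownames(dists$pyro))
  dists <- run_stage("beta", lapply(dists, function(d) {
    dist_matrix(unclass(d)[common, common], metric = attr(d, "metric"))
  }))

  within_sim <- run_stage("beta", lapply(dists, within_group_similarity, meta = meta))
  method_sim_test <- run_stage("beta",
    compare_within_group_similarity(dists$arisa, dists$pyro, meta,
                                    labels = c("arisa", "pyro")))

  anosim_res <- run_stage("anosim", lapply(seq_along(dists), function(i) {
    d <- dists[[i]]
    list(global = anosim(d, meta, config$n_perm_anosim, seed = config$seed + 10L * i),
         pairwise = pairwise_anosim(d, meta, config$n_perm_anosim,
                                    seed = config$seed + 100L * i))
  }))
  names(anosim_res) <- names(dists)

  ords <- run_stage("pcoa", lapply(dists, pcoa, n_axes = 3))
  proc <- run_stage("procrustes",
                    procrustes_monte_carlo(ords$pyro, ords$arisa, n_axes = 3,
                                           n_perm = config$n_perm_procrustes,
                                           seed = config$seed + 7L))
  corr <- run_stage("correlation",
                    correlate_similarity_vectors(dists$arisa, dists$pyro,
                                                 n_perm = config$n_perm_mantel,
                                                 seed = config$seed + 11L))

  structure(list(
    schema_version = "1.0",
    config = list(seed = config$seed, simulate = config$simulate,
                  min_rfu = config$params$min_rfu,
                  min_relative_intensity = config$params$min_relative_intensity,
                  replicate_threshold = config$replicate_threshold,
                  min_count = config$min_count,
                  n_perm_anosim = config$n_perm_anosim,
                  n_perm_procrustes = config$n_perm_procrustes,
                  n_perm_mantel = config$n_perm_mantel,
                  n_bins = n_bins(config$scheme)),
    n_samples = length(common),
    groups = unique(groups_for(meta, common)),
    qc = arisa$qc,
    attrition = arisa$attrition,
    alpha = alpha,
    within_group_similarity = within_sim,
    method_similarity_test = method_sim_test,
    anosim = anosim_res,
    correlation = corr,
    pcoa = ords,
    procrustes = list(m_squared = proc$m_squared, p = proc$p,
                      n_permutations = proc$n_permutations),
    distances = dists,
    tables = tables,
    metadata = meta
  ), class = "comparison_report")
}

# strip heavyweight members down to a JSON-serializable core
report_core <- function(report) {
  list(
    schema_version = report$schema_version,
    config = report$config,
    n_samples = report$n_samples,
    groups = report$groups,
    qc = report$qc,
    attrition = report$attrition,
    alpha = lapply(report$alpha, function(a) a[c("per_group", "group_tests")]),
    within_group_similarity = report$within_group_similarity,
    method_similarity_test = report$method_similarity_test,
    anosim = lapply(report$anosim, function(a) {
      list(global = a$global[c("R", "p", "n_permutations", "exhaustive")],
           pairwise = a$pairwise)
    }),
    correlation = report$correlation,
    procrustes = report$procrustes
  )
}

#' Render a comparison report to disk
#'
#' Writes `report.json` (machine-readable core), the per-method tables as
#' TSV, PCoA coordinates, and static PCoA / Procrustes scatter plots (PNG).
#' Regenerating from the same config yields byte-identical JSON/TSV output;
#' the plots are conveniences.
#'
#' @param report a `comparison_report` from [run_comparison()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort_arisacomp(paste0("cannot write to directory: ", out_dir), "arisacomp_io_error")
  }
  files <- character(0)
  w <- function(name, fun) {
    path <- file.path(out_dir, name)
    fun(path)
    files <<- c(files, path)
  }
  w("report.json", function(p) {
    jsonlite::write_json(report_core(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  })
  for (m in names(report$alpha)) {
    a <- report$alpha[[m]]
    w(sprintf("alpha_%s_per_sample.tsv", m), function(p)
      utils::write.table(a$per_sample, p, sep = "\t", quote = FALSE, row.names = FALSE))
    w(sprintf("alpha_%s_per_group.tsv", m), function(p)
      utils::write.table(a$per_group, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  for (m in names(report$anosim)) {
    tab <- anosim_table(report$anosim[[m]]$pairwise, group_order = rev(report$groups))
    w(sprintf("anosim_%s.tsv", m), function(p)
      utils::write.table(data.frame(group = rownames(tab), tab, check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  for (m in names(report$distances)) {
    w(sprintf("distances_%s.tsv", m), function(p)
      write_distance_matrix(report$distances[[m]], p))
    w(sprintf("pcoa_%s.tsv", m), function(p)
      write_ordination(report$pcoa[[m]], p))
  }
  w("qc.tsv", function(p)
    utils::write.table(report$qc, p, sep = "\t", quote = FALSE, row.names = FALSE))
  # plots: PCoA per method, and the Procrustes superimposition with one
  # segment per sample connecting the two methods
  grp <- groups_for(report$metadata, rownames(report$distances[[1]]))
  cols <- grDevices::hcl.colors(length(unique(grp)), "Dark 3")[factor(grp, levels = unique(grp))]
  for (m in names(report$pcoa)) {
    w(sprintf("pcoa_%s.png", m), function(p) {
      grDevices::png(p, width = 800, height = 700)
      xy <- report$pcoa[[m]]$coordinates
      graphics::plot(xy[, 1], xy[, 2], col = cols, pch = 19,
                     xlab = "PCo1", ylab = "PCo2",
                     main = sprintf("PCoA (Bray-Curtis), %s", m))
      graphics::legend("topright", legend = unique(grp), pch = 19,
                       col = grDevices::hcl.colors(length(unique(grp)), "Dark 3"))
      grDevices::dev.off()
    })
  }
  w("procrustes.png", function(p) {
    fit <- procrustes_fit(report$pcoa$pyro, report$pcoa$arisa, n_axes = 3)
    yrot <- fit$Y_scaled %*% fit$rotation
    grDevices::png(p, width = 800, height = 700)
    graphics::plot(rbind(fit$X_scaled[, 1:2], yrot[, 1:2]), type = "n",
                   xlab = "dim 1", ylab = "dim 2",
                   main = sprintf("Procrustes superimposition (M^2 = %.3f)",
                                  report$procrustes$m_squared))
    graphics::segments(fit$X_scaled[, 1], fit$X_scaled[, 2],
                       yrot[, 1], yrot[, 2], col = "grey50")
    graphics::points(fit$X_scaled[, 1], fit$X_scaled[, 2], col = "orange", pch = 19)
    graphics::points(yrot[, 1], yrot[, 2], col = "black", pch = 19)
    grDevices::dev.off()
  })
  invisible(files)
}
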