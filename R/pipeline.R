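## End-to-end pipeline runner: chains the phantom generators and analysis
## stages per a plain-text (YAML) configuration and writes a machine-
## readable JSON report with per-stage parameters and output checksums.

#' Run the full connectome pipeline from a configuration
#'
#' Executes, depending on \code{pipeline:} in the configuration, either the
#' functional chain (simulate cohort, group ICA, noise screening, component
#' correlation, hierarchical clustering, edge-wise group comparison,
#' seed-based map) or the structural chain (simulate diffusion phantoms,
#' tensor fit, tractography, connectome, graph metrics, voxel-wise FA group
#' comparison). Every stage logs its parameters; all written TSV/JSON
#' outputs are checksummed into the report, so a rerun with the same
#' configuration and seed is byte-identical.
#'
#' Bundled demo configurations:
#' \code{system.file("extdata", "demo_functional.yaml", package = "mconn")}
#' and \code{system.file("extdata", "demo_structural.yaml", package = "mconn")}.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if missing); overrides
#'   \code{out:} in the configuration.
#' @param seed integer seed; overrides \code{seed:} in the configuration.
#' @param verbose print stage progress.
#' @return The report (named list), invisibly; also written to
#'   \code{report.json} in the output directory.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out %||% stopf("no output directory given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kind <- config$pipeline %||% stopf("configuration lacks a 'pipeline' field")
  report <- list(pipeline = kind, seed = seed, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, params, fn) {
    say("stage %s", name)
    res <- tryCatch(fn(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    report$stages[[name]] <<- c(list(params = params), res$log)
    res$value
  }
  if (kind == "functional") {
    cc <- config$cohort %||% list()
    n_per_group <- cc$n_per_group %||% 4L
    tpts <- cc$n_timepoints %||% 300L
    w_hypo <- cc$hypo_cluster1_loading %||% 0.3
    spec_a <- default_rsn_spec(n_timepoints = tpts)
    spec_b <- default_rsn_spec(n_timepoints = tpts,
                               cluster_loading = c(`1` = w_hypo, `2` = 0.6,
                                                   `3` = 0.6, `4` = 0.6))
    cohort <- stage("simulate", list(n_per_group = n_per_group,
                                     n_timepoints = tpts,
                                     hypo_cluster1_loading = w_hypo), function() {
      co <- simulate_cohort(spec_a, spec_b, n_per_group, seed = seed)
      list(value = co, log = list(n_subjects = length(co$images)))
    })
    mask <- cohort$truth$mask
    cs <- stage("ica", list(n_components = config$ica$n_components %||% 12L),
                function() {
      cm <- concatenate_temporal(cohort$images, mask)
      cs <- group_ica(cm, n_components = config$ica$n_components %||% 12L,
                      seed = substream_seed(seed, 2L, 20L))
      list(value = cs, log = list(n_iter = cs$n_iter))
    })
    cs <- stage("classify", list(), function() {
      cs2 <- classify_noise(cs, mask)
      list(value = cs2, log = list(n_noise = sum(cs2$noise_flags)))
    })
    kept <- subset_components(cs, !cs$noise_flags)
    zs <- lapply(component_correlation(kept$timecourses), fisher_z)
    gz <- group_z(lapply(kept$timecourses, stats::cor))
    cl <- stage("cluster", list(k = config$cluster$k %||% 4L), function() {
      ca <- cluster_components(gz, k = config$cluster$k %||% 4L)
      f <- file.path(out_dir, "cluster_assignment.tsv")
      utils::write.table(data.frame(component = seq_along(ca$labels),
                                    cluster = ca$labels),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = ca, log = list(sizes = as.integer(table(ca$labels)),
                                  files = md5_of_files(f)))
    })
    cmp <- stage("compare", list(alpha = config$compare$alpha %||% 0.05,
                                 test = config$compare$test %||% "t"), function() {
      ec <- group_difference_matrix(zs, cohort$group,
                                    alpha = config$compare$alpha %||% 0.05,
                                    method = config$compare$test %||% "t")
      f1 <- file.path(out_dir, "group_difference_z.tsv")
      f2 <- file.path(out_dir, "rejected_edges.tsv")
      write_matrix_tsv(ec$delta, f1)
      utils::write.table(ec$edges[ec$edges$rejected, ], f2, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(value = ec, log = list(n_rejected = sum(ec$edges$rejected),
                                  files = md5_of_files(c(f1, f2))))
    })
    zmap <- stage("seedmap", list(component = config$seedmap$component %||% 1L,
                                  concatenate = TRUE), function() {
      comp <- config$seedmap$component %||% 1L
      mvec <- cohort$truth$maps[comp, ]
      seed_mask <- array(mvec > 0.5 * max(mvec), dim(mask))
      zm <- seed_correlation_map(cohort$images[cohort$group == cohort$group[1]],
                                 seed_mask, mask, concatenate = TRUE)
      f <- file.path(out_dir, "seed_z_map.nii.gz")
      write_nifti(zm, f)
      list(value = zm, log = list(max_z = max(abs(zm))))
    })
    report$summary <- list(
      n_components = nrow(cs$maps),
      n_noise = sum(cs$noise_flags),
      cluster_sizes = as.integer(table(cl$labels)),
      n_rejected_edges = sum(cmp$edges$rejected),
      seedmap_max_z = max(abs(zmap)))
  } else if (kind == "structural") {
    sc <- config$structural %||% list()
    n_per_group <- sc$n_per_group %||% 3L
    lp_b <- sc$hypo_lambda_perp %||% 0.45e-3
    sim <- stage("simulate", list(n_per_group = n_per_group,
                                  hypo_lambda_perp = lp_b), function() {
      one <- simulate_dwi(default_dwi_spec(seed = substream_seed(seed, 1L, 1L),
                                           noise_sigma = 0))
      fa_a <- lapply(seq_len(n_per_group), function(i) {
        fit_tensor(simulate_dwi(default_dwi_spec(
          seed = substream_seed(seed, i, 2L), noise_sigma = 20))$dwi)$fa
      })
      fa_b <- lapply(seq_len(n_per_group), function(i) {
        fit_tensor(simulate_dwi(default_dwi_spec(
          seed = substream_seed(seed, i, 3L), noise_sigma = 20,
          lambda_perp = lp_b))$dwi)$fa
      })
      list(value = list(one = one, fa_a = fa_a, fa_b = fa_b),
           log = list(grid = dim(one$tensors$fa)))
    })
    tf <- stage("tensor_fit", list(), function() {
      tf <- fit_tensor(sim$one$dwi)
      list(value = tf, log = list(n_clamped = tf$n_clamped,
                                  mean_bundle_fa = mean(tf$fa[sim$one$truth$bundle_masks[[1]]])))
    })
    sl <- stage("track", list(n_samples = sc$n_samples %||% 10L), function() {
      seed_mask <- sim$one$truth$endpoint_labels == 1L
      sl <- track_probabilistic(tf, seed_mask,
                                params = list(n_samples_per_seed = sc$n_samples %||% 10L),
                                seed = substream_seed(seed, 4L, 4L))
      f <- file.path(out_dir, "streamlines.txt")
      write_streamlines(sl, f)
      list(value = sl, log = list(n_streamlines = length(sl$streamlines),
                                  files = md5_of_files(f)))
    })
    conn <- stage("connectome", list(), function() {
      cn <- build_connectome(sl, sim$one$truth$endpoint_labels)
      f <- file.path(out_dir, "connectome.tsv")
      write_matrix_tsv(cn$weights, f)
      list(value = cn, log = list(n_connected = sum(cn$counts) / 2,
                                  files = md5_of_files(f)))
    })
    gm <- stage("metrics", list(density = sc$density %||% 0.2), function() {
      labels <- make_parcellation(dim(tf$fa), sc$n_regions %||% 12L,
                                  seed = substream_seed(seed, 5L, 5L),
                                  mask = array(TRUE, dim(tf$fa)))
      cn <- build_connectome(sl, labels)
      g <- proportional_threshold(cn$weights, sc$density %||% 0.2)
      tab <- graph_metric_table(g)
      f <- file.path(out_dir, "graph_metrics.tsv")
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = tab, log = list(global_efficiency = attr(tab, "global_efficiency"),
                                   transitivity = attr(tab, "transitivity"),
                                   files = md5_of_files(f)))
    })
    fa_cmp <- stage("fa_compare", list(alpha = sc$alpha %||% 0.05), function() {
      res <- voxelwise_fa_compare(sim$fa_a, sim$fa_b,
                                  mask = array(TRUE, dim(tf$fa)),
                                  alpha = sc$alpha %||% 0.05)
      list(value = res, log = list(n_rejected = sum(res$rejected)))
    })
    report$summary <- list(
      mean_bundle_fa = mean(tf$fa[sim$one$truth$bundle_masks[[1]]]),
      mean_background_fa = mean(tf$fa[!sim$one$truth$bundle_masks[[1]]]),
      end_to_end_count = conn$counts[1, 2],
      global_efficiency = attr(gm, "global_efficiency"),
      transitivity = attr(gm, "transitivity"),
      fa_voxels_rejected = sum(fa_cmp$rejected))
  } else {
    stopf("unknown pipeline kind: %s", kind)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
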