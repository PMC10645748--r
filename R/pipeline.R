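.pipeline_stages <- c("fixtures", "clusters", "assembly", "sparklets",
                      "ephys")

.pipeline_keys <- c("stages", "seed", "out_dir", "fixtures", "clusters",
                    "assembly", "sparklets", "ephys")

#' Pipeline configuration
#'
#' Bundles stage selection, per-stage parameter blocks, a single global seed,
#' and the output directory. Unknown keys are rejected by name; the config
#' round-trips losslessly through JSON.
#'
#' @param stages character subset of `fixtures`, `clusters`, `assembly`,
#'   `sparklets`, `ephys` (in dependency order).
#' @param seed global integer seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @param out_dir output directory.
#' @param ... named per-stage parameter blocks (lists), e.g.
#'   `clusters = list(intensity_threshold = 50)`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(stages = .pipeline_stages, seed = 1L,
                            out_dir = tempfile("kvclust-run-"), ...) {
  extra <- list(...)
  cfg <- c(list(stages = stages, seed = as.integer(seed), out_dir = out_dir),
           extra)
  unknown <- setdiff(names(cfg), .pipeline_keys)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline config as JSON
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @return `path` (write) / a validated `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config,
          c(list(stages = raw$stages, seed = raw$seed, out_dir = raw$out_dir),
            raw[setdiff(names(raw), c("stages", "seed", "out_dir"))]))
}

.default_stage_params <- function(stage) {
  switch(stage,
    fixtures = list(n_clusters = 300L, mean_volume = 0.12,
                    intensity_per_um3 = 1e4),
    clusters = list(intensity_threshold = 60, membrane_area_um2 = 600,
                    binwidth = 0.02, macro_threshold_um3 = 0.06),
    assembly = list(p_nucleation = 1e-4, p_growth = 0.01, p_removal = 0.05,
                    grid_shape = c(128L, 128L), max_steps = 1500L),
    sparklets = list(n_channels = 3L, kappa_true = 0.4, open_prob = 0.1,
                     quantal_amplitude = 1, noise_sd = 0.2, duration = 20),
    ephys = list(fractions = c(1, 0.5, 0.1, 0.01)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order with per-stage seeds
#' derived from the global seed, writes every product under
#' `config$out_dir`, and records a manifest (parameters, seeds, output files
#' with MD5 hashes, stage timings) as `manifest.json`. Identical configs and
#' seeds give identical output hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(.pipeline_stages, config$stages)
  manifest <- list(seed = config$seed, stages = list(), outputs = list())
  products <- new.env(parent = emptyenv())

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    params <- utils::modifyList(.default_stage_params(stage),
                                config[[stage]] %||% list())
    sseed <- derive_seed(config$seed, stage)
    files <- switch(stage,
      fixtures = {
        spec <- cluster_spec(params$n_clusters, params$mean_volume,
                             seed = sseed)
        pop <- gen_cluster_population(spec)
        assign("pop_truth", pop, envir = products)
        rs <- render_spec(intensity_per_um3 = params$intensity_per_um3,
                          seed = sseed)
        stack <- render_image_stack(pop, rs)
        assign("stack", stack, envir = products)
        f1 <- file.path(out, "clusters_truth.csv")
        write_clusters(pop, f1)
        f2 <- file.path(out, "stack.tif")
        write_stack(stack, f2)
        c(f1, f2, paste0(f2, ".json"))
      },
      clusters = {
        stack <- if (exists("stack", products)) get("stack", products)
          else read_stack(file.path(out, "stack.tif"))
        cfg <- segmentation_config(params$intensity_threshold)
        pop <- segment_stack(stack, cfg)
        met <- cell_metrics(pop, params$membrane_area_um2)
        # the macro/micro boundary is a study-level constant (derived from
        # per-cell mean volumes), not recomputed from one cell's pooled
        # near-exponential volumes, whose sd ~ mean would push it negative
        cls <- classify_macro_micro(pop, params$macro_threshold_um3)
        f1 <- file.path(out, "clusters_segmented.csv")
        write_clusters(pop, f1)
        f2 <- file.path(out, "cell_metrics.json")
        jsonlite::write_json(c(unclass(met), cls), f2, auto_unbox = TRUE,
                             digits = NA)
        c(f1, f2)
      },
      assembly = {
        pars <- assembly_params(params$p_nucleation, params$p_growth,
                                params$p_removal,
                                grid_shape = params$grid_shape,
                                max_steps = params$max_steps, seed = sseed)
        res <- run_to_steady_state(pars)
        f1 <- file.path(out, "assembly_size_distribution.csv")
        write_size_distribution(res$distribution, f1)
        f1
      },
      sparklets = {
        spec <- sparklet_spec(params$n_channels, params$kappa_true,
                              params$open_prob,
                              quantal_amplitude = params$quantal_amplitude,
                              noise_sd = params$noise_sd,
                              duration = params$duration, seed = sseed)
        sim <- gen_sparklet_trace(spec)
        qc <- quantal_config(params$quantal_amplitude,
                             max_levels = params$n_channels)
        rec <- detect_and_idealize(sim$trace, qc)
        act <- compute_nps(rec)
        est <- estimate_kappa(rec, params$n_channels)
        f1 <- file.path(out, "sparklet_trace.csv")
        write_trace(sim$trace, f1)
        f2 <- file.path(out, "sparklet_site.json")
        jsonlite::write_json(list(nPs = act$nPs,
                                  activity_class = act$activity_class,
                                  kappa = est$kappa,
                                  open_prob = est$open_prob,
                                  kappa_true = params$kappa_true),
                             f2, auto_unbox = TRUE, digits = NA)
        c(f1, f2)
      },
      ephys = {
        rows <- do.call(rbind, lapply(c("male", "female"), function(sx) {
          ref <- myocyte_reference_iv(sx)
          do.call(rbind, lapply(params$fractions, function(f) {
            pr <- scale_current(ref, f)
            data.frame(sex = sx, fraction = f, voltage_mV = pr$voltage_mV,
                       reported_density = pr$reported_density)
          }))
        }))
        f1 <- file.path(out, "current_predictions.csv")
        write.csv(rows, f1, row.names = FALSE)
        f1
      })
    manifest$stages[[stage]] <-
      list(seed = sseed, params = params,
           elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    for (f in files)
      manifest$outputs[[basename(f)]] <- unname(tools::md5sum(f))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
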