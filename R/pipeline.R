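#' Run configuration for an end-to-end analysis
#'
#' @param inputs data frame with columns `path` (TIFF file) and `condition`
#'   (group label), one row per image.
#' @param spacing_um voxel spacing `(dz, dy, dx)` in micrometres applied to
#'   every input (spacing comes from configuration, not from TIFF tags).
#' @param seg_params a [segmentation_params()].
#' @param K number of concentric shells (default 24).
#' @param metric_mode distance metric for [distance_transform()].
#' @param ro_size layers per RO (default 4; must divide `K`).
#' @param alpha significance level (default 0.05).
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest (the core pipeline is
#'   deterministic; the seed governs any stochastic diagnostics).
#' @param write_masks also export label and shell masks as 16-bit TIFFs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, spacing_um = c(0.21, 0.05, 0.05),
                       seg_params = segmentation_params(), K = 24,
                       metric_mode = c("physical", "isotropic"), ro_size = 4,
                       alpha = 0.05, out_dir = "nucshells_out", seed = 1,
                       write_masks = FALSE) {
  metric_mode <- match.arg(metric_mode)
  stopifnot(is.data.frame(inputs), all(c("path", "condition") %in%
                                         names(inputs)))
  if (K < 1 || K %% ro_size != 0)
    ns_stop("need K >= 1 and ro_size dividing K", "validation_error")
  if (alpha <= 0 || alpha >= 1)
    ns_stop("alpha must be in (0, 1)", "validation_error")
  structure(list(inputs = inputs, spacing_um = spacing_um,
                 seg_params = seg_params, K = as.integer(K),
                 metric_mode = metric_mode, ro_size = as.integer(ro_size),
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed),
                 write_masks = isTRUE(write_masks)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Mirrors [run_config()]; keys `inputs` (list of `{path, condition}`),
#' `spacing_um`, `K`, `metric_mode`, `ro_size`, `alpha`, `out_dir`, `seed`,
#' `write_masks`, and a `segmentation` block with [segmentation_params()]
#' keys (`sigma_um`, `morph_ops` as a list of `{op, radius}`,
#' `min_volume_um3`, `connectivity`, `threshold_mode`, `n_bins`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  inputs <- do.call(rbind, lapply(y$inputs, function(i)
    data.frame(path = i$path, condition = i$condition,
               stringsAsFactors = FALSE)))
  sp <- y$segmentation %||% list()
  seg <- do.call(segmentation_params, sp[lengths(sp) > 0])
  args <- list(inputs = inputs, seg_params = seg)
  for (k in c("spacing_um", "K", "metric_mode", "ro_size", "alpha",
              "out_dir", "seed", "write_masks"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(args$spacing_um)) args$spacing_um <- as.numeric(args$spacing_um)
  do.call(run_config, args)
}

#' Run the full shell-profiling pipeline over an image set
#'
#' For every input image: segment nuclei ([segment_nuclei()]), compute the
#' distance transform, assign `K` shells, and profile the raw intensities.
#' Profiles from all images are pooled into the per-layer CSV; per-nucleus
#' RO values and group summaries go to the RO CSV; if exactly two
#' conditions each contribute at least two nuclei, per-layer and per-RO
#' two-group comparisons are written as well (otherwise the stats stage is
#' skipped with a logged reason). A JSON manifest captures the full
#' configuration, per-image nucleus counts and d_max values, and the
#' package version, so every output is reproducible from the manifest plus
#' the input TIFFs. Outputs are deterministic for deterministic configs.
#'
#' @param config a [run_config()].
#' @param images optional list of pre-loaded [volume_image()]s (bypasses
#'   TIFF reading; `config$inputs$path` is then used only as an identifier).
#' @return Invisibly, a list with `profiles`, `ro`, `comparisons` (possibly
#'   `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config, images = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  n_img <- nrow(config$inputs)
  profiles <- vector("list", n_img)
  img_log <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    img <- if (!is.null(images)) images[[i]]
           else load_stack(config$inputs$path[i], config$spacing_um,
                           config$inputs$condition[i])
    img$condition <- config$inputs$condition[i]
    labels <- segment_nuclei(img, config$seg_params)
    n_nuc <- max(labels$labels)
    if (n_nuc == 0L)
      ns_stop(sprintf("no nucleus survives segmentation in image '%s'",
                      img$source_id), "empty_result_error")
    dmap <- distance_transform(labels, config$metric_mode)
    shells <- assign_shells(dmap, labels, config$K)
    profiles[[i]] <- layer_profile(img, shells, labels)
    empty_layers <- sum(profiles[[i]]$voxel_count == 0)
    if (empty_layers > 0)
      message(sprintf("image '%s': %d empty (nucleus, layer) cells",
                      img$source_id, empty_layers))
    img_log[[i]] <- list(source_id = img$source_id,
                         condition = img$condition,
                         n_nuclei = n_nuc,
                         dmax = as.numeric(shells$per_nucleus_dmax),
                         empty_layer_cells = empty_layers)
    if (config$write_masks) {
      write_stack(labels, file.path(config$out_dir,
                                    paste0(img$source_id, "_labels.tif")))
      write_stack(shells$layer, file.path(config$out_dir,
                                          paste0(img$source_id,
                                                 "_shells.tif")))
    }
  }
  all_prof <- bind_profiles(profiles)
  write_profiles(all_prof, file.path(config$out_dir, "layer_profiles.csv"))

  ro <- aggregate_ro(all_prof, config$ro_size)
  write.csv(ro$summary, file.path(config$out_dir, "ro_summary.csv"),
            row.names = FALSE)
  write.csv(ro$per_nucleus, file.path(config$out_dir, "ro_per_nucleus.csv"),
            row.names = FALSE)

  comparisons <- NULL
  stats_note <- "ok"
  conds <- unique(config$inputs$condition)
  if (length(conds) != 2L) {
    stats_note <- sprintf("comparison skipped: %d condition(s), need 2",
                          length(conds))
    message(stats_note)
  } else {
    split_prof <- lapply(conds, function(cc) {
      sub <- all_prof[all_prof$condition == cc, ]
      structure(sub, K = attr(all_prof, "K"),
                class = c("radial_profiles", "data.frame"))
    })
    n_by_cond <- vapply(split_prof, function(p)
      length(unique(paste(p$source_id, p$nucleus_id))), integer(1))
    if (any(n_by_cond < 2)) {
      stats_note <- "comparison skipped: a group has < 2 nuclei"
      message(stats_note)
    } else {
      cmp_ro <- compare_groups(split_prof[[1]], split_prof[[2]], "RO",
                               config$alpha, config$ro_size)
      cmp_layer <- compare_groups(split_prof[[1]], split_prof[[2]], "layer",
                                  config$alpha)
      comparisons <- rbind(as.data.frame(cmp_ro), as.data.frame(cmp_layer))
      write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                row.names = FALSE)
    }
  }

  manifest <- list(
    package = "nucshells",
    version = as.character(packageVersion("nucshells")),
    config = list(
      inputs = config$inputs, spacing_um = config$spacing_um,
      K = config$K, metric_mode = config$metric_mode,
      ro_size = config$ro_size, alpha = config$alpha, seed = config$seed,
      segmentation = config$seg_params[c("sigma_um", "min_volume_um3",
                                         "connectivity", "threshold_mode",
                                         "n_bins")],
      morph_ops = config$seg_params$morph_ops),
    images = img_log,
    stats = stats_note)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = all_prof, ro = ro, comparisons = comparisons,
                 manifest = manifest))
}
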