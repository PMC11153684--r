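#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Any block
#' may be omitted to use module defaults; values can also be loaded from a
#' YAML file with [load_config()], where CLI-style overrides take
#' precedence.
#'
#' @param input path to the input NIfTI volume, or `NULL` when `phantom` is
#'   given.
#' @param output_dir directory for all pipeline artifacts.
#' @param phantom optional [phantom_spec()]: generate the input (and ground
#'   truth for scoring) instead of reading a file.
#' @param manual_tumor optional [tumor_spec()] (clinician annotation);
#'   otherwise the tumor is auto-detected.
#' @param graph_params [graph_build_params()] block.
#' @param model_params [model_params()] block.
#' @param alpha heatmap grid strides, see [sample_grid()].
#' @param zeta hard-classifier threshold (`NULL` = uniform baseline).
#' @param truth_mask optional path to a binary metastasis-truth NIfTI for
#'   scoring (phantom runs score against their own ground truth).
#' @param segmentation named list of [segment_lungs()] arguments.
#' @param vessel_threshold intensity threshold for [detect_vessels()].
#' @param seed RNG seed for the phantom stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = "lungmetmap-out",
                            phantom = NULL, manual_tumor = NULL,
                            graph_params = graph_build_params(),
                            model_params = lungmetmap::model_params(),
                            alpha = c(4, 4, 4), zeta = NULL,
                            truth_mask = NULL, segmentation = list(),
                            vessel_threshold = 0.5, seed = 1L) {
  if (is.null(input) && is.null(phantom))
    stop("config needs either an input volume or a phantom spec")
  if (!is.null(input) && !file.exists(input))
    stop("input volume not found: ", input)
  if (!is.null(truth_mask) && !file.exists(truth_mask))
    stop("truth mask not found: ", truth_mask)
  structure(list(input = input, output_dir = output_dir, phantom = phantom,
                 manual_tumor = manual_tumor, graph_params = graph_params,
                 model_params = model_params, alpha = alpha, zeta = zeta,
                 truth_mask = truth_mask, segmentation = segmentation,
                 vessel_threshold = vessel_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file holds one block per module (`graph:`, `biophysics:`,
#' `heatmap:`, `segmentation:`, plus top-level `input`, `output_dir`,
#' `seed`, `manual_tumor`, `phantom`). Entries in `overrides` replace file
#' values.
#'
#' @param path YAML file.
#' @param overrides named list of replacements (e.g. from CLI flags).
#' @return a [pipeline_config()].
#' @export
load_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  gp <- do.call(graph_build_params, y$graph %||% list())
  mp <- do.call(model_params, y$biophysics %||% list())
  ph <- if (!is.null(y$phantom)) do.call(phantom_spec, y$phantom) else NULL
  mt <- if (!is.null(y$manual_tumor))
    tumor_spec(y$manual_tumor$location, y$manual_tumor$size) else NULL
  pipeline_config(input = y$input, output_dir = y$output_dir %||% "lungmetmap-out",
                  phantom = ph, manual_tumor = mt, graph_params = gp,
                  model_params = mp,
                  alpha = y$heatmap$alpha %||% c(4, 4, 4),
                  zeta = y$heatmap$zeta,
                  truth_mask = y$truth_mask,
                  segmentation = y$segmentation %||% list(),
                  vessel_threshold = y$vessel_threshold %||% 0.5,
                  seed = y$seed %||% 1L)
}

#' Run the full pipeline
#'
#' Orchestrates the end-to-end computation: input (file or phantom), primary
#' tumor detection, lung segmentation, vessel detection, graph construction
#' and spanning-tree reduction, heatmap generation, and (when ground truth
#' is available) soft/hard scoring. Every artifact is written under
#' `config$output_dir` and listed, with its MD5 hash and the full parameter
#' set, in `manifest.json`. A stage failure halts the run with the stage
#' name after writing a partial manifest. Identical config + seed yields
#' identical artifact hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `artifacts`, `parameters`,
#'   `stages`, and `scores` when computed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "lungmetmap",
                   version = as.character(utils::packageVersion("lungmetmap")),
                   parameters = manifest_params(config),
                   stages = character(0), artifacts = list())
  truth <- NULL
  add_artifact <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = path,
                                        md5 = unname(tools::md5sum(path)))
  }
  finish_stage <- function(name) manifest$stages <<- c(manifest$stages, name)
  fail <- function(stage, err) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(err)
    write_manifest(manifest, config$output_dir)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(err),
         call. = FALSE)
  }

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    finish_stage(name)
    res
  }

  volume <- stage("input", {
    if (!is.null(config$phantom)) {
      ph <- generate_phantom(config$phantom)
      assign("truth", ph$truth, inherits = TRUE)
      paths <- write_phantom(ph, file.path(config$output_dir, "phantom"))
      for (nm in names(paths)) add_artifact(paste0("phantom_", nm), paths[[nm]])
      ph$volume
    } else {
      read_volume(config$input)
    }
  })

  tumor <- stage("tumor_detection", {
    detect_primary_tumor(volume, manual = config$manual_tumor)
  })

  lung <- stage("lung_segmentation", {
    args <- c(list(volume = volume, tumor = tumor), config$segmentation)
    do.call(segment_lungs, args)
  })
  stage("lung_segmentation_io", {
    p <- file.path(config$output_dir, "lung_mask.nii.gz")
    write_volume(volume_image(lung$mask + 0, volume$spacing), p)
    add_artifact("lung_mask", p)
    if (!is.null(lung$ellipses)) {
      pc <- file.path(config$output_dir, "lung_ellipses.csv")
      utils::write.csv(lung$ellipses, pc, row.names = FALSE)
      add_artifact("lung_ellipses", pc)
    }
    NULL
  })

  tree <- stage("vessel_graph", {
    segs <- detect_vessels(volume, lung,
                           intensity_threshold = config$vessel_threshold,
                           exclude_tumor = tumor)
    if (is.null(segs)) stop("no vessels detected")
    g <- build_vessel_graph(segs, config$graph_params)
    max_radius_spanning_tree(g)
  })
  stage("vessel_graph_io", {
    p <- file.path(config$output_dir, "vessel_graph.json")
    write_vessel_graph(tree, p)
    add_artifact("vessel_graph", p)
    NULL
  })

  hm <- stage("heatmap", {
    generate_heatmap(volume, tumor, lung, tree, alpha = config$alpha,
                     params = config$model_params)
  })
  stage("heatmap_io", {
    pn <- file.path(config$output_dir, "heatmap.nii.gz")
    pc <- file.path(config$output_dir, "heatmap_grid.csv")
    write_heatmap(hm, pn, pc)
    add_artifact("heatmap", pn)
    add_artifact("heatmap_grid", pc)
    NULL
  })

  truth_arr <- NULL
  if (!is.null(truth)) truth_arr <- truth$metastasis_mask
  if (!is.null(config$truth_mask)) truth_arr <- read_volume(config$truth_mask)$data
  if (!is.null(truth_arr)) {
    scores <- stage("scoring", {
      score_prediction(truth_arr, hm, zeta = config$zeta)
    })
    manifest$scores <- scores
    stage("scoring_io", {
      p <- file.path(config$output_dir, "scores.csv")
      utils::write.csv(data.frame(soft = scores$soft, hard = scores$hard,
                                  zeta = scores$zeta), p, row.names = FALSE)
      add_artifact("scores", p)
      NULL
    })
  }

  write_manifest(manifest, config$output_dir)
  invisible(manifest)
}

manifest_params <- function(config) {
  list(graph = config$graph_params,
       biophysics = unclass(config$model_params),
       alpha = config$alpha, zeta = config$zeta,
       vessel_threshold = config$vessel_threshold,
       segmentation = config$segmentation,
       seed = config$seed)
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Serialize / load a vessel graph as JSON
#'
#' Nodes with their full cylinder parameterization and derived endpoints,
#' the edge list with gap and radius weights, and the tree flag.
#'
#' @param g a `vessel_graph`.
#' @param path output / input JSON path.
#' @return `write_vessel_graph()` returns `path` invisibly;
#'   `read_vessel_graph()` returns the `vessel_graph`.
#' @export
write_vessel_graph <- function(g, path) {
  jsonlite::write_json(list(nodes = as.data.frame(g$nodes),
                            edges = g$edges, is_tree = g$is_tree),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vessel_graph
#' @export
read_vessel_graph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- vessel_segments(j$nodes)
  edges <- if (length(j$edges)) as.data.frame(j$edges) else empty_edges()
  new_vessel_graph(nodes, edges, is_tree = isTRUE(j$is_tree))
}
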