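# End-to-end orchestration: synthetic cohort -> channel fusion ->
# segmentation -> skeleton graph -> radius profile -> surface model ->
# hemodynamic simulation -> feature table -> feature selection +
# classification, with per-stage artifacts and a hashed manifest.

#' Default pipeline configuration
#'
#' Every stage's tunables in one nested list. `px_size` (cm per pixel) has
#' no defensible universal default and must be set explicitly before the
#' pipeline will run; 1e-3 cm (10 um) per pixel is a reasonable order of
#' magnitude for fundus imaging of the optic-disc region.
#'
#' @return nested list of stage parameter blocks.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    px_size = NULL, # cm per px; must be set by the user
    cohort = list(n_subjects = 20L, n_diseased = 10L, radius_scale = 0.7),
    synth = list(image_size = c(128L, 128L), n_branch_levels = 2L,
                 root_radius = 5, radius_decay = 0.8),
    fusion = list(g = 1.0),
    segmentation = list(method = "vesselness", scales = c(1.5, 2.5, 4),
                        hysteresis_low = 0.05, hysteresis_high = 0.4),
    skeleton = list(prune_spur_min = 6),
    profile = list(interval = "adaptive", max_search = 15, window = 3L),
    model = list(n_pts = 24L, radius_ratio_threshold = 1.5,
                 smooth_iterations = 3L, lambda = 0.5, save_meshes = TRUE),
    simulate = list(mu = 0.035, steps = 32L, period = 1, peak = 0.01),
    classify = list(method = "ftest_scan", classifier = "svm",
                    nested = FALSE, alpha = 0.05,
                    grid = seq(0.001, 0.10, by = 0.001))
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; missing fields take their defaults.
#' @return full configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

#' Process one fundus image (or bundle) through the geometric stages
#'
#' fuse -> segment -> binarize -> skeletonize -> trace -> prune -> edge map
#' -> profile. Returns all intermediates.
#' @param bundle a `fundus_bundle` (or list with `image`).
#' @param config pipeline configuration.
#' @param model optional trained `denseblock_unet`; otherwise the
#'   vesselness fallback is used.
#' @return list with `fused`, `prob`, `mask`, `skeleton`, `graph`,
#'   `edges`, `profile`.
#' @export
process_image <- function(bundle, config = default_pipeline_config(),
                          model = NULL) {
  if (is.null(config$px_size)) stop("config$px_size is required")
  fused <- fuse_channels(bundle, g = config$fusion$g)
  if (identical(config$segmentation$method, "unet") && !is.null(model)) {
    prob <- predict_segmenter(model, fused)
  } else {
    prob <- segment_vesselness(fused, scales = config$segmentation$scales)
  }
  mask <- hysteresis_mask(prob, config$segmentation$hysteresis_low,
                          config$segmentation$hysteresis_high)
  skel <- zhang_suen_thin(mask)
  graph <- trace_segments(skel)
  graph <- prune_spurs(graph, config$skeleton$prune_spur_min)
  edges <- detect_edges(mask)
  prof <- profile_graph(graph, edges, interval = config$profile$interval,
                        window = config$profile$window,
                        max_search = config$profile$max_search,
                        px_size = config$px_size)
  list(fused = fused, prob = prob, mask = mask, skeleton = skel,
       graph = graph, edges = edges, profile = prof)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates `n_subjects` seeded synthetic fundus images — the diseased half
#' with all vessel radii narrowed by `radius_scale` — pushes each through
#' the geometric and hemodynamic stages, assembles the feature table
#' (features present for every subject only), runs the configured feature
#' selection + classifier, and writes every stage artifact plus a hashed
#' manifest under `output_dir`.
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @param output_dir output directory (created).
#' @return list with `table` (feature_table), `result` (classification),
#'   `selection`, `subjects` (per-subject summaries), `manifest_path`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = tempfile("fvs3d_run_")) {
  if (is.null(config$px_size)) {
    stop("config$px_size is required (cm per pixel); refusing to run")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  co <- config$cohort
  n <- co$n_subjects
  labels <- c(rep(0L, n - co$n_diseased), rep(1L, co$n_diseased))
  rows <- list()
  subjects <- list()
  logline <- function(...) message(sprintf(...))
  for (s in seq_len(n)) {
    sdir <- file.path(output_dir, sprintf("subject_%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    sc <- if (labels[s] == 1L) co$radius_scale else 1
    tree <- generate_vessel_tree(
      image_size = config$synth$image_size,
      n_branch_levels = config$synth$n_branch_levels,
      root_radius = config$synth$root_radius * sc,
      radius_decay = config$synth$radius_decay,
      seed = config$seed + 101L * s)
    tree$class_label <- labels[s]
    bundle <- render_fundus(tree, seed = config$seed + 101L * s + 1L)
    st <- process_image(bundle, config)
    write_image_png(bundle$image, file.path(sdir, "image.png"))
    write_image_png(bundle$mask, file.path(sdir, "mask_truth.png"))
    write_image_png(st$mask, file.path(sdir, "mask_segmented.png"))
    write_image_png(st$skeleton, file.path(sdir, "skeleton.png"))
    write_tree_json(tree, file.path(sdir, "tree.json"))
    write_graph_json(st$graph, file.path(sdir, "graph.json"), st$profile)
    if (isTRUE(config$model$save_meshes)) {
      mesh <- build_vessel_surface(
        st$profile, n_pts = config$model$n_pts,
        radius_ratio_threshold = config$model$radius_ratio_threshold,
        smooth_iterations = config$model$smooth_iterations,
        lambda = config$model$lambda)
      export_mesh(mesh, file.path(sdir, "model.obj"))
    }
    net <- build_flow_network(st$profile, mu = config$simulate$mu)
    wf <- inlet_waveform("halfsine", T = config$simulate$steps,
                         period = config$simulate$period,
                         peak = config$simulate$peak)
    sol <- solve_network(net, wf)
    feats <- extract_hemo_features(sol)
    rows[[s]] <- feats
    seg_m <- evaluate_segmentation(st$prob, bundle$mask,
                                   config$segmentation$hysteresis_high)
    subjects[[s]] <- list(label = labels[s], n_segments = length(st$profile$segments),
                          n_faces = length(sol$faces), seg_auc = seg_m$auc)
    logline("subject %02d: label %d, %d segments, %d faces, seg AUC %.3f",
            s, labels[s], length(st$profile$segments), length(sol$faces),
            seg_m$auc)
  }
  # keep features present for every subject, in stable order
  common <- Reduce(intersect, lapply(rows, names))
  if (length(common) < length(rows[[1L]])) {
    logline("dropping %d features absent for some subjects",
            length(rows[[1L]]) - length(common))
  }
  x <- do.call(rbind, lapply(rows, function(r) r[common]))
  rownames(x) <- sprintf("subject_%02d", seq_len(n))
  # cohort-constant features (e.g. the prescribed inlet flow series) carry
  # no class information; drop them up front
  varying <- apply(x, 2L, function(v) stats::var(v) > 0)
  if (any(!varying)) {
    logline("dropping %d cohort-constant features", sum(!varying))
    x <- x[, varying, drop = FALSE]
  }
  table <- feature_table(x, labels)
  utils::write.csv(data.frame(subject = rownames(x), label = labels, x,
                              check.names = FALSE),
                   file.path(output_dir, "features.csv"), row.names = FALSE)
  cl <- config$classify
  select_fun <- switch(cl$method,
    ttest = function(tb) ttest_filter(tb, cl$alpha),
    ftest_scan = function(tb) ftest_threshold_scan(tb, cl$classifier,
                                                   grid = cl$grid,
                                                   seed = config$seed),
    best_first = function(tb) best_first_search(tb, cl$classifier,
                                                seed = config$seed),
    stop("unknown selection method: ", cl$method))
  result <- classify_with_selection(table, select_fun, cl$classifier,
                                    nested = isTRUE(cl$nested),
                                    seed = config$seed)
  res_obj <- list(method = cl$method, classifier = cl$classifier,
                  nested = isTRUE(cl$nested), accuracy = result$accuracy,
                  selected = if (!is.null(result$selection))
                    result$selection$selected else NULL)
  jsonlite::write_json(res_obj, file.path(output_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  # manifest: every artifact hashed and attributed
  files <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(output_dir, "manifest.json"))
  manifest <- list(
    config = config,
    files = data.frame(
      path = sub(paste0("^", output_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)),
      stage = vapply(files, function(f) {
        b <- basename(f)
        if (grepl("image|mask_truth|tree", b)) "synthetic"
        else if (grepl("mask_segmented", b)) "segmentation"
        else if (grepl("skeleton", b)) "skeleton"
        else if (grepl("graph", b)) "profile"
        else if (grepl("model", b)) "surface"
        else if (grepl("features", b)) "hemodynamics"
        else if (grepl("classification", b)) "classification"
        else "other"
      }, character(1L))
    )
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(table = table, result = res_obj,
       selection = result$selection %||% NULL, subjects = subjects,
       output_dir = output_dir,
       manifest_path = file.path(output_dir, "manifest.json"))
}
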