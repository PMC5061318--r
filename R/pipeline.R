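#' Run the full analysis pipeline over a plate
#'
#' End-to-end flow: for every well in the layout, load its poses from the
#' manifest, localize the brain (best pose, or a manual override), build the
#' healthy-brain template from the positive-control crops (unless one is
#' supplied), score every usable well (BHS, neuron segmentation, features),
#' and compute arm-level screening metrics with bootstrap group averaging.
#' Every well appears exactly once in either the score table or the unusable
#' list, and the per-well provenance log makes the automated choices
#' replayable.
#'
#' @param manifest manifest tibble from [read_manifest()] (or a path to one).
#' @param layout [plate_layout()] tibble with `+`/`-` arm designations.
#' @param config pipeline configuration, see [default_config()].
#' @param manual_poses optional named vector from [read_manual_poses()].
#' @param template optional pre-built [build_template()] result; when `NULL`
#'   one is built from the localized positive-arm crops.
#' @param output_dir optional directory; when given, writes `scores.csv`,
#'   `metrics.json`, `unusable.csv`, `template.tif` and a JSON-lines audit
#'   log.
#' @return list with `scores` (tibble), `metrics` ([screen_metrics()]),
#'   `averaging` (bootstrap table), `unusable` (tibble with reasons),
#'   `template`, and `log` (per-well provenance tibble).
#' @export
run_pipeline <- function(manifest, layout, config = default_config(),
                         manual_poses = NULL, template = NULL,
                         output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(is.data.frame(layout), all(c("well", "condition", "arm") %in% names(layout)))

  wells <- layout$well
  loc_results <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    w <- wells[i]
    entries <- manifest[manifest$well == w, ]
    if (nrow(entries) == 0) {
      loc_results[[i]] <- list(well = w, usable = FALSE, chosen_cycle = NA_integer_,
                               crop = NULL,
                               provenance = tibble::tibble(
                                 cycle = NA_integer_, ok = FALSE,
                                 reason = "not_in_manifest", score = NA_real_,
                                 manual = FALSE))
      next
    }
    cycles <- sort(unique(entries$cycle))
    poses <- lapply(cycles, function(cy) load_pose(manifest, w, cy))
    mc <- if (!is.null(manual_poses) && w %in% names(manual_poses))
      manual_poses[[w]] else NULL
    loc_results[[i]] <- localize_well(poses, manual_choice = mc, well = w,
                                      config = config)
  }

  usable <- vapply(loc_results, function(r) isTRUE(r$usable), logical(1))
  log_tbl <- dplyr::bind_rows(lapply(seq_along(wells), function(i) {
    dplyr::mutate(loc_results[[i]]$provenance, well = wells[i], .before = 1)
  }))

  if (is.null(template)) {
    pos_idx <- which(usable & layout$arm == "+")
    if (length(pos_idx) == 0)
      stop("no usable wells in the positive control arm: cannot build template")
    n_tpl <- min(length(pos_idx), config$template$max_images)
    crops <- lapply(loc_results[pos_idx[seq_len(n_tpl)]], function(r)
      mask_eyes(r$crop$image, r$crop$eye_mask))
    template <- build_template(crops,
                               rolling_ball_radius = config$template$rolling_ball_radius,
                               blur_sigma = config$template$blur_sigma)
  }

  scores <- dplyr::bind_rows(lapply(which(usable), function(i) {
    r <- loc_results[[i]]
    score_crop(r$crop, template, config = config, well = r$well,
               condition = layout$condition[i], chosen_cycle = r$chosen_cycle,
               frame_total_fluor = r$frame_total_fluor)
  }))
  unusable <- dplyr::bind_rows(lapply(which(!usable), function(i) {
    reasons <- loc_results[[i]]$provenance$reason
    tibble::tibble(well = wells[i], condition = layout$condition[i],
                   reason = paste(stats::na.omit(reasons), collapse = ";"))
  }))
  if (nrow(unusable) == 0)
    unusable <- tibble::tibble(well = character(), condition = character(),
                               reason = character())

  metrics <- NULL; averaging <- NULL
  pos_label <- unique(layout$condition[layout$arm == "+"])[1]
  neg_label <- unique(layout$condition[layout$arm == "-"])[1]
  if (!is.na(pos_label) && !is.na(neg_label) && nrow(scores) > 0) {
    metrics <- tryCatch(
      screen_metrics(scores, positive = pos_label, negative = neg_label),
      error = function(e) {
        warning("metrics not computed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(metrics)) {
      # only group sizes that leave at least two groups per arm
      feasible <- config$stats$group_sizes[
        config$stats$group_sizes * 2 <= min(length(metrics$pos),
                                            length(metrics$neg))]
      if (length(feasible) > 0) {
        averaging <- bootstrap_group_averaging(
          metrics$pos, metrics$neg, group_sizes = feasible,
          B = config$stats$bootstrap_B, seed = config$stats$seed)
      }
    }
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(scores, file.path(output_dir, "scores.csv"))
    readr::write_csv(unusable, file.path(output_dir, "unusable.csv"))
    tiff::writeTIFF(template$M, file.path(output_dir, "template.tif"),
                    bits.per.sample = 32L)
    if (!is.null(metrics)) {
      jsonlite::write_json(
        list(metrics = tidy(metrics), arms = metrics$arms,
             averaging = averaging),
        file.path(output_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    }
    log_lines <- vapply(seq_len(nrow(log_tbl)), function(i)
      jsonlite::toJSON(as.list(log_tbl[i, ]), auto_unbox = TRUE), character(1))
    writeLines(log_lines, file.path(output_dir, "audit_log.jsonl"))
  }

  list(scores = scores, metrics = metrics, averaging = averaging,
       unusable = unusable, template = template, log = log_tbl)
}
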