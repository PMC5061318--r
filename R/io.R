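#' Default pipeline configuration
#'
#' Every numeric parameter of every stage in one list, so the method's fixed
#' constants are data rather than code. Defaults are the assay's standard
#' settings: Hough diameter range 80--150 px, 60 x 90 px eye oval,
#' 35 half-size px brain offset, 190 x 220 px crop, 12 px FWHM background
#' smoothing, 5--20 px object diameters with Otsu correction factor 5,
#' rolling-ball radius 150 px and template blur sigma 7 px, 1000 bootstrap
#' replicates over group sizes 1--5.
#'
#' @return nested configuration list (`localization`, `scoring`, `template`,
#'   `stats`).
#' @export
default_config <- function() {
  list(
    localization = list(
      hough_d_min = 80, hough_d_max = 150,
      eye_oval = c(60, 90),
      eye_separation_range = c(40, 120),
      brain_offset = 35,
      crop_size = c(190L, 220L)),
    scoring = list(
      smooth_fwhm = 12,
      diameter_range = c(5, 20),
      correction_factor = 5,
      bhs_input = "masked"),
    template = list(
      rolling_ball_radius = 150,
      blur_sigma = 7,
      max_images = 35),
    stats = list(
      bootstrap_B = 1000,
      group_sizes = 1:5,
      seed = 1L))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_config()
  for (section in intersect(names(user), names(config))) {
    for (key in intersect(names(user[[section]]), names(config[[section]]))) {
      config[[section]][[key]] <- user[[section]][[key]]
    }
  }
  config
}

#' Write a pipeline configuration to YAML
#'
#' @param config configuration list.
#' @param path output YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

valid_wells_96 <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Construct a plate layout
#'
#' @param wells well identifiers (A1--H12).
#' @param condition per-well condition label (e.g. `"DMSO"`, `"Mtz-9mM"`).
#' @param arm per-well arm designation: `"+"` (positive control), `"-"`
#'   (negative control) or `"test"`.
#' @param plate plate identifier.
#' @return `plate_layout` tibble.
#' @export
plate_layout <- function(wells, condition, arm = "test", plate = "plate1") {
  stopifnot(length(wells) >= 1)
  bad <- setdiff(wells, valid_wells_96())
  if (length(bad)) stop("invalid 96-well coordinates: ", paste(bad, collapse = ", "))
  if (anyDuplicated(wells)) stop("duplicate wells in layout")
  out <- tibble::tibble(plate = plate, well = wells,
                        condition = rep_len(condition, length(wells)),
                        arm = rep_len(arm, length(wells)))
  class(out) <- c("plate_layout", class(out))
  out
}

#' Two-arm control plate layout
#'
#' The validation plate design: rows A--D carry the vehicle (DMSO) arm and
#' rows E--H the ablation (Mtz) arm, `n_per_arm` wells each (44 by default,
#' matching the 88-larva validation plate).
#'
#' @param n_per_arm wells per arm (at most 48).
#' @param positive,negative condition labels for the two arms.
#' @return `plate_layout` tibble with arm designations `"+"` and `"-"`.
#' @export
plate_layout_two_arm <- function(n_per_arm = 44,
                                 positive = "DMSO", negative = "Mtz-9mM") {
  stopifnot(n_per_arm >= 1, n_per_arm <= 48)
  top <- paste0(rep(LETTERS[1:4], each = 12), rep(1:12, times = 4))[seq_len(n_per_arm)]
  bottom <- paste0(rep(LETTERS[5:8], each = 12), rep(1:12, times = 4))[seq_len(n_per_arm)]
  plate_layout(c(top, bottom),
               condition = rep(c(positive, negative), each = n_per_arm),
               arm = rep(c("+", "-"), each = n_per_arm))
}

manifest_columns <- c("plate", "well", "cycle", "channel", "z_index", "path")

#' Read and validate an acquisition manifest
#'
#' The manifest is a CSV with columns plate, well, cycle, channel
#' (`BF`/`FLUO`), z_index and path. Validation checks that every
#' (well, cycle) group has exactly one bright-field frame, that fluorescence
#' z-indices are contiguous from 0, and that every referenced file exists;
#' failures name the offending well and cycle.
#'
#' @param path manifest CSV; relative image paths are resolved against its
#'   directory.
#' @param check_files verify that referenced image files exist.
#' @return validated manifest tibble (class `acq_manifest`).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.size(path) > 0) stop("empty manifest file: ", path)
  m <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(manifest_columns, names(m))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(m) == 0) stop("manifest has no rows: ", path)
  if (!all(m$channel %in% c("BF", "FLUO")))
    stop("unknown channel values in manifest")
  base <- dirname(path)
  m$path <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                   file.path(base, m$path))
  groups <- split(m, paste(m$plate, m$well, m$cycle, sep = "|"))
  for (g in groups) {
    id <- sprintf("plate %s well %s cycle %s", g$plate[1], g$well[1], g$cycle[1])
    n_bf <- sum(g$channel == "BF")
    if (n_bf != 1) stop(id, ": expected exactly one BF frame, found ", n_bf)
    z <- sort(g$z_index[g$channel == "FLUO"])
    if (length(z) == 0) stop(id, ": no FLUO slices")
    if (!identical(as.integer(z), seq(0L, length(z) - 1L)))
      stop(id, ": FLUO z-indices not contiguous from 0 (missing slice ",
           paste(setdiff(seq(0L, max(z)), z), collapse = ","), ")")
  }
  if (check_files) {
    missing <- !file.exists(m$path)
    if (any(missing)) {
      mm <- m[missing, ]
      stop("missing image files, e.g. well ", mm$well[1], " cycle ",
           mm$cycle[1], ": ", basename(mm$path[1]),
           " (", sum(missing), " missing in total)")
    }
  }
  class(m) <- c("acq_manifest", class(m))
  m
}

#' Load one pose acquisition from a manifest
#'
#' Reads the bright-field frame and assembles the fluorescence stack in
#' z order, validating that all frames share the same shape.
#'
#' @param manifest manifest tibble from [read_manifest()].
#' @param well,cycle which acquisition to load.
#' @return pose acquisition: list with `well`, `cycle`, `brightfield`
#'   (matrix, counts) and `fluorescence` (`rows x cols x z` array, counts).
#' @export
load_pose <- function(manifest, well, cycle) {
  rows <- manifest[manifest$well == well & manifest$cycle == cycle, ]
  if (nrow(rows) == 0) stop("no manifest entries for well ", well, " cycle ", cycle)
  bf <- read_count_tiff(rows$path[rows$channel == "BF"][1])
  fl_rows <- rows[rows$channel == "FLUO", ]
  fl_rows <- fl_rows[order(fl_rows$z_index), ]
  slices <- lapply(fl_rows$path, read_count_tiff)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != nrow(bf)) || any(dims[2, ] != ncol(bf)))
    stop("shape mismatch between BF and FLUO frames for well ", well,
         " cycle ", cycle)
  fluo <- array(0, dim = c(nrow(bf), ncol(bf), length(slices)))
  for (i in seq_along(slices)) fluo[, , i] <- slices[[i]]
  list(well = well, cycle = cycle, brightfield = bf, fluorescence = fluo)
}

#' Read a manual pose-override file
#'
#' CSV with columns `well` and `chosen_cycle`, replacing the interactive
#' best-pose review with a reproducible flat file.
#'
#' @param path CSV file.
#' @return named integer vector of chosen cycles keyed by well.
#' @export
read_manual_poses <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("well", "chosen_cycle") %in% names(m)))
  stats::setNames(as.integer(m$chosen_cycle), m$well)
}
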