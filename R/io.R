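#' Read a 3D volume from NIfTI
#'
#' Loads voxel data and voxel spacing from the NIfTI header. Fails on
#' anything that is not a plain 3D scalar volume with positive spacing
#' rather than guessing.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach (`"t1w"`, `"t2w"`, `"mask"`).
#' @return An [image_volume].
#' @export
load_volume <- function(path, modality = c("t1w", "t2w", "mask")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(path, " is ", length(d), "-dimensional; a 3D volume is required")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(path, " has no usable voxel spacing in its header")
  image_volume(array(as.numeric(img), dim = d), sp[1:3], modality)
}

#' Write a volume (or binary mask stack) as NIfTI
#'
#' @param volume an [image_volume] or a bare 3D array (then
#'   `spacing_mm` must be given).
#' @param path output file.
#' @param spacing_mm voxel spacing when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing_mm = NULL) {
  if (inherits(volume, "image_volume")) {
    data <- volume$data
    spacing_mm <- volume$spacing_mm
  } else {
    data <- volume
    if (is.null(spacing_mm)) stop("spacing_mm required for bare arrays")
  }
  img <- RNifti::asNifti(data, reference = NULL)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read catheter paths as JSON
#'
#' The JSON records, per catheter: id, slice indices, in-plane voxel
#' coordinates, physical mm coordinates, per-point provenance and the
#' voxel spacing, so a path file is self-contained.
#'
#' @param paths list of `catheter_path`s or phantom ground-truth paths.
#' @param path output JSON file.
#' @param voxel_spacing_mm spacing for paths that do not carry one.
#' @return `write_paths_json` returns `path` invisibly;
#'   `read_paths_json` returns a list of `catheter_path`s.
#' @export
write_paths_json <- function(paths, path, voxel_spacing_mm = NULL) {
  obj <- lapply(paths, function(p) {
    sp <- p$spacing_mm %||% voxel_spacing_mm
    mm <- if (!is.null(sp)) voxel_to_mm(cbind(p$points, p$slices), sp)
    list(
      catheter_id = p$catheter_id,
      slices = p$slices,
      row = as.numeric(p$points[, 1]),
      col = as.numeric(p$points[, 2]),
      x_mm = if (!is.null(mm)) mm[, 1],
      y_mm = if (!is.null(mm)) mm[, 2],
      z_mm = if (!is.null(mm)) mm[, 3],
      provenance = p$provenance %||% rep("truth", length(p$slices)),
      spacing_mm = sp,
      insertion_length_mm = p$insertion_length_mm,
      free_length_mm = p$free_length_mm
    )
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_paths_json
#' @export
read_paths_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i) {
    r <- obj[i, ]
    structure(list(
      catheter_id = r$catheter_id,
      slices = unlist(r$slices),
      points = cbind(row = unlist(r$row), col = unlist(r$col)),
      provenance = unlist(r$provenance),
      spacing_mm = unlist(r$spacing_mm),
      insertion_length_mm = r$insertion_length_mm,
      free_length_mm = r$free_length_mm
    ), class = "catheter_path")
  })
}

#' Run the full phantom-to-evaluation pipeline
#'
#' Executes simulate, (optionally) train, predict, reconstruct and
#' evaluate as one deterministic workflow, writing every artifact plus
#' a manifest with content hashes. All randomness derives from the
#' seeds in the config.
#'
#' @param config a list (or path to a YAML/JSON file) with elements:
#'   \describe{
#'     \item{phantom}{arguments for [phantom_config].}
#'     \item{mask_source}{`"oracle"` (masks rasterized from ground
#'       truth) or `"unet"` (train small networks and predict).}
#'     \item{unet}{arguments for [unet_config] (used when
#'       `mask_source = "unet"`).}
#'     \item{train}{list: `n_patches`, `epochs`, `learning_rate`,
#'       `rng_seed`.}
#'     \item{postprocess}{arguments for [reconstruct_catheters]
#'       (rect_halfsize, neighborhood_px, merge_tolerance_px,
#'       min_component_size).}
#'     \item{evaluate}{`TRUE`/`FALSE`; when the phantom truth is
#'       available, evaluation runs by default.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, a list with the reconstruction paths, the
#'   evaluation report (or `NULL`) and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- character()
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                                    sprintf(...)))

  ## simulate
  pc <- do.call(phantom_config, as.list(config$phantom %||% list()))
  log_stage("simulate", "phantom %dx%dx%d, %d catheters, seed %d",
            pc$shape[1], pc$shape[2], pc$shape[3], pc$n_catheters,
            pc$rng_seed)
  ph <- generate_phantom(pc)
  t1n <- normalize_volume(ph$t1w)
  t2n <- normalize_volume(ph$t2w)
  f_t1 <- file.path(out_dir, "t1w.nii.gz")
  f_t2 <- file.path(out_dir, "t2w.nii.gz")
  write_volume(ph$t1w, f_t1); write_volume(ph$t2w, f_t2)
  f_truth <- file.path(out_dir, "truth_paths.json")
  write_paths_json(ph$paths, f_truth, voxel_spacing_mm = pc$spacing_mm)
  artifacts <- c(artifacts, f_t1, f_t2, f_truth)

  ## masks
  if ((config$mask_source %||% "oracle") == "unet") {
    uc_args <- as.list(config$unet %||% list())
    uc <- do.call(unet_config, uc_args)
    tr <- config$train %||% list()
    labels <- rasterize_truth_mask(ph$paths, pc$shape, pc$catheter_radius)
    masks <- list()
    for (mod in c("t1w", "t2w")) {
      vol <- if (mod == "t1w") t1n else t2n
      log_stage("train", "%s model: %d patches, %d epochs", mod,
                tr$n_patches %||% 1000L, tr$epochs %||% uc$epochs)
      patches <- sample_training_patches(
        vol, labels, n_patches = tr$n_patches %||% 1000L,
        patch_size = uc$patch_size,
        rng_seed = (tr$rng_seed %||% uc$rng_seed) +
          (if (mod == "t2w") 1000L else 0L)
      )
      model <- build_unet(uc, modality = mod)
      fit <- train_unet(model, patches, epochs = tr$epochs,
                        learning_rate = tr$learning_rate)
      log_stage("predict", "%s volume", mod)
      masks[[mod]] <- binarize(predict_mask_stack(fit$model, vol))
    }
    m1 <- masks$t1w; m2 <- masks$t2w
  } else {
    log_stage("masks", "oracle masks rasterized from ground truth")
    m1 <- m2 <- rasterize_truth_mask(ph$paths, pc$shape, pc$catheter_radius)
  }
  f_m1 <- file.path(out_dir, "mask_t1w.nii.gz")
  f_m2 <- file.path(out_dir, "mask_t2w.nii.gz")
  write_volume(m1, f_m1, pc$spacing_mm)
  write_volume(m2, f_m2, pc$spacing_mm)
  artifacts <- c(artifacts, f_m1, f_m2)

  ## reconstruct
  pp <- as.list(config$postprocess %||% list())
  log_stage("reconstruct", "%d catheters from slice %d",
            nrow(ph$geometry$seeds), ph$geometry$start_slice)
  rec <- do.call(reconstruct_catheters, c(
    list(t1w = t1n, t2w = t2n, t1w_mask = m1, t2w_mask = m2,
         geometry = ph$geometry), pp
  ))
  f_paths <- file.path(out_dir, "reconstructed_paths.json")
  f_csv <- file.path(out_dir, "reconstructed_paths.csv")
  write_paths_json(rec, f_paths)
  utils::write.csv(paths_to_df(rec), f_csv, row.names = FALSE)
  artifacts <- c(artifacts, f_paths, f_csv)

  ## evaluate
  report <- NULL
  if (isTRUE(config$evaluate %||% TRUE)) {
    log_stage("evaluate", "dwell positions at 1 mm spacing")
    report <- evaluate_reconstruction(rec, ph$paths, pc$spacing_mm,
                                      shape = pc$shape,
                                      radius = pc$catheter_radius)
    files <- export_report(report, out_dir)
    artifacts <- c(artifacts, unname(files))
  } else {
    log_stage("evaluate", "skipped: no reference paths requested")
  }

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  )
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
  log_stage("done", "%d artifacts in %s", nrow(manifest), out_dir)
  invisible(list(paths = rec, report = report, manifest = manifest))
}
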