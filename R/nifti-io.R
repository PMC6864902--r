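# NIfTI-1 I/O and the 4D volume-series container. File handling is done by
# RNifti; this file only adapts between on-disk volumes and the in-memory
# containers the pipeline uses.

#' 4D BOLD volume series
#'
#' A thin container for a 4D scalar array `(x, y, z, t)` with its
#' voxel-to-world affine and repetition time.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-MNI-mm transform (applied to 0-based voxel
#'   indices, the NIfTI convention).
#' @param tr_s Repetition time in seconds (> 0).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, affine, tr_s) {
  if (length(dim(data)) != 4) stop("data must be a 4D array (x, y, z, t)")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  if (!is.numeric(tr_s) || length(tr_s) != 1 || tr_s <= 0)
    stop("tr_s must be a positive scalar")
  structure(list(data = data, affine = affine, tr_s = tr_s),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_series: %dx%dx%d voxels, %d scans, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Read a 4D BOLD NIfTI file as a volume series
#'
#' @param path Path to a NIfTI-1 file.
#' @param tr_s Repetition time override in seconds; by default taken from
#'   the fourth pixel dimension of the header.
#' @return A [volume_series()].
#' @export
read_bold <- function(path, tr_s = NULL) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 3) dim(im) <- c(d, 1)
  pd <- RNifti::pixdim(im)
  tr <- tr_s %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else
    stop("TR not present in header; pass tr_s"))
  volume_series(unclass(as.array(im)), affine = RNifti::xform(im), tr_s = tr)
}

#' Write a volume series (or 3D volume) to a NIfTI-1 file
#'
#' @param x A [volume_series()], or a 3D/4D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 affine (required when `x` is a bare array).
#' @param tr_s Repetition time stored in the 4th pixel dimension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, affine = NULL, tr_s = NULL) {
  if (inherits(x, "volume_series")) {
    arr <- x$data; affine <- x$affine; tr_s <- tr_s %||% x$tr_s
  } else {
    arr <- x
    if (is.null(affine)) stop("affine is required when writing a bare array")
  }
  storage.mode(arr) <- "double"
  im <- RNifti::asNifti(arr)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(im) <- c(vox, tr_s %||% 1)[seq_len(length(dim(arr)))]
  RNifti::sform(im) <- structure(unname(as.matrix(affine)), code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 3D brain mask
#'
#' @param path Path to a NIfTI-1 file; nonzero voxels are in-mask.
#' @return A list with `mask` (3D logical array) and `affine`.
#' @export
read_mask <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) == 4) arr <- arr[, , , 1]
  list(mask = arr != 0, affine = RNifti::xform(im))
}

#' Write a simulated dataset to disk
#'
#' Writes per-subject BOLD NIfTI volumes and tab-separated event tables, a
#' brain mask, a comma-separated FA table, a JSON ground-truth sidecar and
#' a JSON manifest.
#'
#' @param dataset A `pls_simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  stopifnot(inherits(dataset, "pls_simulated_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE")
  dir.create(file.path(dir, "bold"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "events"), showWarnings = FALSE)
  for (s in dataset$subjects) {
    write_volume(dataset$bold[[s]],
                 file.path(dir, "bold", paste0(s, "_bold.nii.gz")))
    ev <- dataset$events[[s]]
    write.table(ev, file.path(dir, "events", paste0(s, "_events.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_volume(array(as.numeric(dataset$mask), dim = dim(dataset$mask)),
               file.path(dir, "mask.nii.gz"), affine = dataset$affine)
  write.csv(dataset$fa, file.path(dir, "fa.csv"), row.names = FALSE)
  truth <- dataset$truth
  truth_json <- list(
    grid_shape = truth$grid_shape, n_lags = truth$n_lags,
    tr_s = truth$tr_s, conditions = truth$conditions,
    variables = truth$variables, n_components = truth$n_components,
    coupling_strength = truth$coupling_strength, coupling = truth$coupling,
    noise_sd = truth$noise_sd, peak_psc = truth$peak_psc,
    trial_snr = truth$trial_snr, regime = truth$regime,
    generator_seed = truth$generator_seed,
    seed_center_ijk = truth$seed_center_ijk,
    lag_profile = truth$lag_profile,
    components = lapply(truth$components, function(cm) list(
      positive = cm$positive, negative = cm$negative,
      variable_salience = cm$variable_salience))
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    subjects = dataset$subjects, conditions = dataset$conditions,
    tr_s = dataset$tr_s, n_scans = dataset$params$n_scans,
    seed_mni = dataset$seed_spec$mni,
    generator_params = dataset$params,
    fa_missing = dataset$fa_missing,
    truth_hash = object_hash(truth_json))
  manifest$manifest_hash <- object_hash(manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset written by [write_dataset()]
#'
#' Reconstructs the in-memory dataset, including the ground truth (the
#' planted voxel salience is rebuilt from the stored support, signs and
#' lag profile).
#'
#' @param dir Dataset directory.
#' @return A `pls_simulated_dataset` (without the generator's latent
#'   scores, which are not serialised).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  grid_shape <- as.integer(tj$grid_shape)
  n_vox <- prod(grid_shape)
  lag_prof <- as.numeric(tj$lag_profile)
  comp_list <- tj$components
  if (is.data.frame(comp_list))
    comp_list <- lapply(seq_len(nrow(comp_list)), function(i)
      lapply(comp_list, function(col) col[[i]]))
  components <- lapply(comp_list, function(cm) {
    pos <- sort(as.integer(unlist(cm$positive)))
    neg <- sort(as.integer(unlist(cm$negative)))
    spatial <- numeric(n_vox)
    spatial[pos] <- 1
    spatial[neg] <- -1
    sal <- outer(lag_prof, spatial)
    sal <- sal / sqrt(sum(sal^2))
    vs <- cm$variable_salience
    if (is.list(vs)) vs <- do.call(rbind, lapply(vs, unlist))
    vs <- matrix(as.numeric(vs), nrow = length(tj$conditions),
                 dimnames = list(tj$conditions, tj$variables))
    list(voxel_salience = sal, variable_salience = vs,
         positive = pos, negative = neg,
         active_voxel_set = sort(c(pos, neg)))
  })
  truth <- structure(list(
    grid_shape = grid_shape, n_lags = as.integer(tj$n_lags),
    tr_s = tj$tr_s, conditions = tj$conditions, variables = tj$variables,
    n_components = as.integer(tj$n_components),
    coupling_strength = tj$coupling_strength, coupling = tj$coupling,
    noise_sd = tj$noise_sd, peak_psc = tj$peak_psc,
    trial_snr = tj$trial_snr, lag_profile = lag_prof,
    voxel_salience = components[[1]]$voxel_salience,
    variable_salience = components[[1]]$variable_salience,
    active_voxel_set = components[[1]]$active_voxel_set,
    components = components,
    seed_center_ijk = as.integer(tj$seed_center_ijk),
    regime = tj$regime, generator_seed = as.integer(tj$generator_seed)
  ), class = "pls_ground_truth")

  subjects <- manifest$subjects
  mk <- read_mask(file.path(dir, "mask.nii.gz"))
  bold <- setNames(lapply(subjects, function(s)
    read_bold(file.path(dir, "bold", paste0(s, "_bold.nii.gz")))), subjects)
  events <- setNames(lapply(subjects, function(s)
    read_events(file.path(dir, "events", paste0(s, "_events.tsv")))),
    subjects)
  fa <- read_fa_table(file.path(dir, "fa.csv"))
  structure(list(
    bold = bold, events = events, fa = fa, mask = mk$mask,
    affine = bold[[1]]$affine, tr_s = manifest$tr_s, truth = truth,
    latents = NULL, subjects = subjects, conditions = manifest$conditions,
    seed_spec = list(mni = as.numeric(manifest$seed_mni),
                     voxel = truth$seed_center_ijk),
    fa_missing = manifest$fa_missing,
    params = manifest$generator_params
  ), class = "pls_simulated_dataset")
}

#' Read a tab-separated event table
#'
#' Expected columns: `onset` (s), `duration` (s), `condition`, `accuracy`
#' (0/1), `rt` (ms, empty for trials without a response).
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_events <- function(path) {
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "condition", "accuracy", "rt")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  ev
}

#' Read a comma-separated FA table
#'
#' Expected columns: `subject_id`, `tract`, `fa` (in `[0, 1]`).
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_fa_table <- function(path) {
  fa <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "tract", "fa")
  miss <- setdiff(need, names(fa))
  if (length(miss))
    stop("FA table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(fa) && (any(fa$fa < 0, na.rm = TRUE) ||
                   any(fa$fa > 1, na.rm = TRUE)))
    stop("FA values must lie in [0, 1]")
  fa
}
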