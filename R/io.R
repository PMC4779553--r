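#' Write a study to disk in the package's interchange layout
#'
#' Volumes go to NIfTI-1 files (`cine_ED.nii.gz`, `cine_ES.nii.gz`,
#' `lge.nii.gz`) and the annotations to a JSON sidecar
#' (`annotations.json`) holding the per-slice contour point lists in mm,
#' the RV insertion angles in degrees, the culprit artery and both grids.
#' [load_study()] reads the same layout back bit-exactly.
#'
#' @param study A [mar_study()] (for a [generate_case()] result pass
#'   `case$study`).
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tf in study$timeframes)
    RNifti::writeNifti(nifti_volume(study$ce_images[[tf]], study$grid),
                       file.path(dir, sprintf("cine_%s.nii.gz", tf)))
  if (!is.null(study$lge_images))
    RNifti::writeNifti(nifti_volume(study$lge_images, study$lge_grid),
                       file.path(dir, "lge.nii.gz"))
  sidecar <- list(
    culprit = study$culprit,
    rv_anterior = study$rv_anterior,
    rv_anterior_lge = study$rv_anterior_lge,
    grid = unclass(study$grid),
    lge_grid = unclass(study$lge_grid),
    contours = contours_to_json(study$contours),
    lge_contours = if (is.null(study$lge_contours)) NULL
                   else contours_to_json(study$lge_contours))
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(sidecar, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(dir)
}

nifti_volume <- function(arr, grid) {
  RNifti::asNifti(arr, pixdim = c(grid$in_plane_spacing,
                                  grid$in_plane_spacing,
                                  grid$slice_thickness))
}

contours_to_json <- function(cs) {
  out <- list()
  for (tf in c("ED", "ES")) {
    if (is.null(cs[[tf]])) next
    out[[tf]] <- lapply(cs[[tf]], function(sl) {
      if (is.null(sl)) NULL
      else list(endo = unname(apply(sl$endo, 1, c, simplify = FALSE)),
                epi = unname(apply(sl$epi, 1, c, simplify = FALSE)))
    })
  }
  out
}

contours_from_json <- function(j, n_slices) {
  args <- list(ED = NULL, ES = NULL)
  for (tf in names(j)) {
    frames <- j[[tf]]
    if (length(frames) > n_slices)
      stop("sidecar slice index exceeds the image grid")
    args[[tf]] <- lapply(seq_len(n_slices), function(s) {
      if (s > length(frames) || is.null(frames[[s]])) return(NULL)
      sl <- frames[[s]]
      list(endo = do.call(rbind, lapply(sl$endo, as.numeric)),
           epi = do.call(rbind, lapply(sl$epi, as.numeric)))
    })
  }
  contour_set(ED = args$ED, ES = args$ES)
}

grid_from_json <- function(j) {
  voxel_grid(j$rows, j$cols, j$n_slices, as.numeric(j$in_plane_spacing),
             as.numeric(j$slice_thickness))
}

#' Load a study written by [write_study()]
#'
#' @param dir Study directory.
#' @return A [mar_study()]. A missing LGE stack only triggers a warning
#'   (block 4 is then skipped by the pipeline); a missing culprit label is
#'   an error.
#' @export
load_study <- function(dir) {
  sidecar_path <- file.path(dir, "annotations.json")
  if (!file.exists(sidecar_path)) stop("annotations.json not found in ", dir)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (is.null(sc$culprit)) stop("sidecar is missing the culprit artery")
  grid <- grid_from_json(sc$grid)
  ce_images <- list()
  for (tf in c("ED", "ES")) {
    f <- file.path(dir, sprintf("cine_%s.nii.gz", tf))
    if (file.exists(f)) {
      vol <- array(as.numeric(RNifti::readNifti(f)),
                   dim = unname(unlist(sc$grid[c("rows", "cols", "n_slices")])))
      if (!all(dim(vol) == c(grid$rows, grid$cols, grid$n_slices)))
        stop(sprintf("%s does not match the sidecar grid", basename(f)))
      ce_images[[tf]] <- vol
    }
  }
  lge_path <- file.path(dir, "lge.nii.gz")
  lge_images <- NULL
  lge_grid <- grid
  lge_contours <- NULL
  if (file.exists(lge_path)) {
    lge_grid <- grid_from_json(sc$lge_grid)
    lge_images <- array(as.numeric(RNifti::readNifti(lge_path)),
                        dim = c(lge_grid$rows, lge_grid$cols, lge_grid$n_slices))
    lge_contours <- contours_from_json(sc$lge_contours, lge_grid$n_slices)
  } else warning("no LGE stack found; infarct fusion will be skipped")
  mar_study(grid = grid, ce_images = ce_images,
            contours = contours_from_json(sc$contours, grid$n_slices),
            culprit = sc$culprit, rv_anterior = as.numeric(sc$rv_anterior),
            lge_images = lge_images, lge_grid = lge_grid,
            lge_contours = lge_contours,
            rv_anterior_lge = as.numeric(
              if (is.null(sc$rv_anterior_lge)) sc$rv_anterior
              else sc$rv_anterior_lge))
}

#' Write a segmentation result
#'
#' Masks are written as 8-bit NIfTI volumes on the study grid
#' (`mar_ED.nii.gz`, `mar_ES.nii.gz`), the audit trail to `report.json`
#' (`%LVM`, mixture parameters, correction decision, sector provenance) and
#' one summary row to `result.csv`.
#'
#' @param result A `mar_result` from [run_segment_mar()] or a
#'   `threshold_result` from [segment_by_threshold()].
#' @param dir Output directory.
#' @param grid The study [voxel_grid()].
#' @return The directory, invisibly.
#' @export
write_result <- function(result, dir, grid) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tf in names(result$masks))
    RNifti::writeNifti(nifti_volume(result$masks[[tf]] * 1L, grid),
                       file.path(dir, sprintf("mar_%s.nii.gz", tf)),
                       datatype = "uint8")
  report <- result[setdiff(names(result), "masks")]
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  row <- data.frame(
    method = if (inherits(result, "threshold_result")) result$method else "pipeline",
    percent_lvm = result$percent_lvm,
    ed_percent_lvm = result$percent_lvm_by_timeframe["ED"],
    es_percent_lvm = result$percent_lvm_by_timeframe["ES"])
  utils::write.csv(row, file.path(dir, "result.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a mask volume written by [write_result()]
#'
#' @param path NIfTI file path.
#' @return Logical array.
#' @export
read_mask <- function(path) {
  array(as.numeric(RNifti::readNifti(path)) > 0.5,
        dim = dim(RNifti::readNifti(path)))
}

#' Read a flat key-value configuration file
#'
#' Lines of `key = value` (or `key: value`) overriding [mar_config()]
#' defaults; numeric and logical values are parsed, `#` starts a comment.
#'
#' @param path Text file path.
#' @return A [mar_config()] with the overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- mar_config()
  em_names <- names(em_config())
  for (ln in lines) {
    kv <- strsplit(ln, "[:=]", perl = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- suppressWarnings(as.numeric(val))
    if (is.na(parsed)) {
      parsed <- if (toupper(val) %in% c("TRUE", "FALSE"))
        as.logical(toupper(val)) else val
    }
    if (key %in% em_names) cfg$em[[key]] <- parsed
    else if (key %in% names(cfg)) cfg[[key]] <- parsed
    else stop("unknown config key: ", key)
  }
  cfg
}
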