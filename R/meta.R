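FOCUS_STRUCTURES <- c("STN", "SN", "SN/VTA", "SN/STN")

#' Load a table of reported activation foci
#'
#' Reads a CSV of reported STN/SN BOLD fMRI activation coordinates (one row
#' per reported coordinate, study-level fields repeated). Cells marked
#' \code{"N.S."} or \code{"-"} are parsed as missing. If a manifest is given
#' (default: the one shipped next to the packaged fixture), the row count,
#' study count and per-structure row counts are validated against it.
#'
#' @param path CSV file; defaults to the packaged literature table
#'   (52 studies of STN/SN BOLD fMRI, coordinates already in MNI space).
#' @param manifest YAML manifest path, `NULL` to skip validation.
#' @return data.frame with columns study_id, task, field_strength_t,
#'   voxel_volume_mm3, fwhm_mm, structure, space, x, y, z, slice_gap,
#'   excluded_from_figure.
#' @export
loadFoci <- function(path = system.file("extdata", "literature_foci.csv",
                                        package = "subcortmix"),
                     manifest = defaultManifestFor(path)) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("study_id", "task", "field_strength_t", "voxel_volume_mm3",
            "fwhm_mm", "structure", "space", "x", "y", "z", "slice_gap",
            "excluded_from_figure")
  if (!all(need %in% names(raw)))
    stop("focus table header must contain: ", paste(need, collapse = ", "))
  asNum <- function(v, what) {
    v[v %in% c("N.S.", "-", "")] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric %s '%s' in row %d", what, v[bad[1]], bad[1]))
    out
  }
  badStruct <- which(!raw$structure %in% FOCUS_STRUCTURES)
  if (length(badStruct))
    stop(sprintf("unknown structure label '%s' in row %d",
                 raw$structure[badStruct[1]], badStruct[1]))
  badSpace <- which(!raw$space %in% c("MNI", "Talairach"))
  if (length(badSpace))
    stop(sprintf("unknown space '%s' in row %d",
                 raw$space[badSpace[1]], badSpace[1]))
  foci <- data.frame(
    study_id = raw$study_id, task = raw$task,
    field_strength_t = asNum(raw$field_strength_t, "field strength"),
    voxel_volume_mm3 = asNum(raw$voxel_volume_mm3, "voxel volume"),
    fwhm_mm = asNum(raw$fwhm_mm, "FWHM"),
    structure = raw$structure, space = raw$space,
    x = asNum(raw$x, "coordinate"), y = asNum(raw$y, "coordinate"),
    z = asNum(raw$z, "coordinate"),
    slice_gap = raw$slice_gap == "yes",
    excluded_from_figure = raw$excluded_from_figure == "yes")
  if (!is.null(manifest) && nzchar(manifest) && file.exists(manifest)) {
    m <- yaml::read_yaml(manifest)
    if (nrow(foci) != m$n_rows)
      stop(sprintf("fixture has %d rows, manifest expects %d", nrow(foci), m$n_rows))
    if (length(unique(foci$study_id)) != m$n_studies)
      stop("fixture study count disagrees with manifest")
    for (s in names(m$structure_rows))
      if (sum(foci$structure == s) != m$structure_rows[[s]])
        stop(sprintf("fixture has %d '%s' rows, manifest expects %d",
                     sum(foci$structure == s), s, m$structure_rows[[s]]))
  }
  foci
}

defaultManifestFor <- function(path) {
  m <- file.path(dirname(path), "literature_foci_manifest.yaml")
  if (file.exists(m)) m else NULL
}

# Pooled icbm2tal affine of Lancaster et al. (2007), Hum Brain Mapp 28:
# best-fit MNI/ICBM-152 -> Talairach transform pooled over SPM- and
# FSL-normalised data. talToMni applies its inverse.
lancasterIcbm2Tal <- function() {
  rbind(c(0.9357,  0.0029, -0.0072, -1.0423),
        c(-0.0065, 0.9396, -0.0726, -1.3940),
        c(0.0103,  0.0752,  0.8967,  3.6475),
        c(0,       0,       0,       1))
}

applyAffine <- function(A, coords) {
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1) else as.matrix(coords)
  out <- t(A %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (vec) drop(out) else out
}

#' Convert Talairach coordinates to MNI space
#'
#' Applies the inverse of the pooled icbm2tal affine (Lancaster et al. 2007)
#' to map Talairach mm coordinates into MNI space. `mniToTal` is the forward
#' transform; the two are exact inverses.
#'
#' @param coords mm triple or n x 3 matrix.
#' @return transformed coordinates, same shape.
#' @export
talToMni <- function(coords) applyAffine(solve(lancasterIcbm2Tal()), coords)

#' @rdname talToMni
#' @export
mniToTal <- function(coords) applyAffine(lancasterIcbm2Tal(), coords)

#' Assign a hemisphere to a focus from its x coordinate
#'
#' Convention: \code{x < 0} is left, \code{x >= 0} is right, so a midline
#' focus at x = 0 is grouped with the right hemisphere.
#'
#' @param x MNI x coordinate(s) in mm.
#' @return character vector of `"L"` / `"R"`.
#' @export
assignHemisphere <- function(x) {
  if (any(is.na(x))) stop("missing x coordinate")
  ifelse(x < 0, "L", "R")
}

structureGroupRef <- function(structure) {
  ifelse(structure == "STN", "STN", "SN")
}

#' Deviation of reported foci from reference centres of mass
#'
#' For every structure label and hemisphere, computes the signed per-axis
#' deviations (focus minus reference centre of mass; positive x is more
#' right, positive y more anterior, positive z more superior) and the
#' per-focus Euclidean distance, summarised as mean (sample SD) over foci.
#' STN foci are compared against the STN reference; SN, SN/VTA and SN/STN
#' foci against the SN reference. Foci without coordinates are dropped.
#'
#' @param foci data.frame from [loadFoci()].
#' @param refs data.frame with columns structure ("STN"/"SN"), hemisphere
#'   ("L"/"R"), x, y, z — e.g. from [atlasComTable()].
#' @return data.frame, one row per structure label x hemisphere: columns
#'   structure_group, hemisphere, n_coordinates, n_studies, mean_dx, sd_dx,
#'   mean_dy, sd_dy, mean_dz, sd_dz, mean_total, sd_total.
#' @export
deviationStats <- function(foci, refs) {
  f <- foci[!is.na(foci$x) & !is.na(foci$y) & !is.na(foci$z), , drop = FALSE]
  if (!nrow(f)) stop("no foci with complete coordinates")
  f$hemisphere <- assignHemisphere(f$x)
  f$refStructure <- structureGroupRef(f$structure)
  out <- list()
  for (s in intersect(FOCUS_STRUCTURES, unique(f$structure))) {
    for (h in c("L", "R")) {
      g <- f[f$structure == s & f$hemisphere == h, , drop = FALSE]
      if (!nrow(g)) next
      rs <- g$refStructure[1]
      r <- refs[refs$structure == rs & refs$hemisphere == h, , drop = FALSE]
      if (nrow(r) != 1)
        stop(sprintf("missing reference centre of mass for %s %s", rs, h))
      dx <- g$x - r$x; dy <- g$y - r$y; dz <- g$z - r$z
      tot <- sqrt(dx^2 + dy^2 + dz^2)
      out[[length(out) + 1L]] <- data.frame(
        structure_group = s, hemisphere = h, n_coordinates = nrow(g),
        n_studies = length(unique(g$study_id)),
        mean_dx = mean(dx), sd_dx = stats::sd(dx),
        mean_dy = mean(dy), sd_dy = stats::sd(dy),
        mean_dz = mean(dz), sd_dz = stats::sd(dz),
        mean_total = mean(tot), sd_total = stats::sd(tot))
    }
  }
  do.call(rbind, out)
}

perStudyMean <- function(foci, column) {
  vals <- foci[[column]]
  ok <- !is.na(vals)
  if (!any(ok)) return(numeric(0))
  tapply(vals[ok], foci$study_id[ok], mean)
}

#' Smoothing-kernel summary over studies
#'
#' Aggregates FWHM per study (mean over the kernels a study reports; studies
#' reporting none are excluded), then summarises across studies. The modal
#' kernel counts a study once if any of its reported kernels equals the mode.
#'
#' @param foci data.frame from [loadFoci()].
#' @return list with nStudies, nReporting, mean, median, mode, nModeStudies.
#' @export
kernelSummary <- function(foci) {
  if (!nrow(foci)) stop("empty focus table")
  per <- perStudyMean(foci, "fwhm_mm")
  if (!length(per)) stop("no study reports a smoothing kernel")
  ok <- !is.na(foci$fwhm_mm)
  sets <- tapply(foci$fwhm_mm[ok], foci$study_id[ok], unique)
  tab <- table(unlist(sets))
  mode <- as.numeric(names(tab)[which.max(tab)])
  list(nStudies = length(unique(foci$study_id)),
       nReporting = length(per),
       mean = mean(per), median = stats::median(per),
       mode = mode, nModeStudies = max(tab))
}

#' Voxel-volume summary over studies
#'
#' @param foci data.frame from [loadFoci()].
#' @return list with nStudies, nReporting, mean, median, sd, range; `sd` is
#'   `NA` when only one study reports.
#' @export
voxelSummary <- function(foci) {
  if (!nrow(foci)) stop("empty focus table")
  per <- perStudyMean(foci, "voxel_volume_mm3")
  list(nStudies = length(unique(foci$study_id)),
       nReporting = length(per),
       mean = if (length(per)) mean(per) else NA_real_,
       median = if (length(per)) stats::median(per) else NA_real_,
       sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       range = if (length(per)) range(per) else c(NA_real_, NA_real_))
}

#' Correlation between a coordinate axis and kernel size
#'
#' Pearson correlation between the reported coordinate on one axis and the
#' study's smoothing FWHM, over foci with both values present.
#'
#' @param foci data.frame from [loadFoci()].
#' @param structures structure labels to include (default: the SN-type
#'   labels SN, SN/VTA and SN/STN).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return list with r, df (n - 2) and two-sided p.
#' @export
coordKernelCorrelation <- function(foci,
                                   structures = c("SN", "SN/VTA", "SN/STN"),
                                   axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  g <- foci[foci$structure %in% structures &
              !is.na(foci[[axis]]) & !is.na(foci$fwhm_mm), , drop = FALSE]
  if (nrow(g) < 3) stop("need at least 3 complete coordinate/FWHM pairs")
  if (stats::sd(g$fwhm_mm) == 0) stop("FWHM is constant; correlation undefined")
  ct <- stats::cor.test(g[[axis]], g$fwhm_mm, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' STN-SN centre-of-mass separation per hemisphere
#'
#' @param refs data.frame as for [deviationStats()], containing an STN and an
#'   SN row for each hemisphere.
#' @return named numeric, Euclidean mm distance for `L` and `R`.
#' @export
comSeparation <- function(refs) {
  vapply(c(L = "L", R = "R"), function(h) {
    stn <- refs[refs$structure == "STN" & refs$hemisphere == h, , drop = FALSE]
    sn <- refs[refs$structure == "SN" & refs$hemisphere == h, , drop = FALSE]
    if (nrow(stn) != 1 || nrow(sn) != 1)
      stop("reference table must have one STN and one SN row per hemisphere")
    sqrt(sum((c(stn$x, stn$y, stn$z) - c(sn$x, sn$y, sn$z))^2))
  }, numeric(1))
}

#' Ratio of an ROI volume to a nucleus volume
#'
#' E.g. a 10 mm cube ROI (1000 mm^3) against the weighted median STN volume
#' of 131.75 mm^3 gives about 7.6.
#'
#' @param roiVolume,nucleusVolume volumes in mm^3 (positive).
#' @return the ratio.
#' @export
roiVolumeRatio <- function(roiVolume, nucleusVolume) {
  if (any(roiVolume <= 0) || any(nucleusVolume <= 0))
    stop("volumes must be positive")
  roiVolume / nucleusVolume
}

#' Reference centres of mass from a synthetic cohort
#'
#' Builds the four probabilistic atlases (STN/SN x L/R) from a cohort and
#' returns their centres of mass as a reference table.
#'
#' @param cohort list of [SubjectAnatomy-class] from [generateCohort()].
#' @param threshold `NULL` for probability-weighted centres of mass (default),
#'   or a level in \code{[0, 1]} to threshold first and use binary centres.
#' @return data.frame with columns structure, hemisphere, x, y, z, source.
#' @export
atlasComTable <- function(cohort, threshold = NULL) {
  rows <- list()
  for (s in c("STN", "SN")) {
    for (h in c("L", "R")) {
      atlas <- buildProbabilisticAtlas(cohort, s, h)
      com <- if (is.null(threshold)) centerOfMassMm(atlas)
             else centerOfMassMm(thresholdProbability(atlas, threshold))
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, hemisphere = h, x = com[1], y = com[2], z = com[3],
        source = "synthetic_atlas")
    }
  }
  do.call(rbind, rows)
}
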