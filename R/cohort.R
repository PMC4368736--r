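normalizeVec <- function(v) v / sqrt(sum(v^2))

crossVec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# small rotation from per-axis angles (radians), Rz %*% Ry %*% Rx
eulerRotation <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# orthonormal frame adapted to the STN-SN separation axis: p1 is the oblique
# antero-posterior direction perpendicular to `dirv`, p2 completes the frame
separationFrame <- function(dirv) {
  p1 <- c(0.57, -0.78, 0.24)
  p1 <- normalizeVec(p1 - sum(p1 * dirv) * dirv)
  list(p1 = p1, p2 = crossVec(dirv, p1))
}

# default STN orientation: the lens-shaped nucleus lies with its short axis
# along the separation direction (its flat ventro-medial face towards the SN)
# and its long axis oblique antero-posterior
stnDefaultRotation <- function(dirv) {
  fr <- separationFrame(dirv)
  cbind(fr$p1, fr$p2, dirv)
}

# default SN orientation: the long axis runs oblique antero-posterior
# (perpendicular to the separation axis); the medium axis points towards the
# STN but is tilted `tiltDeg` degrees off the contact axis, so the SN's broad
# dorso-lateral face lies under the STN without intersecting it
snDefaultRotation <- function(dirv, tiltDeg) {
  fr <- separationFrame(dirv)
  bTo <- -dirv
  th <- tiltDeg * pi / 180
  bax <- cos(th) * bTo + sin(th) * fr$p2
  cax <- -sin(th) * bTo + cos(th) * fr$p2
  cbind(fr$p1, bax, cax)
}

mirrorX <- function(v) c(-v[1], v[2], v[3])
mirrorRotation <- function(R) diag(c(-1, 1, 1)) %*% R

#' Create a synthetic cohort configuration
#'
#' Defaults encode the emulated study conditions: a 30-subject cohort on a
#' 0.5 mm isotropic grid, mean conjunct STN volume 119.88 mm^3 (the weighted
#' literature average), STN-SN centre-of-mass separations of 6.4 mm (left) and
#' 6.7 mm (right), an elongated oblique SN of 400 mm^3 with semi-axis ratio
#' 3:1.5:1 positioned ventro-medio-posterior to the STN, per-subject
#' positional, volumetric and orientation jitter, and probabilistic one-voxel
#' erosion emulating conservative two-rater conjunct masking. All values are
#' overridable; the shipped `anatomy_defaults.yaml` documents them.
#'
#' @param nSubjects cohort size (default 30).
#' @param seed base integer seed.
#' @param spacing isotropic voxel size, mm.
#' @param stnVolumeMean,stnVolumeSd STN volume distribution, mm^3.
#' @param snVolumeMean,snVolumeSd SN volume distribution, mm^3.
#' @param comSeparation numeric(2), STN-SN centre separation (left, right), mm.
#' @param centerJitterSd per-axis centre jitter SD, mm.
#' @param rotationJitterSd per-axis orientation jitter SD, degrees.
#' @param erosionProb probability of one-voxel conjunct-style erosion.
#' @param stnRatio,snRatio ellipsoid semi-axis ratios.
#' @param stnCenterLeft left STN centre, MNI mm (right mirrored in x).
#' @param separationDir direction from STN to SN centre for the left
#'   hemisphere (normalized internally).
#' @param snTiltDeg tilt of the SN medium axis off the STN-SN separation
#'   axis, degrees (keeps the nuclei disjoint while the SN's broad face lies
#'   under the STN).
#' @param maxFwhm largest FWHM (mm) the cohort grid must support.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nSubjects = 30L, seed = 1L, spacing = 0.5,
                         stnVolumeMean = 119.88, stnVolumeSd = 14,
                         snVolumeMean = 550, snVolumeSd = 60,
                         comSeparation = c(6.4, 6.7),
                         centerJitterSd = 0.3, rotationJitterSd = 3,
                         erosionProb = 0.5,
                         stnRatio = c(1.3, 1.05, 1), snRatio = c(3, 1.5, 1),
                         stnCenterLeft = c(-10, -13, -7),
                         separationDir = c(0.3, -0.4, -0.86),
                         snTiltDeg = 49, maxFwhm = 10) {
  new("CohortConfig", nSubjects = as.integer(nSubjects),
      seed = as.integer(seed), spacing = as.numeric(spacing),
      stnVolumeMean = stnVolumeMean, stnVolumeSd = stnVolumeSd,
      snVolumeMean = snVolumeMean, snVolumeSd = snVolumeSd,
      comSeparation = as.numeric(comSeparation),
      centerJitterSd = centerJitterSd, rotationJitterSd = rotationJitterSd,
      erosionProb = erosionProb, stnRatio = as.numeric(stnRatio),
      snRatio = as.numeric(snRatio),
      stnCenterLeft = as.numeric(stnCenterLeft),
      separationDir = as.numeric(separationDir),
      snTiltDeg = snTiltDeg, maxFwhm = maxFwhm)
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0(
    "CohortConfig: n=%d, seed=%d, %g mm grid\n",
    "  STN %.2f (SD %.1f) mm^3, SN %.0f (SD %.0f) mm^3\n",
    "  STN-SN separation %.1f (L) / %.1f (R) mm, jitter %.2f mm / %.1f deg, erosion p=%.2f\n"),
    object@nSubjects, object@seed, object@spacing,
    object@stnVolumeMean, object@stnVolumeSd,
    object@snVolumeMean, object@snVolumeSd,
    object@comSeparation[1], object@comSeparation[2],
    object@centerJitterSd, object@rotationJitterSd, object@erosionProb))
})

configSlotNames <- function() {
  c("nSubjects", "seed", "spacing", "stnVolumeMean", "stnVolumeSd",
    "snVolumeMean", "snVolumeSd", "comSeparation", "centerJitterSd",
    "rotationJitterSd", "erosionProb", "stnRatio", "snRatio",
    "stnCenterLeft", "separationDir", "snTiltDeg", "maxFwhm")
}

#' Read or write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [CohortConfig-class].
#' @return `readCohortConfig` returns a [CohortConfig-class]; unknown keys are
#'   an error, missing keys take their defaults.
#' @export
readCohortConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- configSlotNames()
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(cohortConfig, vals)
}

#' @rdname readCohortConfig
#' @export
writeCohortConfig <- function(config, path) {
  vals <- lapply(configSlotNames(), function(s) slot(config, s))
  names(vals) <- configSlotNames()
  yaml::write_yaml(vals, path, precision = 12)
  invisible(path)
}

# deterministic per-hemisphere geometry (before jitter) from a config
hemisphereLayout <- function(config, hemisphere) {
  left <- hemisphere == "L"
  dirUnit <- normalizeVec(config@separationDir)
  dirv <- if (left) dirUnit else mirrorX(dirUnit)
  stnC <- if (left) config@stnCenterLeft else mirrorX(config@stnCenterLeft)
  sep <- config@comSeparation[if (left) 1L else 2L]
  stnR <- stnDefaultRotation(dirUnit)
  snR <- snDefaultRotation(dirUnit, config@snTiltDeg)
  if (!left) { stnR <- mirrorRotation(stnR); snR <- mirrorRotation(snR) }
  list(stnCenter = stnC, snCenter = stnC + sep * dirv, dir = dirv,
       stnRotation = stnR, snRotation = snR)
}

# cohort grid for one hemisphere: bounding box of both nuclei plus jitter
# allowance plus a 4-sigma smoothing margin for the largest configured FWHM
cohortGrid <- function(config, hemisphere) {
  lay <- hemisphereLayout(config, hemisphere)
  allow <- 4 * config@centerJitterSd + 1.5
  margin <- 4 * fwhmToSigma(config@maxFwhm) + allow
  stnExt <- max(nucleusGeometry(lay$stnCenter, config@stnRatio,
                                config@stnVolumeMean)@semiAxes) * 1.35
  snExt <- max(nucleusGeometry(lay$snCenter, config@snRatio,
                               config@snVolumeMean)@semiAxes) * 1.35
  lower <- pmin(lay$stnCenter - stnExt, lay$snCenter - snExt) - margin
  upper <- pmax(lay$stnCenter + stnExt, lay$snCenter + snExt) + margin
  makeGrid(lower, upper, config@spacing)
}

# fixed offset between per-subject RNG substreams: adding subjects never
# reshuffles earlier ones
.subjectSeedOffset <- 104729L

generateSubject <- function(config, i, grids) {
  set.seed(config@seed + .subjectSeedOffset * i)
  masks <- list()
  for (h in c("L", "R")) {
    lay <- hemisphereLayout(config, h)
    grid <- grids[[h]]
    vStn <- max(stats::rnorm(1, config@stnVolumeMean, config@stnVolumeSd), 30)
    vSn <- max(stats::rnorm(1, config@snVolumeMean, config@snVolumeSd), 100)
    jStn <- stats::rnorm(3, 0, config@centerJitterSd)
    jSn <- stats::rnorm(3, 0, config@centerJitterSd)
    aStn <- stats::rnorm(3, 0, config@rotationJitterSd) * pi / 180
    aSn <- stats::rnorm(3, 0, config@rotationJitterSd) * pi / 180
    erodeStn <- stats::runif(1) < config@erosionProb
    erodeSn <- stats::runif(1) < config@erosionProb

    stnGeom <- nucleusGeometry(lay$stnCenter + jStn, config@stnRatio, vStn,
                               eulerRotation(aStn) %*% lay$stnRotation)
    stn <- voxelizeCalibrated(grid, stnGeom, erode = erodeStn)
    snCenter <- lay$snCenter + jSn
    snRot <- eulerRotation(aSn) %*% lay$snRotation
    sn <- NULL
    for (step in 0:10) {
      snGeom <- nucleusGeometry(snCenter + step * 0.25 * lay$dir,
                                config@snRatio, vSn, snRot)
      cand <- voxelizeCalibrated(grid, snGeom, erode = erodeSn)
      if (!any(stn@data & cand@data)) { sn <- cand; break }
    }
    if (is.null(sn))
      stop(sprintf("subject %d hemisphere %s: STN and SN overlap beyond repair", i, h))
    masks[[paste0("stn", h)]] <- stn
    masks[[paste0("sn", h)]] <- sn
  }
  new("SubjectAnatomy", subject = as.integer(i), stnL = masks$stnL,
      snL = masks$snL, stnR = masks$stnR, snR = masks$snR)
}

#' Generate a seeded cohort of paired STN/SN masks
#'
#' Draws per-subject nucleus volumes, centre positions and orientations from
#' the configured normal jitter around the hemisphere layout, voxelizes each
#' nucleus as a rotated ellipsoid with its realized (post-erosion) volume
#' calibrated to the drawn target, optionally applies one-voxel erosion
#' (conjunct-rater emulation), and enforces STN/SN disjointness, nudging the
#' SN apart along the separation axis in 0.25 mm steps if jitter makes the
#' nuclei touch. Fully deterministic given the config (including its seed);
#' per-subject RNG substreams use a fixed offset.
#'
#' @param config a [CohortConfig-class].
#' @return a list of [SubjectAnatomy-class] objects, one per subject, with the
#'   shared left/right [VoxelGrid-class] objects in attribute `"grids"` and the
#'   config in attribute `"config"`.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  grids <- list(L = cohortGrid(config, "L"), R = cohortGrid(config, "R"))
  cohort <- lapply(seq_len(config@nSubjects), function(i)
    generateSubject(config, i, grids))
  attr(cohort, "grids") <- grids
  attr(cohort, "config") <- config
  cohort
}

subjectMask <- function(subject, structure, hemisphere) {
  slot(subject, paste0(if (structure == "STN") "stn" else "sn", hemisphere))
}

#' Build a probabilistic atlas from a cohort
#'
#' Each voxel's value is the fraction of subjects whose mask contains it.
#'
#' @param cohort list of [SubjectAnatomy-class] sharing one grid per hemisphere.
#' @param structure `"STN"` or `"SN"`.
#' @param hemisphere `"L"` or `"R"`.
#' @return a probability [BrainVolume-class].
#' @export
buildProbabilisticAtlas <- function(cohort, structure = c("STN", "SN"),
                                    hemisphere = c("L", "R")) {
  structure <- match.arg(structure)
  hemisphere <- match.arg(hemisphere)
  if (!length(cohort)) stop("empty cohort")
  masks <- lapply(cohort, subjectMask, structure = structure,
                  hemisphere = hemisphere)
  grid <- masks[[1]]@grid
  for (m in masks)
    if (!identical(m@grid, grid)) stop("cohort masks are on mixed grids")
  acc <- array(0, grid@dim)
  for (m in masks) acc <- acc + m@data
  new("BrainVolume", grid = grid, data = acc / length(masks),
      space = "MNI", kind = "probability")
}
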