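# Synthetic multi-modality abdominal phantom.
#
# Coordinate convention (canonical RAS axis order): +x toward the patient's
# right, +y anterior, +z superior. Geometry is expressed as fractions of the
# grid so any gridShape works; organs are ellipsoids/cylinders at plausible
# relative positions, jittered per seed for inter-case variability.

#' Default tissue intensity table
#'
#' One row per phantom class giving the class id and the mean intensity in
#' each modality (arbitrary units; HU-like for CT). The orderings encode the
#' physics the transfer argument rests on: dense tissue is bright in CT and
#' dark in T1w (the soft-tissue ordering in T1w is a monotone decreasing map
#' of the CT ordering), fat is brightest in T1w, water-rich organs (kidney,
#' spleen, gallbladder, tumor) are brightest in T2wfs where fat and bone are
#' suppressed, and air is darkest everywhere. The numeric values are package
#' defaults chosen so that the default window segmenter resolves the classes
#' on CT-like input; they are editable via the CSV in
#' `system.file("extdata", "tissues_default.csv", package = "invertseg")`.
#'
#' @return A data.frame with columns `class`, `id`, `ct`, `t1`, `t2fs`.
#' @seealso [generatePhantom()], [defaultWindows()]
#' @export
defaultTissueTable <- function() {
  path <- system.file("extdata", "tissues_default.csv",
                      package = "invertseg", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$id <- as.integer(tab$id)
  tab
}

# Geometry of one phantom subject, as grid fractions: center (x, y, z) and
# ellipsoid semi-axes, or cylinder (center x, y + radius, full z extent).
.phantomGeometry <- function() {
  list(
    body    = list(type = "cylinder", c = c(0.50, 0.50), r = c(0.40, 0.33)),
    muscle  = list(type = "shell", inner = 0.86),   # of the body ellipse
    lung_left  = list(type = "ellipsoid", c = c(0.30, 0.50, 0.88),
                      a = c(0.13, 0.10, 0.085)),
    lung_right = list(type = "ellipsoid", c = c(0.70, 0.50, 0.88),
                      a = c(0.13, 0.10, 0.085)),
    liver   = list(type = "ellipsoid", c = c(0.68, 0.55, 0.64),
                   a = c(0.17, 0.14, 0.13)),
    spleen  = list(type = "ellipsoid", c = c(0.27, 0.52, 0.68),
                   a = c(0.085, 0.075, 0.085)),
    gallbladder = list(type = "ellipsoid", c = c(0.58, 0.55, 0.55),
                       a = c(0.045, 0.035, 0.055)),
    bone    = list(type = "cylinder", c = c(0.50, 0.28), r = c(0.08, 0.08)),
    aorta   = list(type = "cylinder", c = c(0.50, 0.43),
                   r = c(0.042, 0.042)),
    kidney_left  = list(type = "ellipsoid", c = c(0.33, 0.44, 0.42),
                        a = c(0.095, 0.075, 0.135)),
    kidney_right = list(type = "ellipsoid", c = c(0.67, 0.44, 0.42),
                        a = c(0.095, 0.075, 0.135))
  )
}

# Jitter centers (+-2% of grid) and semi-axes (+-8%) reproducibly. The RNG
# stream is already seeded by the caller. Left/right pairs keep their side.
.jitterGeometry <- function(geo) {
  for (nm in names(geo)) {
    g <- geo[[nm]]
    if (g$type == "ellipsoid") {
      g$c <- g$c + stats::runif(3, -0.02, 0.02)
      g$a <- g$a * stats::runif(3, 0.92, 1.08)
    } else if (g$type == "cylinder") {
      g$c <- g$c + stats::runif(2, -0.015, 0.015)
      g$r <- g$r * stats::runif(2, 0.92, 1.08)
    }
    geo[[nm]] <- g
  }
  geo
}

# Per-axis 0-based voxel coordinate grids as fractions of each dimension.
.fracCoords <- function(shape) {
  list(x = (seq_len(shape[1]) - 1) / (shape[1] - 1),
       y = (seq_len(shape[2]) - 1) / (shape[2] - 1),
       z = (seq_len(shape[3]) - 1) / (shape[3] - 1))
}

.ellipsoidMask <- function(shape, co, centre, axes) {
  dx <- (co$x - centre[1]) / axes[1]
  dy <- (co$y - centre[2]) / axes[2]
  dz <- (co$z - centre[3]) / axes[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
}

.cylinderMask <- function(shape, co, centre, radii) {
  dx <- (co$x - centre[1]) / radii[1]
  dy <- (co$y - centre[2]) / radii[2]
  xy <- outer(dx^2, dy^2, "+") <= 1
  array(rep(xy, shape[3]), shape)
}

# Smooth multiplicative bias field: random low-order polynomial in centred
# coordinates, scaled to a maximum relative deviation of `amplitude`.
.biasField <- function(shape, amplitude) {
  if (amplitude <= 0) return(array(1, shape))
  cx <- seq(-1, 1, length.out = shape[1])
  cy <- seq(-1, 1, length.out = shape[2])
  cz <- seq(-1, 1, length.out = shape[3])
  co <- stats::rnorm(9)
  f <- co[1] * outer(outer(cx, rep(1, shape[2])), rep(1, shape[3])) +
       co[2] * outer(outer(rep(1, shape[1]), cy), rep(1, shape[3])) +
       co[3] * outer(outer(rep(1, shape[1]), rep(1, shape[2])), cz) +
       co[4] * outer(outer(cx, cy), rep(1, shape[3])) +
       co[5] * outer(outer(cx, rep(1, shape[2])), cz) +
       co[6] * outer(outer(rep(1, shape[1]), cy), cz) +
       co[7] * outer(outer(cx^2, rep(1, shape[2])), rep(1, shape[3])) +
       co[8] * outer(outer(rep(1, shape[1]), cy^2), rep(1, shape[3])) +
       co[9] * outer(outer(rep(1, shape[1]), rep(1, shape[2])), cz^2)
  1 + amplitude * f / max(abs(f))
}

#' Generate one synthetic phantom case
#'
#' Builds the ground-truth label map from procedurally jittered organ
#' geometry, then renders co-registered CT-like, T1w-like and T2wfs-like
#' volumes from the tissue intensity table, with additive Gaussian noise
#' and a smooth multiplicative bias field. The renal lesion is a sphere of
#' the requested volume centred in the chosen kidney (large lesions balloon
#' beyond it, as renal tumors do), with intensity clearly distinct from
#' kidney parenchyma in CT and T2wfs but subtle in T1w. MRI background air
#' is exactly zero, emulating scanner background masking; CT air carries
#' noise around -1000.
#'
#' The same spec always produces bit-identical output.
#'
#' @param spec A [PhantomSpec-class].
#' @param tissueTable Tissue intensity table (default [defaultTissueTable()]).
#' @return A [PhantomCase-class].
#' @examples
#' case <- generatePhantom(PhantomSpec(gridShape = 48L, seed = 3L))
#' truthLabels(case)
#' @export
generatePhantom <- function(spec, tissueTable = defaultTissueTable()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, .generatePhantomImpl(spec, tissueTable))
}

.generatePhantomImpl <- function(spec, tab) {
  shape <- spec@gridShape
  vox <- prod(spec@spacing)              # mm^3 per voxel
  co <- .fracCoords(shape)
  geo <- .jitterGeometry(.phantomGeometry())

  ids <- stats::setNames(tab$id, tab$class)
  lab <- array(0L, shape)

  body <- .cylinderMask(shape, co, geo$body$c, geo$body$r)
  lab[body] <- ids[["fat"]]
  # muscle: outer shell of the body ellipse
  inner <- .cylinderMask(shape, co, geo$body$c, geo$body$r * geo$muscle$inner)
  lab[body & !inner] <- ids[["muscle"]]
  for (nm in c("lung_left", "lung_right", "liver", "spleen", "gallbladder")) {
    g <- geo[[nm]]
    lab[.ellipsoidMask(shape, co, g$c, g$a)] <- ids[[nm]]
  }
  for (nm in c("bone", "aorta")) {
    g <- geo[[nm]]
    lab[.cylinderMask(shape, co, g$c, g$r) & body] <- ids[[nm]]
  }
  for (nm in c("kidney_left", "kidney_right")) {
    g <- geo[[nm]]
    lab[.ellipsoidMask(shape, co, g$c, g$a)] <- ids[[nm]]
  }

  # lesion: sphere of the requested volume centred in the chosen kidney,
  # clipped to the body; error if the body cannot accommodate it
  kid <- geo[[paste0("kidney_", spec@tumorSide)]]
  rMM <- (3 * spec@tumorVolume * 1000 / (4 * pi))^(1 / 3)
  extentMM <- (shape - 1) * spec@spacing   # fractional coords span shape-1
  tumorMask <- .ellipsoidMask(shape, co, kid$c, rMM / extentMM) & body
  lab[tumorMask] <- ids[["tumor"]]
  realized <- sum(tumorMask) * vox / 1000
  if (abs(realized - spec@tumorVolume) / spec@tumorVolume > 0.10)
    stopf(paste0("tumor of %.3g cm^3 does not fit in the %s kidney region ",
                 "(realized %.3g cm^3)"), spec@tumorVolume, spec@tumorSide,
          realized)

  vocab <- ids[names(ids) != "air"]
  affine <- diag(c(spec@spacing, 1))
  truth <- LabelMap(lab, spacing = spec@spacing, affine = affine,
                    vocabulary = vocab)

  # render modalities: mean intensity lookup, bias field, noise
  lut <- function(column) {
    means <- numeric(max(tab$id) + 1L)
    means[tab$id + 1L] <- tab[[column]]
    array(means[lab + 1L], shape)
  }
  scale <- function(column) diff(range(tab[[column]]))
  render <- function(column, mriMask) {
    img <- lut(column) * .biasField(shape, spec@biasAmplitude)
    noise <- array(stats::rnorm(prod(shape), 0,
                                spec@noiseSD * scale(column)), shape)
    if (mriMask) {
      # scanner-style background masking: air stays exactly 0
      img[lab > 0L] <- img[lab > 0L] + noise[lab > 0L]
      img <- pmax(img, 0)
      img[lab == 0L] <- 0
    } else {
      img <- img + noise
    }
    img
  }
  ct <- Volume(render("ct", FALSE), spacing = spec@spacing,
               affine = affine, modality = "CT")
  t1 <- Volume(render("t1", TRUE), spacing = spec@spacing,
               affine = affine, modality = "T1w")
  t2 <- Volume(render("t2fs", TRUE), spacing = spec@spacing,
               affine = affine, modality = "T2wfs")
  new("PhantomCase", ct = ct, t1 = t1, t2fs = t2, truth = truth, spec = spec)
}

#' Generate a seeded cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from `masterSeed`; tumor
#' volumes are drawn log-uniformly in `tumorVolumeRange` and sides with
#' probabilities `sideFractions`. The defaults mirror a mid-sized renal
#' tumor cohort scaled to the phantom's field of view: volumes from 1 to
#' 200 cm^3 and a 45/55 left/right split.
#'
#' @param n Number of cases (>= 1).
#' @param masterSeed Integer master seed.
#' @param tumorVolumeRange Length-2 numeric `(lo, hi)` in cm^3, `0 < lo < hi`.
#' @param sideFractions Probabilities for `c(left, right)`; need not sum
#'   to 1 (normalized internally).
#' @param ... Further arguments passed to [PhantomSpec()] (e.g. `gridShape`,
#'   `noiseSD`).
#' @return A list of [PhantomCase-class] objects, named `case_01`, ...
#' @examples
#' cohort <- generateCohort(2, masterSeed = 7, gridShape = 48L)
#' @export
generateCohort <- function(n, masterSeed = 1L,
                           tumorVolumeRange = c(1, 200),
                           sideFractions = c(left = 0.45, right = 0.55),
                           ...) {
  if (n < 1) stopf("'n' must be >= 1")
  if (length(tumorVolumeRange) != 2L || tumorVolumeRange[1] <= 0 ||
      tumorVolumeRange[1] >= tumorVolumeRange[2])
    stopf("'tumorVolumeRange' must satisfy 0 < lo < hi")
  draws <- withSeed(masterSeed, {
    vols <- exp(stats::runif(n, log(tumorVolumeRange[1]),
                             log(tumorVolumeRange[2])))
    sides <- sample(c("left", "right"), n, replace = TRUE,
                    prob = sideFractions / sum(sideFractions))
    list(vols = vols, sides = sides)
  })
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- PhantomSpec(tumorVolume = draws$vols[i],
                        tumorSide = draws$sides[i],
                        seed = deriveSeed(masterSeed, i), ...)
    cases[[i]] <- generatePhantom(spec)
  }
  names(cases) <- sprintf("case_%02d", seq_len(n))
  cases
}

#' Write a phantom cohort to disk
#'
#' Writes, per case, `ct.nii.gz`, `t1.nii.gz`, `t2fs.nii.gz` and
#' `truth.nii.gz` (with its vocabulary sidecar) into `dir/<case id>/`,
#' plus a `manifest.json` recording each case's spec and the vocabulary.
#'
#' @param cases A list of [PhantomCase-class] (from [generateCohort()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    cdir <- file.path(dir, nm)
    dir.create(cdir, showWarnings = FALSE)
    writeVolume(cs@ct, file.path(cdir, "ct.nii.gz"))
    writeVolume(cs@t1, file.path(cdir, "t1.nii.gz"))
    writeVolume(cs@t2fs, file.path(cdir, "t2fs.nii.gz"))
    writeVolume(cs@truth, file.path(cdir, "truth.nii.gz"))
    sp <- cs@spec
    manifest[[nm]] <- list(
      gridShape = sp@gridShape, spacing = sp@spacing,
      tumorVolume = sp@tumorVolume, tumorSide = sp@tumorSide,
      noiseSD = sp@noiseSD, biasAmplitude = sp@biasAmplitude, seed = sp@seed)
  }
  manifest$vocabulary <- as.list(vocabulary(cases[[1]]@truth))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Mean intensity per tissue class
#'
#' Averages a volume's intensities within each labelled class of an aligned
#' label map — the per-tissue intensity profile used to verify that
#' inversion restores the CT brightness ordering in T1w images.
#'
#' @param v A [Volume-class].
#' @param labels An aligned [LabelMap-class].
#' @param classes Class names to include (default: all in the vocabulary).
#' @return Named numeric vector of mean intensities.
#' @export
tissueMeans <- function(v, labels, classes = names(vocabulary(labels))) {
  checkSameGrid(v@data, labels@data, "volume and label map")
  voc <- vocabulary(labels)[classes]
  vapply(voc, function(id) mean(v@data[labels@data == id]), numeric(1))
}

#' Non-air tissue classes of the phantom
#'
#' The phantom classes that contain tissue rather than air: everything but
#' background and the air-filled lungs. Used for the mechanism check that
#' inversion aligns the T1w brightness ordering with CT's.
#'
#' @return Character vector of class names.
#' @export
nonAirClasses <- function() {
  setdiff(defaultTissueTable()$class,
          c("air", "lung_left", "lung_right"))
}
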