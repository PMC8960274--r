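#' Parameters of the synthetic bone-phantom generator
#'
#' The generator emulates the statistical structure of a metacarpal-head
#' cohort when no real scans are available: a smooth articular head
#' (superellipsoid) on a cylindrical shaft, with class-specific surface
#' lesions. `"erosive"` phantoms carry hemispherical concavities subtracted at
#' boundary sites in a fixed "bare-area" angular sector; `"proliferative"`
#' phantoms carry spherical-cap protrusions added at sites in a distinct
#' "entheseal" sector; `"control"` phantoms are lesion-free.
#'
#' All linear units are voxels of the generation grid (`base_extent`).
#'
#' @param head_radius_range min/max of the head semi-axis, voxels.
#' @param shaft_radius_fraction shaft radius as a fraction of the head radius.
#' @param lesion_radius_range min/max lesion (ball) radius, voxels; the
#'   maximum must stay below the smallest head radius.
#' @param lesion_count_range min/max number of lesions per diseased phantom.
#' @param intensity_noise_sd SD of additive background noise on the intensity
#'   volume (the bone signal has magnitude ~1).
#' @param texture_smoothness correlation length (voxels) of the multiplicative
#'   trabecular-like texture inside the bone.
#' @param texture_amplitude relative amplitude of that texture.
#' @param base_extent generation grid, components >= 16.
#' @param rotation randomly rotate each scan (small rotations, up to
#'   `max_rotation_deg`), emulating repositioning between repeat scans.
#' @param max_rotation_deg maximum rotation per axis, degrees.
#' @param superellipse_exponent shape exponent of the head (2 = ellipsoid;
#'   larger values flatten the poles the way a metacarpal head is flattened).
#' @param erosion_sector,spur_sector azimuth window (degrees) of the lesion
#'   sectors on the head surface.
#' @param elevation_range elevation window (degrees) for lesion sites.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(head_radius_range = c(14, 18),
                           shaft_radius_fraction = 0.45,
                           lesion_radius_range = c(4.5, 7),
                           lesion_count_range = c(1L, 3L),
                           intensity_noise_sd = 0.05,
                           texture_smoothness = 3,
                           texture_amplitude = 0.3,
                           base_extent = c(64, 64, 40),
                           rotation = TRUE,
                           max_rotation_deg = 12,
                           superellipse_exponent = 2.5,
                           erosion_sector = c(55, 125),
                           spur_sector = c(235, 305),
                           elevation_range = c(-35, 35)) {
  p <- list(head_radius_range = as.numeric(head_radius_range),
            shaft_radius_fraction = as.numeric(shaft_radius_fraction),
            lesion_radius_range = as.numeric(lesion_radius_range),
            lesion_count_range = as.integer(lesion_count_range),
            intensity_noise_sd = as.numeric(intensity_noise_sd),
            texture_smoothness = as.numeric(texture_smoothness),
            texture_amplitude = as.numeric(texture_amplitude),
            base_extent = as.integer(round(base_extent)),
            rotation = isTRUE(rotation),
            max_rotation_deg = as.numeric(max_rotation_deg),
            superellipse_exponent = as.numeric(superellipse_exponent),
            erosion_sector = as.numeric(erosion_sector),
            spur_sector = as.numeric(spur_sector),
            elevation_range = as.numeric(elevation_range))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(p$head_radius_range) || !rng_ok(p$lesion_radius_range) ||
      !rng_ok(p$lesion_count_range))
    stop("all ranges must satisfy min <= max")
  if (p$lesion_radius_range[2] >= p$head_radius_range[1])
    stop("degenerate params: lesion radius must be smaller than the head radius")
  if (length(p$base_extent) != 3 || any(p$base_extent < 16))
    stop("base_extent components must be >= 16")
  if (p$shaft_radius_fraction <= 0 || p$shaft_radius_fraction >= 1)
    stop("shaft_radius_fraction must lie in (0, 1)")
  if (p$intensity_noise_sd < 0 || p$texture_smoothness < 0)
    stop("noise and smoothness parameters must be >= 0")
  invisible(p)
}

phantom_classes <- c("control", "erosive", "proliferative")

rotation_matrix <- function(ax, ay, az) {
  # intrinsic rotations about x, y, z (radians)
  cx <- cos(ax); sx <- sin(ax); cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# sample k lesion directions (unit vectors, object frame) inside an angular
# sector with a minimum pairwise separation
sample_lesion_sites <- function(k, azimuth_deg, elevation_deg, min_sep_deg = 25) {
  dirs <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(dirs) < k && tries < 500) {
    tries <- tries + 1
    az <- runif(1, azimuth_deg[1], azimuth_deg[2]) * pi / 180
    el <- runif(1, elevation_deg[1], elevation_deg[2]) * pi / 180
    u <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    if (nrow(dirs) == 0 ||
        all(acos(pmin(1, dirs %*% u)) * 180 / pi >= min_sep_deg))
      dirs <- rbind(dirs, u)
  }
  dirs
}

#' Generate one labeled bone phantom
#'
#' Deterministic given `(class_label, params, seed, scan_seed)`. The `seed`
#' stream draws the patient's anatomy (head radii, lesion number, sites and
#' sizes); the `scan_seed` stream draws scan-level nuisance (pose rotation,
#' centre jitter, intensity texture and noise), so repeat scans of one
#' patient share anatomy but differ in pose and texture.
#'
#' For `class_label = "undifferentiated"` a hidden truth (erosive or
#' proliferative) is drawn first from the anatomy stream and recorded in the
#' `latent_class` field; the sample itself is labeled `"undifferentiated"`.
#' Training code must never read `latent_class` — it exists solely to
#' validate triage on synthetic data.
#'
#' @param class_label `"control"`, `"erosive"`, `"proliferative"`, or
#'   `"undifferentiated"`.
#' @param params a [phantom_params] object.
#' @param seed anatomy seed (>= 0).
#' @param scan_seed scan-level seed; defaults to `seed`.
#' @return object of class `phantom_sample`: list with `intensity`,
#'   `bone_mask`, `lesion_mask` ([volume_grid]s), `class_label`,
#'   `latent_class`, `patient_id`, `scan_id`.
#' @examples
#' p <- phantom_params(base_extent = c(24, 24, 16), head_radius_range = c(6, 7),
#'                     lesion_radius_range = c(2, 3))
#' ph <- generate_phantom("erosive", p, seed = 7)
#' sum(ph$lesion_mask)
#' @export
generate_phantom <- function(class_label = c("control", "erosive",
                                             "proliferative", "undifferentiated"),
                             params = phantom_params(), seed,
                             scan_seed = seed) {
  class_label <- match.arg(class_label)
  validate_phantom_params(params)
  if (seed < 0) stop("seed must be >= 0")

  geom <- with_local_seed(seed, {
    # NOTE: the latent-class draw must stay the FIRST draw of this stream so
    # that generate_cohort() can predict it from the seed alone.
    latent <- if (class_label == "undifferentiated")
      sample(c("erosive", "proliferative"), 1) else class_label
    a <- runif(1, params$head_radius_range[1], params$head_radius_range[2])
    b <- a * runif(1, 0.85, 1.0)
    cc <- a * runif(1, 1.0, 1.15)
    k <- sample(seq(params$lesion_count_range[1], params$lesion_count_range[2]), 1)
    sector <- switch(latent, erosive = params$erosion_sector,
                     proliferative = params$spur_sector, NULL)
    dirs <- if (latent != "control" && k > 0)
      sample_lesion_sites(k, sector, params$elevation_range) else matrix(0, 0, 3)
    lrad <- if (nrow(dirs) > 0)
      runif(nrow(dirs), params$lesion_radius_range[1], params$lesion_radius_range[2])
      else numeric(0)
    list(latent = latent, radii = c(a, b, cc), dirs = dirs, lrad = lrad)
  })

  e <- params$base_extent
  pose <- with_local_seed(stage_seed(scan_seed, "scan"), {
    ang <- if (params$rotation)
      runif(3, -params$max_rotation_deg, params$max_rotation_deg) * pi / 180
      else c(0, 0, 0)
    jit <- runif(3, -1.5, 1.5)
    ce <- pmax(2L, as.integer(ceiling(e / max(params$texture_smoothness, 1))))
    tex <- array(rnorm(prod(ce)), ce)
    bg <- if (params$intensity_noise_sd > 0)
      array(rnorm(prod(e), sd = params$intensity_noise_sd), e) else 0
    list(ang = ang, jit = jit, tex = tex, bg = bg)
  })

  centre <- c(e[1] / 2 + 0.5, e[2] / 2 + 0.5, 0.62 * e[3]) + pose$jit
  R <- rotation_matrix(pose$ang[1], pose$ang[2], pose$ang[3])
  px <- seq_len(e[1]) - centre[1]
  py <- seq_len(e[2]) - centre[2]
  pz <- seq_len(e[3]) - centre[3]
  X <- array(rep(px, times = e[2] * e[3]), e)
  Y <- array(rep(rep(py, each = e[1]), times = e[3]), e)
  Z <- array(rep(pz, each = e[1] * e[2]), e)
  # object-frame coordinates: p_obj = R^T (p - centre)
  ox <- R[1, 1] * X + R[2, 1] * Y + R[3, 1] * Z
  oy <- R[1, 2] * X + R[2, 2] * Y + R[3, 2] * Z
  oz <- R[1, 3] * X + R[2, 3] * Y + R[3, 3] * Z

  pexp <- params$superellipse_exponent
  r3 <- geom$radii
  head <- (abs(ox) / r3[1])^pexp + (abs(oy) / r3[2])^pexp +
          (abs(oz) / r3[3])^pexp <= 1
  shaft <- (oz < 0) & (sqrt(ox^2 + oy^2) <= params$shaft_radius_fraction * min(r3[1:2]))
  base <- head | shaft

  lesion <- array(FALSE, e)
  if (nrow(geom$dirs) > 0) {
    ball <- array(FALSE, e)
    for (i in seq_len(nrow(geom$dirs))) {
      u <- geom$dirs[i, ]
      tstar <- ((abs(u[1]) / r3[1])^pexp + (abs(u[2]) / r3[2])^pexp +
                (abs(u[3]) / r3[3])^pexp)^(-1 / pexp)
      ctr <- tstar * u
      ball <- ball | ((ox - ctr[1])^2 + (oy - ctr[2])^2 + (oz - ctr[3])^2 <=
                        geom$lrad[i]^2)
    }
    if (geom$latent == "erosive") {
      lesion <- base & ball
      base <- base & !ball
    } else {
      lesion <- ball & !base
      base <- base | ball
    }
  }

  tex <- as_volume_values(resize_uniform(pose$tex, e))
  tex <- tex / max(stats::sd(tex), 1e-12)
  intensity <- base * (1 + params$texture_amplitude * tex) + pose$bg

  structure(list(intensity = volume_grid(intensity),
                 bone_mask = volume_grid(base + 0),
                 lesion_mask = volume_grid(lesion + 0),
                 class_label = class_label,
                 latent_class = geom$latent,
                 patient_id = NA_character_,
                 scan_id = NA_character_),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> class %s%s, bone %d voxels, lesion %d voxels\n",
              x$class_label,
              if (x$class_label != x$latent_class)
                paste0(" (latent ", x$latent_class, ")") else "",
              sum(x$bone_mask), sum(x$lesion_mask)))
  invisible(x)
}

#' Generate a synthetic cohort manifest
#'
#' Samples a per-patient class from `class_proportions`, gives each patient
#' one scan plus one additional repeat scan with probability
#' `repeat_scan_prob` (repeat scans share the patient's anatomy but differ in
#' pose and texture), and assigns per-patient anatomy seeds and per-scan
#' seeds. Volumes are not materialized here; [write_cohort] renders them.
#'
#' The unit of data splitting is always the patient: `scan_id` is unique,
#' `patient_id` repeats across repeat scans, and the class label is constant
#' within a patient.
#'
#' @param n_patients number of labeled patients (>= 1).
#' @param class_proportions length-3 probabilities for
#'   (control, erosive, proliferative); must sum to 1 within 1e-9.
#' @param repeat_scan_prob probability of one additional scan per patient.
#' @param params a [phantom_params].
#' @param seed cohort seed.
#' @param n_undifferentiated additional unlabeled patients whose hidden truth
#'   (erosive or proliferative) is recorded in the `latent_class` sidecar
#'   column, for triage validation only.
#' @return a `cohort_manifest` data frame with columns `patient_id`,
#'   `scan_id`, `class_label`, `latent_class`, `geom_seed`, `scan_seed`, and
#'   (after [write_cohort]) `intensity_path`, `mask_path`, `lesion_path`.
#' @examples
#' m <- generate_cohort(10, c(0.3, 0.4, 0.3), repeat_scan_prob = 0,
#'                      params = phantom_params(), seed = 1)
#' nrow(m)
#' @export
generate_cohort <- function(n_patients,
                            class_proportions = rep(1 / 3, 3),
                            repeat_scan_prob = 0.2,
                            params = phantom_params(),
                            seed = 1,
                            n_undifferentiated = 0) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (length(class_proportions) != 3 ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be 3 values summing to 1")
  if (repeat_scan_prob < 0 || repeat_scan_prob > 1)
    stop("repeat_scan_prob must be a probability")
  validate_phantom_params(params)

  rows <- with_local_seed(seed, {
    n_all <- n_patients + n_undifferentiated
    cls <- c(sample(phantom_classes, n_patients, replace = TRUE,
                    prob = class_proportions),
             rep("undifferentiated", n_undifferentiated))
    out <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      gseed <- sample.int(2147483600L, 1)
      nscan <- 1L + stats::rbinom(1, 1, repeat_scan_prob)
      sseeds <- sample.int(2147483600L, nscan)
      latent <- if (cls[i] == "undifferentiated")
        with_local_seed(gseed, sample(c("erosive", "proliferative"), 1))
        else cls[i]
      pid <- sprintf("P%04d", i)
      out[[i]] <- data.frame(
        patient_id = pid,
        scan_id = sprintf("%s_S%d", pid, seq_len(nscan)),
        class_label = cls[i],
        latent_class = latent,
        geom_seed = gseed,
        scan_seed = sseeds,
        intensity_path = NA_character_,
        mask_path = NA_character_,
        lesion_path = NA_character_,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  structure(rows, params = params, cohort_seed = seed,
            class = c("cohort_manifest", "data.frame"))
}

#' Render a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' Writes one intensity, one bone-mask and one lesion-mask NIfTI file per
#' scan (masks as unsigned 8-bit) and `manifest.csv`, and returns the updated
#' manifest with relative paths filled in. Volumes round-trip losslessly
#' through [read_volume] (masks bitwise).
#'
#' @param manifest a [generate_cohort] manifest.
#' @param directory output directory (created if missing).
#' @param params generator parameters; defaults to those stored on the
#'   manifest.
#' @return the manifest with path columns filled, invisibly also written to
#'   `manifest.csv`; attribute `dir` records `directory`.
#' @export
write_cohort <- function(manifest, directory,
                         params = attr(manifest, "params")) {
  if (is.null(params)) stop("no phantom_params found; pass 'params'")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  for (i in seq_len(nrow(manifest))) {
    s <- generate_phantom(manifest$class_label[i], params,
                          seed = manifest$geom_seed[i],
                          scan_seed = manifest$scan_seed[i])
    id <- manifest$scan_id[i]
    manifest$intensity_path[i] <- paste0(id, "_int.nii.gz")
    manifest$mask_path[i] <- paste0(id, "_mask.nii.gz")
    manifest$lesion_path[i] <- paste0(id, "_lesion.nii.gz")
    write_volume(s$intensity, file.path(directory, manifest$intensity_path[i]),
                 binary = FALSE)
    write_volume(s$bone_mask, file.path(directory, manifest$mask_path[i]))
    write_volume(s$lesion_mask, file.path(directory, manifest$lesion_path[i]))
  }
  write.csv(as.data.frame(manifest), file.path(directory, "manifest.csv"),
            row.names = FALSE)
  attr(manifest, "dir") <- directory
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  f <- file.path(directory, "manifest.csv")
  if (!file.exists(f)) stop("no manifest.csv in ", directory)
  m <- read.csv(f, stringsAsFactors = FALSE)
  structure(m, dir = directory, class = c("cohort_manifest", "data.frame"))
}
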