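# Synthetic cohort generator.
#
# Emulates the data-generating process the accuracy analysis assumes: a
# dental arch with surface landmarks and off-arch fiducial markers, a true
# cast->CBCT rigid transform, CBCT-side landmark localization noise
# (isotropic at fiducial markers; anisotropic at dental surface points, with
# the buccal-lingual component inflated as a metal-streak-artifact
# surrogate), and a guide mechanical error at placement (lateral offset,
# depth offset, tilt). Every draw flows from one recorded seed.

#' Scenario configuration
#'
#' All noise magnitudes of the synthetic model, with units. Cast-side (source)
#' points are treated as noise-free: desktop model scans are an order of
#' magnitude more precise than CBCT landmark localization, which the model
#' treats as the error source.
#'
#' @param n_surface_points Number of dental-surface registration points
#'   (default 5, the usual operator protocol; >= 3).
#' @param n_fiducials Number of fiducial markers (default 4; >= 3).
#' @param arch_radius_mm Half-width of the parabolic dental arch (default 25).
#' @param marker_sigma_mm Isotropic localization noise SD at fiducial markers
#'   (default 0.1 mm).
#' @param surface_sigma_mm In-plane localization noise SD at surface points
#'   (default 0.1 mm).
#' @param artifact_inflation Multiplier on `surface_sigma_mm` along each
#'   surface point's buccal-lingual normal (default 3; >= 1). Models
#'   metal-streak artifacts, which project buccal-lingually and blur those
#'   surfaces on CBCT.
#' @param guide_lateral_sigma_mm SD of the guide's lateral mechanical error
#'   in the plane perpendicular to the planned axis (default 0.3 mm, per
#'   in-plane direction).
#' @param guide_angle_sigma_deg SD of the guide tilt angle (default 1.5
#'   degrees).
#' @param guide_depth_sigma_mm SD of the depth (vertical stop) error along
#'   the planned axis (default 0.4 mm).
#' @param implant_length_mm Planned fixture length (default 10 mm).
#' @param n_implant_sites Number of planned implant sites on the arch
#'   (default 6).
#' @param max_rotation_deg,max_translation_mm Bounds of the true cast->CBCT
#'   transform drawn per scenario (defaults 5 degrees, 10 mm).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_surface_points = 5,
                            n_fiducials = 4,
                            arch_radius_mm = 25,
                            marker_sigma_mm = 0.1,
                            surface_sigma_mm = 0.1,
                            artifact_inflation = 3,
                            guide_lateral_sigma_mm = 0.3,
                            guide_angle_sigma_deg = 1.5,
                            guide_depth_sigma_mm = 0.4,
                            implant_length_mm = 10,
                            n_implant_sites = 6,
                            max_rotation_deg = 5,
                            max_translation_mm = 10) {
  cfg <- list(n_surface_points = as.integer(n_surface_points),
              n_fiducials = as.integer(n_fiducials),
              arch_radius_mm = arch_radius_mm,
              marker_sigma_mm = marker_sigma_mm,
              surface_sigma_mm = surface_sigma_mm,
              artifact_inflation = artifact_inflation,
              guide_lateral_sigma_mm = guide_lateral_sigma_mm,
              guide_angle_sigma_deg = guide_angle_sigma_deg,
              guide_depth_sigma_mm = guide_depth_sigma_mm,
              implant_length_mm = implant_length_mm,
              n_implant_sites = as.integer(n_implant_sites),
              max_rotation_deg = max_rotation_deg,
              max_translation_mm = max_translation_mm)
  sigmas <- c(cfg$marker_sigma_mm, cfg$surface_sigma_mm,
              cfg$guide_lateral_sigma_mm, cfg$guide_angle_sigma_deg,
              cfg$guide_depth_sigma_mm)
  if (any(!is.finite(sigmas)) || any(sigmas < 0)) {
    abort_config("All noise sigmas must be finite and >= 0.")
  }
  if (!is.finite(cfg$artifact_inflation) || cfg$artifact_inflation < 1) {
    abort_config("`artifact_inflation` must be >= 1.")
  }
  if (cfg$n_surface_points < 3L) {
    abort_config("`n_surface_points` must be >= 3 (rigid registration needs 3 non-collinear points).")
  }
  if (cfg$n_fiducials < 3L) {
    abort_config("`n_fiducials` must be >= 3 (rigid registration needs 3 non-collinear points).")
  }
  if (cfg$implant_length_mm <= 0 || cfg$arch_radius_mm <= 0 ||
      cfg$n_implant_sites < 1L) {
    abort_config("Arch radius, implant length and number of sites must be positive.")
  }
  structure(cfg, class = "scenario_config")
}

# Parabolic arch y = R (1 - t^2), x = R t, z = 0, t in [-1, 1]; outward
# (buccal) in-plane normal at parameter t.
arch_point <- function(t, R) cbind(R * t, R * (1 - t^2), 0)

arch_buccal_normal <- function(t) {
  n <- cbind(2 * t, 1, 0)
  n / .row_norms(n)
}

#' Generate a synthetic registration scenario
#'
#' Builds the fixed geometry of one synthetic case: surface landmark points
#' on a parabolic dental arch (with their outward buccal normals), fiducial
#' markers on an off-arch template (buccally offset and above the occlusal
#' plane), planned implants at arch sites with axes near the occlusal
#' direction, and a true cast->CBCT rigid transform (rotation up to
#' `max_rotation_deg`, translation up to `max_translation_mm`).
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `guidedev_scenario` with elements
#'   `surface_points`, `surface_normals`, `fiducial_points` (matrices, cast
#'   space), `planned` (implant tibble, cast space), `true_transform`, and
#'   `config`.
#' @export
generate_scenario <- function(config = scenario_config(), seed = NULL) {
  if (!inherits(config, "scenario_config")) {
    config <- do.call(scenario_config, as.list(config))
  }
  with_seed_or_stream(seed, {
    R <- config$arch_radius_mm
    ts <- seq(-0.9, 0.9, length.out = config$n_surface_points)
    surface <- arch_point(ts, R)
    normals <- arch_buccal_normal(ts)

    tf <- seq(-0.75, 0.75, length.out = config$n_fiducials)
    fid <- arch_point(tf, R) + 6 * arch_buccal_normal(tf) +
      matrix(c(0, 0, 4), config$n_fiducials, 3, byrow = TRUE)

    # Planned implants: platform on the arch, axis tilted <= 5 degrees off
    # the apical (-z) occlusal direction.
    ti <- seq(-0.8, 0.8, length.out = config$n_implant_sites)
    plat <- arch_point(ti, R)
    L <- config$implant_length_mm
    apex <- matrix(NA_real_, config$n_implant_sites, 3)
    for (i in seq_len(config$n_implant_sites)) {
      ax <- drop(random_small_rotation(5) %*% c(0, 0, -1))
      apex[i, ] <- plat[i, ] + L * ax
    }
    planned <- tibble::tibble(id = paste0("site", seq_len(config$n_implant_sites)),
                              px = plat[, 1], py = plat[, 2], pz = plat[, 3],
                              ax = apex[, 1], ay = apex[, 2], az = apex[, 3])

    rot <- random_small_rotation(config$max_rotation_deg)
    dir <- rnorm(3); dir <- dir / .vnorm(dir)
    trans <- dir * runif(1, 0, config$max_translation_mm)

    structure(list(surface_points = surface,
                   surface_normals = normals,
                   fiducial_points = fid,
                   planned = planned,
                   true_transform = rigid_transform(rot, trans),
                   config = config),
              class = "guidedev_scenario")
  })
}

#' @export
print.guidedev_scenario <- function(x, ...) {
  cat("<guidedev_scenario> ", nrow(x$surface_points), " surface points, ",
      nrow(x$fiducial_points), " fiducials, ",
      nrow(x$planned), " planned implants\n", sep = "")
  invisible(x)
}

# Internal: draw anisotropic noise for surface targets. Directions are the
# CBCT-space images of the buccal normals; sigma_normal applies along them,
# sigma_inplane in the two perpendicular directions.
surface_noise <- function(normals_cbct, sigma_inplane, sigma_normal) {
  n <- nrow(normals_cbct)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nm <- normals_cbct[i, ]
    ref <- if (abs(nm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * nm) * nm
    u <- u / .vnorm(u)
    v <- c(nm[2] * u[3] - nm[3] * u[2],
           nm[3] * u[1] - nm[1] * u[3],
           nm[1] * u[2] - nm[2] * u[1])
    out[i, ] <- rnorm(1, 0, sigma_normal) * nm +
      rnorm(1, 0, sigma_inplane) * u + rnorm(1, 0, sigma_inplane) * v
  }
  out
}

#' Corrupt a scenario's correspondences with localization noise
#'
#' Produces the point-correspondence table a registration operator would
#' obtain: source points are the noise-free cast-space landmarks, targets are
#' their true CBCT-space images plus localization noise. In
#' `"fiducial_marker"` mode the noise is isotropic Gaussian with SD
#' `marker_sigma`; in `"dental_surface"` mode it is anisotropic, with SD
#' `surface_sigma` in-plane and `surface_sigma * inflation` along each
#' point's buccal-lingual normal (the streak-artifact direction).
#'
#' @param scenario A [generate_scenario()] result.
#' @param mode `"dental_surface"` or `"fiducial_marker"`.
#' @param marker_sigma,surface_sigma,inflation Noise parameters; default to
#'   the scenario's config.
#' @param noise_scale Extra multiplier on all localization sigmas (used to
#'   model, e.g., harder-to-segment jaws).
#' @param seed Optional integer seed.
#' @return A correspondence tibble with columns `sx`, `sy`, `sz`, `tx`, `ty`,
#'   `tz`, `label`.
#' @export
corrupt_correspondences <- function(scenario,
                                    mode = c("dental_surface", "fiducial_marker"),
                                    marker_sigma = NULL, surface_sigma = NULL,
                                    inflation = NULL, noise_scale = 1,
                                    seed = NULL) {
  if (!inherits(scenario, "guidedev_scenario")) {
    abort_config("`scenario` must come from generate_scenario().")
  }
  if (length(mode) == 1L && !mode %in% c("dental_surface", "fiducial_marker")) {
    abort_config(paste0("Unknown registration mode '", mode,
                        "': use 'dental_surface' or 'fiducial_marker'."))
  }
  mode <- match.arg(mode)
  cfg <- scenario$config
  marker_sigma <- (marker_sigma %||% cfg$marker_sigma_mm) * noise_scale
  surface_sigma <- (surface_sigma %||% cfg$surface_sigma_mm) * noise_scale
  inflation <- inflation %||% cfg$artifact_inflation
  tt <- scenario$true_transform
  with_seed_or_stream(seed, {
    if (mode == "fiducial_marker") {
      src <- scenario$fiducial_points
      tgt <- transform_points(tt, src)
      if (marker_sigma > 0) {
        tgt <- tgt + matrix(rnorm(length(tgt), 0, marker_sigma), nrow(tgt), 3)
      }
      label <- "fiducial"
    } else {
      src <- scenario$surface_points
      tgt <- transform_points(tt, src)
      if (surface_sigma > 0 || inflation > 1) {
        normals_cbct <- scenario$surface_normals %*% t(tt$rotation)
        tgt <- tgt + surface_noise(normals_cbct, surface_sigma,
                                   surface_sigma * inflation)
      }
      label <- "surface"
    }
    tibble::tibble(sx = src[, 1], sy = src[, 2], sz = src[, 3],
                   tx = tgt[, 1], ty = tgt[, 2], tz = tgt[, 3],
                   label = label)
  })
}

# Internal single-implant placement used by both simulate_placement() and the
# cohort loop. platform/apex are length-3 planned centers (cast space);
# d_plat/d_apex are registration TRE displacement vectors at those centers.
place_one <- function(platform, apex, d_plat, d_apex,
                      lat_sigma, depth_sigma, angle_sigma) {
  a <- (apex - platform) / .vnorm(apex - platform)
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * a) * a
  u <- u / .vnorm(u)
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  guide <- rnorm(1, 0, lat_sigma) * u + rnorm(1, 0, lat_sigma) * v +
    rnorm(1, 0, depth_sigma) * a
  plat2 <- platform + d_plat + guide
  apex2 <- apex + d_apex + guide
  if (angle_sigma > 0) {
    phi <- runif(1, 0, 2 * pi)
    tilt_axis <- cos(phi) * u + sin(phi) * v
    Rt <- rotation_axis_angle(tilt_axis, rnorm(1, 0, angle_sigma))
    apex2 <- plat2 + drop(Rt %*% (apex2 - plat2))
  }
  list(platform = plat2, apex = apex2)
}

#' Simulate guided placement of planned implants
#'
#' Displaces each planned implant by (i) the registration error field — the
#' TRE displacement of the estimated versus true transform, evaluated
#' separately at the platform and apex so the angular component of
#' misregistration is preserved — and (ii) a guide mechanical error: an
#' isotropic lateral offset in the plane perpendicular to the planned axis
#' (SD `guide_lateral_sigma_mm` per direction), a depth offset along the axis
#' (SD `guide_depth_sigma_mm`), and a tilt about a random perpendicular axis
#' through the platform (angle SD `guide_angle_sigma_deg`).
#'
#' @param planned Planned implant data frame (columns `id`, `px`..`az`).
#' @param estimated A `rigid_registration` or estimated [rigid_transform()].
#' @param true_transform The scenario's true [rigid_transform()].
#' @param config A [scenario_config()] supplying the guide sigmas.
#' @param guide_scale Multiplier on all three guide sigmas (e.g. for
#'   distal-extension guides that can tilt or bend on their free end).
#' @param seed Optional integer seed.
#' @return A tibble of placed implants with the same columns as `planned`.
#' @export
simulate_placement <- function(planned, estimated, true_transform,
                               config = scenario_config(), guide_scale = 1,
                               seed = NULL) {
  .check_implant_df(planned, "`planned`")
  est <- .as_transform(estimated)
  with_seed_or_stream(seed, {
    P <- as.matrix(planned[, c("px", "py", "pz")])
    A <- as.matrix(planned[, c("ax", "ay", "az")])
    dP <- tre_displacement(est, true_transform, P)
    dA <- tre_displacement(est, true_transform, A)
    out <- tibble::as_tibble(planned)
    for (i in seq_len(nrow(planned))) {
      pl <- place_one(P[i, ], A[i, ], dP[i, ], dA[i, ],
                      config$guide_lateral_sigma_mm * guide_scale,
                      config$guide_depth_sigma_mm * guide_scale,
                      config$guide_angle_sigma_deg * guide_scale)
      out$px[i] <- pl$platform[1]; out$py[i] <- pl$platform[2]; out$pz[i] <- pl$platform[3]
      out$ax[i] <- pl$apex[1]; out$ay[i] <- pl$apex[2]; out$az[i] <- pl$apex[3]
    }
    out
  })
}

#' Cohort factor design
#'
#' A cohort design is a cell-count table over the three design factors:
#' registration method (`dental_surface` / `fiducial_marker`), jaw
#' (`maxilla` / `mandible`), and guide support (`mucosa`, `bilateral_tooth`,
#' `distal_extension`). `default_cohort_design()` returns a fixed 56-implant
#' design whose one-way margins are 21/35 (registration), 23/33 (jaw) and
#' 28/20/8 (guide support) — the layout of a typical partially edentulous
#' sCAIS cohort in which fiducial-marker cases are mostly mucosa-supported.
#'
#' @param design A data frame with columns `registration_method`, `jaw`,
#'   `guide_support`, `n`.
#' @return A validated tibble of class `cohort_design`.
#' @export
cohort_design <- function(design) {
  need <- c("registration_method", "jaw", "guide_support", "n")
  missing <- setdiff(need, names(design))
  if (length(missing)) {
    abort_config(paste0("Design is missing column(s): ",
                        paste(missing, collapse = ", "), "."))
  }
  if (any(design$n < 0) || sum(design$n) < 1) {
    abort_config("Design cell counts must be >= 0 with a positive total.")
  }
  bad <- setdiff(design$registration_method, c("dental_surface", "fiducial_marker"))
  if (length(bad)) abort_config(paste0("Unknown registration method: ", bad[1], "."))
  bad <- setdiff(design$jaw, c("maxilla", "mandible"))
  if (length(bad)) abort_config(paste0("Unknown jaw level: ", bad[1], "."))
  bad <- setdiff(design$guide_support, c("mucosa", "bilateral_tooth", "distal_extension"))
  if (length(bad)) abort_config(paste0("Unknown guide support level: ", bad[1], "."))
  structure(tibble::as_tibble(design), class = c("cohort_design", class(tibble::tibble())))
}

#' @rdname cohort_design
#' @export
default_cohort_design <- function() {
  cohort_design(tibble::tribble(
    ~registration_method, ~jaw, ~guide_support, ~n,
    "dental_surface", "maxilla", "bilateral_tooth", 6,
    "dental_surface", "maxilla", "distal_extension", 2,
    "dental_surface", "maxilla", "mucosa", 1,
    "dental_surface", "mandible", "bilateral_tooth", 8,
    "dental_surface", "mandible", "distal_extension", 4,
    "fiducial_marker", "maxilla", "mucosa", 11,
    "fiducial_marker", "maxilla", "bilateral_tooth", 2,
    "fiducial_marker", "maxilla", "distal_extension", 1,
    "fiducial_marker", "mandible", "mucosa", 16,
    "fiducial_marker", "mandible", "bilateral_tooth", 4,
    "fiducial_marker", "mandible", "distal_extension", 1
  ))
}

#' Group-effect switches for cohort simulation
#'
#' `cohort_effects()` holds the mechanisms that make factor groups differ;
#' `null_effects()` switches them all off (for calibration runs every group
#' is then statistically identical, provided the config's marker and surface
#' sigmas are equal).
#'
#' @param surface_artifact If `TRUE`, dental-surface registrations use the
#'   config's buccal-lingual `artifact_inflation`; if `FALSE` they are
#'   isotropic.
#' @param distal_extension_guide_mult Multiplier on the guide mechanical
#'   sigmas for distal-extension (one-side tooth-supported) guides
#'   (default 2).
#' @param maxilla_noise_mult Multiplier on CBCT localization noise for
#'   maxillary cases (default 1.5; maxillary bone is less dense and harder to
#'   segment).
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(surface_artifact = TRUE,
                           distal_extension_guide_mult = 2,
                           maxilla_noise_mult = 1.5) {
  if (distal_extension_guide_mult < 0 || maxilla_noise_mult < 0) {
    abort_config("Effect multipliers must be >= 0.")
  }
  structure(list(surface_artifact = isTRUE(surface_artifact),
                 distal_extension_guide_mult = distal_extension_guide_mult,
                 maxilla_noise_mult = maxilla_noise_mult),
            class = "cohort_effects")
}

#' @rdname cohort_effects
#' @export
null_effects <- function() {
  cohort_effects(surface_artifact = FALSE,
                 distal_extension_guide_mult = 1,
                 maxilla_noise_mult = 1)
}

#' Generate a synthetic deviation cohort
#'
#' Simulates one full study: a scenario geometry is drawn, then each implant
#' in the design gets an independent registration (its mode's localization
#' noise), an independent guide mechanical error, and its six deviation
#' metrics are measured. Rows are statistically independent, matching the
#' downstream analysis which treats implants as independent observations.
#'
#' @param design A [cohort_design()] (default [default_cohort_design()]).
#' @param config A [scenario_config()].
#' @param effects A [cohort_effects()] list.
#' @param seed Optional integer seed; fixes the whole cohort.
#' @return A deviation tibble (one row per implant) with the six metric
#'   columns of [measure_deviations()] plus `registration_method`, `jaw`,
#'   `guide_support`.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' nrow(coh)  # 56
#' @export
generate_cohort <- function(design = default_cohort_design(),
                            config = scenario_config(),
                            effects = cohort_effects(),
                            seed = NULL) {
  if (!inherits(design, "cohort_design")) design <- cohort_design(design)
  if (!inherits(effects, "cohort_effects")) {
    abort_config("`effects` must come from cohort_effects() or null_effects().")
  }
  with_seed_or_stream(seed, {
    scenario <- generate_scenario(config)
    cfg <- scenario$config
    tt <- scenario$true_transform
    Rt <- tt$rotation
    ttr <- tt$translation

    rows <- design[rep(seq_len(nrow(design)), design$n),
                   c("registration_method", "jaw", "guide_support")]
    n <- nrow(rows)
    surf_src <- scenario$surface_points
    surf_tgt0 <- transform_points(tt, surf_src)
    norm_cbct <- scenario$surface_normals %*% t(Rt)
    fid_src <- scenario$fiducial_points
    fid_tgt0 <- transform_points(tt, fid_src)
    nsites <- nrow(scenario$planned)
    P <- as.matrix(scenario$planned[, c("px", "py", "pz")])
    A <- as.matrix(scenario$planned[, c("ax", "ay", "az")])

    placed_P <- matrix(NA_real_, n, 3)
    placed_A <- matrix(NA_real_, n, 3)
    site <- (seq_len(n) - 1L) %% nsites + 1L
    for (i in seq_len(n)) {
      nm <- if (rows$jaw[i] == "maxilla") effects$maxilla_noise_mult else 1
      if (rows$registration_method[i] == "fiducial_marker") {
        tgt <- fid_tgt0 +
          matrix(rnorm(length(fid_tgt0), 0, cfg$marker_sigma_mm * nm),
                 nrow(fid_tgt0), 3)
        fit <- fit_rigid_core(fid_src, tgt)
      } else {
        infl <- if (effects$surface_artifact) cfg$artifact_inflation else 1
        tgt <- surf_tgt0 + surface_noise(norm_cbct, cfg$surface_sigma_mm * nm,
                                         cfg$surface_sigma_mm * nm * infl)
        fit <- fit_rigid_core(surf_src, tgt)
      }
      s <- site[i]
      p <- P[s, ]; a <- A[s, ]
      d_p <- drop(fit$rotation %*% p) + fit$translation - (drop(Rt %*% p) + ttr)
      d_a <- drop(fit$rotation %*% a) + fit$translation - (drop(Rt %*% a) + ttr)
      gs <- if (rows$guide_support[i] == "distal_extension") {
        effects$distal_extension_guide_mult
      } else 1
      pl <- place_one(p, a, d_p, d_a,
                      cfg$guide_lateral_sigma_mm * gs,
                      cfg$guide_depth_sigma_mm * gs,
                      cfg$guide_angle_sigma_deg * gs)
      placed_P[i, ] <- pl$platform
      placed_A[i, ] <- pl$apex
    }

    planned_tab <- tibble::tibble(
      id = paste0("implant", seq_len(n)),
      px = P[site, 1], py = P[site, 2], pz = P[site, 3],
      ax = A[site, 1], ay = A[site, 2], az = A[site, 3],
      registration_method = rows$registration_method,
      jaw = rows$jaw,
      guide_support = rows$guide_support
    )
    placed_tab <- tibble::tibble(
      id = planned_tab$id,
      px = placed_P[, 1], py = placed_P[, 2], pz = placed_P[, 3],
      ax = placed_A[, 1], ay = placed_A[, 2], az = placed_A[, 3]
    )
    measure_deviations(planned_tab, placed_tab)
  })
}

#' Serialize a scenario to JSON
#'
#' Full-precision JSON serialization of a scenario's geometry and true
#' transform, used for reproducibility checks and by the CLI.
#'
#' @param scenario A [generate_scenario()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  obj <- list(
    surface_points = scenario$surface_points,
    surface_normals = scenario$surface_normals,
    fiducial_points = scenario$fiducial_points,
    planned = scenario$planned,
    true_rotation_row_major = as.numeric(t(scenario$true_transform$rotation)),
    true_translation_mm = scenario$true_transform$translation,
    config = unclass(scenario$config)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
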