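# Synthetic two-class ED/ES left-ventricle cohort generator.
#
# The LV is modeled as two nested truncated prolate spheroids (endocardium
# inside epicardium) sampled on a fixed apex + (rings x longitudes) parameter
# grid below a basal truncation plane; homologous correspondence across cases
# is by grid position.  Four latent remodeling factors -- overall scale,
# sphericity (radius-to-length ratio), wall thickness, and a localized apical
# bulge -- plus a systolic contraction factor are drawn per case around
# class-specific means, so the disease class exhibits the canonical
# post-infarction phenotypes: larger, more spherical ventricles with thinner
# walls, apical bulging, and reduced contraction.  The planted discriminant
# direction is recorded as ground truth for parameter-recovery tests.
#
# Case-to-case variability beyond the latent factors is modeled as a smooth
# random deformation field (a low-order tensor basis over the apex-base and
# circumferential surface parameters, shared by the endo- and epicardial
# surfaces of a frame) plus a small isotropic per-point jitter.  Surface
# models fitted to images vary smoothly, not pointwise, so the population
# covariance is low-rank and a retained-variance PCA cutoff keeps a mode
# count far below the case count -- the same regime as clinical shape
# atlases.

#' Mesh topology of one sampled LV surface
#'
#' One surface is an apex vertex plus `n_rings` rings of `n_long` longitudes
#' (total `1 + n_rings * n_long` vertices).  Faces are returned for the open
#' surface (no basal cap), wound with outward normals.
#'
#' @param n_rings Number of latitude rings below the apex.
#' @param n_long Number of longitudes per ring.
#' @return List with `n_rings`, `n_long`, `n_vertices`, and integer face
#'   matrix `faces` (F x 3, 1-based).
#' @export
lv_topology <- function(n_rings, n_long) {
  n_rings <- as.integer(n_rings); n_long <- as.integer(n_long)
  if (n_rings < 2L || n_long < 3L)
    stopf("topology needs >= 2 rings and >= 3 longitudes")
  v <- function(i, j) 1L + (i - 1L) * n_long + ((j - 1L) %% n_long) + 1L
  faces <- vector("list", n_long * (2L * (n_rings - 1L) + 1L))
  k <- 0L
  for (j in seq_len(n_long)) {         # apex fan
    k <- k + 1L; faces[[k]] <- c(1L, v(1L, j + 1L), v(1L, j))
  }
  for (i in seq_len(n_rings - 1L)) {   # bands
    for (j in seq_len(n_long)) {
      k <- k + 1L; faces[[k]] <- c(v(i, j), v(i, j + 1L), v(i + 1L, j + 1L))
      k <- k + 1L; faces[[k]] <- c(v(i, j), v(i + 1L, j + 1L), v(i + 1L, j))
    }
  }
  faces <- do.call(rbind, faces)
  list(n_rings = n_rings, n_long = n_long,
       n_vertices = 1L + n_rings * n_long, faces = faces)
}

# Close an open LV surface with a basal cap: one added center vertex plus a
# triangle fan over the basal ring, wound to keep normals outward.
close_surface <- function(points, topo) {
  nb <- topo$n_vertices - topo$n_long + seq_len(topo$n_long)  # basal ring
  center <- colMeans(points[nb, , drop = FALSE])
  cid <- nrow(points) + 1L
  jj <- seq_len(topo$n_long)
  cap <- cbind(cid, nb[jj], nb[c(jj[-1L], jj[1L])])
  list(points = rbind(points, center), faces = rbind(topo$faces, cap))
}

# Sample one truncated prolate spheroid surface.  `a` is the long semi-axis
# (mm, apex at z = -a), `b` the equatorial radius, `z_base` the absolute
# truncation height.  `bulge` displaces points radially outward with a
# Gaussian falloff from the apex (width in normalized apex-base parameter).
lv_surface <- function(a, b, z_base, topo, bulge = 0, bulge_width = 0.35) {
  if (a <= 0 || b <= 0) stopf("degenerate geometry: non-positive semi-axes")
  if (z_base <= -a || z_base > a)
    stopf("degenerate geometry: truncation plane outside spheroid")
  u <- seq_len(topo$n_rings) / topo$n_rings
  z <- -a + u * (z_base + a)
  r <- b * sqrt(pmax(0, 1 - (z / a)^2))
  if (r[topo$n_rings] <= 0) stopf("degenerate geometry: zero basal radius")
  th <- 2 * pi * (seq_len(topo$n_long) - 1L) / topo$n_long
  ring <- cbind(rep(r, each = topo$n_long) * cos(th),
                rep(r, each = topo$n_long) * sin(th),
                rep(z, each = topo$n_long))
  pts <- rbind(c(0, 0, -a), ring)
  if (bulge != 0) {
    uu <- c(0, rep(u, each = topo$n_long))
    m <- bulge * exp(-(uu / bulge_width)^2)
    nrm <- sqrt(rowSums(pts^2))
    pts <- pts + pts / pmax(nrm, 1e-12) * m
  }
  pts
}

#' Closed truncated-spheroid test mesh
#'
#' A single closed surface (apex + rings + basal cap) sampled from a prolate
#' spheroid with long semi-axis `a` and equatorial radius `b`, truncated at
#' `z = z_frac * a`.  Mainly useful for validating [mesh_volume()] against
#' the closed-form truncated-spheroid volume.
#'
#' @param a,b Semi-axes (mm): long axis `a` along z, equatorial radius `b`.
#' @param z_frac Truncation height as a fraction of `a`, in (-1, 1].
#' @param n_rings,n_long Sampling density.
#' @return List with `points` (V x 3) and `faces` (F x 3).
#' @export
spheroid_mesh <- function(a, b, z_frac = 0.3, n_rings = 24, n_long = 24) {
  topo <- lv_topology(n_rings, n_long)
  close_surface(lv_surface(a, b, z_frac * a, topo), topo)
}

#' Signed volume of a closed triangulated surface
#'
#' Computes the enclosed volume by the divergence theorem (sum of signed
#' origin tetrahedra over triangles), returned positive for outward-oriented
#' meshes and converted from mm^3 to ml.  The mesh must be combinatorially
#' closed and consistently oriented: every directed edge must appear exactly
#' once, paired with its reverse.
#'
#' @param points Vertex matrix V x 3 (mm) or a [point_set_shape].
#' @param faces Integer face matrix F x 3 (1-based).
#' @return Volume in ml (signed; positive for outward orientation).
#' @export
mesh_volume <- function(points, faces) {
  if (inherits(points, "point_set_shape")) points <- points$points
  points <- as.matrix(points)
  faces <- as.matrix(faces)
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(edges[, 1], edges[, 2])
  if (anyDuplicated(key))
    stopf("mesh is not consistently oriented: duplicated directed edge")
  rev_key <- paste(edges[, 2], edges[, 1])
  if (!all(rev_key %in% key))
    stopf("mesh is open: boundary edges present")
  v1 <- points[faces[, 1], , drop = FALSE]
  v2 <- points[faces[, 2], , drop = FALSE]
  v3 <- points[faces[, 3], , drop = FALSE]
  det3 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(det3) / 6 / 1000
}

default_covariate_params <- function() {
  list(
    control = list(sex_male = 0.49, age = c(61.47, 10.15),
                   height = c(165.97, 9.99), weight = c(76.75, 16.50),
                   systolic_bp = c(126.00, 22.00),
                   diastolic_bp = c(71.49, 10.33),
                   diabetes = 0.3567, smoking = 0.1133),
    case = list(sex_male = 0.80, age = c(62.76, 10.80),
                height = c(173.91, 9.80), weight = c(90.06, 19.15),
                systolic_bp = c(127.50, 20.14),
                diastolic_bp = c(73.86, 11.34),
                diabetes = 0.1311, smoking = 0.1251))
}

#' Parameters of the synthetic LV cohort generator
#'
#' Defaults emulate the clinical study conditions: class sizes 1991
#' asymptomatic controls vs 300 infarct patients, 1682 points per frame
#' (two surfaces of `1 + n_rings * n_long` points each), covariate
#' distributions matching the published demographics, and planted
#' class-mean offsets on the four remodeling phenotypes (scale, sphericity,
#' wall thickness, apical bulge) plus reduced systolic contraction.
#' `hetero_factor` > 1 inflates the disease-class latent SDs, reproducing
#' the heteroscedasticity that violates the LDA equal-covariance assumption.
#'
#' @param n_control,n_case Class sizes (>= 2 each).
#' @param n_rings,n_long Surface sampling grid; points per frame
#'   P = 2 * (1 + n_rings * n_long).  Defaults give P = 1682; the desk-scale
#'   preset `n_rings = 12, n_long = 10` gives P = 242.
#' @param base_geometry ED control geometry (mm) and systolic kinematics:
#'   `long_axis` (endocardial long semi-axis), `base_radius` (endocardial
#'   equatorial radius), `wall_thickness`, `z_frac` (basal truncation as
#'   fraction of the long axis), `es_long_contraction` (fractional long-axis
#'   shortening at ES), `es_wall_gain` (systolic wall thickening factor),
#'   `contraction` (mean fractional radial contraction at ES).
#' @param effect_sizes Disease-class mean offsets for `scale`, `sphericity`
#'   (both multiplicative factors around 1), `wall_thickness` (mm),
#'   `apical_bulge` (mm), and `contraction` (fraction; negative = the
#'   disease class contracts less).
#' @param latent_sd Within-class SDs of the same five latent factors.
#' @param hetero_factor Multiplier on disease-class latent SDs
#'   (1 = homoscedastic classes).
#' @param severe_fraction Fraction of the disease class drawn from a severe
#'   (aneurysmal) remodeling subgroup whose latent means are shifted by
#'   `severe_effects`; makes the disease-class latent distribution bimodal,
#'   emulating the within-class non-normality seen in infarct cohorts.
#'   0 disables the subgroup (Gaussian classes).
#' @param severe_effects Additional latent-mean offsets of the severe
#'   subgroup (same fields as `effect_sizes`).
#' @param smooth_noise_sd Pointwise SD (mm) of the smooth random deformation
#'   field drawn per case per frame on a fixed low-order surface basis
#'   (6 tensor functions of the apex-base parameter and the circumferential
#'   angle, per coordinate, shared across the two surfaces of a frame).
#' @param point_noise_sd Isotropic per-point Gaussian jitter (mm) on top of
#'   the smooth field.
#' @param covariate_params Per-class means/SDs/proportions for the covariate
#'   record; see `lvremodel:::default_covariate_params()`.
#' @param seed Integer seed; the cohort is fully determined by it.
#' @return A validated parameter list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_control = 1991, n_case = 300,
                             n_rings = 28, n_long = 30,
                             base_geometry = list(),
                             effect_sizes = list(),
                             latent_sd = list(),
                             hetero_factor = 1.5,
                             severe_fraction = 0.35,
                             severe_effects = list(),
                             smooth_noise_sd = 1.2,
                             point_noise_sd = 0.1,
                             covariate_params = default_covariate_params(),
                             seed = 1) {
  geom <- utils::modifyList(
    list(long_axis = 50, base_radius = 27, wall_thickness = 9, z_frac = 0.3,
         es_long_contraction = 0.12, es_wall_gain = 1.35, contraction = 0.28),
    base_geometry)
  eff <- utils::modifyList(
    list(scale = 0.05, sphericity = 0.05, wall_thickness = -1.0,
         apical_bulge = 1.5, contraction = -0.05),
    effect_sizes)
  lsd <- utils::modifyList(
    list(scale = 0.06, sphericity = 0.05, wall_thickness = 0.8,
         apical_bulge = 0.8, contraction = 0.03),
    latent_sd)
  if (n_control < 2 || n_case < 2) stopf("need >= 2 cases per class")
  if (any(unlist(lsd) < 0)) stopf("latent SDs must be >= 0")
  if (hetero_factor <= 0) stopf("hetero_factor must be > 0")
  if (geom$wall_thickness <= 0 || geom$long_axis <= 0 || geom$base_radius <= 0)
    stopf("degenerate base geometry")
  if (geom$contraction <= 0 || geom$contraction >= 1)
    stopf("mean contraction must lie in (0, 1)")
  sev <- utils::modifyList(
    list(scale = 0.05, sphericity = 0, wall_thickness = 0,
         apical_bulge = 3.5, contraction = -0.06),
    severe_effects)
  if (severe_fraction < 0 || severe_fraction > 1)
    stopf("severe_fraction must lie in [0, 1]")
  structure(list(n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 n_rings = as.integer(n_rings), n_long = as.integer(n_long),
                 base_geometry = geom, effect_sizes = eff, latent_sd = lsd,
                 hetero_factor = hetero_factor,
                 severe_fraction = severe_fraction, severe_effects = sev,
                 smooth_noise_sd = smooth_noise_sd,
                 point_noise_sd = point_noise_sd,
                 covariate_params = covariate_params,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# Smooth-deformation basis evaluated at every vertex of one surface:
# tensor products {1, u} x {1, cos, sin} of the normalized apex-base
# parameter u and the circumferential angle, columns scaled to unit RMS.
# The same field displaces endo- and epicardium, so wall thickness is
# preserved under it.
smooth_basis <- function(topo) {
  u <- c(0, rep(seq_len(topo$n_rings) / topo$n_rings, each = topo$n_long))
  th <- c(0, rep(2 * pi * (seq_len(topo$n_long) - 1L) / topo$n_long,
                 times = topo$n_rings))
  B <- cbind(1, u, cos(th), sin(th), u * cos(th), u * sin(th))
  sweep(B, 2L, sqrt(colMeans(B^2)), `/`)
}

# Latent factors of one case -> the noise-free concatenated (endo, epi)
# point stack for one frame.
case_frame_points <- function(lat, frame, geom, topo) {
  a <- geom$long_axis * lat$scale
  b <- geom$base_radius * lat$scale * lat$sphericity
  w <- lat$wall
  if (frame == "ES") {
    a <- a * (1 - geom$es_long_contraction)
    b <- b * (1 - lat$contraction)
    w <- w * geom$es_wall_gain
  }
  if (w <= 0) stopf("degenerate geometry: non-positive wall thickness")
  if (b <= 0) stopf("degenerate geometry: non-positive cavity radius")
  z_base <- geom$z_frac * a
  endo <- lv_surface(a, b, z_base, topo, bulge = lat$bulge)
  epi <- lv_surface(a + w, b + w, z_base, topo, bulge = lat$bulge)
  rbind(endo, epi)
}

class_mean_latents <- function(params, class) {
  eff <- params$effect_sizes
  sev <- params$severe_effects
  g <- params$base_geometry
  k <- if (class == 1) 1 else 0
  ks <- k * params$severe_fraction        # expected severe contribution
  list(scale = 1 + k * eff$scale + ks * sev$scale,
       sphericity = 1 + k * eff$sphericity + ks * sev$sphericity,
       wall = g$wall_thickness + k * eff$wall_thickness + ks * sev$wall_thickness,
       bulge = 0 + k * eff$apical_bulge + ks * sev$apical_bulge,
       contraction = g$contraction + k * eff$contraction + ks * sev$contraction)
}

#' Generate a synthetic two-class LV cohort
#'
#' Draws per-case latent remodeling factors around class means, builds the
#' noise-free nested-spheroid ED and ES surfaces at homologous grid
#' positions, adds isotropic per-point Gaussian noise, and draws a clinical
#' covariate record per case.  The output is fully determined by
#' `params$seed`.
#'
#' @param params A [synthetic_params()] object.
#' @return List with `cohort` (a [shape_cohort] whose cases are controls
#'   `ctl001...` followed by patients `mi001...`) and `truth` (per-case
#'   latent factors plus `true_direction`, the unit-norm planted discriminant
#'   direction in concatenated ED&ES point space: the difference between the
#'   noise-free class-mean shapes).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  topo <- lv_topology(params$n_rings, params$n_long)
  geom <- params$base_geometry

  with_seed(params$seed, {
    n <- params$n_control + params$n_case
    class <- rep(c(0L, 1L), c(params$n_control, params$n_case))
    ids <- c(sprintf("ctl%03d", seq_len(params$n_control)),
             sprintf("mi%03d", seq_len(params$n_case)))

    # covariates first, then latents, then point noise: fixed draw order
    covariates <- do.call(rbind, lapply(seq_len(n), function(i) {
      cp <- params$covariate_params[[if (class[i] == 1) "case" else "control"]]
      data.frame(case_id = ids[i],
                 sex = stats::rbinom(1, 1, cp$sex_male),
                 age = stats::rnorm(1, cp$age[1], cp$age[2]),
                 height = stats::rnorm(1, cp$height[1], cp$height[2]),
                 weight = stats::rnorm(1, cp$weight[1], cp$weight[2]),
                 systolic_bp = stats::rnorm(1, cp$systolic_bp[1], cp$systolic_bp[2]),
                 diastolic_bp = stats::rnorm(1, cp$diastolic_bp[1], cp$diastolic_bp[2]),
                 diabetes = stats::rbinom(1, 1, cp$diabetes),
                 smoking = stats::rbinom(1, 1, cp$smoking))
    }))

    eff <- params$effect_sizes
    sev <- params$severe_effects
    lsd <- params$latent_sd
    sdm <- ifelse(class == 1, params$hetero_factor, 1)
    severe <- class * stats::rbinom(n, 1, params$severe_fraction)
    latents <- data.frame(
      case_id = ids, class = class, severe = severe,
      scale = stats::rnorm(n, 1 + class * eff$scale + severe * sev$scale,
                           lsd$scale * sdm),
      sphericity = stats::rnorm(n, 1 + class * eff$sphericity +
                                  severe * sev$sphericity,
                                lsd$sphericity * sdm),
      wall = stats::rnorm(n, geom$wall_thickness + class * eff$wall_thickness +
                            severe * sev$wall_thickness,
                          lsd$wall_thickness * sdm),
      bulge = stats::rnorm(n, class * eff$apical_bulge +
                             severe * sev$apical_bulge,
                           lsd$apical_bulge * sdm),
      contraction = stats::rnorm(n, geom$contraction + class * eff$contraction +
                                   severe * sev$contraction,
                                 lsd$contraction * sdm))
    bad <- latents$wall <= 0 | latents$scale <= 0 | latents$sphericity <= 0 |
      latents$contraction <= 0 | latents$contraction >= 1
    if (any(bad))
      stopf("degenerate geometry drawn for case(s): %s (reduce latent SDs)",
            paste(ids[bad], collapse = ", "))

    surf <- rep(c("endo", "epi"), each = topo$n_vertices)
    B <- smooth_basis(topo)
    K <- ncol(B)
    shapes <- stats::setNames(lapply(seq_len(n), function(i) {
      lat <- as.list(latents[i, ])
      out <- list()
      for (fr in FRAMES) {
        pts <- case_frame_points(lat, fr, geom, topo)
        C <- matrix(stats::rnorm(3L * K, 0, params$smooth_noise_sd / sqrt(K)),
                    K, 3L)
        disp <- B %*% C
        pts <- pts + rbind(disp, disp)   # same field on endo and epi
        pts <- pts + matrix(stats::rnorm(length(pts), 0, params$point_noise_sd),
                            nrow(pts), 3L)
        out[[fr]] <- point_set_shape(ids[i], fr, pts, surface = surf)
      }
      out
    }), ids)

    cohort <- shape_cohort(shapes, stats::setNames(class, ids), covariates,
                           topology = topo)

    mean_shape <- function(cl) {
      lat <- class_mean_latents(params, cl)
      c(t(case_frame_points(lat, "ED", geom, topo)),
        t(case_frame_points(lat, "ES", geom, topo)))
    }
    dvec <- mean_shape(1) - mean_shape(0)
    nv <- sqrt(sum(dvec^2))
    true_direction <- if (nv > 0) dvec / nv else dvec

    list(cohort = cohort,
         truth = list(latents = latents, true_direction = true_direction,
                      frames = FRAMES, seed = params$seed))
  })
}

# Mosteller body-surface area (m^2) from height (cm) and weight (kg).
bsa_mosteller <- function(height, weight) sqrt(height * weight / 3600)

#' Cavity volumes, ejection fraction, and indexed volumes per case
#'
#' Closes each case's endocardial (and epicardial) surface with a basal cap
#' and integrates the cavity volume by the divergence theorem.  EF is
#' (EDV - ESV) / EDV; EDVI/ESVI are indexed to Mosteller body-surface area
#' computed from the covariate height and weight; LV mass uses the
#' myocardial shell volume (epi minus endo) at ED times a density of
#' 1.05 g/ml.
#'
#' @param cohort A meshed [shape_cohort] (must carry a topology, as produced
#'   by [generate_cohort()] or read from a manifest with topology metadata).
#' @return Data frame with one row per case: `edv`, `esv` (ml), `ef`, `bsa`
#'   (m^2), `edvi`, `esvi` (ml/m^2), `lv_mass` (g), and `esv_gt_edv` flag.
#' @export
derived_volumes <- function(cohort) {
  topo <- cohort$topology
  if (is.null(topo))
    stopf("cohort carries no mesh topology; cavity volumes need one")
  nv <- topo$n_vertices
  cav <- function(points, rows) {
    m <- close_surface(points[rows, , drop = FALSE], topo)
    mesh_volume(m$points, m$faces)
  }
  rows <- lapply(cohort$case_ids, function(id) {
    ed <- cohort$shapes[[id]]$ED$points
    es <- cohort$shapes[[id]]$ES$points
    edv <- cav(ed, seq_len(nv))
    esv <- cav(es, seq_len(nv))
    epi_ed <- cav(ed, nv + seq_len(nv))
    if (edv <= 0) stopf("case '%s': non-positive ED cavity volume", id)
    cv <- cohort$covariates[cohort$covariates$case_id == id, ]
    bsa <- bsa_mosteller(cv$height, cv$weight)
    data.frame(case_id = id, edv = edv, esv = esv, ef = (edv - esv) / edv,
               bsa = bsa, edvi = edv / bsa, esvi = esv / bsa,
               lv_mass = (epi_ed - edv) * 1.05, esv_gt_edv = esv > edv)
  })
  out <- do.call(rbind, rows)
  if (any(out$esv_gt_edv))
    warnf("%d case(s) with ESV > EDV (negative EF); flagged, not fatal",
          sum(out$esv_gt_edv))
  out
}
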