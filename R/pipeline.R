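# Orchestration of the full two-step registration.
#
# 2D stage: en-face images (SLO and/or layer-bounded projections) ->
# keypoints -> mutual-NN matching -> RANSAC affine -> warp the moving volume
# and surfaces onto the fixed en-face grid. Z stage: column shifting or
# layer point matching. The mono-/multi-modal switch is configuration only:
# any en-face image can stand on the fixed side.

#' Pipeline configuration
#'
#' @param projection a [projection_spec()] for OCT en-face projections
#'   (default hybrid — the best-performing mode).
#' @param z_method `"column_shift"` (default), `"lpm_rigid"` or
#'   `"lpm_similarity"`.
#' @param net a trained [keypoint_net()] (or path to a weights checkpoint);
#'   not needed in oracle-keypoint mode.
#' @param keypoints a [keypoint_params()].
#' @param ransac a [ransac_params()] (its seed is overridden by `seed`).
#' @param lpm an [lpm_params()] (spacing fields are filled in from the data).
#' @param oracle optional oracle correspondences (list with `fixed_um`,
#'   `moving_um` point matrices, as produced by the phantom generator):
#'   bypasses the network so the geometric stages can run without a model.
#' @param common_pitch_um pixel pitch (micrometres) both en-face images are
#'   resampled to before keypoint extraction, so descriptor patches cover
#'   comparable retinal areas; `NULL` keeps each image's native grid.
#'   Defaults to the fixed image's finer axis pitch.
#' @param seed master seed for all stochastic stages.
#' @export
pipeline_config <- function(projection = projection_spec("hybrid"),
                            z_method = c("column_shift", "lpm_rigid",
                                         "lpm_similarity"),
                            net = NULL,
                            keypoints = keypoint_params(),
                            ransac = ransac_params(),
                            lpm = lpm_params(),
                            oracle = NULL,
                            common_pitch_um = NA,
                            seed = 0L) {
  z_method <- match.arg(z_method)
  if (is.character(net)) net <- load_weights(net)
  list(projection = projection, z_method = z_method, net = net,
       keypoints = keypoints, ransac = ransac, lpm = lpm, oracle = oracle,
       common_pitch_um = common_pitch_um, seed = as.integer(seed))
}

# keypoint_set directly from oracle metric correspondences
oracle_keypoints <- function(points_um, spacing) {
  n <- nrow(points_um)
  xy <- cbind(points_um[, 1] / spacing[2], points_um[, 2] / spacing[1])
  # orthogonal one-hot descriptors make the oracle matching exact
  D <- diag(n)
  keypoint_set(xy, rep(1, n), rep(1, n), rep(1, n), D, spacing)
}

#' Run the full two-step registration on one volume pair
#'
#' @param fixed list with `volume` ([oct_volume()]), `surfaces`
#'   ([surface_set()] with at least ILM) and optionally `enface` (an
#'   [enface_image()]: SLO or a projection; computed from the volume when
#'   absent) and `landmarks` (a [landmark_set()] in the fixed en-face
#'   image).
#' @param moving list with `volume`, `surfaces` and optionally `landmarks`
#'   (in the moving projection).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, transforms, projections and
#'   the report are persisted there.
#' @return List with `transform2d`, `z_transform` ([zshift_field()] or
#'   [bscan_transforms()]), `volume_registered`, `surfaces_registered`,
#'   `report`, and the intermediate `fixed_enface` / `moving_enface` /
#'   `keypoints` / `matches`. When the 2D stage fails, `failed` is `TRUE`,
#'   the report carries the reason and the Z stage is not attempted.
#' @export
register_pair <- function(fixed, moving, config = pipeline_config(),
                          out_dir = NULL) {
  for (side in list(fixed, moving)) {
    assert_that(!is.null(side$volume) && !is.null(side$surfaces),
                "each side needs a volume and surfaces")
    assert_that("ILM" %in% names(side$surfaces$heights),
                "surfaces must include ILM")
  }
  t_start <- Sys.time()
  fixed_grid <- enface_grid(fixed$volume)
  moving_grid <- enface_grid(moving$volume)

  fixed_enface <- fixed$enface %||%
    project_enface(fixed$volume, fixed$surfaces, config$projection,
                   normalize = TRUE)
  moving_enface <- project_enface(moving$volume, moving$surfaces,
                                  config$projection, normalize = TRUE)

  # ---- 2D stage ----
  if (!is.null(config$oracle)) {
    kp_f <- oracle_keypoints(config$oracle$fixed_um, fixed_enface$spacing)
    kp_m <- oracle_keypoints(config$oracle$moving_um, moving_enface$spacing)
    matches <- match_descriptors(kp_f, kp_m)
  } else {
    assert_that(!is.null(config$net),
                "a trained network (or oracle correspondences) is required")
    pitch <- config$common_pitch_um
    if (length(pitch) == 1 && is.na(pitch)) pitch <- min(fixed_enface$spacing)
    ef <- fixed_enface; em <- moving_enface
    if (!is.null(pitch)) {
      ef <- resample_enface(ef, pitch)
      em <- resample_enface(em, pitch)
    }
    kp_f <- extract_keypoints(ef, config$net, config$keypoints)
    kp_m <- extract_keypoints(em, config$net, config$keypoints)
    matches <- match_descriptors(kp_f, kp_m)
  }
  rp <- config$ransac
  rp$seed <- derive_seed(config$seed, "ransac2d")
  T2D <- if (nrow(matches) >= 3) {
    estimate_affine_ransac(matches, kp_f, kp_m, rp)
  } else {
    registration_failure(sprintf("only %d matches", nrow(matches)))
  }

  report <- list(seed = config$seed, z_method = config$z_method,
                 projection_mode = config$projection$mode,
                 n_keypoints_fixed = length(kp_f),
                 n_keypoints_moving = length(kp_m),
                 n_matches = nrow(matches))

  have_lm <- !is.null(fixed$landmarks) && !is.null(moving$landmarks)
  failed_2d <- inherits(T2D, "registration_failure")
  if (!failed_2d && have_lm) {
    report$landmark_error_before_um <-
      landmark_error(fixed$landmarks, moving$landmarks, NULL)
    report$landmark_error_after_um <-
      landmark_error(fixed$landmarks, moving$landmarks, T2D)
    report$failure_2d <- detect_failure(fixed$landmarks, moving$landmarks, T2D)
  } else if (failed_2d) {
    report$failure_2d <- TRUE
    report$failure_reason <- T2D$reason
  }

  result <- list(transform2d = T2D, fixed_enface = fixed_enface,
                 moving_enface = moving_enface,
                 keypoints = list(fixed = kp_f, moving = kp_m),
                 matches = matches)

  if (failed_2d || isTRUE(report$failure_2d)) {
    # an incorrect 2D registration cannot be repaired axially; stop here
    result$failed <- TRUE
    result$report <- report
    if (!is.null(out_dir)) persist_outputs(result, out_dir)
    return(result)
  }
  result$failed <- FALSE

  # ---- warp moving volume + surfaces onto the fixed en-face grid ----
  warped <- apply_enface_transform(moving$volume, moving$surfaces, T2D,
                                   fixed_grid)
  # bring moving heights into the fixed axial pixel scale
  zratio <- moving$volume$spacing[2] / fixed$volume$spacing[2]
  warped_surf <- warped$surfaces
  if (abs(zratio - 1) > 1e-12) {
    warped_surf$heights <- lapply(warped_surf$heights, function(h) h * zratio)
  }

  # ---- Z stage ----
  if (config$z_method == "column_shift") {
    delta <- column_shift_field(fixed$surfaces, warped_surf)
    vol_reg <- apply_column_shift(warped$volume, delta)
    surf_reg <- shift_surfaces(warped_surf, delta)
    z_transform <- delta
  } else {
    model <- if (config$z_method == "lpm_rigid") "rigid" else "similarity"
    lp <- config$lpm
    lp$da_um <- fixed_grid$spacing[2]
    lp$dz_um <- fixed$volume$spacing[2]
    lp$seed <- derive_seed(config$seed, "lpm")
    z_transform <- lpm_register_volume(fixed$surfaces, warped_surf, model, lp)
    vol_reg <- apply_bscan_transforms(warped$volume, z_transform)
    surf_reg <- transform_surfaces_bscanwise(warped_surf, z_transform,
                                             fixed_grid$spacing[2],
                                             fixed$volume$spacing[2])
  }
  result$volume_registered <- vol_reg
  result$surfaces_registered <- surf_reg
  result$z_transform <- z_transform

  # ---- evaluation on the overlap ----
  if ("RPE_outer" %in% names(fixed$surfaces$heights) &&
      "RPE_outer" %in% names(surf_reg$heights)) {
    mask <- overlap_mask(fixed_grid, moving_grid, T2D,
                         fixed_valid = fixed$surfaces$valid$RPE_outer,
                         moving_valid = moving$surfaces$valid$RPE_outer)
    mask <- mask & surf_reg$valid$RPE_outer
    report$z_metrics_um <- rpe_error_metrics(fixed$surfaces$heights$RPE_outer,
                                             surf_reg$heights$RPE_outer,
                                             mask, fixed$volume$spacing[2])
    report$dice <- retina_dice(fixed$surfaces, surf_reg, mask)
    report$overlap_fraction <- mean(mask)
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  result$report <- report
  if (!is.null(out_dir)) persist_outputs(result, out_dir)
  result
}

# surfaces under per-B-scan (a, z) transforms: each valid ILM/RPE point is
# mapped through its B-scan's transform; heights are re-read at the original
# A-scan positions via linear interpolation over the transformed points
transform_surfaces_bscanwise <- function(surfaces, transforms, da_um, dz_um) {
  heights <- surfaces$heights; vmask <- surfaces$valid
  nb <- nrow(heights[[1]]); na_ <- ncol(heights[[1]])
  a_um <- (0:(na_ - 1)) * da_um
  for (nm in names(heights)) {
    for (b in seq_len(nb)) {
      A <- transforms$transforms[[b]]
      if (is.null(A)) next
      ok <- vmask[[nm]][b, ] & is.finite(heights[[nm]][b, ])
      if (sum(ok) < 2) next
      pts <- cbind(a_um[ok], heights[[nm]][b, ok] * dz_um)
      tp <- apply_mat23(A, pts)
      # re-sample z at the native a grid (transformed a may shift slightly)
      newz <- try(stats::approx(tp[, 1], tp[, 2], xout = a_um[ok],
                                rule = 1)$y, silent = TRUE)
      if (inherits(newz, "try-error")) next
      row <- heights[[nm]][b, ]; vrow <- vmask[[nm]][b, ]
      row[ok] <- newz / dz_um
      vrow[ok] <- is.finite(newz)
      row[!vrow] <- NA_real_
      heights[[nm]][b, ] <- row
      vmask[[nm]][b, ] <- vrow
    }
    bad <- !vmask[[nm]]
    heights[[nm]][bad] <- NA_real_
  }
  # interpolation can leave hairline ordering violations; invalidate them
  if (all(c("ILM", "RPE_outer") %in% names(heights))) {
    both <- vmask$ILM & vmask$RPE_outer
    bad <- both & (heights$ILM > heights$RPE_outer)
    for (nm in names(heights)) {
      vmask[[nm]][bad] <- FALSE
      heights[[nm]][bad] <- NA_real_
    }
    if ("IS_OSJ" %in% names(heights)) {
      nn <- function(x) !is.na(x) & x
      bad2 <- vmask$IS_OSJ &
        (nn(vmask$ILM & (heights$IS_OSJ < heights$ILM)) |
         nn(vmask$RPE_outer & (heights$IS_OSJ > heights$RPE_outer)))
      vmask$IS_OSJ[bad2] <- FALSE
      heights$IS_OSJ[bad2] <- NA_real_
    }
  }
  surface_set(heights, vmask)
}

persist_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(result$transform2d, "affine2d")) {
    write_transform(result$transform2d, file.path(out_dir, "transform2d.json"))
  }
  if (!is.null(result$z_transform)) {
    write_transform(result$z_transform, file.path(out_dir, "z_transform.json"))
  }
  write_enface(result$fixed_enface, file.path(out_dir, "fixed_enface.tif"))
  write_enface(result$moving_enface, file.path(out_dir, "moving_enface.tif"))
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       force = TRUE)
  invisible(out_dir)
}
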