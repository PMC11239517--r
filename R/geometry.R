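#' Derive specimen geometry: height, uptake interval, areal coverage
#'
#' Populates the derived columns every downstream analysis consumes:
#'
#' * `height` (mm): for reclining taxa, one-third of the (frond) width — the
#'   convention for recliners whose branches drape over the substrate; for
#'   all other morphogroups, `stem_length + frond_length` with missing parts
#'   contributing 0.
#' * `uptake_lo`, `uptake_hi` (mm): the vertical interval occupied by the
#'   branching (uptake) part. Upright forms: `[stem_length, stem_length +
#'   frond_length]`; reclining forms `[0, height]`.
#' * `areal_coverage` (mm^2): biomass proxy, the sum of the disc ellipse
#'   `pi/4 * disc_length * disc_width`, the frond ellipse
#'   `pi/4 * frond_length * frond_width`, and the stem rectangle
#'   `stem_length * stem_width` (missing parts contribute 0).
#'
#' Specimens with no measurable part get height 0 and coverage 0 and are
#' listed in the `"geometry_log"` attribute. The operation is idempotent:
#' derived columns are recomputed from the raw measurements.
#'
#' @param surface a validated [surface_map()].
#' @return the surface with derived columns populated.
#' @export
derive_geometry <- function(surface) {
  sp <- surface$specimens
  z <- function(v) ifelse(is.na(v), 0, v)
  reclining <- sp$morphogroup == "reclining"
  width <- ifelse(!is.na(sp$frond_width), sp$frond_width, z(sp$disc_width))
  height <- ifelse(reclining, width / 3,
                   z(sp$stem_length) + z(sp$frond_length))
  up_lo <- ifelse(reclining, 0, z(sp$stem_length))
  up_hi <- ifelse(reclining, height,
                  z(sp$stem_length) + z(sp$frond_length))
  coverage <- pi / 4 * z(sp$disc_length) * z(sp$disc_width) +
    pi / 4 * z(sp$frond_length) * z(sp$frond_width) +
    z(sp$stem_length) * z(sp$stem_width)
  no_part <- rowSums(!is.na(sp[, c("disc_length", "stem_length",
                                   "frond_length", "frond_width")])) == 0L
  sp$height <- height
  sp$uptake_lo <- up_lo
  sp$uptake_hi <- up_hi
  sp$areal_coverage <- coverage
  surface$specimens <- sp
  attr(surface, "geometry_log") <-
    if (any(no_part)) sp$specimen_id[no_part] else character(0)
  surface
}

# 2x2 rotation matrix, angle in radians
.rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Transform an ellipse (semi-axes a >= b, long-axis angle phi in radians)
# by the linear map M; returns c(a, b, phi) of the image ellipse.
.transform_ellipse <- function(a, b, phi, M) {
  E <- .rot2(phi) %*% diag(c(a^2, b^2)) %*% t(.rot2(phi))
  E2 <- M %*% E %*% t(M)
  eg <- eigen(E2, symmetric = TRUE)
  v <- eg$vectors[, 1]
  c(sqrt(eg$values[1]), sqrt(max(eg$values[2], 0)), atan2(v[2], v[1]))
}

#' Retrodeform a tectonically sheared surface
#'
#' Holdfast discs were circular in life; tectonic strain turns them into
#' aligned ellipses. This restores the surface by an area-preserving inverse
#' pure shear: discs with both axes measured and mean diameter > 10 mm
#' qualify; their mean long-axis orientation `theta` (axial circular mean)
#' and mean axial ratio `R` (long/short) define the strain, and coordinates
#' are mapped by rotate(-theta), scale x by 1/sqrt(R) and y by sqrt(R),
#' rotate back (applied about the extent centre). Disc ellipses are
#' transformed exactly; stem/frond lengths carry no orientation and are left
#' unchanged, so total areal coverage is invariant.
#'
#' With fewer than `n_min` qualifying discs the surface is returned
#' unchanged with a warning and attribute `"retrodeform_skipped"` — the
#' sparse-holdfast case some surfaces present.
#'
#' @param surface a `surface_map`.
#' @param n_min minimum number of qualifying discs (default 10).
#' @param min_diameter_mm qualifying mean disc diameter threshold (10 mm).
#' @return the retrodeformed surface with `retro_params`
#'   (`theta_deg`, `R`, `n_discs`) recorded.
#' @export
retrodeform <- function(surface, n_min = 10, min_diameter_mm = 10) {
  sp <- surface$specimens
  qual <- !is.na(sp$disc_length) & !is.na(sp$disc_width) &
    (sp$disc_length + sp$disc_width) / 2 > min_diameter_mm
  n_discs <- sum(qual)
  if (n_discs < n_min) {
    warning("surface '", surface$surface_id, "': only ", n_discs,
            " qualifying holdfast discs (< ", n_min,
            "); returned unchanged", call. = FALSE)
    attr(surface, "retrodeform_skipped") <- TRUE
    return(surface)
  }
  long <- pmax(sp$disc_length[qual], sp$disc_width[qual])
  short <- pmin(sp$disc_length[qual], sp$disc_width[qual])
  ratio <- long / short
  R <- mean(ratio)
  # long-axis orientation: as given if length >= width, else rotated 90 deg
  phi <- sp$disc_orientation[qual]
  phi <- ifelse(sp$disc_length[qual] >= sp$disc_width[qual], phi, phi + 90)
  elong <- ratio > 1.05 & !is.na(phi)
  if (!any(elong)) {
    # effectively circular discs: nothing to restore
    surface$retrodeformed <- TRUE
    surface$retro_params <- list(theta_deg = 0, R = R, n_discs = n_discs)
    return(surface)
  }
  ph <- phi[elong] * pi / 180
  theta <- 0.5 * atan2(mean(sin(2 * ph)), mean(cos(2 * ph)))
  M <- .rot2(theta) %*% diag(c(1 / sqrt(R), sqrt(R))) %*% t(.rot2(theta))
  ctr <- c(mean(surface$extent[1:2]), mean(surface$extent[3:4]))
  xy <- t(M %*% rbind(sp$x - ctr[1], sp$y - ctr[2]))
  sp$x <- xy[, 1] + ctr[1]
  sp$y <- xy[, 2] + ctr[2]
  has_disc <- !is.na(sp$disc_length) & !is.na(sp$disc_width)
  for (i in which(has_disc)) {
    a <- max(sp$disc_length[i], sp$disc_width[i]) / 2
    b <- min(sp$disc_length[i], sp$disc_width[i]) / 2
    p0 <- if (!is.na(sp$disc_orientation[i])) {
      if (sp$disc_length[i] >= sp$disc_width[i])
        sp$disc_orientation[i] else sp$disc_orientation[i] + 90
    } else theta * 180 / pi  # strain-induced elongation assumed
    e2 <- .transform_ellipse(a, b, p0 * pi / 180, M)
    sp$disc_length[i] <- 2 * e2[1]
    sp$disc_width[i] <- 2 * e2[2]
    sp$disc_orientation[i] <- (e2[3] * 180 / pi) %% 180
  }
  corners <- rbind(c(surface$extent[1], surface$extent[3]),
                   c(surface$extent[2], surface$extent[3]),
                   c(surface$extent[1], surface$extent[4]),
                   c(surface$extent[2], surface$extent[4]))
  tc <- t(M %*% t(sweep(corners, 2, ctr))) + rep(ctr, each = 4)
  surface$extent <- c(range(tc[, 1]), range(tc[, 2]))
  surface$specimens <- sp
  surface$retrodeformed <- TRUE
  surface$retro_params <- list(theta_deg = (theta * 180 / pi) %% 180,
                               R = R, n_discs = n_discs)
  if (!is.null(sp$height)) surface <- derive_geometry(surface)
  surface
}

#' Apply an area-preserving pure shear to a surface
#'
#' Forward model for tectonic strain, used to test retrodeformation:
#' stretches by `sqrt(factor)` along `orientation_deg` and shrinks by
#' `1/sqrt(factor)` across it, so circular discs become `factor : 1`
#' ellipses while areas and the disc-area sum are preserved. Coordinates and
#' disc ellipses are transformed; extent becomes the transformed bounding
#' box.
#'
#' @param surface a `surface_map`.
#' @param factor axial ratio imposed on initially circular discs (>= 1).
#' @param orientation_deg stretch direction, degrees from the x axis.
#' @return the sheared surface.
#' @export
shear_surface <- function(surface, factor, orientation_deg = 90) {
  stopifnot(factor >= 1)
  th <- orientation_deg * pi / 180
  M <- .rot2(th) %*% diag(c(sqrt(factor), 1 / sqrt(factor))) %*% t(.rot2(th))
  sp <- surface$specimens
  ctr <- c(mean(surface$extent[1:2]), mean(surface$extent[3:4]))
  xy <- t(M %*% rbind(sp$x - ctr[1], sp$y - ctr[2]))
  sp$x <- xy[, 1] + ctr[1]
  sp$y <- xy[, 2] + ctr[2]
  has_disc <- !is.na(sp$disc_length) & !is.na(sp$disc_width)
  for (i in which(has_disc)) {
    a <- max(sp$disc_length[i], sp$disc_width[i]) / 2
    b <- min(sp$disc_length[i], sp$disc_width[i]) / 2
    p0 <- if (!is.na(sp$disc_orientation[i])) {
      if (sp$disc_length[i] >= sp$disc_width[i])
        sp$disc_orientation[i] else sp$disc_orientation[i] + 90
    } else 0
    e2 <- .transform_ellipse(a, b, p0 * pi / 180, M)
    sp$disc_length[i] <- 2 * e2[1]
    sp$disc_width[i] <- 2 * e2[2]
    sp$disc_orientation[i] <- (e2[3] * 180 / pi) %% 180
  }
  corners <- rbind(c(surface$extent[1], surface$extent[3]),
                   c(surface$extent[2], surface$extent[3]),
                   c(surface$extent[1], surface$extent[4]),
                   c(surface$extent[2], surface$extent[4]))
  tc <- t(M %*% t(sweep(corners, 2, ctr))) + rep(ctr, each = 4)
  surface$extent <- c(range(tc[, 1]), range(tc[, 2]))
  surface$specimens <- sp
  if (!is.null(sp$height)) surface <- derive_geometry(surface)
  surface
}
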