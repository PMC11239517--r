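#' Jackknife configuration
#'
#' Settings for spatial jackknife resampling: each replicate captures a
#' fixed areal fraction of the surface (default 66%) inside a box grown
#' around a randomly seeded centre point.
#'
#' @param fraction target areal fraction in (0, 1); default 0.66.
#' @param n_samples number of independent replicates; default 1000.
#' @param seed RNG seed for the centre points (NULL = current RNG state).
#' @param area_tolerance allowed relative deviation of the captured areal
#'   fraction from `fraction` (default 0.01); the expanding-box solver is
#'   exact to numerical precision, so this is a post-hoc check.
#' @return object of class `jackknife_config`.
#' @export
jackknife_config <- function(fraction = 0.66, n_samples = 1000,
                             seed = NULL, area_tolerance = 0.01) {
  stopifnot(fraction > 0, fraction < 1, n_samples >= 1)
  structure(list(fraction = fraction, n_samples = as.integer(n_samples),
                 seed = seed, area_tolerance = area_tolerance),
            class = "jackknife_config")
}

# Captured area of the expanding box at half-width h around centre (cx, cy)
# within the rectangle ext = c(xmin, xmax, ymin, ymax). With isotropic
# growth and per-direction freezing at the surface edge, the extent reached
# in each direction is min(h, distance to that edge).
.box_at <- function(h, cx, cy, ext) {
  c(xmin = cx - min(h, cx - ext[1]), xmax = cx + min(h, ext[2] - cx),
    ymin = cy - min(h, cy - ext[3]), ymax = cy + min(h, ext[4] - cy))
}

.box_area <- function(h, cx, cy, ext) {
  b <- .box_at(h, cx, cy, ext)
  (b[["xmax"]] - b[["xmin"]]) * (b[["ymax"]] - b[["ymin"]])
}

#' Generate spatial jackknife samples of a surface
#'
#' Each replicate seeds a centre point uniformly on the surface and grows a
#' square box isotropically around it; a side that reaches the surface edge
#' freezes while the others keep growing, until the captured area reaches
#' `fraction` of the mapped extent. Because the frozen-edge rule makes the
#' captured area a continuous monotone function of the box half-width, the
#' stopping half-width is found by root-solving, so every replicate captures
#' the target fraction exactly (to numerical tolerance). Replicates are
#' independent and may overlap. Specimens on the box boundary are included
#' (closed intervals).
#'
#' @param surface a `surface_map`.
#' @param cfg a [jackknife_config()].
#' @return object of class `jackknife_samples`: list with `surface_id`,
#'   `fraction`, `boxes` (data frame: sample_index, centre, box,
#'   captured_area_fraction, n_specimens) and `members` (list of integer
#'   row indices into `surface$specimens`).
#' @export
generate_jackknife_samples <- function(surface, cfg = jackknife_config()) {
  ext <- surface$extent
  wx <- ext[2] - ext[1]; wy <- ext[4] - ext[3]
  if (wx <= 0 || wy <= 0)
    stop("degenerate surface extent: target areal fraction unreachable",
         call. = FALSE)
  A <- wx * wy
  target <- cfg$fraction * A
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cx <- stats::runif(cfg$n_samples, ext[1], ext[2])
  cy <- stats::runif(cfg$n_samples, ext[3], ext[4])
  hmax <- wx + wy  # area(hmax) = full extent
  x <- surface$specimens$x; y <- surface$specimens$y
  boxes <- matrix(NA_real_, cfg$n_samples, 4,
                  dimnames = list(NULL, c("xmin", "xmax", "ymin", "ymax")))
  members <- vector("list", cfg$n_samples)
  frac <- numeric(cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    h <- stats::uniroot(function(h) .box_area(h, cx[i], cy[i], ext) - target,
                        c(0, hmax), tol = 1e-12 * max(1, hmax))$root
    b <- .box_at(h, cx[i], cy[i], ext)
    boxes[i, ] <- b
    frac[i] <- .box_area(h, cx[i], cy[i], ext) / A
    members[[i]] <- which(x >= b[["xmin"]] & x <= b[["xmax"]] &
                          y >= b[["ymin"]] & y <= b[["ymax"]])
  }
  off <- abs(frac - cfg$fraction)
  if (any(off > cfg$area_tolerance))
    warning(sum(off > cfg$area_tolerance),
            " jackknife replicate(s) outside the area tolerance",
            call. = FALSE)
  structure(list(surface_id = surface$surface_id,
                 fraction = cfg$fraction,
                 boxes = data.frame(sample_index = seq_len(cfg$n_samples),
                                    cx = cx, cy = cy, boxes,
                                    captured_area_fraction = frac,
                                    n_specimens = lengths(members)),
                 members = members),
            class = "jackknife_samples")
}

#' @export
print.jackknife_samples <- function(x, ...) {
  cat("<jackknife_samples> ", x$surface_id, ": ", nrow(x$boxes),
      " replicates at areal fraction ", x$fraction, "\n", sep = "")
  cat("  mean specimens per replicate: ",
      round(mean(x$boxes$n_specimens), 1), "\n", sep = "")
  invisible(x)
}

#' Jackknife membership as a long table
#'
#' @param samples a `jackknife_samples` object.
#' @param surface the `surface_map` the samples were drawn from.
#' @return data frame (surface_id, sample_index, specimen_id), the CSV
#'   export schema.
#' @export
jackknife_membership <- function(samples, surface) {
  ids <- surface$specimens$specimen_id
  data.frame(
    surface_id = samples$surface_id,
    sample_index = rep(samples$boxes$sample_index, lengths(samples$members)),
    specimen_id = ids[unlist(samples$members)])
}
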