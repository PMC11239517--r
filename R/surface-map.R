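# Canonical specimen columns. Measurement columns are in mm, coordinates in
# metres; missing measurements are NA.
.measure_cols <- c("disc_length", "disc_width", "disc_orientation",
                   "stem_length", "stem_width", "frond_length", "frond_width")
.required_cols <- c("specimen_id", "x", "y", "taxon")
.tax_levels <- c("species", "genus", "morphocategory", "taphomorph")
.morphogroups <- c("reclining", "bradgatia", "pectinifrons", "upright_frond",
                   "other")

#' Construct a bedding-plane surface map
#'
#' A `surface_map` holds one census-mapped fossil community: a specimen table
#' (positions in metres, part measurements in mm), the mapped rectangular
#' extent and its area. Derived geometry (height, uptake interval, areal
#' coverage) is added by [derive_geometry()].
#'
#' @param specimens data frame with at least `specimen_id`, `x`, `y`,
#'   `taxon`. Optional: `tax_level` (species/genus/morphocategory/
#'   taphomorph), `effaced_frond` (logical), `morphogroup`, and part
#'   measurements `disc_length`, `disc_width`, `disc_orientation` (degrees),
#'   `stem_length`, `stem_width`, `frond_length`, `frond_width` (mm).
#' @param surface_id character scalar naming the surface.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres; defaults to
#'   the bounding box of the specimens.
#' @param area_m2 mapped area; defaults to the extent rectangle's area.
#' @return an object of class `surface_map`.
#' @export
surface_map <- function(specimens, surface_id = "surface", extent = NULL,
                        area_m2 = NULL) {
  stopifnot(is.data.frame(specimens))
  specimens <- as.data.frame(specimens, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(specimens))
  if (length(missing_cols))
    stop("surface '", surface_id, "': missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  specimens$specimen_id <- as.character(specimens$specimen_id)
  specimens$taxon <- as.character(specimens$taxon)
  if (is.null(specimens$tax_level)) specimens$tax_level <- "species"
  if (is.null(specimens$effaced_frond)) specimens$effaced_frond <- FALSE
  if (is.null(specimens$morphogroup)) specimens$morphogroup <- "other"
  for (mc in .measure_cols)
    if (is.null(specimens[[mc]])) specimens[[mc]] <- NA_real_ else
      specimens[[mc]] <- as.numeric(specimens[[mc]])
  if (is.null(extent)) {
    extent <- c(min(specimens$x), max(specimens$x),
                min(specimens$y), max(specimens$y))
    # a degenerate bounding box (collinear specimens) still needs area
    if (extent[2] == extent[1]) extent[1:2] <- extent[1] + c(-0.5, 0.5)
    if (extent[4] == extent[3]) extent[3:4] <- extent[3] + c(-0.5, 0.5)
  }
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[2] < extent[1] || extent[4] < extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with xmin <= xmax, ",
         "ymin <= ymax", call. = FALSE)
  if (is.null(area_m2))
    area_m2 <- (extent[2] - extent[1]) * (extent[4] - extent[3])
  obj <- structure(list(surface_id = as.character(surface_id),
                        specimens = specimens,
                        extent = extent,
                        area_m2 = as.numeric(area_m2),
                        retrodeformed = FALSE,
                        retro_params = NULL),
                   class = "surface_map")
  validate_surface_map(obj)
  obj
}

#' Validate a surface map
#'
#' Checks the structural invariants of a [surface_map()]: unique specimen
#' ids, non-negative measurements, positive area, and positions inside the
#' extent. Problem rows are reported by id rather than silently dropped.
#'
#' @param surface a `surface_map`.
#' @return the surface, invisibly; errors describe every offending row.
#' @export
validate_surface_map <- function(surface) {
  sp <- surface$specimens
  problems <- character(0)
  dup <- unique(sp$specimen_id[duplicated(sp$specimen_id)])
  if (length(dup))
    problems <- c(problems, paste0("duplicate specimen_id: ",
                                   paste(dup, collapse = ", ")))
  for (mc in setdiff(.measure_cols, "disc_orientation")) {
    bad <- which(!is.na(sp[[mc]]) & sp[[mc]] < 0)
    if (length(bad))
      problems <- c(problems, paste0("negative ", mc, " in row(s): ",
                                     paste(sp$specimen_id[bad], collapse = ", ")))
  }
  bad_xy <- which(is.na(sp$x) | is.na(sp$y) |
                  sp$x < surface$extent[1] - 1e-9 |
                  sp$x > surface$extent[2] + 1e-9 |
                  sp$y < surface$extent[3] - 1e-9 |
                  sp$y > surface$extent[4] + 1e-9)
  if (length(bad_xy))
    problems <- c(problems, paste0("position outside extent for: ",
                                   paste(sp$specimen_id[bad_xy], collapse = ", ")))
  bad_lvl <- which(!sp$tax_level %in% .tax_levels)
  if (length(bad_lvl))
    problems <- c(problems, paste0("unknown tax_level for: ",
                                   paste(sp$specimen_id[bad_lvl], collapse = ", ")))
  if (!is.finite(surface$area_m2) || surface$area_m2 <= 0)
    problems <- c(problems, "area_m2 must be > 0")
  if (length(problems))
    stop("invalid surface map '", surface$surface_id, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(surface)
}

#' @export
print.surface_map <- function(x, ...) {
  cat("<surface_map> ", x$surface_id, ": ", nrow(x$specimens),
      " specimens, ", sprintf("%.2f", x$area_m2), " m2",
      if (isTRUE(x$retrodeformed)) " (retrodeformed)", "\n", sep = "")
  n_tax <- length(unique(x$specimens$taxon))
  cat("  taxa: ", n_tax, "; extent [",
      paste(sprintf("%.2f", x$extent), collapse = ", "), "] m\n", sep = "")
  if (!is.null(x$specimens$height))
    cat("  derived geometry present\n")
  invisible(x)
}

#' Read a census map table from CSV
#'
#' Reads a per-surface census table (UTF-8, comma-separated, header row,
#' empty cell = missing) and returns a validated [surface_map()]. Columns can
#' be renamed through `schema`, a named character vector mapping canonical
#' names to the file's column names, e.g.
#' `c(specimen_id = "id", frond_length = "FL_mm")`.
#'
#' @param path CSV file path.
#' @param schema optional named character vector, canonical = file column.
#' @param surface_id surface name; defaults to the file name sans extension.
#' @param extent,area_m2 passed to [surface_map()].
#' @return a validated `surface_map` (derived geometry not yet computed).
#' @export
read_surface_map <- function(path, schema = NULL, surface_id = NULL,
                             extent = NULL, area_m2 = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(surface_id))
    surface_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema column '", src, "' (for '", canon,
             "') not present in ", path, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  surface_map(df, surface_id = surface_id, extent = extent,
              area_m2 = area_m2)
}

#' Write a surface map's specimen table to CSV
#'
#' Emits the same schema [read_surface_map()] consumes, so generated
#' surfaces round-trip through files.
#'
#' @param surface a `surface_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(surface$specimens, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a surfaces manifest
#'
#' A manifest lists the surfaces of a study: columns/fields `surface_id`,
#' `file`, and optionally `area_m2`, `jackknife` (logical; FALSE for
#' surfaces excluded from subsampling), `locality`, `formation`,
#' `environment`. YAML manifests hold a list of such records under
#' `surfaces`; CSV manifests hold one row per surface.
#'
#' @param path manifest file (`.yaml`/`.yml` or `.csv`).
#' @return data frame with one row per surface.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    recs <- if (!is.null(y$surfaces)) y$surfaces else y
    df <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r[lengths(r) == 1L], stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("surface_id", "file") %in% names(df)))
    stop("manifest must provide surface_id and file", call. = FALSE)
  if (is.null(df$jackknife)) df$jackknife <- TRUE
  df$jackknife <- as.logical(df$jackknife)
  df
}
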