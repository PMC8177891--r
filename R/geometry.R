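#' Depth-resolved multielectrode array geometry
#'
#' Describes a multi-shank linear electrode array spanning the dorsoventral
#' extent of the spinal gray matter, and the depth cut-points that partition
#' its contacts into the four gross anatomical regions: superficial dorsal
#' horn (sDH, surface to ~400 um), deep dorsal horn (dDH, ~500-1000 um),
#' intermediate gray (IG, ~1100-1300 um) and ventral horn (VH, ~1400 um and
#' deeper). Default cut-points sit at the midpoints of the gaps between those
#' approximate ranges (450, 1050, 1350 um), which with the default 2-shank,
#' 16-contact, 100-um-pitch array yields the canonical per-region electrode
#' counts sDH 8, dDH 12, IG 6, VH 6.
#'
#' Electrode ids are integers `1 .. n_shanks * contacts_per_shank`, numbered
#' down shank 1 first (row 1 = most superficial contact).
#'
#' @param n_shanks number of shanks (default 2).
#' @param contacts_per_shank contacts per shank (default 16).
#' @param pitch_um inter-contact spacing, um (default 100).
#' @param top_row_depth_um depth of the most superficial contact row, um
#'   (default 100, putting the deepest row at 1600 um).
#' @param region_boundaries_um strictly increasing depth cut-points (um)
#'   separating sDH/dDH, dDH/IG and IG/VH. Contacts at depth `<= b1` are sDH,
#'   `(b1, b2]` dDH, `(b2, b3]` IG, `> b3` VH.
#' @return an object of class `array_geometry`: a list with the scalar
#'   parameters plus `$contacts`, a data.frame with columns `electrode_id`,
#'   `shank`, `row`, `depth_um`, `region`.
#' @examples
#' geom <- array_geometry()
#' table(geom$contacts$region)
#' @export
array_geometry <- function(n_shanks = 2, contacts_per_shank = 16,
                           pitch_um = 100, top_row_depth_um = 100,
                           region_boundaries_um = c(450, 1050, 1350)) {
  stopifnot(n_shanks >= 1, contacts_per_shank >= 1, pitch_um > 0,
            top_row_depth_um >= 0, length(region_boundaries_um) == 3)
  if (any(diff(region_boundaries_um) <= 0)) {
    stop("region_boundaries_um must be strictly increasing")
  }
  shank <- rep(seq_len(n_shanks), each = contacts_per_shank)
  row <- rep(seq_len(contacts_per_shank), times = n_shanks)
  depth <- top_row_depth_um + (row - 1) * pitch_um
  geom <- structure(
    list(
      n_shanks = as.integer(n_shanks),
      contacts_per_shank = as.integer(contacts_per_shank),
      pitch_um = pitch_um,
      top_row_depth_um = top_row_depth_um,
      region_boundaries_um = region_boundaries_um,
      contacts = data.frame(
        electrode_id = seq_along(shank),
        shank = shank, row = row, depth_um = depth,
        region = NA_character_
      )
    ),
    class = "array_geometry"
  )
  geom$contacts$region <- assign_region(depth, geom)
  geom
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "Array geometry: %d shank(s) x %d contacts, %g um pitch, rows %g-%g um\n",
    x$n_shanks, x$contacts_per_shank, x$pitch_um,
    min(x$contacts$depth_um), max(x$contacts$depth_um)
  ))
  cat("Region boundaries (um):", paste(x$region_boundaries_um, collapse = ", "), "\n")
  print(region_electrode_counts(x))
  invisible(x)
}

#' Assign a gross anatomical region from recording depth
#'
#' Total piecewise-constant map from depth to one of sDH, dDH, IG, VH using
#' the geometry's depth cut-points (left-open, right-closed intervals, so a
#' contact exactly at a boundary belongs to the shallower region).
#'
#' @param depth_um numeric vector of depths, um (must be `>= 0`).
#' @param geometry an [array_geometry()].
#' @return character vector of region labels.
#' @examples
#' g <- array_geometry()
#' assign_region(c(300, 800, 1500), g) # sDH, dDH, VH
#' @export
assign_region <- function(depth_um, geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (any(is.na(depth_um)) || any(depth_um < 0)) {
    stop("depth_um must be non-negative and non-missing")
  }
  idx <- findInterval(depth_um, geometry$region_boundaries_um, left.open = TRUE)
  REGIONS[idx + 1L]
}

#' Per-region electrode counts of a geometry
#'
#' @param geometry an [array_geometry()].
#' @return named integer vector over sDH, dDH, IG, VH (zeros kept).
#' @export
region_electrode_counts <- function(geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  counts <- table(factor(geometry$contacts$region, levels = REGIONS))
  stats::setNames(as.integer(counts), REGIONS)
}
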