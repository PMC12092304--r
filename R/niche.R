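#' Hexagonal array geometry
#'
#' The grid stores "odd-r" offset coordinates (odd array rows shifted +1/2
#' in x). Neighbor order is graph distance on the hex lattice, computed on
#' axial coordinates: `q = col - (row - row %% 2) / 2`, `r = row`, with
#' `dist = (|dq| + |dr| + |dq + dr|) / 2`.
#'
#' @name hex-geometry
#' @keywords internal
NULL

offset_to_axial <- function(row, col) {
  q <- col - (row - (row %% 2L)) %/% 2L
  cbind(q = q, r = row)
}

hex_graph_distance <- function(row1, col1, row2, col2) {
  a <- offset_to_axial(row1, col1)
  b <- offset_to_axial(row2, col2)
  dq <- a[, "q"] - b[, "q"]
  dr <- a[, "r"] - b[, "r"]
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

#' Array neighbors of a spot at a given hex order
#'
#' Returns the spots at hex graph distance exactly `order` from the query
#' spot, within the same sample. Interior spots have 6 first-order and 12
#' second-order neighbors; edge spots fewer. Only spots present in the grid
#' are returned.
#'
#' @param grid a [make_spot_grid()] grid.
#' @param spot_id query spot id.
#' @param order 1 or 2.
#' @return character vector of neighbor spot ids.
#' @export
hex_neighbors <- function(grid, spot_id, order = 1L) {
  i <- match(spot_id, grid$spot_id)
  if (is.na(i)) stop_invalid("unknown spot id: ", spot_id)
  if (!order %in% c(1L, 2L)) stop_invalid("order must be 1 or 2")
  same <- grid$sample_id == grid$sample_id[i]
  d <- hex_graph_distance(grid$array_row[same], grid$array_col[same],
                          grid$array_row[i], grid$array_col[i])
  grid$spot_id[same][d == order]
}

# Hex-ball membership: ids of all spots with graph distance <= order from
# any seed spot (vectorized over seeds; excludes nothing).
hex_ball <- function(grid, seed_ids, order) {
  if (!length(seed_ids)) return(character(0))
  idx <- match(seed_ids, grid$spot_id)
  if (anyNA(idx)) stop_invalid("unknown spot id(s) in seed set")
  ax <- offset_to_axial(grid$array_row, grid$array_col)
  hit <- rep(FALSE, nrow(grid))
  for (i in idx) {
    same <- grid$sample_id == grid$sample_id[i]
    dq <- ax[, "q"] - ax[i, "q"]
    dr <- ax[, "r"] - ax[i, "r"]
    d <- (abs(dq) + abs(dr) + abs(dq + dr)) / 2
    hit <- hit | (same & d <= order)
  }
  grid$spot_id[hit]
}

#' Mean amyloid-density signal per spot
#'
#' Averages the decayed-density raster over each spot's capture disc
#' (pixel centers within `spot_diameter / 2` of the spot center). Spots
#' flagged `reliable_ab = FALSE`, or whose disc lies fully outside the
#' raster, receive `NA`.
#'
#' @param raster a [density_raster()] covering the grid.
#' @param grid spot grid; spot coordinates must be in the raster frame
#'   (same origin as `origin`).
#' @param spot_diameter capture-spot diameter in um (default: grid
#'   attribute, else 55).
#' @param origin `(x, y)` of the raster's lower corner in grid coordinates.
#' @return named numeric vector of mean intensities (0-255) per spot.
#' @export
spot_signal <- function(raster, grid, spot_diameter = NULL, origin = c(0, 0)) {
  if (!inherits(raster, "raster2d")) stop_invalid("raster must be a raster2d")
  spot_diameter <- spot_diameter %||% attr(grid, "spot_diameter") %||% 55
  ps <- raster$pixel_size
  rad_px <- spot_diameter / 2 / ps
  # disc stencil of pixel-center offsets, shared by all spots
  r_int <- ceiling(rad_px)
  off <- expand.grid(di = -r_int:r_int, dj = -r_int:r_int)
  off <- off[off$di^2 + off$dj^2 <= rad_px^2, , drop = FALSE]
  nr <- nrow(raster$pixels); nc <- ncol(raster$pixels)
  ci <- (grid$y - origin[2]) / ps + 0.5  # fractional pixel index of center
  cj <- (grid$x - origin[1]) / ps + 0.5
  out <- rep(NA_real_, nrow(grid))
  for (s in seq_len(nrow(grid))) {
    if (!grid$reliable_ab[s]) next
    ii <- round(ci[s] + off$di); jj <- round(cj[s] + off$dj)
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    if (!any(ok)) {
      warning("spot ", grid$spot_id[s], " lies outside the raster",
              call. = FALSE)
      next
    }
    out[s] <- mean(raster$pixels[cbind(ii[ok], jj[ok])])
  }
  names(out) <- grid$spot_id
  out
}

#' Classify spots as amyloid-rich
#'
#' A spot is rich when its mean decayed-amyloid intensity strictly exceeds
#' the threshold (default 183 on the 0-255 scale). Missing intensities are
#' never rich.
#'
#' @param intensity per-spot intensity (0-255).
#' @param threshold richness threshold (default 183).
#' @return logical vector.
#' @export
classify_rich <- function(intensity, threshold = 183) {
  if (threshold < 0 || threshold > 255) stop_invalid("threshold must lie in [0, 255]")
  !is.na(intensity) & intensity > threshold
}

#' Assemble amyloid niches from rich spots and their array neighbors
#'
#' The niche consists of rich spots plus their first- and second-order hex
#' neighbors lying in the allowed regions (an approximate 200 um radius at
#' 100 um pitch). Vascular-amyloid (CAA) spots and their first-order
#' neighbors are excluded, as are spots with unreliable amyloid staining;
#' excluded spots are never rich or neighbor. The returned classes
#' partition the grid.
#'
#' @param grid spot grid.
#' @param rich character vector of rich spot ids (e.g. from
#'   [classify_rich()]).
#' @param vascular character vector of vascular/CAA spot ids.
#' @param allowed_regions regions eligible for niche membership (default:
#'   gray and white matter).
#' @param ab_intensity optional named per-spot intensity to carry through.
#' @return data.frame (`niche_annotation`): `spot_id`, `ab_intensity`,
#'   `niche_class` in `{rich, neighbor, outside, excluded}`, `vascular_flag`.
#' @export
assemble_niche <- function(grid, rich, vascular = character(0),
                           allowed_regions = c(GM_REGIONS, "white matter"),
                           ab_intensity = NULL) {
  if (!all(rich %in% grid$spot_id)) stop_invalid("rich set contains unknown spot ids")
  if (!all(vascular %in% grid$spot_id)) stop_invalid("vascular set contains unknown spot ids")
  excluded <- union(hex_ball(grid, vascular, 1L),
                    grid$spot_id[!grid$reliable_ab])
  rich_kept <- setdiff(rich, excluded)
  ball <- hex_ball(grid, rich_kept, 2L)
  allowed <- grid$spot_id[grid$region %in% allowed_regions]
  neigh <- setdiff(intersect(ball, allowed), union(rich_kept, excluded))
  cls <- rep("outside", nrow(grid))
  cls[grid$spot_id %in% neigh] <- "neighbor"
  cls[grid$spot_id %in% rich_kept] <- "rich"
  cls[grid$spot_id %in% excluded] <- "excluded"
  ab <- if (is.null(ab_intensity)) rep(NA_real_, nrow(grid))
        else unname(ab_intensity[grid$spot_id])
  out <- data.frame(spot_id = grid$spot_id,
                    ab_intensity = ab,
                    niche_class = cls,
                    vascular_flag = grid$spot_id %in% vascular,
                    stringsAsFactors = FALSE)
  class(out) <- c("niche_annotation", "data.frame")
  out
}

#' Rule for calling cell-type-enriched spots
#'
#' @param cell_type abundance column the rule applies to.
#' @param allowed_regions regions the rule is evaluated in (per sample).
#' @param mode `"top_quantile"` (top `q` fraction per region) or
#'   `"z_score"` (above mean + z sd over the sample's allowed-region spots).
#' @param q top fraction in `(0, 1]` (top_quantile mode).
#' @param z sd multiplier > 0 (z_score mode).
#' @return an `enrichment_rule` list.
#' @export
enrichment_rule <- function(cell_type, allowed_regions,
                            mode = c("top_quantile", "z_score"),
                            q = 0.05, z = 3) {
  mode <- match.arg(mode)
  if (mode == "top_quantile" && !(q > 0 && q <= 1))
    stop_invalid("q must lie in (0, 1]")
  if (mode == "z_score" && !(z > 0)) stop_invalid("z must be positive")
  structure(list(cell_type = cell_type, allowed_regions = allowed_regions,
                 mode = mode, q = q, z = z),
            class = "enrichment_rule")
}

#' Call cell-type-enriched spots from deconvolution abundances
#'
#' `top_quantile`: within each sample and each allowed region, spots whose
#' abundance is at or above the `1 - q` empirical quantile of that region's
#' abundances (ties at the boundary all included); the result is the union
#' over allowed regions. `z_score`: spots strictly above
#' `mean + z * sd`, both computed over the sample's allowed-region spots
#' pooled; a zero sd selects nothing.
#'
#' @param abundance data.frame with `spot_id` and one column per cell type.
#' @param grid spot grid (provides `sample_id` and `region`).
#' @param rule an [enrichment_rule()].
#' @return character vector of enriched spot ids.
#' @export
enriched_spots <- function(abundance, grid, rule) {
  if (!inherits(rule, "enrichment_rule")) stop_invalid("rule must be an enrichment_rule")
  if (!rule$cell_type %in% colnames(abundance))
    stop_invalid("abundance table lacks cell type '", rule$cell_type, "'")
  ab <- stats::setNames(abundance[[rule$cell_type]], abundance$spot_id)
  if (!all(grid$spot_id %in% names(ab)))
    stop_invalid("abundance rows do not cover the grid")
  out <- character(0)
  for (smp in unique(grid$sample_id)) {
    in_smp <- grid$sample_id == smp
    if (rule$mode == "top_quantile") {
      for (reg in rule$allowed_regions) {
        sel <- in_smp & grid$region == reg
        if (!any(sel)) {
          message("sample ", smp, ": region '", reg, "' absent, skipped")
          next
        }
        v <- ab[grid$spot_id[sel]]
        cut <- stats::quantile(v, probs = 1 - rule$q, type = 7, names = FALSE)
        out <- c(out, names(v)[v >= cut])
      }
    } else {
      sel <- in_smp & grid$region %in% rule$allowed_regions
      if (!any(sel)) {
        message("sample ", smp, ": no allowed-region spots, skipped")
        next
      }
      v <- ab[grid$spot_id[sel]]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) next
      out <- c(out, names(v)[v > mean(v) + rule$z * s])
    }
  }
  unique(out)
}

#' Default per-cell-type enrichment rule table
#'
#' The region-restricted top-quantile rules used for atlas cell types
#' (layer I excluded throughout) and the 3-sd rule used for immunization
#' microglia clusters, as a list of [enrichment_rule()]s editable without
#' code changes.
#'
#' @return named list of `enrichment_rule` objects.
#' @export
default_enrichment_rules <- function() {
  gmwm <- setdiff(c(GM_REGIONS, "white matter"), "layer I")
  gm <- setdiff(GM_REGIONS, "layer I")
  list(
    microglia = enrichment_rule("microglia", gmwm, "top_quantile", q = 0.05),
    astrocytes = enrichment_rule("astrocytes", gmwm, "top_quantile", q = 0.05),
    oligodendrocytes = enrichment_rule("oligodendrocytes", "white matter",
                                       "top_quantile", q = 0.30),
    opc = enrichment_rule("opc", gmwm, "top_quantile", q = 0.05),
    interneurons = enrichment_rule("interneurons", gm, "top_quantile", q = 0.05),
    endothelial = enrichment_rule("endothelial", gmwm, "top_quantile", q = 0.01),
    l23_en = enrichment_rule("l23_en", c("layer II", "layer III"),
                             "top_quantile", q = 0.10),
    l4_en = enrichment_rule("l4_en", "layer IV", "top_quantile", q = 0.50),
    l56_en = enrichment_rule("l56_en", c("layer V", "layer VI"),
                             "top_quantile", q = 0.05),
    microglia_cluster = enrichment_rule("microglia", gm, "z_score", z = 3))
}

#' Nuclei proximity to amyloid plaques
#'
#' Bins segmented nuclei by Euclidean distance to the nearest amyloid mask
#' pixel (0 inside the mask; strict `< cutoff` defines the near bin) and
#' reports per-cell-type composition of the two bins, the near/far
#' enrichment ratio, and a chi-square p-value for type-by-bin association.
#'
#' @param nuclei data.frame with `x`, `y` (um, raster frame) and
#'   `cell_type`.
#' @param ab_mask amyloid [mask_raster()].
#' @param cutoff distance cutoff in um (default 20).
#' @return list: `table` (per-type counts and fractions near/far, ratio),
#'   `p_value`, `distances`.
#' @export
nuclei_near_plaques <- function(nuclei, ab_mask, cutoff = 20) {
  stopifnot(all(c("x", "y", "cell_type") %in% colnames(nuclei)))
  dmap <- distance_from_mask(ab_mask)
  ps <- ab_mask$pixel_size
  ii <- pmin(pmax(ceiling(nuclei$y / ps), 1L), nrow(dmap))
  jj <- pmin(pmax(ceiling(nuclei$x / ps), 1L), ncol(dmap))
  d <- dmap[cbind(ii, jj)]
  near <- d < cutoff
  types <- sort(unique(nuclei$cell_type))
  tab <- data.frame(cell_type = types, stringsAsFactors = FALSE)
  tab$n_near <- vapply(types, function(t) sum(near & nuclei$cell_type == t), 0L)
  tab$n_far <- vapply(types, function(t) sum(!near & nuclei$cell_type == t), 0L)
  n_near <- sum(tab$n_near); n_far <- sum(tab$n_far)
  tab$frac_near <- if (n_near > 0) tab$n_near / n_near else NA_real_
  tab$frac_far <- if (n_far > 0) tab$n_far / n_far else NA_real_
  tab$enrichment_ratio <- tab$frac_near / tab$frac_far
  p <- NA_real_
  if (n_near > 0 && n_far > 0 && length(types) > 1L) {
    m <- as.matrix(tab[, c("n_near", "n_far")])
    keep <- rowSums(m) > 0
    if (sum(keep) > 1L)
      p <- suppressWarnings(stats::chisq.test(m[keep, , drop = FALSE])$p.value)
  }
  list(table = tab, p_value = p, distances = d)
}
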