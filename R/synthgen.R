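#' Parameters of the synthetic tissue generator
#'
#' Bundles every knob of the ground-truth simulator: plaque field geometry,
#' myeloid recruitment, and the negative-binomial expression model with
#' planted niche-responsive and group-responsive gene programs. All values
#' are artifact choices of the simulator, documented in the methods
#' vignette; they are not measurements.
#'
#' @param seed integer seed; every generator call is a pure function of
#'   `(params, seed)`.
#' @param pixel_size raster resolution, micrometres per pixel.
#' @param plaque_rate expected plaques per square millimetre.
#' @param plaque_radius_meanlog,plaque_radius_sdlog log-normal parameters of
#'   the plaque radius in micrometres.
#' @param vessel_count number of synthetic penetrating vessels per field.
#' @param vascular_frac fraction of plaques relocated onto vessels and
#'   labeled vascular (CAA-like).
#' @param recruitment_base,recruitment_near_plaque probability that a
#'   candidate myeloid soma is placed, far from vs within one radius of a
#'   plaque boundary.
#' @param n_genes,n_niche_genes,n_group_genes gene panel sizes; planted
#'   programs must fit in the panel.
#' @param niche_lfc_max peak log2 fold change of niche genes at the plaque
#'   boundary (decays with distance).
#' @param niche_decay_scale e-folding distance (um) of the niche effect.
#' @param group_lfc absolute log2 fold change planted on group genes (half
#'   up, half down in the second group level).
#' @param nb_dispersion negative-binomial size parameter theta
#'   (Var = mu + mu^2/theta), shared across genes.
#' @param libsize_meanlog,libsize_sdlog log-normal spot library size.
#' @param donors_per_group donors simulated per comparison group.
#' @param spots_per_donor spots per donor in [simulate_cohort()].
#' @return a `synth_params` list.
#' @export
synth_params <- function(seed = 1L,
                         pixel_size = 2,
                         plaque_rate = 15,
                         plaque_radius_meanlog = log(25),
                         plaque_radius_sdlog = 0.35,
                         vessel_count = 3L,
                         vascular_frac = 0.15,
                         recruitment_base = 0.05,
                         recruitment_near_plaque = 0.6,
                         n_genes = 2000L,
                         n_niche_genes = 50L,
                         niche_lfc_max = 2,
                         niche_decay_scale = 50,
                         n_group_genes = 100L,
                         group_lfc = 1.5,
                         nb_dispersion = 2,
                         libsize_meanlog = log(5000),
                         libsize_sdlog = 0.3,
                         donors_per_group = 6L,
                         spots_per_donor = 2000L) {
  p <- list(seed = as.integer(seed), pixel_size = pixel_size,
            plaque_rate = plaque_rate,
            plaque_radius_meanlog = plaque_radius_meanlog,
            plaque_radius_sdlog = plaque_radius_sdlog,
            vessel_count = as.integer(vessel_count),
            vascular_frac = vascular_frac,
            recruitment_base = recruitment_base,
            recruitment_near_plaque = recruitment_near_plaque,
            n_genes = as.integer(n_genes),
            n_niche_genes = as.integer(n_niche_genes),
            niche_lfc_max = niche_lfc_max,
            niche_decay_scale = niche_decay_scale,
            n_group_genes = as.integer(n_group_genes),
            group_lfc = group_lfc,
            nb_dispersion = nb_dispersion,
            libsize_meanlog = libsize_meanlog,
            libsize_sdlog = libsize_sdlog,
            donors_per_group = as.integer(donors_per_group),
            spots_per_donor = as.integer(spots_per_donor))
  probs <- c("vascular_frac", "recruitment_base", "recruitment_near_plaque")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1) stop_invalid(nm, " must lie in [0, 1]")
  if (p$pixel_size <= 0) stop_invalid("pixel_size must be positive")
  if (p$plaque_rate < 0) stop_invalid("plaque_rate must be >= 0")
  if (p$niche_decay_scale <= 0) stop_invalid("niche_decay_scale must be positive")
  if (p$nb_dispersion <= 0) stop_invalid("nb_dispersion must be positive")
  if (p$n_niche_genes + p$n_group_genes > p$n_genes)
    stop_invalid("planted gene programs exceed the gene panel")
  structure(p, class = "synth_params")
}

#' Build a hexagonally packed spot grid
#'
#' Pointy-top rows: row spacing `pitch * sqrt(3)/2`, odd rows shifted by
#' `pitch / 2` in x, so every nearest-neighbor center distance equals the
#' pitch exactly. Array coordinates `(array_row, array_col)` are 0-based and
#' stored alongside physical `(x, y)` in micrometres. Regions are assigned
#' as contiguous row bands in the order given (e.g. meninges at the top,
#' then cortical layers, then white matter).
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pitch center-to-center spot distance, um.
#' @param spot_diameter capture-spot diameter, um; must be below the pitch.
#' @param region_layout character vector of region bands, split over rows
#'   proportionally; length 1 annotates every spot identically.
#' @param sample_id sample label carried by every spot.
#' @return a `data.frame` (class `spot_grid`) with columns `spot_id`,
#'   `array_row`, `array_col`, `x`, `y`, `region`, `sample_id`,
#'   `reliable_ab`; attributes `pitch` and `spot_diameter`.
#' @export
make_spot_grid <- function(n_rows, n_cols, pitch, spot_diameter,
                           region_layout = "layer III",
                           sample_id = "S1") {
  if (n_rows < 1 || n_cols < 1) stop_invalid("grid dimensions must be >= 1")
  if (!(pitch > spot_diameter && spot_diameter > 0))
    stop_invalid("need pitch > spot_diameter > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  x <- (col + 0.5 * (row %% 2L)) * pitch
  y <- row * pitch * sqrt(3) / 2
  band <- findInterval(row, seq(0, n_rows, length.out = length(region_layout) + 1L),
                       rightmost.closed = TRUE, left.open = FALSE)
  band <- pmin(pmax(band, 1L), length(region_layout))
  g <- data.frame(
    spot_id = sprintf("%s_spot%05d", sample_id, seq_along(row)),
    array_row = row, array_col = col, x = x, y = y,
    region = region_layout[band],
    sample_id = sample_id,
    reliable_ab = TRUE,
    stringsAsFactors = FALSE)
  attr(g, "pitch") <- pitch
  attr(g, "spot_diameter") <- spot_diameter
  class(g) <- c("spot_grid", "data.frame")
  g
}

grid_bbox <- function(grid, margin = 0) {
  c(xmin = min(grid$x) - margin, xmax = max(grid$x) + margin,
    ymin = min(grid$y) - margin, ymax = max(grid$y) + margin)
}

# Signed-free distance from points to the nearest plaque boundary:
# 0 inside a plaque, Inf when there are no plaques.
dist_to_plaque_boundary <- function(x, y, plaques) {
  if (is.null(plaques) || nrow(plaques) == 0L) return(rep(Inf, length(x)))
  d <- matrix(Inf, length(x), nrow(plaques))
  for (j in seq_len(nrow(plaques))) {
    d[, j] <- sqrt((x - plaques$x[j])^2 + (y - plaques$y[j])^2) - plaques$radius[j]
  }
  pmax(apply(d, 1, min), 0)
}

#' Sample a ground-truth plaque field over a grid's bounding box
#'
#' Plaque count is Poisson in the field area; centers are uniform; radii are
#' log-normal. A `vascular_frac` share of plaques is relocated onto randomly
#' oriented vessel polylines and labeled vascular (CAA-like); the rest are
#' cortical.
#'
#' @param grid a [make_spot_grid()] grid (defines the field extent).
#' @param params a [synth_params()].
#' @param seed overrides `params$seed` when given.
#' @param margin field margin beyond the grid bounding box, um.
#' @return a `synth_truth` list: `plaques` (x, y, radius, class), `vessels`
#'   (list of polyline matrices), `bbox`.
#' @export
sample_plaques <- function(grid, params, seed = params$seed, margin = 100) {
  bbox <- grid_bbox(grid, margin)
  w <- bbox["xmax"] - bbox["xmin"]; h <- bbox["ymax"] - bbox["ymin"]
  area_mm2 <- as.numeric(w * h) / 1e6
  with_local_seed(seed, {
    vessels <- lapply(seq_len(params$vessel_count), function(i) {
      # a vessel crosses the field top to bottom with a random tilt
      x0 <- stats::runif(1, bbox["xmin"], bbox["xmax"])
      x1 <- x0 + stats::runif(1, -0.3, 0.3) * as.numeric(w)
      ys <- seq(bbox["ymin"], bbox["ymax"], length.out = 20)
      cbind(x = seq(x0, x1, length.out = 20), y = ys)
    })
    n <- stats::rpois(1, params$plaque_rate * area_mm2)
    if (n == 0L) {
      plaques <- data.frame(x = numeric(0), y = numeric(0),
                            radius = numeric(0), class = character(0),
                            stringsAsFactors = FALSE)
    } else {
      px <- stats::runif(n, bbox["xmin"], bbox["xmax"])
      py <- stats::runif(n, bbox["ymin"], bbox["ymax"])
      r <- stats::rlnorm(n, params$plaque_radius_meanlog, params$plaque_radius_sdlog)
      cls <- ifelse(stats::runif(n) < params$vascular_frac, "vascular", "cortical")
      if (length(vessels) && any(cls == "vascular")) {
        for (i in which(cls == "vascular")) {
          v <- vessels[[sample.int(length(vessels), 1)]]
          k <- sample.int(nrow(v), 1)
          px[i] <- v[k, "x"]; py[i] <- v[k, "y"]
        }
      }
      plaques <- data.frame(x = px, y = py, radius = r, class = cls,
                            stringsAsFactors = FALSE)
    }
    structure(list(plaques = plaques, vessels = vessels, bbox = bbox),
              class = "synth_truth")
  })
}

render_discs <- function(cx, cy, radius, bbox, pixel_size) {
  nx <- max(1L, ceiling(as.numeric(bbox["xmax"] - bbox["xmin"]) / pixel_size))
  ny <- max(1L, ceiling(as.numeric(bbox["ymax"] - bbox["ymin"]) / pixel_size))
  px <- matrix(0L, ny, nx)
  if (length(cx) == 0L) return(px)
  xc <- bbox["xmin"] + (seq_len(nx) - 0.5) * pixel_size
  yc <- bbox["ymin"] + (seq_len(ny) - 0.5) * pixel_size
  for (i in seq_along(cx)) {
    jx <- which(abs(xc - cx[i]) <= radius[i])
    jy <- which(abs(yc - cy[i]) <= radius[i])
    if (!length(jx) || !length(jy)) next
    dx2 <- (xc[jx] - cx[i])^2
    dy2 <- (yc[jy] - cy[i])^2
    hit <- outer(dy2, dx2, "+") <= radius[i]^2
    px[jy, jx][hit] <- 1L
  }
  px
}

#' Render ground-truth rasters for a plaque field
#'
#' Renders the sampled plaques into a binary amyloid raster, the vascular
#' subset into a separate label raster, and places myeloid (IBA1-like) somata
#' with probability `recruitment_near_plaque` within one radius of a plaque
#' boundary and `recruitment_base` elsewhere.
#'
#' @param grid a spot grid defining the field extent.
#' @param params a [synth_params()].
#' @param seed overrides `params$seed`.
#' @param truth optionally a pre-sampled [sample_plaques()] field; when
#'   omitted one is drawn from `(params, seed)`.
#' @return list: `ab_mask`, `vascular_labels`, `iba1_mask` ([mask_raster()]s)
#'   and `truth` (with per-spot `recruitment_map` added).
#' @export
make_tissue_raster <- function(grid, params, seed = params$seed, truth = NULL) {
  if (params$pixel_size <= 0) stop_invalid("pixel_size must be positive")
  if (is.null(truth)) truth <- sample_plaques(grid, params, seed)
  bbox <- truth$bbox
  pl <- truth$plaques
  ab <- render_discs(pl$x, pl$y, pl$radius, bbox, params$pixel_size)
  vi <- pl$class == "vascular"
  vl <- render_discs(pl$x[vi], pl$y[vi], pl$radius[vi], bbox, params$pixel_size)
  iba <- with_local_seed(seed + 1L, {
    area_mm2 <- as.numeric((bbox["xmax"] - bbox["xmin"]) *
                           (bbox["ymax"] - bbox["ymin"])) / 1e6
    n_cand <- stats::rpois(1, 400 * area_mm2)  # candidate somata per mm^2
    cx <- stats::runif(n_cand, bbox["xmin"], bbox["xmax"])
    cy <- stats::runif(n_cand, bbox["ymin"], bbox["ymax"])
    d <- dist_to_plaque_boundary(cx, cy, pl)
    r_near <- if (nrow(pl)) mean(pl$radius) else 0
    p <- ifelse(d <= r_near, params$recruitment_near_plaque,
                params$recruitment_base)
    keep <- stats::runif(n_cand) < p
    render_discs(cx[keep], cy[keep], rep(8, sum(keep)), bbox, params$pixel_size)
  })
  d_spot <- dist_to_plaque_boundary(grid$x, grid$y, pl)
  truth$recruitment_map <- stats::setNames(
    ifelse(is.finite(d_spot), exp(-d_spot / params$niche_decay_scale), 0),
    grid$spot_id)
  list(ab_mask = mask_raster(ab, params$pixel_size),
       vascular_labels = mask_raster(vl, params$pixel_size),
       iba1_mask = mask_raster(iba, params$pixel_size),
       truth = truth)
}

#' Simulate a deconvolution-style cell-type abundance table
#'
#' Per spot, a Dirichlet draw over cell types scaled by a Poisson
#' total-cells draw (1-10 cells per spot); the microglia concentration is
#' multiplied by `1 + microglia_boost * recruitment_map`, planting
#' plaque-proximal microglial enrichment.
#'
#' @param grid spot grid.
#' @param truth a [make_tissue_raster()] truth carrying `recruitment_map`.
#' @param base_dirichlet named positive concentration vector over cell
#'   types; must include `"microglia"`.
#' @param microglia_boost non-negative multiplier on the recruitment excess.
#' @param seed integer seed.
#' @return data.frame: `spot_id` plus one abundance column per cell type.
#' @export
make_abundances <- function(grid, truth, base_dirichlet, microglia_boost = 3,
                            seed = 1L) {
  if (is.null(names(base_dirichlet)) || !all(nzchar(names(base_dirichlet))))
    stop_invalid("base_dirichlet must be a named vector of cell types")
  if (any(base_dirichlet <= 0)) stop_invalid("Dirichlet concentrations must be positive")
  if (!"microglia" %in% names(base_dirichlet))
    stop_invalid("cell types must include 'microglia'")
  if (microglia_boost < 0) stop_invalid("microglia_boost must be >= 0")
  rec <- truth$recruitment_map[grid$spot_id]
  rec[is.na(rec)] <- 0
  n <- nrow(grid); k <- length(base_dirichlet)
  with_local_seed(seed, {
    alpha <- matrix(rep(base_dirichlet, each = n), n, k)
    colnames(alpha) <- names(base_dirichlet)
    alpha[, "microglia"] <- alpha[, "microglia"] * (1 + microglia_boost * rec)
    draws <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
    fr <- draws / pmax(rowSums(draws), .Machine$double.eps)
    total <- 1 + stats::rpois(n, 5)
    ab <- fr * total
    out <- data.frame(spot_id = grid$spot_id, ab, stringsAsFactors = FALSE)
    colnames(out) <- c("spot_id", names(base_dirichlet))
    out
  })
}

#' Simulate spot-level counts with planted niche and group programs
#'
#' Counts are negative binomial, `NB(mean = L_s * p_g * 2^eff, size = theta)`
#' with spot library size `L_s` log-normal and gene baseline `p_g` a
#' log-normal relative-abundance profile. Niche genes carry
#' `lfc(d) = niche_lfc_max * exp(-d / niche_decay_scale)` with `d` the spot's
#' distance to the nearest plaque boundary (0 inside a plaque); group genes
#' carry `+/- group_lfc` in donors of the second group level. Unit metadata
#' includes donor, group, sex, age, gDNA percentage, region, and the
#' cellular detection rate (fraction of genes detected per spot).
#'
#' @param grid spot grid whose `sample_id` column assigns spots to donors.
#' @param truth plaque-field truth per donor: a single `synth_truth` shared
#'   by all spots, or a named list of truths keyed by donor.
#' @param params a [synth_params()].
#' @param group_label named character vector, donor -> group (two levels).
#' @param seed integer seed.
#' @return list: `counts` (genes x spots integer matrix), `meta` (per-spot
#'   data.frame), `truth_genes` (planted `niche_genes` / `group_genes`
#'   tables).
#' @export
make_counts <- function(grid, truth, params, group_label, seed = params$seed) {
  donors <- unique(grid$sample_id)
  if (is.null(names(group_label)) || !all(donors %in% names(group_label)))
    stop_invalid("group_label must name a group for every donor in the grid")
  groups <- unique(group_label[donors])
  if (length(groups) > 2L) stop_invalid("at most two group levels supported")
  n_genes <- params$n_genes
  genes <- sprintf("gene%04d", seq_len(n_genes))
  niche_ids <- genes[seq_len(params$n_niche_genes)]
  group_ids <- genes[params$n_niche_genes + seq_len(params$n_group_genes)]
  n_up <- ceiling(params$n_group_genes / 2)
  group_sign <- rep(c(1, -1), c(n_up, params$n_group_genes - n_up))
  # distance of each spot to its donor's nearest plaque boundary
  d_spot <- rep(Inf, nrow(grid))
  get_truth <- function(donor) {
    if (inherits(truth, "synth_truth")) truth else truth[[donor]]
  }
  for (donor in donors) {
    idx <- grid$sample_id == donor
    tr <- get_truth(donor)
    d_spot[idx] <- dist_to_plaque_boundary(grid$x[idx], grid$y[idx], tr$plaques)
  }
  niche_eff_spot <- ifelse(is.finite(d_spot),
                           exp(-d_spot / params$niche_decay_scale), 0)
  treated <- group_label[grid$sample_id] == groups[length(groups)]
  with_local_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    baseline <- baseline / sum(baseline)
    names(baseline) <- genes
    L <- stats::rlnorm(nrow(grid), params$libsize_meanlog, params$libsize_sdlog)
    mu <- baseline %o% L
    dimnames(mu) <- list(genes, grid$spot_id)
    if (length(niche_ids))
      mu[niche_ids, ] <- mu[niche_ids, ] *
        2^(params$niche_lfc_max *
           matrix(niche_eff_spot, length(niche_ids), nrow(grid), byrow = TRUE))
    if (length(group_ids) && any(treated))
      mu[group_ids, treated] <- mu[group_ids, treated] *
        2^(params$group_lfc * group_sign)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = params$nb_dispersion),
                     n_genes, nrow(grid),
                     dimnames = list(genes, grid$spot_id))
    storage.mode(counts) <- "integer"
    donor_meta <- data.frame(
      sample_id = donors,
      group = group_label[donors],
      sex = sample(c("F", "M"), length(donors), replace = TRUE),
      age = round(stats::rnorm(length(donors), 80, 7)),
      gdna_pct = round(stats::runif(length(donors), 1, 10), 2),
      stringsAsFactors = FALSE)
    meta <- donor_meta[match(grid$sample_id, donor_meta$sample_id), ]
    meta$spot_id <- grid$spot_id
    meta$region <- grid$region
    meta$cdr <- colMeans(counts > 0L)
    meta$dist_to_plaque <- d_spot
    rownames(meta) <- meta$spot_id
    meta <- meta[, c("spot_id", "sample_id", "group", "sex", "age",
                     "gdna_pct", "region", "cdr", "dist_to_plaque")]
    truth_genes <- list(
      niche_genes = data.frame(gene = niche_ids,
                               max_lfc = rep(params$niche_lfc_max,
                                             length(niche_ids)),
                               stringsAsFactors = FALSE),
      group_genes = data.frame(gene = group_ids, lfc = params$group_lfc * group_sign,
                               stringsAsFactors = FALSE))
    list(counts = counts, meta = meta, truth_genes = truth_genes)
  })
}

#' Simulate a full multi-donor cohort
#'
#' Convenience wrapper: builds one hex grid per donor, samples an
#' independent plaque field per donor, and generates counts plus metadata
#' for a two-group comparison. Rasters are not rendered here (use
#' [make_tissue_raster()] per donor when image-domain output is needed).
#'
#' @param params a [synth_params()].
#' @param pitch,spot_diameter grid geometry, um.
#' @param region_layout row-band regions per donor grid.
#' @param groups the two group labels.
#' @param seed integer seed.
#' @return list: `grid` (all donors combined), `counts`, `meta`, `truths`
#'   (per-donor plaque fields), `truth_genes`.
#' @export
simulate_cohort <- function(params = synth_params(),
                            pitch = 100, spot_diameter = 55,
                            region_layout = c("layer II", "layer III",
                                              "layer IV", "layer V"),
                            groups = c("control", "immunized"),
                            seed = params$seed) {
  n_donors <- 2L * params$donors_per_group
  n_cols <- as.integer(ceiling(sqrt(params$spots_per_donor / 1.2)))
  n_rows <- as.integer(ceiling(params$spots_per_donor / n_cols))
  donors <- sprintf("D%02d", seq_len(n_donors))
  group_label <- stats::setNames(rep(groups, each = params$donors_per_group), donors)
  grids <- vector("list", n_donors)
  truths <- vector("list", n_donors)
  for (i in seq_len(n_donors)) {
    g <- make_spot_grid(n_rows, n_cols, pitch, spot_diameter,
                        region_layout, sample_id = donors[i])
    g <- g[seq_len(min(params$spots_per_donor, nrow(g))), , drop = FALSE]
    grids[[i]] <- g
    truths[[i]] <- sample_plaques(g, params, seed = seed + i)
  }
  grid <- do.call(rbind, grids)
  attr(grid, "pitch") <- pitch
  attr(grid, "spot_diameter") <- spot_diameter
  class(grid) <- c("spot_grid", "data.frame")
  names(truths) <- donors
  cm <- make_counts(grid, truths, params, group_label, seed = seed + 1000L)
  list(grid = grid, counts = cm$counts, meta = cm$meta,
       truths = truths, truth_genes = cm$truth_genes,
       group_label = group_label)
}
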