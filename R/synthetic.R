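#' Tissue geometries for the synthetic bead-array simulator
#'
#' Two footprints cover the shapes the downstream analyses assume: an annular
#' arc emulating a ventricular wall cross-section (a curved band with an inner
#' lumen-facing edge and an outer epicardial edge) and a truncated wedge
#' emulating a valve leaflet (narrow free tip widening toward the base).
#'
#' Spots are laid on a square grid at `spot_spacing` with Gaussian positional
#' jitter, then clipped to the footprint, mirroring beads dispersed in a
#' plane. All lengths are in micrometres.
#'
#' @param center Numeric length-2, centre of the annulus arc.
#' @param r_inner,r_outer Inner and outer radii; `r_inner < r_outer`.
#' @param theta_start,theta_end Angular span of the arc in radians
#'   (default a half-annulus), giving the shape distinct "upper" and
#'   "bottom" ends so an axial coordinate is well defined.
#' @param spot_spacing Grid pitch between bead centres.
#' @param jitter_sd Standard deviation of positional jitter.
#' @return A `tissue_geometry` object.
#' @export
tissue_annulus <- function(center = c(0, 0), r_inner = 300, r_outer = 600,
                           theta_start = 0, theta_end = pi,
                           spot_spacing = 20, jitter_sd = spot_spacing / 10) {
  if (!(is.numeric(center) && length(center) == 2L)) {
    rlang::abort("`center` must be a numeric length-2 vector.")
  }
  if (r_inner <= 0 || r_outer <= 0 || spot_spacing <= 0 || jitter_sd < 0) {
    rlang::abort("All lengths must be positive (jitter_sd may be 0).")
  }
  if (r_inner >= r_outer) {
    rlang::abort("Degenerate annulus: `r_inner` must be smaller than `r_outer`.")
  }
  if (theta_end <= theta_start || theta_end - theta_start > 2 * pi) {
    rlang::abort("Angular span must be positive and at most 2*pi.")
  }
  structure(
    list(
      shape_kind = "annulus", center = center,
      r_inner = r_inner, r_outer = r_outer,
      theta_start = theta_start, theta_end = theta_end,
      spot_spacing = spot_spacing, jitter_sd = jitter_sd
    ),
    class = "tissue_geometry"
  )
}

#' @rdname tissue_annulus
#' @param apex Numeric length-2, position of the leaflet tip.
#' @param base_width Width of the base edge.
#' @param height Tip-to-base extent along the +y axis.
#' @param tip_width Width of the (truncated) tip edge; must be positive so
#'   the tip band contains spots at the default spacing.
#' @export
tissue_wedge <- function(apex = c(0, 0), base_width = 400, height = 600,
                         tip_width = base_width / 4,
                         spot_spacing = 20, jitter_sd = spot_spacing / 10) {
  if (!(is.numeric(apex) && length(apex) == 2L)) {
    rlang::abort("`apex` must be a numeric length-2 vector.")
  }
  if (base_width <= 0 || height <= 0 || tip_width <= 0 ||
      spot_spacing <= 0 || jitter_sd < 0) {
    rlang::abort("All lengths must be positive (jitter_sd may be 0).")
  }
  if (tip_width >= base_width) {
    rlang::abort("`tip_width` must be smaller than `base_width`.")
  }
  structure(
    list(
      shape_kind = "wedge", apex = apex,
      base_width = base_width, height = height, tip_width = tip_width,
      spot_spacing = spot_spacing, jitter_sd = jitter_sd
    ),
    class = "tissue_geometry"
  )
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat("<tissue_geometry>", x$shape_kind, "\n")
  if (x$shape_kind == "annulus") {
    cat("  r:", x$r_inner, "-", x$r_outer, "um, theta:",
        signif(x$theta_start, 3), "-", signif(x$theta_end, 3), "rad\n")
  } else {
    cat("  tip", x$tip_width, "-> base", x$base_width, "um, height",
        x$height, "um\n")
  }
  cat("  spacing:", x$spot_spacing, "um, jitter sd:", x$jitter_sd, "um\n")
  invisible(x)
}

# Internal geometry predicates -------------------------------------------

# normalized angle within span, or NA outside
annulus_theta <- function(geom, x, y) {
  th <- atan2(y - geom$center[2], x - geom$center[1])
  th <- (th - geom$theta_start) %% (2 * pi) + geom$theta_start
  th
}

wedge_halfwidth <- function(geom, t) {
  (geom$tip_width + (geom$base_width - geom$tip_width) * t) / 2
}

geometry_membership <- function(geom, x, y) {
  if (geom$shape_kind == "annulus") {
    r <- sqrt((x - geom$center[1])^2 + (y - geom$center[2])^2)
    th <- annulus_theta(geom, x, y)
    inside <- r >= geom$r_inner & r <= geom$r_outer & th <= geom$theta_end
    radial <- (geom$r_outer - r) / (geom$r_outer - geom$r_inner)
    axial <- (th - geom$theta_start) / (geom$theta_end - geom$theta_start)
    tibble::tibble(inside = inside, radial = radial, axial = axial, r = r,
                   theta = th)
  } else {
    t <- (y - geom$apex[2]) / geom$height
    hw <- wedge_halfwidth(geom, pmax(pmin(t, 1), 0))
    dx <- x - geom$apex[1]                      # signed: <0 left, >0 right
    inside <- t >= 0 & t <= 1 & abs(dx) <= hw
    # tip is the innermost, most immature end: radial fraction 1 at the tip
    tibble::tibble(inside = inside, radial = 1 - t, axial = t, r = dx,
                   theta = NA_real_)
  }
}

# Boundary ring flags: spots within one spot_spacing of the exact boundary.
geometry_boundaries <- function(geom, memb) {
  s <- geom$spot_spacing
  if (geom$shape_kind == "annulus") {
    list(
      inner = memb$r - geom$r_inner <= s,
      outer = geom$r_outer - memb$r <= s,
      upper = memb$r * (memb$theta - geom$theta_start) <= s,
      bottom = memb$r * (geom$theta_end - memb$theta) <= s
    )
  } else {
    hw <- wedge_halfwidth(geom, memb$axial)
    list(
      inner = memb$axial * geom$height <= s,                # tip band
      outer = (1 - memb$axial) * geom$height <= s,          # base band
      upper = hw - abs(memb$r) <= s & memb$r < 0,           # left slant
      bottom = hw - abs(memb$r) <= s & memb$r > 0           # right slant
    )
  }
}

#' Simulate a bead-array spot table with planted ground truth
#'
#' Lays jittered grid spots over a [tissue_annulus()] or [tissue_wedge()]
#' footprint, draws per-spot sequencing depth from a negative binomial
#' (overdispersed bead counts), splits depth over a synthetic gene panel, and
#' optionally plants low-count off-tissue "smear" spots in a sparse halo
#' beyond the tissue margin. Ground truth (radial/axial fractions per spot)
#' and analytic boundary rings (inner/outer/upper/bottom, the spots within
#' one grid spacing of the exact geometric boundary) are returned alongside.
#'
#' The simulator is a pure function of its parameters and `seed`.
#'
#' @param geometry A `tissue_geometry`.
#' @param mean_depth Mean total counts per in-tissue spot.
#' @param dispersion Negative-binomial size parameter for depth (smaller =
#'   more overdispersed).
#' @param smear_fraction Expected number of smear spots as a fraction of the
#'   in-tissue spot count; smear count is Binomial(n_tissue, smear_fraction).
#'   Smears receive uniform counts in `[1, qc_min_counts / 2]` and are
#'   scattered 5-15 grid spacings away from the nearest tissue spot (for the
#'   annulus, always beyond the outer radius), i.e. a sparse off-tissue
#'   field rather than a contiguous rim hugging the margin.
#' @param n_genes Size of the synthetic gene panel.
#' @param qc_min_counts The downstream QC count threshold used only to set
#'   the smear count ceiling.
#' @param condition,day Sample metadata tags carried on every spot.
#' @param seed Integer seed; identical calls reproduce identical output.
#' @return A `spot_sim` list: `spots` (tibble: spot_id, x, y, total_counts,
#'   is_smear, condition, day), `counts` (sparse spots x genes matrix),
#'   `truth` (tibble: spot_id, true_radial_fraction, true_axial_fraction;
#'   NA for smears), `boundaries` (list of spot-id vectors), `geometry`,
#'   `params`.
#' @export
#' @examples
#' sim <- sim_spots(tissue_annulus(r_inner = 300, r_outer = 450), seed = 1)
#' sim$spots
sim_spots <- function(geometry, mean_depth = 1000, dispersion = 2,
                      smear_fraction = 0, n_genes = 40, qc_min_counts = 100,
                      condition = "normal", day = 10, seed = 0) {
  if (!inherits(geometry, "tissue_geometry")) {
    rlang::abort("`geometry` must be created by tissue_annulus() or tissue_wedge().")
  }
  if (mean_depth <= 0) rlang::abort("`mean_depth` must be positive.")
  if (smear_fraction < 0 || smear_fraction >= 1) {
    rlang::abort("`smear_fraction` must be in [0, 1).")
  }

  withr::with_seed(seed, {
    s <- geometry$spot_spacing
    if (geometry$shape_kind == "annulus") {
      cx <- geometry$center[1]; cy <- geometry$center[2]
      gx <- seq(cx - geometry$r_outer - s, cx + geometry$r_outer + s, by = s)
      gy <- seq(cy - geometry$r_outer - s, cy + geometry$r_outer + s, by = s)
    } else {
      ax <- geometry$apex[1]; ay <- geometry$apex[2]
      gx <- seq(ax - geometry$base_width / 2 - s,
                ax + geometry$base_width / 2 + s, by = s)
      gy <- seq(ay - s, ay + geometry$height + s, by = s)
    }
    grid <- expand.grid(x = gx, y = gy)
    grid$x <- grid$x + stats::rnorm(nrow(grid), 0, geometry$jitter_sd)
    grid$y <- grid$y + stats::rnorm(nrow(grid), 0, geometry$jitter_sd)
    memb <- geometry_membership(geometry, grid$x, grid$y)
    keep <- which(memb$inside)
    if (length(keep) == 0L) {
      rlang::abort("Geometry produced no in-tissue spots; check dimensions.")
    }
    tissue <- grid[keep, , drop = FALSE]
    memb <- memb[keep, , drop = FALSE]
    n_tissue <- nrow(tissue)

    rings <- geometry_boundaries(geometry, memb)

    # smears: a sparse off-tissue field, 5-15 spacings from the nearest
    # tissue spot (rejection sampling over the padded bounding box)
    n_smear <- if (smear_fraction > 0) {
      stats::rbinom(1L, n_tissue, smear_fraction)
    } else 0L
    sx <- numeric(0); sy <- numeric(0)
    if (n_smear > 0L) {
      pad <- 15 * s
      xr <- range(tissue$x) + c(-pad, pad)
      yr <- range(tissue$y) + c(-pad, pad)
      tries <- 0L
      while (length(sx) < n_smear && tries < 200L) {
        m <- 4L * n_smear
        cx <- stats::runif(m, xr[1], xr[2])
        cy <- stats::runif(m, yr[1], yr[2])
        d <- nearest_boundary_dist(cx, cy, tissue$x, tissue$y)
        ok <- d >= 5 * s & d <= 15 * s &
          !geometry_membership(geometry, cx, cy)$inside
        if (geometry$shape_kind == "annulus") {
          rr <- sqrt((cx - geometry$center[1])^2 +
                       (cy - geometry$center[2])^2)
          ok <- ok & rr > geometry$r_outer + s   # outside, never in the lumen
        }
        sx <- c(sx, cx[ok]); sy <- c(sy, cy[ok])
        tries <- tries + 1L
      }
      if (length(sx) < n_smear) {
        rlang::abort("Could not place the requested smear spots off-tissue.")
      }
      sx <- sx[seq_len(n_smear)]; sy <- sy[seq_len(n_smear)]
    }

    n_total <- n_tissue + n_smear
    spot_id <- sprintf("spot_%05d", seq_len(n_total))
    depth_tissue <- pmax(1L, stats::rnbinom(n_tissue, mu = mean_depth,
                                            size = dispersion))
    smear_max <- max(1L, floor(qc_min_counts / 2))
    depth_smear <- if (n_smear > 0L) {
      sample.int(smear_max, n_smear, replace = TRUE)
    } else integer(0)
    total_counts <- c(depth_tissue, depth_smear)

    # fixed expression simplex over the synthetic gene panel
    gene_w <- stats::rgamma(n_genes, shape = 1)
    gene_w <- gene_w / sum(gene_w)
    counts <- t(vapply(total_counts, function(tt) {
      stats::rmultinom(1L, tt, gene_w)[, 1L]
    }, integer(n_genes)))
    dimnames(counts) <- list(spot_id, sprintf("gene_%03d", seq_len(n_genes)))
    counts <- Matrix::Matrix(counts, sparse = TRUE)

    spots <- tibble::tibble(
      spot_id = spot_id,
      x = c(tissue$x, sx), y = c(tissue$y, sy),
      total_counts = as.integer(total_counts),
      is_smear = c(rep(FALSE, n_tissue), rep(TRUE, n_smear)),
      condition = condition, day = day
    )
    truth <- tibble::tibble(
      spot_id = spot_id,
      true_radial_fraction = c(memb$radial, rep(NA_real_, n_smear)),
      true_axial_fraction = c(memb$axial, rep(NA_real_, n_smear))
    )
    tissue_ids <- spot_id[seq_len(n_tissue)]
    boundaries <- lapply(rings, function(flag) tissue_ids[flag])

    structure(
      list(
        spots = spots, counts = counts, truth = truth,
        boundaries = boundaries, geometry = geometry,
        params = list(mean_depth = mean_depth, dispersion = dispersion,
                      smear_fraction = smear_fraction, n_genes = n_genes,
                      qc_min_counts = qc_min_counts, seed = seed)
      ),
      class = "spot_sim"
    )
  })
}

#' Radial cell-type composition profiles
#'
#' Helpers building weight functions over the radial fraction (0 = outer
#' boundary, 1 = inner/lumen) for [sim_proportion_field()]. The logistic
#' profile emulates a graded immature-to-mature transition across the wall;
#' the step profile is its sharp limit; the flat profile is a spatially
#' uniform background type.
#'
#' @param midpoint Radial fraction at which the logistic reaches half height.
#' @param slope Logistic steepness; larger = sharper transition.
#' @param direction `"increasing"` toward the inner boundary, or
#'   `"decreasing"`.
#' @param base,scale Affine range of the profile: values span
#'   `[base, base + scale]`.
#' @return A function mapping radial fractions in `[0, 1]` to nonnegative
#'   weights.
#' @export
logistic_profile <- function(midpoint = 0.5, slope = 10,
                             direction = c("increasing", "decreasing"),
                             base = 0, scale = 1) {
  direction <- match.arg(direction)
  sgn <- if (direction == "increasing") 1 else -1
  force(midpoint); force(slope); force(base); force(scale)
  function(t) base + scale * stats::plogis(sgn * slope * (t - midpoint))
}

#' @rdname logistic_profile
#' @param threshold Step location on the radial fraction.
#' @export
step_profile <- function(threshold = 0.5,
                         direction = c("increasing", "decreasing"),
                         base = 0, scale = 1) {
  direction <- match.arg(direction)
  force(threshold); force(base); force(scale)
  if (direction == "increasing") {
    function(t) base + scale * as.numeric(t > threshold)
  } else {
    function(t) base + scale * as.numeric(t <= threshold)
  }
}

#' @rdname logistic_profile
#' @param value Constant weight.
#' @export
flat_profile <- function(value = 1) {
  force(value)
  function(t) rep(value, length(t))
}

#' Simulate deconvolution abundances from radial composition profiles
#'
#' Evaluates each cell type's profile at every in-tissue spot's true radial
#' fraction, adds zero-truncated Gaussian noise, and records the noise-free
#' normalized proportions as ground truth. The result emulates the per-spot
#' cell-type abundance matrix a deconvolution tool would output.
#'
#' @param sim A `spot_sim` from [sim_spots()]; smear spots are skipped (real
#'   deconvolution only sees retained tissue spots).
#' @param profiles Named list (>= 2 entries) of weight functions over the
#'   radial fraction, e.g. from [logistic_profile()].
#' @param noise_sd Standard deviation of additive abundance noise, truncated
#'   at zero.
#' @param seed Integer seed.
#' @return A `proportion_sim` list: `abundance` (tibble, spot_id + one column
#'   per type), `truth_proportions` (noise-free proportions, rows sum to 1),
#'   `params`.
#' @export
sim_proportion_field <- function(sim, profiles, noise_sd = 0, seed = 0) {
  stopifnot(inherits(sim, "spot_sim"))
  if (!is.list(profiles) || length(profiles) < 2L ||
      is.null(names(profiles)) || any(names(profiles) == "")) {
    rlang::abort("`profiles` must be a named list of at least two functions.")
  }
  tissue <- dplyr::filter(sim$spots, !.data$is_smear)
  t_rad <- sim$truth$true_radial_fraction[match(tissue$spot_id,
                                                sim$truth$spot_id)]
  clean <- vapply(profiles, function(f) {
    w <- f(t_rad)
    if (any(w < 0)) rlang::abort("Profiles must return nonnegative weights.")
    w
  }, numeric(length(t_rad)))
  if (max(clean) == 0) {
    rlang::abort("All profiles are zero everywhere; no composition signal.")
  }
  row_tot <- rowSums(clean)
  if (any(row_tot == 0)) {
    rlang::abort("Some spots received zero total weight from all profiles.")
  }
  truth_prop <- clean / row_tot

  withr::with_seed(seed, {
    noisy <- pmax(clean + stats::rnorm(length(clean), 0, noise_sd), 0)
  })
  ab <- tibble::as_tibble(as.data.frame(noisy))
  names(ab) <- names(profiles)
  tp <- tibble::as_tibble(as.data.frame(truth_prop))
  names(tp) <- names(profiles)

  structure(
    list(
      abundance = dplyr::bind_cols(tibble::tibble(spot_id = tissue$spot_id), ab),
      truth_proportions = dplyr::bind_cols(
        tibble::tibble(spot_id = tissue$spot_id), tp),
      params = list(noise_sd = noise_sd, seed = seed)
    ),
    class = "proportion_sim"
  )
}

#' Simulate a directed cell-state transition chain
#'
#' Plants an ordered maturation chain (e.g. immature -> intermediate ->
#' mature) into a cell-by-cell transition-probability matrix and a matched
#' 2-D embedding with velocity vectors, emulating the velocity graph that
#' RNA-velocity tools emit. Each non-terminal cell sends probability mass
#' `forward_p` (split over `n_targets` random next-stage cells) forward along
#' the chain and, optionally, mass `noise_p` to random off-chain cells.
#' Terminal cells have zero outflow (sinks). Velocity vectors point from each
#' cell toward the next stage's centroid with magnitude `1 - stage_fraction`,
#' so early-chain cells move fastest.
#'
#' @param n_per_type Integer vector of cells per stage (recycled if scalar).
#' @param chain Ordered character vector of stage (cell-type) names,
#'   length >= 2.
#' @param forward_p Probability mass sent to the next stage, in (0, 1].
#' @param noise_p Probability mass sent to random non-next-stage cells;
#'   `0 <= noise_p < forward_p`.
#' @param n_targets Number of distinct recipients per cell per destination.
#' @param seed Integer seed.
#' @return A `chain_sim` list: `transition` (sparse cell x cell matrix),
#'   `cells` (tibble: cell_id, cell_type, stage_index, planted_role, x, y,
#'   vx, vy), `params`.
#' @export
sim_transition_chain <- function(n_per_type, chain, forward_p = 0.8,
                                 noise_p = 0, n_targets = 3, seed = 0) {
  if (length(chain) < 2L) rlang::abort("`chain` needs at least two stages.")
  if (length(n_per_type) == 1L) {
    n_per_type <- rep(n_per_type, length(chain))
  }
  if (length(n_per_type) != length(chain)) {
    rlang::abort("`n_per_type` must match the chain length (or be scalar).")
  }
  if (any(n_per_type < 1L)) rlang::abort("Every stage must have >= 1 cell.")
  if (!(noise_p >= 0 && noise_p < forward_p && forward_p <= 1)) {
    rlang::abort("Require 0 <= noise_p < forward_p <= 1.")
  }
  k <- length(chain)

  withr::with_seed(seed, {
    stage_index <- rep(seq_len(k), n_per_type)
    n <- length(stage_index)
    cell_id <- sprintf("%s_%04d", chain[stage_index], seq_len(n))
    stage_frac <- (stage_index - 1) / (k - 1)
    centroids <- cbind(3 * (seq_len(k) - 1), 0)
    px <- centroids[stage_index, 1] + stats::rnorm(n, 0, 0.4)
    py <- centroids[stage_index, 2] + stats::rnorm(n, 0, 0.4)

    vx <- numeric(n); vy <- numeric(n)
    nonterm <- stage_index < k
    if (any(nonterm)) {
      tx <- centroids[stage_index[nonterm] + 1L, 1] - px[nonterm]
      ty <- centroids[stage_index[nonterm] + 1L, 2] - py[nonterm]
      nrm <- sqrt(tx^2 + ty^2)
      mag <- 1 - stage_frac[nonterm]
      vx[nonterm] <- tx / nrm * mag
      vy[nonterm] <- ty / nrm * mag
    }

    ii <- integer(0); jj <- integer(0); pp <- numeric(0)
    for (c_idx in which(nonterm)) {
      nxt <- which(stage_index == stage_index[c_idx] + 1L)
      m <- min(n_targets, length(nxt))
      tgt <- if (length(nxt) == 1L) nxt else sample(nxt, m)
      ii <- c(ii, rep(c_idx, m)); jj <- c(jj, tgt)
      pp <- c(pp, rep(forward_p / m, m))
      if (noise_p > 0) {
        pool <- setdiff(which(stage_index != stage_index[c_idx] + 1L), c_idx)
        m2 <- min(n_targets, length(pool))
        if (m2 > 0L) {
          tgt2 <- if (length(pool) == 1L) pool else sample(pool, m2)
          ii <- c(ii, rep(c_idx, m2)); jj <- c(jj, tgt2)
          pp <- c(pp, rep(noise_p / m2, m2))
        }
      }
    }
    transition <- Matrix::sparseMatrix(
      i = ii, j = jj, x = pp, dims = c(n, n),
      dimnames = list(cell_id, cell_id)
    )

    cells <- tibble::tibble(
      cell_id = cell_id,
      cell_type = chain[stage_index],
      stage_index = stage_index,
      planted_role = dplyr::case_when(
        stage_index == 1L ~ "source",
        stage_index == k ~ "sink",
        TRUE ~ "intermediate"
      ),
      x = px, y = py, vx = vx, vy = vy
    )
    structure(
      list(transition = transition, cells = cells,
           params = list(chain = chain, n_per_type = n_per_type,
                         forward_p = forward_p, noise_p = noise_p,
                         n_targets = n_targets, seed = seed)),
      class = "chain_sim"
    )
  })
}
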