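#' Imaging grid specification
#'
#' Discretizes the B-scan plane: depth (light propagation axis, z, top
#' surface at row 1) by lateral position. One ballistic ray per lateral
#' column; depth cells are dz thick with centers at (i - 1/2) dz.
#'
#' @param n_depth number of depth cells (rows), >= 1.
#' @param n_lateral number of lateral columns, >= 1.
#' @param dz depth cell size in cm.
#' @param dx lateral cell size in cm.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(n_depth, n_lateral, dz, dx) {
  stopifnot(n_depth >= 1, n_lateral >= 1, dz > 0, dx > 0)
  structure(list(n_depth = as.integer(n_depth), n_lateral = as.integer(n_lateral),
                 dz = dz, dx = dx),
            class = "grid_spec")
}

#' Depth coordinates of cell centers
#'
#' @param grid a `grid_spec`.
#' @return vector of depths in cm, length `n_depth`.
#' @export
depth_centers <- function(grid) (seq_len(grid$n_depth) - 0.5) * grid$dz

#' Homogeneous dichroic tissue layer
#'
#' A layer is characterized by its mean absorption coefficient
#' mu_a_mean = (mu_a,o + mu_a,e)/2, its linear dichroism
#' delta_mu_a = mu_a,o - mu_a,e (difference between the ordinary and
#' extraordinary absorption coefficients), and the in-plane orientation
#' phi of its optic axis (the fiber direction).
#'
#' @param thickness layer thickness in cm, > 0.
#' @param mu_a_mean mean absorption coefficient in 1/cm, >= 0.
#' @param delta_mu_a dichroism in 1/cm; |delta_mu_a| <= 2 mu_a_mean so both
#'   polarization absorption coefficients stay nonnegative.
#' @param phi optic-axis orientation in degrees; wrapped to (-90, 90].
#'   Use NA for isotropic media (water).
#' @param label optional name used in error messages.
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(thickness, mu_a_mean, delta_mu_a = 0, phi = NA_real_,
                       label = "layer") {
  if (!is.finite(thickness) || thickness <= 0)
    stop("layer '", label, "': thickness must be > 0", call. = FALSE)
  if (mu_a_mean < 0)
    stop("layer '", label, "': mu_a_mean must be >= 0", call. = FALSE)
  if (abs(delta_mu_a) > 2 * mu_a_mean + 1e-12)
    stop("layer '", label, "': |delta_mu_a| must be <= 2*mu_a_mean ",
         "(both polarization absorptions must be nonnegative)", call. = FALSE)
  structure(list(thickness = thickness, mu_a_mean = mu_a_mean,
                 delta_mu_a = delta_mu_a,
                 phi = if (is.na(phi)) NA_real_ else wrap_orientation(phi),
                 label = label),
            class = "layer_spec")
}

#' Build a gridded layered tissue phantom
#'
#' Stacks layers from the illuminated surface downward along +z. Each depth
#' cell takes the properties of the layer containing its center; cells below
#' the last layer are water (mu_a_mean = delta_mu_a = 0, phi = NA).
#'
#' @param layers list of `layer_spec`, ordered surface first.
#' @param grid a `grid_spec`.
#' @param grueneisen_eta combined Grueneisen parameter x thermal conversion
#'   efficiency scale (dimensionless, spatially invariant).
#' @return object of class `tissue_phantom` with per-pixel maps
#'   `mu_a_mean_map`, `delta_mu_a_map`, `phi_map` (degrees, NA in water),
#'   all n_depth x n_lateral.
#' @export
build_layered_phantom <- function(layers, grid, grueneisen_eta = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  lapply(layers, function(l) stopifnot(inherits(l, "layer_spec")))
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  if (sum(th) > grid$n_depth * grid$dz + 1e-12)
    stop("layers exceed the grid depth: total thickness ", sum(th),
         " cm > ", grid$n_depth * grid$dz, " cm", call. = FALSE)
  bounds <- cumsum(th)
  z <- depth_centers(grid)
  nd <- grid$n_depth; nl <- grid$n_lateral
  mu <- matrix(0, nd, nl)
  dmu <- matrix(0, nd, nl)
  phi <- matrix(NA_real_, nd, nl)
  lo <- 0
  for (k in seq_along(layers)) {
    sel <- z > lo & z < bounds[k] + 1e-12
    mu[sel, ] <- layers[[k]]$mu_a_mean
    dmu[sel, ] <- layers[[k]]$delta_mu_a
    phi[sel, ] <- layers[[k]]$phi
    lo <- bounds[k]
  }
  structure(list(grid = grid, mu_a_mean_map = mu, delta_mu_a_map = dmu,
                 phi_map = phi, grueneisen_eta = grueneisen_eta,
                 layers = layers),
            class = "tissue_phantom")
}

#' Ordinary and extraordinary absorption maps
#'
#' mu_a,o = mu_a_mean + delta_mu_a/2 (polarization perpendicular to the
#' optic axis), mu_a,e = mu_a_mean - delta_mu_a/2 (parallel).
#'
#' @param phantom a `tissue_phantom`.
#' @return list with matrices `ordinary` and `extraordinary` in 1/cm.
#' @export
absorption_components <- function(phantom) {
  list(ordinary = phantom$mu_a_mean_map + phantom$delta_mu_a_map / 2,
       extraordinary = phantom$mu_a_mean_map - phantom$delta_mu_a_map / 2)
}

#' Tendon phantom presets
#'
#' Geometries mirroring the validation experiments: a single homogeneous
#' tendon, and two stacked tendons either perpendicular or at 30 degrees to
#' each other, optionally separated by a water gap. Defaults: mean
#' absorption 5 1/cm, dichroism ratio delta_mu_a/mu_a_mean = 0.1, stacked
#' layer thickness 0.16 cm (two layers span 3.2 mm of tissue); the single
#' tendon is 0.32 cm thick so the fluence-dominance depth 1/mu_a_mean = 2 mm
#' falls inside the tissue. The absolute absorption scale is an assumption
#' (only the dichroism ratio is constrained by tendon optics at 532 nm); all
#' values are overridable.
#'
#' @param name one of "single", "stacked_perpendicular", "stacked_30deg".
#' @param phi1 orientation of the (top) layer in degrees.
#' @param mu_a_mean mean absorption coefficient, 1/cm.
#' @param dichroism_ratio delta_mu_a / mu_a_mean.
#' @param thickness per-layer thickness in cm (default 0.32 single,
#'   0.16 stacked).
#' @param gap water-gap thickness between stacked layers in cm.
#' @param grid a `grid_spec`; default 40 x 16 cells of 0.01 x 0.03 cm.
#' @param grueneisen_eta pressure conversion scale.
#' @return a `tissue_phantom`.
#' @export
tendon_presets <- function(name = c("single", "stacked_perpendicular", "stacked_30deg"),
                           phi1 = 0, mu_a_mean = 5, dichroism_ratio = 0.1,
                           thickness = NULL, gap = 0, grid = NULL,
                           grueneisen_eta = 1) {
  name <- match.arg(name)
  if (is.null(grid)) grid <- grid_spec(40, 16, 0.01, 0.03)
  dmu <- dichroism_ratio * mu_a_mean
  if (name == "single") {
    if (is.null(thickness)) thickness <- 0.32
    layers <- list(layer_spec(thickness, mu_a_mean, dmu, phi1, "tendon"))
  } else {
    if (is.null(thickness)) thickness <- 0.16
    dphi <- if (name == "stacked_perpendicular") 90 else 30
    layers <- list(layer_spec(thickness, mu_a_mean, dmu, phi1, "tendon_top"))
    if (gap > 0) layers <- c(layers, list(layer_spec(gap, 0, 0, NA, "water_gap")))
    layers <- c(layers, list(layer_spec(thickness, mu_a_mean, dmu,
                                        wrap_orientation(phi1 + dphi),
                                        "tendon_bottom")))
  }
  build_layered_phantom(layers, grid, grueneisen_eta)
}

#' @export
print.tissue_phantom <- function(x, ...) {
  g <- x$grid
  cat("<tissue_phantom> ", g$n_depth, "x", g$n_lateral,
      " cells (", g$n_depth * g$dz, " cm deep), ",
      length(x$layers), " layer(s)\n", sep = "")
  for (l in x$layers)
    cat(sprintf("  %-12s %.3f cm  mu_a=%.3g  dmu_a=%.3g  phi=%s\n",
                l$label, l$thickness, l$mu_a_mean, l$delta_mu_a,
                if (is.na(l$phi)) "-" else sprintf("%.1f deg", l$phi)))
  invisible(x)
}

#' Write a phantom description to a YAML config
#'
#' Units are cm and degrees, stated in the file.
#'
#' @param phantom a `tissue_phantom` built from layers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(phantom, path) {
  g <- phantom$grid
  cfg <- list(
    units = list(length = "cm", angle = "deg"),
    grid = list(n_depth = g$n_depth, n_lateral = g$n_lateral, dz = g$dz, dx = g$dx),
    grueneisen_eta = phantom$grueneisen_eta,
    layers = lapply(phantom$layers, function(l)
      list(thickness = l$thickness, mu_a_mean = l$mu_a_mean,
           delta_mu_a = l$delta_mu_a,
           phi = if (is.na(l$phi)) "water" else l$phi,
           label = l$label)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a phantom description from a YAML config
#'
#' @param path file produced by [write_phantom_config()] or hand-written in
#'   the same schema (grid block plus ordered layer list, cm / degrees).
#' @return a `tissue_phantom`.
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  phantom_from_config(cfg)
}

# Build a phantom from an already-parsed config list (grid + layers, or a
# preset block). Shared by read_phantom_config and the pipeline driver.
phantom_from_config <- function(cfg) {
  if (!is.null(cfg$preset)) {
    p <- cfg$preset
    g <- if (!is.null(cfg$grid))
      grid_spec(cfg$grid$n_depth, cfg$grid$n_lateral, cfg$grid$dz, cfg$grid$dx)
    else NULL
    args <- p[names(p) != "name"]
    return(do.call(tendon_presets, c(list(name = p$name, grid = g), args)))
  }
  g <- cfg$grid
  grid <- grid_spec(g$n_depth, g$n_lateral, g$dz, g$dx)
  layers <- lapply(cfg$layers, function(l) {
    phi <- l$phi
    if (is.character(phi) || is.null(phi)) phi <- NA_real_
    layer_spec(l$thickness, l$mu_a_mean, l$delta_mu_a %||% 0, phi,
               l$label %||% "layer")
  })
  build_layered_phantom(layers, grid,
                        grueneisen_eta = cfg$grueneisen_eta %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
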