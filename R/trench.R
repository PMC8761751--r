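#' Finite-difference cross-section grid of the sensor chip
#'
#' Discretises a 2-D vertical cross-section of the chip on a uniform grid for
#' steady-state heat conduction. Each node carries a material (silicon
#' substrate, the thin oxide film on top, the air-filled thermal isolation
#' trench, or tissue), a subset of nodes forms the heater source, and
#' Dirichlet (fixed-temperature) nodes define the boundary condition. An
#' out-of-plane thickness normalises the injected power to watts.
#'
#' @param material Character matrix (rows = depth from the top surface,
#'   columns = lateral position) with values among
#'   `names(conductivity)`.
#' @param conductivity Named vector of thermal conductivities, W m^-1 K^-1.
#' @param spacing_um Node spacing, micrometres.
#' @param heater_mask Logical matrix marking heater source nodes.
#' @param fixed_mask Logical matrix marking fixed-temperature nodes.
#' @param fixed_temp_c Temperature of the fixed nodes, degC: a scalar, or a
#'   matrix of the grid shape giving per-node boundary temperatures.
#' @param heater_power_w Total power injected over the heater nodes, W.
#' @param out_of_plane_mm Out-of-plane thickness used to scale conductances.
#' @param region_mask Optional logical matrix: the region around the heater
#'   over which [uniformity_metric()] is evaluated by default.
#' @return An object of class `cross_section_grid`.
#' @export
cross_section_grid <- function(material,
                               conductivity = c(silicon = 150, oxide = 1.3,
                                                air = 0.026, tissue = 0.5),
                               spacing_um = 20,
                               heater_mask,
                               fixed_mask,
                               fixed_temp_c = 25,
                               heater_power_w = 0.03,
                               out_of_plane_mm = 1,
                               region_mask = NULL) {
  if (!is.matrix(material) || nrow(material) < 3 || ncol(material) < 3) {
    stop("invalid grid: need at least a 3 x 3 material map", call. = FALSE)
  }
  if (!all(material %in% names(conductivity))) {
    stop("invalid grid: unknown material in map", call. = FALSE)
  }
  if (any(conductivity <= 0)) {
    stop("invalid grid: conductivities must be positive", call. = FALSE)
  }
  if (!any(heater_mask)) stop("invalid grid: heater region is empty", call. = FALSE)
  if (!any(fixed_mask)) {
    stop("ill-posed: at least one fixed-temperature node is required",
         call. = FALSE)
  }
  structure(
    list(material = material, conductivity = conductivity,
         spacing_um = spacing_um, heater_mask = heater_mask,
         fixed_mask = fixed_mask, fixed_temp_c = fixed_temp_c,
         heater_power_w = heater_power_w, out_of_plane_mm = out_of_plane_mm,
         region_mask = region_mask),
    class = "cross_section_grid"
  )
}

#' Default chip cross-section, with or without the isolation trench
#'
#' Builds the qualitative cross-section used to study the effect of the
#' thermal isolation trench: a silicon substrate capped by a one-node oxide
#' film layer, a central surface heater, and (optionally) air-filled trenches
#' of 350 um depth flanking the heater. The chip underside and far lateral
#' edges are held at the ambient temperature. The uniformity region is the
#' top-surface strip spanning the heater and its surroundings inside the
#' trench ring.
#'
#' @param width_mm Lateral extent of the modelled cross-section, mm.
#' @param depth_um Substrate depth, um (500 um wafer).
#' @param spacing_um Node spacing, um.
#' @param trench Logical: include the isolation trench?
#' @param trench_depth_um,trench_width_um,trench_offset_um Trench depth,
#'   width, and lateral offset of its centreline from the heater centre, um.
#' @param heater_halfwidth_um Half-width of the heater strip, um.
#' @param ambient_c Boundary temperature, degC.
#' @param heater_power_w Injected heater power, W.
#' @inheritParams cross_section_grid
#' @return A [cross_section_grid()].
#' @export
chip_cross_section <- function(width_mm = 4,
                               depth_um = 500,
                               spacing_um = 20,
                               trench = TRUE,
                               trench_depth_um = 350,
                               trench_width_um = 100,
                               trench_offset_um = 600,
                               heater_halfwidth_um = 250,
                               ambient_c = 25,
                               heater_power_w = 0.03,
                               conductivity = c(silicon = 150, oxide = 1.3,
                                                air = 0.026, tissue = 0.5),
                               out_of_plane_mm = 1) {
  nc <- round(width_mm * 1000 / spacing_um) + 1
  nr <- round(depth_um / spacing_um) + 1
  x <- (seq_len(nc) - (nc + 1) / 2) * spacing_um   # lateral position, um
  depth <- (seq_len(nr) - 1) * spacing_um          # depth from surface, um

  material <- matrix("silicon", nr, nc)
  material[1, ] <- "oxide"
  if (trench) {
    in_trench_col <- abs(abs(x) - trench_offset_um) <= trench_width_um / 2
    in_trench_row <- depth <= trench_depth_um
    material[in_trench_row, in_trench_col] <- "air"
  }

  heater_mask <- matrix(FALSE, nr, nc)
  heater_mask[1, abs(x) <= heater_halfwidth_um] <- TRUE

  fixed_mask <- matrix(FALSE, nr, nc)
  fixed_mask[nr, ] <- TRUE
  fixed_mask[, c(1, nc)] <- TRUE

  region_mask <- matrix(FALSE, nr, nc)
  region_mask[1, abs(x) <= trench_offset_um - trench_width_um] <- TRUE

  cross_section_grid(
    material = material, conductivity = conductivity,
    spacing_um = spacing_um, heater_mask = heater_mask,
    fixed_mask = fixed_mask, fixed_temp_c = ambient_c,
    heater_power_w = heater_power_w, out_of_plane_mm = out_of_plane_mm,
    region_mask = region_mask
  )
}

# assemble the variable-coefficient 5-point system over free nodes.
# conductance of the link between two adjacent nodes is the harmonic mean of
# their conductivities times the out-of-plane thickness (uniform spacing).
.assemble_system <- function(grid) {
  k_node <- matrix(grid$conductivity[grid$material],
                   nrow(grid$material), ncol(grid$material))
  nr <- nrow(k_node); nc <- ncol(k_node)
  t_m <- grid$out_of_plane_mm * 1e-3
  id <- matrix(seq_len(nr * nc), nr, nc)

  links <- function(ia, ib) {
    ka <- k_node[ia]; kb <- k_node[ib]
    data.frame(a = as.vector(ia), b = as.vector(ib),
               g = as.vector(2 * ka * kb / (ka + kb) * t_m))
  }
  horiz <- links(id[, -nc, drop = FALSE], id[, -1, drop = FALSE])
  vert <- links(id[-nr, , drop = FALSE], id[-1, , drop = FALSE])
  all_links <- rbind(horiz, vert)

  free <- !as.vector(grid$fixed_mask)
  free_index <- cumsum(free)           # position among free nodes
  n_free <- sum(free)

  src <- numeric(nr * nc)
  src[as.vector(grid$heater_mask)] <-
    grid$heater_power_w / sum(grid$heater_mask)
  b <- src[free]

  fa <- free[all_links$a]; fb <- free[all_links$b]
  ff <- all_links[fa & fb, ]
  af <- all_links[fa & !fb, ]  # free a, fixed b
  bf <- all_links[!fa & fb, ]  # fixed a, free b

  ii <- c(free_index[ff$a], free_index[ff$b],
          free_index[ff$a], free_index[ff$b],
          free_index[af$a], free_index[bf$b])
  jj <- c(free_index[ff$a], free_index[ff$b],
          free_index[ff$b], free_index[ff$a],
          free_index[af$a], free_index[bf$b])
  xx <- c(ff$g, ff$g, -ff$g, -ff$g, af$g, bf$g)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_free, n_free))

  tfix <- grid$fixed_temp_c
  if (!is.matrix(tfix)) tfix <- matrix(tfix, nr, nc)
  b_dirichlet <- numeric(n_free)
  add_contrib <- function(acc, idx, contrib) {
    if (!length(idx)) return(acc)
    agg <- tapply(contrib, idx, sum)
    acc[as.integer(names(agg))] <- acc[as.integer(names(agg))] + agg
    acc
  }
  b_dirichlet <- add_contrib(b_dirichlet, free_index[af$a], af$g * tfix[af$b])
  b_dirichlet <- add_contrib(b_dirichlet, free_index[bf$b], bf$g * tfix[bf$a])
  list(A = A, b_source = b, b_dirichlet = b_dirichlet, free = free,
       links = all_links, nr = nr, nc = nc)
}

#' Solve the steady-state temperature field
#'
#' Direct sparse solve of the variable-coefficient steady conduction problem
#' (the ex vivo, steady-state reduction of the tissue bioheat equation is the
#' same Poisson form) with harmonic-mean interface conductances. The
#' residual of the discrete linear system and the discrete energy balance
#' (net flux through the fixed boundary versus injected power) are reported.
#'
#' @param grid A [cross_section_grid()].
#' @param tolerance Maximum admissible residual of the discrete system.
#' @return A list with `field` (temperature matrix, degC), `residual`,
#'   `flux_out_w` (net boundary outflux), `power_in_w`, and
#'   `energy_balance_error` (relative).
#' @export
solve_steady <- function(grid, tolerance = 1e-8) {
  stopifnot(inherits(grid, "cross_section_grid"))
  sys <- .assemble_system(grid)
  b <- sys$b_source + sys$b_dirichlet
  x <- as.vector(Matrix::solve(sys$A, b))
  scale <- max(abs(b), 1)
  residual <- max(abs(as.vector(sys$A %*% x) - b)) / scale
  if (!is.finite(residual) || residual > tolerance) {
    stop(sprintf("convergence error: residual %.3g exceeds tolerance %.3g",
                 residual, tolerance), call. = FALSE)
  }
  tfix <- grid$fixed_temp_c
  if (!is.matrix(tfix)) tfix <- matrix(tfix, sys$nr, sys$nc)
  field <- tfix
  field[sys$free] <- x

  lk <- sys$links
  fa <- sys$free[lk$a]; fb <- sys$free[lk$b]
  boundary <- xor(fa, fb)
  lkb <- lk[boundary, ]
  t_free <- ifelse(sys$free[lkb$a], field[lkb$a], field[lkb$b])
  t_fixed <- ifelse(sys$free[lkb$a], field[lkb$b], field[lkb$a])
  flux_out <- sum(lkb$g * (t_free - t_fixed))
  power_in <- grid$heater_power_w
  bal <- if (power_in > 0) abs(flux_out - power_in) / power_in else abs(flux_out)

  list(field = field, residual = residual, flux_out_w = flux_out,
       power_in_w = power_in, energy_balance_error = bal)
}

#' Temperature uniformity around the heater
#'
#' Standard deviation (kelvin) of the steady temperature over a region of
#' interest, by default the grid's top-surface strip around the heater. A
#' smaller value means a more uniform temperature regime.
#'
#' @param field Temperature matrix from [solve_steady()].
#' @param region Logical matrix selecting the region nodes.
#' @return Standard deviation in K (0 for a single-node region).
#' @export
uniformity_metric <- function(field, region) {
  if (!any(region)) stop("input error: empty region", call. = FALSE)
  vals <- field[region]
  if (length(vals) == 1) return(0)
  stats::sd(vals)
}

#' Heater power required to reach a target temperature
#'
#' Bisection on the injected source power until the mean temperature over the
#' heater nodes reaches the target. The discrete problem is linear in the
#' source, so the bracket is expanded geometrically until it encloses the
#' target and then bisected; the result is strictly increasing in the target.
#'
#' @param grid A [cross_section_grid()] (its `heater_power_w` is ignored).
#' @param heater_target_c Desired mean heater-node temperature, degC; must
#'   not be below the boundary temperature.
#' @param tolerance Convergence tolerance on the heater temperature, K.
#' @param power_cap_w Maximum power considered before giving up, W.
#' @return Power in watts.
#' @export
power_for_target <- function(grid, heater_target_c, tolerance = 1e-6,
                             power_cap_w = 100) {
  stopifnot(inherits(grid, "cross_section_grid"))
  t_bnd <- max(grid$fixed_temp_c)
  if (heater_target_c < t_bnd) {
    stop("unreachable target: below the boundary temperature", call. = FALSE)
  }
  if (heater_target_c == t_bnd) return(0)

  mean_heater <- function(power_w) {
    g <- grid
    g$heater_power_w <- power_w
    sol <- solve_steady(g)
    mean(sol$field[grid$heater_mask])
  }
  lo <- 0
  hi <- 1e-3
  while (mean_heater(hi) < heater_target_c) {
    hi <- hi * 2
    if (hi > power_cap_w) {
      stop("unreachable target: power cap exceeded", call. = FALSE)
    }
  }
  while (TRUE) {
    mid <- (lo + hi) / 2
    t_mid <- mean_heater(mid)
    if (abs(t_mid - heater_target_c) < tolerance) return(mid)
    if (t_mid < heater_target_c) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(hi, 1)) return(mid)
  }
}
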