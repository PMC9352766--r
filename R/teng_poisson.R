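#' 2D electrostatic field solution for the device cross-section
#'
#' Solves \eqn{\nabla\cdot(\varepsilon\nabla\phi) = -\rho} on a vertical
#' cross-section of the stack (bottom electrode / Kapton / air gap /
#' optional micropattern band / silk / top electrode) with zero normal
#' displacement field on the outer box (the open-circuit, charge-free
#' far-field condition) and the tribo charge imposed as surface charge on
#' the two facing dielectric surfaces. Electrodes are floating uncharged
#' conductors, modelled as high-permittivity regions; with no free charge
#' placed on them they settle at a uniform potential with zero net charge,
#' which is the open-circuit condition.
#'
#' Discretization is a finite-volume (box) scheme on a tensor grid whose
#' node rows are aligned with every material interface. For the flat
#' geometry the exact potential is piecewise linear with kinks only at the
#' charged interfaces, so the scheme reproduces \eqn{V_{oc} = \sigma
#' x/\varepsilon_0} to machine precision at any resolution; patterned
#' geometries converge under refinement. The domain spans one pattern pitch
#' with mirror-symmetric (zero-flux) side walls. For patterned surfaces the
#' gap is tip-to-surface: the feature band of height h sits on top of the
#' air gap, so gap 0 means the feature tips touch the Kapton face.
#'
#' The tribo charge totals are equal and opposite: the silk-side contour
#' carries \eqn{Q = \sigma L} per pitch, with L the true contour length of
#' the patterned surface (conformal-contact assumption), distributed over
#' the rasterized contour faces in proportion to their length but
#' normalized to L so that stair-stepping does not inflate sloped contours;
#' the flat Kapton face carries \eqn{-Q} uniformly.
#'
#' @param cfg a [teng_config()].
#' @param gap electrode separation (tip-to-surface for patterned), m, >= 0.
#' @param cells_per_layer number of cells across each material band
#'   (>= 4); the pattern band and the lateral direction are refined
#'   proportionally.
#' @param estimate_convergence if `TRUE` (default) the system is re-solved
#'   at doubled resolution and the relative change in V_oc is reported as
#'   `convergence_estimate`.
#' @return an object of class `field_solution`: list with `grid_potential`
#'   (node potentials, rows = y, cols = x), `x_nodes`, `y_nodes`, `cell_size`
#'   (lateral cell width, m), `gap`, `electrode_potentials`
#'   `(V_bottom, V_top)`, `voc`, and `convergence_estimate`.
#' @examples
#' cfg <- teng_config()
#' sol <- solve_poisson_2d(cfg, gap = 1e-4, cells_per_layer = 4)
#' sol$voc / closed_form_voc(1e-4, cfg)  # ~1
#' @export
solve_poisson_2d <- function(cfg, gap, cells_per_layer = 8,
                             estimate_convergence = TRUE) {
  stopifnot(inherits(cfg, "teng_config"), length(gap) == 1, gap >= 0)
  if (cells_per_layer < 4) stop("cells_per_layer must be >= 4")

  sol <- poisson_core(cfg, gap, cells_per_layer)
  conv <- NA_real_
  if (estimate_convergence) {
    fine <- poisson_core(cfg, gap, 2L * cells_per_layer)
    denom <- max(abs(fine$voc), .Machine$double.eps)
    conv <- abs(fine$voc - sol$voc) / denom
  }
  structure(
    list(grid_potential = sol$phi, x_nodes = sol$x_nodes,
         y_nodes = sol$y_nodes, cell_size = sol$dx, gap = gap,
         electrode_potentials = c(V_bottom = sol$v_bottom,
                                  V_top = sol$v_top),
         voc = sol$voc, convergence_estimate = conv),
    class = "field_solution")
}

#' @exportS3Method base::print
print.field_solution <- function(x, ...) {
  cat(sprintf("2D field solution: gap %g m, grid %d x %d nodes\n",
              x$gap, length(x$y_nodes), length(x$x_nodes)))
  cat(sprintf("  V_oc = %g V (electrodes %.6g / %.6g V)\n", x$voc,
              x$electrode_potentials[1], x$electrode_potentials[2]))
  cat(sprintf("  convergence estimate: %g\n", x$convergence_estimate))
  invisible(x)
}

# relative permittivity standing in for the floating gold electrodes;
# large enough to make them equipotential, small enough to keep the
# sparse factorization well conditioned
EPS_CONDUCTOR <- 1e6

# Assemble and solve one finite-volume system. Returns node potentials,
# electrode potentials and V_oc.
poisson_core <- function(cfg, gap, n) {
  pat <- cfg$pattern
  flat <- pat$shape == "flat"
  width <- if (flat) 2e-5 else pat$pitch
  h_f <- pattern_depth(pat)

  # vertical bands, bottom to top: thickness, material, cells
  bands <- list(
    list(t = cfg$electrode_thickness, mat = "cond",   n = n),
    list(t = cfg$d_kapton,            mat = "kapton", n = n),
    list(t = gap,                     mat = "air",    n = n),
    list(t = h_f,                     mat = "feat",   n = max(n, 8L)),
    list(t = cfg$d_silk,              mat = "silk",   n = n),
    list(t = cfg$electrode_thickness, mat = "cond",   n = n))
  bands <- Filter(function(b) b$t > 0, bands)

  nxc <- if (flat) 4L else max(16L, 2L * n)  # lateral cells
  dx <- width / nxc
  x_nodes <- seq(0, width, length.out = nxc + 1L)
  xc <- (x_nodes[-1L] + x_nodes[-(nxc + 1L)]) / 2

  # vertical node coordinates, aligned with band boundaries
  y_nodes <- 0
  cell_mat <- character(0)
  cell_dy <- numeric(0)
  band_lo <- numeric(length(bands)); band_hi <- numeric(length(bands))
  for (k in seq_along(bands)) {
    b <- bands[[k]]
    band_lo[k] <- y_nodes[length(y_nodes)]
    ys <- band_lo[k] + b$t * seq_len(b$n) / b$n
    y_nodes <- c(y_nodes, ys)
    band_hi[k] <- y_nodes[length(y_nodes)]
    cell_mat <- c(cell_mat, rep(b$mat, b$n))
    cell_dy <- c(cell_dy, rep(b$t / b$n, b$n))
  }
  nyc <- length(cell_mat)
  Ny <- nyc + 1L; Nx <- nxc + 1L
  yc <- (y_nodes[-1L] + y_nodes[-Ny]) / 2

  # cell material matrix [x cell, y cell] and permittivity
  mat <- matrix(rep(cell_mat, each = nxc), nrow = nxc)
  featk <- which(vapply(bands, function(b) b$mat == "feat", logical(1)))
  if (length(featk)) {
    y0 <- band_lo[featk]; y1 <- band_hi[featk]
    cx <- width / 2; w2 <- pat$feature_width / 2
    for (jc in which(cell_mat == "feat")) {
      yy <- yc[jc]
      inside <- switch(pat$shape,
        cube    = abs(xc - cx) <= w2,
        pyramid = abs(xc - cx) <= w2 * (yy - y0) / (y1 - y0),
        sphere  = (xc - cx)^2 + (yy - y1)^2 <= w2^2)
      mat[, jc] <- ifelse(inside, "silk", "air")
    }
  }
  eps_of <- c(cond = EPS_CONDUCTOR, kapton = cfg$eps_kapton, air = 1,
              silk = cfg$eps_silk)
  eps <- matrix(EPS0 * eps_of[mat], nrow = nxc)

  idx <- function(i, j) (j - 1L) * Nx + i

  # conductances between adjacent nodes (box integration)
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  # horizontal pairs (i,j)-(i+1,j): cells (i, j-1) and (i, j)
  for (j in seq_len(Ny)) {
    g <- numeric(nxc)
    if (j > 1L)  g <- g + eps[, j - 1L] * (cell_dy[j - 1L] / 2) / dx
    if (j <= nyc) g <- g + eps[, j] * (cell_dy[j] / 2) / dx
    a <- idx(seq_len(nxc), j); b <- idx(seq_len(nxc) + 1L, j)
    ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b)
    gg <- c(gg, -g, -g, g, g)
  }
  # vertical pairs (i,j)-(i,j+1): cells (i-1, j) and (i, j)
  for (j in seq_len(nyc)) {
    g <- numeric(Nx)
    g[1:nxc] <- g[1:nxc] + eps[, j] * (dx / 2) / cell_dy[j]
    g[2:Nx] <- g[2:Nx] + eps[, j] * (dx / 2) / cell_dy[j]
    a <- idx(seq_len(Nx), j); b <- idx(seq_len(Nx), j + 1L)
    ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b)
    gg <- c(gg, -g, -g, g, g)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = gg, dims = c(Nx * Ny, Nx * Ny))

  # surface charge on dielectric-air faces (per unit depth, C/m)
  b_rhs <- numeric(Nx * Ny)
  silk_faces <- list()   # each: c(node_a, node_b, raster_len)
  add_face <- function(store, a, b, len) { store[[length(store) + 1L]] <- c(a, b, len); store }
  kapton_nodes <- NULL
  # horizontal faces between vertically adjacent cells
  for (jc in seq_len(nyc - 1L)) {
    below <- mat[, jc]; above <- mat[, jc + 1L]
    jn <- jc + 1L  # node row at the shared boundary
    for (i in seq_len(nxc)) {
      pair <- c(below[i], above[i])
      if (setequal(pair, c("silk", "air")))
        silk_faces <- add_face(silk_faces, idx(i, jn), idx(i + 1L, jn), dx)
      if (setequal(pair, c("kapton", "air")))
        kapton_nodes <- rbind(kapton_nodes, c(idx(i, jn), idx(i + 1L, jn)))
    }
  }
  # vertical faces between horizontally adjacent cells (pattern walls)
  for (jc in seq_len(nyc)) {
    for (i in seq_len(nxc - 1L)) {
      pair <- c(mat[i, jc], mat[i + 1L, jc])
      if (setequal(pair, c("silk", "air")))
        silk_faces <- add_face(silk_faces, idx(i + 1L, jc), idx(i + 1L, jc + 1L),
                               cell_dy[jc])
    }
  }

  Q <- cfg$sigma * pattern_contour_length(pat) * width / pat$pitch
  if (flat) Q <- cfg$sigma * width
  if (length(silk_faces) && cfg$sigma > 0) {
    lens <- vapply(silk_faces, `[`, numeric(1), 3L)
    qf <- Q * lens / sum(lens)   # normalize raster contour to true charge
    for (k in seq_along(silk_faces)) {
      f <- silk_faces[[k]]
      b_rhs[f[1]] <- b_rhs[f[1]] + qf[k] / 2
      b_rhs[f[2]] <- b_rhs[f[2]] + qf[k] / 2
    }
  }
  if (!is.null(kapton_nodes) && cfg$sigma > 0) {
    qf <- -Q / nrow(kapton_nodes)
    for (k in seq_len(nrow(kapton_nodes))) {
      b_rhs[kapton_nodes[k, 1]] <- b_rhs[kapton_nodes[k, 1]] + qf / 2
      b_rhs[kapton_nodes[k, 2]] <- b_rhs[kapton_nodes[k, 2]] + qf / 2
    }
  }

  # pin one node (pure Neumann problem, compatible RHS by construction)
  A[1, ] <- 0; A[1, 1] <- 1; b_rhs[1] <- 0
  phi <- as.numeric(Matrix::solve(A, b_rhs))
  phi_m <- matrix(phi, nrow = Nx)  # [x node, y node]

  # electrode potentials: average over interior node rows of each band
  band_mat <- vapply(bands, `[[`, character(1), "mat")
  cond_k <- which(band_mat == "cond")
  elec_mean <- function(k) {
    rows <- which(y_nodes > band_lo[k] + 1e-15 & y_nodes < band_hi[k] - 1e-15)
    mean(phi_m[, rows])
  }
  v_bottom <- elec_mean(cond_k[1])
  v_top <- elec_mean(cond_k[2])

  list(phi = t(phi_m), x_nodes = x_nodes, y_nodes = y_nodes, dx = dx,
       v_bottom = v_bottom, v_top = v_top, voc = v_top - v_bottom)
}

#' Open-circuit voltage and capacitance from a field solution
#'
#' The open-circuit voltage is the electrode potential difference; the
#' capacitance follows from the charge-voltage relation \eqn{C = Q/V_{oc}}
#' with \eqn{Q = \sigma A} the nominal tribo charge on the plates. If
#' \eqn{V_{oc}} vanishes (flat device at gap 0) the division is undefined
#' and the series-stack closed form is reported instead, with `flagged =
#' TRUE`.
#'
#' @param sol a `field_solution` from [solve_poisson_2d()].
#' @param cfg the [teng_config()] used to produce it.
#' @return list with `voc` (V), `cap` (F), and `flagged` (logical).
#' @export
extract_voc_capacitance <- function(sol, cfg) {
  stopifnot(inherits(sol, "field_solution"), inherits(cfg, "teng_config"))
  voc <- sol$voc
  Q <- cfg$sigma * cfg$plate_area
  scale <- cfg$sigma / EPS0 * max(sol$gap, 1e-9)
  if (abs(voc) <= 1e-9 * max(scale, 1)) {
    list(voc = voc, cap = closed_form_capacitance(sol$gap, cfg),
         flagged = TRUE)
  } else {
    list(voc = voc, cap = Q / voc, flagged = FALSE)
  }
}
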