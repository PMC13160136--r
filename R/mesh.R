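# Elastic spring-mesh regularization and image warping.
#
# A mesh is a regular grid of control nodes (spacing L0, 4-connected
# springs at rest length L0) carrying a displacement per node. Relaxation
# minimizes
#
#   E = sum_springs 1/2 k (|p_i - p_j| - L0)^2
#     + sum_nodes  1/2 w_n |d_n - t_n|^2
#
# where p = rest position + displacement, and (t_n, w_n) are flow-derived
# targets and weights (w_n = 0 for unconstrained nodes). Boundary nodes obey
# the same spring rule as interior ones: detector distortions concentrate at
# the field-of-view edges, and pinning the boundary would forbid correcting
# them.

#' Create a regular elastic spring mesh
#'
#' Nodes are laid on a regular grid with spacing `spacing`, starting at
#' `origin` and extending far enough to cover `extent` (one extra node ring
#' beyond the far edge when the spacing does not divide the extent).
#'
#' @param extent (ny, nx) of the image region the mesh must cover, pixels.
#' @param spacing rest spring length L0 in pixels (> 0).
#' @param k spring stiffness.
#' @param w default data-term weight for constrained nodes.
#' @param origin position of the first node (y, x).
#' @return a `spring_mesh` with zero displacements.
#' @export
spring_mesh <- function(extent, spacing, k = NULL, w = 1,
                        origin = c(1, 1)) {
  stopifnot(spacing > 0)
  if (is.null(k)) {
    # stiff default: a lone node pulled 1 px against still neighbors moves
    # only ~ w / (w + 4k) of the way, so single-node flow outliers are
    # suppressed while smooth fields (which stretch springs little) pass
    k <- w
  }
  nyn <- max(2L, ceiling((extent[1] - origin[1]) / spacing) + 1L)
  nxn <- max(2L, ceiling((extent[2] - origin[2]) / spacing) + 1L)
  structure(list(origin = origin, spacing = spacing,
                 k = k, w = w,
                 dy = matrix(0, nyn, nxn), dx = matrix(0, nyn, nxn),
                 extent = extent),
            class = "spring_mesh")
}

mesh_node_positions <- function(mesh) {
  list(y = mesh$origin[1] + (seq_len(nrow(mesh$dy)) - 1) * mesh$spacing,
       x = mesh$origin[2] + (seq_len(ncol(mesh$dy)) - 1) * mesh$spacing)
}

#' Build node constraints from a flow field
#'
#' Samples the (dense-interpolated) flow displacement at each mesh node;
#' nodes outside the flow's valid support get weight 0.
#'
#' @param flow a `flow_field`.
#' @param mesh a `spring_mesh`.
#' @param weight data weight given to constrained nodes.
#' @return list of matrices `ty`, `tx` (targets) and `w` (weights), node
#'   grid shaped.
#' @export
flow_constraints <- function(flow, mesh, weight = mesh$w,
                             hull_margin = flow$stride) {
  pos <- mesh_node_positions(mesh)
  ny <- max(flow$node_y); nx <- max(flow$node_x)
  dn <- flow_dense(flow, ny, nx)
  nyn <- length(pos$y); nxn <- length(pos$x)
  yy <- rep(pos$y, times = nxn); xx <- rep(pos$x, each = nyn)
  ty <- matrix(bilinear_sample(dn$dy, clamp(yy, 1, ny), clamp(xx, 1, nx)),
               nyn, nxn)
  tx <- matrix(bilinear_sample(dn$dx, clamp(yy, 1, ny), clamp(xx, 1, nx)),
               nyn, nxn)
  # mesh nodes beyond the flow's node hull (plus a margin) carry no
  # measurement and are left to the springs
  inside <- yy >= min(flow$node_y) - hull_margin &
    yy <= max(flow$node_y) + hull_margin &
    xx >= min(flow$node_x) - hull_margin &
    xx <= max(flow$node_x) + hull_margin
  w <- matrix(weight * inside, nyn, nxn)
  if (!any(flow$valid)) w[] <- 0
  list(ty = ty, tx = tx, w = w)
}

# Merge constraint sets on one mesh by priority: each node takes the first
# set that constrains it (earlier arguments win).
combine_constraints <- function(...) {
  cs <- Filter(Negate(is.null), list(...))
  out <- cs[[1]]
  for (c2 in cs[-1]) {
    take <- out$w <= 0 & c2$w > 0
    out$ty[take] <- c2$ty[take]
    out$tx[take] <- c2$tx[take]
    out$w[take] <- c2$w[take]
  }
  out
}

mesh_energy <- function(mesh, cons) {
  pos <- mesh_node_positions(mesh)
  py <- outer(pos$y, rep(1, ncol(mesh$dy))) + mesh$dy
  px <- outer(rep(1, nrow(mesh$dx)), pos$x) + mesh$dx
  L0 <- mesh$spacing
  e <- 0
  # vertical springs
  dyv <- py[-1, , drop = FALSE] - py[-nrow(py), , drop = FALSE]
  dxv <- px[-1, , drop = FALSE] - px[-nrow(px), , drop = FALSE]
  e <- e + 0.5 * mesh$k * sum((sqrt(dyv^2 + dxv^2) - L0)^2)
  dyh <- py[, -1, drop = FALSE] - py[, -ncol(py), drop = FALSE]
  dxh <- px[, -1, drop = FALSE] - px[, -ncol(px), drop = FALSE]
  e <- e + 0.5 * mesh$k * sum((sqrt(dyh^2 + dxh^2) - L0)^2)
  if (!is.null(cons)) {
    e <- e + 0.5 * sum(cons$w * ((mesh$dy - cons$ty)^2 +
                                   (mesh$dx - cons$tx)^2))
  }
  e
}

mesh_gradient <- function(mesh, cons) {
  pos <- mesh_node_positions(mesh)
  py <- outer(pos$y, rep(1, ncol(mesh$dy))) + mesh$dy
  px <- outer(rep(1, nrow(mesh$dx)), pos$x) + mesh$dx
  L0 <- mesh$spacing
  gy <- matrix(0, nrow(py), ncol(py)); gx <- gy
  add_springs <- function(ay, ax, by, bx) {
    # spring force between node sets a and b (a side receives +grad)
    dy <- ay - by; dx <- ax - bx
    len <- sqrt(dy^2 + dx^2)
    len[len < 1e-12] <- 1e-12
    f <- mesh$k * (len - L0) / len
    list(fy = f * dy, fx = f * dx)
  }
  nr <- nrow(py); nc <- ncol(py)
  if (nr > 1) {
    s <- add_springs(py[-1, , drop = FALSE], px[-1, , drop = FALSE],
                     py[-nr, , drop = FALSE], px[-nr, , drop = FALSE])
    gy[-1, ] <- gy[-1, , drop = FALSE] + s$fy
    gx[-1, ] <- gx[-1, , drop = FALSE] + s$fx
    gy[-nr, ] <- gy[-nr, , drop = FALSE] - s$fy
    gx[-nr, ] <- gx[-nr, , drop = FALSE] - s$fx
  }
  if (nc > 1) {
    s <- add_springs(py[, -1, drop = FALSE], px[, -1, drop = FALSE],
                     py[, -nc, drop = FALSE], px[, -nc, drop = FALSE])
    gy[, -1] <- gy[, -1, drop = FALSE] + s$fy
    gx[, -1] <- gx[, -1, drop = FALSE] + s$fx
    gy[, -nc] <- gy[, -nc, drop = FALSE] - s$fy
    gx[, -nc] <- gx[, -nc, drop = FALSE] - s$fx
  }
  if (!is.null(cons)) {
    gy <- gy + cons$w * (mesh$dy - cons$ty)
    gx <- gx + cons$w * (mesh$dx - cons$tx)
  }
  list(gy = gy, gx = gx)
}

#' Relax a spring mesh against flow constraints
#'
#' Damped gradient descent with momentum and a fixed step chosen from the
#' stability bound `step < 2 / (k * max_degree + max(w))`; iterations that
#' would increase the energy are rejected (step halved, momentum reset), so
#' the energy is non-increasing across accepted iterations. Terminates when
#' the maximum per-node update falls below `tol` or after `max_iters`.
#' Fully deterministic.
#'
#' @param mesh a `spring_mesh`.
#' @param constraints output of [flow_constraints()] (or NULL for none).
#' @param max_iters iteration cap.
#' @param tol convergence threshold on the max per-node update, pixels.
#' @return list with the relaxed `mesh`, final `energy`, and `iterations`.
#' @export
relax_mesh <- function(mesh, constraints = NULL, max_iters = 400L,
                       tol = 1e-3) {
  if (!is.null(constraints)) {
    if (any(!is.finite(constraints$ty)) || any(!is.finite(constraints$tx)) ||
        any(!is.finite(constraints$w))) {
      stop("non-finite constraint values")
    }
  }
  maxw <- if (is.null(constraints)) 0 else max(constraints$w)
  step <- 1.6 / (mesh$k * 4 + maxw + 1e-12)
  mom <- 0.8
  vy <- matrix(0, nrow(mesh$dy), ncol(mesh$dy)); vx <- vy
  e <- mesh_energy(mesh, constraints)
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    g <- mesh_gradient(mesh, constraints)
    vy <- mom * vy - step * g$gy
    vx <- mom * vx - step * g$gx
    cand <- mesh
    cand$dy <- mesh$dy + vy
    cand$dx <- mesh$dx + vx
    e2 <- mesh_energy(cand, constraints)
    if (e2 <= e + 1e-12) {
      upd <- max(abs(vy), abs(vx))
      mesh <- cand; e <- e2
      if (upd < tol) break
    } else {
      vy[] <- 0; vx[] <- 0
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  list(mesh = mesh, energy = e, iterations = it)
}

#' Interpolate mesh displacement at arbitrary positions
#'
#' Bilinear interpolation of node displacements; positions beyond the node
#' grid use the nearest edge value.
#'
#' @param mesh a `spring_mesh`.
#' @param y,x position vectors, pixels.
#' @return list of vectors `dy`, `dx`.
#' @export
mesh_displacement <- function(mesh, y, x) {
  gy <- (y - mesh$origin[1]) / mesh$spacing + 1
  gx <- (x - mesh$origin[2]) / mesh$spacing + 1
  gy <- clamp(gy, 1, nrow(mesh$dy)); gx <- clamp(gx, 1, ncol(mesh$dy))
  y0 <- floor(gy); x0 <- floor(gx)
  y1 <- clamp(y0 + 1, 1, nrow(mesh$dy)); x1 <- clamp(x0 + 1, 1, ncol(mesh$dy))
  fy <- gy - y0; fx <- gx - x0
  iv <- function(m) {
    (1 - fy) * ((1 - fx) * m[cbind(y0, x0)] + fx * m[cbind(y0, x1)]) +
      fy * ((1 - fx) * m[cbind(y1, x0)] + fx * m[cbind(y1, x1)])
  }
  list(dy = iv(mesh$dy), dx = iv(mesh$dx))
}

#' Warp an image through a mesh
#'
#' Backward warp: each output pixel samples the source image at its own
#' position plus the interpolated mesh displacement. Pixels mapping outside
#' the source are 0 (black).
#'
#' @param image numeric matrix.
#' @param mesh a `spring_mesh` (displacements map output -> source).
#' @param output_extent (ny, nx) of the output; defaults to the input shape.
#' @return numeric matrix of size `output_extent`.
#' @export
warp_image <- function(image, mesh, output_extent = dim(image)) {
  ny <- output_extent[1]; nx <- output_extent[2]
  yy <- rep(seq_len(ny), times = nx)
  xx <- rep(seq_len(nx), each = ny)
  d <- mesh_displacement(mesh, yy, xx)
  matrix(bilinear_sample(image, yy + d$dy, xx + d$dx, fill = 0), ny, nx)
}

#' Compose two meshes
#'
#' Returns a mesh representing `outer` followed by `inner` in sampling
#' order: warping an image once by the composition is equivalent (up to
#' interpolation) to warping by `inner` first and the result by `outer`.
#' Node displacements are `d_out(p) + d_in(p + d_out(p))`. Nodes whose
#' intermediate position falls outside the inner mesh's covered extent are
#' flagged in `extrapolated`.
#'
#' @param outer,inner `spring_mesh` objects on compatible domains.
#' @return a `spring_mesh` on `outer`'s grid, with attribute `extrapolated`.
#' @export
compose_meshes <- function(outer, inner) {
  pos <- mesh_node_positions(outer)
  nyn <- nrow(outer$dy); nxn <- ncol(outer$dy)
  yy <- rep(pos$y, times = nxn); xx <- rep(pos$x, each = nyn)
  midy <- yy + as.vector(outer$dy); midx <- xx + as.vector(outer$dx)
  d2 <- mesh_displacement(inner, midy, midx)
  out <- outer
  out$dy <- outer$dy + matrix(d2$dy, nyn, nxn)
  out$dx <- outer$dx + matrix(d2$dx, nyn, nxn)
  ipos <- mesh_node_positions(inner)
  extrap <- matrix(midy < min(ipos$y) - inner$spacing |
                     midy > max(ipos$y) + inner$spacing |
                     midx < min(ipos$x) - inner$spacing |
                     midx > max(ipos$x) + inner$spacing, nyn, nxn)
  attr(out, "extrapolated") <- extrap
  out
}

#' Build a mesh holding a constant translation
#'
#' @param extent (ny, nx) covered extent.
#' @param dy,dx translation components, pixels.
#' @param spacing node spacing.
#' @return a `spring_mesh` whose warp is the pure translation.
#' @export
translation_mesh <- function(extent, dy = 0, dx = 0, spacing = 16) {
  m <- spring_mesh(extent, spacing)
  m$dy[] <- dy; m$dx[] <- dx
  m
}

# Serialize / restore meshes (lossless; re-rendering from a restored mesh is
# bit-identical).
mesh_to_list <- function(mesh) {
  list(origin = mesh$origin, spacing = mesh$spacing, k = mesh$k, w = mesh$w,
       extent = mesh$extent, ny = nrow(mesh$dy), nx = ncol(mesh$dy),
       dy = as.vector(mesh$dy), dx = as.vector(mesh$dx))
}

mesh_from_list <- function(l) {
  structure(list(origin = unlist(l$origin), spacing = l$spacing, k = l$k,
                 w = l$w, dy = matrix(unlist(l$dy), l$ny, l$nx),
                 dx = matrix(unlist(l$dx), l$ny, l$nx),
                 extent = unlist(l$extent)),
            class = "spring_mesh")
}
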