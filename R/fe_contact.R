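#' Frictional contact pair
#'
#' Node-to-surface penalty contact between two surface patches, with
#' Coulomb stick/slip friction by return mapping (tangential traction
#' capped at `mu` times the normal pressure). Nodes of `slave` are tested
#' against the triangles of `master`; the master surface normal (outward
#' from the master body) defines the contact direction. Penalties default
#' to 50x the softer neighbour's Young's modulus divided by the local
#' element edge.
#'
#' @param slave,master patch names.
#' @param mu Coulomb friction coefficient (>= 0; 0 = frictionless).
#' @param normal_penalty,tangential_penalty N/mm^3; `NULL` = default rule.
#' @param master_geom optional analytic description of the master surface
#'   (see [cylinder_surface()] / [plane_surface()]). When given, the gap is
#'   measured against the analytic surface carried by the master body
#'   (slave position pulled back by the local master displacement through a
#'   fixed reference-configuration projection), which removes the
#'   faceting noise of voxel meshes -- essential when the geometric
#'   interference is far smaller than the element size.
#' @param name pair name for reporting.
#' @return contact spec of class `contact_pair`.
#' @export
contact_pair <- function(slave, master, mu = 0, normal_penalty = NULL,
                         tangential_penalty = NULL, master_geom = NULL,
                         name = paste(slave, master, sep = "~")) {
  if (mu < 0) stop("`mu` must be >= 0")
  if (!is.null(normal_penalty) && normal_penalty <= 0)
    stop("penalties must be positive")
  structure(list(slave = slave, master = master, mu = mu,
                 k_n = normal_penalty, k_t = tangential_penalty,
                 geom = master_geom,
                 name = name), class = "contact_pair")
}

#' Analytic cylindrical master surface (z axis)
#'
#' Describes a cylindrical bore wall of the master body: contact pushes
#' the slave radially toward the axis.
#'
#' @param centre length-2 (x, y) of the axis, mm.
#' @param radius bore radius, mm.
#' @param zlim active axial range c(zmin, zmax), mm.
#' @return analytic surface spec.
#' @export
cylinder_surface <- function(centre, radius, zlim = c(-Inf, Inf)) {
  list(type = "cylinder", centre = as.numeric(centre), radius = radius,
       zlim = zlim)
}

#' Analytic plane master surface (z = constant)
#'
#' A horizontal floor of the master body with outward normal -z (contact
#' pushes the slave toward smaller z).
#'
#' @param z plane position, mm.
#' @param centre length-2 (x, y) centre of the active disc, mm.
#' @param radius active radius, mm (`Inf` = whole plane).
#' @return analytic surface spec.
#' @export
plane_surface <- function(z, centre = c(0, 0), radius = Inf) {
  list(type = "plane_z", z = z, centre = as.numeric(centre), radius = radius)
}

# analytic gap (positive = separated), outward-from-master normal, and a
# smooth activation weight at pulled-back slave positions xb (n x 3);
# band edges fade over `fade` mm so forces stay continuous as nodes slide
# across them
analytic_gap <- function(geom, xb, fade = 0.3) {
  ramp <- function(d) pmin(1, pmax(0, d / fade))
  if (geom$type == "cylinder") {
    dx <- xb[, 1] - geom$centre[1]; dy <- xb[, 2] - geom$centre[2]
    rho <- pmax(sqrt(dx^2 + dy^2), 1e-12)
    gap <- geom$radius - rho
    n <- cbind(-dx / rho, -dy / rho, 0)
    w <- ramp(xb[, 3] - geom$zlim[1]) * ramp(geom$zlim[2] - xb[, 3])
    list(gap = gap, normal = n, weight = w)
  } else if (geom$type == "plane_z") {
    gap <- geom$z - xb[, 3]
    n <- cbind(0, 0, rep(-1, nrow(xb)))
    w <- if (is.finite(geom$radius)) {
      rr <- sqrt((xb[, 1] - geom$centre[1])^2 +
                   (xb[, 2] - geom$centre[2])^2)
      ramp(geom$radius - rr)
    } else rep(1, nrow(xb))
    list(gap = gap, normal = n, weight = w)
  } else if (geom$type == "plane_up") {
    # master below the plane, outward normal +z (tibial plateau)
    gap <- xb[, 3] - geom$z
    n <- cbind(0, 0, rep(1, nrow(xb)))
    list(gap = gap, normal = n, weight = rep(1, nrow(xb)))
  } else stop("unknown analytic surface type ", geom$type)
}

# C1 penalty law: quadratic blend over the first `eps` mm of penetration,
# linear beyond. Removes the stiffness jump at activation that otherwise
# makes Newton zigzag around nodes sitting at zero penetration.
# Returns value and derivative of the effective penetration.
smooth_pen <- function(pen, eps = 2e-3) {
  inb <- pen > 0 & pen < eps
  val <- ifelse(pen <= 0, 0, ifelse(inb, pen^2 / (2 * eps), pen - eps / 2))
  der <- ifelse(pen <= 0, 0, ifelse(inb, pen / eps, 1))
  list(val = val, der = der)
}

# small-strain equivalent modulus of a material spec
material_E_equiv <- function(mat, mesh_E_med = NULL) {
  switch(mat$kind,
         linear_elastic = mat$E,
         mapped = if (is.null(mesh_E_med)) 100 else mesh_E_med,
         neo_hookean = 9 * mat$K * mat$G / (3 * mat$K + mat$G))
}

# static data for one pair: slave nodes + tributary areas, master triangles
contact_precompute <- function(mesh, materials, pair) {
  ps <- mesh$patches[[pair$slave]]
  pm <- mesh$patches[[pair$master]]
  if (is.null(ps) || is.null(pm))
    stop("contact pair references unknown patch: ",
         pair$slave, " / ", pair$master)
  g <- face_normals_areas(mesh$nodes, ps$tri)
  snodes <- sort(unique(as.vector(ps$tri)))
  area <- numeric(length(snodes))
  for (k in 1:3) {
    agg <- rowsum(g$area / 3, ps$tri[, k])
    area[match(as.integer(rownames(agg)), snodes)] <-
      area[match(as.integer(rownames(agg)), snodes)] + agg
  }
  # default penalties from the softer neighbouring region
  regs <- unique(c(mesh$region[ps$elem], mesh$region[pm$elem]))
  mesh_E_med <- if (any(!is.na(mesh$E))) stats::median(mesh$E, na.rm = TRUE) else NULL
  Es <- vapply(regs, function(r) material_E_equiv(materials[[r]], mesh_E_med),
               numeric(1))
  k_n <- if (!is.null(pair$k_n)) pair$k_n else 50 * min(Es) / mesh$cell_edge
  # softer tangential penalty: the elastic pre-slip it allows (~10 um at
  # typical pressures) is negligible against the sliding distances of
  # interest, and a razor-thin stick zone destabilises the Newton loop
  k_t <- if (!is.null(pair$k_t)) pair$k_t else k_n / 100
  cd <- list(pair = pair, slave_nodes = snodes, slave_area = area,
             slave_tri = ps$tri, master_tri = pm$tri, k_n = k_n, k_t = k_t,
             t_off_max = 0.35 * mesh$cell_edge, geom = pair$geom)
  if (!is.null(pair$geom)) {
    # fixed reference-configuration projection: master load-transfer
    # weights never change, so the gap is smooth in the displacements
    pr <- contact_project(cd, mesh$nodes)
    cd$ref_tri <- pr$tri
    cd$ref_bary <- pr$bary
    tri <- cd$master_tri[pr$tri, , drop = FALSE]
    cd$ref_mpos <- mesh$nodes[tri[, 1], , drop = FALSE] * pr$bary[, 1] +
      mesh$nodes[tri[, 2], , drop = FALSE] * pr$bary[, 2] +
      mesh$nodes[tri[, 3], , drop = FALSE] * pr$bary[, 3]
  }
  cd
}

# area-weighted outward normal per slave node in configuration x (smooth
# in the deformation, unlike facet normals of the projection target)
slave_node_normals <- function(cd, x) {
  g <- face_normals_areas(x, cd$slave_tri)
  sn <- cd$slave_nodes
  acc <- matrix(0, length(sn), 3)
  for (k in 1:3) {
    idx <- match(cd$slave_tri[, k], sn)
    w <- g$normal * g$area
    for (i in 1:3) {
      agg <- rowsum(w[, i], idx)
      acc[as.integer(rownames(agg)), i] <-
        acc[as.integer(rownames(agg)), i] + agg
    }
  }
  acc / pmax(sqrt(rowSums(acc^2)), 1e-30)
}

# vectorised closest point on triangles (Ericson); all args n x 3
closest_point_triangle <- function(P, A, B, C) {
  dot <- function(u, v) rowSums(u * v)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- dot(ab, ap); d2 <- dot(ac, ap)
  bp <- P - B; d3 <- dot(ab, bp); d4 <- dot(ac, bp)
  cp <- P - C; d5 <- dot(ab, cp); d6 <- dot(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  n <- nrow(P)
  b1 <- numeric(n); b2 <- numeric(n)   # bary of B and C
  done <- logical(n)
  take <- function(cond, v, w) {
    sel <- cond & !done
    b1[sel] <<- v[sel]; b2[sel] <<- w[sel]; done[sel] <<- TRUE
  }
  take(d1 <= 0 & d2 <= 0, numeric(n), numeric(n))            # vertex A
  take(d3 >= 0 & d4 <= d3, rep(1, n), numeric(n))            # vertex B
  take(d6 >= 0 & d5 <= d6, numeric(n), rep(1, n))            # vertex C
  v_ab <- d1 / (d1 - d3)
  take(vc <= 0 & d1 >= 0 & d3 <= 0, v_ab, numeric(n))        # edge AB
  w_ac <- d2 / (d2 - d6)
  take(vb <= 0 & d2 >= 0 & d6 <= 0, numeric(n), w_ac)        # edge AC
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
       1 - w_bc, w_bc)                                       # edge BC
  denom <- 1 / (va + vb + vc)
  take(rep(TRUE, n), vb * denom, vc * denom)                 # interior
  cp_ <- A + ab * b1 + ac * b2
  list(point = cp_, bary = cbind(1 - b1 - b2, b1, b2))
}

# project slave nodes onto the master surface in configuration `x`
# (N x 3 current coordinates); k-nearest-centroid candidate prefilter
contact_project <- function(cd, x, k = 8L) {
  sn <- cd$slave_nodes
  P <- x[sn, , drop = FALSE]
  tri <- cd$master_tri
  cen <- (x[tri[, 1], , drop = FALSE] + x[tri[, 2], , drop = FALSE] +
            x[tri[, 3], , drop = FALSE]) / 3
  ns <- nrow(P); nm <- nrow(cen)
  k <- min(k, nm)
  d2 <- outer(rowSums(P^2), rep(1, nm)) - 2 * P %*% t(cen) +
    outer(rep(1, ns), rowSums(cen^2))
  cand <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  # batch all (node, candidate) pairs
  si <- rep(seq_len(ns), k)
  ti <- as.vector(cand)
  proj <- closest_point_triangle(P[si, , drop = FALSE],
                                 x[tri[ti, 1], , drop = FALSE],
                                 x[tri[ti, 2], , drop = FALSE],
                                 x[tri[ti, 3], , drop = FALSE])
  dist2 <- rowSums((P[si, , drop = FALSE] - proj$point)^2)
  best <- rep(NA_integer_, ns)
  bestd <- rep(Inf, ns)
  for (cc in seq_len(k)) {
    rows <- (cc - 1L) * ns + seq_len(ns)
    upd <- dist2[rows] < bestd
    bestd[upd] <- dist2[rows][upd]
    best[upd] <- rows[upd]
  }
  sel_tri <- ti[best]
  cpt <- proj$point[best, , drop = FALSE]
  # contact direction: negated slave-node outward normal (points from the
  # slave surface into the slave body's outside, i.e. toward the master)
  nrm <- -slave_node_normals(cd, x)
  dvec <- P - cpt
  gap <- rowSums(dvec * nrm)
  # tangential offset of the projection: nodes whose closest master point
  # lies sideways (projection clipped to the patch boundary) are not in
  # contact with this patch
  t_off <- sqrt(pmax(0, rowSums(dvec^2) - gap^2))
  list(tri = sel_tri, point = cpt, bary = proj$bary[best, , drop = FALSE],
       normal = nrm, gap = gap, t_off = t_off)
}

new_contact_state <- function(cd) {
  n <- length(cd$slave_nodes)
  list(active = logical(n), anchor_tri = rep(NA_integer_, n),
       anchor_bary = matrix(NA_real_, n, 3),
       anchor_pos = matrix(NA_real_, n, 3))
}

# world position of stored anchors in configuration x
anchor_positions <- function(cd, state, x) {
  tri <- cd$master_tri
  at <- state$anchor_tri
  ok <- !is.na(at)
  out <- matrix(NA_real_, length(at), 3)
  if (any(ok)) {
    b <- state$anchor_bary[ok, , drop = FALSE]
    out[ok, ] <- x[tri[at[ok], 1], , drop = FALSE] * b[, 1] +
                 x[tri[at[ok], 2], , drop = FALSE] * b[, 2] +
                 x[tri[at[ok], 3], , drop = FALSE] * b[, 3]
  }
  out
}

# evaluate contact nodal forces (and optionally tangent triplets) at
# configuration x; allowance = permitted penetration (shrink-fit ramp)
contact_evaluate <- function(cd, state, x, allowance = 0, want_tangent = TRUE,
                             frozen_t = NULL) {
  if (!is.null(cd$geom))
    return(contact_evaluate_analytic(cd, state, x, allowance, want_tangent,
                                     frozen_t))
  pr <- contact_project(cd, x)
  pen <- -pr$gap - allowance
  sp <- smooth_pen(pen)
  act <- sp$val > 0 & pr$t_off <= cd$t_off_max
  ns <- length(cd$slave_nodes)
  ndof <- 3L * nrow(x)
  f <- numeric(ndof)
  mu <- cd$pair$mu
  info <- list(projection = pr, pen = pen, active = act,
               Fn = numeric(ns), slip = logical(ns),
               t_vec = matrix(0, ns, 3))
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  if (any(act)) {
    ia <- which(act)
    A <- cd$slave_area[ia]
    n <- pr$normal[ia, , drop = FALSE]
    Fn <- cd$k_n * A * sp$val[ia]
    kA_eff <- cd$k_n * A * sp$der[ia]
    info$Fn[ia] <- Fn
    sn <- cd$slave_nodes[ia]
    tri <- cd$master_tri[pr$tri[ia], , drop = FALSE]
    bary <- pr$bary[ia, , drop = FALSE]
    # tangential traction from anchored elastic slip
    tv <- matrix(0, length(ia), 3)
    stick <- rep(FALSE, length(ia))
    if (mu > 0) {
      ap <- anchor_positions(cd, state, x)[ia, , drop = FALSE]
      has_anchor <- !is.na(ap[, 1])
      if (any(has_anchor)) {
        d <- x[sn, , drop = FALSE] - ap
        d[!has_anchor, ] <- 0
        dn <- rowSums(d * n)
        ut <- d - n * dn
        tv <- -cd$k_t * A * ut
        tmag <- sqrt(rowSums(tv^2))
        cap <- mu * Fn
        over <- tmag > cap & tmag > 0
        if (any(over))
          tv[over, ] <- tv[over, , drop = FALSE] * (cap[over] / tmag[over])
        stick <- has_anchor & !over
        info$slip[ia] <- has_anchor & over
      }
    }
    info$t_vec[ia, ] <- tv
    ftot <- n * Fn + tv                       # force on slave nodes
    for (i in 1:3) {
      agg <- rowsum(ftot[, i], 3L * (sn - 1L) + i)
      f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg
      for (k in 1:3) {
        dofm <- 3L * (tri[, k] - 1L) + i
        agg <- rowsum(-ftot[, i] * bary[, k], dofm)
        f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg
      }
    }
    if (want_tangent) {
      # per active node: K3 = k_n A n n' (+ k_t A (I - n n') when sticking),
      # spread over (slave, master1..3) with weights (1, -b1, -b2, -b3)
      nact <- length(ia)
      K3 <- array(0, dim = c(nact, 3, 3))
      for (i in 1:3) for (j in 1:3) {
        K3[, i, j] <- kA_eff * n[, i] * n[, j]
        if (mu > 0) {
          st <- as.numeric(stick)
          K3[, i, j] <- K3[, i, j] +
            cd$k_t * A * st * ((i == j) - n[, i] * n[, j])
        }
      }
      wts <- cbind(1, -bary)
      ndid <- cbind(sn, tri)                  # nact x 4
      nt <- nact * 144L
      ti <- integer(nt); tj <- integer(nt); tx <- numeric(nt)
      pos <- 0L
      for (aa in 1:4) for (bb in 1:4) for (i in 1:3) for (j in 1:3) {
        rng <- pos + seq_len(nact)
        ti[rng] <- 3L * (ndid[, aa] - 1L) + i
        tj[rng] <- 3L * (ndid[, bb] - 1L) + j
        tx[rng] <- wts[, aa] * wts[, bb] * K3[, i, j]
        pos <- pos + nact
      }
    }
  }
  info$force <- f
  info$tangent <- list(i = ti, j = tj, x = tx)
  info
}

# analytic-master path: gap against the analytic surface carried by the
# master body; master displacement pulled back through the fixed
# reference projection. Friction anchors are pulled-back positions.
contact_evaluate_analytic <- function(cd, state, x, allowance = 0,
                                      want_tangent = TRUE,
                                      frozen_t = NULL) {
  sn <- cd$slave_nodes
  ns <- length(sn)
  tri <- cd$master_tri[cd$ref_tri, , drop = FALSE]
  bary <- cd$ref_bary
  # u = x - X for the nodes involved (x holds current coordinates)
  um <- (x[tri[, 1], , drop = FALSE] * bary[, 1] +
           x[tri[, 2], , drop = FALSE] * bary[, 2] +
           x[tri[, 3], , drop = FALSE] * bary[, 3])
  # pulled-back slave position: x_s - u_m, with u_m the master
  # displacement at the fixed reference projection
  xb <- x[sn, , drop = FALSE] - (um - cd$ref_mpos)
  ag <- analytic_gap(cd$geom, xb)
  pen <- -ag$gap - allowance
  sp <- smooth_pen(pen)
  act <- sp$val > 0 & ag$weight > 0
  ndof <- 3L * nrow(x)
  f <- numeric(ndof)
  mu <- cd$pair$mu
  info <- list(pen = pen, active = act, Fn = numeric(ns),
               slip = logical(ns), t_vec = matrix(0, ns, 3),
               projection = list(tri = cd$ref_tri, bary = bary,
                                 normal = ag$normal, point = xb))
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  if (any(act)) {
    ia <- which(act)
    A <- cd$slave_area[ia] * ag$weight[ia]
    n <- ag$normal[ia, , drop = FALSE]
    Fn <- cd$k_n * A * sp$val[ia]
    kA_eff <- cd$k_n * A * sp$der[ia]      # dFn/dpen
    info$Fn[ia] <- Fn
    snia <- sn[ia]
    tria <- tri[ia, , drop = FALSE]
    ba <- bary[ia, , drop = FALSE]
    tv <- matrix(0, length(ia), 3)
    stick <- rep(FALSE, length(ia))
    slip_dir <- matrix(0, length(ia), 3)
    slip_mag <- numeric(length(ia))
    sfac <- numeric(length(ia))      # tanh saturation level per node
    utmag <- numeric(length(ia))
    rat <- numeric(length(ia))       # elastic-to-cap traction ratio
    if (mu > 0) {
      ap <- state$anchor_pos[ia, , drop = FALSE]
      has_anchor <- !is.na(ap[, 1])
      if (any(has_anchor)) {
        d <- xb[ia, , drop = FALSE] - ap
        d[!has_anchor, ] <- 0
        dn <- rowSums(d * n)
        ut <- d - n * dn
        # smooth Coulomb saturation: |t| = mu Fn tanh(k_t |ut| / (mu Fn)).
        # Equals the elastic (stick) law near the anchor and the slip cap
        # far from it, with no kink in between -- the hard stick/slip
        # switch otherwise leaves Newton zigzagging on the cap manifold.
        tmag_el <- cd$k_t * A * sqrt(rowSums(ut^2))
        cap <- mu * Fn
        ratio <- ifelse(cap > 0, tmag_el / pmax(cap, 1e-300), 0)
        s <- tanh(ratio)
        utn <- sqrt(rowSums(ut^2))
        dirv <- -ut / pmax(utn, 1e-300)
        dirv[utn < 1e-300, ] <- 0
        tv <- dirv * (cap * s)
        slip_dir <- dirv
        slip_mag <- utn
        sfac <- s
        utmag <- utn
        rat <- ratio
        over <- tmag_el > cap
        stick <- has_anchor & !over
        info$slip[ia] <- has_anchor & over
      }
    }
    info$t_vec[ia, ] <- tv
    ftot <- n * Fn + tv
    for (i in 1:3) {
      agg <- rowsum(ftot[, i], 3L * (snia - 1L) + i)
      f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg
      for (k in 1:3) {
        dofm <- 3L * (tria[, k] - 1L) + i
        agg <- rowsum(-ftot[, i] * ba[, k], dofm)
        f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg
      }
    }
    if (want_tangent) {
      nact <- length(ia)
      K3 <- array(0, dim = c(nact, 3, 3))
      # full consistent tangent of the smooth friction law (asymmetric:
      # the traction cap follows the normal force one-way):
      #   d|t|/d|ut| = k_t A (1 - s^2) along the slip direction,
      #   |t|/|ut| against rotation of the direction, and the
      #   normal-to-tangential coupling mu g d n' with
      #   g = s - ratio (1 - s^2)
      kmag <- cd$k_t * A * (1 - sfac^2)
      krot <- ifelse(utmag > 1e-12,
                     pmin(cd$k_t * A, mu * Fn * sfac / pmax(utmag, 1e-12)),
                     cd$k_t * A)
      gfac <- sfac - rat * (1 - sfac^2)
      for (i in 1:3) for (j in 1:3) {
        K3[, i, j] <- kA_eff * n[, i] * n[, j]
        if (mu > 0) {
          K3[, i, j] <- K3[, i, j] +
            kmag * slip_dir[, i] * slip_dir[, j] +
            krot * ((i == j) - n[, i] * n[, j] -
                      slip_dir[, i] * slip_dir[, j]) +
            mu * gfac * kA_eff * slip_dir[, i] * n[, j]
        }
      }
      wts <- cbind(1, -ba)
      ndid <- cbind(snia, tria)
      nt <- nact * 144L
      ti <- integer(nt); tj <- integer(nt); tx <- numeric(nt)
      pos <- 0L
      for (aa in 1:4) for (bb in 1:4) for (i in 1:3) for (j in 1:3) {
        rng <- pos + seq_len(nact)
        ti[rng] <- 3L * (ndid[, aa] - 1L) + i
        tj[rng] <- 3L * (ndid[, bb] - 1L) + j
        tx[rng] <- wts[, aa] * wts[, bb] * K3[, i, j]
        pos <- pos + nact
      }
    }
  }
  info$force <- f
  info$tangent <- list(i = ti, j = tj, x = tx)
  info$xb <- xb
  info
}

# commit friction anchors after a converged increment
contact_commit <- function(cd, state, x, info) {
  if (!is.null(cd$geom)) {
    act <- info$active
    state$active <- act
    ia <- which(act)
    if (length(ia)) {
      newly <- ia[is.na(state$anchor_pos[ia, 1])]
      state$anchor_pos[newly, ] <- info$xb[newly, , drop = FALSE]
      slipped <- ia[info$slip[ia]]
      if (length(slipped)) {
        A <- cd$slave_area[slipped]
        tvec <- info$t_vec[slipped, , drop = FALSE]
        xbs <- info$xb[slipped, , drop = FALSE]
        tmag <- sqrt(rowSums(tvec^2))
        cap <- cd$pair$mu * info$Fn[slipped]
        # residual elastic slip that reproduces the smooth-law traction
        ell <- ifelse(cap > 0,
                      cap / (cd$k_t * A) *
                        atanh(pmin(tmag / pmax(cap, 1e-300), 0.999)),
                      0)
        dirv <- tvec / pmax(tmag, 1e-300)
        state$anchor_pos[slipped, ] <- xbs + dirv * ell
      }
    }
    state$anchor_pos[!act, ] <- NA_real_
    return(state)
  }
  contact_commit_mesh(cd, state, x, info)
}

contact_commit_mesh <- function(cd, state, x, info) {
  pr <- info$projection
  act <- info$active
  state$active <- act
  mu <- cd$pair$mu
  ia <- which(act)
  if (length(ia)) {
    # sticking, previously anchored nodes keep their anchors
    keep <- info$slip[ia] | is.na(state$anchor_tri[ia])
    newly <- ia[is.na(state$anchor_tri[ia])]
    state$anchor_tri[newly] <- pr$tri[newly]
    state$anchor_bary[newly, ] <- pr$bary[newly, , drop = FALSE]
    if (mu > 0) {
      slipped <- ia[info$slip[ia]]
      if (length(slipped)) {
        # re-anchor so the residual elastic slip matches the slip traction
        sn <- cd$slave_nodes[slipped]
        A <- cd$slave_area[slipped]
        tvec <- info$t_vec[slipped, , drop = FALSE]
        n <- pr$normal[slipped, , drop = FALSE]
        ps <- x[sn, , drop = FALSE]
        pt <- ps - n * rowSums((ps - pr$point[slipped, , drop = FALSE]) * n)
        target <- pt + tvec / (cd$k_t * A)
        # store as (tri, bary) of the projection of the target point
        tri <- cd$master_tri
        pj <- closest_point_triangle(
          target,
          x[tri[pr$tri[slipped], 1], , drop = FALSE],
          x[tri[pr$tri[slipped], 2], , drop = FALSE],
          x[tri[pr$tri[slipped], 3], , drop = FALSE])
        state$anchor_tri[slipped] <- pr$tri[slipped]
        state$anchor_bary[slipped, ] <- pj$bary
      }
    }
  }
  inact <- which(!act)
  state$anchor_tri[inact] <- NA_integer_
  state$anchor_bary[inact, ] <- NA_real_
  state
}
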