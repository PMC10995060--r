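#' Compression protocol
#'
#' Platen compression of a potted specimen: prescribed uniaxial
#' displacement, stiffness read as the least-squares slope of the
#' force-displacement curve inside a force window.
#'
#' @param displacement applied compression, mm (default 1.0).
#' @param window force window for the stiffness slope, N (default
#'   c(400, 600); if the model never reaches the window the attained range
#'   is used with a warning).
#' @return class `compression_protocol`.
#' @export
compression_protocol <- function(displacement = 1.0, window = c(400, 600)) {
  if (displacement <= 0) stop("`displacement` must be positive")
  if (window[1] >= window[2]) stop("window lower bound must be below upper")
  structure(list(displacement = displacement, window = window),
            class = "compression_protocol")
}

#' Push-in protocol
#'
#' @param indenter_diameter mm (default 6.0; must not exceed the graft).
#' @param displacement indenter travel after first contact, mm.
#' @param mu_bone_bone,mu_cartilage_bone friction coefficients for the
#'   graft-host interfaces (cartilage-on-cartilage is frictionless).
#' @return class `push_in_protocol`.
#' @export
push_in_protocol <- function(indenter_diameter = 6.0, displacement = 1.0,
                             mu_bone_bone = 0.6, mu_cartilage_bone = 0.3) {
  if (displacement <= 0) stop("`displacement` must be positive")
  structure(list(indenter_diameter = indenter_diameter,
                 displacement = displacement,
                 mu_bone_bone = mu_bone_bone,
                 mu_cartilage_bone = mu_cartilage_bone),
            class = "push_in_protocol")
}

# ---------------------------------------------------------------------------
# compression arm

#' Prepare a compression model from a potted specimen
#'
#' Runs the image chain (binarise at 0.5, downsample, mesh, endcap patches)
#' once so repeated material-map evaluations during calibration can reuse
#' the mesh and sampled BV/TV.
#'
#' @param specimen an `oc_specimen` from [generate_condyle_specimen()].
#' @param downsample_factor binning factor; default targets a 0.164 mm
#'   BV/TV voxel from the specimen spacing.
#' @param settings a [mesh_settings()].
#' @param threshold binarisation threshold for the microstructure volume.
#' @return list with `mesh` (patches `endcap_top`, `endcap_bottom`),
#'   `field` (the BV/TV field), `ref` (coupling reference point).
#' @export
prepare_compression_model <- function(specimen,
                                      downsample_factor = NULL,
                                      settings = mesh_settings(),
                                      threshold = 0.5) {
  sp <- specimen$labels$spacing
  if (is.null(downsample_factor))
    downsample_factor <- max(1L, round(0.164 / sp))
  bin <- binarise(specimen$micro, threshold)
  field <- downsample_to_bvtv(bin, downsample_factor)
  mesh <- mesh_labelled_volume(specimen$labels, settings)
  zmin <- min(mesh$nodes[, 3]); zmax <- max(mesh$nodes[, 3])
  mesh <- extract_patch(mesh, "pmma", "void",
                        predicate = function(cen, n)
                          n[, 3] < -0.9 & cen[, 3] < zmin + 1e-6 + 0.1,
                        name = "endcap_bottom")
  mesh <- extract_patch(mesh, "pmma", "void",
                        predicate = function(cen, n)
                          n[, 3] > 0.9 & cen[, 3] > zmax - 1e-6 - 0.1,
                        name = "endcap_top")
  ref <- c(mean(range(mesh$nodes[, 1])), mean(range(mesh$nodes[, 2])), zmax)
  list(mesh = mesh, field = field, ref = ref)
}

#' Run a virtual platen compression test
#'
#' Full pipeline: density mapping onto the prepared mesh, encastre lower
#' endcap, kinematic coupling on the superior endcap with a prescribed
#' uniaxial displacement, linear static solve. Stiffness is the
#' least-squares slope of the force-displacement curve restricted to the
#' protocol's force window (for this linear model the curve is a ray, so
#' the slope equals force/displacement).
#'
#' @param specimen an `oc_specimen`, or a prepared model from
#'   [prepare_compression_model()].
#' @param map a [material_map()].
#' @param protocol a [compression_protocol()].
#' @param materials region materials (defaults include PMMA endcaps).
#' @return list with `stiffness` (N/mm), `curve` (data.frame displacement,
#'   force), `solution`.
#' @export
run_compression_test <- function(specimen, map,
                                 protocol = compression_protocol(),
                                 materials = default_materials()) {
  prep <- if (inherits(specimen, "oc_specimen"))
    prepare_compression_model(specimen) else specimen
  if (!"pmma" %in% prep$mesh$region)
    stop("compression specimen must have PMMA endcaps labelled")
  mesh <- assign_element_moduli(prep$mesh, prep$field, map)
  cons <- list(
    encastre(patch = "endcap_bottom", name = "base"),
    kinematic_coupling("endcap_top", ref_point = prep$ref,
                       displacement = c(0, 0, -protocol$displacement),
                       name = "platen"))
  sol <- solve_linear_static(mesh, materials, cons)
  F_full <- abs(sol$reactions$platen$force[3])
  d <- seq(0, protocol$displacement, length.out = 11L)
  curve <- data.frame(displacement = d,
                      force = F_full * d / protocol$displacement)
  inwin <- curve$force >= protocol$window[1] &
           curve$force <= protocol$window[2]
  pts <- if (sum(inwin) >= 2) curve[inwin, ] else {
    warning("force never spans the stiffness window; ",
            "slope computed over the attained range")
    curve[-1, ]
  }
  k <- stats::coef(stats::lm(force ~ displacement, data = pts))[[2]]
  list(stiffness = unname(k), curve = curve, solution = sol)
}

# ---------------------------------------------------------------------------
# push-in arm

#' Structured cylinder mesh
#'
#' Meshes a circular cylinder by mapping a square-section block lattice
#' onto the disc with the standard elliptical square-to-disc map, so the
#' lateral wall lies exactly on the cylinder and element quality stays
#' uniform (no voxel staircase). The axis is z, the top face is at z = 0
#' and the cylinder extends to z = `length`; the cross-section is centred
#' on (0, 0).
#'
#' @param radius cylinder radius, mm.
#' @param length axial length, mm.
#' @param edge target element edge, mm.
#' @param top_region,body_region region labels for the cap layer (first
#'   `cap_thickness` mm below the top) and the rest.
#' @param cap_thickness cap layer thickness, mm (0 = single region).
#' @return a `tet_mesh` with patches `wall_top` (cap lateral wall, when a
#'   cap exists), `wall_body`, `base` (z = length face) and `top`
#'   (z = 0 face).
#' @export
mesh_cylinder <- function(radius, length, edge = 1.0,
                          top_region = "graft_cartilage",
                          body_region = "graft_bone",
                          cap_thickness = 0) {
  nx <- max(3L, as.integer(ceiling(2 * radius / edge)))
  nz <- max(2L, as.integer(round(length / edge)))
  kcap <- if (cap_thickness > 0) max(1L, round(cap_thickness / edge)) else 0L
  labs <- array(2L, dim = c(nx, nx, nz))
  if (kcap > 0L) {
    labs[, , seq_len(min(kcap, nz))] <- 1L
    ltab <- stats::setNames(c(1L, 2L), c(top_region, body_region))
  } else {
    ltab <- stats::setNames(2L, body_region)
  }
  lv <- label_volume(labs, spacing = edge, labels = ltab,
                     origin = c(edge / 2 - nx * edge / 2,
                                edge / 2 - nx * edge / 2, edge / 2))
  m <- mesh_labelled_volume(lv, mesh_settings(edge))
  # patches on the block, then map
  has_cap <- kcap > 0L
  if (has_cap)
    m <- extract_patch(m, top_region, "void",
                       predicate = function(cen, n) abs(n[, 3]) < 0.5,
                       name = "wall_top")
  m <- extract_patch(m, body_region, "void",
                     predicate = function(cen, n) abs(n[, 3]) < 0.5,
                     name = "wall_body")
  m <- extract_patch(m, body_region, "void",
                     predicate = function(cen, n) n[, 3] > 0.9,
                     name = "base")
  m <- extract_patch(m, if (has_cap) top_region else body_region, "void",
                     predicate = function(cen, n) n[, 3] < -0.9,
                     name = "top")
  # elliptical square-to-disc map on (x, y)
  half <- nx * edge / 2
  sx <- m$nodes[, 1] / half
  sy <- m$nodes[, 2] / half
  m$nodes[, 1] <- radius * sx * sqrt(pmax(0, 1 - sy^2 / 2))
  m$nodes[, 2] <- radius * sy * sqrt(pmax(0, 1 - sx^2 / 2))
  if (min(tet_signed_volumes(m$nodes, m$elements)) <= 0)
    stop("cylinder mapping produced inverted elements")
  m
}

# regularise a voxel-staircase cylindrical wall: iteratively smooth the
# wall nodes tangentially, project them onto the exact cylinder (in-plane;
# z is kept), and relax strictly-interior nodes so elements stay valid
snap_nodes_to_cylinder <- function(mesh, nodes, centre, radius,
                                   n_iter = 20L) {
  project <- function(p) {
    dx <- p[, 1] - centre[1]; dy <- p[, 2] - centre[2]
    r <- pmax(sqrt(dx^2 + dy^2), 1e-9)
    cbind(centre[1] + dx * radius / r, centre[2] + dy * radius / r, p[, 3])
  }
  ed <- unique_edges(mesh$elements)
  ed2 <- rbind(ed, ed[, 2:1])
  is_wall <- logical(nrow(mesh$nodes)); is_wall[nodes] <- TRUE
  ft <- tet_face_table(mesh)
  bfaces <- ft$faces[!(ft$key %in% ft$key[duplicated(ft$key)]), , drop = FALSE]
  on_boundary <- logical(nrow(mesh$nodes))
  on_boundary[unique(as.vector(bfaces))] <- TRUE
  interior <- which(!on_boundary)
  # wall-wall edges for tangential smoothing
  ww <- ed2[is_wall[ed2[, 1]] & is_wall[ed2[, 2]], , drop = FALSE]
  # interior-node edges for relaxation
  ie <- ed2[ed2[, 1] %in% interior, , drop = FALSE]
  trial <- mesh
  trial$nodes[nodes, ] <- project(trial$nodes[nodes, , drop = FALSE])
  for (it in seq_len(n_iter)) {
    mn <- rowsum(trial$nodes[ww[, 2], , drop = FALSE], ww[, 1])
    cnt <- as.vector(rowsum(rep(1, nrow(ww)), ww[, 1]))
    ids <- as.integer(rownames(mn))
    sm <- 0.5 * trial$nodes[ids, , drop = FALSE] + 0.5 * mn / cnt
    sm[, 3] <- trial$nodes[ids, 3]          # staircase is purely in-plane
    trial$nodes[ids, ] <- project(sm)
    if (length(interior)) {
      mi <- rowsum(trial$nodes[ie[, 2], , drop = FALSE], ie[, 1])
      ci <- as.vector(rowsum(rep(1, nrow(ie)), ie[, 1]))
      iid <- as.integer(rownames(mi))
      trial$nodes[iid, ] <- 0.6 * trial$nodes[iid, , drop = FALSE] +
        0.4 * mi / ci
    }
  }
  # guard: back the wall off per-node if anything inverted
  sv <- tet_signed_volumes(trial$nodes, trial$elements)
  if (min(sv) <= 1e-9) {
    p0 <- mesh$nodes
    blend <- 1
    while (min(tet_signed_volumes(trial$nodes, trial$elements)) <= 1e-9 &&
           blend > 0.05) {
      blend <- blend * 0.7
      trial$nodes <- p0 + blend * (trial$nodes - p0)
    }
    if (min(tet_signed_volumes(trial$nodes, trial$elements)) <= 1e-9)
      stop("cylinder regularisation failed: inverted elements remain")
    warning("cylinder regularisation blended to ", signif(blend, 2))
  }
  trial
}

#' Build the graft push-in model
#'
#' Meshes host and graft from a [generate_graft_host_pair()] output, snaps
#' the hole and graft walls onto their exact cylinders (so the diametral
#' interference is represented geometrically), density-maps both bodies,
#' seats the graft coaxially at the hole base, and defines the frictional
#' contact pairs (bone-on-bone, cartilage-on-bone, frictionless
#' cartilage-on-cartilage). The z axis points into the bone (articular
#' surface at z = 0).
#'
#' @param pair output of [generate_graft_host_pair()].
#' @param map a [material_map()].
#' @param protocol a [push_in_protocol()] (supplies the friction pair).
#' @param settings a [mesh_settings()].
#' @param materials region materials.
#' @param stabilization_k weak grounding spring per graft node, N/mm.
#' @param seat `"base"` (tamped down onto the hole base, the experimental
#'   insertion endpoint) or `"flush"` (graft cartilage level with the host
#'   articular surface; leaves base clearance when the hole is deeper than
#'   the graft).
#' @return list with `model` (an [fe_model()]), `geom`, bookkeeping node
#'   sets, and the interference (`delta_r`, radial, mm).
#' @export
build_push_in_model <- function(pair, map, protocol = push_in_protocol(),
                                settings = mesh_settings(),
                                materials = default_materials(),
                                stabilization_k = 5e-4,
                                seat = c("base", "flush"),
                                normal_penalty = NULL) {
  seat <- match.arg(seat)
  geom <- pair$geom
  r_h <- geom$hole_diameter / 2
  r_g <- geom$graft_diameter / 2
  delta_r <- (geom$graft_diameter - geom$hole_diameter) / 2

  host <- mesh_labelled_volume(pair$host$labels, settings)
  hd <- host$nodes
  cx <- mean(range(hd[, 1])); cy <- mean(range(hd[, 2]))
  zmax <- max(hd[, 3])
  edge <- host$cell_edge
  radial <- function(cen) sqrt((cen[, 1] - cx)^2 + (cen[, 2] - cy)^2)
  host <- extract_patch(host, "bone", "void",
                        predicate = function(cen, n)
                          abs(n[, 3]) < 0.5 & radial(cen) < r_h + 0.8 * edge,
                        name = "hole_wall_bone")
  host <- extract_patch(host, "bone", "void",
                        predicate = function(cen, n)
                          n[, 3] < -0.5 & radial(cen) < r_h &
                          cen[, 3] > geom$hole_depth - 1.2 * edge,
                        name = "hole_base")
  host <- tryCatch(
    extract_patch(host, "cartilage", "void",
                  predicate = function(cen, n)
                    abs(n[, 3]) < 0.5 & radial(cen) < r_h + 0.8 * edge,
                  name = "hole_wall_cart"),
    error = function(e) host)
  host <- extract_patch(host, "cartilage", "void",
                        predicate = function(cen, n)
                          n[, 3] < -0.9 & radial(cen) > r_h,
                        name = "host_articular")
  host <- extract_patch(host, "bone", "void",
                        predicate = function(cen, n) n[, 3] > 0.9,
                        name = "host_bottom")
  # the hole wall stays as meshed: the bore geometry is carried
  # analytically by the contact pairs, so the host mesh only provides
  # compliance and load transfer

  # graft: structured cylinder mesh (exact wall radius, uniform quality)
  graft <- mesh_cylinder(r_g, geom$graft_length, edge = settings$target_edge_length,
                         top_region = "graft_cartilage",
                         body_region = "graft_bone",
                         cap_thickness = geom$cartilage_thickness)
  names(graft$patches)[match(c("wall_top", "wall_body", "base", "top"),
                             names(graft$patches))] <-
    c("graft_wall_cart", "graft_wall_bone", "graft_base",
      "graft_cartilage_top")

  # density mapping per body
  dsf <- max(1L, round(0.164 / pair$host$labels$spacing))
  hfield <- downsample_to_bvtv(binarise(pair$host$micro, 0.5), dsf)
  gfield <- downsample_to_bvtv(binarise(pair$graft$micro, 0.5), dsf)
  host <- assign_element_moduli(host, hfield, map, bone_regions = "bone")
  # graft field lives in the graft lattice frame (cylinder axis at the
  # lattice centre, articular surface at z = 0): sample in that frame
  gdim <- dim(pair$graft$micro$values)
  gsp <- pair$graft$micro$spacing
  fcx <- (gdim[1] - 1) / 2 * gsp; fcy <- (gdim[2] - 1) / 2 * gsp
  graft_pre <- graft
  graft_pre$nodes <- sweep(graft$nodes, 2, c(-fcx, -fcy, 0), "-")
  graft_pre <- assign_element_moduli(graft_pre, gfield, map,
                                     bone_regions = "graft_bone")
  graft$E <- graft_pre$E
  graft$bvtv <- graft_pre$bvtv

  # seat the graft: axis on the hole axis, base on the meshed hole base
  # plane (the voxel/mesh quantisation of the drill depth, not the nominal
  # depth, so base contact starts just-touching)
  gzmax <- max(graft$nodes[, 3])
  # the hole base plane is the deepest face of the patch (rim faces of
  # the voxel staircase sit shallower)
  base_z <- max(host$nodes[unique(as.vector(host$patches$hole_base$tri)), 3])
  dz <- if (seat == "base") base_z - gzmax else 0
  dz <- min(dz, base_z - gzmax)   # flush seating never overlaps the base
  graft <- transform_mesh(graft, translate = c(cx, cy, dz))

  mm <- combine_meshes(host, graft)
  graft_nodes <- (nrow(host$nodes) + 1L):nrow(mm$nodes)

  mu_bb <- protocol$mu_bone_bone
  mu_cb <- protocol$mu_cartilage_bone
  has_hc <- !is.null(mm$patches$hole_wall_cart)
  has_gc <- !is.null(mm$patches$graft_wall_cart)
  # analytic bore geometry: the wall is the exact drilled cylinder carried
  # by the host; zlim bands split the cartilage and bone wall sections
  cart_z <- geom$cartilage_thickness
  wall_bone <- cylinder_surface(c(cx, cy), r_h,
                                zlim = c(cart_z, base_z + 0.05))
  wall_cart <- cylinder_surface(c(cx, cy), r_h, zlim = c(-0.5, cart_z))
  base_pl <- plane_surface(base_z, centre = c(cx, cy), radius = r_h + edge)
  contacts <- list(
    contact_pair("graft_wall_bone", "hole_wall_bone", mu = mu_bb,
                 normal_penalty = normal_penalty,
                 master_geom = wall_bone, name = "wall_bone_bone"),
    contact_pair("graft_base", "hole_base", mu = mu_bb,
                 normal_penalty = normal_penalty,
                 master_geom = base_pl, name = "base"))
  if (has_gc)
    contacts <- c(contacts, list(
      contact_pair("graft_wall_cart", "hole_wall_bone", mu = mu_cb,
                   master_geom = wall_bone, name = "wall_cart_bone")))
  if (has_hc)
    contacts <- c(contacts, list(
      contact_pair("graft_wall_bone", "hole_wall_cart", mu = mu_cb,
                   master_geom = wall_cart, name = "wall_bone_cart")))
  if (has_hc && has_gc)
    contacts <- c(contacts, list(
      contact_pair("graft_wall_cart", "hole_wall_cart", mu = 0,
                   master_geom = wall_cart, name = "wall_cart_cart")))

  cons <- list(encastre(patch = "host_bottom", name = "base_fix"))
  model <- fe_model(mm, materials, cons, contacts,
                    stabilization = list(nodes = graft_nodes,
                                         k = stabilization_k))
  # node nearest the graft centroid: pinned during the interference ramp
  # (symmetry makes its reaction negligible), released for the push phase
  gc_pos <- colMeans(mm$nodes[graft_nodes, , drop = FALSE])
  pin_node <- graft_nodes[which.min(rowSums(sweep(
    mm$nodes[graft_nodes, , drop = FALSE], 2, gc_pos)^2))]
  # spin pin: wall-side node on the +x radius at mid-height; fixing its
  # tangential (y) motion removes the frictionless-spin mode without
  # resisting axial sliding or radial compression
  gp <- mm$nodes[graft_nodes, , drop = FALSE]
  score <- (gp[, 1] - cx) - abs(gp[, 2] - cy) -
    0.3 * abs(gp[, 3] - gc_pos[3])
  spin_pin <- graft_nodes[which.max(score)]
  list(model = model, geom = geom, delta_r = delta_r,
       centre = c(cx, cy), graft_nodes = graft_nodes,
       pin_node = pin_node, spin_pin = spin_pin,
       articular_z = min(mm$nodes[, 3]))
}

#' Resolve the interference fit (shrink-fit prestress)
#'
#' Ramps the permitted wall penetration from the radial interference down
#' to zero over `n_steps` equilibrium solves, leaving the seated graft in
#' equilibrium with radial compressive contact pressure on the walls.
#'
#' @param pim output of [build_push_in_model()].
#' @param n_steps ramp steps.
#' @param ... passed to [solve_nonlinear_static()].
#' @return list with `solution`, `flush_offset` (graft cartilage top minus
#'   host articular surface level, mm; negative = below flush), and
#'   `mean_wall_pressure` (MPa).
#' @export
graft_insertion_prestress <- function(pim, n_steps = 4L, ...) {
  dr <- pim$delta_r
  sched <- data.frame(lambda = 0,
                      allowance = dr * (1 - seq_len(n_steps) / n_steps))
  model_pre <- pim$model
  model_pre$constraints <- c(model_pre$constraints,
                             list(prescribed_nodes(pim$pin_node, c(0, 0, 0),
                                                   name = "graft_pin"),
                                  prescribed_nodes(pim$spin_pin, c(NA, 0, NA),
                                                   name = "spin_pin")))
  sol <- solve_nonlinear_static(model_pre, sched, ...)
  mesh <- pim$model$mesh
  x <- mesh$nodes + sol$u
  gtop <- mesh$patches$graft_cartilage_top
  ha <- mesh$patches$host_articular
  flush <- -(min(x[unique(as.vector(gtop$tri)), 3]) -
               min(x[unique(as.vector(ha$tri)), 3]))
  wall <- sol$contact$wall_bone_bone
  act <- wall$active
  mwp <- if (any(act)) sum(wall$Fn[act]) /
    sum(pim$model$cdata[[1]]$slave_area[act]) else 0
  list(solution = sol, flush_offset = flush, mean_wall_pressure = mwp)
}

#' Run a graft push-in test
#'
#' After the interference prestress, a rigid flat circular indenter is
#' seated on the graft cartilage surface and advanced by the protocol
#' displacement; the output is the indenter reaction history and the
#' push-in force at full travel (the sum of the contact nodal reaction
#' forces).
#'
#' @param pim output of [build_push_in_model()].
#' @param protocol a [push_in_protocol()].
#' @param n_steps push increments.
#' @param prestress optional result of [graft_insertion_prestress()] to
#'   reuse; computed here when `NULL`.
#' @param ... passed to [solve_nonlinear_static()].
#' @return list with `force_at_full` (N), `curve` (indenter displacement
#'   vs force), `flush_offset`, `subsidence` (graft axial motion relative
#'   to host during push, mm), `solution`.
#' @export
run_push_in_test <- function(pim, protocol = push_in_protocol(),
                             n_steps = 5L, prestress = NULL, ...) {
  if (is.null(prestress)) prestress <- graft_insertion_prestress(pim, ...)
  sol0 <- prestress$solution
  mesh <- pim$model$mesh
  x0 <- mesh$nodes + sol0$u
  gtop_nodes <- unique(as.vector(mesh$patches$graft_cartilage_top$tri))
  # the rigid flat indenter on the flat graft top is equivalent to
  # prescribing the axial motion of the covered top nodes (lateral motion
  # stays free: the indenter face is frictionless)
  rr <- sqrt((mesh$nodes[gtop_nodes, 1] - pim$centre[1])^2 +
               (mesh$nodes[gtop_nodes, 2] - pim$centre[2])^2)
  ind_nodes <- gtop_nodes[rr <= protocol$indenter_diameter / 2]
  if (!length(ind_nodes))
    stop("indenter does not cover any graft top nodes")
  model2 <- pim$model
  model2$constraints <- c(model2$constraints,
                          list(prescribed_nodes(pim$spin_pin, c(NA, 0, NA),
                                                name = "spin_pin"),
                               prescribed_nodes(ind_nodes,
                                                c(NA, NA,
                                                  protocol$displacement),
                                                name = "indenter")))
  st <- sol0$state
  st$lambda <- 0
  sched <- data.frame(lambda = seq_len(n_steps) / n_steps, allowance = 0)
  sol <- solve_nonlinear_static(model2, sched, state = st, ...)
  hist <- sol$diagnostics$history
  disp <- vapply(hist, function(h) h$lambda * protocol$displacement,
                 numeric(1))
  force <- vapply(hist, function(h)
    if (!is.null(h$reactions)) h$reactions[["indenter"]][3] else NA_real_,
    numeric(1))
  base_nodes <- unique(as.vector(mesh$patches$graft_base$tri))
  host_base_nodes <- unique(as.vector(mesh$patches$hole_base$tri))
  subsidence <- mean(sol$u[base_nodes, 3]) - mean(sol$u[host_base_nodes, 3]) -
    (mean(sol0$u[base_nodes, 3]) - mean(sol0$u[host_base_nodes, 3]))
  list(force_at_full = abs(sol$reactions$indenter$force[3]),
       curve = data.frame(displacement = c(0, disp), force = c(0, abs(force))),
       flush_offset = prestress$flush_offset,
       subsidence = subsidence,
       solution = sol, prestress = prestress)
}
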