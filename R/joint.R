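#' Synthetic tibiofemoral joint geometry
#'
#' Two condylar half-ellipsoids on a femoral block articulating against a
#' flat tibial cartilage layer: the simplest geometry that produces two
#' distinct contact patches per compartment. All dimensions mm; z is up,
#' the tibial articular plane is z = `tibia_cartilage`.
#'
#' @param plate_x,plate_y tibial plate extent.
#' @param tibia_bone,tibia_cartilage tibial layer thicknesses.
#' @param condyle_sep centre-to-centre medial-lateral condyle separation.
#' @param ax,ay,az condyle semi-axes (x = medial-lateral, y =
#'   anterior-posterior, z = vertical).
#' @param femur_cartilage femoral cartilage shell thickness.
#' @param femur_block femoral bone block height above the condyle centres.
#' @param gap initial articular clearance at the condyle apex.
#' @param hole_diameter,hole_depth,graft_diameter defect / graft drilling
#'   parameters (diametral interference = graft - hole diameter).
#' @return object of class `joint_geometry`.
#' @export
joint_geometry <- function(plate_x = 36, plate_y = 22,
                           tibia_bone = 4.5, tibia_cartilage = 1.5,
                           condyle_sep = 16, ax = 7, ay = 8, az = 6.5,
                           femur_cartilage = 1.5, femur_block = 6.5,
                           gap = 0,
                           hole_diameter = 6.35, hole_depth = 10,
                           graft_diameter = 6.5) {
  structure(as.list(environment()), class = "joint_geometry")
}

# condyle centres (x, y) and apex height
joint_centres <- function(geom) {
  cx <- geom$plate_x / 2 + c(-1, 1) * geom$condyle_sep / 2
  cy <- geom$plate_y / 2
  zc <- geom$tibia_cartilage + geom$gap + geom$az
  list(cx = cx, cy = cy, zc = zc)
}

# height field of the femoral (bone) surface: lowest z of the flexed
# condylar ellipsoids over (x, y); flat at the centre height elsewhere.
# Flexion rotates each ellipsoid about the medial-lateral (x) axis
# through its centre.
femoral_height_field <- function(geom, flexion_deg = 0) {
  cen <- joint_centres(geom)
  th <- flexion_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ay2 <- geom$ay^2; az2 <- geom$az^2
  function(x, y) {
    f <- rep(cen$zc, length(x))
    for (k in 1:2) {
      R2 <- 1 - ((x - cen$cx[k]) / geom$ax)^2
      u <- y - cen$cy
      # rotated ellipsoid: quadratic in v = z - zc
      A <- st^2 / ay2 + ct^2 / az2
      B <- 2 * u * ct * st * (1 / ay2 - 1 / az2)
      C <- u^2 * (ct^2 / ay2 + st^2 / az2) - R2
      disc <- B^2 - 4 * A * C
      ok <- R2 > 0 & disc > 0
      vk <- rep(NA_real_, length(x))
      vk[ok] <- (-B[ok] - sqrt(disc[ok])) / (2 * A)
      fk <- cen$zc + vk
      f <- ifelse(!is.na(fk) & fk < f, fk, f)
    }
    f
  }
}

#' Build the synthetic tibiofemoral joint model
#'
#' Meshes tibia (bone + flat cartilage) and femur (height-field condyles
#' with a cartilage shell), applies the per-site cases (defect = open
#' drilled hole; graft = interference-fit osteochondral plug; pin = steel
#' plug of graft geometry), snaps the articular surfaces smooth, and
#' defines contacts and boundary conditions: encastre tibial base,
#' kinematic coupling of the femoral top to a reference point loaded
#' axially. Cartilage-on-cartilage contact is frictionless; graft/pin
#' wall and base contacts use the calibrated friction pair.
#'
#' @param geom a [joint_geometry()].
#' @param flexion_deg femoral flexion angle (degrees).
#' @param cases list(medial=, lateral=) with entries "intact", "defect",
#'   "graft", "graft_recessed" or "pin".
#' @param axial_load N (applied as -z force on the femoral reference).
#' @param mu friction pair c(mu_bone_bone, mu_cartilage_bone).
#' @param bone_E uniform bone modulus, MPa (the synthetic joint carries no
#'   microstructure; pick `conversion factor x mean BV/TV`).
#' @param settings a [mesh_settings()].
#' @param materials region materials; `NULL` = neo-Hookean cartilage with
#'   `bone_E` bone.
#' @param recess below-flush seating depth for "graft_recessed", mm.
#' @return list with `model` (an [fe_model()]), bookkeeping (site info,
#'   patches, geometry), ready for [run_joint_scenario()].
#' @export
build_joint_model <- function(geom = joint_geometry(), flexion_deg = 0,
                              cases = list(medial = "intact",
                                           lateral = "intact"),
                              axial_load = 500,
                              mu = c(0.6, 0.3),
                              bone_E = 60,
                              settings = mesh_settings(1.5),
                              materials = NULL,
                              recess = 0.5) {
  h <- settings$target_edge_length
  cen <- joint_centres(geom)
  ff <- femoral_height_field(geom, flexion_deg)
  if (is.null(materials))
    materials <- region_materials(
      bone = list(kind = "linear_elastic", E = bone_E, nu = 0.3),
      cartilage = list(kind = "neo_hookean", K = 16.67, G = 1.37),
      graft_bone = list(kind = "linear_elastic", E = bone_E, nu = 0.3),
      graft_cartilage = list(kind = "neo_hookean", K = 16.67, G = 1.37),
      pin = list(kind = "linear_elastic", E = 193000, nu = 0.3))

  nx <- as.integer(ceiling(geom$plate_x / h))
  ny <- as.integer(ceiling(geom$plate_y / h))
  xs <- (seq_len(nx) - 0.5) * h
  ys <- (seq_len(ny) - 0.5) * h

  # ---- tibia: bone below z=0... cartilage up to the articular plane
  nzb <- max(2L, round(geom$tibia_bone / h))
  nzc <- max(1L, round(geom$tibia_cartilage / h))
  tib <- array(0L, dim = c(nx, ny, nzb + nzc))
  tib[, , seq_len(nzb)] <- 1L
  tib[, , nzb + seq_len(nzc)] <- 2L
  tib_z0 <- -nzb * h                      # bottom of tibial bone
  art_z <- nzc * h                        # articular plane (exact)
  tibia <- mesh_labelled_volume(
    label_volume(tib, h, c(bone = 1L, cartilage = 2L),
                 origin = c(h / 2, h / 2, tib_z0 + h / 2)),
    mesh_settings(h))
  tibia <- extract_patch(tibia, "bone", "void",
                         predicate = function(c, n) n[, 3] < -0.9,
                         name = "tibia_base")
  tibia <- extract_patch(tibia, "cartilage", "void",
                         predicate = function(c, n) n[, 3] > 0.9,
                         name = "tibial_cartilage_articular")

  # ---- femur: height-field condyles, cartilage shell, optional holes
  fvals <- outer(xs, ys, function(x, y) ff(as.vector(x), as.vector(y)))
  z_top <- cen$zc + geom$femur_block
  nzf <- as.integer(ceiling((z_top - min(fvals)) / h)) + 1L
  fz0 <- floor(min(fvals) / h) * h        # lattice base for femur
  fem <- array(0L, dim = c(nx, ny, nzf))
  zsf <- fz0 + (seq_len(nzf) - 0.5) * h
  for (k in seq_len(nzf)) {
    zk <- zsf[k]
    lay <- ifelse(zk >= fvals & zk <= z_top,
                  ifelse(zk <= fvals + geom$femur_cartilage, 2L, 1L), 0L)
    fem[, , k] <- lay
  }
  # drill holes for non-intact sites (axis z through the contact point)
  sites <- list(medial = 1L, lateral = 2L)
  site_info <- list()
  for (s in names(sites)) {
    cs <- cases[[s]]
    if (is.null(cs) || cs == "intact") {
      site_info[[s]] <- list(case = "intact")
      next
    }
    k <- sites[[s]]
    # contact point of the flexed condyle: minimiser of the height field
    yy <- seq(cen$cy - geom$ay, cen$cy + geom$ay, by = 0.1)
    fk <- ff(rep(cen$cx[k], length(yy)), yy)
    xd <- cen$cx[k]; yd <- yy[which.min(fk)]
    f0 <- min(fk)
    rh <- geom$hole_diameter / 2
    hole <- outer((xs - xd)^2, (ys - yd)^2, "+") <= rh^2
    # carve one extra cell so the (length-quantised) plug never overlaps
    # uncarved bone at the hole bottom
    ztopd <- f0 + geom$hole_depth + 0.75 * h
    for (kk in seq_len(nzf)) {
      if (zsf[kk] <= ztopd) fem[, , kk][hole] <- 0L
    }
    site_info[[s]] <- list(case = cs, xd = xd, yd = yd, f0 = f0,
                           hole_base = ztopd)
  }
  femur <- mesh_labelled_volume(
    label_volume(fem, h, c(bone = 1L, cartilage = 2L),
                 origin = c(h / 2, h / 2, fz0 + h / 2)),
    mesh_settings(h))
  away_from_holes <- function(cn) {
    keep <- rep(TRUE, nrow(cn))
    for (s in names(site_info)) {
      si <- site_info[[s]]
      if (si$case == "intact") next
      keep <- keep & ((cn[, 1] - si$xd)^2 + (cn[, 2] - si$yd)^2 >
                        (geom$hole_diameter / 2 - 0.25 * h)^2)
    }
    keep
  }
  femur <- extract_patch(femur, "cartilage", "void",
                         predicate = function(cn, n)
                           n[, 3] < -0.6 & away_from_holes(cn),
                         name = "femoral_articular")
  femur <- extract_patch(femur, "bone", "void",
                         predicate = function(cn, n)
                           n[, 3] > 0.9 & cn[, 3] > z_top - 1.01 * h,
                         name = "femur_top")
  # snap the articular nodes onto the exact (flexed) condyle surface
  fa_nodes <- unique(as.vector(femur$patches$femoral_articular$tri))
  target_z <- ff(femur$nodes[fa_nodes, 1], femur$nodes[fa_nodes, 2])
  ok <- is.finite(target_z) & abs(target_z - femur$nodes[fa_nodes, 3]) < h
  trial <- femur
  trial$nodes[fa_nodes[ok], 3] <- target_z[ok]
  if (min(tet_signed_volumes(trial$nodes, trial$elements)) > 1e-9)
    femur <- trial

  mm <- combine_meshes(tibia, femur)
  contacts <- list(contact_pair(
    "femoral_articular", "tibial_cartilage_articular", mu = 0,
    master_geom = plane_surface_up(art_z), name = "articular"))
  stab_nodes <- NULL
  implant_info <- list()

  # ---- graft / pin plugs
  for (s in names(site_info)) {
    si <- site_info[[s]]
    if (!si$case %in% c("graft", "graft_recessed", "pin")) next
    rg <- geom$graft_diameter / 2
    cap <- if (si$case == "pin") 0 else geom$femur_cartilage
    plug_len <- geom$hole_depth - (if (si$case == "graft_recessed") recess else 0)
    plug <- mesh_cylinder(rg, plug_len, edge = h,
                          top_region = if (si$case == "pin") "pin"
                                       else "graft_cartilage",
                          body_region = if (si$case == "pin") "pin"
                                        else "graft_bone",
                          cap_thickness = cap)
    pnm <- paste0(s, "_")
    rename <- c(wall_top = "wall_cart", wall_body = "wall_bone",
                base = "base", top = "top")
    names(plug$patches) <- paste0(pnm, rename[names(plug$patches)])
    # seat: articular end at flush (or recessed) level, base upward
    z_seat <- si$f0 + (if (si$case == "graft_recessed") recess else 0)
    plug <- transform_mesh(plug, translate = c(si$xd, si$yd, z_seat))
    # flush cap follows the local condyle curvature
    top_nodes <- unique(as.vector(plug$patches[[paste0(pnm, "top")]]$tri))
    tz <- ff(plug$nodes[top_nodes, 1], plug$nodes[top_nodes, 2]) +
      (if (si$case == "graft_recessed") recess else 0)
    okt <- is.finite(tz) & abs(tz - plug$nodes[top_nodes, 3]) < h
    ptrial <- plug
    ptrial$nodes[top_nodes[okt], 3] <- tz[okt]
    if (min(tet_signed_volumes(ptrial$nodes, ptrial$elements)) > 1e-9)
      plug <- ptrial
    off <- nrow(mm$nodes)
    plug_base_z <- max(plug$nodes[, 3])   # meshed (quantised) plug length
    mm <- combine_meshes(mm, plug)
    stab_nodes <- c(stab_nodes, off + seq_len(nrow(plug$nodes)))
    rh <- geom$hole_diameter / 2
    wall <- cylinder_surface(c(si$xd, si$yd), rh,
                             zlim = c(si$f0 + geom$femur_cartilage,
                                      plug_base_z + 0.05))
    wall_c <- cylinder_surface(c(si$xd, si$yd), rh,
                               zlim = c(si$f0 - 0.5,
                                        si$f0 + geom$femur_cartilage))
    # seat the base plane on the meshed plug base so a flush insertion
    # starts just touching (the drill-depth quantisation stays a property
    # of the femoral mesh, not a spurious pre-penetration)
    base_pl <- plane_surface(plug_base_z, centre = c(si$xd, si$yd),
                             radius = rh + h)
    # femur-side master patches for load transfer
    rad_of <- function(cn) sqrt((cn[, 1] - si$xd)^2 + (cn[, 2] - si$yd)^2)
    mm <- extract_patch(mm, "bone", "void",
                        predicate = function(cn, n)
                          abs(n[, 3]) < 0.5 & rad_of(cn) < rh + 0.8 * h &
                          cn[, 3] > si$f0 - h & cn[, 3] < si$hole_base + h,
                        name = paste0(pnm, "hole_wall"))
    mm <- extract_patch(mm, "bone", "void",
                        predicate = function(cn, n)
                          n[, 3] < -0.5 & rad_of(cn) < rh + 0.3 * h &
                          cn[, 3] > plug_base_z - 1.2 * h &
                          cn[, 3] < plug_base_z + 1.5 * h,
                        name = paste0(pnm, "hole_base"))
    wall_slave_bone <- paste0(pnm, "wall_bone")
    contacts <- c(contacts, list(
      contact_pair(wall_slave_bone, paste0(pnm, "hole_wall"), mu = mu[1],
                   master_geom = wall, name = paste0(pnm, "wall_bb")),
      contact_pair(paste0(pnm, "base"), paste0(pnm, "hole_base"),
                   mu = mu[1], master_geom = base_pl,
                   name = paste0(pnm, "base"))))
    if (cap > 0) {
      contacts <- c(contacts, list(
        contact_pair(paste0(pnm, "wall_cart"), paste0(pnm, "hole_wall"),
                     mu = mu[2], master_geom = wall,
                     name = paste0(pnm, "wall_cb")),
        contact_pair(wall_slave_bone, paste0(pnm, "hole_wall"),
                     mu = mu[2], master_geom = wall_c,
                     name = paste0(pnm, "wall_bc"))))
    }
    # the plug articular face also contacts the tibial plateau
    contacts <- c(contacts, list(
      contact_pair(paste0(pnm, "top"), "tibial_cartilage_articular",
                   mu = 0, master_geom = plane_surface_up(art_z),
                   name = paste0(pnm, "articular"))))
    plug_nodes <- off + seq_len(nrow(plug$nodes))
    pc <- colMeans(mm$nodes[plug_nodes, , drop = FALSE])
    pin_node <- plug_nodes[which.min(rowSums(sweep(
      mm$nodes[plug_nodes, , drop = FALSE], 2, pc)^2))]
    spscore <- (mm$nodes[plug_nodes, 1] - si$xd) -
      abs(mm$nodes[plug_nodes, 2] - si$yd) -
      0.3 * abs(mm$nodes[plug_nodes, 3] - pc[3])
    spin_pin <- plug_nodes[which.max(spscore)]
    implant_info[[s]] <- list(case = si$case, centre = c(si$xd, si$yd),
                              delta_r = (geom$graft_diameter -
                                           geom$hole_diameter) / 2,
                              top_patch = paste0(pnm, "top"),
                              base_patch = paste0(pnm, "base"),
                              hole_base_patch = paste0(pnm, "hole_base"),
                              pin_node = pin_node, spin_pin = spin_pin)
  }

  ref <- c(geom$plate_x / 2, geom$plate_y / 2, z_top)
  cons <- list(
    encastre(patch = "tibia_base", name = "tibia_fix"),
    kinematic_coupling("femur_top", ref_point = ref,
                       displacement = c(0, 0, NA), rotation = c(0, 0, 0),
                       force = c(0, 0, -axial_load), name = "femur_load"))
  model <- fe_model(mm, materials, cons, contacts,
                    stabilization = if (!is.null(stab_nodes))
                      list(nodes = stab_nodes, k = 5e-4) else NULL)
  list(model = model, geom = geom, flexion_deg = flexion_deg,
       cases = cases, axial_load = axial_load, art_z = art_z,
       centres = cen, site_info = site_info, implant_info = implant_info,
       mid_x = geom$plate_x / 2)
}

# tibial articular plane with outward normal +z (master below)
plane_surface_up <- function(z) {
  list(type = "plane_up", z = z)
}

#' Joint loading scenario
#'
#' @param flexion_deg flexion angle, degrees (0, 10, 30 in the standard
#'   protocol; any value allowed).
#' @param cases per-site case list (see [build_joint_model()]).
#' @param axial_load N (default 500).
#' @return class `joint_scenario`.
#' @export
joint_scenario <- function(flexion_deg = 0,
                           cases = list(medial = "intact",
                                        lateral = "intact"),
                           axial_load = 500) {
  if (axial_load <= 0) stop("`axial_load` must be positive")
  structure(list(flexion_deg = flexion_deg, cases = cases,
                 axial_load = axial_load), class = "joint_scenario")
}

#' Run a tibiofemoral joint scenario
#'
#' Builds the case-specific joint, resolves any graft interference by the
#' shrink-fit ramp, ramps the axial load through the femoral coupling,
#' and returns per-compartment contact pressures on the tibial plateau
#' plus graft subsidence.
#'
#' @param scenario a [joint_scenario()].
#' @param geom a [joint_geometry()].
#' @param n_steps load increments.
#' @param pitch sensel pitch for the rasterised maps, mm.
#' @param ... passed to [build_joint_model()] (mesh settings, materials,
#'   friction, ...).
#' @return list with `solution`, `field` (contact cloud), `map` (full
#'   [pressure_map()]), `compartments` (per-side force, area, peak/mean
#'   pressure), `subsidence` (per implanted site, mm), `total_force`.
#' @export
run_joint_scenario <- function(scenario = joint_scenario(),
                               geom = joint_geometry(),
                               n_steps = 5L, pitch = 1.27,
                               verbose = FALSE, ...) {
  jm <- build_joint_model(geom, scenario$flexion_deg, scenario$cases,
                          scenario$axial_load, ...)
  has_plug <- length(jm$implant_info) > 0
  dr <- if (has_plug) jm$implant_info[[1]]$delta_r else 0
  state <- NULL
  if (has_plug && dr > 0) {
    # shrink-fit prestress of the plug(s) first, with the plugs pinned
    # (centroid + spin) so their contact-only rigid modes stay tame
    pins <- list()
    for (ii in jm$implant_info) {
      pins <- c(pins,
                list(prescribed_nodes(ii$pin_node, c(0, 0, 0),
                                      name = "plug_pin"),
                     prescribed_nodes(ii$spin_pin, c(NA, 0, NA),
                                      name = "plug_spin")))
    }
    model_pre <- jm$model
    model_pre$constraints <- c(model_pre$constraints, pins)
    pre <- solve_nonlinear_static(model_pre,
                                  data.frame(lambda = 0,
                                             allowance = dr * c(0.5, 0.25, 0)),
                                  verbose = verbose)
    state <- pre$state
    state$lambda <- 0
  }
  model_load <- jm$model
  if (has_plug) {
    spins <- lapply(jm$implant_info, function(ii)
      prescribed_nodes(ii$spin_pin, c(NA, 0, NA), name = "plug_spin"))
    model_load$constraints <- c(model_load$constraints, unname(spins))
  }
  # settle phase: a small prescribed femoral descent establishes the
  # articular contact before switching to force control (force-driven
  # approach against an open gap has no Newton path into contact)
  model_touch <- model_load
  model_touch$constraints <- lapply(model_touch$constraints, function(cs) {
    if (identical(cs$name, "femur_load"))
      kinematic_coupling(cs$patch, cs$ref_point,
                         displacement = c(0, 0, -0.06),
                         rotation = c(0, 0, 0), name = "femur_load")
    else cs
  })
  pre_t <- solve_nonlinear_static(model_touch,
                                  data.frame(lambda = c(0.5, 1),
                                             allowance = 0),
                                  state = state, verbose = verbose)
  state <- pre_t$state
  state$lambda <- 0
  sched <- data.frame(lambda = seq_len(n_steps) / n_steps, allowance = 0)
  sol <- solve_nonlinear_static(model_load, sched, state = state,
                                verbose = verbose)
  mesh <- jm$model$mesh
  x <- mesh$nodes + sol$u

  # gather articular contact (femoral + plug tops vs tibial plateau)
  art_names <- grep("articular$", names(sol$contact), value = TRUE)
  pts <- NULL; Fn <- NULL; areas <- NULL
  for (nm in art_names) {
    ct <- sol$contact[[nm]]
    cd <- jm$model$cdata[[which(vapply(jm$model$cdata,
                                       function(c) c$pair$name == nm,
                                       logical(1)))]]
    act <- ct$active
    if (!any(act)) next
    sn <- ct$slave_nodes[act]
    pts <- rbind(pts, x[sn, 1:2, drop = FALSE])
    Fn <- c(Fn, ct$Fn[act])
    areas <- c(areas, cd$slave_area[act])
  }
  total_force <- sum(Fn)
  field <- contact_cloud_field(mesh, sol, jm, x)
  map <- rasterise_to_sensels(field, pitch = pitch)
  mid <- jm$mid_x
  comp <- lapply(list(medial = TRUE, lateral = FALSE), function(is_med) {
    sel <- if (is_med) pts[, 1] < mid else pts[, 1] >= mid
    list(force = sum(Fn[sel]),
         area_loaded = sum(areas[sel]),
         peak_pressure = if (any(sel)) max(Fn[sel] / areas[sel]) else 0)
  })
  subsid <- list()
  for (s in names(jm$implant_info)) {
    ii <- jm$implant_info[[s]]
    bn <- unique(as.vector(mesh$patches[[ii$base_patch]]$tri))
    hn <- unique(as.vector(mesh$patches[[ii$hole_base_patch]]$tri))
    # positive = the plug presses deeper into the femur (away from the
    # articular surface) relative to the hole base
    subsid[[s]] <- mean(sol$u[bn, 3]) - mean(sol$u[hn, 3])
  }
  list(solution = sol, field = field, map = map, compartments = comp,
       subsidence = subsid, total_force = total_force, joint = jm,
       load_share_medial = comp$medial$force / max(total_force, 1e-12))
}

# triangulated (x, y) contact-pressure field over the articulating slave
# patches, for sensel rasterisation. Nodal pressures are nodal contact
# force over *projected* tributary area of this triangulation, so the
# rasterised load integral matches the contact force sum exactly.
contact_cloud_field <- function(mesh, sol, jm, x) {
  art_names <- grep("articular$", names(sol$contact), value = TRUE)
  xy <- NULL; tri <- NULL; fn_all <- NULL
  for (nm in art_names) {
    ct <- sol$contact[[nm]]
    cdi <- which(vapply(jm$model$cdata, function(c) c$pair$name == nm,
                        logical(1)))
    cd <- jm$model$cdata[[cdi]]
    fn <- numeric(nrow(mesh$nodes))
    fn[ct$slave_nodes] <- ct$Fn
    ptri <- mesh$patches[[cd$pair$slave]]$tri
    ids <- sort(unique(as.vector(ptri)))
    remap <- integer(nrow(mesh$nodes)); remap[ids] <- seq_along(ids)
    off <- if (is.null(xy)) 0L else nrow(xy)
    xy <- rbind(xy, x[ids, 1:2, drop = FALSE])
    tri <- rbind(tri, matrix(remap[ptri], ncol = 3) + off)
    fn_all <- c(fn_all, fn[ids])
  }
  a <- xy[tri[, 1], , drop = FALSE]
  b <- xy[tri[, 2], , drop = FALSE]
  cc <- xy[tri[, 3], , drop = FALSE]
  ar <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
              (cc[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
  An <- numeric(nrow(xy))
  for (k in 1:3) {
    agg <- rowsum(ar / 3, tri[, k])
    An[as.integer(rownames(agg))] <- An[as.integer(rownames(agg))] + agg
  }
  list(xy = xy, tri = tri,
       pressure = ifelse(An > 1e-12, fn_all / An, 0))
}
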