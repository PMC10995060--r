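#' Assemble a finite element model
#'
#' Precomputes element geometry, the constant stiffness of all linear(ised)
#' elastic regions, and contact pair data. Bone and other linear elastic
#' regions are treated geometrically linear; neo-Hookean regions are fully
#' nonlinear. Units N-mm-MPa.
#'
#' @param mesh a `tet_mesh` with any density mapping already applied.
#' @param materials a [region_materials()].
#' @param constraints list of [encastre()] / [kinematic_coupling()] /
#'   [prescribed_nodes()] specs.
#' @param contacts list of [contact_pair()] specs.
#' @param rigid_planes list of [rigid_plane()] indenter specs.
#' @param stabilization optional list(`nodes`, `k`): weak grounding springs
#'   (N/mm per node) that regularise bodies held only by contact before the
#'   contact engages; keep `k` orders of magnitude below structural
#'   stiffness.
#' @return an `fe_model`.
#' @export
fe_model <- function(mesh, materials = default_materials(),
                     constraints = list(), contacts = list(),
                     rigid_planes = list(), stabilization = NULL) {
  geo <- element_geometry(mesh)
  ep <- element_elastic_params(mesh, materials)
  lin_rows <- which(!ep$nh)
  n3 <- 3L * nrow(mesh$nodes)
  lin <- if (length(lin_rows)) {
    assemble_linear_stiffness(mesh, geo, ep$E, ep$nu, lin_rows)
  } else {
    list(i = integer(0), j = integer(0), x = numeric(0),
         M = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(n3, n3)))
  }
  if (!is.null(stabilization)) {
    dofs <- as.vector(vapply(1:3,
                             function(i) 3L * (stabilization$nodes - 1L) + i,
                             integer(length(stabilization$nodes))))
    lin$i <- c(lin$i, dofs)
    lin$j <- c(lin$j, dofs)
    lin$x <- c(lin$x, rep(stabilization$k, length(dofs)))
    lin$M <- lin$M + Matrix::sparseMatrix(i = dofs, j = dofs,
                                          x = rep(stabilization$k,
                                                  length(dofs)),
                                          dims = c(n3, n3))
  }
  cdata <- lapply(contacts, function(cp) contact_precompute(mesh, materials, cp))
  pdata <- lapply(rigid_planes, function(rp) plane_precompute(mesh, materials, rp))
  structure(list(mesh = mesh, materials = materials,
                 constraints = constraints, contacts = contacts,
                 geo = geo, ep = ep, K_lin = lin$M,
                 lin_trip = lin[c("i", "j", "x")],
                 nh_rows = which(ep$nh), cdata = cdata, pdata = pdata),
            class = "fe_model")
}

#' Rigid flat indenter plane
#'
#' Frictionless penalty contact between a slave patch and a rigid circular
#' plane that advances along an axis with the load factor (the 6 mm flat
#' indenter of the push-in protocol). Reaction force is reported under
#' `name` in the solution's `planes` output.
#'
#' @param patch slave patch name (e.g. the graft cartilage top).
#' @param start axis position of the plane face at lambda = 0, mm.
#' @param travel signed displacement of the plane at lambda = 1, mm.
#' @param radius active radius, mm (`Inf` = unbounded plane).
#' @param centre length-2 centre of the circular face in the plane, mm.
#' @param axis contact axis (3 = z).
#' @param side +1 if the plane pushes toward -axis from above, -1 from
#'   below.
#' @param penalty N/mm^3; `NULL` = default rule from the slave region.
#' @param name reporting name.
#' @return spec of class `rigid_plane`.
#' @export
rigid_plane <- function(patch, start, travel, radius = Inf,
                        centre = c(0, 0), axis = 3L, side = +1,
                        penalty = NULL, name = "indenter") {
  structure(list(patch = patch, start = start, travel = travel,
                 radius = radius, centre = centre, axis = as.integer(axis),
                 side = side, k_n = penalty, name = name),
            class = "rigid_plane")
}

plane_precompute <- function(mesh, materials, rp) {
  ps <- mesh$patches[[rp$patch]]
  if (is.null(ps)) stop("rigid plane references unknown patch ", rp$patch)
  g <- face_normals_areas(mesh$nodes, ps$tri)
  snodes <- sort(unique(as.vector(ps$tri)))
  area <- numeric(length(snodes))
  for (k in 1:3) {
    agg <- rowsum(g$area / 3, ps$tri[, k])
    idx <- match(as.integer(rownames(agg)), snodes)
    area[idx] <- area[idx] + agg
  }
  mesh_E_med <- if (any(!is.na(mesh$E))) stats::median(mesh$E, na.rm = TRUE) else NULL
  regs <- unique(mesh$region[ps$elem])
  Es <- vapply(regs, function(r) material_E_equiv(materials[[r]], mesh_E_med),
               numeric(1))
  k_n <- if (!is.null(rp$k_n)) rp$k_n else 50 * min(Es) / mesh$cell_edge
  list(rp = rp, slave_nodes = snodes, slave_area = area, k_n = k_n)
}

# penalty force of a rigid plane at configuration x and load factor lambda
plane_evaluate <- function(pd, x, lambda) {
  rp <- pd$rp
  zp <- rp$start + lambda * rp$travel
  sn <- pd$slave_nodes
  ax <- rp$axis
  lat <- setdiff(1:3, ax)
  pos <- x[sn, , drop = FALSE]
  # smooth fade of the circular edge so rim nodes do not toggle on/off
  w <- if (is.finite(rp$radius)) {
    rr <- sqrt((pos[, lat[1]] - rp$centre[1])^2 +
                 (pos[, lat[2]] - rp$centre[2])^2)
    pmin(1, pmax(0, (rp$radius - rr) / 0.3))
  } else rep(1, length(sn))
  pen <- rp$side * (pos[, ax] - zp)
  spn <- smooth_pen(pen)
  act <- w > 0 & spn$val > 0
  Fn <- numeric(length(sn))
  Fn[act] <- pd$k_n * pd$slave_area[act] * w[act] * spn$val[act]
  f <- numeric(3L * nrow(x))
  dofs <- 3L * (sn - 1L) + ax
  f[dofs] <- -rp$side * Fn
  kdiag <- numeric(length(sn))
  kdiag[act] <- pd$k_n * pd$slave_area[act] * w[act] * spn$der[act]
  list(force = f, dofs = dofs, kdiag = kdiag, Fn = Fn, active = act,
       total_force = sum(Fn), plane_pos = zp)
}

# full internal force at displacement u (3N)
internal_force <- function(model, u) {
  f <- as.numeric(model$K_lin %*% u)
  if (length(model$nh_rows)) {
    fe <- neo_hookean_forces(model$mesh, model$geo, model$ep$K, model$ep$G,
                             model$nh_rows, u)
    f <- f + scatter_forces(fe, model$mesh$elements[model$nh_rows, , drop = FALSE],
                            length(u))
  }
  f
}

# Cholesky factor of a reduced stiffness, with optional diagonal
# regularisation escalation (modified Newton) when the matrix is
# indefinite or numerically singular
reduced_factor <- function(A, regularize = FALSE) {
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  # LDL' handles the mildly indefinite tangents that contact and
  # compressed hyperelastic elements produce, without the failed-attempt
  # churn of a strict LL' factorisation
  ldl <- function(M) {
    suppressWarnings(tryCatch(Matrix::Cholesky(M, LDL = TRUE, perm = TRUE),
                              error = function(e) NULL))
  }
  ok <- ldl(A)
  if (!is.null(ok) && !regularize) {
    # rank deficiency shows up as vanishing LDL pivots
    dd <- suppressWarnings(Matrix::diag(ok))
    if (any(!is.finite(dd)) ||
        min(abs(dd)) < 1e-10 * max(abs(dd))) ok <- NULL
  }
  if (is.null(ok) && regularize) {
    # nudge the diagonal until the factorisation succeeds (rigid modes
    # held only by contact can be numerically free)
    dscale <- mean(abs(Matrix::diag(A)))
    for (eps in 10^seq(-8, -2)) {
      ok <- ldl(A + Matrix::Diagonal(nrow(A), eps * dscale))
      if (!is.null(ok)) break
    }
  }
  if (is.null(ok)) {
    # singular: estimate the null-space dimension on small systems
    nsd <- if (nrow(A) <= 1500) {
      ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
      sum(abs(ev) < max(abs(ev)) * 1e-10)
    } else NA_integer_
    stop("singular system: unconstrained rigid-body modes remain",
         if (!is.na(nsd)) sprintf(" (null-space dimension %d)", nsd) else "")
  }
  ok
}

solve_reduced <- function(A, b, regularize = FALSE) {
  x <- as.numeric(Matrix::solve(reduced_factor(A, regularize), b))
  # LDL' factorises rank-deficient systems without complaint; verify
  if (!all(is.finite(x)) ||
      sqrt(sum((as.numeric(A %*% x) - b)^2)) >
        1e-6 * max(sqrt(sum(b^2)), 1e-12)) {
    nsd <- if (nrow(A) <= 1500) {
      ev <- eigen(as.matrix(Matrix::forceSymmetric((A + Matrix::t(A)) / 2)),
                  symmetric = TRUE, only.values = TRUE)$values
      sum(abs(ev) < max(abs(ev)) * 1e-10)
    } else NA_integer_
    stop("singular system: unconstrained rigid-body modes remain",
         if (!is.na(nsd)) sprintf(" (null-space dimension %d)", nsd) else "")
  }
  x
}

# sparse LU factor for the asymmetric tangents that Coulomb friction
# produces (the traction cap follows the normal force one-way)
asym_factor <- function(A) {
  f <- tryCatch(Matrix::lu(A), error = function(e) NULL)
  if (is.null(f)) {
    dscale <- mean(abs(Matrix::diag(A)))
    for (eps in 10^seq(-8, -2)) {
      f <- tryCatch(Matrix::lu(A + Matrix::Diagonal(nrow(A), eps * dscale)),
                    error = function(e) NULL)
      if (!is.null(f)) break
    }
  }
  if (is.null(f)) stop("singular system: LU factorisation failed")
  f
}

#' Linear static solve
#'
#' Small-strain TET4 solve under the given constraint set. Neo-Hookean
#' regions are linearised at their small-strain equivalent
#' `E = 9KG/(3K+G)`, `nu = (3K-2G)/(6K+2G)`.
#'
#' @param mesh a `tet_mesh`.
#' @param materials a [region_materials()].
#' @param constraints constraint list; must remove all rigid-body modes.
#' @return a `solution_state`: list with `u` (N x 3, mm), `reactions`
#'   (per constraint: force N, moment N mm at coupling references),
#'   `diagnostics`.
#' @export
solve_linear_static <- function(mesh, materials = default_materials(),
                                constraints = list()) {
  mats <- materials
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (m$kind == "neo_hookean") {
      mats[[nm]] <- list(kind = "linear_elastic",
                         E = 9 * m$K * m$G / (3 * m$K + m$G),
                         nu = (3 * m$K - 2 * m$G) / (6 * m$K + 2 * m$G))
    }
  }
  model <- fe_model(mesh, mats, constraints)
  sys <- build_constraint_system(mesh, constraints, lambda = 1)
  K <- model$K_lin
  A <- Matrix::t(sys$T) %*% K %*% sys$T
  b <- sys$f_red - as.numeric(Matrix::t(sys$T) %*% (K %*% sys$u0))
  q <- solve_reduced(A, b)
  u <- as.numeric(sys$T %*% q) + sys$u0
  resid <- as.numeric(K %*% u)
  structure(list(
    u = matrix(u, ncol = 3, byrow = TRUE),
    u_vec = u,
    reactions = constraint_reactions(sys, resid),
    diagnostics = list(converged = TRUE, n_dof = sys$nq)
  ), class = "solution_state")
}

#' Quasi-static nonlinear solve with load stepping
#'
#' Newton iterations with adaptive increment cutback over a schedule of
#' targets. Each target sets a load factor `lambda` in \[0, 1\] (scaling
#' prescribed motions and applied loads) and a contact `allowance` (mm of
#' permitted penetration, used by the shrink-fit interference ramp;
#' normally 0). Convergence: reduced residual below
#' `max(abs_tol, rel_tol * reference force)`.
#'
#' @param model an [fe_model()].
#' @param schedule data.frame with columns `lambda` and `allowance`, one
#'   row per target, visited in order. Default: 10 equal load increments.
#' @param state optional solver state from a previous call (displacement
#'   and friction anchors carry over).
#' @param rel_tol,abs_tol Newton tolerances (relative; absolute, N).
#' @param max_iter Newton iterations per increment.
#' @param max_cutbacks increment halvings before giving up.
#' @param verbose print per-increment convergence lines.
#' @return a `solution_state` with `u`, `reactions`, `contact` (per-pair
#'   normal force totals and per-node data), `state` (for chaining),
#'   `diagnostics` (residual history).
#' @export
solve_nonlinear_static <- function(model,
                                   schedule = data.frame(
                                     lambda = seq(0.1, 1, by = 0.1),
                                     allowance = 0),
                                   state = NULL,
                                   rel_tol = 1e-6, abs_tol = 0.05,
                                   max_iter = 30L, max_cutbacks = 6L,
                                   verbose = FALSE) {
  mesh <- model$mesh
  ndof <- 3L * nrow(mesh$nodes)
  if (is.null(state)) {
    state <- list(u = numeric(ndof),
                  cstates = lapply(model$cdata, new_contact_state),
                  lambda = 0,
                  allowance = if (nrow(schedule)) schedule$allowance[1] else 0)
  }
  hist <- list()
  cur <- c(state$lambda, state$allowance)
  for (tg in seq_len(nrow(schedule))) {
    target <- c(schedule$lambda[tg], schedule$allowance[tg])
    s_done <- 0
    s_step <- 1
    ncut <- 0L
    while (s_done < 1 - 1e-12) {
      s_try <- min(1, s_done + s_step)
      pars <- cur + s_try * (target - cur)
      res <- newton_increment(model, state, pars[1], pars[2],
                              rel_tol, abs_tol, max_iter, verbose)
      if (res$converged) {
        state <- res$state
        planes_f <- if (length(model$pdata)) {
          stats::setNames(vapply(state$pinfos, function(p) p$total_force,
                                 numeric(1)),
                          vapply(model$pdata, function(p) p$rp$name,
                                 character(1)))
        } else NULL
        fc_full <- numeric(length(state$u))
        for (ci in seq_along(state$cinfos))
          fc_full <- fc_full + state$cinfos[[ci]]$force
        for (pi in seq_along(state$pinfos))
          fc_full <- fc_full + state$pinfos[[pi]]$force
        reac <- constraint_reactions(state$sys,
                                     internal_force(model, state$u) - fc_full)
        hist[[length(hist) + 1L]] <-
          list(lambda = pars[1], allowance = pars[2], iters = res$iters,
               resid = res$resid, planes = planes_f,
               reactions = lapply(reac, function(r) r$force))
        s_done <- s_try
        if (ncut > 0L && res$iters < 6L) { s_step <- s_step * 2; ncut <- ncut - 1L }
      } else {
        ncut <- ncut + 1L
        if (ncut > max_cutbacks)
          stop("nonlinear solve failed to converge after ", max_cutbacks,
               " cutbacks (last residuals: ",
               paste(signif(utils::tail(res$resid_hist, 4), 3), collapse = ", "),
               ")")
        s_step <- s_step / 2
      }
    }
    cur <- target
  }
  state$lambda <- cur[1]
  state$allowance <- cur[2]
  finalize_solution(model, state, hist)
}

# one Newton-solved increment at fixed (lambda, allowance). Friction acts
# through the Coulomb return mapping (anchors fixed at the last committed
# increment); slipping nodes get a symmetrised consistent tangent.
newton_increment <- function(model, state, lambda, allowance,
                             rel_tol, abs_tol, max_iter, verbose) {
  mesh <- model$mesh
  sys <- build_constraint_system(mesh, model$constraints, lambda)
  u <- state$u
  # re-impose prescribed values at this lambda, keep free dofs
  q <- as.numeric(Matrix::solve(
    Matrix::Diagonal(x = Matrix::colSums(sys$T^2)),
    Matrix::t(sys$T) %*% (u - sys$u0)))
  u <- as.numeric(sys$T %*% q) + sys$u0
  resid_hist <- numeric(0)
  iters <- 0L
  # friction enters through the Coulomb return mapping inside the residual
  # (anchors fixed at the last committed increment), with the full
  # asymmetric consistent tangent solved by sparse LU
  has_friction <- any(vapply(model$cdata, function(cd) cd$pair$mu > 0,
                             logical(1)))
  frozen <- vector("list", length(model$cdata))   # NULL per pair

  eval_resid <- function(u, frozen) {
    x <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
    fint <- internal_force(model, u)
    fc <- numeric(length(u))
    ct_i <- integer(0); ct_j <- integer(0); ct_x <- numeric(0)
    cinfos <- vector("list", length(model$cdata))
    fsum <- 0
    for (ci in seq_along(model$cdata)) {
      info <- contact_evaluate(model$cdata[[ci]], state$cstates[[ci]], x,
                               allowance = allowance, want_tangent = TRUE,
                               frozen_t = frozen[[ci]])
      fc <- fc + info$force
      ct_i <- c(ct_i, info$tangent$i)
      ct_j <- c(ct_j, info$tangent$j)
      ct_x <- c(ct_x, info$tangent$x)
      fsum <- fsum + sum(abs(info$Fn))
      cinfos[[ci]] <- info
    }
    pinfos <- vector("list", length(model$pdata))
    for (pi in seq_along(model$pdata)) {
      pin <- plane_evaluate(model$pdata[[pi]], x, lambda)
      fc <- fc + pin$force
      ct_i <- c(ct_i, pin$dofs)
      ct_j <- c(ct_j, pin$dofs)
      ct_x <- c(ct_x, pin$kdiag)
      fsum <- fsum + pin$total_force
      pinfos[[pi]] <- pin
    }
    r_red <- as.numeric(Matrix::t(sys$T) %*% (fint - fc)) - sys$f_red
    fref <- max(sqrt(sum((Matrix::t(sys$T) %*% fint)^2)),
                sqrt(sum(fc^2)), sqrt(sum(sys$f_red^2)), fsum)
    # net force residual: an L2-small but systematically signed residual
    # spread over many dofs can hide a whole-body force imbalance
    rf <- fint - fc
    rf[sys$fixed] <- 0
    rfm <- matrix(rf, ncol = 3, byrow = TRUE)
    body <- if (is.null(mesh$body)) rep(1L, nrow(rfm)) else mesh$body
    rnet <- max(abs(rowsum(rfm, body))) +
      (if (sys$n_ref > 0) max(abs(r_red[seq_len(sys$n_ref)])) else 0)
    list(r_red = r_red, rn = sqrt(sum(r_red^2)), fref = fref, rnet = rnet,
         ct = list(i = ct_i, j = ct_j, x = ct_x),
         cinfos = cinfos, pinfos = pinfos)
  }

  tol_of <- function(ev) max(abs_tol, rel_tol * ev$fref)
  net_ok <- function(ev) ev$rnet <= max(100 * abs_tol, 4e-3 * ev$fref)
  ev <- tryCatch(eval_resid(u, frozen), error = function(e) e)
  if (inherits(ev, "error")) return(list(converged = FALSE,
                                         resid_hist = resid_hist))
  conv_inner <- FALSE
  best_rn <- Inf
  best_state <- NULL       # best point visited in this increment
  fact <- NULL
  fact_age <- 0L
  rebuild <- TRUE
  for (it in seq_len(max_iter)) {
    iters <- iters + 1L
    if (it %% 3L == 0L) gc(FALSE)   # native sparse workspaces add up
    rn <- ev$rn
    resid_hist <- c(resid_hist, rn)
    if (verbose)
      message(sprintf("  it %2d: |r| = %.3e (net %.3e, ref %.3e)",
                      it, rn, ev$rnet, ev$fref))
    if (rn <= tol_of(ev) && net_ok(ev)) { conv_inner <- TRUE; break }
    if (!is.finite(rn)) break
    if (rn < best_rn) {
      best_rn <- rn
      best_state <- list(q = q, u = u, ev = ev)
    }
    # stagnation window: less than 30% progress over the last 5
    # iterations at a mechanically negligible residual level
    if (it >= 6L &&
        rn > 0.7 * resid_hist[length(resid_hist) - 5L] &&
        rn <= max(50 * abs_tol, 0.015 * ev$fref) &&
        net_ok(ev)) {
      conv_inner <- TRUE
      break
    }
    # modified Newton: reuse the factorised tangent while progress is
    # good; rebuilding and refactorising dominate the iteration cost
    if (is.null(fact) || fact_age >= 4L || rebuild) {
      # single-pass assembly from triplets (linear + hyperelastic +
      # contact) keeps the peak memory of the tangent at one copy
      nh <- if (length(model$nh_rows))
        neo_hookean_tangent(mesh, model$geo, model$ep$K, model$ep$G,
                            model$nh_rows, u)
      else list(i = integer(0), j = integer(0), x = numeric(0))
      Kt <- Matrix::sparseMatrix(
        i = c(model$lin_trip$i, nh$i, ev$ct$i),
        j = c(model$lin_trip$j, nh$j, ev$ct$j),
        x = c(model$lin_trip$x, nh$x, ev$ct$x),
        dims = dim(model$K_lin))
      A <- Matrix::t(sys$T) %*% Kt %*% sys$T
      rm(Kt, nh)
      fact <- NULL
      gc(FALSE)   # release native memory of superseded factors promptly
      fact <- tryCatch(
        if (has_friction) asym_factor(A)
        else reduced_factor(A, regularize = TRUE),
        error = function(e) e)
      if (inherits(fact, "error")) break
      fact_age <- 0L
      rebuild <- FALSE
    }
    dq <- as.numeric(Matrix::solve(fact, -ev$r_red))
    fact_age <- fact_age + 1L
    # clamp the increment to half an element edge so bodies approach
    # contact gradually instead of overshooting through it
    du_max <- max(abs(sys$T %*% dq))
    clamp <- 0.5 * model$mesh$cell_edge
    if (is.finite(du_max) && du_max > clamp) dq <- dq * (clamp / du_max)
    # backtracking line search on the residual norm (active-set changes
    # make full Newton steps overshoot); take the best trial
    alpha <- 1
    best <- NULL
    for (ls in 1:12) {
      q_try <- q + alpha * dq
      u_try <- as.numeric(sys$T %*% q_try) + sys$u0
      ev_try <- tryCatch(eval_resid(u_try, frozen), error = function(e) e)
      if (!inherits(ev_try, "error")) {
        if (is.null(best) || ev_try$rn < best$ev$rn)
          best <- list(q = q_try, u = u_try, ev = ev_try)
        if (ev_try$rn < 0.99 * rn) break
      }
      alpha <- alpha / 2
    }
    if (is.null(best)) break
    # poor progress with a stale factor: force a rebuild next iteration
    if (best$ev$rn > 0.5 * rn && fact_age > 1L) rebuild <- TRUE
    q <- best$q; u <- best$u; ev <- best$ev
  }
  if (!conv_inner) {
    # fall back to the best visited point if it is mechanically negligible
    if (!is.null(best_state) && net_ok(best_state$ev) &&
        best_rn <= max(50 * abs_tol, 0.015 * best_state$ev$fref)) {
      q <- best_state$q; u <- best_state$u; ev <- best_state$ev
      conv_inner <- TRUE
    } else {
      return(list(converged = FALSE, resid_hist = resid_hist))
    }
  }
  # final evaluation at the converged state for reporting/commit
  x <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  cinfos <- vector("list", length(model$cdata))
  for (ci in seq_along(model$cdata)) {
    cinfos[[ci]] <- contact_evaluate(model$cdata[[ci]], state$cstates[[ci]],
                                     x, allowance = allowance,
                                     want_tangent = FALSE, frozen_t = NULL)
    state$cstates[[ci]] <- contact_commit(model$cdata[[ci]],
                                          state$cstates[[ci]], x,
                                          cinfos[[ci]])
  }
  state$u <- u
  state$sys <- sys
  state$cinfos <- cinfos
  state$pinfos <- ev$pinfos
  list(converged = TRUE, state = state, iters = iters,
       resid = utils::tail(resid_hist, 1), resid_hist = resid_hist)
}

finalize_solution <- function(model, state, hist) {
  u <- state$u
  sys <- state$sys
  fint <- internal_force(model, u)
  fc <- numeric(length(u))
  contact_out <- list()
  for (ci in seq_along(model$cdata)) {
    info <- state$cinfos[[ci]]
    fc <- fc + info$force
    cd <- model$cdata[[ci]]
    contact_out[[cd$pair$name]] <- list(
      slave_nodes = cd$slave_nodes,
      active = info$active,
      Fn = info$Fn,
      pressure = ifelse(cd$slave_area > 0, info$Fn / cd$slave_area, 0),
      t_vec = info$t_vec,
      tri = info$projection$tri,
      bary = info$projection$bary,
      total_normal_force = colSums(info$projection$normal * info$Fn),
      master_tri_force = {
        agg <- rowsum(info$Fn, info$projection$tri)
        data.frame(tri = as.integer(rownames(agg)), Fn = as.numeric(agg))
      })
  }
  planes_out <- list()
  for (pi in seq_along(model$pdata)) {
    pin <- state$pinfos[[pi]]
    fc <- fc + pin$force
    planes_out[[model$pdata[[pi]]$rp$name]] <-
      list(total_force = pin$total_force, plane_pos = pin$plane_pos,
           slave_nodes = model$pdata[[pi]]$slave_nodes, Fn = pin$Fn,
           active = pin$active)
  }
  structure(list(
    u = matrix(u, ncol = 3, byrow = TRUE),
    u_vec = u,
    reactions = constraint_reactions(sys, fint - fc),
    contact = contact_out,
    planes = planes_out,
    state = state,
    diagnostics = list(converged = TRUE, history = hist)
  ), class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat("<solution_state>",
      if (isTRUE(x$diagnostics$converged)) "converged" else "NOT converged",
      "\n")
  for (nm in names(x$reactions))
    cat(sprintf("  reaction[%s]: F = (%.4g, %.4g, %.4g) N\n", nm,
                x$reactions[[nm]]$force[1], x$reactions[[nm]]$force[2],
                x$reactions[[nm]]$force[3]))
  invisible(x)
}

#' Apply a kinematic coupling and return the constraint
#'
#' Convenience wrapper mirroring the platen loading setup: couples `patch`
#' to `ref_point` and prescribes or loads the reference DOFs.
#'
#' @inheritParams kinematic_coupling
#' @param mesh a `tet_mesh` (used to validate the patch).
#' @return an `fe_constraint`.
#' @export
apply_kinematic_coupling <- function(mesh, patch, ref_point,
                                     displacement = c(NA, NA, NA),
                                     rotation = c(0, 0, 0),
                                     force = c(0, 0, 0), moment = c(0, 0, 0),
                                     name = "coupling") {
  nds <- patch_nodes(mesh, patch)
  r <- sweep(mesh$nodes[nds, , drop = FALSE], 2, as.numeric(ref_point))
  if (max(sqrt(rowSums(r^2))) < 1e-12)
    stop("coupling patch is degenerate (zero extent) at the reference point")
  kinematic_coupling(patch, ref_point, displacement, rotation, force,
                     moment, name)
}
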