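#' Encastre (fully fixed) constraint
#'
#' @param patch patch name whose nodes are fixed, or `NULL` with explicit
#'   `nodes`.
#' @param nodes optional integer node ids.
#' @param name constraint name (reactions are reported under it).
#' @return constraint spec of class `fe_constraint`.
#' @export
encastre <- function(patch = NULL, nodes = NULL, name = "encastre") {
  if (is.null(patch) && is.null(nodes))
    stop("encastre needs a patch name or node ids")
  structure(list(kind = "encastre", patch = patch, nodes = nodes,
                 name = name), class = "fe_constraint")
}

#' Kinematic coupling to a reference point
#'
#' Ties every node of a surface patch rigidly to a 6-DOF reference point.
#' Each reference DOF is either prescribed (finite value, scaled by the
#' load factor during stepping) or free with an applied load. Prescribed
#' rotations are applied as exact rigid rotations (Rodrigues) about the
#' reference point; free rotation DOFs use linearised lever arms, adequate
#' for the small rotations of quasi-static platen loading.
#'
#' @param patch coupled patch name.
#' @param ref_point reference point, mm.
#' @param displacement length-3; numbers = prescribed (mm), `NA` = free.
#' @param rotation length-3 rotation vector entries; numbers = prescribed
#'   (radians), `NA` = free.
#' @param force,moment loads applied on free DOFs (N, N mm), scaled by the
#'   load factor.
#' @param name constraint name.
#' @return constraint spec of class `fe_constraint`.
#' @export
kinematic_coupling <- function(patch, ref_point,
                               displacement = c(NA, NA, NA),
                               rotation = c(0, 0, 0),
                               force = c(0, 0, 0), moment = c(0, 0, 0),
                               name = "coupling") {
  structure(list(kind = "coupling", patch = patch,
                 ref_point = as.numeric(ref_point),
                 displacement = displacement, rotation = rotation,
                 force = force, moment = moment, name = name),
            class = "fe_constraint")
}

#' Prescribed nodal displacements
#' @param nodes integer node ids.
#' @param u length-3 displacement; `NA` components stay free.
#' @param name constraint name.
#' @return constraint spec of class `fe_constraint`.
#' @export
prescribed_nodes <- function(nodes, u, name = "prescribed") {
  structure(list(kind = "prescribed", nodes = nodes, u = u, name = name),
            class = "fe_constraint")
}

patch_nodes <- function(mesh, patch) {
  p <- mesh$patches[[patch]]
  if (is.null(p)) stop("no patch named ", patch)
  sort(unique(as.vector(p$tri)))
}

rodrigues <- function(theta) {
  ang <- sqrt(sum(theta^2))
  if (ang < 1e-14) return(diag(3))
  k <- theta / ang
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(ang) * Kx + (1 - cos(ang)) * (Kx %*% Kx)
}

# Build the reduction of the full nodal system under the constraint set at
# load factor `lambda`:
#   u_full = T q + u0(lambda),  f_ext_full/reduced loads as given.
# Returns T (3N x nq sparse), u0 (3N), f_red_ext (nq applied loads),
# and bookkeeping to recover reactions.
build_constraint_system <- function(mesh, constraints, lambda = 1) {
  N <- nrow(mesh$nodes)
  ndof <- 3L * N
  u0 <- numeric(ndof)
  fixed <- logical(ndof)     # dofs with known motion (incl. slaved)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  q_count <- 0L
  ref_loads <- list()        # per free ref dof: applied load
  coupling_info <- list()

  # first pass: couplings and prescriptions claim their dofs
  for (ci in seq_along(constraints)) {
    cs <- constraints[[ci]]
    if (cs$kind == "encastre") {
      nds <- if (!is.null(cs$patch)) patch_nodes(mesh, cs$patch) else cs$nodes
      dofs <- as.vector(vapply(1:3, function(i) 3L * (nds - 1L) + i,
                               integer(length(nds))))
      fixed[dofs] <- TRUE
      coupling_info[[ci]] <- list(kind = "encastre", nodes = nds,
                                  name = cs$name)
    } else if (cs$kind == "prescribed") {
      for (i in 1:3) {
        if (!is.na(cs$u[i])) {
          dofs <- 3L * (cs$nodes - 1L) + i
          fixed[dofs] <- TRUE
          u0[dofs] <- cs$u[i] * lambda
        }
      }
      coupling_info[[ci]] <- list(kind = "prescribed", nodes = cs$nodes,
                                  name = cs$name)
    } else if (cs$kind == "coupling") {
      nds <- patch_nodes(mesh, cs$patch)
      r <- sweep(mesh$nodes[nds, , drop = FALSE], 2, cs$ref_point)
      if (nrow(r) == 0 || max(sqrt(rowSums(r^2))) < 1e-12)
        stop("kinematic coupling patch degenerate at the reference point")
      dofs_all <- cbind(3L * (nds - 1L) + 1L, 3L * (nds - 1L) + 2L,
                        3L * (nds - 1L) + 3L)
      fixed[as.vector(dofs_all)] <- TRUE
      # prescribed part: translation + exact rotation
      th <- ifelse(is.na(cs$rotation), 0, cs$rotation) * lambda
      tr <- ifelse(is.na(cs$displacement), 0, cs$displacement) * lambda
      R <- rodrigues(th)
      up <- sweep(r %*% t(R) - r, 2, tr, "+")
      for (i in 1:3) u0[dofs_all[, i]] <- up[, i]
      r_rot <- r %*% t(R)    # lever arms in the rotated configuration
      free_t <- which(is.na(cs$displacement))
      free_r <- which(is.na(cs$rotation))
      qids <- integer(6); qids[] <- NA_integer_
      for (d in free_t) {
        q_count <- q_count + 1L
        qids[d] <- q_count
        trip_i[[length(trip_i) + 1L]] <- dofs_all[, d]
        trip_j[[length(trip_j) + 1L]] <- rep(q_count, length(nds))
        trip_x[[length(trip_x) + 1L]] <- rep(1, length(nds))
        ref_loads[[q_count]] <- cs$force[d]
      }
      for (d in free_r) {
        q_count <- q_count + 1L
        qids[3L + d] <- q_count
        ed <- c(0, 0, 0); ed[d] <- 1
        lv <- cbind(ed[2] * r_rot[, 3] - ed[3] * r_rot[, 2],
                    ed[3] * r_rot[, 1] - ed[1] * r_rot[, 3],
                    ed[1] * r_rot[, 2] - ed[2] * r_rot[, 1])
        for (i in 1:3) {
          trip_i[[length(trip_i) + 1L]] <- dofs_all[, i]
          trip_j[[length(trip_j) + 1L]] <- rep(q_count, length(nds))
          trip_x[[length(trip_x) + 1L]] <- lv[, i]
        }
        ref_loads[[q_count]] <- cs$moment[d]
      }
      coupling_info[[ci]] <- list(kind = "coupling", nodes = nds,
                                  dofs_all = dofs_all, r = r, r_rot = r_rot,
                                  qids = qids, name = cs$name)
    }
  }

  # second pass: remaining free nodal dofs map one-to-one
  free_dofs <- which(!fixed)
  nq_nodal <- length(free_dofs)
  qi <- q_count + seq_len(nq_nodal)
  Tmat <- Matrix::sparseMatrix(
    i = c(unlist(trip_i), free_dofs),
    j = c(unlist(trip_j), qi),
    x = c(unlist(trip_x), rep(1, nq_nodal)),
    dims = c(ndof, q_count + nq_nodal))
  f_red <- numeric(q_count + nq_nodal)
  if (q_count > 0)
    f_red[seq_len(q_count)] <- unlist(ref_loads) * lambda
  list(T = Tmat, u0 = u0, f_red = f_red, nq = q_count + nq_nodal,
       n_ref = q_count, fixed = fixed, info = coupling_info)
}

# reactions per constraint from the full residual vector (f_int - f_ext):
# encastre/prescribed -> summed nodal force; coupling -> force and moment
# at the reference point
constraint_reactions <- function(sys, resid_full) {
  out <- list()
  for (ci in seq_along(sys$info)) {
    info <- sys$info[[ci]]
    if (is.null(info)) next
    nds <- info$nodes
    Fm <- cbind(resid_full[3 * (nds - 1) + 1],
                resid_full[3 * (nds - 1) + 2],
                resid_full[3 * (nds - 1) + 3])
    force <- colSums(Fm)
    res <- list(force = force)
    if (info$kind == "coupling") {
      r <- info$r_rot
      res$moment <- c(sum(r[, 2] * Fm[, 3] - r[, 3] * Fm[, 2]),
                      sum(r[, 3] * Fm[, 1] - r[, 1] * Fm[, 3]),
                      sum(r[, 1] * Fm[, 2] - r[, 2] * Fm[, 1]))
    }
    out[[info$name]] <- res
  }
  out
}
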