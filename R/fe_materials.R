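#' Region material assignments
#'
#' Maps mesh region labels to constitutive models. Three kinds are
#' supported: `linear_elastic` (E in MPa, Poisson ratio nu),
#' `neo_hookean` (compressible, bulk modulus K and shear modulus G in MPa,
#' strain energy `W = G/2 (Ibar1 - 3) + K/2 (J - 1)^2`), and `mapped`
#' (linear elastic with per-element E from the density mapping, shared nu).
#' Units are N-mm-MPa throughout.
#'
#' @param ... named region entries, each a list with a `kind` field.
#' @return named list of class `region_materials`.
#' @examples
#' mats <- region_materials(
#'   bone = list(kind = "mapped", nu = 0.3),
#'   cartilage = list(kind = "neo_hookean", K = 16.67, G = 1.37)
#' )
#' @export
region_materials <- function(...) {
  out <- list(...)
  for (nm in names(out)) {
    m <- out[[nm]]
    if (!m$kind %in% c("linear_elastic", "neo_hookean", "mapped"))
      stop("unknown material kind for region ", nm, ": ", m$kind)
    if (m$kind == "linear_elastic" &&
        (m$E <= 0 || m$nu <= 0 || m$nu >= 0.5))
      stop("linear_elastic needs E > 0 and 0 < nu < 0.5 (region ", nm, ")")
    if (m$kind == "neo_hookean" && (m$K <= 0 || m$G <= 0))
      stop("neo_hookean needs K > 0 and G > 0 (region ", nm, ")")
  }
  structure(out, class = "region_materials")
}

#' Linearise hyperelastic materials
#'
#' Replaces every neo-Hookean entry by its small-strain equivalent linear
#' elastic material (`E = 9KG/(3K+G)`, `nu = (3K-2G)/(6K+2G)`). Useful
#' where cartilage strains stay small and the constant tangent makes the
#' contact solver substantially faster (e.g. the friction-calibration
#' sweeps).
#'
#' @param materials a [region_materials()].
#' @return a [region_materials()] with no neo-Hookean entries.
#' @export
linearised_materials <- function(materials = default_materials()) {
  for (nm in names(materials)) {
    m <- materials[[nm]]
    if (m$kind == "neo_hookean") {
      materials[[nm]] <- list(kind = "linear_elastic",
                              E = 9 * m$K * m$G / (3 * m$K + m$G),
                              nu = (3 * m$K - 2 * m$G) / (6 * m$K + 2 * m$G))
    }
  }
  materials
}

#' Default material set
#'
#' Density-mapped linear elastic bone (nu = 0.3), compressible neo-Hookean
#' cartilage with K = 16.67 MPa and G = 1.37 MPa, PMMA at E = 2450 MPa /
#' nu = 0.3, and stainless-steel pins at E = 193 GPa / nu = 0.3.
#'
#' @return a [region_materials()] covering the standard region labels.
#' @export
default_materials <- function() {
  region_materials(
    bone = list(kind = "mapped", nu = 0.3),
    graft_bone = list(kind = "mapped", nu = 0.3),
    cartilage = list(kind = "neo_hookean", K = 16.67, G = 1.37),
    graft_cartilage = list(kind = "neo_hookean", K = 16.67, G = 1.37),
    pmma = list(kind = "linear_elastic", E = 2450, nu = 0.3),
    pin = list(kind = "linear_elastic", E = 193000, nu = 0.3)
  )
}

# per-element reference geometry: shape-function gradients (4 x 3 per
# element, stored as a list of 12 vectors) and volumes
element_geometry <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elements
  x1 <- nd[el[, 1], , drop = FALSE]
  e1 <- nd[el[, 2], , drop = FALSE] - x1
  e2 <- nd[el[, 3], , drop = FALSE] - x1
  e3 <- nd[el[, 4], , drop = FALSE] - x1
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  if (any(det <= 0)) stop("element(s) with non-positive volume: ",
                          paste(utils::head(which(det <= 0), 5), collapse = ", "))
  V <- det / 6
  # D has columns (e1, e2, e3); rows of D^{-1} are the reciprocal vectors
  # (e2 x e3)/det, (e3 x e1)/det, (e1 x e2)/det, and grad N_{a+1} = row a
  cross3 <- function(p, q) {
    cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
          p[, 3] * q[, 1] - p[, 1] * q[, 3],
          p[, 1] * q[, 2] - p[, 2] * q[, 1])
  }
  inv <- array(0, dim = c(nrow(el), 3, 3))
  inv[, 1, ] <- cross3(e2, e3) / det
  inv[, 2, ] <- cross3(e3, e1) / det
  inv[, 3, ] <- cross3(e1, e2) / det
  gradN <- array(0, dim = c(nrow(el), 4, 3))
  gradN[, 2, ] <- inv[, 1, ]
  gradN[, 3, ] <- inv[, 2, ]
  gradN[, 4, ] <- inv[, 3, ]
  gradN[, 1, ] <- -(inv[, 1, ] + inv[, 2, ] + inv[, 3, ])
  list(gradN = gradN, V = V)
}

# per-element E and nu for linear/mapped regions; NA rows for neo-Hookean
element_elastic_params <- function(mesh, materials) {
  m <- nrow(mesh$elements)
  E <- rep(NA_real_, m); nu <- rep(NA_real_, m)
  nh <- rep(FALSE, m); K <- rep(NA_real_, m); G <- rep(NA_real_, m)
  for (reg in unique(mesh$region)) {
    mat <- materials[[reg]]
    if (is.null(mat)) stop("no material assigned to region ", reg)
    rows <- mesh$region == reg
    if (mat$kind == "linear_elastic") {
      E[rows] <- mat$E; nu[rows] <- mat$nu
    } else if (mat$kind == "mapped") {
      if (anyNA(mesh$E[rows]))
        stop("region ", reg, " is density-mapped but per-element E is ",
             "missing; run assign_element_moduli() first")
      E[rows] <- mesh$E[rows]; nu[rows] <- mat$nu
    } else {
      nh[rows] <- TRUE; K[rows] <- mat$K; G[rows] <- mat$G
    }
  }
  list(E = E, nu = nu, nh = nh, K = K, G = G)
}

# sparse stiffness for all linear(-ised) elastic elements, vectorised over
# elements via the isotropic kernel
# K[ai, bj] = V (lambda gNa_i gNb_j + mu gNa_j gNb_i + mu d_ij gNa.gNb)
assemble_linear_stiffness <- function(mesh, geo, E, nu, rows_sel) {
  el <- mesh$elements[rows_sel, , drop = FALSE]
  gN <- geo$gradN[rows_sel, , , drop = FALSE]
  V <- geo$V[rows_sel]
  Ee <- E[rows_sel]; nue <- nu[rows_sel]
  lam <- Ee * nue / ((1 + nue) * (1 - 2 * nue))
  mu <- Ee / (2 * (1 + nue))
  nel <- nrow(el)
  ntrip <- nel * 144L
  ii <- integer(ntrip); jj <- integer(ntrip); xx <- numeric(ntrip)
  pos <- 0L
  dots <- array(0, dim = c(nel, 4, 4))
  for (a in 1:4) for (b in 1:4)
    dots[, a, b] <- gN[, a, 1] * gN[, b, 1] + gN[, a, 2] * gN[, b, 2] +
                    gN[, a, 3] * gN[, b, 3]
  for (a in 1:4) for (b in 1:4) for (i in 1:3) for (j in 1:3) {
    val <- V * (lam * gN[, a, i] * gN[, b, j] + mu * gN[, a, j] * gN[, b, i] +
                  (if (i == j) mu * dots[, a, b] else 0))
    rng <- pos + seq_len(nel)
    ii[rng] <- 3L * (el[, a] - 1L) + i
    jj[rng] <- 3L * (el[, b] - 1L) + j
    xx[rng] <- val
    pos <- pos + nel
  }
  list(i = ii, j = jj, x = xx,
       M = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(3L * nrow(mesh$nodes),
                                         3L * nrow(mesh$nodes))))
}

# internal nodal forces of neo-Hookean elements at displacement u (3N vec);
# vectorised over the selected elements. Returns triplets (dof, force).
neo_hookean_forces <- function(mesh, geo, K, G, rows_sel, u) {
  el <- mesh$elements[rows_sel, , drop = FALSE]
  gN <- geo$gradN[rows_sel, , , drop = FALSE]
  V <- geo$V[rows_sel]
  Ke <- K[rows_sel]; Ge <- G[rows_sel]
  nel <- nrow(el)
  U <- array(0, dim = c(nel, 4, 3))
  for (a in 1:4) for (i in 1:3) U[, a, i] <- u[3 * (el[, a] - 1) + i]
  nh_force_from_U(U, gN, V, Ke, Ge, el)
}

# core: forces given nodal displacements U [nel,4,3]
nh_force_from_U <- function(U, gN, V, Ke, Ge, el) {
  nel <- dim(U)[1]
  FF <- array(0, dim = c(nel, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (a in 1:4) s <- s + U[, a, i] * gN[, a, j]
    FF[, i, j] <- s + (i == j)
  }
  J <- FF[, 1, 1] * (FF[, 2, 2] * FF[, 3, 3] - FF[, 2, 3] * FF[, 3, 2]) -
       FF[, 1, 2] * (FF[, 2, 1] * FF[, 3, 3] - FF[, 2, 3] * FF[, 3, 1]) +
       FF[, 1, 3] * (FF[, 2, 1] * FF[, 3, 2] - FF[, 2, 2] * FF[, 3, 1])
  if (any(J <= 0))
    stop("element inversion in neo-Hookean region (", sum(J <= 0),
         " element(s))")
  # F^{-T} via adjugate: (F^{-1})_{ij} = cof(F)_{ji} / J -> F^{-T}_{ij} = cof(F)_{ij}/J
  cof <- array(0, dim = c(nel, 3, 3))
  cof[, 1, 1] <- FF[, 2, 2] * FF[, 3, 3] - FF[, 2, 3] * FF[, 3, 2]
  cof[, 1, 2] <- FF[, 2, 3] * FF[, 3, 1] - FF[, 2, 1] * FF[, 3, 3]
  cof[, 1, 3] <- FF[, 2, 1] * FF[, 3, 2] - FF[, 2, 2] * FF[, 3, 1]
  cof[, 2, 1] <- FF[, 1, 3] * FF[, 3, 2] - FF[, 1, 2] * FF[, 3, 3]
  cof[, 2, 2] <- FF[, 1, 1] * FF[, 3, 3] - FF[, 1, 3] * FF[, 3, 1]
  cof[, 2, 3] <- FF[, 1, 2] * FF[, 3, 1] - FF[, 1, 1] * FF[, 3, 2]
  cof[, 3, 1] <- FF[, 1, 2] * FF[, 2, 3] - FF[, 1, 3] * FF[, 2, 2]
  cof[, 3, 2] <- FF[, 1, 3] * FF[, 2, 1] - FF[, 1, 1] * FF[, 2, 3]
  cof[, 3, 3] <- FF[, 1, 1] * FF[, 2, 2] - FF[, 1, 2] * FF[, 2, 1]
  I1 <- FF[, 1, 1]^2 + FF[, 1, 2]^2 + FF[, 1, 3]^2 +
        FF[, 2, 1]^2 + FF[, 2, 2]^2 + FF[, 2, 3]^2 +
        FF[, 3, 1]^2 + FF[, 3, 2]^2 + FF[, 3, 3]^2
  Jm23 <- J^(-2 / 3)
  P <- array(0, dim = c(nel, 3, 3))
  FinvT <- cof / array(J, dim = c(nel, 3, 3))
  for (i in 1:3) for (j in 1:3)
    P[, i, j] <- Ge * Jm23 * (FF[, i, j] - I1 / 3 * FinvT[, i, j]) +
                 Ke * (J - 1) * J * FinvT[, i, j]
  f <- array(0, dim = c(nel, 4, 3))
  for (a in 1:4) for (i in 1:3)
    f[, a, i] <- V * (P[, i, 1] * gN[, a, 1] + P[, i, 2] * gN[, a, 2] +
                        P[, i, 3] * gN[, a, 3])
  f
}

# accumulate element force array [nel,4,3] into a global 3N force vector
scatter_forces <- function(f, el, ndof) {
  idx <- as.vector(vapply(1:3, function(i) 3L * (el - 1L) + i,
                          matrix(0L, nrow(el), 4)))
  val <- as.vector(f)   # [nel, a, i] matches idx ordering (e, a, i)
  out <- numeric(ndof)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# numeric tangent of the neo-Hookean elements (forward differences on the
# 12 element dofs, vectorised across elements); returns a sparse matrix
neo_hookean_tangent <- function(mesh, geo, K, G, rows_sel, u, h = 1e-7) {
  el <- mesh$elements[rows_sel, , drop = FALSE]
  gN <- geo$gradN[rows_sel, , , drop = FALSE]
  V <- geo$V[rows_sel]
  Ke <- K[rows_sel]; Ge <- G[rows_sel]
  nel <- nrow(el)
  U <- array(0, dim = c(nel, 4, 3))
  for (a in 1:4) for (i in 1:3) U[, a, i] <- u[3 * (el[, a] - 1) + i]
  f0 <- nh_force_from_U(U, gN, V, Ke, Ge, el)
  scale <- max(1, max(abs(u)))
  hh <- h * scale
  nt <- nel * 144L
  ii <- integer(nt); jj <- integer(nt); xx <- numeric(nt)
  pos <- 0L
  for (b in 1:4) for (j in 1:3) {
    Up <- U
    Up[, b, j] <- Up[, b, j] + hh
    fp <- nh_force_from_U(Up, gN, V, Ke, Ge, el)
    dK <- (fp - f0) / hh            # [nel, 4, 3] = dF_{a i}/du_{b j}
    for (a in 1:4) for (i in 1:3) {
      rng <- pos + seq_len(nel)
      ii[rng] <- 3L * (el[, a] - 1L) + i
      jj[rng] <- 3L * (el[, b] - 1L) + j
      xx[rng] <- dK[, a, i]
      pos <- pos + nel
    }
  }
  # triplets only; the solver assembles one combined tangent (the slight
  # forward-difference asymmetry is handled by the factorisation path)
  list(i = ii, j = jj, x = xx)
}
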