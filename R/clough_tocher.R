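# Reduced Hsieh-Clough-Tocher (HCT) C1 piecewise-cubic interpolation on a
# regular grid.
#
# Each grid cell is split into two triangles; each triangle is split at its
# centroid into three cubic Bezier mini-patches. The element interpolates
# values and gradients at the triangle vertices and enforces C1 continuity
# across all edges, with the "reduced" closure that the normal derivative
# varies linearly along the outer edges. Vertex gradients are estimated by
# finite differences (central in the interior, one-sided at the boundary),
# which makes the whole interpolant a fixed linear operator on the grid
# values: it is assembled once per (grid, target) pair and cached, so
# interpolating a frame is a single matrix-vector product.
#
# The element reproduces linear polynomials exactly (the gradient stencils
# are linear-precise) and reproduces grid values at the nodes by
# construction.

# Bezier index triples (i, j, k), i + j + k = 3, in a fixed order.
.ct_idx <- local({
  m <- NULL
  for (i in 3:0) for (j in (3 - i):0) {
    m <- rbind(m, c(i, j, 3L - i - j))
  }
  m
})

.ct_pos <- function(i, j, k) which(.ct_idx[, 1] == i & .ct_idx[, 2] == j &
                                   .ct_idx[, 3] == k)

# Solve for the 30 x 9 map from (f1..3, g1r, g1c, g2r, g2c, g3r, g3c) to the
# 3 x 10 Bezier coefficients of the centroid-split patches of one triangle.
# P is a 3 x 2 matrix of vertex (row, col) coordinates.
.ct_patch_map <- function(P) {
  V0 <- colMeans(P)
  np <- 10L
  nu <- 3L * np           # unknown coefficients, patch-major
  coefi <- function(patch, i, j, k) (patch - 1L) * np + .ct_pos(i, j, k)
  E <- NULL; Fm <- NULL
  add <- function(erow, frow) {
    E <<- rbind(E, erow); Fm <<- rbind(Fm, frow)
  }
  fidx <- function(v) v                    # f_v is data column v
  gidx <- function(v) 3L + (v - 1L) * 2L   # +1 = d/drow, +2 = d/dcol

  verts <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))  # (A_k, B_k) per patch
  for (k in 1:3) {
    A <- verts[k, 1]; B <- verts[k, 2]
    PA <- P[A, ]; PB <- P[B, ]
    # corner values
    e <- numeric(nu); e[coefi(k, 3, 0, 0)] <- 1
    f <- numeric(9); f[fidx(A)] <- 1; add(e, f)
    e <- numeric(nu); e[coefi(k, 0, 3, 0)] <- 1
    f <- numeric(9); f[fidx(B)] <- 1; add(e, f)
    # corner gradients: b210 = fA + (PB-PA).gA/3 etc.
    grad_con <- function(ci, corner, dirvec) {
      e <- numeric(nu); e[ci] <- 1
      f <- numeric(9); f[fidx(corner)] <- 1
      f[gidx(corner) + 1L] <- dirvec[1] / 3
      f[gidx(corner) + 2L] <- dirvec[2] / 3
      add(e, f)
    }
    grad_con(coefi(k, 2, 1, 0), A, PB - PA)
    grad_con(coefi(k, 2, 0, 1), A, V0 - PA)
    grad_con(coefi(k, 1, 2, 0), B, PA - PB)
    grad_con(coefi(k, 0, 2, 1), B, V0 - PB)
  }
  # C0 across interior edges (B_k -- V0), shared with patch k+1
  for (k in 1:3) {
    k2 <- k %% 3L + 1L
    for (jj in list(c(0, 3, 0, 3, 0, 0), c(0, 2, 1, 2, 0, 1),
                    c(0, 1, 2, 1, 0, 2), c(0, 0, 3, 0, 0, 3))) {
      e <- numeric(nu)
      e[coefi(k, jj[1], jj[2], jj[3])] <- 1
      e[coefi(k2, jj[4], jj[5], jj[6])] <- e[coefi(k2, jj[4], jj[5], jj[6])] - 1
      add(e, numeric(9))
    }
  }
  # C1 across interior edges: with the centroid split, C = 3*V0 - A - B gives
  # barycentric weights (alpha, beta, gamma) = (-1, 3, -1) w.r.t.
  # (B_k, V0, A_k).  For i + j = 2:
  #   b^{k+1}_{i,1,j} = -b^k_{0,i+1,j} + 3 b^k_{0,i,j+1} - b^k_{1,i,j}
  for (k in 1:3) {
    k2 <- k %% 3L + 1L
    for (ij in list(c(2, 0), c(1, 1), c(0, 2))) {
      i <- ij[1]; j <- ij[2]
      e <- numeric(nu)
      e[coefi(k2, i, 1, j)] <- 1
      e[coefi(k, 0, i + 1, j)] <- e[coefi(k, 0, i + 1, j)] + 1
      e[coefi(k, 0, i, j + 1)] <- e[coefi(k, 0, i, j + 1)] - 3
      e[coefi(k, 1, i, j)] <- e[coefi(k, 1, i, j)] + 1
      add(e, numeric(9))
    }
  }
  # Reduced closure: normal derivative linear along each outer edge (A,B).
  # Directional derivative coefficients on the edge are the quadratic
  # Bernstein coefficients q0, q1, q2; linearity <=> q1 = (q0 + q2) / 2.
  for (k in 1:3) {
    A <- verts[k, 1]; B <- verts[k, 2]
    PA <- P[A, ]; PB <- P[B, ]
    tang <- PB - PA
    nvec <- c(-tang[2], tang[1])
    # barycentric direction of nvec w.r.t. (PA, PB, V0)
    Mb <- rbind(cbind(PA, PB, V0), 1)
    delta <- solve(Mb, c(nvec, 0))
    e <- numeric(nu)
    acc <- function(i, j, m, w) e[coefi(k, i, j, m)] <<- e[coefi(k, i, j, m)] + w
    # q1 terms (from index (1,1,0)): delta1*b210 + delta2*b120 + delta3*b111
    acc(2, 1, 0, delta[1]); acc(1, 2, 0, delta[2]); acc(1, 1, 1, delta[3])
    # -(q0)/2 from (2,0,0): delta1*b300 + delta2*b210 + delta3*b201
    acc(3, 0, 0, -delta[1] / 2); acc(2, 1, 0, -delta[2] / 2)
    acc(2, 0, 1, -delta[3] / 2)
    # -(q2)/2 from (0,2,0): delta1*b120 + delta2*b030 + delta3*b021
    acc(1, 2, 0, -delta[1] / 2); acc(0, 3, 0, -delta[2] / 2)
    acc(0, 2, 1, -delta[3] / 2)
    add(e, numeric(9))
  }
  # Least-squares solve of the (consistent, over-determined) system E x = F d
  M <- qr.solve(E, Fm)                     # 30 x 9
  resid <- max(abs(E %*% M - Fm))
  if (resid > 1e-8)
    stop("internal error: inconsistent Clough-Tocher constraint system")
  M
}

# Finite-difference gradient stencils for an nr x nc grid with unit spacing,
# as two (nr*nc) x (nr*nc) matrices (d/drow and d/dcol). Linear-precise.
.ct_grad_ops <- function(nr, nc) {
  nn <- nr * nc
  Gr <- matrix(0, nn, nn); Gc <- matrix(0, nn, nn)
  id <- function(r, c) r + (c - 1L) * nr
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    i <- id(r, c)
    if (r == 1L)       { Gr[i, id(2, c)] <- 1;      Gr[i, id(1, c)] <- -1 }
    else if (r == nr)  { Gr[i, id(nr, c)] <- 1;     Gr[i, id(nr - 1, c)] <- -1 }
    else               { Gr[i, id(r + 1, c)] <- .5; Gr[i, id(r - 1, c)] <- -.5 }
    if (c == 1L)       { Gc[i, id(r, 2)] <- 1;      Gc[i, id(r, 1)] <- -1 }
    else if (c == nc)  { Gc[i, id(r, nc)] <- 1;     Gc[i, id(r, nc - 1)] <- -1 }
    else               { Gc[i, id(r, c + 1)] <- .5; Gc[i, id(r, c - 1)] <- -.5 }
  }
  list(Gr = Gr, Gc = Gc)
}

# Bernstein cubic weights for barycentric (s1, s2, s3), in .ct_idx order.
.ct_bernstein <- function(s) {
  i <- .ct_idx[, 1]; j <- .ct_idx[, 2]; k <- .ct_idx[, 3]
  factorial(3) / (factorial(i) * factorial(j) * factorial(k)) *
    s[1]^i * s[2]^j * s[3]^k
}

.ct_cache <- new.env(parent = emptyenv())

#' Linear operator performing Clough-Tocher interpolation of a grid
#'
#' Builds (and caches) the dense matrix that maps values on an
#' `nr x nc` unit-spaced grid to their reduced Hsieh-Clough-Tocher
#' interpolant evaluated on a uniform `nx x ny` target lattice spanning
#' the grid extent: `nx` points along the column axis over `[1, nc]` and
#' `ny` points along the row axis over `[1, nr]`.
#'
#' @param nr,nc source grid rows and columns.
#' @param nx,ny target lattice sizes along the column (x) and row (y) axes.
#' @return A `(nx * ny) x (nr * nc)` matrix `A`; for a source matrix `V`,
#'   `matrix(A %*% as.vector(V), nx, ny)[i, j]` is the interpolant at
#'   `(row = yj, col = xi)`.
#' @keywords internal
ct_operator <- function(nr, nc, nx, ny) {
  key <- paste(nr, nc, nx, ny, sep = "_")
  if (!is.null(.ct_cache[[key]])) return(.ct_cache[[key]])
  nn <- nr * nc
  G <- .ct_grad_ops(nr, nc)
  # the two congruent triangle shapes of a unit cell, by local offsets
  # lower: (0,0), (1,0), (0,1); upper: (1,0), (1,1), (0,1)
  shapes <- list(lower = rbind(c(0, 0), c(1, 0), c(0, 1)),
                 upper = rbind(c(1, 0), c(1, 1), c(0, 1)))
  maps <- lapply(shapes, .ct_patch_map)
  xs <- seq(1, nc, length.out = nx)
  ys <- seq(1, nr, length.out = ny)
  A <- matrix(0, nx * ny, nn)
  id <- function(r, c) r + (c - 1L) * nr
  for (j in seq_len(ny)) {
    yr <- ys[j]
    r0 <- min(floor(yr), nr - 1L); fr <- yr - r0
    for (i in seq_len(nx)) {
      xc <- xs[i]
      c0 <- min(floor(xc), nc - 1L); fc <- xc - c0
      lower <- (fr + fc) <= 1
      sh <- if (lower) "lower" else "upper"
      off <- shapes[[sh]]
      Pv <- cbind(off[, 1] + r0, off[, 2] + c0)   # vertex (row, col)
      nodes <- id(Pv[, 1], Pv[, 2])
      # macro barycentric coordinates of (fr, fc) w.r.t. local offsets
      Mb <- rbind(t(off), 1)
      u <- solve(Mb, c(fr, fc, 1))
      # mini patch: the patch (P_k, P_k+1, V0) where u of excluded vertex
      # is the minimum
      kex <- which.min(u)                         # excluded vertex index
      k <- kex %% 3L + 1L                         # patch spanning the others
      kp <- k %% 3L + 1L
      s <- c(u[k] - u[kex], u[kp] - u[kex], 3 * u[kex])
      w <- .ct_bernstein(s)
      Mk <- maps[[sh]][(k - 1L) * 10L + 1:10, , drop = FALSE]
      wd <- as.numeric(crossprod(Mk, w))          # length-9 weights on data
      row <- numeric(nn)
      for (v in 1:3) {
        row[nodes[v]] <- row[nodes[v]] + wd[v]
        gi <- 3L + (v - 1L) * 2L
        row <- row + wd[gi + 1L] * G$Gr[nodes[v], ] +
                     wd[gi + 2L] * G$Gc[nodes[v], ]
      }
      A[i + (j - 1L) * nx, ] <- row
    }
  }
  .ct_cache[[key]] <- A
  A
}
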