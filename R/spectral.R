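## Internal spectral/tridiagonal machinery shared by the pressure projection
## and all implicit (Helmholtz) solves.  The grid is periodic in x and z, so
## second-difference operators diagonalize under the DFT in those axes,
## leaving one small tridiagonal system per (kx, kz) mode along y.

## FFT along dims 1 and 3 of a 3D array
.fft_xz <- function(a, inverse = FALSE) {
  d <- dim(a)
  m <- stats::mvfft(matrix(a, nrow = d[1]), inverse = inverse)
  a <- array(m, d)
  a <- aperm(a, c(3, 2, 1))
  m <- stats::mvfft(matrix(a, nrow = d[3]), inverse = inverse)
  a <- aperm(array(m, c(d[3], d[2], d[1])), c(3, 2, 1))
  if (inverse) a / (d[1] * d[3]) else a
}

## eigenvalues of the periodic central second difference, as an (nx, nz)
## matrix flattened column-major to length nx*nz
.lam_xz <- function(n, h_m) {
  lx <- (2 * cos(2 * pi * (seq_len(n[1]) - 1) / n[1]) - 2) / h_m[1]^2
  lz <- (2 * cos(2 * pi * (seq_len(n[3]) - 1) / n[3]) - 2) / h_m[3]^2
  c(outer(lx, lz, "+"))
}

## Thomas algorithm for N independent tridiagonal systems with a shared
## scalar off-diagonal `off` and diagonals Dg (N x ny, real).  The
## factorization depends only on (Dg, off), which are fixed per solver
## configuration, so it is computed once and cached.
.tri_factor <- function(Dg, off) {
  ny <- ncol(Dg)
  cp <- matrix(0, nrow(Dg), ny)
  minv <- matrix(0, nrow(Dg), ny)
  m <- Dg[, 1]
  minv[, 1] <- 1 / m
  cp[, 1] <- off / m
  if (ny > 1L) {
    for (j in 2:ny) {
      m <- Dg[, j] - off * cp[, j - 1]
      minv[, j] <- 1 / m
      cp[, j] <- off / m
    }
  }
  list(cp = cp, minv = minv, off = off, ny = ny)
}

.tri_apply <- function(fac, R) {
  ny <- fac$ny
  dp <- R
  dp[, 1] <- R[, 1] * fac$minv[, 1]
  if (ny > 1L) {
    for (j in 2:ny) {
      dp[, j] <- (R[, j] - fac$off * dp[, j - 1]) * fac$minv[, j]
    }
    for (j in (ny - 1):1) dp[, j] <- dp[, j] - fac$cp[, j] * dp[, j + 1]
  }
  dp
}

## factorization cache (per solver configuration)
.solver_cache <- new.env(parent = emptyenv())

.cached_factor <- function(key, make_Dg, off) {
  fac <- .solver_cache[[key]]
  if (is.null(fac)) {
    fac <- .tri_factor(make_Dg(), off)
    .solver_cache[[key]] <- fac
  }
  fac
}

## reshape (nx, ny, nz) -> (nx*nz, ny) mode-major matrix and back
.to_modes <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 3, 2)), ncol = d[2])
}
.from_modes <- function(m, d) {
  aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
}

## Solve the pressure Poisson problem  Lxz phi + D2y phi = rhs
## with a Neumann condition at the y = 0 wall (outer wall, fixed v) and a
## homogeneous Dirichlet condition at the y = Ly outlet face.  Nonsingular
## for every mode including (0, 0).
.poisson_solve <- function(rhs, grid) {
  n <- grid$n; h <- grid$parcel_m
  off <- 1 / h[2]^2
  key <- paste("poisson", n[1], n[2], n[3], h[1], h[2], h[3])
  fac <- .cached_factor(key, function() {
    Dg <- matrix(.lam_xz(n, h), nrow = n[1] * n[3], ncol = n[2]) - 2 * off
    Dg[, 1] <- Dg[, 1] + off         # Neumann at outer wall
    Dg[, n[2]] <- Dg[, n[2]] - off   # Dirichlet at outlet face
    Dg
  }, off)
  R <- .to_modes(.fft_xz(rhs))
  X <- .tri_apply(fac, R)
  Re(.fft_xz(.from_modes(X, n), inverse = TRUE))
}

## Solve (1 - c Lap) q = rhs for a field stored cell-centered along y
## (ny_eff rows given by dim(rhs)[2]), with boundary treatments:
##   "neumann"    ghost = adjacent value (zero normal gradient)
##   "wall"       ghost = -adjacent value (no-slip wall at the face)
##   "dirichlet0" boundary value known to be zero (no adjustment)
.helmholtz_solve <- function(rhs, cvisc, grid, ybc_bottom, ybc_top) {
  d <- dim(rhs)
  h <- grid$parcel_m
  off <- -cvisc / h[2]^2
  key <- paste("helm", cvisc, d[1], d[2], d[3], h[1], h[2], h[3],
               ybc_bottom, ybc_top)
  fac <- .cached_factor(key, function() {
    lam <- .lam_xz(c(d[1], 1L, d[3]), h)
    Dg <- matrix(1 - cvisc * lam, nrow = d[1] * d[3], ncol = d[2]) +
      2 * cvisc / h[2]^2
    adj <- function(bc) switch(bc, neumann = -cvisc / h[2]^2,
                               wall = cvisc / h[2]^2,
                               dirichlet0 = 0)
    Dg[, 1] <- Dg[, 1] + adj(ybc_bottom)
    Dg[, d[2]] <- Dg[, d[2]] + adj(ybc_top)
    Dg
  }, off)
  R <- .to_modes(.fft_xz(rhs))
  X <- .tri_apply(fac, R)
  Re(.fft_xz(.from_modes(X, d), inverse = TRUE))
}

## circular shift: out[i] = a[i + s] along `axis` (periodic)
.shiftp <- function(a, axis, s) {
  d <- dim(a)
  idx <- ((seq_len(d[axis]) - 1 + s) %% d[axis]) + 1
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}
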