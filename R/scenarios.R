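## Programmatic generation of every initial condition used in the case
## studies: colony-like placements, random suspensions, two-cell probes,
## floor-attached biofilms, and the metabolic kickstart.  All placements are
## reproducible from (recipe, parameters, seed).

## default cell-cell minimum separation = one cell diameter
.MIN_SEP_UM <- 2 * 0.47

## random-sequential-addition target volume fraction for "densely packed"
## colonies; RSA of equal spheres jams near 0.38, and 0.375 is the fraction
## implied by ~430 cells of 0.436 um^3 per 500 um^3 parcel
.PACK_FRACTION <- 0.35

#' Split a population between the two species (largest-remainder rounding)
#'
#' @param n total cell count.
#' @param ratio length-2 numeric, E. coli : S. enterica (default 1.86:1).
#' @return named integer vector `c(ECOLI = , SENTERICA = )`.
#' @export
split_ratio <- function(n, ratio = c(1.86, 1)) {
  w <- ratio / sum(ratio)
  q <- n * w
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    ord <- order(q - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(fl), c("ECOLI", "SENTERICA"))
}

## interleave species labels randomly at the given counts
.species_labels <- function(counts) {
  sample(rep(names(counts), counts))
}

## random sequential addition of points with minimum separation inside a
## region defined by a sampler function; returns an n x 3 matrix (um)
.rsa_pack <- function(n, sampler, min_sep = .MIN_SEP_UM,
                      max_attempts = 400L * n, context = "packing") {
  pos <- matrix(NA_real_, n, 3)
  got <- 0L
  att <- 0L
  sep2 <- min_sep^2
  while (got < n) {
    att <- att + 1L
    if (att > max_attempts) {
      stop(sprintf("%s: could not place %d cells at separation %.2f um (placed %d); enlarge the region",
                   context, n, min_sep, got))
    }
    p <- sampler()
    if (got > 0L) {
      d2 <- (pos[seq_len(got), 1] - p[1])^2 +
        (pos[seq_len(got), 2] - p[2])^2 +
        (pos[seq_len(got), 3] - p[3])^2
      if (min(d2) < sep2) next
    }
    got <- got + 1L
    pos[got, ] <- p
  }
  pos
}

#' Dense spherical colony
#'
#' Non-overlapping positions inside the minimal sphere holding `n` cells at
#' the random-packing volume fraction, species randomly interleaved at the
#' requested ratio.
#'
#' @param n total cell count.
#' @param ratio length-2 numeric E. coli : S. enterica split.
#' @param center colony center, um (default: domain center).
#' @param grid a [grid_spec()].
#' @param params species parameter list (cell volumes).
#' @return list `species` (character), `position` (n x 3, um),
#'   `radius` (colony radius, um).
#' @export
place_dense_sphere <- function(n, ratio = c(1.86, 1), center = NULL,
                               grid = grid_spec(), params = default_species()) {
  if (is.null(center)) center <- grid$extent_um / 2
  V_cell <- params[[1]]$V_cell
  R <- (3 * n * V_cell / (4 * pi * .PACK_FRACTION))^(1 / 3)
  sampler <- function() {
    repeat {
      p <- stats::runif(3, -R, R)
      if (sum(p^2) <= R^2) return(center + p)
    }
  }
  pos <- .rsa_pack(n, sampler, context = "place_dense_sphere")
  list(species = .species_labels(split_ratio(n, ratio)), position = pos,
       radius = R)
}

#' Spherical-Gaussian colony
#'
#' Isotropic Gaussian scatter of cells about a center, overlap-resolved by
#' rejection.  `sigma` defaults to twice the dense-colony radius for the
#' same `n` (loose aggregate).
#'
#' @inheritParams place_dense_sphere
#' @param sigma radial standard deviation, um.
#' @return list `species`, `position`, `sigma`.
#' @export
place_gaussian_sphere <- function(n, ratio = c(1.86, 1), center = NULL,
                                  sigma = NULL, grid = grid_spec(),
                                  params = default_species()) {
  if (is.null(center)) center <- grid$extent_um / 2
  if (is.null(sigma)) {
    V_cell <- params[[1]]$V_cell
    sigma <- 2 * (3 * n * V_cell / (4 * pi * .PACK_FRACTION))^(1 / 3)
  }
  if (sigma <= 0) {
    return(c(place_dense_sphere(n, ratio, center, grid, params),
             list(sigma = 0)))
  }
  rmax <- params[[1]]$r_um
  sampler <- function() {
    repeat {
      p <- center + stats::rnorm(3, 0, sigma)
      p[1] <- p[1] %% grid$extent_um[1]
      p[3] <- p[3] %% grid$extent_um[3]
      if (p[2] >= rmax && p[2] <= grid$extent_um[2] - rmax) return(p)
    }
  }
  pos <- .rsa_pack(n, sampler, context = "place_gaussian_sphere")
  list(species = .species_labels(split_ratio(n, ratio)), position = pos,
       sigma = sigma)
}

#' Uniform random suspension
#'
#' Uniform positions throughout the domain, overlap-rejected.
#'
#' @inheritParams place_dense_sphere
#' @return list `species`, `position`.
#' @export
place_random_uniform <- function(n, ratio = c(1.86, 1), grid = grid_spec(),
                                 params = default_species()) {
  rmax <- params[[1]]$r_um
  ext <- grid$extent_um
  sampler <- function() {
    c(stats::runif(1, 0, ext[1]),
      stats::runif(1, rmax, ext[2] - rmax),
      stats::runif(1, 0, ext[3]))
  }
  pos <- .rsa_pack(n, sampler, context = "place_random_uniform")
  list(species = .species_labels(split_ratio(n, ratio)), position = pos)
}

## the largest achievable separation under the periodic metric on x/z and
## the half-extent on y: |(Lx/2, Ly/2, Lz/2)| = 217.9 um for the default box
.max_two_cell_sep <- function(grid) sqrt(sum((grid$extent_um / 2)^2))

#' One E. coli and one S. enterica at a prescribed separation
#'
#' Cells are placed symmetrically about the domain center along the box
#' diagonal, giving separations from contact (1 um) up to the maximal
#' separation under the periodic metric (~218 um in the default box).
#'
#' @param distance separation, um.
#' @param grid a [grid_spec()].
#' @return list `species`, `position`.
#' @export
place_two_cells <- function(distance, grid = grid_spec()) {
  dmax <- .max_two_cell_sep(grid)
  if (distance <= 0) stop("place_two_cells: distance must be > 0")
  if (distance > dmax * 1.005) {
    stop(sprintf("place_two_cells: distance %.1f exceeds the maximal separation %.1f um",
                 distance, dmax))
  }
  distance <- min(distance, dmax)
  u <- (grid$extent_um / 2) / dmax
  center <- grid$extent_um / 2
  pos <- rbind(center - distance / 2 * u, center + distance / 2 * u)
  list(species = c("ECOLI", "SENTERICA"), position = pos)
}

#' Two separated single-species Gaussian colonies
#'
#' One colony per species, centers placed symmetrically about the domain
#' center at the requested (default: maximal) separation.
#'
#' @param n1,n2 cell counts for the E. coli and S. enterica colonies.
#' @param distance center-to-center separation, um (default maximal).
#' @param sigma Gaussian radial scatter, um (default per colony size).
#' @param grid a [grid_spec()].
#' @param params species parameter list.
#' @return list `species`, `position`, `centers` (2 x 3).
#' @export
place_separated_colonies <- function(n1, n2, distance = NULL, sigma = NULL,
                                     grid = grid_spec(),
                                     params = default_species()) {
  dmax <- .max_two_cell_sep(grid)
  if (is.null(distance)) distance <- dmax
  if (distance > dmax * 1.005) {
    stop("place_separated_colonies: distance exceeds the maximal separation")
  }
  distance <- min(distance, dmax)
  u <- (grid$extent_um / 2) / dmax
  center <- grid$extent_um / 2
  c1 <- center - distance / 2 * u
  c2 <- center + distance / 2 * u
  g1 <- place_gaussian_sphere(n1, c(1, 0), c1, sigma, grid, params)
  g2 <- place_gaussian_sphere(n2, c(0, 1), c2, sigma, grid, params)
  list(species = c(rep("ECOLI", n1), rep("SENTERICA", n2)),
       position = rbind(g1$position, g2$position),
       centers = rbind(c1, c2))
}

#' Floor-attached biofilm colony
#'
#' A densely packed colony tangent to the floor (the y = 0 outer wall, the
#' "down" direction in 1 g): either a sphere or a one-cell-thick 2D disc.
#'
#' @param shape `"SPHERE"` or `"CIRCLE_2D"`.
#' @inheritParams place_dense_sphere
#' @return list `species`, `position`, `radius` (colony radius, um).
#' @export
place_floor_biofilm <- function(shape = c("SPHERE", "CIRCLE_2D"), n,
                                ratio = c(1.86, 1), grid = grid_spec(),
                                params = default_species()) {
  shape <- match.arg(shape)
  r_cell <- params[[1]]$r_um
  cxz <- grid$extent_um[c(1, 3)] / 2
  if (shape == "SPHERE") {
    V_cell <- params[[1]]$V_cell
    R <- (3 * n * V_cell / (4 * pi * .PACK_FRACTION))^(1 / 3)
    center <- c(cxz[1], R + r_cell, cxz[2])
    sampler <- function() {
      repeat {
        p <- stats::runif(3, -R, R)
        if (sum(p^2) <= R^2) return(center + p)
      }
    }
  } else {
    phi2d <- 0.45
    R <- r_cell * sqrt(n / phi2d)
    center <- c(cxz[1], r_cell, cxz[2])
    sampler <- function() {
      repeat {
        p <- stats::runif(2, -R, R)
        if (sum(p^2) <= R^2) return(center + c(p[1], 0, p[2]))
      }
    }
  }
  pos <- .rsa_pack(n, sampler,
                   context = sprintf("place_floor_biofilm(%s)", shape))
  pos[, 2] <- pmax(pos[, 2], r_cell)
  list(species = .species_labels(split_ratio(n, ratio)), position = pos,
       radius = R)
}

#' Metabolic kickstart
#'
#' Gives every cell an intracellular stock of its own secreted product
#' (E. coli: acetate; S. enterica: methionine), which the film law then
#' releases to the surroundings; this breaks the obligate-mutualism
#' deadlock at inoculation.
#'
#' @param cells a `cell_table`.
#' @param amount cell equivalents of product per cell.
#' @return updated `cell_table`.
#' @export
kickstart <- function(cells, amount) {
  if (amount < 0) stop("kickstart: amount must be >= 0")
  cells$pool_pro <- cells$pool_pro + amount
  cells
}
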