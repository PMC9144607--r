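## Analysis metrics used to summarize runs: relative growth rates, the
## colony gradient-direction diagnostic, and the solid/liquid colony
## transition estimate.

#' Growth rate as a percentage of the maximum
#'
#' `SPECIES` normalizes by the species' own mu_max; `COMBINED` by the sum of
#' the two species' maxima (a community-level normalization).
#'
#' @param mu_bar mean specific growth rate, 1/s.
#' @param species `"ECOLI"` or `"SENTERICA"` (ignored for `COMBINED`).
#' @param normalization `"SPECIES"` or `"COMBINED"`.
#' @param params species parameter list.
#' @return percentage (0-100 scale).
#' @export
percent_of_mu_max <- function(mu_bar, species = "ECOLI",
                              normalization = c("SPECIES", "COMBINED"),
                              params = default_species()) {
  normalization <- match.arg(normalization)
  denom <- if (normalization == "SPECIES") {
    params[[species]]$mu_max
  } else {
    sum(vapply(params, function(p) p$mu_max, numeric(1)))
  }
  100 * mu_bar / denom
}

#' Direction of the radial concentration gradient around a colony
#'
#' Averages the radial derivative of a metabolite field over shells around
#' the colony center.  Negative means concentration falls outward (the
#' colony is a net exporter, a sustainable configuration); positive means a
#' net importer.
#'
#' @param field concentration array.
#' @param center colony center, um.
#' @param grid a [grid_spec()].
#' @param r_range radial range examined, um (default one to six parcels).
#' @param tol derivative magnitude below which the field is called flat.
#' @return -1, 0, or +1; attribute `slope` carries the mean derivative.
#' @export
gradient_direction <- function(field, center, grid = grid_spec(),
                               r_range = c(5, 30), tol = 1e-15) {
  n <- grid$n
  h <- grid$parcel_um
  cx <- (seq_len(n[1]) - 0.5) * h[1]
  cy <- (seq_len(n[2]) - 0.5) * h[2]
  cz <- (seq_len(n[3]) - 0.5) * h[3]
  ## periodic minimal-image distance on x/z
  per <- function(d, L) (d + L / 2) %% L - L / 2
  X <- array(per(cx - center[1], grid$extent_um[1]), n)
  Y <- aperm(array(cy - center[2], c(n[2], n[1], n[3])), c(2, 1, 3))
  Z <- aperm(array(per(cz - center[3], grid$extent_um[3]), c(n[3], n[1], n[2])),
             c(2, 3, 1))
  R <- sqrt(X^2 + Y^2 + Z^2)
  sel <- R >= r_range[1] & R <= r_range[2]
  if (sum(sel) < 8) stop("gradient_direction: radial range too narrow")
  fit <- stats::lm.fit(cbind(1, R[sel]), field[sel])
  slope <- fit$coefficients[2]
  out <- if (abs(slope) < tol) 0 else sign(slope)
  attr(out, "slope") <- unname(slope)
  out
}

#' Solid-liquid colony-size transition
#'
#' Finds the colony size at which the growth-rate curves under biofilm
#' (low) and liquid (high) diffusivity cross, by linear interpolation
#' between tested sizes.
#'
#' @param n_cells vector of tested colony sizes.
#' @param mu_biofilm,mu_liquid matching growth rates under the two
#'   diffusivity regimes.
#' @return the interpolated crossing size, or `NA` (with a message
#'   attribute) if the curves do not cross in range.
#' @export
solid_liquid_transition <- function(n_cells, mu_biofilm, mu_liquid) {
  stopifnot(length(n_cells) == length(mu_biofilm),
            length(n_cells) == length(mu_liquid))
  ord <- order(n_cells)
  n_cells <- n_cells[ord]
  d <- (mu_biofilm - mu_liquid)[ord]
  sg <- sign(d)
  flip <- which(sg[-1] * sg[-length(sg)] < 0)
  if (length(flip) == 0) {
    out <- NA_real_
    attr(out, "message") <- "no crossing in the tested range"
    return(out)
  }
  i <- flip[1]
  ## linear interpolation of the difference zero
  n_cells[i] + (n_cells[i + 1] - n_cells[i]) * d[i] / (d[i] - d[i + 1])
}
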