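#' Ternary solvent composition
#'
#' A water/methanol/chloroform composition in percent, on either a volume
#' (`"volume"`) or weight (`"weight"`) basis. Components must be non-negative
#' and sum to 100 (within 1e-6).
#'
#' @param water,methanol,chloroform Component percentages.
#' @param basis `"volume"` or `"weight"`.
#' @return Object of class `ternary_composition`.
#' @examples
#' ternary_composition(30, 40, 30)
#' @export
ternary_composition <- function(water, methanol, chloroform,
                                basis = c("volume", "weight")) {
  basis <- match.arg(basis)
  v <- c(water, methanol, chloroform)
  if (any(!is.finite(v)) || any(v < 0))
    .stopf("composition components must be finite and >= 0")
  if (abs(sum(v) - 100) > 1e-6)
    .stopf("composition must sum to 100 (got %.8g)", sum(v))
  structure(list(water = water, methanol = methanol, chloroform = chloroform,
                 basis = basis),
            class = "ternary_composition")
}

#' @export
print.ternary_composition <- function(x, ...) {
  cat(sprintf("Ternary composition (%s %%): water %.2f / MeOH %.2f / CHCl3 %.2f\n",
              x$basis, x$water, x$methanol, x$chloroform))
  invisible(x)
}

.as_ternary <- function(x) {
  if (inherits(x, "ternary_composition")) return(x)
  .stopf("expected a 'ternary_composition'; see ternary_composition()")
}

#' Solvent density set
#'
#' Densities in g/cm^3 used for volume/weight basis conversion. Defaults are
#' the rounded handbook values 1.0 (water), 0.8 (methanol), 1.5 (chloroform).
#'
#' @param water,methanol,chloroform Densities in g/cm^3 (> 0).
#' @return Object of class `density_set`.
#' @export
density_set <- function(water = 1.0, methanol = 0.8, chloroform = 1.5) {
  for (nm in c("water", "methanol", "chloroform"))
    .check_positive_scalar(get(nm), nm)
  structure(list(water = water, methanol = methanol, chloroform = chloroform),
            class = "density_set")
}

#' Convert a ternary composition between volume and weight bases
#'
#' Weight fractions follow w_i = phi_i rho_i / sum_j phi_j rho_j and the
#' inverse phi_i = (w_i/rho_i) / sum_j (w_j/rho_j); conversion is exact and
#' round trips to machine precision.
#'
#' @param comp A [ternary_composition()].
#' @param densities A [density_set()].
#' @param target `"volume"` or `"weight"`.
#' @return The converted `ternary_composition` (unchanged if already on the
#'   target basis).
#' @examples
#' convert_basis(ternary_composition(30, 40, 30), target = "weight")
#' @export
convert_basis <- function(comp, densities = density_set(),
                          target = c("weight", "volume")) {
  comp <- .as_ternary(comp)
  target <- match.arg(target)
  if (comp$basis == target) return(comp)
  x <- c(comp$water, comp$methanol, comp$chloroform)
  rho <- c(densities$water, densities$methanol, densities$chloroform)
  y <- if (target == "weight") x * rho else x / rho
  y <- 100 * y / sum(y)
  ternary_composition(y[1], y[2], y[3], basis = target)
}

#' Pool volume additions into a composition
#'
#' Ideal (volume-additive) mixing of an ordered series of solvent additions.
#' Each addition is a volume in microlitres plus a volume-basis composition;
#' the pooled composition is the volume-weighted mean and total volume is
#' conserved.
#'
#' @param volumes Numeric vector of addition volumes in uL (> 0).
#' @param compositions List of volume-basis [ternary_composition()] objects,
#'   same length as `volumes`. Pure solvents can be given by name
#'   (`"water"`, `"methanol"`, `"chloroform"`).
#' @return List with `composition` (volume basis) and `total_volume` (uL).
#' @examples
#' bd_mix(c(90, 300, 90), list("water", "methanol", "chloroform"))
#' @export
bd_mix <- function(volumes, compositions) {
  if (length(volumes) < 1L) .stopf("at least one addition is required")
  if (length(volumes) != length(compositions))
    .stopf("'volumes' and 'compositions' must have equal length")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    .stopf("all volumes must be positive")
  pure <- list(
    water = ternary_composition(100, 0, 0),
    methanol = ternary_composition(0, 100, 0),
    chloroform = ternary_composition(0, 0, 100)
  )
  comp_of <- function(ci) {
    if (is.character(ci)) {
      if (!ci %in% names(pure)) .stopf("unknown pure solvent '%s'", ci)
      return(pure[[ci]])
    }
    ci <- .as_ternary(ci)
    if (ci$basis != "volume")
      .stopf("bd_mix additions must be on the volume basis")
    ci
  }
  tot <- sum(volumes)
  acc <- c(0, 0, 0)
  for (i in seq_along(volumes)) {
    ci <- comp_of(compositions[[i]])
    acc <- acc + volumes[i] *
      c(ci$water, ci$methanol, ci$chloroform) / 100
  }
  frac <- 100 * acc / tot
  list(composition = ternary_composition(frac[1], frac[2], frac[3]),
       total_volume = tot)
}

#' Binodal boundary model for the Bligh-Dyer diagram
#'
#' An ordered polyline of weight-basis compositions tracing the
#' monophasic/biphasic (1-phase to 2-phase) boundary of the
#' water/methanol/chloroform diagram. The two-phase region is the area
#' enclosed between the polyline and the methanol-free (water-chloroform)
#' edge. The packaged default asset is a synthetic piecewise-linear boundary
#' passing through the commonly cited critical composition (ca. 30% water,
#' 15% methanol, 55% chloroform w/w); replace it with a digitized curve via
#' `path`.
#'
#' @param path CSV file with header `w_water,w_methanol,w_chloroform` (weight
#'   percent, ordered along the curve). Default: the packaged asset.
#' @return Object of class `binodal_model` containing the boundary points.
#' @export
binodal_model <- function(path = system.file("extdata",
                                             "bd_binodal_synthetic.csv",
                                             package = "lipoplexr")) {
  pts <- read_binodal_csv(path)
  if (nrow(pts) < 3L) .stopf("binodal needs at least 3 boundary points")
  structure(list(points = pts, source = path), class = "binodal_model")
}

# map weight-% composition to 2-D ternary plot coordinates
.ternary_xy <- function(w_water, w_methanol, w_chloroform) {
  cbind(x = w_chloroform + w_methanol / 2,
        y = w_methanol * sqrt(3) / 2)
}

# ray-casting point-in-polygon; vertices as two-column matrix
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

# minimum distance from point to polyline segments
.dist_to_polyline <- function(px, py, vx, vy) {
  d <- Inf
  for (i in seq_len(length(vx) - 1L)) {
    ax <- vx[i]; ay <- vy[i]; bx <- vx[i + 1L]; by <- vy[i + 1L]
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
      ((bx - ax)^2 + (by - ay)^2)
    t <- min(max(t, 0), 1)
    d <- min(d, sqrt((px - (ax + t * (bx - ax)))^2 +
                       (py - (ay + t * (by - ay)))^2))
  }
  d
}

#' Classify a composition as monophasic or biphasic
#'
#' Tests whether a composition lies inside the two-phase region enclosed by
#' the binodal polyline and the methanol-free edge of the ternary diagram.
#' Classification is always performed on the weight basis regardless of the
#' input basis. Points within `boundary_tol` (weight-%) of the binodal are
#' labelled `"boundary"`.
#'
#' @param comp A [ternary_composition()] (either basis).
#' @param binodal A [binodal_model()].
#' @param densities A [density_set()] for basis conversion.
#' @param boundary_tol Distance tolerance in weight-% units.
#' @return `"monophasic"`, `"biphasic"` or `"boundary"`.
#' @export
classify_phase <- function(comp, binodal = binodal_model(),
                           densities = density_set(), boundary_tol = 0.5) {
  comp <- convert_basis(.as_ternary(comp), densities, "weight")
  stopifnot(inherits(binodal, "binodal_model"))
  pts <- binodal$points
  bxy <- .ternary_xy(pts$w_water, pts$w_methanol, pts$w_chloroform)
  if (nrow(unique(bxy)) < 3L) .stopf("degenerate binodal polyline")
  pxy <- .ternary_xy(comp$water, comp$methanol, comp$chloroform)
  # close the 2-phase polygon along the methanol-free edge
  vx <- c(bxy[, "x"], bxy[nrow(bxy), "x"], bxy[1, "x"])
  vy <- c(bxy[, "y"], 0, 0)
  if (.dist_to_polyline(pxy[1], pxy[2], bxy[, "x"], bxy[, "y"]) < boundary_tol)
    return("boundary")
  if (.in_polygon(pxy[1], pxy[2], vx, vy)) "biphasic" else "monophasic"
}

#' Lever rule along a tie-line
#'
#' Mass-balance fractions of the two coexisting phases for a composition
#' lying on the tie-line between the light- and heavy-phase endpoints. The
#' fractions are the linear-interpolation weights and always sum to 1.
#'
#' @param comp Overall [ternary_composition()].
#' @param endpoint_light,endpoint_heavy Tie-line endpoint compositions (same
#'   basis as `comp`).
#' @param tol Off-tie-line tolerance in composition units.
#' @return List with `fraction_light` and `fraction_heavy`.
#' @export
lever_rule <- function(comp, endpoint_light, endpoint_heavy, tol = 1e-6) {
  comp <- .as_ternary(comp)
  a <- .as_ternary(endpoint_light); b <- .as_ternary(endpoint_heavy)
  if (a$basis != comp$basis || b$basis != comp$basis)
    .stopf("lever_rule requires all compositions on the same basis")
  p <- c(comp$water, comp$methanol, comp$chloroform)
  pa <- c(a$water, a$methanol, a$chloroform)
  pb <- c(b$water, b$methanol, b$chloroform)
  ab <- pb - pa
  denom <- sum(ab^2)
  if (denom == 0) .stopf("degenerate tie-line: identical endpoints")
  t <- sum((p - pa) * ab) / denom
  off <- sqrt(sum((pa + t * ab - p)^2))
  if (off > tol || t < -tol || t > 1 + tol)
    .stopf("composition is not on the tie-line (offset %.3g, t = %.3g)",
           off, t)
  t <- min(max(t, 0), 1)
  list(fraction_light = 1 - t, fraction_heavy = t)
}
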