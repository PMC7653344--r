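#' Solvent-accessible surface area
#'
#' Computes per-atom and total solvent-accessible surface area (SASA) of a
#' set of atomic spheres. Each atom is expanded by the probe radius; the
#' accessible area is the part of the expanded sphere lying outside every
#' other expanded sphere.
#'
#' Two backends are provided. `"lee_richards"` slices each expanded sphere
#' into sections perpendicular to the z axis, measures the accessible arc of
#' the section circle against the section circles of neighbouring atoms, and
#' accumulates arc-angle x R x dz. Slice thickness adapts per atom so that an
#' isolated sphere is exact to machine precision. `"points"` distributes a
#' quasi-uniform (Fibonacci) lattice on each expanded sphere and counts the
#' fraction of points outside all other expanded spheres; it is the slow,
#' simple cross-check oracle.
#'
#' Atoms with identical centres and radii would mutually occlude each other
#' completely under either rule; instead the shared accessible area is
#' computed once and split equally among the coincident atoms, so the total
#' is unaffected by duplication.
#'
#' @param atoms An [atom_spheres()] object (or data frame with `x,y,z,radius`).
#' @param r_prob Probe radius, Angstrom (default 1.4, a water molecule).
#' @param backend `"lee_richards"` (default) or `"points"`.
#' @param resolution Slice spacing in Angstrom for `"lee_richards"` (default
#'   0.1) or points per atom for `"points"` (default 10000). Must be > 0.
#' @return An object of class `"surface_result"`: a list with
#'   `per_atom_sas` (A^2), `total_sas` (A^2, the exact sum of the per-atom
#'   areas), `method`, `resolution`, and `r_prob`.
#' @examples
#' a <- atom_spheres(0, 0, 0, radius = 1.7)
#' sasa(a)$total_sas          # 4*pi*(1.7+1.4)^2
#' @export
sasa <- function(atoms, r_prob = 1.4,
                 backend = c("lee_richards", "points"),
                 resolution = NULL) {
  backend <- match.arg(backend)
  if (is.null(atoms) || nrow(atoms) < 1L) stop_fe("at least one atom required")
  check_number(r_prob, "r_prob", lower = 0)
  resolution <- resolution %||% switch(backend,
                                       lee_richards = 0.1,
                                       points = 10000)
  check_number(resolution, "resolution", lower = 0, strict_lower = TRUE)

  R <- atoms$radius + r_prob
  cx <- atoms$x; cy <- atoms$y; cz <- atoms$z
  n <- length(R)

  # Coincident-sphere tie-break: compute on unique (centre, radius)
  # representatives, then split each representative's area equally.
  key <- sprintf("%.9f_%.9f_%.9f_%.9f", cx, cy, cz, R)
  grp <- match(key, key)            # index of first member of each group
  reps <- which(grp == seq_len(n))  # representatives
  gsize <- tabulate(match(grp, reps), nbins = length(reps))

  ux <- cx[reps]; uy <- cy[reps]; uz <- cz[reps]; uR <- R[reps]
  m <- length(reps)
  rep_area <- numeric(m)

  # neighbour lists among representatives (expanded spheres that intersect)
  d2 <- (outer(ux, ux, "-"))^2 + (outer(uy, uy, "-"))^2 +
    (outer(uz, uz, "-"))^2
  sumR2 <- (outer(uR, uR, "+"))^2
  nb <- lapply(seq_len(m), function(i) {
    j <- which(d2[i, ] < sumR2[i, ] & seq_len(m) != i)
    j
  })

  if (backend == "lee_richards") {
    for (i in seq_len(m)) {
      rep_area[i] <- lr_atom_area(i, ux, uy, uz, uR, nb[[i]], resolution)
    }
  } else {
    npts <- as.integer(resolution)
    pts <- fibonacci_sphere(npts)
    for (i in seq_len(m)) {
      P <- pts * uR[i]
      px <- P[, 1] + ux[i]; py <- P[, 2] + uy[i]; pz <- P[, 3] + uz[i]
      buried <- logical(npts)
      for (j in nb[[i]]) {
        buried <- buried |
          ((px - ux[j])^2 + (py - uy[j])^2 + (pz - uz[j])^2 < uR[j]^2)
      }
      rep_area[i] <- 4 * pi * uR[i]^2 * (sum(!buried) / npts)
    }
  }

  per_atom <- rep_area[match(grp, reps)] / gsize[match(grp, reps)]
  structure(list(per_atom_sas = per_atom,
                 total_sas = sum(per_atom),
                 method = backend,
                 resolution = resolution,
                 r_prob = r_prob),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat(sprintf("<surface_result> total SASA = %.3f A^2 over %d atoms (%s)\n",
              x$total_sas, length(x$per_atom_sas), x$method))
  invisible(x)
}

# Lee-Richards accessible area of one expanded sphere against its
# neighbours. Slice thickness is 2R/n with n = ceiling(2R/spacing) so the
# slab stack covers the sphere exactly (isolated spheres are then exact:
# sum over slices of 2*pi*R*dz = 4*pi*R^2).
lr_atom_area <- function(i, ux, uy, uz, uR, nbr, spacing) {
  Ri <- uR[i]
  nsl <- max(1L, ceiling(2 * Ri / spacing))
  dz <- 2 * Ri / nsl
  zs <- uz[i] - Ri + (seq_len(nsl) - 0.5) * dz
  if (length(nbr) == 0L) return(4 * pi * Ri^2)

  area <- 0
  for (z in zs) {
    ci <- sqrt(Ri^2 - (z - uz[i])^2)  # section-circle radius, > 0 at midpoints
    lo <- numeric(0); hi <- numeric(0)
    open_angle <- 2 * pi
    for (j in nbr) {
      h <- z - uz[j]
      if (abs(h) >= uR[j]) next
      cj <- sqrt(uR[j]^2 - h^2)
      dx <- ux[j] - ux[i]; dy <- uy[j] - uy[i]
      d <- sqrt(dx^2 + dy^2)
      if (d >= ci + cj) next              # sections disjoint
      if (d + cj <= ci) next              # neighbour section inside ours
      if (d + ci <= cj) { open_angle <- 0; break }  # fully occluded slice
      cosa <- (d^2 + ci^2 - cj^2) / (2 * d * ci)
      cosa <- min(1, max(-1, cosa))
      alpha <- acos(cosa)
      theta <- atan2(dy, dx)
      lo <- c(lo, theta - alpha); hi <- c(hi, theta + alpha)
    }
    if (open_angle > 0 && length(lo)) {
      open_angle <- 2 * pi - covered_angle(lo, hi)
    }
    area <- area + open_angle * Ri * dz
  }
  area
}

# Total angular measure covered by the union of arcs [lo, hi] on a circle.
covered_angle <- function(lo, hi) {
  width <- hi - lo
  lo <- lo %% (2 * pi); hi <- lo + width  # keep widths, shift starts
  # split arcs that wrap past 2*pi
  wrap <- hi > 2 * pi
  if (any(wrap)) {
    lo <- c(lo[!wrap], lo[wrap], rep(0, sum(wrap)))
    hi <- c(hi[!wrap], rep(2 * pi, sum(wrap)), hi[wrap] - 2 * pi)
  }
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[k])
    } else {
      tot <- tot + (cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    }
  }
  tot + (cur_hi - cur_lo)
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * k
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Buried surface area of an atom
#'
#' The complement of an atom's accessible area against its full expanded
#' sphere: \eqn{BSAS_i = 4\pi (r_i + r_{prob})^2 - SAS_i}.
#'
#' @param radius Atom radius (or radii), Angstrom; an [atom_spheres()] object
#'   is also accepted.
#' @param sas Accessible area(s) for the same atom(s), A^2.
#' @param r_prob Probe radius, Angstrom.
#' @return Buried area(s), A^2 (zero for a fully exposed atom, the full
#'   expanded-sphere area for a fully buried one).
#' @export
bsas <- function(radius, sas, r_prob = 1.4) {
  if (inherits(radius, "atom_spheres")) radius <- radius$radius
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop_fe("radii must be finite and > 0")
  }
  if (any(!is.finite(sas)) || any(sas < 0)) stop_fe("'sas' must be >= 0")
  check_number(r_prob, "r_prob", lower = 0)
  full <- 4 * pi * (radius + r_prob)^2
  out <- full - sas
  bad <- out < -1e-6 * pmax(full, 1)
  if (any(bad)) {
    stop_fe("sas exceeds full expanded-sphere area for atom(s) %s: inconsistent inputs",
            paste(which(bad), collapse = ", "))
  }
  pmax(out, 0)
}

#' WSAS configurational entropy estimate
#'
#' The weighted solvent-accessible surface-area (WSAS) model estimates the
#' configurational entropy of a molecule from cheap surface-area terms in
#' place of a normal-mode analysis:
#' \deqn{S_{conf} = \sum_i w_i (SAS_i - k \cdot BSAS_i),}
#' where \eqn{w_i} is an atom-type-specific weight, \eqn{k} scales the
#' buried-area contribution, and the sum runs over atoms.
#'
#' The returned value carries the weights' units; with weights in
#' kcal/(mol K A^2) the product \eqn{T \cdot S_{conf}} is in kcal/mol and can
#' be passed as the entropy term of an ESMACS free energy.
#'
#' @param atoms An [atom_spheres()] object; every `atom_type` present must
#'   have a weight in `params`.
#' @param params A [wsas_params()] object.
#' @param surface Optional precomputed [sasa()] result; must have been
#'   computed with `params$r_prob`. Computed on the fly if omitted.
#' @return The entropy estimate (a single number), with the per-atom
#'   contributions attached as attribute `"per_atom"`.
#' @export
wsas_entropy <- function(atoms, params, surface = NULL) {
  stopifnot(inherits(params, "wsas_params"))
  if (is.null(surface)) {
    surface <- sasa(atoms, r_prob = params$r_prob)
  } else {
    if (!inherits(surface, "surface_result")) {
      stop_fe("'surface' must be a surface_result")
    }
    if (abs(surface$r_prob - params$r_prob) > 1e-12) {
      stop_fe("surface was computed with r_prob = %g but params$r_prob = %g",
              surface$r_prob, params$r_prob)
    }
    if (length(surface$per_atom_sas) != nrow(atoms)) {
      stop_fe("surface has %d atoms but 'atoms' has %d",
              length(surface$per_atom_sas), nrow(atoms))
    }
  }
  missing <- setdiff(unique(atoms$atom_type), names(params$weights))
  if (length(missing)) {
    stop_fe("no WSAS weight for atom type(s): %s",
            paste(missing, collapse = ", "))
  }
  w <- params$weights[atoms$atom_type]
  sas_i <- surface$per_atom_sas
  bsas_i <- bsas(atoms$radius, sas_i, params$r_prob)
  per_atom <- w * (sas_i - params$k * bsas_i)
  structure(sum(per_atom), per_atom = unname(per_atom))
}
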