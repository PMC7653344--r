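#' Atomic sphere set
#'
#' The unit of all surface-area work: a set of atoms, each a sphere with a
#' position (Angstrom), a van der Waals radius (Angstrom), an optional
#' categorical atom type (used to look up WSAS entropy weights) and an
#' optional partial charge (elementary charge units, e).
#'
#' @param x,y,z Numeric coordinate vectors, Angstrom.
#' @param radius Positive radii, Angstrom (recycled if length 1).
#' @param atom_type Character atom-type labels (default `"ANY"`).
#' @param charge Partial charges in e (default `NA`).
#' @return A data frame of class `"atom_spheres"` with columns
#'   `x, y, z, radius, atom_type, charge`.
#' @examples
#' atom_spheres(0, 0, 0, radius = 1.7, atom_type = "C")
#' @export
atom_spheres <- function(x, y, z, radius, atom_type = "ANY", charge = NA_real_) {
  n <- length(x)
  if (n < 1L) stop_fe("at least one atom is required")
  if (length(y) != n || length(z) != n) {
    stop_fe("coordinate vectors must have equal length")
  }
  radius <- rep_len(as.numeric(radius), n)
  atom_type <- rep_len(as.character(atom_type), n)
  charge <- rep_len(as.numeric(charge), n)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop_fe("atom coordinates must be finite")
  }
  if (!all(is.finite(radius)) || any(radius <= 0)) {
    stop_fe("atom radii must be finite and > 0")
  }
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                    radius = radius, atom_type = atom_type, charge = charge,
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_spheres", "data.frame")
  out
}

#' @export
print.atom_spheres <- function(x, ...) {
  cat(sprintf("<atom_spheres> %d atoms, radii %.2f-%.2f A\n",
              nrow(x), min(x$radius), max(x$radius)))
  NextMethod()
}

# Bondi-style van der Waals radii (Angstrom) used when reading PDB files,
# which carry no radius column. Configurable via read_pdb_atoms().
default_element_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

#' WSAS entropy parameters
#'
#' Parameter bundle for the weighted solvent-accessible surface-area (WSAS)
#' configurational-entropy model: per-atom-type weights \eqn{w_i}, the
#' buried-area scaling parameter \eqn{k}, and the probe radius used for the
#' underlying surface computation.
#'
#' The weights were calibrated in the WSAS literature against normal-mode
#' entropies; this package does not ship production values. A unit-weight
#' default (`w = 1` for every type, `k = 0`) is provided for testing, and
#' production weights are loaded from a two-column parameter file via
#' [read_wsas_params()].
#'
#' @param weights Named numeric vector mapping atom type to weight
#'   (entropy per area; multiplied by areas in A^2).
#' @param k Dimensionless buried-surface-area scaling parameter.
#' @param r_prob Probe radius, Angstrom (default 1.4, water).
#' @return An object of class `"wsas_params"`.
#' @seealso [wsas_entropy()], [read_wsas_params()]
#' @export
wsas_params <- function(weights = c(ANY = 1), k = 0, r_prob = 1.4) {
  if (length(weights) == 0L || is.null(names(weights)) ||
      any(!nzchar(names(weights)))) {
    stop_fe("'weights' must be a named numeric vector (atom_type -> w)")
  }
  check_number(k, "k")
  check_number(r_prob, "r_prob", lower = 0)
  structure(list(weights = weights, k = k, r_prob = r_prob),
            class = "wsas_params")
}

#' Read a WSAS parameter file
#'
#' Tab- or whitespace-delimited text with `#` comments and two columns,
#' `atom_type` and `weight`; `k` and the probe radius are given as header
#' comments of the form `# k = 0.461` / `# r_prob = 1.4`, or overridden by
#' the arguments.
#'
#' @param path Path to the parameter file.
#' @param k,r_prob Optional overrides of values read from the file.
#' @return A [wsas_params()] object.
#' @export
read_wsas_params <- function(path, k = NULL, r_prob = NULL) {
  if (!file.exists(path)) stop_fe("WSAS parameter file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  pick <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9.eE+-]+)"), hdr))
    v <- unlist(lapply(m, function(g) if (length(g) == 2L) g[2] else NULL))
    if (length(v)) as.numeric(v[[1]]) else NULL
  }
  tab <- utils::read.table(text = grep("^\\s*(#|$)", lines, value = TRUE,
                                       invert = TRUE),
                           col.names = c("atom_type", "weight"),
                           stringsAsFactors = FALSE)
  w <- stats::setNames(as.numeric(tab$weight), tab$atom_type)
  wsas_params(weights = w,
              k = k %||% pick("k") %||% 0,
              r_prob = r_prob %||% pick("r_prob") %||% 1.4)
}
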