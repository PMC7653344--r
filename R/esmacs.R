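#' Nonpolar solvation free energy from SASA
#'
#' Linear surface-area model for the nonpolar part of the solvation free
#' energy: \eqn{G_{SA} = \gamma \cdot SASA + b}, with the widely used default
#' coefficients \eqn{\gamma = 0.00542} kcal/mol/A^2 and \eqn{b = 0.92}
#' kcal/mol.
#'
#' @param sasa Solvent-accessible surface area(s), A^2 (>= 0).
#' @param gamma Surface tension, kcal/mol/A^2.
#' @param b Offset, kcal/mol.
#' @return Nonpolar solvation free energy, kcal/mol.
#' @examples
#' gsa_from_sasa(1000)  # 6.34 kcal/mol
#' @export
gsa_from_sasa <- function(sasa, gamma = fe_constants$gamma_sa,
                          b = fe_constants$b_sa) {
  if (any(!is.finite(sasa)) || any(sasa < 0)) stop_fe("'sasa' must be >= 0")
  gamma * sasa + b
}

#' Ensemble of per-frame energy components
#'
#' Validates and tags a table of per-frame MMPBSA-style energy components
#' for one or more species. Required columns: `species` (one of
#' `"complex"`, `"receptor"`, `"ligand"`), `replica`, `time_ns`, `e_int`,
#' `e_vdw`, `e_ele`, `g_pb`, and either `g_sa` or `sasa` (from which `g_sa`
#' is derived via [gsa_from_sasa()]). An optional `minus_ts` column carries a
#' per-frame \eqn{-T S_{conf}} term.
#'
#' @param frames A data frame with the columns above.
#' @param gamma,b Surface-area model coefficients used when `g_sa` must be
#'   derived from `sasa`.
#' @return A data frame of class `"energy_frames"` with a resolved `g_sa`
#'   column.
#' @export
energy_frames <- function(frames, gamma = fe_constants$gamma_sa,
                          b = fe_constants$b_sa) {
  need <- c("species", "replica", "time_ns", "e_int", "e_vdw", "e_ele", "g_pb")
  miss <- setdiff(need, names(frames))
  if (length(miss)) {
    stop_fe("missing energy-frame column(s): %s", paste(miss, collapse = ", "))
  }
  if (!"g_sa" %in% names(frames)) {
    if (!"sasa" %in% names(frames)) {
      stop_fe("missing energy-frame column: need either 'g_sa' or 'sasa'")
    }
    frames$g_sa <- gsa_from_sasa(frames$sasa, gamma = gamma, b = b)
  }
  bad <- setdiff(unique(frames$species), c("complex", "receptor", "ligand"))
  if (length(bad)) {
    stop_fe("unknown species tag(s): %s", paste(bad, collapse = ", "))
  }
  num <- c("time_ns", "e_int", "e_vdw", "e_ele", "g_pb", "g_sa")
  for (cn in num) {
    if (!all(is.finite(frames[[cn]]))) stop_fe("non-finite values in '%s'", cn)
  }
  key <- paste(frames$species, frames$replica, frames$time_ns)
  if (anyDuplicated(key)) {
    stop_fe("duplicate (species, replica, time_ns) keys in energy frames")
  }
  class(frames) <- c("energy_frames", "data.frame")
  frames
}

#' Per-frame species free energy
#'
#' The endpoint free energy of one species in one frame:
#' \eqn{G = E_{int} + E_{vdW} + E_{ele} + G_{PB} + G_{SA} (- T S_{conf})}.
#' The molecular-mechanics terms and the polar solvation term \eqn{G_{PB}}
#' are inputs (the latter from an external continuum solver); the nonpolar
#' term comes from [gsa_from_sasa()] when only `sasa` is present.
#'
#' @param frames An [energy_frames()] table (or a data frame acceptable to
#'   it).
#' @param minus_ts Optional \eqn{-T S_{conf}} term, kcal/mol: a single
#'   number applied to every frame, or `NULL` to use the table's `minus_ts`
#'   column when present (and none otherwise).
#' @return Numeric vector of per-frame free energies, kcal/mol.
#' @export
species_free_energy <- function(frames, minus_ts = NULL) {
  if (!inherits(frames, "energy_frames")) frames <- energy_frames(frames)
  g <- frames$e_int + frames$e_vdw + frames$e_ele + frames$g_pb + frames$g_sa
  if (!is.null(minus_ts)) {
    g <- g + minus_ts
  } else if ("minus_ts" %in% names(frames)) {
    g <- g + frames$minus_ts
  }
  g
}

#' Uniform frame times over the tail of a trajectory
#'
#' Returns `n_frames` uniformly spaced snapshot times across the final
#' `window_length` nanoseconds of a trajectory. The convention is
#' endpoint-anchored: with trajectory length \eqn{L} and window \eqn{W} the
#' times are \eqn{L - W + k W/n} for \eqn{k = 1, \dots, n}, so the final
#' frame is always included and `n_frames = 1` yields the final time. The
#' protocol default (50 frames over the last 10 ns) matches ensemble
#' endpoint practice on slowly converging receptor systems.
#'
#' @param trajectory_length Total trajectory length, ns.
#' @param window_length Averaging window at the tail, ns (default 10).
#' @param n_frames Number of frames (default 50).
#' @return Numeric vector of `n_frames` times, ns.
#' @export
select_frames <- function(trajectory_length, window_length = 10,
                          n_frames = 50) {
  check_number(trajectory_length, "trajectory_length", lower = 0)
  check_number(window_length, "window_length", lower = 0, strict_lower = TRUE)
  check_number(n_frames, "n_frames", lower = 1)
  if (window_length > trajectory_length) {
    stop_fe("window_length (%g ns) exceeds trajectory_length (%g ns)",
            window_length, trajectory_length)
  }
  start <- trajectory_length - window_length
  start + seq_len(n_frames) * (window_length / n_frames)
}

# Per-replica means of per-frame free energies for one species.
replica_means <- function(frames, minus_ts = NULL) {
  g <- species_free_energy(frames, minus_ts = minus_ts)
  tapply(g, frames$replica, mean)
}

# Component means (mean over all frames, replica-mean-of-means) per term.
component_means <- function(frames, minus_ts = NULL) {
  terms <- c("e_int", "e_vdw", "e_ele", "g_pb", "g_sa")
  out <- vapply(terms, function(tn) {
    mean(tapply(frames[[tn]], frames$replica, mean))
  }, numeric(1))
  ts_col <- if (!is.null(minus_ts)) {
    rep(minus_ts, nrow(frames))
  } else if ("minus_ts" %in% names(frames)) frames$minus_ts else NULL
  if (!is.null(ts_col)) {
    out <- c(out, minus_ts = mean(tapply(ts_col, frames$replica, mean)))
  }
  out
}

#' ESMACS ensemble binding free energy
#'
#' Aggregates per-frame endpoint free energies over replica ensembles into a
#' binding free energy
#' \deqn{\Delta G = \langle G_{complex}\rangle - \langle G_{receptor}\rangle
#'   - \langle G_{ligand}\rangle,}
#' where each ensemble average is the mean over replicas of each replica's
#' frame-average (identical to the pooled mean on balanced designs, and the
#' natural unit for resampling). The standard error is a bootstrap over
#' replicas -- the independent sampling unit of ensemble simulation -- with
#' the finite-sample correction \eqn{\sqrt{n/(n-1)}} so that the bootstrap
#' standard deviation estimates the classical SEM without small-n bias.
#'
#' In `"one_traj"` mode the receptor and ligand frames must be derived from
#' the complex frames (identical replica/time keys) and the bootstrap
#' resamples replicas jointly (paired). In `"three_traj"` mode the three
#' ensembles are independent and are resampled independently; the point
#' estimate is identical in the two modes when fed identical frames.
#'
#' @param complex_set,receptor_set,ligand_set [energy_frames()] tables for
#'   the three species (each containing only its own species' rows).
#' @param mode `"one_traj"` or `"three_traj"`.
#' @param entropy Optional named list/vector of \eqn{-T S_{conf}} terms
#'   (kcal/mol) with elements `complex`, `receptor`, `ligand`; `NULL` uses
#'   any `minus_ts` columns present (or none).
#' @param window_ns,n_frames Optional tail-window frame selection applied to
#'   each replica (via [select_frames()] on each replica's time span);
#'   `NULL` (default) uses all frames provided.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `"esmacs_result"`: a list with `delta_g`,
#'   `sem` (both kcal/mol), `mode`, `entropy_included`, `components` (named
#'   per-term breakdown summing to `delta_g`), `n_replicas`, and
#'   `replica_delta_g` (per-replica differences in `"one_traj"` mode).
#' @export
esmacs_binding_free_energy <- function(complex_set, receptor_set, ligand_set,
                                       mode = c("one_traj", "three_traj"),
                                       entropy = NULL,
                                       window_ns = NULL, n_frames = NULL,
                                       n_boot = 5000, seed = NULL) {
  mode <- match.arg(mode)
  sets <- list(complex = complex_set, receptor = receptor_set,
               ligand = ligand_set)
  sets <- lapply(sets, function(s) {
    if (!inherits(s, "energy_frames")) s <- energy_frames(s)
    s
  })
  for (nm in names(sets)) {
    if (nrow(sets[[nm]]) == 0L) stop_fe("empty frame selection for %s", nm)
  }
  if (!is.null(window_ns)) {
    sets <- lapply(sets, select_tail_frames, window_ns = window_ns,
                   n_frames = n_frames %||% 50)
  }
  mts <- function(sp) if (is.null(entropy)) NULL else {
    v <- entropy[[sp]]
    if (is.null(v)) stop_fe("entropy term missing for species '%s'", sp)
    v
  }

  rm_list <- lapply(names(sets), function(sp) replica_means(sets[[sp]], mts(sp)))
  names(rm_list) <- names(sets)

  if (mode == "one_traj") {
    key <- function(s) sort(paste(s$replica, s$time_ns))
    kc <- key(sets$complex)
    if (!identical(kc, key(sets$receptor)) ||
        !identical(kc, key(sets$ligand))) {
      stop_fe("one_traj mode requires receptor and ligand frames derived from the complex (identical replica/time keys)")
    }
    reps <- names(rm_list$complex)
    if (!identical(reps, names(rm_list$receptor)) ||
        !identical(reps, names(rm_list$ligand))) {
      stop_fe("one_traj mode: replica labels differ between species")
    }
  }

  means <- vapply(rm_list, mean, numeric(1))
  delta_g <- means[["complex"]] - means[["receptor"]] - means[["ligand"]]

  cm <- lapply(names(sets), function(sp) component_means(sets[[sp]], mts(sp)))
  names(cm) <- names(sets)
  term_order <- intersect(c("e_int", "e_vdw", "e_ele", "g_pb", "g_sa",
                            "minus_ts"),
                          unique(unlist(lapply(cm, names))))
  pad <- function(v) {
    out <- stats::setNames(numeric(length(term_order)), term_order)
    out[names(v)] <- v
    out
  }
  comp <- pad(cm$complex) - pad(cm$receptor) - pad(cm$ligand)

  boot <- with_seed(seed, {
    if (n_boot < 1L) {
      NA_real_
    } else if (mode == "one_traj") {
      d <- rm_list$complex - rm_list$receptor - rm_list$ligand
      n <- length(d)
      if (n > 1L) {
        idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
        rowMeans(matrix(d[idx], nrow = n_boot))
      } else NA_real_
    } else {
      resample <- function(v) {
        n <- length(v)
        idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
        rowMeans(matrix(v[idx], nrow = n_boot))
      }
      ns <- vapply(rm_list, length, integer(1))
      if (all(ns > 1L)) {
        resample(rm_list$complex) - resample(rm_list$receptor) -
          resample(rm_list$ligand)
      } else NA_real_
    }
  })
  sem <- if (all(is.na(boot))) NA_real_ else {
    n_eff <- length(rm_list$complex)
    stats::sd(boot) * sqrt(n_eff / (n_eff - 1))
  }

  structure(list(delta_g = unname(delta_g),
                 sem = unname(sem),
                 mode = mode,
                 entropy_included = !is.null(entropy) ||
                   any(vapply(sets, function(s) "minus_ts" %in% names(s),
                              logical(1))),
                 components = comp,
                 n_replicas = vapply(rm_list, length, integer(1)),
                 replica_delta_g = if (mode == "one_traj") {
                   unname(rm_list$complex - rm_list$receptor - rm_list$ligand)
                 } else NULL),
            class = "esmacs_result")
}

# Subset an energy_frames table to the tail-window frames of each replica
# (nearest available frame to each requested time, per species/replica).
select_tail_frames <- function(frames, window_ns, n_frames) {
  pieces <- split(seq_len(nrow(frames)),
                  paste(frames$species, frames$replica))
  keep <- unlist(lapply(pieces, function(ix) {
    tt <- frames$time_ns[ix]
    want <- select_frames(max(tt) - min(tt), window_ns, n_frames) + min(tt)
    unique(ix[vapply(want, function(w) which.min(abs(tt - w)), integer(1))])
  }), use.names = FALSE)
  out <- frames[sort(keep), , drop = FALSE]
  class(out) <- class(frames)
  out
}

#' @export
print.esmacs_result <- function(x, ...) {
  cat(sprintf("ESMACS binding free energy (%s mode%s)\n", x$mode,
              if (x$entropy_included) ", with -T*S_conf" else ""))
  cat(sprintf("  dG = %.3f +/- %.3f kcal/mol (bootstrap SEM over %d replicas)\n",
              x$delta_g, x$sem, x$n_replicas[["complex"]]))
  cat("  components (kcal/mol):\n")
  for (nm in names(x$components)) {
    cat(sprintf("    %-8s %10.3f\n", nm, x$components[[nm]]))
  }
  invisible(x)
}

#' Running ensemble average diagnostic
#'
#' Convergence diagnostic for ensemble endpoint calculations: the binding
#' free energy recomputed on expanding time windows, so slow drift is
#' visible. No stopping rule is applied.
#'
#' @inheritParams esmacs_binding_free_energy
#' @param n_points Number of expanding windows (default 20).
#' @return Data frame with `time_ns` (window end) and `delta_g`.
#' @export
esmacs_running_average <- function(complex_set, receptor_set, ligand_set,
                                   mode = "one_traj", n_points = 20) {
  cs <- energy_frames(complex_set)
  tt <- sort(unique(cs$time_ns))
  ends <- tt[unique(pmax(1L, round(seq_along(tt) * seq_len(n_points) /
                                     n_points)))]
  ends <- unique(ends)
  dg <- vapply(ends, function(e) {
    sub <- function(s) {
      out <- s[s$time_ns <= e, , drop = FALSE]
      class(out) <- class(s)
      out
    }
    esmacs_binding_free_energy(sub(cs), sub(energy_frames(receptor_set)),
                               sub(energy_frames(ligand_set)),
                               mode = mode, n_boot = 0, seed = 1)$delta_g
  }, numeric(1))
  data.frame(time_ns = ends, delta_g = dg)
}
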