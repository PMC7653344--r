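# Synthetic-input generators. Every generator is deterministic under its
# seed and returns its ground truth in a `truth` sidecar; recovery tests
# read only the sidecar, never the generator's internals. Noise is i.i.d.
# normal throughout -- the simplest model consistent with ensemble-mean
# machinery.

#' Generate a random atom cluster
#'
#' Seeded random spheres for surface-area testing. `"dense"` mode scatters
#' atoms uniformly in a cubic box (overlapping spheres); `"separated"` mode
#' spaces atoms far enough apart that no expanded spheres can overlap, so
#' the total SASA is the sum of isolated-sphere closed forms.
#'
#' @param n Number of atoms.
#' @param seed Integer seed (fixed seed, identical output).
#' @param radius_range Atom radius range, Angstrom (default 1.2-1.9).
#' @param box Box edge for `"dense"` mode, Angstrom (default 4).
#' @param mode `"dense"` (default) or `"separated"`.
#' @param r_prob Probe radius used for the separated-mode closed form.
#' @return List with `atoms` (an [atom_spheres()]) and `truth` (mode,
#'   radii, and for `"separated"` the closed-form `total_sas` at `r_prob`).
#' @export
gen_atom_cluster <- function(n, seed = NULL, radius_range = c(1.2, 1.9),
                             box = 4, mode = c("dense", "separated"),
                             r_prob = 1.4) {
  mode <- match.arg(mode)
  check_number(n, "n", lower = 1)
  if (diff(radius_range) < 0 || radius_range[1] <= 0) {
    stop_fe("'radius_range' must be positive and increasing")
  }
  with_seed(seed, {
    radius <- stats::runif(n, radius_range[1], radius_range[2])
    if (mode == "dense") {
      pos <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
    } else {
      # grid spacing beyond any possible expanded-sphere contact
      spacing <- 2 * (radius_range[2] + r_prob) + 1
      k <- ceiling(n^(1 / 3))
      g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
      pos <- as.matrix(g[seq_len(n), ]) * spacing
    }
    atoms <- atom_spheres(pos[, 1], pos[, 2], pos[, 3], radius = radius)
    truth <- list(kind = "atoms", mode = mode, n = n, radii = radius,
                  r_prob = r_prob,
                  total_sas = if (mode == "separated") {
                    sum(4 * pi * (radius + r_prob)^2)
                  } else NA_real_)
    list(atoms = atoms, truth = truth)
  })
}

#' Generate a synthetic thermodynamic-integration leg
#'
#' Per-window, per-replica dV/dlambda samples drawn i.i.d. normal around a
#' known mean function mu(lambda), with the analytic integral of mu stored
#' as ground truth. Defaults mirror the ensemble-TI protocol geometry:
#' 5 replicas in each of the 13 default lambda windows.
#'
#' @param mu Function of lambda giving the true mean integrand
#'   (kcal/mol per unit lambda).
#' @param sigma Sample noise SD (>= 0).
#' @param n_replicas Replicas per window (default 5).
#' @param n_samples Samples per replica (default 1000).
#' @param lambdas Window placement (default [default_lambdas()]).
#' @param leg Leg label.
#' @param seed Integer seed.
#' @return List with `leg` (a [ti_leg()]) and `truth` (the integral of mu
#'   over [0, 1], plus the generator parameters).
#' @export
gen_ti_dataset <- function(mu = function(lam) 2 * lam, sigma = 0.5,
                           n_replicas = 5, n_samples = 1000,
                           lambdas = default_lambdas(),
                           leg = "aqueous", seed = NULL) {
  check_number(sigma, "sigma", lower = 0)
  true_int <- stats::integrate(function(l) vapply(l, mu, numeric(1)),
                               0, 1, rel.tol = 1e-10)$value
  with_seed(seed, {
    windows <- lapply(lambdas, function(lam) {
      lambda_window(lam, lapply(seq_len(n_replicas), function(k) {
        stats::rnorm(n_samples, mean = mu(lam), sd = sigma)
      }))
    })
    list(leg = ti_leg(windows, leg = leg),
         truth = list(kind = "ti_samples", integral = true_int,
                      sigma = sigma, n_replicas = n_replicas,
                      n_samples = n_samples, lambdas = lambdas))
  })
}

#' Generate synthetic ESMACS energy-frame ensembles
#'
#' Per-frame species free energies drawn i.i.d. normal around known species
#' means and decomposed into fixed component shares (so components always
#' sum to the drawn total). Defaults mirror the ensemble endpoint protocol:
#' 25 replicas, 50 frames over a 10 ns tail window. The generator's true
#' binding free energy, `mean_complex - mean_receptor - mean_ligand`, is
#' recorded in the sidecar.
#'
#' @param means Named vector of species means, kcal/mol
#'   (`complex`, `receptor`, `ligand`).
#' @param sd Per-frame noise SD, kcal/mol (default 2).
#' @param n_replicas Replicas per species (default 25).
#' @param n_frames Frames per replica (default 50).
#' @param window_ns Time span of the frames, ns (default 10, appended to a
#'   30 ns production prefix so times run 30.2, 30.4, ..., 40).
#' @param one_traj If `TRUE` (default) the receptor and ligand frames copy
#'   the complex frames' replica/time keys (frames "extracted from the
#'   complex trajectory"); values are still drawn independently.
#' @param seed Integer seed.
#' @return List with `complex`, `receptor`, `ligand` ([energy_frames()]
#'   tables) and `truth` (`delta_g`, the parameters).
#' @export
gen_energy_frames <- function(means = c(complex = -100, receptor = -60,
                                        ligand = -30),
                              sd = 2, n_replicas = 25, n_frames = 50,
                              window_ns = 10, one_traj = TRUE, seed = NULL) {
  stopifnot(all(c("complex", "receptor", "ligand") %in% names(means)))
  check_number(sd, "sd", lower = 0)
  check_number(n_replicas, "n_replicas", lower = 1)
  start <- 30
  times <- start + seq_len(n_frames) * (window_ns / n_frames)
  shares <- c(e_int = 0.15, e_vdw = 0.25, e_ele = 0.30, g_pb = 0.20,
              g_sa = 0.10)
  with_seed(seed, {
    one_species <- function(sp) {
      g <- stats::rnorm(n_replicas * n_frames, mean = means[[sp]], sd = sd)
      df <- data.frame(species = sp,
                       replica = rep(seq_len(n_replicas), each = n_frames),
                       time_ns = rep(times, n_replicas))
      for (term in names(shares)) df[[term]] <- shares[[term]] * g
      energy_frames(df)
    }
    out <- list(complex = one_species("complex"),
                receptor = one_species("receptor"),
                ligand = one_species("ligand"))
    out$truth <- list(kind = "energy_frames",
                      delta_g = means[["complex"]] - means[["receptor"]] -
                        means[["ligand"]],
                      means = means, sd = sd, n_replicas = n_replicas,
                      n_frames = n_frames, one_traj = one_traj)
    out
  })
}

#' Generate a ligand pair with known common region
#'
#' Builds a random connected ligand L1 (a tree over C/N/O atoms with
#' net-neutral partial charges) and derives L2 by adding a branch of
#' `n_add` atoms drawn from elements absent from the core (so the true
#' maximum common subgraph is exactly the shared core) and perturbing
#' `n_perturb` core charges by `perturb` e. Pairs perturbed beyond the
#' 0.1 e pruning threshold are recorded as prune-expected in the sidecar.
#' Charge conservation is restored on the added branch, keeping both
#' molecules net-neutral.
#'
#' @param n_atoms Core atoms (<= 12 keeps exhaustive oracles cheap).
#' @param n_add Atoms in the L2-only branch (>= 1 when `n_perturb` > 0, to
#'   absorb the compensating charge).
#' @param n_perturb Number of core atoms whose charge is shifted in L2.
#' @param perturb Charge shift magnitude, e (default 0.15, beyond the 0.1 e
#'   pruning threshold).
#' @param seed Integer seed.
#' @return List with `l1`, `l2` ([ligand_graph()]s) and `truth`
#'   (`common_pairs` identity mapping of the core, `appearing` L2 branch
#'   indices, `disappearing` (empty), `prune_expected` core indices).
#' @export
gen_ligand_pair <- function(n_atoms = 8, n_add = 2, n_perturb = 1,
                            perturb = 0.15, seed = NULL) {
  check_number(n_atoms, "n_atoms", lower = 2, upper = 12)
  check_number(n_add, "n_add", lower = 0)
  if (n_perturb > 0 && n_add < 1) {
    stop_fe("n_add must be >= 1 when charges are perturbed (conservation)")
  }
  if (n_perturb > n_atoms) stop_fe("n_perturb exceeds n_atoms")
  with_seed(seed, {
    core_elems <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
    parents <- if (n_atoms > 1L) {
      vapply(2:n_atoms, function(k) sample.int(k - 1L, 1L), integer(1))
    } else integer(0)
    bonds1 <- cbind(parents, 2:n_atoms)[seq_len(n_atoms - 1L), ,
                                        drop = FALSE]
    q <- round(stats::runif(n_atoms, -0.3, 0.3), 3)
    q[n_atoms] <- -sum(q[-n_atoms])  # net-neutral core
    l1 <- ligand_graph(data.frame(element = core_elems, charge = q,
                                  stringsAsFactors = FALSE),
                       cbind(bonds1, 1L), net_charge = 0)

    q2 <- q
    perturbed <- integer(0)
    if (n_perturb > 0) {
      perturbed <- sort(sample.int(n_atoms, n_perturb))
      q2[perturbed] <- q2[perturbed] +
        sample(c(-1, 1), n_perturb, replace = TRUE) * perturb
    }
    elems2 <- core_elems
    bonds2 <- bonds1
    if (n_add > 0) {
      branch_elems <- sample(c("F", "S", "P"), n_add, replace = TRUE)
      elems2 <- c(core_elems, branch_elems)
      attach_to <- sample.int(n_atoms, 1L)
      new_idx <- n_atoms + seq_len(n_add)
      branch_bonds <- cbind(c(attach_to, new_idx[-n_add]), new_idx)
      bonds2 <- rbind(bonds1, branch_bonds)
      qb <- round(stats::runif(n_add, -0.2, 0.2), 3)
      qb[n_add] <- -(sum(q2) + sum(qb[-n_add]))  # restore neutrality
      q2 <- c(q2, qb)
    }
    l2 <- ligand_graph(data.frame(element = elems2, charge = q2,
                                  stringsAsFactors = FALSE),
                       cbind(bonds2, 1L), net_charge = 0)
    list(l1 = l1, l2 = l2,
         truth = list(kind = "ligand_pair",
                      common_pairs = cbind(l1 = seq_len(n_atoms),
                                           l2 = seq_len(n_atoms)),
                      appearing = if (n_add > 0) n_atoms + seq_len(n_add)
                                  else integer(0),
                      disappearing = integer(0),
                      prune_expected = perturbed[abs(q2[perturbed] -
                                                       q[perturbed]) > 0.1],
                      perturb = perturb))
  })
}

#' Generate a synthetic affinity table
#'
#' Random ligand binding free energies and uncertainties for two receptors,
#' in the wide format of [read_affinity_table()], with the drawn values as
#' ground truth.
#'
#' @param n_ligands Number of ligands.
#' @param dg_range Free-energy range, kcal/mol.
#' @param err_range Uncertainty range, kcal/mol.
#' @param seed Integer seed.
#' @return List with `table` (wide data frame) and `truth`.
#' @export
gen_affinity_table <- function(n_ligands = 8, dg_range = c(-13, -7),
                               err_range = c(0.05, 0.45), seed = NULL) {
  check_number(n_ligands, "n_ligands", lower = 2)
  with_seed(seed, {
    ids <- sprintf("LIG%02d", seq_len(n_ligands))
    tab <- data.frame(
      ligand = ids, abbreviation = ids, type = "antagonist", pdb = NA,
      dg_a2a = round(stats::runif(n_ligands, dg_range[1], dg_range[2]), 2),
      err_a2a = round(stats::runif(n_ligands, err_range[1], err_range[2]), 2),
      dg_a1 = round(stats::runif(n_ligands, dg_range[1], dg_range[2]), 2),
      err_a1 = round(stats::runif(n_ligands, err_range[1], err_range[2]), 2),
      stringsAsFactors = FALSE)
    list(table = tab, truth = list(kind = "affinity_table", table = tab))
  })
}
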