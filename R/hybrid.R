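#' Ligand graph
#'
#' A small-molecule representation sufficient for hybrid-topology
#' construction: atoms with element labels and partial charges (optionally
#' coordinates), an undirected bond list (optionally with integer bond
#' orders), and the molecule's net charge.
#'
#' @param atoms Data frame with columns `element` (character) and `charge`
#'   (e); optional `x, y, z` coordinates (Angstrom).
#' @param bonds Two-column matrix/data frame of 1-based atom indices;
#'   an optional third column `order` holds integer bond orders (default 1).
#' @param net_charge Net molecular charge in e; defaults to the rounded sum
#'   of partial charges. The partial charges must sum to it within 1e-6 e.
#' @return An object of class `"ligand_graph"`.
#' @export
ligand_graph <- function(atoms, bonds, net_charge = NULL) {
  if (!all(c("element", "charge") %in% names(atoms))) {
    stop_fe("'atoms' needs columns 'element' and 'charge'")
  }
  n <- nrow(atoms)
  if (n < 1L) stop_fe("a ligand needs at least one atom")
  if (any(!is.finite(atoms$charge))) stop_fe("non-finite partial charge")
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0L) {
    if (ncol(bonds) < 2L) stop_fe("'bonds' needs two index columns")
    b <- bonds[, 1:2, drop = FALSE]
    storage.mode(b) <- "integer"
    dimnames(b) <- NULL
    if (any(b < 1L) || any(b > n) || any(b[, 1] == b[, 2])) {
      stop_fe("bond indices out of range or self-bonds present")
    }
    order <- if (ncol(bonds) >= 3L) as.integer(bonds[, 3]) else
      rep(1L, nrow(b))
  } else {
    b <- matrix(integer(0), ncol = 2)
    order <- integer(0)
  }
  net_charge <- net_charge %||% round(sum(atoms$charge))
  if (abs(sum(atoms$charge) - net_charge) > 1e-6) {
    stop_fe("partial charges sum to %.8f but net_charge = %g (tolerance 1e-6 e)",
            sum(atoms$charge), net_charge)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(b)) g <- igraph::add_edges(g, as.integer(t(b)))
  if (n > 1L && !igraph::is_connected(g)) {
    stop_fe("ligand graph must be connected")
  }
  structure(list(atoms = atoms, bonds = b, bond_order = order,
                 net_charge = net_charge, n = n),
            class = "ligand_graph")
}

# n x n bond-order matrix (0 = not bonded).
bond_matrix <- function(lig) {
  A <- matrix(0L, lig$n, lig$n)
  if (nrow(lig$bonds)) {
    A[lig$bonds] <- lig$bond_order
    A[lig$bonds[, 2:1, drop = FALSE]] <- lig$bond_order
  }
  A
}

#' Match the common region of two ligands
#'
#' Finds the maximum common connected subgraph of two ligand graphs --
#' the shared chemical scaffold on which an alchemical transformation is
#' anchored -- as an atom pairing that respects element labels and bond
#' topology (induced matching: two paired L1 atoms are bonded if and only if
#' their L2 partners are, with equal bond order).
#'
#' Implemented by exhaustive backtracking over connected mappings (McGregor
#' style): mappings grow only through bonds, so connectedness holds by
#' construction, and a visited-set memo collapses the many growth orders
#' that reach the same mapping. This is equivalent to clique detection on
#' the modular product graph but scales to the intended ligand sizes. Ties
#' are broken deterministically: larger pairing first, then
#' lexicographically smallest sorted (L1 index, L2 index) sequence.
#'
#' @param l1,l2 [ligand_graph()] objects.
#' @param min_common_atoms Smallest acceptable common region (default 1);
#'   anything smaller is an error, since a transformation without a common
#'   scaffold is not meaningful.
#' @return Integer matrix with columns `l1` and `l2`, one row per matched
#'   atom pair, ordered by L1 index.
#' @export
match_common_region <- function(l1, l2, min_common_atoms = 1) {
  stopifnot(inherits(l1, "ligand_graph"), inherits(l2, "ligand_graph"))
  A1 <- bond_matrix(l1); A2 <- bond_matrix(l2)
  el1 <- toupper(l1$atoms$element); el2 <- toupper(l2$atoms$element)
  n1 <- l1$n; n2 <- l2$n
  if (!any(outer(el1, el2, "=="))) {
    stop_fe("empty common region: no element-compatible atom pairs")
  }

  env <- new.env(parent = emptyenv())
  env$best1 <- integer(0); env$best2 <- integer(0)
  env$seen <- new.env(hash = TRUE, parent = emptyenv())

  extend <- function(m1, m2) {
    key <- paste(sort((m1 - 1L) * n2 + m2), collapse = ",")
    if (!is.null(env$seen[[key]])) return(invisible())
    env$seen[[key]] <- TRUE
    if (length(m1) > length(env$best1) ||
        (length(m1) == length(env$best1) &&
           pairing_before(m1, m2, env$best1, env$best2))) {
      env$best1 <- m1; env$best2 <- m2
    }
    # frontier: unmapped L1 atoms bonded to the mapped set
    cand <- setdiff(which(colSums(A1[m1, , drop = FALSE] > 0L) > 0L), m1)
    for (i in cand) {
      for (j in setdiff(which(el2 == el1[i]), m2)) {
        # induced compatibility against every mapped pair
        if (all(A1[i, m1] == A2[j, m2])) extend(c(m1, i), c(m2, j))
      }
    }
    invisible()
  }
  for (i in seq_len(n1)) {
    for (j in which(el2 == el1[i])) extend(i, j)
  }
  pairing <- cbind(l1 = env$best1, l2 = env$best2)
  pairing <- pairing[order(pairing[, 1]), , drop = FALSE]
  if (nrow(pairing) < min_common_atoms) {
    stop_fe("common region has %d atom(s), below min_common_atoms = %d",
            nrow(pairing), min_common_atoms)
  }
  pairing
}

# TRUE if pairing (a1, a2) precedes (b1, b2) lexicographically when both
# are sorted by (L1 index, L2 index); used only at equal size.
pairing_before <- function(a1, a2, b1, b2) {
  ka <- order(a1, a2); kb <- order(b1, b2)
  va <- c(rbind(a1[ka], a2[ka])); vb <- c(rbind(b1[kb], b2[kb]))
  d <- which(va != vb)
  length(d) > 0L && va[d[1]] < vb[d[1]]
}

#' Prune a common region by charge difference
#'
#' Atoms whose partial charges differ between the two ligands by strictly
#' more than `threshold` (default 0.1 e) are removed from the common region:
#' such atoms change their electrostatic character too much to be treated as
#' shared. A pair with exactly the threshold difference is retained. If the
#' pruning disconnects the remaining region, the largest connected component
#' is kept (a common "region" is one connected scaffold); ties go to the
#' component with the lexicographically smallest L1 indices.
#'
#' @param pairing Pairing matrix from [match_common_region()].
#' @param l1,l2 The [ligand_graph()] objects the pairing refers to.
#' @param threshold Charge-difference threshold, e (default 0.1).
#' @return Pruned pairing matrix; error if nothing survives.
#' @export
prune_by_charge <- function(pairing, l1, l2, threshold = 0.1) {
  check_number(threshold, "threshold", lower = 0)
  if (nrow(pairing) == 0L) stop_fe("empty pairing")
  dq <- abs(l1$atoms$charge[pairing[, 1]] - l2$atoms$charge[pairing[, 2]])
  keep <- dq <= threshold          # "more than" is strict removal
  pairing <- pairing[keep, , drop = FALSE]
  if (nrow(pairing) == 0L) {
    stop_fe("empty common region after charge pruning (threshold %g e)",
            threshold)
  }
  # re-validate connectivity; keep the largest connected component
  A1 <- bond_matrix(l1)
  sub <- igraph::graph_from_adjacency_matrix(
    A1[pairing[, 1], pairing[, 1], drop = FALSE] > 0L, mode = "undirected")
  memb <- igraph::components(sub)$membership
  sizes <- tabulate(memb)
  cand <- which(sizes == max(sizes))
  pick <- cand[which.min(vapply(cand, function(cc) {
    min(pairing[memb == cc, 1])
  }, numeric(1)))]
  pairing[memb == pick, , drop = FALSE]
}

#' Assign hybrid-ligand charges
#'
#' Builds the dual-topology hybrid from a (pruned) common-region pairing:
#' the common atoms receive one shared charge, the average of their charges
#' in the two ligands; the charge displaced by averaging is redistributed
#' uniformly over the corresponding end state's unique atoms (disappearing
#' atoms for L1, appearing atoms for L2) so that each end state's net charge
#' is conserved exactly. Uniform redistribution is the minimal
#' conservation-preserving substitute for a full charge refit.
#'
#' @param pairing Pairing matrix (see [prune_by_charge()]).
#' @param l1,l2 [ligand_graph()] objects.
#' @return An object of class `"hybrid_ligand"`: `common_pairs`,
#'   `disappearing` and `appearing` index vectors, `common_charges`, and the
#'   adjusted `disappearing_charges` / `appearing_charges`. End-state sums
#'   are verified to 1e-6 e.
#' @export
assign_hybrid_charges <- function(pairing, l1, l2) {
  if (nrow(pairing) == 0L) stop_fe("empty pairing")
  q1 <- l1$atoms$charge[pairing[, 1]]
  q2 <- l2$atoms$charge[pairing[, 2]]
  common <- (q1 + q2) / 2
  dis <- setdiff(seq_len(l1$n), pairing[, 1])
  app <- setdiff(seq_len(l2$n), pairing[, 2])

  adjust <- function(net, unique_idx, unique_q, who) {
    residual <- net - sum(common) - sum(unique_q)
    if (length(unique_idx) == 0L) {
      if (abs(residual) > 1e-6) {
        stop_fe("%s end state has no unique atoms to absorb a %.4g e residual: cannot conserve net charge",
                who, residual)
      }
      return(numeric(0))
    }
    unique_q + residual / length(unique_idx)
  }
  dis_q <- adjust(l1$net_charge, dis, l1$atoms$charge[dis], "L1")
  app_q <- adjust(l2$net_charge, app, l2$atoms$charge[app], "L2")

  stopifnot(abs(sum(common) + sum(dis_q) - l1$net_charge) <= 1e-6,
            abs(sum(common) + sum(app_q) - l2$net_charge) <= 1e-6)
  structure(list(common_pairs = pairing,
                 disappearing = dis, appearing = app,
                 common_charges = common,
                 disappearing_charges = dis_q,
                 appearing_charges = app_q,
                 l1_net = l1$net_charge, l2_net = l2$net_charge),
            class = "hybrid_ligand")
}

#' Build a hybrid ligand end to end
#'
#' Convenience wrapper: [match_common_region()], then [prune_by_charge()],
#' then [assign_hybrid_charges()].
#'
#' @inheritParams match_common_region
#' @param charge_threshold Charge-difference pruning threshold, e.
#' @return A `"hybrid_ligand"` (see [assign_hybrid_charges()]).
#' @export
build_hybrid <- function(l1, l2, charge_threshold = 0.1,
                         min_common_atoms = 1) {
  p <- match_common_region(l1, l2, min_common_atoms = min_common_atoms)
  p <- prune_by_charge(p, l1, l2, threshold = charge_threshold)
  if (nrow(p) < min_common_atoms) {
    stop_fe("common region has %d atom(s) after pruning, below min_common_atoms = %d",
            nrow(p), min_common_atoms)
  }
  assign_hybrid_charges(p, l1, l2)
}

#' @export
print.hybrid_ligand <- function(x, ...) {
  cat(sprintf("<hybrid_ligand> %d common pairs, %d disappearing, %d appearing\n",
              nrow(x$common_pairs), length(x$disappearing),
              length(x$appearing)))
  cat(sprintf("  end-state net charges: L1 = %+.4f e, L2 = %+.4f e\n",
              sum(x$common_charges) + sum(x$disappearing_charges),
              sum(x$common_charges) + sum(x$appearing_charges)))
  invisible(x)
}
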