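# Independent oracles used by the tests. These deliberately share no code
# with the implementation: exhaustive search, leave-one-out refits and
# textbook formulas, at sizes where brute force is affordable.

# --- maximum common connected induced subgraph, exhaustive backtracking ---

oracle_bond_matrix <- function(lig) {
  A <- matrix(0L, lig$n, lig$n)
  if (nrow(lig$bonds)) {
    for (r in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds[r, 1]; j <- lig$bonds[r, 2]
      A[i, j] <- A[j, i] <- lig$bond_order[r]
    }
  }
  A
}

# Largest connected element/bond-compatible atom pairing between two
# ligand graphs; returns its size. Backtracking over mappings grown only
# through bonds (connectedness by construction), seeded at every
# compatible start pair. A visited table skips mapping SETS already
# expanded: a mapping's possible extensions depend only on the set of
# mapped pairs, not on the order they were added, so this prunes duplicate
# work without skipping any state.
oracle_mcs_size <- function(l1, l2) {
  A1 <- oracle_bond_matrix(l1); A2 <- oracle_bond_matrix(l2)
  e1 <- toupper(l1$atoms$element); e2 <- toupper(l2$atoms$element)
  best <- 0L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  extend <- function(m1, m2) {
    state <- paste(sort(paste(m1, m2, sep = ":")), collapse = "|")
    if (isTRUE(visited[[state]])) return()
    visited[[state]] <- TRUE
    best <<- max(best, length(m1))
    # frontier: unmapped l1 atoms bonded to the mapped set
    cand1 <- setdiff(which(colSums(A1[m1, , drop = FALSE] > 0) > 0), m1)
    for (i in cand1) {
      for (j in setdiff(which(e2 == e1[i]), m2)) {
        # induced compatibility against every mapped pair
        if (all(A1[i, m1] == A2[j, m2])) extend(c(m1, i), c(m2, j))
      }
    }
  }
  for (i in seq_len(l1$n)) {
    for (j in which(e2 == e1[i])) extend(i, j)
  }
  best
}

# TRUE if `pairing` is a valid common connected induced subgraph pairing.
oracle_valid_pairing <- function(pairing, l1, l2) {
  if (nrow(pairing) == 0L) return(FALSE)
  if (anyDuplicated(pairing[, 1]) || anyDuplicated(pairing[, 2])) {
    return(FALSE)
  }
  e1 <- toupper(l1$atoms$element); e2 <- toupper(l2$atoms$element)
  if (!all(e1[pairing[, 1]] == e2[pairing[, 2]])) return(FALSE)
  A1 <- oracle_bond_matrix(l1); A2 <- oracle_bond_matrix(l2)
  S1 <- A1[pairing[, 1], pairing[, 1], drop = FALSE]
  S2 <- A2[pairing[, 2], pairing[, 2], drop = FALSE]
  if (!all(S1 == S2)) return(FALSE)
  if (nrow(pairing) == 1L) return(TRUE)
  # connectivity of the common region (breadth-first over common bonds)
  seen <- 1L
  repeat {
    grow <- which(colSums(S1[seen, , drop = FALSE] > 0) > 0)
    new <- setdiff(grow, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == nrow(pairing)
}

# --- Cook's distance by leave-one-out refit -------------------------------

oracle_cooks <- function(x, y) {
  n <- length(x)
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  s2 <- sum(residuals(fit)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    f2 <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(f2)[1] + coef(f2)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# --- textbook Pearson correlation ----------------------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# --- hand-rolled trapezoid summation -------------------------------------

oracle_trapezoid <- function(lam, val) {
  tot <- 0
  for (k in seq_len(length(lam) - 1)) {
    tot <- tot + (lam[k + 1] - lam[k]) * (val[k] + val[k + 1]) / 2
  }
  tot
}

# small hand-built ligand fixtures (ethane- and ethanol-like heavy+H toys)
toy_ethane <- function() {
  ligand_graph(
    data.frame(element = c("C", "C", "H", "H", "H", "H", "H", "H"),
               charge = c(-0.06, -0.06, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)),
    cbind(c(1, 1, 1, 1, 2, 2, 2), c(2, 3, 4, 5, 6, 7, 8), 1L),
    net_charge = 0)
}

toy_ethanol <- function() {
  ligand_graph(
    data.frame(element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
               charge = c(-0.09, 0.13, -0.60, 0.03, 0.03, 0.03, 0.02, 0.02,
                          0.43)),
    cbind(c(1, 1, 1, 1, 2, 2, 2, 3), c(2, 4, 5, 6, 3, 7, 8, 9), 1L),
    net_charge = 0)
}
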