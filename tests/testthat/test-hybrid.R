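test_that("identical ligands match completely with no unique atoms", {
  l <- toy_ethane()
  p <- match_common_region(l, l)
  expect_equal(nrow(p), l$n)
  expect_equal(p[, 1], p[, 2])
  h <- assign_hybrid_charges(prune_by_charge(p, l, l), l, l)
  expect_length(h$disappearing, 0)
  expect_length(h$appearing, 0)
  expect_equal(h$common_charges, l$atoms$charge, tolerance = 1e-12)
})

test_that("ethane/ethanol match equals the exhaustive oracle", {
  l1 <- toy_ethane()
  l2 <- toy_ethanol()
  p <- match_common_region(l1, l2)
  expect_equal(nrow(p), oracle_mcs_size(l1, l2))
  expect_true(oracle_valid_pairing(p, l1, l2))
})

test_that("dissimilar molecules yield a small fragment or a rejection", {
  methane <- ligand_graph(
    data.frame(element = c("C", "H", "H", "H", "H"),
               charge = c(-0.4, 0.1, 0.1, 0.1, 0.1)),
    cbind(1, 2:5, 1L), net_charge = 0)
  ring <- ligand_graph(
    data.frame(element = rep("C", 6), charge = rep(0, 6)),
    cbind(1:6, c(2:6, 1), 1L), net_charge = 0)
  # only single atoms are compatible (induced matching forbids taking two
  # bonded ring carbons for methane's C-H)
  p <- match_common_region(methane, ring)
  expect_equal(nrow(p), oracle_mcs_size(methane, ring))
  expect_error(match_common_region(methane, ring, min_common_atoms = 4),
               "below min_common_atoms")
})

test_that("charge pruning is strict-greater at the 0.1e boundary", {
  mk <- function(q) ligand_graph(
    data.frame(element = c("C", "C", "C"), charge = c(q, 0.1, -0.1 - q)),
    cbind(1:2, 2:3, 1L), net_charge = 0)
  l1 <- mk(0)
  exact <- mk(0.10)   # atom 1 differs by exactly 0.10 e
  over <- mk(0.15)    # atom 1 differs by 0.15 e
  p <- match_common_region(l1, l1)
  expect_equal(nrow(prune_by_charge(p, l1, exact)), 3)  # retained
  pruned <- prune_by_charge(p, l1, over)
  expect_false(1 %in% pruned[, 1])                      # removed
  # third atom's charge also shifts; keep only the |dq| <= 0.1 scaffold
  expect_true(all(abs(l1$atoms$charge[pruned[, 1]] -
                        over$atoms$charge[pruned[, 2]]) <= 0.1))
})

test_that("pruning keeps one connected scaffold", {
  # path A-B-C-D-E where the middle atom's charge is shifted: pruning C
  # splits {A,B} from {D,E}; the largest (here tie -> lexicographically
  # first) component must be returned, not a disconnected remnant
  mkpath <- function(qc) ligand_graph(
    data.frame(element = rep("C", 5),
               charge = c(0.05, 0.05, qc, 0.05, -0.15 - qc)),
    cbind(1:4, 2:5, 1L), net_charge = 0)
  l1 <- mkpath(0)
  l2 <- mkpath(0.2)
  l2$atoms$charge[5] <- l1$atoms$charge[5] + 0  # keep ends comparable
  p <- match_common_region(l1, l1)  # identity pairing of the path
  pr <- prune_by_charge(p, l1, l2)
  expect_lte(nrow(pr), 2)
  # connected: consecutive path indices
  expect_true(all(diff(sort(pr[, 1])) == 1))
})

test_that("hybrid charges average and conserve each end state", {
  # force a single common pair with charges +0.30 / +0.40
  l1 <- ligand_graph(data.frame(element = c("C", "H"),
                                charge = c(0.30, -0.30)),
                     cbind(1, 2, 1L), net_charge = 0)
  l2 <- ligand_graph(data.frame(element = c("C", "F"),
                                charge = c(0.40, -0.40)),
                     cbind(1, 2, 1L), net_charge = 0)
  p <- match_common_region(l1, l2)   # the carbon pair only
  h <- assign_hybrid_charges(p, l1, l2)
  expect_equal(h$common_charges, 0.35)
  # L1 residual -0.05 lands on the disappearing H, L2 residual +0.05 on F
  expect_equal(h$disappearing_charges, -0.35)
  expect_equal(h$appearing_charges, -0.35)
  expect_equal(sum(h$common_charges) + sum(h$disappearing_charges), 0,
               tolerance = 1e-12)
  expect_equal(sum(h$common_charges) + sum(h$appearing_charges), 0,
               tolerance = 1e-12)
})

test_that("conservation fails loudly when no unique atoms can absorb it", {
  l1 <- ligand_graph(data.frame(element = "C", charge = 0.2),
                     matrix(integer(0), ncol = 2), net_charge = 0.2)
  l2 <- ligand_graph(data.frame(element = "C", charge = 0.3),
                     matrix(integer(0), ncol = 2), net_charge = 0.3)
  p <- match_common_region(l1, l2)
  expect_error(assign_hybrid_charges(p, l1, l2), "cannot conserve")
})

test_that("generated pairs: oracle equivalence, conservation, symmetry", {
  for (s in 1:12) {
    gp <- gen_ligand_pair(n_atoms = 4 + (s %% 6), n_add = 1 + (s %% 3),
                          seed = s)
    p <- match_common_region(gp$l1, gp$l2)
    expect_equal(nrow(p), oracle_mcs_size(gp$l1, gp$l2))
    expect_true(oracle_valid_pairing(p, gp$l1, gp$l2))
    # construction bookkeeping: true common region is the full core
    expect_equal(nrow(p), nrow(gp$truth$common_pairs))

    h <- build_hybrid(gp$l1, gp$l2)
    expect_lt(abs(sum(h$common_charges) + sum(h$disappearing_charges) -
                    gp$l1$net_charge), 1e-6)
    expect_lt(abs(sum(h$common_charges) + sum(h$appearing_charges) -
                    gp$l2$net_charge), 1e-6)
    # prune-expected pairs are indeed outside the pruned common region
    pr <- prune_by_charge(p, gp$l1, gp$l2)
    for (i in gp$truth$prune_expected) {
      expect_false(i %in% pr[, 1])
    }

    # symmetry: swapping ligand roles swaps appearing/disappearing
    hs <- build_hybrid(gp$l2, gp$l1)
    expect_equal(sort(hs$appearing), sort(h$disappearing))
    expect_equal(sort(hs$disappearing), sort(h$appearing))
  }
})

test_that("rebuilding from a built hybrid's end states reproduces it", {
  gp <- gen_ligand_pair(seed = 77)
  h <- build_hybrid(gp$l1, gp$l2)
  # reconstruct the two end-state ligands with hybrid charges
  q1 <- gp$l1$atoms$charge
  q1[h$common_pairs[, 1]] <- h$common_charges
  q1[h$disappearing] <- h$disappearing_charges
  e1 <- ligand_graph(transform(gp$l1$atoms, charge = q1),
                     cbind(gp$l1$bonds, gp$l1$bond_order),
                     net_charge = gp$l1$net_charge)
  q2 <- gp$l2$atoms$charge
  q2[h$common_pairs[, 2]] <- h$common_charges
  q2[h$appearing] <- h$appearing_charges
  e2 <- ligand_graph(transform(gp$l2$atoms, charge = q2),
                     cbind(gp$l2$bonds, gp$l2$bond_order),
                     net_charge = gp$l2$net_charge)
  h2 <- build_hybrid(e1, e2)
  expect_equal(h2$common_pairs, h$common_pairs)
  expect_equal(h2$common_charges, h$common_charges, tolerance = 1e-12)
  expect_equal(h2$disappearing_charges, h$disappearing_charges,
               tolerance = 1e-12)
  expect_equal(h2$appearing_charges, h$appearing_charges, tolerance = 1e-12)
})
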