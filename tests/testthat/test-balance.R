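test_that("verify_balance sums elements and charge to zero", {
  chems <- hexokinase_chemicals()
  expect_true(verify_balance(hexokinase_participants(TRUE), chems))
  expect_false(verify_balance(hexokinase_participants(FALSE), chems))
  expect_true(verify_balance(
    data.frame(chemical_id = character(), stoichiometry = integer(),
               role = character()), chems))
  # missing formula or charge gives the unknown signal, never FALSE
  chems$glc$formula <- NULL
  expect_true(is.na(verify_balance(hexokinase_participants(TRUE), chems)))
})

test_that("a stripped proton is restored with original stoichiometries", {
  chems <- hexokinase_chemicals()
  rxn <- reaction_entity("hex", participants =
                           hexokinase_participants(FALSE))
  res <- balance_reaction(rxn, chems)
  expect_equal(res$status, "rebalanced")
  expect_equal(nrow(res$delta), 1L)
  expect_equal(res$delta$chemical_id, "H+")
  expect_equal(res$delta$new_stoich, 1L)
  # original participants untouched
  orig <- hexokinase_participants(FALSE)
  kept <- res$participants[res$participants$chemical_id != "H+", ]
  expect_equal(kept$stoichiometry, orig$stoichiometry)
  expect_true(isTRUE(verify_balance(res$participants, chems)))
})

test_that("balanced reactions are recognised and balancing is idempotent", {
  chems <- hexokinase_chemicals()
  rxn <- reaction_entity("hex", participants =
                           hexokinase_participants(TRUE))
  res <- balance_reaction(rxn, chems)
  expect_equal(res$status, "already_balanced")
  expect_equal(nrow(res$delta), 0L)
  # rebalanced output re-balances to already_balanced
  broken <- reaction_entity("hex", participants =
                              hexokinase_participants(FALSE))
  fixed <- balance_reaction(broken, chems)
  again <- balance_reaction(reaction_entity("hex",
                                            participants =
                                              fixed$participants), chems)
  expect_equal(again$status, "already_balanced")
})

test_that("missing composition or impossible chemistry is reported", {
  chems <- list(A = chemical_entity("A", formula = "CH4", charge = 0L),
                B = chemical_entity("B", formula = "CO2", charge = 0L),
                C = chemical_entity("C", name = "class node"))
  p <- data.frame(chemical_id = c("A", "B"), stoichiometry = c(-1L, 1L),
                  role = "reactant")
  res <- balance_reaction(reaction_entity("r", participants = p), chems,
                          kg_config(balance = list(max_coefficient = 5L)))
  expect_equal(res$status, "unbalanceable")
  p2 <- data.frame(chemical_id = c("A", "C"), stoichiometry = c(-1L, 1L),
                   role = "reactant")
  expect_equal(balance_reaction(reaction_entity("r2", participants = p2),
                                chems)$status, "unknown")
})

test_that("the solver optimum equals exhaustive enumeration", {
  set.seed(31)
  pool <- list(
    chemical_entity("a", formula = "CH2O", charge = 0L),
    chemical_entity("b", formula = "C2H4O2", charge = 0L),
    chemical_entity("c", formula = "C3H6O3", charge = 0L),
    chemical_entity("d", formula = "CH3N", charge = 0L),
    chemical_entity("e", formula = "C2H5NO", charge = -1L),
    chemical_entity("f", formula = "HO", charge = -1L))
  chems <- stats::setNames(pool, vapply(pool, `[[`, character(1), "id"))
  cfg <- kg_config(balance = list(max_coefficient = 3L))
  n_checked <- 0L
  for (case in 1:40) {
    k <- sample(2:5, 1)
    ids <- sample(names(chems), k)
    side <- c(-1L, 1L, sample(c(-1L, 1L), k - 2, replace = TRUE))
    mags <- sample(1:3, k, replace = TRUE)
    p <- data.frame(chemical_id = ids, stoichiometry = side * mags,
                    role = "reactant", stringsAsFactors = FALSE)
    res <- balance_reaction(reaction_entity("r", participants = p),
                            chems, cfg)
    opt <- oracle_balance_optimum(p, chems, max_coef = 3L)
    if (is.null(opt)) {
      expect_equal(res$status, "unbalanceable", info = case)
    } else {
      expect_true(res$status %in% c("already_balanced", "rebalanced"),
                  info = case)
      dev <- sum(abs(res$delta$new_stoich[res$delta$old_stoich != 0] -
                       res$delta$old_stoich[res$delta$old_stoich != 0]))
      added <- sum(abs(res$delta$new_stoich[res$delta$old_stoich == 0]))
      expect_equal(c(dev, added), opt, info = case)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 0L)   # the case set must exercise feasible repairs
})

test_that("all corrupted fixture reactions recover their stoichiometries", {
  d <- tempfile()
  truth <- generate_fixture(fixture_spec(seed = 42), d)
  g <- suppressWarnings(build_graph(d))$graph
  expect_gt(length(truth$unbalanced_ids), 0L)
  for (rid in truth$unbalanced_ids) {
    p <- get_node(g, "Reaction", rid)$participants
    o <- truth$original_participants[[rid]]
    expect_equal(sort(paste(p$chemical_id, p$stoichiometry)),
                 sort(paste(o$chemical_id, o$stoichiometry)), info = rid)
    expect_true(isTRUE(get_node(g, "Reaction", rid)$balance))
  }
  # soundness: every reaction with full composition data verifies
  for (rid in graph_nodes(g, "Reaction")) {
    v <- verify_balance(get_node(g, "Reaction", rid)$participants,
                        g$nodes$Chemical)
    expect_true(isTRUE(v), info = rid)
  }
  unlink(d, recursive = TRUE)
})
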