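# GPR parsing, pseudo-enzyme coding, isozyme detection, mutated bounds.

clause_keys <- function(rule) {
  sort(vapply(rule$clauses, paste, character(1), collapse = "&"))
}

test_that("parse_gpr normalizes rules to DNF clauses", {
  expect_identical(clause_keys(parse_gpr("G1 and G2")), "G1&G2")
  expect_identical(clause_keys(parse_gpr("(G1 and G2) or G3")),
                   c("G1&G2", "G3"))
  expect_identical(clause_keys(parse_gpr("G1 or G2")), c("G1", "G2"))
  # case-insensitive operators, distribution over AND
  expect_identical(clause_keys(parse_gpr("G1 AND (G2 OR G3)")),
                   c("G1&G2", "G1&G3"))
  # duplicate and absorbed clauses are removed
  expect_identical(clause_keys(parse_gpr("G1 or (G1 and G2) or G1")), "G1")
  expect_identical(length(parse_gpr("")$clauses), 0L)
})

test_that("malformed GPR strings fail with a positioned parse error", {
  expect_error(parse_gpr("(G1 and G2"), "position 1")
  expect_error(parse_gpr("G1 and or G2"), "parse error")
  expect_error(parse_gpr("G1 %% G2"), "position")
})

test_that("pseudo-enzyme codes are shared across reactions and isozymes detected", {
  rules <- list(R1 = parse_gpr("G1 or G2"),
                R2 = parse_gpr("G1 or G2"),
                R3 = parse_gpr("G1"),
                R4 = parse_gpr("G1 or (G2 and G3)"))
  tab <- build_pseudoenzyme_table(rules)
  # {G1} and {G2} coded once, shared by R1 and R2
  expect_identical(tab$reaction_enzymes$R1, tab$reaction_enzymes$R2)
  expect_identical(length(tab$codes), 3L)  # {G1}, {G2}, {G2&G3}
  # sole-enzyme reaction is not isozyme-backed
  expect_false("R3" %in% tab$isozyme_set$G1)
  # OR of a single gene with an AND pair: every involved gene is isozymic
  expect_true(all(c("R1", "R2", "R4") %in% tab$isozyme_set$G1))
  expect_true("R4" %in% tab$isozyme_set$G2)
  expect_true("R4" %in% tab$isozyme_set$G3)
  # gene -> reaction index covers every mention
  expect_setequal(tab$gene_reactions$G1, c("R1", "R2", "R3", "R4"))
  expect_setequal(tab$gene_reactions$G3, "R4")
})

make_mut_fixture <- function() {
  mets <- rbind(met_row("A"), met_row("B"))
  rxns <- data.frame(id = c("EX_A", "RU", "RI1", "RI2", "EX_B"),
                     lb = c(0, 0, 0, 0, 0), ub = c(10, 10, 10, 10, 20),
                     gpr = c("", "GU", "GX or GY", "GZ", ""),
                     stringsAsFactors = FALSE)
  net <- make_net(mets, rxns, list(
    c(A_c = 1), c(A_c = -1, B_c = 1), c(A_c = -1, B_c = 1),
    c(A_c = -1, B_c = 1), c(B_c = -1)))
  split <- split_reversible(net)
  basal <- list(vf = stats::setNames(c(6, 2, 2, 2, 6), rxns$id),
                vb = stats::setNames(rep(0, 5), rxns$id))
  list(split = split, table = build_pseudoenzyme_table(net), basal = basal)
}

test_that("upregulation interpolates the forward bound towards its maximum", {
  fx <- make_mut_fixture()
  spec <- dysregulation_spec("GU", "up", 0.5, basal = fx$basal)
  mb <- mutate_bounds(fx$split, fx$table, spec)
  expect_equal(mb$vf_lb[["RU"]], 6)   # (1-0.5)*2 + 0.5*10
  expect_equal(mb$vf_ub[["RU"]], 10)
  # delta = 1 pins the flux at the upper bound
  mb1 <- mutate_bounds(fx$split, fx$table,
                       dysregulation_spec("GU", "up", 1, basal = fx$basal))
  expect_equal(mb1$vf_lb[["RU"]], 10)
  expect_equal(mb1$vf_ub[["RU"]], 10)
})

test_that("down/knockout spare isozyme-backed reactions; reaction mode does not", {
  fx <- make_mut_fixture()
  # GX's only reaction RI1 is OR-ed with GY: knockout leaves bounds unchanged
  mb <- mutate_bounds(fx$split, fx$table,
                      dysregulation_spec("GX", "knockout", 1, basal = fx$basal))
  expect_length(mb$omu, 0L)
  expect_equal(mb$vf_ub[["RI1"]], fx$split$vf_ub[["RI1"]])
  # GZ has no isozyme: knockout zeroes the reaction
  mb2 <- mutate_bounds(fx$split, fx$table,
                       dysregulation_spec("GZ", "knockout", 1, basal = fx$basal))
  expect_equal(mb2$vf_ub[["RI2"]], 0)
  expect_equal(mb2$vf_lb[["RI2"]], 0)
  # reaction-level targeting bypasses the exemption
  mb3 <- mutate_bounds(fx$split, fx$table,
                       dysregulation_spec("RI1", "knockout", 1,
                                          type = "reaction",
                                          basal = fx$basal))
  expect_equal(mb3$vf_ub[["RI1"]], 0)
  # downregulation of GZ shrinks the forward cap towards the lower bound
  mb4 <- mutate_bounds(fx$split, fx$table,
                       dysregulation_spec("GZ", "down", 0.25, basal = fx$basal))
  expect_equal(mb4$vf_ub[["RI2"]], 0.75 * 2 + 0.25 * 0)
})

test_that("dysregulation domain errors are caught early", {
  fx <- make_mut_fixture()
  expect_error(dysregulation_spec("GU", "up", 0), "\\(0, 1\\]")
  expect_error(dysregulation_spec("GU", "up", 1.2), "\\(0, 1\\]")
  expect_error(dysregulation_spec("GU", "sideways", 0.5), "mode")
  expect_error(mutate_bounds(fx$split, fx$table,
                             dysregulation_spec("NOPE", "up", 0.5,
                                                basal = fx$basal)),
               "unknown gene")
  # opposing up/down on one reaction never materializes for genes: the
  # isozyme exemption silently drops the down branch on RI1
  mb_ok <- mutate_bounds(fx$split, fx$table,
                         dysregulation_spec(c("GX", "GY"), c("up", "down"),
                                            0.5, basal = fx$basal))
  expect_identical(unname(mb_ok$mode["RI1"]), "up")
  # a reaction-level target bypasses the exemption and exposes the conflict
  expect_error(mutate_bounds(fx$split, fx$table,
                             dysregulation_spec(c("GX", "RI1"), c("up", "down"),
                                                0.5,
                                                type = c("gene", "reaction"),
                                                basal = fx$basal)),
               "conflicting")
})

test_that("mutated intervals nest, move monotonically in delta, and hit the basal limit", {
  fx <- make_mut_fixture()
  deltas <- seq(0.05, 1, by = 0.05)
  prev_lb <- -Inf
  prev_ub <- Inf
  for (d in deltas) {
    up <- mutate_bounds(fx$split, fx$table,
                        dysregulation_spec("GU", "up", d, basal = fx$basal))
    dn <- mutate_bounds(fx$split, fx$table,
                        dysregulation_spec("GZ", "down", d, basal = fx$basal))
    # nesting within the original split box
    expect_gte(up$vf_lb[["RU"]], fx$split$vf_lb[["RU"]])
    expect_lte(up$vf_ub[["RU"]], fx$split$vf_ub[["RU"]])
    expect_gte(dn$vf_lb[["RI2"]], fx$split$vf_lb[["RI2"]])
    expect_lte(dn$vf_ub[["RI2"]], fx$split$vf_ub[["RI2"]])
    # monotone in delta
    expect_gte(up$vf_lb[["RU"]], prev_lb)
    expect_lte(dn$vf_ub[["RI2"]], prev_ub)
    prev_lb <- up$vf_lb[["RU"]]
    prev_ub <- dn$vf_ub[["RI2"]]
  }
  # delta -> 0+ limit: interval approaches [basal, ub] (up) / [lb, basal] (down)
  eps <- 1e-9
  up0 <- mutate_bounds(fx$split, fx$table,
                       dysregulation_spec("GU", "up", eps, basal = fx$basal))
  dn0 <- mutate_bounds(fx$split, fx$table,
                       dysregulation_spec("GZ", "down", eps, basal = fx$basal))
  expect_equal(up0$vf_lb[["RU"]], fx$basal$vf[["RU"]], tolerance = 1e-6)
  expect_equal(dn0$vf_ub[["RI2"]], fx$basal$vf[["RI2"]], tolerance = 1e-6)
})
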