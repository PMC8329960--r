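# SBML reading/writing, reversible-flux splitting, flux consistency.

tiny_sbml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="tiny">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="m" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="M_pyr_c" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '      <species id="M_pyr_m" compartment="m" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="R_EX_pyr" reversible="false">',
    '        <listOfProducts>',
    '          <speciesReference species="M_pyr_c" stoichiometry="1" constant="true"/>',
    '        </listOfProducts>',
    '      </reaction>',
    '      <reaction id="R_T1" reversible="true">',
    '        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: GA or GB</p></body></notes>',
    '        <listOfReactants>',
    '          <speciesReference species="M_pyr_c" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '        <listOfProducts>',
    '          <speciesReference species="M_pyr_m" stoichiometry="1" constant="true"/>',
    '        </listOfProducts>',
    '      </reaction>',
    '      <reaction id="R_DM_pyr" reversible="false">',
    '        <listOfReactants>',
    '          <speciesReference species="M_pyr_m" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}

test_that("read_sbml extracts counts, compartments, base ids and notes-GPR", {
  path <- tiny_sbml(withr::local_tempfile(fileext = ".xml"))
  expect_warning(net <- read_sbml(path), "defaults applied")
  expect_equal(dim(net$S), c(2L, 3L))
  expect_setequal(net$metabolites$base_id, "pyr")
  expect_setequal(net$metabolites$compartment, c("c", "m"))
  expect_equal(net$reactions$gpr[net$reactions$id == "T1"], "GA or GB")
  # default bounds per reversibility
  t1 <- net$reactions[net$reactions$id == "T1", ]
  expect_equal(c(t1$lb, t1$ub), c(-1000, 1000))
  ex <- net$reactions[net$reactions$id == "EX_pyr", ]
  expect_equal(c(ex$lb, ex$ub), c(0, 1000))
  expect_true(all(net$reactions$is_exchange[net$reactions$id != "T1"]))
})

test_that("truncated or non-SBML input raises a format error, never a partial network", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?><sbml><model><listOfSpec', bad)
  expect_error(read_sbml(bad), "format error")
  notsbml <- withr::local_tempfile(fileext = ".xml")
  writeLines("<foo/>", notsbml)
  expect_error(read_sbml(notsbml), "not <sbml>")
  expect_error(read_sbml(file.path(tempdir(), "does_not_exist.xml")),
               "not found")
})

test_that("SBML round trip preserves stoichiometry, bounds and GPR semantics", {
  pair <- toy_pair_cached()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(pair$normal, path)
  back <- read_sbml(path)
  expect_identical(back$reactions$id, pair$normal$reactions$id)
  expect_identical(back$metabolites$base_id, pair$normal$metabolites$base_id)
  expect_identical(back$metabolites$compartment,
                   pair$normal$metabolites$compartment)
  expect_equal(back$S, pair$normal$S)
  expect_equal(back$reactions$lb, pair$normal$reactions$lb)
  expect_equal(back$reactions$ub, pair$normal$reactions$ub)
  # GPR strings may re-parenthesize; compare parsed DNF clause sets
  for (k in seq_len(nrow(back$reactions))) {
    a <- parse_gpr(pair$normal$reactions$gpr[k])$clauses
    b <- parse_gpr(back$reactions$gpr[k])$clauses
    key <- function(cl) sort(vapply(cl, paste, character(1), collapse = "&"))
    expect_identical(key(a), key(b))
  }
})

test_that("an independent SBML reader recovers the written model", {
  # COBRApy (separate codebase) as read-back oracle for the writer
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  pair <- toy_pair_cached()
  dir <- withr::local_tempdir()
  write_sbml(pair$normal, file.path(dir, "normal.xml"))
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import cobra, sys",
    sprintf("m = cobra.io.read_sbml_model(%s)",
            deparse(file.path(dir, "normal.xml"))),
    "r = m.reactions.get_by_id('PS')",
    "print(len(m.metabolites), len(m.reactions), len(m.genes))",
    "print(r.lower_bound, r.upper_bound)",
    "print(sorted(g.id for g in r.genes))"), script)
  out <- suppressWarnings(system2(py, script, stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 3, "cobra unavailable")
  expect_identical(out[1], paste(nrow(pair$normal$metabolites),
                                 nrow(pair$normal$reactions), 10))
  ps <- pair$normal$reactions[pair$normal$reactions$id == "PS", ]
  expect_equal(as.numeric(strsplit(out[2], " ")[[1]]), c(ps$lb, ps$ub))
  expect_identical(out[3], "['G7']")
})

test_that("split_reversible follows the sign convention and is lossless", {
  mets <- rbind(met_row("A"), met_row("B"))
  rxns <- data.frame(id = c("REV", "IRR"), lb = c(-10, 0), ub = c(20, 5),
                     gpr = "", stringsAsFactors = FALSE)
  net <- make_net(mets, rxns, list(c(A_c = -1, B_c = 1), c(A_c = -1, B_c = 1)))
  sp <- split_reversible(net)
  expect_equal(unname(sp$vf_lb), c(0, 0))
  expect_equal(unname(sp$vf_ub), c(20, 5))
  expect_equal(unname(sp$vb_lb), c(0, 0))
  expect_equal(unname(sp$vb_ub), c(10, 0))
  # identity mapping: any feasible net flux maps into the split box
  for (v in c(-10, -3.5, 0, 7, 20)) {
    vf <- max(v, 0); vb <- max(-v, 0)
    expect_true(vf >= sp$vf_lb["REV"] && vf <= sp$vf_ub["REV"])
    expect_true(vb >= sp$vb_lb["REV"] && vb <= sp$vb_ub["REV"])
    expect_equal(vf - vb, v)
  }
  # reconstructed net flux ranges over exactly [lb, ub]
  expect_equal(sp$vf_ub[["REV"]] - sp$vb_lb[["REV"]], 20)
  expect_equal(sp$vf_lb[["REV"]] - sp$vb_ub[["REV"]], -10)
})

test_that("flux_consistent_subset keeps a live chain and drops dead ends", {
  # chain EX_A -> A -> B -> EX_B: all consistent
  net <- chain_network()
  expect_setequal(flux_consistent_subset(split_reversible(net)),
                  net$reactions$id)
  # dead-end: C produced but never consumed
  mets <- rbind(met_row("A"), met_row("B"), met_row("C"))
  rxns <- data.frame(id = c("EX_A", "R1", "DEAD", "EX_B"),
                     lb = 0, ub = 10, gpr = "", stringsAsFactors = FALSE)
  net2 <- make_net(mets, rxns, list(
    c(A_c = 1), c(A_c = -1, B_c = 1), c(A_c = -1, C_c = 1), c(B_c = -1)))
  expect_setequal(flux_consistent_subset(split_reversible(net2)),
                  c("EX_A", "R1", "EX_B"))
})

test_that("flux_consistent_subset matches the per-reaction LP oracle", {
  for (s in c(3, 11, 27)) {
    net <- random_network(s)
    got <- flux_consistent_subset(split_reversible(net), tol = 1e-6)
    want <- character(0)
    for (j in seq_len(nrow(net$reactions))) {
      cc <- rep(0, nrow(net$reactions)); cc[j] <- 1
      mx <- lp_vertex_oracle(cc, net$S, net$reactions$lb, net$reactions$ub)
      mn <- lp_vertex_oracle(cc, net$S, net$reactions$lb, net$reactions$ub,
                             maximize = FALSE)
      if (!is.null(mx) && (mx > 1e-6 || (!is.null(mn) && -mn > 1e-6))) {
        want <- c(want, net$reactions$id[j])
      }
    }
    expect_setequal(got, want)
  }
})
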