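# Metabolite-flow variability analysis and interval membership machinery.

test_that("a single-path chain has zero-width intervals at zeta = 1", {
  net <- chain_network()
  sp <- split_reversible(net)
  obj <- chain_objective()
  mv <- mfva(sp, NULL, obj, zeta_grid = 1)
  fb <- solve_fba(sp, NULL, obj)
  uf <- solve_ufd(sp, NULL, obj, fb$obj_value)
  point <- flux_sum(net, uf)
  for (i in seq_len(nrow(mv$intervals))) {
    row <- mv$intervals[i, ]
    # width limited by the shared objective relaxation
    expect_equal(row$r_min, row$r_max, tolerance = 1e-4)
    expect_equal(row$r_min, point[[row$metabolite]], tolerance = 1e-4)
  }
})

test_that("MFVA intervals match the brute-force LP oracle on the parallel fixture", {
  net <- parallel_network()
  sp <- split_reversible(net)
  obj <- cellular_objective("BIO", "BIO", 0, 1)
  obj_star <- solve_fba(sp, NULL, obj)$obj_value
  grid <- c(0.5, 1.0)
  mv <- mfva(sp, NULL, obj, zeta_grid = grid)
  # all reactions irreversible: flux-sum is linear in net flux space
  cc_obj <- as.numeric(net$reactions$id == "BIO")
  pos <- pmax(net$S, 0)
  base <- net$metabolites$base_id
  for (bm in unique(base)) {
    cc <- colSums(pos[base == bm, , drop = FALSE])
    lo <- Inf; hi <- -Inf
    for (z in grid) {
      Aineq <- matrix(-cc_obj, 1)
      bineq <- -z * obj_star
      lo <- min(lo, lp_vertex_oracle(cc, net$S, net$reactions$lb,
                                     net$reactions$ub, Aineq, bineq,
                                     maximize = FALSE))
      hi <- max(hi, lp_vertex_oracle(cc, net$S, net$reactions$lb,
                                     net$reactions$ub, Aineq, bineq,
                                     maximize = TRUE))
    }
    row <- mv$intervals[mv$intervals$metabolite == bm, ]
    expect_equal(row$r_min, lo, tolerance = 1e-4)
    expect_equal(row$r_max, hi, tolerance = 1e-4)
  }
})

test_that("relaxing the growth fraction can only widen the intervals", {
  pair <- toy_pair_cached()
  sp <- split_reversible(pair$normal)
  tight <- mfva(sp, NULL, pair$objective, zeta_grid = 1)
  wide <- mfva(sp, NULL, pair$objective, zeta_grid = c(0.5, 1))
  m <- match(tight$intervals$metabolite, wide$intervals$metabolite)
  expect_true(all(wide$intervals$r_min[m] <= tight$intervals$r_min + 1e-8))
  expect_true(all(wide$intervals$r_max[m] >= tight$intervals$r_max - 1e-8))
})

test_that("the point UFD flux-sum lies within its MFVA interval at zeta = 1", {
  pair <- toy_pair_cached()
  sp <- split_reversible(pair$normal)
  mv <- mfva(sp, NULL, pair$objective, zeta_grid = 1)
  point <- flux_sum(pair$normal, pair$basal)
  for (i in seq_len(nrow(mv$intervals))) {
    row <- mv$intervals[i, ]
    expect_gte(point[[row$metabolite]], row$r_min - 1e-6)
    expect_lte(point[[row$metabolite]], row$r_max + 1e-6)
  }
})

test_that("interval fold change maps endpoints monotonically with the floor", {
  got <- interval_lfc(2, 8, 2)
  expect_equal(c(got$lo, got$hi), c(0, 2))
  # degenerate interval collapses to the point fold change
  got2 <- interval_lfc(3, 3, 6)
  expect_equal(got2$lo, got2$hi)
  expect_equal(got2$lo, -1)
  # all-zero flows resolve to zero via the floor
  got3 <- interval_lfc(0, 0, 0, floor = 1e-6)
  expect_equal(c(got3$lo, got3$hi), c(0, 0))
  expect_error(interval_lfc(5, 2, 1), "hi < lo")
  expect_error(interval_lfc(-1, 2, 1), "non-negative")
})

test_that("interval membership equals a dense-grid oracle over random intervals", {
  set.seed(19)
  for (i in 1:120) {
    peak <- stats::runif(1, -3, 3)
    lb <- peak - stats::runif(1, 0.05, 4)
    ub <- peak + stats::runif(1, 0.05, 4)
    a <- sort(stats::runif(2, lb - 2, ub + 2))
    got <- interval_membership(a[1], a[2], lb, peak, ub, log2(1.05))
    xs <- seq(a[1], a[2], length.out = 10001)
    if (peak >= a[1] && peak <= a[2]) xs <- c(xs, peak)
    gr <- vapply(xs, membership_oracle, numeric(1), lb = lb, peak = peak,
                 ub = ub, tol_plus = log2(1.05))
    expect_equal(got$lo, min(gr), tolerance = 1e-9)
    expect_equal(got$hi, max(gr), tolerance = 1e-9)
  }
  # point interval reduces to the point grade
  g <- interval_membership(1.1, 1.1, 0.5, 2, 8, log2(1.05))
  expect_equal(g$lo, g$hi)
  expect_equal(g$lo, membership_grade(1.1, 0.5, 2, 8, log2(1.05)))
  # interval containing the peak attains the maximum grade of 1
  expect_equal(interval_membership(0, 4, 0.5, 2, 8, log2(1.05))$hi, 1)
  # interval entirely beyond the upper bound grades [0, 0]
  z <- interval_membership(9, 11, 0.5, 2, 8, log2(1.05))
  expect_equal(c(z$lo, z$hi), c(0, 0))
})

test_that("interval decision grade averages componentwise", {
  expect_equal(interval_decision_grade(c(1, 1), c(1, 1)), list(lo = 1, hi = 1))
  expect_equal(interval_decision_grade(c(0, 0), c(1, 1)), list(lo = 0, hi = 1))
  expect_equal(interval_decision_grade(c(0, 1), c(0, 1)),
               list(lo = 0.5, hi = 0.5))
  expect_error(interval_decision_grade(numeric(0), numeric(0)), "empty")
})

test_that("the point membership grade lies within the interval grade band", {
  pair <- toy_pair_cached()
  nsp <- split_reversible(pair$normal)
  tpl <- pair$expected_template
  basal <- list(vf = tpl$basal_state$vf, vb = tpl$basal_state$vb)
  cm <- tpl$components[tpl$components$type == "metabolite", ]
  for (g in c("G7", "G5", "G6")) {
    spec <- dysregulation_spec(g, "up", 0.3, basal = basal)
    point <- score_mutant(nsp, tpl, spec, pair$table)
    bounds <- mutate_bounds(nsp, pair$table, spec)
    irep <- interval_grade_report(nsp, bounds, tpl, zeta_grid = c(0.5, 1))
    pm <- point$components[point$components$type == "metabolite", ]
    eta_point <- mean(pm$grade)
    expect_gte(eta_point, irep$eta_e_interval$lo - 1e-6)
    expect_lte(eta_point, irep$eta_e_interval$hi + 1e-6)
    # per-metabolite containment as well
    m <- match(irep$table$metabolite, pm$id)
    expect_true(all(pm$grade[m] >= irep$table$eta_min - 1e-6))
    expect_true(all(pm$grade[m] <= irep$table$eta_max + 1e-6))
  }
})

test_that("the flux-sum bound matrix stacks mutants and the template", {
  pair <- toy_pair_cached()
  nsp <- split_reversible(pair$normal)
  csp <- split_reversible(pair$cancer)
  tpl <- pair$expected_template
  basal <- list(vf = tpl$basal_state$vf, vb = tpl$basal_state$vb)
  specs <- list(g7 = dysregulation_spec("G7", "up", 0.5, basal = basal),
                g3ko = dysregulation_spec("G3", "knockout", 1, basal = basal))
  M <- sum(tpl$components$type == "metabolite")
  mat <- flux_sum_bound_matrix(specs, nsp, pair$table, tpl, csp,
                               zeta_grid = c(0.5, 1))
  expect_equal(dim(mat), c(2L * M, 3L))
  expect_identical(colnames(mat), c("g7", "g3ko", "template"))
  lower <- mat[seq(1, 2 * M, by = 2), ]
  upper <- mat[seq(2, 2 * M, by = 2), ]
  expect_true(all(lower <= upper + 1e-9))
  # delegation: columns equal per-mutant mfva calls
  bounds <- mutate_bounds(nsp, pair$table, specs$g7)
  direct <- mfva(nsp, bounds, tpl$objective, c(0.5, 1),
                 metabolites = tpl$components$id[tpl$components$type == "metabolite"])
  expect_equal(unname(mat[, "g7"]),
               as.vector(rbind(direct$intervals$r_min, direct$intervals$r_max)),
               tolerance = 1e-9)
  # the no-op mutant column equals the normal model's own intervals
  mat0 <- flux_sum_bound_matrix(
    list(noop = dysregulation_spec("G3", "knockout", 1, basal = basal)),
    nsp, pair$table, tpl, csp, zeta_grid = c(0.5, 1))
  plain <- mfva(nsp, NULL, tpl$objective, c(0.5, 1),
                metabolites = tpl$components$id[tpl$components$type == "metabolite"])
  expect_equal(unname(mat0[, "noop"]),
               as.vector(rbind(plain$intervals$r_min, plain$intervals$r_max)),
               tolerance = 1e-9)
})
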