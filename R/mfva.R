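# Metabolite-flow variability analysis and interval membership grades.
#
# For a linear functional over a polytope that only grows as the growth
# fraction zeta decreases, min/max over zeta in (0, 1] are attained at the
# smallest zeta; the grid keeps each (metabolite, zeta, sense) an explicit
# LP and makes the cost visible.

# production-form coefficient vector of a base metabolite over x = c(vf, vb)
flow_coefficients <- function(net, base_ids = NULL) {
  S <- net$S
  pos <- pmax(S, 0)
  neg <- pmax(-S, 0)
  base <- net$metabolites$base_id
  if (is.null(base_ids)) base_ids <- sort(unique(base))
  lapply(stats::setNames(base_ids, base_ids), function(bm) {
    rows <- which(base == bm)
    cf <- colSums(pos[rows, , drop = FALSE])
    cb <- colSums(neg[rows, , drop = FALSE])
    c(cf, cb)
  })
}

#' Metabolite-flow variability analysis
#'
#' For each base metabolite, computes the attainable interval of its
#' flux-sum synthesis rate over steady-state fluxes within bounds that
#' retain at least a fraction `zeta` of the FBA optimum, minimized and
#' maximized over the `zeta` grid. Each (metabolite, zeta, sense) bound is a
#' single LP on the production form of the flow rate.
#'
#' @param split a [split_reversible()] network.
#' @param bounds optional [mutate_bounds()] result.
#' @param objective a [cellular_objective()].
#' @param zeta_grid growth fractions in (0, 1].
#' @param metabolites base-metabolite subset, default all.
#' @param rel_tol relative relaxation of the objective constraint; matches
#'   the [solve_ufd()] default so the minimum-norm point always stays inside
#'   the reported intervals.
#' @return object of class `mfva_result`: `intervals` data.frame
#'   (`metabolite`, `r_min`, `r_max`), the `zeta_grid`, and `obj_star`.
#' @export
mfva <- function(split, bounds = NULL, objective,
                 zeta_grid = seq(0.1, 1, by = 0.1), metabolites = NULL,
                 rel_tol = 1e-6) {
  stopifnot(length(zeta_grid) > 0, all(zeta_grid > 0), all(zeta_grid <= 1))
  fba <- solve_fba(split, bounds, objective)
  obj_star <- fba$obj_value
  mm <- split_matrices(split, bounds)
  cc_obj <- objective_vector(split, objective)
  coefs <- flow_coefficients(split$parent, metabolites)
  slack <- rel_tol * max(abs(obj_star), 1)
  out <- lapply(names(coefs), function(bm) {
    cc <- coefs[[bm]]
    r_min <- Inf; r_max <- -Inf
    any_ok <- FALSE
    for (z in sort(zeta_grid)) {
      Aineq <- matrix(-cc_obj, 1L)
      bineq <- -(z * obj_star - slack)
      lo <- lp_solve(cc, Aeq = mm$Aeq, beq = mm$beq, Aineq = Aineq,
                     bineq = bineq, lb = mm$lb, ub = mm$ub, maximize = FALSE)
      hi <- lp_solve(cc, Aeq = mm$Aeq, beq = mm$beq, Aineq = Aineq,
                     bineq = bineq, lb = mm$lb, ub = mm$ub, maximize = TRUE)
      if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal")) {
        warning("MFVA LP not solved at zeta = ", z, " for ", bm, "; skipped")
        next
      }
      any_ok <- TRUE
      r_min <- min(r_min, lo$value)
      r_max <- max(r_max, hi$value)
    }
    if (!any_ok) stop("MFVA infeasible at every zeta for metabolite ", bm)
    data.frame(metabolite = bm, r_min = r_min, r_max = r_max,
               stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, out)
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, zeta_grid = sort(zeta_grid),
                 obj_star = obj_star),
            class = "mfva_result")
}

#' @export
print.mfva_result <- function(x, ...) {
  cat(sprintf("<mfva_result> %d metabolite intervals, zeta grid {%s}, obj* %.6g\n",
              nrow(x$intervals), paste(x$zeta_grid, collapse = ", "),
              x$obj_star))
  invisible(x)
}

#' Interval log2 fold change
#'
#' Maps a non-negative flow interval through the floored log2 fold change
#' against a scalar baseline; log2 is increasing, so endpoints map to
#' endpoints.
#'
#' @param lo,hi interval endpoints, `0 <= lo <= hi` (vectorized).
#' @param r_bl baseline flow rate(s).
#' @param floor positive flux floor.
#' @return list with vectors `lo` and `hi`.
#' @export
interval_lfc <- function(lo, hi, r_bl, floor = 1e-6) {
  stopifnot(floor > 0)
  if (any(lo < -1e-12) || any(r_bl < -1e-12)) {
    stop("interval fold change requires non-negative rates")
  }
  if (any(hi < lo - 1e-12)) stop("invalid interval: hi < lo")
  den <- pmax(r_bl, floor)
  list(lo = log2(pmax(lo, floor) / den), hi = log2(pmax(hi, floor) / den))
}

#' Interval fuzzy membership grade
#'
#' Exact image of the triangular membership function over a fold-change
#' interval: the function is unimodal with peak at the template fold change,
#' so the maximum is 1 when the interval contains the peak and the larger
#' endpoint grade otherwise, and the minimum is the smaller endpoint grade.
#' Degenerate template components use the point no-change rule applied
#' interval-wise.
#'
#' @param lfc_lo,lfc_hi fold-change interval endpoints (vectorized).
#' @param lb,lfc_ca,ub template component (vectorized).
#' @param tol_plus no-change tolerance for degenerate components.
#' @return list with grade vectors `lo` and `hi`.
#' @export
interval_membership <- function(lfc_lo, lfc_hi, lb, lfc_ca, ub, tol_plus) {
  k <- length(lfc_lo)
  stopifnot(length(lfc_hi) == k)
  lb <- rep_len(lb, k); ub <- rep_len(ub, k); lfc_ca <- rep_len(lfc_ca, k)
  if (any(lfc_hi < lfc_lo - 1e-12)) stop("invalid interval: hi < lo")
  g_lo <- membership_grade(lfc_lo, lb, lfc_ca, ub, tol_plus)
  g_hi <- membership_grade(lfc_hi, lb, lfc_ca, ub, tol_plus)
  degen <- (ub - lb) <= 1e-12
  eta_max <- ifelse(lfc_ca >= lfc_lo & lfc_ca <= lfc_hi, 1, pmax(g_lo, g_hi))
  eta_min <- pmin(g_lo, g_hi)
  if (any(degen)) {
    band_lo <- lfc_ca[degen] - tol_plus
    band_hi <- lfc_ca[degen] + tol_plus
    eta_max[degen] <- as.numeric(lfc_lo[degen] <= band_hi &
                                   lfc_hi[degen] >= band_lo)
    eta_min[degen] <- as.numeric(lfc_lo[degen] >= band_lo &
                                   lfc_hi[degen] <= band_hi)
  }
  list(lo = eta_min, hi = eta_max)
}

#' Interval decision grade
#'
#' Componentwise mean of the lower and of the upper membership grades.
#'
#' @param lo,hi per-metabolite grade interval endpoints.
#' @return list with scalars `lo` and `hi`.
#' @export
interval_decision_grade <- function(lo, hi) {
  if (length(lo) == 0L) stop("interval decision grade of an empty set")
  stopifnot(length(hi) == length(lo))
  list(lo = mean(lo), hi = mean(hi))
}

#' Interval membership report for one mutant
#'
#' Chains [mfva()], [interval_lfc()] against the template's basal flows, and
#' [interval_membership()] against the template's metabolite components, then
#' aggregates to the interval decision grade.
#'
#' @param split normal-state [split_reversible()] network.
#' @param bounds mutated bounds for the mutant (or `NULL` for the normal
#'   model itself).
#' @param template a [build_template()] template.
#' @param zeta_grid growth-fraction grid.
#' @return object of class `interval_grade_report`: per-metabolite table
#'   (`metabolite`, `r_min`, `r_max`, `lfc_lo`, `lfc_hi`, `eta_min`,
#'   `eta_max`), aggregate `eta_e_interval`, and the grid.
#' @export
interval_grade_report <- function(split, bounds, template,
                                  zeta_grid = seq(0.1, 1, by = 0.1)) {
  comp <- template$components
  mets <- comp$id[comp$type == "metabolite"]
  mv <- mfva(split, bounds, template$objective, zeta_grid, metabolites = mets)
  iv <- mv$intervals
  iv <- iv[match(mets, iv$metabolite), , drop = FALSE]
  lf <- interval_lfc(iv$r_min, iv$r_max, template$basal_flow[mets],
                     template$floor)
  cm <- comp[comp$type == "metabolite", , drop = FALSE]
  gr <- interval_membership(lf$lo, lf$hi, cm$lb, cm$lfc, cm$ub,
                            template$tol_plus)
  agg <- interval_decision_grade(gr$lo, gr$hi)
  structure(list(
    table = data.frame(metabolite = mets, r_min = iv$r_min, r_max = iv$r_max,
                       lfc_lo = lf$lo, lfc_hi = lf$hi, eta_min = gr$lo,
                       eta_max = gr$hi, stringsAsFactors = FALSE),
    eta_e_interval = agg, zeta_grid = sort(zeta_grid)),
    class = "interval_grade_report")
}

#' @export
print.interval_grade_report <- function(x, ...) {
  cat(sprintf("<interval_grade_report> %d metabolites, eta_E in [%.4f, %.4f]\n",
              nrow(x$table), x$eta_e_interval$lo, x$eta_e_interval$hi))
  invisible(x)
}

#' Flux-sum bound matrix across mutants
#'
#' Stacks each mutant's MFVA interval as a (lower, upper) row pair per
#' observed metabolite, one column per mutant, with the template (cancer
#' model) bounds appended as the last column — the input matrix for
#' downstream multivariate analysis.
#'
#' @param specs named list of [dysregulation_spec()]s (names label columns).
#' @param split normal-state [split_reversible()] network.
#' @param table pseudo-enzyme table for the normal network.
#' @param template template whose basal state supplies missing basal fluxes.
#' @param cancer cancer-state [split_reversible()] network for the template
#'   column.
#' @param zeta_grid growth-fraction grid.
#' @return numeric matrix with `2 * M` rows (`<met>|min`, `<met>|max`) and
#'   one column per mutant plus `template`.
#' @export
flux_sum_bound_matrix <- function(specs, split, table, template, cancer,
                                  zeta_grid = seq(0.1, 1, by = 0.1)) {
  stopifnot(length(specs) > 0, !is.null(names(specs)))
  mets <- template$components$id[template$components$type == "metabolite"]
  col_of <- function(iv) {
    iv <- iv[match(mets, iv$metabolite), , drop = FALSE]
    as.vector(rbind(iv$r_min, iv$r_max))
  }
  cols <- vapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    if (is.null(spec$basal)) {
      spec$basal <- list(vf = template$basal_state$vf,
                         vb = template$basal_state$vb)
    }
    bounds <- mutate_bounds(split, table, spec)
    col_of(mfva(split, bounds, template$objective, zeta_grid,
                metabolites = mets)$intervals)
  }, numeric(2L * length(mets)))
  tpl_col <- col_of(mfva(cancer, NULL, template$objective, zeta_grid,
                         metabolites = mets)$intervals)
  out <- cbind(cols, template = tpl_col)
  rownames(out) <- as.vector(rbind(paste0(mets, "|min"),
                                   paste0(mets, "|max")))
  out
}
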