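# Inner optimization problems and the cancer-versus-normal template.

#' Cellular objective
#'
#' The FBA objective is a weighted sum of an ATP-producing (maintenance)
#' reaction flux and the biomass reaction flux,
#' `w_atp * v_atp + w_biomass * v_biomass`.
#'
#' @param atp,biomass reaction ids.
#' @param w_atp,w_biomass non-negative weights, not both zero.
#' @export
cellular_objective <- function(atp, biomass, w_atp = 0.5, w_biomass = 0.5) {
  stopifnot(w_atp >= 0, w_biomass >= 0, w_atp + w_biomass > 0)
  structure(list(atp = atp, biomass = biomass,
                 w_atp = w_atp, w_biomass = w_biomass),
            class = "cellular_objective")
}

#' Build the cellular objective from a configuration list
#'
#' @param config settings list from [read_config()]/[default_config()].
#' @return a [cellular_objective()].
#' @export
objective_from_config <- function(config) {
  o <- config$objective
  cellular_objective(o$atp, o$biomass, o$w_atp, o$w_biomass)
}

# objective coefficient vector over x = c(vf, vb)
objective_vector <- function(split, objective) {
  ids <- names(split$vf_ub)
  n <- length(ids)
  miss <- setdiff(c(objective$atp, objective$biomass), ids)
  if (length(miss) > 0L) {
    stop("objective reaction(s) not in network: ", paste(miss, collapse = ", "))
  }
  cc <- rep(0, 2L * n)
  ia <- match(objective$atp, ids)
  ib <- match(objective$biomass, ids)
  cc[ia] <- cc[ia] + objective$w_atp
  cc[ia + n] <- cc[ia + n] - objective$w_atp
  cc[ib] <- cc[ib] + objective$w_biomass
  cc[ib + n] <- cc[ib + n] - objective$w_biomass
  cc
}

as_flux_state <- function(split, x, obj_value) {
  ids <- names(split$vf_ub)
  n <- length(ids)
  structure(list(vf = stats::setNames(x[seq_len(n)], ids),
                 vb = stats::setNames(x[n + seq_len(n)], ids),
                 obj_value = obj_value),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state> objective %.6g, %d/%d reactions active\n",
              x$obj_value, sum(abs(x$vf - x$vb) > 1e-9), length(x$vf)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the cellular objective over steady-state split fluxes within
#' bounds: `max w_atp v_atp + w_biomass v_biomass` subject to
#' `N (vf - vb) = 0` and the (possibly mutated) box bounds.
#'
#' @param split a [split_reversible()] network.
#' @param bounds optional [mutate_bounds()] result; `NULL` uses the split
#'   network's own bounds.
#' @param objective a [cellular_objective()].
#' @return a `flux_state` with the optimal `obj_value`.
#' @export
solve_fba <- function(split, bounds = NULL, objective) {
  mm <- split_matrices(split, bounds)
  cc <- objective_vector(split, objective)
  res <- lp_solve(cc, Aeq = mm$Aeq, beq = mm$beq, lb = mm$lb, ub = mm$ub,
                  maximize = TRUE)
  if (!identical(res$status, "optimal")) {
    stop(structure(class = c("oncoflux_infeasible", "error", "condition"),
                   list(message = paste0("FBA ", res$status,
                                         ": no optimal steady-state flux"),
                        call = sys.call())))
  }
  as_flux_state(split, res$x, res$value)
}

#' Uniform flux distribution
#'
#' Among near-optimal FBA solutions, selects the flux vector of minimal
#' squared norm: `min sum(vf^2 + vb^2)` subject to steady state, bounds, and
#' `obj >= zeta * obj*` (relaxed by `rel_tol` to avoid degeneracy at the LP
#' optimum boundary). With `ufd_set = "internal"` only internal reactions
#' enter the norm; exchange fluxes then carry a vanishing ridge weight that
#' keeps the program strictly convex.
#'
#' @param split a [split_reversible()] network.
#' @param bounds optional mutated bounds.
#' @param objective a [cellular_objective()].
#' @param obj_star FBA optimum from [solve_fba()] under identical bounds.
#' @param zeta growth fraction in (0, 1]; 1 for the screening pipeline.
#' @param ufd_set `"all"` or `"internal"`.
#' @param rel_tol relative relaxation of the objective constraint.
#' @return a `flux_state`; `obj_value` is the realized objective.
#' @export
solve_ufd <- function(split, bounds = NULL, objective, obj_star,
                      zeta = 1, ufd_set = "all", rel_tol = 1e-6) {
  stopifnot(zeta > 0, zeta <= 1)
  mm <- split_matrices(split, bounds)
  cc <- objective_vector(split, objective)
  n <- mm$n
  w <- rep(1, 2L * n)
  if (identical(ufd_set, "internal")) {
    internal <- split$parent$reactions$is_internal
    w[c(!internal, !internal)] <- 0
  }
  thresh <- zeta * obj_star - rel_tol * max(abs(obj_star), 1)
  res <- qp_min_norm(w, Aeq = mm$Aeq, beq = mm$beq,
                     Ageq = matrix(cc, 1L), bgeq = thresh,
                     lb = mm$lb, ub = mm$ub)
  if (!identical(res$status, "optimal")) {
    stop("UFD quadratic program infeasible; consider increasing rel_tol ",
         "or re-solving FBA under the same bounds (", res$message, ")")
  }
  as_flux_state(split, res$x, sum(cc * res$x))
}

#' Metabolite-flow (flux-sum) profile
#'
#' The flow rate of a base metabolite is its total synthesis rate pooled
#' over compartment instances: per instance, the sum of `N_ij * vf_j` over
#' producing coefficients plus `-N_ij * vb_j` over consuming coefficients
#' (production carried by the backward direction), then summed across
#' compartments.
#'
#' @param net a [metabolic_network()].
#' @param state a `flux_state` consistent with `net`.
#' @return named non-negative vector over base metabolite ids.
#' @export
flux_sum <- function(net, state) {
  S <- net$S
  pos <- pmax(S, 0)
  neg <- pmax(-S, 0)
  per_instance <- as.vector(pos %*% state$vf + neg %*% state$vb)
  base <- net$metabolites$base_id
  r <- tapply(per_instance, base, sum)
  out <- stats::setNames(as.vector(r), names(r))
  out[sort(names(out))]
}

# per-direction flux component vector named "<rxn>|f" / "<rxn>|b"
flux_components <- function(state) {
  c(stats::setNames(state$vf, paste0(names(state$vf), "|f")),
    stats::setNames(state$vb, paste0(names(state$vb), "|b")))
}

#' Log2 fold change with a floor
#'
#' `log2(max(x_mu, floor) / max(x_bl, floor))` per shared component; the
#' floor keeps fold changes finite when either side is (numerically) zero.
#'
#' @param x_mu,x_bl named non-negative vectors over the same components.
#' @param floor positive flux floor.
#' @return named vector of finite log2 fold changes.
#' @export
log2_fold_change <- function(x_mu, x_bl, floor = 1e-6) {
  stopifnot(floor > 0)
  shared <- intersect(names(x_mu), names(x_bl))
  a <- x_mu[shared]
  b <- x_bl[shared]
  if (any(a < 0) || any(b < 0)) {
    stop("fold changes are defined for non-negative rates only")
  }
  log2(pmax(a, floor) / pmax(b, floor))
}

template_bounds <- function(lfc, factor) {
  lb <- ifelse(lfc > 0, lfc / factor, factor * lfc)
  ub <- ifelse(lfc >= 0, factor * lfc, lfc / factor)
  list(lb = lb, ub = ub)
}

#' Build the cancer-versus-normal template
#'
#' Solves FBA + UFD on both models (no dysregulation), computes
#' metabolite-flow and per-direction flux log2 fold changes over the shared
#' component universe (base metabolites and reactions present in both
#' models), and attaches fuzzy bounds: `lfc/factor` and `factor*lfc` ordered
#' by sign, collapsing to a point at `lfc = 0`. The normal-state solution is
#' retained as the basal reference mutants are compared against.
#'
#' @param normal,cancer [split_reversible()] networks.
#' @param objective a [cellular_objective()] valid in both models.
#' @param epsilon flux-alteration percentage behind the tolerances
#'   `tol_plus = log2(1+epsilon)`, `tol_minus = log2(1-epsilon)`.
#' @param bound_factor fuzzy bound spread factor.
#' @param floor fold-change floor.
#' @param flux_directions `"both"` keeps forward and backward components for
#'   every shared reaction; `"active"` keeps only directions carrying basal
#'   flux above the floor in either model.
#' @param ufd_set passed to [solve_ufd()].
#' @return object of class `flux_template`.
#' @export
build_template <- function(normal, cancer, objective, epsilon = 0.05,
                           bound_factor = 4, floor = 1e-6,
                           flux_directions = "both", ufd_set = "all") {
  stopifnot(epsilon > 0, epsilon < 1, bound_factor >= 1)
  run <- function(split) {
    fba <- solve_fba(split, NULL, objective)
    ufd <- solve_ufd(split, NULL, objective, fba$obj_value, ufd_set = ufd_set)
    list(state = ufd, flow = flux_sum(split$parent, ufd),
         flux = flux_components(ufd))
  }
  nb <- run(normal)
  cb <- run(cancer)
  met_shared <- intersect(names(nb$flow), names(cb$flow))
  rxn_shared <- intersect(names(normal$vf_ub), names(cancer$vf_ub))
  flux_ids <- c(paste0(rxn_shared, "|f"), paste0(rxn_shared, "|b"))
  if (identical(flux_directions, "active")) {
    act <- abs(nb$flux[flux_ids]) > floor | abs(cb$flux[flux_ids]) > floor
    flux_ids <- flux_ids[act]
  }
  if (length(met_shared) == 0L && length(flux_ids) == 0L) {
    stop("empty component universe: the two models share no metabolites or reactions")
  }
  lfc_m <- log2_fold_change(cb$flow[met_shared], nb$flow[met_shared], floor)
  lfc_f <- log2_fold_change(cb$flux[flux_ids], nb$flux[flux_ids], floor)
  lfc <- c(lfc_m, lfc_f)
  bd <- template_bounds(lfc, bound_factor)
  components <- data.frame(
    id = c(met_shared, flux_ids),
    type = c(rep("metabolite", length(met_shared)),
             rep("flux", length(flux_ids))),
    lfc = unname(lfc), lb = unname(bd$lb), ub = unname(bd$ub),
    stringsAsFactors = FALSE)
  coverage <- list(
    n_met_normal = length(nb$flow), n_met_cancer = length(cb$flow),
    n_met_shared = length(met_shared),
    n_rxn_normal = length(normal$vf_ub), n_rxn_cancer = length(cancer$vf_ub),
    n_rxn_shared = length(rxn_shared), n_flux_components = length(flux_ids))
  structure(list(components = components,
                 basal_state = nb$state, basal_flow = nb$flow,
                 cancer_state = cb$state, cancer_flow = cb$flow,
                 epsilon = epsilon,
                 tol_plus = log2(1 + epsilon), tol_minus = log2(1 - epsilon),
                 bound_factor = bound_factor, floor = floor,
                 objective = objective, coverage = coverage),
            class = "flux_template")
}

#' @export
print.flux_template <- function(x, ...) {
  cm <- x$components
  cat(sprintf(paste0("<flux_template> %d components (%d metabolite-flow, %d flux), ",
                     "epsilon %.3g, bound factor %g\n"),
              nrow(cm), sum(cm$type == "metabolite"), sum(cm$type == "flux"),
              x$epsilon, x$bound_factor))
  cat(sprintf("  shared universe: %d/%d normal, %d/%d cancer base metabolites\n",
              x$coverage$n_met_shared, x$coverage$n_met_normal,
              x$coverage$n_met_shared, x$coverage$n_met_cancer))
  invisible(x)
}

#' Serialize a template to a tab-separated file
#'
#' The component table is written with commented header lines holding the
#' scalar settings and the basal reference needed to score mutants, so the
#' file reloads into a fully functional template via [read_template()].
#'
#' @param template a [build_template()] result.
#' @param path output path.
#' @export
write_template <- function(template, path) {
  hdr <- c(
    sprintf("# oncoflux_template v1"),
    sprintf("# epsilon\t%.17g", template$epsilon),
    sprintf("# bound_factor\t%.17g", template$bound_factor),
    sprintf("# floor\t%.17g", template$floor),
    sprintf("# objective\t%s\t%s\t%.17g\t%.17g", template$objective$atp,
            template$objective$biomass, template$objective$w_atp,
            template$objective$w_biomass))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  cm <- template$components
  extras <- rbind(
    data.frame(id = names(template$basal_flow), type = "basal_flow",
               lfc = unname(template$basal_flow), lb = NA, ub = NA),
    data.frame(id = names(template$basal_state$vf), type = "basal_vf",
               lfc = unname(template$basal_state$vf), lb = NA, ub = NA),
    data.frame(id = names(template$basal_state$vb), type = "basal_vb",
               lfc = unname(template$basal_state$vb), lb = NA, ub = NA))
  utils::write.table(rbind(cm, extras), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reload a serialized template
#'
#' @param path file written by [write_template()].
#' @return a `flux_template` (without the cancer-state extras).
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    row <- hdr[startsWith(hdr, paste0("# ", key))]
    if (length(row) != 1L) stop("template file missing header: ", key)
    strsplit(sub(paste0("# ", key, "\t"), "", row), "\t")[[1]]
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  comp <- tab[tab$type %in% c("metabolite", "flux"), , drop = FALSE]
  pull <- function(what) {
    rows <- tab[tab$type == what, , drop = FALSE]
    stats::setNames(rows$lfc, rows$id)
  }
  vf <- pull("basal_vf")
  vb <- pull("basal_vb")
  obj <- get("objective")
  eps <- as.numeric(get("epsilon"))
  structure(list(components = comp[, c("id", "type", "lfc", "lb", "ub")],
                 basal_state = structure(list(vf = vf, vb = vb,
                                              obj_value = NA_real_),
                                         class = "flux_state"),
                 basal_flow = pull("basal_flow"),
                 epsilon = eps,
                 tol_plus = log2(1 + eps), tol_minus = log2(1 - eps),
                 bound_factor = as.numeric(get("bound_factor")),
                 floor = as.numeric(get("floor")),
                 objective = cellular_objective(obj[1], obj[2],
                                                as.numeric(obj[3]),
                                                as.numeric(obj[4])),
                 coverage = NULL),
            class = "flux_template")
}
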