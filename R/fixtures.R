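# Deterministic toy-network generator with planted dysregulations.
#
# The toy topology is the smallest structure exercising every code path of
# the screening pipeline: an uptake, an AND-regulated entry step, an
# isozyme-regulated ATP-producing branch in parallel with a plain branch
# (so the minimum-norm program has a genuine choice), a reversible
# two-compartment transport (so flux-sum pooling over compartments is
# exercised), a distal synthesis step that is the canonical planted target,
# a nested OR/AND side branch, and separate ATP-maintenance and biomass
# drains for the two-term cellular objective.

#' Describe a toy-network fixture
#'
#' @param n_metabolites total base metabolites; the 6-metabolite core is
#'   always present, extras become decoy side chains with their own genes.
#' @param n_isozyme_pairs number of OR-regulated (isozyme) branches >= 1.
#' @param n_compartments number of compartments >= 2 (cytosol + organelle;
#'   extras chain additional transports of the carrier metabolite).
#' @param seed RNG seed controlling decoy bound draws.
#' @param planted named list (`gene`, `mode`, `delta`) defining the
#'   dysregulation from which the paired "cancer" model is derived.
#' @param uptake substrate uptake capacity (flux units).
#' @return object of class `toy_network_spec`.
#' @export
toy_network_spec <- function(n_metabolites = 6, n_isozyme_pairs = 1,
                             n_compartments = 2, seed = 17,
                             planted = list(gene = "G7", mode = "up",
                                            delta = 0.5),
                             uptake = 10) {
  stopifnot(n_metabolites >= 6, n_isozyme_pairs >= 1, n_compartments >= 2,
            uptake > 0)
  structure(list(n_metabolites = n_metabolites,
                 n_isozyme_pairs = n_isozyme_pairs,
                 n_compartments = n_compartments,
                 seed = seed, planted = planted, uptake = uptake),
            class = "toy_network_spec")
}

toy_normal_network <- function(spec) {
  rng <- local({ set.seed(spec$seed); NULL })
  met <- function(base, comp) data.frame(
    id = paste0(base, "_", comp), base_id = base, compartment = comp,
    name = base, stringsAsFactors = FALSE)
  mets <- rbind(met("A", "c"), met("B", "c"), met("P", "c"), met("P", "m"),
                met("Q", "m"), met("ATP", "c"))
  rx <- list()
  add_rx <- function(id, stoich, lb, ub, gpr = "") {
    rx[[length(rx) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                   ub = ub, gpr = gpr)
  }
  add_rx("EX_A", c(A_c = 1), 0, spec$uptake)
  add_rx("U1", c(A_c = -1, B_c = 1), 0, 2 * spec$uptake, "G1 and G2")
  add_rx("PK1", c(B_c = -1, P_c = 1, ATP_c = 1), 0, 2 * spec$uptake,
         "G3 or G4")
  add_rx("PK2", c(B_c = -1, P_c = 1), 0, 2 * spec$uptake, "G5")
  add_rx("TP", c(P_c = -1, P_m = 1), -2 * spec$uptake, 2 * spec$uptake, "G6")
  add_rx("PS", c(P_m = -1, Q_m = 1), 0, spec$uptake, "G7")
  add_rx("NQ", c(B_c = -1, Q_m = 1), 0, spec$uptake, "G9 or (G8 and G10)")
  add_rx("EX_Q", c(Q_m = -1), 0, 2 * spec$uptake)
  add_rx("EX_Pm", c(P_m = -1), 0, 2 * spec$uptake)
  add_rx("ATPM", c(ATP_c = -1), 0, 2 * spec$uptake)
  add_rx("BIOMASS", c(P_c = -1, ATP_c = -1), 0, 2 * spec$uptake)
  # extra isozyme branches: OR-regulated parallel conversions of B to P
  if (spec$n_isozyme_pairs > 1) {
    for (k in seq_len(spec$n_isozyme_pairs - 1L)) {
      add_rx(sprintf("PKX%d", k), c(B_c = -1, P_c = 1), 0, spec$uptake,
             sprintf("GIa%d or GIb%d", k, k))
    }
  }
  # extra compartments: chain the carrier metabolite outward
  if (spec$n_compartments > 2) {
    comps <- paste0("x", seq_len(spec$n_compartments - 2L))
    prev <- "P_m"
    for (cp in comps) {
      mets <- rbind(mets, met("P", cp))
      add_rx(paste0("TPX_", cp),
             stats::setNames(c(-1, 1), c(prev, paste0("P_", cp))),
             0, 2 * spec$uptake, "G6")
      add_rx(paste0("EX_P", cp),
             stats::setNames(-1, paste0("P_", cp)), 0, 2 * spec$uptake)
      prev <- paste0("P_", cp)
    }
  }
  # decoy side chains with their own genes, bounds drawn from the seed
  n_extra <- spec$n_metabolites - 6L
  if (n_extra > 0L) {
    caps <- sample(seq(4, 12, by = 2), n_extra, replace = TRUE)
    for (k in seq_len(n_extra)) {
      dm <- sprintf("D%d", k)
      mets <- rbind(mets, met(dm, "c"))
      add_rx(sprintf("DS%d", k),
             stats::setNames(c(-1, 1), c("B_c", paste0(dm, "_c"))),
             0, caps[k], sprintf("GD%d", k))
      add_rx(sprintf("EX_%s", dm),
             stats::setNames(-1, paste0(dm, "_c")), 0, caps[k])
    }
  }
  rid <- vapply(rx, `[[`, character(1), "id")
  S <- matrix(0, nrow(mets), length(rx), dimnames = list(mets$id, rid))
  for (k in seq_along(rx)) {
    S[names(rx[[k]]$stoich), k] <- rx[[k]]$stoich
  }
  n_sub <- colSums(S != 0)
  reactions <- data.frame(
    id = rid,
    lb = vapply(rx, `[[`, numeric(1), "lb"),
    ub = vapply(rx, `[[`, numeric(1), "ub"),
    gpr = vapply(rx, `[[`, character(1), "gpr"),
    is_exchange = n_sub == 1L,
    is_internal = n_sub > 1L,
    stringsAsFactors = FALSE)
  metabolic_network(mets, reactions, S,
                    objective_ids = list(atp = "ATPM", biomass = "BIOMASS"))
}

# collapse mutated split bounds back to net bounds; errors when the mutated
# box is not representable as a single net-flux interval
collapse_split_bounds <- function(bounds) {
  if (any(bounds$vf_lb > 1e-12 & bounds$vb_ub > 1e-12)) {
    bad <- names(bounds$vf_ub)[bounds$vf_lb > 1e-12 & bounds$vb_ub > 1e-12]
    stop("mutated bounds not representable as net bounds for: ",
         paste(bad, collapse = ", "),
         " (choose an irreversible planted target)")
  }
  list(lb = bounds$vf_lb - bounds$vb_ub, ub = bounds$vf_ub - bounds$vb_lb)
}

#' Generate a paired normal/cancer toy fixture
#'
#' Builds the normal-state network, solves its basal FBA + UFD state, applies
#' the planted dysregulation through the same bound-mutation rule the
#' screening uses, and materializes the "cancer" model as the normal model
#' with those bounds — so the ground truth is exact by construction. The
#' expected template is computed at generation time.
#'
#' @param spec a [toy_network_spec()].
#' @param dir optional directory; when given, `normal.xml` and `cancer.xml`
#'   are written there (deterministically for a fixed spec).
#' @param config settings list; objective/epsilon/bound-factor defaults.
#' @return object of class `fixture_pair`: `normal`, `cancer`
#'   ([metabolic_network()]s), `truth` (the planted [dysregulation_spec()]
#'   with basal fluxes attached), `expected_template`, `objective`, `table`,
#'   and `paths` when written.
#' @export
generate_toy_pair <- function(spec = toy_network_spec(), dir = NULL,
                              config = default_config()) {
  stopifnot(inherits(spec, "toy_network_spec"))
  normal <- toy_normal_network(spec)
  objective <- cellular_objective("ATPM", "BIOMASS",
                                  config$objective$w_atp,
                                  config$objective$w_biomass)
  nsplit <- split_reversible(normal)
  consistent <- flux_consistent_subset(nsplit)
  if (!setequal(consistent, normal$reactions$id)) {
    stop("toy network not flux-consistent; blocked: ",
         paste(setdiff(normal$reactions$id, consistent), collapse = ", "))
  }
  fba <- solve_fba(nsplit, NULL, objective)
  basal <- solve_ufd(nsplit, NULL, objective, fba$obj_value,
                     ufd_set = config$ufd_set)
  table <- build_pseudoenzyme_table(normal)
  truth <- dysregulation_spec(spec$planted$gene, spec$planted$mode,
                              spec$planted$delta,
                              basal = list(vf = basal$vf, vb = basal$vb))
  mb <- mutate_bounds(nsplit, table, truth)
  net_bounds <- collapse_split_bounds(mb)
  cancer <- normal
  cancer$reactions$lb <- unname(net_bounds$lb[cancer$reactions$id])
  cancer$reactions$ub <- unname(net_bounds$ub[cancer$reactions$id])
  csplit <- split_reversible(cancer)
  # the cancer model must itself be feasible, else regenerate is hopeless
  tryCatch(solve_fba(csplit, NULL, objective),
           error = function(e) stop("planted dysregulation makes the cancer ",
                                    "model infeasible: ", conditionMessage(e)))
  template <- build_template(nsplit, csplit, objective,
                             epsilon = config$epsilon,
                             bound_factor = config$bound_factor,
                             floor = config$lfc_floor,
                             flux_directions = config$flux_directions,
                             ufd_set = config$ufd_set)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(normal = file.path(dir, "normal.xml"),
                  cancer = file.path(dir, "cancer.xml"))
    write_sbml(normal, paths$normal)
    write_sbml(cancer, paths$cancer)
  }
  structure(list(normal = normal, cancer = cancer, truth = truth,
                 expected_template = template, objective = objective,
                 table = table, basal = basal, spec = spec, paths = paths),
            class = "fixture_pair")
}

#' @export
print.fixture_pair <- function(x, ...) {
  cat(sprintf("<fixture_pair> planted %s (%s, delta=%.3g); %d metabolites, %d reactions\n",
              x$truth$targets$target[1], x$truth$targets$mode[1],
              x$truth$targets$delta[1], nrow(x$normal$metabolites),
              nrow(x$normal$reactions)))
  invisible(x)
}
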