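# Constraint-based model containers and SBML input/output.

#' Construct a metabolic network
#'
#' The central container: an ordered metabolite table, an ordered reaction
#' table and the m-by-n stoichiometric matrix relating them. Metabolites are
#' compartment instances (`base_id` + `compartment`); the same chemical
#' species in two compartments is two rows. Reaction bounds are net-flux
#' bounds (`lb <= ub`), with negative `lb` marking reversibility.
#'
#' @param metabolites data.frame with columns `id`, `base_id`, `compartment`,
#'   `name`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`,
#'   `is_exchange`, `is_internal`.
#' @param S numeric matrix of dim `nrow(metabolites)` x `nrow(reactions)`;
#'   row/column order must match the tables.
#' @param objective_ids optional named list/character with entries `atp` and
#'   `biomass` naming the cellular-objective reactions.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, S, objective_ids = NULL) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  need_m <- c("id", "base_id", "compartment", "name")
  need_r <- c("id", "lb", "ub", "gpr", "is_exchange", "is_internal")
  if (!all(need_m %in% names(metabolites))) {
    stop("metabolites table must have columns: ", paste(need_m, collapse = ", "))
  }
  if (!all(need_r %in% names(reactions))) {
    stop("reactions table must have columns: ", paste(need_r, collapse = ", "))
  }
  if (any(!nzchar(metabolites$compartment))) {
    stop("every metabolite needs a non-empty compartment")
  }
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(paste(metabolites$base_id, metabolites$compartment))) {
    stop("duplicate (base_id, compartment) pairs")
  }
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (any(reactions$lb > reactions$ub)) {
    stop("reaction bounds violated: lb > ub for ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))
  }
  S <- as.matrix(S)
  if (nrow(S) != nrow(metabolites) || ncol(S) != nrow(reactions)) {
    stop("S dimensions do not match metabolite/reaction tables")
  }
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (any(colSums(abs(S)) == 0)) {
    stop("reactions with empty stoichiometry: ",
         paste(reactions$id[colSums(abs(S)) == 0], collapse = ", "))
  }
  if (!is.null(objective_ids)) {
    objective_ids <- as.list(objective_ids)
    miss <- setdiff(unlist(objective_ids), reactions$id)
    if (length(miss) > 0L) {
      stop("objective reaction(s) absent from network: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(metabolites = metabolites, reactions = reactions, S = S,
                 objective_ids = objective_ids),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites x %d reactions (%d exchanges, %d genes in GPR)\n",
              nrow(x$metabolites), nrow(x$reactions),
              sum(x$reactions$is_exchange),
              length(unique(unlist(lapply(x$reactions$gpr, gpr_genes))))))
  invisible(x)
}

#' Default configuration
#'
#' All tunables of the pipeline with their defaults: cellular-objective
#' reaction ids and weights, compartment-dialect switch for SBML species ids,
#' default bounds applied when a file omits them, exchange-id prefixes, the
#' flux-alteration percentage `epsilon` behind the fold-change tolerances,
#' the fuzzy bound factor, the fold-change floor, and scoring conventions.
#'
#' @return named list of settings.
#' @export
default_config <- function() {
  list(
    objective = list(atp = "ATPM", biomass = "BIOMASS",
                     w_atp = 0.5, w_biomass = 0.5),
    compartment_dialect = "suffix",       # "suffix" or "attribute"
    default_bounds = list(irreversible = c(0, 1000),
                          reversible = c(-1000, 1000)),
    exchange_prefixes = c("EX_", "DM_", "SINK_"),
    epsilon = 0.05,
    bound_factor = 4,
    lfc_floor = 1e-6,
    ufd_set = "all",                      # "all" or "internal"
    sr_convention = "match_fraction",     # or "literal"
    eta_e_pooling = "pooled",             # or "split"
    obj_rel_tol = 1e-6,
    flux_directions = "both"              # or "active"
  )
}

#' Read a configuration file
#'
#' YAML key-value file; keys present override [default_config()], absent keys
#' keep their defaults.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

strip_sbml_prefix <- function(id, prefix) sub(paste0("^", prefix), "", id)

derive_base_id <- function(id, compartment, dialect) {
  out <- id
  suf <- paste0("_", compartment)
  hit <- substring(out, nchar(out) - nchar(suf) + 1L) == suf
  out[hit] <- substring(out[hit], 1L, nchar(out[hit]) - nchar(suf[hit]))
  if (dialect == "suffix") {
    # no attribute to lean on: strip a short trailing tag when present
    rest <- !hit & grepl("_[a-z][a-z0-9]?$", out)
    out[rest] <- sub("_[a-z][a-z0-9]?$", "", out[rest])
  }
  out
}

xml_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

fbc_assoc_to_string <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm %in% c("geneProductAssociation")) {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0L) return("")
    return(fbc_assoc_to_string(kids[[1]], gp_map))
  }
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lbl <- gp_map[[ref]]
    return(if (is.null(lbl)) ref else lbl)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_assoc_to_string, character(1), gp_map = gp_map)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Read an SBML model
#'
#' Parses an SBML Level 2/3 file into a [metabolic_network()]. Flux bounds
#' are taken from the fbc package attributes when present, else from
#' COBRA-style `kineticLaw` parameters (`LOWER_BOUND`/`UPPER_BOUND`), else
#' from the configured defaults (with a warning). GPR rules come from
#' `fbc:geneProductAssociation` or from `GENE_ASSOCIATION:` notes strings.
#' Boundary-condition species are dropped from the mass balance.
#'
#' @param path SBML file path.
#' @param config settings list from [read_config()]/[default_config()].
#' @return a [metabolic_network()].
#' @export
read_sbml <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML format error in '", path, "': ", conditionMessage(e))
  })
  if (xml2::xml_name(xml2::xml_root(doc)) != "sbml") {
    stop("SBML format error: root element is not <sbml>")
  }

  # gene products (fbc)
  gps <- xml_local(doc, "geneProduct")
  gp_map <- list()
  for (gp in gps) {
    gid <- xml2::xml_attr(gp, "id")
    lbl <- xml2::xml_attr(gp, "label")
    gp_map[[gid]] <- if (!is.na(lbl) && nzchar(lbl)) lbl else gid
  }

  # global parameters (fbc bound refs)
  pars <- xml_local(doc, "parameter")
  par_val <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(pars, "value"))),
    xml2::xml_attr(pars, "id"))

  sp_nodes <- xml_local(doc, "species")
  if (length(sp_nodes) == 0L) stop("SBML format error: no species found")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bound <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  keep <- !sp_bound
  sp_id <- sp_id[keep]; sp_name <- sp_name[keep]; sp_comp <- sp_comp[keep]
  short <- strip_sbml_prefix(sp_id, "M_")
  if (config$compartment_dialect == "suffix") {
    comp <- sub("^.*_([a-z][a-z0-9]?)$", "\\1", short)
    no_suf <- comp == short
    comp[no_suf] <- sp_comp[no_suf]
  } else {
    comp <- sp_comp
  }
  if (any(is.na(comp) | !nzchar(comp))) {
    stop("SBML format error: species without resolvable compartment")
  }
  base <- derive_base_id(short, comp, config$compartment_dialect)
  metabolites <- data.frame(id = short, base_id = base, compartment = comp,
                            name = ifelse(is.na(sp_name), short, sp_name),
                            stringsAsFactors = FALSE)

  rx_nodes <- xml_local(doc, "reaction")
  if (length(rx_nodes) == 0L) stop("SBML format error: no reactions found")
  n <- length(rx_nodes)
  m <- nrow(metabolites)
  S <- matrix(0, m, n)
  row_of <- stats::setNames(seq_len(m), sp_id)
  rid <- character(n); lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  defaulted <- logical(n)
  for (k in seq_len(n)) {
    rx <- rx_nodes[[k]]
    rid[k] <- strip_sbml_prefix(xml2::xml_attr(rx, "id"), "R_")
    rev <- xml2::xml_attr(rx, "reversible") %in% c("true", NA)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        rx, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- suppressWarnings(as.numeric(xml2::xml_attr(ref, "stoichiometry")))
        if (is.na(st)) st <- 1
        i <- row_of[sp]
        if (!is.na(i)) S[i, k] <- S[i, k] + sgn * st
      }
    }
    # bounds: fbc attributes -> kineticLaw parameters -> defaults
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    lo <- if (!is.na(lb_ref)) unname(par_val[lb_ref]) else NA_real_
    hi <- if (!is.na(ub_ref)) unname(par_val[ub_ref]) else NA_real_
    if (is.na(lo) || is.na(hi)) {
      kl <- xml2::xml_find_all(
        rx, "./*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(kl) > 0L) {
        kid <- xml2::xml_attr(kl, "id")
        kval <- suppressWarnings(as.numeric(xml2::xml_attr(kl, "value")))
        if (is.na(lo) && "LOWER_BOUND" %in% kid) lo <- kval[kid == "LOWER_BOUND"][1]
        if (is.na(hi) && "UPPER_BOUND" %in% kid) hi <- kval[kid == "UPPER_BOUND"][1]
      }
    }
    if (is.na(lo) || is.na(hi)) {
      db <- if (rev) config$default_bounds$reversible else config$default_bounds$irreversible
      if (is.na(lo)) lo <- db[1]
      if (is.na(hi)) hi <- db[2]
      defaulted[k] <- TRUE
    }
    lb[k] <- lo; ub[k] <- hi
    # GPR
    assoc <- xml2::xml_find_first(
      rx, "./*[local-name()='geneProductAssociation']")
    if (!inherits(assoc, "xml_missing")) {
      gpr[k] <- fbc_assoc_to_string(assoc, gp_map)
    } else {
      notes <- xml2::xml_find_first(rx, "./*[local-name()='notes']")
      gpr[k] <- ""
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        mt <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^<\n]*", txt))
        if (length(mt) == 1L) {
          gpr[k] <- trimws(sub("GENE_ASSOCIATION:", "", mt))
        }
      }
    }
  }
  if (any(defaulted)) {
    warning(sum(defaulted), " reaction(s) had no bounds in the file; ",
            "configured defaults applied")
  }
  n_met_in <- colSums(S != 0)
  is_ex <- n_met_in == 1L | vapply(
    rid, function(x) any(startsWith(x, config$exchange_prefixes)), logical(1))
  reactions <- data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                          is_exchange = unname(is_ex),
                          is_internal = unname(!is_ex),
                          stringsAsFactors = FALSE)
  metabolites$id <- strip_sbml_prefix(metabolites$id, "M_")
  obj <- config$objective
  obj_ids <- NULL
  if (all(c(obj$atp, obj$biomass) %in% reactions$id)) {
    obj_ids <- list(atp = obj$atp, biomass = obj$biomass)
  }
  metabolic_network(metabolites, reactions, S, objective_ids = obj_ids)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

gpr_to_fbc_xml <- function(rule, indent) {
  pad <- strrep(" ", indent)
  if (length(rule$clauses) == 0L) return(character(0))
  clause_xml <- function(cl, ind) {
    p <- strrep(" ", ind)
    if (length(cl) == 1L) {
      sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', p, cl)
    } else {
      c(sprintf("%s<fbc:and>", p),
        vapply(cl, function(g)
          sprintf('%s  <fbc:geneProductRef fbc:geneProduct="G_%s"/>', p, g),
          character(1)),
        sprintf("%s</fbc:and>", p))
    }
  }
  if (length(rule$clauses) == 1L) {
    body <- clause_xml(rule$clauses[[1]], indent + 2L)
  } else {
    body <- c(sprintf("%s  <fbc:or>", pad),
              unlist(lapply(rule$clauses, clause_xml, ind = indent + 4L)),
              sprintf("%s  </fbc:or>", pad))
  }
  c(sprintf("%s<fbc:geneProductAssociation>", pad), body,
    sprintf("%s</fbc:geneProductAssociation>", pad))
}

#' Write a network as SBML Level 3 (fbc v2)
#'
#' Deterministic writer: the same network always yields byte-identical
#' output. Bounds go to fbc flux-bound parameters; GPR rules are emitted both
#' as `fbc:geneProductAssociation` trees and kept readable by downstream
#' COBRA tooling.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  mets <- net$metabolites
  rxns <- net$reactions
  comps <- sort(unique(mets$compartment))
  genes <- sort(unique(unlist(lapply(rxns$gpr, gpr_genes))))
  fmt_num <- function(x) formatC(x, format = "g", digits = 12)
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            mets$id, xml_escape(mets$name), mets$compartment),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
            rxns$id, fmt_num(rxns$lb)),
    sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
            rxns$id, fmt_num(rxns$ub)),
    "    </listOfParameters>",
    "    <listOfReactions>")
  for (k in seq_len(nrow(rxns))) {
    col <- net$S[, k]
    rea <- which(col < 0)
    pro <- which(col > 0)
    L <- c(L, sprintf(paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
                             'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">'),
                      rxns$id[k], if (rxns$lb[k] < 0) "true" else "false",
                      rxns$id[k], rxns$id[k]))
    if (length(rea) > 0L) {
      L <- c(L, "        <listOfReactants>",
             sprintf(paste0('          <speciesReference species="M_%s" ',
                            'stoichiometry="%s" constant="true"/>'),
                     mets$id[rea], fmt_num(-col[rea])),
             "        </listOfReactants>")
    }
    if (length(pro) > 0L) {
      L <- c(L, "        <listOfProducts>",
             sprintf(paste0('          <speciesReference species="M_%s" ',
                            'stoichiometry="%s" constant="true"/>'),
                     mets$id[pro], fmt_num(col[pro])),
             "        </listOfProducts>")
    }
    if (nzchar(rxns$gpr[k])) {
      L <- c(L, gpr_to_fbc_xml(parse_gpr(rxns$gpr[k]), 8L))
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>")
  if (length(genes) > 0L) {
    L <- c(L, "    <fbc:listOfGeneProducts>",
           sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                   genes, genes),
           "    </fbc:listOfGeneProducts>")
  }
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path, useBytes = TRUE)
  invisible(path)
}

#' Split reversible reactions into forward/backward flux pairs
#'
#' Rewrites net fluxes `v` in `[lb, ub]` as `v = vf - vb` with `vf, vb >= 0`.
#' For a reversible reaction with bounds `[lb, ub]`, `vf` ranges over
#' `[max(lb,0), max(ub,0)]` and `vb` over `[max(-ub,0), max(-lb,0)]`; for an
#' irreversible reaction `vb` is pinned at 0. Mass balance
#' `N (vf - vb) = 0` is then equivalent to the original `N v = 0`.
#'
#' @param net a [metabolic_network()].
#' @return object of class `split_network`: the parent network plus named
#'   bound vectors `vf_lb`, `vf_ub`, `vb_lb`, `vb_ub`.
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  rx <- net$reactions
  if (any(rx$lb > rx$ub)) stop("invalid bounds: lb > ub")
  ids <- rx$id
  out <- structure(list(
    parent = net,
    vf_lb = stats::setNames(pmax(rx$lb, 0), ids),
    vf_ub = stats::setNames(pmax(rx$ub, 0), ids),
    vb_lb = stats::setNames(pmax(-rx$ub, 0), ids),
    vb_ub = stats::setNames(pmax(-rx$lb, 0), ids)),
    class = "split_network")
  out
}

#' @export
print.split_network <- function(x, ...) {
  cat(sprintf("<split_network> %d reactions (%d reversible) over %d metabolites\n",
              length(x$vf_ub), sum(x$vb_ub > 0), nrow(x$parent$metabolites)))
  invisible(x)
}

# stacked constraint pieces for the split flux vector x = c(vf, vb)
split_matrices <- function(split, bounds = NULL) {
  S <- split$parent$S
  n <- ncol(S)
  b <- if (is.null(bounds)) split else bounds
  list(Aeq = cbind(S, -S), beq = rep(0, nrow(S)),
       lb = c(b$vf_lb, b$vb_lb), ub = c(b$vf_ub, b$vb_ub), n = n)
}

#' Flux-consistent subset of a network
#'
#' A reaction is flux-consistent when some steady-state flux vector within
#' bounds carries it at absolute flux above `tol`. Each reaction is probed by
#' two LPs (maximize its forward then its backward split flux) without any
#' objective constraint.
#'
#' @param split a [split_reversible()] network.
#' @param tol positive consistency threshold (flux units).
#' @return character vector of flux-consistent reaction ids.
#' @export
flux_consistent_subset <- function(split, tol = 1e-6) {
  stopifnot(inherits(split, "split_network"), tol > 0)
  mm <- split_matrices(split)
  n <- mm$n
  ids <- split$parent$reactions$id
  ok <- logical(n)
  for (j in seq_len(n)) {
    for (side in c(0L, n)) {
      if (ok[j]) break
      cc <- rep(0, 2L * n)
      cc[j + side] <- 1
      if (mm$ub[j + side] <= tol) next  # direction closed by bounds
      res <- lp_solve(cc, Aeq = mm$Aeq, beq = mm$beq,
                      lb = mm$lb, ub = mm$ub, maximize = TRUE)
      if (identical(res$status, "infeasible")) {
        stop("network infeasible: no steady-state flux vector within bounds")
      }
      if (identical(res$status, "optimal") && res$value > tol) ok[j] <- TRUE
    }
  }
  ids[ok]
}
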