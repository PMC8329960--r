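# Gene-protein-reaction rules, pseudo-enzymes, and dysregulated bounds.

gpr_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0L) {
      stop(sprintf("GPR parse error at position %d: unexpected character '%s'",
                   i, ch))
    }
    low <- tolower(m)
    type <- if (low %in% c("and", "&", "&&")) "and"
            else if (low %in% c("or", "|", "||")) "or"
            else "gene"
    toks[[length(toks) + 1L]] <- list(type = type, value = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

# grammar: expr := term ('or' term)* ; term := factor ('and' factor)* ;
# factor := gene | '(' expr ')'
gpr_parse_tokens <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) stop("GPR parse error: unexpected end of rule")
    if (t$type == "gene") {
      advance()
      return(list(op = "gene", gene = t$value))
    }
    if (t$type == "(") {
      advance()
      e <- parse_expr()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") {
        stop(sprintf("GPR parse error at position %d: unbalanced parentheses",
                     t$pos))
      }
      advance()
      return(e)
    }
    stop(sprintf("GPR parse error at position %d: unexpected token '%s'",
                 t$pos, t$type))
  }
  e <- parse_expr()
  if (!is.null(peek())) {
    stop(sprintf("GPR parse error at position %d: trailing input", peek()$pos))
  }
  e
}

gpr_dnf <- function(node) {
  if (node$op == "gene") return(list(node$gene))
  parts <- lapply(node$args, gpr_dnf)
  if (node$op == "or") {
    clauses <- do.call(c, parts)
  } else {
    clauses <- Reduce(function(acc, nxt) {
      out <- list()
      for (a in acc) for (b in nxt) {
        out[[length(out) + 1L]] <- union(a, b)
      }
      out
    }, parts)
  }
  clauses <- lapply(clauses, function(cl) sort(unique(cl)))
  keys <- vapply(clauses, paste, character(1), collapse = "&")
  clauses <- clauses[!duplicated(keys)]
  # absorption: a clause that contains another clause is redundant
  redundant <- vapply(seq_along(clauses), function(i) {
    any(vapply(seq_along(clauses), function(j) {
      i != j && length(clauses[[j]]) < length(clauses[[i]]) &&
        all(clauses[[j]] %in% clauses[[i]])
    }, logical(1)))
  }, logical(1))
  clauses[!redundant]
}

#' Parse a GPR rule string
#'
#' Accepts the usual `and`/`or`/parenthesis grammar (case-insensitive; `&`
#' and `|` also recognized) and normalizes the rule to disjunctive normal
#' form: a set of AND-clauses, each a sorted gene vector, OR-ed together.
#' Redundant clauses (duplicates and supersets of smaller clauses) are
#' removed. An empty string yields an empty rule.
#'
#' @param text GPR rule string.
#' @return object of class `gpr_rule` with elements `text` and `clauses`.
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(structure(list(text = "", clauses = list()), class = "gpr_rule"))
  }
  tree <- gpr_parse_tokens(gpr_tokenize(text))
  structure(list(text = text, clauses = gpr_dnf(tree)), class = "gpr_rule")
}

#' @export
print.gpr_rule <- function(x, ...) {
  if (length(x$clauses) == 0L) {
    cat("<gpr_rule> (unregulated)\n")
  } else {
    cat("<gpr_rule>",
        paste(vapply(x$clauses, function(cl)
          if (length(cl) > 1L) paste0("(", paste(cl, collapse = " and "), ")")
          else cl, character(1)), collapse = " or "), "\n")
  }
  invisible(x)
}

gpr_genes <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  unique(unlist(parse_gpr(text)$clauses))
}

#' Build the pseudo-enzyme table of a network
#'
#' Every distinct AND-clause across all GPR rules gets one integer
#' pseudo-enzyme code; identical gene combinations appearing on several
#' reactions share a code. A reaction is isozyme-regulated with respect to a
#' gene when, among the reaction's codes, at least one contains the gene and
#' at least one does not: the network can then catalyze the reaction without
#' that gene.
#'
#' @param net a [metabolic_network()], or a named list of `gpr_rule`s
#'   (names = reaction ids).
#' @return object of class `pseudo_enzyme_table` with `codes` (named integer
#'   vector keyed by sorted gene combination), `clauses` (gene vector per
#'   code), `reaction_enzymes` (reaction id -> code set), `isozyme_set`
#'   (gene -> reaction ids with an alternative pseudo-enzyme), and
#'   `gene_reactions` (gene -> all reactions whose rule mentions it).
#' @export
build_pseudoenzyme_table <- function(net) {
  rules <- if (inherits(net, "metabolic_network")) {
    stats::setNames(lapply(net$reactions$gpr, parse_gpr), net$reactions$id)
  } else {
    net
  }
  stopifnot(!is.null(names(rules)))
  keys_per_rxn <- lapply(rules, function(r)
    vapply(r$clauses, paste, character(1), collapse = "&"))
  all_keys <- sort(unique(unlist(keys_per_rxn)))
  codes <- stats::setNames(seq_along(all_keys), all_keys)
  clauses <- stats::setNames(strsplit(all_keys, "&", fixed = TRUE), NULL)
  reaction_enzymes <- lapply(keys_per_rxn, function(k) unname(codes[k]))
  genes <- sort(unique(unlist(clauses)))
  gene_in_code <- lapply(stats::setNames(genes, genes), function(g)
    which(vapply(clauses, function(cl) g %in% cl, logical(1))))
  gene_reactions <- lapply(gene_in_code, function(cds)
    names(reaction_enzymes)[vapply(reaction_enzymes, function(ce)
      any(ce %in% cds), logical(1))])
  isozyme_set <- lapply(stats::setNames(genes, genes), function(g) {
    cds <- gene_in_code[[g]]
    hits <- vapply(reaction_enzymes, function(ce)
      any(ce %in% cds) && any(!(ce %in% cds)), logical(1))
    names(reaction_enzymes)[hits]
  })
  structure(list(codes = codes, clauses = clauses,
                 reaction_enzymes = reaction_enzymes,
                 isozyme_set = isozyme_set,
                 gene_reactions = gene_reactions,
                 genes = genes),
            class = "pseudo_enzyme_table")
}

#' @export
print.pseudo_enzyme_table <- function(x, ...) {
  cat(sprintf("<pseudo_enzyme_table> %d pseudo-enzymes over %d genes, %d regulated reactions\n",
              length(x$codes), length(x$genes),
              sum(lengths(x$reaction_enzymes) > 0)))
  invisible(x)
}

#' Specify a dysregulation
#'
#' One or more gene- or reaction-level perturbations applied together:
#' `mode` is `"up"`, `"down"` or `"knockout"`, `delta` the regulated
#' strength in (0, 1] interpolating the mutated bound between the basal flux
#' (`delta -> 0`) and the bound extreme (`delta = 1`). Basal fluxes are the
#' normal-state forward/backward solution the bounds pivot around.
#'
#' @param targets character vector of gene or reaction ids.
#' @param mode per-target mode, recycled if scalar.
#' @param delta per-target strength in (0, 1], recycled if scalar.
#' @param type `"gene"` or `"reaction"` per target, recycled. Reaction-level
#'   targets bypass the GPR table and the isozyme exemption.
#' @param basal list with named numeric vectors `vf` and `vb` (normal-state
#'   split fluxes).
#' @return object of class `dysregulation_spec`.
#' @export
dysregulation_spec <- function(targets, mode, delta = 0.5, type = "gene",
                               basal = NULL) {
  k <- length(targets)
  mode <- rep_len(mode, k)
  delta <- rep_len(delta, k)
  type <- rep_len(type, k)
  if (!all(mode %in% c("up", "down", "knockout"))) {
    stop("mode must be one of 'up', 'down', 'knockout'")
  }
  if (!all(type %in% c("gene", "reaction"))) {
    stop("type must be 'gene' or 'reaction'")
  }
  if (any(delta <= 0 | delta > 1)) {
    stop("delta must lie in (0, 1]")
  }
  if (anyDuplicated(targets)) stop("duplicate targets in dysregulation spec")
  structure(list(targets = data.frame(target = targets, mode = mode,
                                      delta = delta, type = type,
                                      stringsAsFactors = FALSE),
                 basal = basal),
            class = "dysregulation_spec")
}

#' Translate a dysregulation into mutated flux bounds
#'
#' Applies the bound-interpolation rule per affected reaction. For
#' upregulation the forward flux is forced into
#' `[(1-delta) vf_basal + delta vf_ub, vf_ub]` and the backward flux capped
#' at `(1-delta) vb_basal + delta vb_lb`; downregulation mirrors this towards
#' the lower extreme; knockout pins both directions at zero. Downregulation
#' and knockout of a gene do not touch reactions backed by an isozyme
#' (an alternative pseudo-enzyme not containing the gene); upregulation and
#' reaction-level targets carry no such exemption.
#'
#' @param split a [split_reversible()] network.
#' @param table a [build_pseudoenzyme_table()] result.
#' @param spec a [dysregulation_spec()]; its `basal` element must hold the
#'   normal-state split fluxes for every affected reaction.
#' @return object of class `mutated_bounds`: full bound vectors plus the
#'   affected reaction set `omu` and the per-reaction mode applied.
#' @export
mutate_bounds <- function(split, table, spec) {
  stopifnot(inherits(split, "split_network"),
            inherits(table, "pseudo_enzyme_table"),
            inherits(spec, "dysregulation_spec"))
  basal <- spec$basal
  if (is.null(basal)) stop("spec carries no basal fluxes")
  ids <- names(split$vf_ub)
  out <- list(vf_lb = split$vf_lb, vf_ub = split$vf_ub,
              vb_lb = split$vb_lb, vb_ub = split$vb_ub)
  assigned_mode <- stats::setNames(rep(NA_character_, length(ids)), ids)
  omu <- character(0)
  tg <- spec$targets
  for (t in seq_len(nrow(tg))) {
    target <- tg$target[t]
    mode <- tg$mode[t]
    delta <- tg$delta[t]
    if (tg$type[t] == "gene") {
      if (!(target %in% table$genes)) {
        stop("unknown gene in dysregulation spec: ", target)
      }
      rxns <- table$gene_reactions[[target]]
      exempt <- if (mode %in% c("down", "knockout")) {
        table$isozyme_set[[target]]
      } else {
        character(0)
      }
      rxns <- setdiff(rxns, exempt)
    } else {
      if (!(target %in% ids)) {
        stop("unknown reaction in dysregulation spec: ", target)
      }
      rxns <- target
    }
    for (r in rxns) {
      if (!is.na(assigned_mode[r]) && assigned_mode[r] != mode) {
        stop("conflicting dysregulation modes on reaction ", r)
      }
      assigned_mode[r] <- mode
      vfb <- basal$vf[r]
      vbb <- basal$vb[r]
      if (is.na(vfb) || is.na(vbb)) {
        stop("basal fluxes missing for reaction ", r)
      }
      if (vfb < split$vf_lb[r] - 1e-6 || vfb > split$vf_ub[r] + 1e-6 ||
          vbb < split$vb_lb[r] - 1e-6 || vbb > split$vb_ub[r] + 1e-6) {
        stop("basal flux outside original bounds for reaction ", r)
      }
      vfb <- min(max(vfb, split$vf_lb[r]), split$vf_ub[r])
      vbb <- min(max(vbb, split$vb_lb[r]), split$vb_ub[r])
      if (mode == "up") {
        out$vf_lb[r] <- (1 - delta) * vfb + delta * split$vf_ub[r]
        out$vb_ub[r] <- (1 - delta) * vbb + delta * split$vb_lb[r]
      } else if (mode == "down") {
        out$vf_ub[r] <- (1 - delta) * vfb + delta * split$vf_lb[r]
        out$vb_lb[r] <- (1 - delta) * vbb + delta * split$vb_ub[r]
      } else {
        out$vf_lb[r] <- 0; out$vf_ub[r] <- 0
        out$vb_lb[r] <- 0; out$vb_ub[r] <- 0
      }
      omu <- union(omu, r)
    }
  }
  structure(c(out, list(omu = omu,
                        mode = assigned_mode[!is.na(assigned_mode)])),
            class = "mutated_bounds")
}

#' @export
print.mutated_bounds <- function(x, ...) {
  cat(sprintf("<mutated_bounds> %d mutated reaction(s): %s\n",
              length(x$omu), paste(x$omu, collapse = ", ")))
  invisible(x)
}
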