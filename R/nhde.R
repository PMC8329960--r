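# Outer-level search: per-gene screening and multi-gene hybrid DE.

#' NHDE search configuration
#'
#' Controls both the per-gene strength optimization and the multi-gene
#' differential evolution. The per-gene search is one-dimensional in the
#' regulated strength, so a coarse strength grid plus golden-section
#' refinement suffices; the multi-gene search runs DE/rand/1/bin with a
#' migration operator (population re-seeding around the incumbent when
#' diversity collapses) and an acceleration operator (local strength
#' refinement of the incumbent), with elitist selection.
#'
#' @param population_size DE population; default `10 * (3 * K)`.
#' @param generations DE generations.
#' @param crossover_rate binomial crossover probability.
#' @param mutation_scale_range range the per-generation scale factor is
#'   drawn from.
#' @param migration_threshold normalized population-diversity level below
#'   which the migration operator re-seeds.
#' @param seed RNG seed; the whole search is deterministic given the seed.
#' @param delta_grid strength grid for the per-gene screen.
#' @param refine_iters golden-section iterations refining the grid optimum.
#' @param modes dysregulation modes screened per gene.
#' @export
nhde_config <- function(population_size = NULL, generations = 60,
                        crossover_rate = 0.8,
                        mutation_scale_range = c(0.1, 1.0),
                        migration_threshold = 0.05, seed = 1,
                        delta_grid = c(0.001, 0.005, 0.01, 0.02, 0.05,
                                       seq(0.1, 1, by = 0.1)),
                        refine_iters = 20,
                        modes = c("up", "down", "knockout")) {
  stopifnot(is.null(population_size) || population_size >= 4,
            generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            all(mutation_scale_range > 0), all(mutation_scale_range <= 2),
            all(delta_grid > 0), all(delta_grid <= 1))
  structure(list(population_size = population_size, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_scale_range = mutation_scale_range,
                 migration_threshold = migration_threshold, seed = seed,
                 delta_grid = sort(unique(delta_grid)),
                 refine_iters = refine_iters, modes = modes),
            class = "nhde_config")
}

new_eval_context <- function(split, template, table,
                             sr_convention = "match_fraction",
                             eta_e_pooling = "pooled", ufd_set = "all") {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$evaluations <- 0L
  env$split <- split
  env$template <- template
  env$table <- table
  env$sr_convention <- sr_convention
  env$eta_e_pooling <- eta_e_pooling
  env$ufd_set <- ufd_set
  env
}

#' Evaluate one dysregulation candidate
#'
#' Delegates to [score_mutant()] with the infeasible-mutant-scores-zero
#' policy, caching results by (targets, modes, strength quantized to 1e-3)
#' so repeated individuals cost a single inner solve.
#'
#' @param genes character vector of targets (size K).
#' @param modes per-target modes.
#' @param deltas per-target strengths in (0, 1].
#' @param ctx evaluation context from the screening functions (holds the
#'   network, template, pseudo-enzyme table and the cache).
#' @param type `"gene"` or `"reaction"` targets.
#' @return list with `eta_d` and the full `report`.
#' @keywords internal
evaluate_dysregulation <- function(genes, modes, deltas, ctx, type = "gene") {
  key <- paste(genes, modes, sprintf("%.3f", round(deltas, 3)), type,
               sep = ":", collapse = "|")
  hit <- get0(key, envir = ctx$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- tryCatch({
    spec <- dysregulation_spec(genes, modes, deltas, type = type)
    rep <- score_mutant(ctx$split, ctx$template, spec, ctx$table,
                        sr_convention = ctx$sr_convention,
                        eta_e_pooling = ctx$eta_e_pooling,
                        ufd_set = ctx$ufd_set)
    list(eta_d = rep$summary$eta_d, report = rep)
  }, error = function(e) {
    list(eta_d = 0,
         report = list(summary = data.frame(
           sr_m = 0, sr_f = 0, eta_s = 0, eta_e = 0, eta_d = 0,
           n_m = NA_integer_, n_f = NA_integer_,
           status = paste0("error: ", conditionMessage(e)),
           stringsAsFactors = FALSE)))
  })
  ctx$evaluations <- ctx$evaluations + 1L
  assign(key, res, envir = ctx$cache)
  res
}

golden_refine <- function(f, lo, hi, iters) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(iters)) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  if (f1 >= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' Screen candidate genes one at a time
#'
#' For each candidate gene, every dysregulation mode is optimized over the
#' regulated strength (coarse grid plus golden-section refinement around the
#' grid optimum; knockout needs no strength), and the best
#' (mode, strength, fitness) is recorded. Candidates absent from the GPR
#' association are skipped with a warning. The result is ranked by fitness,
#' ties broken by membership grade then gene id.
#'
#' @param candidates character vector of gene ids (or reaction ids with
#'   `type = "reaction"`).
#' @param split normal-state [split_reversible()] network.
#' @param template the [build_template()] template.
#' @param table the [build_pseudoenzyme_table()] table.
#' @param config an [nhde_config()].
#' @param type `"gene"` or `"reaction"` targets.
#' @param sr_convention,eta_e_pooling,ufd_set scoring options, see
#'   [score_mutant()].
#' @return object of class `screening_result`: `ranking` data.frame
#'   (gene, mode, delta, sr_m, sr_f, eta_s, eta_e, eta_d, status) and the
#'   inner-solve count `evaluations`.
#' @export
screen_genes <- function(candidates, split, template, table,
                         config = nhde_config(), type = "gene",
                         sr_convention = "match_fraction",
                         eta_e_pooling = "pooled", ufd_set = "all") {
  known <- if (type == "gene") table$genes else names(split$vf_ub)
  absent <- setdiff(candidates, known)
  if (length(absent) > 0L) {
    warning("candidate(s) not available in the GPR association, skipped: ",
            paste(absent, collapse = ", "))
  }
  candidates <- intersect(candidates, known)
  if (length(candidates) == 0L) stop("no screenable candidates")
  ctx <- new_eval_context(split, template, table, sr_convention,
                          eta_e_pooling, ufd_set)
  rows <- list()
  for (g in candidates) {
    best <- NULL
    for (mode in config$modes) {
      if (mode == "knockout") {
        ev <- evaluate_dysregulation(g, mode, 1, ctx, type)
        cand <- list(mode = mode, delta = 1, ev = ev)
      } else {
        f <- function(d) evaluate_dysregulation(g, mode, d, ctx, type)$eta_d
        grid <- config$delta_grid
        vals <- vapply(grid, f, numeric(1))
        k <- which.max(vals)
        lo <- if (k > 1L) grid[k - 1L] else grid[1L]
        hi <- if (k < length(grid)) grid[k + 1L] else grid[length(grid)]
        ref <- golden_refine(f, lo, hi, config$refine_iters)
        d_star <- if (ref$f > vals[k]) ref$x else grid[k]
        ev <- evaluate_dysregulation(g, mode, d_star, ctx, type)
        cand <- list(mode = mode, delta = d_star, ev = ev)
      }
      if (is.null(best) || cand$ev$eta_d > best$ev$eta_d ||
          (cand$ev$eta_d == best$ev$eta_d &&
           cand$ev$report$summary$eta_e > best$ev$report$summary$eta_e)) {
        best <- cand
      }
    }
    s <- best$ev$report$summary
    rows[[g]] <- data.frame(gene = g, mode = best$mode, delta = best$delta,
                            sr_m = s$sr_m, sr_f = s$sr_f, eta_s = s$eta_s,
                            eta_e = s$eta_e, eta_d = s$eta_d,
                            status = s$status, stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$eta_d, -ranking$eta_e, ranking$gene)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, evaluations = ctx$evaluations,
                 config = config),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d candidate(s), %d inner solves\n",
              nrow(x$ranking), x$evaluations))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

decode_individual <- function(x, K, n_genes, modes) {
  gi <- pmin(pmax(floor(x[seq_len(K)]), 1L), n_genes)
  # repair duplicate gene indices deterministically
  if (anyDuplicated(gi)) {
    used <- unique(gi)
    free <- setdiff(seq_len(n_genes), used)
    dup <- which(duplicated(gi))
    for (d in dup) {
      if (length(free) == 0L) break
      gi[d] <- free[1L]
      free <- free[-1L]
    }
  }
  mi <- pmin(pmax(floor(x[K + seq_len(K)]), 1L), length(modes))
  dd <- pmin(pmax(x[2L * K + seq_len(K)], 1e-3), 1)
  list(genes = gi, modes = modes[mi], deltas = dd)
}

#' Multi-gene dysregulation search by hybrid differential evolution
#'
#' Searches gene K-sets jointly with their modes and strengths under a mixed
#' encoding (gene and mode indices rounded from continuous coordinates,
#' strengths continuous). DE/rand/1/bin mutation-crossover with greedy
#' (elitist) selection; when normalized population diversity drops below the
#' migration threshold the population is re-seeded around the incumbent;
#' each generation the incumbent's strengths are refined by a bounded local
#' line search. `K = 1` delegates to [screen_genes()], to which the encoding
#' degenerates.
#'
#' @inheritParams screen_genes
#' @param K genes perturbed simultaneously per individual.
#' @return a `screening_result`; `ranking` rows are the best evaluation per
#'   distinct (gene set, modes) with columns `genes` (comma-separated),
#'   `modes`, `delta` and the score columns.
#' @export
optimize_multigene <- function(candidates, K, split, template, table,
                               config = nhde_config(), type = "gene",
                               sr_convention = "match_fraction",
                               eta_e_pooling = "pooled", ufd_set = "all") {
  stopifnot(K >= 1)
  if (K > length(candidates)) {
    stop("K exceeds the number of candidate genes")
  }
  if (K == 1L) {
    return(screen_genes(candidates, split, template, table, config, type,
                        sr_convention, eta_e_pooling, ufd_set))
  }
  known <- if (type == "gene") table$genes else names(split$vf_ub)
  candidates <- intersect(candidates, known)
  if (K > length(candidates)) stop("K exceeds the screenable candidates")
  modes <- config$modes
  G <- length(candidates)
  dim <- 3L * K
  NP <- if (is.null(config$population_size)) 10L * dim else config$population_size
  set.seed(config$seed)
  lo <- c(rep(1, K), rep(1, K), rep(1e-3, K))
  hi <- c(rep(G + 1 - 1e-9, K), rep(length(modes) + 1 - 1e-9, K), rep(1, K))
  ctx <- new_eval_context(split, template, table, sr_convention,
                          eta_e_pooling, ufd_set)
  fit_of <- function(x) {
    d <- decode_individual(x, K, G, modes)
    evaluate_dysregulation(candidates[d$genes], d$modes, d$deltas, ctx,
                           type)$eta_d
  }
  pop <- t(replicate(NP, stats::runif(dim, lo, hi)))
  fit <- apply(pop, 1L, fit_of)
  best_hist <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    Fs <- stats::runif(1, config$mutation_scale_range[1],
                       config$mutation_scale_range[2])
    b <- which.max(fit)
    for (i in seq_len(NP)) {
      r <- sample(setdiff(seq_len(NP), i), 3L)
      trial <- pop[r[1], ] + Fs * (pop[r[2], ] - pop[r[3], ])
      jrand <- sample.int(dim, 1L)
      cross <- stats::runif(dim) < config$crossover_rate
      cross[jrand] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lo), hi)
      ft <- fit_of(trial)
      if (ft >= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
      }
    }
    # acceleration: refine incumbent strengths by a shrinking line search
    b <- which.max(fit)
    step <- 0.1
    for (k in seq_len(K)) {
      for (s in c(step, -step, step / 4, -step / 4)) {
        cand <- pop[b, ]
        cand[2L * K + k] <- min(max(cand[2L * K + k] + s, 1e-3), 1)
        fc <- fit_of(cand)
        if (fc > fit[b]) {
          pop[b, ] <- cand
          fit[b] <- fc
        }
      }
    }
    # migration: re-seed around the incumbent when diversity collapses
    spread <- mean(apply(pop, 2L, stats::sd) / (hi - lo))
    if (spread < config$migration_threshold) {
      b <- which.max(fit)
      keep <- pop[b, ]
      for (i in seq_len(NP)) {
        if (i == b) next
        pop[i, ] <- pmin(pmax(keep + stats::runif(dim, -0.25, 0.25) *
                                (hi - lo), lo), hi)
        fit[i] <- fit_of(pop[i, ])
      }
    }
    best_hist[gen] <- max(fit)
  }
  # collate distinct gene-set evaluations from the cache
  keys <- ls(ctx$cache)
  rows <- lapply(keys, function(k) {
    res <- get(k, envir = ctx$cache)
    parts <- strsplit(strsplit(k, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    genes <- vapply(parts, `[[`, character(1), 1L)
    mds <- vapply(parts, `[[`, character(1), 2L)
    dls <- as.numeric(vapply(parts, `[[`, character(1), 3L))
    o <- order(genes)
    s <- res$report$summary
    data.frame(genes = paste(genes[o], collapse = ","),
               modes = paste(mds[o], collapse = ","),
               delta = paste(sprintf("%.3f", dls[o]), collapse = ","),
               sr_m = s$sr_m, sr_f = s$sr_f, eta_s = s$eta_s,
               eta_e = s$eta_e, eta_d = s$eta_d, status = s$status,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # best row per distinct gene set + modes
  grp <- paste(tab$genes, tab$modes)
  tab <- do.call(rbind, lapply(split(tab, grp), function(d)
    d[which.max(d$eta_d), , drop = FALSE]))
  ord <- order(-tab$eta_d, -tab$eta_e, tab$genes)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(ranking = tab, evaluations = ctx$evaluations,
                 config = config, best_history = best_hist),
            class = "screening_result")
}
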