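# Scoring a mutant flux pattern against the cancer template.

#' Similarity indicator of one component
#'
#' +1 when mutant and template fold changes both exceed `tol_plus`
#' (concordant increase), -1 when both fall below `tol_minus` (concordant
#' decrease), 0 otherwise.
#'
#' @param lfc_mu,lfc_ca mutant-vs-basal and cancer-vs-basal log2 fold
#'   changes (vectorized).
#' @param tol_plus,tol_minus tolerances, `tol_minus < 0 < tol_plus`.
#' @return integer vector in {-1, 0, +1}.
#' @export
similarity_indicator <- function(lfc_mu, lfc_ca, tol_plus, tol_minus) {
  stopifnot(tol_minus < 0, tol_plus > 0)
  ifelse(lfc_mu > tol_plus & lfc_ca > tol_plus, 1L,
         ifelse(lfc_mu < tol_minus & lfc_ca < tol_minus, -1L, 0L))
}

#' Similarity ratio
#'
#' Aggregates per-component indicators. Under the `"literal"` convention the
#' ratio is the signed mean of the indicators. Under the default
#' `"match_fraction"` convention a component counts as matched when the
#' indicator is nonzero (concordant change in either direction) or when both
#' fold changes sit inside the no-change band; the ratio is the matched
#' fraction, in [0, 1].
#'
#' @param indicators integer vector from [similarity_indicator()].
#' @param both_unchanged logical vector: both fold changes within
#'   `[tol_minus, tol_plus]`. Required for `"match_fraction"`.
#' @param convention `"match_fraction"` or `"literal"`.
#' @return scalar ratio.
#' @export
similarity_ratio <- function(indicators, both_unchanged = NULL,
                             convention = c("match_fraction", "literal")) {
  convention <- match.arg(convention)
  if (length(indicators) == 0L) stop("similarity ratio of an empty component set")
  if (convention == "literal") {
    return(mean(indicators))
  }
  if (is.null(both_unchanged)) {
    stop("match_fraction convention needs the both-unchanged flags")
  }
  stopifnot(length(both_unchanged) == length(indicators))
  mean(abs(indicators) == 1L | both_unchanged)
}

#' Fuzzy-equal membership grade
#'
#' Triangular membership peaking at the template fold change `lfc_ca`:
#' left limb `(x - lb)/(lfc_ca - lb)`, right limb `(ub - x)/(ub - lfc_ca)`,
#' clipped into [0, 1]. A degenerate component (`lb = ub = lfc_ca`, the
#' unchanged-template case) grades 1 when the mutant is itself within the
#' no-change tolerance of the peak and 0 otherwise.
#'
#' @param lfc_mu mutant fold change (vectorized).
#' @param lb,lfc_ca,ub template component bounds and peak (vectorized).
#' @param tol_plus no-change tolerance used for degenerate components.
#' @return grades in [0, 1].
#' @export
membership_grade <- function(lfc_mu, lb, lfc_ca, ub, tol_plus) {
  k <- length(lfc_mu)
  lb <- rep_len(lb, k); ub <- rep_len(ub, k); lfc_ca <- rep_len(lfc_ca, k)
  if (any(lb > ub + 1e-12)) stop("invalid template component: lb > ub")
  if (any(lfc_ca < lb - 1e-9 | lfc_ca > ub + 1e-9)) {
    stop("invalid template component: peak outside [lb, ub]")
  }
  degen <- (ub - lb) <= 1e-12
  left_den <- lfc_ca - lb
  right_den <- ub - lfc_ca
  eta_l <- ifelse(left_den > 1e-12, (lfc_mu - lb) / left_den,
                  ifelse(lfc_mu >= lfc_ca - 1e-12, 1, 0))
  eta_r <- ifelse(right_den > 1e-12, (ub - lfc_mu) / right_den,
                  ifelse(lfc_mu <= lfc_ca + 1e-12, 1, 0))
  g <- pmax(pmin(eta_l, eta_r, 1), 0)
  g[degen] <- ifelse(abs(lfc_mu[degen] - lfc_ca[degen]) <= tol_plus, 1, 0)
  g
}

#' Mean membership grade
#'
#' @param grades numeric vector of grades in [0, 1].
#' @return their arithmetic mean.
#' @export
decision_grade <- function(grades) {
  if (length(grades) == 0L) stop("decision grade of an empty grade set")
  if (any(grades < -1e-9 | grades > 1 + 1e-9)) {
    stop("grades must lie in [0, 1]")
  }
  mean(grades)
}

#' Combined fitness
#'
#' Mixes the weighted-sum and minimum decisions of the similarity objective
#' `eta_s` and the fuzzy-equal objective `eta_e`:
#' `eta_d = ((eta_s + eta_e)/2 + min(eta_s, eta_e)) / 2`.
#'
#' @param eta_s,eta_e scalars in [0, 1].
#' @return scalar fitness in [0, 1].
#' @export
combined_fitness <- function(eta_s, eta_e) {
  if (any(c(eta_s, eta_e) < -1e-9) || any(c(eta_s, eta_e) > 1 + 1e-9)) {
    stop("eta_s and eta_e must lie in [0, 1]")
  }
  ((eta_s + eta_e) / 2 + pmin(eta_s, eta_e)) / 2
}

#' Score a dysregulation against the template
#'
#' Runs the full inner pipeline for one mutant: mutated bounds, FBA, UFD,
#' metabolite-flow and flux fold changes against the template's basal
#' (normal-state) reference, then similarity ratios, membership grades and
#' the combined fitness. An infeasible mutant is not an error: it returns a
#' report flagged `status = "infeasible"` with zero fitness so that
#' screening loops stay total.
#'
#' @param split normal-state [split_reversible()] network.
#' @param template a [build_template()]/[read_template()] template.
#' @param spec a [dysregulation_spec()]; if it carries no basal fluxes the
#'   template's basal state is used.
#' @param table a [build_pseudoenzyme_table()] for the normal network.
#' @param sr_convention passed to [similarity_ratio()].
#' @param eta_e_pooling `"pooled"` averages metabolite-flow and flux grades
#'   as one list; `"split"` averages the two families separately and means
#'   the pair.
#' @param ufd_set passed to [solve_ufd()].
#' @return object of class `score_report`: `summary` (one-row data.frame
#'   with `sr_m`, `sr_f`, `eta_s`, `eta_e`, `eta_d`, `n_m`, `n_f`,
#'   `status`), `components` (per-component audit table) and the mutant
#'   `state`.
#' @export
score_mutant <- function(split, template, spec, table,
                         sr_convention = c("match_fraction", "literal"),
                         eta_e_pooling = c("pooled", "split"),
                         ufd_set = "all") {
  sr_convention <- match.arg(sr_convention)
  eta_e_pooling <- match.arg(eta_e_pooling)
  if (is.null(spec$basal)) {
    spec$basal <- list(vf = template$basal_state$vf,
                       vb = template$basal_state$vb)
  }
  bounds <- mutate_bounds(split, table, spec)
  fail <- function(status) {
    structure(list(
      summary = data.frame(sr_m = 0, sr_f = 0, eta_s = 0, eta_e = 0,
                           eta_d = 0, n_m = NA_integer_, n_f = NA_integer_,
                           status = status, stringsAsFactors = FALSE),
      components = NULL, state = NULL, bounds = bounds),
      class = "score_report")
  }
  fba <- tryCatch(solve_fba(split, bounds, template$objective),
                  oncoflux_infeasible = function(e) NULL,
                  error = function(e) NULL)
  if (is.null(fba)) return(fail("infeasible"))
  ufd <- tryCatch(solve_ufd(split, bounds, template$objective, fba$obj_value,
                            ufd_set = ufd_set),
                  error = function(e) NULL)
  if (is.null(ufd)) return(fail("qp_failed"))

  flow_mu <- flux_sum(split$parent, ufd)
  flux_mu <- flux_components(ufd)
  flow_bl <- template$basal_flow
  flux_bl <- flux_components(template$basal_state)

  cm <- template$components
  mu_val <- numeric(nrow(cm))
  is_met <- cm$type == "metabolite"
  lfc_mu_m <- log2_fold_change(flow_mu, flow_bl, template$floor)
  lfc_mu_f <- log2_fold_change(flux_mu, flux_bl, template$floor)
  mu_val[is_met] <- lfc_mu_m[cm$id[is_met]]
  mu_val[!is_met] <- lfc_mu_f[cm$id[!is_met]]
  if (anyNA(mu_val)) {
    stop("template components missing from the mutant model: ",
         paste(utils::head(cm$id[is.na(mu_val)], 5), collapse = ", "))
  }

  tp <- template$tol_plus
  tm <- template$tol_minus
  ind <- similarity_indicator(mu_val, cm$lfc, tp, tm)
  unchanged <- mu_val >= tm & mu_val <= tp & cm$lfc >= tm & cm$lfc <= tp
  grades <- membership_grade(mu_val, cm$lb, cm$lfc, cm$ub, tp)

  sr_m <- similarity_ratio(ind[is_met], unchanged[is_met], sr_convention)
  sr_f <- similarity_ratio(ind[!is_met], unchanged[!is_met], sr_convention)
  eta_s <- (sr_m + sr_f) / 2
  eta_e <- if (eta_e_pooling == "pooled") {
    decision_grade(grades)
  } else {
    mean(c(decision_grade(grades[is_met]), decision_grade(grades[!is_met])))
  }
  eta_d <- combined_fitness(eta_s, eta_e)
  structure(list(
    summary = data.frame(sr_m = sr_m, sr_f = sr_f, eta_s = eta_s,
                         eta_e = eta_e, eta_d = eta_d,
                         n_m = sum(is_met), n_f = sum(!is_met),
                         status = "ok", stringsAsFactors = FALSE),
    components = data.frame(id = cm$id, type = cm$type, lfc_mu = mu_val,
                            lfc_ca = cm$lfc, indicator = ind,
                            grade = grades, stringsAsFactors = FALSE),
    state = ufd, bounds = bounds),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<score_report> status %s | SR_M %.3f SR_F %.3f | ",
                     "eta_S %.3f eta_E %.3f eta_D %.3f (%s metabolites, %s fluxes)\n"),
              s$status, s$sr_m, s$sr_f, s$eta_s, s$eta_e, s$eta_d,
              s$n_m, s$n_f))
  invisible(x)
}

#' Write a score report as tab-separated tables
#'
#' The per-component audit table followed by a one-row summary block.
#'
#' @param report a [score_mutant()] result.
#' @param path output path.
#' @export
write_score_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- report$summary
  writeLines(sprintf("# sr_m\t%.6f", s$sr_m), con)
  writeLines(sprintf("# sr_f\t%.6f", s$sr_f), con)
  writeLines(sprintf("# eta_s\t%.6f", s$eta_s), con)
  writeLines(sprintf("# eta_e\t%.6f", s$eta_e), con)
  writeLines(sprintf("# eta_d\t%.6f", s$eta_d), con)
  writeLines(sprintf("# status\t%s", s$status), con)
  if (!is.null(report$components)) {
    utils::write.table(report$components, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
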