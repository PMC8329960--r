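# Shared fixtures and independent oracles used across the suite.
# The LP oracle enumerates polytope vertices by brute force and never calls
# the package's solver path.

# --- tiny networks built in code ------------------------------------------

make_net <- function(mets, rxns, stoich, objective = NULL) {
  S <- matrix(0, nrow(mets), length(rxns$id), dimnames = list(mets$id, rxns$id))
  for (k in seq_along(stoich)) S[names(stoich[[k]]), k] <- stoich[[k]]
  n_sub <- colSums(S != 0)
  rxns$is_exchange <- n_sub == 1L
  rxns$is_internal <- n_sub > 1L
  metabolic_network(mets, rxns, S, objective_ids = objective)
}

met_row <- function(base, comp = "c") data.frame(
  id = paste0(base, "_", comp), base_id = base, compartment = comp,
  name = base, stringsAsFactors = FALSE)

# linear chain: EX_A(<=10) -> A -> B -> biomass drain
chain_network <- function(uptake = 10) {
  mets <- rbind(met_row("A"), met_row("B"))
  rxns <- data.frame(id = c("EX_A", "R1", "BIO"),
                     lb = c(0, 0, 0), ub = c(uptake, 50, 50),
                     gpr = c("", "G1", ""), stringsAsFactors = FALSE)
  make_net(mets, rxns, list(c(A_c = 1), c(A_c = -1, B_c = 1), c(B_c = -1)))
}

chain_objective <- function() cellular_objective("BIO", "BIO", 0, 1)

# two identical parallel paths A -> B with a demand drain
parallel_network <- function(uptake = 10) {
  mets <- rbind(met_row("A"), met_row("B"))
  rxns <- data.frame(id = c("EX_A", "R1", "R2", "BIO"),
                     lb = c(0, 0, 0, 0), ub = c(uptake, 50, 50, 50),
                     gpr = c("", "G1", "G2", ""), stringsAsFactors = FALSE)
  make_net(mets, rxns, list(c(A_c = 1), c(A_c = -1, B_c = 1),
                            c(A_c = -1, B_c = 1), c(B_c = -1)))
}

# two-substrate fixture with a reversible interconversion (<= 8 reactions)
two_substrate_network <- function() {
  mets <- rbind(met_row("A"), met_row("B"), met_row("C"))
  rxns <- data.frame(
    id = c("EX_A", "EX_B", "RA", "RB", "INT", "BIO"),
    lb = c(0, 0, 0, 0, -20, 0),
    ub = c(6, 4, 20, 20, 20, 30),
    gpr = c("", "", "G1", "G2", "G3", ""), stringsAsFactors = FALSE)
  make_net(mets, rxns, list(
    c(A_c = 1), c(B_c = 1), c(A_c = -1, C_c = 1), c(B_c = -1, C_c = 1),
    c(A_c = -1, B_c = 1), c(C_c = -1)))
}

# random small irreversible network generator for property tests
random_network <- function(seed, n_mets = 3, n_rxns = 6) {
  set.seed(seed)
  repeat {
    mets <- do.call(rbind, lapply(seq_len(n_mets), function(i)
      met_row(paste0("X", i))))
    ids <- paste0("R", seq_len(n_rxns))
    stoich <- vector("list", n_rxns)
    # uptake for X1, drain for Xn, random internal conversions between
    stoich[[1]] <- c(X1_c = 1)
    stoich[[n_rxns]] <- stats::setNames(-1, paste0("X", n_mets, "_c"))
    for (k in seq(2, n_rxns - 1)) {
      from <- sample(n_mets - 1, 1)
      to <- sample(setdiff(seq_len(n_mets), from), 1)
      stoich[[k]] <- stats::setNames(c(-1, sample(1:2, 1)),
                                     paste0("X", c(from, to), "_c"))
    }
    ub <- round(stats::runif(n_rxns, 2, 15), 1)
    rxns <- data.frame(id = ids, lb = 0, ub = ub, gpr = "",
                       stringsAsFactors = FALSE)
    net <- tryCatch(make_net(mets, rxns, stoich), error = function(e) NULL)
    if (!is.null(net)) return(net)
  }
}

# --- brute-force LP oracle -------------------------------------------------

# maximize c'v over {N v = 0, lb <= v <= ub} by enumerating candidate
# vertices: the equality rows plus every choice of active bound facets.
lp_vertex_oracle <- function(cc, N, lb, ub, Aineq = NULL, bineq = NULL,
                             maximize = TRUE, tol = 1e-7) {
  n <- length(cc)
  rows <- list()
  rhs <- c()
  for (i in seq_len(nrow(N))) { rows[[length(rows) + 1]] <- N[i, ]; rhs <- c(rhs, 0) }
  n_eq <- length(rows)
  facets <- list()
  frhs <- c()
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    facets[[length(facets) + 1]] <- e; frhs <- c(frhs, lb[j])
    facets[[length(facets) + 1]] <- e; frhs <- c(frhs, ub[j])
  }
  if (!is.null(Aineq)) {
    for (i in seq_len(nrow(Aineq))) {
      facets[[length(facets) + 1]] <- Aineq[i, ]; frhs <- c(frhs, bineq[i])
    }
  }
  best <- NULL
  nf <- length(facets)
  for (k in 0:(n - 1)) {
    if (n_eq + k > n) break
    combs <- if (k == 0) matrix(integer(0), ncol = 1) else utils::combn(nf, k)
    for (ci in seq_len(ncol(combs))) {
      sel <- if (k == 0) integer(0) else combs[, ci]
      A <- do.call(rbind, c(rows, facets[sel]))
      b <- c(rhs, frhs[sel])
      if (qr(A)$rank < n) next
      v <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(v)) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (any(abs(N %*% v) > tol)) next
      if (!is.null(Aineq) && any(Aineq %*% v > bineq + tol)) next
      val <- sum(cc * v)
      if (is.null(best) || (maximize && val > best) ||
          (!maximize && val < best)) best <- val
    }
  }
  best
}

# objective value of FBA on a network, via the oracle (net-flux space; valid
# for irreversible-or-plain-reversible nets since c acts on net flux)
fba_oracle <- function(net, objective) {
  ids <- net$reactions$id
  cc <- rep(0, length(ids))
  cc[match(objective$atp, ids)] <- cc[match(objective$atp, ids)] + objective$w_atp
  cc[match(objective$biomass, ids)] <- cc[match(objective$biomass, ids)] +
    objective$w_biomass
  lp_vertex_oracle(cc, net$S, net$reactions$lb, net$reactions$ub)
}

# dense-grid oracle for the triangular membership function
membership_oracle <- function(x, lb, peak, ub, tol_plus) {
  if (ub - lb <= 1e-12) return(as.numeric(abs(x - peak) <= tol_plus))
  eta_l <- if (peak - lb > 1e-12) (x - lb) / (peak - lb) else
    as.numeric(x >= peak - 1e-12)
  eta_r <- if (ub - peak > 1e-12) (ub - x) / (ub - peak) else
    as.numeric(x <= peak + 1e-12)
  max(min(eta_l, eta_r, 1), 0)
}

toy_pair_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_toy_pair()
    cache
  }
})
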