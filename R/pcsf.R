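#' PCSF solver configuration
#'
#' @param mu Hub penalty: node-inclusion cost `mu * degree` (degree in the
#'   full network).
#' @param omega Cost of opening each tree of the forest.
#' @param beta Prize scale.
#' @param runs Ensemble runs.
#' @param r Edge-cost noise level of the ensemble (multiplicative uniform on
#'   `[-r, r]`).
#' @param seed Integer seed.
#' @return An object of class `pcsf_config`.
#' @export
pcsf_config <- function(mu = 0.0005, omega = 0.6, beta = 1000, runs = 10,
                        r = 0.1, seed = 1L) {
  stopifnot(mu >= 0, omega >= 0, beta >= 0, r >= 0, runs >= 1)
  structure(list(mu = mu, omega = omega, beta = beta, runs = runs, r = r,
                 seed = as.integer(seed)), class = "pcsf_config")
}

#' Select terminal molecules and prizes from factor weights
#'
#' Per modality, absolute factor weights are normalised by the modality's
#' maximum; the chance expectation is the mean normalised weight over that
#' modality's features; features at or above `fold` times the expectation
#' are kept, truncated to the top `max_per_modality` by prize. Prizes are
#' the normalised absolute weights. Features without a network node are
#' dropped and listed.
#'
#' @param model A [fit_mofa()] model.
#' @param factor Factor index.
#' @param node_map [harmonize_ids()] table.
#' @param max_per_modality Maximum terminals per modality.
#' @param fold Required fold over the chance expectation.
#' @return data.table `node_id`, `modality`, `feature_id`, `prize`, with
#'   attribute `unmapped_terminals`.
#' @export
select_terminals <- function(model, factor = 1, node_map,
                             max_per_modality = 200, fold = 2) {
  if (factor < 1 || factor > ncol(model$Z)) stop("factor index out of range")
  rows <- list(); unmapped <- character(0)
  for (m in names(model$W)) {
    w <- abs(model$W[[m]][, factor])
    if (max(w) == 0) next
    wn <- w / max(w)
    expect <- mean(wn)
    sel <- which(wn >= fold * expect)
    if (length(sel) == 0) next
    dt <- data.table::data.table(
      feature_id = rownames(model$W[[m]])[sel], modality = m,
      prize = wn[sel])
    dt <- merge(dt, node_map[, .(feature_id, node_id)], by = "feature_id")
    unmapped <- c(unmapped, dt$feature_id[is.na(dt$node_id)])
    dt <- dt[!is.na(node_id)]
    data.table::setorder(dt, -prize, feature_id)
    rows[[m]] <- utils::head(dt, max_per_modality)
  }
  out <- data.table::rbindlist(rows)
  if (length(unmapped) > 0) {
    message(length(unmapped), " terminal candidate(s) without a network ",
            "node dropped")
  }
  data.table::setattr(out, "unmapped_terminals", unmapped)
  out
}

# ---- internal solver representation -------------------------------------

# net: igraph with edge attribute cost; terminals: data.table node_id, prize
# (multiple features on one node combine by their maximum prize)
pcsf_instance <- function(net, terminals, config, cost = NULL) {
  nodes <- igraph::V(net)$name
  ed <- igraph::as_data_frame(net, what = "edges")
  ia <- match(ed$from, nodes); ib <- match(ed$to, nodes)
  cost <- cost %||% ed$cost %||% numeric(0)
  deg <- igraph::degree(net)
  prize <- rep(0, length(nodes)); names(prize) <- nodes
  tin <- terminals[node_id %in% nodes]
  if (nrow(tin) > 0) {
    agg <- tin[, .(prize = max(prize)), by = node_id]
    prize[agg$node_id] <- agg$prize
  }
  list(nodes = nodes, ia = ia, ib = ib, cost = cost, deg = unname(deg),
       prize = unname(prize),
       pi_true = config$beta * unname(prize) - config$mu * unname(deg),
       config = config)
}

#' Recompute the PCSF objective from a solution's parts
#'
#' `sum(edge costs) + mu * sum(deg(v)) + omega * n_trees -
#' beta * sum(prizes)`, degrees taken in the full network.
#'
#' @param sol A `forest_solution`.
#' @return The objective value.
#' @export
pcsf_objective <- function(sol) {
  if (length(sol$nodes) == 0) return(0)
  sum(sol$edges$cost) + sol$config$mu * sum(sol$deg_included) +
    sol$config$omega * sol$n_trees - sol$config$beta * sum(sol$prize_included)
}

make_solution <- function(inst, keep_nodes, keep_edges, terminals,
                          status = "ok") {
  nodes <- inst$nodes[keep_nodes]
  kidx <- which(keep_edges)
  ed <- data.table::data.table(
    from = inst$nodes[inst$ia[kidx]],
    to = inst$nodes[inst$ib[kidx]],
    cost = inst$cost[kidx])
  parent <- seq_along(nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x] <<- parent[parent[x]]
    x
  }
  if (nrow(ed) > 0) {
    for (i in seq_len(nrow(ed))) {
      a <- find(idx[[ed$from[i]]]); b <- find(idx[[ed$to[i]]])
      if (a != b) parent[b] <- a
    }
  }
  tree_id <- integer(0)
  if (length(nodes) > 0) {
    roots <- vapply(seq_along(nodes), find, 0L)
    tree_id <- match(roots, unique(roots))
  }
  term_nodes <- unique(terminals$node_id)
  term_nodes <- term_nodes[term_nodes %in% inst$nodes]
  sol <- list(nodes = nodes,
              edges = ed,
              tree_id = stats::setNames(tree_id, nodes),
              n_trees = length(unique(tree_id)),
              prize_included = inst$prize[keep_nodes],
              deg_included = inst$deg[keep_nodes],
              terminals_covered = sum(term_nodes %in% nodes),
              n_terminals = length(term_nodes),
              coverage = if (length(term_nodes) > 0) {
                sum(term_nodes %in% nodes) / length(term_nodes)
              } else NA_real_,
              steiner = setdiff(nodes, term_nodes),
              config = inst$config,
              status = status)
  class(sol) <- "forest_solution"
  sol$objective <- pcsf_objective(sol)
  sol
}

# exhaustive solver: enumerate node subsets; for a fixed subset the optimal
# edge set is the induced minimum spanning forest with edges >= omega removed
pcsf_exact <- function(inst, terminals) {
  n <- length(inst$nodes)
  stopifnot(n <= 20)
  eord <- order(inst$cost, inst$ia, inst$ib)
  ia <- inst$ia[eord]; ib <- inst$ib[eord]; cost <- inst$cost[eord]
  omega <- inst$config$omega
  base <- inst$config$mu * inst$deg - inst$config$beta * inst$prize
  bits <- bitwShiftL(1L, 0:(n - 1))
  best_obj <- 0; best_nodes <- integer(0); best_edges <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    if (mask == 0L) next
    inS <- bitwAnd(mask, bits) != 0L
    S <- which(inS)
    parent <- seq_len(n)
    kept <- integer(0); csum <- 0; ncomp <- length(S)
    for (k in seq_along(cost)) {
      if (cost[k] >= omega) break
      if (!inS[ia[k]] || !inS[ib[k]]) next
      a <- ia[k]; while (parent[a] != a) a <- parent[a] <- parent[parent[a]]
      b <- ib[k]; while (parent[b] != b) b <- parent[b] <- parent[parent[b]]
      if (a != b) {
        parent[b] <- a; kept <- c(kept, k); csum <- csum + cost[k]
        ncomp <- ncomp - 1
      }
    }
    obj <- csum + omega * ncomp + sum(base[S])
    if (obj < best_obj - 1e-12) {
      best_obj <- obj; best_nodes <- S; best_edges <- eord[kept]
    }
  }
  keep_nodes <- logical(n); keep_nodes[best_nodes] <- TRUE
  keep_edges <- logical(length(inst$cost)); keep_edges[best_edges] <- TRUE
  make_solution(inst, keep_nodes, keep_edges, terminals,
                status = if (!any(keep_nodes)) "empty" else "ok")
}

# Goemans-Williamson moat growth on the virtual-root transformation,
# followed by strong pruning. pi_plus = max(0, beta*prize - mu*deg) drives
# the growth; the exact pi enters pruning and the objective.
pcsf_gw <- function(inst, terminals) {
  n <- length(inst$nodes)
  omega <- inst$config$omega
  pi_true <- inst$pi_true
  pi_plus <- pmax(0, pi_true)
  rc <- n + 1L  # virtual root
  comp <- seq_len(n + 1L)
  members <- as.list(seq_len(n + 1L))
  potential <- c(pi_plus, 0)
  active <- c(pi_plus > 0, FALSE)
  slack <- inst$cost
  rslack <- rep(omega, n)
  # merge forest: child node -> parent node (rc for root edges) + edge index
  f_edge <- integer(0); f_u <- integer(0); f_v <- integer(0)

  repeat {
    cu <- comp[inst$ia]; cv <- comp[inst$ib]
    er <- (active[cu] + active[cv]) * (cu != cv)
    te <- ifelse(er > 0, slack / er, Inf)
    rr <- as.numeric(active[comp[seq_len(n)]])
    tr <- ifelse(rr > 0, rslack / rr, Inf)
    td <- ifelse(active, potential, Inf)
    m1 <- if (length(te)) min(te) else Inf
    m2 <- if (length(tr)) min(tr) else Inf
    m3 <- if (length(td)) min(td) else Inf
    delta <- min(m1, m2, m3)
    if (!is.finite(delta)) break
    delta <- max(delta, 0)
    slack <- slack - delta * er
    rslack <- rslack - delta * rr
    potential[active] <- potential[active] - delta
    if (m1 <= m2 && m1 <= m3) {
      k <- which.min(te)
      a <- comp[inst$ia[k]]; b <- comp[inst$ib[k]]
      if (b == rc) { tmp <- a; a <- rc; b <- tmp }
      into <- if (a == rc) rc else a
      from <- if (a == rc) b else b
      comp[members[[from]]] <- into
      members[[into]] <- c(members[[into]], members[[from]])
      members[[from]] <- integer(0)
      potential[into] <- potential[into] + potential[from]
      active[from] <- FALSE
      active[into] <- into != rc
      f_edge <- c(f_edge, k)
      f_u <- c(f_u, inst$ia[k]); f_v <- c(f_v, inst$ib[k])
      slack[k] <- Inf  # edge consumed
    } else if (m2 <= m3) {
      v <- which.min(tr)
      from <- comp[v]
      comp[members[[from]]] <- rc
      members[[rc]] <- c(members[[rc]], members[[from]])
      members[[from]] <- integer(0)
      active[from] <- FALSE
      f_edge <- c(f_edge, 0L); f_u <- c(f_u, v); f_v <- c(f_v, rc)
      rslack[v] <- Inf
    } else {
      c0 <- which.min(td)
      active[c0] <- FALSE
    }
  }

  # adjacency of the merge forest with per-edge cost and instance index
  adj <- vector("list", n + 1L)
  for (i in seq_along(f_u)) {
    cst <- if (f_edge[i] == 0L) omega else inst$cost[f_edge[i]]
    adj[[f_u[i]]] <- rbind(adj[[f_u[i]]], c(f_v[i], cst, f_edge[i]))
    adj[[f_v[i]]] <- rbind(adj[[f_v[i]]], c(f_u[i], cst, f_edge[i]))
  }
  # BFS from the virtual root
  parent <- rep(NA_integer_, n + 1L)
  parent_cost <- rep(NA_real_, n + 1L)
  parent_eidx <- rep(NA_integer_, n + 1L)
  visited <- logical(n + 1L)
  order_bfs <- integer(0)
  queue <- rc; visited[rc] <- TRUE
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, u)
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      v <- nb[j, 1]
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u; parent_cost[v] <- nb[j, 2]
        parent_eidx[v] <- nb[j, 3]
        queue <- c(queue, v)
      }
    }
  }
  # strong pruning: keep a branch iff its subtree worth exceeds the edge cost
  worth <- c(pi_true, 0)
  keep_branch <- rep(FALSE, n + 1L)
  for (u in rev(order_bfs)) {
    if (is.na(parent[u])) next
    if (worth[u] - parent_cost[u] > 1e-12) {
      keep_branch[u] <- TRUE
      worth[parent[u]] <- worth[parent[u]] + worth[u] - parent_cost[u]
    }
  }
  keep_nodes <- logical(n)
  keep_edges <- logical(length(inst$cost))
  for (u in order_bfs) {
    if (u == rc) next
    if (keep_branch[u] && (parent[u] == rc || keep_nodes[parent[u]])) {
      keep_nodes[u] <- TRUE
      if (parent[u] != rc) keep_edges[parent_eidx[u]] <- TRUE
    }
  }
  # any node worth opening as its own tree is always included
  keep_nodes[inst$pi_true > inst$config$omega + 1e-12] <- TRUE
  ref <- refine_nodeset(inst, keep_nodes)
  if (length(inst$nodes) <= 400) {
    ref <- local_search(inst, ref$keep_nodes)
  }
  make_solution(inst, ref$keep_nodes, ref$keep_edges, terminals,
                status = if (!any(ref$keep_nodes)) "empty" else "ok")
}

# single-node add/remove moves, each followed by refinement; used to polish
# solutions on instances small enough to afford it
local_search <- function(inst, keep_nodes, max_rounds = 50) {
  obj_of <- function(ref) {
    sum(inst$cost[ref$keep_edges]) +
      inst$config$omega * (sum(ref$keep_nodes) - sum(ref$keep_edges)) +
      sum(inst$config$mu * inst$deg[ref$keep_nodes]) -
      sum(inst$config$beta * inst$prize[ref$keep_nodes])
  }
  cur <- refine_nodeset(inst, keep_nodes)
  cur_obj <- obj_of(cur)
  for (round in seq_len(max_rounds)) {
    best <- NULL; best_obj <- cur_obj
    for (v in seq_along(inst$nodes)) {
      kn <- cur$keep_nodes
      kn[v] <- !kn[v]
      if (!any(kn)) next
      ref <- refine_nodeset(inst, kn)
      o <- obj_of(ref)
      if (o < best_obj - 1e-12) { best <- ref; best_obj <- o }
    }
    if (is.null(best)) break
    cur <- best; cur_obj <- best_obj
  }
  cur
}

# improve a candidate node set to a local optimum: induced minimum spanning
# forest with edges >= omega removed, then optimal-subtree (strong) pruning
# of each tree, iterated until the objective stops improving
refine_nodeset <- function(inst, keep_nodes) {
  omega <- inst$config$omega
  pi_true <- inst$pi_true
  eord <- order(inst$cost, inst$ia, inst$ib)
  obj_of <- function(kn, ke) {
    sum(inst$cost[ke]) + omega * count_trees(kn, ke) +
      sum(inst$config$mu * inst$deg[kn]) -
      sum(inst$config$beta * inst$prize[kn])
  }
  count_trees <- function(kn, ke) {
    sum(kn) - sum(ke)  # forest: components = nodes - edges
  }
  best_edges <- msf_edges(inst, keep_nodes, eord, omega)
  best_obj <- obj_of(keep_nodes, best_edges)
  repeat {
    msf <- msf_edges(inst, keep_nodes, eord, omega)
    pruned <- prune_forest(inst, keep_nodes, msf, omega)
    obj <- obj_of(pruned$keep_nodes, pruned$keep_edges)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      keep_nodes <- pruned$keep_nodes
      best_edges <- pruned$keep_edges
    } else break
  }
  list(keep_nodes = keep_nodes, keep_edges = best_edges)
}

# induced minimum spanning forest over the kept nodes, edges >= omega dropped
msf_edges <- function(inst, keep_nodes, eord, omega) {
  n <- length(inst$nodes)
  parent <- seq_len(n)
  keep_edges <- logical(length(inst$cost))
  for (k in eord) {
    if (inst$cost[k] >= omega) break
    u <- inst$ia[k]; v <- inst$ib[k]
    if (!keep_nodes[u] || !keep_nodes[v]) next
    while (parent[u] != u) u <- parent[u] <- parent[parent[u]]
    while (parent[v] != v) v <- parent[v] <- parent[parent[v]]
    if (u != v) { parent[v] <- u; keep_edges[k] <- TRUE }
  }
  keep_edges
}

# optimal connected-subtree pruning of every tree of a forest: rerooting DP
# finds the maximum-net-worth subtree; trees worth <= omega are dropped
prune_forest <- function(inst, keep_nodes, keep_edges, omega) {
  n <- length(inst$nodes)
  pi_true <- inst$pi_true
  adj <- vector("list", n)
  for (k in which(keep_edges)) {
    u <- inst$ia[k]; v <- inst$ib[k]
    adj[[u]] <- rbind(adj[[u]], c(v, inst$cost[k], k))
    adj[[v]] <- rbind(adj[[v]], c(u, inst$cost[k], k))
  }
  out_nodes <- logical(n)
  out_edges <- logical(length(inst$cost))
  visited <- logical(n)
  for (s in which(keep_nodes)) {
    if (visited[s]) next
    # collect the tree by BFS
    comp <- integer(0); queue <- s; visited[s] <- TRUE
    parent <- rep(NA_integer_, n); pcost <- rep(NA_real_, n)
    peidx <- rep(NA_integer_, n)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]; comp <- c(comp, u)
      nb <- adj[[u]]
      if (!is.null(nb)) for (j in seq_len(nrow(nb))) {
        v <- nb[j, 1]
        if (!visited[v]) {
          visited[v] <- TRUE; parent[v] <- u
          pcost[v] <- nb[j, 2]; peidx[v] <- nb[j, 3]
          queue <- c(queue, v)
        }
      }
    }
    # down pass: best subtree containing v inside its rooted subtree
    G <- pi_true
    for (u in rev(comp)) {
      if (!is.na(parent[u])) {
        G[parent[u]] <- G[parent[u]] + max(0, G[u] - pcost[u])
      }
    }
    # up pass: best subtree containing parent(v) avoiding v's subtree
    U <- rep(0, n)
    for (u in comp) {
      p <- parent[u]
      if (is.na(p)) { U[u] <- -Inf; next }
      up_p <- if (is.infinite(U[p])) 0 else max(0, U[p] - pcost[p])
      U[u] <- G[p] - max(0, G[u] - pcost[u]) + up_p
    }
    B <- vapply(comp, function(u) {
      G[u] + if (is.na(parent[u])) 0 else max(0, U[u] - pcost[u])
    }, 0)
    best <- max(B)
    if (best <= omega + 1e-12) next  # whole tree not worth opening
    r <- comp[which.max(B)]
    # reconstruct: rooted DP from r
    parent2 <- rep(NA_integer_, n); pcost2 <- rep(NA_real_, n)
    peidx2 <- rep(NA_integer_, n)
    comp2 <- integer(0); queue <- r
    seen <- logical(n); seen[r] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]; comp2 <- c(comp2, u)
      nb <- adj[[u]]
      if (!is.null(nb)) for (j in seq_len(nrow(nb))) {
        v <- nb[j, 1]
        if (!seen[v]) {
          seen[v] <- TRUE; parent2[v] <- u
          pcost2[v] <- nb[j, 2]; peidx2[v] <- nb[j, 3]
          queue <- c(queue, v)
        }
      }
    }
    G2 <- pi_true
    for (u in rev(comp2)) {
      if (!is.na(parent2[u])) {
        G2[parent2[u]] <- G2[parent2[u]] + max(0, G2[u] - pcost2[u])
      }
    }
    out_nodes[r] <- TRUE
    for (u in comp2) {
      if (u == r) next
      if (out_nodes[parent2[u]] && G2[u] - pcost2[u] > 1e-12) {
        out_nodes[u] <- TRUE
        out_edges[peidx2[u]] <- TRUE
      }
    }
  }
  list(keep_nodes = out_nodes, keep_edges = out_edges)
}

#' Solve the prize-collecting Steiner forest problem
#'
#' Minimises `sum(edge costs) + mu * sum(degrees) + omega * (number of
#' trees) - beta * sum(prizes)` over forests of the network. Small instances
#' (<= 12 nodes) are solved exactly by subset enumeration with an induced
#' minimum-spanning-forest inner step; larger instances use a
#' Goemans-Williamson-style moat-growth phase on a virtual-root
#' transformation (the root is connected to every node at cost omega)
#' followed by strong pruning. Deterministic; ties broken by node index.
#'
#' @param net igraph network with edge attribute `cost`.
#' @param terminals [select_terminals()] table (`node_id`, `prize`).
#' @param config A [pcsf_config()].
#' @param cost Optional replacement edge-cost vector (used by the ensemble).
#' @param force_heuristic Use the moat-growth solver even on small
#'   instances (for oracle comparisons).
#' @return A `forest_solution`: included nodes/edges, tree membership,
#'   objective, terminal coverage, and Steiner node list.
#' @export
solve_pcsf <- function(net, terminals, config = pcsf_config(), cost = NULL,
                       force_heuristic = FALSE) {
  inst <- pcsf_instance(net, terminals, config, cost)
  term_in <- unique(terminals$node_id)
  if (length(term_in) == 0 || !any(term_in %in% inst$nodes)) {
    return(make_solution(inst, logical(length(inst$nodes)),
                         logical(length(inst$cost)), terminals,
                         status = "no-terminal"))
  }
  if (length(inst$nodes) <= 12 && !force_heuristic) {
    pcsf_exact(inst, terminals)
  } else {
    pcsf_gw(inst, terminals)
  }
}

#' Grid search over tree cost and prize scale
#'
#' Records terminal coverage and tree count at each grid point (hub penalty
#' fixed) and chooses the smallest prize scale at which coverage has
#' saturated (within 2 percentage points of every larger prize scale's
#' coverage), among tree costs whose solution has a tree count inside
#' `tree_band`. The full curve is returned for inspection.
#'
#' @param net igraph network with `cost` edge attribute.
#' @param terminals Terminal table.
#' @param omega_grid,beta_grid Grid values.
#' @param mu Fixed hub penalty.
#' @param tree_band Acceptable range of tree counts.
#' @return List with `chosen` ([pcsf_config()]) and `curve` (data.table).
#' @export
grid_search <- function(net, terminals,
                        omega_grid = seq(0.2, 1, by = 0.2),
                        beta_grid = c(100, 250, 500, 1000, 2000),
                        mu = 0.0005, tree_band = c(3, 30)) {
  stopifnot(length(omega_grid) > 0, length(beta_grid) > 0)
  beta_grid <- sort(beta_grid)
  rows <- list()
  for (om in omega_grid) {
    for (be in beta_grid) {
      cfg <- pcsf_config(mu = mu, omega = om, beta = be)
      sol <- solve_pcsf(net, terminals, cfg)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        omega = om, beta = be,
        coverage = 100 * sol$coverage, n_trees = sol$n_trees,
        n_nodes = length(sol$nodes), objective = sol$objective)
    }
  }
  curve <- data.table::rbindlist(rows)
  cand <- list()
  for (om in omega_grid) {
    sub <- curve[omega == om]
    cv <- sub$coverage
    sat <- length(beta_grid)
    for (i in seq_along(beta_grid)) {
      later <- cv[seq_along(beta_grid) > i]
      if (length(later) == 0 || all(cv[i] >= later - 2)) { sat <- i; break }
    }
    cand[[length(cand) + 1L]] <- sub[sat]
  }
  cand <- data.table::rbindlist(cand)
  ok <- cand[n_trees >= tree_band[1] & n_trees <= tree_band[2]]
  if (nrow(ok) == 0) {
    warning("no grid point with tree count in the acceptable band; ",
            "returning the best-coverage point")
    ok <- curve
  }
  data.table::setorder(ok, -coverage, omega, beta)
  chosen <- pcsf_config(mu = mu, omega = ok$omega[1], beta = ok$beta[1])
  list(chosen = chosen, curve = curve)
}

#' Randomized-ensemble Steiner forest
#'
#' Runs the solver `runs` times with multiplicative uniform noise on the
#' edge costs (`cost * (1 + u)`, `u ~ U(-r, r)` i.i.d. per run) and returns
#' the union network of all solutions, annotated with per-edge and per-node
#' selection frequencies.
#'
#' @param net igraph network.
#' @param terminals Terminal table.
#' @param config [pcsf_config()] (fields `runs`, `r`, `seed`).
#' @return igraph union network with `frequency` attributes.
#' @export
ensemble_solve <- function(net, terminals, config = pcsf_config()) {
  if (config$r < 0) stop("noise level r must be >= 0")
  base_cost <- igraph::E(net)$cost
  node_tally <- list(); edge_tally <- list()
  for (run in seq_len(config$runs)) {
    set.seed(config$seed + run)
    noise <- 1 + stats::runif(length(base_cost), -config$r, config$r)
    sol <- solve_pcsf(net, terminals, config, cost = base_cost * noise)
    for (v in sol$nodes) node_tally[[v]] <- (node_tally[[v]] %||% 0) + 1
    if (nrow(sol$edges) > 0) {
      keys <- paste(pmin(sol$edges$from, sol$edges$to),
                    pmax(sol$edges$from, sol$edges$to), sep = "|")
      for (k in keys) edge_tally[[k]] <- (edge_tally[[k]] %||% 0) + 1
    }
  }
  nodes <- sort(names(node_tally))
  vfull <- data.table::as.data.table(
    igraph::as_data_frame(net, what = "vertices"))
  vdt <- data.table::data.table(
    name = nodes, frequency = unlist(node_tally[nodes]) / config$runs)
  vdt <- merge(vdt, vfull, by = "name", all.x = TRUE, sort = TRUE)
  ekeys <- sort(names(edge_tally))
  if (length(ekeys) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (nrow(vdt) > 0) {
      g <- igraph::add_vertices(g, nrow(vdt), name = vdt$name,
                                frequency = vdt$frequency)
    }
    return(g)
  }
  full <- data.table::as.data.table(igraph::as_data_frame(net, "edges"))
  full[, key := paste(pmin(from, to), pmax(from, to), sep = "|")]
  ed <- full[key %in% ekeys]
  ed[, frequency := unlist(edge_tally[key]) / config$runs]
  ed[, key := NULL]
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vdt)
}

#' Edge-betweenness clustering of a network
#'
#' Girvan-Newman edge-betweenness hierarchy, cut at maximum modularity
#' (edge costs act as distances). Disconnected components are never merged;
#' singleton clusters are allowed.
#'
#' @param g igraph network.
#' @return List with `membership` (named integer vector) and the
#'   `communities` object.
#' @export
cluster_network <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty network")
  w <- igraph::E(g)$cost
  cm <- suppressWarnings(igraph::cluster_edge_betweenness(
    g, weights = w, directed = FALSE))
  list(membership = igraph::membership(cm), communities = cm)
}

#' Per-cluster contrast profiles
#'
#' For every cluster and contrast: the mean log2 fold change over the
#' molecules mapped to the cluster's nodes and the percentage with a
#' significant adjusted p-value. Molecules measured in several modalities
#' contribute once per modality.
#'
#' @param membership Named cluster membership from [cluster_network()].
#' @param tables Nested contrast list from [fit_all_contrasts()].
#' @param node_map [harmonize_ids()] table.
#' @return data.table `cluster`, `group`, `timepoint`, `n_molecules`,
#'   `mean_logfc`, `pct_significant`.
#' @export
cluster_profiles <- function(membership, tables, node_map) {
  memb <- data.table::data.table(node_id = names(membership),
                                 cluster = as.integer(membership))
  mapped <- merge(node_map[!is.na(node_id)], memb, by = "node_id")
  rows <- list()
  for (m in names(tables)) {
    for (nm in names(tables[[m]])) {
      ct <- tables[[m]][[nm]]
      meta <- attr(ct, "contrast")
      dd <- merge(mapped[modality == m],
                  ct[, .(feature_id, logFC, significant)],
                  by = "feature_id")
      if (nrow(dd) == 0) next
      rows[[length(rows) + 1L]] <-
        dd[, .(modality = m, group = meta$group,
               timepoint = meta$timepoint, n_molecules = .N,
               sum_logfc = sum(logFC), n_sig = sum(significant)),
           by = cluster]
    }
  }
  if (length(rows) == 0) {
    return(data.table::data.table(cluster = integer(), group = character(),
                                  timepoint = numeric(),
                                  n_molecules = integer(),
                                  mean_logfc = numeric(),
                                  pct_significant = numeric()))
  }
  all <- data.table::rbindlist(rows)
  prof <- all[, .(n_molecules = sum(n_molecules),
                  mean_logfc = sum(sum_logfc) / sum(n_molecules),
                  pct_significant = 100 * sum(n_sig) / sum(n_molecules)),
              by = .(cluster, group, timepoint)]
  empty <- setdiff(unique(memb$cluster), unique(prof$cluster))
  if (length(empty) > 0) {
    prof <- data.table::rbindlist(list(
      prof,
      data.table::data.table(cluster = empty, group = NA_character_,
                             timepoint = NA_real_, n_molecules = 0L,
                             mean_logfc = NA_real_,
                             pct_significant = NA_real_)))
  }
  data.table::setorder(prof, cluster, group, timepoint, na.last = TRUE)
  prof
}
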