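#' Build the candidate-link graph between localizations
#'
#' Candidate links connect every pair of localizations separated by at most
#' `max_dist` micrometers in space and at most `max_gap` frames in time
#' (gaps allow a molecule to be missed for up to `max_gap - 1` frames).
#' The edge set equals brute-force pair enumeration; frames are indexed to
#' keep the search near-linear in practice.
#'
#' @param localizations `data.frame` with columns `frame`, `x_um`, `y_um`
#'   (e.g. from [localize_spots()]). Row order defines detection ids.
#' @param max_dist Maximum link displacement in um (default 1.25).
#' @param max_gap Maximum frame gap (default 3).
#' @return List of class `smt_link_graph`: `nodes` (the localization table
#'   with an `id` column), `edges` (`data.frame`: `src`, `dst`, `delta`,
#'   `dist_um`, plus `log_lik`, `p` once inferred), `max_dist`, `max_gap`.
#' @export
build_link_graph <- function(localizations, max_dist = 1.25, max_gap = 3L) {
  loc <- as.data.frame(localizations)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(loc)))
  loc$id <- seq_len(nrow(loc))
  edges <- list()
  ne <- 0L
  if (nrow(loc) > 1L) {
    by_frame <- split(loc$id, loc$frame)
    frames <- as.integer(names(by_frame))
    for (fi in seq_along(frames)) {
      for (delta in seq_len(max_gap)) {
        tj <- match(frames[fi] + delta, frames)
        if (is.na(tj)) next
        src <- by_frame[[fi]]; dst <- by_frame[[tj]]
        dx <- outer(loc$x_um[src], loc$x_um[dst], "-")
        dy <- outer(loc$y_um[src], loc$y_um[dst], "-")
        d <- sqrt(dx^2 + dy^2)
        hit <- which(d <= max_dist, arr.ind = TRUE)
        if (nrow(hit) > 0L) {
          ne <- ne + 1L
          edges[[ne]] <- data.frame(src = src[hit[, 1L]],
                                    dst = dst[hit[, 2L]],
                                    delta = delta,
                                    dist_um = d[hit])
        }
      }
    }
  }
  edges <- if (ne > 0L) do.call(rbind, edges) else
    data.frame(src = integer(), dst = integer(), delta = integer(),
               dist_um = numeric())
  edges <- edges[order(edges$src, edges$delta, edges$dst), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = loc, edges = edges, max_dist = max_dist,
                 max_gap = as.integer(max_gap)),
            class = "smt_link_graph")
}

#' Infer marginal link probabilities under a Brownian-motion model
#'
#' Iterative variational scheme that jointly estimates marginal link
#' probabilities and a per-spot diffusion coefficient:
#'
#' 1. Each candidate link's likelihood is the 2-D Gaussian density of its
#'    displacement with per-axis variance `2 * D * (delta * dt) +
#'    2 * sigma_loc^2`, where `D` blends (averages) the source and target
#'    per-spot estimates. Each detection also carries a constant-density
#'    "no-link" alternative (appearance/disappearance), by default uniform
#'    over the search disc at `delta = 1`: `1 / (pi * max_dist^2)` per um^2.
#' 2. Marginal probabilities are the normalized responsibilities over each
#'    detection's alternatives, with the source (outgoing) and target
#'    (incoming) sides symmetrized by sum-product message passing on the
#'    one-link-per-detection constraint graph: with odds
#'    `lambda_e = lik_e / nolink_density`, messages
#'    `alpha_e = 1 / (1 + sum_{e' out of src(e), e' != e} lambda β)` and
#'    `beta_e = 1 / (1 + sum_{e' into dst(e), e' != e} lambda α)` are
#'    iterated to a fixed point, at which the responsibility
#'    `p_e = lambda alpha beta / (1 + lambda alpha beta)` agrees between
#'    the two sides.
#' 3. For small connected components of the candidate graph (at most
#'    `exact_max_edges` edges) the marginals are instead computed exactly by
#'    enumerating all conflict-free link configurations weighted by
#'    `prod(lambda)` — the same distribution the messages approximate —
#'    so the approximation is only used where enumeration would be
#'    expensive.
#' 4. Per-spot diffusion coefficients are re-estimated from
#'    probability-weighted squared displacements of incident links.
#'
#' Outer rounds stop when the largest marginal change falls below `tol` or
#' after `max_rounds` rounds. On output, for every detection
#' `p(no outgoing) + sum p(outgoing) = 1` and likewise for incoming.
#'
#' @param graph `smt_link_graph` from [build_link_graph()].
#' @param dt Frame interval in seconds.
#' @param sigma_loc Localization error (1-D RMSD) in um (default 0.035).
#' @param nolink_density Density of the no-link alternative in um^-2
#'   (default `1 / (pi * max_dist^2)`).
#' @param d_init Initial per-spot diffusion coefficient in um^2/s
#'   (default 0.5).
#' @param tol Convergence tolerance on marginals (default 1e-4).
#' @param max_rounds Maximum iteration rounds (default 20).
#' @param exact_max_edges Components with at most this many candidate links
#'   get exact enumeration instead of message passing (default 10; set to 0
#'   to force message passing everywhere).
#' @return The graph with `edges$log_lik`, `edges$p`, per-node `D_hat`,
#'   `p_no_out`, `p_no_in` filled in.
#' @export
infer_link_probabilities <- function(graph, dt, sigma_loc = 0.035,
                                     nolink_density = NULL, d_init = 0.5,
                                     tol = 1e-4, max_rounds = 20L,
                                     exact_max_edges = 10L) {
  stopifnot(inherits(graph, "smt_link_graph"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive frame interval in seconds")
  n <- nrow(graph$nodes)
  e <- graph$edges
  if (is.null(nolink_density)) nolink_density <- 1 / (pi * graph$max_dist^2)
  D_hat <- rep(d_init, n)
  if (nrow(e) == 0L) {
    graph$nodes$D_hat <- D_hat
    graph$nodes$p_no_out <- rep(1, n)
    graph$nodes$p_no_in <- rep(1, n)
    graph$edges$log_lik <- numeric(0)
    graph$edges$p <- numeric(0)
    graph$nolink_density <- nolink_density
    return(graph)
  }
  p <- rep(0, nrow(e))
  comp <- edge_components(e, n)
  small <- which(tabulate(comp, nbins = max(comp))[comp] <= exact_max_edges)
  small_by_comp <- split(small, comp[small])
  for (round in seq_len(max_rounds)) {
    Dbar <- (D_hat[e$src] + D_hat[e$dst]) / 2
    v <- 2 * Dbar * (e$delta * dt) + 2 * sigma_loc^2
    lik <- exp(-e$dist_um^2 / (2 * v)) / (2 * pi * v)
    lambda <- lik / nolink_density
    alpha <- rep(1, nrow(e)); beta <- rep(1, nrow(e))
    for (bp in 1:200) {
      lb <- lambda * beta
      beta_new <- 1 / (1 + tapply_sum(lambda * alpha, e$dst, n)[e$dst] -
                         lambda * alpha)
      alpha_new <- 1 / (1 + tapply_sum(lb, e$src, n)[e$src] - lb)
      moved <- max(abs(alpha_new - alpha), abs(beta_new - beta))
      alpha <- alpha_new; beta <- beta_new
      if (moved < 1e-9) break
    }
    lab <- lambda * alpha * beta
    p_new <- lab / (1 + lab)
    for (idx in small_by_comp)
      p_new[idx] <- exact_link_marginals(lambda[idx], e$src[idx], e$dst[idx])
    # M-step: probability-weighted apparent diffusion of incident links
    d_contrib <- pmax(e$dist_um^2 / (4 * e$delta * dt) -
                        sigma_loc^2 / (e$delta * dt), 1e-4)
    num <- tapply_sum(p_new * d_contrib, e$src, n) +
           tapply_sum(p_new * d_contrib, e$dst, n)
    den <- tapply_sum(p_new, e$src, n) + tapply_sum(p_new, e$dst, n)
    D_hat <- ifelse(den > 1e-8, pmin(pmax(num / pmax(den, 1e-8), 1e-4), 100),
                    d_init)
    done <- max(abs(p_new - p)) < tol
    p <- p_new
    ll <- log(lik)
    if (done) break
  }
  graph$edges$log_lik <- ll
  graph$edges$p <- p
  graph$nodes$D_hat <- D_hat
  graph$nodes$p_no_out <- pmax(1 - tapply_sum(p, e$src, n), 0)
  graph$nodes$p_no_in <- pmax(1 - tapply_sum(p, e$dst, n), 0)
  graph$nolink_density <- nolink_density
  graph
}

# connected components of the candidate graph, labeling edges by component
edge_components <- function(e, n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(e))) {
    a <- find(e$src[k]); b <- find(e$dst[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(e$src, find, integer(1))
  match(roots, unique(roots))
}

# exact marginal link probabilities of one component: enumerate all
# conflict-free link subsets M with weight prod(lambda[M]) and marginalize
exact_link_marginals <- function(lambda, src, dst) {
  ne <- length(lambda)
  tot <- 0
  per_edge <- numeric(ne)
  rec <- function(k, wt, used_src, used_dst, chosen) {
    if (k > ne) {
      tot <<- tot + wt
      per_edge[chosen] <<- per_edge[chosen] + wt
      return()
    }
    rec(k + 1L, wt, used_src, used_dst, chosen)
    if (!(src[k] %in% used_src) && !(dst[k] %in% used_dst))
      rec(k + 1L, wt * lambda[k], c(used_src, src[k]), c(used_dst, dst[k]),
          c(chosen, k))
  }
  rec(1L, 1, integer(0), integer(0), integer(0))
  per_edge / tot
}

# sum x by integer group id over 1..n (dense, zero-filled)
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# objective of a matching: sum of log p over selected links plus log no-link
# mass for every detection left unmatched on its outgoing / incoming side.
# Detections with no candidate edges on a side contribute a constant and are
# ignored.
matching_objective <- function(graph, sel, floor_p = 1e-12) {
  e <- graph$edges
  n <- nrow(graph$nodes)
  has_out <- unique(e$src); has_in <- unique(e$dst)
  out_used <- e$src[sel]; in_used <- e$dst[sel]
  obj <- sum(log(pmax(e$p[sel], floor_p)))
  q <- pmax(graph$nodes$p_no_out, floor_p)
  r <- pmax(graph$nodes$p_no_in, floor_p)
  obj + sum(log(q[setdiff(has_out, out_used)])) +
    sum(log(r[setdiff(has_in, in_used)]))
}

#' Select a conflict-free set of links by hill climbing
#'
#' Finds a local optimum of the matching objective — the sum of log marginal
#' probabilities of the selected links plus the log no-link masses of
#' detections left unlinked — under the constraint that no detection starts
#' or ends more than one link. Moves are: add a link; remove a link; swap
#' (add a link after removing the one or two links it conflicts with); and
#' rotation (a swap that additionally reconnects the displaced endpoints
#' through another candidate link, which is what lets two competing
#' assignments exchange targets in one improving step). The best strictly
#' improving move is applied until none exists. The result is
#' deterministic given the input order (ties broken by edge order, which is
#' sorted by `(src, delta, dst)`).
#'
#' Links whose marginal probability falls below `prune_factor` times the
#' smaller of the two incident no-link masses are pruned before climbing.
#'
#' @param graph `smt_link_graph` with marginals from
#'   [infer_link_probabilities()].
#' @param prune_factor Pruning threshold factor (default 0.5).
#' @return Integer vector of selected edge indices into `graph$edges`, with
#'   attribute `objective`.
#' @export
select_links <- function(graph, prune_factor = 0.5) {
  stopifnot(inherits(graph, "smt_link_graph"))
  e <- graph$edges
  if (nrow(e) == 0L) return(structure(integer(), objective = 0))
  if (is.null(e$p)) stop("run infer_link_probabilities() first")
  nolink <- pmin(graph$nodes$p_no_out[e$src], graph$nodes$p_no_in[e$dst])
  active <- which(e$p > prune_factor * nolink & e$p > 0)
  if (length(active) == 0L) return(structure(integer(), objective = 0))
  floor_p <- 1e-12
  lp <- log(pmax(e$p, floor_p))
  lq <- log(pmax(graph$nodes$p_no_out, floor_p))
  lr <- log(pmax(graph$nodes$p_no_in, floor_p))
  # gain of adding edge k to an empty slot pair
  gain <- lp[active] - lq[e$src[active]] - lr[e$dst[active]]
  sel <- logical(length(active))
  asrc <- e$src[active]; adst <- e$dst[active]
  out_of <- integer(nrow(graph$nodes))  # active-index of edge using node's out slot
  in_of <- integer(nrow(graph$nodes))
  by_dst <- split(seq_along(active), adst)   # active indices by target node
  by_src <- split(seq_along(active), asrc)
  repeat {
    best_delta <- 1e-9
    best_move <- NULL
    for (k in seq_along(active)) {
      if (sel[k]) {
        d <- -gain[k]   # removal
        if (d > best_delta) { best_delta <- d; best_move <- list(rm = k) }
        next
      }
      co <- out_of[asrc[k]]; ci <- in_of[adst[k]]
      d <- gain[k]
      rm <- integer()
      if (co > 0L) { d <- d - gain[co]; rm <- c(rm, co) }
      if (ci > 0L && ci != co) { d <- d - gain[ci]; rm <- c(rm, ci) }
      if (d > best_delta) { best_delta <- d; best_move <- list(add = k, rm = rm) }
      # rotation: reconnect the slots freed by the displaced links
      if (co > 0L || ci > 0L) {
        j2 <- if (co > 0L) adst[co] else 0L   # in-slot freed by removing co
        i2 <- if (ci > 0L) asrc[ci] else 0L   # out-slot freed by removing ci
        r1 <- 0L; r2 <- 0L
        if (j2 > 0L) {
          for (f in by_dst[[as.character(j2)]]) {
            if (f == co || f == k || sel[f]) next
            oo <- out_of[asrc[f]]
            if ((oo == 0L || oo == ci) && asrc[f] != asrc[k] &&
                gain[f] > (if (r1 > 0L) gain[r1] else 0)) r1 <- f
          }
        }
        if (i2 > 0L) {
          for (f in by_src[[as.character(i2)]]) {
            if (f == ci || f == k || sel[f]) next
            ii <- in_of[adst[f]]
            if ((ii == 0L || ii == co) && adst[f] != adst[k] &&
                gain[f] > (if (r2 > 0L) gain[r2] else 0)) r2 <- f
          }
        }
        adds <- k
        if (r1 > 0L && r2 > 0L && r1 != r2 && asrc[r1] == asrc[r2])
          r2 <- 0L   # the two reconnections would share an out slot
        if (r1 > 0L && r2 > 0L && r1 != r2 && adst[r1] == adst[r2])
          r2 <- 0L
        dr <- d
        if (r1 > 0L) { dr <- dr + gain[r1]; adds <- c(adds, r1) }
        if (r2 > 0L && r2 != r1) { dr <- dr + gain[r2]; adds <- c(adds, r2) }
        if (length(adds) > 1L && dr > best_delta) {
          best_delta <- dr; best_move <- list(add = adds, rm = rm)
        }
      }
    }
    if (is.null(best_move)) break
    for (k in best_move$rm) {
      sel[k] <- FALSE
      out_of[asrc[k]] <- 0L
      in_of[adst[k]] <- 0L
    }
    for (k in best_move$add) {
      sel[k] <- TRUE
      out_of[asrc[k]] <- k
      in_of[adst[k]] <- k
    }
  }
  chosen <- active[sel]
  structure(chosen, objective = matching_objective(graph, chosen))
}

#' Assemble trajectories from a selected link set
#'
#' Connected components of the conflict-free link subgraph become
#' trajectories; detections with no selected link become length-1
#' trajectories. Every localization appears in exactly one trajectory.
#'
#' @param graph `smt_link_graph`.
#' @param selected Integer edge indices from [select_links()].
#' @param dt Frame interval in seconds (used to compute jump intervals).
#' @return List of class `smt_trajectories`: `points` (localization table
#'   with `trajectory` column, ordered by trajectory then frame) and
#'   `jumps` (`data.frame`: `trajectory`, `dx_um`, `dy_um`, `delta`,
#'   `dt_s`, `d2_um2`).
#' @export
assemble_trajectories <- function(graph, selected, dt) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  e <- graph$edges[selected, , drop = FALSE]
  if (anyDuplicated(e$src) || anyDuplicated(e$dst))
    stop("selected links violate the matching constraint")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(e))) {
    a <- find(e$src[k]); b <- find(e$dst[k])
    if (a == b) stop("cycle in selected links (should be impossible)")
    parent[b] <- a
  }
  root <- vapply(seq_len(n), find, integer(1))
  traj_id <- match(root, unique(root[order(nodes$frame, nodes$y_um, nodes$x_um)]))
  pts <- nodes
  pts$trajectory <- traj_id
  pts <- pts[order(pts$trajectory, pts$frame), , drop = FALSE]
  if (anyDuplicated(pts[, c("trajectory", "frame")]))
    stop("two localizations share a frame within one trajectory")
  rownames(pts) <- NULL
  jumps <- compute_jumps(pts, dt)
  structure(list(points = pts, jumps = jumps), class = "smt_trajectories")
}

compute_jumps <- function(points, dt) {
  sp <- split(points, points$trajectory)
  res <- lapply(sp, function(p) {
    if (nrow(p) < 2L) return(NULL)
    dxs <- diff(p$x_um); dys <- diff(p$y_um); dels <- diff(p$frame)
    data.frame(trajectory = p$trajectory[1L], dx_um = dxs, dy_um = dys,
               delta = dels, dt_s = dels * dt, d2_um2 = dxs^2 + dys^2)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(trajectory = integer(), dx_um = numeric(),
                      dy_um = numeric(), delta = integer(), dt_s = numeric(),
                      d2_um2 = numeric())
  rownames(res) <- NULL
  res
}

#' Track: detections to trajectories in one call
#'
#' Convenience wrapper chaining [build_link_graph()],
#' [infer_link_probabilities()], [select_links()] and
#' [assemble_trajectories()].
#'
#' @param localizations Localization table with `frame`, `x_um`, `y_um`.
#' @param dt Frame interval (s).
#' @param max_dist,max_gap Candidate-link bounds (um, frames).
#' @param ... Passed to [infer_link_probabilities()].
#' @return `smt_trajectories`.
#' @export
link_trajectories <- function(localizations, dt, max_dist = 1.25,
                              max_gap = 3L, ...) {
  g <- build_link_graph(localizations, max_dist = max_dist, max_gap = max_gap)
  g <- infer_link_probabilities(g, dt = dt, ...)
  sel <- select_links(g)
  assemble_trajectories(g, sel, dt)
}
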