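# Exact optimal transport (Earth Mover's Distance) via the transportation
# simplex. No installed R package provides an exact EMD solver, so the
# network-simplex specialisation is implemented here directly: basic
# feasible solutions are spanning trees of the bipartite supply/demand
# graph, potentials are solved on the tree, and the entering/leaving pivots
# walk the unique tree cycle. A deterministic infinitesimal perturbation of
# the supplies avoids degenerate cycling; the returned allocations are
# re-solved exactly on the optimal basis with the unperturbed marginals, so
# the marginal constraints hold to machine precision.

#' Exact Earth Mover's Distance coupling
#'
#' Solves \code{min <gamma, cost>} subject to \code{gamma . 1 = a},
#' \code{t(gamma) . 1 = b}, \code{gamma >= 0} exactly.
#'
#' @param cost n x m cost matrix.
#' @param a,b supply/demand marginals (defaults: uniform 1/n and 1/m).
#' @return list with \code{gamma} (n x m coupling) and \code{objective}
#'   (the Frobenius inner product at optimum).
#' @export
emd_exact <- function(cost, a = NULL, b = NULL) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  stopifnot(length(a) == n, length(b) == m, all(a > 0), all(b > 0))
  if (abs(sum(a) - sum(b)) > 1e-9 * max(sum(a), sum(b)))
    stop("emd_exact: marginals must have equal total mass")
  # deterministic anti-degeneracy perturbation, removed again at the end
  delta <- 1e-11 * max(sum(a), 1)
  ap <- a + delta * seq_len(n)
  bp <- b * (sum(ap) / sum(b))

  # north-west corner initial basis
  Fl <- matrix(0, n, m)
  B <- matrix(FALSE, n, m)
  ra <- ap; rb <- bp
  i <- 1L; j <- 1L
  while (i <= n && j <= m) {
    f <- min(ra[i], rb[j])
    Fl[i, j] <- f; B[i, j] <- TRUE
    ra[i] <- ra[i] - f; rb[j] <- rb[j] - f
    if (i == n && j == m) break
    if (ra[i] <= rb[j] && i < n) i <- i + 1L else j <- j + 1L
  }

  max_iter <- 20L * (n + m)^2 + 1000L
  for (iter in seq_len(max_iter)) {
    uv <- tree_potentials(B, cost, n, m)
    red <- cost - outer(uv$u, rep(1, m)) - outer(rep(1, n), uv$v)
    red[B] <- 0
    k <- which.min(red)
    if (red[k] >= -1e-11) break
    ei <- (k - 1L) %% n + 1L
    ej <- (k - 1L) %/% n + 1L
    path <- tree_path(B, ei, ej, n, m)   # node sequence row ei ... col ej
    # cycle = entering edge (+) then path edges alternating -, +, -, ...
    sign_ <- -1
    theta <- Inf; leave <- NULL
    edges <- path$edges
    for (e in seq_len(nrow(edges))) {
      if (sign_ < 0 && Fl[edges[e, 1], edges[e, 2]] < theta) {
        theta <- Fl[edges[e, 1], edges[e, 2]]
        leave <- edges[e, ]
      }
      sign_ <- -sign_
    }
    sign_ <- -1
    for (e in seq_len(nrow(edges))) {
      Fl[edges[e, 1], edges[e, 2]] <- Fl[edges[e, 1], edges[e, 2]] + sign_ * theta
      sign_ <- -sign_
    }
    Fl[ei, ej] <- theta
    B[ei, ej] <- TRUE
    B[leave[1], leave[2]] <- FALSE
    Fl[leave[1], leave[2]] <- 0
  }
  gamma <- tree_flow(B, a, b, n, m)
  list(gamma = gamma, objective = sum(gamma * cost))
}

# Potentials u, v with u[1] = 0 solving u_i + v_j = C_ij over basis edges.
tree_potentials <- function(B, cost, n, m) {
  u <- rep(NA_real_, n); v <- rep(NA_real_, m)
  u[1] <- 0
  repeat {
    changed <- FALSE
    for (i in which(!is.na(u))) {
      js <- which(B[i, ] & is.na(v))
      if (length(js)) { v[js] <- cost[i, js] - u[i]; changed <- TRUE }
    }
    for (j in which(!is.na(v))) {
      is_ <- which(B[, j] & is.na(u))
      if (length(is_)) { u[is_] <- cost[is_, j] - v[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  # disconnected components (can arise transiently): pin them at zero
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  list(u = u, v = v)
}

# Unique path of basis edges from row node `ri` to column node `cj`;
# returns edges as an (i, j) matrix in walk order starting at `ri`.
tree_path <- function(B, ri, cj, n, m) {
  # nodes: rows 1..n, cols n+1..n+m; parent-pointer BFS
  parent <- integer(n + m); parent[] <- -1L
  parent[ri] <- 0L
  queue <- ri
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    if (nd == n + cj) break
    if (nd <= n) {
      nb <- which(B[nd, ]) + n
    } else {
      nb <- which(B[, nd - n])
    }
    nb <- nb[parent[nb] == -1L]
    parent[nb] <- nd
    queue <- c(queue, nb)
  }
  nodes <- n + cj
  while (nodes[1] != ri) nodes <- c(parent[nodes[1]], nodes)
  edges <- matrix(0L, length(nodes) - 1L, 2)
  for (e in seq_len(nrow(edges))) {
    p <- nodes[e]; q <- nodes[e + 1]
    if (p <= n) edges[e, ] <- c(p, q - n) else edges[e, ] <- c(q, p - n)
  }
  list(nodes = nodes, edges = edges)
}

# Exact allocations on the basis tree for given marginals (leaf elimination).
tree_flow <- function(B, a, b, n, m) {
  gamma <- matrix(0, n, m)
  deg_r <- rowSums(B); deg_c <- colSums(B)
  ra <- a; rb <- b
  Bw <- B
  active_r <- rep(TRUE, n); active_c <- rep(TRUE, m)
  total_edges <- sum(Bw)
  for (step in seq_len(total_edges)) {
    li <- which(active_r & deg_r == 1L)
    if (length(li)) {
      i <- li[1]
      j <- which(Bw[i, ])[1]
      gamma[i, j] <- ra[i]
      rb[j] <- rb[j] - ra[i]; ra[i] <- 0
      Bw[i, j] <- FALSE; deg_r[i] <- 0L; deg_c[j] <- deg_c[j] - 1L
      active_r[i] <- FALSE
      next
    }
    lj <- which(active_c & deg_c == 1L)
    if (length(lj)) {
      j <- lj[1]
      i <- which(Bw[, j])[1]
      gamma[i, j] <- rb[j]
      ra[i] <- ra[i] - rb[j]; rb[j] <- 0
      Bw[i, j] <- FALSE; deg_c[j] <- 0L; deg_r[i] <- deg_r[i] - 1L
      active_c[j] <- FALSE
      next
    }
    break
  }
  # numerical guard: clip the sub-machine-precision negatives a degenerate
  # basis can leave behind
  gamma[gamma < 0 & gamma > -1e-9] <- 0
  gamma
}

#' Optimal-transport pairing of control and stimulated cells
#'
#' For each cell type present in both conditions: PCA (fit on the pooled
#' control + stimulated cells of that type) to \code{n_pcs} dimensions,
#' Euclidean cost between condition groups, exact EMD with uniform
#' marginals, and each control cell is paired with the stimulated cell
#' holding the largest mass in its coupling row (ties broken toward the
#' lowest stimulated index). Stimulated cells may be reused across pairs.
#' Types with fewer than 2 cells in either condition are skipped with a
#' warning.
#'
#' @param ctrl,stim \code{processed_matrix} objects (or matrices) for the
#'   two conditions.
#' @param ctrl_labels,stim_labels per-cell type labels (defaults: the
#'   \code{cell_labels} carried by the processed matrices).
#' @param n_pcs PCA dimensionality of the cost space (default 50).
#' @return list with \code{plan} (per-type couplings, costs and uniform
#'   weights) and \code{pairs} (a [paired_dataset()], origin
#'   \code{ot_matched}).
#' @export
ot_pair_perturbation <- function(ctrl, stim, ctrl_labels = NULL,
                                 stim_labels = NULL, n_pcs = 50) {
  vc <- if (inherits(ctrl, "processed_matrix")) ctrl$values else as.matrix(ctrl)
  vs <- if (inherits(stim, "processed_matrix")) stim$values else as.matrix(stim)
  if (is.null(ctrl_labels) && inherits(ctrl, "processed_matrix"))
    ctrl_labels <- ctrl$cell_labels
  if (is.null(stim_labels) && inherits(stim, "processed_matrix"))
    stim_labels <- stim$cell_labels
  ctrl_labels <- as.character(ctrl_labels); stim_labels <- as.character(stim_labels)
  stopifnot(length(ctrl_labels) == nrow(vc), length(stim_labels) == nrow(vs))
  shared <- intersect(unique(ctrl_labels), unique(stim_labels))
  if (length(shared) == 0) stop("ot_pair_perturbation: no shared cell types")
  plan <- list()
  prs <- NULL
  for (k in shared) {
    ic <- which(ctrl_labels == k)
    is_ <- which(stim_labels == k)
    if (length(ic) < 2 || length(is_) < 2) {
      warning("ot_pair_perturbation: type '", k,
              "' has fewer than 2 cells in a condition; skipped")
      next
    }
    pooled <- rbind(vc[ic, , drop = FALSE], vs[is_, , drop = FALSE])
    pe <- pca_embed(pooled, n_pcs)
    pc <- pe[seq_along(ic), , drop = FALSE]
    ps <- pe[length(ic) + seq_along(is_), , drop = FALSE]
    M <- euclidean_cross_dist(pc, ps)
    sol <- emd_exact(M)
    match_j <- ot_row_match(sol$gamma)
    plan[[k]] <- list(gamma = sol$gamma, cost = M,
                      w_ctr = rep(1 / length(ic), length(ic)),
                      w_sti = rep(1 / length(is_), length(is_)),
                      objective = sol$objective,
                      ctrl_idx = ic, stim_idx = is_)
    prs <- rbind(prs, data.frame(idx1 = ic, idx2 = is_[match_j],
                                 origin = "ot_matched", group = k,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(prs)) stop("ot_pair_perturbation: no type had enough cells to pair")
  list(plan = plan,
       pairs = structure(list(pairs = prs), class = "paired_dataset"))
}

# Row-wise argmax with a small tolerance so that exact ties (equal coupling
# mass up to floating noise) resolve to the lowest stimulated index.
ot_row_match <- function(gamma, tol = 1e-9) {
  apply(gamma, 1, function(v) min(which(v >= max(v) - tol)))
}

euclidean_cross_dist <- function(x, y) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

# Plain PCA embedding (centered, unscaled), capped at n - 1 components.
pca_embed <- function(x, n_pcs) {
  x <- as.matrix(x)
  k <- min(n_pcs, nrow(x) - 1L, ncol(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  p$x
}
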