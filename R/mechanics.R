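#' Build the seven-cell hexagonal mechanical patch
#'
#' Constructs a central regular hexagonal cell and its six neighbours in the
#' apical plane. Cell vertices are network nodes joined by actin-belt edges
#' along all cell boundaries; each cell additionally has a virtual centre
#' node connected to its six vertices by transverse (apical actomyosin)
#' edges. All rest lengths are set to the current lengths, so the passive
#' network starts prestress-free. Each belt edge carries a Kelvin-Voigt
#' element (spring + dashpot) in parallel with a constant contractile active
#' force; transverse edges are passive by default.
#'
#' The belt graph of the patch has 24 vertex nodes and 30 edges; with the 7
#' centre nodes the full network has 31 nodes and 72 edges.
#'
#' @param edge_length Hexagon side (micrometres).
#' @param KN,KT Belt/transverse spring stiffness (pN/um). The default keeps
#'   the patch away from the collapse threshold (`K * edge_length` must
#'   exceed the sum of the active force and the magnitude of compressive
#'   boundary forces).
#' @param Xi Damping coefficient (pN s/um), used for the edge dashpots in
#'   inertial mode and as the drag coefficient in overdamped mode.
#' @param FA_belt,FA_transverse Constant contractile active force per edge
#'   (pN).
#' @param mass Nominal node mass (model mass units); small enough that
#'   inertial and overdamped stationary states agree.
#' @return Object of class `"mech_network"`: a list with `pos` (n x 2 matrix,
#'   um), `vel` (n x 2), `mass`, `belt` and `transverse` edge tables
#'   (`from`, `to`, `rest`, `K`, `Xi`, `FA`), `cells` (per cell: ordered
#'   vertex ids and centre-node id), `boundary` (exterior vertex ids) and
#'   `centroid` of the initial configuration.
#' @export
build_hex_patch <- function(edge_length = 1, KN = 1500, KT = 1500, Xi = 100,
                            FA_belt = 900, FA_transverse = 0, mass = 1) {
  if (edge_length <= 0) stop("`edge_length` must be positive", call. = FALSE)
  a <- edge_length
  centers <- rbind(c(0, 0),
                   t(vapply(0:5, function(k) {
                     th <- pi / 6 + k * pi / 3
                     sqrt(3) * a * c(cos(th), sin(th))
                   }, numeric(2))))
  hex_vertices <- function(cc) {
    t(vapply(0:5, function(k) {
      th <- k * pi / 3
      cc + a * c(cos(th), sin(th))
    }, numeric(2)))
  }
  # collect unique vertices with a tolerance-based key
  key <- function(p) paste(round(p[1] / a, 6), round(p[2] / a, 6))
  pos_list <- list()
  vid <- new.env(parent = emptyenv())
  get_id <- function(p) {
    k <- key(p)
    if (!is.null(vid[[k]])) return(vid[[k]])
    pos_list[[length(pos_list) + 1L]] <<- p
    vid[[k]] <- length(pos_list)
    vid[[k]]
  }
  cells <- vector("list", 7)
  belt_set <- new.env(parent = emptyenv())
  belt <- list()
  for (ci in 1:7) {
    vv <- hex_vertices(centers[ci, ])
    ids <- vapply(seq_len(6), function(k) get_id(vv[k, ]), integer(1))
    cells[[ci]] <- list(vertices = ids)
    for (k in 1:6) {
      i <- ids[k]; j <- ids[if (k == 6) 1 else k + 1]
      ek <- paste(min(i, j), max(i, j))
      if (is.null(belt_set[[ek]])) {
        belt_set[[ek]] <- TRUE
        belt[[length(belt) + 1L]] <- c(min(i, j), max(i, j))
      }
    }
  }
  n_vertex <- length(pos_list)
  pos <- do.call(rbind, pos_list)
  # virtual centre nodes
  for (ci in 1:7) {
    pos <- rbind(pos, centers[ci, ])
    cells[[ci]]$center <- n_vertex + ci
  }
  n <- nrow(pos)
  belt <- do.call(rbind, belt)
  belt_df <- data.frame(from = belt[, 1], to = belt[, 2])
  len <- function(e) sqrt(rowSums((pos[e$to, , drop = FALSE] -
                                     pos[e$from, , drop = FALSE])^2))
  belt_df$rest <- len(belt_df)
  belt_df$K <- KN; belt_df$Xi <- Xi; belt_df$FA <- FA_belt
  tr <- do.call(rbind, lapply(1:7, function(ci)
    data.frame(from = cells[[ci]]$vertices, to = cells[[ci]]$center)))
  tr$rest <- len(tr)
  tr$K <- KT; tr$Xi <- Xi; tr$FA <- FA_transverse
  # exterior vertices: every hull vertex, i.e. all belt nodes that are not
  # vertices of the central cell
  belt_nodes <- sort(unique(c(belt_df$from, belt_df$to)))
  boundary <- setdiff(belt_nodes, cells[[1]]$vertices)

  net <- structure(list(pos = pos, vel = matrix(0, n, 2),
                        mass = rep(mass, n),
                        belt = belt_df, transverse = tr,
                        cells = cells, boundary = boundary,
                        belt_nodes = belt_nodes,
                        centroid = colMeans(pos[seq_len(n_vertex), ,
                                                drop = FALSE]),
                        Xi = Xi),
                   class = "mech_network")
  validate_mech_network(net)
  net
}

validate_mech_network <- function(net) {
  stopifnot(is.matrix(net$pos), ncol(net$pos) == 2)
  edges <- rbind(net$belt[c("from", "to", "rest")],
                 net$transverse[c("from", "to", "rest")])
  if (any(edges$rest <= 0)) stop("rest lengths must be positive",
                                 call. = FALSE)
  if (any(edges$from == edges$to)) stop("self-loop edge", call. = FALSE)
  g <- igraph::graph_from_edgelist(as.matrix(edges[c("from", "to")]),
                                   directed = FALSE)
  if (igraph::components(g)$no != 1)
    stop("network graph must be connected", call. = FALSE)
  invisible(net)
}

#' @export
print.mech_network <- function(x, ...) {
  cat(sprintf(paste0("Mechanical cell network: %d nodes (%d boundary), ",
                     "%d belt + %d transverse edges, %d cells\n"),
              nrow(x$pos), length(x$boundary), nrow(x$belt),
              nrow(x$transverse), length(x$cells)))
  invisible(x)
}

#' Graph Laplacians of the belt and transverse networks
#'
#' Returns the (optionally stiffness-weighted) graph Laplacians of the
#' actin-belt and transverse connection graphs over all network nodes:
#' symmetric, zero row sums, `-1` (or `-K`) per off-diagonal edge.
#'
#' @param network A [build_hex_patch()] network.
#' @param weighted Use spring stiffnesses as edge weights.
#' @return List with dense matrices `belt` and `transverse`.
#' @export
graph_laplacians <- function(network, weighted = FALSE) {
  n <- nrow(network$pos)
  lap <- function(e) {
    g <- igraph::graph_from_edgelist(as.matrix(e[c("from", "to")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    w <- if (weighted) e$K else NULL
    as.matrix(igraph::laplacian_matrix(g, weights = w, sparse = FALSE))
  }
  list(belt = lap(network$belt), transverse = lap(network$transverse))
}

# per-node forces -------------------------------------------------------------

edge_force_terms <- function(pos, vel, e, with_damping = TRUE) {
  d <- pos[e$to, , drop = FALSE] - pos[e$from, , drop = FALSE]
  L <- sqrt(rowSums(d^2))
  if (any(L < 1e-12)) stop("zero-length edge", call. = FALSE)
  u <- d / L
  Fs <- e$K * (L - e$rest)              # spring tension, >0 when stretched
  Fd <- if (with_damping) {
    rel <- vel[e$to, , drop = FALSE] - vel[e$from, , drop = FALSE]
    e$Xi * rowSums(rel * u)
  } else 0
  Ft <- Fs + Fd + e$FA                  # total tension along the edge
  list(u = u, L = L, tension = Ft, spring = Fs)
}

#' Net force on every node
#'
#' Accumulates, per edge, the spring force `K (L - l)`, the dashpot force
#' `Xi` times the relative velocity projected on the edge, and the constant
#' contractile active force `FA`, all acting along the edge unit vector with
#' equal and opposite contributions on the two endpoints, plus any imposed
#' boundary forces.
#'
#' @param network A `mech_network`.
#' @param imposed Signed imposed force magnitude (pN) applied to every
#'   boundary node along the outward ray from the current network centroid
#'   (positive = stretch, negative = compression); or a vector over boundary
#'   nodes. Using the instantaneous centroid keeps a rigid translation of
#'   the patch force-free.
#' @param with_damping Include the edge dashpot terms (uses current
#'   velocities).
#' @return n x 2 matrix of node forces (pN).
#' @export
edge_forces <- function(network, imposed = 0, with_damping = TRUE) {
  pos <- network$pos; vel <- network$vel
  n <- nrow(pos)
  Fm <- matrix(0, n, 2)
  for (e in list(network$belt, network$transverse)) {
    tm <- edge_force_terms(pos, vel, e, with_damping)
    fe <- tm$tension * tm$u               # force on `from`, toward `to`
    for (col in 1:2) {
      Fm[, col] <- Fm[, col] +
        tapply_add(fe[, col], e$from, n) - tapply_add(fe[, col], e$to, n)
    }
  }
  imp <- rep_len(imposed, length(network$boundary))
  if (any(imp != 0)) {
    b <- network$boundary
    ctr <- colMeans(pos[network$belt_nodes, , drop = FALSE])
    dirs <- pos[b, , drop = FALSE] -
      matrix(ctr, length(b), 2, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    Fm[b, ] <- Fm[b, ] + imp * dirs
  }
  Fm
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Elastic plus kinetic energy of the network
#'
#' @param network A `mech_network`.
#' @return Named vector `c(elastic, kinetic)` (pN um).
#' @export
network_energy <- function(network) {
  el <- 0
  for (e in list(network$belt, network$transverse)) {
    d <- network$pos[e$to, , drop = FALSE] -
      network$pos[e$from, , drop = FALSE]
    L <- sqrt(rowSums(d^2))
    el <- el + sum(e$K / 2 * (L - e$rest)^2)
  }
  kin <- sum(network$mass / 2 * rowSums(network$vel^2))
  c(elastic = el, kinetic = kin)
}

#' Integrate the network dynamics
#'
#' In `"inertial"` mode the full momentum balance
#' `M x'' = F_spring + F_dashpot + F_active + F_imposed` is integrated; in
#' `"overdamped"` mode the mass term is dropped and the edge dashpots are
#' replaced by an equivalent drag to the substrate,
#' `Xi x' = F_spring + F_active + F_imposed`, which has the same stationary
#' states. Integration stops early once the maximum node speed falls below
#' `v_tol`.
#'
#' @param network A `mech_network`.
#' @param imposed Imposed boundary force (see [edge_forces()]).
#' @param horizon Time horizon (s).
#' @param mode `"overdamped"` (default) or `"inertial"`.
#' @param v_tol Stationarity tolerance on the maximum node speed (um/s).
#' @param n_out Number of saved snapshots.
#' @return The network with updated positions/velocities, with attributes
#'   `stationary` (logical), `time` (reached), and `trajectory` (data.frame
#'   of time, max speed, energies).
#' @export
integrate_network <- function(network, imposed = 0, horizon = 60,
                              mode = c("overdamped", "inertial"),
                              v_tol = 1e-4, n_out = 25) {
  mode <- match.arg(mode)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  n <- nrow(network$pos)
  times <- seq(0, horizon, length.out = max(2, n_out))
  net <- network
  # already stationary: nothing to integrate
  F0 <- edge_forces(net, imposed, with_damping = FALSE)
  v0 <- if (mode == "overdamped") 0 else max(sqrt(rowSums(net$vel^2)))
  if (max(max(sqrt(rowSums(F0^2))) / net$Xi, v0) <= v_tol) {
    net$vel <- matrix(0, n, 2)
    attr(net, "stationary") <- TRUE
    attr(net, "time") <- 0
    return(net)
  }
  if (mode == "overdamped") {
    y0 <- as.vector(net$pos)
    rhs <- function(t, y, p) {
      net$pos <- matrix(y, n, 2)
      F <- edge_forces(net, imposed, with_damping = FALSE)
      list(as.vector(F / net$Xi))
    }
    root <- function(t, y, p) {
      net$pos <- matrix(y, n, 2)
      F <- edge_forces(net, imposed, with_damping = FALSE)
      max(sqrt(rowSums(F^2))) / net$Xi - v_tol
    }
    sol <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                           rootfunc = root, atol = 1e-8, rtol = 1e-8)
    yf <- sol[nrow(sol), -1]
    net$pos <- matrix(yf, n, 2)
    net$vel <- matrix(edge_forces(net, imposed, with_damping = FALSE) /
                        net$Xi, n, 2)
  } else {
    y0 <- c(as.vector(net$pos), as.vector(net$vel))
    rhs <- function(t, y, p) {
      net$pos <- matrix(y[1:(2 * n)], n, 2)
      net$vel <- matrix(y[(2 * n + 1):(4 * n)], n, 2)
      F <- edge_forces(net, imposed, with_damping = TRUE)
      list(c(y[(2 * n + 1):(4 * n)], as.vector(F / net$mass)))
    }
    root <- function(t, y, p) {
      net$pos <- matrix(y[1:(2 * n)], n, 2)
      net$vel <- matrix(y[(2 * n + 1):(4 * n)], n, 2)
      F <- edge_forces(net, imposed, with_damping = TRUE)
      # stationary only when both speeds and accelerations have died out
      max(max(sqrt(rowSums(net$vel^2))),
          max(sqrt(rowSums(F^2))) / net$Xi) - v_tol
    }
    sol <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                           rootfunc = root, atol = 1e-8, rtol = 1e-8)
    yf <- sol[nrow(sol), -1]
    net$pos <- matrix(yf[1:(2 * n)], n, 2)
    net$vel <- matrix(yf[(2 * n + 1):(4 * n)], n, 2)
  }
  if (any(!is.finite(net$pos)) ||
      max(sqrt(rowSums(net$vel^2))) > 1e3)
    stop("network integration diverged; reduce forcing or horizon",
         call. = FALSE)
  speed <- max(sqrt(rowSums(net$vel^2)))
  attr(net, "stationary") <- speed <= v_tol * 1.0001
  attr(net, "time") <- sol[nrow(sol), 1]
  net
}

#' Swell one cell by rescaling its rest lengths
#'
#' Multiplies the rest lengths of the target cell's belt and transverse
#' edges by `sqrt(area_scale)`, emulating a volume change (e.g. osmotic
#' water uptake). Positions are unchanged; relaxation happens in
#' [integrate_network()]. No volume conservation is imposed.
#'
#' @param network A `mech_network`.
#' @param cell_id Cell index, 1 = centre.
#' @param area_scale Target area ratio (> 0).
#' @return The modified network.
#' @export
apply_swelling <- function(network, cell_id = 1, area_scale = 1.5) {
  if (area_scale <= 0) stop("`area_scale` must be positive", call. = FALSE)
  if (!cell_id %in% seq_along(network$cells))
    stop(sprintf("unknown cell %s", cell_id), call. = FALSE)
  s <- sqrt(area_scale)
  cl <- network$cells[[cell_id]]
  vs <- cl$vertices
  on_cell_belt <- network$belt$from %in% vs & network$belt$to %in% vs
  network$belt$rest[on_cell_belt] <- network$belt$rest[on_cell_belt] * s
  on_cell_tr <- network$transverse$to == cl$center |
    network$transverse$from == cl$center
  network$transverse$rest[on_cell_tr] <- network$transverse$rest[on_cell_tr] * s
  network
}

#' Grow rest lengths
#'
#' Relative (exponential) growth `l <- l * exp(rate * dt)` applied per edge.
#'
#' @param network A `mech_network`.
#' @param belt_rates,transverse_rates Growth rates (1/s or 1/min, matching
#'   `dt`), length 1 or one per edge.
#' @param dt Time increment.
#' @return The modified network.
#' @export
grow_rest_lengths <- function(network, belt_rates = 0, transverse_rates = 0,
                              dt) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  network$belt$rest <- network$belt$rest *
    exp(rep_len(belt_rates, nrow(network$belt)) * dt)
  network$transverse$rest <- network$transverse$rest *
    exp(rep_len(transverse_rates, nrow(network$transverse)) * dt)
  network
}

#' Cell polygon areas
#'
#' Shoelace area of each cell's vertex polygon.
#'
#' @param network A `mech_network`.
#' @return Numeric vector of cell areas (um^2).
#' @export
cell_areas <- function(network) {
  vapply(network$cells, function(cl) {
    p <- network$pos[cl$vertices, , drop = FALSE]
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
}

#' Per-cell side lengths
#'
#' @param network A `mech_network`.
#' @param cell_id Cell index.
#' @return Vector of the 6 current side lengths of the cell (um).
#' @export
cell_side_lengths <- function(network, cell_id) {
  vs <- network$cells[[cell_id]]$vertices
  p <- network$pos[vs, , drop = FALSE]
  q <- p[c(2:6, 1), , drop = FALSE]
  sqrt(rowSums((q - p)^2))
}

#' Junctional tension at a node
#'
#' The tension reported to the alpha-catenin module: the mean of the
#' positive (tensile) total tensions (spring + active) of the belt edges
#' incident on the node. Compressed edges contribute zero - compression is
#' not transmitted to the CCC.
#'
#' @param network A `mech_network`.
#' @param nodes Node ids (default: all belt nodes).
#' @return Named numeric vector of tensions (pN, >= 0).
#' @export
node_tension <- function(network, nodes = NULL) {
  e <- network$belt
  tm <- edge_force_terms(network$pos, network$vel, e, with_damping = FALSE)
  tens <- pmax(tm$tension, 0)
  all_nodes <- sort(unique(c(e$from, e$to)))
  if (is.null(nodes)) nodes <- all_nodes
  out <- vapply(nodes, function(i) {
    k <- which(e$from == i | e$to == i)
    if (length(k) == 0)
      stop(sprintf("node %d has no belt edges", i), call. = FALSE)
    mean(tens[k])
  }, numeric(1))
  setNames(out, nodes)
}
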