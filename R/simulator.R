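#' Validate a network adjacency matrix
#' @keywords internal
check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix")
  if (!all(adj %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  invisible(adj)
}

#' Erdos-Renyi random network
#'
#' Each unordered node pair carries an edge independently with probability
#' `S` (the network sparsity). Expected edge count is `choose(p, 2) * S`.
#'
#' @param p number of nodes (>= 2).
#' @param S edge probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return p x p binary adjacency matrix, symmetric with zero diagonal.
#' @export
random_network <- function(p, S, seed = NULL) {
  if (p < 2) stop("p must be at least 2")
  if (S < 0 || S > 1) stop("S must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(0L, p, p)
  up <- upper.tri(adj)
  adj[up] <- stats::rbinom(sum(up), 1L, S)
  adj <- adj + t(adj)
  dimnames(adj) <- list(node_names(p), node_names(p))
  adj
}

#' @keywords internal
node_names <- function(p) paste0("g", seq_len(p))

#' Random precision matrix for a given network
#'
#' Builds a precision matrix supported on the edges of `graph`: unit
#' diagonal, zero on non-edges, and on each edge an initial weight drawn
#' uniformly from `[-1, -0.05] U [0.05, 1]`. To guarantee positive
#' definiteness each off-diagonal entry of row i is then divided by
#' `1.5 * sum_{j != i} |omega_ij|` (row-wise diagonal dominance), and the
#' rescaled matrix is averaged with its transpose to restore symmetry.
#'
#' @param graph binary adjacency matrix.
#' @param seed optional integer seed.
#' @return symmetric positive-definite precision matrix with unit diagonal.
#' @export
random_precision <- function(graph, seed = NULL) {
  check_adjacency(graph)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(graph)
  omega <- matrix(0, p, p)
  up <- which(upper.tri(omega) & graph == 1)
  m <- length(up)
  if (m > 0) {
    # uniform on [-1,-0.05] U [0.05,1]: random sign, magnitude U(0.05, 1)
    w <- sample(c(-1, 1), m, replace = TRUE) * stats::runif(m, 0.05, 1)
    omega[up] <- w
    omega <- omega + t(omega)
    rs <- rowSums(abs(omega))
    scal <- ifelse(rs > 0, 1.5 * rs, 1)
    omega <- omega / scal          # row-wise rescale of off-diagonals
    omega <- (omega + t(omega)) / 2
  }
  diag(omega) <- 1
  dimnames(omega) <- dimnames(graph)
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("constructed precision matrix not positive definite; ",
         "smallest eigenvalue ", format(ev))
  omega
}

#' Scale-free network by preferential attachment
#'
#' Grows a tree by Barabasi-Albert preferential attachment, one edge per
#' new node, yielding exactly `p - 1` edges and hub-prone degrees.
#'
#' @param p number of nodes (>= 2).
#' @param seed optional integer seed.
#' @return p x p binary adjacency matrix.
#' @export
scale_free_network <- function(p, seed = NULL) {
  if (p < 2) stop("p must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj[adj > 0] <- 1L
  storage.mode(adj) <- "integer"
  dimnames(adj) <- list(node_names(p), node_names(p))
  adj
}

#' Precision matrix with homogeneous edge partial correlation
#'
#' Constructs `Omega = I - rho_target * A` (unit diagonal), so that every
#' edge of `A` has partial correlation exactly `rho_target` and every
#' non-edge exactly zero. Feasibility requires
#' `|rho_target| < 1 / max|eigenvalue(A)|`; violating it cannot give a
#' positive-definite matrix and raises an error reporting the bound.
#'
#' @param graph binary adjacency matrix.
#' @param rho_target common partial correlation on the edges (signed).
#' @return symmetric positive-definite precision matrix, unit diagonal.
#' @export
homogeneous_precision <- function(graph, rho_target) {
  check_adjacency(graph)
  if (rho_target == 0) {
    omega <- diag(ncol(graph))
    dimnames(omega) <- dimnames(graph)
    return(omega)
  }
  ev <- eigen(graph, symmetric = TRUE, only.values = TRUE)$values
  lam <- max(abs(ev))
  if (abs(rho_target) * lam >= 1)
    stop("infeasible rho_target: |rho| must be below 1/", format(lam),
         " = ", format(1 / lam), " for this graph (extreme adjacency ",
         "eigenvalue ", format(lam), ")")
  omega <- diag(ncol(graph)) - rho_target * graph
  dimnames(omega) <- dimnames(graph)
  omega
}

#' Fixed two-hub benchmark network
#'
#' A deterministic 50-node tree with 49 edges and two hub nodes: node 2 has
#' degree 14 and node 4 degree 7. The remaining nodes are attached by a
#' fixed-seed preferential scheme over the non-hub nodes, so the fixture is
#' identical on every call. Its precision matrix sets every edge's partial
#' correlation to -0.216 via [homogeneous_precision()].
#'
#' @return list with components `graph` (50 x 50 adjacency) and `omega`
#'   (precision matrix).
#' @export
m3_fixture <- function() {
  p <- 50
  adj <- matrix(0L, p, p)
  add_edge <- function(a, i, j) { a[i, j] <- a[j, i] <- 1L; a }
  # hub node 2: 14 neighbours (node 4 among them)
  for (k in c(1, 3:15)) adj <- add_edge(adj, 2, k)
  # hub node 4: 6 further neighbours for total degree 7
  for (k in 16:21) adj <- add_edge(adj, 4, k)
  # attach remaining 29 nodes preferentially among non-hub nodes
  rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(20221110L)
  for (k in 22:50) {
    elig <- setdiff(which(rowSums(adj) > 0), c(2, 4))
    target <- sample(elig, 1, prob = rowSums(adj)[elig])
    adj <- add_edge(adj, target, k)
  }
  if (is.null(rng)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", rng, envir = globalenv())
  }
  dimnames(adj) <- list(node_names(p), node_names(p))
  list(graph = adj, omega = homogeneous_precision(adj, -0.216))
}

#' Benchmark simulation settings
#'
#' Named presets for the benchmark regimes: random networks
#' `M1.1` (p = 25, S = 0.05), `M1.2` (p = 25, S = 0.10),
#' `M1.3` (p = 50, S = 0.05), `M1.4` (p = 50, S = 0.10); scale-free trees
#' `M2.1` (p = 25) and `M2.2` (p = 50); and the fixed two-hub network `M3`
#' (p = 50, homogeneous partial correlation -0.216). Sample size defaults
#' to n = 250 in all regimes.
#'
#' @param regime one of `"M1.1"`, `"M1.2"`, `"M1.3"`, `"M1.4"`, `"M2.1"`,
#'   `"M2.2"`, `"M3"`, or `"M1"`/`"M2"` with explicit `p` (and `S`).
#' @param n sample size.
#' @param p,S optional overrides for custom M1/M2 settings.
#' @return list of class `"simulation_setting"`.
#' @export
simulation_setting <- function(regime, n = 250, p = NULL, S = NULL) {
  presets <- list(
    "M1.1" = list(family = "M1", p = 25, S = 0.05),
    "M1.2" = list(family = "M1", p = 25, S = 0.10),
    "M1.3" = list(family = "M1", p = 50, S = 0.05),
    "M1.4" = list(family = "M1", p = 50, S = 0.10),
    "M2.1" = list(family = "M2", p = 25, S = NA_real_),
    "M2.2" = list(family = "M2", p = 50, S = NA_real_),
    "M3"   = list(family = "M3", p = 50, S = NA_real_)
  )
  if (regime %in% names(presets)) {
    cfg <- presets[[regime]]
  } else if (regime %in% c("M1", "M2")) {
    if (is.null(p)) stop("custom ", regime, " setting needs p")
    if (regime == "M1" && is.null(S)) stop("custom M1 setting needs S")
    cfg <- list(family = regime, p = p, S = if (regime == "M1") S else NA_real_)
  } else stop("unknown regime: ", regime)
  if (n < 2) stop("n must be at least 2")
  out <- c(cfg, list(n = n, regime = regime))
  class(out) <- "simulation_setting"
  out
}

#' Simulate a benchmark data set
#'
#' Draws the true network and precision matrix of a benchmark regime and
#' generates `n` multivariate normal samples from it. For `M3` the network
#' is the fixed fixture and only the data vary with the seed.
#'
#' @param setting a [simulation_setting()] (or regime name passed through).
#' @param seed integer seed controlling both graph and data.
#' @param rho_target edge partial correlation used for scale-free (`M2`)
#'   precision matrices; default -0.216.
#' @return list with `graph`, `omega`, `x` (n x p data, unstandardized),
#'   and the `setting`.
#' @export
simulate_setting <- function(setting, seed = NULL, rho_target = -0.216) {
  if (is.character(setting)) setting <- simulation_setting(setting)
  if (!is.null(seed)) set.seed(seed)
  if (setting$family == "M1") {
    graph <- random_network(setting$p, setting$S)
    omega <- random_precision(graph)
  } else if (setting$family == "M2") {
    graph <- scale_free_network(setting$p)
    omega <- homogeneous_precision(graph, rho_target)
  } else {
    fx <- m3_fixture()
    graph <- fx$graph
    omega <- fx$omega
  }
  x <- sample_mvn(omega, setting$n)
  list(graph = graph, omega = omega, x = x, setting = setting)
}
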