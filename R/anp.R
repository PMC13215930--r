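#' Saaty random consistency indices RI(1..15)
#'
#' Random indices for reciprocal judgment matrices of order 1 to 15, used in
#' the consistency ratio CR = CI / RI. Orders 1-10 are Saaty's classic
#' values; 11-15 the extended table, needed because a criterion influencing
#' many factors (such as a root cause reaching most of the network) yields a
#' comparison of that order.
#' @format Numeric vector of length 15.
#' @keywords internal
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59)

.check_reciprocal <- function(P, tol = 1e-6) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("judgment matrix must be square", call. = FALSE)
  if (any(P <= 0)) stop("judgment matrix entries must be positive", call. = FALSE)
  if (max(abs(P * t(P) - 1)) > tol) {
    stop("judgment matrix is not reciprocal (p_ji != 1/p_ij beyond tolerance)",
         call. = FALSE)
  }
  if (max(abs(diag(P) - 1)) > tol) {
    stop("judgment matrix diagonal must be 1", call. = FALSE)
  }
  P
}

#' Priority vector of a Saaty judgment matrix (eigenvalue method)
#'
#' The local weights are the principal right eigenvector of the positive
#' reciprocal matrix P, normalized to sum 1; lambda_max is the principal
#' eigenvalue (>= m, with equality iff P is perfectly consistent).
#'
#' @param P positive reciprocal m x m judgment matrix.
#' @param tol reciprocity tolerance.
#' @return List with `weights` (sum 1, named after P's dimnames) and
#'   `lambda_max`.
#' @examples
#' priority_vector(matrix(c(1, 2, 0.5, 1), 2, 2))$weights  # 1/3, 2/3
#' @export
priority_vector <- function(P, tol = 1e-6) {
  P <- .check_reciprocal(P, tol)
  e <- eigen(P)
  i <- which.max(Re(e$values))
  w <- abs(Re(e$vectors[, i]))
  w <- w / sum(w)
  names(w) <- rownames(P)
  list(weights = w, lambda_max = Re(e$values[i]))
}

#' Consistency report for a judgment matrix
#'
#' CI = (lambda_max - m) / (m - 1); CR = CI / RI(m) with Saaty's random
#' index table; the acceptance gate is CR < 0.1. For m <= 2 a reciprocal
#' matrix is always consistent and CR is defined as 0.
#'
#' @param P positive reciprocal judgment matrix (order at most 10).
#' @return List with `lambda_max`, `CI`, `RI`, `CR`, and `pass`
#'   (CR < 0.1).
#' @examples
#' consistency(matrix(c(1, 3, 1/3, 1), 2, 2))$CR  # 0
#' @export
consistency <- function(P) {
  P <- .check_reciprocal(P)
  m <- nrow(P)
  if (m > length(saaty_ri)) {
    stop("no random index for order ", m,
         "; decompose the comparison into smaller matrices", call. = FALSE)
  }
  pv <- priority_vector(P)
  if (m <= 2L) {
    return(list(lambda_max = pv$lambda_max, CI = 0, RI = 0, CR = 0,
                pass = TRUE))
  }
  ci <- (pv$lambda_max - m) / (m - 1)
  ri <- saaty_ri[m]
  cr <- ci / ri
  list(lambda_max = pv$lambda_max, CI = ci, RI = ri, CR = cr, pass = cr < 0.1)
}

#' Build the ANP influence network from a relation matrix and clusters
#'
#' Records a directed influence edge j -> i for every off-diagonal entry
#' (j, i) = 1 of the supplied relation matrix (typically the ISM reachability
#' matrix, so direct and indirect influence both enter the network; an
#' adjacency matrix restricts it to direct edges). Factors are grouped into
#' Haddon-matrix clusters.
#'
#' @param relation_matrix binary square matrix over the factors (reachability
#'   or adjacency); rownames are factor ids.
#' @param cluster_of named character vector mapping every factor id to its
#'   cluster label.
#' @param extra_edges optional data.frame `from`, `to` of additional directed
#'   influence edges (inner dependences beyond the relation matrix).
#' @return Object of class `"anp_network"`: list with `factors`, `clusters`
#'   (ordered unique labels), `cluster_of`, `edges` (data.frame `from`,
#'   `to`), `targets` (per-factor list of influenced factors), `influencers`
#'   (per-factor list), `sources` (factors no one influences), `sinks`
#'   (factors influencing no one).
#' @examples
#' fx <- drowning_fixtures()
#' m <- reachability_from_sets(fx$reachable_sets)
#' net <- build_network(m, stats::setNames(fx$factors$cluster, fx$factors$code))
#' net$sources  # "F1" "F8" "F15" "F16"
#' @export
build_network <- function(relation_matrix, cluster_of, extra_edges = NULL) {
  m <- as.matrix(relation_matrix)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  missing_cluster <- setdiff(ids, names(cluster_of))
  if (length(missing_cluster)) {
    stop("unclustered factor(s): ", paste(missing_cluster, collapse = ", "),
         call. = FALSE)
  }
  s <- (m != 0) * 1L
  diag(s) <- 0L
  if (!is.null(extra_edges) && nrow(extra_edges)) {
    for (r in seq_len(nrow(extra_edges))) {
      s[extra_edges$from[r], extra_edges$to[r]] <- 1L
    }
    diag(s) <- 0L
  }
  e <- which(s == 1L, arr.ind = TRUE)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  edges <- data.frame(from = ids[e[, 1L]], to = ids[e[, 2L]],
                      stringsAsFactors = FALSE)
  targets <- lapply(ids, function(f) ids[s[f, ] == 1L])
  influencers <- lapply(ids, function(f) ids[s[, f] == 1L])
  names(targets) <- names(influencers) <- ids
  structure(
    list(
      factors = ids,
      clusters = unique(unname(cluster_of[ids])),
      cluster_of = cluster_of[ids],
      edges = edges,
      targets = targets,
      influencers = influencers,
      sources = ids[lengths(influencers) == 0L],
      sinks = ids[lengths(targets) == 0L]
    ),
    class = "anp_network"
  )
}

#' @export
print.anp_network <- function(x, ...) {
  cat("ANP network:", length(x$factors), "factors in",
      length(x$clusters), "clusters;", nrow(x$edges), "influence edges\n")
  cat("  sources (uninfluenced):", paste(x$sources, collapse = ", "), "\n")
  cat("  sinks (influence no one):", paste(x$sinks, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the unweighted supermatrix from local priorities
#'
#' Column j of the unweighted supermatrix W0 distributes factor j's influence
#' over the factors it influences: the rows of j's target set hold the
#' priority vector of the judgment matrix comparing those targets with
#' respect to j (orientation: entry (i, j) > 0 iff j influences i). A factor
#' with a single target needs no judgment (that entry is 1); a sink receives
#' a diagonal 1 (absorbing self-loop) so every column sums to 1.
#'
#' @param network an [build_network()] result.
#' @param judgments named list of judgment matrices, one per factor with >= 2
#'   targets; each matrix must carry its compared target ids as dimnames.
#' @return n x n matrix with attribute `stage = "unweighted"`.
#' @export
assemble_unweighted <- function(network, judgments) {
  ids <- network$factors
  n <- length(ids)
  w0 <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in ids) {
    tg <- network$targets[[j]]
    if (length(tg) == 0L) {
      w0[j, j] <- 1
    } else if (length(tg) == 1L) {
      w0[tg, j] <- 1
    } else {
      P <- judgments[[j]]
      if (is.null(P)) {
        stop("missing judgment matrix for criterion ", j,
             " comparing {", paste(tg, collapse = ", "), "}", call. = FALSE)
      }
      if (is.null(rownames(P)) || !setequal(rownames(P), tg)) {
        stop("judgment matrix for ", j, " compares {",
             paste(rownames(P), collapse = ", "), "} but the network expects {",
             paste(tg, collapse = ", "), "}", call. = FALSE)
      }
      pv <- priority_vector(P)
      w0[names(pv$weights), j] <- pv$weights
    }
  }
  attr(w0, "stage") <- "unweighted"
  w0
}

.cluster_connectivity <- function(W0, cluster_of, clusters) {
  conn <- matrix(FALSE, length(clusters), length(clusters),
                 dimnames = list(clusters, clusters))
  nz <- which(W0 > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    conn[cluster_of[[rownames(W0)[nz[r, 1L]]]],
         cluster_of[[colnames(W0)[nz[r, 2L]]]]] <- TRUE
  }
  conn
}

#' Cluster weight matrix for the weighted supermatrix
#'
#' In this package's supermatrix orientation a column distributes its
#' factor's influence over the factors it reaches, so block column c of W0
#' is nonzero exactly at the clusters *receiving* cluster c's influence.
#' Column c of the cluster weight matrix accordingly holds the relative
#' weights of those receiving clusters (compared with respect to c); cluster
#' pairs with no inter-cluster link are structural zeros. With no judgment
#' supplied for a column its linked clusters are weighted uniformly (1/k),
#' the documented fallback when inter-cluster comparisons are unavailable.
#'
#' @param W0 unweighted supermatrix (from [assemble_unweighted()]).
#' @param network the [build_network()] result behind `W0`.
#' @param cluster_judgments optional named list of judgment matrices keyed by
#'   criterion cluster c, comparing the clusters linked to c (dimnames must
#'   be those cluster labels).
#' @return k x k matrix (clusters x clusters); every column with any entry
#'   sums to 1.
#' @export
cluster_weight_matrix <- function(W0, network, cluster_judgments = NULL) {
  clusters <- network$clusters
  conn <- .cluster_connectivity(W0, network$cluster_of, clusters)
  a <- matrix(0, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  for (cl in clusters) {
    linked <- clusters[conn[, cl]]
    if (length(linked) == 0L) next
    P <- cluster_judgments[[cl]]
    if (is.null(P)) {
      a[linked, cl] <- 1 / length(linked)
    } else {
      if (is.null(rownames(P)) || !setequal(rownames(P), linked)) {
        stop("cluster judgment for ", cl, " compares {",
             paste(rownames(P), collapse = ", "),
             "} but the clusters linked to ", cl, " in the network are {",
             paste(linked, collapse = ", "), "}", call. = FALSE)
      }
      pv <- priority_vector(P)
      a[names(pv$weights), cl] <- pv$weights
    }
  }
  a
}

#' Apply cluster weights to the unweighted supermatrix
#'
#' Scales each block W_rc of W0 (rows in cluster r, columns in cluster c) by
#' the cluster weight a_rc -- the blockwise (Hadamard-style) product of the
#' cluster weight matrix with the unweighted supermatrix -- then renormalizes
#' every column to sum 1, yielding the column-stochastic weighted
#' supermatrix.
#'
#' @param W0 unweighted supermatrix.
#' @param clusterA cluster weight matrix from [cluster_weight_matrix()].
#' @param cluster_of named cluster assignment of the factors.
#' @return Column-stochastic matrix with attribute `stage = "weighted"`.
#' @export
apply_cluster_weights <- function(W0, clusterA, cluster_of) {
  ids <- rownames(W0)
  scale <- clusterA[cbind(
    match(unname(cluster_of[ids]), rownames(clusterA))[row(W0)],
    match(unname(cluster_of[ids]), colnames(clusterA))[col(W0)]
  )]
  w <- W0 * matrix(scale, nrow(W0), ncol(W0))
  cs <- colSums(w)
  if (any(cs == 0)) {
    stop("zero column after cluster weighting (column(s) ",
         paste(ids[cs == 0], collapse = ", "),
         "); check the cluster weight matrix", call. = FALSE)
  }
  w <- sweep(w, 2L, cs, "/")
  dimnames(w) <- dimnames(W0)
  attr(w, "stage") <- "weighted"
  w
}

#' Limit supermatrix by repeated squaring
#'
#' Raises the column-stochastic weighted supermatrix to increasing powers by
#' repeated squaring until the fixed-point test |Z W - Z| < `tol` holds
#' (method `"power"`). If the power sequence does not settle within
#' `max_squarings` squarings (periodic or otherwise non-convergent chains),
#' the Cesaro average of a window of consecutive powers is returned and
#' flagged (method `"cesaro"`).
#'
#' @param W column-stochastic weighted supermatrix.
#' @param tol convergence tolerance (max-abs), default 1e-10.
#' @param max_squarings cap on squarings before falling back, default 200.
#' @param cesaro_window number of consecutive powers averaged in the
#'   fallback, default 32.
#' @return Matrix with attributes `stage = "limit"`, `method`
#'   (`"power"`/`"cesaro"`), and `squarings`.
#' @examples
#' w <- matrix(c(0, 1, 0, 1), 2, 2)  # absorbing 2-chain
#' limit_supermatrix(w)[2, 1]        # all of column 1's mass at the sink
#' @export
limit_supermatrix <- function(W, tol = 1e-10, max_squarings = 200,
                              cesaro_window = 32) {
  w <- as.matrix(W)
  if (any(w < 0) || max(abs(colSums(w) - 1)) > 1e-9) {
    stop("limit requires a column-stochastic (weighted) supermatrix",
         call. = FALSE)
  }
  z <- w
  method <- NULL
  for (k in seq_len(max_squarings)) {
    if (max(abs(z %*% w - z)) < tol) {
      method <- "power"
      break
    }
    z <- z %*% z
    z <- sweep(z, 2L, colSums(z), "/")  # guard numeric drift
  }
  if (is.null(method)) {
    acc <- matrix(0, nrow(w), ncol(w))
    for (j in seq_len(cesaro_window)) {
      acc <- acc + z
      z <- z %*% w
    }
    z <- acc / cesaro_window
    method <- "cesaro"
    k <- max_squarings
  }
  dimnames(z) <- dimnames(w)
  attr(z, "stage") <- "limit"
  attr(z, "method") <- method
  attr(z, "squarings") <- k
  z
}

#' Global factor weights from the limit supermatrix
#'
#' When the limit's columns agree (irreducible networks) any column is the
#' global weight vector; otherwise (reducible networks with several absorbing
#' components) the row-wise mean across columns is taken and renormalized.
#' Ranks are assigned by descending weight with ties sharing the smaller
#' rank, tie order by factor position.
#'
#' @param limit limit supermatrix from [limit_supermatrix()].
#' @param digits optional rounding applied to the reported weights (full
#'   precision kept when `NULL`).
#' @return data.frame with columns `factor`, `weight`, `rank`.
#' @export
global_weights <- function(limit, digits = NULL) {
  l <- as.matrix(limit)
  ids <- rownames(l)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(l)))
  spread <- max(apply(l, 1L, function(r) diff(range(r))))
  w <- if (spread < 1e-6) l[, 1L] else rowMeans(l)
  w <- w / sum(w)
  if (!is.null(digits)) w <- round(w, digits)
  rk <- rank(-w, ties.method = "min")
  data.frame(factor = ids, weight = unname(w), rank = as.integer(rk),
             stringsAsFactors = FALSE)
}

#' Full ANP pipeline: priorities, supermatrices, limit, global weights
#'
#' Runs consistency audits on every judgment matrix (refusing on any
#' CR >= 0.1 unless `allow_inconsistent = TRUE`), assembles the unweighted
#' supermatrix, applies cluster weights, computes the limit, and extracts
#' global weights. Deterministic given its inputs.
#'
#' @param network an [build_network()] result.
#' @param judgments named list of judgment matrices per multi-target
#'   criterion factor (see [assemble_unweighted()]).
#' @param cluster_judgments optional per-cluster judgment matrices (see
#'   [cluster_weight_matrix()]); uniform weights are used where absent.
#' @param allow_inconsistent logical; proceed despite failing consistency
#'   gates.
#' @param limit_tol,limit_max_squarings passed to [limit_supermatrix()].
#' @return Object of class `"anp_result"`: list with `weights` (data.frame),
#'   `consistency` (per-criterion reports), `W0`, `clusterA`, `W`, `limit`,
#'   and `limit_method`.
#' @export
anp_pipeline <- function(network, judgments, cluster_judgments = NULL,
                         allow_inconsistent = FALSE,
                         limit_tol = 1e-10, limit_max_squarings = 200) {
  audits <- lapply(judgments, consistency)
  cl_audits <- if (length(cluster_judgments)) {
    lapply(cluster_judgments, consistency)
  } else NULL
  failing <- c(
    names(audits)[!vapply(audits, `[[`, logical(1), "pass")],
    names(cl_audits)[!vapply(cl_audits, `[[`, logical(1), "pass")]
  )
  if (length(failing) && !allow_inconsistent) {
    stop("judgment matrix(es) fail the CR < 0.1 gate: ",
         paste(failing, collapse = ", "),
         " (set allow_inconsistent = TRUE to override)", call. = FALSE)
  }
  w0 <- assemble_unweighted(network, judgments)
  a <- cluster_weight_matrix(w0, network, cluster_judgments)
  w <- apply_cluster_weights(w0, a, network$cluster_of)
  lim <- limit_supermatrix(w, tol = limit_tol,
                           max_squarings = limit_max_squarings)
  structure(
    list(
      weights = global_weights(lim),
      consistency = c(audits, cl_audits),
      W0 = w0, clusterA = a, W = w, limit = lim,
      limit_method = attr(lim, "method")
    ),
    class = "anp_result"
  )
}

#' @export
print.anp_result <- function(x, ...) {
  cat("ANP global weights (limit method:", x$limit_method, ")\n")
  ord <- order(x$weights$rank, x$weights$factor)
  print(transform(x$weights[ord, ], weight = round(weight, 4)),
        row.names = FALSE)
  invisible(x)
}
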