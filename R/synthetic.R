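#' Generate Likert responses with a planted common-factor structure
#'
#' Draws standard-normal latent factors, forms item scores as
#' loadings-weighted factor sums plus normal noise, z-scales each item,
#' maps to mean 3 / SD 1, rounds half-up and clips to the 1--5 Likert range.
#' Pure function of its arguments: the seed fixes the whole output and the
#' global RNG stream is left untouched.
#'
#' @param n_respondents number of respondents (rows).
#' @param loadings item x factor loading matrix (entries in \[-1, 1\]).
#' @param noise_sd per-item noise standard deviation (scalar or vector).
#' @param seed integer RNG seed.
#' @param likert_bounds score range, default `c(1, 5)`.
#' @return Integer matrix, respondents x items; item ids from
#'   `rownames(loadings)` or `item1..itemP`.
#' @examples
#' l <- matrix(0.7 * diag(3)[rep(1:3, each = 3), ], ncol = 3)
#' x <- generate_responses(100, l, noise_sd = 0.5, seed = 1)
#' dim(x)
#' @export
generate_responses <- function(n_respondents, loadings, noise_sd = 0.5,
                               seed = 1, likert_bounds = c(1L, 5L)) {
  loadings <- as.matrix(loadings)
  if (max(abs(loadings)) > 1) {
    stop("loadings must lie in [-1, 1]", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  p <- nrow(loadings)
  k <- ncol(loadings)
  noise_sd <- rep_len(noise_sd, p)
  dead <- rowSums(abs(loadings)) == 0 & noise_sd == 0
  if (any(dead)) {
    stop("item(s) with zero loadings and zero noise would be constant: ",
         paste(which(dead), collapse = ", "), call. = FALSE)
  }
  x <- withr::with_seed(as.integer(seed), {
    f <- matrix(stats::rnorm(n_respondents * k), n_respondents, k)
    e <- matrix(stats::rnorm(n_respondents * p), n_respondents, p)
    f %*% t(loadings) + sweep(e, 2L, noise_sd, "*")
  })
  x <- scale(x)                       # z-scale each item
  x <- x + 3                          # Likert midpoint, SD 1
  x <- floor(x + 0.5)                 # round half-up
  x <- pmin(pmax(x, likert_bounds[1L]), likert_bounds[2L])
  ids <- rownames(loadings)
  if (is.null(ids)) ids <- paste0("item", seq_len(p))
  x <- matrix(as.integer(x), n_respondents, p, dimnames = list(NULL, ids))
  x
}

#' Generate a reciprocal judgment matrix from a ground-truth weight vector
#'
#' Constructs p_ij = (w_i / w_j) * exp(e_ij) with antisymmetric normal noise
#' (e_ji = -e_ij), so reciprocity holds exactly for every noise level. With
#' `delta = 0` the matrix is perfectly consistent: its priority vector equals
#' `w` and CR = 0. Optional rounding snaps each upper-triangle entry to the
#' nearest Saaty scale value in {1..9} or its reciprocal (nearest in log
#' space), keeping reciprocity exact.
#'
#' @param w positive weight vector (normalized internally).
#' @param delta standard deviation of the log-scale perturbation, >= 0.
#' @param seed integer RNG seed.
#' @param saaty_rounding logical; snap entries to the 1--9 scale.
#' @param elements optional labels for the compared elements (dimnames);
#'   defaults to `names(w)`.
#' @return m x m reciprocal judgment matrix.
#' @examples
#' generate_judgment(c(2/3, 1/3), saaty_rounding = TRUE)  # [[1,2],[1/2,1]]
#' @export
generate_judgment <- function(w, delta = 0, seed = 1, saaty_rounding = FALSE,
                              elements = names(w)) {
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  m <- length(w)
  w <- w / sum(w)
  P <- outer(w, w, "/")
  if (delta > 0) {
    eps <- matrix(0, m, m)
    up <- upper.tri(eps)
    eps[up] <- withr::with_seed(as.integer(seed),
                                stats::rnorm(sum(up), 0, delta))
    eps <- eps - t(eps)
    P <- P * exp(eps)
  }
  if (saaty_rounding) {
    scale_vals <- c(1 / (9:2), 1:9)  # symmetric: k and 18-k are reciprocals
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        idx <- which.min(abs(log(scale_vals) - log(P[i, j])))
        P[i, j] <- scale_vals[idx]
        P[j, i] <- scale_vals[18L - idx]
      }
    }
  }
  diag(P) <- 1
  if (!is.null(elements)) dimnames(P) <- list(elements, elements)
  P
}

#' Generate a random directed acyclic adjacency matrix
#'
#' Draws a uniform random permutation as a topological order and includes
#' each forward pair as an edge independently with probability
#' `edge_density`; the result is acyclic by construction and a deterministic
#' function of the seed.
#'
#' @param n number of factors.
#' @param edge_density probability in \[0, 1\] of each admissible edge.
#' @param seed integer RNG seed.
#' @return n x n binary adjacency matrix with ids F1..Fn.
#' @examples
#' a <- generate_random_dag(5, 0.4, seed = 7)
#' sum(a * t(a))  # 0: no mutual pairs
#' @export
generate_random_dag <- function(n, edge_density, seed = 1) {
  if (edge_density < 0 || edge_density > 1) {
    stop("edge_density must lie in [0, 1]", call. = FALSE)
  }
  ids <- paste0("F", seq_len(n))
  a <- matrix(0L, n, n, dimnames = list(ids, ids))
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (ord[i] < ord[j] && stats::runif(1) < edge_density) {
          a[i, j] <- 1L
        }
      }
    }
  })
  a
}

#' Seeded consistent judgment matrices for every multi-target criterion
#'
#' For each factor of the network that influences two or more targets, draws
#' a positive weight vector (log-normal, fixed seed) over its targets and
#' builds the perfectly consistent judgment matrix of its ratios. Stands in
#' for unpublished expert comparisons when only structural conclusions (for
#' example which factors receive zero global weight) are of interest.
#'
#' @param network an [build_network()] result.
#' @param seed integer RNG seed.
#' @param delta optional log-scale inconsistency (default 0: consistent).
#' @return Named list of judgment matrices keyed by criterion factor.
#' @export
seeded_judgments <- function(network, seed = 1, delta = 0) {
  multi <- network$factors[lengths(network$targets) >= 2L]
  out <- vector("list", length(multi))
  names(out) <- multi
  for (idx in seq_along(multi)) {
    j <- multi[idx]
    tg <- network$targets[[j]]
    sub_seed <- (as.integer(seed) * 1009L + idx * 101L) %% .Machine$integer.max
    w <- withr::with_seed(sub_seed, exp(stats::rnorm(length(tg), 0, 0.5)))
    names(w) <- tg
    out[[idx]] <- generate_judgment(w, delta = delta, seed = sub_seed + 1L)
  }
  out
}

#' Uniform (all-ones) judgment matrices for every multi-target criterion
#'
#' The indifference fallback: every pairwise comparison equals 1, so each
#' criterion's targets share its influence equally.
#'
#' @param network an [build_network()] result.
#' @return Named list of judgment matrices keyed by criterion factor.
#' @export
uniform_judgments <- function(network) {
  multi <- network$factors[lengths(network$targets) >= 2L]
  out <- lapply(multi, function(j) {
    tg <- network$targets[[j]]
    matrix(1, length(tg), length(tg), dimnames = list(tg, tg))
  })
  names(out) <- multi
  out
}
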