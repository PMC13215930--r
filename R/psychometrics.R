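#' Pearson correlation matrix of questionnaire items
#'
#' Computes the item correlation matrix of a respondents-by-items Likert
#' response matrix, with an exact unit diagonal and an explicit error for
#' zero-variance items (for which a Pearson correlation is undefined).
#'
#' @param responses numeric matrix, respondents in rows, items in columns.
#'   Column names, if present, are carried through as item ids.
#' @return Symmetric correlation matrix with unit diagonal.
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))
#' item_correlations(x)
#' @export
item_correlations <- function(responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2L) {
    stop("need at least 2 respondents to correlate items", call. = FALSE)
  }
  if (ncol(responses) < 2L) {
    stop("need at least 2 items", call. = FALSE)
  }
  if (anyNA(responses)) {
    stop("missing responses present; remove or impute before correlating",
         call. = FALSE)
  }
  v <- apply(responses, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(responses)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(responses)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{s_i^2} are the sample variances (denominator \eqn{n-1}) of the
#' \eqn{k} items and \eqn{s_T^2} the sample variance of the total score.
#'
#' @param responses numeric matrix, respondents x items.
#' @param items optional character or integer vector selecting an item
#'   subset (e.g. one Haddon dimension); defaults to all items.
#' @return The alpha coefficient (scalar).
#' @examples
#' x <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(responses, items = NULL) {
  responses <- as.matrix(responses)
  if (!is.null(items)) responses <- responses[, items, drop = FALSE]
  k <- ncol(responses)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  if (nrow(responses) < 2L) stop("need at least 2 respondents", call. = FALSE)
  total_var <- stats::var(rowSums(responses))
  if (total_var == 0) {
    stop("total-score variance is 0; alpha is undefined", call. = FALSE)
  }
  item_var <- sum(apply(responses, 2L, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO compares squared correlations with squared anti-image partial
#' correlations: \eqn{\mathrm{KMO} = \sum r^2 / (\sum r^2 + \sum q^2)} over
#' off-diagonal pairs, where the partials \eqn{q_{ij} = -c_{ij} /
#' \sqrt{c_{ii} c_{jj}}} come from the inverse correlation matrix
#' \eqn{C = R^{-1}}. Per-item measures use the same ratio restricted to one
#' row. On an identity correlation matrix (no common variance at all) the
#' ratio is 0/0; by convention 0 is returned with a warning.
#'
#' @param corr correlation matrix (e.g. from [item_correlations()]).
#' @param ridge nonnegative ridge added to the diagonal before inversion for
#'   near-singular matrices; default 0 (off).
#' @return List with `overall` (scalar in \[0, 1\]) and `msa` (per-item
#'   measures).
#' @examples
#' r <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3)
#' kmo(r)$overall
#' @export
kmo <- function(corr, ridge = 0) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  off <- upper.tri(corr) | lower.tri(corr)
  if (all(abs(corr[off]) < 1e-12)) {
    warning("identity correlation matrix: no sampling adequacy, KMO set to 0")
    return(list(overall = 0, msa = stats::setNames(rep(0, p), colnames(corr))))
  }
  cinv <- tryCatch(
    solve(corr + diag(ridge, p)),
    error = function(e) {
      stop("correlation matrix is singular; retry with a small `ridge` ",
           "(e.g. 1e-8)", call. = FALSE)
    }
  )
  s <- 1 / sqrt(diag(cinv))
  q <- -cinv * outer(s, s)      # anti-image partial correlations
  diag(q) <- 0
  r2 <- corr^2; diag(r2) <- 0
  q2 <- q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa) <- colnames(corr)
  list(overall = overall, msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' \eqn{\chi^2 = -\left(n - 1 - \frac{2p + 5}{6}\right) \ln|R|} on
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param corr correlation matrix over `p` items.
#' @param n number of respondents behind `corr`; must exceed `p`.
#' @return List with `statistic`, `df`, and `p.value`.
#' @examples
#' r <- matrix(c(1, .3, .3, 1), 2, 2)
#' bartlett_sphericity(r, n = 50)
#' @export
bartlett_sphericity <- function(corr, n) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n <= p) {
    stop("Bartlett's test needs more respondents (n = ", n,
         ") than items (p = ", p, ")", call. = FALSE)
  }
  d <- det(corr)
  if (d <= 0) {
    stop("non-positive determinant: correlation matrix is singular or invalid",
         call. = FALSE)
  }
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Exploratory factor analysis by principal-component extraction
#'
#' Eigendecomposes a correlation matrix, retains components by the chosen
#' rule, scales eigenvectors to loadings (\eqn{\sqrt{\lambda_j} v_j}), and
#' varimax-rotates the retained loadings. The variance-contribution column is
#' \eqn{100 \lambda_j / p} (percent of the item block's total variance) and
#' the cumulative column its prefix sum, matching the layout of published
#' initial-eigenvalue tables.
#'
#' @param corr correlation matrix of the item block (one Haddon dimension or
#'   the whole questionnaire).
#' @param retention retention rule: `"eigenvalue"` keeps components with
#'   eigenvalue strictly greater than `threshold` (default 1, the Kaiser
#'   criterion); `"cumulative"` keeps the smallest k whose cumulative
#'   contribution reaches `cum_target` percent; `"fixed"` keeps exactly `k`.
#' @param threshold eigenvalue cutoff for `retention = "eigenvalue"`.
#' @param cum_target cumulative-percent target for `retention = "cumulative"`.
#' @param k number of factors for `retention = "fixed"`.
#' @param rotate logical; varimax-rotate the retained loadings (default TRUE;
#'   a single factor is returned unrotated either way).
#' @return Object of class `"efa"`: list with `eigenvalues` (all p,
#'   descending), `loadings` (items x retained factors, rotated),
#'   `contribution` and `cumulative` (percent, for all p components),
#'   `retained_k`, and `retention`.
#' @examples
#' r <- diag(6)
#' r[1:3, 1:3] <- 0.8; r[4:6, 4:6] <- 0.8; diag(r) <- 1
#' ef <- efa(r)
#' ef$retained_k
#' @export
efa <- function(corr, retention = c("eigenvalue", "cumulative", "fixed"),
                threshold = 1, cum_target = 85, k = NULL, rotate = TRUE) {
  retention <- match.arg(retention)
  corr <- as.matrix(corr)
  p <- ncol(corr)
  e <- eigen(corr, symmetric = TRUE)
  ev <- e$values
  contribution <- 100 * ev / p
  cumulative <- cumsum(contribution)
  retained_k <- switch(retention,
    eigenvalue = sum(ev > threshold),
    cumulative = {
      m <- which(cumulative >= cum_target)
      if (length(m) == 0L) 0L else m[1L]
    },
    fixed = {
      if (is.null(k)) stop("retention = \"fixed\" requires `k`", call. = FALSE)
      as.integer(k)
    }
  )
  if (retained_k < 1L) {
    stop("retention rule \"", retention, "\" retains 0 factors", call. = FALSE)
  }
  load <- e$vectors[, seq_len(retained_k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(retained_k)]), retained_k)
  if (rotate && retained_k >= 2L) load <- varimax_rotate(load)
  # sign convention: dominant loading of each factor positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(corr)
  colnames(load) <- paste0("factor", seq_len(retained_k))
  structure(
    list(eigenvalues = ev, loadings = load, contribution = contribution,
         cumulative = cumulative, retained_k = retained_k,
         retention = retention),
    class = "efa"
  )
}

#' @export
print.efa <- function(x, ...) {
  cat("Exploratory factor analysis (principal components, varimax)\n")
  cat("  items:", length(x$eigenvalues), " retained factors:", x$retained_k,
      " rule:", x$retention, "\n")
  cat("  cumulative contribution at k:",
      sprintf("%.3f%%", x$cumulative[x$retained_k]), "\n")
  invisible(x)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (variance of squared
#' loadings per factor), via [stats::varimax()] without Kaiser row
#' normalization so the rotation acts on the raw loadings. A single-factor
#' matrix is returned unchanged. Row communalities are preserved exactly by
#' orthogonality.
#'
#' @param loadings numeric matrix, items x factors.
#' @return Rotated loading matrix of the same shape.
#' @examples
#' l <- cbind(c(.8, .8, 0, 0), c(0, 0, .8, .8))
#' varimax_rotate(l)
#' @export
varimax_rotate <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 1L) stop("need at least one factor", call. = FALSE)
  if (ncol(loadings) == 1L) return(loadings)
  r <- stats::varimax(loadings, normalize = FALSE, eps = 1e-10)
  out <- loadings %*% r$rotmat
  dimnames(out) <- dimnames(loadings)
  out
}

#' Varimax simplicity criterion of a loading matrix
#'
#' The objective maximized by [varimax_rotate()]: the summed per-factor
#' variance of squared loadings,
#' \eqn{\sum_j \left[ \frac{1}{p}\sum_i \lambda_{ij}^4 -
#' \left(\frac{1}{p}\sum_i \lambda_{ij}^2\right)^2 \right]}.
#'
#' @param loadings numeric matrix, items x factors.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  l2 <- loadings^2
  sum(colSums(l2^2) / p - (colSums(l2) / p)^2)
}

#' Reliability and validity report for a Likert questionnaire
#'
#' Convenience wrapper computing, in one pass, overall Cronbach's alpha,
#' per-dimension alphas, the overall KMO statistic, and Bartlett's test of
#' sphericity for a respondents-by-items matrix.
#'
#' @param responses numeric matrix, respondents x items.
#' @param dimension_of_item optional named character vector mapping item ids
#'   (column names) to dimension labels; when given, per-dimension alphas and
#'   KMOs are included.
#' @return List with `alpha_overall`, `kmo_overall`, `bartlett` (statistic,
#'   df, p.value), `n_respondents`, `n_items`, and, when dimensions are
#'   supplied, `alpha_by_dimension` and `kmo_by_dimension`.
#' @export
reliability_report <- function(responses, dimension_of_item = NULL) {
  responses <- as.matrix(responses)
  r <- item_correlations(responses)
  out <- list(
    n_respondents = nrow(responses),
    n_items = ncol(responses),
    alpha_overall = cronbach_alpha(responses),
    kmo_overall = kmo(r)$overall,
    bartlett = bartlett_sphericity(r, nrow(responses))
  )
  if (!is.null(dimension_of_item)) {
    dims <- unique(dimension_of_item)
    items_of <- lapply(dims, function(d) names(dimension_of_item)[dimension_of_item == d])
    names(items_of) <- dims
    out$alpha_by_dimension <- vapply(
      items_of, function(it) cronbach_alpha(responses, it), numeric(1)
    )
    out$kmo_by_dimension <- vapply(
      items_of,
      function(it) kmo(item_correlations(responses[, it, drop = FALSE]))$overall,
      numeric(1)
    )
  }
  out
}
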