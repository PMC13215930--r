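#' Build an ISM adjacency matrix from V/A/X/O relation codes
#'
#' Expert pairwise influence judgments use four codes for an ordered pair
#' (Fi, Fj): `V` -- Fi influences Fj (a_ij = 1, a_ji = 0); `A` -- Fj
#' influences Fi (a_ij = 0, a_ji = 1); `X` -- mutual influence (both 1);
#' `O` -- no direct influence (both 0). Pairs not listed default to `O`;
#' the diagonal is always 0.
#'
#' @param relations data.frame with columns `source`, `target`, `code`
#'   (values in V/A/X/O). Factor ids must appear in `factor_ids`.
#' @param factor_ids character vector of all factor labels, fixing matrix
#'   order.
#' @return Binary adjacency matrix with `factor_ids` as dimnames.
#' @examples
#' rel <- data.frame(source = "F1", target = "F2", code = "V")
#' build_adjacency(rel, c("F1", "F2"))
#' @export
build_adjacency <- function(relations, factor_ids) {
  n <- length(factor_ids)
  a <- matrix(0L, n, n, dimnames = list(factor_ids, factor_ids))
  if (is.null(relations) || nrow(relations) == 0L) return(a)
  need <- c("source", "target", "code")
  if (!all(need %in% names(relations))) {
    stop("relations need columns source, target, code", call. = FALSE)
  }
  unknown <- setdiff(unique(c(relations$source, relations$target)), factor_ids)
  if (length(unknown)) {
    stop("unknown factor id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(relations$code), c("V", "A", "X", "O"))
  if (length(bad)) {
    stop("invalid relation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(relations$source == relations$target)) {
    stop("self-relations are not allowed (diagonal is fixed at 0)",
         call. = FALSE)
  }
  # canonical (unordered) pair key; flip A/V so the code is orientation-free
  key <- ifelse(relations$source < relations$target,
                paste(relations$source, relations$target),
                paste(relations$target, relations$source))
  canon <- ifelse(relations$source < relations$target, relations$code,
                  chartr("VA", "AV", relations$code))
  conflicts <- tapply(canon, key, function(z) length(unique(z)) > 1L)
  if (any(conflicts)) {
    stop("conflicting duplicate relation(s) for pair(s): ",
         paste(names(conflicts)[conflicts], collapse = "; "), call. = FALSE)
  }
  keep <- !duplicated(key)
  for (r in which(keep)) {
    i <- relations$source[r]; j <- relations$target[r]
    switch(relations$code[r],
      V = { a[i, j] <- 1L },
      A = { a[j, i] <- 1L },
      X = { a[i, j] <- 1L; a[j, i] <- 1L },
      O = NULL
    )
  }
  a
}

#' Reflexive transitive closure (reachability matrix) of an adjacency matrix
#'
#' Computes the ISM reachability matrix M as the Boolean fixed point of
#' \eqn{(A + I)^k}, by repeated Boolean squaring until
#' \eqn{(A+I)^k = (A+I)^{k+1}}. M has a unit diagonal (every factor reaches
#' itself) and M\[i, j\] = 1 iff some directed path leads from i to j.
#'
#' @param adjacency binary square matrix (0/1), zero diagonal.
#' @return Binary reachability matrix with attribute `closed = TRUE`.
#' @examples
#' a <- build_adjacency(
#'   data.frame(source = c("F1", "F2"), target = c("F2", "F3"), code = "V"),
#'   c("F1", "F2", "F3"))
#' transitive_closure(a)["F1", "F3"]  # 1: path F1 -> F2 -> F3
#' @export
transitive_closure <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  b <- (a != 0) * 1L
  diag(b) <- 1L
  repeat {
    b2 <- (b %*% b > 0) * 1L
    if (identical(b2, b)) break
    b <- b2
  }
  dimnames(b) <- dimnames(a)
  attr(b, "closed") <- TRUE
  b
}

#' Reconstruct a reachability matrix from per-factor reachable sets
#'
#' Builds M with M\[i, j\] = 1 iff factor j is listed in R(Fi). This is the
#' entry point for published reachable-set tables whose underlying adjacency
#' matrix is unavailable. The matrix is *not* assumed transitively closed:
#' the `closed` attribute is set by an explicit [check_closure()] scan.
#'
#' @param reachable_sets named list; element i holds the integer indices (or
#'   labels matching `names(reachable_sets)`) of the factors reachable from
#'   factor i, including i itself.
#' @return Binary reachability matrix with attribute `closed` (TRUE/FALSE).
#' @examples
#' m <- reachability_from_sets(drowning_fixtures()$reachable_sets)
#' attr(m, "closed")  # FALSE: the printed sets are not perfectly closed
#' @export
reachability_from_sets <- function(reachable_sets) {
  ids <- names(reachable_sets)
  n <- length(reachable_sets)
  if (is.null(ids)) ids <- paste0("F", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ri <- reachable_sets[[i]]
    if (is.character(ri)) ri <- match(ri, ids)
    ri <- as.integer(ri)
    if (any(is.na(ri)) || any(ri < 1L) || any(ri > n)) {
      stop("reachable set of ", ids[i], " contains unknown factors",
           call. = FALSE)
    }
    if (!(i %in% ri)) {
      stop("factor ", ids[i], " missing from its own reachable set",
           call. = FALSE)
    }
    m[i, ri] <- 1L
  }
  attr(m, "closed") <- nrow(check_closure(m)) == 0L
  m
}

#' Reachable, antecedent and intersection sets of a reachability matrix
#'
#' Row reads of M give the reachable set R(Fi), column reads the antecedent
#' set Q(Fi), and their elementwise intersection the R(Fi) ∩ Q(Fi) column of
#' the standard ISM worksheet.
#'
#' @param M binary reachability matrix.
#' @return List with named lists `reachable`, `antecedent`, `intersection`
#'   (integer indices, ascending).
#' @examples
#' m <- reachability_from_sets(drowning_fixtures()$reachable_sets)
#' factor_sets(m)$antecedent[["F18"]]  # 15 16 17 18
#' @export
factor_sets <- function(M) {
  m <- as.matrix(M)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(m)))
  reach <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1L))
  ante <- lapply(seq_len(nrow(m)), function(i) which(m[, i] == 1L))
  inter <- Map(intersect, reach, ante)
  reach <- lapply(reach, function(z) as.integer(unname(z)))
  ante <- lapply(ante, function(z) as.integer(unname(z)))
  inter <- lapply(inter, function(z) as.integer(unname(z)))
  names(reach) <- names(ante) <- names(inter) <- ids
  list(reachable = reach, antecedent = ante, intersection = inter)
}

#' ISM level partition of a reachability matrix
#'
#' Iteratively extracts every factor satisfying R(Fi) ∩ Q(Fi) = R(Fi) as the
#' current level, removes those factors, recomputes the sets on the remaining
#' submatrix, and repeats until no factor is left. Level 1 (extracted first)
#' holds the surface factors -- the sinks of the influence relation, i.e. the
#' direct consequences; the last level holds the root causes.
#'
#' A non-closed matrix is partitioned as given, with a warning (published
#' reachable-set tables are sometimes not perfectly closed yet still
#' partition cleanly); `reclose = TRUE` re-closes first. If an iteration
#' extracts no factor the stuck factor set is reported.
#'
#' @param M binary reachability matrix.
#' @param reclose logical; apply [transitive_closure()] before partitioning.
#' @return Object of class `"ism_partition"`: list with `levels` (list of
#'   character vectors of factor ids, level 1 first) and `level_of` (named
#'   integer vector).
#' @examples
#' m <- reachability_from_sets(drowning_fixtures()$reachable_sets)
#' partition_levels(m)$levels[[1]]  # "F4" "F5" "F18"
#' @export
partition_levels <- function(M, reclose = FALSE) {
  m <- as.matrix(M)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  if (reclose) {
    m <- transitive_closure(m)
  } else if (nrow(check_closure(m)) > 0L) {
    warning("reachability matrix is not transitively closed; ",
            "partitioning as given (use reclose = TRUE to close first)")
  }
  remaining <- seq_len(nrow(m))
  levels <- list()
  while (length(remaining)) {
    sub <- m[remaining, remaining, drop = FALSE]
    is_level <- vapply(seq_along(remaining), function(k) {
      r <- which(sub[k, ] == 1L)
      q <- which(sub[, k] == 1L)
      all(r %in% q)
    }, logical(1))
    if (!any(is_level)) {
      stop("level extraction stuck: no factor satisfies R ∩ Q = R among ",
           paste(ids[remaining], collapse = ", "), call. = FALSE)
    }
    levels <- c(levels, list(ids[remaining[is_level]]))
    remaining <- remaining[!is_level]
  }
  level_of <- stats::setNames(
    rep(seq_along(levels), lengths(levels))[order(match(unlist(levels), ids))],
    ids
  )
  structure(list(levels = levels, level_of = level_of),
            class = "ism_partition")
}

#' @export
print.ism_partition <- function(x, ...) {
  cat("ISM level partition (level 1 = surface):\n")
  for (l in seq_along(x$levels)) {
    cat("  L", l, ": ", paste(x$levels[[l]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Transitivity violations of a reachability matrix
#'
#' Lists every triple (i, j, k) with M\[i,j\] = M\[j,k\] = 1 but
#' M\[i,k\] = 0. An empty result means M is transitively closed.
#'
#' @param M binary reachability matrix.
#' @return data.frame with columns `i`, `j`, `k` (factor labels).
#' @examples
#' nrow(check_closure(transitive_closure(diag(3))))  # 0
#' @export
check_closure <- function(M) {
  m <- as.matrix(M)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(m)))
  out <- list()
  for (j in seq_len(nrow(m))) {
    bad <- which(outer(m[, j] == 1L, m[j, ] == 1L) & m == 0L, arr.ind = TRUE)
    if (nrow(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        i = ids[bad[, 1L]], j = ids[j], k = ids[bad[, 2L]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(i = character(), j = character(), k = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Transitive reduction of a strict reachability relation
#'
#' Keeps the minimal edge set generating the same reachability: an edge
#' (i, j) is dropped when some intermediate k gives both i -> k and k -> j.
#' Defined for acyclic relations (the matrix may be reflexive; the diagonal
#' is ignored). Mutual pairs make the reduction non-unique and raise an
#' error.
#'
#' @param M binary reachability matrix (closed or not; it is closed
#'   internally before the redundancy test).
#' @return Binary matrix of the reduced strict edge set.
#' @export
transitive_reduction <- function(M) {
  m <- as.matrix(M)
  s <- transitive_closure(m)
  diag(s) <- 0L
  attr(s, "closed") <- NULL
  if (any(s == 1L & t(s) == 1L)) {
    stop("relation contains mutual reachability (a cycle); ",
         "transitive reduction is not unique", call. = FALSE)
  }
  red <- s
  n <- nrow(s)
  for (i in seq_len(n)) {
    for (j in which(s[i, ] == 1L)) {
      through <- which(s[i, ] == 1L & s[, j] == 1L)
      if (length(setdiff(through, c(i, j)))) red[i, j] <- 0L
    }
  }
  dimnames(red) <- dimnames(m)
  red
}

#' Multi-level hierarchy digraph of an ISM model
#'
#' Groups factors by partition level and keeps the transitive reduction of
#' the strict reachability relation as the edge set, so risk transmits
#' stepwise along the drawn arrows. Node and edge order are deterministic
#' (ascending factor index).
#'
#' @param M binary reachability matrix.
#' @param partition result of [partition_levels()] on `M` (computed if
#'   omitted).
#' @return Object of class `"ism_digraph"`: list with `nodes` (data.frame
#'   `factor`, `level`) and `edges` (data.frame `from`, `to`).
#' @seealso [write_dot()] for Graphviz export.
#' @export
hierarchy_digraph <- function(M, partition = NULL) {
  m <- as.matrix(M)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  if (is.null(partition)) {
    partition <- suppressWarnings(partition_levels(m))
  }
  red <- transitive_reduction(m)
  e <- which(red == 1L, arr.ind = TRUE)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  edges <- data.frame(from = ids[e[, 1L]], to = ids[e[, 2L]],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(factor = ids,
                      level = unname(partition$level_of[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ism_digraph")
}

#' @export
print.ism_digraph <- function(x, ...) {
  cat("ISM hierarchy digraph:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges,", max(x$nodes$level), "levels\n")
  invisible(x)
}
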