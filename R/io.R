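#' Read a V/A/X/O relation list from CSV
#'
#' Expects columns `source`, `target`, `code` (UTF-8, comma-separated).
#' Malformed codes are reported with their line number (header = line 1).
#'
#' @param file path to the CSV file.
#' @return data.frame with columns `source`, `target`, `code`.
#' @export
read_relations <- function(file) {
  rel <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("source", "target", "code")
  if (!all(need %in% names(rel))) {
    stop("relations file must have columns source, target, code: ", file,
         call. = FALSE)
  }
  bad <- which(!rel$code %in% c("V", "A", "X", "O"))
  if (length(bad)) {
    stop("invalid relation code \"", rel$code[bad[1L]], "\" at line ",
         bad[1L] + 1L, " of ", file, call. = FALSE)
  }
  rel[need]
}

#' Write a V/A/X/O relation list to CSV
#' @param relations data.frame with columns `source`, `target`, `code`.
#' @param file output path.
#' @export
write_relations <- function(relations, file) {
  utils::write.csv(relations[c("source", "target", "code")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write a binary factor matrix as CSV
#'
#' CSV layout: header row and first column carry the factor ids; cells are
#' 0/1.
#'
#' @param file path.
#' @return `read_matrix_csv`: integer matrix with factor-id dimnames.
#' @export
read_matrix_csv <- function(file) {
  d <- utils::read.csv(file, row.names = 1L, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_matrix_csv
#' @param m matrix to write (dimnames become the id row/column).
#' @export
write_matrix_csv <- function(m, file) {
  utils::write.csv(as.data.frame(as.matrix(m)), file, quote = FALSE)
  invisible(file)
}

#' Read / write factor sets (reachable/antecedent) as JSON
#'
#' Sets are stored as sorted ascending integer lists, never abbreviated to
#' ranges.
#'
#' @param file path.
#' @return `read_sets_json`: named list of integer vectors.
#' @export
read_sets_json <- function(file) {
  sets <- jsonlite::read_json(file, simplifyVector = TRUE)
  lapply(sets, function(z) sort(as.integer(z)))
}

#' @rdname read_sets_json
#' @param sets named list of integer vectors.
#' @export
write_sets_json <- function(sets, file) {
  jsonlite::write_json(lapply(sets, function(z) sort(as.integer(z))), file,
                       pretty = TRUE)
  invisible(file)
}

#' Read / write judgment matrices as JSON
#'
#' Each record holds `criterion` (the factor or cluster the comparison is
#' made with respect to), `elements` (compared ids, fixing row/column
#' order), and `matrix` (row-major list of rows). Matrices are validated for
#' reciprocity on read.
#'
#' @param file path.
#' @return `read_judgments_json`: named list of judgment matrices keyed by
#'   criterion.
#' @export
read_judgments_json <- function(file) {
  recs <- jsonlite::read_json(file, simplifyVector = FALSE)
  out <- list()
  for (r in recs) {
    elements <- unlist(r$elements)
    P <- do.call(rbind, lapply(r$matrix, function(row) unlist(row)))
    dimnames(P) <- list(elements, elements)
    out[[r$criterion[[1L]]]] <- .check_reciprocal(P)
  }
  out
}

#' @rdname read_judgments_json
#' @param judgments named list of judgment matrices keyed by criterion.
#' @export
write_judgments_json <- function(judgments, file) {
  recs <- lapply(names(judgments), function(cr) {
    P <- judgments[[cr]]
    list(criterion = cr, elements = rownames(P),
         matrix = lapply(seq_len(nrow(P)), function(i) unname(P[i, ])))
  })
  jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Export an ISM hierarchy digraph to Graphviz DOT
#'
#' Nodes are grouped into `rank = same` blocks by partition level (surface
#' level at the top via `rankdir = BT`), and edges follow the transitive
#' reduction. Output is deterministic: nodes and edges in ascending factor
#' order.
#'
#' @param digraph an [hierarchy_digraph()] result.
#' @param file optional output path; when `NULL` the DOT text is returned.
#' @param name graph name.
#' @return The DOT source, invisibly when written to `file`.
#' @export
write_dot <- function(digraph, file = NULL, name = "ism") {
  nodes <- digraph$nodes
  lines <- c(
    paste0("digraph ", name, " {"),
    "  rankdir=BT;",
    "  node [shape=box];"
  )
  for (l in sort(unique(nodes$level))) {
    ids <- nodes$factor[nodes$level == l]
    lines <- c(lines, paste0("  { rank=same; ",
                             paste0("\"", ids, "\"; ", collapse = ""), "}"))
  }
  if (nrow(digraph$edges)) {
    lines <- c(lines, paste0("  \"", digraph$edges$from, "\" -> \"",
                             digraph$edges$to, "\";"))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Write the Table-style variance breakdown of per-dimension factor analyses
#'
#' Mirrors the usual initial-eigenvalue table layout: one row per retained
#' component with its eigenvalue, variance contribution (percent of the
#' block) and cumulative contribution.
#'
#' @param efa_by_dimension named list of [efa()] results, one per dimension.
#' @param file output CSV path.
#' @return The assembled data.frame, invisibly.
#' @export
write_variance_table <- function(efa_by_dimension, file) {
  rows <- lapply(names(efa_by_dimension), function(d) {
    ef <- efa_by_dimension[[d]]
    k <- ef$retained_k
    data.frame(
      dimension = d,
      component = seq_len(k),
      eigenvalue = round(ef$eigenvalues[seq_len(k)], 3),
      contribution = round(ef$contribution[seq_len(k)], 3),
      cumulative = round(ef$cumulative[seq_len(k)], 3),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
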