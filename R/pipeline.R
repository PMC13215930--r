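#' End-to-end ISM-ANP pipeline over a risk-factor system
#'
#' Chains the package's stages on in-memory inputs and (optionally) writes
#' every artifact to an output directory: questionnaire reliability report,
#' per-dimension variance table, reachability matrix, factor-set worksheet,
#' level partition, hierarchy DOT digraph, the three supermatrix stages, the
#' global weight table, and a JSON manifest recording seeds and settings.
#' Rerunning with identical inputs reproduces every artifact byte-for-byte
#' (no timestamps outside the manifest, which carries none by default).
#'
#' Exactly one of `relations` (direct V/A/X/O codes, closed internally) or
#' `reachable_sets` (a published reachability table) must describe the
#' influence structure.
#'
#' @param cluster_of named character vector, factor id -> cluster label.
#' @param relations optional data.frame `source`, `target`, `code`.
#' @param reachable_sets optional named list of reachable sets (see
#'   [reachability_from_sets()]).
#' @param responses optional respondents x items Likert matrix; when given,
#'   a reliability report is included.
#' @param dimension_of_item optional item -> dimension map for per-dimension
#'   reliability.
#' @param judgments `"seeded"` (consistent matrices from `seed`),
#'   `"uniform"` (all comparisons 1), or a named list of judgment matrices.
#' @param cluster_judgments optional per-cluster judgment matrices; uniform
#'   fallback where absent.
#' @param seed integer seed for `judgments = "seeded"`.
#' @param reclose logical; transitively close the reachability input before
#'   partitioning.
#' @param out_dir optional directory; created if needed, artifacts written
#'   there.
#' @param allow_inconsistent passed to [anp_pipeline()].
#' @return List with `reachability`, `factor_sets`, `partition`, `digraph`,
#'   `anp` (an `anp_result`), optional `reliability`, and `manifest`.
#' @examples
#' fx <- drowning_fixtures()
#' res <- run_pipeline(
#'   cluster_of = stats::setNames(fx$factors$cluster, fx$factors$code),
#'   reachable_sets = fx$reachable_sets, judgments = "seeded", seed = 42
#' )
#' res$partition$levels[[1]]
#' @export
run_pipeline <- function(cluster_of,
                         relations = NULL,
                         reachable_sets = NULL,
                         responses = NULL,
                         dimension_of_item = NULL,
                         judgments = "seeded",
                         cluster_judgments = NULL,
                         seed = 1,
                         reclose = FALSE,
                         out_dir = NULL,
                         allow_inconsistent = FALSE) {
  if (is.null(relations) == is.null(reachable_sets)) {
    stop("supply exactly one of `relations` or `reachable_sets`",
         call. = FALSE)
  }
  factor_ids <- names(cluster_of)

  m <- if (!is.null(relations)) {
    transitive_closure(build_adjacency(relations, factor_ids))
  } else {
    reachability_from_sets(reachable_sets)
  }
  sets <- factor_sets(m)
  part <- if (reclose) partition_levels(m, reclose = TRUE) else {
    suppressWarnings(partition_levels(m))
  }
  dg <- hierarchy_digraph(m, part)

  net <- build_network(m, cluster_of)
  if (is.character(judgments)) {
    judgments <- switch(judgments,
      seeded = seeded_judgments(net, seed = seed),
      uniform = uniform_judgments(net),
      stop("judgments must be \"seeded\", \"uniform\", or a named list ",
           "of judgment matrices", call. = FALSE)
    )
  }
  anp <- anp_pipeline(net, judgments, cluster_judgments,
                      allow_inconsistent = allow_inconsistent)

  rel_report <- if (!is.null(responses)) {
    reliability_report(responses, dimension_of_item)
  } else NULL

  manifest <- list(
    package = "ismanp",
    version = as.character(utils::packageVersion("ismanp")),
    seed = seed,
    n_factors = length(factor_ids),
    reclose = reclose,
    limit_method = anp$limit_method,
    input = if (!is.null(relations)) "relations" else "reachable_sets",
    checksums = list(
      reachability = sum(m),
      weights = round(sum(anp$weights$weight), 12)
    )
  )

  out <- list(reachability = m, factor_sets = sets, partition = part,
              digraph = dg, anp = anp, reliability = rel_report,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_csv(m, file.path(out_dir, "reachability.csv"))
    write_sets_json(sets$reachable, file.path(out_dir, "reachable_sets.json"))
    write_sets_json(sets$antecedent, file.path(out_dir, "antecedent_sets.json"))
    lev <- data.frame(
      level = rep(seq_along(part$levels), lengths(part$levels)),
      factor = unlist(part$levels), stringsAsFactors = FALSE
    )
    utils::write.csv(lev, file.path(out_dir, "levels.csv"),
                     row.names = FALSE, quote = FALSE)
    write_dot(dg, file.path(out_dir, "hierarchy.dot"))
    utils::write.csv(
      data.frame(anp$weights[1L],
                 weight = sprintf("%.4f", anp$weights$weight),
                 rank = anp$weights$rank),
      file.path(out_dir, "weights.csv"), row.names = FALSE, quote = FALSE
    )
    for (stage in c("W0", "W", "limit")) {
      utils::write.csv(as.data.frame(unclass(anp[[stage]])),
                       file.path(out_dir, paste0("supermatrix_",
                                                 tolower(stage), ".csv")))
    }
    if (!is.null(rel_report)) {
      jsonlite::write_json(rel_report, file.path(out_dir, "reliability.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
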