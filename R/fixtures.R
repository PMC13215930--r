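#' Fixtures from a published ISM-ANP drowning risk-factor study
#'
#' Bundles the printed tables of a published interpretive-structural-model /
#' analytic-network-process analysis of drowning risk factors in preschool
#' children, transcribed verbatim. The study condensed 50 questionnaire items
#' into 18 common factors (F1--F18), assigned them to four Haddon-matrix
#' clusters, derived a reachability structure among them, partitioned the
#' factors into five hierarchy levels, and reported ANP global weights.
#'
#' The transcription is verbatim, including two internal inconsistencies of
#' the printed tables that the package deliberately preserves rather than
#' corrects: the printed antecedent set of F2 omits F16 even though F2 is
#' listed in the reachable set of F16, and the printed level partition omits
#' F8 entirely (the extraction rule places it in level 3). The printed
#' reachable sets are also not perfectly transitively closed; see
#' [check_closure()].
#'
#' @return A list with components:
#' \describe{
#'   \item{factors}{data.frame with `code` (\code{"F1"}..\code{"F18"}),
#'     `label`, and `cluster` (one of \code{"host"}, \code{"medium"},
#'     \code{"physical environment"}, \code{"social environment"}).}
#'   \item{variance_table}{data.frame of the per-dimension exploratory factor
#'     analysis: `dimension`, `code`, `eigenvalue`, `contribution` (% of
#'     block variance), `cumulative` (% running sum within block).}
#'   \item{reachable_sets}{named list, integer indices of the printed
#'     reachable set R(Fi) for each factor (ranges expanded; every factor
#'     lists itself).}
#'   \item{antecedent_sets}{named list, the printed antecedent sets Q(Fi).}
#'   \item{intersections}{named list, the printed R(Fi) ∩ Q(Fi) columns
#'     (all singletons).}
#'   \item{level_partition}{list of integer vectors, the printed five-level
#'     partition, surface level first (17 factors as printed; F8 absent).}
#'   \item{global_weights}{data.frame `code`, `weight`, `rank`: the reported
#'     ANP global weights (comparison only; the underlying expert judgment
#'     matrices were not published).}
#'   \item{survey}{list of respondent counts: `distributed`, `valid`,
#'     `male`, `female`.}
#' }
#' @examples
#' fx <- drowning_fixtures()
#' fx$reachable_sets[["F13"]]   # 4, 5, 13
#' fx$level_partition[[5]]      # 15, 16
#' @export
drowning_fixtures <- function() {
  labels <- c(
    "Individual inherent characteristics",
    "Physical and mental abilities and health status",
    "Water skills and cognitive biases",
    "Risky behaviors",
    "Lack of immediate response and protection",
    "Safety defects in equipment and facilities",
    "Risks related to vessels",
    "Characteristics of water environment",
    "Lack of protective facilities in places",
    "Environmental risks",
    "Family environmental exposure",
    "Supervision and time-space factors",
    "Caregiver behavior and supervision",
    "Caregiver knowledge and cognition",
    "Community safety and education system",
    "Family economic background",
    "Emergency preparedness and response mechanisms",
    "Medical rescue and follow-up support"
  )
  cluster <- c(rep("host", 5), rep("medium", 3),
               rep("physical environment", 4), rep("social environment", 6))
  factors <- data.frame(
    code = paste0("F", 1:18), label = labels, cluster = cluster,
    stringsAsFactors = FALSE
  )

  variance_table <- data.frame(
    dimension = c(rep("host", 5), rep("medium", 3),
                  rep("physical environment", 4), rep("social environment", 6)),
    code = paste0("F", 1:18),
    eigenvalue = c(3.855, 2.105, 1.411, 1.274, 1.073,
                   3.381, 2.376, 1.244,
                   3.722, 1.573, 1.478, 1.039,
                   4.569, 4.188, 2.323, 2.195, 2.039, 1.134),
    contribution = c(35.047, 19.135, 12.826, 11.583, 9.758,
                     42.256, 29.695, 15.556,
                     41.355, 17.48, 16.424, 11.55,
                     24.05, 22.04, 12.225, 11.552, 10.732, 5.966),
    cumulative = c(35.047, 54.182, 67.008, 78.591, 88.349,
                   42.256, 71.952, 87.508,
                   41.355, 58.836, 75.26, 86.81,
                   24.05, 46.09, 58.315, 69.867, 80.599, 86.566),
    stringsAsFactors = FALSE
  )

  reachable <- list(
    1:5, 2:5, 3:5, 4L, 5L,
    c(5L, 6L, 13L), c(4L, 5L, 7L, 13L), c(4L, 5L, 8L, 13L),
    c(4L, 5L, 9L, 10L, 13L), c(4L, 5L, 10L, 13L), c(4L, 5L, 11L, 13L),
    c(4L, 5L, 12L, 13L), c(4L, 5L, 13L), c(4L, 5L, 11L, 13L, 14L),
    c(6L, 7L, 9:15, 17L, 18L), c(2L, 4:7, 9:14, 16:18),
    c(17L, 18L), 18L
  )
  antecedent <- list(
    1L, c(1L, 2L), 1:3, c(1:4, 7:14, 16L), c(1:3, 5:14, 16L),
    c(6L, 15L, 16L), c(7L, 15L, 16L), 8L, c(9L, 15L, 16L),
    c(9L, 10L, 15L, 16L), c(11L, 14:16), c(12L, 15L, 16L),
    6:16, 14:16, 15L, 16L, 15:17, 15:18
  )
  reachable <- lapply(reachable, as.integer)
  antecedent <- lapply(antecedent, as.integer)
  names(reachable) <- names(antecedent) <- paste0("F", 1:18)
  intersections <- as.list(1:18)
  names(intersections) <- paste0("F", 1:18)

  level_partition <- list(
    c(4L, 5L, 18L),
    c(3L, 13L, 17L),
    c(2L, 6L, 7L, 10L, 11L, 12L),
    c(1L, 9L, 14L),
    c(15L, 16L)
  )

  global_weights <- data.frame(
    code = paste0("F", 1:18),
    weight = c(0, 0.069, 0.0709, 0.2806, 0.1469, 0.0355, 0.0031, 0,
               0.0326, 0.0111, 0.0231, 0.0072, 0.2326, 0.0405, 0, 0,
               0.014, 0.0329),
    rank = c(15L, 5L, 4L, 1L, 3L, 7L, 14L, 15L, 9L, 12L, 10L, 13L,
             2L, 6L, 15L, 15L, 11L, 8L),
    stringsAsFactors = FALSE
  )

  fx <- list(
    factors = factors,
    variance_table = variance_table,
    reachable_sets = reachable,
    antecedent_sets = antecedent,
    intersections = intersections,
    level_partition = level_partition,
    global_weights = global_weights,
    survey = list(distributed = 220L, valid = 205L, male = 87L, female = 118L)
  )
  .check_fixture_integrity(fx)
  fx
}

# Count/sum invariants frozen at transcription time; guard accidental edits.
.check_fixture_integrity <- function(fx) {
  ok <- sum(lengths(fx$reachable_sets)) == 78L &&
    sum(unlist(fx$reachable_sets)) == 671L &&
    sum(lengths(fx$antecedent_sets)) == 77L &&
    sum(unlist(fx$antecedent_sets)) == 820L &&
    sum(lengths(fx$level_partition)) == 17L &&
    abs(sum(fx$global_weights$weight) - 1) < 1e-9 &&
    nrow(fx$factors) == 18L &&
    all(vapply(seq_len(18L), function(i) i %in% fx$reachable_sets[[i]], logical(1)))
  if (!ok) {
    stop("fixture integrity check failed: transcribed tables were modified",
         call. = FALSE)
  }
  invisible(TRUE)
}
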