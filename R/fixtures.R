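#' Literature fixtures for Sure Thing Principle experiments
#'
#' Condition-probability triples from published Prisoner's Dilemma and
#' two-stage gamble experiments, as printed in the originating reports:
#' the probability of the focal action (defect / play) when the first
#' condition is known (`p_known_1`), when the second condition is known
#' (`p_known_2`), and when the condition is unknown (`p_unknown_observed`),
#' plus the prior on the first condition (0.5 throughout). Table ids:
#' `T1` (pooled Prisoner's Dilemma studies), `T2` (two-stage gamble studies),
#' `T9` (the guessed-condition games), `T10` (seven Prisoner's Dilemma
#' games from one lab). A `note` column records fixture-level caveats,
#' including the column-order discrepancy of the `T9` Average row.
#'
#' @param table_id Optional filter: one of `"T1"`, `"T2"`, `"T9"`, `"T10"`.
#' @return A tibble with columns `table_id`, `study`, `game`, `p_known_1`,
#'   `p_known_2`, `p_unknown_observed`, `prior1`, `note`.
#' @export
stp_studies <- function(table_id = NULL) {
  path <- system.file("extdata", "stp_studies.csv", package = "qlbn",
                      mustWork = TRUE)
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(note = "character")))
  if (!is.null(table_id)) {
    if (!all(table_id %in% out$table_id)) {
      abort(sprintf("Unknown table id: %s",
                    paste(setdiff(table_id, out$table_id), collapse = ", ")))
    }
    out <- out[out$table_id %in% table_id, ]
  }
  out
}

#' Build the two-node network for a literature record
#'
#' Deterministic constructor mapping a study row to the canonical decision
#' scenario: the first condition variable with its prior, and the decision
#' variable conditioned on it with the two known-condition probabilities.
#' Prisoner's Dilemma records use P1/P2 with defect/cooperate states; gamble
#' records use G1 (win/lose) and G2 (play/stop), positive outcome first.
#'
#' @param record A one-row tibble/data frame with columns `game`,
#'   `p_known_1`, `p_known_2`, `prior1` (as returned by [stp_studies()]).
#' @return A [qlbn_net()].
#' @export
record_to_network <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  if (identical(record$game, "two_stage_gamble")) {
    two_node_net(record$p_known_1, record$p_known_2, record$prior1,
                 parent = "G1", child = "G2",
                 parent_states = c("win", "lose"),
                 child_states = c("play", "stop"))
  } else {
    two_node_net(record$p_known_1, record$p_known_2, record$prior1)
  }
}

# decision variable of a record's network (the child node)
record_target <- function(record) {
  if (identical(record$game, "two_stage_gamble")) "G2" else "P2"
}

#' Generate seeded random networks for property testing
#'
#' Produces reproducible random scenarios: two-node uniform-prior networks
#' (the experimental design the literature fixtures share) plus random
#' chains/trees of up to `max_nodes` binary variables, with every
#' conditional probability drawn uniformly on [0.05, 0.95] so that no
#' evidence is impossible.
#'
#' @param n Number of networks.
#' @param seed Integer seed.
#' @param max_nodes Maximum number of variables (2 to 5).
#' @return A list of [qlbn_net()] objects.
#' @export
synth_scenarios <- function(n, seed, max_nodes = 5L) {
  stopifnot(n >= 1L, max_nodes >= 2L, max_nodes <= 5L)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5 || max_nodes == 2L) {
        two_node_net(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
      } else {
        k <- sample(2:max_nodes, 1L)
        nms <- paste0("X", seq_len(k))
        variables <- setNames(replicate(k, c("yes", "no"),
                                        simplify = FALSE), nms)
        tables <- setNames(lapply(seq_len(k), function(j) {
          # tree/chain: at most one parent, drawn from earlier nodes
          parents <- if (j == 1L) character() else
            nms[sample.int(j - 1L, 1L)]
          if (!length(parents)) {
            list(parents = parents,
                 rows = data.frame(p = runif(1, 0.05, 0.95)))
          } else {
            rows <- setNames(
              data.frame(c("yes", "no"), runif(2, 0.05, 0.95),
                         stringsAsFactors = FALSE),
              c(parents, "p"))
            list(parents = parents, rows = rows)
          }
        }), nms)
        qlbn_net(variables, tables)
      }
    })
  })
}
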