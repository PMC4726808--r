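#' Build a Bayesian network of binary variables
#'
#' A `qlbn_net` is a directed acyclic graph of binary random variables, each
#' carrying a conditional probability table (CPT). Variable states are an
#' ordered pair of labels; the first-listed state is the "positive" outcome
#' (e.g. defect, play) and this ordering fixes the enumeration order used by
#' the full joint distribution and by interference pairing downstream.
#'
#' @param variables Named list. Each element is a character vector of length
#'   two giving the ordered state labels of that variable; names are the
#'   variable names.
#' @param tables Named list, one element per variable (names are the child
#'   variable). Each element is a list with fields `parents` (character
#'   vector, possibly empty) and `rows`: a data frame with one column per
#'   parent (holding parent state labels) and a column `p` with the
#'   probability of the child's *first* state given that parent assignment.
#'   For a parentless variable, `rows` is a one-row data frame with only `p`.
#'
#' @return An object of class `qlbn_net`.
#' @examples
#' net <- qlbn_net(
#'   variables = list(P1 = c("defect", "cooperate"),
#'                    P2 = c("defect", "cooperate")),
#'   tables = list(
#'     P1 = list(parents = character(), rows = data.frame(p = 0.5)),
#'     P2 = list(parents = "P1",
#'               rows = data.frame(P1 = c("defect", "cooperate"),
#'                                 p = c(0.87, 0.74)))
#'   )
#' )
#' full_joint(net)
#' @export
qlbn_net <- function(variables, tables) {
  if (is.null(names(variables)) || any(names(variables) == "")) {
    abort("`variables` must be a fully named list.")
  }
  vars <- lapply(variables, as.character)
  for (nm in names(vars)) {
    st <- vars[[nm]]
    if (length(st) != 2L || anyDuplicated(st)) {
      abort(sprintf("Variable '%s' must have exactly two distinct states.", nm))
    }
  }
  if (!setequal(names(tables), names(vars))) {
    abort("`tables` must contain exactly one table per declared variable.")
  }
  tabs <- list()
  for (child in names(vars)) {
    tb <- tables[[child]]
    parents <- as.character(tb$parents %||% character())
    if (!all(parents %in% names(vars))) {
      abort(sprintf("Table for '%s' references undeclared parents.", child))
    }
    rows <- as_tibble(tb$rows)
    if (!"p" %in% names(rows)) {
      abort(sprintf("Table for '%s' must have a `p` column.", child))
    }
    if (!all(parents %in% names(rows))) {
      abort(sprintf("Table for '%s' is missing parent columns.", child))
    }
    if (any(rows$p < 0 | rows$p > 1 | !is.finite(rows$p))) {
      abort(sprintf("Probabilities for '%s' must lie in [0, 1].", child))
    }
    # one row per full parent assignment
    expected <- if (length(parents)) 2L^length(parents) else 1L
    key <- assignment_key(rows[parents])
    if (nrow(rows) != expected || anyDuplicated(key)) {
      abort(sprintf(
        "Table for '%s' needs exactly one row per parent assignment (%d rows).",
        child, expected
      ))
    }
    for (pa in parents) {
      if (!all(rows[[pa]] %in% vars[[pa]])) {
        abort(sprintf("Table for '%s' uses unknown states of parent '%s'.",
                      child, pa))
      }
    }
    tabs[[child]] <- list(child = child, parents = parents,
                          rows = rows[c(parents, "p")])
  }
  # acyclicity by repeated removal of parentless nodes
  remaining <- names(vars)
  repeat {
    free <- remaining[vapply(remaining, function(v) {
      !any(tabs[[v]]$parents %in% remaining)
    }, logical(1))]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining)) {
    abort(sprintf("Parent structure is cyclic (involves: %s).",
                  paste(remaining, collapse = ", ")))
  }
  ord <- sort(names(vars))
  structure(list(variables = vars[ord], tables = tabs[ord]),
            class = "qlbn_net")
}

#' @export
print.qlbn_net <- function(x, ...) {
  cat(sprintf("<qlbn_net: %d binary variables>\n", length(x$variables)))
  for (nm in names(x$variables)) {
    pa <- x$tables[[nm]]$parents
    cat(sprintf("  %s (%s | %s)%s\n", nm,
                x$variables[[nm]][1], x$variables[[nm]][2],
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Variables of a network as a tibble
#'
#' @param net A [qlbn_net()].
#' @return A tibble with columns `name`, `state1`, `state2`.
#' @export
net_variables <- function(net) {
  stopifnot(inherits(net, "qlbn_net"))
  tibble(
    name = names(net$variables),
    state1 = vapply(net$variables, `[`, character(1), 1L),
    state2 = vapply(net$variables, `[`, character(1), 2L)
  )
}

# collapse parent-state columns into a single matching key
assignment_key <- function(df) {
  if (!ncol(df)) return(rep("", max(nrow(df), 1L)))
  do.call(paste, c(as.list(df), sep = "\r"))
}

#' Enumerate all joint assignments of a set of variables
#'
#' Assignments are enumerated in the canonical order used throughout the
#' package: variables sorted alphabetically by name, the alphabetically first
#' variable most significant, and within each variable the first-listed state
#' before the second. Interference pairing of hidden completions relies on
#' this order being stable.
#'
#' @param net A [qlbn_net()].
#' @param vars Character vector of variable names (default: all).
#' @return A tibble with one column per variable and one row per assignment.
#' @export
enumerate_assignments <- function(net, vars = names(net$variables)) {
  vars <- sort(vars)
  if (!length(vars)) return(tibble(.rows = 1L))
  states <- lapply(net$variables[vars], identity)
  grid <- expand.grid(rev(states), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  as_tibble(grid[, rev(seq_along(vars)), drop = FALSE]) |>
    setNames(vars)
}

#' Full joint distribution of a network
#'
#' Multiplies the conditional table entries along each variable's parents to
#' obtain the probability of every complete assignment.
#'
#' @param net A [qlbn_net()].
#' @return A tibble with one column per variable plus a `prob` column; rows in
#'   canonical enumeration order and summing to 1.
#' @export
full_joint <- function(net) {
  stopifnot(inherits(net, "qlbn_net"))
  asg <- enumerate_assignments(net)
  prob <- rep(1, nrow(asg))
  for (child in names(net$variables)) {
    tb <- net$tables[[child]]
    if (length(tb$parents)) {
      lookup <- setNames(tb$rows$p, assignment_key(tb$rows[tb$parents]))
      p_first <- unname(lookup[assignment_key(asg[tb$parents])])
    } else {
      p_first <- rep(tb$rows$p, nrow(asg))
    }
    first <- asg[[child]] == net$variables[[child]][1]
    prob <- prob * ifelse(first, p_first, 1 - p_first)
  }
  asg$prob <- prob
  asg
}

# normalize evidence input to a named character vector and validate
check_evidence <- function(net, evidence, target = NULL) {
  if (is.null(evidence) || !length(evidence)) return(character())
  ev <- unlist(evidence)
  if (is.null(names(ev)) || any(names(ev) == "")) {
    abort("`evidence` must be named, e.g. c(P1 = \"defect\").")
  }
  for (nm in names(ev)) {
    if (!nm %in% names(net$variables)) {
      abort(sprintf("Evidence variable '%s' is not declared.", nm))
    }
    if (!ev[[nm]] %in% net$variables[[nm]]) {
      abort(sprintf("'%s' is not a state of '%s'.", ev[[nm]], nm))
    }
  }
  if (!is.null(target) && target %in% names(ev)) {
    abort("The query target cannot appear in the evidence.")
  }
  ev
}

#' Classical exact inference by enumeration
#'
#' Sums the full-joint entries consistent with the evidence for each state of
#' the target variable and normalizes, i.e. Pr(X | e) with the normalization
#' constant taken over the target's two states.
#'
#' @param net A [qlbn_net()].
#' @param target Name of the query variable.
#' @param evidence Named character vector of observed states (optional).
#' @return A tibble with columns `state` and `prob` (two rows, summing to 1).
#' @export
classical_infer <- function(net, target, evidence = NULL) {
  stopifnot(inherits(net, "qlbn_net"))
  if (!target %in% names(net$variables)) {
    abort(sprintf("Unknown target variable '%s'.", target))
  }
  ev <- check_evidence(net, evidence, target)
  joint <- full_joint(net)
  for (nm in names(ev)) joint <- joint[joint[[nm]] == ev[[nm]], ]
  states <- net$variables[[target]]
  score <- vapply(states, function(s) sum(joint$prob[joint[[target]] == s]),
                  numeric(1))
  total <- sum(score)
  if (total <= 0) {
    abort("Evidence has probability zero: conditional is undefined.",
          class = "qlbn_impossible_evidence")
  }
  tibble(state = states, prob = unname(score) / total)
}

#' Law-of-total-probability prediction
#'
#' The classical prediction for an unknown condition:
#' `prior1 * p_given_cond1 + (1 - prior1) * p_given_cond2`.
#'
#' @param p_given_cond1,p_given_cond2 Conditional probabilities of the focal
#'   outcome under the two known conditions.
#' @param prior1 Prior probability of the first condition (default 0.5).
#' @return Numeric vector of total probabilities.
#' @export
ltp_predict <- function(p_given_cond1, p_given_cond2, prior1 = 0.5) {
  p <- c(p_given_cond1, p_given_cond2, prior1)
  if (any(p < 0 | p > 1 | !is.finite(p))) {
    abort("All arguments must be probabilities in [0, 1].")
  }
  prior1 * p_given_cond1 + (1 - prior1) * p_given_cond2
}

#' Test for a Sure Thing Principle violation
#'
#' A violation occurs when the observed unknown-condition probability falls
#' outside the interval spanned by the two known-condition probabilities —
#' a pattern no classical mixture (law of total probability) can produce.
#'
#' @param p_known1,p_known2 Probabilities of the focal action under the two
#'   known conditions.
#' @param p_unknown Observed probability under the unknown condition.
#' @return A tibble with `violation` (logical) and `direction` (`"below"`,
#'   `"above"`, or `"none"`).
#' @export
check_stp_violation <- function(p_known1, p_known2, p_unknown) {
  p <- c(p_known1, p_known2, p_unknown)
  if (any(p < 0 | p > 1 | !is.finite(p))) {
    abort("All arguments must be probabilities in [0, 1].")
  }
  lo <- pmin(p_known1, p_known2)
  hi <- pmax(p_known1, p_known2)
  direction <- dplyr::case_when(
    p_unknown < lo ~ "below",
    p_unknown > hi ~ "above",
    TRUE ~ "none"
  )
  tibble(violation = direction != "none", direction = direction)
}

#' Two-node network for a known/unknown condition experiment
#'
#' Builds the canonical decision scenario: a parent variable (the unknown
#' condition, e.g. the other player's action or the first gamble's outcome)
#' with a prior, and a child decision variable whose focal-outcome probability
#' is given under each parent state.
#'
#' @param p_cond1 Probability of the child's first state given the parent's
#'   first state.
#' @param p_cond2 Probability of the child's first state given the parent's
#'   second state.
#' @param prior1 Prior probability of the parent's first state.
#' @param parent,child Variable names.
#' @param parent_states,child_states Ordered state labels.
#' @return A [qlbn_net()].
#' @export
two_node_net <- function(p_cond1, p_cond2, prior1 = 0.5,
                         parent = "P1", child = "P2",
                         parent_states = c("defect", "cooperate"),
                         child_states = c("defect", "cooperate")) {
  qlbn_net(
    variables = setNames(list(parent_states, child_states), c(parent, child)),
    tables = setNames(list(
      list(parents = character(), rows = data.frame(p = prior1)),
      list(parents = parent,
           rows = setNames(data.frame(parent_states, c(p_cond1, p_cond2),
                                      stringsAsFactors = FALSE),
                           c(parent, "p")))
    ), c(parent, child))
  )
}

#' Read / write a network as JSON
#'
#' The serialization schema is
#' `{"variables": [{"name", "states"}], "tables": [{"child", "parents",
#' "rows": [{"given": {...}, "p_first_state"}]}]}`. Round-trips exactly.
#'
#' @param path File path.
#' @return `read_qlbn_json()` returns a [qlbn_net()]; `write_qlbn_json()`
#'   returns `path` invisibly.
#' @export
read_qlbn_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = FALSE)
  variables <- setNames(
    lapply(doc$variables, function(v) unlist(v$states)),
    vapply(doc$variables, function(v) v$name, character(1))
  )
  tables <- setNames(lapply(doc$tables, function(tb) {
    parents <- as.character(unlist(tb$parents))
    rows <- purrr::map_dfr(tb$rows, function(r) {
      given <- lapply(r$given, as.character)
      as_tibble(c(given, list(p = r$p_first_state)))
    })
    if (!length(tb$rows)) rows <- tibble(p = numeric())
    list(parents = parents, rows = rows)
  }), vapply(doc$tables, function(tb) tb$child, character(1)))
  qlbn_net(variables, tables)
}

#' @rdname read_qlbn_json
#' @param net A [qlbn_net()].
#' @export
write_qlbn_json <- function(net, path) {
  stopifnot(inherits(net, "qlbn_net"))
  doc <- list(
    variables = lapply(names(net$variables), function(nm) {
      list(name = nm, states = net$variables[[nm]])
    }),
    tables = lapply(net$tables, function(tb) {
      rows <- lapply(seq_len(nrow(tb$rows)), function(i) {
        given <- as.list(tb$rows[i, tb$parents, drop = FALSE])
        list(given = given, p_first_state = tb$rows$p[i])
      })
      list(child = tb$child, parents = tb$parents, rows = rows)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
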