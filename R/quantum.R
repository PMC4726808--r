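#' Born-rule amplitude representation of the full joint
#'
#' Maps each full-joint entry p to an amplitude of magnitude sqrt(p). Phases
#' are left symbolic (stored as 0) because they are attached at inference
#' time: the similarity heuristic derives them per query.
#'
#' @param net A [qlbn_net()].
#' @return A tibble like [full_joint()] but with `magnitude` and `phase`
#'   columns instead of `prob`; the squared magnitudes sum to 1.
#' @export
born_joint <- function(net) {
  joint <- full_joint(net)
  joint$magnitude <- sqrt(joint$prob)
  joint$phase <- 0
  joint$prob <- NULL
  joint
}

# resolve a phase spec against the i<j pairs of n hidden completions:
# a single number is shared across all pairs; a named vector uses "i-j" keys.
resolve_phases <- function(phases, n) {
  if (n < 2L) return(numeric())
  pairs <- utils::combn(n, 2L)
  keys <- paste(pairs[1, ], pairs[2, ], sep = "-")
  if (is.numeric(phases) && length(phases) == 1L && is.null(names(phases))) {
    return(setNames(rep(as.numeric(phases), ncol(pairs)), keys))
  }
  if (is.numeric(phases) && !is.null(names(phases))) {
    if (!all(keys %in% names(phases))) {
      abort(sprintf("Phase spec must cover every hidden-completion pair (%s).",
                    paste(setdiff(keys, names(phases)), collapse = ", ")))
    }
    return(setNames(as.numeric(phases[keys]), keys))
  }
  abort("`phases` must be a single phase difference or a named per-pair vector.")
}

#' Quantum-like inference with interference terms
#'
#' For each state of the target, the unnormalized score is the classical sum
#' over hidden completions plus pairwise interference:
#' `sum_i |psi_i|^2 + 2 * sum_{i<j} |psi_i||psi_j| cos(dtheta_ij)`,
#' where the magnitudes are Born amplitudes of the joint entries consistent
#' with the evidence and that target state. The same phase spec is applied to
#' both target states, and the two scores are then alpha-normalized. At a
#' phase difference of pi/2 every cosine vanishes and the result collapses to
#' [classical_infer()].
#'
#' @param net A [qlbn_net()].
#' @param target Name of the query variable.
#' @param phases Either a single shared phase difference (radians) or a named
#'   numeric vector with one entry per hidden-completion pair, keyed `"i-j"`
#'   with `i < j` indices in canonical enumeration order.
#' @param evidence Named character vector of observed states (optional).
#' @return An object of class `qlbn_infer` with fields `target`, `states`,
#'   `scores`, `alpha`, `prob`, `interference` (per-pair tibble), `phases`,
#'   and `nonphysical` (TRUE if extreme phases drove a score negative).
#' @export
quantum_infer <- function(net, target, phases, evidence = NULL) {
  stopifnot(inherits(net, "qlbn_net"))
  if (!target %in% names(net$variables)) {
    abort(sprintf("Unknown target variable '%s'.", target))
  }
  ev <- check_evidence(net, evidence, target)
  joint <- full_joint(net)
  for (nm in names(ev)) joint <- joint[joint[[nm]] == ev[[nm]], ]
  states <- net$variables[[target]]
  hidden <- setdiff(names(net$variables), c(target, names(ev)))

  # magnitudes per target state; full_joint rows restricted to a fixed
  # target/evidence assignment are already in hidden-completion enumeration
  # order, so row order is the pairing order
  mags <- lapply(states, function(s) sqrt(joint$prob[joint[[target]] == s]))
  n_hidden <- length(mags[[1]])
  delta <- resolve_phases(phases, n_hidden)

  per_state <- purrr::map2(states, mags, function(s, m) {
    if (n_hidden < 2L) {
      return(list(score = sum(m^2),
                  rows = tibble(state = character(), i = integer(),
                                j = integer(), contribution = numeric())))
    }
    pairs <- utils::combn(n_hidden, 2L)
    contrib <- 2 * m[pairs[1, ]] * m[pairs[2, ]] *
      cos(delta[paste(pairs[1, ], pairs[2, ], sep = "-")])
    list(score = sum(m^2) + sum(contrib),
         rows = tibble(state = s, i = pairs[1, ], j = pairs[2, ],
                       contribution = unname(contrib)))
  })
  scores <- vapply(per_state, `[[`, numeric(1), "score")
  interference <- purrr::map_dfr(per_state, `[[`, "rows")

  total <- sum(scores)
  if (total == 0) {
    abort("Total score is zero: normalization undefined.",
          class = "qlbn_impossible_evidence")
  }
  nonphysical <- any(scores < 0)
  if (nonphysical) {
    warn("Negative unnormalized score: result flagged non-physical.")
  }
  structure(list(
    target = target, states = states, scores = setNames(scores, states),
    alpha = 1 / total, prob = setNames(scores / total, states),
    interference = interference, phases = delta, evidence = ev,
    n_hidden = n_hidden, nonphysical = nonphysical
  ), class = "qlbn_infer")
}

#' @export
print.qlbn_infer <- function(x, ...) {
  cat(sprintf("<qlbn_infer: Pr(%s | %s)>\n", x$target,
              if (length(x$evidence)) {
                paste(names(x$evidence), x$evidence, sep = "=", collapse = ", ")
              } else "no evidence"))
  for (s in x$states) {
    cat(sprintf("  %s: score %.6f -> prob %.4f\n", s, x$scores[s], x$prob[s]))
  }
  cat(sprintf("  alpha = %.4f, %d hidden completion(s)%s\n", x$alpha,
              x$n_hidden, if (x$nonphysical) " [non-physical]" else ""))
  invisible(x)
}

#' @export
tidy.qlbn_infer <- function(x, ...) {
  tibble(state = x$states, score = unname(x$scores), prob = unname(x$prob))
}

#' @export
glance.qlbn_infer <- function(x, ...) {
  tibble(alpha = x$alpha, n_hidden = x$n_hidden,
         n_pairs = nrow(x$interference) / length(x$states),
         nonphysical = x$nonphysical)
}

#' Sweep the shared phase difference over a grid
#'
#' Evaluates [quantum_infer()] at each grid point with a shared phase and
#' records the normalized probability of a chosen target state. Useful to map
#' the attainable probability range of a scenario.
#'
#' @param net A [qlbn_net()].
#' @param target Name of the query variable.
#' @param grid Numeric vector of phase differences (radians); default a
#'   1001-point grid over `[0, 2*pi]`.
#' @param state Target state to track (default: the first-listed state).
#' @param evidence Named character vector of observed states (optional).
#' @return A tibble of class `qlbn_sweep` with columns `delta_theta` and
#'   `p_target`, and attributes `minimum`, `maximum`, `argmin`, `argmax`.
#' @export
sweep_phase <- function(net, target, grid = seq(0, 2 * pi, length.out = 1001),
                        state = NULL, evidence = NULL) {
  if (!length(grid)) abort("`grid` must be nonempty.")
  stopifnot(inherits(net, "qlbn_net"))
  state <- state %||% net$variables[[target]][1]
  p <- vapply(grid, function(d) {
    quantum_infer(net, target, phases = d, evidence = evidence)$prob[[state]]
  }, numeric(1))
  out <- tibble(delta_theta = grid, p_target = p)
  class(out) <- c("qlbn_sweep", class(out))
  attr(out, "target") <- target
  attr(out, "state") <- state
  attr(out, "minimum") <- min(p)
  attr(out, "maximum") <- max(p)
  attr(out, "argmin") <- grid[which.min(p)]
  attr(out, "argmax") <- grid[which.max(p)]
  out
}

#' @export
glance.qlbn_sweep <- function(x, ...) {
  tibble(minimum = attr(x, "minimum"), maximum = attr(x, "maximum"),
         argmin = attr(x, "argmin"), argmax = attr(x, "argmax"))
}
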