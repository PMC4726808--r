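#' Outcome vectors for an interference pair
#'
#' For a query on a binary target, each hidden-completion pair (i, j) defines
#' two 2-component vectors: `a` holds the classical joint probabilities of
#' (target = queried state, completion i) and (target = queried state,
#' completion j); `b` the same for the opposite state. These are the feature
#' vectors whose triangle geometry drives the similarity heuristic.
#'
#' @param net A [qlbn_net()].
#' @param target Name of the query variable.
#' @param state Queried state (default: the target's first-listed state);
#'   vector `a` is always built for this state.
#' @param evidence Named character vector of observed states (optional).
#' @param pair Integer pair of hidden-completion indices (enumeration order).
#' @return A list of class `qlbn_vectors` with fields `a`, `b`, `pair`,
#'   `states` (queried state first), `target`.
#' @export
build_vectors <- function(net, target, state = NULL, evidence = NULL,
                          pair = c(1L, 2L)) {
  stopifnot(inherits(net, "qlbn_net"))
  ev <- check_evidence(net, evidence, target)
  states <- net$variables[[target]]
  state <- state %||% states[1]
  if (!state %in% states) {
    abort(sprintf("'%s' is not a state of '%s'.", state, target))
  }
  other <- setdiff(states, state)
  joint <- full_joint(net)
  for (nm in names(ev)) joint <- joint[joint[[nm]] == ev[[nm]], ]
  comp_a <- joint$prob[joint[[target]] == state]
  comp_b <- joint$prob[joint[[target]] == other]
  if (length(comp_a) < 2L) {
    abort("Fewer than two hidden completions: no interference pair.",
          class = "qlbn_no_pair")
  }
  pair <- sort(as.integer(pair))
  if (any(pair < 1L) || any(pair > length(comp_a)) || pair[1] == pair[2]) {
    abort("`pair` must index two distinct hidden completions.")
  }
  structure(list(a = comp_a[pair], b = comp_b[pair], pair = pair,
                 states = c(state, other), target = target),
            class = "qlbn_vectors")
}

#' Triangle geometry of two outcome vectors
#'
#' Joins the tips of vectors `a` and `b` by the Euclidean difference vector
#' `c` and recovers the triangle's inner angles via the law of cosines
#' (arccos arguments clamped to `[-1, 1]` as a floating-point guard):
#' `theta_A` faces `a` (between `b` and `c`), `theta_B` faces `b`, and
#' `theta_C` faces `c` (the angle between `a` and `b`). The similarity ratio
#' is `phi = (theta_C - theta_B) / theta_A`.
#'
#' @param vectors A `qlbn_vectors` object, or a numeric vector `a`.
#' @param b Numeric vector (when `vectors` is a bare numeric `a`).
#' @return A one-row tibble of class `qlbn_angles` with columns `norm_a`,
#'   `norm_b`, `norm_c`, `theta_A`, `theta_B`, `theta_C`, `phi`.
#' @export
triangle <- function(vectors, b = NULL) {
  if (inherits(vectors, "qlbn_vectors")) {
    a <- vectors$a
    b <- vectors$b
  } else {
    a <- as.numeric(vectors)
    if (is.null(b)) abort("Supply `b` when `vectors` is a plain vector.")
  }
  norm_a <- sqrt(sum(a^2))
  norm_b <- sqrt(sum(b^2))
  norm_c <- sqrt(sum((a - b)^2))
  if (min(norm_a, norm_b, norm_c) <= 0) {
    abort("Degenerate triangle: a zero-length side.",
          class = "qlbn_degenerate")
  }
  law <- function(opp, s1, s2) acos(clamp1((s1^2 + s2^2 - opp^2) / (2 * s1 * s2)))
  theta_A <- law(norm_a, norm_b, norm_c)
  theta_B <- law(norm_b, norm_a, norm_c)
  theta_C <- law(norm_c, norm_a, norm_b)
  out <- tibble(norm_a = norm_a, norm_b = norm_b, norm_c = norm_c,
                theta_A = theta_A, theta_B = theta_B, theta_C = theta_C,
                phi = (theta_C - theta_B) / theta_A)
  class(out) <- c("qlbn_angles", class(out))
  out
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Similarity heuristic for the interference phase
#'
#' The piecewise rule mapping triangle geometry to a phase parameter:
#' `pi` when `phi < 0`, `pi - theta_C / 2` when `phi > 0.2`, and
#' `pi - theta_C` otherwise (boundaries fall in the otherwise branch; the
#' inequalities are strict). All branches give `cos` at most 0 for
#' `theta_C <= pi/2`, i.e. destructive interference, which is the direction
#' Sure-Thing-Principle violations require.
#'
#' @param angles A `qlbn_angles` row from [triangle()].
#' @return A list with `theta` (radians) and `branch` (one of `"phi<0"`,
#'   `"phi>0.2"`, `"otherwise"`).
#' @export
heuristic_phase <- function(angles) {
  stopifnot(is.data.frame(angles), nrow(angles) == 1L)
  phi <- angles$phi
  if (phi < 0) {
    list(theta = pi, branch = "phi<0")
  } else if (phi > 0.2) {
    list(theta = pi - angles$theta_C / 2, branch = "phi>0.2")
  } else {
    list(theta = pi - angles$theta_C, branch = "otherwise")
  }
}

#' End-to-end heuristic prediction
#'
#' Runs the full pipeline for a query: build outcome vectors, compute the
#' triangle angles, pick the phase with the similarity heuristic, and perform
#' the interference marginalization with that phase shared across both target
#' states. With more than two hidden completions a separate phase is derived
#' per completion pair from the vectors restricted to that pair
#' (experimental generalization). A degenerate triangle (zero-length side)
#' falls back to the classical collapse phase `pi/2` with a warning.
#'
#' @param net A [qlbn_net()].
#' @param target Name of the query variable.
#' @param state Queried state (default: the target's first-listed state).
#' @param evidence Named character vector of observed states (optional).
#' @param observed Observed probability of the queried state (optional);
#'   when supplied, the percent fit error is attached.
#' @return An object of class `qlbn_prediction`: fields `vectors`, `angles`,
#'   `theta`, `branch`, `result` (a `qlbn_infer`), `p` (probability of the
#'   queried state), `classical`, `observed`, `fit_error`, `degenerate`.
#' @export
qlbn_predict <- function(net, target, state = NULL, evidence = NULL,
                         observed = NULL) {
  stopifnot(inherits(net, "qlbn_net"))
  states <- net$variables[[target]]
  state <- state %||% states[1]
  # completions consistent with the evidence
  ev <- check_evidence(net, evidence, target)
  joint <- full_joint(net)
  for (nm in names(ev)) joint <- joint[joint[[nm]] == ev[[nm]], ]
  n_hidden <- sum(joint[[target]] == state)
  if (n_hidden < 2L) {
    abort("Fewer than two hidden completions: no interference pair.",
          class = "qlbn_no_pair")
  }

  derive_one <- function(pair) {
    vec <- build_vectors(net, target, state = state, evidence = evidence,
                         pair = pair)
    ang <- tryCatch(triangle(vec), qlbn_degenerate = function(cnd) NULL)
    if (is.null(ang)) {
      return(list(vectors = vec, angles = NULL, theta = pi / 2,
                  branch = "degenerate"))
    }
    hp <- heuristic_phase(ang)
    list(vectors = vec, angles = ang, theta = hp$theta, branch = hp$branch)
  }

  if (n_hidden == 2L) {
    one <- derive_one(c(1L, 2L))
    phases <- one$theta
  } else {
    pairs <- utils::combn(n_hidden, 2L)
    per <- lapply(seq_len(ncol(pairs)), function(k) derive_one(pairs[, k]))
    phases <- setNames(
      vapply(per, `[[`, numeric(1), "theta"),
      paste(pairs[1, ], pairs[2, ], sep = "-")
    )
    one <- per[[1]]
    one$per_pair <- per
  }
  if (one$branch == "degenerate") {
    warn("Degenerate outcome-vector triangle: falling back to the classical collapse phase pi/2.")
  }

  result <- quantum_infer(net, target, phases = phases, evidence = evidence)
  classical <- classical_infer(net, target, evidence = evidence)
  p <- result$prob[[state]]
  fit <- if (!is.null(observed)) fit_error(p, observed) else NA_real_
  structure(list(
    target = target, state = state, vectors = one$vectors,
    angles = one$angles, theta = unname(one$theta), branch = one$branch,
    phases = phases, result = result, p = p,
    classical = classical$prob[classical$state == state],
    observed = observed %||% NA_real_, fit_error = fit,
    degenerate = identical(one$branch, "degenerate")
  ), class = "qlbn_prediction")
}

#' @export
print.qlbn_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("<qlbn_prediction: Pr(%s = %s)>\n", x$target, x$state))
  cat(sprintf("  a = [%s], b = [%s]\n",
              paste(round(x$vectors$a, digits), collapse = ", "),
              paste(round(x$vectors$b, digits), collapse = ", ")))
  if (!is.null(x$angles)) {
    with(x$angles, cat(sprintf(
      "  |a| = %.4f, |b| = %.4f, |c| = %.4f\n  theta_A = %.4f, theta_B = %.4f, theta_C = %.4f, phi = %.4f\n",
      norm_a, norm_b, norm_c, theta_A, theta_B, theta_C, phi
    )))
  }
  cat(sprintf("  branch: %s -> theta = %.4f\n", x$branch, x$theta))
  cat(sprintf("  scores: %s; alpha = %.4f\n",
              paste(sprintf("%s %.4f", x$result$states,
                            x$result$scores), collapse = ", "),
              x$result$alpha))
  cat(sprintf("  Pr(%s = %s) = %.4f (classical %.4f)\n",
              x$target, x$state, x$p, x$classical))
  if (!is.na(x$fit_error)) {
    cat(sprintf("  fit error vs observed %.4f: %.2f%%\n",
                x$observed, x$fit_error))
  }
  invisible(x)
}

#' @export
tidy.qlbn_prediction <- function(x, ...) {
  ang <- x$angles %||% tibble(norm_a = NA_real_, norm_b = NA_real_,
                              norm_c = NA_real_, theta_A = NA_real_,
                              theta_B = NA_real_, theta_C = NA_real_,
                              phi = NA_real_)
  dplyr::bind_cols(
    tibble(target = x$target, state = x$state),
    as_tibble(ang),
    tibble(branch = x$branch, theta = x$theta, p = x$p,
           classical = x$classical, observed = x$observed,
           fit_error = x$fit_error)
  )
}

#' @export
glance.qlbn_prediction <- function(x, ...) {
  tibble(branch = x$branch, theta = x$theta, alpha = x$result$alpha,
         p = x$p, classical = x$classical, fit_error = x$fit_error,
         degenerate = x$degenerate)
}
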