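# Brute-force enumeration oracle, independent of the package's joint/infer
# code path: per-row CPT lookup with explicit loops.

oracle_joint <- function(net) {
  vars <- names(net$variables)
  grid <- do.call(expand.grid,
                  c(rev(net$variables), stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_along(vars)), drop = FALSE]
  names(grid) <- vars
  prob <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pr <- 1
    for (v in vars) {
      tb <- net$tables[[v]]
      rows <- tb$rows
      sel <- rep(TRUE, nrow(rows))
      for (pa in tb$parents) sel <- sel & rows[[pa]] == grid[r, pa]
      pf <- rows$p[sel]
      pr <- pr * if (grid[r, v] == net$variables[[v]][1]) pf else 1 - pf
    }
    prob[r] <- pr
  }
  grid$prob <- prob
  grid
}

oracle_infer <- function(net, target, evidence = NULL) {
  joint <- oracle_joint(net)
  if (!is.null(evidence)) {
    for (nm in names(evidence)) {
      joint <- joint[joint[[nm]] == evidence[[nm]], ]
    }
  }
  states <- net$variables[[target]]
  num <- vapply(states, function(s) {
    sum(joint$prob[joint[[target]] == s])
  }, numeric(1))
  num / sum(num)
}

pd_average_net <- function() two_node_net(0.87, 0.74)

# a fixed three-variable chain used in several unit tests
chain3_net <- function() {
  qlbn_net(
    variables = list(A = c("t", "f"), B = c("t", "f"), C = c("t", "f")),
    tables = list(
      A = list(parents = character(), rows = data.frame(p = 0.3)),
      B = list(parents = "A",
               rows = data.frame(A = c("t", "f"), p = c(0.8, 0.2))),
      C = list(parents = "B",
               rows = data.frame(B = c("t", "f"), p = c(0.6, 0.1)))
    )
  )
}
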