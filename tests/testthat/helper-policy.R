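# Exhaustive stationary-policy evaluation oracle: f = c_pi + gamma * P_pi f,
# f = 0 at terminals; returns the minimal value vector over all policies.
enumerate_policies <- function(transition, cost, terminal, gamma = 1) {
  ns <- nrow(transition); na <- ncol(transition)
  combos <- expand.grid(rep(list(seq_len(na)), ns))
  best <- rep(Inf, ns)
  for (r in seq_len(nrow(combos))) {
    pick <- as.integer(combos[r, ])
    P <- matrix(0, ns, ns); cvec <- numeric(ns)
    for (s in seq_len(ns)) {
      if (terminal[s]) next
      nxt <- transition[s, pick[s]]
      if (is.na(nxt)) { cvec[s] <- Inf; next }
      P[s, nxt] <- gamma
      cvec[s] <- cost[s, pick[s]]
    }
    if (any(!is.finite(cvec))) next
    f <- tryCatch(solve(diag(ns) - P, cvec), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f)) || any(f < -1e-9)) next
    best <- pmin(best, f)
  }
  best
}
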