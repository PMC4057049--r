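#' A finite screw-state decision process
#'
#' Perception-action control of the knee is cast as a finite Markov decision
#' process over screw states: in state `p` the controller chooses a screw
#' action `q`, pays the stage cost `R(p, q)` (by default the magnitude of
#' their virtual coefficient, the energy a unit wrench on `q` spends through
#' a unit twist about `p`), and moves to the transition state. The optimal
#' return satisfies the Bellman recursion
#' `f(p) = min_q { R(p, q) + gamma * f(T(p, q)) }`,
#' and the minimizing `q(p)` is the optimal policy. The printed recursion in
#' this tradition carries no explicit discount or horizon; the process is
#' implemented with absorbing terminal states and an optional discount
#' `gamma` in (0, 1] (default 1 with terminals).
#'
#' @param states List of screws (or state labels).
#' @param actions List of screws (or action labels), shared across states.
#' @param transition Integer matrix `n_states x n_actions`: next-state index
#'   (`NA` = action unavailable in that state).
#' @param cost Numeric matrix `n_states x n_actions` of finite stage costs;
#'   if `NULL` and states/actions are screws, `|vc(state, action)|` is used.
#' @param terminal Logical vector marking absorbing zero-cost states.
#' @param gamma Discount in (0, 1].
#' @return An object of class `screw_mdp`.
#' @export
screw_mdp <- function(states, actions, transition, cost = NULL,
                      terminal = NULL, gamma = 1) {
  ns <- length(states); na <- length(actions)
  transition <- matrix(as.integer(transition), ns, na)
  if (any(!is.na(transition) & (transition < 1 | transition > ns))) {
    abort_input("transition indices must map into the state set")
  }
  if (is.null(cost)) {
    if (!all(vapply(states, is_screw, TRUE)) || !all(vapply(actions, is_screw, TRUE))) {
      abort_input("cost = NULL needs screw states and actions")
    }
    cost <- outer(seq_len(ns), seq_len(na),
                  Vectorize(function(i, j) abs(virtual_coefficient(states[[i]], actions[[j]]))))
  }
  cost <- matrix(as.numeric(cost), ns, na)
  if (any(!is.finite(cost[!is.na(transition)]))) abort_input("costs must be finite")
  if (is.null(terminal)) terminal <- rep(FALSE, ns)
  if (gamma <= 0 || gamma > 1) abort_input("gamma must be in (0, 1]")
  if (gamma == 1 && !any(terminal)) {
    abort_input("an undiscounted process needs at least one terminal state")
  }
  structure(list(states = states, actions = actions, transition = transition,
                 cost = cost, terminal = as.logical(terminal), gamma = gamma),
            class = "screw_mdp")
}

#' Value iteration for a screw decision process
#'
#' Iterates the Bellman recursion from an all-zero value function until the
#' sup-norm change between sweeps falls below `tol`; for nonnegative costs
#' the sweeps are monotone nondecreasing. The returned policy is greedy with
#' respect to the returned values, ties broken toward the lowest action
#' index.
#'
#' @param mdp A [screw_mdp()].
#' @param tol Positive convergence tolerance (sup norm).
#' @param max_iter Sweep budget.
#' @return Object of class `screw_policy`: `values`, `policy` (action index
#'   per state), `iterations`, `residual`.
#' @export
value_iteration <- function(mdp, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(mdp, "screw_mdp"))
  if (tol <= 0) abort_input("tol must be positive")
  ns <- nrow(mdp$transition)
  f <- rep(0, ns)
  residual <- Inf
  for (it in seq_len(max_iter)) {
    q <- mdp$cost + mdp$gamma * matrix(f[mdp$transition], ns)
    q[is.na(mdp$transition)] <- Inf
    fn <- apply(q, 1, min)
    fn[mdp$terminal] <- 0
    residual <- max(abs(fn - f))
    f <- fn
    if (residual < tol) break
  }
  if (residual >= tol) {
    rlang::abort(sprintf("value iteration did not converge in %d sweeps (last residual %.3g)",
                         max_iter, residual),
                 class = "screwgait_error_convergence")
  }
  q <- mdp$cost + mdp$gamma * matrix(f[mdp$transition], ns)
  q[is.na(mdp$transition)] <- Inf
  policy <- apply(q, 1, which.min)     # which.min takes the lowest index on ties
  policy[mdp$terminal] <- NA_integer_
  structure(list(values = f, policy = policy, iterations = it,
                 residual = residual, mdp = mdp),
            class = "screw_policy")
}

#' @export
print.screw_policy <- function(x, ...) {
  cat(sprintf("<screw_policy: %d states, converged in %d sweeps (residual %.3g)>\n",
              length(x$values), x$iterations, x$residual))
  invisible(x)
}

#' @rdname value_iteration
#' @param x A `screw_policy`.
#' @param ... Unused.
#' @export
tidy.screw_policy <- function(x, ...) {
  tibble::tibble(state = seq_along(x$values), value = x$values,
                 action = x$policy, terminal = x$mdp$terminal)
}

#' @rdname value_iteration
#' @export
glance.screw_policy <- function(x, ...) {
  tibble::tibble(n_states = length(x$values),
                 n_actions = ncol(x$mdp$transition),
                 iterations = x$iterations, residual = x$residual,
                 gamma = x$mdp$gamma)
}

#' Reciprocity-seeking stance policy
#'
#' For each frame of an IAK track, selects the candidate screw minimizing
#' the magnitude of its virtual coefficient with the frame's IAK: the
#' constraint or muscle line most nearly reciprocal to the current knee
#' freedom, i.e. the line along which a force disturbs the joint least.
#' Ties are broken toward the lowest candidate index and the rule is
#' recorded.
#'
#' @param iak_track A `twist_track` of IAK screws.
#' @param candidates Non-empty list of candidate screws (named or not).
#' @return A tibble `policy_trace`: per frame `frame`, `time`, `choice`
#'   (candidate index), `candidate` (name if available), `cost` (m), `tie`
#'   (was the minimum attained by several candidates). Frames with no valid
#'   rotation axis (null or translation-dominated) get `NA` rows.
#' @export
stance_policy <- function(iak_track, candidates) {
  if (!length(candidates)) abort_input("need at least one candidate screw")
  cand <- lapply(candidates, as_screw)
  nms <- names(candidates)
  if (is.null(nms)) nms <- as.character(seq_along(cand))
  invalid <- rep(FALSE, nrow(iak_track))
  if ("translation_dominated" %in% names(iak_track)) {
    invalid <- invalid | iak_track$translation_dominated
  }
  out <- purrr::map_dfr(seq_len(nrow(iak_track)), function(i) {
    s <- iak_track$screw[[i]]
    if (is.null(s) || invalid[i]) {
      return(tibble::tibble(frame = iak_track$frame[i], time = iak_track$time[i],
                            choice = NA_integer_, candidate = NA_character_,
                            cost = NA_real_, tie = NA))
    }
    costs <- vapply(cand, function(q) abs(virtual_coefficient(q, s)), 0)
    j <- which.min(costs)
    tibble::tibble(frame = iak_track$frame[i], time = iak_track$time[i],
                   choice = j, candidate = nms[j], cost = costs[j],
                   tie = sum(costs <= costs[j] + 1e-15) > 1)
  })
  class(out) <- c("policy_trace", class(out))
  out
}
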