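# Independent oracles used to cross-check the implementation.

# Literal re-derivation of the session domain score, written as a direct
# transcription of the rule over explicit status sets (independent of the
# vectorized implementation in R/scoring.R).
oracle_session_score <- function(ranks, status, L) {
  passed <- ranks[status == "passed"]
  working <- ranks[status == "working"]
  failed <- ranks[status == "failed"]
  hi_candidates <- c(passed, working)
  lo_candidates <- c(working, failed)
  if (length(hi_candidates) > 0 && length(lo_candidates) > 0) {
    hi <- max(hi_candidates)
    lo <- min(lo_candidates)
    hi_adj <- if (hi %in% passed) hi else max(hi - 1, 0)
    lo_adj <- max(lo - 1, 0)               # lo is working or failed by construction
  } else if (length(hi_candidates) > 0) {  # all tasks passed
    hi_adj <- max(passed)
    lo_adj <- max(passed)
  } else {                                 # all tasks failed
    hi_adj <- max(min(failed) - 1, 0)
    lo_adj <- hi_adj
  }
  (hi_adj + lo_adj) / 2 / L
}

# representative accuracy for each task status
acc_for_status <- function(status) {
  c(passed = 0.95, working = 0.65, failed = 0.20)[status]
}

# Enumerate every session of n_tasks distinct ranks out of 1..L crossed
# with every status pattern; returns a data.frame of cases.
enumerate_sessions <- function(L, n_tasks) {
  combs <- utils::combn(L, n_tasks)
  statuses <- c("passed", "working", "failed")
  patterns <- as.matrix(expand.grid(rep(list(statuses), n_tasks),
                                    stringsAsFactors = FALSE))
  list(combs = combs, patterns = patterns)
}

# Upper-tail Tukey p by direct numerical integration of the studentized
# range CDF at df = Inf: P(range of k std normals <= q) =
# k * Int phi(z) [Phi(z) - Phi(z - q)]^(k-1) dz.
oracle_tukey_p <- function(t_ratio, k) {
  q <- abs(t_ratio) * sqrt(2)
  cdf <- k * stats::integrate(
    function(z) stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q))^(k - 1),
    -Inf, Inf, rel.tol = 1e-10)$value
  1 - cdf
}

# Replay of the adaptive-difficulty state machine over an observed
# accuracy sequence: returns the rank that should have been practiced at
# each session. Used to check simulate_patient's emitted ranks.
replay_ranks <- function(accuracy, L, demotion_window = 3) {
  rank <- 1L; pass_count <- 0L; stall <- 0L; last <- -Inf
  out <- integer(length(accuracy))
  for (i in seq_along(accuracy)) {
    out[i] <- rank
    a <- accuracy[i]
    if (a >= 0.90) pass_count <- pass_count + 1L
    stall <- if (a > last) 0L else stall + 1L
    last <- a
    if (pass_count >= 2L) {
      rank <- min(rank + 1L, L); pass_count <- 0L; stall <- 0L; last <- -Inf
    } else if (a < 0.40 || stall >= demotion_window) {
      rank <- max(rank - 1L, 1L); pass_count <- 0L; stall <- 0L; last <- -Inf
    }
  }
  out
}
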