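# Independent oracles used to cross-check the implementation.
# These deliberately take the brute-force route: time-expanded graph
# search instead of safe intervals, explicit summation instead of the
# simulator, so that agreement is informative.

# Earliest arrival time from start to goal by BFS over (cell, time),
# against dynamic obstacles inflated by `safe_gap` (Chebyshev), with
# exchange conflicts forbidden, and requiring the goal to remain safe
# forever after arrival. Obstacles park at their final cell.
oracle_earliest_arrival <- function(grid, obstacles, start, goal,
                                    safe_gap = 1, horizon = 40) {
  pos_at <- function(tr, t) tr$path[min(t, tr$arrival) + 1L, ]
  obs_pos <- lapply(0:(horizon + 1L), function(t)
    if (length(obstacles)) t(vapply(obstacles, pos_at, integer(2), t = t))
    else matrix(integer(0), ncol = 2))
  cheb_ok <- function(rc, t) {
    p <- obs_pos[[min(t, horizon + 1L) + 1L]]
    nrow(p) == 0 ||
      all(pmax(abs(p[, 1] - rc[1]), abs(p[, 2] - rc[2])) > safe_gap)
  }
  exchange <- function(from, to, t) {
    p0 <- obs_pos[[min(t, horizon + 1L) + 1L]]
    p1 <- obs_pos[[min(t + 1L, horizon + 1L) + 1L]]
    nrow(p0) > 0 &&
      any(pmax(abs(p0[, 1] - to[1]), abs(p0[, 2] - to[2])) <= safe_gap &
          pmax(abs(p1[, 1] - from[1]), abs(p1[, 2] - from[2])) <= safe_gap)
  }
  goal_safe_forever <- function(t) {
    all(vapply(t:horizon, function(tt) cheb_ok(goal, tt), TRUE)) &&
      cheb_ok(goal, horizon + 1L)   # stationary past the horizon
  }
  key <- function(rc, t) paste(rc[1], rc[2], t)
  if (!cheb_ok(start, 0L)) return(Inf)
  frontier <- list(list(rc = start, t = 0L))
  seen <- new.env(parent = emptyenv())
  assign(key(start, 0L), TRUE, envir = seen)
  steps <- list(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  while (length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      if (identical(node$rc, goal) && goal_safe_forever(node$t))
        return(node$t)
      if (node$t >= horizon) next
      for (s in steps) {
        rc <- node$rc + s
        if (rc[1] < 0 || rc[1] >= grid$rows ||
            rc[2] < 0 || rc[2] >= grid$cols) next
        if (!cheb_ok(rc, node$t + 1L)) next
        if (exchange(node$rc, rc, node$t)) next
        k <- key(rc, node$t + 1L)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(rc = rc, t = node$t + 1L)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

# Expected number of target objects collected from one droplet in a
# single pass: sum over true contents (h, b) of the collection
# probability times h, truncated where the Poisson mass is negligible.
oracle_expected_collected_target <- function(lambda_t, lambda_b, precision,
                                             kmax = 30) {
  h <- 0:kmax
  b <- 0:kmax
  ph <- dpois(h, lambda_t)
  pb <- dpois(b, lambda_b)
  sum(outer(ph * h * precision^h, pb * (1 - precision)^b))
}

# Same truncated double sum for collected background objects.
oracle_expected_collected_background <- function(lambda_t, lambda_b,
                                                 precision, kmax = 30) {
  h <- 0:kmax
  b <- 0:kmax
  ph <- dpois(h, lambda_t)
  pb <- dpois(b, lambda_b)
  sum(outer(ph * precision^h, pb * b * (1 - precision)^b))
}
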