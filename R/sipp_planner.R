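#' Electrode grid for droplet routing
#'
#' The planner's world: a rows x cols grid of electrodes, 0-based
#' row-major coordinates, optionally with statically blocked cells.
#' Droplets occupy one electrode and move in unit steps to 4-neighbours
#' (diagonal motion is not an electrowetting primitive) or wait.
#'
#' @param rows,cols Grid dimensions (>= 1). The full chip is 128 x 128.
#' @param blocked Optional integer matrix of statically blocked cells,
#'   one `(row, col)` per row.
#' @return An object of class `dmf_grid`.
#' @export
dmf_grid <- function(rows = 128, cols = 128, blocked = NULL) {
  if (rows < 1 || cols < 1) stop("grid dimensions must be >= 1")
  if (!is.null(blocked)) {
    blocked <- matrix(as.integer(blocked), ncol = 2)
    if (any(blocked[, 1] < 0 | blocked[, 1] >= rows |
            blocked[, 2] < 0 | blocked[, 2] >= cols))
      stop("blocked cells outside the grid")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 blocked = blocked),
            class = "dmf_grid")
}

#' A timed droplet trajectory
#'
#' A sequence of grid cells at integer times 0, 1, 2, ...; consecutive
#' cells are equal (wait) or 4-neighbours (unit move). After its last
#' recorded time the droplet is parked at its final cell forever.
#'
#' @param path Integer matrix, one `(row, col)` per time step, first row
#'   is the position at t = 0.
#' @param droplet_id Identifier carried through planning and validation.
#' @return Object of class `trajectory` with fields `droplet_id`, `path`,
#'   `arrival` (last time index, = `nrow(path) - 1`).
#' @export
trajectory <- function(path, droplet_id = NA_character_) {
  path <- matrix(as.integer(path), ncol = 2)
  if (nrow(path) > 1) {
    d <- abs(diff(path))
    if (any(rowSums(d) > 1))
      stop("consecutive trajectory cells must be identical or 4-neighbours")
  }
  structure(list(droplet_id = droplet_id, path = path,
                 arrival = nrow(path) - 1L),
            class = "trajectory")
}

# position of a trajectory at integer time t (parked at goal after arrival)
.traj_at <- function(traj, t) {
  traj$path[min(t, traj$arrival) + 1L, ]
}

.chebyshev <- function(a, b) max(abs(a - b))

#' Build the safe-interval map for a set of dynamic obstacles
#'
#' A cell is unsafe at time t when any obstacle droplet then occupies a
#' cell within Chebyshev distance `safe_gap` of it: the merge-avoidance
#' safe distance of one electrode inflates every obstacle to a 3 x 3
#' block. An obstacle that has arrived blocks its (inflated) goal cell
#' forever. Safe intervals are the maximal complementary time windows per
#' cell, closed-open `[lo, hi)` with `hi = Inf` for the unbounded tail.
#'
#' @param grid A [dmf_grid()].
#' @param obstacles List of [trajectory()] objects already committed.
#' @param safe_gap Safe distance in electrodes (default 1, the chip's
#'   merge-avoidance distance; 0 reproduces classical SIPP occupancy).
#' @param horizon Latest time modelled explicitly; must exceed every
#'   obstacle's arrival time.
#' @return Object of class `safe_interval_map`.
#' @export
build_safe_intervals <- function(grid, obstacles = list(), safe_gap = 1,
                                 horizon = NULL) {
  max_arr <- if (length(obstacles)) max(vapply(obstacles, `[[`, 0L, "arrival")) else 0L
  if (is.null(horizon)) horizon <- max_arr + 4L * (grid$rows + grid$cols)
  if (horizon <= max_arr)
    stop("horizon must exceed the longest obstacle trajectory")
  nc <- grid$rows * grid$cols
  nt <- horizon + 1L
  unsafe <- matrix(FALSE, nrow = nc, ncol = nt)

  inflate <- function(rc) {
    rr <- max(0L, rc[1] - safe_gap):min(grid$rows - 1L, rc[1] + safe_gap)
    cc <- max(0L, rc[2] - safe_gap):min(grid$cols - 1L, rc[2] + safe_gap)
    as.vector(outer(rr, cc, function(r, c) r * grid$cols + c + 1L))
  }
  obstacle_pos <- vector("list", nt)
  for (t in 0:horizon) {
    obstacle_pos[[t + 1L]] <-
      if (length(obstacles))
        t(vapply(obstacles, .traj_at, integer(2), t = t))
      else matrix(integer(0), ncol = 2)
  }
  for (ob in obstacles) {
    for (t in 0:ob$arrival) unsafe[inflate(ob$path[t + 1L, ]), t + 1L] <- TRUE
    if (ob$arrival < horizon)   # parked at goal for the rest of time
      unsafe[inflate(ob$path[ob$arrival + 1L, ]), (ob$arrival + 2L):nt] <- TRUE
  }
  if (!is.null(grid$blocked))
    unsafe[grid$blocked[, 1] * grid$cols + grid$blocked[, 2] + 1L, ] <- TRUE

  intervals <- vector("list", nc)
  for (cell in seq_len(nc)) {
    r <- rle(unsafe[cell, ])
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    free <- !r$values
    if (!any(free)) {
      intervals[[cell]] <- matrix(numeric(0), ncol = 2)
      next
    }
    lo <- starts[free]
    hi <- ends[free]
    # an interval reaching the cap truly extends forever: all obstacles
    # are parked by then, so occupancy is stationary past the horizon
    hi[hi == nt] <- Inf
    intervals[[cell]] <- cbind(lo, hi)
  }
  structure(list(grid = grid, safe_gap = safe_gap, horizon = horizon,
                 intervals = intervals, obstacle_pos = obstacle_pos),
            class = "safe_interval_map")
}

# exchange conflict: moving from -> to over [tau, tau+1] crosses an
# obstacle's own move through the inflated region
.move_conflict <- function(sim, from, to, tau) {
  p0 <- sim$obstacle_pos[[min(tau, sim$horizon) + 1L]]
  p1 <- sim$obstacle_pos[[min(tau + 1L, sim$horizon) + 1L]]
  if (nrow(p0) == 0) return(FALSE)
  g <- sim$safe_gap
  any(pmax(abs(p0[, 1] - to[1]), abs(p0[, 2] - to[2])) <= g &
      pmax(abs(p1[, 1] - from[1]), abs(p1[, 2] - from[2])) <= g)
}

#' Single-droplet safe-interval A* search
#'
#' Plans a minimal-arrival-time trajectory from `start` to `goal` through
#' the safe-interval map: A* over (cell, safe interval) states with the
#' Manhattan-distance heuristic, waits allowed inside an interval, and
#' transitions rejected when they would cross an obstacle's simultaneous
#' move through the inflated region. The goal must be occupiable forever
#' (its arrival interval unbounded), since a routed droplet parks there.
#'
#' @param start,goal Cells as `(row, col)` 0-based integer pairs.
#' @param sim A [build_safe_intervals()] map.
#' @param horizon Give up (infeasible) if no arrival by this time.
#' @return A [trajectory()] on success, or an object of class
#'   `sipp_infeasible` (with `$reason`) when no path exists.
#' @export
sipp_search <- function(start, goal, sim, horizon = sim$horizon) {
  grid <- sim$grid
  cols <- grid$cols
  cell_id <- function(rc) rc[1] * cols + rc[2] + 1L
  infeasible <- function(reason)
    structure(list(ok = FALSE, reason = reason), class = "sipp_infeasible")

  s_id <- cell_id(start)
  g_id <- cell_id(goal)
  ivs <- sim$intervals
  s_ivs <- ivs[[s_id]]
  s_int <- which(s_ivs[, 1] <= 0 & s_ivs[, 2] > 0)
  if (length(s_int) == 0) return(infeasible("start not safe at t = 0"))
  if (nrow(ivs[[g_id]]) == 0 || !is.infinite(ivs[[g_id]][nrow(ivs[[g_id]]), 2]))
    return(infeasible("goal is never permanently safe"))

  max_iv <- max(vapply(ivs, nrow, 0L), 1L)
  sid <- function(cell, k) (cell - 1L) * max_iv + k
  nstate <- (grid$rows * cols) * max_iv
  gsc <- rep(Inf, nstate)
  parent <- integer(nstate)
  closed <- logical(nstate)

  h_of <- function(cell) {
    r <- (cell - 1L) %/% cols
    c <- (cell - 1L) %% cols
    abs(r - goal[1]) + abs(c - goal[2])
  }
  # open list as growable parallel vectors; pop by linear min scan
  open_s <- sid(s_id, s_int[1])
  open_f <- h_of(s_id)
  gsc[open_s] <- 0

  repeat {
    if (length(open_s) == 0) return(infeasible("search space exhausted"))
    j <- which.min(open_f)
    cur <- open_s[j]
    open_s <- open_s[-j]; open_f <- open_f[-j]
    if (closed[cur]) next
    closed[cur] <- TRUE
    cell <- (cur - 1L) %/% max_iv + 1L
    k <- (cur - 1L) %% max_iv + 1L
    t <- gsc[cur]
    if (t > horizon) return(infeasible("horizon exceeded"))
    if (cell == g_id && is.infinite(ivs[[cell]][k, 2])) {
      # reconstruct: walk parents, fill waits between arrivals
      chain_cell <- integer(0); chain_t <- numeric(0)
      node <- cur
      while (node != 0L) {
        chain_cell <- c((node - 1L) %/% max_iv + 1L, chain_cell)
        chain_t <- c(gsc[node], chain_t)
        node <- parent[node]
      }
      path <- matrix(0L, nrow = t + 1L, ncol = 2)
      for (i in seq_along(chain_cell)) {
        ce <- chain_cell[i]
        rc <- c((ce - 1L) %/% cols, (ce - 1L) %% cols)
        t_from <- chain_t[i]
        t_to <- if (i < length(chain_cell)) chain_t[i + 1L] - 1L else t
        if (t_to >= t_from)
          path[(t_from:t_to) + 1L, ] <- matrix(rc, t_to - t_from + 1L, 2,
                                               byrow = TRUE)
      }
      return(trajectory(path))
    }
    hi <- ivs[[cell]][k, 2]
    rc <- c((cell - 1L) %/% cols, (cell - 1L) %% cols)
    for (step in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nb <- rc + step
      if (nb[1] < 0 || nb[1] >= grid$rows || nb[2] < 0 || nb[2] >= cols) next
      nb_id <- cell_id(nb)
      nb_ivs <- ivs[[nb_id]]
      if (nrow(nb_ivs) == 0) next
      for (kk in seq_len(nrow(nb_ivs))) {
        lo2 <- nb_ivs[kk, 1]; hi2 <- nb_ivs[kk, 2]
        arr <- max(t + 1, lo2)          # earliest arrival in this interval
        if (arr >= hi2 || arr > hi) next  # depart at arr-1 must be inside [.., hi)
        # advance past exchange conflicts with simultaneous obstacle moves
        while (arr < hi2 && arr <= hi && arr <= horizon + 1 &&
               .move_conflict(sim, rc, nb, arr - 1)) arr <- arr + 1
        if (arr >= hi2 || arr > hi || arr > horizon + 1) next
        ns <- sid(nb_id, kk)
        if (!closed[ns] && arr < gsc[ns]) {
          gsc[ns] <- arr
          parent[ns] <- cur
          open_s <- c(open_s, ns)
          open_f <- c(open_f, arr + h_of(nb_id))
        }
      }
    }
  }
}

#' A multi-droplet routing request
#'
#' @param starts,goals Named lists (by droplet id) of `(row, col)` cells.
#'   Starts must pairwise respect the safe gap, as must goals.
#' @param safe_gap Safe distance in electrodes (default 1).
#' @param horizon Optional planning horizon.
#' @return Object of class `plan_request`.
#' @export
plan_request <- function(starts, goals, safe_gap = 1, horizon = NULL) {
  if (!setequal(names(starts), names(goals)) || is.null(names(starts)))
    stop("starts and goals must be named by the same droplet ids")
  check_sep <- function(cells, what) {
    ids <- names(cells)
    for (i in seq_along(cells)) for (j in seq_len(i - 1L)) {
      if (.chebyshev(cells[[i]], cells[[j]]) <= safe_gap)
        stop(sprintf("%s of droplets '%s' and '%s' violate the safe gap",
                     what, ids[i], ids[j]))
    }
  }
  check_sep(starts, "starts")
  check_sep(goals, "goals")
  structure(list(starts = starts, goals = goals[names(starts)],
                 safe_gap = safe_gap, horizon = horizon),
            class = "plan_request")
}

#' Prioritised multi-droplet planning with SIPP
#'
#' Plans droplets one at a time. Each planned trajectory becomes a
#' dynamic obstacle for the droplets planned after it; droplets not yet
#' planned are treated as obstacles parked at their start cells. The
#' default priority plans droplets in ascending order of Manhattan
#' start-to-goal distance, ties broken by id.
#'
#' @param request A [plan_request()].
#' @param grid A [dmf_grid()].
#' @param obstacles Extra pre-existing [trajectory()] obstacles.
#' @param priority Either `"distance"` (default) or a character vector of
#'   droplet ids giving an explicit order.
#' @return List with `ok` (logical), `trajectories` (named list, possibly
#'   partial), and on failure `failed` (the first unroutable droplet id)
#'   and `reason`.
#' @export
plan_all <- function(request, grid, obstacles = list(),
                     priority = "distance") {
  ids <- names(request$starts)
  if (identical(priority, "distance")) {
    dist <- vapply(ids, function(i)
      sum(abs(request$starts[[i]] - request$goals[[i]])), 0)
    order_ids <- ids[order(dist, ids)]
  } else {
    if (!setequal(priority, ids)) stop("priority must permute the droplet ids")
    order_ids <- priority
  }
  parked <- function(id) trajectory(matrix(request$starts[[id]], 1), id)
  planned <- list()
  horizon <- request$horizon
  if (is.null(horizon)) horizon <- 6L * (grid$rows + grid$cols)
  for (pos in seq_along(order_ids)) {
    id <- order_ids[pos]
    pending <- order_ids[-seq_len(pos)]
    obs <- c(obstacles, unname(planned), lapply(pending, parked))
    sim <- build_safe_intervals(grid, obs, request$safe_gap,
                                horizon = horizon)
    res <- sipp_search(request$starts[[id]], request$goals[[id]], sim)
    if (inherits(res, "sipp_infeasible")) {
      return(list(ok = FALSE, trajectories = planned, failed = id,
                  reason = res$reason))
    }
    res$droplet_id <- id
    planned[[id]] <- res
  }
  list(ok = TRUE, trajectories = planned)
}

#' Validate a multi-droplet plan against the merge-avoidance rule
#'
#' Checks, at every integer time up to the latest arrival, that all
#' droplet pairs keep Chebyshev distance strictly greater than
#' `safe_gap` (i.e. at least `safe_gap` empty electrodes between them),
#' and that no pair exchanges positions through the inflated region
#' between consecutive times. Shorter trajectories are padded at their
#' goals.
#'
#' @param trajectories Named list of [trajectory()] objects.
#' @param safe_gap Safe distance in electrodes.
#' @return List with `ok`, a data frame `violations` (`time`, `id1`,
#'   `id2`, `type`), and `min_clearance`: the minimum number of empty
#'   electrodes between any pair at any time (`Inf` for < 2 droplets).
#' @export
validate_plan <- function(trajectories, safe_gap = 1) {
  n <- length(trajectories)
  ids <- vapply(trajectories, function(tr)
    as.character(tr$droplet_id), "")
  if (n < 2)
    return(list(ok = TRUE,
                violations = data.frame(time = integer(0), id1 = character(0),
                                        id2 = character(0), type = character(0)),
                min_clearance = Inf))
  tmax <- max(vapply(trajectories, `[[`, 0L, "arrival"))
  viol <- list()
  min_clear <- Inf
  pos <- lapply(0:tmax, function(t)
    t(vapply(trajectories, .traj_at, integer(2), t = t)))
  for (t in 0:tmax) {
    p <- pos[[t + 1L]]
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      d <- max(abs(p[i, ] - p[j, ]))
      min_clear <- min(min_clear, d - 1)
      if (d <= safe_gap)
        viol[[length(viol) + 1L]] <- data.frame(
          time = t, id1 = ids[i], id2 = ids[j], type = "proximity")
    }
    if (t < tmax) {
      q <- pos[[t + 2L]]
      for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
        if (max(abs(q[i, ] - p[j, ])) <= safe_gap &&
            max(abs(p[i, ] - q[j, ])) <= safe_gap)
          viol[[length(viol) + 1L]] <- data.frame(
            time = t, id1 = ids[i], id2 = ids[j], type = "exchange")
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(time = integer(0), id1 = character(0),
                    id2 = character(0), type = character(0))
  list(ok = nrow(violations) == 0, violations = violations,
       min_clearance = min_clear)
}

#' Default sorting zones on the electrode grid
#'
#' Slot layout for routing classified droplets: collection slots
#' (`TARGET_ONLY`) along the east edge, waste slots along the west edge
#' (`BACKGROUND_ONLY` on column 0, `EMPTY` two columns in), and retained
#' (`MIXED`) slots along the centre column. Slots are spaced every
#' `spacing` rows so that all pairs respect a safe gap of `spacing - 1`.
#'
#' @param grid A [dmf_grid()].
#' @param spacing Row spacing between slots (default 2, matching the
#'   1-electrode safe distance).
#' @return Named list mapping each droplet label to a slot matrix.
#' @export
default_zones <- function(grid, spacing = 2) {
  rows <- seq(0L, grid$rows - 1L, by = spacing)
  col_slots <- function(col) cbind(rows, rep(as.integer(col), length(rows)))
  list(TARGET_ONLY = col_slots(grid$cols - 1L),
       BACKGROUND_ONLY = col_slots(0L),
       EMPTY = col_slots(2L),
       MIXED = col_slots(grid$cols %/% 2L))
}

#' Assign classified droplets to zone slots
#'
#' Deterministic goal assignment: droplets are processed in sorted id
#' order, and each takes the nearest (Manhattan distance from its start)
#' still-free slot in its class's zone, ties broken by slot order
#' (row-major as produced by [default_zones()]).
#'
#' @param starts Named list (droplet id -> `(row, col)`) of current cells.
#' @param labels Named character vector (droplet id -> predicted label).
#' @param zones Named list of slot matrices, as from [default_zones()].
#' @return Named list droplet id -> goal cell.
#' @export
assign_goals <- function(starts, labels, zones) {
  ids <- sort(names(starts))
  if (!all(ids %in% names(labels))) stop("every droplet needs a label")
  used <- lapply(zones, function(z) logical(nrow(z)))
  goals <- list()
  for (id in ids) {
    lab <- labels[[id]]
    z <- zones[[lab]]
    if (is.null(z)) stop(sprintf("no zone defined for label '%s'", lab))
    free <- which(!used[[lab]])
    if (length(free) == 0)
      stop(sprintf("zone capacity exceeded for label '%s'", lab))
    d <- abs(z[free, 1] - starts[[id]][1]) + abs(z[free, 2] - starts[[id]][2])
    pick <- free[which.min(d)]   # which.min takes the first = row-major tie-break
    used[[lab]][pick] <- TRUE
    goals[[id]] <- z[pick, ]
  }
  goals
}

#' Generate a random feasible planner instance
#'
#' Samples `n_droplets` start and goal cells on an open grid such that
#' all sampled cells (starts and goals together) pairwise respect the
#' safe gap, which keeps prioritised planning feasible with high
#' probability on sparsely-populated grids.
#'
#' @param rows,cols Grid dimensions.
#' @param n_droplets Number of droplets.
#' @param safe_gap Safe distance in electrodes.
#' @return List with `grid`, `request`.
#' @export
random_planner_instance <- function(rows, cols, n_droplets, safe_gap = 1) {
  grid <- dmf_grid(rows, cols)
  need <- 2L * n_droplets
  cells <- list()
  tries <- 0L
  while (length(cells) < need) {
    cand <- c(sample.int(rows, 1) - 1L, sample.int(cols, 1) - 1L)
    ok <- all(vapply(cells, function(x) .chebyshev(x, cand) > safe_gap, TRUE))
    if (ok) cells[[length(cells) + 1L]] <- cand
    tries <- tries + 1L
    if (tries > 10000L) stop("grid too dense to place droplets with the safe gap")
  }
  ids <- sprintf("d%02d", seq_len(n_droplets))
  starts <- stats::setNames(cells[seq_len(n_droplets)], ids)
  goals <- stats::setNames(cells[n_droplets + seq_len(n_droplets)], ids)
  list(grid = grid, request = plan_request(starts, goals, safe_gap))
}
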