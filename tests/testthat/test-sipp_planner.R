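test_that("safe intervals: free grid, parked obstacles, passing obstacles", {
  g <- dmf_grid(5, 5)
  sim <- build_safe_intervals(g, list(), safe_gap = 1)
  expect_true(all(vapply(sim$intervals, function(iv)
    nrow(iv) == 1 && iv[1, 1] == 0 && is.infinite(iv[1, 2]), TRUE)))

  # obstacle parked at (2,2) forever: its 3x3 inflated block is never safe
  ob <- trajectory(matrix(c(2L, 2L), 1), "ob")
  sim2 <- build_safe_intervals(g, list(ob), safe_gap = 1)
  for (r in 0:4) for (c in 0:4) {
    iv <- sim2$intervals[[r * 5 + c + 1]]
    if (max(abs(c(r, c) - c(2, 2))) <= 1) {
      expect_equal(nrow(iv), 0)
    } else {
      expect_equal(nrow(iv), 1)
      expect_true(is.infinite(iv[1, 2]))
    }
  }

  # obstacle passing through (1,2) at t = 2, gap 0: split intervals [0,2), [3,Inf)
  g3 <- dmf_grid(3, 5)
  obp <- trajectory(rbind(c(0L, 2L), c(0L, 2L), c(1L, 2L), c(2L, 2L)), "x")
  sim3 <- build_safe_intervals(g3, list(obp), safe_gap = 0)
  expect_equal(sim3$intervals[[1 * 5 + 2 + 1]], cbind(lo = c(0, 3), hi = c(2, Inf)),
               ignore_attr = TRUE)

  # statically blocked cell has no safe interval
  gb <- dmf_grid(4, 4, blocked = rbind(c(1L, 1L)))
  simb <- build_safe_intervals(gb, list(), safe_gap = 1)
  expect_equal(nrow(simb$intervals[[1 * 4 + 1 + 1]]), 0)
})

test_that("single-agent search attains the Manhattan bound on open grids", {
  g <- dmf_grid(5, 5)
  sim <- build_safe_intervals(g, list(), safe_gap = 1)
  tr <- sipp_search(c(0L, 0L), c(4L, 4L), sim)
  expect_s3_class(tr, "trajectory")
  expect_equal(tr$arrival, 8)

  # random start/goal pairs on random open grids
  set.seed(50)
  for (k in 1:20) {
    rows <- sample(4:10, 1); cols <- sample(4:10, 1)
    s <- c(sample(rows, 1) - 1L, sample(cols, 1) - 1L)
    gl <- c(sample(rows, 1) - 1L, sample(cols, 1) - 1L)
    simk <- build_safe_intervals(dmf_grid(rows, cols), list(), safe_gap = 1)
    trk <- sipp_search(s, gl, simk)
    expect_equal(trk$arrival, sum(abs(s - gl)))
  }
})

test_that("unreachable goals are reported infeasible, not as errors", {
  g <- dmf_grid(5, 5)
  ob <- trajectory(matrix(c(2L, 2L), 1), "ob")
  sim <- build_safe_intervals(g, list(ob), safe_gap = 1)
  res <- sipp_search(c(0L, 0L), c(2L, 2L), sim)
  expect_s3_class(res, "sipp_infeasible")
  expect_match(res$reason, "never permanently safe")
})

test_that("search arrival equals time-expanded BFS oracle with dynamic obstacles", {
  set.seed(51)
  checked <- 0
  for (k in 1:15) {
    rows <- sample(5:8, 1); cols <- sample(5:8, 1)
    g <- dmf_grid(rows, cols)
    # one moving obstacle: straight sweep along a random row
    orow <- sample(rows, 1) - 1L
    path <- cbind(rep(orow, cols), 0:(cols - 1L))
    ob <- trajectory(path, "ob")
    gap <- sample(0:1, 1)
    start <- c(sample(rows, 1) - 1L, sample(cols, 1) - 1L)
    goal <- c(sample(rows, 1) - 1L, sample(cols, 1) - 1L)
    sim <- build_safe_intervals(g, list(ob), safe_gap = gap)
    res <- sipp_search(start, goal, sim, horizon = 40)
    oracle <- oracle_earliest_arrival(g, list(ob), start, goal,
                                      safe_gap = gap, horizon = 40)
    if (inherits(res, "sipp_infeasible")) {
      expect_equal(oracle, Inf)
    } else {
      expect_equal(res$arrival, oracle)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 5)   # the comparison must actually bite
})

test_that("a crossing obstacle forces a wait and the optimum is still met", {
  # corridor row 1 of a 3x5 grid; obstacle cuts across column 2
  g <- dmf_grid(3, 5)
  ob <- trajectory(rbind(c(0L, 2L), c(0L, 2L), c(1L, 2L), c(2L, 2L)), "x")
  sim <- build_safe_intervals(g, list(ob), safe_gap = 0)
  tr <- sipp_search(c(1L, 0L), c(1L, 4L), sim, horizon = 40)
  oracle <- oracle_earliest_arrival(g, list(ob), c(1L, 0L), c(1L, 4L),
                                    safe_gap = 0, horizon = 40)
  expect_equal(tr$arrival, oracle)
  expect_gt(tr$arrival, 4)   # strictly above the Manhattan bound: waited or detoured
  # trajectory is well-formed: unit moves or waits only
  expect_s3_class(trajectory(tr$path), "trajectory")
})

test_that("prioritised planning resolves crossing shortest paths", {
  starts <- list(a = c(3L, 0L), b = c(0L, 3L))
  goals <- list(a = c(3L, 6L), b = c(6L, 3L))
  req <- plan_request(starts, goals, safe_gap = 1)
  pl <- plan_all(req, dmf_grid(7, 7))
  expect_true(pl$ok)
  v <- validate_plan(pl$trajectories, safe_gap = 1)
  expect_true(v$ok)
  expect_gte(v$min_clearance, 1)
  man <- sum(abs(starts$a - goals$a)) + sum(abs(starts$b - goals$b))
  total <- sum(vapply(pl$trajectories, `[[`, 0L, "arrival"))
  expect_gte(total, man)

  # single droplet degenerates to plain search
  req1 <- plan_request(list(a = c(0L, 0L)), list(a = c(4L, 4L)))
  pl1 <- plan_all(req1, dmf_grid(5, 5))
  expect_equal(pl1$trajectories$a$arrival, 8)

  # starts already at goals: zero-length waits
  req0 <- plan_request(list(a = c(0L, 0L), b = c(4L, 4L)),
                       list(a = c(0L, 0L), b = c(4L, 4L)))
  pl0 <- plan_all(req0, dmf_grid(5, 5))
  expect_true(pl0$ok)
  expect_equal(pl0$trajectories$a$arrival, 0)
  expect_equal(pl0$trajectories$b$arrival, 0)
})

test_that("plan validation flags proximity and exchange violations", {
  # parked one apart (edge-adjacent): proximity violation
  t1 <- trajectory(matrix(c(0L, 0L), 1), "a")
  t2 <- trajectory(matrix(c(0L, 1L), 1), "b")
  v <- validate_plan(list(a = t1, b = t2), safe_gap = 1)
  expect_false(v$ok)
  expect_true(all(v$violations$type == "proximity"))

  # parked two apart (one empty electrode between): fine at gap 1
  t3 <- trajectory(matrix(c(0L, 2L), 1), "c")
  v2 <- validate_plan(list(a = t1, c = t3), safe_gap = 1)
  expect_true(v2$ok)
  expect_equal(v2$min_clearance, 1)

  # head-on swap through each other: exchange violation at gap 0
  ta <- trajectory(rbind(c(0L, 0L), c(0L, 1L)), "a")
  tb <- trajectory(rbind(c(0L, 1L), c(0L, 0L)), "b")
  v3 <- validate_plan(list(a = ta, b = tb), safe_gap = 0)
  expect_false(v3$ok)
  expect_true("exchange" %in% v3$violations$type)
})

test_that("fuzzed multi-droplet instances always yield valid plans", {
  set.seed(60)
  n_ok <- 0
  for (k in 1:40) {
    size <- sample(12:20, 1)
    nd <- sample(3:10, 1)
    inst <- random_planner_instance(size, size, nd, safe_gap = 1)
    pl <- plan_all(inst$request, inst$grid)
    if (!pl$ok) next   # prioritised planning is incomplete; skip rare failures
    v <- validate_plan(pl$trajectories, safe_gap = 1)
    expect_true(v$ok)
    expect_gte(v$min_clearance, 1)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 35)
})

test_that("plan validity is priority-order independent", {
  set.seed(61)
  inst <- random_planner_instance(10, 10, 3, safe_gap = 1)
  ids <- names(inst$request$starts)
  perms <- list(ids, rev(ids), ids[c(2, 3, 1)])
  for (ord in perms) {
    pl <- plan_all(inst$request, inst$grid, priority = ord)
    if (pl$ok) expect_true(validate_plan(pl$trajectories, 1)$ok)
  }
})

test_that("goal assignment is deterministic, injective and gap-safe", {
  g <- dmf_grid(128, 128)
  zones <- default_zones(g)
  starts <- list(d1 = c(10L, 60L), d2 = c(12L, 60L), d3 = c(40L, 60L))
  labels <- c(d1 = "TARGET_ONLY", d2 = "TARGET_ONLY", d3 = "BACKGROUND_ONLY")
  goals <- assign_goals(starts, labels, zones)
  # nearest east-edge slot for the target droplet
  expect_equal(unname(goals$d1), c(10L, 127L))
  # same-class droplets get distinct slots
  expect_false(identical(goals$d1, goals$d2))
  expect_equal(unname(goals$d3[2]), 0L)

  # a full 64-droplet array: assignment succeeds, goals pairwise gap-safe
  set.seed(62)
  arr <- sample_array(loading_spec(1, ratio = 1), 64)
  labs <- true_label(arr)
  ids <- sprintf("d%02d", 1:64)
  # droplets parked on the array region, spaced 2 apart
  sts <- setNames(lapply(1:64, function(i)
    c(2L * ((i - 1L) %/% 8L) + 40L, 2L * ((i - 1L) %% 8L) + 40L)), ids)
  gls <- assign_goals(sts, setNames(labs, ids), default_zones(g))
  expect_length(gls, 64)
  gm <- do.call(rbind, gls)
  for (i in 1:63) for (j in (i + 1):64) {
    expect_gt(max(abs(gm[i, ] - gm[j, ])), 1)
  }

  # capacity overflow is a clear error
  tiny <- list(TARGET_ONLY = rbind(c(0L, 0L)))
  expect_error(assign_goals(list(a = c(0L, 1L), b = c(0L, 3L)),
                            c(a = "TARGET_ONLY", b = "TARGET_ONLY"), tiny),
               "capacity")
})

test_that("plan request enforces the pairwise safe gap on starts and goals", {
  expect_error(plan_request(list(a = c(0L, 0L), b = c(0L, 1L)),
                            list(a = c(4L, 4L), b = c(4L, 0L))),
               "safe gap")
  expect_error(plan_request(list(a = c(0L, 0L)), list(b = c(1L, 1L))),
               "same droplet ids")
})
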