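#' Sorting policy: droplet fates and cycle count
#'
#' Maps each predicted droplet label to a fate. The default policy
#' collects predicted target-only droplets, wastes predicted empty and
#' background-only droplets, and retains predicted mixed droplets for the
#' next cycle, where they are pooled with fresh empty droplets (which act
#' as diluents, lowering the occupancy mean) and re-split into a full
#' array.
#'
#' @param n_droplets Array size rebuilt every cycle (default 64).
#' @param n_cycles Number of sort-collect-replenish cycles.
#' @param fates Named character vector mapping every label in
#'   [DROPLET_LABELS] to one of `"collect"`, `"waste"`, `"retain"`.
#' @return An object of class `sorting_policy`.
#' @export
sorting_policy <- function(n_droplets = 64, n_cycles = 1,
                           fates = c(EMPTY = "waste",
                                     TARGET_ONLY = "collect",
                                     BACKGROUND_ONLY = "waste",
                                     MIXED = "retain")) {
  if (!setequal(names(fates), DROPLET_LABELS))
    stop("fates must name every droplet label exactly once")
  if (!all(fates %in% c("collect", "waste", "retain")))
    stop("fates must be 'collect', 'waste' or 'retain'")
  if (n_droplets < 1 || n_cycles < 0) stop("n_droplets >= 1, n_cycles >= 0")
  structure(list(n_droplets = as.integer(n_droplets),
                 n_cycles = as.integer(n_cycles),
                 fates = fates[DROPLET_LABELS]),
            class = "sorting_policy")
}

#' Fate map for a background-depletion (pre-sorting) pass
#'
#' In a pre-sorting pass the abundant background class is the one being
#' removed: predicted background-only droplets go to waste, predicted
#' target-only droplets are retained (not collected, so no target is
#' committed yet), mixed droplets are retained, empties are wasted.
#'
#' @return Named fate vector usable in [sorting_policy()].
#' @export
presort_fates <- function() {
  c(EMPTY = "waste", TARGET_ONLY = "retain",
    BACKGROUND_ONLY = "waste", MIXED = "retain")
}

#' Initialise the sorting state
#'
#' Samples the initial droplet array and records the ground-truth species
#' totals against which recovery is later measured.
#'
#' @param spec A [loading_spec()].
#' @param policy A [sorting_policy()].
#' @return An object of class `sorting_state`: the current droplet array,
#'   cumulative collected/wasted tallies per species, the initial totals,
#'   the cycle index and the per-cycle occupancy-mean history.
#' @export
init_state <- function(spec, policy = sorting_policy()) {
  droplets <- sample_array(spec, policy$n_droplets)
  tot <- colSums(droplets)
  structure(list(
    cycle_index = 0L,
    droplets = droplets,
    collected = c(target = 0L, background = 0L),
    wasted = c(target = 0L, background = 0L),
    initial = c(target = tot[[1]], background = tot[[2]]),
    lambda_history = data.frame(cycle = 0L,
                                lambda_target = tot[[1]] / policy$n_droplets,
                                lambda_background = tot[[2]] / policy$n_droplets)),
    class = "sorting_state")
}

#' @export
print.sorting_state <- function(x, ...) {
  m <- sorting_metrics(x)
  cat(sprintf(
    "sorting_state: cycle %d | collected %d/%d target, %d background | recovery %.3f, purity %s\n",
    x$cycle_index, x$collected[["target"]], x$initial[["target"]],
    x$collected[["background"]],
    m$recovery, ifelse(is.na(m$purity), "NA", sprintf("%.3f", m$purity))))
  invisible(x)
}

# collected + wasted + on-array must equal the initial totals, per species
.check_conservation <- function(state) {
  onchip <- colSums(state$droplets)
  ok <- all(state$collected + state$wasted +
              c(onchip[[1]], onchip[[2]]) == state$initial)
  if (!ok) stop("internal consistency error: species tallies do not balance")
  invisible(TRUE)
}

#' Run one sort-collect-replenish cycle
#'
#' One cycle comprises: (1) read every droplet with the virtual
#' classifier; (2) apply the policy's fates, moving each droplet's true
#' contents to the collected or wasted tallies or keeping them on chip;
#' (3) pool the retained droplets with fresh empty droplets (diluents
#' carrying neither species) back up to a full array; (4) re-split the
#' pooled objects, each retained object landing in one of the
#' `n_droplets` droplets uniformly at random; (5) recompute the occupancy
#' means from the retained counts and append them to the history.
#' Classifier errors are redrawn independently every cycle.
#'
#' @param state A `sorting_state`.
#' @param classifier A [classifier_spec()].
#' @param policy A [sorting_policy()].
#' @return The advanced `sorting_state`.
#' @export
run_cycle <- function(state, classifier = classifier_spec(),
                      policy = sorting_policy()) {
  .check_conservation(state)
  det <- detect_array(state$droplets, classifier)
  fate <- unname(policy$fates[det$predicted_label])

  add_tally <- function(rows) {
    if (!any(rows)) return(c(target = 0L, background = 0L))
    s <- colSums(state$droplets[rows, , drop = FALSE])
    c(target = s[[1]], background = s[[2]])
  }
  state$collected <- state$collected + add_tally(fate == "collect")
  state$wasted <- state$wasted + add_tally(fate == "waste")

  pooled <- add_tally(fate == "retain")
  n <- policy$n_droplets
  # uniform multinomial re-split of the pooled objects over a fresh array
  state$droplets <- cbind(
    n_target = as.integer(stats::rmultinom(1, pooled[["target"]], rep(1, n))),
    n_background = as.integer(stats::rmultinom(1, pooled[["background"]], rep(1, n))))
  state$cycle_index <- state$cycle_index + 1L
  state$lambda_history <- rbind(
    state$lambda_history,
    data.frame(cycle = state$cycle_index,
               lambda_target = pooled[["target"]] / n,
               lambda_background = pooled[["background"]] / n))
  .check_conservation(state)
  state
}

#' Recovery and purity of a sorting state
#'
#' Recovery is the fraction of all target cells initially in the sample
#' that have been collected; purity is the fraction of collected objects
#' that are target cells. Purity is `NA` when nothing has been collected;
#' recovery is `NA` when the sample held no target cells.
#'
#' @param state A `sorting_state`.
#' @return List with numeric fields `recovery` and `purity`.
#' @export
sorting_metrics <- function(state) {
  ct <- state$collected[["target"]]
  cb <- state$collected[["background"]]
  it <- state$initial[["target"]]
  list(recovery = if (it > 0) ct / it else NA_real_,
       purity = if (ct + cb > 0) ct / (ct + cb) else NA_real_)
}

# deterministic per-replicate seed derived from (root, i); kept < 2^31
.child_seed <- function(root_seed, i) {
  (as.double(root_seed) * 48271 + i * 16807) %% 2147483647
}

#' Run a replicated multi-cycle sorting simulation
#'
#' Runs `policy$n_cycles` cycles of the sorting engine for each of
#' `n_replicates` independent replicates, recording recovery and purity
#' after every cycle. Each replicate uses its own seed derived
#' deterministically from `root_seed`, so the whole table is reproducible.
#'
#' @param spec A [loading_spec()].
#' @param classifier A [classifier_spec()].
#' @param policy A [sorting_policy()] (its `n_cycles` sets the horizon).
#' @param n_replicates Independent repetitions (default 10).
#' @param root_seed Integer seed governing all randomness.
#' @return Tidy data frame with one row per (replicate, cycle):
#'   `replicate`, `cycle`, `recovery`, `purity`, `lambda_target`,
#'   `lambda_background`, `collected_target`, `collected_background`.
#' @examples
#' tab <- run_sorting(loading_spec(1, ratio = 1),
#'                    classifier_spec(0.985),
#'                    sorting_policy(n_cycles = 4), n_replicates = 10,
#'                    root_seed = 1)
#' aggregate(cbind(recovery, purity) ~ cycle, tab, mean)
#' @export
run_sorting <- function(spec, classifier = classifier_spec(),
                        policy = sorting_policy(), n_replicates = 10,
                        root_seed = 1) {
  rows <- vector("list", n_replicates * policy$n_cycles)
  k <- 0L
  for (i in seq_len(n_replicates)) {
    set.seed(.child_seed(root_seed, i))
    st <- init_state(spec, policy)
    for (cy in seq_len(policy$n_cycles)) {
      st <- run_cycle(st, classifier, policy)
      m <- sorting_metrics(st)
      lam <- st$lambda_history[st$lambda_history$cycle == cy, ]
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = i, cycle = cy,
        recovery = m$recovery, purity = m$purity,
        lambda_target = lam$lambda_target,
        lambda_background = lam$lambda_background,
        collected_target = st$collected[["target"]],
        collected_background = st$collected[["background"]])
    }
  }
  do.call(rbind, rows)
}

#' Per-cycle summary of a replicated sorting run
#'
#' Means and standard deviations of recovery and purity across
#' replicates, per cycle. Replicates with undefined purity (nothing
#' collected yet) are dropped from the purity average rather than counted
#' as zero.
#'
#' @param table Output of [run_sorting()].
#' @return Data frame with one row per cycle: `cycle`, `mean_recovery`,
#'   `sd_recovery`, `mean_purity`, `sd_purity`, `n_replicates`.
#' @export
sorting_summary <- function(table) {
  out <- lapply(split(table, table$cycle), function(d) {
    data.frame(cycle = d$cycle[1],
               mean_recovery = mean(d$recovery, na.rm = TRUE),
               sd_recovery = stats::sd(d$recovery, na.rm = TRUE),
               mean_purity = mean(d$purity, na.rm = TRUE),
               sd_purity = stats::sd(d$purity, na.rm = TRUE),
               n_replicates = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cycle), ]
}
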