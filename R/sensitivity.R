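# Raw-data examination procedures: modifying cluster-period event counts
# with refitting, and the tipping-point search for the number of events
# whose removal reverses the odds ratio.

#' Set the event count of one cluster period
#'
#' Seeded relabelling of `safety_event` within one site-by-month cell so
#' that the cell's event count equals `k`: surplus events are switched
#' off (or non-events switched on) at random within the cell; all other
#' cells and all denominators are untouched. Setting a cell to its
#' current count returns the data unchanged.
#'
#' @param data trial data frame.
#' @param design an [sw_design].
#' @param site,month cluster-period address (month = calendar month index
#'   since study start, as in [tabulate_cluster_periods]).
#' @param k desired event count, `0 <= k <=` cell denominator.
#' @param seed integer seed.
#' @return the modified data frame.
#' @export
set_cluster_period_events <- function(data, design, site, month, k,
                                      seed = NULL) {
  cell <- which(data$site == site & month_index(data$day, design) == month)
  if (!length(cell))
    stop("cluster period (", site, ", month ", month, ") has no records",
         call. = FALSE)
  if (k < 0 || k > length(cell))
    stop("infeasible event count ", k, " for a cell with ", length(cell),
         " records", call. = FALSE)
  cur <- sum(data$safety_event[cell])
  if (k == cur) return(data)
  with_seed(seed, {
    if (k < cur) {
      on_rows <- cell[data$safety_event[cell] == 1]
      data$safety_event[sample_int(on_rows, cur - k)] <- 0L
    } else {
      off_rows <- cell[data$safety_event[cell] == 0]
      data$safety_event[sample_int(off_rows, k - cur)] <- 1L
    }
    data
  })
}

# sample() misbehaves on length-1 vectors; always treat x as a set
sample_int <- function(x, size) x[sample.int(length(x), size)]

#' Crude odds ratio from a 2x2 table
#'
#' `OR = a d / (b c)` from events/denominators of two groups, with a
#' continuity correction of 0.5 added to every cell when any cell is zero.
#' Undefined (NA) if a full margin is zero.
#'
#' @param events_a,n_a events and denominator of the first group.
#' @param events_b,n_b events and denominator of the second group.
#' @return the odds ratio (group a vs group b).
#' @export
crude_or <- function(events_a, n_a, events_b, n_b) {
  stopifnot(events_a >= 0, events_b >= 0, events_a <= n_a, events_b <= n_b)
  a <- events_a; b <- events_b
  c_ <- n_a - events_a; d <- n_b - events_b
  if ((a + b) == 0 || (c_ + d) == 0) {
    warning("odds ratio undefined: a full margin of the 2x2 table is zero")
    return(NA_real_)
  }
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

#' Tipping-point search over removed events
#'
#' How many safety events must be subtracted from those occurring under
#' one condition within one phase for the model's odds ratio to cross 1?
#' Events are removed one at a time, always from the cluster period that
#' currently holds the most events in the targeted stratum (ties broken
#' by design site order, then month; the event removed within a cell is
#' chosen by seeded sampling), and the model is refitted after each
#' removal. The search stops at the first odds ratio past 1 (below 1 for
#' intervention-side removals, above 1 for control-side) or when the
#' stratum is exhausted.
#'
#' @param data trial data frame.
#' @param design an [sw_design].
#' @param code analysis model to refit (default `"A"`).
#' @param condition stratum condition events are removed from.
#' @param phase stratum phase (default the randomisation phase, where
#'   contemporaneous comparisons live).
#' @param adjustment,method passed to [run_analysis].
#' @param seed integer seed.
#' @param max_k optional cap on removals.
#' @return list of class `sw_tipping`: `k_star` (minimal removals needed;
#'   0 if already past 1; NA if not reached), `modified_or`,
#'   `modified_ci`, and the `trajectory` data frame of (k, OR, CI).
#' @export
tipping_point <- function(data, design, code = "A",
                          condition = c("intervention", "control"),
                          phase = "randomisation", adjustment = "none",
                          method = "Laplace", seed = NULL, max_k = NULL) {
  condition <- match.arg(condition)
  spec <- model_spec(code)
  d <- derive_variables(data, design, timing = spec$timing)
  stratum <- which(d$condition == condition & d$phase == phase &
                     d$safety_event == 1)
  if (!length(stratum))
    stop("no events in the targeted (", condition, ", ", phase, ") stratum",
         call. = FALSE)
  past_one <- if (condition == "intervention") function(or) or < 1
              else function(or) or > 1

  fit0 <- run_analysis(data, design, code, adjustment, outcome = "safety",
                       method = method)
  traj <- data.frame(k = 0L, or = fit0$effect$estimate,
                     ci_low = fit0$effect$ci_low,
                     ci_high = fit0$effect$ci_high, converged = fit0$converged)
  if (past_one(fit0$effect$estimate)) {
    out <- list(k_star = 0L, modified_or = fit0$effect$estimate,
                modified_ci = c(fit0$effect$ci_low, fit0$effect$ci_high),
                trajectory = traj)
    class(out) <- "sw_tipping"
    return(out)
  }

  # removal order: dynamically the fullest cell, ties by site order then month
  site_rank <- match(d$site[stratum], design$site_ids)
  cellm <- month_index(d$day[stratum], design)
  order_seed <- with_seed(seed, sample.int(.Machine$integer.max / 2, 1))
  remaining <- stratum
  rank_site <- site_rank; rank_month <- cellm
  removal_order <- integer(0)
  while (length(remaining)) {
    keym <- paste(rank_site, rank_month)
    counts <- table(keym)
    best <- names(counts)[order(-as.integer(counts),
                                as.integer(sub(" .*", "", names(counts))),
                                as.integer(sub(".* ", "", names(counts))))][1]
    in_cell <- which(keym == best)
    pick <- with_seed(order_seed + length(removal_order),
                      sample_int(in_cell, 1))
    removal_order <- c(removal_order, remaining[pick])
    remaining <- remaining[-pick]
    rank_site <- rank_site[-pick]; rank_month <- rank_month[-pick]
  }
  if (!is.null(max_k)) removal_order <- removal_order[seq_len(min(max_k,
                                                      length(removal_order)))]

  mod <- data
  k_star <- NA_integer_
  last_or <- fit0$effect$estimate
  last_ci <- c(fit0$effect$ci_low, fit0$effect$ci_high)
  for (k in seq_along(removal_order)) {
    mod$safety_event[removal_order[k]] <- 0L
    fk <- tryCatch(run_analysis(mod, design, code, adjustment,
                                outcome = "safety", method = method),
                   error = function(e) NULL)
    if (is.null(fk)) {
      traj <- rbind(traj, data.frame(k = k, or = NA, ci_low = NA,
                                     ci_high = NA, converged = FALSE))
      next
    }
    traj <- rbind(traj, data.frame(k = k, or = fk$effect$estimate,
                                   ci_low = fk$effect$ci_low,
                                   ci_high = fk$effect$ci_high,
                                   converged = fk$converged))
    last_or <- fk$effect$estimate
    last_ci <- c(fk$effect$ci_low, fk$effect$ci_high)
    if (past_one(fk$effect$estimate)) {
      k_star <- k
      break
    }
  }
  out <- list(k_star = k_star, modified_or = last_or, modified_ci = last_ci,
              trajectory = traj)
  class(out) <- "sw_tipping"
  out
}

#' @export
print.sw_tipping <- function(x, ...) {
  cat("Tipping-point analysis over removed events\n")
  if (is.na(x$k_star)) cat("  odds ratio never crossed 1 (stratum exhausted)\n")
  else cat("  k* =", x$k_star, "events removed to cross 1\n")
  cat(sprintf("  final OR %.3f [%.3f, %.3f]\n", x$modified_or,
              x$modified_ci[1], x$modified_ci[2]))
  invisible(x)
}

#' Median cluster-period event count
#'
#' Median number of events over the cluster periods of one phase that
#' contain at least one presentation (zero-event cells included).
#'
#' @inheritParams tipping_point
#' @param phase phase to tabulate.
#' @return the median event count.
#' @export
median_cluster_period_events <- function(data, design,
                                         phase = "randomisation") {
  d <- data[phase_of(data$day, design) == phase, , drop = FALSE]
  tab <- tabulate_cluster_periods(d, design)
  stats::median(tab$events[tab$denominator > 0])
}
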