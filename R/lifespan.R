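#' Operational stop-of-division criterion
#'
#' A cell is considered to have stopped dividing if it divides no more until
#' the end of its observation AND the gap between its last division and the
#' end of the observation exceeds the average interdivision interval by a
#' given factor; cells observed for less than a minimum span are excluded
#' altogether. These rules guard against mistaking slow division for a
#' terminal arrest and against under-observed cells.
#'
#' @param interval_factor how many mean interdivision intervals the terminal
#'   gap must exceed (strictly) to call a stop; default 2.
#' @param min_observation minimum observation span in minutes; default 850
#'   (170 frames at 5 min/frame).
#' @param mean_interdivision mean interdivision interval in minutes; when
#'   `NULL` it is estimated from the data by [assign_fates()].
#' @return an object of class `stop_criterion`.
#' @export
stop_criterion <- function(interval_factor = 2, min_observation = 850,
                           mean_interdivision = NULL) {
  if (interval_factor <= 1) {
    poleage_error("poleage_config_error", "interval_factor must exceed 1")
  }
  if (min_observation <= 0) {
    poleage_error("poleage_config_error", "min_observation must be positive")
  }
  structure(list(interval_factor = interval_factor,
                 min_observation = min_observation,
                 mean_interdivision = mean_interdivision),
            class = "stop_criterion")
}

#' Classify one individual's fate under the stop criterion
#'
#' @param birth_time_min,division_times_min,last_obs_time_min the individual's
#'   birth time, vector of division times, and last observed time (minutes).
#' @param experiment_end end of the experiment in minutes; the observation
#'   window closes at `min(experiment_end, last_obs_time_min)`.
#' @param criterion a [stop_criterion()] with `mean_interdivision` set.
#' @return one of `"stopped"`, `"censored"`, `"excluded"`.
#' @examples
#' cr <- stop_criterion(mean_interdivision = 40)
#' detect_stop(0, c(460, 500), 900, 900, cr)  # "stopped": gap 400 > 80
#' detect_stop(0, c(840, 880), 900, 900, cr)  # "censored": gap 20
#' @export
detect_stop <- function(birth_time_min, division_times_min, last_obs_time_min,
                        experiment_end, criterion) {
  stopifnot(inherits(criterion, "stop_criterion"))
  if (is.null(criterion$mean_interdivision)) {
    poleage_error("poleage_config_error",
                  "criterion$mean_interdivision must be set (or use assign_fates)")
  }
  if (any(c(birth_time_min, division_times_min, last_obs_time_min) < 0, na.rm = TRUE)) {
    poleage_error("poleage_validation_error", "negative times are not allowed")
  }
  obs_end <- min(experiment_end, last_obs_time_min, na.rm = TRUE)
  if (obs_end < birth_time_min) {
    poleage_error("poleage_validation_error", "observation ends before birth")
  }
  span <- obs_end - birth_time_min
  if (span < criterion$min_observation) return("excluded")
  last_div <- if (length(division_times_min)) max(division_times_min) else birth_time_min
  gap <- obs_end - last_div
  if (gap > criterion$interval_factor * criterion$mean_interdivision) "stopped" else "censored"
}

#' Assign fates to all individuals of a lineage
#'
#' Applies [detect_stop()] to every individual. When the criterion's
#' `mean_interdivision` is `NULL` it is estimated as the mean of all observed
#' interdivision intervals of included individuals (the interval from an
#' individual's birth to its first division counts, as do intervals between
#' its consecutive divisions). Stopped individuals receive
#' `stop_pole_age = n_divisions + 1`, the pole age they hold after their final
#' division.
#'
#' @param individuals the `individuals` data.frame of [assign_pole_ages()], or
#'   any data.frame with columns `individual_id`, `birth_time_min`,
#'   `n_divisions`, `division_times_min` (";"-separated),
#'   `last_obs_time_min` and optionally `included`.
#' @param experiment_end end of the experiment (minutes).
#' @param criterion a [stop_criterion()].
#' @return the input with columns `fate`, `stop_pole_age` and
#'   `mean_interdivision_used` added; excluded and non-included individuals
#'   keep `fate` `"excluded"` / their `included` flag.
#' @export
assign_fates <- function(individuals, experiment_end, criterion = stop_criterion()) {
  ind <- individuals
  if (!"included" %in% names(ind)) ind$included <- TRUE
  div_list <- split_semi(ind$division_times_min)
  mid <- criterion$mean_interdivision
  if (is.null(mid)) {
    ivs <- unlist(lapply(which(ind$included), function(i) {
      d <- div_list[[i]]
      if (!length(d)) return(numeric(0))
      diff(c(ind$birth_time_min[i], d))
    }))
    if (!length(ivs)) {
      poleage_error("poleage_insufficient_data",
                    "no interdivision intervals observed; supply mean_interdivision")
    }
    mid <- mean(ivs)
  }
  crit <- stop_criterion(criterion$interval_factor, criterion$min_observation, mid)
  fate <- character(nrow(ind))
  for (i in seq_len(nrow(ind))) {
    fate[i] <- detect_stop(ind$birth_time_min[i], div_list[[i]],
                           ind$last_obs_time_min[i], experiment_end, crit)
  }
  ind$fate <- fate
  ind$stop_pole_age <- ifelse(fate == "stopped", ind$n_divisions + 1L, NA_integer_)
  ind$mean_interdivision_used <- mid
  ind
}

#' Per-division and cumulative probability of stopping division
#'
#' Builds the replicative-lifespan curve over pole ages. An individual is at
#' risk at pole age `a` if it was observed holding that age with a
#' classifiable outcome: stopped individuals are at risk up to their stop age,
#' censored ones up to the age of their last observed division (they leave the
#' risk set afterwards). The per-division (hazard) probability at age `a` is
#' the number of individuals stopping at `a` divided by the number at risk,
#' and the cumulative probability is
#' \eqn{1 - \prod_{i \le a} (1 - \mathrm{hazard}(i))}.
#'
#' @param individuals data.frame with columns `fate` (`"stopped"`,
#'   `"censored"`, or `"excluded"`) and `n_divisions`; rows with
#'   `included == FALSE` or fate `"excluded"` are ignored.
#' @return an object of classes `stop_curve`/`data.frame` with columns
#'   `pole_age`, `n_at_risk`, `n_events`, `hazard`, `cumulative`.
#' @export
stop_curve <- function(individuals) {
  ind <- individuals
  if (!"included" %in% names(ind)) ind$included <- TRUE
  ind <- ind[ind$included & ind$fate %in% c("stopped", "censored"), , drop = FALSE]
  if (!nrow(ind)) {
    poleage_error("poleage_empty_curve", "no classifiable individuals for a stop curve")
  }
  last_risk_age <- ifelse(ind$fate == "stopped", ind$n_divisions + 1L, ind$n_divisions)
  amax <- max(last_risk_age)
  if (amax < 1L) {
    poleage_error("poleage_empty_curve",
                  "no individual was at risk at any pole age (all censored before dividing)")
  }
  ages <- seq_len(amax)
  n_at_risk <- vapply(ages, function(a) sum(last_risk_age >= a), 0L)
  stops <- ind$n_divisions[ind$fate == "stopped"] + 1L
  n_events <- vapply(ages, function(a) sum(stops == a), 0L)
  hazard <- ifelse(n_at_risk > 0, n_events / n_at_risk, NA_real_)
  cumulative <- 1 - cumprod(1 - hazard)
  out <- data.frame(pole_age = ages, n_at_risk = n_at_risk, n_events = n_events,
                    hazard = hazard, cumulative = cumulative)
  class(out) <- c("stop_curve", "data.frame")
  out
}

#' Median pole age at which cells stop dividing
#'
#' @param curve a [stop_curve()].
#' @param method `"discrete"`: smallest pole age whose cumulative stop
#'   probability reaches 0.5 (an integer); `"interpolated"`: linear
#'   interpolation of the 0.5 crossing on the cumulative curve (real-valued).
#' @return the median pole age, or `NA` if the curve never reaches 0.5.
#' @examples
#' cv <- data.frame(pole_age = 1:4, cumulative = c(0, 0.25, 0.55, 0.8))
#' class(cv) <- c("stop_curve", "data.frame")
#' median_stop_age(cv)                          # 3
#' median_stop_age(cv, "interpolated")          # 2.8333
#' @export
median_stop_age <- function(curve, method = c("discrete", "interpolated")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(curve), all(c("pole_age", "cumulative") %in% names(curve)))
  Fv <- curve$cumulative
  a <- curve$pole_age
  hit <- which(Fv >= 0.5)
  if (!length(hit)) return(NA_real_)
  k <- hit[1]
  if (method == "discrete") return(as.numeric(a[k]))
  F_lo <- if (k == 1L) 0 else Fv[k - 1L]
  a_lo <- if (k == 1L) a[1] - 1 else a[k - 1L]
  a_lo + (0.5 - F_lo) / (Fv[k] - F_lo) * (a[k] - a_lo)
}

#' Expand individuals into per-division stop/continue opportunities
#'
#' Each pole age at which an individual was at risk becomes one binary
#' observation: did the individual stop at that age (1) or divide on (0)?
#' Censored individuals contribute rows up to their last observed division.
#'
#' @param individuals as for [stop_curve()].
#' @return data.frame with `individual_id`, `pole_age`, `stopped`.
#' @export
division_opportunities <- function(individuals) {
  ind <- individuals
  if (!"included" %in% names(ind)) ind$included <- TRUE
  ind <- ind[ind$included & ind$fate %in% c("stopped", "censored"), , drop = FALSE]
  last_risk_age <- ifelse(ind$fate == "stopped", ind$n_divisions + 1L, ind$n_divisions)
  keep <- last_risk_age >= 1L
  ind <- ind[keep, , drop = FALSE]
  last_risk_age <- last_risk_age[keep]
  n <- sum(last_risk_age)
  data.frame(
    individual_id = rep(ind$individual_id, last_risk_age),
    pole_age = unlist(lapply(last_risk_age, seq_len)),
    stopped = unlist(Map(function(k, f) {
      v <- integer(k)
      if (f == "stopped") v[k] <- 1L
      v
    }, last_risk_age, ind$fate))
  )
}

#' Test for an age trend in the per-division stop probability
#'
#' Logistic regression of the per-division stop indicator on pole age,
#' treating each division opportunity of each cell as an independent data
#' point. Returns the slope (log-odds per unit pole age) and its Wald p-value.
#' Complete or quasi-complete separation is flagged (the slope estimate is
#' then unbounded and reported as fitted, with a warning).
#'
#' @param x either a data.frame of individuals (see [stop_curve()]) or the
#'   output of [division_opportunities()].
#' @return list with `slope`, `se`, `p_value`, `n_opportunities`,
#'   `separation`.
#' @export
hazard_trend_test <- function(x) {
  opp <- if (all(c("pole_age", "stopped") %in% names(x))) x else division_opportunities(x)
  if (length(unique(opp$pole_age[opp$stopped == 1])) < 1L ||
      length(unique(opp$pole_age)) < 2L) {
    poleage_error("poleage_insufficient_data",
                  "need events and at least two distinct pole ages")
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stopped ~ pole_age, family = stats::binomial(), data = opp),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- summary(fit)$coefficients
  slope <- co["pole_age", "Estimate"]
  separation <- sep_warn || abs(slope) > 15
  if (separation) {
    poleage_warn("poleage_separation",
                 "separation detected in the hazard trend fit; slope is unbounded")
  }
  list(slope = slope, se = co["pole_age", "Std. Error"],
       p_value = co["pole_age", "Pr(>|z|)"],
       n_opportunities = nrow(opp), separation = separation)
}

#' Which cell states predict that a division is a cell's last?
#'
#' Fits, separately per predictor, a logistic regression of the is-last-
#' division indicator on the predictor over all observed divisions (each
#' division one row), and reports the coefficient sign and p-value. In the
#' short-lived mutant, smaller post-division size and higher reporter
#' concentration mark last divisions.
#'
#' @param records data.frame with one row per division: logical/0-1 column
#'   `is_last` plus the predictor columns.
#' @param predictors character vector of predictor column names present in
#'   `records`.
#' @return data.frame with `predictor`, `coefficient`, `p_value`, `n`,
#'   `separation` (`TRUE` when the classes separate completely and the Wald
#'   p-value is meaningless).
#' @export
last_division_predictors <- function(records,
                                     predictors = intersect(
                                       c("length_after_um", "conc_au_per_um3"),
                                       names(records))) {
  if (!"is_last" %in% names(records)) {
    poleage_error("poleage_io_error", "records need an is_last column")
  }
  if (!length(predictors)) {
    poleage_error("poleage_config_error", "no predictor columns found")
  }
  out <- lapply(predictors, function(p) {
    d <- records[stats::complete.cases(records[, c("is_last", p)]), c("is_last", p)]
    if (nrow(d) < 2L || length(unique(d[[p]])) < 2L || length(unique(d$is_last)) < 2L) {
      poleage_error("poleage_degenerate_model",
                    paste0("predictor '", p, "' (or outcome) is constant or n < 2"))
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(stats::reformulate(p, "is_last"),
                 family = stats::binomial(), data = d),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    co <- summary(fit)$coefficients
    data.frame(predictor = p, coefficient = co[p, "Estimate"],
               p_value = co[p, "Pr(>|z|)"], n = nrow(d),
               separation = sep || abs(co[p, "Estimate"]) > 50)
  })
  do.call(rbind, out)
}

#' Does a cell's birth state predict its replicative potential?
#'
#' Spearman rank correlation between per-individual birth-state variables
#' (e.g. reporter concentration or cell length at emergence as a new-pole
#' cell) and the total number of divisions the individual completes.
#'
#' @param records data.frame with column `replicative_potential` plus the
#'   predictor columns; one row per individual.
#' @param predictors character vector of predictor column names.
#' @return data.frame with `predictor`, `rho`, `p_value`, `n`.
#' @export
birth_state_vs_potential <- function(records,
                                     predictors = intersect(
                                       c("birth_conc_au_per_um3", "birth_length_um"),
                                       names(records))) {
  if (!"replicative_potential" %in% names(records)) {
    poleage_error("poleage_io_error", "records need a replicative_potential column")
  }
  out <- lapply(predictors, function(p) {
    d <- records[stats::complete.cases(records[, c("replicative_potential", p)]), ]
    if (nrow(d) < 3L) {
      poleage_error("poleage_insufficient_data",
                    "need at least 3 individuals for a rank correlation")
    }
    if (length(unique(d[[p]])) < 2L || length(unique(d$replicative_potential)) < 2L) {
      poleage_error("poleage_degenerate_model",
                    paste0("rank correlation undefined: '", p, "' or the potential is constant"))
    }
    ct <- suppressWarnings(
      stats::cor.test(d[[p]], d$replicative_potential, method = "spearman")
    )
    data.frame(predictor = p, rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d))
  })
  do.call(rbind, out)
}

#' Compare first interdivision intervals of mothers and their last daughters
#'
#' Pairs each focal individual's first interdivision interval (birth to first
#' division) with the first interval of its last daughter, and tests the
#' group difference with a one-way ANOVA. Indistinguishable intervals support
#' the rejuvenation of new-pole daughters even when born of old mothers.
#'
#' @param individuals the individuals data.frame of [assign_pole_ages()] after
#'   [assign_fates()]; needs `mother_individual_id`, `birth_index`,
#'   `birth_time_min`, `division_times_min`, `n_divisions`.
#' @param focal_ids optional character vector restricting the focal set;
#'   defaults to all included individuals with at least one division whose
#'   last daughter also divided.
#' @return list with `n_pairs`, `mean_focal`, `mean_daughter`,
#'   `mean_difference`, `p_value`.
#' @export
interdivision_comparison <- function(individuals, focal_ids = NULL) {
  ind <- individuals
  if (!"included" %in% names(ind)) ind$included <- TRUE
  div_list <- split_semi(ind$division_times_min)
  first_iv <- vapply(seq_len(nrow(ind)), function(i) {
    d <- div_list[[i]]
    if (!length(d)) return(NA_real_)
    d[1] - ind$birth_time_min[i]
  }, 1)
  if (is.null(focal_ids)) {
    focal_ids <- ind$individual_id[ind$included & ind$n_divisions >= 1L]
  }
  x <- numeric(0); y <- numeric(0); dropped <- 0L
  for (fid in focal_ids) {
    i <- match(fid, ind$individual_id)
    if (is.na(i) || is.na(first_iv[i])) { dropped <- dropped + 1L; next }
    kd <- which(ind$mother_individual_id %in% fid &
                  ind$birth_index == ind$n_divisions[i])
    if (!length(kd) || is.na(first_iv[kd[1]])) { dropped <- dropped + 1L; next }
    x <- c(x, first_iv[i]); y <- c(y, first_iv[kd[1]])
  }
  if (dropped > 0L) {
    poleage_warn("poleage_unpaired",
                 sprintf("%d focal individuals had no paired last-daughter interval and were dropped", dropped))
  }
  if (length(x) < 2L) {
    poleage_error("poleage_insufficient_data", "fewer than 2 mother/daughter pairs")
  }
  d <- data.frame(interval = c(x, y),
                  group = factor(rep(c("focal_first", "last_daughter_first"),
                                     c(length(x), length(y)))))
  p <- summary(stats::aov(interval ~ group, data = d))[[1]][["Pr(>F)"]][1]
  list(n_pairs = length(x), mean_focal = mean(x), mean_daughter = mean(y),
       mean_difference = mean(y) - mean(x), p_value = p)
}

#' Per-division measurement records
#'
#' One row per observed division of every included classifiable individual:
#' the pole age at division, the old-pole product's length (and, when
#' fluorescence is available, cylinder-approximation concentration) right
#' after division, and whether the division was the cell's last. The final
#' division of a censored individual is dropped (whether it was the last is
#' unknown).
#'
#' @param assigned a [assign_pole_ages()] result.
#' @param fates the individuals data.frame after [assign_fates()].
#' @param channel_width_um cylinder diameter for [concentration()].
#' @return data.frame with `individual_id`, `division_index`, `pole_age`,
#'   `length_after_um`, `conc_au_per_um3` (NA without fluorescence),
#'   `is_last`.
#' @export
division_records <- function(assigned, fates, channel_width_um = 1.2) {
  stopifnot(inherits(assigned, "pole_assignment"))
  cells <- assigned$cells
  have_fluor <- "first_mean_fluor" %in% names(cells)
  keep <- fates$included & fates$fate %in% c("stopped", "censored")
  out <- lapply(which(keep), function(i) {
    chain <- cells[cells$individual_id %in% fates$individual_id[i], , drop = FALSE]
    chain <- chain[order(chain$pole_age), ]
    k <- fates$n_divisions[i]
    if (k < 1L) return(NULL)
    jmax <- if (fates$fate[i] == "stopped") k else k - 1L
    if (jmax < 1L) return(NULL)
    j <- seq_len(jmax)
    after <- chain[j + 1L, ]           # the old-pole product of division j
    conc <- if (have_fluor && !anyNA(after$first_mean_fluor)) {
      concentration(after$first_mean_fluor * after$first_pixel_count,
                    after$first_length, channel_width_um)
    } else rep(NA_real_, length(j))
    data.frame(individual_id = fates$individual_id[i], division_index = j,
               pole_age = j, length_after_um = after$first_length,
               conc_au_per_um3 = conc,
               is_last = fates$fate[i] == "stopped" & j == k,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    poleage_error("poleage_insufficient_data", "no divisions to record")
  }
  rownames(res) <- NULL
  res
}

#' Birth-state records with replicative potential
#'
#' One row per included stopped individual: its length (and concentration,
#' when available) at emergence as a new-pole cell, and its total replicative
#' potential (the number of divisions it completed before stopping).
#'
#' @inheritParams division_records
#' @return data.frame with `individual_id`, `birth_length_um`,
#'   `birth_conc_au_per_um3`, `replicative_potential`.
#' @export
birth_records <- function(assigned, fates, channel_width_um = 1.2) {
  stopifnot(inherits(assigned, "pole_assignment"))
  cells <- assigned$cells
  have_fluor <- "first_mean_fluor" %in% names(cells)
  keep <- which(fates$included & fates$fate %in% "stopped")
  if (!length(keep)) {
    poleage_error("poleage_insufficient_data", "no stopped individuals")
  }
  out <- lapply(keep, function(i) {
    chain <- cells[cells$individual_id %in% fates$individual_id[i], , drop = FALSE]
    first <- chain[which.min(chain$pole_age), ]
    conc <- if (have_fluor && !is.na(first$first_mean_fluor)) {
      concentration(first$first_mean_fluor * first$first_pixel_count,
                    first$first_length, channel_width_um)
    } else NA_real_
    data.frame(individual_id = fates$individual_id[i],
               birth_length_um = first$first_length,
               birth_conc_au_per_um3 = conc,
               replicative_potential = fates$n_divisions[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residual elongation after the last division
#'
#' Percent length change of a stopped cell over a fixed horizon after its last
#' division: `100 * (L(t_last + horizon) - L(t_last)) / L(t_last)`. Lengths at
#' off-frame times are linearly interpolated between the nearest frames.
#'
#' @param time_min,length_um the post-last-division cell's length trajectory.
#' @param t_last time of the last division (minutes); defaults to the first
#'   trajectory time.
#' @param horizon horizon in minutes (default 25).
#' @return percent length change (numeric scalar).
#' @export
post_last_division_elongation <- function(time_min, length_um, t_last = min(time_min),
                                          horizon = 25) {
  if (max(time_min) < t_last + horizon || min(time_min) > t_last) {
    poleage_error("poleage_trajectory_too_short",
                  "length trajectory does not cover the horizon after the last division")
  }
  L0 <- stats::approx(time_min, length_um, xout = t_last)$y
  L1 <- stats::approx(time_min, length_um, xout = t_last + horizon)$y
  100 * (L1 - L0) / L0
}

#' Residual elongation for every stopped individual of a lineage
#'
#' @param assigned a [assign_pole_ages()] result whose individuals carry fates
#'   (see [assign_fates()]).
#' @param fates the fated individuals data.frame.
#' @param horizon minutes after the last division (default 25).
#' @return data.frame with `individual_id`, `percent_elongation` (NA with a
#'   reason when the trajectory is too short).
#' @export
elongation_after_stop <- function(assigned, fates, horizon = 25) {
  stopifnot(inherits(assigned, "pole_assignment"))
  stopped <- fates[fates$fate %in% "stopped" & fates$included, , drop = FALSE]
  tab <- assigned$table
  out <- lapply(seq_len(nrow(stopped)), function(i) {
    cell <- stopped$terminal_cell_id[i]
    tr <- tab[tab$cell_id == cell, , drop = FALSE]
    tr <- tr[order(tr$time_min), ]
    # the terminal cell of a stopped individual is born at its last division;
    # its first tracked frame is the closest observation to that moment
    val <- tryCatch(
      post_last_division_elongation(tr$time_min, tr$length_um,
                                    t_last = min(tr$time_min), horizon = horizon),
      poleage_trajectory_too_short = function(e) NA_real_
    )
    data.frame(individual_id = stopped$individual_id[i], percent_elongation = val)
  })
  if (!length(out)) {
    return(data.frame(individual_id = character(0), percent_elongation = numeric(0)))
  }
  do.call(rbind, out)
}
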