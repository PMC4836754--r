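#' Fluorescent-reporter configuration for the lineage simulator
#'
#' Two reporter dynamics are emulated. The *aggregate-like* signal (a polar
#' inclusion such as glycogen reported by a synthase-GFP fusion) is produced
#' at a constant rate in every cell; at division the pre-existing polar
#' aggregate stays with the old-pole cell, and of the material produced during
#' the cycle the old-pole cell keeps a fraction `retention`, the daughter the
#' rest. Mothers therefore accumulate signal with pole age while daughters are
#' born with an approximately constant amount. The *chromosome-like* signal
#' doubles over a normal cycle (replication) and is split equally at division;
#' in the cycle that ends in a cell's last division, replication is suppressed
#' and the daughter inherits nearly all of it (the mother retains
#' `chromosome_last_retention`), emulating nucleoid exclusion by the polar
#' aggregate. Both signals are conserved exactly at every division.
#'
#' @param aggregate_rate production rate of the aggregate signal, AU/min.
#' @param retention fraction of the current cycle's aggregate production kept
#'   by the old-pole cell at division; in \[0.5, 1\].
#' @param chromosome_level nominal chromosome-signal amount at birth, AU.
#' @param chromosome_retention fraction of the (replicated) chromosome signal
#'   kept by the old-pole cell at a normal division.
#' @param chromosome_last_retention fraction kept at the mother's last
#'   division (small: the chromosome segregates to the daughter).
#' @param exclusion_threshold optional aggregate amount (AU) above which a
#'   cell deterministically ceases division, used *instead of* the hazard
#'   schedule (mechanistic stopping).
#' @param emit_profile also emit per-frame long-axis intensity profiles
#'   (column `profile`, ";"-separated, old pole first).
#' @param diffuse_au_per_um cytoplasmic capacity of the reporter: up to this
#'   much signal per micrometer of cell length stays diffuse (uniform along
#'   the long axis); the excess packs at the old pole. Young cells therefore
#'   show a flat profile, old ones a polar one.
#' @param packing_au_per_um linear packing density of the polar aggregate;
#'   sets how far the packed excess extends from the old pole.
#' @param column_um spatial resolution of profiles and of `pixel_count`, in
#'   micrometers per column.
#' @param width_um cell (channel) width used for `pixel_count`.
#' @return an object of class `fluor_config`.
#' @export
fluor_config <- function(aggregate_rate = 5, retention = 0.85,
                         chromosome_level = 1000, chromosome_retention = 0.5,
                         chromosome_last_retention = 0.02,
                         exclusion_threshold = NULL, emit_profile = FALSE,
                         diffuse_au_per_um = 50, packing_au_per_um = 400,
                         column_um = 0.1, width_um = 1.2) {
  if (retention < 0.5 || retention > 1) {
    poleage_error("poleage_config_error", "retention must lie in [0.5, 1]")
  }
  if (aggregate_rate < 0 || chromosome_level < 0) {
    poleage_error("poleage_config_error", "rates and levels must be >= 0")
  }
  structure(list(aggregate_rate = aggregate_rate, retention = retention,
                 chromosome_level = chromosome_level,
                 chromosome_retention = chromosome_retention,
                 chromosome_last_retention = chromosome_last_retention,
                 exclusion_threshold = exclusion_threshold,
                 emit_profile = emit_profile,
                 diffuse_au_per_um = diffuse_au_per_um,
                 packing_au_per_um = packing_au_per_um,
                 column_um = column_um, width_um = width_um),
            class = "fluor_config")
}

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic time-lapse experiment:
#' pole-age-dependent cessation of division (a [hazard_schedule()] or a
#' mechanistic aggregate threshold), lognormal interdivision times,
#' exponential length growth with division at twice the birth length,
#' truncation of the observation at `duration` discretized to frames, and
#' either agar-colony geometry (the full binary tree is observed) or
#' mother-machine geometry (one bottom cell per channel whose initial pole
#' age is unknown; cells pushed out of the channel vanish after their first
#' division).
#'
#' @param schedule a [hazard_schedule()].
#' @param seed integer seed; mandatory for reproducibility.
#' @param interdivision_mean,interdivision_cv mean (minutes) and coefficient
#'   of variation of the lognormal interdivision time.
#' @param duration experiment duration in minutes.
#' @param frame_interval imaging interval in minutes (typically 5 or 10).
#' @param geometry `"agar_colony"` or `"mother_machine"`.
#' @param n_founders founder cells (agar) — each founds one microcolony.
#' @param n_channels channels (mother machine) — each holds one bottom cell.
#' @param mm_generations mother machine only: number of successive fully
#'   observed bottom-most lineages per channel (the bottom cell, then — after
#'   each arrest — its last daughter; default 3).
#' @param birth_length_um founder birth length.
#' @param division_noise_cv multiplicative noise on the division-site position.
#' @param residual_elongation fractional length increase of a stopped cell
#'   after its last division (default 0.075, i.e. 7.5%).
#' @param elongation_ramp_min minutes over which the residual elongation is
#'   completed (linear ramp, then halt).
#' @param last_division_size_penalty multiplicative size penalty on the
#'   old-pole product of a division after which the mother stops (1 = none).
#' @param fluor optional [fluor_config()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(schedule, seed,
                       interdivision_mean = 40, interdivision_cv = 0.1,
                       duration = 2000, frame_interval = 5,
                       geometry = c("agar_colony", "mother_machine"),
                       n_founders = 1L, n_channels = 1L, mm_generations = 3L,
                       birth_length_um = 2, division_noise_cv = 0.02,
                       residual_elongation = 0.075, elongation_ramp_min = 25,
                       last_division_size_penalty = 1, fluor = NULL) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  geometry <- match.arg(geometry)
  if (missing(seed) || is.null(seed)) {
    poleage_error("poleage_config_error", "seed is mandatory")
  }
  if (duration <= 0 || frame_interval <= 0 || interdivision_cv < 0 ||
      interdivision_mean <= 0) {
    poleage_error("poleage_config_error",
                  "duration, frame_interval and interdivision_mean must be positive; cv >= 0")
  }
  if (!is.null(fluor)) stopifnot(inherits(fluor, "fluor_config"))
  structure(list(schedule = schedule, seed = as.integer(seed),
                 interdivision_mean = interdivision_mean,
                 interdivision_cv = interdivision_cv,
                 duration = duration, frame_interval = frame_interval,
                 geometry = geometry, n_founders = as.integer(n_founders),
                 n_channels = as.integer(n_channels),
                 mm_generations = as.integer(mm_generations),
                 birth_length_um = birth_length_um,
                 division_noise_cv = division_noise_cv,
                 residual_elongation = residual_elongation,
                 elongation_ramp_min = elongation_ramp_min,
                 last_division_size_penalty = last_division_size_penalty,
                 fluor = fluor),
            class = "sim_config")
}

# lognormal with given mean and cv (cv = 0 degenerates to the mean)
rinterval <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# mutable cell store with growth by doubling
new_cell_store <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$cap <- 256L
  fields <- c("parent", "individual", "pole_age", "birth", "end", "birth_len",
              "interval", "A0", "C0", "kindi", "tracki", "chan", "cflat")
  for (f in fields) e[[f]] <- rep(NA_real_, e$cap)
  e$fields <- fields
  e
}

store_add <- function(e, parent, individual, pole_age, birth, end, birth_len,
                      interval, A0, C0, kindi, tracki, chan) {
  if (e$n == e$cap) {
    for (f in e$fields) e[[f]] <- c(e[[f]], rep(NA_real_, e$cap))
    e$cap <- e$cap * 2L
  }
  e$n <- e$n + 1L
  i <- e$n
  e$parent[i] <- parent; e$individual[i] <- individual
  e$pole_age[i] <- pole_age; e$birth[i] <- birth; e$end[i] <- end
  e$birth_len[i] <- birth_len; e$interval[i] <- interval
  e$A0[i] <- A0; e$C0[i] <- C0
  e$kindi[i] <- kindi; e$tracki[i] <- tracki; e$chan[i] <- chan
  e$cflat[i] <- as.numeric(!is.na(kindi) && kindi == KIND_STOP)
  i
}

# kind codes: 1 divides, 2 stopped, 3 censored-by-duration, 4 pushed out
KIND_DIV <- 1; KIND_STOP <- 2; KIND_CENS <- 3; KIND_PUSHED <- 4

#' Agent-based simulation of a time-lapse lineage experiment
#'
#' Generates a tracking table (schema of [read_tracking_table()], with
#' trailing columns `old_pole_child` and, with fluorescence enabled,
#' `agg_au`, `chrom_au` and optionally `profile`) together with ground-truth
#' individuals, by simulating pole-defined individuals under the configured
#' stopping rule. See [sim_config()] for the generative model.
#'
#' @param config a [sim_config()].
#' @return an object of class `poleage_sim`: list with `table` (tracking
#'   table), `individuals` (ground truth: `individual_id`,
#'   `mother_individual_id`, `birth_index`, `birth_time_min`, `n_divisions`,
#'   `fate` = stopped/censored/discarded, `stop_pole_age`, `channel_id`),
#'   `divisions` (per-division audit of the length and signal partition) and
#'   `config`.
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cs <- new_cell_store()
  fl <- config$fluor
  h_at <- function(a) hazard_at(config$schedule, a)
  thr <- if (!is.null(fl)) fl$exclusion_threshold else NULL

  n_ind <- 0L
  ind_mother <- integer(0); ind_birth_index <- integer(0); ind_ndiv <- integer(0)
  new_ind <- function(mother, birth_index) {
    n_ind <<- n_ind + 1L
    ind_mother[n_ind] <<- mother
    ind_birth_index[n_ind] <<- birth_index
    ind_ndiv[n_ind] <<- 0L
    n_ind
  }

  stop_rule <- function(age, A_birth) {
    if (!is.null(thr)) A_birth >= thr else stats::runif(1) < h_at(age)
  }

  # per-division audit (signal partition), used to verify conservation
  da <- new.env(parent = emptyenv())
  da$parent <- integer(0); da$t <- numeric(0)
  da$A_before <- numeric(0); da$A_old <- numeric(0); da$A_new <- numeric(0)
  da$C_before <- numeric(0); da$C_old <- numeric(0); da$C_new <- numeric(0)
  da$L_before <- numeric(0); da$L_old <- numeric(0); da$L_new <- numeric(0)

  C_level <- if (!is.null(fl)) fl$chromosome_level else 0

  # process one cell; returns NULL or the spec of its two children
  process_cell <- function(i) {
    birth <- cs$birth[i]; age <- cs$pole_age[i]
    interval <- cs$interval[i]
    if (cs$tracki[i] == 2) {               # pushed out of the channel
      cs$end[i] <- min(birth + interval, config$duration)
      cs$kindi[i] <- KIND_PUSHED
      return(NULL)
    }
    if (!is.na(cs$kindi[i]) && cs$kindi[i] == KIND_STOP) {
      cs$end[i] <- config$duration
      return(NULL)
    }
    div_t <- birth + interval
    if (div_t >= config$duration) {
      cs$end[i] <- config$duration
      cs$kindi[i] <- KIND_CENS
      return(NULL)
    }
    cs$end[i] <- div_t
    cs$kindi[i] <- KIND_DIV
    L_div <- 2 * cs$birth_len[i]
    # aggregate partition: polar stock stays with the mother, the daughter
    # receives (1 - retention) of this cycle's production
    A0 <- cs$A0[i]
    if (!is.null(fl)) {
      P <- fl$aggregate_rate * interval
      A_div <- A0 + P
      D_A <- (1 - fl$retention) * P
      M_A <- A_div - D_A
    } else {
      M_A <- 0; D_A <- 0
    }
    new_age <- age + 1
    stop_next <- stop_rule(new_age, M_A)
    if (!is.null(fl)) {
      if (stop_next) {          # replication fails in the terminal cycle
        C_div <- cs$C0[i]
        M_C <- fl$chromosome_last_retention * C_div
      } else {
        C_div <- 2 * cs$C0[i]
        M_C <- fl$chromosome_retention * C_div
      }
      D_C <- C_div - M_C
    } else {
      M_C <- 0; D_C <- 0
    }
    cs$cflat[i] <- as.numeric(stop_next)   # terminal cycle: no replication
    pen <- if (stop_next) config$last_division_size_penalty else 1
    q <- 0.5 * pen * exp(stats::rnorm(1, 0, config$division_noise_cv))
    q <- min(max(q, 0.2), 0.8)
    stop_d <- stop_rule(1, D_A)
    k <- length(da$parent) + 1L
    da$parent[k] <- i; da$t[k] <- div_t
    da$A_before[k] <- if (is.null(fl)) 0 else A_div
    da$A_old[k] <- M_A; da$A_new[k] <- D_A
    da$C_before[k] <- if (is.null(fl)) 0 else C_div
    da$C_old[k] <- M_C; da$C_new[k] <- D_C
    da$L_before[k] <- L_div
    da$L_old[k] <- q * L_div; da$L_new[k] <- (1 - q) * L_div
    list(div_t = div_t, new_age = new_age,
         old = list(len = q * L_div, A0 = M_A, C0 = M_C, will_stop = stop_next),
         new = list(len = (1 - q) * L_div, A0 = D_A, C0 = D_C, will_stop = stop_d))
  }

  add_cell <- function(parent, individual, pole_age, birth, birth_len, A0, C0,
                       will_stop, tracki, chan) {
    store_add(cs, parent, individual, pole_age, birth, NA_real_, birth_len,
              rinterval(1, config$interdivision_mean, config$interdivision_cv),
              A0, C0, if (will_stop) KIND_STOP else NA_real_, tracki, chan)
  }

  if (config$geometry == "agar_colony") {
    queue <- integer(0)
    for (f in seq_len(config$n_founders)) {
      ii <- new_ind(NA_integer_, NA_integer_)
      i <- add_cell(NA, ii, 1, 0, config$birth_length_um, 0, C_level,
                    will_stop = stop_rule(1, 0), tracki = 1, chan = f)
      queue <- c(queue, i)
    }
    hp <- 1L
    while (hp <= length(queue)) {
      i <- queue[hp]; hp <- hp + 1L
      res <- process_cell(i)
      if (is.null(res)) next
      ii <- cs$individual[i]
      ind_ndiv[ii] <- ind_ndiv[ii] + 1L
      io <- add_cell(i, ii, res$new_age, res$div_t, res$old$len, res$old$A0,
                     res$old$C0, res$old$will_stop, 1, cs$chan[i])
      jj <- new_ind(ii, ind_ndiv[ii])
      inew <- add_cell(i, jj, 1, res$div_t, res$new$len, res$new$A0,
                       res$new$C0, res$new$will_stop, 1, cs$chan[i])
      queue <- c(queue, io, inew)
    }
  } else {
    # mother machine: per channel, the bottom cell's chain is observed fully.
    # When the bottom-most dividing cell arrests, its last daughter becomes
    # the new bottom-most dividing cell and is itself observed fully, for up
    # to mm_generations full chains per channel; every other daughter is
    # pushed out after its first division, and deeper descendants are never
    # seen.
    simulate_chain <- function(root_cell_idx, chan) {
      daughters <- list()
      i <- root_cell_idx
      n_div <- 0L
      repeat {
        res <- process_cell(i)
        if (is.null(res)) break
        n_div <- n_div + 1L
        ii <- cs$individual[i]
        io <- add_cell(i, ii, res$new_age, res$div_t, res$old$len, res$old$A0,
                       res$old$C0, res$old$will_stop, 1, chan)
        daughters[[n_div]] <- list(parent = i, birth = res$div_t,
                                   len = res$new$len, A0 = res$new$A0,
                                   C0 = res$new$C0, will_stop = res$new$will_stop,
                                   birth_index = n_div)
        i <- io
      }
      list(daughters = daughters,
           stopped = !is.na(cs$kindi[i]) && cs$kindi[i] == KIND_STOP)
    }
    descend <- function(root_cell_idx, root_ind, chan, level) {
      res <- simulate_chain(root_cell_idx, chan)
      nd <- length(res$daughters)
      focal_k <- if (res$stopped && nd > 0L && level < config$mm_generations - 1L) nd else 0L
      for (k in seq_len(nd)) {
        d <- res$daughters[[k]]
        di <- new_ind(root_ind, d$birth_index)
        ci <- add_cell(d$parent, di, 1, d$birth, d$len, d$A0, d$C0,
                       d$will_stop, if (k == focal_k) 1 else 2, chan)
        if (k == focal_k) {
          descend(ci, di, chan, level + 1L)
        } else {
          process_cell(ci)
        }
      }
    }
    for (ch in seq_len(config$n_channels)) {
      bi <- new_ind(NA_integer_, NA_integer_)
      broot <- add_cell(NA, bi, 1, 0, config$birth_length_um, 0, C_level,
                        will_stop = stop_rule(1, 0), tracki = 1, chan = ch)
      descend(broot, bi, ch, 0L)
    }
  }

  if (cs$n == 0L) poleage_error("poleage_config_error", "simulation produced no cells")
  out <- sim_cells_to_output(cs, config, n_ind, ind_mother, ind_birth_index)
  out$divisions <- data.frame(
    parent_cell_id = sprintf("c%06d", da$parent), time_min = da$t,
    A_before = da$A_before, A_old = da$A_old, A_new = da$A_new,
    C_before = da$C_before, C_old = da$C_old, C_new = da$C_new,
    L_before = da$L_before, L_old = da$L_old, L_new = da$L_new,
    stringsAsFactors = FALSE)
  out
}

# frame sampling and assembly of the tracking table + ground truth
sim_cells_to_output <- function(cs, config, n_ind, ind_mother, ind_birth_index) {
  n <- cs$n
  idx <- seq_len(n)
  fl <- config$fluor
  fi <- config$frame_interval
  kind <- cs$kindi[idx]
  birth <- cs$birth[idx]; endt <- cs$end[idx]

  # frames: a dividing/pushed cell is observed on frames in [birth, end);
  # terminal cells (stopped/censored) also on the final frame <= duration
  first_fr <- ceiling(birth / fi - 1e-9)
  last_fr <- ifelse(kind %in% c(KIND_DIV, KIND_PUSHED),
                    ceiling(endt / fi - 1e-9) - 1,
                    floor(endt / fi + 1e-9))
  nfr <- pmax(0L, as.integer(last_fr - first_fr + 1))
  if (any(nfr == 0L & kind == KIND_DIV)) {
    poleage_warn("poleage_frame_skip",
                 "some dividing cells were never sampled on a frame (interval close to frame spacing)")
  }
  keep <- nfr > 0L
  rows_cell <- rep(idx[keep], nfr[keep])
  fr <- unlist(lapply(idx[keep], function(i) seq.int(first_fr[i], last_fr[i])))
  t_fr <- fr * fi

  b <- birth[rows_cell]; L0 <- cs$birth_len[rows_cell]
  intv <- cs$interval[rows_cell]
  kd <- kind[rows_cell]
  dt <- t_fr - b
  len <- ifelse(kd == KIND_STOP,
                L0 * (1 + config$residual_elongation *
                        pmin(dt / config$elongation_ramp_min, 1)),
                L0 * 2^(dt / intv))

  cell_ids <- sprintf("c%06d", idx)
  parent_ids <- ifelse(is.na(cs$parent[idx]), NA_character_,
                       sprintf("c%06d", cs$parent[idx]))
  # which child carries the old pole: the one continuing its parent's individual
  old_flag <- ifelse(is.na(cs$parent[idx]), NA_real_,
                     as.numeric(cs$individual[idx] ==
                                  cs$individual[pmax(cs$parent[idx], 1)]))

  tab <- data.frame(
    frame = fr,
    time_min = t_fr,
    cell_id = cell_ids[rows_cell],
    parent_id = parent_ids[rows_cell],
    length_um = len,
    mean_fluor = NA_real_,
    pixel_count = NA_integer_,
    channel_id = sprintf("ch%04d", cs$chan[rows_cell]),
    old_pole_child = old_flag[rows_cell],
    stringsAsFactors = FALSE
  )

  if (!is.null(fl)) {
    # production requires the chromosome: a stopped cell's signal is frozen
    A <- ifelse(kd == KIND_STOP, cs$A0[rows_cell],
                cs$A0[rows_cell] + fl$aggregate_rate * dt)
    chrom_flat <- cs$cflat[rows_cell] == 1
    C <- ifelse(chrom_flat, cs$C0[rows_cell], cs$C0[rows_cell] * 2^(dt / intv))
    width_px <- max(1L, round(fl$width_um / fl$column_um))
    ncolm <- pmax(4L, as.integer(round(len / fl$column_um)))
    px <- ncolm * width_px
    tab$mean_fluor <- A / px
    tab$pixel_count <- px
    tab$agg_au <- A
    tab$chrom_au <- C
    if (isTRUE(fl$emit_profile)) {
      tab$profile <- vapply(seq_along(rows_cell), function(r) {
        paste(format(aggregate_profile(len[r], ncolm[r], A[r],
                                       fl$diffuse_au_per_um,
                                       fl$packing_au_per_um),
                     trim = TRUE, scientific = FALSE), collapse = ";")
      }, "")
    }
  }
  o <- order(tab$frame, tab$cell_id)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL

  # ground truth per individual
  gt <- sim_ground_truth(cs, config, n_ind, ind_mother, ind_birth_index)
  structure(list(table = tab, individuals = gt, config = config),
            class = "poleage_sim")
}

sim_ground_truth <- function(cs, config, n_ind, ind_mother, ind_birth_index) {
  n <- cs$n
  idx <- seq_len(n)
  out <- lapply(seq_len(n_ind), function(ii) {
    cells <- idx[cs$individual[idx] == ii]
    cells <- cells[order(cs$pole_age[cells])]
    kinds <- cs$kindi[cells]
    n_div <- sum(kinds == KIND_DIV, na.rm = TRUE)
    fate <- if (any(kinds == KIND_STOP, na.rm = TRUE)) "stopped"
      else if (any(kinds == KIND_CENS, na.rm = TRUE)) "censored"
      else "discarded"
    data.frame(
      individual_id = sprintf("gt%05d", ii),
      mother_individual_id = ifelse(is.na(ind_mother[ii]), NA_character_,
                                    sprintf("gt%05d", ind_mother[ii])),
      birth_index = ind_birth_index[ii],
      birth_time_min = cs$birth[cells[1]],
      n_divisions = n_div,
      fate = fate,
      stop_pole_age = if (fate == "stopped") cs$pole_age[cells[kinds == KIND_STOP][1]]
        else NA_integer_,
      channel_id = sprintf("ch%04d", cs$chan[cells[1]]),
      first_cell_id = sprintf("c%06d", cells[1]),
      stringsAsFactors = FALSE
    )
  })
  gt <- do.call(rbind, out)
  rownames(gt) <- NULL
  gt
}

# long-axis intensity profile of the aggregate signal: the cytoplasm holds up
# to diffuse_per_um * L of signal uniformly; the excess is packed against the
# old pole at linear density `packing`, so it claims successive quarters as it
# grows. Columns are old-pole first; the column sums add up to the total A.
aggregate_profile <- function(L, ncol, A, diffuse_per_um, packing) {
  diffuse <- min(A, diffuse_per_um * L)
  base <- rep(diffuse / ncol, ncol)
  polar <- A - diffuse
  if (polar <= 0) return(base)
  x <- min(L, polar / packing)
  if (x <= 0) { base[1] <- base[1] + polar; return(base) }
  edges <- seq(0, L, length.out = ncol + 1)
  overlap <- pmax(0, pmin(edges[-1], x) - pmin(edges[-(ncol + 1)], x))
  base + polar * overlap / sum(overlap)
}

#' Draw uncensored replicative lifespans from a hazard schedule
#'
#' Samples, for `n` independent individuals, the pole age at which they stop
#' dividing: at each pole age `a` (starting from 1) the individual stops with
#' probability `h(a)`, else divides and moves to age `a + 1`. The result feeds
#' directly into [stop_curve()] (all fates `"stopped"`, no censoring).
#'
#' @param n number of individuals.
#' @param schedule a [hazard_schedule()].
#' @param seed optional integer seed.
#' @param max_age safety cap on the stop age.
#' @return data.frame with `individual_id`, `n_divisions`, `stop_pole_age`,
#'   `fate`, `included`.
#' @export
simulate_individuals <- function(n, schedule, seed = NULL, max_age = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  alive <- rep(TRUE, n)
  stop_age <- rep(NA_integer_, n)
  a <- 1L
  while (any(alive) && a <= max_age) {
    p <- hazard_at(schedule, a)
    if (p > 0) {
      s <- alive & (stats::runif(n) < p)
      stop_age[s] <- a
      alive <- alive & !s
    }
    a <- a + 1L
  }
  if (any(alive)) {
    poleage_error("poleage_config_error",
                  "some individuals never stopped within max_age; schedule hazard too small")
  }
  data.frame(individual_id = sprintf("s%06d", seq_len(n)),
             n_divisions = stop_age - 1L,
             stop_pole_age = stop_age,
             fate = "stopped",
             included = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate microplate optical-density growth curves
#'
#' Generates one or more OD600 time courses: constant at `od0` during the lag,
#' exactly exponential at the given per-minute rate below half the carrying
#' capacity, then a logistic approach to `od_max`; each read carries
#' multiplicative lognormal noise.
#'
#' @param growth_rate per-minute exponential growth rate.
#' @param od0 initial optical density.
#' @param lag lag time, minutes.
#' @param od_max saturation OD (> `od0`).
#' @param noise_cv coefficient of variation of the per-read noise.
#' @param rate_cv well-to-well coefficient of variation of the growth rate
#'   (lognormal across wells; default 0 = all wells share the nominal rate).
#' @param read_interval minutes between reads (default 2).
#' @param duration total read time, minutes.
#' @param n_wells number of wells.
#' @param strain strain label recycled across wells.
#' @param seed optional integer seed.
#' @return data.frame with `well`, `strain`, `time_min`, `od600`.
#' @export
simulate_od <- function(growth_rate, od0 = 0.005, lag = 120, od_max = 1.2,
                        noise_cv = 0.01, rate_cv = 0, read_interval = 2,
                        duration = 600, n_wells = 1L, strain = "strain",
                        seed = NULL) {
  if (any(growth_rate <= 0)) {
    poleage_error("poleage_config_error", "growth rate must be positive")
  }
  if (od_max <= od0) {
    poleage_error("poleage_config_error", "od_max must exceed od0")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = read_interval)
  clean <- function(t, r) {
    e <- ifelse(t <= lag, od0, od0 * exp(r * (t - lag)))
    half <- od_max / 2
    if (any(e > half)) {
      t_half <- lag + log(half / od0) / r
      lo <- e > half
      e[lo] <- od_max / (1 + exp(-r * (t[lo] - t_half)))
    }
    e
  }
  s2 <- log(1 + noise_cv^2)
  sr2 <- log(1 + rate_cv^2)
  strain_w <- rep_len(strain, n_wells)
  out <- lapply(seq_len(n_wells), function(w) {
    r_w <- if (rate_cv > 0) {
      growth_rate * stats::rlnorm(1, meanlog = -sr2 / 2, sdlog = sqrt(sr2))
    } else growth_rate
    noise <- if (noise_cv > 0) {
      stats::rlnorm(length(times), meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else rep(1, length(times))
    data.frame(well = sprintf("w%02d", w),
               strain = strain_w[w],
               time_min = times,
               od600 = clean(times, r_w) * noise,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read simulator configuration as YAML
#'
#' Keys mirror [sim_config()]; the hazard schedule is stored as `hazard` (the
#' per-age vector) and `hazard_tail`, the fluorescence block under `fluor`.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$hazard <- config$schedule$h
  x$hazard_tail <- config$schedule$tail
  x$schedule <- NULL
  if (!is.null(x$fluor)) x$fluor <- unclass(x$fluor)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sched <- hazard_schedule(unlist(x$hazard %||% numeric(0)),
                           tail = x$hazard_tail %||% 0)
  fl <- if (!is.null(x$fluor)) do.call(fluor_config, x$fluor) else NULL
  sim_config(schedule = sched, seed = x$seed,
             interdivision_mean = x$interdivision_mean,
             interdivision_cv = x$interdivision_cv,
             duration = x$duration, frame_interval = x$frame_interval,
             geometry = x$geometry, n_founders = x$n_founders,
             n_channels = x$n_channels,
             mm_generations = x$mm_generations %||% 3L,
             birth_length_um = x$birth_length_um,
             division_noise_cv = x$division_noise_cv,
             residual_elongation = x$residual_elongation,
             elongation_ramp_min = x$elongation_ramp_min,
             last_division_size_penalty = x$last_division_size_penalty,
             fluor = fl)
}

#' Run manifest for reproducible pipeline artifacts
#'
#' Records the configuration (as plain lists), the seed, the package version
#' and a content hash in a JSON manifest, so that a pipeline run is fully
#' identified by one file.
#'
#' @param config any serializable list-like configuration.
#' @param seed the seed used.
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
pipeline_manifest <- function(config, seed, path) {
  payload <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  # polynomial rolling hash over the serialized configuration
  hash <- 7
  for (b in utf8ToInt(as.character(payload))) {
    hash <- (hash * 31 + b) %% 2147483647
  }
  manifest <- list(config = config, seed = seed,
                   config_hash = sprintf("%08x", hash),
                   package = "poleage",
                   version = as.character(utils::packageVersion("poleage")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(manifest)
}
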