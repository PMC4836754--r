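#' Read and write time-lapse tracking tables
#'
#' A tracking table holds one row per cell and frame, as produced by
#' segmentation/tracking software or by [simulate_lineage()]. The CSV header
#' starts with the canonical columns
#' `frame,time_min,cell_id,parent_id,length_um,mean_fluor,pixel_count,channel_id`;
#' any trailing columns (e.g. `old_pole_child`, ground-truth signal totals,
#' `profile`) are preserved. An empty `parent_id` marks a root cell.
#'
#' @param path file path of the CSV.
#' @return `read_tracking_table`: a data.frame with `parent_id` as `NA` for
#'   roots.
#' @export
read_tracking_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("frame", "time_min", "cell_id", "parent_id", "length_um",
                 "mean_fluor", "pixel_count", "channel_id")
  if (length(names(tab)) < length(canonical) ||
      !identical(names(tab)[seq_along(canonical)], canonical)) {
    poleage_error("poleage_io_error",
                  paste0("tracking CSV header must start with: ",
                         paste(canonical, collapse = ",")))
  }
  tab$cell_id <- as.character(tab$cell_id)
  tab$parent_id <- as.character(tab$parent_id)
  tab$parent_id[!nzchar(tab$parent_id) | is.na(tab$parent_id)] <- NA_character_
  tab
}

#' @rdname read_tracking_table
#' @param table a tracking-table data.frame.
#' @export
write_tracking_table <- function(table, path) {
  tab <- table
  tab$parent_id[is.na(tab$parent_id)] <- ""
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_tracking <- function(table) {
  needed <- c("frame", "time_min", "cell_id", "parent_id", "length_um")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    poleage_error("poleage_io_error",
                  paste("tracking table lacks columns:", paste(miss, collapse = ", ")))
  }
  if (any(table$length_um <= 0, na.rm = TRUE)) {
    poleage_error("poleage_validation_error", "cell lengths must be positive")
  }
  if (any(table$time_min < 0, na.rm = TRUE)) {
    poleage_error("poleage_validation_error", "times must be non-negative")
  }
  ord <- order(table$cell_id, table$frame)
  t_ord <- table$time_min[ord]
  id_ord <- table$cell_id[ord]
  same <- id_ord[-1] == id_ord[-length(id_ord)]
  if (any(same & diff(t_ord) <= 0)) {
    poleage_error("poleage_validation_error",
                  "time must strictly increase with frame within each cell")
  }
  invisible(TRUE)
}

#' Build a binary lineage tree from a tracking table
#'
#' Collapses the per-frame tracking rows into one node per cell cycle (a cell
#' identity between two divisions) and connects parents to their two
#' post-division children. The division time of a parent is taken as the time
#' of its last observed frame. Cells without children are leaves: cells still
#' present at the end of the experiment, cells that stopped dividing, or cells
#' that left the field of view (e.g. pushed out of a mother-machine channel).
#'
#' @param table a tracking-table data.frame (see [read_tracking_table()]).
#' @return an object of class `lineage_tree`: a list with `cells` (one row per
#'   cell cycle: `cell_id`, `parent_id`, `first_time`, `last_time`,
#'   `first_frame`, `last_frame`, `last_length`, `n_children`,
#'   `old_pole_child`, `channel_id`), `roots` (cell ids) and the original
#'   `table`.
#' @export
build_lineage <- function(table) {
  validate_tracking(table)
  ids <- unique(table$cell_id)
  first_idx <- match(ids, table$cell_id)
  o <- order(table$cell_id, table$frame)
  tab_o <- table[o, , drop = FALSE]
  last_of <- !duplicated(tab_o$cell_id, fromLast = TRUE)
  first_of <- !duplicated(tab_o$cell_id)
  firsts <- tab_o[first_of, , drop = FALSE]
  lasts <- tab_o[last_of, , drop = FALSE]
  m <- match(ids, firsts$cell_id)
  ml <- match(ids, lasts$cell_id)
  cells <- data.frame(
    cell_id = ids,
    parent_id = firsts$parent_id[m],
    first_frame = firsts$frame[m],
    first_time = firsts$time_min[m],
    last_frame = lasts$frame[ml],
    last_time = lasts$time_min[ml],
    first_length = firsts$length_um[m],
    last_length = lasts$length_um[ml],
    stringsAsFactors = FALSE
  )
  if ("mean_fluor" %in% names(table)) {
    cells$first_mean_fluor <- firsts$mean_fluor[m]
    cells$first_pixel_count <- firsts$pixel_count[m]
  }
  if ("old_pole_child" %in% names(table)) {
    cells$old_pole_child <- firsts$old_pole_child[m]
  } else {
    cells$old_pole_child <- NA_real_
  }
  cells$channel_id <- if ("channel_id" %in% names(table)) firsts$channel_id[m] else NA_character_

  non_root <- !is.na(cells$parent_id)
  orphan <- non_root & !(cells$parent_id %in% cells$cell_id)
  if (any(orphan)) {
    poleage_error("poleage_missing_reference",
                  paste("parent_id not found for cells:",
                        paste(utils::head(cells$cell_id[orphan], 5), collapse = ", ")))
  }
  kid_counts <- table(cells$parent_id[non_root])
  cells$n_children <- as.integer(kid_counts[cells$cell_id])
  cells$n_children[is.na(cells$n_children)] <- 0L
  if (any(cells$n_children > 2L)) {
    poleage_error("poleage_malformed_division",
                  "a cell has more than two children; divisions must be binary")
  }
  if (any(cells$n_children == 1L)) {
    poleage_error("poleage_malformed_division",
                  "a division produced a single tracked child; each division must yield two")
  }
  # cycle check: walking up parent pointers must terminate at a root
  pidx <- match(cells$parent_id, cells$cell_id)
  depth <- rep(NA_integer_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    j <- i
    steps <- 0L
    while (!is.na(pidx[j])) {
      if (!is.na(depth[j])) { steps <- steps + depth[j]; j <- NA_integer_; break }
      j <- pidx[j]
      steps <- steps + 1L
      if (steps > nrow(cells)) {
        poleage_error("poleage_structural_error", "cycle detected in parent pointers")
      }
    }
    depth[i] <- steps
  }
  structure(list(cells = cells,
                 roots = cells$cell_id[is.na(cells$parent_id)],
                 table = table),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("Lineage tree:", nrow(x$cells), "cell cycles,",
      length(x$roots), "root(s),",
      sum(x$cells$n_children == 2L), "divisions\n")
  invisible(x)
}

#' Assign pole ages and pole-defined individual identities
#'
#' Implements pole-age bookkeeping on a lineage tree: every cell carries the
#' age of its older pole, and the older pole defines the individual. A new
#' individual emerges from division holding a pole of age 1; at each division
#' the old-pole product keeps the individual identity and its pole age
#' increases by one, while the new-pole product starts a new individual at
#' pole age 1. Which child inherits the old pole must be declared in the
#' tracking table (column `old_pole_child`, 1 for the old-pole product); no
#' geometric inference is attempted.
#'
#' Root cells have unknown initial pole age; ages along the root's chain are
#' therefore relative (the root is bookkept as age 1). The `policy` controls
#' which individuals enter downstream statistics:
#' \describe{
#'   \item{`exclude_first_division`}{agar-pad colonies: the founder individual
#'     (whose first division cannot be oriented) is excluded, all others kept.
#'     The default.}
#'   \item{`discard_root_use_last_daughter`}{mother-machine channels with a
#'     short-lived strain: the bottom (root) cell is discarded and only its
#'     last daughter — plus all later individuals — is analyzed.}
#'   \item{`keep_root_as_unknown`}{mother-machine channels for long-lived
#'     strains: the bottom cell is kept, its ages being lower bounds.}
#' }
#'
#' @param tree a [build_lineage()] result.
#' @param policy root-handling policy, see Details.
#' @return an object of class `pole_assignment`: list with `cells` (the tree's
#'   cell table plus `pole_age` and `individual_id`), `individuals` (one row
#'   per individual: `individual_id`, `mother_individual_id`, `birth_index`,
#'   `birth_time_min`, `n_divisions`, `division_times_min` (";"-separated),
#'   `pole_ages_at_division`, `lengths_at_division_um`, `last_obs_time_min`,
#'   `terminal_cell_id`, `founder`, `ambiguous_first_division`, `included`)
#'   and the `policy`.
#' @export
assign_pole_ages <- function(tree,
                             policy = c("exclude_first_division",
                                        "discard_root_use_last_daughter",
                                        "keep_root_as_unknown")) {
  stopifnot(inherits(tree, "lineage_tree"))
  policy <- tryCatch(match.arg(policy),
                     error = function(e) poleage_error("poleage_config_error",
                                                       "unknown root policy"))
  cells <- tree$cells
  n <- nrow(cells)
  idx <- seq_len(n)
  names(idx) <- cells$cell_id
  kids <- split(idx[!is.na(cells$parent_id)], cells$parent_id[!is.na(cells$parent_id)])

  pole_age <- rep(NA_integer_, n)
  ind_of <- rep(NA_character_, n)

  ind <- new.env(parent = emptyenv())
  ind$rows <- list()
  n_ind <- 0L
  new_individual <- function(mother, birth_index, birth_time, founder, channel) {
    n_ind <<- n_ind + 1L
    id <- sprintf("i%05d", n_ind)
    ind$rows[[id]] <- list(individual_id = id, mother_individual_id = mother,
                           birth_index = birth_index, birth_time_min = birth_time,
                           division_times = numeric(0), lengths = numeric(0),
                           last_obs_time_min = NA_real_, terminal_cell_id = NA_character_,
                           founder = founder, channel_id = channel)
    id
  }

  queue <- integer(0)
  for (r in tree$roots) {
    i <- idx[[r]]
    ind_of[i] <- new_individual(NA_character_, NA_integer_, cells$first_time[i],
                                founder = TRUE, channel = cells$channel_id[i])
    pole_age[i] <- 1L
    queue <- c(queue, i)
  }
  head_ptr <- 1L
  while (head_ptr <= length(queue)) {
    i <- queue[head_ptr]; head_ptr <- head_ptr + 1L
    ii <- ind_of[i]
    ch <- kids[[cells$cell_id[i]]]
    if (is.null(ch) || length(ch) == 0L) {
      ind$rows[[ii]]$last_obs_time_min <- cells$last_time[i]
      ind$rows[[ii]]$terminal_cell_id <- cells$cell_id[i]
      next
    }
    flags <- cells$old_pole_child[ch]
    if (anyNA(flags) || sum(flags == 1) != 1L) {
      poleage_error("poleage_orientation_error",
                    paste0("old-pole orientation missing or ambiguous at division of cell ",
                           cells$cell_id[i],
                           "; provide an old_pole_child column with exactly one 1 per sibling pair"))
    }
    old_c <- ch[flags == 1]
    new_c <- ch[flags != 1]
    t_div <- cells$last_time[i]
    rec <- ind$rows[[ii]]
    rec$division_times <- c(rec$division_times, t_div)
    rec$lengths <- c(rec$lengths, cells$last_length[i])
    ind$rows[[ii]] <- rec
    # old-pole product: same individual, one age older
    ind_of[old_c] <- ii
    pole_age[old_c] <- pole_age[i] + 1L
    # new-pole product: a new individual at pole age 1
    ind_of[new_c] <- new_individual(ii, length(rec$division_times), t_div,
                                    founder = FALSE, channel = cells$channel_id[new_c])
    pole_age[new_c] <- 1L
    queue <- c(queue, old_c, new_c)
  }

  cells$pole_age <- pole_age
  cells$individual_id <- ind_of

  rows <- ind$rows
  individuals <- data.frame(
    individual_id = vapply(rows, `[[`, "", "individual_id"),
    mother_individual_id = vapply(rows, `[[`, "", "mother_individual_id"),
    birth_index = vapply(rows, function(r) as.integer(r$birth_index), 1L),
    birth_time_min = vapply(rows, `[[`, 1, "birth_time_min"),
    n_divisions = vapply(rows, function(r) length(r$division_times), 1L),
    last_obs_time_min = vapply(rows, `[[`, 1, "last_obs_time_min"),
    terminal_cell_id = vapply(rows, `[[`, "", "terminal_cell_id"),
    founder = vapply(rows, `[[`, TRUE, "founder"),
    channel_id = vapply(rows, function(r) as.character(r$channel_id %||% NA), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  individuals$division_times_min <- join_semi(lapply(rows, `[[`, "division_times"))
  individuals$lengths_at_division_um <- join_semi(lapply(rows, `[[`, "lengths"))
  individuals$ambiguous_first_division <- individuals$founder

  included <- !individuals$founder
  if (policy == "keep_root_as_unknown") {
    included <- rep(TRUE, nrow(individuals))
  } else if (policy == "discard_root_use_last_daughter") {
    founder_ids <- individuals$individual_id[individuals$founder]
    for (fid in founder_ids) {
      ndiv <- individuals$n_divisions[individuals$individual_id == fid]
      early <- individuals$mother_individual_id %in% fid &
        individuals$birth_index < ndiv
      included[early] <- FALSE
    }
  }
  individuals$included <- included

  structure(list(cells = cells, individuals = individuals, policy = policy,
                 table = tree$table),
            class = "pole_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pole_assignment <- function(x, ...) {
  cat("Pole-age assignment (policy:", x$policy, ")\n")
  cat(" ", nrow(x$individuals), "individuals,",
      sum(x$individuals$included), "included for statistics\n")
  invisible(x)
}

#' Pole-age census of a lineage
#'
#' Tabulates pole ages over cells of an annotated lineage tree. In a fully
#' dividing population the leaf census recovers the exponential pole-age
#' distribution: a fraction \eqn{2^{-n}} of cells holds a pole of age `n`.
#'
#' @param assigned a [assign_pole_ages()] result.
#' @param leaves_only count only terminal cell cycles (default) or all cycles.
#' @return data.frame with `pole_age`, `count` and `fraction`.
#' @export
pole_age_census <- function(assigned, leaves_only = TRUE) {
  stopifnot(inherits(assigned, "pole_assignment"))
  cells <- assigned$cells
  if (leaves_only) cells <- cells[cells$n_children == 0L, , drop = FALSE]
  tab <- table(factor(cells$pole_age, levels = seq_len(max(cells$pole_age))))
  data.frame(pole_age = as.integer(names(tab)),
             count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}

#' Write / read the per-individual summary CSV
#'
#' Columns: `individual_id,birth_time_min,n_divisions,fate,stop_pole_age,`
#' `division_times_min` (";"-separated), plus bookkeeping columns used by the
#' lifespan statistics.
#'
#' @param individuals the `individuals` data.frame of a [assign_pole_ages()]
#'   result (optionally after [assign_fates()]).
#' @param path output CSV path.
#' @export
write_individuals <- function(individuals, path) {
  cols <- c("individual_id", "birth_time_min", "n_divisions", "fate",
            "stop_pole_age", "division_times_min")
  ind <- individuals
  if (!"fate" %in% names(ind)) ind$fate <- NA_character_
  if (!"stop_pole_age" %in% names(ind)) ind$stop_pole_age <- NA_integer_
  extra <- setdiff(names(ind), cols)
  utils::write.csv(ind[, c(cols, extra)], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_individuals
#' @export
read_individuals <- function(path) {
  ind <- utils::read.csv(path, stringsAsFactors = FALSE)
  ind$individual_id <- as.character(ind$individual_id)
  ind
}
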