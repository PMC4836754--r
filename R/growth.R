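#' Doubling time from a windowed log-linear fit of an OD600 series
#'
#' Restricts the series to readings with OD between the window bounds
#' (inclusive), regresses the natural log of OD on time, and converts the
#' slope to a doubling time `log(2)/slope`. The base of the logarithm is
#' immaterial: regressing log2(OD) and taking `1/slope` gives the identical
#' estimate. A fit is rejected when the windowed R-squared (squared Pearson
#' product-moment correlation) falls below `r2_min` or the slope is not
#' positive.
#'
#' @param time_min,od600 the series (minutes, OD600 readings > 0).
#' @param window inclusive OD window; default `c(0.0625, 0.125)`.
#' @param r2_min minimum windowed R-squared; default 0.99.
#' @return an object of class `doubling_fit`: list with `doubling_time_min`
#'   (NA when rejected), `slope_per_min`, `r_squared`, `n_points`, `accepted`,
#'   `reason`.
#' @examples
#' t <- seq(0, 400, by = 2)
#' fit <- estimate_doubling_time(t, 0.005 * exp(log(2) / 40 * t))
#' fit$doubling_time_min  # 40
#' @export
estimate_doubling_time <- function(time_min, od600, window = c(0.0625, 0.125),
                                   r2_min = 0.99) {
  if (any(od600 <= 0, na.rm = TRUE)) {
    poleage_error("poleage_validation_error", "OD readings must be positive")
  }
  inw <- which(od600 >= window[1] & od600 <= window[2])
  if (length(inw) < 3L) {
    poleage_error("poleage_insufficient_window",
                  sprintf("only %d readings inside the OD window [%g, %g]; need >= 3",
                          length(inw), window[1], window[2]))
  }
  fit <- stats::lm(log(od600[inw]) ~ time_min[inw])
  slope <- unname(stats::coef(fit)[2])
  # summary.lm warns on exact fits (noiseless exponentials); R^2 is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- list(doubling_time_min = NA_real_, slope_per_min = slope,
              r_squared = r2, n_points = length(inw),
              accepted = FALSE, reason = NA_character_)
  if (slope <= 0) {
    out$reason <- "non-positive slope"
  } else if (r2 < r2_min) {
    out$reason <- sprintf("r_squared %.4f below %.2f", r2, r2_min)
  } else {
    out$doubling_time_min <- log(2) / slope
    out$accepted <- TRUE
  }
  class(out) <- "doubling_fit"
  out
}

#' @export
print.doubling_fit <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("Doubling time %.2f min (R^2 = %.4f, %d in-window reads)\n",
                x$doubling_time_min, x$r_squared, x$n_points))
  } else {
    cat("Rejected fit:", x$reason, "\n")
  }
  invisible(x)
}

#' Per-well doubling-time estimates for a whole plate
#'
#' @param od data.frame with columns `well`, `strain`, `time_min`, `od600`
#'   (see [simulate_od()] / [read_od_series()]).
#' @inheritParams estimate_doubling_time
#' @return data.frame with one row per well: `well`, `strain`,
#'   `doubling_time_min`, `r_squared`, `n_points`, `accepted`, `reason`.
#' @export
estimate_plate <- function(od, window = c(0.0625, 0.125), r2_min = 0.99) {
  out <- lapply(split(od, paste(od$strain, od$well)), function(d) {
    d <- d[order(d$time_min), ]
    fit <- tryCatch(
      estimate_doubling_time(d$time_min, d$od600, window, r2_min),
      poleage_insufficient_window = function(e) {
        list(doubling_time_min = NA_real_, slope_per_min = NA_real_,
             r_squared = NA_real_, n_points = 0L, accepted = FALSE,
             reason = "insufficient window")
      })
    data.frame(well = d$well[1], strain = d$strain[1],
               doubling_time_min = fit$doubling_time_min,
               r_squared = fit$r_squared, n_points = fit$n_points,
               accepted = fit$accepted,
               reason = ifelse(is.na(fit$reason), "", fit$reason),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare doubling times between two strains
#'
#' Means and standard errors of the accepted per-well doubling times of each
#' strain, with a Welch two-sample t test and the 95% confidence interval of
#' the difference (strain A minus strain B).
#'
#' @param estimates a data.frame as from [estimate_plate()] containing both
#'   strains, or for `strain_a`/`strain_b` two numeric vectors of accepted
#'   per-well doubling times.
#' @param strain_a,strain_b the two strain labels (taken from the data when
#'   `NULL` and exactly two strains are present).
#' @return list with per-strain `n`, `mean`, `se`, plus `difference`,
#'   `conf_int` (95%), `p_value`.
#' @export
compare_strains <- function(estimates, strain_a = NULL, strain_b = NULL) {
  if (is.data.frame(estimates)) {
    acc <- estimates[estimates$accepted & !is.na(estimates$doubling_time_min), ]
    strains <- unique(acc$strain)
    if (is.null(strain_a)) {
      if (length(strains) != 2L) {
        poleage_error("poleage_config_error",
                      "need exactly two strains (or name them explicitly)")
      }
      strain_a <- strains[1]; strain_b <- strains[2]
    }
    a <- acc$doubling_time_min[acc$strain == strain_a]
    b <- acc$doubling_time_min[acc$strain == strain_b]
  } else {
    a <- estimates; b <- strain_a
    strain_a <- "A"; strain_b <- "B"
  }
  if (length(a) < 2L || length(b) < 2L) {
    poleage_error("poleage_empty_group",
                  "fewer than 2 accepted wells in a group; SE undefined")
  }
  tt <- stats::t.test(a, b)
  list(strains = c(strain_a, strain_b),
       n = c(length(a), length(b)),
       mean = c(mean(a), mean(b)),
       se = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))),
       difference = mean(a) - mean(b),
       conf_int = unname(tt$conf.int),
       p_value = tt$p.value)
}

#' Write / read an OD600 plate CSV (`well,strain,time_min,od600`)
#'
#' @param od the plate data.frame.
#' @param path CSV path.
#' @export
write_od_series <- function(od, path) {
  utils::write.csv(od[, c("well", "strain", "time_min", "od600")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_od_series
#' @export
read_od_series <- function(path) {
  od <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "strain", "time_min", "od600")
  if (!all(need %in% names(od))) {
    poleage_error("poleage_io_error",
                  paste("OD CSV needs columns:", paste(need, collapse = ",")))
  }
  od
}
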