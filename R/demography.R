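#' Per-pole-age hazard schedule
#'
#' A hazard schedule gives, for each pole age \eqn{a = 1, 2, \dots}, the
#' probability \eqn{h(a)} that a cell holding pole age \eqn{a} never divides
#' again, i.e. that its previous division was its last. Ages beyond the
#' explicitly listed ones take the `tail` value.
#'
#' @param h numeric vector of per-age stop probabilities for ages `1..length(h)`;
#'   all values in \[0, 1\].
#' @param tail stop probability for every age beyond `length(h)`; defaults to
#'   the last listed value (0 for an empty `h`).
#' @return an object of class `hazard_schedule`.
#' @examples
#' sched <- hazard_schedule(c(0, 0, 0.25, 0.40, 0.55, 0.65))
#' hazard_at(sched, 1:8)
#' @export
hazard_schedule <- function(h = numeric(0), tail = if (length(h)) h[length(h)] else 0) {
  h <- as.numeric(h)
  if (any(is.na(h)) || any(h < 0) || any(h > 1)) {
    poleage_error("poleage_config_error", "hazard values must lie in [0, 1]")
  }
  if (length(tail) != 1L || is.na(tail) || tail < 0 || tail > 1) {
    poleage_error("poleage_config_error", "tail hazard must be a single value in [0, 1]")
  }
  structure(list(h = h, tail = as.numeric(tail)), class = "hazard_schedule")
}

#' @rdname hazard_schedule
#' @param schedule a `hazard_schedule`.
#' @param ages integer vector of pole ages (>= 1).
#' @export
hazard_at <- function(schedule, ages) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  if (any(ages < 1)) poleage_error("poleage_domain_error", "pole ages start at 1")
  ifelse(ages <= length(schedule$h), schedule$h[pmin(ages, length(schedule$h))], schedule$tail)
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat("Per-pole-age hazard schedule\n")
  cat("  ages 1..", length(x$h), ": ", paste(format(x$h), collapse = " "),
      "  (tail ", format(x$tail), ")\n", sep = "")
  invisible(x)
}

#' Survivorship: probability of completing the n-th division
#'
#' `l(n)` is the probability that an individual completes its \eqn{n}-th
#' division, the cumulative product \eqn{\prod_{i=1}^{n} (1 - h(i))} of the
#' per-age probabilities of continuing to divide. The empty product gives
#' `l(0) = 1`.
#'
#' @param schedule a [hazard_schedule()].
#' @param n vector of division indices (>= 1; 0 is allowed and gives 1).
#' @return numeric vector of survivorships, non-increasing in `n`.
#' @examples
#' survivorship(hazard_schedule(c(0, 0, 0.25, 0.40)), 1:4)  # 1 1 0.75 0.45
#' @export
survivorship <- function(schedule, n) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  if (any(n < 0)) poleage_error("poleage_domain_error", "division index must be >= 0")
  nmax <- max(n, 0L)
  if (nmax == 0L) return(rep(1, length(n)))
  l <- cumprod(1 - hazard_at(schedule, seq_len(nmax)))
  c(1, l)[n + 1L]
}

#' Age-structured demographic model of pole-age-specific mortality
#'
#' Couples a fixed interdivision time `T` (minutes) with a per-pole-age
#' [hazard_schedule()]. Each completed division contributes exactly one
#' newborn individual (the new-pole daughter); the old-pole cell retains its
#' identity and moves up one pole-age class. The Malthusian rate `r` solves
#' the discrete-renewal Euler-Lotka equation
#' \deqn{1 = \sum_{n \ge 1} l(n)\, e^{-r n T}.}
#'
#' @param T interdivision time in minutes (> 0).
#' @param schedule a [hazard_schedule()].
#' @param n_terms_cap hard cap on the number of renewal terms (default 500).
#' @param term_tol terms with \eqn{l(n) x^n} below this are dropped (default 1e-16).
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(T, schedule, n_terms_cap = 500L, term_tol = 1e-16) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0) {
    poleage_error("poleage_config_error", "interdivision time T must be a positive scalar")
  }
  stopifnot(inherits(schedule, "hazard_schedule"))
  structure(list(T = T, schedule = schedule,
                 n_terms_cap = as.integer(n_terms_cap), term_tol = term_tol),
            class = "demographic_model")
}

# survivorship sequence l(1..cap), truncated where it hits exact zero
el_survivorship_seq <- function(model) {
  l <- survivorship(model$schedule, seq_len(model$n_terms_cap))
  nz <- which(l > 0)
  if (!length(nz)) return(numeric(0))
  l[seq_len(max(nz))]
}

#' Solve the Euler-Lotka equation for the population growth rate
#'
#' Finds the per-minute Malthusian rate `r` satisfying
#' \eqn{1 = \sum_n l(n) e^{-r n T}} by bisection on \eqn{x = e^{-rT}} over
#' (0, 1) to an `x`-tolerance of 1e-14, then `r = -log(x)/T`. With an all-zero
#' hazard the closed form `r = log(2)/T` is returned exactly.
#'
#' @param model a [demographic_model()].
#' @return the per-minute growth rate `r` (numeric scalar).
#' @examples
#' m <- demographic_model(T = 40, hazard_schedule())  # immortal reference
#' euler_lotka_rate(m) * 40 / log(2)                  # 1
#' @export
euler_lotka_rate <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  h <- model$schedule
  if (length(h$h) == 0 && h$tail == 0) return(log(2) / model$T)
  if (all(h$h == 0) && h$tail == 0) return(log(2) / model$T)
  l <- el_survivorship_seq(model)
  if (!length(l) || max(l) <= 0) {
    poleage_error("poleage_no_growth", "no positive fecundity: every individual stops before dividing")
  }
  n <- seq_along(l)
  f <- function(x) sum(l * x^n) - 1
  lo <- 0
  hi <- 1 - 1e-12
  if (f(hi) < 0) {
    poleage_error("poleage_no_growth",
                  "expected lifetime offspring <= 1: population cannot grow")
  }
  while (hi - lo > 1e-14) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  x <- (lo + hi) / 2
  -log(x) / model$T
}

#' Relative growth-rate reduction due to age-specific mortality
#'
#' Compares the Euler-Lotka rate `r` under the model's hazard schedule with
#' the immortal reference \eqn{r_0 = \log(2)/T} and returns the dimensionless
#' relative reduction \eqn{(r_0 - r)/r_0}. For schedules expressed per
#' division the result is invariant under rescaling of `T`.
#'
#' @param model a [demographic_model()].
#' @return relative reduction in \[0, 1\].
#' @export
growth_reduction <- function(model) {
  r <- euler_lotka_rate(model)
  r0 <- log(2) / model$T
  (r0 - r) / r0
}

#' Stable pole-age distribution of an exponentially growing population
#'
#' In the stable age structure, the fraction of extant cells holding pole age
#' \eqn{n} is proportional to \eqn{l(n-1)\,(x^{n-1} - x^{n})} with
#' \eqn{x = e^{-rT}} and \eqn{l} the survivorship; it is normalized to sum to
#' one over the computed range. With zero hazard this reduces to the classic
#' \eqn{2^{-n}}: half of all cells hold a pole of age one, a quarter age two,
#' and so on.
#'
#' @param model a [demographic_model()].
#' @param n_max largest pole age reported; defaults to where the mass falls
#'   below `model$term_tol` (capped at `n_terms_cap`).
#' @return data.frame with columns `pole_age` and `fraction` (sums to 1).
#' @export
stable_pole_age_distribution <- function(model, n_max = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (hazard_at(model$schedule, 1L) >= 1) {
    poleage_error("poleage_no_growth",
                  "every cell stops before its first division: no stable age structure")
  }
  r <- euler_lotka_rate(model)
  x <- exp(-r * model$T)
  cap <- if (is.null(n_max)) model$n_terms_cap else as.integer(n_max)
  ages <- seq_len(cap)
  S <- survivorship(model$schedule, ages - 1L)   # S(n-1), S(0) = 1
  w <- S * (x^(ages - 1L) - x^ages)
  if (is.null(n_max)) {
    keep <- which(w > model$term_tol)
    if (length(keep)) {
      ages <- ages[seq_len(max(keep))]
      w <- w[seq_len(max(keep))]
    }
  }
  data.frame(pole_age = ages, fraction = w / sum(w))
}

#' Mortality-onset sweep of the growth-rate reduction
#'
#' Shifts a hazard schedule so that its first nonzero hazard occurs at each
#' requested onset pole age (zeros are prepended or stripped; the shape of the
#' hazard sequence from onset onward is preserved) and computes the relative
#' growth-rate reduction for each onset. The reduction is strictly decreasing
#' in the onset age: mortality confined to ever-older pole ages affects an
#' exponentially shrinking fraction of the population.
#'
#' @param schedule a [hazard_schedule()] with at least one nonzero hazard.
#' @param onsets positive integer vector of onset pole ages.
#' @param T interdivision time in minutes (the reduction does not depend on it).
#' @return data.frame with columns `onset_age` and `reduction`.
#' @examples
#' onset_sweep(hazard_schedule(numeric(0), tail = 1), onsets = c(3, 17, 18))
#' @export
onset_sweep <- function(schedule, onsets, T = 40) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  onsets <- as.integer(onsets)
  if (any(onsets < 1)) poleage_error("poleage_domain_error", "onset ages must be >= 1")
  nz <- which(schedule$h > 0)
  if (length(nz)) {
    core <- schedule$h[min(nz):length(schedule$h)]
  } else if (schedule$tail > 0) {
    core <- numeric(0)          # hazard begins in the tail
  } else {
    poleage_error("poleage_config_error", "onset sweep needs a schedule with some nonzero hazard")
  }
  red <- vapply(onsets, function(a) {
    shifted <- hazard_schedule(c(rep(0, a - 1L), core), tail = schedule$tail)
    tryCatch(growth_reduction(demographic_model(T, shifted)),
             poleage_no_growth = function(e) 1)   # total loss of growth
  }, numeric(1))
  data.frame(onset_age = onsets, reduction = red, no_growth = red >= 1)
}

#' Selection threshold set by the effective population size
#'
#' Purifying selection removes deleterious effects larger than roughly the
#' reciprocal of the effective population size; smaller effects are
#' effectively neutral and can accumulate over evolutionary time.
#'
#' @param Ne effective population size (> 0).
#' @param reduction optional relative growth-rate reduction(s) to classify.
#' @return list with `threshold` (= 1/Ne) and, when `reduction` is supplied,
#'   a character `verdict` per value: `"purged"` if reduction >= threshold,
#'   else `"effectively_neutral"`.
#' @examples
#' selection_threshold(1e5, reduction = c(0.06, 5.5e-6))
#' @export
selection_threshold <- function(Ne, reduction = NULL) {
  if (!is.numeric(Ne) || length(Ne) != 1L || Ne <= 0) {
    poleage_error("poleage_config_error", "Ne must be a positive scalar")
  }
  out <- list(threshold = 1 / Ne)
  if (!is.null(reduction)) {
    out$reduction <- reduction
    out$verdict <- ifelse(reduction >= out$threshold, "purged", "effectively_neutral")
  }
  out
}

#' Leslie projection matrix for pole-age classes
#'
#' Independent cross-check of the Euler-Lotka solver. One projection step is
#' one division interval `T`. A cell in pole-age class `i` completes its
#' division with probability \eqn{1 - h(i)}, in which case it contributes one
#' newborn to class 1 and itself advances to class `i + 1`.
#'
#' @param schedule a [hazard_schedule()].
#' @param n_classes number of pole-age classes kept; survival out of the last
#'   class is discarded, so choose `n_classes` large enough that the
#'   survivorship is negligible there (exact when some age has hazard 1).
#' @return an `n_classes` x `n_classes` matrix.
#' @export
leslie_matrix <- function(schedule, n_classes) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  n_classes <- as.integer(n_classes)
  p <- 1 - hazard_at(schedule, seq_len(n_classes))
  A <- matrix(0, n_classes, n_classes)
  A[1, ] <- p
  for (i in seq_len(n_classes - 1L)) A[i + 1L, i] <- p[i]
  A
}

#' @rdname leslie_matrix
#' @param T interdivision time in minutes.
#' @return `leslie_growth_rate`: per-minute rate `log(lambda)/T`, with
#'   `lambda` the dominant eigenvalue.
#' @export
leslie_growth_rate <- function(schedule, T, n_classes = 200L) {
  A <- leslie_matrix(schedule, n_classes)
  lambda <- max(Re(eigen(A, only.values = TRUE)$values))
  if (lambda <= 0) poleage_error("poleage_no_growth", "non-positive dominant eigenvalue")
  log(lambda) / T
}
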