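#' Hill dose-response curve
#'
#' `y = fmax * c^n / (K^n + c^n)`, the phenomenological model of cooperative
#' triplet invasion of structured templates: extension switches on steeply
#' once the substrate concentration suffices to invade and unravel template
#' secondary structure.
#'
#' @param conc Concentrations (>= 0).
#' @param fmax Saturating response.
#' @param K Half-saturation concentration.
#' @param n Hill coefficient.
#' @return Numeric vector of responses.
#' @export
hill_curve <- function(conc, fmax, K, n) {
  fmax * conc^n / (K^n + conc^n)
}

#' Fit a Hill model to dose-response data
#'
#' Deterministic multi-start least squares: Levenberg-Marquardt fits are run
#' from a fixed grid of starting values (`n` in {0.5, 1, 2, 4, 8}, `K` at the
#' quartiles of the positive concentrations, `fmax` at the maximum response)
#' and the best converged fit is returned. `fmax` is bounded to (0, 1.2]
#' (extension fractions slightly above 1 absorb normalisation error), `K` and
#' `n` to positive values.
#'
#' @param data Tibble with columns `conc` and `response` (at least 4 points
#'   spanning at least a 4-fold concentration range).
#' @return Object of class `hill_fit`: list with `fmax`, `K`, `n`, `rss`,
#'   `fitted` (tibble of data plus fitted values), `starts` (per-start
#'   diagnostics), `n_obs`.
#' @examples
#' d <- gen_dose_response(1, 2, 4, c(0.5, 1, 2, 4, 8))
#' hill_fit(d)
#' @export
hill_fit <- function(data) {
  stopifnot(all(c("conc", "response") %in% names(data)))
  conc <- data$conc
  y <- data$response
  if (length(conc) < 4L) abort("at least 4 dose-response points are required.")
  pos <- conc[conc > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 4)
    abort("concentrations must span at least a 4-fold range.")

  f0 <- min(max(max(y), 1e-3), 1.2)
  k_starts <- unique(unname(quantile(pos, c(0.25, 0.5, 0.75))))
  n_starts <- c(0.5, 1, 2, 4, 8)
  grid <- tidyr::expand_grid(n0 = n_starts, K0 = k_starts)

  fits <- purrr::pmap(grid, function(n0, K0) {
    start <- list(fmax = f0, K = K0, n = n0)
    rss0 <- sum((y - hill_curve(conc, f0, K0, n0))^2)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ fmax * conc^n / (K^n + conc^n),
        data = data.frame(conc = conc, response = y),
        start = start,
        lower = c(fmax = 1e-9, K = 1e-12, n = 1e-3),
        upper = c(fmax = 1.2, K = Inf, n = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      list(ok = FALSE, rss = Inf, rss0 = rss0, start = start,
           message = conditionMessage(fit))
    } else {
      p <- as.list(stats::coef(fit))
      list(ok = TRUE, rss = sum(stats::resid(fit)^2), rss0 = rss0,
           start = start, par = p, message = NA_character_)
    }
  })

  starts <- tibble(
    n0 = grid$n0, K0 = grid$K0,
    converged = purrr::map_lgl(fits, "ok"),
    rss_start = purrr::map_dbl(fits, "rss0"),
    rss = purrr::map_dbl(fits, "rss"),
    message = purrr::map_chr(fits, "message")
  )
  if (!any(starts$converged))
    abort(c("Hill fit failed from every start.",
            stats::setNames(starts$message[!starts$converged],
                            rep("x", sum(!starts$converged)))))
  best <- fits[[which.min(starts$rss)]]
  p <- best$par
  structure(
    list(
      fmax = p$fmax, K = p$K, n = p$n, rss = best$rss,
      fitted = tibble(conc = conc, response = y,
                      fitted = hill_curve(conc, p$fmax, p$K, p$n)),
      starts = starts,
      n_obs = length(conc)
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: fmax = %.4g, K = %.4g, n = %.3g (RSS %.3g, %d points)\n",
    x$fmax, x$K, x$n, x$rss, x$n_obs))
  invisible(x)
}

#' Free concentrations of one triplet:anti-triplet pair
#'
#' Mass-action dimerization of a complementary pair A + B <-> AB with
#' dissociation constant `Kd` (`free_a * free_b = Kd * dimer`): the unique
#' non-negative solution of the closed-form quadratic under mass balance.
#' Vectorised over all arguments.
#'
#' @param total_a,total_b Total concentrations (>= 0, any shared unit).
#' @param kd Dissociation constant (> 0, same unit).
#' @return Tibble with columns `free_a`, `free_b`, `dimer`.
#' @examples
#' pair_free_concentration(1, 1, 1) # free 0.6180, dimer 0.3820
#' @export
pair_free_concentration <- function(total_a, total_b, kd) {
  stopifnot(all(total_a >= 0), all(total_b >= 0), all(kd > 0))
  s <- total_a + total_b + kd
  # smaller quadratic root, written to avoid cancellation for large kd
  dimer <- 2 * total_a * total_b / (s + sqrt(s^2 - 4 * total_a * total_b))
  dimer[total_a == 0 | total_b == 0] <- 0
  tibble(free_a = unname(total_a - dimer), free_b = unname(total_b - dimer),
         dimer = unname(dimer))
}

#' Specify a triplet pool with an affinity model
#'
#' A pool assigns a total concentration to each of the 64 triplets (default:
#' an equimolar random pool at 5 uM each, the standard `pppNNN` condition)
#' together with a minimal duplex affinity model: the free energy of a
#' triplet:anti-triplet duplex is `g_init + n_gc * g_gc + n_au * g_au` over
#' its three base pairs, and `Kd = exp(dG / RT)` at the given temperature
#' (266 K, the eutectic phase at -7 degrees C). The default increments are
#' illustrative composition parameters, not fitted thermodynamics.
#'
#' @param totals Named numeric vector of total concentrations (uM) for all 64
#'   triplets (names = [all_triplets()]), or a single value recycled.
#' @param g_gc,g_au Free-energy increments per G:C / A:U pair (kcal/mol).
#' @param g_init Duplex initiation penalty (kcal/mol).
#' @param temperature Temperature in K.
#' @return Object of class `pool_spec`.
#' @export
pool_spec <- function(totals = 5, g_gc = -2.0, g_au = -0.5, g_init = 3.5,
                      temperature = 266) {
  trips <- all_triplets()
  if (length(totals) == 1L) totals <- setNames(rep(totals, 64L), trips)
  if (is.null(names(totals)) || !setequal(names(totals), trips))
    abort("totals must be named by the 64 triplets.")
  totals <- totals[trips]
  if (any(totals < 0)) abort("totals must be >= 0.")
  stopifnot(temperature > 0)
  structure(
    list(totals = totals,
         params = list(g_gc = g_gc, g_au = g_au, g_init = g_init,
                       temperature = temperature)),
    class = "pool_spec"
  )
}

#' Duplex dissociation constant of a triplet under a pool's affinity model
#'
#' @param triplet Character vector of triplets.
#' @param pool A [pool_spec()].
#' @return Kd in uM (standard state 1 M converted to uM).
#' @export
triplet_kd <- function(triplet, pool) {
  p <- pool$params
  n_gc <- stringr::str_count(triplet, "[GC]")
  dg <- p$g_init + n_gc * p$g_gc + (3 - n_gc) * p$g_au
  R <- 0.0019872  # kcal / (mol K)
  exp(dg / (R * p$temperature)) * 1e6
}

#' Free triplet concentrations in a dimerizing pool
#'
#' Partitions the 64 triplets into their 32 perfect-complement pairs (every
#' triplet has exactly one reverse-complement partner and none is its own,
#' so the pairs are independent) and solves each pair's mass-action
#' equilibrium with [pair_free_concentration()]. GC-rich pairs bind more
#' strongly, so their free concentrations are buffered down relative to
#' AU-rich triplets — the proposed systems-level fidelity mechanism of random
#' triplet pools.
#'
#' @param pool A [pool_spec()].
#' @return Tibble of class `pool_free` with one row per triplet, sorted by
#'   descending GC count: `triplet`, `partner`, `gc_count`, `kd`, `total`,
#'   `free`, `dimer`, `free_fraction` (`NaN` for a zero-total triplet).
#' @export
pool_free_concentrations <- function(pool) {
  stopifnot(inherits(pool, "pool_spec"))
  trips <- all_triplets()
  partner <- rna_revcomp(trips)
  first <- trips < partner          # each unordered pair once
  pairs <- tibble(a = trips[first], b = partner[first])
  pairs$kd <- triplet_kd(pairs$a, pool)
  sol <- pair_free_concentration(pool$totals[pairs$a], pool$totals[pairs$b],
                                 pairs$kd)
  per <- dplyr::bind_rows(
    tibble(triplet = pairs$a, partner = pairs$b, kd = pairs$kd,
           free = sol$free_a, dimer = sol$dimer),
    tibble(triplet = pairs$b, partner = pairs$a, kd = pairs$kd,
           free = sol$free_b, dimer = sol$dimer)
  )
  per$total <- unname(pool$totals[per$triplet])
  per$gc_count <- stringr::str_count(per$triplet, "[GC]")
  per$free_fraction <- per$free / per$total
  per <- per[order(-per$gc_count, per$triplet),
             c("triplet", "partner", "gc_count", "kd", "total", "free",
               "dimer", "free_fraction")]
  structure(per, class = c("pool_free", class(tibble())))
}

#' Predicted change in a mispair:cognate error ratio between pool conditions
#'
#' Under competitive incorporation the odds of misincorporation are
#' proportional to the ratio of free mispair to free cognate concentrations.
#' Comparing two pool conditions, the predicted proportional change in the
#' mispair:cognate incorporation ratio is `1 - ratio_new / ratio_baseline`
#' (positive = predicted error reduction). This is a direction-level model:
#' e.g. adding the complements of a GC-rich mispair and a weaker-pairing
#' cognate buffers the mispair's free concentration more, predicting a
#' positive reduction.
#'
#' @param free `pool_free` table for the new condition (see
#'   [pool_free_concentrations()]).
#' @param baseline_free `pool_free` table for the baseline condition.
#' @param cognate,mispair The competing triplets.
#' @return Predicted proportional reduction (a rate; `NA` with a warning if a
#'   free cognate concentration is zero).
#' @export
predicted_error_modulation <- function(free, baseline_free, cognate, mispair) {
  ratio <- function(tbl) {
    fc <- tbl$free[tbl$triplet == cognate]
    fm <- tbl$free[tbl$triplet == mispair]
    if (length(fc) != 1L || length(fm) != 1L)
      abort("both triplets must be present in the pool tables.")
    if (fc <= 0) {
      warn("zero free cognate concentration: modulation undefined.")
      return(NA_real_)
    }
    fm / fc
  }
  r_new <- ratio(free)
  r_base <- ratio(baseline_free)
  if (is.na(r_new) || is.na(r_base)) return(NA_real_)
  1 - r_new / r_base
}
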