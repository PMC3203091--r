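#' Optimizer configuration
#'
#' Settings for the cyclic one-dimensional (Brent) maximization of the
#' mixture likelihood. Branch-length intervals are bounded above because
#' the likelihood flattens as branches grow (the probability of observing
#' discordant gene trees goes to zero), so unbounded optimization can drift
#' indefinitely; 5.0 coalescent units is the simulation-study bound and 2.0
#' the empirical-analysis bound.
#'
#' @param gamma_bounds Bounds for the hybridization proportion.
#' @param t_upper Upper bound for each interval, coalescent units.
#' @param t_lower Lower bound for each interval (kept slightly above zero
#'   to avoid degenerate zero-duration populations).
#' @param brent_tol Absolute tolerance of each one-dimensional search.
#' @param max_cycles Maximum number of full coordinate cycles.
#' @param loglik_tol,param_tol Convergence is declared when, across a full
#'   cycle, the relative log-likelihood change is below `loglik_tol` and the
#'   largest parameter change is below `param_tol`.
#' @param max_resolutions Cap on binary resolutions per polytomous gene tree.
#' @return A list of class `hyb_optimizer_config`.
#' @export
optimizer_config <- function(gamma_bounds = c(0, 1), t_upper = 5, t_lower = 1e-6,
                             brent_tol = 1e-5, max_cycles = 100,
                             loglik_tol = 1e-6, param_tol = 1e-4,
                             max_resolutions = 1000) {
  stopifnot(t_lower > 0, t_lower < t_upper, brent_tol > 0,
            loglik_tol > 0, param_tol > 0, max_cycles >= 1)
  structure(
    list(gamma_bounds = gamma_bounds, t_upper = t_upper, t_lower = t_lower,
         brent_tol = brent_tol, max_cycles = max_cycles,
         loglik_tol = loglik_tol, param_tol = param_tol,
         max_resolutions = max_resolutions),
    class = "hyb_optimizer_config"
  )
}

#' Bounded one-dimensional minimization (Brent)
#'
#' Brent's parabolic-interpolation/golden-section search on a closed
#' interval, with the interval endpoints also evaluated so that boundary
#' minima are returned exactly as `lo` or `hi` (the plain interior search
#' never samples the endpoints, and boundary maxima of the likelihood are
#' an expected, flagged outcome here).
#'
#' @param f Scalar function, finite on `[lo, hi]`.
#' @param lo,hi Interval bounds, `lo < hi`.
#' @param tol Absolute tolerance on the minimizer.
#' @param f_tol Optional early stop: end the search once two consecutive
#'   iterations improve the best objective by less than this (0 disables).
#' @return A list with `minimum` (the argmin) and `objective` (`f` there).
#' @export
#' @examples
#' brent_minimize(function(x) (x - 0.3)^2, 0, 1)$minimum
brent_minimize <- function(f, lo, hi, tol = 1e-5, f_tol = 0) {
  stopifnot(lo < hi)
  gr <- (3 - sqrt(5)) / 2
  a <- lo
  b <- hi
  x <- w <- v <- a + gr * (b - a)
  fx <- fw <- fv <- f(x)
  if (!is.finite(fx)) abort("non-finite objective during Brent search")
  d <- e <- 0
  stall <- 0L
  for (iter in seq_len(200)) {
    xm <- (a + b) / 2
    tol1 <- tol
    tol2 <- 2 * tol1
    if (abs(x - xm) <= tol2 - (b - a) / 2) break
    use_golden <- TRUE
    if (abs(e) > tol1) {
      ## parabolic interpolation through (v, w, x)
      r <- (x - w) * (fx - fv)
      q <- (x - v) * (fx - fw)
      p <- (x - v) * q - (x - w) * r
      q <- 2 * (q - r)
      if (q > 0) p <- -p
      q <- abs(q)
      etemp <- e
      e <- d
      if (abs(p) < abs(q * etemp / 2) && p > q * (a - x) && p < q * (b - x)) {
        d <- p / q
        u <- x + d
        if (u - a < tol2 || b - u < tol2) d <- sign(xm - x) * tol1
        use_golden <- FALSE
      }
    }
    if (use_golden) {
      e <- if (x >= xm) a - x else b - x
      d <- gr * e
    }
    u <- if (abs(d) >= tol1) x + d else x + sign(d) * tol1
    fu <- f(u)
    if (is.na(fu)) abort("objective returned NA during Brent search")
    f_best_before <- fx
    if (fu <= fx) {
      if (u >= x) a <- x else b <- x
      v <- w; fv <- fw
      w <- x; fw <- fx
      x <- u; fx <- fu
    } else {
      if (u < x) a <- u else b <- u
      if (fu <= fw || w == x) {
        v <- w; fv <- fw
        w <- u; fw <- fu
      } else if (fu <= fv || v == x || v == w) {
        v <- u; fv <- fu
      }
    }
    if (f_tol > 0) {
      stall <- if (f_best_before - fx < f_tol) stall + 1L else 0L
      if (stall >= 2L) break
    }
  }
  ## boundary minima: the interior search never lands exactly on an
  ## endpoint, so check any endpoint the iterate converged towards
  if (x - lo < 2 * tol) {
    flo <- f(lo)
    if (!is.na(flo) && flo <= fx) {
      x <- lo
      fx <- flo
    }
  }
  if (hi - x < 2 * tol) {
    fhi <- f(hi)
    if (!is.na(fhi) && fhi <= fx) {
      x <- hi
      fx <- fhi
    }
  }
  list(minimum = x, objective = fx)
}

#' Fit the hybridization mixture model by cyclic Brent optimization
#'
#' Maximizes the mixture log-likelihood in `(gamma, t1, t2, t3)` by
#' repeatedly applying a bounded one-dimensional Brent search to one
#' parameter at a time, in that order, until the convergence criteria of
#' the supplied [optimizer_config()] are met.
#'
#' @param trees Gene-tree sample: list/`multiPhylo` of rooted topologies on
#'   the identical individual set.
#' @param S A [hybrid_species_tree()].
#' @param map A taxon map.
#' @param config An [optimizer_config()].
#' @param gamma_fixed Optional: hold the hybridization proportion fixed at
#'   this value and optimize only the intervals (the restricted fit of the
#'   likelihood-ratio test uses `gamma_fixed = 0`).
#' @param init Starting values `c(gamma, t1, t2, t3)`.
#' @param eval_fn Prebuilt log-likelihood evaluator, shared between the
#'   restricted and unrestricted fits of [likelihood_ratio_test()]; built
#'   from the data when `NULL`.
#' @return An object of class `hyb_fit` with elements `gamma`, `t`, `lnL`,
#'   `cycles`, `converged`, `boundary` (named logicals), and a per-cycle
#'   `trace` tibble. [tidy()] and [glance()] methods are provided.
#' @export
fit_hybrid_model <- function(trees, S, map, config = optimizer_config(),
                             gamma_fixed = NULL, init = c(0.5, 1, 1, 1),
                             eval_fn = NULL) {
  stopifnot(inherits(S, "hyb_species_tree"))
  if (is.null(eval_fn)) {
    eval_fn <- .prep_likelihood(trees, S, map, max_resolutions = config$max_resolutions)
  }
  n_loci <- if (inherits(trees, "phylo")) 1L else length(trees)

  p <- init
  if (!is.null(gamma_fixed)) p[1] <- gamma_fixed
  lo <- c(config$gamma_bounds[1], rep(config$t_lower, 3))
  hi <- c(config$gamma_bounds[2], rep(config$t_upper, 3))
  p <- pmin(pmax(p, lo), hi)
  free <- if (is.null(gamma_fixed)) 1:4 else 2:4

  lnL <- eval_fn(p[1], p[2:4])
  if (!is.finite(lnL)) {
    abort("log-likelihood is -Inf at the starting point; check trees and taxon map")
  }
  trace <- list(c(cycle = 0, gamma = p[1], t1 = p[2], t2 = p[3], t3 = p[4], lnL = lnL))
  converged <- FALSE
  cycles <- 0L
  for (cy in seq_len(config$max_cycles)) {
    cycles <- cy
    p_old <- p
    lnL_old <- lnL
    ## coarse-to-fine: early cycles only need to move towards the optimum,
    ## so their one-dimensional searches may stop early; the final cycles
    ## run at the configured tolerance, which is what convergence is
    ## declared against
    cycle_tol <- max(config$brent_tol, 0.05 * 16^(-(cy - 1)))
    cycle_ftol <- max(1e-9, 1e-3 * 100^(-(cy - 1)))
    full_tol_cycle <- cycle_tol <= config$brent_tol * 1.001 && cycle_ftol <= 1.001e-9
    for (k in free) {
      f <- function(x) {
        q <- p
        q[k] <- x
        -eval_fn(q[1], q[2:4])
      }
      ## the one-dimensional profiles can be multimodal (deep intervals in
      ## particular); bracket the best basin with a coarse scan, then let
      ## Brent refine inside it
      scan <- sort(unique(c(seq(lo[k], hi[k], length.out = 12), p[k])))
      fscan <- vapply(scan, f, 0)
      b <- which.min(fscan)
      blo <- scan[max(b - 1L, 1L)]
      bhi <- scan[min(b + 1L, length(scan))]
      res <- brent_minimize(f, blo, bhi, tol = cycle_tol, f_tol = cycle_ftol)
      if (fscan[b] < res$objective) res <- list(minimum = scan[b], objective = fscan[b])
      if (-res$objective >= lnL) {  # accept only non-decreasing moves
        p[k] <- res$minimum
        lnL <- -res$objective
      }
    }
    trace[[length(trace) + 1]] <- c(cycle = cy, gamma = p[1], t1 = p[2],
                                    t2 = p[3], t3 = p[4], lnL = lnL)
    rel <- abs(lnL - lnL_old) / (abs(lnL_old) + 1e-12)
    ## convergence may only be declared off a cycle whose one-dimensional
    ## searches ran at the full configured tolerance
    if (full_tol_cycle && rel < config$loglik_tol &&
        max(abs(p - p_old)) < config$param_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("coordinate optimization did not converge in ", config$max_cycles, " cycles"))
  }
  btol <- 10 * config$param_tol
  boundary <- c(
    gamma_lower = is.null(gamma_fixed) && p[1] - lo[1] < btol,
    gamma_upper = is.null(gamma_fixed) && hi[1] - p[1] < btol,
    t1 = hi[2] - p[2] < btol,
    t2 = hi[3] - p[3] < btol,
    t3 = hi[4] - p[4] < btol
  )
  structure(
    list(gamma = p[1], t = p[2:4], lnL = lnL, cycles = cycles,
         converged = converged, boundary = boundary,
         gamma_fixed = gamma_fixed, n_loci = n_loci, config = config,
         S = S,
         trace = tibble::as_tibble(do.call(rbind, trace))),
    class = "hyb_fit"
  )
}

#' @export
print.hyb_fit <- function(x, ...) {
  cat("Hybridization mixture model fit (", x$n_loci, " loci)\n", sep = "")
  if (!is.null(x$gamma_fixed)) {
    cat(sprintf("  gamma fixed at %.4g\n", x$gamma_fixed))
  } else {
    cat(sprintf("  gamma_hat = %.4f%s\n", x$gamma,
                if (x$boundary[["gamma_upper"]]) " [at upper bound]"
                else if (x$boundary[["gamma_lower"]]) " [at lower bound]" else ""))
  }
  for (k in 1:3) {
    cat(sprintf("  t%d_hat    = %.4f%s\n", k, x$t[k],
                if (x$boundary[[paste0("t", k)]]) " [at upper bound]" else ""))
  }
  cat(sprintf("  lnL = %.6f after %d cycle(s)%s\n", x$lnL, x$cycles,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @rdname fit_hybrid_model
#' @param x A `hyb_fit`.
#' @param ... Unused.
#' @export
tidy.hyb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "t1", "t2", "t3"),
    estimate = c(x$gamma, x$t),
    fixed = c(!is.null(x$gamma_fixed), FALSE, FALSE, FALSE),
    at_bound = c(x$boundary[["gamma_lower"]] || x$boundary[["gamma_upper"]],
                 x$boundary[["t1"]], x$boundary[["t2"]], x$boundary[["t3"]])
  )
}

#' @rdname fit_hybrid_model
#' @export
glance.hyb_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$lnL, n_loci = x$n_loci, cycles = x$cycles,
    converged = x$converged,
    any_boundary = any(x$boundary)
  )
}

#' Likelihood-ratio test for hybridization
#'
#' Tests the null hypothesis of no hybridization (`gamma = 0`, the hybrid
#' derived entirely from one parental species) against the unrestricted
#' mixture. The statistic is `Delta = -2 log(L0 / L1)` with the interval
#' vector re-optimized under each hypothesis. Because the null pins `gamma`
#' to the boundary of its parameter space, `Delta` is compared to a 50:50
#' mixture of a point mass at 0 and a chi-squared distribution with one
#' degree of freedom: `p = 1` if `Delta <= 0`, else
#' `p = 0.5 * P(chisq_1 >= Delta)`.
#'
#' If the unrestricted coordinate search from the default start ends below
#' the restricted optimum (a local-maximum artifact), it is restarted from
#' the restricted solution so the nesting inequality holds.
#'
#' @inheritParams fit_hybrid_model
#' @return An object of class `hyb_lrt`: `delta`, `p_value`, and the two
#'   fits (`fit_null`, `fit_alt`).
#' @export
likelihood_ratio_test <- function(trees, S, map, config = optimizer_config()) {
  eval_fn <- .prep_likelihood(trees, S, map,
                              max_resolutions = config$max_resolutions)
  fit1 <- fit_hybrid_model(trees, S, map, config, eval_fn = eval_fn)
  ## the restricted fit re-optimizes the intervals under gamma = 0; the
  ## unrestricted solution is a cheap, valid starting point for them
  fit0 <- fit_hybrid_model(trees, S, map, config, gamma_fixed = 0,
                           init = c(0, fit1$t), eval_fn = eval_fn)
  if (fit1$lnL < fit0$lnL) {
    fit1b <- fit_hybrid_model(trees, S, map, config, init = c(0, fit0$t),
                              eval_fn = eval_fn)
    if (fit1b$lnL > fit1$lnL) fit1 <- fit1b
  }
  delta <- 2 * (fit1$lnL - fit0$lnL)
  if (delta < -1e-8) {
    abort(sprintf("likelihood-ratio statistic is %.3g < 0: optimizer failure", delta))
  }
  delta <- max(delta, 0)
  p <- if (delta <= 0) 1 else 0.5 * pchisq(delta, df = 1, lower.tail = FALSE)
  structure(
    list(delta = delta, p_value = p, fit_null = fit0, fit_alt = fit1),
    class = "hyb_lrt"
  )
}

#' @export
print.hyb_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of no hybridization (gamma = 0)\n")
  cat(sprintf("  Delta = %.4f, p = %.4g (null: 0.5*point mass at 0 + 0.5*chisq_1)\n",
              x$delta, x$p_value))
  cat(sprintf("  gamma_hat = %.4f, lnL_alt = %.4f, lnL_null = %.4f\n",
              x$fit_alt$gamma, x$fit_alt$lnL, x$fit_null$lnL))
  invisible(x)
}

#' Does the test reject at level alpha?
#'
#' @param x A `hyb_lrt`.
#' @param alpha Significance level.
#' @return Logical.
#' @export
reject_at <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "hyb_lrt"))
  x$p_value <= alpha
}

#' @rdname likelihood_ratio_test
#' @param x A `hyb_lrt`.
#' @param ... Unused.
#' @export
tidy.hyb_lrt <- function(x, ...) {
  tibble::tibble(
    delta = x$delta, p_value = x$p_value,
    gamma_hat = x$fit_alt$gamma,
    t1_hat = x$fit_alt$t[1], t2_hat = x$fit_alt$t[2], t3_hat = x$fit_alt$t[3],
    lnL_alt = x$fit_alt$lnL, lnL_null = x$fit_null$lnL
  )
}

#' @rdname likelihood_ratio_test
#' @export
glance.hyb_lrt <- function(x, ...) tidy(x)

#' Cycle the hybrid assignment over the ingroup species
#'
#' When no hybrid can be designated a priori, each ingroup species is tried
#' in turn as the putative hybrid of the remaining pair (three assignments
#' for three ingroup species), the model is fitted and the
#' likelihood-ratio test performed for each, and the results are tabulated
#' for comparison. The outgroup stays fixed.
#'
#' @param trees Gene-tree sample.
#' @param ingroup_species Character vector of at least three ingroup
#'   species labels; only the three-species case is supported.
#' @param outgroup Outgroup species label.
#' @param map A taxon map.
#' @param config An [optimizer_config()].
#' @return A tibble with one row per hybrid assignment: the designation,
#'   parameter estimates, log-likelihood, `delta` and `p_value`.
#' @export
iterate_hybrid_assignments <- function(trees, ingroup_species, outgroup, map,
                                       config = optimizer_config()) {
  if (length(ingroup_species) != 3) {
    abort("exactly three ingroup species are supported; the hybrid joins the remaining pair")
  }
  purrr::map_dfr(seq_along(ingroup_species), function(k) {
    h <- ingroup_species[k]
    pars <- sort(ingroup_species[-k])
    S <- hybrid_species_tree(h, pars[1], pars[2], outgroup)
    lrt <- likelihood_ratio_test(trees, S, map, config)
    tibble::tibble(
      hybrid = h, parent1 = pars[1], parent2 = pars[2], outgroup = outgroup,
      gamma_hat = lrt$fit_alt$gamma,
      t1_hat = lrt$fit_alt$t[1], t2_hat = lrt$fit_alt$t[2], t3_hat = lrt$fit_alt$t[3],
      lnL = lrt$fit_alt$lnL, delta = lrt$delta, p_value = lrt$p_value
    )
  })
}
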