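#' Simulate an ensemble of mean coincidence distances
#'
#' For each alphabet size in `m_grid` and each rank in `ranks`, draws
#' `trials` i.i.d. sequences of `samples` symbols from the family's
#' distribution and records the mean observed coincidence distance of the
#' empirically rank-`r` symbol.  This is the raw material to which the
#' forward model `M = G(theta; D)` is fitted.
#'
#' @param family distribution family passed to [zml_model()].
#' @param m_grid alphabet sizes (each `>= max(ranks) + 1` and `>= 2`).
#' @param ranks ranks whose distances are recorded (default 1).
#' @param trials replicate sequences per alphabet size.
#' @param samples symbols per replicate.
#' @param seed master RNG seed; the same seed reproduces the ensemble
#'   exactly.
#' @param B continuation branching for `family = "czml2"`.
#' @return `data.frame` with columns `M`, `rank`, `D_bar` (ensemble mean of
#'   the per-trial mean distance), `sd` (between-trial spread), `trials`.
#' @examples
#' simulate_distance_ensemble("equiprobable", m_grid = 2, trials = 20,
#'                            samples = 2000, seed = 1)  # D_bar ~ 2.5
#' @export
simulate_distance_ensemble <- function(family = "zml", m_grid, ranks = 1L,
                                       trials = 50L, samples = 1e5,
                                       seed = 1L, B = NULL) {
  stopifnot(length(m_grid) >= 1, all(m_grid >= 2), all(ranks >= 1))
  if (any(m_grid < max(ranks)))
    stop_zml("every M in m_grid must be >= max(ranks)",
             class = "zml_calibration_error")
  seeds <- matrix(derive_seeds(seed, length(m_grid) * trials),
                  nrow = length(m_grid))
  out <- vector("list", length(m_grid))
  for (i in seq_along(m_grid)) {
    M <- m_grid[i]
    dist <- zml_model(M, family, B = B)
    dbar <- matrix(NA_real_, nrow = trials, ncol = length(ranks))
    for (t in seq_len(trials)) {
      x <- with_seed(seeds[i, t],
                     sample.int(dist$support, samples, replace = TRUE,
                                prob = dist$p))
      counts <- tabulate(x, nbins = dist$support)
      ord <- order(-counts)
      for (j in seq_along(ranks)) {
        pos <- which(x == ord[ranks[j]])
        if (length(pos) < 2L)
          stop_zml(paste0("rank-%d symbol never repeated within %g samples",
                          " (M=%g, trial %d); increase samples"),
                   ranks[j], samples, M, t, class = "zml_no_coincidence")
        dbar[t, j] <- mean(diff(pos) + 1L)
      }
    }
    out[[i]] <- data.frame(M = M, rank = ranks,
                           D_bar = colMeans(dbar),
                           sd = apply(dbar, 2, stats::sd),
                           trials = trials)
  }
  res <- do.call(rbind, out)
  attr(res, "family") <- family
  attr(res, "B") <- B
  attr(res, "config") <- list(trials = trials, samples = samples, seed = seed)
  res
}

#' Fit the invertible forward model M = G(theta; D)
#'
#' Fits, per rank, a curve mapping the mean coincidence distance `D` to the
#' alphabet size `M`.  The `"power"` family `M = a D^b + c` (the default) is
#' invertible in closed form, `D = ((M - c)/a)^(1/b)`.  The `"polynomial"`
#' family expresses `log M` as a degree-`degree` polynomial in `log D` and
#' is inverted numerically.  Both are fitted on log-transformed `M` for
#' numerical stability across wide alphabet ranges.  An ensemble whose
#' `D_bar` is not strictly increasing in `M` (at any rank) is rejected:
#' the forward map must be invertible.
#'
#' @param ensemble output of [simulate_distance_ensemble()].
#' @param fit `"power"` or `"polynomial"`.
#' @param degree polynomial degree (polynomial fit only).
#' @return a `zml_calibration` object; see [zml_calibrate()].
#' @export
fit_forward_model <- function(ensemble, fit = c("power", "polynomial"),
                              degree = 4L) {
  fit <- match.arg(fit)
  stopifnot(all(c("M", "rank", "D_bar") %in% names(ensemble)))
  ranks <- sort(unique(ensemble$rank))
  models <- list()
  for (r in ranks) {
    sub <- ensemble[ensemble$rank == r, , drop = FALSE]
    sub <- sub[order(sub$M), , drop = FALSE]
    if (nrow(sub) < 3)
      stop_zml("need >= 3 distinct M values per rank (rank %d has %d)",
               r, nrow(sub), class = "zml_calibration_error")
    if (any(diff(sub$D_bar) <= 0))
      stop_zml(paste0("ensemble not strictly increasing in M at rank %d; ",
                      "the forward model would not be invertible ",
                      "(increase samples/trials)"), r,
               class = "zml_nonmonotone_ensemble")
    D <- sub$D_bar; M <- sub$M
    if (fit == "power") {
      lmfit <- stats::lm(log(M) ~ log(D))
      start <- list(a = exp(stats::coef(lmfit)[[1]]),
                    b = stats::coef(lmfit)[[2]], c = 0)
      nl <- minpack.lm::nlsLM(log(M) ~ log(a * D^b + c), start = start,
                              lower = c(a = 1e-12, b = 1e-6, c = -Inf),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-14, ptol = 1e-14))
      th <- as.list(stats::coef(nl))
      pred <- th$a * D^th$b + th$c
      models[[as.character(r)]] <-
        list(a = th$a, b = th$b, c = th$c,
             valid_range = range(D),
             max_rel_resid = max(abs(pred - M) / M))
    } else {
      pf <- stats::lm(log(M) ~ stats::poly(log(D), degree, raw = TRUE))
      coefs <- unname(stats::coef(pf))
      pred <- exp(stats::fitted(pf))
      models[[as.character(r)]] <-
        list(coefs = coefs, degree = degree,
             valid_range = range(D),
             max_rel_resid = max(abs(pred - M) / M))
    }
  }
  structure(list(fit = fit,
                 family = attr(ensemble, "family") %||% "zml",
                 B = attr(ensemble, "B"),
                 ranks = ranks, models = models,
                 metadata = c(list(m_grid = sort(unique(ensemble$M))),
                              attr(ensemble, "config"))),
            class = "zml_calibration")
}

#' Calibrate the coincidence-distance estimator by simulation
#'
#' One-call wrapper: simulates the distance ensemble for a model family and
#' fits the invertible forward model per rank.  The default grid of ~25
#' integer alphabet sizes log-spaced in `[12, 100]` brackets the alphabet
#' sizes of typical interest (20-40) while keeping the 3-parameter power
#' law an accurate description of the distance curve.
#'
#' For an exact, simulation-free alternative see
#' [analytic_calibration()], the package default for estimation.
#'
#' @inheritParams simulate_distance_ensemble
#' @inheritParams fit_forward_model
#' @return an object of class `zml_calibration` with elements `fit`,
#'   `family`, `ranks`, `models` (per-rank parameters, valid `D` range and
#'   residual summary) and `metadata` (grid, trials, samples, seed).
#' @examples
#' \donttest{
#' cal <- zml_calibrate("zml", trials = 10, samples = 2e4, seed = 1)
#' predict_M(cal, D = 7, r = 1)
#' }
#' @seealso [predict_M()], [predict_D()], [analytic_calibration()]
#' @export
zml_calibrate <- function(family = "zml",
                          m_grid = default_m_grid(),
                          ranks = 1L, trials = 50L, samples = 1e5,
                          seed = 1L, fit = c("power", "polynomial"),
                          degree = 4L, B = NULL) {
  ens <- simulate_distance_ensemble(family, m_grid = m_grid, ranks = ranks,
                                    trials = trials, samples = samples,
                                    seed = seed, B = B)
  fit_forward_model(ens, fit = fit, degree = degree)
}

#' @rdname zml_calibrate
#' @export
default_m_grid <- function() {
  unique(round(exp(seq(log(12), log(100), length.out = 25))))
}

#' Closed-form calibration from the model's own gap distribution
#'
#' For i.i.d. draws the gap between consecutive occurrences of a symbol
#' with probability `p` is geometric with mean `1/p`, so under the distance
#' convention `D = gap + 1` the exact forward curve is
#' `D(M; r) = 1 + 1/P(r; M)`.  This calibration inverts that relation by
#' monotone root-finding (closed form `M = D - 1` for the equiprobable
#' family) -- deterministic, with no simulation noise or curve-fit bias,
#' and is the package default for estimation.
#'
#' @param family distribution family (see [zml_model()]).
#' @param B continuation branching for `czml2`.
#' @param ranks ranks the calibration will be asked about (any rank works;
#'   recorded for bookkeeping only).
#' @return a `zml_calibration` with `fit = "analytic"`.
#' @examples
#' cal <- analytic_calibration("zml")
#' predict_D(cal, M = 30, r = 1)            # 1 + 1/p(1; 30)
#' predict_M(cal, predict_D(cal, 30), 1)    # 30
#' @export
analytic_calibration <- function(family = "zml", B = NULL, ranks = 1:40) {
  family <- match.arg(family, c("zml", "czml1", "czml2", "equiprobable"))
  structure(list(fit = "analytic", family = family, B = B,
                 ranks = ranks, models = NULL,
                 metadata = list(forward = "D(M;r) = 1 + 1/P(r;M)")),
            class = "zml_calibration")
}

analytic_forward_D <- function(calib, M, r) {
  dist <- zml_model(M, calib$family, B = calib$B)
  if (r > dist$support)
    stop_zml("rank %d exceeds the support of M=%g", r, M,
             class = "zml_calibration_error")
  1 + 1 / prob_of_rank(dist, r)
}

# Smallest admissible alphabet size for a family/rank combination.
analytic_M_min <- function(calib, r) {
  max(if (calib$family %in% c("czml1", "czml2")) 3 else 2, r)
}

#' Estimate the alphabet size from a mean coincidence distance
#'
#' Evaluates the calibrated forward model `M_hat = G(theta; D)` at rank
#' `r`.  Outside the calibration's valid `D` range the value is still
#' returned but flagged: a warning is raised and the result carries
#' `attr(, "extrapolated") = TRUE`.
#'
#' @param calib a `zml_calibration` (from [zml_calibrate()],
#'   [fit_forward_model()] or [analytic_calibration()]).
#' @param D mean coincidence distance(s), `> 0` (and `> 1` for the
#'   analytic fit, where `D = 1 + 1/p`).
#' @param r rank (must be covered by the calibration).
#' @return estimated alphabet size(s) `M_hat` (continuous; not rounded).
#' @examples
#' predict_M(analytic_calibration("equiprobable"), D = 31)  # 30
#' @export
predict_M <- function(calib, D, r = 1L) {
  stopifnot(inherits(calib, "zml_calibration"))
  if (any(D <= 0)) stop_zml("D must be positive", class = "zml_calibration_error")
  if (calib$fit == "analytic") {
    M_min <- analytic_M_min(calib, r)
    out <- vapply(D, function(d) {
      if (calib$family == "equiprobable") return(max(d - 1, 2))
      d_lo <- analytic_forward_D(calib, M_min, r)
      if (d <= d_lo) return(M_min)
      # solve in log(M): D grows roughly logarithmically in M, so M_hat can
      # be astronomically large for sparse streams (large-support models are
      # evaluated analytically, see zml_rank_sums)
      g <- function(t) analytic_forward_D(calib, exp(t), r) - d
      t_lo <- log(M_min); t_hi <- t_lo + 2
      while (g(t_hi) < 0 && t_hi < 600) t_hi <- t_hi + 2
      if (g(t_hi) < 0)
        stop_zml("distance D=%g exceeds the invertible range", d,
                 class = "zml_calibration_error")
      exp(stats::uniroot(g, c(t_lo, t_hi), tol = 1e-12)$root)
    }, numeric(1))
    lo_flag <- calib$family != "equiprobable" &
      D <= analytic_forward_D(calib, M_min, r)
    if (any(lo_flag))
      warning(sprintf("D below the minimum model distance at rank %d; clamped to M=%g",
                      r, M_min))
    attr(out, "extrapolated") <- any(lo_flag)
    return(out)
  }
  m <- calib$models[[as.character(r)]]
  if (is.null(m))
    stop_zml("rank %d not present in this calibration (ranks: %s)", r,
             paste(calib$ranks, collapse = ", "),
             class = "zml_calibration_error")
  outside <- D < m$valid_range[1] | D > m$valid_range[2]
  if (any(outside))
    warning(sprintf("D outside calibrated range [%.3g, %.3g] at rank %d; extrapolating",
                    m$valid_range[1], m$valid_range[2], r))
  out <- if (calib$fit == "power") {
    m$a * D^m$b + m$c
  } else {
    exp(vapply(D, function(d)
      sum(m$coefs * log(d)^(0:m$degree)), numeric(1)))
  }
  attr(out, "extrapolated") <- any(outside)
  out
}

#' Expected mean coincidence distance for an alphabet size
#'
#' The inverse direction of the calibration: `D_hat(M; r)`.  Closed form
#' `((M - c)/a)^(1/b)` for the power fit; `1 + 1/P(r; M)` for the analytic
#' calibration; numeric inversion for the polynomial fit.
#'
#' @inheritParams predict_M
#' @param M alphabet size(s); for the power fit `M > c` is required.
#' @return predicted mean distance(s) `D_hat`.
#' @examples
#' cal <- analytic_calibration("equiprobable")
#' predict_D(cal, M = 30)  # 31
#' @export
predict_D <- function(calib, M, r = 1L) {
  stopifnot(inherits(calib, "zml_calibration"))
  if (calib$fit == "analytic") {
    if (calib$family == "equiprobable")
      return(M + 1)
    return(vapply(M, function(mm) analytic_forward_D(calib, mm, r),
                  numeric(1)))
  }
  m <- calib$models[[as.character(r)]]
  if (is.null(m))
    stop_zml("rank %d not present in this calibration", r,
             class = "zml_calibration_error")
  if (calib$fit == "power") {
    if (any(M <= m$c))
      stop_zml("M must exceed the offset c=%.4g for the inverse model", m$c,
               class = "zml_calibration_error")
    ((M - m$c) / m$a)^(1 / m$b)
  } else {
    vapply(M, function(mm) {
      g <- function(d) {
        v <- predict_M(calib, d, r)
        suppressWarnings(as.numeric(v)) - mm
      }
      lo <- m$valid_range[1] / 2; hi <- m$valid_range[2] * 2
      suppressWarnings(stats::uniroot(g, c(lo, hi), extendInt = "upX",
                                      tol = 1e-9)$root)
    }, numeric(1))
  }
}

#' @export
#' @method predict zml_calibration
predict.zml_calibration <- function(object, D = NULL, M = NULL, r = 1L, ...) {
  if (!is.null(D) && !is.null(M))
    stop_zml("give D (to get M_hat) or M (to get D_hat), not both",
             class = "zml_calibration_error")
  if (!is.null(D)) predict_M(object, D, r)
  else if (!is.null(M)) predict_D(object, M, r)
  else stop_zml("give D or M", class = "zml_calibration_error")
}

#' @export
print.zml_calibration <- function(x, ...) {
  cat(sprintf("<zml_calibration> fit=%s family=%s ranks=%s\n",
              x$fit, x$family,
              if (length(x$ranks) > 6)
                sprintf("1..%d", max(x$ranks))
              else paste(x$ranks, collapse = ",")))
  if (x$fit == "analytic") {
    cat("  exact forward model D(M;r) = 1 + 1/P(r;M)\n")
  } else {
    md <- x$metadata
    cat(sprintf("  grid %g..%g (%d points), %d trials x %g samples, seed %s\n",
                min(md$m_grid), max(md$m_grid), length(md$m_grid),
                md$trials, md$samples, format(md$seed)))
    r1 <- x$models[[1]]
    if (x$fit == "power")
      cat(sprintf("  rank %s: M = %.4g * D^%.4g + %.4g  (max rel resid %.2g)\n",
                  names(x$models)[1], r1$a, r1$b, r1$c, r1$max_rel_resid))
  }
  invisible(x)
}

#' @export
summary.zml_calibration <- function(object, ...) {
  print(object)
  if (object$fit != "analytic") {
    tab <- do.call(rbind, lapply(names(object$models), function(r) {
      m <- object$models[[r]]
      data.frame(rank = as.integer(r), D_lo = m$valid_range[1],
                 D_hi = m$valid_range[2], max_rel_resid = m$max_rel_resid)
    }))
    print(tab, row.names = FALSE)
    invisible(tab)
  } else invisible(NULL)
}

#' Serialize / restore a calibration as JSON
#'
#' The JSON carries the fit family, per-rank parameters, valid ranges and
#' full metadata (grid, trials, samples, seed), so a stored calibration is
#' reproducible and auditable.
#'
#' @param calib a `zml_calibration`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   the restored `zml_calibration`.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "zml_calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$ranks <- as.integer(obj$ranks)
  if (!is.null(obj$models))
    obj$models <- lapply(obj$models, function(m) {
      m$valid_range <- as.numeric(m$valid_range); m
    })
  structure(obj, class = "zml_calibration")
}
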