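# Nonlinear least-squares machinery for the exponential demand equation.
# All fits minimize sum((log10 Q_obs - predicted)^2) over points with Q > 0
# (log of zero consumption is undefined; exclusions are recorded in
# n_points_used). Optimization is on (log Q0, log alpha, log k) so positivity
# is enforced by construction, with multi-start jitter under a fixed seed.

check_curve <- function(price, consumption) {
  if (length(price) != length(consumption))
    stop("`price` and `consumption` must have equal length", call. = FALSE)
  if (any(!is.finite(price)) || any(price <= 0))
    stop("prices must be finite and > 0", call. = FALSE)
  if (anyDuplicated(price))
    stop("prices must be unique within a curve", call. = FALSE)
  if (any(!is.finite(consumption)) || any(consumption < 0))
    stop("consumption must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}

# residual sum of squares on the log10 scale; par = (log q0, log alpha)
rss_fixed_k <- function(par, pr, logq, k) {
  q0 <- exp(par[1L]); alpha <- exp(par[2L])
  pred <- par[1L] / log(10) + k * (exp(-alpha * q0 * pr) - 1)
  sum((logq - pred)^2)
}

rss_free_k <- function(par, pr, logq) {
  rss_fixed_k(par[1:2], pr, logq, exp(par[3L]))
}

# coarse alpha grid used to seed the optimizer: q0 anchored at consumption
# near zero price, alpha scanned over 8 decades
alpha_grid_init <- function(pr, logq, k) {
  lq0 <- max(logq) * log(10)
  la_grid <- seq(log(1e-8), log(1), length.out = 60)
  rss <- vapply(la_grid, function(la) rss_fixed_k(c(lq0, la), pr, logq, k),
                numeric(1))
  c(lq0, la_grid[which.min(rss)])
}

optim_ms <- function(fn, start, n_starts, seed, ...) {
  jit <- with_seed(seed, matrix(rnorm((n_starts - 1L) * length(start), 0, 0.6),
                                ncol = length(start)))
  starts <- rbind(start, sweep(jit, 2L, start, `+`))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14), ...),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("demand fit failed to converge from any start",
                          call. = FALSE)
  best
}

# damped Gauss-Newton polish on the residual vector; BFGS stalls near
# zero-residual optima, GN converges quadratically there
gn_polish <- function(resid_fn, par, maxit = 40L) {
  r <- resid_fn(par); rss <- sum(r^2)
  lambda <- 1e-10
  for (it in seq_len(maxit)) {
    J <- vapply(seq_along(par), function(j) {
      h <- 1e-6 * (abs(par[j]) + 1e-6)
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      (resid_fn(pp) - resid_fn(pm)) / (2 * h)
    }, numeric(length(r)))
    ok <- FALSE
    for (try in 1:8) {
      step <- tryCatch(
        solve(crossprod(J) + lambda * diag(length(par)), crossprod(J, r)),
        error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      par_new <- par - drop(step)
      r_new <- resid_fn(par_new); rss_new <- sum(r_new^2)
      if (is.finite(rss_new) && rss_new <= rss) {
        improve <- rss - rss_new
        par <- par_new; r <- r_new; rss <- rss_new
        lambda <- lambda / 10; ok <- TRUE
        if (improve < 1e-15 * (rss + 1e-15)) return(list(par = par, rss = rss))
        break
      }
      lambda <- lambda * 10
    }
    if (!ok) break
  }
  list(par = par, rss = rss)
}

resid_fixed_k <- function(par, pr, logq, k) {
  q0 <- exp(par[1L]); alpha <- exp(par[2L])
  logq - (par[1L] / log(10) + k * (exp(-alpha * q0 * pr) - 1))
}

fit_curve_fixed_k <- function(pr, logq, k, n_starts = 5L, seed = 1L) {
  start <- alpha_grid_init(pr, logq, k)
  best <- optim_ms(function(p) rss_fixed_k(p, pr, logq, k),
                   start, n_starts, seed)
  pol <- gn_polish(function(p) resid_fixed_k(p, pr, logq, k), best$par)
  list(q0 = exp(pol$par[1L]), alpha = exp(pol$par[2L]), k = k,
       rss = pol$rss, converged = best$convergence == 0L)
}

finish_fit <- function(core, price, consumption, logq, subject_id, group,
                       k_mode) {
  params <- demand_params(core$q0, core$alpha, core$k)
  pmax <- tryCatch(pmax_analytic(params), error = function(e) NA_real_)
  omax <- if (is.na(pmax)) NA_real_ else omax_analytic(params)
  sst <- sum((logq - mean(logq))^2)
  structure(list(
    subject_id = subject_id, group = group,
    q0 = core$q0, alpha = core$alpha, k = core$k, k_mode = k_mode,
    ev = essential_value(params), pmax = pmax,
    omax_analytic = omax,
    omax_observed = observed_omax(price, consumption)$omax,
    rss = core$rss, n_points_used = length(logq),
    r_squared = if (sst > 0) 1 - core$rss / sst else NA_real_,
    converged = core$converged), class = "demand_fit")
}

#' @export
print.demand_fit <- function(x, ...) {
  cat(sprintf(
    "Demand fit%s: Q0 = %.3f, alpha = %.3g, k = %.3f (%s)\n  EV = %.3f, Pmax = %.2f, Omax = %.2f (observed %.2f)\n  RSS = %.4g on %d points, R^2 = %.3f\n",
    if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
    x$q0, x$alpha, x$k, x$k_mode, x$ev, x$pmax, x$omax_analytic,
    x$omax_observed, x$rss, x$n_points_used, x$r_squared))
  invisible(x)
}

#' Fit the exponential demand equation to one consumption curve
#'
#' Nonlinear least squares on the log10 consumption scale. Zero-consumption
#' points are excluded (their log is undefined); the number of points that
#' entered the fit is reported as `n_points_used`.
#'
#' @param price Unit prices (responses per reinforcer), > 0, unique.
#' @param consumption Consumption at each price (reinforcers or mg/kg), >= 0.
#' @param k Either `"free"` (fit k; needs >= 4 positive points) or a fixed
#'   positive value (needs >= 3 positive points).
#' @param subject_id,group Optional labels carried into the result.
#' @param n_starts Number of optimizer starts (first from a deterministic
#'   grid, the rest jittered under `seed`).
#' @param seed Seed for the start jitter.
#' @return A `demand_fit` object: fitted `q0`, `alpha`, `k`, derived `ev`,
#'   `pmax`, `omax_analytic`, `omax_observed`, plus `rss`, `n_points_used`,
#'   `r_squared` and a `converged` flag.
#' @export
#' @examples
#' pr <- default_fr_ladder()
#' q <- 10^predict_log10_consumption(demand_params(10, 0.003, 2.5), pr)
#' fit_demand(pr, q, k = "free")
fit_demand <- function(price, consumption, k = "free", subject_id = NULL,
                       group = NA_character_, n_starts = 5L, seed = 1L) {
  check_curve(price, consumption)
  pos <- consumption > 0
  if (!any(pos)) stop("unfittable curve: all consumption is zero", call. = FALSE)
  free_k <- identical(k, "free")
  need <- if (free_k) 4L else 3L
  if (sum(pos) < need)
    stop("need at least ", need, " points with positive consumption",
         call. = FALSE)
  pr <- price[pos]; logq <- log10(consumption[pos])
  if (free_k) {
    k0 <- max(logq) - min(logq) + 0.5
    start <- c(alpha_grid_init(pr, logq, k0), log(k0))
    best <- optim_ms(function(p) rss_free_k(p, pr, logq), start, n_starts, seed)
    pol <- gn_polish(function(p) resid_fixed_k(p[1:2], pr, logq, exp(p[3L])),
                     best$par)
    core <- list(q0 = exp(pol$par[1L]), alpha = exp(pol$par[2L]),
                 k = exp(pol$par[3L]), rss = pol$rss,
                 converged = best$convergence == 0L)
    k_mode <- "free"
  } else {
    if (!is.numeric(k) || length(k) != 1L || k <= 0)
      stop("`k` must be \"free\" or a single positive number", call. = FALSE)
    core <- fit_curve_fixed_k(pr, logq, k, n_starts, seed)
    k_mode <- "fixed"
  }
  finish_fit(core, price, consumption, logq, subject_id, group, k_mode)
}

split_curves <- function(data, by = "subject") {
  req <- c("price", "consumption",
           if (by == "subject") "subject_id" else "group")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (by == "group") {
    # grouped approach: mean consumption across subjects at each price
    agg <- stats::aggregate(consumption ~ group + price, data = data, FUN = mean)
    split(agg[c("price", "consumption", "group")], agg$group)
  } else {
    grp <- if ("group" %in% names(data)) data$group else NA_character_
    data$group <- grp
    split(data[c("price", "consumption", "group")], data$subject_id)
  }
}

pooled_rss_at_k <- function(curvedat, k, n_starts, seed) {
  fits <- lapply(seq_along(curvedat), function(i) {
    d <- curvedat[[i]]
    fit_curve_fixed_k(d$pr, d$logq, k, n_starts, seed + i)
  })
  list(rss = sum(vapply(fits, `[[`, numeric(1), "rss")), fits = fits)
}

#' Jointly fit demand curves with a single shared k
#'
#' Minimizes the pooled log10-scale residual sum of squares over per-curve
#' `(Q0, alpha)` plus one global range constant `k` (total parameter count
#' `2 * n_curves + 1`). Because the problem separates across curves once `k`
#' is fixed, the joint optimum is found by profiling: pooled RSS(k) is
#' minimized by a coarse log-scale grid followed by Brent refinement, and
#' each curve is refit at the selected `k`.
#'
#' @param data Long-format data frame with columns `subject_id`, `group`
#'   (optional when `by = "subject"`), `price`, `consumption`.
#' @param by `"subject"` (one curve per subject) or `"group"` (curves are
#'   group mean consumption at each price — the grouped approach).
#' @param k_interval Search interval for the shared `k`.
#' @param n_starts,seed Multi-start policy passed to the per-curve fits.
#' @return List with `k` (shared estimate), `fits` (list of `demand_fit`,
#'   one per curve, `k_mode = "shared"`), `rss_pooled` and `n_points_total`.
#'   With a single fittable curve, delegates to [fit_demand()] with free `k`.
#' @export
fit_demand_shared_k <- function(data, by = c("subject", "group"),
                                k_interval = c(0.9, 25), n_starts = 5L,
                                seed = 1L) {
  by <- match.arg(by)
  curves <- split_curves(as.data.frame(data), by)
  curvedat <- list(); labels <- character(0); groups <- character(0)
  kept_curves <- list()
  for (nm in names(curves)) {
    d <- curves[[nm]]
    check_curve(d$price, d$consumption)
    pos <- d$consumption > 0
    if (sum(pos) < 3L) {
      warning("curve '", nm, "' has fewer than 3 positive points; dropped")
      next
    }
    curvedat[[length(curvedat) + 1L]] <-
      list(pr = d$price[pos], logq = log10(d$consumption[pos]))
    labels <- c(labels, nm)
    groups <- c(groups, as.character(d$group[1L]))
    kept_curves[[length(kept_curves) + 1L]] <- d
  }
  if (length(curvedat) == 0L) stop("no fittable curves", call. = FALSE)
  if (length(curvedat) == 1L) {
    d <- kept_curves[[1L]]
    fit <- fit_demand(d$price, d$consumption, k = "free",
                      subject_id = labels, group = groups,
                      n_starts = n_starts, seed = seed)
    return(list(k = fit$k, fits = list(fit), rss_pooled = fit$rss,
                n_points_total = fit$n_points_used))
  }
  # conventional seeding rule for k, added to the profile grid
  all_logq <- unlist(lapply(curvedat, `[[`, "logq"))
  k_conv <- max(all_logq) - min(all_logq) + 0.5
  grid <- sort(unique(c(exp(seq(log(k_interval[1]), log(k_interval[2]),
                                length.out = 12)),
                        min(max(k_conv, k_interval[1]), k_interval[2]))))
  prof <- vapply(grid, function(k)
    pooled_rss_at_k(curvedat, k, n_starts = 2L, seed)$rss, numeric(1))
  i <- which.min(prof)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  k_hat <- if (lo < hi)
    optimize(function(k) pooled_rss_at_k(curvedat, k, 2L, seed)$rss,
             c(lo, hi), tol = 1e-7)$minimum
  else grid[i]
  final <- pooled_rss_at_k(curvedat, k_hat, n_starts, seed)
  fits <- lapply(seq_along(final$fits), function(j) {
    d <- kept_curves[[j]]
    pos <- d$consumption > 0
    f <- finish_fit(final$fits[[j]], d$price, d$consumption,
                    log10(d$consumption[pos]), labels[j], groups[j], "shared")
    f
  })
  list(k = k_hat, fits = fits, rss_pooled = final$rss,
       n_points_total = sum(vapply(curvedat, function(d) length(d$logq),
                                   integer(1))))
}

# reduced model for the F test: per-curve Q0, single alpha, single k
rss_reduced <- function(par, curvedat) {
  n <- length(curvedat)
  la <- par[n + 1L]; lk <- par[n + 2L]
  alpha <- exp(la); k <- exp(lk)
  tot <- 0
  for (i in seq_len(n)) {
    q0 <- exp(par[i])
    pred <- par[i] / log(10) +
      k * (exp(-alpha * q0 * curvedat[[i]]$pr) - 1)
    tot <- tot + sum((curvedat[[i]]$logq - pred)^2)
  }
  tot
}

#' Compare demand elasticity between two groups (extra sum-of-squares F test)
#'
#' Fits a full model in which each group has its own `alpha` (and `Q0`) with
#' one shared `k`, and a reduced model constraining `alpha` to be common, then
#' compares them with the extra sum-of-squares F test:
#' `F = ((RSS_red - RSS_full) / (df_red - df_full)) / (RSS_full / df_full)`.
#' Only `alpha` is unshared between the models, so the numerator has 1 df.
#'
#' @param data Long-format data frame (`subject_id`, `group`, `price`,
#'   `consumption`) with exactly two groups.
#' @param approach `"group_mean"` fits each group's mean consumption at each
#'   price (the grouped approach); `"pooled"` fits all subject-level points
#'   with group-level parameters.
#' @param n_starts,seed Multi-start policy.
#' @return List of class `demand_f_test`: `f_stat`, `df_num`, `df_den`,
#'   `p_value`, `rss_full`, `rss_reduced`, per-group `alpha_full`,
#'   `alpha_reduced`, `k_full`, `k_reduced`, `n_points`.
#' @export
compare_alpha_f_test <- function(data, approach = c("group_mean", "pooled"),
                                 n_starts = 5L, seed = 1L) {
  approach <- match.arg(approach)
  data <- as.data.frame(data)
  if (!"group" %in% names(data)) stop("`data` needs a `group` column",
                                      call. = FALSE)
  glev <- unique(as.character(data$group))
  if (length(glev) != 2L) stop("exactly 2 groups required", call. = FALSE)
  curvedat <- lapply(glev, function(g) {
    d <- data[data$group == g, , drop = FALSE]
    if (approach == "group_mean") {
      agg <- stats::aggregate(consumption ~ price, data = d, FUN = mean)
      d <- agg
    }
    pos <- d$consumption > 0
    if (sum(pos) < 3L) stop("group '", g, "' is not fittable", call. = FALSE)
    list(pr = d$price[pos], logq = log10(d$consumption[pos]))
  })
  names(curvedat) <- glev

  # full model: shared k, per-group (Q0, alpha) -> 5 parameters
  k_conv <- {
    lq <- unlist(lapply(curvedat, `[[`, "logq")); max(lq) - min(lq) + 0.5
  }
  prof <- function(k) pooled_rss_at_k(curvedat, k, 3L, seed)
  grid <- sort(unique(c(exp(seq(log(0.9), log(25), length.out = 12)), k_conv)))
  rssg <- vapply(grid, function(k) prof(k)$rss, numeric(1))
  i <- which.min(rssg)
  k_full <- optimize(function(k) prof(k)$rss,
                     c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))]),
                     tol = 1e-8)$minimum
  full <- prof(k_full)
  n_pts <- sum(vapply(curvedat, function(d) length(d$logq), integer(1)))
  p_full <- 5L
  df_den <- n_pts - p_full
  if (df_den <= 0L) stop("too few points for the full model", call. = FALSE)

  # reduced model: common alpha, init from the full fit
  alphas <- vapply(full$fits, `[[`, numeric(1), "alpha")
  q0s <- vapply(full$fits, `[[`, numeric(1), "q0")
  start <- c(log(q0s), log(exp(mean(log(alphas)))), log(k_full))
  red <- optim_ms(function(p) rss_reduced(p, curvedat), start, n_starts, seed)
  rss_full <- full$rss
  rss_red <- max(red$value, rss_full) # nested models: enforce exact ordering
  f <- if (rss_full <= 0) Inf else (rss_red - rss_full) / (rss_full / df_den)
  structure(list(
    f_stat = f, df_num = 1L, df_den = df_den,
    p_value = if (is.infinite(f)) 0 else pf(f, 1, df_den, lower.tail = FALSE),
    rss_full = rss_full, rss_reduced = red$value,
    alpha_full = setNames(alphas, glev),
    q0_full = setNames(q0s, glev),
    q0_reduced = setNames(exp(red$par[seq_along(curvedat)]), glev),
    alpha_reduced = exp(red$par[length(curvedat) + 1L]),
    k_full = k_full, k_reduced = exp(red$par[length(curvedat) + 2L]),
    n_points = n_pts, approach = approach), class = "demand_f_test")
}

#' @export
print.demand_f_test <- function(x, ...) {
  cat(sprintf("Extra sum-of-squares F test (alpha shared vs per-group)\n  F(%d, %d) = %.3f, p = %.3g\n  RSS full = %.4g, RSS reduced = %.4g (%s fit)\n",
              x$df_num, x$df_den, x$f_stat, x$p_value, x$rss_full,
              x$rss_reduced, x$approach))
  invisible(x)
}

#' Profile-likelihood confidence interval for alpha
#'
#' F-based profile interval on the nonlinear least-squares fit: the bound for
#' `log(alpha)` is where the profiled residual sum of squares (re-minimizing
#' over the remaining parameters) crosses
#' `RSS_min * (1 + qf(level, 1, n - p) / (n - p))`.
#'
#' @param object A `demand_fit` from [fit_demand()].
#' @param price,consumption The data the fit was computed from.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Named numeric vector `c(lower, upper)` for `alpha`.
#' @export
confint.demand_fit <- function(object, price, consumption, level = 0.95,
                               ...) {
  check_curve(price, consumption)
  pos <- consumption > 0
  pr <- price[pos]; logq <- log10(consumption[pos])
  free_k <- object$k_mode == "free"
  n <- length(logq); p <- if (free_k) 3L else 2L
  if (n <= p) stop("no residual degrees of freedom", call. = FALSE)
  rss0 <- object$rss
  if (rss0 <= 0) stop("zero-residual fit: profile interval undefined",
                      call. = FALSE)
  cutoff <- rss0 * (1 + stats::qf(level, 1, n - p) / (n - p))
  prof <- function(la) { # re-minimize over log q0 (and log k when free)
    if (free_k) {
      optim(c(log(object$q0), log(object$k)),
            function(b) rss_free_k(c(b[1L], la, b[2L]), pr, logq),
            method = "BFGS", control = list(maxit = 200, reltol = 1e-12))$value
    } else {
      optimize(function(lq0) rss_fixed_k(c(lq0, la), pr, logq, object$k),
               log(object$q0) + c(-8, 8), tol = 1e-10)$objective
    }
  }
  la_hat <- log(object$alpha)
  bound <- function(dir) {
    step <- 0.25; la <- la_hat
    for (i in 1:80) {
      la_next <- la + dir * step
      if (prof(la_next) >= cutoff)
        return(uniroot(function(l) prof(l) - cutoff, sort(c(la, la_next)),
                       tol = 1e-7)$root)
      la <- la_next
    }
    dir * Inf # profile never crossed: unbounded on this side
  }
  exp(c(lower = bound(-1), upper = bound(+1)))
}

#' Collect a list of demand fits into a data frame
#'
#' @param fits A list of `demand_fit` objects (e.g. from
#'   [fit_demand_shared_k()]`$fits`).
#' @return Data frame with one row per fit, mirroring the `demand_fits.tsv`
#'   output columns.
#' @export
demand_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    subject_id = f$subject_id %||% NA_character_, group = f$group,
    q0 = f$q0, alpha = f$alpha, k = f$k, ev = f$ev, pmax = f$pmax,
    omax_analytic = f$omax_analytic, omax_observed = f$omax_observed,
    rss = f$rss, n_points_used = f$n_points_used, r_squared = f$r_squared,
    stringsAsFactors = FALSE)))
}
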