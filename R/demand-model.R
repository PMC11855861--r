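#' Default escalating fixed-ratio price ladder
#'
#' The daily FR schedule of reinforcement used for the demand assessment:
#' each value is the number of responses required per reinforcer, i.e. the
#' behavioral-economic unit price.
#'
#' @return Integer vector of 13 strictly increasing prices.
#' @export
#' @examples
#' default_fr_ladder()
default_fr_ladder <- function() {
  c(1L, 3L, 5L, 8L, 12L, 18L, 26L, 38L, 58L, 86L, 130L, 195L, 292L)
}

#' Construct exponential demand parameters
#'
#' Container for the three parameters of the exponential demand equation
#' \deqn{\log_{10} Q = \log_{10} Q_0 + k (e^{-\alpha Q_0 C} - 1)}
#' where `Q` is consumption at unit price `C`, `Q0` is the intensity of
#' demand (consumption at zero price), `alpha` the rate of decline in
#' relative log consumption with increasing price, and `k` the constant
#' setting the log10 range of the curve (often shared across curves).
#'
#' @param q0 Demand intensity, > 0.
#' @param alpha Demand elasticity rate parameter, > 0.
#' @param k Log10 range constant, > 0.
#' @return An object of class `demand_params`.
#' @export
#' @examples
#' demand_params(q0 = 10, alpha = 0.003, k = 2.5)
demand_params <- function(q0, alpha, k) {
  for (nm in c("q0", "alpha", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single finite positive number", call. = FALSE)
  }
  structure(list(q0 = q0, alpha = alpha, k = k), class = "demand_params")
}

#' @export
print.demand_params <- function(x, ...) {
  cat(sprintf("Exponential demand parameters: Q0 = %.4g, alpha = %.4g, k = %.4g\n",
              x$q0, x$alpha, x$k))
  invisible(x)
}

as_demand_params <- function(x) {
  if (inherits(x, "demand_params")) return(x)
  if (inherits(x, "demand_fit")) return(demand_params(x$q0, x$alpha, x$k))
  if (is.list(x) && all(c("q0", "alpha", "k") %in% names(x)))
    return(demand_params(x$q0, x$alpha, x$k))
  stop("cannot interpret `params`: supply demand_params() or a demand fit",
       call. = FALSE)
}

#' Predicted log10 consumption under the exponential demand equation
#'
#' @param params A [demand_params()] object (or a demand fit).
#' @param price Vector of unit prices, >= 0. Price 0 is the intensity limit
#'   where predicted consumption equals `Q0`.
#' @return Numeric vector of predicted log10 consumption values.
#' @export
#' @examples
#' p <- demand_params(10, 0.003, 2.5)
#' predict_log10_consumption(p, c(0, 1, 10, 100))
predict_log10_consumption <- function(params, price) {
  params <- as_demand_params(params)
  if (!is.numeric(price) || any(!is.finite(price)) || any(price < 0))
    stop("`price` must be finite and >= 0", call. = FALSE)
  log10(params$q0) + params$k * (exp(-params$alpha * params$q0 * price) - 1)
}

#' Essential value of a reinforcer
#'
#' `EV = 1 / (100 * alpha * k^1.5)`, a price-scale-free index of a
#' reinforcer's ability to maintain responding as costs escalate; strictly
#' decreasing in both `alpha` and `k`.
#'
#' @inheritParams predict_log10_consumption
#' @return Essential value (scalar).
#' @export
#' @examples
#' essential_value(demand_params(19, 0.00332, 2.38))
essential_value <- function(params) {
  params <- as_demand_params(params)
  1 / (100 * params$alpha * params$k^1.5)
}

# Smaller root u* of u * exp(-u) = 1/(k ln 10) on (0, 1); at u = alpha*Q0*C
# this is the unit-elasticity point of the expenditure curve. A root exists
# iff 1/(k ln 10) < exp(-1), i.e. k > e/ln 10.
unit_elasticity_u <- function(k) {
  rhs <- 1 / (k * log(10))
  if (rhs >= exp(-1))
    stop("no unit-elastic point: k * ln(10) <= e (k too small)", call. = FALSE)
  uniroot(function(u) u * exp(-u) - rhs,
          lower = .Machine$double.eps, upper = 1, tol = 1e-14)$root
}

#' Price of maximal expenditure (Pmax)
#'
#' The unit price at which modeled expenditure `C * Q(C)` peaks and demand
#' passes from inelastic to elastic. Computed from the exact stationarity
#' condition: `Pmax = u* / (alpha * Q0)` with `u*` the smaller root of
#' `u e^{-u} = 1/(k ln 10)`.
#'
#' @inheritParams predict_log10_consumption
#' @return Pmax (scalar price).
#' @export
pmax_analytic <- function(params) {
  params <- as_demand_params(params)
  unit_elasticity_u(params$k) / (params$alpha * params$q0)
}

#' Maximal expenditure (Omax)
#'
#' Analytic Omax is the modeled expenditure at Pmax,
#' `Omax = Pmax * 10^(predicted log10 Q at Pmax)`. The ratio
#' `Omax / (Q0 * Pmax)` depends on `k` alone, as does `Omax / EV`, so both
#' are constant across subjects fitted with a shared `k`.
#'
#' @inheritParams predict_log10_consumption
#' @return Analytic Omax (scalar expenditure, responses per day).
#' @seealso [observed_omax()] for the empirical counterpart.
#' @export
omax_analytic <- function(params) {
  params <- as_demand_params(params)
  pmax <- pmax_analytic(params)
  pmax * 10^predict_log10_consumption(params, pmax)
}

#' Largest observed expenditure on a consumption curve
#'
#' The maximum of `price * consumption` over the observed points. Ties or
#' plateaus resolve to the lowest-price maximizer.
#'
#' @param price,consumption Paired observation vectors.
#' @return List with `omax` and the `price` at which it occurred.
#' @export
observed_omax <- function(price, consumption) {
  stopifnot(length(price) == length(consumption), length(price) >= 1L)
  exp_ <- price * consumption
  i <- which.max(exp_) # which.max returns the first maximizer
  list(omax = exp_[i], price = price[i])
}

#' Convert earned infusions to self-administered dose
#'
#' @param n_infusions Number of infusions earned, >= 0 (may be a per-session
#'   mean, hence fractional).
#' @param unit_dose Dose per infusion in mg/kg; defaults to 0.05 mg/kg/inf.
#' @return Dose in mg/kg.
#' @export
#' @examples
#' dose_from_infusions(258.83) # 12.94 mg/kg
dose_from_infusions <- function(n_infusions, unit_dose = 0.05) {
  if (any(n_infusions < 0)) stop("`n_infusions` must be >= 0", call. = FALSE)
  if (!is.numeric(unit_dose) || unit_dose <= 0)
    stop("`unit_dose` must be > 0", call. = FALSE)
  n_infusions * unit_dose
}

#' Back-solve the shared range constant k from a k-only ratio
#'
#' Under a shared `k`, both `Omax/(Q0*Pmax)` and `Omax/EV` are functions of
#' `k` alone:
#' `Omax/(Q0*Pmax) = 10^(k (e^{-u*} - 1))` and
#' `Omax/EV = 100 k^{1.5} u* 10^(k (e^{-u*} - 1))`,
#' with `u*` from [pmax_analytic()]'s stationarity condition. Given an
#' observed ratio this inverts the corresponding map numerically.
#'
#' @param ratio Observed ratio value.
#' @param type `"omax_q0pmax"` or `"omax_ev"`.
#' @param interval Search interval for `k`.
#' @return The implied `k`.
#' @export
solve_k_from_ratio <- function(ratio, type = c("omax_q0pmax", "omax_ev"),
                               interval = c(1.2, 50)) {
  type <- match.arg(type)
  f <- function(k) {
    u <- unit_elasticity_u(k)
    val <- 10^(k * (exp(-u) - 1))
    if (type == "omax_ev") val <- 100 * k^1.5 * u * val
    val - ratio
  }
  uniroot(f, interval, tol = 1e-12)$root
}
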