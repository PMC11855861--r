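# Per-gene negative-binomial regression of expression on a subject-level
# covariate (the individual essential value). The NB GLM with log link is
# fitted by iteratively reweighted least squares, alternating with
# maximum-likelihood estimation of the dispersion theta (Fisher scoring on
# the theta score, initialized from a method-of-moments estimate and bounded
# to [1e-3, 1e6]). Wald z and two-sided p are reported for the covariate
# slope. FPKM-like values are rounded half-up to integer counts before
# fitting by default; a continuous quasi-likelihood variant keeps them as-is.

nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta) + y * log(mu + (y == 0)) -
        (theta + y) * log(theta + mu))
}

theta_score_info <- function(y, mu, theta) {
  s <- sum(digamma(y + theta) - digamma(theta) + log(theta) + 1 -
             log(theta + mu) - (y + theta) / (theta + mu))
  i <- sum(-trigamma(y + theta) + trigamma(theta) - 1 / theta +
             2 / (theta + mu) - (y + theta) / (theta + mu)^2)
  c(score = s, info = i)
}

theta_ml <- function(y, mu, lower = 1e-3, upper = 1e6, maxit = 50L,
                     tol = 1e-8) {
  n <- length(y)
  denom <- sum((y / mu - 1)^2)
  th <- if (denom > 0) min(max(n / denom, lower), upper) else upper
  ok <- FALSE
  for (it in seq_len(maxit)) {
    si <- theta_score_info(y, mu, th)
    if (!is.finite(si[["info"]]) || si[["info"]] <= 0) break
    del <- si[["score"]] / si[["info"]]
    th_new <- min(max(th + del, lower), upper)
    if (abs(th_new - th) < tol * (th + tol)) { th <- th_new; ok <- TRUE; break }
    th <- th_new
  }
  if (!ok) { # fall back to bounded profile-likelihood search
    opt <- optimize(function(lt) -nb_loglik(y, mu, exp(lt)),
                    c(log(lower), log(upper)), tol = 1e-8)
    th <- exp(opt$minimum)
    ok <- TRUE
  }
  list(theta = th, converged = ok)
}

#' Negative-binomial GLM of expression on one covariate
#'
#' Fits `y ~ NB(mu, theta)` with `log(mu) = b0 + b1 * x (+ offset)` by IRLS,
#' alternating with ML estimation of `theta`, and reports the Wald test for
#' the covariate slope.
#'
#' @param y Non-negative response values (FPKM-like; rounded to counts unless
#'   `rounding = FALSE`).
#' @param x Covariate with nonzero variance (e.g. per-sample essential value).
#' @param offset Optional log-scale offset (e.g. log library size factor).
#' @param rounding Round `y` half-up to integers before fitting (the NB
#'   likelihood is a count likelihood). `FALSE` keeps continuous values and
#'   yields a quasi-likelihood fit with the same estimating equations.
#' @param maxit,tol Outer-loop control.
#' @return List of class `nb_fit`: `intercept`, `slope`, `se`, `z`, `p`,
#'   `theta`, `converged`, `n`, `fitted`.
#' @export
#' @examples
#' y <- c(3, 8, 10, 25, 40, 12, 7, 30, 22, 15, 9)
#' x <- c(0.1, 0.8, 1.0, 2.6, 4.2, 1.8, 0.2, 2.0, 1.5, 1.0, 0.7)
#' fit_nb_glm(y, x)
fit_nb_glm <- function(y, x, offset = NULL, rounding = TRUE, maxit = 50L,
                       tol = 1e-10) {
  if (length(y) != length(x)) stop("`y` and `x` lengths differ", call. = FALSE)
  if (length(y) < 4L) stop("need >= 4 observations", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0))
    stop("`y` must be finite and >= 0", call. = FALSE)
  if (var(x) == 0) stop("covariate has zero variance", call. = FALSE)
  if (rounding) y <- floor(y + 0.5)
  if (all(y == 0)) stop("all-zero response", call. = FALSE)
  off <- offset %||% rep(0, length(y))
  X <- cbind(intercept = 1, slope = x)
  mu <- pmax(y, 0.5)
  eta <- log(mu) - off
  theta <- 10
  beta <- c(NA_real_, NA_real_)
  converged <- FALSE
  for (outer in seq_len(maxit)) {
    # IRLS for beta at current theta
    for (inner in 1:50) {
      w <- mu / (1 + mu / theta)
      z <- eta + (y - mu) / mu
      fit <- lm.wfit(X, z, w)
      beta_new <- fit$coefficients
      eta_new <- pmin(pmax(drop(X %*% beta_new), -30), 30)
      mu_new <- exp(eta_new + off)
      done <- all(abs(eta_new - eta) < 1e-10 * (abs(eta) + 1e-10))
      eta <- eta_new; mu <- mu_new
      if (done) break
    }
    tm <- theta_ml(y, mu)
    theta_new <- tm$theta
    conv_beta <- !anyNA(beta) &&
      all(abs(fit$coefficients - beta) < tol * (abs(beta) + tol))
    conv_theta <- abs(theta_new - theta) < 1e-8 * (theta + 1e-8)
    beta <- fit$coefficients; theta <- theta_new
    if (conv_beta && conv_theta && tm$converged) { converged <- TRUE; break }
  }
  w <- mu / (1 + mu / theta)
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(diag(vc))
  z_stat <- beta[2L] / se[2L]
  structure(list(intercept = unname(beta[1L]), slope = unname(beta[2L]),
                 se = unname(se[2L]), z = unname(z_stat),
                 p = unname(2 * pnorm(-abs(z_stat))), theta = theta,
                 converged = converged && all(is.finite(se)),
                 n = length(y), fitted = mu), class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("NB GLM: slope = %.4f (SE %.4f), z = %.3f, p = %.3g, theta = %.3g%s\n",
              x$slope, x$se, x$z, x$p, x$theta,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control: with `m` tests and sorted
#' raw p-values, `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1 and
#' returned in the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Validate a gene-by-sample expression matrix against its metadata
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids); all values finite and >= 0.
#' @param meta Data frame with one row per sample: `sample_id` plus any of
#'   `subject_id`, `group`, `region`, `ev`.
#' @return Invisibly, `meta` reordered to match `colnames(mat)`.
#' @export
validate_expression <- function(mat, meta) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("`mat` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("`mat` needs gene rownames and sample colnames", call. = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("`meta` needs a `sample_id` column", call. = FALSE)
  idx <- match(colnames(mat), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "), call. = FALSE)
  invisible(meta[idx, , drop = FALSE])
}

#' Per-gene NB regression of expression on essential value
#'
#' Fits [fit_nb_glm()] gene by gene with the per-sample EV as covariate.
#' Genes with fewer than `min_nonzero` nonzero samples are skipped (reported
#' with `skipped = TRUE`, not tested). BH adjustment is applied across the
#' converged fits of the run; non-converged genes are flagged and excluded
#' from the FDR pool.
#'
#' @param mat,meta Expression matrix and metadata (see
#'   [validate_expression()]); `meta` must carry an `ev` column with at least
#'   two distinct values.
#' @param min_nonzero Minimum number of samples with nonzero expression.
#' @param rounding Passed to [fit_nb_glm()].
#' @return Data frame with one row per gene: `gene_id`, `intercept`,
#'   `slope_ev`, `se`, `z`, `p_raw`, `p_adj`, `theta`, `converged`, `skipped`.
#' @export
regress_all_genes <- function(mat, meta, min_nonzero = 3L, rounding = TRUE) {
  meta <- validate_expression(mat, meta)
  if (!"ev" %in% names(meta)) stop("`meta` needs an `ev` column", call. = FALSE)
  ev <- as.numeric(meta$ev)
  if (anyNA(ev)) stop("every sample needs an EV value", call. = FALSE)
  if (length(unique(ev)) < 2L)
    stop("need >= 2 distinct EV values", call. = FALSE)
  res <- lapply(rownames(mat), function(g) {
    y <- mat[g, ]
    if (sum(y > 0) < min_nonzero)
      return(data.frame(gene_id = g, intercept = NA_real_,
                        slope_ev = NA_real_, se = NA_real_, z = NA_real_,
                        p_raw = NA_real_, theta = NA_real_, converged = FALSE,
                        skipped = TRUE, stringsAsFactors = FALSE))
    f <- tryCatch(fit_nb_glm(y, ev, rounding = rounding),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(gene_id = g, intercept = NA_real_,
                        slope_ev = NA_real_, se = NA_real_, z = NA_real_,
                        p_raw = NA_real_, theta = NA_real_, converged = FALSE,
                        skipped = TRUE, stringsAsFactors = FALSE))
    data.frame(gene_id = g, intercept = f$intercept, slope_ev = f$slope,
               se = f$se, z = f$z, p_raw = f$p, theta = f$theta,
               converged = f$converged, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  pool <- out$converged & !out$skipped & is.finite(out$p_raw)
  if (any(pool)) out$p_adj[pool] <- bh_adjust(out$p_raw[pool])
  out[c("gene_id", "intercept", "slope_ev", "se", "z", "p_raw", "p_adj",
        "theta", "converged", "skipped")]
}

#' Filter a differential-expression table to DEGs
#'
#' Retains exactly the rows with `log2_fc > 1` or `log2_fc < -1` (strict) and
#' `p_value < 0.05` (strict), and labels the direction of change.
#'
#' @param table Data frame with columns `gene_id`, `log2_fc`, `p_value`.
#' @return The retained rows with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
#' @examples
#' filter_degs(data.frame(gene_id = c("Pex5", "gX", "gY"),
#'                        log2_fc = c(-14.82, 0, 1), p_value = c(.01, .001, .01)))
filter_degs <- function(table) {
  table <- as.data.frame(table)
  req <- c("gene_id", "log2_fc", "p_value")
  if (!all(req %in% names(table)))
    stop("`table` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(!is.finite(table$log2_fc)))
    stop("`log2_fc` must be finite", call. = FALSE)
  if (any(table$p_value < 0 | table$p_value > 1, na.rm = TRUE))
    stop("`p_value` must lie in [0, 1]", call. = FALSE)
  keep <- (table$log2_fc > 1 | table$log2_fc < -1) &
    !is.na(table$p_value) & table$p_value < 0.05
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2_fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Simplified per-gene NB group contrast
#'
#' Fits a per-gene NB GLM with a group indicator (reference group coded 0)
#' and reports the log2 fold change (`slope / ln 2`) and the NB-Wald p-value.
#' A lightweight stand-in so the pipeline can produce a DEG table end to end;
#' it does not attempt library-size normalization or dispersion shrinkage.
#'
#' @param mat,meta Expression matrix and metadata with a `group` column.
#' @param groups Length-2 vector: reference group first.
#' @param min_nonzero,rounding As in [regress_all_genes()].
#' @return Data frame `gene_id`, `log2_fc`, `p_value`, `converged`; feed to
#'   [filter_degs()].
#' @export
nb_group_contrast <- function(mat, meta, groups = NULL, min_nonzero = 3L,
                              rounding = TRUE) {
  meta <- validate_expression(mat, meta)
  if (!"group" %in% names(meta)) stop("`meta` needs a `group` column",
                                      call. = FALSE)
  glev <- groups %||% unique(as.character(meta$group))
  if (length(glev) != 2L) stop("exactly 2 groups required", call. = FALSE)
  if (min(table(factor(meta$group, levels = glev))) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  x <- as.numeric(meta$group == glev[2L])
  res <- lapply(rownames(mat), function(g) {
    y <- mat[g, ]
    f <- if (sum(y > 0) >= min_nonzero)
      tryCatch(fit_nb_glm(y, x, rounding = rounding), error = function(e) NULL)
    else NULL
    data.frame(gene_id = g,
               log2_fc = if (is.null(f)) NA_real_ else f$slope / log(2),
               p_value = if (is.null(f)) NA_real_ else f$p,
               converged = !is.null(f) && f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
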