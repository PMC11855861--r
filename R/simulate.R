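# Synthetic cohort generator. Emulates the study design the analysis
# assumes: 6 METH + 6 saline subjects run up the escalating FR ladder with
# multiplicative (log10-additive Gaussian) consumption noise and
# group-separated lognormal (Q0, alpha) heterogeneity, and a gene-by-sample
# negative-binomial expression matrix in which a small planted fraction of
# genes has a log-mean linear in the subject's essential value. Behavioral
# and expression draws use separate derived seeds so changing the gene panel
# never perturbs the behavioral cohort.

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator, with defaults emulating the
#' study conditions the package targets: 6 vs 6 subjects, the 13-step FR
#' ladder, shared k = 2.4, log10 consumption noise SD 0.1, ~10-fold group
#' separation in alpha (METH low, saline high), 2,000 genes with 2.5% planted
#' EV-linked genes at slope 0.5 on the log-mean scale, NB dispersion
#' theta = 10, and one METH expression sample dropped (the unbalanced
#' 11-sample design of a cohort that lost a sample in transport).
#'
#' @param n_meth,n_sal Subjects per group (>= 1).
#' @param ladder Price ladder, strictly increasing, > 0.
#' @param k_true Shared range constant used to generate consumption.
#' @param q0_logmean_meth,q0_logsd_meth,q0_logmean_sal,q0_logsd_sal Lognormal
#'   (natural-log scale) parameters for demand intensity per group.
#' @param alpha_logmean_meth,alpha_logsd_meth,alpha_logmean_sal,alpha_logsd_sal
#'   Lognormal parameters for demand elasticity per group.
#' @param noise_sd_log10 SD of the additive Gaussian noise on log10
#'   consumption, >= 0.
#' @param unit_dose Dose per infusion (mg/kg); consumption is generated in
#'   mg/kg and divided by this to decide when earned infusions round to zero.
#' @param n_genes Number of genes in the expression matrix.
#' @param frac_linked Fraction of genes whose log-mean depends on EV.
#' @param slope_linked Log-mean slope per unit EV for linked genes.
#' @param baseline_logmean,baseline_logsd Natural-log-scale distribution of
#'   per-gene baseline expression.
#' @param theta NB dispersion used to generate counts.
#' @param libsize_jitter SD of the lognormal per-sample library-size factor.
#' @param drop_meth_sample Drop one METH sample from the expression matrix
#'   (keeps the behavioral cohort complete).
#' @param region Region label written into the sample metadata.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(n_meth = 6L, n_sal = 6L,
                              ladder = default_fr_ladder(), k_true = 2.4,
                              q0_logmean_meth = 1.93, q0_logsd_meth = 0.65,
                              q0_logmean_sal = 0.10, q0_logsd_sal = 0.55,
                              alpha_logmean_meth = -6.34,
                              alpha_logsd_meth = 0.70,
                              alpha_logmean_sal = -3.90,
                              alpha_logsd_sal = 0.50,
                              noise_sd_log10 = 0.1, unit_dose = 0.05,
                              n_genes = 2000L, frac_linked = 0.025,
                              slope_linked = 0.5,
                              baseline_logmean = 3.5, baseline_logsd = 1.0,
                              theta = 10, libsize_jitter = 0.05,
                              drop_meth_sample = TRUE, region = "PFC",
                              seed = 1L) {
  cfg <- list(n_meth = as.integer(n_meth), n_sal = as.integer(n_sal),
              ladder = as.numeric(ladder), k_true = k_true,
              q0_logmean_meth = q0_logmean_meth, q0_logsd_meth = q0_logsd_meth,
              q0_logmean_sal = q0_logmean_sal, q0_logsd_sal = q0_logsd_sal,
              alpha_logmean_meth = alpha_logmean_meth,
              alpha_logsd_meth = alpha_logsd_meth,
              alpha_logmean_sal = alpha_logmean_sal,
              alpha_logsd_sal = alpha_logsd_sal,
              noise_sd_log10 = noise_sd_log10, unit_dose = unit_dose,
              n_genes = as.integer(n_genes),
              frac_linked = frac_linked, slope_linked = slope_linked,
              baseline_logmean = baseline_logmean,
              baseline_logsd = baseline_logsd, theta = theta,
              libsize_jitter = libsize_jitter,
              drop_meth_sample = isTRUE(drop_meth_sample),
              region = as.character(region), seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_meth < 1L || cfg$n_sal < 1L)
    stop("subject counts must be >= 1", call. = FALSE)
  lad <- cfg$ladder
  if (length(lad) < 3L || any(lad <= 0) || any(diff(lad) <= 0))
    stop("`ladder` must be strictly increasing and > 0", call. = FALSE)
  for (nm in c("k_true", "q0_logsd_meth", "q0_logsd_sal", "alpha_logsd_meth",
               "alpha_logsd_sal", "theta", "unit_dose"))
    if (cfg[[nm]] <= 0) stop("`", nm, "` must be > 0", call. = FALSE)
  for (nm in c("noise_sd_log10", "libsize_jitter"))
    if (cfg[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  if (cfg$frac_linked < 0 || cfg$frac_linked > 1)
    stop("`frac_linked` must lie in [0, 1]", call. = FALSE)
  if (cfg$n_genes < 1L) stop("`n_genes` must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# distinct deterministic streams per stage
stream_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Simulate a demand cohort on the FR ladder
#'
#' Per subject, `(Q0, alpha)` are drawn lognormally from the group
#' distribution and consumption (in mg/kg) at each ladder price is
#' `10^(demand prediction + N(0, noise_sd_log10))` under the shared
#' `k_true`. Mimicking the escalating-FR stopping rule (a rat progresses
#' until it fails to earn at least one infusion), the ladder is truncated at
#' the first price from the fourth step onward where the earned infusions
#' (`consumption / unit_dose`) round to zero; that failing price is recorded
#' with consumption 0. The first three prices are always administered so
#' every curve is fittable.
#'
#' @param config A [simulation_config()].
#' @return List with `consumption` (long data frame: `subject_id`, `group`,
#'   `price`, `consumption`) and `truth` (per-subject generating `q0`,
#'   `alpha`, `k`, and true `ev`).
#' @export
simulate_demand_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  with_seed(stream_seed(cfg$seed, 1L), {
    groups <- c(rep("METH", cfg$n_meth), rep("SAL", cfg$n_sal))
    ids <- c(sprintf("M%02d", seq_len(cfg$n_meth)),
             sprintf("S%02d", seq_len(cfg$n_sal)))
    rows <- list(); truth <- list()
    for (i in seq_along(ids)) {
      meth <- groups[i] == "METH"
      q0 <- exp(rnorm(1, if (meth) cfg$q0_logmean_meth else cfg$q0_logmean_sal,
                      if (meth) cfg$q0_logsd_meth else cfg$q0_logsd_sal))
      alpha <- exp(rnorm(1, if (meth) cfg$alpha_logmean_meth else
        cfg$alpha_logmean_sal,
        if (meth) cfg$alpha_logsd_meth else cfg$alpha_logsd_sal))
      par <- demand_params(q0, alpha, cfg$k_true)
      pred <- predict_log10_consumption(par, cfg$ladder)
      q <- 10^(pred + rnorm(length(cfg$ladder), 0, cfg$noise_sd_log10))
      keep <- length(q)
      for (j in seq_along(q)) {
        if (j > 3L && round(q[j] / cfg$unit_dose) == 0) {
          q[j] <- 0; keep <- j; break
        }
      }
      rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                              price = cfg$ladder[seq_len(keep)],
                              consumption = q[seq_len(keep)],
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                               q0 = q0, alpha = alpha, k = cfg$k_true,
                               ev = essential_value(par),
                               stringsAsFactors = FALSE)
    }
    list(consumption = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate an EV-linked negative-binomial expression matrix
#'
#' For gene `g` and sample `s`, counts are drawn
#' `NB(mu = L_s * exp(b0_g + beta_g * EV_s), size = theta)` with
#' `b0_g ~ N(baseline_logmean, baseline_logsd)`, `beta_g = slope_linked` for
#' a randomly placed `frac_linked` fraction of genes and 0 otherwise, and a
#' lognormal per-sample library-size factor `L_s`.
#'
#' @param config A [simulation_config()].
#' @param ev_by_subject Data frame `subject_id`, `group`, `ev` (one row per
#'   subject), e.g. the truth table of [simulate_demand_cohort()] or fitted
#'   EVs.
#' @return List with `mat` (genes x samples matrix), `meta` (`sample_id`,
#'   `subject_id`, `group`, `region`, `ev`) and `truth_genes` (`gene_id`,
#'   `b0`, `beta`, `linked`).
#' @export
simulate_expression <- function(config, ev_by_subject) {
  cfg <- validate_sim_config(config)
  ev_by_subject <- as.data.frame(ev_by_subject)
  req <- c("subject_id", "group", "ev")
  if (!all(req %in% names(ev_by_subject)))
    stop("`ev_by_subject` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyNA(ev_by_subject$ev))
    stop("EV must be available for every subject", call. = FALSE)
  with_seed(stream_seed(cfg$seed, 2L), {
    samples <- ev_by_subject
    if (cfg$drop_meth_sample) {
      drop <- which(samples$group == "METH")[1L]
      if (!is.na(drop)) samples <- samples[-drop, , drop = FALSE]
    }
    n_s <- nrow(samples); n_g <- cfg$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(n_g))
    n_linked <- round(cfg$frac_linked * n_g)
    linked <- rep(FALSE, n_g)
    if (n_linked > 0) linked[sample.int(n_g, n_linked)] <- TRUE
    b0 <- rnorm(n_g, cfg$baseline_logmean, cfg$baseline_logsd)
    beta <- ifelse(linked, cfg$slope_linked, 0)
    libsize <- exp(rnorm(n_s, 0, cfg$libsize_jitter))
    mu <- exp(outer(b0, rep(1, n_s)) + outer(beta, samples$ev)) *
      rep(libsize, each = n_g)
    mat <- matrix(rnbinom(n_g * n_s, mu = mu, size = cfg$theta), nrow = n_g,
                  dimnames = list(gene_ids,
                                  paste0(cfg$region, "_", samples$subject_id)))
    meta <- data.frame(sample_id = colnames(mat),
                       subject_id = samples$subject_id,
                       group = samples$group, region = cfg$region,
                       ev = samples$ev, stringsAsFactors = FALSE)
    list(mat = mat, meta = meta,
         truth_genes = data.frame(gene_id = gene_ids, b0 = b0, beta = beta,
                                  linked = linked, stringsAsFactors = FALSE))
  })
}
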