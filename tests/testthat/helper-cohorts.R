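# shared fixtures, all generated in code

# noiseless consumption curve from known parameters
noiseless_curve <- function(params, ladder = default_fr_ladder()) {
  10^predict_log10_consumption(params, ladder)
}

# the 11-sample EV design of the unbalanced expression cohort (one METH
# sample dropped from the packaged reference cohort)
ev_design_11 <- function() {
  ev <- reference_cohort(behavioral_only = TRUE)$ev
  ev[-5][1:11]
}

# two-group long table built from two parameter sets plus optional noise
two_group_curves <- function(p_a, p_b, noise_sd = 0, seed = 1,
                             ladder = default_fr_ladder()) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    qa <- 10^(predict_log10_consumption(p_a, ladder) +
                rnorm(length(ladder), 0, noise_sd))
    qb <- 10^(predict_log10_consumption(p_b, ladder) +
                rnorm(length(ladder), 0, noise_sd))
    rbind(data.frame(subject_id = "a", group = "A", price = ladder,
                     consumption = qa),
          data.frame(subject_id = "b", group = "B", price = ladder,
                     consumption = qb))
  })
}

# NB expression matrix with the first `n_planted` genes EV-linked
planted_matrix <- function(ev, n_planted, n_null, slope = 0.5, theta = 10,
                           baseline_logmean = 3.5, seed = 1) {
  set.seed(seed)
  n_g <- n_planted + n_null
  b0 <- rnorm(n_g, baseline_logmean, 1)
  beta <- c(rep(slope, n_planted), rep(0, n_null))
  mat <- t(vapply(seq_len(n_g), function(g)
    rnbinom(length(ev), mu = exp(b0[g] + beta[g] * ev), size = theta),
    numeric(length(ev))))
  rownames(mat) <- sprintf("g%04d", seq_len(n_g))
  colnames(mat) <- sprintf("s%03d", seq_along(ev))
  list(mat = mat,
       meta = data.frame(sample_id = colnames(mat), ev = ev),
       planted = seq_len(n_planted))
}
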