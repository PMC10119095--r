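# Shared fixtures: everything is generated in code at test time.

# Reference with near-degenerate noise: biomarkers sit on their lines.
tiny_noise_params <- function(s = 1e-6) {
  p <- default_biomarker_params()
  p$s <- s
  p
}

small_reference <- function(n = 2000, seed = 3,
                            params = default_biomarker_params()) {
  generate_reference(reference_config(n = n, seed = seed,
                                      biomarker_params = params))
}

# Panel lying exactly on the trained mean trajectory at age `a` for sex `sx`:
# x_i = q_i + k_i * a (CRP exponentiated back from the log-scale line).
panel_on_trajectory <- function(params, a, sx) {
  p <- params[[sx]]
  panel <- as.list(p$q + p$k * a)
  names(panel) <- names(p$q)
  panel$crp <- exp(panel$log_crp)
  panel$log_crp <- NULL
  out <- as.data.frame(panel)
  # PhenoAge markers not trained by KDM are irrelevant here; fill plausibly
  pheno_markers <- c("albumin", "creatinine", "glucose", "crp",
                     "lymphocyte_pct", "mcv", "rdw", "alp", "wbc")
  for (bm in setdiff(pheno_markers, names(out))) {
    out[[bm]] <- c(glucose = 92, lymphocyte_pct = 29, mcv = 83, rdw = 13.5,
                   wbc = 6.8)[[bm]]
  }
  out
}

# Random plausible PhenoAge panels for property grids.
random_pheno_panel <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    albumin = runif(n, 3.8, 5.2), creatinine = runif(n, 0.5, 1.4),
    glucose = runif(n, 70, 160), crp = exp(runif(n, -4, 1.5)),
    lymphocyte_pct = runif(n, 10, 45), mcv = runif(n, 75, 95),
    rdw = runif(n, 11.5, 16.5), alp = runif(n, 40, 140),
    wbc = runif(n, 3.5, 11))
}

# Small pre-scored cohort for association tests.
scored_cohort <- function(n = 8000, seed = 21, ...) {
  score_cohort(generate_cohort(cohort_config(n = n, seed = seed, ...)))
}
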