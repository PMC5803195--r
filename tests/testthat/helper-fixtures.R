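# shared fixtures and independent brute-force oracles

b9 <- c(0, 10, 20, 50, 100, 200, 500, 800, 1000)
proto9 <- acquisition_protocol(b9, c(60, 70, 80, 90, 100, 120))
proto60 <- acquisition_protocol(b9, 60)

# central published prostate parameter sets (1e-3 mm^2/s scale for D, D*)
gt_pz <- function(s0 = 1, t2t = 136, t2b = 275)
  tissue_ground_truth(s0 = s0, d = 1.568e-3, d_star = 9.150e-3, f = 0.097,
                      t2_tissue = t2t, t2_blood = t2b)
gt_cz <- function(s0 = 1, t2t = 80, t2b = 275)
  tissue_ground_truth(s0 = s0, d = 1.211e-3, d_star = 13.443e-3, f = 0.111,
                      t2_tissue = t2t, t2_blood = t2b)

# dense brute-force grid minimisation of the mono-exponential SSE;
# independent of the package's fitting path
grid_min_monoexp <- function(b, s, n = 201) {
  a_grid <- seq(0.5 * max(s), 2 * max(s), length.out = n)
  k_grid <- seq(0, 5e-3, length.out = n)
  best <- Inf
  for (a in a_grid) {
    sse <- colSums((s - a * exp(-outer(b, k_grid)))^2)
    best <- min(best, min(sse))
  }
  best
}

# brute-force 1-D grid for the D* stage objective
grid_min_dstar <- function(b, s, s0, f, d, n = 20001) {
  ds_grid <- seq(d, 0.5, length.out = n)
  model <- f * exp(-outer(b, ds_grid)) + (1 - f) * exp(-b * d)
  min(colSums((s - s0 * model)^2))
}

cv_bin_of <- ivimte:::cv_bin

# ground-truth draw under the config's own seed
with_seed_gt <- function(cfg) {
  set.seed(cfg$seed)
  sample_ground_truth(cfg)
}

# noiseless multi-TE series set for one ground truth
series_at_tes <- function(gt, tes, protocol = proto9)
  lapply(tes, function(te)
    signal_series(protocol, te,
                  extended_ivim_signal(gt, protocol$b_values, te)))
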