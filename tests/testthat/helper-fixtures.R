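# Shared fixture builders (everything is generated in code at test time).

# single-vessel OMAG-V phantom at a programmed velocity and SNR
vessel_phantom <- function(velocity_mm_s, snr = 10, seed = 1,
                           n_positions = 20, depth_px = 48,
                           static_amplitude = 1) {
  phantom_spec(
    preset = "omag-v", n_positions = n_positions, depth_px = depth_px,
    noise_sigma = sqrt(1 / snr), static_amplitude = static_amplitude,
    seed = seed,
    flow_segments = list(list(
      positions = c(max(2, round(0.25 * n_positions)),
                    round(0.75 * n_positions)),
      depths = c(max(2, round(0.3542 * depth_px)),
                 round(0.625 * depth_px)),
      velocity_mm_s = velocity_mm_s,
      amplitude = 1)))
}

# lumen field used by the particle-analysis examples: 10 large + 5 small
standard_lumen_field <- function(pixel_um = 1) {
  big <- expand.grid(x_um = seq(20, 180, by = 40),
                     y_um = c(30, 90))
  small <- data.frame(x_um = seq(30, 190, by = 40), y_um = 150)
  lumens <- rbind(data.frame(big, area_um2 = 50),
                  data.frame(small, area_um2 = 10))
  make_lumen_image(lumens, pixel_um = pixel_um,
                   image_shape = c(200, 220))
}

# rank-based AUC (Wilcoxon identity), independent of any package
rank_auc <- function(score, label) {
  r <- rank(score)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}

# brute-force upper-tail hypergeometric by direct combinatorial sums
hyper_tail_bruteforce <- function(k, n_pathway, n_universe, n_de) {
  j <- k:min(n_pathway, n_de)
  sum(choose(n_pathway, j) * choose(n_universe - n_pathway, n_de - j)) /
    choose(n_universe, n_de)
}

# Benjamini-Hochberg step-up computed from first principles
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
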