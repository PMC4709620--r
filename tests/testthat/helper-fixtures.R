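# shared fixtures, all generated in code

std_schedule <- function() c(0, 0.25, 0.5, 1, 3, 6, 9, 12)

gaussian_chrom <- function(rt = 10, area = 5, sigma = 0.1, duration = 20,
                           rate = 5, noise = 0, seed = NULL) {
  generate_chromatogram(peak_spec("X", rt, area = area, sigma = sigma),
                        duration = duration, sampling_rate = rate,
                        baseline_noise_sd = noise, seed = seed)
}

single_gaussian_peak <- function(...) {
  detect_peaks(gaussian_chrom(...), min_height = 1)[1, ]
}

# synthetic peak-measurement row with exactly chosen metric inputs
synthetic_peak_row <- function(rt, width_at_half, tailing = 1) {
  # choose 5% widths so the USP tailing factor equals `tailing`
  w5 <- 2.081 * width_at_half           # Gaussian ratio, shape irrelevant here
  front <- w5 / (2 * tailing)
  data.frame(analyte_id = "synthetic", retention_time = rt,
             height = 10, area = 1, width_at_half = width_at_half,
             width_at_5pct = w5, front_at_5pct = front)
}
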