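# Independent closed-form oracles, written directly from the governing
# equations; these stay separate from the package implementation paths.

oracle_meniscus <- function(sigma, th_h, th_w, h, w) {
  max(-2 * sigma * (cos(th_h * pi / 180) / h + cos(th_w * pi / 180) / w), 0)
}

oracle_poiseuille <- function(Q, mu, w, h, L) {
  12 * mu * L * Q / (w * h^3 * (1 - 0.63 * h / w))
}

oracle_series_R <- function(thicknesses, Ks) sum(thicknesses / Ks)

oracle_advdiff <- function(x, L, Pe, c0 = 1, cL = 0) {
  if (abs(Pe) < 1e-12) c0 + (cL - c0) * x / L
  else c0 + (cL - c0) * (exp(Pe * x / L) - 1) / (exp(Pe) - 1)
}

# disk / square rasterizers for morphometry oracles
raster_disk <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  ((xx - n / 2)^2 + (yy - n / 2)^2 <= r^2) * 1
}

raster_square <- function(a, pad = 10) {
  n <- a + 2 * pad
  m <- matrix(0, n, n)
  m[pad + seq_len(a), pad + seq_len(a)] <- 1
  m
}
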