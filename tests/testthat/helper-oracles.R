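# Independent oracles: deliberately simple re-derivations used to check the
# package's implementations. They must not call the code paths they verify.

# fine-grid Riemann (midpoint) integral of a function of wavelength
riemann_fun <- function(f, lo, hi, n = 2e5) {
  x <- seq(lo, hi, length.out = n + 1)
  mid <- (x[-1] + x[-(n + 1)]) / 2
  sum(f(mid) * diff(x))
}

# fine-grid integral of tabulated values, via linear interpolation
riemann_tab <- function(wl, v, n = 2e5) {
  riemann_fun(function(x) stats::approx(wl, v, xout = x)$y,
              min(wl), max(wl), n)
}

# trichromat receptor-noise distance, written out by hand
jnd_closed_form <- function(qa, qb, eta = c(1, 4, 4), w = 0.05) {
  e <- w * sqrt(max(eta) / eta)
  f <- log(qa / qb)
  num <- e[1]^2 * (f[3] - f[2])^2 + e[2]^2 * (f[3] - f[1])^2 +
    e[3]^2 * (f[2] - f[1])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

# A1 alpha-band absorbance formula, independent copy for dense scans
a1_template_fun <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# smooth positive test spectrum on the canonical grid
smooth_spct <- function(seed, kind = "photon_radiance", base = 1) {
  wl <- 380:700
  set.seed(seed)
  a <- runif(3, 0.1, 1); ph <- runif(3, 0, 2 * pi)
  v <- base * (1.5 + a[1] * sin(wl / 40 + ph[1]) +
                 a[2] * sin(wl / 90 + ph[2]) + a[3] * sin(wl / 17 + ph[3]))
  spct(wl, pmax(v, 0.05), kind)
}
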