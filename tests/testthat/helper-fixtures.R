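# Shared fixtures, built in code. All stochastic fixtures carry explicit
# seeds so every test is reproducible bit-for-bit.

water_cfg <- function() optical_config(532, 90, 1.333, 293.15, 1.002)

# the DLS parameter point used throughout: extrusion-I 50 nm POPC vesicles
STUDY_GAMMA <- 0.00240   # 1/us
STUDY_MU2 <- 5.5e-7      # 1/us^2

bimodal_dist <- function() size_distribution(c(0.001, 0.01), c(0.5, 0.5))

# hand-evaluated reference pair: gamma = (200*50)/(250*5) = 8,
# alpha = 1.25, upsilon = 1.25 -> C2 = 10/74, C1 = 80/74
reference_pair <- function(se1 = 0, se2 = 0) {
  extrusion_pair(m0 = 1, v1 = 0.8, vt = 1.8, d1 = 50, d2 = 5,
                 i1 = 200, i2 = 250, se_i1 = se1, se_i2 = se2)
}

random_valid_pair <- function() {
  m0 <- runif(1, 0.2, 5)
  v1 <- runif(1, 0.3, 2)
  vt <- v1 + runif(1, 0.2, 2)
  extrusion_pair(m0 = m0, v1 = v1, vt = vt,
                 d1 = runif(1, 1, 100), d2 = runif(1, 1, 20),
                 i1 = runif(1, 10, 1000), i2 = runif(1, 10, 1000),
                 se_i1 = 0, se_i2 = 0)
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}
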