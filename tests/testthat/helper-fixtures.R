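# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

# a plausible single ring-width series: negative-exponential age trend with
# multiplicative lognormal noise
make_series <- function(n = 25, seed = 1, id = "XX101a", first_year = 1997,
                        sd_log = 0.2, stock = "XX1", shoot = "01",
                        radius = "a") {
  set.seed(seed)
  tau <- seq_len(n)
  w <- round((600 * exp(-0.07 * tau) + 250) * exp(rnorm(n, 0, sd_log)))
  rws(id, w, first_year, site = substr(id, 1, 2), stock = stock,
      shoot = shoot, radius = radius)
}

# one shoot with four radii sharing a common year signal
make_shoot <- function(stock = "XX1", shoot = "01", n = 25, seed = 1,
                       first_year = 1997, noise = 0.05) {
  set.seed(seed)
  common <- rnorm(n, 0, 0.25)
  tau <- seq_len(n)
  base <- 600 * exp(-0.07 * tau) + 250
  lapply(c(a = "a", b = "b", c = "c", d = "d"), function(r) {
    w <- round(base * exp(common + rnorm(n, 0, noise)))
    rws(paste0(stock, shoot, r), w, first_year, site = substr(stock, 1, 2),
        stock = stock, shoot = shoot, radius = r)
  })
}

quiet_scenario <- function(seed, ...) {
  args <- list(...)
  if (!"pulse_years" %in% names(args)) args["pulse_years"] <- list(NULL)
  if (!"disturbance" %in% names(args))
    args$disturbance <- c(prob = 0, depth = 0.5, duration = 2)
  args$seed <- seed
  do.call(sim_params, args)
}
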