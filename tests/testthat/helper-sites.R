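# Fixture builders shared across the suite.

# A site with every month identical; defaults give tavg 15 everywhere.
constant_site <- function(tmin = 10, tmax = 20, precip = 26, rh = 0.5,
                          lat = -41, id = "const") {
  location_climate(id, lat = lat, lon = 0,
                   tmin = rep(tmin, 12), tmax = rep(tmax, 12),
                   precip = rep(precip, 12),
                   rh09 = rep(rh, 12), rh15 = rep(rh, 12))
}

# A random but valid site (sinusoidal cycle, positive rainfall).
random_site <- function(id = "rnd", lat = runif(1, -60, 60)) {
  tavg <- runif(1, -5, 25) + runif(1, 2, 12) * cos(2 * pi * (1:12) / 12)
  dtr <- runif(1, 4, 12)
  location_climate(id, lat = lat, lon = runif(1, -180, 180),
                   tmin = tavg - dtr / 2, tmax = tavg + dtr / 2,
                   precip = runif(12, 0, 200),
                   rh09 = runif(12, 0.2, 0.95),
                   rh15 = runif(12, 0.05, 0.9))
}
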