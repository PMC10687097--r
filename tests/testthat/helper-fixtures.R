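# Shared fixtures and independent brute-force oracles. Landscapes are
# memoised per configuration so expensive generation runs once per session.

.fixture_cache <- new.env(parent = emptyenv())

test_landscape <- function(seed = 1, years = 2014:2016, n_districts = 6,
                           n_rows = 60, n_cols = 60, n_settlements = 5) {
  key <- paste(seed, paste(years, collapse = "-"), n_districts, n_rows,
               n_cols, n_settlements, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- default_landscape(
      seed = seed, years = years, n_districts = n_districts,
      n_rows = n_rows, n_cols = n_cols, n_settlements = n_settlements)
  }
  .fixture_cache[[key]]
}

# exhaustive min-over-sources distance, deliberately naive
brute_force_distance <- function(geometry, mask) {
  cc <- cell_centers(geometry)
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  for (i in seq_len(geometry$n_rows)) {
    for (j in seq_len(geometry$n_cols)) {
      best <- Inf
      for (s in seq_len(nrow(src))) {
        d <- sqrt((cc$y[i] - cc$y[src[s, 1]])^2 +
                    (cc$x[j] - cc$x[src[s, 2]])^2)
        if (d < best) best <- d
      }
      out[i, j] <- best
    }
  }
  out
}

# O(n^2) pairwise enumeration of the Mann-Kendall statistic and tau-b
brute_force_mk <- function(x) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  }
  ties <- table(x)
  t <- as.numeric(ties[ties > 1])
  D <- n * (n - 1) / 2
  denom <- sqrt((D - sum(t * (t - 1) / 2)) * D)
  list(S = S, tau = if (denom > 0) S / denom else 0)
}

brute_force_sen <- function(x, times = seq_along(x)) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[j] != times[i])
        slopes <- c(slopes, (x[j] - x[i]) / (times[j] - times[i]))
    }
  }
  stats::median(slopes)
}

# small hand-built census table
toy_census <- function() {
  expand <- expand.grid(district_id = 1:3, year = 2000:2004,
                        species = c("small_ruminant", "horse"),
                        stringsAsFactors = FALSE)
  expand$headcount <- seq_len(nrow(expand)) * 10
  expand$area_km2 <- rep(c(50, 100, 200), length.out = nrow(expand))
  expand[order(expand$district_id, expand$species, expand$year), ]
}
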