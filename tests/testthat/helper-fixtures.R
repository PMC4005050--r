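# fixtures built in code

# series whose pixels all share one per-composite value sequence
constant_series <- function(values, years, doys, nr = 2, nc = 2) {
  composite_series(mapply(function(v, y, d) {
    evi_composite(matrix(v, nr, nc), y, d, scale_factor = 1)
  }, values, years, doys, SIMPLIFY = FALSE))
}

# one crop year of sowing-window composites (DOY 225..337 of `year`)
sowing_doys <- seq(225L, 337L, 16L)
# the wrap-around maximum-development window of crop year `year`
maxdev_tags <- function(year) {
  data.frame(year = c(year, year + 1, year + 1, year + 1),
             doy = c(353L, 1L, 17L, 33L))
}

# random series with optional NA holes, for oracle comparisons
random_series <- function(nr, nc, n, seed, na_frac = 0.1,
                          years = 2006L, doys = NULL) {
  if (is.null(doys)) doys <- seq(225L, by = 16L, length.out = n)
  with_seed <- function(s, expr) {
    set.seed(s); expr
  }
  with_seed(seed, {
    comps <- lapply(seq_len(n), function(i) {
      v <- matrix(runif(nr * nc, 0, 1), nr, nc)
      if (na_frac > 0) v[runif(nr * nc) < na_frac] <- NA
      evi_composite(v, years, doys[i], scale_factor = 1)
    })
    composite_series(comps)
  })
}

# brute-force per-pixel MinMean: pairwise means with surviving-member
# fallback, minimum over pairs
brute_min_mean <- function(series) {
  vals <- lapply(series$composites, `[[`, "values")
  nr <- nrow(vals[[1]]); nc <- ncol(vals[[1]])
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    x <- vapply(vals, function(v) v[r, c], numeric(1))
    pms <- c()
    for (i in seq_len(length(x) - 1)) {
      pair <- x[c(i, i + 1)]
      if (all(is.na(pair))) next
      pms <- c(pms, mean(pair, na.rm = TRUE))
    }
    if (length(pms)) out[r, c] <- min(pms)
  }
  out
}

# brute-force per-pixel MaxMean: mean of the first four composites, masked
# values excluded
brute_max_mean <- function(series) {
  vals <- lapply(series$composites[seq_len(min(4, length(series)))], `[[`, "values")
  nr <- nrow(vals[[1]]); nc <- ncol(vals[[1]])
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    x <- vapply(vals, function(v) v[r, c], numeric(1))
    if (any(!is.na(x))) out[r, c] <- mean(x, na.rm = TRUE)
  }
  out
}

# brute-force accuracy tally from a labelled sample
brute_metrics <- function(m) {
  n <- sum(m)
  list(
    overall = 100 * (m[1, 1] + m[2, 2]) / n,
    users_soy = 100 * m[1, 1] / (m[1, 1] + m[1, 2]),
    producers_soy = 100 * m[1, 1] / (m[1, 1] + m[2, 1]),
    kappa = {
      p_o <- (m[1, 1] + m[2, 2]) / n
      p_e <- ((m[1, 1] + m[1, 2]) * (m[1, 1] + m[2, 1]) +
                (m[2, 1] + m[2, 2]) * (m[1, 2] + m[2, 2])) / n^2
      (p_o - p_e) / (1 - p_e)
    }
  )
}
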