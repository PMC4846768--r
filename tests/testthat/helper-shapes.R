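# Shared geometric fixtures, all built in code.

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  polygon_xy(c(x0, x0 + side, x0 + side, x0),
             c(y0, y0, y0 + side, y0 + side))
}

# regular 5-pointed star with outer radius R and inner radius r,
# first outer point at angle pi/2
star5 <- function(R = 1, r = 0.4) {
  ang <- pi / 2 + (0:9) * pi / 5
  rad <- rep(c(R, r), 5)
  polygon_xy(rad * cos(ang), rad * sin(ang))
}

# disk with sinusoidal boundary serration (many small protuberances)
serrated_disk <- function(R = 1, amp = 0.05, waves = 40, n = 2000) {
  th <- 2 * pi * (0:(n - 1)) / n
  rad <- R * (1 + amp * sin(waves * th))
  polygon_xy(rad * cos(th), rad * sin(th))
}

random_simple_polygon <- function(n = 12) {
  # star-shaped about the origin, hence simple
  th <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.3, 1)
  polygon_xy(rad * cos(th), rad * sin(th))
}

# brute-force convex hull: the subset of points that are vertices of the
# hull, found by testing all point triples (only usable at tiny n)
brute_hull_vertices <- function(x, y) {
  n <- length(x)
  on_hull <- rep(TRUE, n)
  for (p in seq_len(n)) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (length(unique(c(i, j, k, p))) < 4) next
      # p strictly inside triangle ijk?
      d1 <- sign((x[j]-x[i])*(y[p]-y[i]) - (y[j]-y[i])*(x[p]-x[i]))
      d2 <- sign((x[k]-x[j])*(y[p]-y[j]) - (y[k]-y[j])*(x[p]-x[j]))
      d3 <- sign((x[i]-x[k])*(y[p]-y[k]) - (y[i]-y[k])*(x[p]-x[k]))
      if (all(c(d1, d2, d3) > 0) || all(c(d1, d2, d3) < 0)) {
        on_hull[p] <- FALSE
        break
      }
    }
  }
  which(on_hull)
}
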