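# Brute-force oracles, deliberately independent of the package's code paths.

oracle_path_length <- function(track) {
  n <- nrow(track)
  sum(sapply(2:n, function(j) {
    sqrt((track$x_um[j] - track$x_um[j - 1])^2 +
         (track$y_um[j] - track$y_um[j - 1])^2)
  }))
}

oracle_velocity <- function(track) {
  oracle_path_length(track) / (track$t_min[nrow(track)] - track$t_min[1])
}

oracle_persistence <- function(track) {
  n <- nrow(track)
  net <- sqrt((track$x_um[n] - track$x_um[1])^2 +
              (track$y_um[n] - track$y_um[1])^2)
  net / oracle_path_length(track)
}

# Angle-of-each-segment differencing with explicit wrap-around into
# (-180, 180].
oracle_deviation_angles <- function(track) {
  seg <- atan2(diff(track$y_um), diff(track$x_um)) * 180 / pi
  d <- diff(seg)
  d <- d - 360 * floor(d / 360 + 0.5)
  d[d <= -180] <- d[d <= -180] + 360
  d
}

# A random free-diffusion track; uses the ambient RNG state.
random_track <- function(n_points = NULL) {
  n <- if (is.null(n_points)) sample(5:20, 1) else n_points
  data.frame(t_min = cumsum(runif(n, 5, 15)),
             x_um = cumsum(rnorm(n)),
             y_um = cumsum(rnorm(n)))
}

# Rotate by `angle_deg` about the origin, then translate.
rigid_transform <- function(track, angle_deg, dx, dy) {
  th <- angle_deg * pi / 180
  out <- track
  out$x_um <- cos(th) * track$x_um - sin(th) * track$y_um + dx
  out$y_um <- sin(th) * track$x_um + cos(th) * track$y_um + dy
  out
}

# A one-side phenotype record as a plain list.
make_record <- function(pouch = rep("normal", 5), cb = rep("normal", 5),
                        fusions = "") {
  rec <- c(as.list(stats::setNames(pouch, paste0("p", 1:5))),
           as.list(stats::setNames(cb, paste0("cb", 1:5))))
  rec$fusions <- fusions
  rec
}

make_phenotype_row <- function(embryo_id, genotype, side,
                               pouch = rep("normal", 5),
                               cb = rep("normal", 5), fusions = "") {
  row <- data.frame(embryo_id = embryo_id, genotype = genotype, side = side,
                    stringsAsFactors = FALSE)
  row[paste0("p", 1:5)] <- as.list(pouch)
  row[paste0("cb", 1:5)] <- as.list(cb)
  row$fusions <- fusions
  row
}
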