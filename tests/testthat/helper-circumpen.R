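# shared fixtures and independent oracles

steel_probe <- function() probe_spec(bending_stiffness = 6.96,
                                     material = "steel")
brass_probe <- function() probe_spec(bending_stiffness = 2.96,
                                     material = "brass")

# noise-free single-treatment angle series around a target deflection
angle_series_for <- function(delta_c, f = 1, ls = 45, minutes = 60) {
  delta_alpha <- 2 * asin(delta_c / ls) * 180 / pi
  t <- seq(0, minutes - 1)
  period <- minutes / f
  data.frame(time_min = t,
             angle_deg = delta_alpha / 2 * cos(2 * pi * t / period))
}

# brute-force flood fill: independent connected-component oracle
flood_fill_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  if (connectivity == 6)
    off <- off[abs(off$di) + abs(off$dj) + abs(off$dk) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (p in which(mask != 0)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      k0 <- (q - 1) %/% (d[1] * d[2])
      j0 <- ((q - 1) %% (d[1] * d[2])) %/% d[1]
      i0 <- (q - 1) %% d[1]
      ii <- i0 + off$di; jj <- j0 + off$dj; kk <- k0 + off$dk
      ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
      nb <- 1 + ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok])
      nb <- nb[mask[nb] != 0 & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

# canonical relabelling by first occurrence, to compare partitions
canonical_labels <- function(lab) {
  pos <- lab != 0
  u <- unique(lab[pos])
  lab[pos] <- match(lab[pos], u)
  lab
}

# reduced phantom for fast unit tests
small_phantom_config <- function(...) {
  phantom_config(domain_diameter_mm = 4, domain_height_mm = 4.4,
                 voxel_edge_um = 50, halo_lambda_mm = 0.8, ...)
}
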