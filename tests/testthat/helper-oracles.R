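# Independent oracles used to cross-check the implementation.

shift_arr <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (off[a] >= 0) {
      dst[[a]] <- seq_len(d[a] - off[a]) + off[a]
      src[[a]] <- seq_len(d[a] - off[a])
    } else {
      dst[[a]] <- seq_len(d[a] + off[a])
      src[[a]] <- seq_len(d[a] + off[a]) - off[a]
    }
    if (length(dst[[a]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

conn_offsets <- function(connectivity) {
  if (connectivity == 6)
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, ]
  }
}

# dilation-fixpoint flood fill: an algorithm independent of the
# queue-based growth it checks
flood_fill_oracle <- function(vol, seeds, lower, upper, bbox = NULL,
                              connectivity = 6) {
  d <- dim(vol$data)
  adm <- vol$data >= lower & vol$data <= upper
  if (!is.null(bbox)) {
    sel <- array(FALSE, d)
    sel[(bbox$lo[1] + 1):bbox$hi[1], (bbox$lo[2] + 1):bbox$hi[2],
        (bbox$lo[3] + 1):bbox$hi[3]] <- TRUE
    adm <- adm & sel
  }
  mask <- array(FALSE, d)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ] + 1L
    if (adm[s[1], s[2], s[3]]) mask[s[1], s[2], s[3]] <- TRUE
  }
  offs <- conn_offsets(connectivity)
  repeat {
    grown <- mask
    for (k in seq_len(nrow(offs)))
      grown <- grown | shift_arr(mask, offs[k, ])
    grown <- grown & adm
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

random_grow_case <- function(n_max = 16) {
  d <- sample(4:n_max, 3, replace = TRUE)
  vol <- volume(array(runif(prod(d)), d))
  k <- sample(1:3, 1)
  seeds <- cbind(sample(0:(d[1] - 1), k, TRUE),
                 sample(0:(d[2] - 1), k, TRUE),
                 sample(0:(d[3] - 1), k, TRUE))
  thr <- sort(runif(2))
  lo <- sapply(d, function(n) sample(0:(n - 2), 1))
  hi <- mapply(function(l, n) sample((l + 1):n, 1), lo, d)
  list(vol = vol, seeds = seeds, lower = thr[1], upper = thr[2],
       bbox = bounding_box(lo, hi),
       connectivity = sample(c(6L, 26L), 1))
}
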