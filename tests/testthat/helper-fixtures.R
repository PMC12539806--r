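# shared fixture builders (everything generated in code; no stored data)

# slice with axis-aligned rectangular bars: bars = list(list(label, rows, cols))
bar_slice <- function(h, w, bars) {
  sl <- matrix(0L, h, w)
  for (b in bars) sl[b$rows, b$cols] <- as.integer(b$label)
  sl
}

two_bar_volume <- function(n_slices = 2, gap_cols = 11:14,
                           pixel_size = 4.5, z_spacing = 30) {
  sl <- bar_slice(30, 30, list(list(label = 1, rows = 10:20, cols = 5:10),
                               list(label = 2, rows = 10:20, cols = 15:20)))
  label_volume(rep(list(sl), n_slices), pixel_size, z_spacing)
}

three_tube_phantom <- function(n_slices = 4) {
  make_tube_phantom(tube_phantom_spec(
    n_slices = n_slices, image_shape = c(30, 48),
    tubes = list(list(label = 1L, centers = c(15, 10), radius = 4),
                 list(label = 2L, centers = c(15, 20), radius = 4),
                 list(label = 3L, centers = c(15, 36), radius = 4)),
    pixel_size = 4.5, z_spacing = 30))
}

planted_4x10 <- function(seed) {
  make_planted_adjacency(planted_adjacency_spec(
    rep(10L, 4), within_mean = 100, within_sd = 10,
    between_mean = 1, between_sd = 1, seed = seed))
}

cuboid_mask <- function(nx = 30, ny = 24, nz = 20, margin = 2) {
  arr <- array(0L, c(ny + 2 * margin, nx + 2 * margin, nz + 2 * margin))
  arr[margin + seq_len(ny), margin + seq_len(nx), margin + seq_len(nz)] <- 1L
  arr
}
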