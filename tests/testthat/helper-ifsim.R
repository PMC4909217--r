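# shared fixtures for the test suite

vim_params <- function(...) if_params(...)                 # vimentin/desmin
ker_params <- function(...) if_params(max_bond_angle = 25, ...)  # keratin

# straight filament along +x with constant bond length (nm)
straight_filament <- function(n_beads, bond = 11) {
  cbind(x = (0:(n_beads - 1)) * bond, y = 0, z = 0)
}

# brute-force minimum image over all 27 periodic shifts (p, q inside box)
min_image_brute <- function(p, q, edge) {
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)) * edge
  d <- t(q - p + t(shifts))
  unname(d[which.min(rowSums(d^2)), ])
}
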