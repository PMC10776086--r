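# shared fixture builders; everything is generated in code

# small three-Delta PGSE scheme for fast unit tests
tiny_scheme <- function(n_dir = 6, deltas = c(17, 35, 61), sdelta = 7,
                        shells = c(2000, 4000)) {
  dirs1 <- axdiam:::repulsion_dirs(n_dir)
  block_b <- c(0, rep(shells, each = n_dir))
  block_d <- rbind(c(0, 0, 0), dirs1, dirs1)
  ax_scheme(rep(block_b, length(deltas)),
            do.call(rbind, rep(list(block_d), length(deltas))),
            big_delta = rep(deltas, each = length(block_b)),
            small_delta = sdelta, sequence = "PGSE")
}

# single-population voxel with tortuosity-consistent hindered compartment
tiny_params <- function(lambda = 3, f = 0.35, d_a = 1.5, slope = -0.003,
                        u = c(0.3, 0.5, sqrt(1 - 0.34)), sigma = 0.058,
                        weighting = "volume") {
  voxel_params(u, f, d_intra_axial = d_a,
               d_extra_radial_min = tortuosity_radial(d_a, f),
               slope = slope, d_extra_axial = d_a, lambda = lambda,
               sigma = sigma, s0 = 1, t1 = 1700, weighting = weighting)
}
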