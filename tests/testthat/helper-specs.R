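# Shared fixtures, built in code.

wlc_ref <- wlc(Lc = 85, lp = 50)          # the 249 bp test sample
kBT_ref <- 4.114

# Uniform angular prior over [lo, hi] on bins of `bw` degrees.
flat_prior <- function(lo = 20, hi = 120, bw = 5) {
  edges <- seq(lo, hi, by = bw)
  angular_distribution(edges, rep(1 / (hi - lo), length(edges) - 1L))
}

# Hand-built quadratic free-energy landscape G = k/2 (theta - theta0)^2 kBT
# (angles in radians for the curvature), on a dense grid so the internal
# linear interpolation is effectively exact.
quadratic_landscape <- function(k = 10, theta0 = 85, lo = 55, hi = 115,
                                step = 0.1) {
  theta <- seq(lo, hi, by = step)
  G <- 0.5 * k * ((theta - theta0) * pi / 180)^2
  structure(list(theta = theta, G = G - min(G),
                 valid_range = range(theta), spline = NULL,
                 bin_width = step),
            class = "free_energy_landscape")
}

# Toy sub-single-turn nucleosome construct: 30 bp wrapped over 0.3 turns,
# short linkers.  Small enough for exhaustive brute-force cross-checks and
# well below one wrap turn, so the tangent-line span grows monotonically
# with unwrapping (the full 1.67-turn construct rotates its exit tangents
# through more than 360 degrees, making the angle map oscillatory).
toy_spec <- nucleosome_spec(total_bp = 50L, wrapped_bp = 30L,
                            linker_bp = 10L, superhelix_turns = 0.3,
                            outer_turn_bp = 10L, unwrap_bin = 3L)

# Total-variation distance between two distributions on identical bins.
tv_distance <- function(a, b) {
  stopifnot(isTRUE(all.equal(a$bin_edges, b$bin_edges)))
  0.5 * sum(abs(a$density - b$density) * diff(a$bin_edges))
}
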