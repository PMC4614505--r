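# Independent oracles used across tests.

# Triclinic cell volume via the Gram (metric) determinant: built from dot
# products of the lattice vectors only, independent of any Cartesian
# construction used by the package.
gram_volume <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  sqrt(det(G))
}

# Sneddon cone force coefficient in nN/nm^2 for E in Pa, delta in nm.
cone_coefficient <- function(E, nu = 0.5, theta_deg = 35) {
  (2 / pi) * tan(theta_deg * pi / 180) * E / (1 - nu^2) * 1e-9
}

# Closed-form Sneddon/Oliver-Pharr identity: for F = C delta^2 analyzed
# with the matched ideal cone area function, beta = 1 and
# epsilon = 2(pi-2)/pi, the recovered modulus equals the true one:
#   S = 2 C dmax, h_c = (2/pi) dmax, A = pi tan^2(theta) h_c^2,
#   E_r = sqrt(pi)/2 * S / sqrt(A) = E/(1-nu^2).
# Verified symbolically before the analyzer was written; tests assert the
# numeric recovery against E itself.

# Quick lognormal cohort groups table
groups_tbl <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(genotype = r[[1]], medium = r[[2]], mean = r[[3]],
               sd = r[[4]], n = r[[5]])
  }))
}
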