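# Shared helpers: published derived cells for reproduction checks, and
# small geometry utilities for the superposition/field tests.

# Derived cells as printed alongside the 17x3 docking-score table
# (converted values at 3 d.p., composites at 3 d.p., weights in percent).
printed_table1 <- list(
  converted = cbind(
    `2PIA` = c(0.509, 0.385, 0.367, 0.347, 0.551, 0.266, 0.679, 0.552,
               0.427, 0.322, 0.511, 0.100, 0.873, 0.338, 0.423, 0.731, 1.000),
    `2ZYI` = c(0.100, 0.357, 0.364, 0.303, 0.485, 0.330, 0.727, 0.726,
               0.390, 0.296, 0.258, 0.297, 0.309, 0.322, 0.446, 0.956, 1.000),
    `3CN7` = c(0.380, 0.409, 0.547, 0.100, 0.711, 0.361, 0.872, 0.656,
               0.549, 0.518, 0.695, 0.170, 0.955, 0.594, 0.314, 1.000, 0.996)),
  composite = c(0.323, 0.380, 0.408, 0.272, 0.564, 0.313, 0.743, 0.643,
                0.442, 0.358, 0.459, 0.191, 0.679, 0.393, 0.406, 0.880, 0.999),
  E = c(1.799, 1.792, 1.497),
  H = c(0.799, 0.792, 0.497),
  W_pct = c(38.28, 37.93, 23.79))

# Printed change-rate columns of the 30-derivative prediction table.
printed_table3 <- list(
  composite = c(8.52, 15.19, 21.48, 29.26, -0.37, -15.56, 0.74, -5.56,
                -16.67, -5.56, -7.78, -2.96, -0.37, -5.19, 7.04, -12.96,
                -1.11, -1.11, 5.19, -4.07, 14.81, -3.33, 32.22, 39.63,
                44.07, 50.37, 23.33, 27.04, 31.85, 37.04),
  s2PIA = c(1.20, 3.45, 5.49, 7.29, -1.26, -13.32, -9.17, -5.46, -10.83,
            -11.35, 1.58, 3.00, 5.78, -1.18, 9.68, 3.32, -1.54, -2.89,
            0.92, -2.26, 4.11, -3.73, 13.41, 15.85, 17.86, 20.74, 9.10,
            10.43, 12.44, 14.58),
  s2ZYI = c(11.08, 13.65, 14.59, 20.45, 2.48, 2.72, 1.57, 3.48, -0.70,
            7.79, -2.46, 3.42, 4.48, 4.27, 5.50, 1.40, 16.67, 21.66,
            23.69, 15.37, 27.71, 26.24, 17.77, 21.55, 21.19, 22.87,
            22.68, 25.22, 24.82, 26.39),
  s3CN7 = c(21.66, 21.94, 23.92, 22.82, 20.06, 18.99, 23.15, 17.52,
            21.89, 15.86, 20.85, 20.62, 21.46, 18.28, 23.32, 24.96,
            17.46, 16.37, 16.03, 20.99, 17.97, 17.61, 18.25, 17.44,
            18.31, 20.62, 16.31, 16.34, 16.73, 19.15),
  ratio = c("27.13:35.95:36.92", "28.91:39.30:31.80", "31.14:36.94:31.92",
            "32.29:35.60:32.11", "18.93:47.15:33.92", "20.06:48.51:31.42",
            "23.04:45.97:30.99", "24.25:43.89:31.86"))

# Printed change-rate/BCF columns of the property table (parent row NA).
printed_table5 <- list(
  energy = c(NA, -19.91, -25.04, -30.17, -35.30, -22.01, -27.13, -32.26,
             -37.39),
  logLC50 = c(NA, 29.00, 32.36, 33.00, 38.91, 2.73, 4.82, 5.64, 16.09),
  logt12 = c(NA, -3.64, -2.98, -2.34, -1.87, -7.29, -7.03, -6.37, -6.12),
  logKOA = c(NA, 13.79, 13.87, 14.10, 16.80, 10.98, 11.29, 11.58, 13.11),
  BCF = c(18.37, 75.68, 98.17, 109.90, 130.62, 37.07, 39.81, 44.98, 52.00))

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_test_molecule <- function(id = "m", n = 5) {
  molecule(id, data.frame(
    element = "C",
    x = stats::rnorm(n), y = stats::rnorm(n), z = stats::rnorm(n),
    charge = round(stats::rnorm(n, 0, 0.3), 3),
    vdw = round(stats::runif(n, 1.2, 2), 3),
    hydrophob = round(stats::rnorm(n), 3),
    donor = stats::rbinom(n, 1, 0.4),
    acceptor = stats::rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE))
}

transform_molecule <- function(mol, R, shift) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  mol$atoms[, c("x", "y", "z")] <- xyz
  mol
}
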