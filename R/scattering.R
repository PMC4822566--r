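## X-ray atomic scattering factors.
## Four-Gaussian-plus-constant coefficients (a1..a4, b1..b4, c) from the
## standard International Tables tabulation, f(sin(theta)/lambda) =
## sum_i a_i exp(-b_i (sin(theta)/lambda)^2) + c, for the elements a
## protonation-mode scoring run encounters (protein + common ligands/ions).

.cromer_mann <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "CL", "ZN"),
  a1 = c(0.489918, 2.31000, 12.2126, 3.04850, 3.53920, 6.43450, 6.90530, 11.4604, 14.0743),
  a2 = c(0.262003, 1.02000, 3.13220, 2.28680, 2.64120, 4.17910, 5.20340, 7.19640, 7.03180),
  a3 = c(0.196767, 1.58860, 2.01250, 1.54630, 1.51700, 1.78000, 1.43790, 6.25560, 5.16520),
  a4 = c(0.049879, 0.865000, 1.16630, 0.867000, 1.02430, 1.49080, 1.58630, 1.64550, 2.41000),
  b1 = c(20.6593, 20.8439, 0.005700, 13.2771, 10.2825, 1.90670, 1.46790, 0.010400, 3.26550),
  b2 = c(7.74039, 10.2075, 9.89330, 5.70110, 4.29440, 27.1570, 22.2151, 1.16620, 0.233300),
  b3 = c(49.5519, 0.568700, 28.9975, 0.323900, 0.261500, 0.526000, 0.253600, 18.5194, 10.3163),
  b4 = c(2.20159, 51.6512, 0.582600, 32.9089, 26.1476, 68.1645, 56.1720, 47.7784, 58.7097),
  c  = c(0.001305, 0.215600, -11.5290, 0.250800, 0.277600, 1.11490, 0.866900, -9.55740, 1.30410),
  stringsAsFactors = FALSE
)

#' X-ray scattering-factor coefficient table
#'
#' @return data.frame of sum-of-Gaussians coefficients per element. f(0)
#'   equals the neutral-atom electron count to within 2%.
#' @export
scattering_factor_table <- function() .cromer_mann

#' Atomic scattering factor f(s)
#'
#' @param element Element symbol (case-insensitive).
#' @param s Scattering-vector magnitude, s = 2 sin(theta)/lambda = 1/d,
#'   in reciprocal Angstrom.
#' @param table Coefficient table (see [scattering_factor_table()]).
#' @return f(s), electrons.
#' @export
xray_form_factor <- function(element, s, table = scattering_factor_table()) {
  row <- table[table$element == toupper(element), , drop = FALSE]
  if (nrow(row) != 1L) stop("element not in scattering-factor table: ", element)
  stol2 <- (s / 2)^2                       # (sin(theta)/lambda)^2
  row$a1 * exp(-row$b1 * stol2) + row$a2 * exp(-row$b2 * stol2) +
    row$a3 * exp(-row$b3 * stol2) + row$a4 * exp(-row$b4 * stol2) + row$c
}
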