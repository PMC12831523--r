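# Independent direct-summation oracles: deliberately written as plain
# term-by-term loops over (Z, A, I) triples, sharing no code with the package.

oracle_element_table <- function() {
  # same physical data as the bundled table, stated independently
  list(H = c(1, 1.008, 19.2), C = c(6, 12.011, 81.0), N = c(7, 14.007, 82.0),
       O = c(8, 15.999, 106.0), Mg = c(12, 24.305, 156.0),
       Si = c(14, 28.086, 173.0), P = c(15, 30.974, 173.0),
       Cl = c(17, 35.450, 174.0), Ca = c(20, 40.078, 191.0))
}

oracle_zeff <- function(w, n = 3.21) {
  tab <- oracle_element_table()
  num <- 0; den <- 0
  for (s in names(w)) {
    e <- tab[[s]]
    num <- num + w[[s]] * (e[1] / e[2]) * e[1]^n
    den <- den + w[[s]] * (e[1] / e[2])
  }
  (num / den)^(1 / n)
}

oracle_lnI <- function(w) {
  tab <- oracle_element_table()
  num <- 0; den <- 0
  for (s in names(w)) {
    e <- tab[[s]]
    num <- num + w[[s]] * (e[1] / e[2]) * log(e[3])
    den <- den + w[[s]] * (e[1] / e[2])
  }
  num / den
}

oracle_red <- function(w, rho) {
  tab <- oracle_element_table()
  za <- 0
  for (s in names(w)) {
    e <- tab[[s]]
    za <- za + w[[s]] * e[1] / e[2]
  }
  rho_e_water <- 6.02214076e23 * (0.1119 / 1.008 + 0.8881 * 8 / 15.999)
  rho * 6.02214076e23 * za / rho_e_water
}

oracle_rsp <- function(red, I_ev, T_mev) {
  b2 <- 1 - (938.272 / (T_mev + 938.272))^2
  br <- function(I) log(2 * 0.511e6 * b2 / (1 - b2)) - b2 - log(I)
  red * br(I_ev) / br(75.3)
}

# random normalized composition over 2-5 elements of the oracle table
random_composition_weights <- function() {
  tab <- oracle_element_table()
  k <- sample(2:5, 1)
  syms <- sample(names(tab), k)
  w <- stats::runif(k)
  stats::setNames(w / sum(w), syms)
}

water_weights <- c(H = 0.1119, O = 0.8881)

make_composition <- function(w) composition(names(w), unname(w))
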