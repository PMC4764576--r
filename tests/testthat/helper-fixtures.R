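# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed where randomness is involved.

# model i with widely separated sensor midpoints (clear intermediate plateau)
separated_model <- function() {
  allosteric_model(
    L = 0.005,
    J1 = thermo_transition(40, 40 / 270),
    J2 = thermo_transition(100, 100 / 315),
    D = 50, E = 600,
    K1 = 500, F_na = 0.1, G = 0.01, H = 0.5)
}

# model with every coupling factor neutral: Po must be L/(1+L) everywhere
neutral_model <- function(L = 0.3) {
  allosteric_model(L = L,
                   J1 = thermo_transition(30, 0.1),
                   J2 = thermo_transition(60, 0.19),
                   K1 = 100, K2 = 1e6)
}

# random log-uniform parameter draw for oracle-equivalence sweeps
random_model <- function() {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  allosteric_model(
    L = lu(1e-4, 10),
    J1 = thermo_transition(stats::runif(1, -20, 60), stats::runif(1, -0.05, 0.2)),
    J2 = thermo_transition(stats::runif(1, -20, 120), stats::runif(1, -0.05, 0.4)),
    D = lu(0.1, 100), E = lu(0.1, 1000),
    K1 = lu(1, 1e3), F_na = lu(0.01, 10), G = lu(0.01, 10), H = lu(0.01, 10),
    K2 = lu(1, 1e8),
    caps = list(c_L = lu(0.1, 1e4), c_J1 = lu(0.1, 10), c_J2 = lu(0.1, 10),
                c_Na = lu(0.1, 10)),
    coop = stats::runif(1, 1, 2))
}

random_condition <- function() {
  list(temp = stats::runif(1, 260, 340),
       na = stats::runif(1, 0, 0.3),
       caps = stats::runif(1, 0, 2e-5))
}

# open probability by brute-force enumeration (independent summation path)
po_by_enumeration <- function(model, temp, na, caps) {
  st <- enumerate_states(model, temp, na, caps)
  sum(st$weight[st$pore == "open"]) / sum(st$weight)
}

fna_by_enumeration <- function(model, temp, na, caps) {
  st <- enumerate_states(model, temp, na, caps)
  sum(st$weight[st$na_bound]) / sum(st$weight)
}
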