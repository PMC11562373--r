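# shared oracles and small builders used across test files

# numerical diagonalization of the P x P ring-polymer Hessian for a
# harmonic mode (independent route to the normal-mode frequencies)
ring_hessian_freqs2 <- function(P, omega, omegaP) {
  H <- diag(omega^2 + 2 * omegaP^2, P)
  for (j in seq_len(P)) {
    H[j, j %% P + 1] <- H[j, j %% P + 1] - omegaP^2
    H[j %% P + 1, j] <- H[j %% P + 1, j] - omegaP^2
  }
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

# harmonic 1D model for a given frequency (cm^-1) and mass (electron masses)
make_harmonic <- function(nu_cm1 = 1000, mass = 1822.888) {
  omega <- cm1_to_omega_au(nu_cm1)
  list(model = potential_model("harmonic1d", list(k = mass * omega^2)),
       omega = omega, mass = mass)
}

oh_model <- function() {
  read_potential_config(system.file("extdata", "morse_oh.cfg",
                                    package = "ringdeconv"))
}

water_model <- function() {
  read_potential_config(system.file("extdata", "water_harmonic.cfg",
                                    package = "ringdeconv"))
}

# small weight tables are expensive enough to share across tests
cached_table <- local({
  cache <- list()
  function(key, fn) {
    if (is.null(cache[[key]])) cache[[key]] <<- fn()
    cache[[key]]
  }
})
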