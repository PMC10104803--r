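# Fixture builders shared across test files.

# Write a tidy dose-response CSV and return its path.
write_dr_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# A two-ligand, three-dose dose-response table (raw signal units).
example_dr_table <- function(dose_unit = "M") {
  data.frame(
    ligand = rep(c("epi", "c-epi"), each = 3),
    receptor = "b2ar", pathway = "arrestin",
    dose = rep(c(1e-9, 1e-8, 1e-7), 2),
    dose_unit = dose_unit,
    signal = c(210, 480, 900, 230, 300, 620),
    replicate = "1"
  )
}

# A kinetics CSV with `n` association traces (zero-noise mass-action).
write_kinetics_csv <- function(concs = c(0, 1e-8, 3e-8),
                               rl = radioligand_kinetics(3e7, 3e-3, 0.25e-9),
                               k3 = 1e6, k4 = 5e-3, bmax = 100,
                               t = seq(60, 3600, length.out = 8),
                               path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(seq_along(concs), function(i) {
    data.frame(trace_id = paste0("tr", i), trace_type = "association",
               competitor = "cmp", competitor_conc = concs[i],
               conc_unit = "M", time = t, time_unit = "s",
               signal = mm_bound(t, rl, k3, k4, concs[i], bmax))
  }))
  write.csv(df, path, row.names = FALSE)
  path
}

# Apply a rigid rotation + translation to a structure model.
rigid_transform <- function(model, angle = 0.7, axis = c(0, 0, 1),
                            shift = c(5, -3, 1)) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  R <- c_ * diag(3) + s_ * matrix(c(0, a[3], -a[2],
                                    -a[3], 0, a[1],
                                    a[2], -a[1], 0), 3) +
    (1 - c_) * outer(a, a)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% R
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

# Operational-model response for constructing ground-truth curves.
op_response <- function(dose, em, n, log_tau, log_ka) {
  tau <- 10^log_tau; ka <- 10^log_ka
  em * (tau * dose)^n / ((dose + ka)^n + (tau * dose)^n)
}
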