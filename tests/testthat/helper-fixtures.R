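# shared builders for small deterministic fixtures

# a 4x4 matrix with per-cycle death probability p from every alive state
# and no other movement
death_only_matrix <- function(p) {
  m <- diag(4) * (1 - p)
  m[, 4] <- p
  m[4, ] <- c(0, 0, 0, 1)
  dimnames(m) <- list(melcea::health_states, melcea::health_states)
  m
}

identity_schedule <- function(cycles, arm = "toy") {
  melcea::transition_schedule(arm, replicate(cycles, diag(4), simplify = FALSE))
}

# immortal background population
zero_life_table <- function() melcea::life_table(54:120, 0, 0)

# constant-hazard targets on a monthly grid
constant_hazard_targets <- function(h_os, h_pfs, months = 78) {
  melcea::survival_targets(data.frame(
    month = 0:months,
    os = exp(-h_os * (0:months)),
    pfs = exp(-h_pfs * (0:months))
  ))
}

# configuration with all PSA spread removed (point-mass draws)
degenerate_config <- function(config = melcea::default_config()) {
  config$ci <- NULL
  config$hr_ci <- NULL
  config
}
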