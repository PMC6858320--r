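# deterministic straight-line trajectory used throughout the suite
make_linear_traj <- function(...) linear_trajectory(...)

# reference species with the filament-level quality factor q applied the way
# the scenario machinery applies it
scaled_species <- function(name, q) {
  sp <- reference_species(name)
  sp$v0_max <- sp$v0_max * q
  sp$F_stall <- sp$F_stall * q
  sp$k_det_c <- sp$k_det_c * q
  sp
}
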